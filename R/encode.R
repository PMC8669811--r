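#' Amino acid composition (AAC) features
#'
#' Encodes every peptide as the 20 per-residue frequencies
#' `AAC(j) = N(j) / L`, where `N(j)` counts occurrences of amino acid `j`
#' and `L` is the peptide length. Columns are in fixed alphabetical order
#' A..Y and each row sums to 1.
#'
#' @param peptides A validated peptide tibble (see [read_peptides()]).
#' @return A feature tibble: `sample_id`, optional `label`, then 20 columns
#'   named `AAC:A` .. `AAC:Y`.
#' @examples
#' p <- tibble::tibble(id = "P1", sequence = "AAAAC")
#' encode_aac(validate_peptides(p))
#' @export
encode_aac <- function(peptides) {
  check_peptide_input(peptides, min_len = 1)
  counts <- t(vapply(
    strsplit(peptides$sequence, "", fixed = TRUE),
    function(s) tabulate(match(s, AA_ALPHABET), nbins = 20L),
    integer(20)
  ))
  values <- counts / nchar(peptides$sequence)
  colnames(values) <- paste0("AAC:", AA_ALPHABET)
  feature_tibble(peptides, values)
}

#' g-gap dipeptide composition (GDC) features
#'
#' Counts ordered residue pairs at positions `(i, i + g)` — adjacent pairs
#' for `g = 1`, one skipped residue for `g = 2`, and so on — and normalises
#' by the number of pairs, which is `L - g` for a peptide of length `L`.
#' The 400 columns follow the fixed dipeptide order AA, AC, ..., YY; each
#' row sums to 1. Every peptide must satisfy `L > g` so at least one pair
#' exists; with the minimum supported length of 5 this allows g up to 4.
#'
#' @inheritParams encode_aac
#' @param g Gap parameter, an integer in 1..4.
#' @return A feature tibble with 400 columns named `GDC<g>:AA` .. `GDC<g>:YY`.
#' @examples
#' p <- validate_peptides(tibble::tibble(id = "P1", sequence = "ACDEF"))
#' m <- encode_gdc(p, g = 4)  # single pair (A, F)
#' m[["GDC4:AF"]]
#' @export
encode_gdc <- function(peptides, g = 1) {
  g <- as.integer(g)
  if (length(g) != 1 || is.na(g) || g < 1 || g > 4) {
    abort("g must be a single integer in 1..4")
  }
  check_peptide_input(peptides, min_len = g + 1L,
                      why = paste0("g-gap encoding with g = ", g,
                                   " requires length > ", g))
  prefix <- paste0("GDC", g, ":")
  values <- t(vapply(peptides$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(chars)
    pairs <- paste0(chars[seq_len(L - g)], chars[seq_len(L - g) + g])
    tabulate(match(pairs, DIPEPTIDES), nbins = 400L) / (L - g)
  }, numeric(400), USE.NAMES = FALSE))
  colnames(values) <- paste0(prefix, DIPEPTIDES)
  feature_tibble(peptides, values)
}

#' Dipeptide deviation from expected mean (DDE) features
#'
#' For each of the 400 ordered dipeptides `j` with first residue `j1` and
#' second residue `j2`, computes the standardised deviation of the observed
#' adjacent-dipeptide frequency from a codon-usage expectation:
#' \deqn{DC(j) = n_j / (L - 1)}
#' \deqn{TM(j) = (C_{j1}/CN) \times (C_{j2}/CN)}
#' \deqn{TV(j) = TM(j)\,(1 - TM(j)) / (L - 1)}
#' \deqn{DDE(j) = (DC(j) - TM(j)) / \sqrt{TV(j)}}
#' where `n_j` counts adjacent occurrences of dipeptide `j`, `L` is the
#' peptide length, `C_j1`/`C_j2` are the numbers of sense codons encoding
#' the two residues and `CN` the total number of sense codons (61 for the
#' standard genetic code). TM lies strictly inside (0, 1), so TV is never
#' zero for valid input.
#'
#' @inheritParams encode_aac
#' @param codons A codon table from [codon_table()].
#' @return A feature tibble with 400 columns named `DDE:AA` .. `DDE:YY`.
#' @export
encode_dde <- function(peptides, codons = codon_table()) {
  check_peptide_input(peptides, min_len = 2L,
                      why = "DDE requires at least one adjacent dipeptide (length >= 2)")
  frac <- codons$counts / codons$cn
  tm <- as.vector(t(outer(frac, frac)))  # row-major, matches DIPEPTIDES
  values <- t(vapply(peptides$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(chars)
    pairs <- paste0(chars[-L], chars[-1])
    dc <- tabulate(match(pairs, DIPEPTIDES), nbins = 400L) / (L - 1)
    tv <- tm * (1 - tm) / (L - 1)
    (dc - tm) / sqrt(tv)
  }, numeric(400), USE.NAMES = FALSE))
  colnames(values) <- paste0("DDE:", DIPEPTIDES)
  feature_tibble(peptides, values)
}

#' Combine feature blocks column-wise
#'
#' Concatenates feature tibbles produced by the encoders (in the given
#' order) into one combined feature tibble, e.g. AAC + DDE + GDC-gap1 gives
#' 20 + 400 + 400 = 820 feature columns. All blocks must describe the same
#' samples in the same order.
#'
#' @param ... Feature tibbles, or a single list of them.
#' @return One combined feature tibble.
#' @export
combine_features <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) && !is.data.frame(blocks[[1]])) {
    blocks <- blocks[[1]]
  }
  if (length(blocks) == 0) abort("no feature blocks to combine")
  ids <- blocks[[1]]$sample_id
  for (b in blocks[-1]) {
    if (!identical(b$sample_id, ids)) {
      abort("feature blocks describe different samples or sample orders")
    }
  }
  labels <- purrr::detect(blocks, ~ "label" %in% names(.x))
  out <- dplyr::bind_cols(
    tibble(sample_id = ids),
    if (!is.null(labels)) tibble(label = labels$label),
    purrr::map(blocks, ~ .x[, feature_names(.x), drop = FALSE]),
    .name_repair = "minimal"
  )
  if (anyDuplicated(names(out))) {
    abort("duplicate feature names across blocks")
  }
  out
}

#' Encode peptides with a set of descriptors
#'
#' Convenience wrapper running one or more encoders and combining the
#' blocks. Recognised encoder names: `"aac"`, `"dde"`, `"gdc1"` .. `"gdc4"`.
#'
#' @inheritParams encode_aac
#' @param encoders Character vector of encoder names, applied in order.
#' @param codons Codon table used by the DDE block.
#' @return A combined feature tibble.
#' @examples
#' p <- simulate_peptides(n_pos = 3, n_neg = 3, seed = 1)
#' dim(encode_peptides(p, c("aac", "dde", "gdc1")))  # 6 x 822
#' @export
encode_peptides <- function(peptides, encoders = c("aac", "dde", "gdc1"),
                            codons = codon_table()) {
  known <- c("aac", "dde", paste0("gdc", 1:4))
  encoders <- tolower(encoders)
  bad <- setdiff(encoders, known)
  if (length(bad) > 0) {
    abort(paste0("unknown encoder(s): ", paste(bad, collapse = ", "),
                 " (available: ", paste(known, collapse = ", "), ")"))
  }
  blocks <- purrr::map(encoders, function(e) {
    switch(substr(e, 1, 3),
      aac = encode_aac(peptides),
      dde = encode_dde(peptides, codons),
      gdc = encode_gdc(peptides, g = as.integer(substr(e, 4, 4)))
    )
  })
  combine_features(blocks)
}

#' Feature column names of a feature tibble
#'
#' @param features A feature tibble.
#' @return Character vector of feature column names (everything except
#'   `sample_id` and `label`).
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("sample_id", "label"))
}

#' Extract the numeric feature matrix
#'
#' @param features A feature tibble.
#' @return A numeric matrix (samples x features) with `sample_id` rownames.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[, feature_names(features), drop = FALSE])
  rownames(m) <- features$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write / read a feature tibble as TSV
#'
#' The layout is: `sample_id` first, then one column per feature, then an
#' optional trailing `label` column. Round-trips losslessly at full double
#' precision.
#'
#' @param features A feature tibble.
#' @param path File path.
#' @return `path` invisibly for the writer; a feature tibble for the reader.
#' @export
write_features <- function(features, path) {
  cols <- c("sample_id", feature_names(features),
            intersect("label", names(features)))
  readr::write_tsv(features[, cols], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  if ("label" %in% names(out)) {
    out$label <- check_binary_label(out$label)
    out <- out[, c("sample_id", "label",
                   setdiff(names(out), c("sample_id", "label")))]
  }
  out
}

feature_tibble <- function(peptides, values) {
  out <- dplyr::bind_cols(
    tibble(sample_id = peptides$id),
    if ("label" %in% names(peptides)) tibble(label = peptides$label),
    as_tibble(values, .name_repair = "minimal")
  )
  out
}

check_peptide_input <- function(peptides, min_len, why = NULL) {
  stopifnot(is.data.frame(peptides))
  if (nrow(peptides) == 0) abort("empty peptide set")
  if (!all(c("id", "sequence") %in% names(peptides))) {
    abort("peptides must have 'id' and 'sequence' columns")
  }
  lens <- nchar(peptides$sequence)
  short <- lens < min_len
  if (any(short)) {
    abort(paste0(
      "record '", peptides$id[short][1], "' (length ", lens[short][1],
      ") is too short: ", why %||% paste0("minimum length is ", min_len)
    ))
  }
  invisible(peptides)
}
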