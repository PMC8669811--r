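#' Read peptide sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file of peptide
#' sequences, validates every record against the 20-letter standard
#' amino-acid alphabet and a minimum length, and returns a peptide tibble.
#'
#' Records failing validation are handled according to `policy`:
#' \describe{
#'   \item{`"reject"`}{any invalid record is an error naming the record id;}
#'   \item{`"skip"`}{invalid records are dropped with a warning giving the
#'     count of skipped records;}
#'   \item{`"sanitize"`}{sequences are uppercased first, then records that
#'     still contain letters outside the standard alphabet (or are too
#'     short) are dropped with a warning.}
#' }
#' Lowercase letters are always uppercased before the alphabet check.
#'
#' @param path Path to a FASTA file.
#' @param label Optional binary class label (1 = positive / AIP, 0 =
#'   negative) attached to every record in the file. Use `NULL` for
#'   unlabelled input.
#' @param min_length Minimum accepted peptide length (residues). Defaults to
#'   5, the shortest peptide the descriptors are designed for (g-gap
#'   encoding with g up to 4 needs at least 5 residues).
#' @param policy One of `"reject"`, `"skip"`, `"sanitize"`.
#'
#' @return A tibble with columns `id` (character), `sequence` (character,
#'   uppercase), `length` (integer) and, when `label` is given, `label`
#'   (integer, 0/1).
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "ACDEF", ">P2", "GGGGG"), fa)
#' read_peptides(fa, label = 1)
#' @export
read_peptides <- function(path, label = NULL, min_length = 5,
                          policy = c("reject", "skip", "sanitize")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("Cannot read FASTA file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(seqs) == 0) {
    abort(paste0("FASTA file '", path, "' contains no records"))
  }
  peptides <- tibble(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
  if (!is.null(label)) {
    peptides$label <- check_binary_label(label)
  }
  validate_peptides(peptides, min_length = min_length, policy = policy)
}

#' Validate a peptide tibble
#'
#' Checks sequences against the 20-letter amino-acid alphabet and a minimum
#' length, uppercasing first. Validation is idempotent: a valid set passes
#' through unchanged (apart from the recomputed `length` column).
#'
#' @param peptides A tibble with at least `id` and `sequence` columns.
#' @inheritParams read_peptides
#' @return The validated peptide tibble with `length` filled in.
#' @export
validate_peptides <- function(peptides, min_length = 5,
                              policy = c("reject", "skip", "sanitize")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(peptides))
  if (!all(c("id", "sequence") %in% names(peptides))) {
    abort("peptides must have 'id' and 'sequence' columns")
  }
  if (anyDuplicated(peptides$id)) {
    dup <- peptides$id[duplicated(peptides$id)][1]
    abort(paste0("duplicate record id: '", dup, "'"))
  }
  peptides <- as_tibble(peptides)
  peptides$sequence <- toupper(peptides$sequence)

  bad_alpha <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                      peptides$sequence)
  too_short <- nchar(peptides$sequence) < min_length
  invalid <- bad_alpha | too_short

  if (any(invalid)) {
    if (policy == "reject") {
      first <- peptides$id[invalid][1]
      why <- if (bad_alpha[match(first, peptides$id)]) {
        "contains letters outside the 20 standard amino acids"
      } else {
        paste0("is shorter than min_length = ", min_length)
      }
      abort(paste0("invalid record '", first, "': sequence ", why,
                   " (policy = 'reject')"))
    }
    warn(paste0(sum(invalid), " record(s) dropped during validation (policy = '",
                policy, "'): ",
                paste(utils::head(peptides$id[invalid], 5), collapse = ", "),
                if (sum(invalid) > 5) ", ..." else ""))
    peptides <- peptides[!invalid, , drop = FALSE]
  }
  peptides$length <- nchar(peptides$sequence)
  front <- intersect(c("id", "sequence", "length", "label"), names(peptides))
  peptides[, c(front, setdiff(names(peptides), front))]
}

#' Write peptides to a FASTA file
#'
#' Sequences are written one per line (no wrapping). Round-trips with
#' [read_peptides()]: ids and sequences are reproduced exactly.
#'
#' @param peptides A validated peptide tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  stopifnot(is.data.frame(peptides))
  if (nrow(peptides) == 0) {
    abort("cannot write an empty peptide set")
  }
  set <- Biostrings::AAStringSet(setNames(peptides$sequence, peptides$id))
  Biostrings::writeXStringSet(set, path,
                              width = max(nchar(peptides$sequence)))
  invisible(path)
}

#' Attach class labels from a two-column TSV
#'
#' @param peptides A peptide tibble.
#' @param path Path to a headerless or headered TSV with columns id, label.
#' @return The peptide tibble with a `label` column.
#' @export
label_peptides <- function(peptides, path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (identical(tolower(unlist(tab[1, ])), c("id", "label"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (ncol(tab) != 2) abort("label file must have exactly two columns: id, label")
  labels <- setNames(check_binary_label(as.numeric(tab[[2]])), tab[[1]])
  missing <- setdiff(peptides$id, names(labels))
  if (length(missing) > 0) {
    abort(paste0("no label for record(s): ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  peptides$label <- unname(labels[peptides$id])
  peptides
}

check_binary_label <- function(label) {
  label <- as.integer(label)
  if (any(is.na(label)) || !all(label %in% c(0L, 1L))) {
    abort("labels must be binary (0 = negative, 1 = positive)")
  }
  label
}
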