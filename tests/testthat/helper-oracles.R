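# Independent brute-force oracles used to verify the package's formula
# implementations. These deliberately share no code with R/.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DIPEP400 <- as.vector(t(outer(AA20, AA20, paste0)))

# Count ordered residue pairs (i, i + g) by explicit enumeration.
oracle_gap_pairs <- function(seq, g) {
  chars <- strsplit(seq, "")[[1]]
  counts <- setNames(numeric(400), DIPEP400)
  for (i in seq_len(length(chars) - g)) {
    pair <- paste0(chars[i], chars[i + g])
    counts[pair] <- counts[pair] + 1
  }
  counts / sum(counts)
}

# DDE by direct per-dipeptide evaluation of DC, TM, TV.
oracle_dde <- function(seq, codon_counts = c(
                         A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2,
                         I = 3, K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2,
                         R = 6, S = 6, T = 4, V = 4, W = 1, Y = 2)) {
  cn <- sum(codon_counts)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- setNames(numeric(400), DIPEP400)
  for (d in DIPEP400) {
    n_j <- 0
    for (i in seq_len(L - 1)) {
      if (chars[i] == substr(d, 1, 1) && chars[i + 1] == substr(d, 2, 2)) {
        n_j <- n_j + 1
      }
    }
    dc <- n_j / (L - 1)
    tm <- (codon_counts[[substr(d, 1, 1)]] / cn) *
      (codon_counts[[substr(d, 2, 2)]] / cn)
    tv <- tm * (1 - tm) / (L - 1)
    out[d] <- (dc - tm) / sqrt(tv)
  }
  out
}

# AUC as the Mann-Whitney probability, all positive/negative pairs, ties 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# One-way ANOVA F statistic through R's linear-model machinery.
oracle_f_statistic <- function(x, group) {
  stats::anova(stats::lm(x ~ factor(group)))[["F value"]][1]
}

random_peptides <- function(n, len_range = c(5, 12), seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    tibble::tibble(
      id = paste0("R", seq_len(n)),
      sequence = vapply(lens, function(L) {
        paste(sample(AA20, L, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

peptide_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = paste0("P", seq_along(seqs)), sequence = seqs)
}

# 40-sample linearly separable toy set: one informative feature plus noise.
separable_features <- function(n = 40, noise_features = 2, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), each = n / 2)
    informative <- label + stats::runif(n, -0.2, 0.2)
    noise <- matrix(stats::rnorm(n * noise_features), nrow = n,
                    ncol = noise_features,
                    dimnames = list(NULL, if (noise_features > 0) {
                      paste0("noise", seq_len(noise_features))
                    }))
    dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("S", seq_len(n)), label = label,
                     sep = informative),
      tibble::as_tibble(noise)
    )
  })
}

# Full pipeline (encode -> ANOVA -> IFS -> RF under 5-fold CV) on synthetic
# peptides; returns the pooled cross-validated AUC of the selected subset.
pipeline_auc <- function(effect, seed, dipeptide_effect = 0, n = 200,
                         step = 200) {
  p <- simulate_peptides(n_pos = n, n_neg = n, effect = effect,
                         dipeptide_effect = dipeptide_effect, seed = seed)
  f <- encode_peptides(p, c("aac", "dde", "gdc1"))
  fit <- aip_fit(f, step = step, config = rf_config(seed = seed),
                 cv_seed = seed)
  fit$cv$pooled$auc
}
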