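#' Sense-codon counts of the standard genetic code
#'
#' Number of sense codons encoding each of the 20 standard amino acids,
#' used by the DDE descriptor to form the theoretical mean of a dipeptide's
#' frequency. The three stop codons are excluded, so the counts sum to
#' `CN = 61`.
#'
#' @param counts Optional named integer vector overriding the default
#'   per-amino-acid codon counts; must cover all 20 standard amino acids
#'   with positive integers.
#' @return A list with components `counts` (named integer vector, ordered
#'   A..Y) and `cn` (total number of sense codons).
#' @examples
#' codon_table()$cn  # 61
#' @export
codon_table <- function(counts = NULL) {
  default <- c(
    A = 4L, C = 2L, D = 2L, E = 2L, F = 2L, G = 4L, H = 2L, I = 3L,
    K = 2L, L = 6L, M = 1L, N = 2L, P = 4L, Q = 2L, R = 6L, S = 6L,
    T = 4L, V = 4L, W = 1L, Y = 2L
  )
  if (is.null(counts)) {
    counts <- default
  } else {
    if (!all(AA_ALPHABET %in% names(counts))) {
      abort("codon counts must name all 20 standard amino acids")
    }
    counts <- as.integer(counts[AA_ALPHABET])
    names(counts) <- AA_ALPHABET
    if (any(is.na(counts)) || any(counts < 1L)) {
      abort("codon counts must be positive integers")
    }
  }
  list(counts = counts, cn = sum(counts))
}
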