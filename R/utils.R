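#' @useDynLib proseqid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' The canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in the fixed row order used by every
#' readout matrix and profile in this package (alphabetical:
#' \code{ACDEFGHIKLMNPQRSTVWY}).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# index of each letter in the fixed alphabet; NA for anything non-canonical
.aaIndex <- function(chars) {
  match(chars, aminoAcids())
}

# round half away from zero (base round() is round-half-even)
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# deterministic 32-bit seed derived from (seed, key string); keeps parallel
# per-protein substreams independent of iteration order
deriveSeed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(key)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer((seed + h) %% 2147483647)
}

# sequence string -> 0-based integer codes for the C++ kernel
encodeSequence <- function(sequence) {
  idx <- .aaIndex(strsplit(sequence, "", fixed = TRUE)[[1]])
  if (anyNA(idx)) {
    stop("sequence contains residues outside the canonical 20-letter alphabet")
  }
  as.integer(idx - 1L)
}

.checkBackground <- function(background) {
  stopifnot(is.numeric(background), length(background) == 20L)
  if (any(background < 0)) {
    stop("background frequencies must be non-negative")
  }
  if (abs(sum(background) - 1) > 1e-12) {
    stop("background frequencies must sum to 1")
  }
  if (is.null(names(background))) {
    names(background) <- aminoAcids()
  }
  background[aminoAcids()]
}
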