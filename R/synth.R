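#' Human-like amino-acid background preset
#'
#' A fixed 20-vector of amino-acid frequencies approximating the composition
#' of a curated human proteome, with the characteristic abundance ordering:
#' L, S, E, A and G are the five most abundant residues and W, M, C, H and Y
#' the five least abundant.  Reduced-detection-set experiments on synthetic
#' databases drawn from this preset therefore behave qualitatively like the
#' human case without requiring any external download.
#'
#' @return Named numeric 20-vector (order \code{\link{aminoAcids}()})
#'   summing to 1.
#' @export
#' @examples
#' abundanceRanking(humanLikeBackground())[1:5]    # L S E A G
#' rev(abundanceRanking(humanLikeBackground()))[1:5]
humanLikeBackground <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f / sum(f)
}

#' Generate a synthetic protein database
#'
#' Sequences are i.i.d. draws from the background frequency vector, with
#' lengths drawn from a fixed value, a discrete uniform range, or a
#' log-normal distribution (median 411 residues by default, matching a
#' typical curated proteome).  Accessions are \code{SYN000001, ...}.
#' Identical \code{(spec, seed)} always produce byte-identical databases.
#'
#' @param n Number of sequences (>= 1).
#' @param lengths Length specification: a single value L (fixed length), a
#'   2-vector \code{c(a, b)} (discrete uniform in [a, b]), or \code{NULL}
#'   for the log-normal default (\code{lognormalMedian},
#'   \code{lognormalSigma}).
#' @param background 20-vector of residue frequencies; default
#'   \code{\link{humanLikeBackground}()}.
#' @param seed Integer RNG seed.
#' @param enforceDistinct Regenerate duplicated sequences until all are
#'   unique (errors if infeasible for the requested length range).
#' @param lognormalMedian,lognormalSigma Parameters of the default length
#'   distribution (median in residues and log-sd).
#' @param minLength Lower truncation of generated lengths (residues).
#' @return A \linkS4class{SequenceDatabase} (uncurated; background slot
#'   computed from the generated records).
#' @export
#' @examples
#' db <- generateDatabase(n = 10, lengths = 50, seed = 1)
#' dbSize(db)
generateDatabase <- function(n, lengths = NULL,
                             background = humanLikeBackground(), seed = 1L,
                             enforceDistinct = TRUE, lognormalMedian = 411,
                             lognormalSigma = 0.75, minLength = 30L) {
  stopifnot(n >= 1L)
  background <- .checkBackground(background)
  old <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  drawLengths <- function(m) {
    if (is.null(lengths)) {
      pmax(minLength,
           as.integer(round(stats::rlnorm(m, log(lognormalMedian),
                                          lognormalSigma))))
    } else if (length(lengths) == 1L) {
      rep(as.integer(lengths), m)
    } else {
      as.integer(sample(seq(lengths[1], lengths[2]), m, replace = TRUE))
    }
  }
  minPossible <- if (is.null(lengths)) minLength else min(lengths)
  if (enforceDistinct && log(n) > minPossible * log(20)) {
    stop("cannot generate ", n, " distinct sequences of length ",
         minPossible)
  }
  drawOne <- function(L) {
    paste(sample(aminoAcids(), L, replace = TRUE, prob = background),
          collapse = "")
  }
  seqs <- vapply(drawLengths(n), drawOne, character(1))
  if (enforceDistinct) {
    for (iter in seq_len(1000L)) {
      dup <- which(duplicated(seqs))
      if (length(dup) == 0L) break
      seqs[dup] <- vapply(drawLengths(length(dup)), drawOne, character(1))
    }
    if (anyDuplicated(seqs)) {
      stop("failed to generate distinct sequences")
    }
  }
  names(seqs) <- sprintf("SYN%06d", seq_len(n))
  .newSequenceDatabase(Biostrings::AAStringSet(seqs))
}

#' Bundled worked-example readouts
#'
#' Small fixed readouts of the peptide \code{QFEGSAL} with known truth, for
#' demonstrations and tests: (a) an error-free readout from a device that
#' identifies all 20 amino acids at pMax = 1/2; (b) a readout from a device
#' detecting only L, S and E at pMax = 9/10, carrying one deletion (the F
#' column is missing) and one insertion (a spurious column suggesting L
#' after the E), so it is again 20 x 7.  A tiny synthetic database
#' containing the source peptide is included.
#'
#' @return List with elements \code{fullSignal} (\linkS4class{Readout}),
#'   \code{reducedWithErrors} (\linkS4class{Readout}), and \code{database}
#'   (a \linkS4class{SequenceDatabase} whose record \code{QFX1} is the
#'   source peptide).
#' @export
#' @examples
#' fx <- fixtureReadouts()
#' readoutMatrix(fx$fullSignal)["Q", 1]   # 0.5
fixtureReadouts <- function() {
  peptide <- "QFEGSAL"
  devA <- DeviceConfig(pMax = 0.5)
  full <- simulateReadout(peptide, devA, sourceAccession = "QFX1")

  devB <- DeviceConfig(pMax = 0.9, detectionSet = "LSE")
  clean <- .posteriorColumns(devB)[, .aaIndex(strsplit(peptide, "")[[1]])]
  # deletion of the F column (position 2), then an insertion after the E
  # (spurious column suggesting L): back to 7 columns
  afterDel <- clean[, -2, drop = FALSE]
  insCol <- posteriorColumn("L", devB)
  withIns <- cbind(afterDel[, 1:2], insCol, afterDel[, 3:6])
  reduced <- Readout(unname(withIns), sourceAccession = "QFX1",
                     nInsertions = 1L, nDeletions = 1L)

  others <- generateDatabase(n = 4, lengths = c(7, 12), seed = 42,
                             background = rep(1 / 20, 20))
  seqs <- c(stats::setNames(peptide, "QFX1"),
            stats::setNames(as.character(sequences(others)),
                            paste0("BG", 1:4)))
  list(fullSignal = full, reducedWithErrors = reduced,
       database = .newSequenceDatabase(Biostrings::AAStringSet(seqs)))
}
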