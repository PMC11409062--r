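#' Build a profile HMM from a readout
#'
#' One match state per readout column, with the posterior probabilities
#' copied verbatim as match emissions.  Insert states emit the background;
#' the Plan7 transition parameters are applied uniformly at every position.
#' Entry is Begin -> M1 with probability 1 and exit is from the final match
#' or delete state with probability 1 (the readout is one complete sequenced
#' molecule: glocal over the query), while the target is scored locally
#' (flanking residues absorbed at zero log-odds cost).
#'
#' @param readout A \linkS4class{Readout} (or a bare 20 x L column-stochastic
#'   matrix).
#' @param params A \linkS4class{ProfileParams}; the default uses
#'   \code{ProfileParams()} with a uniform background.
#' @param alignmentMode \code{"glocal-query/local-target"} (default) or
#'   \code{"local-query/local-target"}.
#' @return A \linkS4class{ProfileHMM}.
#' @export
#' @examples
#' r <- simulateReadout("QFEGSAL", DeviceConfig(pMax = 0.5))
#' hmm <- buildProfile(r)
#' profileLength(hmm)   # 7
buildProfile <- function(readout, params = ProfileParams(),
                         alignmentMode = "glocal-query/local-target") {
  m <- if (is(readout, "Readout")) readout@matrix else readout
  if (!is.matrix(m) || ncol(m) < 1L) {
    stop("readout must contain at least one position")
  }
  new("ProfileHMM", matchEmissions = m, params = params,
      alignmentMode = alignmentMode)
}

.transVector <- function(params) {
  c(params@tMM, params@tMI, params@tMD, params@tIM, params@tII,
    params@tDM, params@tDD)
}

# shared entry point to the C++ kernel; targets = list of 0-based codes
.scoreEncoded <- function(profile, encoded, background,
                          forward = TRUE, viterbi = FALSE) {
  scoreTargetsCpp(profile@matchEmissions, .checkBackground(background),
                  .transVector(profile@params), encoded,
                  forward, viterbi,
                  identical(profile@alignmentMode, "local-query/local-target"))
}

#' Forward log-odds score of a target sequence
#'
#' Returns \code{log2 P(target | profile) / P(target | null)} in bits, where
#' the null model emits residues i.i.d. from the background.  Computed by
#' the Forward recursion over match/insert/delete states, summing over all
#' alignments, with flanking target residues absorbed at zero log-odds cost.
#' The dynamic programming runs in rescaled odds space and is numerically
#' stable for full-length proteins; zero-probability emissions (pMax = 1)
#' give \code{-Inf} contributions without overflow.
#'
#' @param profile A \linkS4class{ProfileHMM}.
#' @param target Amino-acid string to score.
#' @param background Numeric 20-vector for the null model; defaults to the
#'   profile's background.
#' @return Log-odds score in bits (possibly \code{-Inf}).
#' @export
#' @examples
#' hmm <- buildProfile(simulateReadout("ACDE", DeviceConfig(pMax = 0.9)))
#' forwardScore(hmm, "MMACDEMM")
forwardScore <- function(profile, target,
                         background = profile@params@background) {
  .scoreEncoded(profile, list(encodeSequence(target)), background)[1, 1]
}

#' Viterbi log-odds score of a target sequence
#'
#' As \code{\link{forwardScore}} but maximising over alignments instead of
#' summing; always \code{<=} the Forward score.
#'
#' @inheritParams forwardScore
#' @return Log-odds score in bits (possibly \code{-Inf}).
#' @export
viterbiScore <- function(profile, target,
                         background = profile@params@background) {
  .scoreEncoded(profile, list(encodeSequence(target)), background,
                forward = FALSE, viterbi = TRUE)[1, 2]
}

#' Brute-force path-enumeration score (test oracle)
#'
#' Enumerates every legal state path of the profile against the target and
#' accumulates exact path odds; ground truth for the dynamic-programming
#' implementations on tiny instances.  Exponential: restricted to profiles
#' of at most 5 match states and targets of at most 6 residues.
#'
#' @inheritParams forwardScore
#' @param mode \code{"sum"} (Forward analogue) or \code{"max"} (Viterbi).
#' @return Log-odds score in bits (possibly \code{-Inf}).
#' @export
bruteForceScore <- function(profile, target,
                            background = profile@params@background,
                            mode = c("sum", "max")) {
  mode <- match.arg(mode)
  Lq <- ncol(profile@matchEmissions)
  t <- encodeSequence(target) + 1L
  Lt <- length(t)
  if (Lq > 5L || Lt > 6L) {
    stop("instance too large for path enumeration (Lq <= 5, Lt <= 6)")
  }
  bg <- .checkBackground(background)
  # emission odds; names stripped so path products stay bare scalars
  eo <- unname(profile@matchEmissions) / unname(bg)
  p <- profile@params
  local <- identical(profile@alignmentMode, "local-query/local-target")
  w <- if (local) 2 / (Lq * (Lq + 1)) else 1
  acc <- new.env()
  acc$sum <- 0
  acc$max <- 0
  acc$n <- 0L
  record <- function(odds) {
    acc$sum <- acc$sum + odds
    if (odds > acc$max) acc$max <- odds
    acc$n <- acc$n + 1L
  }

  # visit(state, k, j, odds): just arrived in `state` at match position k
  # having consumed target prefix of length j (emission already applied)
  visit <- function(state, k, j, odds) {
    if (odds == 0) return(invisible())
    if (state == "M") {
      if (local) record(odds)                      # exit allowed anywhere
      if (k == Lq) {
        if (!local) record(odds)                   # M_L -> E, prob 1
        return(invisible())
      }
      if (j < Lt) {
        visit("M", k + 1L, j + 1L, odds * p@tMM * eo[t[j + 1L], k + 1L])
        visit("I", k, j + 1L, odds * p@tMI)        # insert emits at odds 1
      }
      visit("D", k + 1L, j, odds * p@tMD)
    } else if (state == "I") {
      if (j < Lt) {
        visit("M", k + 1L, j + 1L, odds * p@tIM * eo[t[j + 1L], k + 1L])
        visit("I", k, j + 1L, odds * p@tII)
      }
    } else { # D
      if (k == Lq) {
        if (!local) record(odds)                   # D_L -> E, prob 1
        return(invisible())
      }
      if (j < Lt) {
        visit("M", k + 1L, j + 1L, odds * p@tDM * eo[t[j + 1L], k + 1L])
      }
      visit("D", k + 1L, j, odds * p@tDD)
    }
    invisible()
  }

  entries <- if (local) seq_len(Lq) else 1L
  for (s in seq_len(Lt) - 1L) {       # core starts after s flank residues
    for (k0 in entries) {
      visit("M", k0, s + 1L, w * eo[t[s + 1L], k0])
    }
  }
  if (acc$n == 0L || acc$sum == 0) return(-Inf)
  if (mode == "sum") log2(acc$sum) else log2(acc$max)
}
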