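#' @importClassesFrom Biostrings AAStringSet
NULL

#' Curated protein sequence database
#'
#' Holds an ordered set of protein sequences (as a
#' \linkS4class{AAStringSet}), the background amino-acid frequencies computed
#' from them, and the length cut applied during curation.  Accessions are the
#' names of the string set and must be unique.
#'
#' @slot sequences An \code{AAStringSet} of protein sequences over the
#'   20-letter alphabet; names are accessions.
#' @slot background Numeric vector of 20 amino-acid frequencies (fixed
#'   alphabetical order), summing to 1.
#' @slot lengthCut Numeric scalar: the length threshold recorded by
#'   \code{\link{curateDb}} (\code{Inf} before curation).
#' @slot curationPercentile The percentile the database has been curated at
#'   (\code{NA} before curation); makes re-curation at the same percentile a
#'   no-op.
#'
#' @seealso \code{\link{readProteinDb}}, \code{\link{curateDb}},
#'   \code{\link{generateDatabase}}
#' @export
setClass("SequenceDatabase",
  representation(
    sequences  = "AAStringSet",
    background = "numeric",
    lengthCut  = "numeric",
    curationPercentile = "numeric"
  )
)

setValidity("SequenceDatabase", function(object) {
  msg <- character()
  acc <- names(object@sequences)
  if (is.null(acc) || anyDuplicated(acc)) {
    msg <- c(msg, "accessions must be present and unique")
  }
  if (length(object@sequences) == 0L) {
    msg <- c(msg, "database must contain at least one record")
  }
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-12 ||
      any(object@background < 0)) {
    msg <- c(msg, "background must be a 20-vector of frequencies summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Sequencer device configuration
#'
#' Describes the signal model of the hypothetical single-molecule sequencer:
#' the posterior probability \code{pMax} assigned to the correct amino acid
#' and the subset of amino acids the device can discriminate.  Residues
#' outside the detection set yield a flat 1/20 posterior.
#'
#' @slot pMax Numeric in [0.05, 1]; 0.05 (= 1/20) is the fully unresolved
#'   limit, 1 is a perfect device.
#' @slot detectionSet Character vector of detectable amino acids (subset of
#'   \code{\link{aminoAcids}()}); defaults to all 20.
#'
#' @export
setClass("DeviceConfig",
  representation(pMax = "numeric", detectionSet = "character")
)

setValidity("DeviceConfig", function(object) {
  msg <- character()
  if (length(object@pMax) != 1L || object@pMax < 0.05 - 1e-12 ||
      object@pMax > 1 + 1e-12) {
    msg <- c(msg, "pMax must be a single value in [0.05, 1]")
  }
  if (length(object@detectionSet) == 0L ||
      !all(object@detectionSet %in% aminoAcids()) ||
      anyDuplicated(object@detectionSet)) {
    msg <- c(msg, "detectionSet must be a non-empty subset of the 20 amino acids")
  }
  if (length(msg)) msg else TRUE
})

#' Indel error model for simulated readouts
#'
#' Exact-count error rates: a readout of pre-error length L receives
#' round(deletionRate * L) deletions followed by round(insertionRate * L)
#' insertions (rounding half away from zero).  These are not per-position
#' Bernoulli probabilities.
#'
#' @slot insertionRate Numeric >= 0.
#' @slot deletionRate Numeric in [0, 1).
#'
#' @export
setClass("ErrorModel",
  representation(insertionRate = "numeric", deletionRate = "numeric")
)

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (length(object@insertionRate) != 1L || object@insertionRate < 0) {
    msg <- c(msg, "insertionRate must be a single non-negative value")
  }
  if (length(object@deletionRate) != 1L || object@deletionRate < 0 ||
      object@deletionRate >= 1) {
    msg <- c(msg, "deletionRate must be a single value in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Fragment sampling plan
#'
#' @slot length Integer fragment length in residues (>= 1).
#' @slot nFragments Integer number of fragments drawn per protein (>= 1),
#'   independently and with replacement.
#'
#' @export
setClass("FragmentPlan",
  representation(length = "integer", nFragments = "integer")
)

setValidity("FragmentPlan", function(object) {
  msg <- character()
  if (length(object@length) != 1L || object@length < 1L) {
    msg <- c(msg, "fragment length must be a single integer >= 1")
  }
  if (length(object@nFragments) != 1L || object@nFragments < 1L) {
    msg <- c(msg, "nFragments must be a single integer >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Probabilistic sequencer readout
#'
#' The decoded output of the simulated device for one molecule: a 20 x L'
#' matrix of per-position posterior probabilities over the amino acids (rows
#' in the fixed alphabetical order), plus provenance.
#'
#' @slot matrix Numeric 20 x L' matrix; every column sums to 1.
#' @slot sourceAccession Accession of the originating protein ("" if unknown).
#' @slot fragmentStart,fragmentEnd 0-based half-open interval of the fragment
#'   within the source protein (\code{NA} for full-length readouts).
#' @slot nInsertions,nDeletions Counts of indel errors applied.
#'
#' @seealso \code{\link{simulateReadout}}, \code{\link{buildProfile}}
#' @export
setClass("Readout",
  representation(
    matrix          = "matrix",
    sourceAccession = "character",
    fragmentStart   = "integer",
    fragmentEnd     = "integer",
    nInsertions     = "integer",
    nDeletions      = "integer"
  )
)

setValidity("Readout", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != 20L || ncol(m) < 1L) {
    msg <- c(msg, "readout matrix must be 20 x L with L >= 1")
  } else {
    if (any(m < 0)) msg <- c(msg, "posterior probabilities must be >= 0")
    if (any(abs(colSums(m) - 1) > 1e-12)) {
      msg <- c(msg, "every readout column must sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Core transition parameters of a readout profile HMM
#'
#' Plan7-style transition probabilities applied uniformly at every match
#' position: match-to-match 0.8 with 0.1 each to the insert and delete
#' states, and 0.9/0.1 continuation defaults for the insert and delete
#' states.  The background vector doubles as the insert-state emission
#' distribution and the null model.
#'
#' @slot tMM,tMI,tMD Match-state outgoing probabilities (sum to 1).
#' @slot tIM,tII Insert-state outgoing probabilities (sum to 1).
#' @slot tDM,tDD Delete-state outgoing probabilities (sum to 1).
#' @slot background Numeric 20-vector of frequencies summing to 1.
#'
#' @export
setClass("ProfileParams",
  representation(
    tMM = "numeric", tMI = "numeric", tMD = "numeric",
    tIM = "numeric", tII = "numeric",
    tDM = "numeric", tDD = "numeric",
    background = "numeric"
  )
)

setValidity("ProfileParams", function(object) {
  p <- c(object@tMM, object@tMI, object@tMD, object@tIM, object@tII,
         object@tDM, object@tDD)
  msg <- character()
  if (length(p) != 7L || any(p <= 0) || any(p >= 1)) {
    msg <- c(msg, "all transition probabilities must lie strictly in (0, 1)")
  } else {
    if (abs(object@tMM + object@tMI + object@tMD - 1) > 1e-12) {
      msg <- c(msg, "tMM + tMI + tMD must equal 1")
    }
    if (abs(object@tIM + object@tII - 1) > 1e-12) {
      msg <- c(msg, "tIM + tII must equal 1")
    }
    if (abs(object@tDM + object@tDD - 1) > 1e-12) {
      msg <- c(msg, "tDM + tDD must equal 1")
    }
  }
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-12 || any(object@background < 0)) {
    msg <- c(msg, "background must be a 20-vector of frequencies summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Profile HMM built from a readout
#'
#' One match state per readout column, with the readout posteriors as match
#' emissions; insert states emit the background.  Alignment is glocal over
#' the query (the readout is one complete sequenced molecule) and local over
#' the target (flanking residues are absorbed at zero log-odds cost).
#'
#' @slot matchEmissions Numeric 20 x L matrix of match emissions.
#' @slot params A \linkS4class{ProfileParams}.
#' @slot alignmentMode \code{"glocal-query/local-target"} (default) or
#'   \code{"local-query/local-target"} (uniform entry/exit over match-state
#'   pairs, for sensitivity analysis).
#'
#' @seealso \code{\link{buildProfile}}, \code{\link{forwardScore}}
#' @export
setClass("ProfileHMM",
  representation(
    matchEmissions = "matrix",
    params         = "ProfileParams",
    alignmentMode  = "character"
  )
)

setValidity("ProfileHMM", function(object) {
  m <- object@matchEmissions
  msg <- character()
  if (nrow(m) != 20L || ncol(m) < 1L) {
    msg <- c(msg, "matchEmissions must be 20 x L with L >= 1")
  } else if (any(abs(colSums(m) - 1) > 1e-9)) {
    msg <- c(msg, "every match-emission column must sum to 1")
  }
  if (!(object@alignmentMode %in%
        c("glocal-query/local-target", "local-query/local-target"))) {
    msg <- c(msg, "unsupported alignment mode")
  }
  if (length(msg)) msg else TRUE
})
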