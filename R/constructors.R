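#' @importFrom Biostrings AAStringSet width
NULL

#' Construct a sequencer device configuration
#'
#' @param pMax Posterior probability assigned to the correct amino acid, in
#'   [0.05, 1].  0.05 = 1/20 makes all amino acids indistinguishable.
#' @param detectionSet Character vector of detectable amino acids, either as
#'   one-letter codes (\code{c("L","S")}) or a single collapsed string
#'   (\code{"LS"}).  Default: all 20.
#' @return A \linkS4class{DeviceConfig}.
#' @export
#' @examples
#' DeviceConfig(pMax = 0.9, detectionSet = "LSE")
DeviceConfig <- function(pMax, detectionSet = aminoAcids()) {
  if (length(detectionSet) == 1L && nchar(detectionSet) > 1L) {
    detectionSet <- strsplit(detectionSet, "", fixed = TRUE)[[1]]
  }
  new("DeviceConfig", pMax = as.numeric(pMax),
      detectionSet = sort(unique(detectionSet)))
}

#' Construct an indel error model
#'
#' @param insertionRate Fraction of (pre-error) positions receiving an
#'   inserted spurious posterior column; >= 0.
#' @param deletionRate Fraction of (pre-error) positions deleted; in [0, 1).
#' @return An \linkS4class{ErrorModel}.
#' @export
ErrorModel <- function(insertionRate = 0, deletionRate = 0) {
  new("ErrorModel", insertionRate = as.numeric(insertionRate),
      deletionRate = as.numeric(deletionRate))
}

#' Construct a fragment sampling plan
#'
#' @param length Fragment length in residues.
#' @param nFragments Number of fragments drawn per protein (independently,
#'   with replacement).
#' @return A \linkS4class{FragmentPlan}.
#' @export
FragmentPlan <- function(length, nFragments = 1L) {
  new("FragmentPlan", length = as.integer(length),
      nFragments = as.integer(nFragments))
}

#' Construct profile HMM transition parameters
#'
#' Defaults encode the identification model: match-to-match 0.8 with 0.1
#' each into the insert and delete branches, and 0.9/0.1 continuation for
#' the insert and delete states.
#'
#' @param tMM,tMI,tMD Match-state outgoing probabilities (must sum to 1).
#' @param tIM,tII Insert-state outgoing probabilities (must sum to 1).
#' @param tDM,tDD Delete-state outgoing probabilities (must sum to 1).
#' @param background 20-vector of amino-acid frequencies (null model and
#'   insert emissions); default uniform.
#' @return A \linkS4class{ProfileParams}.
#' @export
ProfileParams <- function(tMM = 0.8, tMI = 0.1, tMD = 0.1,
                          tIM = 0.9, tII = 0.1,
                          tDM = 0.9, tDD = 0.1,
                          background = rep(1 / 20, 20)) {
  new("ProfileParams", tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
      tDM = tDM, tDD = tDD, background = .checkBackground(background))
}

#' Construct a readout object from a posterior matrix
#'
#' Mostly used internally by \code{\link{simulateReadout}}; exposed so
#' readouts can be assembled from external decoders.
#'
#' @param matrix 20 x L matrix of column-stochastic posteriors (rows in the
#'   fixed order \code{\link{aminoAcids}()}).
#' @param sourceAccession Accession of the originating protein, if known.
#' @param fragmentStart,fragmentEnd 0-based half-open source interval
#'   (\code{NA} for full length).
#' @param nInsertions,nDeletions Applied indel error counts.
#' @return A \linkS4class{Readout}.
#' @export
Readout <- function(matrix, sourceAccession = "", fragmentStart = NA_integer_,
                    fragmentEnd = NA_integer_, nInsertions = 0L,
                    nDeletions = 0L) {
  rownames(matrix) <- aminoAcids()
  new("Readout", matrix = matrix, sourceAccession = sourceAccession,
      fragmentStart = as.integer(fragmentStart),
      fragmentEnd = as.integer(fragmentEnd),
      nInsertions = as.integer(nInsertions),
      nDeletions = as.integer(nDeletions))
}

setMethod("show", "SequenceDatabase", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("SequenceDatabase with", length(object@sequences), "records\n")
  cat("  lengths: ", min(w), "-", max(w),
      " (median ", stats::median(w), ")\n", sep = "")
  cat("  length cut:", object@lengthCut, "\n")
  top <- names(sort(object@background, decreasing = TRUE))[1:5]
  cat("  top-5 abundant residues:", paste(top, collapse = " "), "\n")
})

setMethod("show", "DeviceConfig", function(object) {
  cat("DeviceConfig: pMax =", object@pMax, "; detects",
      if (length(object@detectionSet) == 20L) "all 20 amino acids" else
        paste(object@detectionSet, collapse = ""), "\n")
})

setMethod("show", "Readout", function(object) {
  cat("Readout: 20 x", ncol(object@matrix), "posterior matrix")
  if (nzchar(object@sourceAccession)) {
    cat(" from", object@sourceAccession)
  }
  if (!is.na(object@fragmentStart)) {
    cat(sprintf(" [%d, %d)", object@fragmentStart, object@fragmentEnd))
  }
  cat("\n  errors applied:", object@nDeletions, "deletions,",
      object@nInsertions, "insertions\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM with", ncol(object@matchEmissions), "match states;",
      object@alignmentMode, "\n")
})

#' @rdname accessors
#' @export
setGeneric("readoutMatrix", function(x) standardGeneric("readoutMatrix"))

#' Accessors for package classes
#'
#' \code{readoutMatrix} returns the 20 x L posterior matrix of a readout or
#' the match emissions of a profile; \code{dbSize} the number of database
#' records; \code{sequences} the underlying \code{AAStringSet};
#' \code{accessions} the record identifiers; \code{background} the
#' amino-acid frequency vector; \code{profileLength} the number of match
#' states.
#'
#' @param x The object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases readoutMatrix dbSize sequences accessions background profileLength
NULL

#' @rdname accessors
#' @export
setMethod("readoutMatrix", "Readout", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("readoutMatrix", "ProfileHMM", function(x) x@matchEmissions)

#' @rdname accessors
#' @export
setGeneric("dbSize", function(x) standardGeneric("dbSize"))

#' @rdname accessors
#' @export
setMethod("dbSize", "SequenceDatabase", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setMethod("sequences", "SequenceDatabase", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessors
#' @export
setMethod("accessions", "SequenceDatabase", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname accessors
#' @export
setMethod("background", "SequenceDatabase", function(x) x@background)

#' @rdname accessors
#' @export
setMethod("background", "ProfileParams", function(x) x@background)

#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' @rdname accessors
#' @export
setMethod("profileLength", "ProfileHMM", function(x) ncol(x@matchEmissions))
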