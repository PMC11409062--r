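#' Score every database sequence against a readout profile
#'
#' Computes the Forward log-odds score of each database record under the
#' profile, using the database background frequencies as the null model.
#' Deterministic for fixed inputs, and independent of any partitioning of
#' the database (scores are computed record-by-record).
#'
#' @param profile A \linkS4class{ProfileHMM}.
#' @param db A curated, non-empty \linkS4class{SequenceDatabase}.
#' @param encoded Optional pre-encoded database (from
#'   \code{\link{encodeDatabase}}), to avoid re-encoding in tight loops.
#' @param background Null-model frequencies; defaults to the database
#'   background.
#' @return A data.frame with columns \code{accession} and \code{score_bits},
#'   in database record order.
#' @export
scoreDatabase <- function(profile, db, encoded = NULL,
                          background = db@background) {
  stopifnot(is(profile, "ProfileHMM"), is(db, "SequenceDatabase"))
  if (is.null(encoded)) {
    encoded <- encodeDatabase(db)
  }
  s <- .scoreEncoded(profile, encoded, background)[, 1]
  data.frame(accession = accessions(db), score_bits = s,
             stringsAsFactors = FALSE)
}

#' Pre-encode database sequences for repeated scoring
#'
#' @param db A \linkS4class{SequenceDatabase}.
#' @return List of 0-based integer vectors, one per record.
#' @export
encodeDatabase <- function(db) {
  lapply(as.character(sequences(db)), encodeSequence)
}

#' Infer the originating protein from hit scores
#'
#' The hit with the highest score is the inferred protein.  Ties are broken
#' deterministically by lexicographically smallest accession and flagged;
#' when the truth is known, a tie resolved away from the truth counts as
#' incorrect (conservative accuracy).
#'
#' @param scores A data.frame with columns \code{accession} and
#'   \code{score_bits} (as from \code{\link{scoreDatabase}} or
#'   \code{\link{combineFragments}}).
#' @param truth The true source accession, or \code{NULL} if unknown.
#' @return A list with \code{rankedHits} (data.frame sorted by descending
#'   score, ties by accession), \code{inferredAccession}, \code{tieFlag},
#'   and \code{correct} (\code{NA} when no truth given).
#' @export
inferProtein <- function(scores, truth = NULL) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    stop("scores must be a non-empty data.frame")
  }
  ord <- order(-scores$score_bits, scores$accession)
  ranked <- scores[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  top <- ranked$score_bits[1]
  tie <- sum(scores$score_bits == top) > 1L
  list(rankedHits = ranked,
       inferredAccession = ranked$accession[1],
       tieFlag = tie,
       correct = if (is.null(truth)) NA else
         identical(ranked$accession[1], truth))
}

#' Combine hit scores across multiple fragments of one protein
#'
#' Per-accession sum of the Forward bit scores over all fragment readouts
#' (no per-fragment normalisation), ordered by descending total.  All
#' fragments must have been scored against the same database.
#'
#' @param perFragmentScores List of score data.frames (columns
#'   \code{accession}, \code{score_bits}), one per fragment.
#' @return A data.frame with columns \code{accession} and \code{score_bits}
#'   (the summed scores), sorted descending (ties by accession).
#' @export
#' @examples
#' a <- data.frame(accession = c("X", "Y"), score_bits = c(1, 3))
#' b <- data.frame(accession = c("X", "Y"), score_bits = c(4, 0))
#' combineFragments(list(a, b))   # X: 5, Y: 3
combineFragments <- function(perFragmentScores) {
  stopifnot(is.list(perFragmentScores), length(perFragmentScores) > 0L)
  ref <- sort(perFragmentScores[[1]]$accession)
  total <- NULL
  for (sc in perFragmentScores) {
    if (!identical(sort(sc$accession), ref)) {
      stop("all fragments must be scored against the same accession set")
    }
    v <- sc$score_bits[order(sc$accession)]
    total <- if (is.null(total)) v else total + v
  }
  out <- data.frame(accession = ref, score_bits = total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score_bits, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
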