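#' Identification accuracy from a set of results
#'
#' Accuracy is the fraction of readouts whose inferred protein equals the
#' true source.
#'
#' @param results List of results from \code{\link{inferProtein}} (each with
#'   a logical \code{correct}), or a logical vector of correctness flags.
#' @return A list with \code{n}, \code{nCorrect} and \code{accuracy}.
#' @export
#' @examples
#' computeAccuracy(c(rep(TRUE, 7), rep(FALSE, 3)))$accuracy   # 0.7
computeAccuracy <- function(results) {
  flags <- if (is.logical(results)) results else
    vapply(results, function(r) isTRUE(r$correct), logical(1))
  if (length(flags) == 0L) {
    stop("no identification results supplied")
  }
  list(n = length(flags), nCorrect = sum(flags),
       accuracy = mean(flags))
}

#' Percentile bootstrap confidence interval for an accuracy
#'
#' Resamples the per-protein correctness values with replacement and takes
#' percentile bounds of the resampled means.  Deterministic for a fixed
#' seed.
#'
#' @param flags Logical or numeric vector (per-protein correctness, possibly
#'   fractional when averaged over fragment repetitions).
#' @param nBoot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed, or \code{NULL} to use the current RNG stream.
#' @return Numeric vector \code{c(low, high)}.
#' @export
bootstrapCI <- function(flags, nBoot = 1000L, level = 0.95, seed = NULL) {
  stopifnot(length(flags) > 0L)
  x <- as.numeric(flags)
  if (!is.null(seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
  }
  n <- length(x)
  means <- vapply(seq_len(nBoot),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
}

#' Run one experimental condition over a whole database
#'
#' For every protein in the database: simulate readout(s) under the device
#' and error models, build the readout profile, score all database
#' sequences, and infer the originating protein.  With a fragment plan,
#' \code{nFragments} random fragments are drawn per protein; the
#' per-fragment accuracy averages correctness over the repetitions, and
#' (optionally) the combined inference sums each target's scores over all
#' fragments before taking the argmax.
#'
#' Per-protein RNG substreams are derived deterministically from
#' \code{(seed, accession)}, so results do not depend on iteration order.
#'
#' @param db A curated \linkS4class{SequenceDatabase}.
#' @param device A \linkS4class{DeviceConfig}.
#' @param plan A \linkS4class{FragmentPlan}, or \code{NULL} for full-length
#'   readouts.
#' @param errors An \linkS4class{ErrorModel}, or \code{NULL} for error-free
#'   readouts.
#' @param combine Also compute the combined (summed-score) inference when a
#'   fragment plan with more than one fragment is used.
#' @param seed Integer seed for the condition.
#' @param nBoot Bootstrap resamples for the confidence interval.
#' @param params \linkS4class{ProfileParams} template; its background is
#'   replaced by the database background.
#' @param alignmentMode Alignment mode passed to \code{\link{buildProfile}};
#'   the default glocal query exploits completeness of the readout, the
#'   local-query mode mirrors conventional local search engines.
#' @return A data.frame with one row per reported mode (per-fragment, and
#'   combined when requested): columns \code{p_max}, \code{fragment_length},
#'   \code{n_fragments}, \code{detection_set}, \code{ins_rate},
#'   \code{del_rate}, \code{combined}, \code{n}, \code{n_correct},
#'   \code{accuracy}, \code{ci_low}, \code{ci_high}, \code{n_ties},
#'   \code{seed}.
#' @export
runCondition <- function(db, device, plan = NULL, errors = NULL,
                         combine = FALSE, seed = 1L, nBoot = 1000L,
                         params = ProfileParams(),
                         alignmentMode = "glocal-query/local-target") {
  stopifnot(is(db, "SequenceDatabase"), is(device, "DeviceConfig"))
  encoded <- encodeDatabase(db)
  acc <- accessions(db)
  seqs <- as.character(sequences(db))
  bg <- db@background
  prm <- ProfileParams(tMM = params@tMM, tMI = params@tMI, tMD = params@tMD,
                       tIM = params@tIM, tII = params@tII,
                       tDM = params@tDM, tDD = params@tDD, background = bg)
  nFrag <- if (is.null(plan)) 1L else plan@nFragments
  fragCorrect <- matrix(NA, nrow = length(acc), ncol = nFrag)
  fragTies <- matrix(FALSE, nrow = length(acc), ncol = nFrag)
  combCorrect <- rep(NA, length(acc))
  combTies <- rep(FALSE, length(acc))

  for (i in seq_along(acc)) {
    set.seed(deriveSeed(seed, acc[i]))
    seqStr <- seqs[i]
    L <- nchar(seqStr)
    if (is.null(plan)) {
      ivs <- cbind(start = 0L, end = L)
    } else {
      ivs <- sampleFragments(L, plan)
    }
    scoreList <- vector("list", nrow(ivs))
    for (f in seq_len(nrow(ivs))) {
      frag <- substr(seqStr, ivs[f, "start"] + 1L, ivs[f, "end"])
      ro <- simulateReadout(frag, device, errors = errors,
                            sourceAccession = acc[i],
                            fragmentStart = ivs[f, "start"],
                            fragmentEnd = ivs[f, "end"])
      hmm <- buildProfile(ro, prm, alignmentMode = alignmentMode)
      sc <- scoreDatabase(hmm, db, encoded = encoded)
      scoreList[[f]] <- sc
      res <- inferProtein(sc, truth = acc[i])
      fragCorrect[i, f] <- res$correct
      fragTies[i, f] <- res$tieFlag
    }
    if (combine && nFrag > 1L) {
      res <- inferProtein(combineFragments(scoreList), truth = acc[i])
      combCorrect[i] <- res$correct
      combTies[i] <- res$tieFlag
    }
  }

  condRow <- function(correctPerProtein, nCorrect, combined, nTies) {
    ci <- bootstrapCI(correctPerProtein, nBoot = nBoot,
                      seed = deriveSeed(seed, "bootstrap"))
    data.frame(
      p_max = device@pMax,
      fragment_length = if (is.null(plan)) NA_integer_ else plan@length,
      n_fragments = nFrag,
      detection_set = paste(device@detectionSet, collapse = ""),
      ins_rate = if (is.null(errors)) 0 else errors@insertionRate,
      del_rate = if (is.null(errors)) 0 else errors@deletionRate,
      combined = combined,
      n = length(correctPerProtein),
      n_correct = nCorrect,
      accuracy = mean(correctPerProtein),
      ci_low = ci[1], ci_high = ci[2],
      n_ties = nTies,
      seed = seed,
      stringsAsFactors = FALSE)
  }

  out <- condRow(rowMeans(fragCorrect), sum(fragCorrect), FALSE,
                 sum(fragTies))
  if (combine && nFrag > 1L) {
    out <- rbind(out, condRow(combCorrect, sum(combCorrect), TRUE,
                              sum(combTies)))
  }
  out
}

#' Specification of an experiment grid
#'
#' @param pMaxGrid Numeric vector of \code{pMax} values.
#' @param fragmentLengths Integer vector of fragment lengths; \code{NA}
#'   means full-length readouts.
#' @param nFragments Fragments per protein for fragment conditions.
#' @param detectionSets List of detection sets (character vectors or
#'   collapsed strings such as \code{"LSEAG"}).
#' @param insertionRates,deletionRates Numeric vectors of error rates.
#' @param seed Integer seed for the whole sweep.
#' @param combine Also report combined-fragment inference.
#' @return A classed list used by \code{\link{runSweep}}.
#' @export
SweepSpec <- function(pMaxGrid, fragmentLengths = NA_integer_,
                      nFragments = 1L, detectionSets = list(aminoAcids()),
                      insertionRates = 0, deletionRates = 0, seed = 1L,
                      combine = FALSE) {
  stopifnot(length(pMaxGrid) > 0L, length(fragmentLengths) > 0L,
            length(detectionSets) > 0L, length(insertionRates) > 0L,
            length(deletionRates) > 0L)
  structure(list(pMaxGrid = pMaxGrid, fragmentLengths = fragmentLengths,
                 nFragments = as.integer(nFragments),
                 detectionSets = detectionSets,
                 insertionRates = insertionRates,
                 deletionRates = deletionRates,
                 seed = as.integer(seed), combine = combine),
            class = "SweepSpec")
}

#' Run an experiment-grid sweep
#'
#' Executes \code{\link{runCondition}} over the Cartesian product of the
#' grids of the sweep specification.  Results are appended to a TSV as each condition
#' completes; on rerun, conditions already present in the TSV are skipped,
#' making sweeps resumable.
#'
#' @param spec A \code{\link{SweepSpec}}.
#' @param db The database to sweep over.
#' @param outPath Optional TSV path for persistence/resumability.
#' @param nBoot Bootstrap resamples per condition.
#' @return A data.frame of all condition rows (persisted and newly run).
#' @export
runSweep <- function(spec, db, outPath = NULL, nBoot = 1000L) {
  stopifnot(inherits(spec, "SweepSpec"))
  setLabel <- function(s) {
    paste(sort(if (length(s) == 1L && nchar(s) > 1L)
      strsplit(s, "", fixed = TRUE)[[1]] else s), collapse = "")
  }
  grid <- expand.grid(
    p_max = spec$pMaxGrid,
    fragment_length = spec$fragmentLengths,
    detection_set = vapply(spec$detectionSets, setLabel, character(1)),
    ins_rate = spec$insertionRates,
    del_rate = spec$deletionRates,
    stringsAsFactors = FALSE)
  done <- NULL
  if (!is.null(outPath) && file.exists(outPath)) {
    done <- utils::read.table(outPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    done$detection_set <- as.character(done$detection_set)
  }
  keyOf <- function(d) {
    paste(format(d$p_max), d$fragment_length, d$detection_set,
          format(d$ins_rate), format(d$del_rate), sep = "|")
  }
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- grid[g, , drop = FALSE]
    if (!is.null(done) && keyOf(cond) %in% unique(keyOf(done))) {
      rows[[length(rows) + 1L]] <- done[keyOf(done) == keyOf(cond), ,
                                        drop = FALSE]
      next
    }
    device <- DeviceConfig(cond$p_max, cond$detection_set)
    plan <- if (is.na(cond$fragment_length)) NULL else
      FragmentPlan(cond$fragment_length, spec$nFragments)
    errors <- if (cond$ins_rate == 0 && cond$del_rate == 0) NULL else
      ErrorModel(cond$ins_rate, cond$del_rate)
    res <- runCondition(db, device, plan = plan, errors = errors,
                        combine = spec$combine, seed = spec$seed,
                        nBoot = nBoot)
    rows[[length(rows) + 1L]] <- res
    if (!is.null(outPath)) {
      utils::write.table(res, outPath, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(outPath),
                         append = file.exists(outPath))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
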