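#' @importFrom stats runif
NULL

#' Posterior probability column for one amino acid
#'
#' The device's decoded output for a single position: if the amino acid is
#' in the detection set, the correct residue receives \code{pMax} and the
#' remaining \code{1 - pMax} is divided equally among the 19 incorrect
#' residues; if it is not detectable, the posterior is flat (1/20
#' everywhere).
#'
#' @param aa A single canonical one-letter amino-acid code.
#' @param device A \linkS4class{DeviceConfig}.
#' @return Named numeric 20-vector summing to 1 (order
#'   \code{\link{aminoAcids}()}).
#' @export
#' @examples
#' posteriorColumn("Q", DeviceConfig(pMax = 0.5))["Q"]     # 0.5
#' posteriorColumn("F", DeviceConfig(0.9, "LSE"))          # flat 1/20
posteriorColumn <- function(aa, device) {
  i <- .aaIndex(aa)
  if (length(aa) != 1L || is.na(i)) {
    stop("aa must be a single canonical amino-acid letter")
  }
  col <- .posteriorColumns(device)[, i]
  names(col) <- aminoAcids()
  col
}

# 20 x 20 matrix whose column j is the device posterior for amino acid j
.posteriorColumns <- function(device) {
  p <- device@pMax
  m <- matrix(1 / 20, nrow = 20L, ncol = 20L)
  if (p == 0.05) {
    return(m)  # 1/20 for the correct residue: exactly the flat column
  }
  detected <- aminoAcids() %in% device@detectionSet
  for (j in which(detected)) {
    m[, j] <- (1 - p) / 19
    m[j, j] <- p
  }
  m
}

#' Simulate a sequencer readout for a protein or fragment
#'
#' Builds the error-free 20 x L posterior matrix column-by-column from the
#' device model, then (optionally) applies the indel error process via
#' \code{\link{applyErrors}}: deletions first, then insertions, both with
#' exact counts derived from the pre-error length.
#'
#' @param sequence Amino-acid string (the molecule entering the device).
#' @param device A \linkS4class{DeviceConfig}.
#' @param errors An \linkS4class{ErrorModel}, or \code{NULL} for an
#'   error-free readout.
#' @param sourceAccession,fragmentStart,fragmentEnd Provenance recorded on
#'   the returned object (0-based half-open fragment interval).
#' @param seed Optional integer seed making the error process reproducible;
#'   when \code{NULL} the current RNG stream is used.
#' @return A \linkS4class{Readout}.
#' @export
#' @examples
#' r <- simulateReadout("QFEGSAL", DeviceConfig(pMax = 0.5))
#' dim(readoutMatrix(r))   # 20 x 7
simulateReadout <- function(sequence, device, errors = NULL,
                            sourceAccession = "", fragmentStart = NA_integer_,
                            fragmentEnd = NA_integer_, seed = NULL) {
  idx <- .aaIndex(strsplit(as.character(sequence), "", fixed = TRUE)[[1]])
  if (length(idx) == 0L) {
    stop("sequence must contain at least one residue")
  }
  if (anyNA(idx)) {
    stop("sequence contains non-canonical residues")
  }
  m <- .posteriorColumns(device)[, idx, drop = FALSE]
  nDel <- 0L
  nIns <- 0L
  if (!is.null(errors)) {
    if (!is.null(seed)) {
      old <- .GlobalEnv$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = .GlobalEnv))
      set.seed(seed)
    }
    res <- applyErrors(m, errors, device)
    m <- res$matrix
    nDel <- res$nDeletions
    nIns <- res$nInsertions
  }
  Readout(m, sourceAccession = sourceAccession,
          fragmentStart = fragmentStart, fragmentEnd = fragmentEnd,
          nInsertions = nIns, nDeletions = nDel)
}

#' Apply the indel error process to a posterior matrix
#'
#' Exact-count errors on a matrix of pre-error length L: first
#' \code{round(deletionRate * L)} columns are removed at distinct positions
#' chosen uniformly at random; then \code{round(insertionRate * L)} spurious
#' columns are inserted at gap positions of the post-deletion matrix, chosen
#' uniformly with replacement.  Each inserted column is the device posterior
#' of an amino acid drawn uniformly from the 20 (so insertions look like
#' genuine decoded positions).  Rounding is half away from zero; deleting
#' first guarantees insertions are never subsequently deleted.
#'
#' @param matrix 20 x L column-stochastic posterior matrix.
#' @param errors An \linkS4class{ErrorModel}.
#' @param device The \linkS4class{DeviceConfig} used for inserted columns.
#' @return List with \code{matrix} (20 x L'), \code{nDeletions},
#'   \code{nInsertions}; always L' = L - nDeletions + nInsertions.
#' @export
applyErrors <- function(matrix, errors, device) {
  stopifnot(is(errors, "ErrorModel"), is(device, "DeviceConfig"),
            nrow(matrix) == 20L)
  L <- ncol(matrix)
  nDel <- as.integer(roundHalfAway(errors@deletionRate * L))
  nIns <- as.integer(roundHalfAway(errors@insertionRate * L))
  if (nDel >= L) {
    stop("deletion count (", nDel, ") must be smaller than readout length (",
         L, ")")
  }
  if (nDel > 0L) {
    drop <- sample.int(L, nDel)
    matrix <- matrix[, -drop, drop = FALSE]
  }
  if (nIns > 0L) {
    cols <- .posteriorColumns(device)[, sample.int(20L, nIns, replace = TRUE),
                                      drop = FALSE]
    # gaps 0..ncol of the post-deletion matrix, drawn with replacement;
    # stable placement via order of (gap, draw index)
    gaps <- sample.int(ncol(matrix) + 1L, nIns, replace = TRUE) - 1L
    out <- matrix(0, nrow = 20L, ncol = ncol(matrix) + nIns)
    pos <- seq_len(ncol(matrix)) + vapply(seq_len(ncol(matrix)),
                                          function(j) sum(gaps < j), 0L)
    out[, pos] <- matrix
    out[, setdiff(seq_len(ncol(out)), pos)] <-
      cols[, order(gaps), drop = FALSE]
    matrix <- out
  }
  list(matrix = matrix, nDeletions = nDel, nInsertions = nIns)
}

#' Sample random fragment intervals from a protein
#'
#' Fragment start positions are drawn uniformly from the valid range
#' (independently, with replacement across draws).  A protein shorter than
#' or equal to the fragment length contributes its full sequence for every
#' draw.
#'
#' @param proteinLength Length of the source protein in residues.
#' @param plan A \linkS4class{FragmentPlan}.
#' @return Integer matrix with \code{nFragments} rows and columns
#'   \code{start}, \code{end} (0-based half-open).
#' @export
sampleFragments <- function(proteinLength, plan) {
  stopifnot(is(plan, "FragmentPlan"), proteinLength >= 1L)
  n <- plan@nFragments
  if (proteinLength <= plan@length) {
    starts <- rep(0L, n)
    ends <- rep(as.integer(proteinLength), n)
  } else {
    starts <- sample.int(proteinLength - plan@length + 1L, n,
                         replace = TRUE) - 1L
    ends <- starts + plan@length
  }
  cbind(start = starts, end = ends)
}

#' Write a readout to its TSV interchange format
#'
#' One row per position with 20 columns headed by the amino-acid letters,
#' preceded by '#'-prefixed metadata lines (source accession, fragment
#' interval, applied error counts).
#'
#' @param readout A \linkS4class{Readout}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeReadout <- function(readout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# source_accession=", readout@sourceAccession),
    paste0("# fragment_start=", readout@fragmentStart),
    paste0("# fragment_end=", readout@fragmentEnd),
    paste0("# n_insertions=", readout@nInsertions),
    paste0("# n_deletions=", readout@nDeletions),
    paste(aminoAcids(), collapse = "\t")
  ), con)
  utils::write.table(t(readout@matrix), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a readout from its TSV interchange format
#'
#' @param path Path written by \code{\link{writeReadout}}.
#' @return A \linkS4class{Readout}.
#' @export
readReadout <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getMeta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  stopifnot(identical(header, aminoAcids()))
  vals <- do.call(rbind, lapply(strsplit(body[-1], "\t", fixed = TRUE),
                                as.numeric))
  asInt <- function(x) suppressWarnings(as.integer(x))
  Readout(t(vals),
          sourceAccession = getMeta("source_accession", ""),
          fragmentStart = asInt(getMeta("fragment_start", NA)),
          fragmentEnd = asInt(getMeta("fragment_end", NA)),
          nInsertions = asInt(getMeta("n_insertions", 0)),
          nDeletions = asInt(getMeta("n_deletions", 0)))
}
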