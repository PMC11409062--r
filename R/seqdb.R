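#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
#'   letterFrequency width
#' @importFrom stats quantile
NULL

# residue-mapping policy for nonstandard letters: selenocysteine (U) is the
# cysteine analogue, pyrrolysine (O) the lysine analogue; anything else
# non-canonical (B, Z, J, X, ...) makes a record undecodable and drops it.
.mapResidues <- function(sequence) {
  chartr("UO", "CK", toupper(sequence))
}

.newSequenceDatabase <- function(seqs, lengthCut = Inf,
                                 curationPercentile = NA_real_) {
  db <- new("SequenceDatabase", sequences = seqs,
            background = rep(1 / 20, 20), lengthCut = lengthCut,
            curationPercentile = curationPercentile)
  db@background <- computeBackground(db)
  db
}

#' Read a protein FASTA file into a SequenceDatabase
#'
#' Sequences are upper-cased and the residue-mapping policy is applied:
#' U -> C and O -> K; records still containing any letter outside the
#' canonical 20-letter alphabet are dropped (with a message reporting the
#' count).  The accession is the first whitespace-delimited token of each
#' FASTA header.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return An uncurated \linkS4class{SequenceDatabase} (no length cut
#'   applied; background frequencies computed from the retained records).
#' @export
#' @seealso \code{\link{curateDb}}, \code{\link{writeProteinDb}}
readProteinDb <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  raw <- Biostrings::readAAStringSet(path)
  if (length(raw) == 0L) {
    stop("no FASTA records in ", path)
  }
  seqs <- vapply(as.character(raw), .mapResidues, character(1),
                 USE.NAMES = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(raw))
  ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  nDropped <- sum(!ok)
  if (nDropped > 0L) {
    message(nDropped, " record(s) dropped (unmappable residues): ",
            paste(utils::head(names(seqs)[!ok], 5), collapse = ", "))
  }
  seqs <- seqs[ok]
  if (length(seqs) == 0L) {
    stop("no valid records after residue mapping")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate accessions in ", path)
  }
  .newSequenceDatabase(Biostrings::AAStringSet(seqs))
}

#' Write a SequenceDatabase to FASTA (with optional curation report)
#'
#' @param db A \linkS4class{SequenceDatabase}.
#' @param path Output FASTA path.
#' @param reportPath Optional path for a TSV report (accession, length).
#' @return Invisibly, \code{path}.
#' @export
writeProteinDb <- function(db, path, reportPath = NULL) {
  Biostrings::writeXStringSet(db@sequences, path, width = 60L)
  if (!is.null(reportPath)) {
    utils::write.table(
      data.frame(accession = accessions(db),
                 length = Biostrings::width(db@sequences)),
      reportPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Curate a database by discarding extreme-length proteins
#'
#' Removes every record whose length is strictly greater than the requested
#' percentile of the length distribution (linear-interpolation percentile,
#' i.e. \code{quantile(..., type = 7)}).  This mirrors the usual pruning of
#' extreme outliers such as titin before large identification benchmarks.
#' Curation is declarative: a database already curated at the requested
#' percentile is returned unchanged, so repeated curation does not keep
#' shaving the length distribution.
#'
#' @param db A non-empty \linkS4class{SequenceDatabase}.
#' @param percentile Fraction in (0, 1]; default 0.99.
#' @return A curated \linkS4class{SequenceDatabase}; record order is
#'   preserved, \code{lengthCut} records the computed threshold and the
#'   background is recomputed on the retained records.
#' @export
#' @examples
#' db <- generateDatabase(n = 50, lengths = c(100, 500), seed = 1)
#' curated <- curateDb(db, percentile = 0.99)
curateDb <- function(db, percentile = 0.99) {
  stopifnot(is(db, "SequenceDatabase"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 1) {
    stop("percentile must be a single value in (0, 1]")
  }
  if (!is.na(db@curationPercentile) &&
      db@curationPercentile == percentile) {
    return(db)
  }
  w <- Biostrings::width(db@sequences)
  cut <- unname(stats::quantile(w, percentile, type = 7))
  keep <- w <= cut
  .newSequenceDatabase(db@sequences[keep], lengthCut = cut,
                       curationPercentile = percentile)
}

#' Amino-acid background frequencies of a database
#'
#' Frequency of each amino acid = its residue count over all records divided
#' by the total residue count, in the fixed order \code{\link{aminoAcids}()}.
#'
#' @param db A non-empty \linkS4class{SequenceDatabase}.
#' @return Named numeric 20-vector summing to 1.
#' @export
computeBackground <- function(db) {
  stopifnot(is(db, "SequenceDatabase"), length(db@sequences) > 0L)
  counts <- colSums(Biostrings::letterFrequency(db@sequences,
                                                letters = aminoAcids()))
  counts / sum(counts)
}

#' Rank amino acids by abundance
#'
#' @param background Numeric 20-vector of frequencies (named or in the fixed
#'   alphabetical order).
#' @return Character vector of the 20 amino acids, most to least frequent;
#'   ties broken alphabetically (stable).
#' @export
#' @examples
#' abundanceRanking(humanLikeBackground())[1:5]   # L S E A G
abundanceRanking <- function(background) {
  background <- .checkBackground(background)
  aa <- aminoAcids()
  aa[order(-background, aa)]
}
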