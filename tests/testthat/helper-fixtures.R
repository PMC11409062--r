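# shared helpers for the test suite; everything is built in code

# a tiny FASTA file on disk, returns its path
writeTestFasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(entries), function(nm) {
    c(paste0(">", nm), entries[[nm]])
  }))
  writeLines(lines, path)
  path
}

# database straight from named sequences (bypasses disk)
dbFromSequences <- function(seqs) {
  proseqid:::.newSequenceDatabase(Biostrings::AAStringSet(seqs))
}

# random column-stochastic emission matrix
randomEmissions <- function(Lq) {
  em <- matrix(stats::rexp(20 * Lq), nrow = 20)
  sweep(em, 2, colSums(em), "/")
}

# random frequency vector
randomBackground <- function() {
  b <- stats::rexp(20)
  b / sum(b)
}

randomPeptide <- function(L) {
  paste(sample(aminoAcids(), L, replace = TRUE), collapse = "")
}
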