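#' Export a readout profile as a HMMER3 ASCII file
#'
#' Writes the profile in the \code{HMMER3/f} plain-text dialect so an
#' external \code{hmmsearch} can consume it for cross-validation: match and
#' insert emission lines as negative natural-log probabilities (with the
#' \code{*} token for probability zero), one transition line per node, and
#' the package's glocal entry/exit encoded in the node-0 and final-node
#' transitions (Begin to M1 with probability 1; M_L to End with probability
#' 1).  Insert emissions are the profile background.
#'
#' @param profile A \linkS4class{ProfileHMM}.
#' @param path Output file path.
#' @param name Profile name recorded in the file.
#' @return Invisibly, \code{path}.
#' @export
writeHmmer3Profile <- function(profile, path, name = "readout_profile") {
  stopifnot(is(profile, "ProfileHMM"))
  m <- profile@matchEmissions
  L <- ncol(m)
  p <- profile@params
  bg <- p@background
  nl <- function(prob) {
    vapply(prob, function(x) {
      if (x <= 0) "*" else sprintf("%.5f", -log(x))
    }, character(1))
  }
  fmt <- function(x) paste(sprintf("%8s", x), collapse = "  ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "HMMER3/f [proseqid readout profile export]",
    paste0("NAME  ", name),
    paste0("LENG  ", L),
    "ALPH  amino",
    "RF    no",
    "MM    no",
    "CONS  yes",
    "CS    no",
    "MAP   yes",
    "STATS LOCAL MSV       -9.0000  0.70000",
    "STATS LOCAL VITERBI   -9.0000  0.70000",
    "STATS LOCAL FORWARD   -9.0000  0.70000",
    paste0("HMM      ", paste(sprintf("%8s", aminoAcids()), collapse = "  ")),
    paste0("         ",
           fmt(c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")))
  ), con)
  # node 0: insert-0 emissions, then B-state transitions (B -> M1 = 1)
  writeLines(paste0("         ", fmt(nl(bg))), con)
  writeLines(paste0("         ",
                    fmt(c("0.00000", "*", "*",
                          sprintf("%.5f", -log(c(p@tIM, p@tII))),
                          "0.00000", "*"))), con)
  ins <- fmt(nl(bg))
  midTrans <- fmt(sprintf("%.5f", -log(c(p@tMM, p@tMI, p@tMD, p@tIM, p@tII,
                                         p@tDM, p@tDD))))
  endTrans <- fmt(c("0.00000", "*", "*", "0.00000", "*", "0.00000", "*"))
  for (k in seq_len(L)) {
    cons <- tolower(aminoAcids()[which.max(m[, k])])
    writeLines(paste0(sprintf("%7d  ", k), fmt(nl(m[, k])),
                      sprintf("  %d %s - - -", k, cons)), con)
    writeLines(paste0("         ", ins), con)
    writeLines(paste0("         ",
                      if (k == L) endTrans else midTrans), con)
  }
  writeLines("//", con)
  invisible(path)
}
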