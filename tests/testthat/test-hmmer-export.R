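# minimal independent reader of the HMMER3 ASCII dialect, used only to
# check the writer; returns emissions as probabilities
parseHmmer3 <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^HMMER3/f", lines[1]))
  leng <- as.integer(sub("^LENG\\s+", "", grep("^LENG", lines, value = TRUE)))
  hmmAt <- grep("^HMM\\s", lines)
  body <- lines[(hmmAt + 2):length(lines)]
  body <- body[!grepl("^//", body)]
  toks <- lapply(strsplit(trimws(body), "\\s+"), identity)
  # node 0 = 2 lines; nodes 1..L = 3 lines each
  prob <- function(x) {
    vapply(x, function(v) if (v == "*") 0 else exp(-as.numeric(v)),
           numeric(1), USE.NAMES = FALSE)
  }
  match <- matrix(0, 20, leng)
  ins <- matrix(0, 20, leng)
  trans <- matrix(0, 7, leng)
  for (k in seq_len(leng)) {
    base <- 2 + (k - 1) * 3
    mt <- toks[[base + 1]]
    stopifnot(as.integer(mt[1]) == k)
    match[, k] <- prob(mt[2:21])
    ins[, k] <- prob(toks[[base + 2]][1:20])
    trans[, k] <- prob(toks[[base + 3]][1:7])
  }
  list(length = leng, match = match, insert = ins, trans = trans,
       node0trans = prob(toks[[2]][1:7]))
}

test_that("the HMMER3 export encodes the profile faithfully", {
  r <- simulateReadout("QFEGSAL", DeviceConfig(pMax = 0.5))
  hmm <- buildProfile(r, ProfileParams(background = humanLikeBackground()))
  path <- tempfile(fileext = ".hmm")
  writeHmmer3Profile(hmm, path, name = "qfexample")
  parsed <- parseHmmer3(path)
  expect_equal(parsed$length, 7L)
  # emissions are written as -ln(posterior), five printed decimals
  expect_equal(parsed$match, unname(readoutMatrix(r)), tolerance = 1e-4)
  expect_equal(parsed$insert[, 1], unname(humanLikeBackground()),
               tolerance = 1e-4)
  # uniform core transitions at internal nodes
  expect_equal(parsed$trans[, 3],
               c(0.8, 0.1, 0.1, 0.9, 0.1, 0.9, 0.1), tolerance = 1e-4)
  # entry B->M1 = 1 and exit M_L->E = 1 encode the glocal query
  expect_equal(parsed$node0trans[1:3], c(1, 0, 0))
  expect_equal(parsed$trans[1:3, 7], c(1, 0, 0))
})

test_that("zero-probability emissions use the '*' infinity token", {
  pep <- "ACDEF"
  hmm <- buildProfile(readoutMatrix(simulateReadout(pep, DeviceConfig(1))))
  path <- tempfile(fileext = ".hmm")
  writeHmmer3Profile(hmm, path)
  lines <- readLines(path)
  expect_true(any(grepl("\\*", lines)))
  parsed <- parseHmmer3(path)
  expect_equal(parsed$match[, 1],
               as.numeric(aminoAcids() == "A"))
})

test_that("an external hmmsearch accepts exported profiles", {
  skip_if(Sys.which("hmmsearch") == "", "hmmsearch binary not on PATH")
  db <- generateDatabase(n = 15, lengths = c(60, 120), seed = 51)
  fa <- tempfile(fileext = ".fasta")
  writeProteinDb(db, fa)
  s <- as.character(sequences(db))[4]
  ro <- simulateReadout(substr(s, 6, 55), DeviceConfig(0.9),
                        sourceAccession = accessions(db)[4])
  hmm <- buildProfile(ro, ProfileParams(background = background(db)))
  path <- tempfile(fileext = ".hmm")
  writeHmmer3Profile(hmm, path, name = "interop")
  tbl <- tempfile()
  statusOut <- system2("hmmsearch",
                       c("--max", "-T", "-1000", "--tblout", tbl, path, fa),
                       stdout = TRUE, stderr = TRUE)
  status <- attr(statusOut, "status")
  expect_true(is.null(status) || status == 0)
  hits <- readLines(tbl)
  hits <- hits[!startsWith(hits, "#")]
  expect_gt(length(hits), 0)
  topHit <- strsplit(trimws(hits[1]), "\\s+")[[1]][1]
  expect_equal(topHit, accessions(db)[4])
})
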