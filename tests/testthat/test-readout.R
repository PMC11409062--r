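test_that("posterior columns follow the pMax / detection-set model", {
  colQ <- posteriorColumn("Q", DeviceConfig(pMax = 0.5))
  expect_equal(unname(colQ["Q"]), 0.5)
  expect_equal(unname(colQ["A"]), 0.5 / 19)
  expect_equal(sum(colQ), 1)

  # undetectable residue: flat posterior
  colF <- posteriorColumn("F", DeviceConfig(pMax = 0.9, detectionSet = "LSE"))
  expect_equal(unname(colF), rep(1 / 20, 20))

  # pMax = 1/20 is the indistinguishable limit even for detected residues
  colA <- posteriorColumn("A", DeviceConfig(pMax = 0.05))
  expect_equal(unname(colA), rep(1 / 20, 20))

  expect_error(posteriorColumn("B", DeviceConfig(0.5)), "canonical")
  expect_error(DeviceConfig(0.04), "pMax")
  expect_error(DeviceConfig(0.5, character(0)))
})

test_that("error-free readouts encode the sequence position-wise", {
  r <- simulateReadout("QFEGSAL", DeviceConfig(pMax = 0.5))
  m <- readoutMatrix(r)
  expect_equal(dim(m), c(20L, 7L))
  expect_equal(unname(colSums(m)), rep(1, 7))
  expect_equal(unname(m["Q", 1]), 0.5)
  expect_equal(unname(m["L", 7]), 0.5)

  # perfect device: one-hot columns reconstruct the peptide by argmax
  set.seed(31)
  pep <- randomPeptide(40)
  m1 <- readoutMatrix(simulateReadout(pep, DeviceConfig(pMax = 1)))
  expect_equal(paste(aminoAcids()[apply(m1, 2, which.max)], collapse = ""),
               pep)
  expect_equal(range(m1), c(0, 1))

  expect_error(simulateReadout("", DeviceConfig(0.5)), "at least one")
})

test_that("indel error counts are exact and deletion precedes insertion", {
  dev <- DeviceConfig(pMax = 0.8)
  m <- readoutMatrix(simulateReadout(randomPeptide(100), dev))

  set.seed(5)
  insOnly <- applyErrors(m, ErrorModel(insertionRate = 0.1), dev)
  expect_equal(insOnly$nInsertions, 10L)
  expect_equal(ncol(insOnly$matrix), 110L)

  delOnly <- applyErrors(m, ErrorModel(deletionRate = 0.1), dev)
  expect_equal(delOnly$nDeletions, 10L)
  expect_equal(ncol(delOnly$matrix), 90L)

  none <- applyErrors(m, ErrorModel(), dev)
  expect_identical(none$matrix, m)
  expect_equal(c(none$nDeletions, none$nInsertions), c(0L, 0L))

  expect_error(applyErrors(m, ErrorModel(deletionRate = 0.999), dev),
               "deletion count")
})

test_that("post-error length follows L' = L - round(dL) + round(iL)", {
  dev <- DeviceConfig(pMax = 0.6, detectionSet = "LSEAG")
  set.seed(77)
  for (trial in 1:20) {
    L <- sample(20:120, 1)
    d <- runif(1, 0, 0.5)
    i <- runif(1, 0, 0.5)
    m <- readoutMatrix(simulateReadout(randomPeptide(L), dev))
    res <- applyErrors(m, ErrorModel(i, d), dev)
    rha <- function(x) sign(x) * floor(abs(x) + 0.5)
    expect_equal(res$nDeletions, as.integer(rha(d * L)))
    expect_equal(res$nInsertions, as.integer(rha(i * L)))
    expect_equal(ncol(res$matrix), L - res$nDeletions + res$nInsertions)
    expect_equal(colSums(res$matrix), rep(1, ncol(res$matrix)))
  }
})

test_that("inserted columns are genuine device posterior columns", {
  dev <- DeviceConfig(pMax = 0.9, detectionSet = "LSE")
  pep <- randomPeptide(50)
  m <- readoutMatrix(simulateReadout(pep, dev))
  set.seed(12)
  res <- applyErrors(m, ErrorModel(insertionRate = 0.2), dev)
  valid <- cbind(proseqid:::.posteriorColumns(dev))
  for (j in seq_len(ncol(res$matrix))) {
    col <- res$matrix[, j]
    match <- any(apply(valid, 2, function(v) max(abs(v - col)) < 1e-12))
    expect_true(match)
  }
})

test_that("fragment sampling covers the valid start range", {
  set.seed(8)
  ivs <- sampleFragments(411, FragmentPlan(100, nFragments = 500))
  expect_equal(nrow(ivs), 500L)
  expect_true(all(ivs[, "end"] - ivs[, "start"] == 100L))
  expect_true(all(ivs[, "start"] >= 0L & ivs[, "start"] <= 311L))
  # with 500 draws over 312 starts, both extremes should be reachable
  expect_true(min(ivs[, "start"]) < 20L)
  expect_true(max(ivs[, "start"]) > 290L)

  short <- sampleFragments(80, FragmentPlan(100, nFragments = 10))
  expect_true(all(short[, "start"] == 0L & short[, "end"] == 80L))
})

test_that("readout simulation is reproducible for a fixed seed", {
  dev <- DeviceConfig(pMax = 0.7)
  err <- ErrorModel(0.2, 0.2)
  pep <- randomPeptide(60)
  r1 <- simulateReadout(pep, dev, errors = err, seed = 123)
  r2 <- simulateReadout(pep, dev, errors = err, seed = 123)
  expect_identical(readoutMatrix(r1), readoutMatrix(r2))
  r3 <- simulateReadout(pep, dev, errors = err, seed = 124)
  expect_false(identical(readoutMatrix(r1), readoutMatrix(r3)))
})

test_that("readouts round-trip through the TSV interchange format", {
  r <- simulateReadout("QFEGSAL", DeviceConfig(0.5), sourceAccession = "QFX1",
                       fragmentStart = 3L, fragmentEnd = 10L)
  path <- tempfile(fileext = ".tsv")
  writeReadout(r, path)
  back <- readReadout(path)
  expect_equal(readoutMatrix(back), readoutMatrix(r), tolerance = 1e-12)
  expect_equal(back@sourceAccession, "QFX1")
  expect_equal(back@fragmentStart, 3L)
  expect_equal(back@fragmentEnd, 10L)
})
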