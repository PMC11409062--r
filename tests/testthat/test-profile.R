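test_that("profile construction copies emissions and validates transitions", {
  r <- simulateReadout("QFEGSAL", DeviceConfig(pMax = 0.5))
  hmm <- buildProfile(r)
  expect_equal(profileLength(hmm), 7L)
  expect_identical(readoutMatrix(hmm), readoutMatrix(r))
  p <- hmm@params
  expect_equal(p@tMM + p@tMI + p@tMD, 1)
  expect_equal(p@tIM + p@tII, 1)
  expect_equal(p@tDM + p@tDD, 1)
  expect_equal(c(p@tMM, p@tMI, p@tMD), c(0.8, 0.1, 0.1))

  expect_error(ProfileParams(tMM = 0.8, tMI = 0.3, tMD = 0.1), "equal 1")
  expect_error(buildProfile(matrix(numeric(0), nrow = 20)), "at least one")
})

test_that("a forced single-path profile scores exactly log2(20) bits", {
  m <- matrix(0, 20, 1)
  m["A" == aminoAcids(), 1] <- 1
  hmm <- buildProfile(m)
  expect_equal(forwardScore(hmm, "A"), log2(20))
  expect_equal(viterbiScore(hmm, "A"), log2(20))
  expect_equal(bruteForceScore(hmm, "A", mode = "sum"), log2(20))
  expect_equal(bruteForceScore(hmm, "A", mode = "max"), log2(20))
})

test_that("DP scores agree with path enumeration on the worked QF example", {
  hmm <- buildProfile(simulateReadout("QF", DeviceConfig(pMax = 0.5)))
  expect_equal(forwardScore(hmm, "QF"), bruteForceScore(hmm, "QF", mode = "sum"),
               tolerance = 1e-9)
  expect_equal(viterbiScore(hmm, "QF"), bruteForceScore(hmm, "QF", mode = "max"),
               tolerance = 1e-9)
  expect_lt(viterbiScore(hmm, "QF"), forwardScore(hmm, "QF"))
})

test_that("DP matches the enumeration oracle on random instances", {
  set.seed(2024)
  for (trial in 1:60) {
    Lq <- sample(1:4, 1)
    Lt <- sample(1:5, 1)
    mode <- sample(c("glocal-query/local-target",
                     "local-query/local-target"), 1)
    hmm <- buildProfile(randomEmissions(Lq),
                        ProfileParams(background = randomBackground()),
                        alignmentMode = mode)
    tg <- randomPeptide(Lt)
    expect_equal(forwardScore(hmm, tg),
                 bruteForceScore(hmm, tg, mode = "sum"), tolerance = 1e-9)
    expect_equal(viterbiScore(hmm, tg),
                 bruteForceScore(hmm, tg, mode = "max"), tolerance = 1e-9)
  }
})

test_that("oracle preconditions and score ordering hold", {
  hmm <- buildProfile(randomEmissions(6))
  expect_error(bruteForceScore(hmm, "ACD"), "too large")
  hmm2 <- buildProfile(randomEmissions(2))
  expect_error(bruteForceScore(hmm2, "ACDEFGH"), "too large")
  set.seed(3)
  for (trial in 1:10) {
    hmm <- buildProfile(randomEmissions(sample(2:8, 1)))
    tg <- randomPeptide(sample(3:12, 1))
    expect_lte(viterbiScore(hmm, tg), forwardScore(hmm, tg) + 1e-9)
  }
})

test_that("scores are composition-neutral when emissions equal background", {
  # uniform emissions + uniform background: emission odds cancel exactly,
  # leaving only path structure, which depends on target length alone
  hmm <- buildProfile(matrix(1 / 20, 20, 5))
  set.seed(6)
  lens <- c(5, 9, 9, 14, 14)
  scores <- vapply(lens, function(L) forwardScore(hmm, randomPeptide(L)),
                   numeric(1))
  expect_identical(scores[2], scores[3])
  expect_identical(scores[4], scores[5])
  expect_false(scores[1] == scores[2])
})

test_that("perfect-signal profiles strictly prefer their true sequence", {
  set.seed(10)
  pep <- randomPeptide(30)
  hmm <- buildProfile(readoutMatrix(simulateReadout(pep, DeviceConfig(1))))
  sTrue <- forwardScore(hmm, pep)
  expect_true(is.finite(sTrue))
  for (trial in 1:10) {
    mutated <- strsplit(pep, "")[[1]]
    pos <- sample(30, sample(1:5, 1))
    mutated[pos] <- vapply(mutated[pos], function(a)
      sample(setdiff(aminoAcids(), a), 1), character(1))
    expect_lt(forwardScore(hmm, paste(mutated, collapse = "")), sTrue)
  }
})

test_that("long-sequence scoring stays finite and stable", {
  set.seed(11)
  pep <- randomPeptide(1200)
  bg <- humanLikeBackground()
  hmm <- buildProfile(readoutMatrix(simulateReadout(pep, DeviceConfig(0.9))),
                      ProfileParams(background = bg))
  s <- forwardScore(hmm, pep)
  expect_true(is.finite(s))
  expect_gt(s, 1000)  # ~4 bits per well-resolved position
  # an unrelated same-length sequence scores far below the source
  expect_lt(forwardScore(hmm, randomPeptide(1200)), s / 2)
})
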