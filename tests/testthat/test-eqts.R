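test_that("system construction sorts records and validates", {
  sys <- enhancedQuartetSystem(
    ground = c("d", "c", "b", "a", "e"),
    quartets = c("a,b|d,e", "a,b|c,d"),
    gamma = c(2L, 0L),
    nuNear = c("PLAIN", "AUG"),
    nuFar = c("AUG", "PLAIN"))
  expect_identical(eqtsGround(sys), c("a", "b", "c", "d", "e"))
  expect_identical(eqtsQuartets(sys), c("a,b|c,d", "a,b|d,e"))
  expect_identical(gammaOf(sys, "a,b|d,e"), 2L)
  expect_identical(gammaOf(sys, "a,c|d,e"), -1L)
  expect_error(medianStatus(sys, "a,c|d,e", c("a", "c", "d")), "absent")
})

test_that("medianStatus follows the missing-taxon rule", {
  sys <- enhancedQuartetSystem(letters[1:4], "a,b|c,d", 0L, "AUG", "PLAIN")
  ## triples containing the first pair name the pair-1-side median
  expect_identical(medianStatus(sys, "a,b|c,d", c("a", "b", "c")), "AUG")
  expect_identical(medianStatus(sys, "a,b|c,d", c("a", "b", "d")), "AUG")
  expect_identical(medianStatus(sys, "a,b|c,d", c("a", "c", "d")), "PLAIN")
  expect_identical(medianStatus(sys, "a,b|c,d", c("b", "c", "d")), "PLAIN")
  expect_error(medianStatus(sys, "a,b|c,d", c("a", "b", "x")), "three")
})

test_that("TSV IO round-trips and rejects malformed files", {
  sys <- inducedEQTS(caterpillar5())
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  writeEQTS(sys, path)
  expect_true(eqtsEqual(readEQTS(path), sys))
  expect_error(readEQTS(textConnection("a\tb")), "#EQTS")
  expect_error(readEQTS(textConnection(c("#EQTS v1", "x\ty"))),
               "no quartet rows|bad column header")
  hdr <- "a\tb\tc\td\tgamma\tnu_ab\tnu_cd"
  expect_error(readEQTS(textConnection(c("#EQTS v1", hdr,
                                         "2\t1\t4\t5\t0\t0\t0"))),
               "canonical")
  expect_error(readEQTS(textConnection(c("#EQTS v1", hdr,
                                         "1\t2\t4\t5\t0\t0\t9"))),
               "marks")
  expect_error(readEQTS(textConnection(c("#EQTS v1", hdr,
                                         "1\t2\t4\t5\t-1\t0\t0"))),
               "negative")
})

test_that("induced systems satisfy the six properties", {
  for (seed in 51:70) {
    at <- randomAugmentedTree(5 + (seed %% 5), pAug = 0.4, seed = seed)
    expect_true(reportPasses(checkProperties(inducedEQTS(at))))
  }
})

test_that("augmentation points of induced systems are supported", {
  sys <- inducedEQTS(caterpillar5())
  sup <- isSupported(sys, "1,2|4,5", 1)
  expect_true(isTRUE(sup))
  w <- attr(sup, "witness")
  expect_identical(unname(w["z"]), "3")
  expect_error(isSupported(sys, "1,2|4,5", 2), "out of range")
  expect_error(isSupported(sys, "1,3|2,4", 1), "absent")
})

test_that("reconstruction inverts the encoding", {
  at <- caterpillar5()
  expect_true(augmentationEquivalent(
    reconstructAugmentedTree(inducedEQTS(at)), at))
  for (seed in 71:85) {
    at <- randomAugmentedTree(5 + (seed %% 5), pAug = 0.5, seed = seed)
    rec <- reconstructAugmentedTree(inducedEQTS(at))
    expect_true(augmentationEquivalent(rec, at))
  }
})

test_that("reconstruction rejects every shipped counterexample", {
  for (nm in independenceFixture()) {
    expect_error(reconstructAugmentedTree(independenceFixture(nm)))
  }
})

test_that("eqtsEqual is exact record equality", {
  a <- inducedEQTS(caterpillar5())
  expect_true(eqtsEqual(a, a))
  b <- enhancedQuartetSystem(eqtsGround(a), eqtsQuartets(a),
                             c(0L, 0L, 1L, 0L, 1L),
                             a@nuNear, a@nuFar)
  expect_false(eqtsEqual(a, b))
})
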