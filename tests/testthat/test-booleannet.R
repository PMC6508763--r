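test_that("quadrant counting drops intermediates and missings", {
  A <- c(0L, 0L, 2L, 2L)
  B <- c(0L, 2L, 0L, 2L)
  expect_identical(countQuadrants(A, B),
                   c(a00 = 1L, a01 = 1L, a10 = 1L, a11 = 1L, total = 4L))
  # intermediate in either gene excludes the sample
  expect_identical(countQuadrants(c(0L, 1L, 2L), c(2L, 2L, 2L))[["total"]], 2L)
  # missing likewise
  expect_identical(countQuadrants(c(0L, NA, 2L), c(2L, 2L, 2L))[["total"]], 2L)
  expect_error(countQuadrants(c(0L, 2L), c(0L, 2L, 2L)), "length")
})

test_that("quadrant counts always sum to the total", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:100, 1)
    A <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE)
    B <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE)
    cnt <- countQuadrants(A, B)
    expect_identical(sum(cnt[1:4]), cnt[["total"]])
  }
})

test_that("quadrant test reproduces the hand-computed statistics", {
  q <- quadrantTest(c(a00 = 40, a01 = 0, a10 = 30, a11 = 30), "01")
  expect_equal(q$expected, 12)          # R=40, C=30, E=40*30/100
  expect_equal(q$statistic, 12 / sqrt(12))
  expect_equal(q$error_rate, 0)
  expect_true(q$sparse)

  # perfect independence: O = E so the statistic vanishes
  q2 <- quadrantTest(c(a00 = 25, a01 = 25, a10 = 25, a11 = 25), "01")
  expect_equal(q2$statistic, 0)
  expect_equal(q2$error_rate, 0.5)
  expect_false(q2$sparse)

  # zero margin: untestable, never sparse
  q3 <- quadrantTest(c(a00 = 0, a01 = 0, a10 = 10, a11 = 10), "01")
  expect_true(is.na(q3$statistic))
  expect_false(q3$sparse)
})

test_that("decreasing the observed count never decreases the statistic", {
  # tables sharing margins R = 40 (A low), C = 30 (B high), total = 100,
  # with the 01 quadrant's observed count o sweeping 0..12
  stats <- sapply(0:12, function(o) {
    quadrantTest(c(a00 = 40 - o, a01 = o, a10 = 30 + o, a11 = 30 - o),
                 "01")$statistic
  })
  expect_true(all(diff(stats) < 0))  # strictly worse as o grows
})

test_that("classifier maps sparse patterns onto the six classes", {
  expect_identical(classifyPair(c(a00 = 40, a01 = 0, a10 = 30, a11 = 30)), "lolo")
  expect_identical(classifyPair(c(a00 = 0, a01 = 40, a10 = 30, a11 = 30)), "lohi")
  expect_identical(classifyPair(c(a00 = 30, a01 = 30, a10 = 40, a11 = 0)), "hilo")
  expect_identical(classifyPair(c(a00 = 30, a01 = 30, a10 = 0, a11 = 40)), "hihi")
  expect_identical(classifyPair(c(a00 = 50, a01 = 0, a10 = 0, a11 = 50)), "eqv")
  expect_identical(classifyPair(c(a00 = 0, a01 = 50, a10 = 50, a11 = 0)), "opo")
  expect_identical(classifyPair(c(a00 = 25, a01 = 25, a10 = 25, a11 = 25)), "none")
})

test_that("classifier agrees with the brute-force oracle on random tables", {
  set.seed(17)
  for (i in 1:1000) {
    cnt <- randomCountTable()
    expect_identical(
      classifyPair(cnt),
      oracleClassify(cnt[["a00"]], cnt[["a01"]], cnt[["a10"]], cnt[["a11"]])
    )
  }
})

test_that("order reversal maps classes by contraposition", {
  swapMap <- c(lolo = "hihi", lohi = "lohi", hilo = "hilo", hihi = "lolo",
               eqv = "eqv", opo = "opo", none = "none")
  set.seed(23)
  for (i in 1:1000) {
    cnt <- randomCountTable()
    fwd <- classifyPair(cnt)
    # swapping genes transposes the table: a01 <-> a10
    rev <- classifyPair(c(a00 = cnt[["a00"]], a01 = cnt[["a10"]],
                          a10 = cnt[["a01"]], a11 = cnt[["a11"]]))
    expect_identical(rev, unname(swapMap[fwd]))
  }
})

test_that("negating gene B permutes the classes consistently", {
  negBMap <- c(lolo = "lohi", lohi = "lolo", hilo = "hihi", hihi = "hilo",
               eqv = "opo", opo = "eqv", none = "none")
  set.seed(29)
  for (i in 1:500) {
    cnt <- randomCountTable()
    fwd <- classifyPair(cnt)
    # negating B swaps its low and high columns: a00 <-> a01, a10 <-> a11
    neg <- classifyPair(c(a00 = cnt[["a01"]], a01 = cnt[["a00"]],
                          a10 = cnt[["a11"]], a11 = cnt[["a10"]]))
    expect_identical(neg, unname(negBMap[fwd]))
  }
})

test_that("symmetric classes require both diagonal quadrants individually", {
  set.seed(31)
  for (i in 1:400) {
    cnt <- randomCountTable()
    rel <- classifyPair(cnt)
    if (rel == "eqv") {
      expect_true(quadrantTest(cnt, "01")$sparse)
      expect_true(quadrantTest(cnt, "10")$sparse)
    } else if (rel == "opo") {
      expect_true(quadrantTest(cnt, "00")$sparse)
      expect_true(quadrantTest(cnt, "11")$sparse)
    }
  }
})

test_that("network building stores symmetric classes in both orders", {
  m <- toyMatrix()
  net <- buildNetwork(discretize(m, minLow = 2, minHigh = 2))
  ed <- edges(net)
  eqv <- ed[ed$relationship == "eqv", ]
  expect_identical(nrow(eqv), 2L)
  expect_setequal(paste(eqv$geneA, eqv$geneB),
                  c("gA gB", "gB gA"))
  expect_false("gF" %in% networkGenes(net))
})

test_that("a planted lolo pair is stored with its hihi contrapositive", {
  pp <- data.frame(geneA = "A1", geneB = "B1",
                   relationship = "lolo", leakage = 0)
  sim <- generateExpression(generatorSpec(nSamples = 300, nDynamic = 2,
                                          nFlat = 0, plantedPairs = pp,
                                          seed = 91))
  net <- buildNetwork(discretize(sim$matrix))
  ed <- edges(net)
  expect_identical(ed$relationship[ed$geneA == "A1" & ed$geneB == "B1"], "lolo")
  expect_identical(ed$relationship[ed$geneA == "B1" & ed$geneB == "A1"], "hihi")
})

test_that("independent genes produce an empty network", {
  probs <- matrix(0.5, 8, 1, dimnames = list(sprintf("DG%03d", 1:8), "bulk"))
  hits <- vapply(1:20, function(s) {
    sim <- generateExpression(generatorSpec(
      nSamples = 200, tissueProps = c(bulk = 1), nDynamic = 8, nFlat = 0,
      activationProbs = probs, seed = 1000 + s))
    nrow(edges(buildNetwork(discretize(sim$matrix))))
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("build parameters are recorded in the network", {
  m <- toyMatrix()
  net <- buildNetwork(discretize(m, margin = 0.4, minLow = 2, minHigh = 2),
                      sMin = 2.5, eMax = 0.2)
  expect_equal(net@params$margin, 0.4)
  expect_equal(net@params$sMin, 2.5)
  expect_equal(net@params$eMax, 0.2)
})
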