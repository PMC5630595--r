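test_that("EC50 weights are linear in log potency and clamped", {
  expect_equal(ec50Weight(-9), 1.0)
  expect_equal(ec50Weight(0), 0.0)
  expect_equal(ec50Weight(-4.5), 0.5)
  expect_equal(ec50Weight(NA), 0)       # negative screen
  expect_equal(ec50Weight(c(-9, NA, -3)), c(1, 0, 1 / 3))
})

makeScreenDf <- function(nCan, kCan, nNon, kNon, ec50 = -9) {
  data.frame(
    receptor = rep(c("CAN", "NON"), c(nCan, nNon)),
    odorant = "o",
    log10Ec50 = c(rep(ec50, kCan), rep(NA, nCan - kCan),
                  rep(ec50, kNon), rep(NA, nNon - kNon)),
    stringsAsFactors = FALSE)
}
canStatus <- c(CAN = "canonical", NON = "non_canonical")

test_that("activity statistics reproduce the published DRY contingency", {
  st <- positionActivityStats(makeScreenDf(8815, 102, 1089, 1), canStatus)
  expect_equal(st$nCanonicalPositive, 102)
  expect_equal(st$nNonCanonicalPositive, 1)
  expect_gte(st$foldEnrichment, 12)
  expect_equal(st$foldEnrichment, (102 / 8815) / (1 / 1089),
               tolerance = 1e-12)
  expect_gte(st$hypergeomP, 7.5e-5)
  expect_lte(st$hypergeomP, 8.5e-5)
})

test_that("equal positive rates give unit fold enrichment", {
  st <- positionActivityStats(makeScreenDf(100, 10, 50, 5), canStatus)
  expect_equal(st$foldEnrichment, 1)
  st0 <- positionActivityStats(makeScreenDf(100, 10, 50, 0), canStatus)
  expect_equal(st0$foldEnrichment, Inf)
})

test_that("the hypergeometric tail equals exact enumeration", {
  # N=10, K=5 positives, n=4 non-canonical draws, k=1 -> 55/210
  st <- positionActivityStats(makeScreenDf(6, 4, 4, 1), canStatus)
  expect_equal(st$hypergeomP, 55 / 210, tolerance = 1e-12)
  # enumeration oracle on a population of <= 30
  enumTail <- function(N, K, n, k) {
    tot <- 0
    for (i in 0:k) tot <- tot + choose(K, i) * choose(N - K, n - i)
    tot / choose(N, n)
  }
  for (case in list(c(20, 7, 6, 2), c(30, 12, 10, 3), c(25, 5, 8, 0))) {
    N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
    st <- positionActivityStats(
      makeScreenDf(N - n, K - k, n, k), canStatus)
    expect_equal(st$hypergeomP, enumTail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("weighted and unweighted counts agree at full potency", {
  st <- positionActivityStats(makeScreenDf(50, 8, 20, 2, ec50 = -9),
                              canStatus)
  expect_equal(st$weightedCanonicalPositive, st$nCanonicalPositive)
  expect_equal(st$weightedNonCanonicalPositive, st$nNonCanonicalPositive)
  stHalf <- positionActivityStats(makeScreenDf(50, 8, 20, 2, ec50 = -4.5),
                                  canStatus)
  expect_equal(stHalf$weightedCanonicalPositive, 4)
})

test_that("unknown-status receptors are dropped from the contingency", {
  tb <- makeScreenDf(10, 2, 5, 1)
  tb <- rbind(tb, data.frame(receptor = "MYST", odorant = "o",
                             log10Ec50 = -9))
  st <- positionActivityStats(tb, c(canStatus, MYST = "unknown"))
  expect_equal(st$nCanonicalScreens + st$nNonCanonicalScreens, 15)
})

test_that("odor responses average EC50 weight over allele copies", {
  screenDf <- data.frame(
    receptor = c("R1", "R2", "R1"),
    odorant = c("od1", "od1", "od2"),
    log10Ec50 = c(-7.2, -9, NA),   # R1 binds od1 (w=0.8), R2 binds od1
    stringsAsFactors = FALSE)
  lof <- matrix(0L, 2, 3, dimnames = list(c("R1", "R2"),
                                          c("I1", "I2", "I3")))
  lof["R1", "I2"] <- 1L                 # heterozygous LoF in R1
  lof["R1", "I3"] <- 2L; lof["R2", "I3"] <- 2L  # homozygous everywhere
  resp <- individualOdorResponse(lof, screenDf)
  # I1 no LoF: mean of weights (0.8 + 1)/2
  expect_equal(resp["od1", "I1"], 0.9)
  # I2 het in R1: (0.8/2 + 1)/2
  expect_equal(resp["od1", "I2"], 0.7)
  # I3 homozygous LoF in every binding receptor -> anosmia
  expect_equal(resp["od1", "I3"], 0)
  # odorant with no positive screen -> undefined
  expect_true(is.na(resp["od2", "I1"]))
})

test_that("single heterozygous receptor halves the weight", {
  screenDf <- data.frame(receptor = "R1", odorant = "od",
                         log10Ec50 = -7.2, stringsAsFactors = FALSE)
  lof <- matrix(c(0L, 1L, 2L), 1, 3,
                dimnames = list("R1", c("I1", "I2", "I3")))
  resp <- individualOdorResponse(lof, screenDf)
  expect_equal(unname(resp["od", ]), c(0.8, 0.4, 0))
})

test_that("responses are monotone non-increasing in LoF alleles", {
  set.seed(4)
  screenDf <- data.frame(
    receptor = sample(sprintf("R%d", 1:6), 20, replace = TRUE),
    odorant = sample(c("a", "b", "c"), 20, replace = TRUE),
    log10Ec50 = runif(20, -9, -3), stringsAsFactors = FALSE)
  screenDf <- screenDf[!duplicated(screenDf[1:2]), ]
  for (trial in 1:5) {
    lof <- matrix(sample(0:2, 6, replace = TRUE), 6, 1,
                  dimnames = list(sprintf("R%d", 1:6), "I"))
    more <- lof
    i <- sample(which(more < 2L), 1)
    more[i] <- more[i] + 1L
    r1 <- individualOdorResponse(lof, screenDf)
    r2 <- individualOdorResponse(more, screenDf)
    ok <- !is.na(r1[, 1])
    expect_true(all(r2[ok, 1] <= r1[ok, 1] + 1e-12))
  }
})

test_that("population odor matrix normalizes to the maximum group", {
  resp <- matrix(c(0.2, 0.4, 0.1,
                   0,   0,   0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("od1", "od2"),
                                 c("I1", "I2", "I3")))
  groups <- c("A", "B", "B")
  m <- populationOdorMatrix(resp, groups)
  expect_equal(m["od1", "A"], 0.2 / 0.25)
  expect_equal(m["od1", "B"], 1.0)
  expect_equal(unname(m["od2", ]), c(0, 0))   # all-zero rows stay 0
  # single group: every non-zero row is 1
  m1 <- populationOdorMatrix(resp, c("G", "G", "G"))
  expect_equal(unname(m1[, 1]), c(1, 0))
  # three-group hand computation
  resp3 <- matrix(c(0.1, 0.3, 0.6), 1,
                  dimnames = list("od", c("I1", "I2", "I3")))
  m3 <- populationOdorMatrix(resp3, c("A", "B", "C"))
  expect_equal(unname(m3["od", c("A", "B", "C")]), c(1 / 6, 0.5, 1))
})

test_that("DRY-like variant rows select missense at the conserved column", {
  vs <- toyVariantSet()
  idx <- domainIndex(list(toyAlignment()))
  rows <- dryVariantRows(vs, idx, "TOY", 2L)
  v <- variantInfo(vs)[rows, ]
  expect_setequal(paste(v$protein, v$position),
                  c("P1 4", "P2 3", "P3 2"))
  lof <- lofAlleleCounts(vs, dryVariants = rows)
  # I2: P2:3 het (1) + P3:2 hom (2) -> capped per receptor
  expect_equal(lof["P3", "I2"], 2L)
  expect_equal(lof["P1", "I1"], 1L)
})
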