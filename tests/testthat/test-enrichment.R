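test_that("expected counts follow the uniform-placement formula", {
  expect_equal(expectedCount(1000, 10000, 10, 1), 1.0)
  expect_equal(expectedCount(1000, 10000, 10, 50), 50.0)
  expect_error(expectedCount(10, 0, 1, 1), "proteomeLength")
})

test_that("log-odds are base 2 with an -Inf marker at zero observed", {
  expect_equal(logOdds(8, 8), 0)
  expect_equal(logOdds(16, 8), 1)       # the enrichment threshold
  expect_equal(logOdds(0, 5), -Inf)
  expect_error(logOdds(1, 0), "expected")
  # strictly increasing in observed at fixed expected
  lo <- logOdds(1:50, 7.3)
  expect_true(all(diff(lo) > 0))
})

test_that("binomial p-values match the exact summation oracle", {
  expect_equal(binomialPvalue(0, 10, 0.3), 1.0)
  expect_equal(binomialPvalue(2, 2, 0.5), 0.25)
  # direct summation: sum_{i>=5} C(10,i) 0.1^i 0.9^(10-i)
  oracle <- sum(vapply(5:10, function(i)
    choose(10, i) * 0.1^i * 0.9^(10 - i), 0))
  expect_equal(binomialPvalue(5, 10, 0.1), oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.634937e-3, tolerance = 1e-6)
})

test_that("BH correction matches the hand-computed step-up", {
  expect_equal(bhFdr(0.037), 0.037)
  # p*m/rank = (.03, .03, .03); cumulative min from the largest
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # order-preserving and equal to a literal step-up implementation
  set.seed(1)
  p <- runif(40)^2
  stepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(m); out[o] <- pmin(q, 1); out
  }
  expect_equal(bhFdr(p), stepUp(p), tolerance = 1e-12)
})

test_that("shuffle prior is uniform within the protein", {
  # P3 of the toy set is 10 residues long with a 6-column domain at 1..6;
  # restrict to a single-residue target: column 2 is residue 2 in P3 only
  vs <- toyVariantSet()
  # keep only the P3 variant so every allele shuffles within P3
  keep <- variantInfo(vs)$protein == "P3"
  vsP3 <- new("VariantSet", variants = variantInfo(vs)[keep, ],
              geno = genotypes(vs)[keep, , drop = FALSE],
              cohort = cohort(vs))
  members <- data.frame(protein = "P3", start = 2L, end = 2L,
                        stringsAsFactors = FALSE)
  one <- new("FamilyAlignment", family = "ONE", modelLength = 1L,
             members = members, columnMaps = list(P3 = 1L),
             residueMatrix = matrix("R", 1, 1), consensus = data.frame())
  prot <- new("Proteome", alignments = list(ONE = one),
              proteins = toyProteins(),
              cds = Biostrings::DNAStringSet(
                vapply(as.character(toyProteins()), function(s)
                  paste(rep("GCT", nchar(s)), collapse = ""), "")))
  pr <- shufflePrior(vsP3, prot, "ONE", 1L, nShuffles = 4000L, seed = 5L)
  expect_equal(as.numeric(pr), 1 / 10, tolerance = 0.15)
  # reproducible for a fixed seed
  pr2 <- shufflePrior(vsP3, prot, "ONE", 1L, nShuffles = 4000L, seed = 5L)
  expect_identical(as.numeric(pr), as.numeric(pr2))
})

test_that("shuffle prior converges to the analytic landing probability", {
  cfg <- smallConfig(seed = 23L)
  prot <- generateProteome(cfg)
  vs <- generateVariants(prot, generateCohort(cfg), cfg)
  fam <- "FAM01"; col <- 10L
  # analytic: sum_p alleles_p * (residues of p mapping to target) / L_p,
  # over total alleles
  idx <- domainIndex(prot)
  inst <- idx$instances
  v <- variantInfo(vs)
  pooled <- alleleCounts(vs)
  mis <- v$consequence == "missense"
  perProt <- tapply(pooled[mis], v$protein[mis], sum)
  lens <- setNames(Biostrings::width(prot@proteins),
                   names(prot@proteins))
  expected <- 0
  for (p in names(perProt)) {
    nMapped <- 0
    for (i in which(inst$protein == p & inst$family == fam))
      nMapped <- nMapped + sum(!is.na(idx$maps[[i]]) &
                               idx$maps[[i]] == col)
    expected <- expected + perProt[[p]] * nMapped / lens[[p]]
  }
  expected <- expected / sum(pooled[mis])
  pr <- shufflePrior(vs, prot, fam, col, nShuffles = 3000L, seed = 2L)
  expect_equal(as.numeric(pr), expected, tolerance = 0.1)
})

test_that("column observed counts conserve the family totals", {
  cfg <- smallConfig(seed = 31L)
  prot <- generateProteome(cfg)
  vs <- generateVariants(prot, generateCohort(cfg), cfg)
  enr <- positionEnrichment(vs, prot, nShuffles = 5L, seed = 1L)
  byFam <- tapply(enr$columns$observed, enr$columns$family, sum)
  expect_equal(as.numeric(byFam[enr$families$family]),
               enr$families$observed)
})

test_that("toy-proteome counts match the brute-force placement oracle", {
  cfg <- syntheticConfig(nIndividuals = 20L, nFamilies = 2L,
                         membersPerFamily = c(2L, 2L),
                         modelLength = c(10L, 15L),
                         baseVariantRate = 5e-3,
                         plantedPositions = data.frame(family = integer(),
                                                       column = integer(),
                                                       multiplier = numeric()),
                         seed = 3L)
  prot <- generateProteome(cfg)
  vs <- generateVariants(prot, generateCohort(cfg), cfg)
  enr <- positionEnrichment(vs, prot, nShuffles = 2L, seed = 1L)
  oracle <- bruteForceColumnCounts(vs, prot)
  for (fam in names(oracle)) {
    got <- enr$columns[enr$columns$family == fam, ]
    expect_equal(got$observed, oracle[[fam]]$observed, tolerance = 1e-12)
    expect_equal(got$expected, oracle[[fam]]$expected, tolerance = 1e-12)
    pos <- got$observed > 0
    expect_equal(got$logOdds[pos],
                 log2(oracle[[fam]]$observed[pos] /
                      oracle[[fam]]$expected[pos]), tolerance = 1e-12)
  }
})

test_that("enrichment filters apply the inclusive thresholds", {
  base <- data.frame(family = "F", column = 1:4,
                     observed = c(49, 50, 100, 100),
                     expected = c(4.9, 4.9, 50, 50),
                     logOdds = c(3, 1.0, 1.0, 0.99),
                     qValue = c(0.001, 0.01, 0.01, 0.001),
                     nGenesWithVariants = c(20, 20, 20, 20))
  out <- enrichedPositions(base)
  # row 1 fails both count floors despite q; rows 2-3 are exactly at the
  # inclusive thresholds; row 4 fails log-odds
  expect_equal(out$column, c(2L, 3L))
  # the gene floor is configurable
  base$nGenesWithVariants <- 5
  expect_equal(nrow(enrichedPositions(base)), 0L)
  expect_equal(nrow(enrichedPositions(base,
                                      minMembersWithVariants = NA)), 2L)
})
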