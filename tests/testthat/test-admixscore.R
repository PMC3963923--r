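test_that("ancestral frequency estimation matches stratified counts and EM", {
  # phase-unambiguous data: closed-form stratified counts, no EM needed
  g <- c(2L, 1L, 0L, 1L, 0L, 2L)
  a <- c(2L, 2L, 2L, 0L, 0L, 0L)
  fr <- estimateAncestralFreqs(g, a, controlsOnly = FALSE)
  expect_equal(unname(fr["pA"]), 3 / 6)
  expect_equal(unname(fr["pE"]), 3 / 6)

  # one background absent errors
  expect_error(estimateAncestralFreqs(c(1L, 2L), c(2L, 2L),
                                      controlsOnly = FALSE), "backgrounds")

  # EM recovery of (0.42, 0.51) at n = 5000
  set.seed(41)
  d <- simulateScoreMarker(0, 5000, c(0.82, 0.1), pA = 0.42, pE = 0.51)
  fr2 <- estimateAncestralFreqs(d$g, d$a, d$status, controlsOnly = TRUE)
  seA <- sqrt(0.42 * 0.58 / sum(d$a))
  seE <- sqrt(0.51 * 0.49 / sum(2 - d$a))
  expect_lt(abs(fr2["pA"] - 0.42), 3 * seA)
  expect_lt(abs(fr2["pE"] - 0.51), 3 * seE)
})

test_that("ADM is exactly null at the balanced configuration", {
  sc <- admScore(rep(1L, 50), rep(0.5, 50))
  expect_equal(sc$statistic, 0, tolerance = 1e-8)
  expect_equal(sc$p, 1)
  expect_equal(sc$lambdaHat, 1, tolerance = 1e-4)
  expect_error(admScore(integer(), numeric()), "no informative")
  # boundary-theta individuals are skipped, not fatal
  sc2 <- admScore(c(2L, rep(1L, 30)), c(1, rep(0.5, 30)))
  expect_equal(sc2$statistic, 0, tolerance = 1e-8)
})

test_that("ADM recovers a simulated ancestry odds multiplier", {
  set.seed(42)
  lamHat <- replicate(40, {
    d <- simulateScoreMarker(1000, 0, c(0.82, 0.1), pA = 0.5, pE = 0.5,
                             r = 1, lambdaExtra = 1.3)
    admScore(d$a, d$theta)$lambdaHat
  })
  se <- sd(lamHat) / sqrt(length(lamHat))
  expect_lt(abs(mean(lamHat) - 1.3), 2 * se)
})

test_that("SNP1 with fixed equal frequencies matches a case-only binomial LRT", {
  # a in {0, 2}: haplotype origins are unambiguous, so with frequencies
  # held fixed the SNP1 LRT reduces to a case-haplotype binomial LRT with
  # the null success probability at the fixed frequency
  set.seed(43)
  n <- 400
  a <- rep(c(0L, 2L), n / 2)
  st <- rbinom(n, 1, 0.5)
  p <- 0.35
  g <- rbinom(n, 2, p)
  s1 <- snp1Score(g, a, st, pA = p, pE = p, profileFreqs = FALSE)
  caseAll <- sum(g[st == 1]); caseHap <- 2 * sum(st == 1)
  qHat <- caseAll / caseHap
  llCase <- function(q) caseAll * log(q) + (caseHap - caseAll) * log(1 - q)
  oracle <- 2 * (llCase(qHat) - llCase(p))
  expect_equal(s1$statistic, oracle, tolerance = 1e-6)
  # r-hat maps back to the case allele frequency: q = p r / (1 + (r-1) p)
  expect_equal(s1$rHat * p / (1 + (s1$rHat - 1) * p), qHat,
               tolerance = 1e-4)
  expect_error(snp1Score(rep(1L, 10), a[1:10], st[1:10]), "monomorphic")
  expect_error(snp1Score(g, a, st, pA = 0, pE = 1, profileFreqs = FALSE),
               "degenerate")
})

test_that("SNP1 recovers a simulated allelic odds ratio", {
  set.seed(44)
  rHat <- replicate(40, {
    d <- simulateScoreMarker(600, 600, c(0.82, 0.1), pA = 0.3, pE = 0.45,
                             r = 2)
    snp1Score(d$g, d$a, d$status)$rHat
  })
  se <- sd(rHat) / sqrt(length(rHat))
  expect_lt(abs(mean(rHat) - 2), 2 * se)
})

test_that("MIX collapses onto SNP1 when the frequency differential vanishes", {
  set.seed(45)
  d <- simulateScoreMarker(300, 300, c(0.8, 0.1), pA = 0.4, pE = 0.4,
                           r = 1.5)
  s1 <- snp1Score(d$g, d$a, d$status, pA = 0.4, pE = 0.4,
                  profileFreqs = FALSE)
  mx <- mixScore(d$g, d$a, d$status, d$theta, pA = 0.4, pE = 0.4,
                 profileFreqs = FALSE)
  expect_equal(mx$statistic, s1$statistic, tolerance = 1e-6)
  adm <- admScore(d$a[d$status == 1], d$theta[d$status == 1])
  dif <- diffScore(adm, s1, mx)
  expect_equal(dif$statistic, adm$statistic, tolerance = 1e-6)
})

test_that("constrained optimum agrees with a dense grid search", {
  set.seed(46)
  d <- simulateScoreMarker(400, 400, c(0.8, 0.1), pA = 0.2, pE = 0.55,
                           r = 1.8)
  mx <- mixScore(d$g, d$a, d$status, d$theta, pA = 0.2, pE = 0.55,
                 profileFreqs = FALSE)
  grid <- exp(seq(log(1 / 50), log(50), length.out = 200001))
  cells <- admixfine:::.cellCounts(d$g, d$a, d$status)
  isCase <- d$status == 1
  ll <- vapply(grid, function(r) {
    admixfine:::.snp1Loglik(r, cells, 0.2, 0.55) +
      admixfine:::.admLoglik(lambdaOf(r, 0.2, 0.55), d$a[isCase],
                             d$theta[isCase])
  }, numeric(1))
  expect_lt(abs(log(mx$rHat) - log(grid[which.max(ll)])), 1e-4)
})

test_that("a pure ancestry signal loads on DIFF, not MIX", {
  set.seed(47)
  reps <- replicate(40, {
    d <- simulateScoreMarker(500, 500, c(0.82, 0.1), pA = 0.3, pE = 0.55,
                             r = 1, lambdaExtra = 1.6)
    sc <- admixtureScores(d$g, d$a, d$status, d$theta)
    c(diff = sc@diff, mix = sc@mix)
  })
  expect_gt(median(reps["diff", ]), median(reps["mix", ]))
})

test_that("DIFF identity and non-negativity hold across random scenarios", {
  set.seed(48)
  for (i in 1:40) {
    r <- exp(runif(1, -0.7, 0.7))
    le <- exp(runif(1, -0.4, 0.4))
    pA <- runif(1, 0.05, 0.9); pE <- runif(1, 0.05, 0.9)
    d <- simulateScoreMarker(300, 300, c(0.8, 0.12), pA = pA, pE = pE,
                             r = r, lambdaExtra = le)
    if (var(d$g) == 0) next
    sc <- admixtureScores(d$g, d$a, d$status, d$theta)
    expect_lt(abs(sc@diff - (sc@adm + sc@snp1 - sc@mix)), 1e-8)
    expect_gte(sc@adm, 0); expect_gte(sc@snp1, 0)
    expect_gte(sc@mix, 0); expect_gte(sc@diff, 0)
    expect_lte(sc@mix, sc@adm + sc@snp1 + 1e-8)
  }
})

test_that("diffScore clips tolerable negatives and rejects real ones", {
  d0 <- diffScore(1.2, 0.8, 2.0)
  expect_equal(d0$statistic, 0)
  expect_equal(d0$p, 1)
  d1 <- diffScore(1.2, 0.8, 2.0 + 1e-9)
  expect_equal(d1$statistic, 0)
  expect_error(diffScore(1, 1, 3), "negative DIFF")
})

test_that("MIX outpowers SNP1 at a causal SNP with a large frequency gap", {
  # scenario: r = 1.5, pA = 0.09, pE = 0.65
  set.seed(49)
  stats <- replicate(60, {
    d <- simulateScoreMarker(500, 500, c(0.82, 0.1), pA = 0.09, pE = 0.65,
                             r = 1.5)
    sc <- admixtureScores(d$g, d$a, d$status, d$theta)
    c(mix = sc@mix, snp1 = sc@snp1)
  })
  expect_gt(mean(stats["mix", ]), mean(stats["snp1", ]))
})

test_that("subsample-averaged MIX is deterministic and collapses at n = 1", {
  co <- toyCohort(n = 150, nFam = 25, nMarkers = 10, seed = 81)
  s <- sampleInfo(co)
  nCa <- sum(s$status == 1); nCo <- sum(s$status == 0)
  ped <- cohortPedigree(co)
  rel <- pedigreeRelationship(ped)[s$id, s$id]
  pool <- unrelatedSubset(rel)
  pc <- length(intersect(pool, s$id[s$status == 1]))
  pu <- length(intersect(pool, s$id[s$status == 0]))
  sizes <- c(cases = pc, controls = pu)
  # drawing the whole unrelated pool makes the subsample deterministic
  set.seed(1)
  one <- averagedMix(co, "snp0003", nSamples = 1, subsampleSizes = sizes)
  ids <- pool
  j <- match(ids, s$id)
  i <- match("snp0003", markerInfo(co)$id)
  direct <- admixtureScores(genotypes(co)[i, j], localAncestry(co)[i, j],
                            s$status[j], s$theta[j], marker = "snp0003")
  expect_equal(one@mix, direct@mix, tolerance = 1e-10)
  expect_equal(one@diff, direct@diff, tolerance = 1e-10)

  set.seed(99)
  r1 <- averagedMix(co, "snp0003", nSamples = 5,
                    subsampleSizes = c(pc - 5, pu - 5))
  set.seed(99)
  r2 <- averagedMix(co, "snp0003", nSamples = 5,
                    subsampleSizes = c(pc - 5, pu - 5))
  expect_equal(r1@mix, r2@mix)
  expect_equal(r1@adm, r2@adm)
  expect_lt(abs(r1@diff - (r1@adm + r1@snp1 - r1@mix)), 1e-8)
  expect_error(averagedMix(co, "snp0003", nSamples = 2,
                           subsampleSizes = c(cases = 10000,
                                              controls = 10000)),
               "pool too small")
})

test_that("region boundaries follow the first/last significant marker", {
  expect_equal(regionBoundaries(c(10, 20, 30, 40, 50),
                                c(0.2, 0.01, 0.3, 0.04, 0.9)),
               c(start = 20, end = 40))
  expect_equal(regionBoundaries(1:4, rep(0.01, 4)),
               c(start = 1, end = 4))
  expect_null(regionBoundaries(1:4, rep(0.5, 4)))
  expect_error(regionBoundaries(1:3, c(0.1, 0.2)), "equal length")
})

test_that("the tiered screen applies both the p and confounding filters", {
  assoc <- data.frame(marker = c("a", "b", "c"), p = c(0.2, 0.01, 0.01))
  cf <- c(a = 0.01, b = 0.5, c = 0.02)
  expect_identical(tieredScreen(assoc, cf), "c")
  expect_identical(significanceTier(c(1e-9, 1e-6, 0.01, 0.5)),
                   c("genome-wide", "suggestive", "nominal", "ns"))
})
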