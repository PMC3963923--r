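test_that("haplotype ancestry honours absorbing and stationary cases", {
  pos <- sort(sample.int(1e8, 500))
  expect_equal(simulateLocalAncestry(1, pos), rep(1L, 500))
  expect_equal(simulateLocalAncestry(0, pos), rep(0L, 500))
  expect_error(simulateLocalAncestry(0.5, c(10, 5, 20)), "increasing")

  set.seed(21)
  # marginal P(African) = theta at every marker; per-haplotype means are
  # independent across haplotypes, so a t-type check applies
  means <- replicate(400, mean(simulateLocalAncestry(0.8, pos, 7)))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.8), 3 * se)
})

test_that("ancestry switch rate matches the Markov redraw model", {
  set.seed(22)
  pos <- seq(1, 1e8, length.out = 2000)  # 1 Morgan
  g <- 7; theta <- 0.7
  d <- diff(pos) * 1e-8
  expSwitches <- sum((1 - exp(-g * d)) * 2 * theta * (1 - theta))
  switches <- replicate(300, {
    h <- simulateLocalAncestry(theta, pos, g)
    sum(diff(h) != 0)
  })
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - expSwitches), 3 * se)
})

test_that("genotypes are consistent with ancestry-specific frequencies", {
  set.seed(23)
  ft <- data.frame(id = sprintf("s%02d", 1:20),
                   fAFR = rep(0.42, 20), fCEU = rep(0.51, 20))
  ft$fAFR[1] <- 1; ft$fCEU[1] <- 1    # fixed everywhere
  ft$fCEU[2] <- 0                     # allele absent on European haplotypes
  co <- simulateCohort(simConfig(nIndividuals = 2500, nFamilies = 0,
                                 nMarkers = 20, freqTable = ft, seed = 23))
  g <- genotypes(co); a <- localAncestry(co)
  expect_true(all(g[1, ] == 2L))
  # with fCEU = 0 the risk allele can only sit on African-origin haplotypes
  expect_true(all(g[2, ] <= a[2, ]))

  # allele frequency on African-ancestry haplotypes: phase-unambiguous
  # individuals (a = 2) give a binomial count oracle
  m <- 5
  hom <- a[m, ] == 2L
  nHap <- 2 * sum(hom)
  pHat <- sum(g[m, hom]) / nHap
  se <- sqrt(0.42 * 0.58 / nHap)
  expect_lt(abs(pHat - 0.42), 3 * se)

  # E[g | a] = a fAFR + (2 - a) fCEU, pooled over markers 3..20
  idx <- 3:20
  for (aa in 0:2) {
    sel <- a[idx, ] == aa
    nObs <- sum(sel)
    expG <- aa * 0.42 + (2 - aa) * 0.51
    se <- sqrt(2 * 0.5 * 0.5 / nObs)  # conservative Bernoulli-sum bound
    expect_lt(abs(mean(g[idx, ][sel]) - expG), 4 * se)
  }
})

test_that("theta Beta moment matching rejects impossible dispersion", {
  expect_error(simulateCohort(simConfig(nIndividuals = 10, nFamilies = 0,
                                        nMarkers = 5, thetaMean = 0.8,
                                        thetaSd = 0.45, seed = 1)),
               "incompatible")
})

test_that("phenotype assignment follows the logistic model", {
  set.seed(24)
  co <- toyCohort(n = 1200, nFam = 0, nMarkers = 10, seed = 31,
                  disease = diseaseModel(intercept = qlogis(0.5)))
  frac <- mean(sampleInfo(co)$status)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1200))

  # single causal marker log r = log 2: crude allelic OR from the collapsed
  # 2x2 allele-count table recovers 2
  ft <- data.frame(id = sprintf("s%02d", 1:5), fAFR = 0.4, fCEU = 0.4)
  dm <- diseaseModel(intercept = qlogis(0.4), causal = c(s03 = log(2)))
  co2 <- simulateCohort(simConfig(nIndividuals = 6000, nFamilies = 0,
                                  nMarkers = 5, freqTable = ft,
                                  disease = dm, seed = 32))
  g <- genotypes(co2)[3, ]; st <- sampleInfo(co2)$status
  tab <- c(a = sum(g[st == 1]), b = 2 * sum(st == 1) - sum(g[st == 1]),
           c = sum(g[st == 0]), d = 2 * sum(st == 0) - sum(g[st == 0]))
  orHat <- tab["a"] * tab["d"] / (tab["b"] * tab["c"])
  seLog <- sqrt(sum(1 / tab))
  expect_lt(abs(log(orHat) - log(2)), 3 * seLog)

  # subphenotype proportions among cases with follow-up
  co3 <- toyCohort(n = 3000, nFam = 0, nMarkers = 5, seed = 33)
  s <- sampleInfo(co3)
  sub <- s$subphenotype[s$status == 1 & !is.na(s$subphenotype)]
  nFu <- length(sub)
  probs <- c(resolved = 0.331, stage1_3 = 0.465, stage4 = 0.204)
  for (lab in names(probs)) {
    p <- probs[[lab]]
    expect_lt(abs(mean(sub == lab) - p), 3 * sqrt(p * (1 - p) / nFu))
  }
  expect_true(all(is.na(s$subphenotype[s$status == 0])))
})

test_that("non-finite linear predictor and missing causal marker error", {
  co <- toyCohort(n = 50, nFam = 0, nMarkers = 5, seed = 41)
  expect_error(assignPhenotypes(co, diseaseModel(causal = c(nope = 0.1))),
               "not present")
  bad <- diseaseModel()
  bad$intercept <- Inf
  expect_error(assignPhenotypes(co, bad), "finite|non-finite")
})

test_that("cohort files round-trip exactly and are seed-deterministic", {
  co <- toyCohort(n = 60, nFam = 10, nMarkers = 15, seed = 51,
                  missingRate = 0.05)
  expect_true(anyNA(genotypes(co)))
  d1 <- withr::local_tempdir()
  writeCohort(co, d1)
  # missing genotypes encoded as ./.
  vcfLines <- readLines(file.path(d1, "genotypes.vcf"))
  expect_true(any(grepl("\\./\\.", vcfLines)))
  back <- readCohort(d1)
  expect_identical(unname(genotypes(back)), unname(genotypes(co)))
  expect_identical(unname(localAncestry(back)), unname(localAncestry(co)))
  sA <- sampleInfo(co); sB <- sampleInfo(back)
  expect_identical(sB$status, sA$status)
  expect_identical(sB$subphenotype, sA$subphenotype)
  expect_equal(sB$theta, sA$theta)
  expect_identical(markerInfo(back)$id, markerInfo(co)$id)

  # identical seed => bitwise-identical files
  co2 <- toyCohort(n = 60, nFam = 10, nMarkers = 15, seed = 51,
                   missingRate = 0.05)
  d2 <- withr::local_tempdir()
  writeCohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("an empty cohort writes valid headers and zero records", {
  samples <- data.frame(id = c("A", "B"), familyId = c("A", "B"),
                        sex = c(1L, 2L), status = c(1L, 0L),
                        theta = c(0.5, 0.5))
  geno <- matrix(integer(), 0, 2)
  anc <- matrix(integer(), 0, 2)
  mk <- GenomicRanges::GRanges(id = character(), ref = character(),
                               alt = character())
  co <- AdmixedCohort(geno, anc, samples, mk)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  vcf <- readLines(file.path(d, "genotypes.vcf"))
  expect_identical(vcf[1], "##fileformat=VCFv4.2")
  expect_length(grep("^#CHROM", vcf), 1L)
  expect_length(grep("^[^#]", vcf), 0L)
})
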