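test_that("singleton clusters reduce the GEE to ordinary logistic ML", {
  set.seed(31)
  for (i in 1:10) {
    n <- 80
    X <- cbind(1, g = rbinom(n, 2, 0.4), z = rnorm(n))
    y <- rbinom(n, 1, plogis(X %*% c(-0.3, 0.5, 0.2)))
    fit <- geeLogistic(y, X, seq_len(n))
    ml <- suppressWarnings(glm.fit(X, y, family = binomial()))
    expect_lt(max(abs(fit$coef - ml$coefficients)), 1e-6)
  }
})

test_that("cluster-robust covariance matches hand and library oracles", {
  # 6 individuals, 3 clusters: hand-computed bread/meat sandwich
  y <- c(1, 0, 1, 1, 0, 0)
  X <- cbind(1, g = c(2, 1, 0, 1, 2, 0))
  cl <- c("a", "a", "b", "b", "c", "c")
  fit <- geeLogistic(y, X, cl)
  mu <- plogis(drop(X %*% fit$coef))
  bread <- solve(t(X) %*% (X * mu * (1 - mu)))
  sc <- X * (y - mu)
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    s <- colSums(sc[cl == g, , drop = FALSE])
    meat <- meat + s %*% t(s)
  }
  expect_equal(unname(fit$vcov), unname(bread %*% meat %*% bread),
               tolerance = 1e-10)

  skip_if_not_installed("sandwich")
  set.seed(32)
  n <- 150
  X2 <- cbind(1, g = rbinom(n, 2, 0.3), th = runif(n))
  y2 <- rbinom(n, 1, plogis(X2 %*% c(-0.5, 0.4, 0.3)))
  cl2 <- rep(1:50, each = 3)
  f2 <- geeLogistic(y2, X2, cl2)
  gl <- glm(y2 ~ X2 - 1, family = binomial)
  V <- sandwich::vcovCL(gl, cluster = cl2, type = "HC0", cadjust = FALSE)
  expect_equal(unname(f2$vcov), unname(V), tolerance = 1e-4)
})

test_that("a 2x2 collapse gives the closed-form log odds ratio", {
  a <- 37; b <- 63; c <- 21; d <- 79
  g <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  y <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  fit <- geeLogistic(y, cbind(1, genotype = g), seq_along(y))
  expect_lt(abs(fit$coef["genotype"] - log(a * d / (b * c))), 1e-6)
})

test_that("separation and rank deficiency raise informative errors", {
  y <- rep(c(0, 1), each = 20)
  X <- cbind(`(Intercept)` = 1, sep = y)  # perfect separation
  expect_error(geeLogistic(y, X, seq_along(y)), "separation")
  X2 <- cbind(a = rnorm(40), b = 0)
  X2 <- cbind(1, X2, dup = X2[, "a"])
  expect_error(geeLogistic(y, X2, seq_along(y)), "rank deficient")
})

test_that("snpAssociation recovers a simulated multiplicative effect", {
  ft <- data.frame(id = sprintf("s%02d", 1:5), fAFR = 0.35, fCEU = 0.35)
  dm <- diseaseModel(intercept = qlogis(0.35), causal = c(s03 = log(2)))
  co <- simulateCohort(simConfig(nIndividuals = 5000, nFamilies = 500,
                                 nMarkers = 5, freqTable = ft, disease = dm,
                                 seed = 71))
  res <- snpAssociation(co, "s03")
  expect_lt(abs(res$beta - log(2)), 2 * res$se)
  expect_true(res$ciLow <= res$or && res$or <= res$ciHigh)
  # monomorphic marker errors
  co2 <- toyCohort(n = 50, nFam = 0, nMarkers = 5, seed = 72,
                   freqTable = data.frame(id = sprintf("s%02d", 1:5),
                                          fAFR = c(1, 0.4, 0.4, 0.4, 0.4),
                                          fCEU = c(1, 0.4, 0.4, 0.4, 0.4)))
  expect_error(snpAssociation(co2, "s01"), "monomorphic")
})

test_that("null markers give nominal Wald CI coverage", {
  set.seed(33)
  covered <- replicate(400, {
    d <- simulateScoreMarker(150, 150, c(0.8, 0.1), pA = 0.4, pE = 0.4,
                             r = 1)
    co <- manualCohort(matrix(d$g, 1), matrix(d$a, 1), d$status,
                       theta = d$theta)
    res <- snpAssociation(co, "m001", codeMinor = FALSE)
    res$ciLow <= 1 && 1 <= res$ciHigh
  })
  p <- mean(covered)
  expect_lt(abs(p - 0.95), 3 * sqrt(0.95 * 0.05 / 400))
})

test_that("confounding ratio is plain arithmetic with a zero guard", {
  expect_equal(confoundingRatio(0.7, 0.7), 0)
  expect_equal(confoundingRatio(log(1.5), log(3)),
               abs(log(1.5) - log(3)) / log(3))
  expect_equal(round(confoundingRatio(log(1.5), log(3)), 3), 0.631)
  expect_error(confoundingRatio(0.1, 0), "undefined")
})

test_that("ancestry-stratified ORs are homogeneous under a shared effect", {
  set.seed(34)
  d <- simulateScoreMarker(1200, 1200, c(0.7, 0.12), pA = 0.35, pE = 0.35,
                           r = 1.6)
  co <- manualCohort(matrix(d$g, 1), matrix(d$a, 1), d$status,
                     theta = d$theta)
  res <- stratifiedOrByAncestry(co, "m001", codeMinor = FALSE)
  expect_identical(res$ancestry, 0:2)
  avail <- res[res$available, ]
  expect_gte(nrow(avail), 2L)
  for (i in seq_len(nrow(avail) - 1)) {
    b1 <- log(avail$or[i]); b2 <- log(avail$or[i + 1])
    se12 <- sqrt((log(avail$ciHigh[i] / avail$or[i]) / 1.96)^2 +
                   (log(avail$ciHigh[i + 1] / avail$or[i + 1]) / 1.96)^2)
    expect_lt(abs(b1 - b2), 3 * se12)
  }
  # an empty stratum is reported unavailable, not an error
  dAll2 <- d; dAll2$a <- rep(2L, length(d$a))
  co2 <- manualCohort(matrix(dAll2$g, 1), matrix(dAll2$a, 1), dAll2$status,
                      theta = dAll2$theta)
  res2 <- stratifiedOrByAncestry(co2, "m001", codeMinor = FALSE)
  expect_false(res2$available[1])
  expect_false(res2$available[2])
  expect_true(res2$available[3])
})

test_that("conditioning on the causal SNP removes the ancestry signal", {
  set.seed(35)
  d <- simulateScoreMarker(600, 600, c(0.82, 0.1), pA = 0.1, pE = 0.6,
                           r = 2)
  co <- manualCohort(matrix(d$g, 1), matrix(d$a, 1), d$status,
                     theta = d$theta)
  un <- laAssociation(co, "m001")
  cond <- laAssociation(co, "m001", conditioningMarkers = "m001")
  expect_lt(un$p, 0.05)    # strong induced ancestry signal
  expect_gt(cond$p, un$p)
  # zero-variance ancestry errors
  co2 <- manualCohort(matrix(d$g, 1), matrix(rep(2L, 1200), 1), d$status,
                      theta = d$theta)
  expect_error(laAssociation(co2, "m001"), "zero-variance")
})

test_that("forward selection finds independent causals and stops cleanly", {
  set.seed(36)
  ft <- data.frame(id = sprintf("s%02d", 1:6), fAFR = 0.4, fCEU = 0.4)
  dm <- diseaseModel(intercept = qlogis(0.35),
                     causal = c(s02 = log(2.2), s05 = log(1.7)))
  co <- simulateCohort(simConfig(nIndividuals = 3000, nFamilies = 0,
                                 nMarkers = 6, freqTable = ft, disease = dm,
                                 seed = 73))
  sel <- forwardSelect(co, markerInfo(co)$id, alpha = 1e-3)
  expect_setequal(sel$marker, c("s02", "s05"))
  expect_identical(sel$marker[1], "s02")  # stronger effect enters first

  # invariance to marker input order
  sel2 <- forwardSelect(co, rev(markerInfo(co)$id), alpha = 1e-3)
  expect_identical(sel2$marker, sel$marker)

  # a duplicated (perfectly correlated) marker is never selected second
  g <- genotypes(co); a <- localAncestry(co)
  g2 <- rbind(g, dup = g["s02", ]); a2 <- rbind(a, a["s02", ])
  s <- sampleInfo(co)
  mk <- c(markerInfo(co)$id, "dup")
  codup <- manualCohort(g2, a2, s$status, theta = s$theta, sex = s$sex,
                        familyId = s$familyId)
  mkIds <- markerInfo(codup)$id
  sel3 <- forwardSelect(codup, mkIds, alpha = 1e-3)
  expect_lte(sum(sel3$marker %in% c(mkIds[2], mkIds[7])), 1L)

  # nothing significant -> empty selection
  co0 <- toyCohort(n = 200, nFam = 0, nMarkers = 5, seed = 74)
  sel0 <- forwardSelect(co0, markerInfo(co0)$id, alpha = 1e-6)
  expect_identical(nrow(sel0), 0L)
})

test_that("composite LD r2 behaves at its boundary cases", {
  set.seed(37)
  g <- rbinom(250, 2, 0.4)
  expect_equal(ldR2(g, g), 1)
  expect_equal(ldR2(g, 2L - g), 1)  # allele relabelling
  indep <- replicate(200, ldR2(rbinom(250, 2, 0.3), rbinom(250, 2, 0.3)))
  expect_gte(mean(indep < 0.05), 0.95)
  expect_error(ldR2(g, rep(1L, 250)), "polymorphic")
})
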