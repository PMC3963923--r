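#' Ancestry odds multiplier induced by a single causal allele
#'
#' Under the single-causal-variant model, an allelic odds ratio `r` at a
#' marker with ancestral risk-allele frequencies `pA` (African) and `pE`
#' (European) induces an ancestry odds multiplier
#' `lambda(r) = (1 + (r - 1) pA) / (1 + (r - 1) pE)` per African-origin
#' haplotype.
#'
#' @param r allelic odds ratio.
#' @param pA,pE ancestral risk-allele frequencies.
#' @return the induced ancestry odds multiplier.
#' @export
lambdaOf <- function(r, pA, pE) {
  (1 + (r - 1) * pA) / (1 + (r - 1) * pE)
}

#' Estimate ancestral allele frequencies from admixed individuals
#'
#' Maximum-likelihood frequencies of the coded allele on African- and
#' European-origin haplotypes. Each haplotype's allele is Bernoulli given
#' its origin; ancestry-heterozygous individuals (one haplotype of each
#' origin, unphased) are handled by an EM that sums over the two possible
#' allele-to-origin assignments.
#'
#' @param genotypes coded-allele counts 0/1/2 (`NA` dropped).
#' @param ancestry African-allele counts 0/1/2, same individuals.
#' @param status optional 0/1 case status, required when
#'   `controlsOnly = TRUE`.
#' @param controlsOnly estimate from controls only (the usual choice, so
#'   frequencies are not distorted by the disease association)?
#' @param tol,maxIter EM convergence controls.
#' @return named vector `c(pA = , pE = )`.
#' @export
estimateAncestralFreqs <- function(genotypes, ancestry, status = NULL,
                                   controlsOnly = TRUE, tol = 1e-10,
                                   maxIter = 1000L) {
  if (controlsOnly) {
    stopIf(is.null(status), "status required when controlsOnly = TRUE")
    keep <- status == 0L
    genotypes <- genotypes[keep]; ancestry <- ancestry[keep]
  }
  ok <- !is.na(genotypes) & !is.na(ancestry)
  g <- genotypes[ok]; a <- ancestry[ok]
  nAHap <- sum(a)
  nEHap <- sum(2L - a)
  stopIf(nAHap == 0L || nEHap == 0L,
         "both ancestral backgrounds must be represented")
  # sufficient statistics from phase-unambiguous individuals
  sA2 <- sum(g[a == 2L]); tA2 <- 2L * sum(a == 2L)
  sE0 <- sum(g[a == 0L]); tE0 <- 2L * sum(a == 0L)
  g1 <- g[a == 1L]
  n1 <- c(sum(g1 == 0L), sum(g1 == 1L), sum(g1 == 2L))
  pA <- if (tA2 > 0) sA2 / tA2 else 0.5
  pE <- if (tE0 > 0) sE0 / tE0 else 0.5
  if (sum(n1) == 0L) return(c(pA = pA, pE = pE))
  for (it in seq_len(maxIter)) {
    # E-step: P(A-origin haplotype carries the allele | g = 1)
    num <- pA * (1 - pE)
    den <- num + (1 - pA) * pE
    w <- if (den > 0) num / den else 0.5
    sA <- sA2 + n1[2] * w + n1[3]
    sE <- sE0 + n1[2] * (1 - w) + n1[3]
    tA <- tA2 + sum(n1)
    tE <- tE0 + sum(n1)
    pAn <- sA / tA; pEn <- sE / tE
    if (abs(pAn - pA) + abs(pEn - pE) < tol) {
      pA <- pAn; pE <- pEn
      break
    }
    pA <- pAn; pE <- pEn
  }
  c(pA = pA, pE = pE)
}

# --- likelihood building blocks ---------------------------------------------

# affected-only admixture log-likelihood: a_j ~ Bin(2, lambda th/(lambda th + 1 - th))
.admLoglik <- function(lambda, a, theta) {
  pi <- lambda * theta / (lambda * theta + 1 - theta)
  sum(stats::dbinom(a, 2L, pi, log = TRUE))
}

# 3 x 3 x 2 cell counts: [ancestry+1, genotype+1, status+1]
.cellCounts <- function(g, a, status) {
  ok <- !is.na(g) & !is.na(a) & !is.na(status)
  idx <- a[ok] + 3L * g[ok] + 9L * status[ok] + 1L
  array(tabulate(idx, nbins = 18L), c(3L, 3L, 2L))
}

# log P(genotype | ancestry, status) for all 3x3x2 cells given per-origin
# allele probabilities (qA0/qE0 controls, qA1/qE1 cases)
.cellLogP <- function(qA0, qE0, qA1, qE1) {
  layer <- function(qA, qE) {
    rbind(
      c(stats::dbinom(0:2, 2, qE, log = FALSE)),          # a = 0
      c((1 - qA) * (1 - qE), qA * (1 - qE) + (1 - qA) * qE, qA * qE), # a = 1
      c(stats::dbinom(0:2, 2, qA, log = FALSE)))          # a = 2
  }
  lp <- array(0, c(3L, 3L, 2L))
  lp[, , 1] <- log(pmax(layer(qA0, qE0), 1e-300))
  lp[, , 2] <- log(pmax(layer(qA1, qE1), 1e-300))
  lp
}

.caseQ <- function(p, r) p * r / (1 + (r - 1) * p)

# ancestry-conditional retrospective log-likelihood of the allelic OR r
.snp1Loglik <- function(r, cells, pA, pE) {
  lp <- .cellLogP(pA, pE, .caseQ(pA, r), .caseQ(pE, r))
  sum(cells * lp)
}

.logRBound <- log(50)

.clampP <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# Maximise the SNP1 likelihood over (log r, logit pA, logit pE), the
# frequencies treated as profiled nuisance parameters, optionally adding
# the constrained admixture part (MIX). Returns list(ll, r, pA, pE).
.snp1AltMax <- function(cells, p0A, p0E, aCase = NULL, thCase = NULL) {
  withAdm <- !is.null(aCase)
  obj <- function(u) {
    r <- exp(u[1])
    pA <- stats::plogis(u[2]); pE <- stats::plogis(u[3])
    ll <- .snp1Loglik(r, cells, pA, pE)
    if (withAdm) ll <- ll + .admLoglik(lambdaOf(r, pA, pE), aCase, thCase)
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  # start from the fixed-frequency 1-D optimum in r
  f1 <- function(logR) {
    r <- exp(logR)
    ll <- .snp1Loglik(r, cells, p0A, p0E)
    if (withAdm) ll <- ll + .admLoglik(lambdaOf(r, p0A, p0E), aCase, thCase)
    ll
  }
  o1 <- maximize1d(f1, -.logRBound, .logRBound)
  start <- c(o1$maximum, stats::qlogis(.clampP(p0A)),
             stats::qlogis(.clampP(p0E)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (-opt$value < o1$objective) {
    opt <- list(par = start, value = -o1$objective)
  }
  list(ll = -opt$value, r = exp(opt$par[1]),
       pA = stats::plogis(opt$par[2]), pE = stats::plogis(opt$par[3]))
}

#' Affected-only admixture score (ADM)
#'
#' One-degree-of-freedom likelihood-ratio test of the ancestry odds
#' multiplier `lambda` in the case-only model
#' `a_j ~ Binomial(2, lambda theta_j / (lambda theta_j + 1 - theta_j))`:
#' `ADM = 2 [l(lambda-hat) - l(1)]`. Cases with `theta` at 0 or 1 carry no
#' information and are skipped.
#'
#' @param caseAncestry African-allele counts 0/1/2 for cases.
#' @param caseTheta global African ancestry proportions for the same cases.
#' @return list with `statistic`, `p` (1-df chi-square upper tail) and
#'   `lambdaHat`.
#' @export
admScore <- function(caseAncestry, caseTheta) {
  stopIf(length(caseAncestry) != length(caseTheta),
         "ancestry and theta must have equal length")
  ok <- !is.na(caseAncestry) & !is.na(caseTheta) &
    caseTheta > 0 & caseTheta < 1
  a <- caseAncestry[ok]; th <- caseTheta[ok]
  stopIf(length(a) == 0L, "no informative cases")
  f <- function(logLam) .admLoglik(exp(logLam), a, th)
  opt <- maximize1d(f, -.logRBound, .logRBound)
  ll1 <- f(0)
  stat <- max(0, 2 * (opt$objective - ll1))
  list(statistic = stat, p = chisq1P(stat), lambdaHat = exp(opt$maximum))
}

#' Ancestry-conditional allelic score (SNP1)
#'
#' One-degree-of-freedom likelihood-ratio test of the allelic odds ratio `r`
#' in the ancestry-conditional retrospective likelihood: a case haplotype of
#' origin with ancestral frequency `p` carries the coded allele with
#' probability `p r / (1 + (r - 1) p)`, a control haplotype with
#' probability `p`; ancestry-heterozygous individuals are summed over the
#' two unphased allele-to-origin assignments.
#'
#' With `profileFreqs = TRUE` (the default when no frequencies are given)
#' the ancestral frequencies are nuisance parameters maximised under both
#' hypotheses (the null maximum is the pooled EM of
#' [estimateAncestralFreqs()]), which keeps the statistic 1-df chi-square
#' calibrated; with `profileFreqs = FALSE` the supplied `pA`, `pE` are held
#' fixed (the constrained-likelihood algebra of the collapse identities,
#' but anti-conservative as a test because the frequency-estimation
#' variance is ignored).
#'
#' @param genotypes,ancestry,status per-individual vectors (counts 0/1/2 and
#'   0/1 status).
#' @param pA,pE ancestral allele-frequency estimates, e.g. from
#'   [estimateAncestralFreqs()]; starting values when `profileFreqs =
#'   TRUE`, fixed otherwise. Estimated internally when `NULL`.
#' @param profileFreqs treat the frequencies as profiled nuisance
#'   parameters?
#' @return list with `statistic`, `p` and `rHat`.
#' @export
snp1Score <- function(genotypes, ancestry, status, pA = NULL, pE = NULL,
                      profileFreqs = is.null(pA)) {
  stopIf(stats::var(genotypes, na.rm = TRUE) == 0, "marker is monomorphic")
  cells <- .cellCounts(genotypes, ancestry, status)
  if (profileFreqs) {
    p0 <- estimateAncestralFreqs(genotypes, ancestry, status,
                                 controlsOnly = FALSE)
    ll0 <- .snp1Loglik(1, cells, p0["pA"], p0["pE"])
    alt <- .snp1AltMax(cells, pA %||% p0[["pA"]], pE %||% p0[["pE"]])
    stat <- max(0, 2 * (alt$ll - ll0))
    return(list(statistic = stat, p = chisq1P(stat), rHat = alt$r,
                pA = alt$pA, pE = alt$pE, null = ll0, alt = alt$ll))
  }
  stopIf(is.null(pA) || is.null(pE),
         "pA and pE required when profileFreqs = FALSE")
  stopIf((pA %in% c(0, 1)) && (pE %in% c(0, 1)),
         "degenerate ancestral frequencies on both backgrounds")
  f <- function(logR) .snp1Loglik(exp(logR), cells, pA, pE)
  opt <- maximize1d(f, -.logRBound, .logRBound)
  ll1 <- f(0)
  stat <- max(0, 2 * (opt$objective - ll1))
  list(statistic = stat, p = chisq1P(stat), rHat = exp(opt$maximum),
       pA = pA, pE = pE, null = ll1, alt = opt$objective)
}

#' Single-causal-variant MIX score
#'
#' One-degree-of-freedom likelihood-ratio test in the joint likelihood
#' `l(lambda, r) = l_ADM(lambda) + l_SNP1(r)` under the single-causal
#' constraint `lambda = lambda(r) = (1 + (r-1) pA) / (1 + (r-1) pE)`:
#' `MIX = 2 [l(lambda(r-hat), r-hat) - l(1, 1)]`, maximised over `r` by a
#' bracketing grid plus Brent search on `log r` in `[log 1/50, log 50]`.
#' A small MIX p-value indicates the SNP can explain the ancestry signal.
#'
#' The frequencies are profiled nuisance parameters by default (see
#' [snp1Score()]); the MIX null log-likelihood shares the SNP1 null
#' (`r = 1` implies `lambda = 1`), which makes
#' `DIFF = ADM + SNP1 - MIX` an exact identity of nested maximisations.
#'
#' @inheritParams snp1Score
#' @param theta global ancestry proportions (all individuals; only cases
#'   with `theta` in (0,1) inform the admixture part).
#' @return list with `statistic`, `p` and `rHat` (the constrained optimum).
#' @export
mixScore <- function(genotypes, ancestry, status, theta, pA = NULL,
                     pE = NULL, profileFreqs = is.null(pA)) {
  isCase <- status == 1L & !is.na(status)
  okAdm <- isCase & !is.na(ancestry) & !is.na(theta) & theta > 0 & theta < 1
  aC <- ancestry[okAdm]; thC <- theta[okAdm]
  stopIf(length(aC) == 0L, "no informative cases")
  cells <- .cellCounts(genotypes, ancestry, status)
  if (profileFreqs) {
    p0 <- estimateAncestralFreqs(genotypes, ancestry, status,
                                 controlsOnly = FALSE)
    ll0 <- .snp1Loglik(1, cells, p0["pA"], p0["pE"]) +
      .admLoglik(1, aC, thC)
    alt <- .snp1AltMax(cells, pA %||% p0[["pA"]], pE %||% p0[["pE"]],
                       aCase = aC, thCase = thC)
    stat <- max(0, 2 * (alt$ll - ll0))
    stopIf(!is.finite(stat), "MIX optimisation failed")
    return(list(statistic = stat, p = chisq1P(stat), rHat = alt$r,
                pA = alt$pA, pE = alt$pE, null = ll0, alt = alt$ll))
  }
  stopIf(is.null(pA) || is.null(pE),
         "pA and pE required when profileFreqs = FALSE")
  stopIf((pA %in% c(0, 1)) && (pE %in% c(0, 1)),
         "degenerate ancestral frequencies on both backgrounds")
  f <- function(logR) {
    r <- exp(logR)
    .admLoglik(lambdaOf(r, pA, pE), aC, thC) + .snp1Loglik(r, cells, pA, pE)
  }
  opt <- maximize1d(f, -.logRBound, .logRBound)
  ll1 <- f(0)
  stat <- max(0, 2 * (opt$objective - ll1))
  stopIf(!is.finite(stat),
         "MIX optimisation failed (pA = %.4g, pE = %.4g)", pA, pE)
  list(statistic = stat, p = chisq1P(stat), rHat = exp(opt$maximum),
       pA = pA, pE = pE, null = ll1, alt = opt$objective)
}

#' DIFF score from its components
#'
#' `DIFF = ADM + SNP1 - MIX`, the 1-df test of the single-causal-variant
#' constraint; values negative within numerical tolerance are clipped to 0.
#' A DIFF p below 0.05 indicates more than one variant likely drives the
#' local-ancestry signal.
#'
#' @param adm,snp1,mix the three component statistics (numbers or the lists
#'   returned by their score functions).
#' @return list with `statistic` and `p`.
#' @export
diffScore <- function(adm, snp1, mix) {
  val <- function(x) if (is.list(x)) x$statistic else x
  stat <- val(adm) + val(snp1) - val(mix)
  stopIf(stat < -1e-6, "negative DIFF beyond tolerance (%.3g)", stat)
  stat <- max(0, stat)
  list(statistic = stat, p = chisq1P(stat))
}

#' All four admixture-signal scores for one marker
#'
#' Prepares a single common analysis set (complete cases for genotype,
#' ancestry, status and theta) and computes ADM, SNP1, MIX and DIFF on
#' identical individual sets with a shared null likelihood, so that the
#' identity `DIFF = ADM + SNP1 - MIX` holds exactly and `MIX <= ADM + SNP1`
#' by nesting. Ancestral frequencies are profiled nuisance parameters; the
#' pooled-EM null estimates (or control-only ones via `controlsOnly`) seed
#' the optimiser.
#'
#' @param genotypes,ancestry,status,theta per-individual vectors.
#' @param pA,pE optional starting values for the ancestral frequencies;
#'   estimated from the data when `NULL`.
#' @param marker marker id used for labelling.
#' @param controlsOnly estimate the starting frequencies from controls
#'   only?
#' @return an [AdmixtureScores-class] object.
#' @export
admixtureScores <- function(genotypes, ancestry, status, theta,
                            pA = NULL, pE = NULL, marker = "marker",
                            controlsOnly = TRUE) {
  ok <- !is.na(genotypes) & !is.na(ancestry) & !is.na(status) & !is.na(theta)
  g <- genotypes[ok]; a <- ancestry[ok]; st <- status[ok]; th <- theta[ok]
  if (is.null(pA) || is.null(pE)) {
    fr <- estimateAncestralFreqs(g, a, st, controlsOnly = controlsOnly)
    pA <- unname(fr["pA"]); pE <- unname(fr["pE"])
  }
  isCase <- st == 1L
  adm <- admScore(a[isCase], th[isCase])
  mx <- mixScore(g, a, st, th, pA = pA, pE = pE, profileFreqs = TRUE)
  s1 <- snp1Score(g, a, st, pA = pA, pE = pE, profileFreqs = TRUE)
  # enforce nesting numerically: the joint optimum is a feasible point of
  # each marginal maximisation
  cells <- .cellCounts(g, a, st)
  sAtMix <- .snp1Loglik(mx$rHat, cells, mx$pA, mx$pE)
  if (sAtMix > s1$alt) {
    s1$alt <- sAtMix
    s1$statistic <- max(0, 2 * (s1$alt - s1$null))
    s1$p <- chisq1P(s1$statistic)
    s1$rHat <- mx$rHat
  }
  okAdm <- isCase & th > 0 & th < 1
  aAtMix <- .admLoglik(lambdaOf(mx$rHat, mx$pA, mx$pE), a[okAdm], th[okAdm])
  admLl1 <- .admLoglik(1, a[okAdm], th[okAdm])
  if (2 * (aAtMix - admLl1) > adm$statistic) {
    adm$statistic <- 2 * (aAtMix - admLl1)
    adm$p <- chisq1P(adm$statistic)
  }
  df <- diffScore(adm, s1, mx)
  new("AdmixtureScores", marker = marker,
      adm = adm$statistic, admP = adm$p,
      snp1 = s1$statistic, snp1P = s1$p,
      mix = mx$statistic, mixP = mx$p,
      diff = df$statistic, diffP = df$p,
      rHat = mx$rHat, lambdaHat = adm$lambdaHat,
      pA = s1$pA, pE = s1$pE,
      nCases = sum(isCase), nControls = sum(!isCase))
}

#' MIX score averaged over unrelated subsamples
#'
#' The MIX framework assumes unrelated cases and controls. This draws
#' `nSamples` independent random subsamples of unrelated individuals (of the
#' requested case/control sizes), computes the four statistics on each, and
#' averages the statistics; p-values come from the averaged statistics
#' (1-df chi-square).
#'
#' @param cohort an [AdmixedCohort-class].
#' @param marker marker id.
#' @param nSamples number of subsamples (100 in the analysis this package
#'   reimplements).
#' @param subsampleSizes `c(cases = , controls = )` drawn per subsample.
#' @param relationship optional relationship matrix (2 x kinship) used to
#'   build the unrelated pool; computed from the stored pedigree when
#'   `NULL`.
#' @param threshold relationship threshold defining unrelated (< 0.125).
#' @return an [AdmixtureScores-class] with averaged statistics.
#' @export
averagedMix <- function(cohort, marker, nSamples = 100L,
                        subsampleSizes = c(cases = 933L, controls = 846L),
                        relationship = NULL, threshold = 0.125) {
  s <- sampleInfo(cohort)
  if (is.null(relationship)) {
    ped <- cohortPedigree(cohort)
    stopIf(is.null(ped), "no pedigree stored; supply a relationship matrix")
    rel <- pedigreeRelationship(ped)
    rel <- rel[s$id, s$id]
  } else rel <- relationship
  pool <- unrelatedSubset(rel, threshold = threshold)
  poolCase <- intersect(pool, s$id[s$status == 1L])
  poolCtrl <- intersect(pool, s$id[s$status == 0L])
  nCa <- subsampleSizes[[1]]; nCo <- subsampleSizes[[2]]
  stopIf(length(poolCase) < nCa || length(poolCtrl) < nCo,
         "unrelated pool too small (%d cases, %d controls available)",
         length(poolCase), length(poolCtrl))
  i <- match(marker, markerInfo(cohort)$id)
  stopIf(is.na(i), "marker '%s' not present in cohort", marker)
  g <- genotypes(cohort)[i, ]; a <- localAncestry(cohort)[i, ]
  acc <- NULL
  for (k in seq_len(nSamples)) {
    ids <- c(sample(poolCase, nCa), sample(poolCtrl, nCo))
    j <- match(ids, s$id)
    sc <- admixtureScores(g[j], a[j], s$status[j], s$theta[j],
                          marker = marker)
    v <- c(sc@adm, sc@snp1, sc@mix, sc@diff, sc@rHat, sc@lambdaHat,
           sc@pA, sc@pE)
    acc <- if (is.null(acc)) v else acc + v
  }
  m <- acc / nSamples
  mixStat <- max(0, m[1] + m[2] - m[4])  # averaging preserves the identity
  new("AdmixtureScores", marker = marker,
      adm = m[1], admP = chisq1P(m[1]),
      snp1 = m[2], snp1P = chisq1P(m[2]),
      mix = mixStat, mixP = chisq1P(mixStat),
      diff = m[4], diffP = chisq1P(m[4]),
      rHat = m[5], lambdaHat = m[6], pA = m[7], pE = m[8],
      nCases = as.integer(nCa), nControls = as.integer(nCo))
}

#' Admixture-region boundaries from affected-only p-values
#'
#' The closed interval from the first to the last marker with affected-only
#' admixture p-value below `alpha`; `NULL` when no marker qualifies.
#'
#' @param positions sorted marker positions.
#' @param admPvalues affected-only admixture p-values, same length.
#' @param alpha significance threshold (default 0.05).
#' @return `c(start, end)` (1-based, closed) or `NULL`.
#' @export
regionBoundaries <- function(positions, admPvalues, alpha = 0.05) {
  stopIf(length(positions) != length(admPvalues),
         "positions and p-values must have equal length")
  stopIf(is.unsorted(positions), "positions must be sorted")
  hit <- which(admPvalues < alpha)
  if (!length(hit)) return(NULL)
  c(start = positions[min(hit)], end = positions[max(hit)])
}

#' Tiered screen for MIX testing
#'
#' Selects the markers carried forward to MIX scoring: unadjusted
#' association p below `pThreshold` and confounding by local ancestry below
#' `confoundingThreshold`.
#'
#' @param assocResults data.frame with columns `marker` and `p`
#'   (unadjusted).
#' @param confounding named vector of confounding ratios keyed by marker
#'   (see [confoundingRatio()]).
#' @param pThreshold association screen (default 0.05).
#' @param confoundingThreshold maximal confounding ratio counted as
#'   "minimal confounding" (default 0.15).
#' @return character vector of marker ids passing the screen.
#' @export
tieredScreen <- function(assocResults, confounding, pThreshold = 0.05,
                         confoundingThreshold = 0.15) {
  cf <- confounding[assocResults$marker]
  keep <- assocResults$p < pThreshold & !is.na(cf) &
    cf < confoundingThreshold
  assocResults$marker[keep]
}

#' Label a p-value with the genome-wide significance tier
#'
#' `"genome-wide"` at 5e-8, `"suggestive"` at 1e-5, `"nominal"` at 0.05,
#' else `"ns"`. Labels only; never used as filters.
#'
#' @param p p-value vector.
#' @return character vector of tier labels.
#' @export
significanceTier <- function(p) {
  ifelse(p < 5e-8, "genome-wide",
         ifelse(p < 1e-5, "suggestive",
                ifelse(p < 0.05, "nominal", "ns")))
}
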