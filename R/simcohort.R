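#' Disease model for the synthetic cohort
#'
#' Multiplicative (log-additive) logistic disease model:
#' `logit P(case) = intercept + sum(logOR * genotype) + gamma * theta +
#' delta * I(female) + sum(ancestryLogOR * localAncestry)`.
#' The optional direct local-ancestry term simulates an admixture signal not
#' explained by any typed variant.
#'
#' @param intercept baseline log-odds. The default gives a case fraction
#'   near the study composition (1,271 / 2,727) when all effects are zero.
#' @param causal named numeric vector of allelic log odds ratios, names are
#'   marker ids (or a list of `(marker, logOR)` pairs).
#' @param gamma log-odds per unit global African ancestry proportion.
#' @param delta log-odds for female sex.
#' @param ancestryEffects named numeric vector of log-odds per African
#'   allele at the named markers (direct local-ancestry effects).
#' @return a list of class `diseaseModel`.
#' @export
diseaseModel <- function(intercept = stats::qlogis(1271 / 2727),
                         causal = numeric(), gamma = 0, delta = 0,
                         ancestryEffects = numeric()) {
  stopIf(!all(is.finite(c(intercept, causal, gamma, delta, ancestryEffects))),
         "disease model parameters must be finite")
  structure(list(intercept = intercept, causal = causal, gamma = gamma,
                 delta = delta, ancestryEffects = ancestryEffects),
            class = "diseaseModel")
}

#' Simulation configuration for a two-way admixed cohort
#'
#' Defaults emulate the study sample the package targets: African Americans
#' with mean African ancestry proportion 0.823 (SD 0.10), about seven
#' generations since the admixture pulse, sibship family structure, and case
#' subphenotypes (resolved / persistent Stage I-III / Stage IV) in
#' proportions 0.331 / 0.465 / 0.204 among cases with follow-up, with 26.8%
#' of cases missing follow-up.
#'
#' @param nIndividuals total cohort size.
#' @param nFamilies number of sibships (each of `sibshipSize` genotyped
#'   siblings sharing two simulated, un-genotyped parents); remaining
#'   individuals are singletons.
#' @param sibshipSize siblings per family.
#' @param nMarkers number of markers on the single simulated chromosome.
#' @param chromLength chromosome length in base pairs (bp are mapped to
#'   Morgans at a constant 1e-8 per bp).
#' @param generations generations since admixture; per-Morgan ancestry
#'   switch rate of the haplotype Markov chain.
#' @param thetaMean,thetaSd mean and SD of the Beta distribution individual
#'   ancestry proportions are drawn from (moment-matched).
#' @param freqTable data.frame with columns `id`, `fAFR`, `fCEU` (and
#'   optionally `pos`, `ref`, `alt`); if `NULL`, frequencies are drawn
#'   uniformly on (0.05, 0.95).
#' @param disease a [diseaseModel()].
#' @param subphenotypeProbs probabilities (summing to 1) of resolved,
#'   persistent Stage I-III, and Stage IV disease among cases with
#'   follow-up.
#' @param followupMissing proportion of cases missing follow-up (no
#'   subphenotype assigned).
#' @param missingRate genotype missingness rate injected uniformly.
#' @param seed optional integer seed.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nIndividuals = 500L, nFamilies = 50L, sibshipSize = 2L,
                      nMarkers = 200L, chromLength = 1e8,
                      generations = 7, thetaMean = 0.823, thetaSd = 0.10,
                      freqTable = NULL, disease = diseaseModel(),
                      subphenotypeProbs = c(resolved = 0.331,
                                            stage1_3 = 0.465,
                                            stage4 = 0.204),
                      followupMissing = 0.268,
                      missingRate = 0, seed = NULL) {
  stopIf(thetaMean <= 0 || thetaMean >= 1, "thetaMean must be in (0, 1)")
  stopIf(thetaSd <= 0, "thetaSd must be positive")
  stopIf(nMarkers < 1L, "nMarkers must be >= 1")
  stopIf(abs(sum(subphenotypeProbs) - 1) > 1e-8,
         "subphenotypeProbs must sum to 1")
  stopIf(nFamilies * sibshipSize > nIndividuals,
         "nFamilies * sibshipSize exceeds nIndividuals")
  if (!is.null(freqTable)) {
    stopIf(!all(c("fAFR", "fCEU") %in% colnames(freqTable)),
           "freqTable needs columns fAFR and fCEU")
    stopIf(any(freqTable$fAFR < 0 | freqTable$fAFR > 1 |
               freqTable$fCEU < 0 | freqTable$fCEU > 1),
           "ancestral frequencies must lie in [0, 1]")
  }
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nFamilies = as.integer(nFamilies),
                 sibshipSize = as.integer(sibshipSize),
                 nMarkers = as.integer(nMarkers),
                 chromLength = chromLength, generations = generations,
                 thetaMean = thetaMean, thetaSd = thetaSd,
                 freqTable = freqTable, disease = disease,
                 subphenotypeProbs = subphenotypeProbs,
                 followupMissing = followupMissing,
                 missingRate = missingRate, seed = seed),
            class = "simConfig")
}

#' Simulate one haplotype's ancestry along a chromosome
#'
#' Two-state Markov chain with stationary distribution `(theta, 1 - theta)`
#' over (African, European) origin: between adjacent markers separated by
#' `d` Morgans (bp x 1e-8) an ancestry-redraw event occurs with probability
#' `1 - exp(-generations * d)`, after which origin is redrawn from the
#' stationary distribution, so the marginal P(African) is `theta` at every
#' marker.
#'
#' @param theta African ancestry proportion in `[0, 1]`.
#' @param positions strictly increasing marker positions (bp).
#' @param generations generations since admixture (switch rate per Morgan).
#' @return integer vector of 0/1 (1 = African origin) per marker.
#' @export
simulateLocalAncestry <- function(theta, positions, generations = 7) {
  stopIf(theta < 0 || theta > 1, "theta must lie in [0, 1]")
  stopIf(length(positions) < 1L, "at least one position required")
  stopIf(is.unsorted(positions, strictly = TRUE),
         "positions must be strictly increasing")
  m <- length(positions)
  first <- stats::rbinom(1L, 1L, theta)
  if (m == 1L) return(first)
  d <- diff(positions) * 1e-8
  ev <- stats::rbinom(m - 1L, 1L, 1 - exp(-generations * d))
  redraw <- stats::rbinom(sum(ev), 1L, theta)
  vals <- c(first, redraw)
  vals[cumsum(c(1L, ev))]
}

# One meiotic gamete from a parent's pair of haplotypes: crossover process at
# 1 per Morgan (Haldane), template chosen at random at the left end.
.gamete <- function(hap1, hap2, positions) {
  m <- length(positions)
  cur <- stats::rbinom(1L, 1L, 0.5)
  if (m > 1L) {
    d <- diff(positions) * 1e-8
    rec <- stats::rbinom(m - 1L, 1L, 0.5 * (1 - exp(-2 * d)))
    tmpl <- (cur + cumsum(c(0L, rec))) %% 2L
  } else tmpl <- cur
  list(anc = ifelse(tmpl == 0L, hap1$anc, hap2$anc),
       all = ifelse(tmpl == 0L, hap1$all, hap2$all))
}

.hap <- function(theta, positions, generations, fAFR, fCEU) {
  anc <- simulateLocalAncestry(theta, positions, generations)
  all <- stats::rbinom(length(positions), 1L, ifelse(anc == 1L, fAFR, fCEU))
  list(anc = anc, all = all)
}

#' Simulate an admixed cohort
#'
#' Draws per-individual ancestry proportions from a moment-matched Beta
#' distribution, simulates two ancestry haplotypes per individual (Markov
#' chain along the chromosome), places alleles Bernoulli(`fAFR`) on
#' African-origin and Bernoulli(`fCEU`) on European-origin haplotypes
#' (independent across markers given ancestry), builds sibships by meiosis
#' from two simulated parents, assigns phenotypes under the configured
#' disease model, and optionally injects genotype missingness.
#'
#' @param config a [simConfig()].
#' @return an [AdmixedCohort-class]; the pedigree (siblings with their
#'   un-genotyped parents as founders) is stored in `metadata(x)$pedigree`
#'   and the frequency table in `metadata(x)$freqTable`.
#' @export
simulateCohort <- function(config) {
  stopIf(!inherits(config, "simConfig"), "config must come from simConfig()")
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- config$thetaMean; ts <- config$thetaSd
  conc <- tm * (1 - tm) / ts^2 - 1
  stopIf(conc <= 0,
         "thetaSd %.3f incompatible with Beta moment matching at mean %.3f",
         ts, tm)
  alpha <- tm * conc; beta <- (1 - tm) * conc

  M <- config$nMarkers
  ft <- config$freqTable
  if (is.null(ft)) {
    ft <- data.frame(id = sprintf("snp%04d", seq_len(M)),
                     fAFR = stats::runif(M, 0.05, 0.95),
                     fCEU = stats::runif(M, 0.05, 0.95))
  }
  stopIf(nrow(ft) != M, "freqTable must have nMarkers rows")
  if (is.null(ft$pos))
    ft$pos <- sort(sample.int(config$chromLength, M))
  stopIf(is.unsorted(ft$pos, strictly = TRUE),
         "freqTable positions must be strictly increasing")
  if (is.null(ft$ref)) ft$ref <- "A"
  if (is.null(ft$alt)) ft$alt <- "G"
  pos <- ft$pos

  n <- config$nIndividuals
  nFam <- config$nFamilies; sib <- config$sibshipSize
  geno <- matrix(0L, M, n)
  anc <- matrix(0L, M, n)
  famId <- character(n)
  ped <- list()
  k <- 0L
  mkId <- function(i) sprintf("I%05d", i)

  for (f in seq_len(nFam)) {
    fam <- sprintf("F%04d", f)
    thP <- stats::rbeta(2, alpha, beta)
    par1 <- list(.hap(thP[1], pos, config$generations, ft$fAFR, ft$fCEU),
                 .hap(thP[1], pos, config$generations, ft$fAFR, ft$fCEU))
    par2 <- list(.hap(thP[2], pos, config$generations, ft$fAFR, ft$fCEU),
                 .hap(thP[2], pos, config$generations, ft$fAFR, ft$fCEU))
    fatherId <- paste0(fam, "_P1"); motherId <- paste0(fam, "_P2")
    ped[[length(ped) + 1L]] <- data.frame(
      familyId = fam, id = c(fatherId, motherId), father = "0", mother = "0",
      sex = c(1L, 2L), phenotype = 0L)
    for (s in seq_len(sib)) {
      k <- k + 1L
      g1 <- .gamete(par1[[1]], par1[[2]], pos)
      g2 <- .gamete(par2[[1]], par2[[2]], pos)
      anc[, k] <- g1$anc + g2$anc
      geno[, k] <- g1$all + g2$all
      famId[k] <- fam
      ped[[length(ped) + 1L]] <- data.frame(
        familyId = fam, id = mkId(k), father = fatherId, mother = motherId,
        sex = NA_integer_, phenotype = NA_integer_)
    }
  }
  while (k < n) {
    k <- k + 1L
    th <- stats::rbeta(1, alpha, beta)
    h1 <- .hap(th, pos, config$generations, ft$fAFR, ft$fCEU)
    h2 <- .hap(th, pos, config$generations, ft$fAFR, ft$fCEU)
    anc[, k] <- h1$anc + h2$anc
    geno[, k] <- h1$all + h2$all
    famId[k] <- mkId(k)
    ped[[length(ped) + 1L]] <- data.frame(
      familyId = famId[k], id = mkId(k), father = "0", mother = "0",
      sex = NA_integer_, phenotype = NA_integer_)
  }

  if (config$missingRate > 0) {
    drop <- stats::runif(length(geno)) < config$missingRate
    geno[drop] <- NA_integer_
  }

  samples <- data.frame(id = mkId(seq_len(n)), familyId = famId,
                        sex = sample(1:2, n, replace = TRUE),
                        status = NA_integer_,
                        subphenotype = NA_character_)
  samples$theta <- colMeans(anc) / 2

  ped <- do.call(rbind, ped)
  idx <- match(ped$id, samples$id)
  ped$sex[!is.na(idx)] <- samples$sex[idx[!is.na(idx)]]

  markers <- GRanges("chr1", IRanges(pos, width = 1L),
                     id = ft$id, ref = ft$ref, alt = ft$alt,
                     fAFR = ft$fAFR, fCEU = ft$fCEU)
  cohort <- AdmixedCohort(geno, anc, samples, markers, pedigree = ped)
  metadata(cohort)$freqTable <- ft
  metadata(cohort)$config <- config
  cohort <- assignPhenotypes(cohort, config$disease,
                             subphenotypeProbs = config$subphenotypeProbs,
                             followupMissing = config$followupMissing)
  ped <- cohortPedigree(cohort)
  idx <- match(ped$id, samples$id)
  st <- sampleInfo(cohort)$status
  ped$phenotype[!is.na(idx)] <- st[idx[!is.na(idx)]] + 1L
  metadata(cohort)$pedigree <- ped
  cohort
}

#' Assign case status and subphenotypes under a disease model
#'
#' Draws per-individual case labels Bernoulli on the logit scale:
#' `logit P = intercept + sum(logOR * g) + gamma * theta + delta * female +
#' sum(ancestry effects)`. Among cases, follow-up is available with
#' probability `1 - followupMissing`; subphenotype labels are drawn
#' multinomially among cases with follow-up.
#'
#' @param cohort an [AdmixedCohort-class].
#' @param model a [diseaseModel()]; its marker names must exist in the
#'   cohort.
#' @param subphenotypeProbs,followupMissing see [simConfig()].
#' @return the cohort with `status` and `subphenotype` filled in.
#' @export
assignPhenotypes <- function(cohort, model,
                             subphenotypeProbs = c(resolved = 0.331,
                                                   stage1_3 = 0.465,
                                                   stage4 = 0.204),
                             followupMissing = 0.268) {
  samples <- sampleInfo(cohort)
  n <- nrow(samples)
  lp <- rep(model$intercept, n)
  mids <- markerInfo(cohort)$id
  causal <- unlist(model$causal)
  for (nm in names(causal)) {
    i <- match(nm, mids)
    stopIf(is.na(i), "causal marker '%s' not present in cohort", nm)
    g <- genotypes(cohort)[i, ]
    g[is.na(g)] <- 0L  # missing genotypes contribute no risk
    lp <- lp + causal[[nm]] * g
  }
  aeff <- unlist(model$ancestryEffects)
  for (nm in names(aeff)) {
    i <- match(nm, mids)
    stopIf(is.na(i), "ancestry-effect marker '%s' not present in cohort", nm)
    lp <- lp + aeff[[nm]] * localAncestry(cohort)[i, ]
  }
  lp <- lp + model$gamma * samples$theta + model$delta * (samples$sex == 2L)
  stopIf(any(!is.finite(lp)), "non-finite linear predictor")
  status <- stats::rbinom(n, 1L, stats::plogis(lp))
  sub <- rep(NA_character_, n)
  cases <- which(status == 1L)
  if (length(cases)) {
    hasFu <- stats::runif(length(cases)) >= followupMissing
    labs <- names(subphenotypeProbs)
    sub[cases[hasFu]] <- sample(labs, sum(hasFu), replace = TRUE,
                                prob = subphenotypeProbs)
  }
  colData(cohort)$status <- status
  colData(cohort)$subphenotype <- sub
  validObject(cohort)
  cohort
}

#' Simulate a single marker under the retrospective single-causal model
#'
#' Generates one marker's data for score testing without simulating whole
#' chromosomes. Haplotypes are independent given case status (multiplicative
#' model, rare-disease retrospective sampling): control haplotypes have
#' African origin with probability `theta` and carry the risk allele with
#' probability `pA` (African origin) or `pE` (European); case haplotypes
#' have origin probability `lambda * theta / (lambda * theta + 1 - theta)`
#' with `lambda = lambdaOf(r, pA, pE) * lambdaExtra`, and carry the allele
#' with probability `p * r / (1 + (r - 1) * p)` on origin with frequency
#' `p`. `lambdaExtra > 1` injects an ancestry signal not explained by the
#' marker (e.g. a second causal variant elsewhere in the region).
#'
#' @param nCases,nControls sample sizes.
#' @param theta either a vector of per-individual ancestry proportions
#'   (length `nCases + nControls`) or `c(mean, sd)` of a Beta to draw from.
#' @param pA,pE ancestral risk-allele frequencies.
#' @param r allelic odds ratio at the marker (1 = null).
#' @param lambdaExtra extra ancestry odds multiplier (1 = none).
#' @return list with integer vectors `g` (genotype 0/1/2), `a` (African
#'   alleles 0/1/2), `status` (0/1) and numeric `theta`.
#' @export
simulateScoreMarker <- function(nCases, nControls, theta = c(0.823, 0.10),
                                pA, pE, r = 1, lambdaExtra = 1) {
  n <- nCases + nControls
  if (length(theta) == 2L && n != 2L) {
    conc <- theta[1] * (1 - theta[1]) / theta[2]^2 - 1
    th <- stats::rbeta(n, theta[1] * conc, (1 - theta[1]) * conc)
  } else {
    stopIf(length(theta) != n, "theta must have length nCases + nControls")
    th <- theta
  }
  status <- rep(c(1L, 0L), c(nCases, nControls))
  lam <- lambdaOf(r, pA, pE) * lambdaExtra
  pOrig <- ifelse(status == 1L, lam * th / (lam * th + 1 - th), th)
  qA <- ifelse(status == 1L, pA * r / (1 + (r - 1) * pA), pA)
  qE <- ifelse(status == 1L, pE * r / (1 + (r - 1) * pE), pE)
  o1 <- stats::rbinom(n, 1L, pOrig); o2 <- stats::rbinom(n, 1L, pOrig)
  x1 <- stats::rbinom(n, 1L, ifelse(o1 == 1L, qA, qE))
  x2 <- stats::rbinom(n, 1L, ifelse(o2 == 1L, qA, qE))
  list(g = x1 + x2, a = o1 + o2, status = status, theta = th)
}
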