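#' Ancestry-based relationship matrix
#'
#' The local-ancestry analogue of a genetic relationship matrix: the
#' African-allele count is used in place of the genotype, standardised
#' locus-wise, `A_jk = (1/M) sum_m (a_jm - 2 pbar_m)(a_km - 2 pbar_m) /
#' (2 pbar_m (1 - pbar_m))` with `pbar_m` the sample mean African ancestry
#' proportion at marker `m`. Markers without ancestry variance are dropped
#' from `M`.
#'
#' @param ancestry marker-by-individual matrix of African-allele counts
#'   0/1/2.
#' @param standardize divide each locus by `2 pbar (1 - pbar)`? With
#'   `FALSE`, the raw centred covariance is used.
#' @return n x n symmetric matrix with attributes `M` (markers used) and
#'   `source = "ancestry"`.
#' @export
ancestryGRM <- function(ancestry, standardize = TRUE) {
  stopIf(ncol(ancestry) < 2L, "at least two individuals required")
  v <- apply(ancestry, 1L, stats::var)
  keep <- which(v > 0)
  stopIf(length(keep) == 0L, "no marker with ancestry variance")
  a <- ancestry[keep, , drop = FALSE]
  pbar <- rowMeans(a) / 2
  Z <- a - 2 * pbar
  if (standardize) Z <- Z / sqrt(2 * pbar * (1 - pbar))
  K <- crossprod(Z) / length(keep)
  structure(K, M = length(keep), source = "ancestry")
}

#' Genotype-based relationship matrix
#'
#' Standard allele-frequency-standardised GRM over markers with minor
#' allele frequency above `mafFloor` (common variants). Missing genotypes
#' are mean-imputed per marker before standardisation.
#'
#' @param genotypes marker-by-individual matrix of allele counts 0/1/2,
#'   `NA` missing.
#' @param mafFloor markers with MAF at or below this are excluded
#'   (default 0.01).
#' @return n x n symmetric matrix with attributes `M`, `source =
#'   "genotype"`.
#' @export
genotypeGRM <- function(genotypes, mafFloor = 0.01) {
  stopIf(ncol(genotypes) < 2L, "at least two individuals required")
  p <- rowMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(maf > mafFloor)
  stopIf(length(keep) == 0L, "no marker retained above the MAF floor")
  g <- genotypes[keep, , drop = FALSE]
  p <- p[keep]
  g[is.na(g)] <- (2 * p)[row(g)[is.na(g)]]
  Z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  K <- crossprod(Z) / length(keep)
  structure(K, M = length(keep), source = "genotype")
}

# REML log-likelihood pieces on the rotated scale. d = h*lambda + (1-h).
.remlProfile <- function(h, lam, yr, Xr) {
  d <- h * lam + (1 - h)
  if (any(d <= 0)) return(list(ll = -Inf))
  w <- 1 / d
  XtWX <- crossprod(Xr, Xr * w)
  XtWy <- crossprod(Xr, yr * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  quad <- sum(yr^2 * w) - sum(XtWy * beta)
  n <- length(yr); p <- ncol(Xr)
  if (quad <= 0) return(list(ll = -Inf))
  s2 <- quad / (n - p)
  ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(ch))) +
                  (n - p) * (log(s2) + 1 + log(2 * pi)))
  list(ll = ll, s2 = s2, beta = beta)
}

#' Single-component REML for a binary (or quantitative) trait
#'
#' Restricted maximum likelihood for the model
#' `y = X beta + g + e`, `g ~ N(0, sigma2_a K)`, `e ~ N(0, sigma2_e I)`,
#' fitted on the observed scale (0/1 phenotypes are analysed directly; see
#' [liabilityTransform()]). The GRM is eigendecomposed once and the REML
#' log-likelihood profiled over `h2 = sigma2_a / (sigma2_a + sigma2_e)`,
#' which is maximised globally by a bracketing grid plus Brent search. The
#' SE of `h2` comes from the inverse curvature (numerical Hessian) of the
#' REML log-likelihood in `(sigma2_a, sigma2_e)` via the delta method; the
#' LRT against `sigma2_a = 0` is referred to a 1-df chi-square.
#'
#' @param y phenotype vector (0/1 case status in the intended use).
#' @param X fixed-effects design matrix (global ancestry and sex in the
#'   intended use); an intercept is added if absent.
#' @param K relationship matrix from [ancestryGRM()] or [genotypeGRM()].
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`, useful when
#'   refitting many phenotypes on one GRM.
#' @param prevalence population prevalence for the liability transform
#'   (`NA` to skip).
#' @return a [VarianceComponents-class] object.
#' @export
remlFit <- function(y, X = NULL, K, eig = NULL, prevalence = NA_real_) {
  n <- length(y)
  stopIf(nrow(K) != n, "K must be n x n")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0)))
    X <- cbind(1, X)
  stopIf(n <= ncol(X), "more covariates than samples")
  offDiag <- K; diag(offDiag) <- 0
  stopIf(max(abs(offDiag)) < 1e-10 && stats::sd(diag(K)) < 1e-10,
         "K proportional to the identity: variance components not identifiable")
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)  # clamp tiny negative eigenvalues
  U <- eig$vectors
  yr <- crossprod(U, y)[, 1]
  Xr <- crossprod(U, X)
  f <- function(h) .remlProfile(h, lam, yr, Xr)$ll
  opt <- maximize1d(f, 0, 1 - 1e-6)
  h <- opt$maximum
  if (f(0) >= opt$objective) { h <- 0; opt$objective <- f(0) }
  prof <- .remlProfile(h, lam, yr, Xr)
  s2 <- prof$s2
  sigmaA <- h * s2; sigmaE <- (1 - h) * s2
  ll0 <- f(0)
  lrt <- max(0, 2 * (opt$objective - ll0))
  # full (unprofiled) REML loglik at (sa, se), for the curvature-based SE
  llFull <- function(sa, se) {
    d <- sa * lam + se
    if (any(d <= 0)) return(-Inf)
    w <- 1 / d
    XtWX <- crossprod(Xr, Xr * w)
    XtWy <- crossprod(Xr, yr * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    quad <- sum(yr^2 * w) - sum(XtWy * beta)
    -0.5 * (sum(log(d)) + 2 * sum(log(diag(ch))) + quad +
              (length(yr) - ncol(Xr)) * log(2 * pi))
  }
  h2SE <- NA_real_
  sa0 <- max(sigmaA, 1e-6 * s2); se0 <- max(sigmaE, 1e-6 * s2)
  step <- 1e-4 * s2
  Hm <- matrix(NA_real_, 2, 2)
  fc <- llFull(sa0, se0)
  Hm[1, 1] <- (llFull(sa0 + step, se0) - 2 * fc + llFull(sa0 - step, se0)) / step^2
  Hm[2, 2] <- (llFull(sa0, se0 + step) - 2 * fc + llFull(sa0, se0 - step)) / step^2
  Hm[1, 2] <- Hm[2, 1] <-
    (llFull(sa0 + step, se0 + step) - llFull(sa0 + step, se0 - step) -
       llFull(sa0 - step, se0 + step) + llFull(sa0 - step, se0 - step)) /
    (4 * step^2)
  covM <- tryCatch(solve(-Hm), error = function(e) NULL)
  if (!is.null(covM) && all(is.finite(covM)) && all(diag(covM) > 0)) {
    tot <- sa0 + se0
    grad <- c(se0, -sa0) / tot^2
    v <- drop(t(grad) %*% covM %*% grad)
    if (is.finite(v) && v > 0) h2SE <- sqrt(v)
  }
  caseProp <- if (all(y %in% c(0, 1))) mean(y) else NA_real_
  h2Liab <- if (is.finite(prevalence) && is.finite(caseProp) &&
                caseProp > 0 && caseProp < 1)
    liabilityTransform(h, prevalence, caseProp) else NA_real_
  new("VarianceComponents", sigmaA = sigmaA, sigmaE = sigmaE,
      h2Obs = h, h2SE = h2SE, h2Liab = h2Liab,
      prevalence = prevalence, caseProp = caseProp %||% NA_real_,
      lrt = lrt, p = chisq1P(lrt), logLik = opt$objective,
      n = as.integer(n),
      source = attr(K, "source") %||% "unknown")
}

#' Observed-scale to liability-scale heritability
#'
#' The ascertainment-corrected threshold-model transform for case-control
#' samples: `h2_liab = h2_obs K^2 (1 - K)^2 / (z^2 P (1 - P))`, where `K`
#' is the population prevalence, `P` the sample case proportion, and `z`
#' the standard normal density at the liability threshold (the `(1 - K)`
#' quantile). Values above 1 are capped with a warning.
#'
#' @param h2Obs observed-scale heritability in `[0, 1]`.
#' @param K population prevalence in `(0, 1)` (1/1000 for the disease this
#'   package targets).
#' @param P sample case proportion in `(0, 1)`.
#' @return liability-scale heritability.
#' @export
liabilityTransform <- function(h2Obs, K, P) {
  stopIf(K <= 0 || K >= 1 || P <= 0 || P >= 1,
         "K and P must lie strictly inside (0, 1)")
  stopIf(h2Obs < 0 || h2Obs > 1, "h2Obs must lie in [0, 1]")
  z <- stats::dnorm(stats::qnorm(1 - K))
  out <- h2Obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  if (out > 1) {
    warning("liability-scale heritability capped at 1")
    out <- 1
  }
  out
}

.markersInRegion <- function(cohort, region) {
  if (is.null(region)) return(logical(nrow(cohort)))
  pos <- start(markerInfo(cohort))
  pos >= region[1] & pos <= region[2]  # closed interval, 1-based
}

#' Heritability of liability from local ancestry or genotypes
#'
#' The full heritability pathway: restrict to pedigree-unrelated
#' individuals (coefficient of relationship < `relationshipMax`), build the
#' ancestry or genotype relationship matrix (optionally excluding a closed
#' genomic region), fit the single-component REML of case status on the
#' observed scale with global ancestry and sex as fixed effects, and
#' transform to the liability scale at the given prevalence.
#'
#' @param cohort an [AdmixedCohort-class] with phenotypes.
#' @param source `"ancestry"` or `"genotype"` relationship matrix.
#' @param prevalence population prevalence (default 1/1000).
#' @param region optional `c(start, end)` closed interval of marker
#'   positions to exclude from the matrix.
#' @param subgroup optional case subphenotype label; cases are restricted
#'   to that label (all controls kept) and the case proportion recomputed.
#' @param relationshipMax retain individuals whose pairwise coefficient of
#'   relationship is strictly below this (default 0.125, first cousins).
#' @param eig optional precomputed eigendecomposition (advanced use;
#'   only valid with `region = NULL` and no subsetting changes).
#' @return a [VarianceComponents-class].
#' @export
fitHeritability <- function(cohort, source = c("ancestry", "genotype"),
                            prevalence = 0.001, region = NULL,
                            subgroup = NULL, relationshipMax = 0.125,
                            eig = NULL) {
  source <- match.arg(source)
  s <- sampleInfo(cohort)
  keep <- !is.na(s$status)
  if (!is.null(subgroup)) {
    stopIf(!any(s$subphenotype == subgroup & s$status == 1L, na.rm = TRUE),
           "empty case subgroup '%s'", subgroup)
    keep <- keep & (s$status == 0L |
                      (!is.na(s$subphenotype) & s$subphenotype == subgroup))
  }
  ped <- cohortPedigree(cohort)
  if (!is.null(ped)) {
    rel <- pedigreeRelationship(ped)
    ids <- intersect(unrelatedSubset(rel, threshold = relationshipMax),
                     s$id[keep])
    keep <- keep & s$id %in% ids
  }
  idx <- which(keep)
  stopIf(length(idx) < 10L, "too few individuals for REML (%d)", length(idx))
  inRegion <- .markersInRegion(cohort, region)
  stopIf(!is.null(region) && all(inRegion),
         "region excludes all markers")
  mat <- if (source == "ancestry")
    localAncestry(cohort)[!inRegion, idx, drop = FALSE]
  else genotypes(cohort)[!inRegion, idx, drop = FALSE]
  K <- if (source == "ancestry") ancestryGRM(mat) else genotypeGRM(mat)
  y <- s$status[idx]
  X <- cbind(1, theta = s$theta[idx], female = as.integer(s$sex[idx] == 2L))
  remlFit(y, X, K, eig = eig, prevalence = prevalence)
}

#' Effect of removing an admixture locus on heritability
#'
#' Re-estimates heritability with all markers in the closed interval
#' `region` excluded from the relationship matrix, and reports the full and
#' region-removed estimates with their difference.
#'
#' @inheritParams fitHeritability
#' @param region `c(start, end)` closed interval of positions to drop.
#' @return list with `full` and `dropped` ([VarianceComponents-class]) and
#'   `difference` (`full h2 - dropped h2`, observed scale).
#' @export
dropRegionHeritability <- function(cohort, source = c("ancestry", "genotype"),
                                   region, prevalence = 0.001, ...) {
  source <- match.arg(source)
  full <- fitHeritability(cohort, source, prevalence = prevalence, ...)
  dropped <- fitHeritability(cohort, source, prevalence = prevalence,
                             region = region, ...)
  list(full = full, dropped = dropped,
       difference = full@h2Obs - dropped@h2Obs)
}

#' Heritability for a case subphenotype versus controls
#'
#' @inheritParams fitHeritability
#' @param subgroup subphenotype label (`"resolved"`, `"stage1_3"`,
#'   `"stage4"`) compared against all controls.
#' @return a [VarianceComponents-class].
#' @export
subgroupHeritability <- function(cohort, subgroup,
                                 source = c("ancestry", "genotype"),
                                 prevalence = 0.001, ...) {
  fitHeritability(cohort, match.arg(source), prevalence = prevalence,
                  subgroup = subgroup, ...)
}
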