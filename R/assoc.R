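#' Logistic estimating equations with cluster-robust variance
#'
#' Fits a logistic model by ordinary maximum likelihood — which is exactly
#' the estimating-equation solution under an independence working
#' correlation — and computes the cluster-robust (sandwich) covariance,
#' treating each family as a cluster: `V = B M B` with bread
#' `B = (X'WX)^-1` and meat `M = sum_c s_c s_c'`, where `s_c` is the summed
#' score `x_i (y_i - mu_i)` over cluster `c` (HC0-style, no small-sample
#' correction by default).
#'
#' @param y binary outcome vector.
#' @param X design matrix (including intercept), full column rank.
#' @param clusters cluster (family) ids partitioning the samples; with every
#'   individual its own cluster this reduces to the heteroskedasticity-
#'   robust sandwich around the ordinary logistic MLE.
#' @param smallSample apply the `G/(G-1)` cluster correction to the meat?
#' @return list with `coef`, `vcov`, `se`, `z`, `p`, `n`, `nClusters`.
#' @export
geeLogistic <- function(y, X, clusters, smallSample = FALSE) {
  X <- as.matrix(X)
  stopIf(length(y) != nrow(X), "y and X dimensions disagree")
  stopIf(length(clusters) != length(y),
         "clusters must have one value per sample")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient (column(s): ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  sep <- !fit$converged || max(abs(beta)) > 15 ||
    (any(mu > 1 - 1e-8 | mu < 1e-8) && max(abs(beta)) > 10)
  if (sep) {
    worst <- colnames(X)[which.max(abs(beta))] %||% which.max(abs(beta))
    stop("perfect or quasi-perfect separation detected (column: ",
         worst, ")", call. = FALSE)
  }
  W <- mu * (1 - mu)
  bread <- solve(crossprod(X, X * W))
  sc <- X * (y - mu)
  scByCl <- rowsum(sc, group = clusters)
  meat <- crossprod(scByCl)
  G <- nrow(scByCl)
  if (smallSample) meat <- meat * G / (G - 1)
  V <- bread %*% meat %*% bread
  se <- sqrt(diag(V))
  z <- beta / se
  list(coef = beta, vcov = V, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), n = length(y), nClusters = G)
}

.assocData <- function(cohort, marker, codeMinor = TRUE) {
  mids <- markerInfo(cohort)$id
  i <- match(marker, mids)
  stopIf(is.na(i), "marker '%s' not present in cohort", marker)
  g <- genotypes(cohort)[i, ]
  s <- sampleInfo(cohort)
  flip <- FALSE
  if (codeMinor && mean(g, na.rm = TRUE) / 2 > 0.5) {
    g <- 2L - g
    flip <- TRUE
  }
  list(i = i, g = g, a = localAncestry(cohort)[i, ], status = s$status,
       theta = s$theta, female = as.integer(s$sex == 2L),
       cluster = s$familyId, flipped = flip,
       allele = if (flip) markerInfo(cohort)$ref[i]
                else markerInfo(cohort)$alt[i])
}

#' Single-marker ancestry-aware association
#'
#' GEE logistic fit of case status on the risk-allele count under the
#' multiplicative (log-additive) model, with global African ancestry and sex
#' as covariates in every model and, optionally, the local-ancestry dosage
#' at the marker. `OR = exp(beta)` with Wald 95% CI
#' `exp(beta +/- 1.96 SE)` from the cluster-robust variance. The coded
#' allele is the cohort minor allele; individuals missing the tested
#' genotype are dropped for that marker only.
#'
#' @param cohort an [AdmixedCohort-class] with phenotypes assigned.
#' @param marker marker id.
#' @param adjustLocalAncestry include the local African-allele count at the
#'   marker as a covariate?
#' @param extraCovariates optional numeric matrix of additional covariates
#'   (rows in cohort sample order).
#' @param codeMinor orient the coded allele to the cohort minor allele?
#' @return one-row data.frame: `marker`, `allele`, `beta`, `se`, `or`,
#'   `ciLow`, `ciHigh`, `p`, `fCase`, `fControl`, `adjustedLocal`, `n`,
#'   `nClusters`.
#' @export
snpAssociation <- function(cohort, marker, adjustLocalAncestry = FALSE,
                           extraCovariates = NULL, codeMinor = TRUE) {
  d <- .assocData(cohort, marker, codeMinor)
  keep <- !is.na(d$g) & !is.na(d$status)
  g <- d$g[keep]
  stopIf(stats::var(g) == 0, "marker '%s' is monomorphic", marker)
  X <- cbind(`(Intercept)` = 1, genotype = g, theta = d$theta[keep],
             female = d$female[keep])
  if (adjustLocalAncestry)
    X <- cbind(X, localAncestry = d$a[keep])
  if (!is.null(extraCovariates)) {
    ec <- as.matrix(extraCovariates)
    X <- cbind(X, ec[keep, , drop = FALSE])
  }
  fit <- geeLogistic(d$status[keep], X, d$cluster[keep])
  b <- fit$coef["genotype"]; se <- fit$se["genotype"]
  st <- d$status[keep]
  data.frame(marker = marker, allele = d$allele,
             beta = unname(b), se = unname(se),
             or = exp(unname(b)),
             ciLow = exp(unname(b - 1.96 * se)),
             ciHigh = exp(unname(b + 1.96 * se)),
             p = unname(fit$p["genotype"]),
             fCase = mean(g[st == 1L]) / 2,
             fControl = mean(g[st == 0L]) / 2,
             adjustedLocal = adjustLocalAncestry,
             n = fit$n, nClusters = fit$nClusters,
             stringsAsFactors = FALSE)
}

#' Confounding of an allelic effect by local ancestry
#'
#' The absolute difference between the local-ancestry-adjusted and
#' unadjusted log odds ratios, divided by the absolute unadjusted log odds
#' ratio.
#'
#' @param betaAdjusted,betaUnadjusted log odds ratios from the adjusted and
#'   unadjusted fits.
#' @return non-negative proportion.
#' @export
confoundingRatio <- function(betaAdjusted, betaUnadjusted) {
  stopIf(any(betaUnadjusted == 0),
         "confounding ratio undefined for zero unadjusted log OR")
  abs(betaAdjusted - betaUnadjusted) / abs(betaUnadjusted)
}

#' Stratified odds ratios by local-ancestry count
#'
#' Fits the association separately within strata of individuals carrying
#' zero, one, or two African alleles at the marker (same covariates as
#' [snpAssociation()] minus local ancestry). An empty or monomorphic
#' stratum is reported as unavailable rather than raising an error.
#'
#' @inheritParams snpAssociation
#' @return data.frame with one row per stratum (`ancestry` = 0, 1, 2) and an
#'   `available` flag.
#' @export
stratifiedOrByAncestry <- function(cohort, marker, codeMinor = TRUE) {
  d <- .assocData(cohort, marker, codeMinor)
  out <- lapply(0:2, function(stratum) {
    keep <- which(d$a == stratum & !is.na(d$g) & !is.na(d$status))
    base <- data.frame(ancestry = stratum, available = FALSE, or = NA_real_,
                       ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
                       n = length(keep))
    if (length(keep) < 10L || stats::var(d$g[keep]) == 0 ||
          stats::var(d$status[keep]) == 0)
      return(base)
    X <- cbind(`(Intercept)` = 1, genotype = d$g[keep],
               theta = d$theta[keep], female = d$female[keep])
    fit <- tryCatch(geeLogistic(d$status[keep], X, d$cluster[keep]),
                    error = function(e) NULL)
    if (is.null(fit)) return(base)
    b <- fit$coef["genotype"]; se <- fit$se["genotype"]
    data.frame(ancestry = stratum, available = TRUE, or = exp(unname(b)),
               ciLow = exp(unname(b - 1.96 * se)),
               ciHigh = exp(unname(b + 1.96 * se)),
               p = unname(fit$p["genotype"]), n = length(keep))
  })
  do.call(rbind, out)
}

#' Case-control local-ancestry association, optionally conditional on SNPs
#'
#' GEE logistic fit of case status on the local African-allele count at a
#' locus, adjusted for global ancestry and sex, and optionally conditioned
#' on the genotypes of one or more candidate SNPs. A non-significant
#' ancestry p after conditioning indicates the SNPs explain the admixture
#' signal.
#'
#' @param cohort an [AdmixedCohort-class].
#' @param locus marker id whose local ancestry is tested.
#' @param conditioningMarkers character vector of marker ids whose genotypes
#'   enter as covariates.
#' @return one-row data.frame: `locus`, `beta`, `se`, `or`, `ciLow`,
#'   `ciHigh`, `p`, `nConditioning`, `n`.
#' @export
laAssociation <- function(cohort, locus, conditioningMarkers = character()) {
  mids <- markerInfo(cohort)$id
  i <- match(locus, mids)
  stopIf(is.na(i), "locus '%s' not present in cohort", locus)
  s <- sampleInfo(cohort)
  a <- localAncestry(cohort)[i, ]
  stopIf(stats::var(a) == 0, "zero-variance local ancestry at locus '%s'",
         locus)
  X <- cbind(`(Intercept)` = 1, localAncestry = a, theta = s$theta,
             female = as.integer(s$sex == 2L))
  keep <- !is.na(s$status)
  for (cm in conditioningMarkers) {
    j <- match(cm, mids)
    stopIf(is.na(j), "conditioning marker '%s' not present", cm)
    gj <- genotypes(cohort)[j, ]
    X <- cbind(X, gj)
    colnames(X)[ncol(X)] <- cm
    keep <- keep & !is.na(gj)
  }
  fit <- geeLogistic(s$status[keep], X[keep, , drop = FALSE],
                     s$familyId[keep])
  b <- fit$coef["localAncestry"]; se <- fit$se["localAncestry"]
  data.frame(locus = locus, beta = unname(b), se = unname(se),
             or = exp(unname(b)), ciLow = exp(unname(b - 1.96 * se)),
             ciHigh = exp(unname(b + 1.96 * se)),
             p = unname(fit$p["localAncestry"]),
             nConditioning = length(conditioningMarkers), n = fit$n,
             stringsAsFactors = FALSE)
}

#' Forward selection of independently associated markers in a region
#'
#' Iteratively adds the marker with the smallest conditional p-value
#' (conditioning on the genotypes of all previously selected markers, with
#' global ancestry and sex always included), stopping when the best
#' conditional p exceeds `alpha` or `maxSteps` is reached. Markers perfectly
#' correlated with an already-selected marker are skipped (collinearity
#' guard); p-value ties break by genomic position.
#'
#' @param cohort an [AdmixedCohort-class].
#' @param markers marker ids of the region (>= 1).
#' @param alpha stopping threshold on the conditional p-value.
#' @param maxSteps maximum number of markers selected.
#' @return data.frame of selected markers in order, with their conditional
#'   association results (`step`, plus [snpAssociation()] columns).
#' @export
forwardSelect <- function(cohort, markers, alpha = 0.05, maxSteps = 10L) {
  stopIf(length(markers) < 1L, "at least one marker required")
  mids <- markerInfo(cohort)$id
  stopIf(!all(markers %in% mids), "unknown marker(s): %s",
         paste(setdiff(markers, mids), collapse = ", "))
  pos <- start(markerInfo(cohort))[match(markers, mids)]
  selected <- character()
  results <- list()
  G <- genotypes(cohort)
  repeat {
    if (length(selected) >= maxSteps) break
    candidates <- setdiff(markers, selected)
    if (!length(candidates)) break
    cond <- if (length(selected))
      t(G[match(selected, mids), , drop = FALSE]) else NULL
    fits <- lapply(candidates, function(mk) {
      gk <- G[match(mk, mids), ]
      if (length(selected)) {
        r2 <- vapply(selected, function(smk) {
          gs <- G[match(smk, mids), ]
          ok <- !is.na(gk) & !is.na(gs)
          if (stats::var(gk[ok]) == 0 || stats::var(gs[ok]) == 0) return(1)
          stats::cor(gk[ok], gs[ok])^2
        }, numeric(1))
        if (any(r2 > 1 - 1e-8)) return(NULL)
      }
      tryCatch(snpAssociation(cohort, mk, extraCovariates = cond),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) break
    ps <- vapply(fits[ok], function(f) f$p, numeric(1))
    cand <- candidates[ok]
    ord <- order(ps, pos[match(cand, markers)])
    best <- ord[1L]
    if (ps[best] > alpha) break
    selected <- c(selected, cand[best])
    row <- fits[ok][[best]]
    row$step <- length(selected)
    results[[length(results) + 1L]] <- row
  }
  if (!length(results))
    return(data.frame(step = integer(), marker = character(),
                      p = numeric()))
  do.call(rbind, results)
}

#' Composite linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages (composite LD; no
#' phasing needed).
#'
#' @param genotypesA,genotypesB dosage vectors for the two markers over the
#'   same individuals.
#' @return r-squared in `[0, 1]`.
#' @export
ldR2 <- function(genotypesA, genotypesB) {
  stopIf(length(genotypesA) != length(genotypesB),
         "genotype vectors must cover the same individuals")
  ok <- !is.na(genotypesA) & !is.na(genotypesB)
  stopIf(stats::var(genotypesA[ok]) == 0 || stats::var(genotypesB[ok]) == 0,
         "both markers must be polymorphic")
  stats::cor(genotypesA[ok], genotypesB[ok])^2
}
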