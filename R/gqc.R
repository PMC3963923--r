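#' Quality-control thresholds
#'
#' Defaults reproduce a standard GWAS marker/sample screen: markers kept at
#' call rate > 0.95, minor allele frequency > 0.01, Hardy-Weinberg exact
#' p > 1e-4 in cases and > 1e-3 in controls, and case-control differential
#' missingness p > 1e-3; samples kept at call rate >= 0.90, heterozygosity
#' within 5 SD of the mean, and no duplicate/cryptic-relative pair with IBD
#' proportion > 0.25; genotype posterior calls require probability >= 0.9.
#'
#' @param minCallRate,minMAF,hweCaseFloor,hweControlFloor,diffMissFloor
#'   marker thresholds.
#' @param sampleCallRate,hetSdBound,duplicateIbd,posteriorThreshold sample
#'   and genotype-calling thresholds.
#' @return a list of class `qcThresholds`.
#' @export
qcThresholds <- function(minCallRate = 0.95, minMAF = 0.01,
                         hweCaseFloor = 1e-4, hweControlFloor = 1e-3,
                         diffMissFloor = 1e-3, sampleCallRate = 0.90,
                         hetSdBound = 5, duplicateIbd = 0.25,
                         posteriorThreshold = 0.9) {
  props <- c(minCallRate, minMAF, sampleCallRate, duplicateIbd,
             posteriorThreshold)
  stopIf(any(props < 0 | props > 1), "proportions must lie in [0, 1]")
  stopIf(hetSdBound <= 0, "hetSdBound must be positive")
  structure(list(minCallRate = minCallRate, minMAF = minMAF,
                 hweCaseFloor = hweCaseFloor,
                 hweControlFloor = hweControlFloor,
                 diffMissFloor = diffMissFloor,
                 sampleCallRate = sampleCallRate, hetSdBound = hetSdBound,
                 duplicateIbd = duplicateIbd,
                 posteriorThreshold = posteriorThreshold),
            class = "qcThresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditional on the allele counts: the p-value is the
#' summed probability mass of all heterozygote configurations no more
#' probable than the observed one (Wigginton-style enumeration).
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative, total >= 1).
#' @return p-value in `(0, 1]`.
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  stopIf(any(counts < 0) || any(counts != round(counts)),
         "genotype counts must be non-negative integers")
  n <- sum(counts)
  stopIf(n < 1, "total genotype count must be >= 1")
  nAlt <- 2L * nHomAlt + nHet
  nRef <- 2L * nHomRef + nHet
  rare <- min(nAlt, nRef)
  if (rare == 0L) return(1)  # monomorphic: single configuration
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(nHet = h | allele counts): multivariate conditional distribution
  lp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - rare - hets) / 2 + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(nHet, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Marker quality control
#'
#' Applies the marker screen: a marker fails when its call rate is at or
#' below `minCallRate`, its minor allele frequency at or below `minMAF`,
#' its Hardy-Weinberg exact p at or below the case or control floor, or the
#' Fisher exact test of case-control differential missingness at or below
#' `diffMissFloor`. Every marker appears exactly once in the report.
#'
#' Imputed markers may additionally carry a precomputed imputation-quality
#' (info) measure, thresholded at `infoFloor`; the measure is never
#' recomputed here.
#'
#' @param genotypes marker-by-individual matrix of counts 0/1/2, `NA`
#'   missing.
#' @param status 0/1 case status per individual.
#' @param thresholds a [qcThresholds()].
#' @param info optional per-marker imputation info measure (`NA` for
#'   directly genotyped markers).
#' @param infoFloor markers with `info < infoFloor` fail (default 0.5).
#' @return data.frame with one row per marker: metrics, `pass`, and a
#'   comma-separated `reasons` string for failures.
#' @export
markerQC <- function(genotypes, status, thresholds = qcThresholds(),
                     info = NULL, infoFloor = 0.5) {
  stopIf(!is.matrix(genotypes) || nrow(genotypes) == 0L ||
           ncol(genotypes) == 0L, "genotypes must be a non-empty matrix")
  stopIf(length(status) != ncol(genotypes),
         "status must have one value per individual")
  isCase <- status == 1L
  M <- nrow(genotypes)
  res <- data.frame(marker = rownames(genotypes) %||%
                      sprintf("m%d", seq_len(M)),
                    callRate = NA_real_, maf = NA_real_,
                    hweCase = NA_real_, hweControl = NA_real_,
                    diffMissP = NA_real_, pass = TRUE,
                    reasons = "", stringsAsFactors = FALSE)
  for (m in seq_len(M)) {
    g <- genotypes[m, ]
    obs <- !is.na(g)
    cr <- mean(obs)
    af <- mean(g[obs]) / 2
    maf <- min(af, 1 - af)
    tabC <- tabulate(g[obs & isCase] + 1L, 3L)
    tabU <- tabulate(g[obs & !isCase] + 1L, 3L)
    hweC <- if (sum(tabC) > 0) hweExactTest(tabC[1], tabC[2], tabC[3]) else NA
    hweU <- if (sum(tabU) > 0) hweExactTest(tabU[1], tabU[2], tabU[3]) else NA
    missTab <- rbind(case = c(sum(!obs & isCase), sum(obs & isCase)),
                     control = c(sum(!obs & !isCase), sum(obs & !isCase)))
    dm <- if (all(rowSums(missTab) > 0))
      stats::fisher.test(missTab)$p.value else NA
    reasons <- character()
    if (cr <= thresholds$minCallRate) reasons <- c(reasons, "call_rate")
    if (is.na(maf) || maf <= thresholds$minMAF) reasons <- c(reasons, "maf")
    if (!is.na(hweC) && hweC <= thresholds$hweCaseFloor)
      reasons <- c(reasons, "hwe_case")
    if (!is.na(hweU) && hweU <= thresholds$hweControlFloor)
      reasons <- c(reasons, "hwe_control")
    if (!is.na(dm) && dm <= thresholds$diffMissFloor)
      reasons <- c(reasons, "diff_missingness")
    if (!is.null(info) && !is.na(info[m]) && info[m] < infoFloor)
      reasons <- c(reasons, "imputation_info")
    res$callRate[m] <- cr; res$maf[m] <- maf
    res$hweCase[m] <- hweC; res$hweControl[m] <- hweU
    res$diffMissP[m] <- dm
    res$pass[m] <- length(reasons) == 0L
    res$reasons[m] <- paste(reasons, collapse = ",")
  }
  res
}

#' Sample quality control
#'
#' Flags samples with call rate below `sampleCallRate`, heterozygosity more
#' than `hetSdBound` SD from the cohort mean, or membership in a
#' duplicate/cryptic-relative pair (IBD proportion above `duplicateIbd` in
#' the supplied relatedness matrix among pairs expected unrelated); of each
#' such pair the sample with the lower id is retained. Applied cohort-wide;
#' pairs within the same declared family can be exempted via
#' `withinFamilies = FALSE`.
#'
#' @param genotypes marker-by-individual matrix.
#' @param relatedness optional symmetric matrix of IBD proportions
#'   (e.g. `2 *` [kingKinship()]); duplicates are skipped when `NULL`.
#' @param thresholds a [qcThresholds()].
#' @param familyId optional family ids; with `withinFamilies = FALSE`,
#'   same-family pairs are not screened as duplicates.
#' @param withinFamilies apply the duplicate screen within families too?
#' @return data.frame with one row per sample: metrics, `pass`, `reasons`.
#' @export
sampleQC <- function(genotypes, relatedness = NULL,
                     thresholds = qcThresholds(), familyId = NULL,
                     withinFamilies = TRUE) {
  n <- ncol(genotypes)
  stopIf(n < 2L, "at least two samples required")
  ids <- colnames(genotypes) %||% sprintf("s%d", seq_len(n))
  cr <- colMeans(!is.na(genotypes))
  het <- colMeans(genotypes == 1L, na.rm = TRUE)
  z <- (het - mean(het)) / stats::sd(het)
  if (!is.finite(stats::sd(het)) || stats::sd(het) == 0) z <- rep(0, n)
  dupFlag <- rep(FALSE, n)
  if (!is.null(relatedness)) {
    stopIf(!all(dim(relatedness) == n),
           "relatedness matrix must be %d x %d", n, n)
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (!withinFamilies && !is.null(familyId) &&
            familyId[i] == familyId[j]) next
      if (relatedness[i, j] > thresholds$duplicateIbd) {
        drop <- if (ids[i] <= ids[j]) j else i  # lower id retained
        dupFlag[drop] <- TRUE
      }
    }
  }
  reasons <- vapply(seq_len(n), function(i) {
    r <- character()
    if (cr[i] < thresholds$sampleCallRate) r <- c(r, "call_rate")
    if (abs(z[i]) > thresholds$hetSdBound) r <- c(r, "heterozygosity")
    if (dupFlag[i]) r <- c(r, "duplicate")
    paste(r, collapse = ",")
  }, character(1))
  data.frame(id = ids, callRate = cr, hetRate = het, hetZ = z,
             pass = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call genotypes from posterior probabilities
#'
#' The most likely genotype is called when its posterior probability reaches
#' the threshold (inclusive); otherwise the genotype is set missing.
#'
#' @param posteriors length-3 vector or n-by-3 matrix of genotype posterior
#'   probabilities (each row non-negative, summing to 1 within 1e-6).
#' @param threshold posterior required to make a call (default 0.9).
#' @return integer genotype(s) 0/1/2, `NA` when below threshold.
#' @export
callFromProbabilities <- function(posteriors, threshold = 0.9) {
  p <- if (is.matrix(posteriors)) posteriors else matrix(posteriors, 1L)
  stopIf(ncol(p) != 3L, "posteriors must have three columns")
  stopIf(any(p < 0), "posterior probabilities must be non-negative")
  stopIf(any(abs(rowSums(p) - 1) > 1e-6),
         "each posterior triple must sum to 1")
  best <- max.col(p, ties.method = "first")
  out <- ifelse(p[cbind(seq_len(nrow(p)), best)] >= threshold,
                best - 1L, NA_integer_)
  as.integer(out)
}
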