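#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowRanges assayNames
#' @importFrom GenomicRanges GRanges start
#' @importFrom IRanges IRanges
NULL

#' Container for a two-way admixed case-control cohort
#'
#' `AdmixedCohort` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with two marker-by-individual assays: `genotype` (risk/coded-allele counts
#' 0/1/2, `NA` = missing) and `localAncestry` (counts 0/1/2 of African-origin
#' alleles). `rowRanges` holds the marker map (1-based positions, alleles and,
#' when known, the ancestral allele frequencies `fAFR`/`fCEU`); `colData`
#' holds one row per individual: `id`, `familyId`, `sex` (1 = male,
#' 2 = female), `status` (0/1), `subphenotype` (`"resolved"`, `"stage1_3"`,
#' `"stage4"`, or `NA` for controls and cases without follow-up) and the
#' global African ancestry proportion `theta`. A 6-column linkage pedigree,
#' when available, lives in `metadata(x)$pedigree`.
#'
#' @seealso [simulateCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("AdmixedCohort", contains = "RangedSummarizedExperiment")

setValidity("AdmixedCohort", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("genotype", "localAncestry") %in% an))
    msg <- c(msg, "assays must include 'genotype' and 'localAncestry'")
  else {
    g <- assay(object, "genotype")
    a <- assay(object, "localAncestry")
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype values must be 0/1/2 or NA")
    if (anyNA(a) || !all(a %in% c(0L, 1L, 2L)))
      msg <- c(msg, "localAncestry values must be 0/1/2 with no missing")
  }
  cd <- colData(object)
  need <- c("id", "familyId", "sex", "status")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if ("status" %in% colnames(cd) && !all(cd$status %in% c(0L, 1L, NA)))
    msg <- c(msg, "status must be 0/1 (NA allowed before phenotype assignment)")
  if ("theta" %in% colnames(cd)) {
    th <- cd$theta
    if (any(th < 0 | th > 1, na.rm = TRUE))
      msg <- c(msg, "theta must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AdmixedCohort
#'
#' @param genotype integer matrix, markers x individuals, values 0/1/2/NA.
#' @param localAncestry integer matrix of African-allele counts 0/1/2,
#'   same dimensions as `genotype`.
#' @param samples data.frame with columns `id`, `familyId`, `sex`, `status`
#'   (and optionally `subphenotype`, `theta`), one row per individual.
#' @param markers [GenomicRanges::GRanges] of marker positions (width 1) with
#'   metadata columns `id`, `ref`, `alt` and optionally `fAFR`, `fCEU`.
#' @param pedigree optional 6-column linkage pedigree data.frame
#'   (`familyId`, `id`, `father`, `mother`, `sex`, `phenotype`).
#' @return An [AdmixedCohort-class] object.
#' @export
AdmixedCohort <- function(genotype, localAncestry, samples, markers,
                          pedigree = NULL) {
  storage.mode(genotype) <- "integer"
  storage.mode(localAncestry) <- "integer"
  if (!"theta" %in% colnames(samples))
    samples$theta <- colMeans(localAncestry, na.rm = TRUE) / 2
  if (!"subphenotype" %in% colnames(samples))
    samples$subphenotype <- NA_character_
  cd <- DataFrame(samples)
  rownames(cd) <- samples$id
  colnames(genotype) <- colnames(localAncestry) <- samples$id
  rownames(genotype) <- rownames(localAncestry) <- markers$id
  se <- SummarizedExperiment(
    assays = list(genotype = genotype, localAncestry = localAncestry),
    rowRanges = markers, colData = cd)
  obj <- new("AdmixedCohort", se)
  metadata(obj)$pedigree <- pedigree
  obj
}

#' Single-marker admixture-signal score set
#'
#' Holds the four likelihood-ratio statistics for one marker: the
#' affected-only admixture score (ADM), the ancestry-conditional allelic
#' score (SNP1), the single-causal-variant MIX score, and the model-adequacy
#' DIFF score (`DIFF = ADM + SNP1 - MIX`), each with a 1-df chi-square
#' upper-tail p-value, together with the estimated allelic odds ratio `rHat`,
#' ancestry odds multiplier `lambdaHat`, and the ancestral allele-frequency
#' estimates used.
#'
#' @seealso [admixtureScores()]
#' @export
setClass("AdmixtureScores", representation(
  marker = "character",
  adm = "numeric", admP = "numeric",
  snp1 = "numeric", snp1P = "numeric",
  mix = "numeric", mixP = "numeric",
  diff = "numeric", diffP = "numeric",
  rHat = "numeric", lambdaHat = "numeric",
  pA = "numeric", pE = "numeric",
  nCases = "integer", nControls = "integer"))

setValidity("AdmixtureScores", function(object) {
  msg <- character()
  stats <- c(object@adm, object@snp1, object@mix, object@diff)
  if (any(stats < -1e-8, na.rm = TRUE))
    msg <- c(msg, "all statistics must be non-negative")
  dev <- object@diff - (object@adm + object@snp1 - object@mix)
  if (is.finite(dev) && abs(dev) > 1e-6)
    msg <- c(msg, "DIFF must equal ADM + SNP1 - MIX")
  if (length(msg)) msg else TRUE
})

#' @describeIn AdmixtureScores-class compact display
#' @param object an `AdmixtureScores` object
#' @export
setMethod("show", "AdmixtureScores", function(object) {
  cat("AdmixtureScores for marker", object@marker, "\n")
  cat(sprintf("  cases: %d  controls: %d  pA-hat: %.4f  pE-hat: %.4f\n",
              object@nCases, object@nControls, object@pA, object@pE))
  m <- rbind(ADM = c(object@adm, object@admP),
             SNP1 = c(object@snp1, object@snp1P),
             MIX = c(object@mix, object@mixP),
             DIFF = c(object@diff, object@diffP))
  colnames(m) <- c("statistic", "p")
  print(signif(m, 4))
  cat(sprintf("  rHat: %.4f  lambdaHat: %.4f\n",
              object@rHat, object@lambdaHat))
})

#' Variance components for a binary trait on the observed scale
#'
#' Result of a single-component REML fit: additive and residual variances,
#' observed-scale heritability with its standard error, the liability-scale
#' transform (given prevalence `K` and sample case proportion `P`), and the
#' 1-df likelihood-ratio test of the additive component.
#'
#' @seealso [remlFit()], [liabilityTransform()]
#' @export
setClass("VarianceComponents", representation(
  sigmaA = "numeric", sigmaE = "numeric",
  h2Obs = "numeric", h2SE = "numeric",
  h2Liab = "numeric",
  prevalence = "numeric", caseProp = "numeric",
  lrt = "numeric", p = "numeric",
  logLik = "numeric", n = "integer", source = "character"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@sigmaA < 0 || object@sigmaE < 0)
    msg <- c(msg, "variances must be non-negative")
  if (object@h2Obs < -1e-12 || object@h2Obs > 1 + 1e-12)
    msg <- c(msg, "h2Obs must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn VarianceComponents-class compact display
#' @param object a `VarianceComponents` object
#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@source, " relationship matrix, n = ",
      object@n, ")\n", sep = "")
  cat(sprintf("  sigma2_a = %.4f  sigma2_e = %.4f\n",
              object@sigmaA, object@sigmaE))
  cat(sprintf("  h2 (observed) = %.4f (SE %.4f)\n", object@h2Obs, object@h2SE))
  if (is.finite(object@h2Liab))
    cat(sprintf("  h2 (liability, K = %g, P = %.3f) = %.4f\n",
                object@prevalence, object@caseProp, object@h2Liab))
  cat(sprintf("  LRT = %.3f, 1-df p = %.3g\n", object@lrt, object@p))
})
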