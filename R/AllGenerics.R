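#' Accessors for AdmixedCohort
#'
#' `genotypes()` and `localAncestry()` return the marker-by-individual count
#' matrices; `sampleInfo()` the per-individual table as a data.frame;
#' `markerInfo()` the marker map as a `GRanges`; `cohortPedigree()` the
#' linkage pedigree (or `NULL`).
#'
#' @param x an [AdmixedCohort-class]
#' @return see individual descriptions above.
#' @name cohort-accessors
#' @aliases genotypes localAncestry sampleInfo markerInfo cohortPedigree
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname cohort-accessors
#' @export
setMethod("genotypes", "AdmixedCohort", function(x) assay(x, "genotype"))

#' @rdname cohort-accessors
#' @export
setGeneric("localAncestry", function(x) standardGeneric("localAncestry"))

#' @rdname cohort-accessors
#' @export
setMethod("localAncestry", "AdmixedCohort",
          function(x) assay(x, "localAncestry"))

#' @rdname cohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname cohort-accessors
#' @export
setMethod("sampleInfo", "AdmixedCohort",
          function(x) as.data.frame(colData(x)))

#' @rdname cohort-accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname cohort-accessors
#' @export
setMethod("markerInfo", "AdmixedCohort", function(x) rowRanges(x))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortPedigree", function(x) standardGeneric("cohortPedigree"))

#' @rdname cohort-accessors
#' @export
setMethod("cohortPedigree", "AdmixedCohort",
          function(x) metadata(x)$pedigree)

#' Global ancestry proportion
#'
#' The genome-wide African ancestry proportion of each individual, computed
#' as the mean over markers of half the diploid African-allele count
#' (`theta_j = mean_m a_jm / 2`). Invariant to marker order.
#'
#' @param x an [AdmixedCohort-class] or a marker-by-individual matrix of
#'   local-ancestry counts 0/1/2 (`NA` allowed and ignored).
#' @return named numeric vector of proportions in `[0, 1]`, one per
#'   individual.
#' @export
setGeneric("globalAncestry", function(x) standardGeneric("globalAncestry"))

#' @rdname globalAncestry
#' @export
setMethod("globalAncestry", "matrix", function(x) {
  stopIf(nrow(x) < 1L, "at least one marker is required")
  nObs <- colSums(!is.na(x))
  stopIf(any(nObs == 0L),
         "individual(s) with all-missing local ancestry: %s",
         paste(colnames(x)[nObs == 0L], collapse = ", "))
  colMeans(x, na.rm = TRUE) / 2
})

#' @rdname globalAncestry
#' @export
setMethod("globalAncestry", "AdmixedCohort",
          function(x) globalAncestry(localAncestry(x)))
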