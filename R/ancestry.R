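#' Majority-vote local-ancestry imputation
#'
#' Combines the diploid ancestry calls a marker receives from overlapping
#' estimation windows into a single call: the modal count wins; ties are
#' broken deterministically in favour of the smallest count.
#'
#' @param windowCalls non-empty vector of ancestry counts in `{0, 1, 2}`
#'   from the windows overlapping the marker.
#' @return a single ancestry count (integer 0, 1 or 2).
#' @export
majorityVoteImpute <- function(windowCalls) {
  stopIf(length(windowCalls) == 0L, "windowCalls must be non-empty")
  stopIf(!all(windowCalls %in% c(0L, 1L, 2L)),
         "window calls must be 0, 1 or 2")
  tab <- tabulate(windowCalls + 1L, nbins = 3L)
  as.integer(which.max(tab) - 1L)  # which.max takes the first (lowest) tie
}

#' Nearest-genotyped-marker ancestry assignment
#'
#' Assigns each query position the local-ancestry call of the closest typed
#' marker; equidistant ties go to the lower (left) position. Coordinates are
#' 1-based.
#'
#' @param typedPositions sorted, non-empty positions of typed markers.
#' @param typedAncestry ancestry counts at the typed markers (same length;
#'   may also be a matrix with one row per typed marker).
#' @param queryPositions positions to impute.
#' @return ancestry counts at the query positions (vector, or matrix with
#'   one row per query when `typedAncestry` is a matrix).
#' @export
nearestMarkerAssign <- function(typedPositions, typedAncestry,
                                queryPositions) {
  stopIf(length(typedPositions) == 0L, "typed marker set must be non-empty")
  stopIf(is.unsorted(typedPositions), "typedPositions must be sorted")
  nT <- length(typedPositions)
  if (is.matrix(typedAncestry)) {
    stopIf(nrow(typedAncestry) != nT,
           "typedAncestry must have one row per typed position")
  } else {
    stopIf(length(typedAncestry) != nT,
           "typedAncestry must match typedPositions in length")
  }
  left <- findInterval(queryPositions, typedPositions)
  right <- pmin(left + 1L, nT)
  left <- pmax(left, 1L)
  dLeft <- abs(queryPositions - typedPositions[left])
  dRight <- abs(typedPositions[right] - queryPositions)
  pick <- ifelse(dRight < dLeft, right, left)  # tie -> left (lower position)
  if (is.matrix(typedAncestry)) typedAncestry[pick, , drop = FALSE]
  else typedAncestry[pick]
}

#' Annotate local-ancestry provenance
#'
#' Records, per marker, how its local-ancestry calls were obtained:
#' `"direct"` (estimated at the marker), `"window-vote"` (majority vote over
#' overlapping windows) or `"nearest-marker"`.
#'
#' @param cohort an [AdmixedCohort-class].
#' @param provenance character vector, one value per marker.
#' @return the cohort with a `provenance` column on its marker map.
#' @export
setAncestryProvenance <- function(cohort, provenance) {
  ok <- c("direct", "window-vote", "nearest-marker")
  stopIf(length(provenance) != nrow(cohort),
         "provenance must have one value per marker")
  stopIf(!all(provenance %in% ok), "provenance values must be one of: %s",
         paste(ok, collapse = ", "))
  rowRanges(cohort)$provenance <- provenance
  cohort
}
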