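#' Relationship coefficients from a pedigree
#'
#' Recursive kinship computation over an acyclic pedigree, returning the
#' coefficient-of-relationship matrix `2 phi` (parent-offspring 0.5, full
#' sibs 0.5, first cousins 0.125; diagonal 1). Self-kinship is fixed at 0.5
#' (no-inbreeding assumption); founders from different families are
#' unrelated.
#'
#' @param ped pedigree data.frame with columns `familyId`, `id`, `father`,
#'   `mother` (`"0"` = founder).
#' @return symmetric matrix of relationship coefficients, dimnames = ids.
#' @export
pedigreeRelationship <- function(ped) {
  ids <- as.character(ped$id)
  stopIf(anyDuplicated(ids) > 0, "duplicate individual ids in pedigree")
  n <- length(ids)
  fa <- match(as.character(ped$father), ids)
  mo <- match(as.character(ped$mother), ids)
  # topological order: parents before children
  done <- is.na(fa) & is.na(mo)
  order <- which(done)
  while (length(order) < n) {
    ready <- which(!done & (is.na(fa) | done[fa]) & (is.na(mo) | done[mo]))
    stopIf(length(ready) == 0L, "pedigree contains a cycle")
    done[ready] <- TRUE
    order <- c(order, ready)
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in order) {
    for (j in order) {
      if (j == i) break
      v <- 0
      if (!is.na(fa[i])) v <- v + 0.5 * phi[fa[i], j]
      if (!is.na(mo[i])) v <- v + 0.5 * phi[mo[i], j]
      phi[i, j] <- phi[j, i] <- v
    }
    phi[i, i] <- 0.5
  }
  2 * phi
}

#' KING-robust kinship from genotypes
#'
#' The robust between-family kinship estimator from identity-by-state
#' counts: `phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`, where
#' `N_AaAa` counts markers heterozygous in both individuals, `N_AAaa`
#' counts opposite homozygotes, and `N_Aa(i)` counts heterozygous markers
#' in individual `i` among markers observed in both. Self-kinship is
#' exactly 0.5.
#'
#' @param genotypes marker-by-individual matrix of allele counts 0/1/2,
#'   `NA` missing. At least ~100 polymorphic markers are recommended; fewer
#'   produce a warning.
#' @return symmetric kinship matrix `phi`, with attribute
#'   `source = "genotype"`.
#' @export
kingKinship <- function(genotypes) {
  n <- ncol(genotypes)
  stopIf(n < 2L, "at least two individuals required")
  obs <- !is.na(genotypes)
  stopIf(any(colSums(obs) == 0L), "individual(s) with all-missing genotypes")
  if (nrow(genotypes) < 100L)
    warning("fewer than 100 markers: kinship estimates will be noisy")
  het <- (genotypes == 1L) & obs
  homR <- (genotypes == 0L) & obs
  homA <- (genotypes == 2L) & obs
  storage.mode(het) <- storage.mode(homR) <- storage.mode(homA) <- "double"
  vObs <- matrix(as.double(obs), nrow(genotypes))
  nHetHet <- crossprod(het)
  nOpp <- crossprod(homR, homA); nOpp <- nOpp + t(nOpp)
  nHetI <- crossprod(het, vObs)        # [i, j] = het in i among obs in j
  denom <- nHetI + t(nHetI)
  phi <- (nHetHet - 2 * nOpp) / denom
  phi[denom == 0] <- NA_real_
  ids <- colnames(genotypes)
  if (!is.null(ids)) dimnames(phi) <- list(ids, ids)
  structure(phi, source = "genotype")
}

#' Greedy unrelated-subset selection
#'
#' Repeatedly removes the individual with the most pairwise relationships
#' at or above the threshold until none remain, so the retained set
#' contains no pair with relationship `>= threshold` (strictly-less-than
#' retained). Degree ties are broken deterministically by removing the
#' largest id.
#'
#' @param relationship symmetric relationship (or `2 *` kinship) matrix.
#' @param threshold relationship at or above which a pair counts as
#'   related (default 0.125, first cousins).
#' @return character vector (or integer indices when unnamed) of retained
#'   individuals.
#' @export
unrelatedSubset <- function(relationship, threshold = 0.125) {
  stopIf(nrow(relationship) != ncol(relationship),
         "relationship matrix must be square")
  n <- nrow(relationship)
  ids <- rownames(relationship) %||% as.character(seq_len(n))
  adj <- !is.na(relationship) & relationship >= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    drop <- worst[order(ids[worst], decreasing = TRUE)[1L]]
    alive[drop] <- FALSE
    adj[drop, ] <- adj[, drop] <- FALSE
  }
  if (is.null(rownames(relationship))) which(alive) else ids[alive]
}

#' Classify relationship degree from a kinship coefficient
#'
#' Standard KING bins: monozygotic/duplicate (`phi > 2^-1.5`), 1st degree
#' (`(2^-2.5, 2^-1.5]`), 2nd degree, 3rd degree, else unrelated.
#'
#' @param phi kinship coefficient(s).
#' @return character vector of degree labels.
#' @export
kinshipDegree <- function(phi) {
  cut(phi, breaks = c(-Inf, 2^-4.5, 2^-3.5, 2^-2.5, 2^-1.5, Inf),
      labels = c("unrelated", "3rd", "2nd", "1st", "duplicate/MZ"),
      right = TRUE) |> as.character()
}
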