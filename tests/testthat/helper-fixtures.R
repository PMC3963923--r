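# Shared fixtures, built in code.

# small cohort with known structure for fast unit tests
toyCohort <- function(n = 120, nFam = 20, nMarkers = 30, seed = 101,
                      disease = diseaseModel(), ...) {
  simulateCohort(simConfig(nIndividuals = n, nFamilies = nFam,
                           sibshipSize = 2, nMarkers = nMarkers,
                           disease = disease, seed = seed, ...))
}

# cohort assembled directly from matrices (full control over values)
manualCohort <- function(geno, anc, status, theta = NULL, sex = NULL,
                         familyId = NULL, pos = NULL) {
  n <- ncol(geno); M <- nrow(geno)
  samples <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    familyId = familyId %||% sprintf("S%03d", seq_len(n)),
    sex = sex %||% rep(c(1L, 2L), length.out = n),
    status = status,
    subphenotype = NA_character_)
  if (!is.null(theta)) samples$theta <- theta
  markers <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos %||% seq_len(M) * 1000L, width = 1L),
    id = sprintf("m%03d", seq_len(M)), ref = "A", alt = "G")
  AdmixedCohort(geno, anc, samples, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# phenotype table with fixed marginal counts, in the publication's layout
fixedPhenotypes <- function() {
  nCase <- 1271; nCtrl <- 1456
  maleCase <- 322; maleCtrl <- 400
  nRes <- 308; nS13 <- 433; nS4 <- 190          # cases with follow-up: 931
  nMiss <- nCase - (nRes + nS13 + nS4)          # 340
  sub <- c(rep("resolved", nRes), rep("stage1_3", nS13),
           rep("stage4", nS4), rep(NA_character_, nMiss))
  data.frame(
    id = sprintf("P%04d", seq_len(nCase + nCtrl)),
    familyId = sprintf("P%04d", seq_len(nCase + nCtrl)),
    sex = c(rep(1L, maleCase), rep(2L, nCase - maleCase),
            rep(1L, maleCtrl), rep(2L, nCtrl - maleCtrl)),
    status = rep(c(1L, 0L), c(nCase, nCtrl)),
    subphenotype = c(sub, rep(NA_character_, nCtrl)))
}

# O(n^2 M) double-loop GRM oracle
naiveGRM <- function(mat, standardize = TRUE) {
  keep <- apply(mat, 1, var) > 0
  mat <- mat[keep, , drop = FALSE]
  M <- nrow(mat); n <- ncol(mat)
  p <- rowMeans(mat) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (m in seq_len(M)) {
      num <- (mat[m, j] - 2 * p[m]) * (mat[m, k] - 2 * p[m])
      s <- s + if (standardize) num / (2 * p[m] * (1 - p[m])) else num
    }
    K[j, k] <- s / M
  }
  K
}

# direct HWE enumeration oracle: normalised probabilities from the closed
# form, independent of the package's recurrence-free implementation path
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- (2 * n - rare - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAB]
  sum(pr[pr <= obs * (1 + 1e-9)])
}
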