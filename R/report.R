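#' Demographic and clinical cohort summary
#'
#' Counts and percentages by status, sex and radiographic subphenotype, plus
#' mean (SD) global African ancestry by status, with the denominators used
#' in publication-style tables: male percentage against the status stratum;
#' resolved / persistent against cases with follow-up (non-missing
#' subphenotype); Stage I-III and Stage IV against persistent cases;
#' missing follow-up against all cases. Percentages are rounded half away
#' from zero at one decimal.
#'
#' @param x an [AdmixedCohort-class], or a data.frame with columns `status`,
#'   `sex` and optionally `subphenotype`, `theta`.
#' @return a list of class `cohortSummary` with components `n`, `male`,
#'   `ancestry`, `subphenotype` (each a small data.frame).
#' @export
cohortSummary <- function(x) {
  s <- if (is(x, "AdmixedCohort")) sampleInfo(x) else as.data.frame(x)
  s <- s[!is.na(s$status), , drop = FALSE]
  nCase <- sum(s$status == 1L)
  nCtrl <- sum(s$status == 0L)
  stopIf(nCase == 0L, "no cases in cohort")
  pct <- function(num, den) roundHalfUp(100 * num / den, 1)
  male <- data.frame(
    status = c("affected", "unaffected"),
    n = c(sum(s$status == 1L & s$sex == 1L),
          sum(s$status == 0L & s$sex == 1L)),
    total = c(nCase, nCtrl))
  male$percent <- pct(male$n, male$total)
  ancestry <- NULL
  if (!is.null(s$theta)) {
    ancestry <- data.frame(
      status = c("affected", "unaffected"),
      mean = c(roundHalfUp(100 * mean(s$theta[s$status == 1L]), 1),
               roundHalfUp(100 * mean(s$theta[s$status == 0L]), 1)),
      sd = c(roundHalfUp(100 * stats::sd(s$theta[s$status == 1L]), 1),
             roundHalfUp(100 * stats::sd(s$theta[s$status == 0L]), 1)))
  }
  sub <- NULL
  if (!is.null(s$subphenotype)) {
    isCase <- s$status == 1L
    hasFu <- isCase & !is.na(s$subphenotype)
    nFu <- sum(hasFu)
    nRes <- sum(hasFu & s$subphenotype == "resolved")
    nPer <- sum(hasFu & s$subphenotype %in% c("stage1_3", "stage4"))
    nS13 <- sum(hasFu & s$subphenotype == "stage1_3")
    nS4 <- sum(hasFu & s$subphenotype == "stage4")
    nMiss <- nCase - nFu
    sub <- data.frame(
      group = c("resolved", "persistent", "stage1_3", "stage4",
                "missing_followup"),
      n = c(nRes, nPer, nS13, nS4, nMiss),
      denominator = c(nFu, nFu, nPer, nPer, nCase))
    sub$percent <- ifelse(sub$denominator > 0,
                          pct(sub$n, sub$denominator), NA_real_)
  }
  structure(list(n = data.frame(cases = nCase, controls = nCtrl,
                                total = nCase + nCtrl),
                 male = male, ancestry = ancestry, subphenotype = sub),
            class = "cohortSummary")
}

#' @export
print.cohortSummary <- function(x, ...) {
  cat("Cohort:", x$n$cases, "cases,", x$n$controls, "controls (total",
      paste0(x$n$total, ")\n"))
  cat("Male n (%):\n"); print(x$male, row.names = FALSE)
  if (!is.null(x$ancestry)) {
    cat("Percent African ancestry, mean (SD):\n")
    print(x$ancestry, row.names = FALSE)
  }
  if (!is.null(x$subphenotype)) {
    cat("Radiographic phenotype:\n")
    print(x$subphenotype, row.names = FALSE)
  }
  invisible(x)
}

.pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full fine-mapping pipeline
#'
#' Orchestrates the analysis chain on a simulated or loaded cohort:
#' marker QC; affected-only admixture scan and region boundary definition;
#' ancestry-adjusted and unadjusted association with the confounding ratio;
#' the tiered screen; MIX/DIFF scoring (subsample-averaged when requested);
#' forward selection within the region; local-ancestry heritability with
#' and without the region; and the cohort summary. All stage outputs are
#' written as TSV/JSON with a manifest, deterministic under a fixed seed.
#'
#' @param config either a list or a YAML file path. Recognised fields:
#'   `seed`; `cohort_dir` (load a cohort written by [writeCohort()]) or
#'   `simulate` (arguments to [simConfig()]); `alpha` (region/selection
#'   threshold, default 0.05); `confounding_threshold` (default 0.15);
#'   `n_subsamples` (default 1; > 1 triggers [averagedMix()]);
#'   `subsample_cases`, `subsample_controls`; `prevalence` (default 0.001).
#' @param outDir output directory.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    stopIf(!file.exists(config), "missing config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  alpha <- config$alpha %||% 0.05
  confThr <- config$confounding_threshold %||% 0.15
  nSub <- config$n_subsamples %||% 1L
  prevalence <- config$prevalence %||% 0.001
  manifest <- list(seed = seed,
                   package = as.character(utils::packageVersion("admixfine")),
                   rVersion = paste(R.version$major, R.version$minor,
                                    sep = "."),
                   outputs = list())
  emit <- function(name, df) {
    path <- file.path(outDir, paste0(name, ".tsv"))
    data.table::fwrite(df, path, sep = "\t")
    manifest$outputs[[name]] <<- basename(path)
  }

  cohort <- .pipelineStage("load", {
    if (!is.null(config$cohort_dir)) readCohort(config$cohort_dir)
    else {
      args <- config$simulate %||% list()
      args$seed <- args$seed %||% seed
      simulateCohort(do.call(simConfig, args))
    }
  })
  .pipelineStage("write_cohort", writeCohort(cohort,
                                             file.path(outDir, "cohort")))
  manifest$outputs$cohort <- "cohort"

  qc <- .pipelineStage("marker_qc", {
    s <- sampleInfo(cohort)
    markerQC(genotypes(cohort), s$status)
  })
  emit("qc_markers", qc)
  keepMarkers <- qc$marker[qc$pass]
  cohortQC <- cohort[match(keepMarkers, markerInfo(cohort)$id), ]

  admScan <- .pipelineStage("adm_scan", {
    s <- sampleInfo(cohortQC)
    isCase <- s$status == 1L
    la <- localAncestry(cohortQC)
    out <- lapply(seq_len(nrow(cohortQC)), function(i) {
      sc <- admScore(la[i, isCase], s$theta[isCase])
      data.frame(marker = markerInfo(cohortQC)$id[i],
                 pos = start(markerInfo(cohortQC))[i],
                 adm = sc$statistic, p = sc$p, lambdaHat = sc$lambdaHat)
    })
    do.call(rbind, out)
  })
  emit("adm_scan", admScan)
  region <- regionBoundaries(admScan$pos, admScan$p, alpha = alpha)
  regionMarkers <- if (is.null(region)) character() else
    admScan$marker[admScan$pos >= region[1] & admScan$pos <= region[2]]
  manifest$region <- if (is.null(region)) NULL else as.list(region)

  assocTab <- .pipelineStage("association", {
    rows <- lapply(regionMarkers, function(mk) {
      un <- tryCatch(snpAssociation(cohortQC, mk), error = function(e) NULL)
      ad <- tryCatch(snpAssociation(cohortQC, mk,
                                    adjustLocalAncestry = TRUE),
                     error = function(e) NULL)
      if (is.null(un) || is.null(ad)) return(NULL)
      un$betaAdjusted <- ad$beta
      un$pAdjusted <- ad$p
      un$confounding <- if (un$beta != 0)
        confoundingRatio(ad$beta, un$beta) else NA_real_
      un$tier <- significanceTier(un$p)
      un
    })
    do.call(rbind, rows)
  })
  if (!is.null(assocTab) && nrow(assocTab)) emit("association", assocTab)

  mixTab <- .pipelineStage("mixscore", {
    if (is.null(assocTab) || !nrow(assocTab)) return(NULL)
    cf <- stats::setNames(assocTab$confounding, assocTab$marker)
    targets <- tieredScreen(assocTab, cf, pThreshold = alpha,
                            confoundingThreshold = confThr)
    rows <- lapply(targets, function(mk) {
      s <- sampleInfo(cohortQC)
      i <- match(mk, markerInfo(cohortQC)$id)
      sc <- if (nSub > 1L)
        averagedMix(cohortQC, mk, nSamples = nSub,
                    subsampleSizes = c(config$subsample_cases %||% 933L,
                                       config$subsample_controls %||% 846L))
      else admixtureScores(genotypes(cohortQC)[i, ],
                           localAncestry(cohortQC)[i, ],
                           s$status, s$theta, marker = mk)
      data.frame(marker = mk, adm = sc@adm, admP = sc@admP,
                 snp1 = sc@snp1, snp1P = sc@snp1P,
                 mix = sc@mix, mixP = sc@mixP,
                 diff = sc@diff, diffP = sc@diffP,
                 rHat = sc@rHat, lambdaHat = sc@lambdaHat,
                 tier = significanceTier(sc@mixP))
    })
    do.call(rbind, rows)
  })
  if (!is.null(mixTab) && nrow(mixTab)) emit("mixscore", mixTab)

  fwd <- .pipelineStage("forward_selection", {
    if (!length(regionMarkers)) return(NULL)
    forwardSelect(cohortQC, regionMarkers, alpha = alpha)
  })
  if (!is.null(fwd) && nrow(fwd)) emit("forward_selection", fwd)

  h2 <- .pipelineStage("heritability", {
    fit <- fitHeritability(cohort, "ancestry", prevalence = prevalence)
    row <- data.frame(analysis = "all_markers", h2Obs = fit@h2Obs,
                      h2SE = fit@h2SE, h2Liab = fit@h2Liab,
                      lrt = fit@lrt, p = fit@p, n = fit@n)
    if (!is.null(region)) {
      dr <- fitHeritability(cohort, "ancestry", prevalence = prevalence,
                            region = region)
      row <- rbind(row, data.frame(analysis = "region_removed",
                                   h2Obs = dr@h2Obs, h2SE = dr@h2SE,
                                   h2Liab = dr@h2Liab, lrt = dr@lrt,
                                   p = dr@p, n = dr@n))
    }
    row
  })
  emit("heritability", h2)

  summ <- .pipelineStage("summary", cohortSummary(cohort))
  jsonlite::write_json(
    list(n = summ$n, male = summ$male, ancestry = summ$ancestry,
         subphenotype = summ$subphenotype),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  manifest$outputs$summary <- "summary.json"

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
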