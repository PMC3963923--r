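#' Write a cohort to disk
#'
#' Writes the standard file set: `genotypes.vcf` (VCF v4.2, GT field only,
#' ALT = coded/risk allele, missing as `./.`), `local_ancestry.tsv`
#' (`marker_id` then one column per individual, values 0/1/2),
#' `phenotypes.tsv` (`id`, `family_id`, `sex` (1 = male, 2 = female),
#' `status`, `subphenotype`, `theta`), `pedigree.ped` (6-column linkage
#' format) and, when ancestral frequencies are known,
#' `ancestral_freqs.tsv` (`marker_id`, `fAFR`, `fCEU`).
#'
#' @param cohort an [AdmixedCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopIf(!dir.exists(dir), "cannot create directory %s", dir)
  mk <- markerInfo(cohort)
  g <- genotypes(cohort)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  vcf <- file.path(dir, "genotypes.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- if (nrow(g)) {
    paste(as.character(GenomicRanges::seqnames(mk)), start(mk), mk$id,
          mk$ref, mk$alt, ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(hdr, body), vcf)

  laf <- file.path(dir, "local_ancestry.tsv")
  la <- data.table::data.table(marker_id = mk$id)
  la <- cbind(la, data.table::as.data.table(localAncestry(cohort)))
  data.table::fwrite(la, laf, sep = "\t")

  phf <- file.path(dir, "phenotypes.tsv")
  s <- sampleInfo(cohort)
  ph <- data.frame(id = s$id, family_id = s$familyId, sex = s$sex,
                   status = s$status, subphenotype = s$subphenotype,
                   theta = s$theta)
  data.table::fwrite(ph, phf, sep = "\t")

  pedf <- file.path(dir, "pedigree.ped")
  ped <- cohortPedigree(cohort)
  if (is.null(ped)) {
    ped <- data.frame(familyId = s$familyId, id = s$id, father = "0",
                      mother = "0", sex = s$sex,
                      phenotype = ifelse(is.na(s$status), 0L, s$status + 1L))
  }
  data.table::fwrite(ped, pedf, sep = "\t", col.names = FALSE)

  paths <- c(vcf = vcf, localAncestry = laf, phenotypes = phf,
             pedigree = pedf)
  if (!is.null(mk$fAFR)) {
    frf <- file.path(dir, "ancestral_freqs.tsv")
    data.table::fwrite(data.frame(marker_id = mk$id, fAFR = mk$fAFR,
                                  fCEU = mk$fCEU), frf, sep = "\t")
    paths <- c(paths, freqs = frf)
  }
  invisible(paths)
}

.gtToCount <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read a cohort from disk
#'
#' Reads back the file set written by [writeCohort()]; the round trip is
#' exact for genotypes, local ancestry and phenotypes.
#'
#' @param dir directory containing `genotypes.vcf`, `local_ancestry.tsv`,
#'   `phenotypes.tsv` and optionally `pedigree.ped`,
#'   `ancestral_freqs.tsv`.
#' @return an [AdmixedCohort-class].
#' @export
readCohort <- function(dir) {
  vcfPath <- file.path(dir, "genotypes.vcf")
  for (p in c(vcfPath, file.path(dir, c("local_ancestry.tsv",
                                        "phenotypes.tsv"))))
    stopIf(!file.exists(p), "missing input file: %s", p)
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  nm <- nrow(fix)
  if (nm > 0) {
    gtRaw <- vcfR::extract.gt(v)
    geno <- matrix(.gtToCount(gtRaw), nrow(gtRaw), ncol(gtRaw),
                   dimnames = dimnames(gtRaw))
  }
  la <- data.table::fread(file.path(dir, "local_ancestry.tsv"))
  ancIds <- la$marker_id
  anc <- as.matrix(la[, -1])
  rownames(anc) <- ancIds
  ph <- data.table::fread(file.path(dir, "phenotypes.tsv"),
                          na.strings = c("", "NA"))
  samples <- data.frame(id = ph$id, familyId = ph$family_id, sex = ph$sex,
                        status = ph$status,
                        subphenotype = as.character(ph$subphenotype),
                        theta = ph$theta)
  if (nm == 0) {
    geno <- matrix(integer(), 0L, nrow(samples),
                   dimnames = list(NULL, samples$id))
    anc <- matrix(integer(), 0L, nrow(samples))
    markers <- GRanges(id = character(), ref = character(),
                       alt = character())
  } else {
    geno <- geno[, samples$id, drop = FALSE]
    anc <- anc[match(fix$ID, ancIds), samples$id, drop = FALSE]
    markers <- GRanges(fix$CHROM, IRanges(as.integer(fix$POS), width = 1L),
                       id = fix$ID, ref = fix$REF, alt = fix$ALT)
  }
  frf <- file.path(dir, "ancestral_freqs.tsv")
  if (file.exists(frf) && nm > 0) {
    fr <- data.table::fread(frf)
    i <- match(markers$id, fr$marker_id)
    markers$fAFR <- fr$fAFR[i]
    markers$fCEU <- fr$fCEU[i]
  }
  ped <- NULL
  pedf <- file.path(dir, "pedigree.ped")
  if (file.exists(pedf) && file.size(pedf) > 0) {
    ped <- data.table::fread(pedf, header = FALSE,
                             col.names = c("familyId", "id", "father",
                                           "mother", "sex", "phenotype"))
    ped <- as.data.frame(ped)
    ped$id <- as.character(ped$id)
    ped$familyId <- as.character(ped$familyId)
    ped$father <- as.character(ped$father)
    ped$mother <- as.character(ped$mother)
  }
  AdmixedCohort(geno, anc, samples, markers, pedigree = ped)
}

#' Read a 6-column linkage pedigree file
#'
#' @param path PED file (whitespace separated: family, id, father, mother,
#'   sex, phenotype; `0` = founder/unknown).
#' @return data.frame with columns `familyId`, `id`, `father`, `mother`,
#'   `sex`, `phenotype`.
#' @export
readPedigree <- function(path) {
  stopIf(!file.exists(path), "missing pedigree file: %s", path)
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("familyId", "id", "father",
                                         "mother", "sex", "phenotype"))
  for (cl in c("familyId", "id", "father", "mother"))
    ped[[cl]] <- as.character(ped[[cl]])
  ped
}
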