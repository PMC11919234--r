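# Per-patient genotype assembly, diagnostic status (M0/M1/M2), cohort yield
# and screening arithmetic.

#' Assemble per-proband genotypes from variant calls and a pedigree
#'
#' Places each proband variant on a parental allele by trio transmission: a
#' substitution carried by exactly one parent is phased to that parent's
#' allele; CNV calls use their inheritance annotation (a homozygous
#' biparental deletion fills both alleles). Variants carried by both or
#' neither parent stay unphased and are flagged. Two variants phased to the
#' same parental allele are both recorded there (separated by `";"`), so they
#' never masquerade as biallelic.
#'
#' @param snvVcf path to a VCF with GT genotypes for probands and parents
#'   (requires the VariantAnnotation package), or `NULL`.
#' @param cnvCalls `GRanges` from [callCnv()]/[annotateInheritance()], or
#'   `NULL`.
#' @param ped pedigree data.frame (`fam,id,father,mother,...`).
#' @param model [TranscriptModel-class] used to express CNV calls as exon
#'   ranges and to name VCF variants by cDNA position when they lack ids.
#' @return data.frame with one row per proband: `patient_id`,
#'   `paternal_allele`, `maternal_allele` (`""` when empty), `unphased`,
#'   `phase_source`, `warnings` (Mendelian inconsistencies).
#' @export
assembleGenotypes <- function(snvVcf = NULL, cnvCalls = NULL, ped,
                              model = loadTranscript("slc26a4_fixture")) {
  probands <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  out <- data.frame(patient_id = probands$id, paternal_allele = "",
                    maternal_allele = "", unphased = "", phase_source = "",
                    warnings = "", stringsAsFactors = FALSE)
  addAllele <- function(i, side, v) {
    cur <- out[[side]][i]
    out[[side]][i] <<- if (nzchar(cur)) paste(cur, v, sep = ";") else v
    out$phase_source[i] <<- "trio"
  }
  if (!is.null(snvVcf)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading a VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(snvVcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    ids <- rownames(gt)
    carried <- function(g) !g %in% c("0/0", "0|0", "./.", ".")
    for (i in seq_len(nrow(probands))) {
      pid <- probands$id[i]
      fa <- probands$father[i]; mo <- probands$mother[i]
      if (!pid %in% colnames(gt)) next
      for (v in seq_along(ids)) {
        if (!carried(gt[v, pid])) next
        faC <- fa %in% colnames(gt) && carried(gt[v, fa])
        moC <- mo %in% colnames(gt) && carried(gt[v, mo])
        if (faC && !moC) addAllele(i, "paternal_allele", ids[v])
        else if (moC && !faC) addAllele(i, "maternal_allele", ids[v])
        else if (faC && moC) {
          out$unphased[i] <- paste0(out$unphased[i],
                                    if (nzchar(out$unphased[i])) ";", ids[v])
        } else {
          out$unphased[i] <- paste0(out$unphased[i],
                                    if (nzchar(out$unphased[i])) ";", ids[v])
          out$warnings[i] <- paste0(out$warnings[i],
                                    if (nzchar(out$warnings[i])) ";",
                                    "untransmitted: ", ids[v])
        }
      }
    }
  }
  if (!is.null(cnvCalls) && length(cnvCalls)) {
    for (k in seq_along(cnvCalls)) {
      smp <- cnvCalls$sample[k]
      i <- match(smp, out$patient_id)
      if (is.na(i)) next
      lab <- sprintf("Exons %d-%d deletion", cnvCalls$exonFrom[k],
                     cnvCalls$exonTo[k])
      inh <- cnvCalls$inheritance[k]
      if (cnvCalls$state[k] == "CN0" && inh == "homozygous_biparental") {
        addAllele(i, "paternal_allele", lab)
        addAllele(i, "maternal_allele", lab)
      } else if (inh == "paternal") addAllele(i, "paternal_allele", lab)
      else if (inh == "maternal") addAllele(i, "maternal_allele", lab)
      else out$unphased[i] <- paste0(out$unphased[i],
                                     if (nzchar(out$unphased[i])) ";", lab)
    }
  }
  out$phase_source[out$phase_source == ""] <-
    ifelse(out$paternal_allele[out$phase_source == ""] == "" &
             out$maternal_allele[out$phase_source == ""] == "", "", "unknown")
  out
}

#' Diagnostic status of one patient genotype
#'
#' M2 when both parental alleles carry a Pathogenic or Likely Pathogenic
#' variant (biallelic, in trans); M1 when exactly one does; M0 otherwise.
#' VUS alleles never count. Every referenced variant must have a
#' classification, otherwise the variant is named in an error.
#'
#' @param genotype one row of [assembleGenotypes()] (or any list with
#'   `paternal_allele` / `maternal_allele` strings; `";"` separates variants).
#' @param classifications named character vector mapping variant id to
#'   `"Pathogenic"`, `"LikelyPathogenic"` or `"VUS"`.
#' @return `"M0"`, `"M1"` or `"M2"`.
#' @export
diagnosticStatus <- function(genotype, classifications) {
  plp <- function(allele) {
    if (is.na(allele) || !nzchar(allele)) return(FALSE)
    vs <- strsplit(allele, ";", fixed = TRUE)[[1]]
    miss <- setdiff(vs, names(classifications))
    if (length(miss))
      stop("no classification for variant(s): ", paste(miss, collapse = ", "))
    any(classifications[vs] %in% c("Pathogenic", "LikelyPathogenic"))
  }
  n <- plp(genotype$paternal_allele) + plp(genotype$maternal_allele)
  c("M0", "M1", "M2")[n + 1]
}

#' Cohort diagnostic yield
#'
#' @param statuses character vector of per-patient statuses (`"M0"`/`"M1"`/
#'   `"M2"`).
#' @return list `n_diagnosed` (M2 count), `n_total`, `percent` (rounded
#'   half-up to an integer).
#' @examples
#' cohortYield(c(rep("M2", 9), "M1", rep("M0", 3)))
#' @export
cohortYield <- function(statuses) {
  stopifnot(length(statuses) >= 1)
  nd <- sum(statuses == "M2")
  list(n_diagnosed = nd, n_total = length(statuses),
       percent = roundHalfUp(100 * nd / length(statuses)))
}

#' Carrier frequency in a screening cohort, in per mille
#'
#' @param carriers number of carriers found.
#' @param cohortSize screened cohort size.
#' @return per-mille frequency rounded (half-up) to 2 decimals.
#' @examples
#' screenFrequency(5, 20666)  # 0.24
#' @export
screenFrequency <- function(carriers, cohortSize) {
  if (cohortSize <= 0) stop("cohort size must be positive")
  stopifnot(carriers >= 0, carriers <= cohortSize)
  roundHalfUp(1000 * carriers / cohortSize, 2)
}

#' Count patients carrying at least one exonic-deletion allele
#'
#' @param genotypes genotype data.frame (fixture layout or
#'   [assembleGenotypes()] output) whose allele strings label deletions as
#'   `"Exons a-b deletion ..."`.
#' @export
countDeletionCarriers <- function(genotypes) {
  pat <- grepl("deletion", genotypes$paternal_allele, ignore.case = TRUE) |
    grepl("deletion", genotypes$maternal_allele, ignore.case = TRUE)
  sum(pat)
}

#' Diagnose the fixture cohort from the published tables
#'
#' Runs the classification engine over the evidence table, adds the
#' supplementary (supplied) classifications, and scores every proband's
#' printed genotype; the M0/M1/M2 statuses and the yield summary mirror the
#' published cohort arithmetic.
#'
#' @param fixtures result of [buildTableFixtures()].
#' @return list: `statuses` (named by patient), `yield` ([cohortYield()]
#'   result), `classifications`, `deletion_carriers`.
#' @export
diagnoseFixtureCohort <- function(fixtures = buildTableFixtures()) {
  cls <- classifyTable(fixtures$evidence)
  classifications <- stats::setNames(cls$classification, cls$id)
  sup <- fixtures$supplementary
  if (!is.null(sup) && nrow(sup))
    classifications <- c(classifications,
                         stats::setNames(sup$classification, sup$id))
  gt <- fixtures$genotypes
  statuses <- vapply(seq_len(nrow(gt)), function(i)
    diagnosticStatus(list(paternal_allele = gt$paternal_allele[i],
                          maternal_allele = gt$maternal_allele[i]),
                     classifications), character(1))
  names(statuses) <- gt$patient_id
  list(statuses = statuses, yield = cohortYield(statuses),
       classifications = classifications,
       deletion_carriers = countDeletionCarriers(gt))
}
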