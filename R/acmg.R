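# ACMG/AMP classification engine as specialised for hearing loss: criterion
# evaluation (PVS1, PS3, PM2, PM3 with point scaling, PP3, PP4), strength
# modifiers, and the combining rules. Benign-side criteria are out of scope;
# the classification floor is VUS.

strengthLevels <- c("Supporting", "Moderate", "Strong", "VeryStrong")

defaultStrength <- function(code) {
  switch(substr(code, 1, 3),
         PVS = "VeryStrong",
         PS1 = , PS2 = , PS3 = , PS4 = "Strong",
         PM1 = , PM2 = , PM3 = , PM4 = , PM5 = , PM6 = "Moderate",
         PP1 = , PP2 = , PP3 = , PP4 = , PP5 = "Supporting",
         stop("unknown criterion code: ", code))
}

#' Construct an ACMG criterion (code at an effective strength)
#'
#' @param code criterion code (`"PVS1"`, `"PM3"`, ...).
#' @param strength effective strength; defaults to the strength the code
#'   prefix implies (PVS = VeryStrong, PS = Strong, PM = Moderate,
#'   PP = Supporting).
#' @param rationale free-text evidence summary.
#' @return one-row data.frame (`code`, `strength`, `rationale`, `label`);
#'   `label` is `code` when the strength is the default, else
#'   `code_strength` (e.g. `"PM3_VeryStrong"`).
#' @export
criterion <- function(code, strength = NULL, rationale = "") {
  if (is.null(strength)) strength <- defaultStrength(code)
  stopifnot(strength %in% strengthLevels)
  label <- if (identical(strength, defaultStrength(code))) code
           else paste0(code, "_", strength)
  data.frame(code = code, strength = strength, rationale = rationale,
             label = label, stringsAsFactors = FALSE)
}

#' @rdname criterion
#' @param label a printed label such as `"PM3_VeryStrong"` or `"PM2"`.
#' @export
parseCriterion <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  criterion(parts[1], if (length(parts) > 1) parts[2] else NULL)
}

#' PM3 point scaling (in-trans observations in a recessive disorder)
#'
#' Observations of the variant with a pathogenic variant score 1.0 per
#' confirmed in-trans occurrence and 0.5 per homozygous or phase-unknown
#' occurrence; summed points map to a strength
#' (>= 4 VeryStrong, >= 2 Strong, >= 1 Moderate, >= 0.5 Supporting).
#'
#' @param confirmedInTrans,homozygous,phaseUnknown non-negative observation
#'   counts.
#' @param weights points per observation class.
#' @param thresholds named increasing point cut-offs per strength.
#' @return list with `points` and `strength` (`NA` below the Supporting
#'   cut-off).
#' @examples
#' pm3Strength(4, 0, 4)   # 6 points, VeryStrong
#' pm3Strength(0, 4, 2)   # 3 points, Strong
#' @export
pm3Strength <- function(confirmedInTrans, homozygous = 0, phaseUnknown = 0,
                        weights = c(confirmed = 1, homozygous = 0.5,
                                    phase_unknown = 0.5),
                        thresholds = c(Supporting = 0.5, Moderate = 1,
                                       Strong = 2, VeryStrong = 4)) {
  stopifnot(confirmedInTrans >= 0, homozygous >= 0, phaseUnknown >= 0)
  points <- weights[["confirmed"]] * confirmedInTrans +
    weights[["homozygous"]] * homozygous +
    weights[["phase_unknown"]] * phaseUnknown
  met <- thresholds[points >= thresholds]
  list(points = points,
       strength = if (length(met)) names(met)[length(met)] else NA_character_)
}

#' PM2 rarity check against population frequency
#'
#' Absent from the population database, or below the disease-specific
#' subpopulation threshold, earns PM2 at Moderate; below the looser threshold,
#' PM2 at Supporting; otherwise no criterion.
#'
#' @param freq allele frequency in `[0, 1]`, or `NA`/`"absent"` for a variant
#'   not found in the database.
#' @param subpopThreshold frequency below which PM2 applies at Moderate.
#' @param supportingThreshold frequency below which PM2_Supporting applies.
#' @return a [criterion()] row, or `NULL`.
#' @examples
#' pm2Check(0.00005437)$label  # "PM2"
#' pm2Check(0.000272)$label    # "PM2_Supporting"
#' @export
pm2Check <- function(freq, subpopThreshold = 7e-5, supportingThreshold = 7e-4) {
  stopifnot(subpopThreshold < supportingThreshold)
  if (identical(freq, "absent") || is.null(freq) || is.na(freq))
    return(criterion("PM2", rationale = "not found in the population database"))
  if (freq < 0) stop("negative allele frequency")
  if (freq < subpopThreshold)
    return(criterion("PM2", rationale = sprintf("allele frequency %.8g < %g",
                                                freq, subpopThreshold)))
  if (freq < supportingThreshold)
    return(criterion("PM2", "Supporting",
                     sprintf("allele frequency %.8g < %g", freq,
                             supportingThreshold)))
  NULL
}

#' Variant-intrinsic criteria from an evidence profile
#'
#' PVS1 for null variant classes (nonsense, frameshift, canonical splice site,
#' exonic deletion) in a gene where loss of function is the disease mechanism;
#' PS3 at the stated functional-evidence strength; PP3 for a REVEL score above
#' 0.7 (missense) or a dbscSNV ADA score above 0.957 (splice region); PP4 for
#' a phenotype highly specific for the gene. Computational scores are consumed
#' as annotations, never computed.
#'
#' @param profile a list or one-row data.frame with fields `variant_class`,
#'   `functional_level` (`"none"`, `"supporting"`, `"moderate"`, `"strong"`),
#'   `revel`, `ada` (NA when not annotated), `phenotype_specific` (logical).
#' @return data.frame of [criterion()] rows (possibly empty).
#' @export
structuralCriteria <- function(profile) {
  out <- list()
  nullClasses <- c("nonsense", "frameshift", "canonical_splice",
                   "exonic_deletion")
  cls <- profile$variant_class
  if (cls %in% nullClasses)
    out <- c(out, list(criterion("PVS1",
      rationale = "null variant in a gene with established LOF mechanism")))
  fl <- profile$functional_level
  if (!is.null(fl) && !is.na(fl) && fl != "none") {
    strength <- c(supporting = "Supporting", moderate = "Moderate",
                  strong = "Strong")[[tolower(fl)]]
    out <- c(out, list(criterion("PS3", strength,
                                 "validated functional studies")))
  }
  revel <- profile$revel; ada <- profile$ada
  if (!is.null(revel) && !is.na(revel) && revel > 0.7) {
    if (cls != "missense")
      warning("REVEL score supplied for non-missense class ", cls)
    out <- c(out, list(criterion("PP3", rationale = "REVEL score > 0.7")))
  } else if (!is.null(ada) && !is.na(ada) && ada > 0.957) {
    out <- c(out, list(criterion("PP3",
      rationale = sprintf("dbscSNV ADA score = %g", ada))))
  }
  if (isTRUE(profile$phenotype_specific))
    out <- c(out, list(criterion("PP4",
      rationale = "phenotype highly specific for the gene")))
  if (!length(out)) return(criterion("PP4")[0, ])
  do.call(rbind, out)
}

#' Combine pathogenic-side criteria into a classification
#'
#' Counts criteria at their effective strengths and applies the standard
#' combining rules for Pathogenic and Likely Pathogenic; anything weaker is
#' VUS (benign-side evidence is out of scope).
#'
#' @param criteria data.frame of [criterion()] rows.
#' @return `"Pathogenic"`, `"LikelyPathogenic"` or `"VUS"`.
#' @examples
#' combineCriteria(rbind(criterion("PVS1"), criterion("PM2"),
#'                       criterion("PM3", "VeryStrong"), criterion("PP4")))
#' @export
combineCriteria <- function(criteria) {
  if (is.null(criteria) || nrow(criteria) == 0) return("VUS")
  if (anyDuplicated(criteria$code))
    stop("duplicate criterion code: ",
         paste(criteria$code[duplicated(criteria$code)], collapse = ", "))
  n <- table(factor(criteria$strength, levels = strengthLevels))
  P <- n[["Supporting"]]; M <- n[["Moderate"]]
  S <- n[["Strong"]]; VS <- n[["VeryStrong"]]
  pathogenic <- VS >= 2 ||
    (VS == 1 && (S >= 1 || M >= 2 || (M == 1 && P >= 1) || P >= 2)) ||
    S >= 2 ||
    (S == 1 && (M >= 3 || (M == 2 && P >= 2) || (M == 1 && P >= 4)))
  if (pathogenic) return("Pathogenic")
  likely <- (VS == 1 && M >= 1) ||
    (S == 1 && M >= 1) ||
    (S == 1 && P >= 2) ||
    M >= 3 ||
    (M == 2 && P >= 2) ||
    (M == 1 && P >= 4)
  if (likely) return("LikelyPathogenic")
  "VUS"
}

#' Classify the cohort's evidence table and report concordance
#'
#' Derives each variant's criteria from its structured evidence (PVS1/PS3/
#' PP3/PP4 via [structuralCriteria()], PM2 via [pm2Check()], PM3 via
#' [pm3Strength()]), combines them, and compares both the criteria and the
#' classification with the printed columns. Mismatches are reported, never
#' overridden.
#'
#' @param evidence evidence data.frame as returned in
#'   `buildTableFixtures()$evidence`.
#' @return data.frame with one row per variant: `id`, `criteria` (engine
#'   labels, comma-joined), `classification`, `printed_class`,
#'   `class_concordant`, `criteria_concordant`, `pm3_points`.
#' @export
classifyTable <- function(evidence = buildTableFixtures()$evidence) {
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    ev <- evidence[i, ]
    crit <- structuralCriteria(ev)
    pm2 <- pm2Check(ev$gnomad_freq)
    pm3 <- pm3Strength(ev$pm3_confirmed, ev$pm3_homozygous,
                       ev$pm3_phase_unknown)
    critList <- list(crit)
    if (!is.null(pm2)) critList <- c(critList, list(pm2))
    if (!is.na(pm3$strength))
      critList <- c(critList, list(criterion("PM3", pm3$strength,
        sprintf("%.1f in-trans points", pm3$points))))
    crit <- do.call(rbind, critList)
    cls <- combineCriteria(crit)
    printed <- sort(unlist(ev$printed_criteria))
    data.frame(id = ev$id,
               criteria = paste(sort(crit$label), collapse = ","),
               classification = cls,
               printed_class = ev$printed_class,
               class_concordant = cls == ev$printed_class,
               criteria_concordant = identical(sort(crit$label), printed),
               pm3_points = pm3$points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
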