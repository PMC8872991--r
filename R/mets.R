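#' Default metabolic-syndrome criteria thresholds
#'
#' Thresholds for the three criteria sets (Japanese committee, IDF,
#' NCEP-ATPIII) and the ABSI substitution for abdominal obesity. All values
#' are the printed defaults of the study design this package reproduces:
#'
#' * shared components: TG >= 1.69 mmol/L, HDL-C < 1.03 mmol/L (strict <),
#'   SBP >= 130 and/or DBP >= 85 mmHg;
#' * glucose: FPG >= 6.11 mmol/L (Japanese, IDF) or >= 5.55 mmol/L (NCEP,
#'   after the ADA lowered the impaired-fasting-glucose limit);
#' * waist cutoffs (metres): Japanese 0.85 (men) / 0.90 (women), IDF
#'   0.90 / 0.80, NCEP 1.02 / 0.88;
#' * ABSI >= 0.080 in both sexes when ABSI replaces waist circumference.
#'
#' Note the IDF glucose threshold follows this study's printed 6.11 mmol/L,
#' not the canonical IDF 5.6 mmol/L.
#'
#' @return nested list of thresholds, editable before passing to the
#'   diagnosis functions.
#' @export
default_criteria <- function() {
  list(
    absi_cutoff = 0.080,
    tg_mmol_l = 1.69,
    hdl_mmol_l = 1.03,
    sbp_mmhg = 130,
    dbp_mmhg = 85,
    japanese = list(wc_male_m = 0.85, wc_female_m = 0.90, fpg_mmol_l = 6.11),
    idf = list(wc_male_m = 0.90, wc_female_m = 0.80, fpg_mmol_l = 6.11),
    ncep = list(wc_male_m = 1.02, wc_female_m = 0.88, fpg_mmol_l = 5.55)
  )
}

criteria_sets <- function() c("japanese", "idf", "ncep")
obesity_modes <- function() c("wc", "absi")

match_criteria <- function(criteria) match.arg(tolower(criteria), criteria_sets())
match_mode <- function(mode) match.arg(tolower(mode), obesity_modes())

#' Abdominal obesity under a criteria set and obesity-index mode
#'
#' In WC mode the sex- and criteria-specific waist cutoff applies
#' (inclusive >=); in ABSI mode the single cutoff ABSI >= 0.080 applies to
#' both sexes under every criteria set.
#'
#' @param sex "M"/"F" vector.
#' @param wc_m waist circumference, metres (used in WC mode).
#' @param absi ABSI values (used in ABSI mode).
#' @param criteria one of "japanese", "idf", "ncep".
#' @param mode "wc" or "absi".
#' @param thresholds threshold list, see [default_criteria()].
#' @return logical vector.
#' @export
abdominal_obesity <- function(sex, wc_m, absi, criteria, mode,
                              thresholds = default_criteria()) {
  criteria <- match_criteria(criteria)
  mode <- match_mode(mode)
  sexf <- sex_factor(sex)
  if (mode == "absi") {
    return(absi >= thresholds$absi_cutoff)
  }
  th <- thresholds[[criteria]]
  cut <- ifelse(sexf == "F", th$wc_female_m, th$wc_male_m)
  wc_m >= cut
}

#' Component abnormality flags under a criteria set
#'
#' Treatment semantics as printed: drug treatment for dyslipidemia,
#' hypertension or diabetes counts as positive for the respective
#' abnormality. Under the Japanese criteria the lipid component is the
#' combined TG-and/or-HDL abnormality, so dyslipidemia treatment sets it;
#' under IDF and NCEP-ATPIII hypo-HDL is an independent component that
#' treatment never sets (treatment counts only toward the TG component).
#'
#' @param profile data.frame with columns sex, wc_m, absi, sbp_mmhg,
#'   dbp_mmhg, fpg_mmol_l, tg_mmol_l, hdl_mmol_l and logical/0-1 tx_htn,
#'   tx_dm, tx_dlp.
#' @param criteria one of "japanese", "idf", "ncep".
#' @param thresholds threshold list, see [default_criteria()].
#' @return data.frame of logical component columns (excluding abdominal
#'   obesity, which [abdominal_obesity()] supplies).
#' @export
mets_components <- function(profile, criteria, thresholds = default_criteria()) {
  criteria <- match_criteria(criteria)
  th <- thresholds
  fpg_cut <- th[[criteria]]$fpg_mmol_l
  tx_htn <- as.logical(profile$tx_htn)
  tx_dm <- as.logical(profile$tx_dm)
  tx_dlp <- as.logical(profile$tx_dlp)
  bp <- profile$sbp_mmhg >= th$sbp_mmhg | profile$dbp_mmhg >= th$dbp_mmhg | tx_htn
  glucose <- profile$fpg_mmol_l >= fpg_cut | tx_dm
  if (criteria == "japanese") {
    lipid <- profile$tg_mmol_l >= th$tg_mmol_l |
      profile$hdl_mmol_l < th$hdl_mmol_l | tx_dlp
    return(data.frame(lipid = lipid, bp = bp, glucose = glucose))
  }
  tg <- profile$tg_mmol_l >= th$tg_mmol_l | tx_dlp
  hdl <- profile$hdl_mmol_l < th$hdl_mmol_l # treatment never counts here
  data.frame(tg = tg, hdl = hdl, bp = bp, glucose = glucose)
}

#' Diagnose metabolic syndrome
#'
#' Combination rules: Japanese and IDF require abdominal obesity as a
#' mandatory gate plus at least two of their (3 resp. 4) other components;
#' NCEP-ATPIII has no gate and requires at least three of five components,
#' abdominal obesity counting as one of the five.
#'
#' @inheritParams mets_components
#' @param mode "wc" or "absi".
#' @return data.frame with the component flags, `abdominal_obesity`,
#'   `n_positive_components` (count of non-obesity components that are
#'   positive) and the logical `verdict`; attributes `criteria` and `mode`
#'   record the definition.
#' @export
mets_diagnose <- function(profile, criteria, mode, thresholds = default_criteria()) {
  criteria <- match_criteria(criteria)
  mode <- match_mode(mode)
  comp <- mets_components(profile, criteria, thresholds)
  obese <- abdominal_obesity(profile$sex, profile$wc_m, profile$absi,
    criteria, mode, thresholds)
  npos <- rowSums(comp)
  verdict <- if (criteria == "ncep") {
    npos + as.integer(obese) >= 3
  } else {
    obese & npos >= 2
  }
  out <- cbind(comp, data.frame(
    abdominal_obesity = obese,
    n_positive_components = as.integer(npos),
    verdict = verdict
  ))
  attr(out, "criteria") <- criteria
  attr(out, "mode") <- mode
  out
}

#' Classify a baseline cohort under all six definitions
#'
#' Applies the three criteria sets in both obesity-index modes to one
#' baseline row per subject.
#'
#' @param baseline data.frame with one row per subject; must contain
#'   `subject_id` plus the [mets_components()] profile columns.
#' @param thresholds threshold list.
#' @return data.frame of `subject_id` and six logical columns named
#'   `mets_<criteria>_<mode>`.
#' @export
classify_cohort <- function(baseline, thresholds = default_criteria()) {
  if (anyDuplicated(baseline$subject_id)) {
    stop("duplicate subject_id at baseline: ",
      paste(utils::head(unique(baseline$subject_id[duplicated(baseline$subject_id)]), 5),
        collapse = ", "))
  }
  out <- data.frame(subject_id = baseline$subject_id)
  for (cr in criteria_sets()) {
    for (md in obesity_modes()) {
      out[[paste("mets", cr, md, sep = "_")]] <-
        mets_diagnose(baseline, cr, md, thresholds)$verdict
    }
  }
  out
}

#' Prevalence summary of the six definitions
#'
#' @param classified output of [classify_cohort()].
#' @return data.frame with definition, counts and prevalence in percent
#'   (one decimal, the reporting convention of screening tables).
#' @export
mets_prevalence <- function(classified) {
  cols <- grep("^mets_", names(classified), value = TRUE)
  n <- nrow(classified)
  data.frame(
    definition = cols,
    n_positive = vapply(classified[cols], sum, integer(1)),
    n_total = n,
    prevalence_pct = vapply(classified[cols], function(x) pct(sum(x), n), numeric(1)),
    row.names = NULL
  )
}
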