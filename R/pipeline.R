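cohort_schema <- function() {
  c("subject_id", "visit_index", "sex", "age_years", "height_m", "weight_kg",
    "wc_m", "sbp_mmhg", "dbp_mmhg", "cavi", "abi", "fpg_mmol_l", "tc_mmol_l",
    "hdl_mmol_l", "tg_mmol_l", "creatinine_mg_dl", "dipstick", "tx_htn",
    "tx_dm", "tx_dlp", "smoker", "alcohol")
}

#' Validate a cohort table against the screening schema
#'
#' Checks column presence, types, plausibility ranges (including the
#' waist-circumference unit guard: values above 3 are flagged as probable
#' centimetres), dipstick grades, duplicate (subject, visit) pairs, and
#' lists subjects lacking the full set of four visits.
#'
#' @param x a data.frame or a CSV path.
#' @return list: `ok` (logical), `errors`, `warnings` (character vectors),
#'   `incomplete_subjects` (ids lacking 4 visits), and `counts`
#'   (rows, subjects).
#' @export
validate_cohort <- function(x) {
  df <- if (is.character(x)) read_cohort_csv(x) else x
  errors <- character(0)
  warnings <- character(0)
  missing_cols <- setdiff(cohort_schema(), names(df))
  if (length(missing_cols)) {
    return(list(ok = FALSE,
      errors = paste("missing column(s):", paste(missing_cols, collapse = ", ")),
      warnings = character(0), incomplete_subjects = character(0),
      counts = c(rows = nrow(df), subjects = NA)))
  }
  num_cols <- setdiff(cohort_schema(), c("subject_id", "sex", "dipstick"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) errors <- c(errors, paste0("non-numeric column: ", cl))
  }
  if (!all(is.na(df$sex) | df$sex %in% c("M", "F"))) {
    errors <- c(errors, "sex contains values other than M/F")
  }
  bad_dip <- !is.na(df$dipstick) & !df$dipstick %in% dipstick_levels()
  if (any(bad_dip)) {
    errors <- c(errors, paste0("unknown dipstick grade at row(s): ",
      paste(utils::head(which(bad_dip), 5), collapse = ", ")))
  }
  if (is.numeric(df$wc_m) && any(df$wc_m > 3, na.rm = TRUE)) {
    errors <- c(errors, "wc_m contains values > 3: waist circumference appears to be in centimetres, not metres")
  }
  if (is.numeric(df$height_m) && any(df$height_m <= 0.5 | df$height_m >= 2.5, na.rm = TRUE)) {
    errors <- c(errors, "height_m outside (0.5, 2.5)")
  }
  if (is.numeric(df$sbp_mmhg) && is.numeric(df$dbp_mmhg) &&
      any(df$sbp_mmhg <= df$dbp_mmhg, na.rm = TRUE)) {
    warnings <- c(warnings, "rows with sbp_mmhg <= dbp_mmhg present")
  }
  key <- paste(df$subject_id, df$visit_index)
  if (anyDuplicated(key)) {
    errors <- c(errors, paste0("duplicate (subject_id, visit_index) at row(s): ",
      paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
  }
  by_subj <- split(df$visit_index, df$subject_id)
  complete <- vapply(by_subj, function(v) setequal(v, 0:3), logical(1))
  incomplete <- names(by_subj)[!complete]
  list(ok = length(errors) == 0, errors = errors, warnings = warnings,
    incomplete_subjects = incomplete,
    counts = c(rows = nrow(df), subjects = length(by_subj)))
}

#' Add derived indices and flags to a visit table
#'
#' Computes BMI, ABSI, eGFR, Friedewald LDL-C (NA above the triglyceride
#' validity limit) and the threshold flags for every row.
#'
#' @param visits long-format visit data.frame (see [validate_cohort()]).
#' @return the input with columns bmi, absi, egfr, ldl_mmol_l, high_cavi,
#'   low_egfr, proteinuria, high_ldl, abi_exclude appended.
#' @export
compute_visit_indices <- function(visits) {
  visits$bmi <- compute_bmi(visits$weight_kg, visits$height_m)
  visits$absi <- compute_absi(visits$wc_m, visits$bmi, visits$height_m)
  visits$egfr <- compute_egfr(visits$creatinine_mg_dl, visits$age_years, visits$sex)
  visits$ldl_mmol_l <- compute_ldl_friedewald(visits$tc_mmol_l, visits$hdl_mmol_l,
    visits$tg_mmol_l)
  fl <- derive_flags(cavi = visits$cavi, egfr = visits$egfr,
    dipstick = visits$dipstick, ldl_mmol_l = visits$ldl_mmol_l, abi = visits$abi)
  cbind(visits, fl)
}

#' Detect incident renal function decline
#'
#' Among subjects at risk (baseline eGFR >= 60), finds the first follow-up
#' visit (1-3) with eGFR < 60. Time is the visit index in years; subjects
#' event-free at the last visit are censored at t = 3.
#'
#' @param visits visit table with `egfr` computed (see
#'   [compute_visit_indices()]).
#' @return data.frame per at-risk subject: subject_id, time, event.
#' @export
detect_events <- function(visits) {
  b <- visits[visits$visit_index == 0, ]
  at_risk <- b$subject_id[!is.na(b$egfr) & b$egfr >= 60]
  fu <- visits[visits$visit_index > 0 & visits$subject_id %in% at_risk, ]
  fu <- fu[order(fu$subject_id, fu$visit_index), ]
  low <- !is.na(fu$egfr) & fu$egfr < 60
  first_low <- tapply(ifelse(low, fu$visit_index, NA_integer_), fu$subject_id,
    function(v) if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE))
  tmax <- max(visits$visit_index)
  data.frame(
    subject_id = names(first_low),
    time = ifelse(is.na(first_low), tmax, first_low),
    event = !is.na(first_low),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Baseline characteristics table for one MetS definition
#'
#' Median (IQR) with Mann-Whitney U p-values for continuous rows, count
#' (percent, via the shared [pct()] path) with Fisher exact p-values for
#' categorical rows, comparing subjects with and without the diagnosis.
#' LDL-C rows honour the Friedewald validity exclusion (TG >= 4.52 mmol/L
#' rows are dropped from LDL summaries only).
#'
#' @param baseline baseline rows with indices computed
#'   ([compute_visit_indices()]).
#' @param verdict logical vector aligned with `baseline`: the MetS verdicts.
#' @return data.frame: variable, type, overall, mets_neg, mets_pos, p, test.
#' @export
baseline_table <- function(baseline, verdict) {
  stopifnot(nrow(baseline) == length(verdict))
  cont <- c(age = "age_years", bmi = "bmi", wc_m = "wc_m", absi = "absi",
    sbp = "sbp_mmhg", dbp = "dbp_mmhg", cavi = "cavi", fpg = "fpg_mmol_l",
    ldl = "ldl_mmol_l", hdl = "hdl_mmol_l", tg = "tg_mmol_l",
    creatinine = "creatinine_mg_dl", egfr = "egfr")
  catg <- list(
    male = baseline$sex == "M",
    age_ge_65 = baseline$age_years >= 65,
    smoker = baseline$smoker == 1,
    alcohol = baseline$alcohol == 1,
    bmi_ge_25 = baseline$bmi >= 25,
    high_cavi = baseline$high_cavi,
    fpg_gt_5.55 = baseline$fpg_mmol_l > 5.55,
    fpg_gt_6.11 = baseline$fpg_mmol_l > 6.11,
    high_ldl = baseline$high_ldl,
    tx_htn = baseline$tx_htn == 1,
    tx_dm = baseline$tx_dm == 1,
    tx_dlp = baseline$tx_dlp == 1,
    low_egfr = baseline$low_egfr,
    proteinuria = baseline$proteinuria
  )
  digits <- c(age = 0, bmi = 1, wc_m = 3, absi = 4, sbp = 0, dbp = 0, cavi = 1,
    fpg = 2, ldl = 2, hdl = 2, tg = 2, creatinine = 2, egfr = 1)
  pos <- which(verdict)
  neg <- which(!verdict)
  rows <- list()
  for (nm in names(cont)) {
    x <- baseline[[cont[[nm]]]]
    p <- if (length(pos) >= 2 && length(neg) >= 2 &&
        sum(!is.na(x[pos])) >= 2 && sum(!is.na(x[neg])) >= 2) {
      stats::wilcox.test(x[neg], x[pos], exact = FALSE)$p.value
    } else NA_real_
    d <- digits[[nm]]
    rows[[length(rows) + 1]] <- data.frame(
      variable = nm, type = "continuous",
      overall = fmt_median_iqr(x, d),
      mets_neg = if (length(neg)) fmt_median_iqr(x[neg], d) else NA_character_,
      mets_pos = if (length(pos)) fmt_median_iqr(x[pos], d) else NA_character_,
      p = p, test = "mann-whitney", stringsAsFactors = FALSE)
  }
  for (nm in names(catg)) {
    x <- catg[[nm]]
    tab_ok <- length(pos) >= 1 && length(neg) >= 1 && !all(is.na(x))
    p <- if (tab_ok && length(unique(stats::na.omit(x))) == 2) {
      stats::fisher.test(table(factor(verdict, c(FALSE, TRUE)),
        factor(x, c(FALSE, TRUE))))$p.value
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = nm, type = "categorical",
      overall = fmt_count_pct(sum(x, na.rm = TRUE), sum(!is.na(x))),
      mets_neg = fmt_count_pct(sum(x[neg], na.rm = TRUE), sum(!is.na(x[neg]))),
      mets_pos = fmt_count_pct(sum(x[pos], na.rm = TRUE), sum(!is.na(x[pos]))),
      p = p, test = "fisher", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mets_definitions <- function() {
  expand.grid(criteria = criteria_sets(), mode = obesity_modes(),
    stringsAsFactors = FALSE)
}

definition_col <- function(criteria, mode) paste("mets", criteria, mode, sep = "_")

#' Run the full study replication on a cohort
#'
#' Reproduces the analysis sequence of the screening study on a (synthetic
#' or user-supplied) four-visit cohort:
#'
#' 1. exclude subjects without exactly visits 0-3 (logged);
#' 2. exclude subjects with baseline ankle-brachial index < 0.90 (CAVI
#'    invalid under arterial occlusion; logged);
#' 3. compute indices and flags at every visit;
#' 4. classify the six MetS definitions (3 criteria x WC/ABSI) at baseline;
#' 5. baseline characteristics tables per definition;
#' 6. age-adjusted CAVI comparison (ANCOVA) per definition, pooled and by
#'    sex, Bonferroni-corrected over the six definitions run together;
#' 7. exclude subjects with baseline eGFR < 60 from incidence analyses
#'    (logged); detect first eGFR < 60 over visits 1-3;
#' 8. Kaplan-Meier curves and log-rank tests per definition;
#' 9. Cox models: Model 1 (all confounders + Japanese WC-MetS) and Model 2
#'    (all confounders + Japanese ABSI-MetS); gender-specific analyses per
#'    definition with (2nd) and without (1st) high CAVI as confounder;
#' 10. ROC of baseline ABSI for the incident event with Youden cutoff.
#'
#' Deterministic given the input: no step draws random numbers.
#'
#' @param visits long-format visit table (data.frame or CSV path).
#' @param thresholds criteria thresholds, see [default_criteria()].
#' @param age_strata logical; if TRUE, the Cox models stratify the baseline
#'   hazard on integer age instead of entering age as a covariate (the
#'   study's text and its reported age hazard ratio disagree on which was
#'   done; both variants are provided).
#' @return list of class `absimets_study`: `ledger` (named exclusion
#'   counts), `classified`, `prevalence`, `baseline_tables`, `ancova`,
#'   `km`, `logrank`, `cox_model1`, `cox_model2`, `cox_gender`, `roc`,
#'   `events`, `notes`.
#' @export
run_study <- function(visits, thresholds = default_criteria(), age_strata = FALSE) {
  if (is.character(visits)) visits <- read_cohort_csv(visits)
  val <- validate_cohort(visits)
  if (!val$ok) stop("cohort failed validation: ", paste(val$errors, collapse = "; "))
  notes <- character(0)
  ledger <- c(input_rows = nrow(visits),
    input_subjects = length(unique(visits$subject_id)))

  # (1) four-visit completeness
  if (length(val$incomplete_subjects)) {
    visits <- visits[!visits$subject_id %in% val$incomplete_subjects, ]
  }
  ledger["excluded_incomplete_visits"] <- length(val$incomplete_subjects)

  # (2) ABI exclusion at baseline
  b0 <- visits[visits$visit_index == 0, ]
  abi_out <- b0$subject_id[!is.na(b0$abi) & b0$abi < 0.90]
  visits <- visits[!visits$subject_id %in% abi_out, ]
  ledger["excluded_abi_lt_0.90"] <- length(abi_out)

  # (3) indices and flags
  visits <- compute_visit_indices(visits)
  baseline <- visits[visits$visit_index == 0, ]
  ledger["analyzed_subjects"] <- nrow(baseline)

  # (4) six MetS definitions at baseline
  classified <- classify_cohort(baseline, thresholds)
  prevalence <- mets_prevalence(classified)
  defs <- mets_definitions()

  # (5) baseline tables
  baseline_tables <- list()
  for (i in seq_len(nrow(defs))) {
    col <- definition_col(defs$criteria[i], defs$mode[i])
    baseline_tables[[col]] <- baseline_table(baseline, classified[[col]])
  }

  # (6) age-adjusted CAVI (ANCOVA), Bonferroni over the six definitions
  ancova <- list()
  for (i in seq_len(nrow(defs))) {
    col <- definition_col(defs$criteria[i], defs$mode[i])
    v <- classified[[col]]
    grp <- factor(ifelse(v, "mets", "non_mets"), c("non_mets", "mets"))
    res <- list()
    res$pooled <- try_ancova(baseline$cavi, grp, baseline$age_years, nrow(defs))
    for (sx in c("M", "F")) {
      sel <- baseline$sex == sx
      res[[sx]] <- try_ancova(baseline$cavi[sel], grp[sel],
        baseline$age_years[sel], nrow(defs))
    }
    ancova[[col]] <- res
  }

  # (7) incidence population and events
  low0 <- !is.na(baseline$egfr) & baseline$egfr < 60
  ledger["excluded_baseline_egfr_lt_60"] <- sum(low0)
  surv <- detect_events(visits)
  ledger["at_risk_subjects"] <- nrow(surv)
  ledger["incident_events"] <- sum(surv$event)
  bidx <- match(surv$subject_id, baseline$subject_id)
  surv$male <- as.integer(baseline$sex[bidx] == "M")
  surv$sex <- baseline$sex[bidx]
  surv$age <- baseline$age_years[bidx]
  surv$high_cavi <- as.integer(baseline$high_cavi[bidx])
  surv$proteinuria <- as.integer(baseline$proteinuria[bidx])
  surv$tx_dm <- baseline$tx_dm[bidx]
  surv$tx_htn <- baseline$tx_htn[bidx]
  surv$tx_dlp <- baseline$tx_dlp[bidx]
  surv$absi <- baseline$absi[bidx]
  cidx <- match(surv$subject_id, classified$subject_id)
  for (i in seq_len(nrow(defs))) {
    col <- definition_col(defs$criteria[i], defs$mode[i])
    surv[[col]] <- as.integer(classified[[col]][cidx])
  }

  # (8) KM + log-rank per definition
  km <- list(); logrank <- list()
  have_events <- nrow(surv) > 0 && sum(surv$event) > 0
  for (i in seq_len(nrow(defs))) {
    col <- definition_col(defs$criteria[i], defs$mode[i])
    km[[col]] <- list(
      mets = if (any(surv[[col]] == 1)) {
        km_curve(surv$time[surv[[col]] == 1], surv$event[surv[[col]] == 1])
      },
      non_mets = if (any(surv[[col]] == 0)) {
        km_curve(surv$time[surv[[col]] == 0], surv$event[surv[[col]] == 0])
      }
    )
    logrank[[col]] <- if (have_events && length(unique(surv[[col]])) == 2) {
      logrank_test(surv$time, surv$event, surv[[col]])
    } else {
      notes <- c(notes, paste0("log-rank skipped for ", col,
        ": no events or single group"))
      NULL
    }
  }

  # (9) Cox models
  strat <- if (age_strata) "age" else NULL
  base_cov <- c(if (!age_strata) "age", "male", "high_cavi", "proteinuria",
    "tx_dm", "tx_htn", "tx_dlp")
  cox_model1 <- cox_model2 <- NULL
  cox_gender <- list()
  if (have_events) {
    cox_model1 <- try_cox(surv, c(base_cov, "mets_japanese_wc"), strat)
    cox_model2 <- try_cox(surv, c(base_cov, "mets_japanese_absi"), strat)
    for (m in c("cox_model1", "cox_model2")) {
      pz <- attr(get(m), "proportionality_global_p")
      if (!is.null(pz)) {
        notes <- c(notes, sprintf("%s global Schoenfeld proportionality p = %.3g",
          m, pz))
      }
    }
    for (sx in c("M", "F")) {
      ssex <- surv[surv$sex == sx, ]
      for (i in seq_len(nrow(defs))) {
        col <- definition_col(defs$criteria[i], defs$mode[i])
        cov1 <- c(if (!age_strata) "age", "proteinuria", "tx_dm", "tx_htn",
          "tx_dlp", col)
        cox_gender[[paste(sx, col, "1st", sep = ".")]] <-
          try_cox(ssex, cov1, strat)
        cox_gender[[paste(sx, col, "2nd", sep = ".")]] <-
          try_cox(ssex, c(cov1, "high_cavi"), strat)
      }
    }
  } else {
    notes <- c(notes, "Cox stage skipped: no incident events")
  }

  # (10) ROC of baseline ABSI for the incident event
  roc <- if (have_events) roc_youden(surv$absi, surv$event) else NULL
  if (!have_events) notes <- c(notes, "ROC skipped: no incident events")

  structure(list(
    ledger = ledger, classified = classified, prevalence = prevalence,
    baseline_tables = baseline_tables, ancova = ancova, km = km,
    logrank = logrank, cox_model1 = cox_model1, cox_model2 = cox_model2,
    cox_gender = cox_gender, roc = roc, events = surv, notes = notes
  ), class = "absimets_study")
}

try_ancova <- function(outcome, group, age, n_comparisons) {
  tryCatch(ancova_adjusted_means(outcome, group, age, n_comparisons),
    error = function(e) list(error = conditionMessage(e)))
}

try_cox <- function(data, covariates, strata) {
  tryCatch(cox_fit(data, covariates = covariates, strata = strata),
    error = function(e) list(error = conditionMessage(e)))
}

#' @export
print.absimets_study <- function(x, ...) {
  cat("absimets study result\n")
  cat("  subjects analyzed:", x$ledger[["analyzed_subjects"]], "\n")
  cat("  exclusions: incomplete", x$ledger[["excluded_incomplete_visits"]],
    "| ABI", x$ledger[["excluded_abi_lt_0.90"]],
    "| baseline eGFR<60", x$ledger[["excluded_baseline_egfr_lt_60"]], "\n")
  cat("  incident events:", x$ledger[["incident_events"]], "of",
    x$ledger[["at_risk_subjects"]], "at risk\n")
  cat("  MetS prevalence (%):\n")
  print(x$prevalence, row.names = FALSE)
  invisible(x)
}
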