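#' Body mass index
#'
#' BMI in kg/m^2 from weight in kilograms and height in metres.
#'
#' @param weight_kg body weight in kg (positive).
#' @param height_m standing height in metres; values outside (0.5, 2.5) are
#'   rejected as probable unit errors.
#' @return numeric vector of BMI values (kg/m^2).
#' @examples
#' compute_bmi(70, 1.78)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  stopifnot(is.numeric(weight_kg), is.numeric(height_m))
  ok <- is.na(weight_kg) | weight_kg > 0
  if (!all(ok)) stop("weight_kg must be strictly positive")
  ok <- is.na(height_m) | (height_m > 0.5 & height_m < 2.5)
  if (!all(ok)) stop("height_m must lie in (0.5, 2.5) metres")
  weight_kg / height_m^2
}

#' A Body Shape Index (ABSI)
#'
#' ABSI = WC / (BMI^(2/3) * height^(1/2)), with waist circumference and
#' height in metres. On this unit convention typical adult values fall near
#' 0.08, and ABSI is by construction nearly uncorrelated with BMI in
#' populations where WC scales allometrically with BMI and height.
#'
#' Waist circumferences above 3 m are rejected rather than rescaled: they are
#' almost certainly centimetres, and silent unit coercion is the classic ABSI
#' mistake.
#'
#' @param wc_m waist circumference in metres.
#' @param bmi body mass index in kg/m^2 (positive).
#' @param height_m height in metres.
#' @return numeric vector of ABSI values (m^(11/6) kg^(-2/3)).
#' @examples
#' compute_absi(0.790, 21.9, 1.60)
#' @export
compute_absi <- function(wc_m, bmi, height_m) {
  stopifnot(is.numeric(wc_m), is.numeric(bmi), is.numeric(height_m))
  if (any(wc_m > 3, na.rm = TRUE)) {
    stop("wc_m > 3: waist circumference looks like centimetres; supply metres")
  }
  if (any(wc_m <= 0, na.rm = TRUE)) stop("wc_m must be strictly positive")
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be strictly positive")
  if (any(height_m <= 0, na.rm = TRUE)) stop("height_m must be strictly positive")
  wc_m / (bmi^(2 / 3) * sqrt(height_m))
}

#' Estimated glomerular filtration rate (Japanese Society of Nephrology)
#'
#' eGFR (mL/min/1.73 m^2) = 194 * creatinine^-1.094 * age^-0.287, multiplied
#' by 0.739 for women. Strictly decreasing in both creatinine and age.
#'
#' @param creatinine_mg_dl serum creatinine in mg/dL (positive).
#' @param age_years age in years.
#' @param sex character vector, "M" or "F".
#' @return numeric vector of eGFR values.
#' @examples
#' compute_egfr(0.71, 48, "M")
#' @export
compute_egfr <- function(creatinine_mg_dl, age_years, sex) {
  stopifnot(is.numeric(creatinine_mg_dl), is.numeric(age_years))
  if (any(creatinine_mg_dl <= 0, na.rm = TRUE)) {
    stop("creatinine_mg_dl must be strictly positive")
  }
  if (any(age_years <= 0, na.rm = TRUE)) stop("age_years must be positive")
  sexf <- sex_factor(sex)
  194 * creatinine_mg_dl^-1.094 * age_years^-0.287 * ifelse(sexf == "F", 0.739, 1)
}

sex_factor <- function(sex) {
  s <- toupper(as.character(sex))
  bad <- !is.na(s) & !s %in% c("M", "F")
  if (any(bad)) stop("sex must be 'M' or 'F'; got: ", paste(unique(s[bad]), collapse = ", "))
  s
}

#' Friedewald LDL cholesterol
#'
#' LDL-C from total cholesterol, HDL-C and triglycerides, all in mmol/L.
#' The Friedewald relation is stated on the mg/dL scale
#' (LDL = TC - HDL - TG/5); the computation runs internally in mg/dL
#' (cholesterol x 38.67, triglycerides x 88.57) and converts back, which on
#' the mmol/L scale equals TC - HDL - TG/2.2 (with 2.2 = 5 x 38.67/88.57
#' up to the conversion constants used). The relation is invalid at
#' TG >= 4.52 mmol/L (400 mg/dL); such rows return NA.
#'
#' @param tc_mmol_l total cholesterol, mmol/L.
#' @param hdl_mmol_l HDL cholesterol, mmol/L (must not exceed TC).
#' @param tg_mmol_l fasting triglycerides, mmol/L.
#' @param tg_limit_mmol_l validity limit, default 4.52 mmol/L.
#' @return numeric vector of LDL-C (mmol/L); NA where TG >= the limit.
#' @examples
#' compute_ldl_friedewald(5.17, 1.29, 1.13)
#' @export
compute_ldl_friedewald <- function(tc_mmol_l, hdl_mmol_l, tg_mmol_l,
                                   tg_limit_mmol_l = 4.52) {
  stopifnot(is.numeric(tc_mmol_l), is.numeric(hdl_mmol_l), is.numeric(tg_mmol_l))
  if (any(tc_mmol_l < 0 | hdl_mmol_l < 0 | tg_mmol_l < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative")
  }
  if (any(hdl_mmol_l > tc_mmol_l, na.rm = TRUE)) {
    stop("hdl_mmol_l exceeds tc_mmol_l")
  }
  chol <- 38.67 # mg/dL per mmol/L, cholesterol
  tg <- 88.57 # mg/dL per mmol/L, triglycerides
  ldl_mg <- tc_mmol_l * chol - hdl_mmol_l * chol - (tg_mmol_l * tg) / 5
  out <- ldl_mg / chol
  out[!is.na(tg_mmol_l) & tg_mmol_l >= tg_limit_mmol_l] <- NA_real_
  out
}

#' Cardio-ankle vascular index (CAVI)
#'
#' CAVI = a * [(2 rho / dP) * ln(Ps/Pd) * PWV^2] + b, where Ps/Pd are
#' systolic/diastolic pressure (mmHg), dP = Ps - Pd, rho is blood density and
#' PWV the heart-to-ankle pulse wave velocity. The device constants a and b
#' are proprietary and unpublished; defaults a = 1, b = 0, rho = 1.05 g/cm^3
#' reproduce the bracketed stiffness term itself and must be overridden to
#' emulate a specific device scale.
#'
#' The bracket has a finite limit as Ps -> Pd (ln(Ps/Pd)/dP -> 1/Pd), which
#' the implementation evaluates stably instead of returning NaN.
#'
#' @param sbp_mmhg systolic pressure, mmHg.
#' @param dbp_mmhg diastolic pressure, mmHg; must satisfy 0 < dbp < sbp.
#' @param pwv_m_s pulse wave velocity, m/s.
#' @param a,b device calibration constants.
#' @param rho blood density, g/cm^3.
#' @return numeric vector of CAVI values (dimensionless up to the unit
#'   convention embedded in a and b).
#' @export
compute_cavi <- function(sbp_mmhg, dbp_mmhg, pwv_m_s, a = 1, b = 0, rho = 1.05) {
  stopifnot(is.numeric(sbp_mmhg), is.numeric(dbp_mmhg), is.numeric(pwv_m_s))
  if (any(dbp_mmhg <= 0, na.rm = TRUE)) stop("dbp_mmhg must be positive")
  if (any(sbp_mmhg <= dbp_mmhg, na.rm = TRUE)) {
    stop("sbp_mmhg must exceed dbp_mmhg (dP <= 0)")
  }
  if (a < 0) stop("a must be non-negative")
  x <- (sbp_mmhg - dbp_mmhg) / dbp_mmhg
  # ln(Ps/Pd)/dP = log1p(x)/(Pd*x); series for tiny x avoids 0/0
  ratio <- ifelse(x < 1e-8,
    (1 - x / 2 + x^2 / 3) / dbp_mmhg,
    log1p(x) / (dbp_mmhg * x)
  )
  a * (2 * rho * ratio * pwv_m_s^2) + b
}

#' Threshold flags for a screening visit
#'
#' Derives the boolean risk flags used throughout the analysis: high CAVI
#' (>= 9.0, inclusive), low eGFR (< 60, strict), dipstick proteinuria
#' ((1+) or more; (-) and (+-) are negative), high LDL-C (>= 3.62 mmol/L)
#' and the ankle-brachial index exclusion (ABI < 0.90, which invalidates
#' CAVI through arterial occlusion). Missing inputs yield NA flags, never
#' imputed values.
#'
#' @param cavi CAVI values.
#' @param egfr eGFR values, mL/min/1.73 m^2.
#' @param dipstick character urinalysis grades among "-", "+-", "1+", "2+", "3+".
#' @param ldl_mmol_l LDL-C, mmol/L.
#' @param abi ankle-brachial index.
#' @param high_cavi_cutoff,low_egfr_cutoff,high_ldl_cutoff,abi_cutoff thresholds.
#' @return data.frame of logical columns high_cavi, low_egfr, proteinuria,
#'   high_ldl, abi_exclude.
#' @export
derive_flags <- function(cavi = NA_real_, egfr = NA_real_, dipstick = NA_character_,
                         ldl_mmol_l = NA_real_, abi = NA_real_,
                         high_cavi_cutoff = 9.0, low_egfr_cutoff = 60,
                         high_ldl_cutoff = 3.62, abi_cutoff = 0.90) {
  n <- max(length(cavi), length(egfr), length(dipstick), length(ldl_mmol_l), length(abi))
  cavi <- rep_len(cavi, n)
  egfr <- rep_len(egfr, n)
  dipstick <- rep_len(as.character(dipstick), n)
  ldl_mmol_l <- rep_len(ldl_mmol_l, n)
  abi <- rep_len(abi, n)
  lv <- dipstick_levels()
  bad <- !is.na(dipstick) & !dipstick %in% lv
  if (any(bad)) {
    stop("unknown dipstick grade(s): ", paste(unique(dipstick[bad]), collapse = ", "))
  }
  data.frame(
    high_cavi = cavi >= high_cavi_cutoff,
    low_egfr = egfr < low_egfr_cutoff,
    proteinuria = ifelse(is.na(dipstick), NA, dipstick %in% c("1+", "2+", "3+")),
    high_ldl = ldl_mmol_l >= high_ldl_cutoff,
    abi_exclude = abi < abi_cutoff
  )
}

dipstick_levels <- function() c("-", "+-", "1+", "2+", "3+")
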