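#' Kaplan-Meier curve with Greenwood confidence limits
#'
#' Product-limit survival estimate over the annual event grid, with pointwise
#' 95% limits from the Greenwood variance on the plain (linear) scale —
#' S(t) +/- 1.96 se, truncated to [0, 1].
#'
#' @param time follow-up time (years to event or censoring).
#' @param event logical/0-1 event indicator.
#' @return data.frame with one row per distinct observed time: time, n_risk,
#'   n_event, n_censor, survival, ci_low, ci_high.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
    conf.type = "plain", conf.int = 0.95)
  out <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv,
    ci_low = pmax(fit$lower, 0),
    ci_high = pmin(fit$upper, 1)
  )
  # all-censored samples: survfit reports surv = 1 with NaN limits
  out$ci_low[is.na(out$ci_low) & out$n_event == 0] <- 1
  out$ci_high[is.na(out$ci_high) & out$n_event == 0] <- 1
  out
}

#' Two-group log-rank test
#'
#' @param time follow-up time.
#' @param event logical/0-1 event indicator.
#' @param group two-level grouping vector.
#' @return list with chisq, df (= 1) and p.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) {
    stop("logrank_test requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
    p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the (optionally stratified) partial likelihood with Efron tie
#' handling by default — the annual screening grid produces heavy ties, for
#' which Efron's approximation is less biased than Breslow's. Reports per
#' covariate the coefficient, hazard ratio, Wald 95% CI and p-value.
#'
#' @param data data.frame holding all variables.
#' @param time,event column names of follow-up time and event indicator.
#' @param covariates character vector of covariate column names.
#' @param strata optional column name to stratify the baseline hazard on
#'   (e.g. integer age for the age-stratified variant).
#' @param ties "efron" (default) or "breslow".
#' @return data.frame: term, beta, se, hr, ci_low, ci_high, p; the global
#'   Schoenfeld proportionality p-value is attached as attribute
#'   `proportionality_global_p` (a logged diagnostic, never an assertion).
#' @export
cox_fit <- function(data, time = "time", event = "event", covariates,
                    strata = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(covariates) >= 1)
  if (sum(data[[event]], na.rm = TRUE) == 0) stop("no events in sample")
  for (v in covariates) {
    x <- data[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    if (length(unique(stats::na.omit(as.numeric(x)))) < 2) {
      stop("covariate is constant: ", v)
    }
  }
  rhs <- paste(c(
    covariates,
    if (!is.null(strata)) sprintf("survival::strata(%s)", strata)
  ), collapse = " + ")
  fml <- stats::as.formula(sprintf("survival::Surv(%s, as.integer(%s)) ~ %s",
    time, event, rhs))
  fit <- survival::coxph(fml, data = data, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit dropped aliased covariate(s): ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  s <- summary(fit)
  beta <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  z <- stats::qnorm(0.975)
  out <- data.frame(
    term = rownames(s$coefficients),
    beta = unname(beta),
    se = unname(se),
    hr = unname(exp(beta)),
    ci_low = unname(exp(beta - z * se)),
    ci_high = unname(exp(beta + z * se)),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    row.names = NULL
  )
  # Schoenfeld-style proportionality summary, logged not asserted
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  if (!is.null(zph)) {
    attr(out, "proportionality_global_p") <- unname(zph$table["GLOBAL", "p"])
  }
  out
}

#' Age-adjusted group means by analysis of covariance
#'
#' Fits outcome ~ group + age and evaluates each group's adjusted mean at the
#' pooled mean age. The adjusted-mean difference equals the group coefficient
#' of the linear model (an algebraic identity of the parallel-slopes ANCOVA).
#' The group p-value is Bonferroni-multiplied by the number of comparisons
#' run together as one family.
#'
#' @param outcome numeric outcome (here: CAVI).
#' @param group two-level grouping vector.
#' @param age numeric covariate.
#' @param n_comparisons size of the Bonferroni family (default 1).
#' @return list with `groups` (data.frame: group, n, adjusted_mean, sd),
#'   `difference` (adjusted mean difference, level 2 minus level 1),
#'   `p_raw`, `p_bonferroni`, and `age_at` (the pooled mean age used).
#' @export
ancova_adjusted_means <- function(outcome, group, age, n_comparisons = 1) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop("ancova_adjusted_means requires two non-empty groups")
  keep <- stats::complete.cases(outcome, g, age)
  outcome <- outcome[keep]; g <- droplevels(g[keep]); age <- age[keep]
  if (stats::var(age) == 0) stop("age is constant; ANCOVA covariate degenerate")
  if (all(tapply(age, g, stats::var) == 0)) stop("age collinear with group")
  fit <- stats::lm(outcome ~ g + age)
  if (any(is.na(stats::coef(fit)))) stop("collinear design in ANCOVA")
  age_at <- mean(age)
  nd <- data.frame(g = factor(levels(g), levels = levels(g)), age = age_at)
  adj <- stats::predict(fit, newdata = nd)
  p_raw <- summary(fit)$coefficients[2, 4]
  list(
    groups = data.frame(
      group = levels(g),
      n = as.integer(table(g)),
      adjusted_mean = unname(adj),
      sd = as.numeric(tapply(outcome, g, stats::sd)),
      row.names = NULL
    ),
    difference = unname(adj[2] - adj[1]),
    p_raw = p_raw,
    p_bonferroni = min(1, p_raw * n_comparisons),
    age_at = age_at
  )
}

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' Sweeps every observed score value as a threshold (positive if
#' score >= threshold), computes sensitivity and specificity, the area under
#' the ROC curve by the trapezoidal rule (which equals the Mann-Whitney
#' U statistic divided by n1*n0, ties counted 1/2), and the cutoff
#' maximizing the Youden index J = sensitivity + specificity - 1. Ties in J
#' are broken toward the lower score value.
#'
#' @param scores numeric predictor.
#' @param labels logical/0-1 outcome; both classes must be present.
#' @return list: auc, cutoff, sensitivity and specificity at the cutoff,
#'   youden (J at the cutoff), and the full `curve` data.frame
#'   (threshold, sensitivity, specificity).
#' @export
roc_youden <- function(scores, labels) {
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]
  y <- as.logical(labels[keep])
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("roc_youden requires both classes present")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(scores[y] >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!y] < t) / n0, numeric(1))
  # ROC polygon from (1,1) (threshold below min) down to (0,0)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # thr sorted ascending: first max = lowest score
  list(
    auc = auc,
    cutoff = thr[best],
    sensitivity = sens[best],
    specificity = spec[best],
    youden = j[best],
    curve = data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  )
}
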