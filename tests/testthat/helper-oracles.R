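# Independent brute-force oracles. Each is coded from the printed rules or
# textbook definitions, deliberately avoiding the package's code paths.

# --- MetS classifier: explicit per-criteria logic on a single profile row
oracle_mets <- function(p, criteria, mode) {
  obese <- if (mode == "absi") {
    p$absi >= 0.080
  } else if (criteria == "japanese") {
    if (p$sex == "M") p$wc_m >= 0.85 else p$wc_m >= 0.90
  } else if (criteria == "idf") {
    if (p$sex == "M") p$wc_m >= 0.90 else p$wc_m >= 0.80
  } else {
    if (p$sex == "M") p$wc_m >= 1.02 else p$wc_m >= 0.88
  }
  bp <- p$sbp_mmhg >= 130 || p$dbp_mmhg >= 85 || p$tx_htn
  if (criteria == "japanese") {
    lipid <- p$tg_mmol_l >= 1.69 || p$hdl_mmol_l < 1.03 || p$tx_dlp
    glu <- p$fpg_mmol_l >= 6.11 || p$tx_dm
    return(obese && (lipid + bp + glu) >= 2)
  }
  tg <- p$tg_mmol_l >= 1.69 || p$tx_dlp
  hdl <- p$hdl_mmol_l < 1.03
  if (criteria == "idf") {
    glu <- p$fpg_mmol_l >= 6.11 || p$tx_dm
    return(obese && (tg + hdl + bp + glu) >= 2)
  }
  glu <- p$fpg_mmol_l >= 5.55 || p$tx_dm
  (tg + hdl + bp + glu + obese) >= 3
}

# --- Kaplan-Meier product-limit, recomputed from first principles
oracle_km <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  out <- data.frame(time = tt, survival = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# Greenwood plain-scale 95% CI
oracle_km_ci <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  gw <- 0
  out <- data.frame(time = tt, survival = NA_real_, low = NA_real_, high = NA_real_)
  for (i in seq_along(tt)) {
    n <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / n)
    if (d > 0) gw <- gw + d / (n * (n - d))
    se <- s * sqrt(gw)
    out$survival[i] <- s
    out$low[i] <- max(0, s - qnorm(0.975) * se)
    out$high[i] <- min(1, s + qnorm(0.975) * se)
  }
  out
}

# --- two-group log-rank by observed-minus-expected sums
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) # 1/2
  tt <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# --- Cox partial log-likelihood for one covariate, Breslow form, no ties
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid search + golden refinement, independent of coxph
oracle_cox_beta <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(oracle_cox_loglik, c(b0 - 0.02, b0 + 0.02), time = time,
    event = event, x = x, maximum = TRUE, tol = 1e-10)$maximum
}

# --- AUC via the Mann-Whitney U identity (ties count 1/2)
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- least squares via normal equations
oracle_lm_coef <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# --- Fisher exact two-sided p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  # margins: row1 = a+b, col1 = a+c, N = a+b+c+d
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- small random survival sample builder
random_surv_sample <- function(n, p_event = 0.6, tmax = 5) {
  time <- sample(seq_len(tmax), n, replace = TRUE)
  event <- runif(n) < p_event
  data.frame(time = time, event = event)
}

# profile row builder with neutral defaults
make_profile <- function(sex = "M", wc_m = 0.75, absi = 0.075, sbp = 110,
                         dbp = 70, fpg = 4.8, tg = 0.9, hdl = 1.8,
                         tx_htn = FALSE, tx_dm = FALSE, tx_dlp = FALSE) {
  data.frame(sex = sex, wc_m = wc_m, absi = absi, sbp_mmhg = sbp,
    dbp_mmhg = dbp, fpg_mmol_l = fpg, tg_mmol_l = tg, hdl_mmol_l = hdl,
    tx_htn = tx_htn, tx_dm = tx_dm, tx_dlp = tx_dlp,
    stringsAsFactors = FALSE)
}
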