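test_that("abdominal obesity cutoffs are sex-, criteria- and mode-specific", {
  th <- default_criteria()
  # inclusive >= at the printed male Japanese waist cutoff
  expect_true(abdominal_obesity("M", 0.85, 0.07, "japanese", "wc", th))
  expect_false(abdominal_obesity("M", 0.8499, 0.07, "japanese", "wc", th))
  # ABSI mode ignores sex and criteria, inclusive at 0.080
  for (cr in c("japanese", "idf", "ncep")) {
    expect_true(abdominal_obesity("F", 0.7, 0.080, cr, "absi", th))
    expect_false(abdominal_obesity("M", 1.2, 0.0799, cr, "absi", th))
  }
  # female 0.85 m: above the IDF cutoff (0.80) but below the Japanese (0.90)
  expect_true(abdominal_obesity("F", 0.85, 0.07, "idf", "wc", th))
  expect_false(abdominal_obesity("F", 0.85, 0.07, "japanese", "wc", th))
  expect_error(abdominal_obesity("X", 0.85, 0.07, "idf", "wc", th), "sex")
})

test_that("treatment counting: dyslipidemia therapy sets TG, never HDL", {
  p <- make_profile(tx_dlp = TRUE, tg = 0.8, hdl = 1.8)
  idf <- mets_components(p, "idf")
  expect_true(idf$tg)
  expect_false(idf$hdl)
  ncep <- mets_components(p, "ncep")
  expect_true(ncep$tg)
  expect_false(ncep$hdl)
  # Japanese combined lipid component is set by treatment
  expect_true(mets_components(p, "japanese")$lipid)
})

test_that("glucose thresholds differ between NCEP and Japanese/IDF", {
  p <- make_profile(fpg = 5.8)
  expect_true(mets_components(p, "ncep")$glucose) # >= 5.55
  expect_false(mets_components(p, "idf")$glucose) # < 6.11
  expect_false(mets_components(p, "japanese")$glucose)
  # all clear profile has no positive components anywhere
  q <- make_profile()
  expect_false(any(unlist(mets_components(q, "japanese"))))
  expect_false(any(unlist(mets_components(q, "idf"))))
  expect_false(any(unlist(mets_components(q, "ncep"))))
})

test_that("combination rules: obesity gate for Japanese/IDF, 3-of-5 for NCEP", {
  # Japanese: all three components but no obesity -> negative
  p <- make_profile(wc_m = 0.80, absi = 0.075, tg = 2.0, sbp = 140, fpg = 6.5)
  expect_false(mets_diagnose(p, "japanese", "wc")$verdict)
  expect_equal(mets_diagnose(p, "japanese", "wc")$n_positive_components, 3L)
  # NCEP: tg + hdl + bp true without obesity -> positive (3 of 5)
  q <- make_profile(wc_m = 0.80, absi = 0.075, tg = 2.0, hdl = 0.9, sbp = 140)
  expect_true(mets_diagnose(q, "ncep", "wc")$verdict)
  # IDF ABSI mode: obesity by ABSI plus bp + glucose
  r <- make_profile(sex = "F", absi = 0.081, sbp = 135, fpg = 6.2)
  expect_true(mets_diagnose(r, "idf", "absi")$verdict)
})

test_that("engine matches an independent classifier over the exhaustive grid", {
  grid <- expand.grid(
    sex = c("M", "F"),
    wc_m = c(0.75, 0.86, 0.91, 1.03), # straddles every criteria cutoff
    absi = c(0.079, 0.081),
    tg = c(0.8, 1.70),
    hdl = c(0.9, 1.8),
    sbp = c(120, 131),
    dbp = c(70, 86),
    fpg = c(5.0, 5.8, 6.2), # below NCEP, between, above Japanese/IDF
    tx_htn = c(FALSE, TRUE),
    tx_dm = c(FALSE, TRUE),
    tx_dlp = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  profile <- data.frame(
    sex = grid$sex, wc_m = grid$wc_m, absi = grid$absi,
    sbp_mmhg = grid$sbp, dbp_mmhg = grid$dbp, fpg_mmol_l = grid$fpg,
    tg_mmol_l = grid$tg, hdl_mmol_l = grid$hdl,
    tx_htn = grid$tx_htn, tx_dm = grid$tx_dm, tx_dlp = grid$tx_dlp,
    stringsAsFactors = FALSE
  )
  for (cr in c("japanese", "idf", "ncep")) {
    for (md in c("wc", "absi")) {
      got <- mets_diagnose(profile, cr, md)$verdict
      want <- vapply(seq_len(nrow(profile)),
        function(i) oracle_mets(profile[i, ], cr, md), logical(1))
      expect_identical(got, want,
        label = paste("verdicts", cr, md))
    }
  }
})

test_that("verdicts are monotone in the components", {
  set.seed(21)
  for (rep in 1:50) {
    p <- make_profile(
      sex = sample(c("M", "F"), 1),
      wc_m = runif(1, 0.6, 1.1), absi = runif(1, 0.07, 0.09),
      sbp = runif(1, 100, 160), dbp = runif(1, 60, 100),
      fpg = runif(1, 4, 7), tg = runif(1, 0.5, 3), hdl = runif(1, 0.8, 2.5),
      tx_htn = runif(1) < 0.3, tx_dm = runif(1) < 0.3, tx_dlp = runif(1) < 0.3
    )
    worse <- p
    worse$tg_mmol_l <- 5; worse$hdl_mmol_l <- 0.5; worse$sbp_mmhg <- 180
    worse$fpg_mmol_l <- 8; worse$wc_m <- 1.2; worse$absi <- 0.095
    for (cr in c("japanese", "idf", "ncep")) {
      for (md in c("wc", "absi")) {
        if (mets_diagnose(p, cr, md)$verdict) {
          expect_true(mets_diagnose(worse, cr, md)$verdict)
        }
      }
    }
  }
})

test_that("WC and ABSI modes coincide when obesity holds in both", {
  set.seed(22)
  p <- make_profile(
    sex = sample(c("M", "F"), 20, replace = TRUE),
    wc_m = runif(20, 1.05, 1.3), absi = runif(20, 0.081, 0.09),
    sbp = runif(20, 100, 160), dbp = runif(20, 60, 100),
    fpg = runif(20, 4, 7), tg = runif(20, 0.5, 3), hdl = runif(20, 0.8, 2.5),
    tx_htn = runif(20) < 0.3, tx_dm = runif(20) < 0.3, tx_dlp = runif(20) < 0.3
  )
  for (cr in c("japanese", "idf", "ncep")) {
    expect_identical(mets_diagnose(p, cr, "wc")$verdict,
      mets_diagnose(p, cr, "absi")$verdict)
  }
})

test_that("cohort classification counts prevalence and rejects duplicates", {
  # toy cohort: exactly one of three satisfies Japanese ABSI-MetS
  b <- make_profile(
    sex = c("F", "F", "M"),
    absi = c(0.081, 0.081, 0.075),
    sbp = c(135, 120, 120),
    fpg = c(6.2, 4.8, 4.8)
  )
  b$subject_id <- c("a", "b", "c")
  cl <- classify_cohort(b)
  expect_equal(cl$mets_japanese_absi, c(TRUE, FALSE, FALSE))
  pv <- mets_prevalence(cl)
  expect_equal(pv$prevalence_pct[pv$definition == "mets_japanese_absi"], 33.3)
  # threshold-free cohort has zero prevalence everywhere
  clean <- make_profile(sex = c("M", "F"))
  clean$subject_id <- c("a", "b")
  expect_true(all(mets_prevalence(classify_cohort(clean))$prevalence_pct == 0))
  dup <- b; dup$subject_id <- c("a", "a", "c")
  expect_error(classify_cohort(dup), "duplicate")
})

test_that("thresholds are config-driven: shifting a cutoff moves the verdict", {
  th <- default_criteria()
  p <- make_profile(sex = "M", wc_m = 0.83, tg = 2.0, sbp = 140)
  expect_false(mets_diagnose(p, "japanese", "wc", th)$verdict)
  th$japanese$wc_male_m <- 0.82
  expect_true(mets_diagnose(p, "japanese", "wc", th)$verdict)
})
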