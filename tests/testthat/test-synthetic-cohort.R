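test_that("default cohort has 211 records with reference glucose in band", {
  co <- generate_cohort(cohort_config(ppg = FALSE), seed = 1)
  expect_equal(nrow(co), 211)
  expect_true(all(co$BG_ref_mmolL >= 4.1))
  expect_true(all(co$BG_ref_mmolL <= 10))
  expect_true(all(co$BG_true_mmolL >= 4.1 & co$BG_true_mmolL <= 10))
  expect_equal(length(unique(co$record_id)), 211)
  expect_true(all(co$timepoint_label %in%
                    c("pre-meal", "30min", "60min", "90min", "120min")))
})

test_that("cohorts are reproducible by seed and differ across seeds", {
  a <- generate_cohort(cohort_config(n_records = 40, ppg = FALSE), seed = 8)
  b <- generate_cohort(cohort_config(n_records = 40, ppg = FALSE), seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_config(n_records = 40, ppg = FALSE), seed = 9)
  expect_false(identical(a$BG_ref_mmolL, c2$BG_ref_mmolL))
})

test_that("every generated frame is admissible and reproduces its target heat", {
  co <- generate_cohort(cohort_config(n_records = 2000, ppg = FALSE),
                        seed = 2)
  # no domain errors across all draws
  for (i in sample(nrow(co), 50)) {
    expect_s3_class(
      sensor_frame(co$Tr_K[i], co$tw_C[i], co$ts_C[i], co$He_frac[i],
                   co$BF_pu[i]),
      "sensor_frame")
  }
  hf <- metabolic_heat(list(Tr = co$Tr_K, tw = co$tw_C, ts = co$ts_C,
                            He = co$He_frac))
  expect_equal(hf$H, co$H_true_Wm2, tolerance = 1e-8)
  # and the ground-truth relation holds on the noiseless glucose
  bg <- ground_truth_F(co$H_true_Wm2, co$SpO2_true_pct, co$HR_true_bpm,
                       co$BF_pu)
  expect_equal(bg, co$BG_true_mmolL, tolerance = 1e-8)
})

test_that("registered truth families match their frozen fixture table", {
  pts <- read.csv(system.file("extdata",
                              "ground_truth_points_synthetic.csv",
                              package = "glucoheat"))
  for (fam in unique(pts$family)) {
    p <- pts[pts$family == fam, ]
    expect_equal(ground_truth_F(p$H, p$SpO2, p$HR, p$BF, family = fam),
                 p$bg, tolerance = 1e-12)
  }
  expect_error(ground_truth_F(500, 96, 75, 10, family = "quadratic"))
})

test_that("synthetic waveforms round-trip their vitals through the optical chain", {
  for (case in list(c(60, 98), c(85, 95), c(140, 97))) {
    w <- generate_ppg(case[1], case[2], fs = 100, duration = 10)
    v <- process_ppg(w)
    expect_lt(abs(v$HR - case[1]), 1)
    expect_lt(abs(v$SpO2 - case[2]), 0.5)
  }
  # 60 bpm for 10 s carries 10 beats
  w <- generate_ppg(60, 97, fs = 100, duration = 10)
  expect_equal(detect_peaks(w$ir, 100)$npeak, 10)
  # DC invariance of the implied ratio
  w2 <- generate_ppg(72, 95, dc = c(red = 40000, ir = 48000))
  w1 <- generate_ppg(72, 95, dc = c(red = 20000, ir = 24000))
  expect_equal(perfusion_ratio(w1), perfusion_ratio(w2), tolerance = 1e-9)
  expect_error(generate_ppg(30, 97), "40, 180")
  expect_error(generate_ppg(72, 140), "0, 100")
})

test_that("zero-noise cohort lets MPR4 recover the generating relation", {
  co <- generate_cohort(cohort_config(n_records = 150, noise_sd = 0,
                                      ppg = FALSE), seed = 5)
  feats <- cohort_features(co)
  m <- fit_mpr4(feats)
  # the mpr4-span truth uses terms x1, x3, x4, x3:x4 plus intercept
  coefs <- m$coefficients
  expect_equal(unname(coefs["(Intercept)"]), -42, tolerance = 1e-4)
  expect_equal(unname(coefs["x1"]), 0.095, tolerance = 1e-6)
  expect_equal(unname(coefs["x3"]), 0.012, tolerance = 1e-4)
  expect_equal(unname(coefs["x4"]), 0.05, tolerance = 1e-4)
  expect_equal(unname(coefs["x3:x4"]), 4e-4, tolerance = 1e-6)
  expect_lt(mard(feats$bg_ref, predict(m, feats)), 1e-8)
})

test_that("full pipeline at zero noise attains test mARD below 0.5%", {
  cfg <- cohort_config(n_records = 120, noise_sd = 0, duration = 12)
  co <- generate_cohort(cfg, seed = 6)
  feats <- extract_features(co)   # H from frames, vitals from waveforms
  feats$bg_ref <- co$BG_ref_mmolL
  sp <- holdout_split(feats, seed = 6)
  m <- fit_mpr4(sp$train)
  expect_lt(mard(sp$test$bg_ref, predict(m, sp$test)), 0.5)
})

test_that("5% noise keeps both models under the noise-implied error bound", {
  # multiplicative noise sd 0.05 implies a test mARD floor near
  # 100 * 0.05 * sqrt(2/pi) ~ 4.0%; the bound below allows 2.5x that for
  # estimation error on a 211-record cohort
  bound <- 2.5 * 100 * 0.05 * sqrt(2 / pi)
  co <- generate_cohort(cohort_config(ppg = FALSE), seed = 7)
  feats <- cohort_features(co)
  sp <- holdout_split(feats, seed = 7)
  m <- fit_mpr4(sp$train)
  b <- suppressWarnings(fit_bpnn(sp$train, seed = 7))
  expect_lt(mard(sp$test$bg_ref, predict(m, sp$test)), bound)
  expect_lt(mard(sp$test$bg_ref, predict(b, sp$test)), bound)
})

test_that("the network outperforms the polynomial on the saturating family", {
  # fixed seed batch; compared on the batch mean
  seeds <- 1:5
  res <- vapply(seeds, function(s) {
    co <- generate_cohort(cohort_config(ppg = FALSE, truth = "saturating"),
                          seed = s)
    feats <- cohort_features(co)
    sp <- holdout_split(feats, seed = s)
    m <- fit_mpr4(sp$train)
    b <- suppressWarnings(fit_bpnn(sp$train, seed = s))
    c(mard(sp$test$bg_ref, predict(m, sp$test)),
      mard(sp$test$bg_ref, predict(b, sp$test)))
  }, numeric(2))
  expect_lte(mean(res[2, ]), mean(res[1, ]))
})

test_that("configuration is validated", {
  expect_error(cohort_config(bg_range = c(10, 4)), "bg_range")
  expect_error(cohort_config(noise_sd = -0.1))
  expect_error(cohort_config(hr_range = c(10, 300)))
})
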