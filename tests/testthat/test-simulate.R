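test_that("generators are pure functions of parameters and seed", {
  a <- gen_cpmg_series(5, 100, 50, seed = 42)
  b <- gen_cpmg_series(5, 100, 50, seed = 42)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities,
                         gen_cpmg_series(5, 100, 50, seed = 43)$intensities))

  p1 <- gen_displacement_panel(c(x = 2), seed = 5)
  p2 <- gen_displacement_panel(c(x = 2), seed = 5)
  expect_identical(p1$table, p2$table)

  t1 <- gen_spr_titration(1.5, 50, noise_sd = 1, seed = 7)
  t2 <- gen_spr_titration(1.5, 50, noise_sd = 1, seed = 7)
  expect_identical(t1$responses, t2$responses)

  # generators do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_spr_titration(1, 10, seed = 2)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("noiseless CPMG series embed the mixed relaxation rate", {
  s <- gen_cpmg_series(5, 100, 50, noise_sd = 0, seed = 1)
  truth <- attr(s, "truth")
  fb <- 3.29589 / 100
  expect_equal(truth$fb, fb, tolerance = 1e-5)
  expect_equal(truth$R2_obs, 3 + fb * (245.7 - 3), tolerance = 1e-4)
  fit <- fit_t2(s)
  expect_equal(fit$R2, truth$R2_obs, tolerance = 1e-9)
  # free spy decays at the free rate
  s0 <- gen_cpmg_series(0, 100, 50, noise_sd = 0, seed = 1)
  expect_equal(attr(s0, "truth")$R2_obs, 3)
  # calibrated bound rate reproduces the observed with-protein rate
  expect_equal(attr(s, "truth")$R2_obs, 11, tolerance = 0.01)
})

test_that("noiseless displacement panels round-trip exactly", {
  panel <- gen_displacement_panel(c(a = 0.5, b = 1.5, c = 5, d = 20),
                                  I0_comp = 10, noise_sd = 0, seed = 1,
                                  n_replicates = 1)
  res <- analyze_displacement_table(panel$table)
  expect_equal(res$ki_mean[match(panel$truth$peptide_id, res$peptide_id)],
               panel$truth$ki_true, tolerance = 1e-6)
})

test_that("noisy displacement panels recover Ki within 15%", {
  panel <- gen_displacement_panel(c(a = 0.5, b = 1.5, c = 5, d = 20),
                                  I0_comp = 10, noise_sd = 0.01, seed = 42)
  res <- analyze_displacement_table(panel$table)
  res <- res[match(panel$truth$peptide_id, res$peptide_id), ]
  expect_lt(max(abs(res$ki_mean - panel$truth$ki_true) /
                  panel$truth$ki_true), 0.15)
})

test_that("non-binders come back flagged as showing no displacement", {
  panel <- gen_displacement_panel(c(dead = 1e6), I0_comp = 10,
                                  noise_sd = 0.01, seed = 8)
  res <- analyze_displacement_table(panel$table)
  flags <- strsplit(res$flags, ",")[[1]]
  expect_gte(sum(flags == "no_displacement"), 3)
})

test_that("configured noise levels match empirical noise", {
  # multiplicative CPMG noise, pooled over seeds
  eps <- unlist(lapply(1:400, function(s) {
    ser <- gen_cpmg_series(0, 100, 50, noise_sd = 0.01, seed = s)
    ser$intensities / (1000 * exp(-ser$delays * 3)) - 1
  }))
  expect_lt(abs(sd(eps) - 0.01) / 0.01, 0.10)
  # additive SPR noise
  conc <- spr_default_concentrations()
  resid <- unlist(lapply(1:400, function(s) {
    tit <- gen_spr_titration(10, 100, noise_sd = 1, seed = s)
    tit$responses - 100 * conc / (10 + conc)
  }))
  expect_lt(abs(sd(resid) - 1), 0.10)
})

test_that("planted hotspots are recovered across seeds", {
  # one strong (4-fold) alanine effect among neutral positions; the
  # pipeline generates both assays, fits them, and calls hotspots
  conc <- spr_default_concentrations()
  hit <- vapply(1:60, function(seed) {
    kd_true <- c(WT = 2, p1 = 2.1, p2 = 8, p3 = 1.9)   # p2 planted 4-fold
    ki_true <- c(WT = 2, p1 = 2.0, p2 = 8.5, p3 = 2.2)
    kd_fit <- vapply(seq_along(kd_true), function(i) {
      tit <- gen_spr_titration(kd_true[i], Rmax = 100, noise_sd = 1,
                               seed = seed * 100 + i)
      fit_spr_steady_state(tit)$KD
    }, numeric(1))
    pan <- gen_displacement_panel(ki_true, I0_comp = 10, noise_sd = 0.01,
                                  seed = seed)
    ki_fit <- analyze_displacement_table(pan$table)
    ki_fit <- ki_fit$ki_mean[match(names(ki_true), ki_fit$peptide_id)]
    tab <- data.frame(
      peptide_id = names(kd_true), panel = "SYN",
      sequence = "AApYAAA",
      position_label = c("WT", "pY(+1)", "pY(+2)", "pY(+3)"),
      kd_spr_uM = kd_fit, kd_spr_sem = NA, ki_nmr_uM = ki_fit,
      ki_nmr_sem = NA, offset = c(NA, 1, 2, 3))
    class(tab) <- c("panel_table", "data.frame")
    hs <- call_hotspots(tab)
    identical(hs$hotspots$SYN, "pY(+2)")
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
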