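test_that("trace metrics recover the generated sustained/peak ratio", {
  tr <- gen_current_traces(trace_gen_spec(seed = 1, ratio = 0.10,
                                          noise_sd = 0), 1)[[1]]
  m <- trace_metrics(tr)
  expect_equal(m$ratio, 0.10, tolerance = 1e-6)
  expect_equal(m$i_peak, 5, tolerance = 1e-6)
  expect_equal(m$baseline, 0, tolerance = 1e-12)

  # wild-type-like 1 mM ratio of 0.03, with recording noise
  trs <- gen_current_traces(trace_gen_spec(seed = 2, ratio = 0.03,
                                           noise_sd = 0.02), 5)
  ratios <- vapply(trs, function(t) trace_metrics(t)$ratio, numeric(1))
  expect_equal(mean(ratios), 0.03, tolerance = 0.01)
})

test_that("trace metrics are offset-invariant and sign-equivariant", {
  tr <- gen_current_traces(trace_gen_spec(seed = 3, ratio = 0.08,
                                          noise_sd = 0.01), 1)[[1]]
  m0 <- trace_metrics(tr)
  up <- current_trace(tr$t, tr$i + 3.7, tr$protocol)
  flip <- current_trace(tr$t, -tr$i, tr$protocol)
  expect_equal(trace_metrics(up)$ratio, m0$ratio, tolerance = 1e-12)
  expect_equal(trace_metrics(flip)$ratio, m0$ratio, tolerance = 1e-12)
  expect_equal(trace_metrics(flip)$i_peak, m0$i_peak, tolerance = 1e-12)
})

test_that("trace/protocol inconsistencies are rejected or flagged", {
  p <- stimulus_protocol(5, 15)
  expect_error(current_trace(seq(0, 10, 0.01), rep(0, 1001), p),
               "exceeds trace length")
  short <- stimulus_protocol(5, 6.5)
  tr <- gen_current_traces(trace_gen_spec(seed = 1, protocol = short,
                                          noise_sd = 0), 1)[[1]]
  expect_error(trace_metrics(tr), "shorter than")
  # unusable flag below the noise floor
  quiet <- gen_current_traces(trace_gen_spec(seed = 1, i_peak = -0.01,
                                             noise_sd = 0), 1)[[1]]
  expect_false(trace_metrics(quiet, noise_floor = 0.5)$usable)
})

test_that("trace CSV + protocol JSON round-trips", {
  tr <- gen_current_traces(trace_gen_spec(seed = 4), 1)[[1]]
  csv <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_trace_csv(tr, csv, pj)
  back <- read_trace_csv(csv, pj)
  expect_equal(back$i, tr$i, tolerance = 1e-12)
  expect_equal(back$protocol$acid_end, tr$protocol$acid_end)
})

test_that("SSD fits recover noiseless parameters over the whole grid", {
  for (phd in c(6.8, 7.1, 7.4)) {
    for (nh in c(1, 3, 6)) {
      s <- gen_ssd_series(seq(phd - 0.7, phd + 0.7, length.out = 9),
                          pHD50 = phd, nH = nh, Imax = 1, noise_sd = 0)
      f <- fit_ssd(s$pH, s$I)
      expect_equal(f$pHD50, phd, tolerance = 1e-6)
      expect_equal(f$nH, nh, tolerance = 1e-5)
      expect_equal(f$Imax, 1, tolerance = 1e-6)
      # midpoint identity: fitted curve passes Imax/2 at pHD50
      expect_equal(unname(f$fitted(f$pHD50)), f$Imax / 2, tolerance = 1e-9)
    }
  }
})

test_that("SSD fit errors on degenerate input", {
  expect_error(fit_ssd(c(7.0, 7.2), c(1, 0.5)), "4 distinct")
  expect_error(fit_ssd(seq(6.8, 7.6, 0.2), rep(1, 5)), "degenerate")
})

test_that("dose-response fits recover truth and anchor r_0 at c = 0", {
  d <- gen_dose_response_series(EC50 = 37e-6, noise_sd = 0)
  f <- fit_dose_response(d$conc, d$ratio)
  expect_equal(f$EC50, 37e-6, tolerance = 0.01)
  expect_equal(f$hill, 1, tolerance = 1e-3)
  expect_equal(unname(f$fitted(0)), f$r_0, tolerance = 1e-12)

  d2 <- gen_dose_response_series(EC50 = 11e-6, r_max = 0.17, noise_sd = 0)
  f2 <- fit_dose_response(d2$conc, d2$ratio)
  expect_equal(f2$EC50, 11e-6, tolerance = 0.01)
})

test_that("exponential kinetics recover decay and rise rates", {
  k <- gen_kinetic_series(rate = 0.025, mode = "decay", noise_sd = 0)
  f <- fit_exponential_kinetics(k$t, k$y, "decay")
  expect_equal(f$rate, 0.025, tolerance = 1e-6)
  expect_true(is.na(f$k_on))

  kr <- gen_kinetic_series(t = seq(0, 400, 25), rate = 162 * 5e-5,
                           mode = "rise", noise_sd = 0)
  fr <- fit_exponential_kinetics(kr$t, kr$y, "rise", ligand_conc = 5e-5)
  expect_equal(fr$k_on, 162, tolerance = 1e-4)

  # two-state variant subtracts the dissociation rate
  fr2 <- fit_exponential_kinetics(kr$t, kr$y, "rise", ligand_conc = 5e-5,
                                  kon_model = "with_koff", k_off = 0.002)
  expect_equal(fr2$k_on, (fr$rate - 0.002) / 5e-5, tolerance = 1e-6)

  expect_error(fit_exponential_kinetics(1:10, rep(2, 10), "decay"),
               "constant")
})

test_that("fits beat or match the generating parameters in RSS", {
  # on noiseless data the fitted RSS cannot exceed the truth RSS
  s <- gen_ssd_series(pHD50 = 7.25, nH = 2.5, noise_sd = 0)
  f <- fit_ssd(s$pH, s$I)
  rss_truth <- sum((s$I - hill_ssd(s$pH, 7.25, 2.5, 1))^2)
  expect_lte(f$rss, rss_truth + 1e-10)
  d <- gen_dose_response_series(noise_sd = 0.001, seed = 8)
  fd <- fit_dose_response(d$conc, d$ratio)
  r_truth <- gen_dose_response_series(noise_sd = 0)$ratio
  expect_lte(fd$rss, sum((d$ratio - r_truth)^2) + 1e-12)
})

test_that("modulation comparison flags suppressed and enhanced effects", {
  # identical populations: everything "="
  same <- gen_modulation_dataset(seed = 21, fold_mult = 1, dphd50_mult = 1,
                                 nh_attenuation = 0)
  cmp <- compare_modulation(same$wt, list(M = same$mut))
  expect_equal(unname(unlist(cmp[, c("sym_isust", "sym_dphd50", "sym_nh")])),
               c("=", "=", "="))

  # effect at 25% of WT with low noise: suppressed sustained-current symbol
  supp <- gen_modulation_dataset(seed = 22, fold_mult = 0.25, cv = 0.05)
  cmp2 <- compare_modulation(supp$wt, list(M = supp$mut))
  expect_equal(cmp2$sym_isust, "<")
  expect_lt(cmp2$fold_change_ratio, 1)

  expect_error(compare_modulation(same$wt[1:2, ], list(M = same$mut)),
               "3 replicates")
})
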