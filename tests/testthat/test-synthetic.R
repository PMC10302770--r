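test_that("noiseless RTCA trace is the viability curve with NCI(0) = 1", {
  st <- state_at(15)
  cfg <- sim_config()
  sc <- synth_config(p_control_q0(), noise_sigma = 0, seed = 4)
  rt <- generate_rtca(st, cfg, sc)
  expect_identical(rt$full$nci[rt$full$time_h == 0], 1)
  # at whole hours the trace equals viability/100 exactly (no interpolation)
  hours <- rt$full$time_h %% 1 == 0
  expect_equal(rt$full$nci[hours],
               rt$sim$viability[match(rt$full$time_h[hours], rt$sim$times)] / 100)
  expect_identical(rt$fit$time_h, c(24, 36, 48, 60, 72))
  expect_equal(rt$fit$viability_pct,
               rt$sim$viability[match(rtca_fit_times(), rt$sim$times)])
  # 15-min sampling
  expect_equal(diff(rt$full$time_h)[1], 0.25)

  # raw impedance trace: R = R_t0 + F * CI with F = 15 ohm
  rt2 <- generate_rtca(st, cfg, sc, raw = TRUE, ci0 = 2, r_t0 = 100)
  expect_equal(rt2$raw$resistance_ohm, 100 + 15 * 2 * rt2$full$nci)
})

test_that("RTCA generation is seed-deterministic and honors the noise law", {
  st <- state_at(11)
  cfg <- sim_config()
  sc <- synth_config(p_control_q0(), noise_sigma = 0.03, seed = 21)
  r1 <- generate_rtca(st, cfg, sc)
  r2 <- generate_rtca(st, cfg, sc)
  expect_identical(r1$full, r2$full)
  expect_identical(r1$fit, r2$fit)

  # Monte-Carlo check of the multiplicative law: pooled SD of nci/truth
  # across seeds and sample times stays near sigma = 0.03
  ratios <- unlist(lapply(1:12, function(s) {
    sc_s <- synth_config(p_control_q0(), noise_sigma = 0.03, seed = s)
    rt <- generate_rtca(st, cfg, sc_s)
    truth <- stats::approx(rt$sim$times, rt$sim$viability / 100,
                           xout = rt$full$time_h)$y
    (rt$full$nci / truth)[rt$full$time_h > 0]
  }))
  expect_gt(length(ratios), 1000)
  expect_gt(sd(ratios), 0.025)
  expect_lt(sd(ratios), 0.035)
})

test_that("flow snapshots split viability into four fractions summing to 100", {
  st <- state_at(15)
  cfg <- sim_config()
  truth <- p_treated_q0()

  # deterministic split without jitter
  sc0 <- synth_config(truth, f_early = 0.1, f_late = 0.8,
                      dirichlet_conc = Inf, seed = 3)
  fl <- generate_flow(st, cfg, sc0)
  sim <- simulate_viability(st, truth, cfg, keep_fields = FALSE)
  for (k in 1:2) {
    fr <- fl$fractions[[k]]
    V <- sim$viability[sim$times == fr$t]
    expect_equal(fr$viable_pct, V * 0.9)
    expect_equal(fr$early_pct, V * 0.1)
    expect_equal(fr$late_pct, (100 - V) * 0.8)
    expect_equal(fr$necrosis_pct, (100 - V) * 0.2)
    # pooled viability equals the simulator's viability exactly
    expect_equal(pooled_viability(fr), V)
  }

  # degenerate split: everything early-free and late
  scd <- synth_config(truth, f_early = 0, f_late = 1,
                      dirichlet_conc = Inf, seed = 3)
  fr <- generate_flow(st, cfg, scd)$fractions[[1]]
  V <- sim$viability[sim$times == 24]
  expect_equal(unlist(fr[c("viable_pct", "early_pct", "late_pct",
                           "necrosis_pct")]),
               c(viable_pct = V, early_pct = 0, late_pct = 100 - V,
                 necrosis_pct = 0))

  # jittered fractions still sum to 100 within 1e-9, deterministically
  scj <- synth_config(truth, dirichlet_conc = 200, seed = 17)
  flj <- generate_flow(st, cfg, scj)
  for (fr in flj$fractions) {
    expect_lt(abs(fr$viable_pct + fr$early_pct + fr$late_pct +
                    fr$necrosis_pct - 100), 1e-9)
  }
  expect_identical(generate_flow(st, cfg, scj)$series, flj$series)

  # growing cultures (viability > 100 %) cannot be expressed as fractions
  scg <- synth_config(p_control_q0(), dirichlet_conc = Inf, seed = 3)
  expect_error(generate_flow(st, cfg, scg), "outside \\[0, 100\\]")
})

test_that("flow fraction container validates range and sum", {
  expect_error(flow_fractions(24, 50, 10, 30, 8), "sum to 100")
  expect_error(flow_fractions(24, -1, 11, 82, 8), "\\[0, 100\\]")
  fr <- flow_fractions(24, 54, 6, 32, 8)
  expect_equal(pooled_viability(fr), 60)
})

test_that("blob images are deterministic, bounded and threshold-countable", {
  img <- generate_blob_image(48, 40, 5, seed = 7)
  expect_equal(dim(img), c(40, 48))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(generate_blob_image(48, 40, 5, seed = 7), img)
  expect_false(identical(generate_blob_image(48, 40, 5, seed = 8), img))
  # exhaustive pixel-scan oracle for the thresholded cell count
  expect_identical(sum(img > 0.5), length(which(as.vector(img) > 0.5)))
  expect_gt(sum(img > 0.5), 0)
  expect_error(generate_blob_image(8, 8, 1, seed = 1), ">= 16")
  expect_error(generate_blob_image(32, 32, 1), "seed")
})

test_that("synthetic config validates its noise model", {
  expect_error(synth_config(p_control_q0(), noise_sigma = -0.1, seed = 1),
               "noise_sigma")
  expect_error(synth_config(p_control_q0(), f_early = 1.2, seed = 1),
               "f_early")
  expect_error(synth_config(p_control_q0(), noise_sigma = 0.1), "seed")
})

test_that("RTCA and flow CSV dialects round-trip", {
  st <- state_at(11)
  cfg <- sim_config()
  sc <- synth_config(p_treated_q0(), noise_sigma = 0.02, seed = 5)
  rt <- generate_rtca(st, cfg, sc)
  fl <- generate_flow(st, cfg, sc)

  rpath <- withr::local_tempfile(fileext = ".csv")
  write_rtca_csv(rt$full, rpath)
  back <- read_rtca_csv(rpath)
  expect_equal(back, rt$full, tolerance = 1e-12)
  fit <- rtca_fit_series(back)
  expect_equal(fit$viability_pct, rt$fit$viability_pct, tolerance = 1e-10)

  fpath <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(fl$fractions, fpath)
  fracs <- read_flow_csv(fpath)
  expect_equal(flow_series(fracs)$viability_pct, fl$series$viability_pct,
               tolerance = 1e-9)

  # invalid sums are rejected
  bad <- data.frame(time_h = 24, viable_pct = 50, early_pct = 10,
                    late_pct = 30, necrosis_pct = 8)
  bpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, bpath, row.names = FALSE)
  expect_error(read_flow_csv(bpath), "sum to 100")
})
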