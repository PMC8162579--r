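test_that("the low-pass filter has unit DC gain and kills high frequencies", {
  rate <- 200
  tt <- (0:799) / rate
  const <- rep(2.5, 800)
  expect_lt(max(abs(butterworth_lowpass(const, rate) - 2.5)), 1e-9)

  x <- sin(2 * pi * 50 * tt)
  y <- butterworth_lowpass(x, rate, cutoff = 8, order = 4)
  # analytic two-pass Butterworth magnitude at 50 Hz bounds the amplitude
  # far below 1% of the input
  mag2 <- (1 / sqrt(1 + (50 / 8)^(2 * 4)))^2
  amp <- max(abs(y[100:700]))
  expect_lt(amp, 0.01)
  expect_lt(mag2, 1e-5)
  # default arguments are the 8 Hz, 4th-order design
  expect_equal(butterworth_lowpass(x, rate),
               butterworth_lowpass(x, rate, cutoff = 8, order = 4))
  expect_error(butterworth_lowpass(x, rate, cutoff = 120), "Nyquist")
})

test_that("filtering a band-limited signal barely disturbs its second derivative", {
  rate <- 200
  tt <- (0:999) / rate
  x <- 0.6 * sin(2 * pi * 2 * tt) + 0.3 * sin(2 * pi * 3.5 * tt)
  acc_true <- -0.6 * (2 * pi * 2)^2 * sin(2 * pi * 2 * tt) -
    0.3 * (2 * pi * 3.5)^2 * sin(2 * pi * 3.5 * tt)
  xf <- butterworth_lowpass(x, rate)
  traj <- coordinate_trajectory(tt, matrix(xf, ncol = 1, dimnames = list(NULL, "s")))
  acc <- differentiate(traj)$qdd[, 1]
  interior <- 50:950
  expect_lt(rmse(acc[interior], acc_true[interior]) /
              sqrt(mean(acc_true[interior]^2)), 0.01)
})

test_that("gait events match the analytic crossings of a trapezoidal burst", {
  rate <- 200
  tt <- (0:299) / rate
  bw <- 100
  thr <- 0.05 * bw
  # trapezoid: rises 0.2-0.3 s, plateau at bw, falls 0.7-0.8 s
  fy <- pmin(1, pmax(0, (tt - 0.2) / 0.1)) * pmin(1, pmax(0, (0.8 - tt) / 0.1)) * bw
  grf <- ground_reaction(tt, force = cbind(0, fy, 0),
                         cop = matrix(0, 300, 3),
                         free_moment = matrix(0, 300, 3),
                         applied_body = "foot_r")
  ev <- detect_gait_events(grf, bw)
  t_strike <- 0.2 + 0.1 * 0.05   # threshold crossing of the rising ramp
  t_off <- 0.8 - 0.1 * 0.05
  expect_equal(ev$foot_strike, t_strike, tolerance = 1 / rate)
  expect_equal(ev$foot_off, t_off, tolerance = 1 / rate)

  silent <- ground_reaction(tt, force = matrix(0, 300, 3),
                            cop = matrix(0, 300, 3),
                            free_moment = matrix(0, 300, 3),
                            applied_body = "foot_r")
  ev0 <- detect_gait_events(silent, bw)
  expect_length(ev0$foot_strike, 0)
  expect_length(ev0$foot_off, 0)
  expect_error(detect_gait_events(grf, bw, threshold_fraction = 0), "threshold")
})

test_that("debouncing removes sub-50 ms chatter", {
  rate <- 200
  tt <- (0:299) / rate
  fy <- rep(0, 300)
  fy[60:200] <- 100
  fy[100:103] <- 0        # 20 ms dropout inside the contact
  fy[250:252] <- 100      # 15 ms spurious blip
  grf <- ground_reaction(tt, force = cbind(0, fy, 0), cop = matrix(0, 300, 3),
                         free_moment = matrix(0, 300, 3), applied_body = "foot_r")
  ev <- detect_gait_events(grf, 100)
  expect_length(ev$foot_strike, 1)
  expect_length(ev$foot_off, 1)
})

test_that("gait-cycle normalization interpolates onto 101 points", {
  tt <- (0:329) / 200
  cycle <- c(0.25, 1.4)
  lin <- 2 * tt + 1
  out <- normalize_gait_cycle(tt, lin, cycle)
  expect_length(out, 101)
  expect_equal(out[1], 2 * cycle[1] + 1, tolerance = 1e-12)
  expect_equal(out[101], 2 * cycle[2] + 1, tolerance = 1e-12)
  grid <- seq(cycle[1], cycle[2], length.out = 101)
  expect_equal(as.numeric(out), 2 * grid + 1, tolerance = 1e-12)

  s <- sin(2 * pi * (tt - cycle[1]) / diff(cycle))
  outs <- normalize_gait_cycle(tt, s, cycle)
  expect_lt(max(abs(outs - sin(2 * pi * (grid - cycle[1]) / diff(cycle)))), 1e-3)

  expect_error(normalize_gait_cycle(tt, lin, c(-1, 1)), "outside")
})

test_that("rmse has the metric properties and the hand-computed value", {
  a <- c(0, 0); b <- c(3, 4)
  expect_equal(rmse(a, b), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(rmse(b, a), rmse(a, b))
  expect_equal(rmse(b, b), 0)
  # constant offset: rmse equals the offset (the "offset phenomenology")
  x <- stats::rnorm(50)
  expect_equal(rmse(x, x + 0.7), 0.7, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("evaluation of an encoder-registered model on clean data is exact", {
  m <- robot_fixture()
  spec <- gait_spec()
  trial <- make_dataset(spec, noise_sigma = 0, seed = 6)
  reg <- encoder_register(m, trial$static_markers, trial$static_encoders)
  walk <- decimate_markers(trial$markers, 8)
  # truth on the same sampling grid, so the cycle normalization of both
  # series interpolates identically and the comparison isolates IK error
  keep <- seq(1, n_frames(trial$markers), by = 8)
  truth <- coordinate_trajectory(trial$truth$time[keep], trial$truth$q[keep, ])
  ev <- evaluate_registration(reg, walk, trial$grf, truth)
  expect_true(all(ev$angle_rmse_deg < 1e-4))
  expect_lt(ev$marker_rmse_mean_mm, 1e-6)
  # report mirrors the published table layout: six angle rows + marker row
  expect_equal(rownames(ev$report),
               c("Hip flexion", "Hip adduction", "Hip rotation", "Knee flexion",
                 "Ankle flexion", "Ankle inversion", "Marker error (mm)"))
  # the single-support window sits inside the analyzed cycle
  expect_true(all(is.finite(ev$single_support)))
  expect_gt(ev$single_support[1], ev$cycle[1])
  expect_lt(ev$single_support[2], ev$cycle[2])
})
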