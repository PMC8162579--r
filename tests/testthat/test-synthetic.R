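test_that("generated gait walks at the spec'd speed with the spec'd stride", {
  m <- robot_fixture()
  spec <- gait_spec(n_cycles = 2)
  tr <- generate_gait(spec, m)
  tN <- nrow(tr$q)
  expect_equal(tN, round(2 * spec$cycle_duration * spec$sample_rate))
  # average forward root velocity over the integer number of cycles
  v <- (tr$q[tN, "pelvis_tx"] - tr$q[1, "pelvis_tx"]) / (tr$time[tN] - tr$time[1])
  expect_equal(unname(v), 0.4, tolerance = 1e-6)
  # consecutive ipsilateral footfalls are one stride (2 steps) apart
  ph <- (tr$time / spec$cycle_duration) %% 1
  stance <- ph < spec$duty
  ax <- vapply(seq_len(tN), function(f)
    forward_kinematics(m, tr$q[f, ])$segment_p[["foot_r"]][1], numeric(1))
  s1 <- mean(ax[stance & tr$time < spec$cycle_duration])
  s2 <- mean(ax[stance & tr$time >= spec$cycle_duration])
  expect_equal(s2 - s1, 2 * 0.33, tolerance = 1e-3)
})

test_that("feet stay on the ground in stance and clear it in swing", {
  m <- robot_fixture()
  spec <- gait_spec(n_cycles = 1)
  tr <- generate_gait(spec, m)
  ph <- (tr$time / spec$cycle_duration) %% 1
  sole <- vapply(seq_len(nrow(tr$q)), function(f) {
    mk <- forward_kinematics(m, tr$q[f, ])$markers
    min(mk[2, c("RHEE", "RTOE", "RMT5")])
  }, numeric(1))
  # stance: foot markers near their standing height, never below ground
  expect_gt(min(sole), 0)
  expect_lt(max(abs(sole[ph < spec$duty] - sole[1])), 2e-3)
  # mid-swing: clear clearance above the stance-phase height
  midswing <- ph > 0.75 & ph < 0.9
  expect_gt(min(sole[midswing]) - sole[1], 0.01)
})

test_that("a zero-speed spec yields a constant standing pose", {
  m <- robot_fixture()
  tr <- generate_gait(gait_spec(speed = 0, n_cycles = 1), m)
  expect_true(all(apply(tr$q, 2, function(col) max(abs(col - col[1]))) == 0))
  d <- differentiate(tr)
  expect_equal(max(abs(d$qd)), 0)
})

test_that("an out-of-reach spec is rejected as infeasible", {
  m <- robot_fixture()
  expect_error(generate_gait(gait_spec(step_length = 0.6), m), "infeasible")
})

test_that("synthetic markers reproduce FK exactly and calibrate their noise", {
  m <- robot_fixture()
  spec <- gait_spec(n_cycles = 1, sample_rate = 100)
  truth <- generate_gait(spec, m)
  clean <- synthesize_markers(m, truth, noise_sigma = 0)
  f <- 7
  expect_equal(frame_markers(clean, f),
               forward_kinematics(m, truth$q[f, ])$markers, tolerance = 1e-14)
  expect_equal(n_frames(clean), round(spec$cycle_duration * 100))

  noisy1 <- synthesize_markers(m, truth, noise_sigma = 1e-3, seed = 3)
  noisy2 <- synthesize_markers(m, truth, noise_sigma = 1e-3, seed = 3)
  expect_identical(noisy1$pos, noisy2$pos)
  resid <- noisy1$pos - clean$pos
  expect_gt(length(resid), 1e4)
  expect_equal(stats::sd(resid), 1e-3, tolerance = 0.05)
})

test_that("static one-foot standing gives weight on the plate with COP under the foot", {
  m <- robot_fixture()
  q <- robot_static_pose(m)
  com_of <- function(q) {
    pose <- forward_kinematics(m, q)
    Reduce(`+`, lapply(names(m$segments), function(s)
      m$segments[[s]]$mass * (pose$segment_p[[s]] +
        as.numeric(pose$segment_R[[s]] %*% m$segments[[s]]$com_local)))) /
      sum(vapply(m$segments, function(s) s$mass, numeric(1)))
  }
  # adduct the stance hip until the body COM sits over the right ankle
  # (a root translation cannot do it: it carries the foot along)
  for (i in 1:4) {
    pose <- forward_kinematics(m, q)
    dz <- com_of(q)[3] - pose$segment_p[["foot_r"]][3]
    # positive adduction swings the right foot toward -z
    q["hip_adduction_r"] <- q["hip_adduction_r"] - dz / 0.45
  }
  traj <- constant_trajectory(m, q, tN = 50)
  grf <- synthesize_grf(m, traj, gait_spec(speed = 0, n_cycles = 1),
                        support = "r")
  f <- 25
  expect_equal(grf$r$force[f, 2], total_weight(m), tolerance = 1e-9)
  expect_lt(max(abs(grf$l$force)), 1e-12)
  # COP inside the foot outline (heel to toe, medial to lateral)
  pose <- forward_kinematics(m, q)
  local_cop <- t_apply(t_inverse(new_transform(pose$segment_R$foot_r,
                                               pose$segment_p$foot_r)),
                       grf$r$cop[f, ])
  expect_gt(local_cop[1], -0.06); expect_lt(local_cop[1], 0.11)
  expect_gt(local_cop[3], -0.045); expect_lt(local_cop[3], 0.045)
})

test_that("synthesized walking GRF closes the dynamic balance", {
  m <- robot_fixture()
  spec <- gait_spec(n_cycles = 2)
  tr <- generate_gait(spec, m)
  grf <- synthesize_grf(m, tr, spec)
  mom <- inverse_dynamics(m, tr, grf)
  bw <- total_weight(m)
  ph <- (tr$time / spec$cycle_duration) %% 1
  ss <- ph > (spec$duty - 0.5) & ph < 0.5  # right single support
  resF <- sqrt(rowSums(mom$moments[, c("pelvis_tx", "pelvis_ty", "pelvis_tz")]^2))
  expect_lt(max(resF[ss]) / bw, 0.01)
  # vertical impulse over the integer cycles balances body weight
  Fy <- grf$r$force[, 2] + grf$l$force[, 2]
  expect_equal(mean(Fy) / bw, 1, tolerance = 0.02)
})

test_that("datasets are deterministic under seed, down to the written bytes", {
  spec <- gait_spec(n_cycles = 1)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  make_dataset(spec, noise_sigma = 5e-4, seed = 9, out_dir = d1)
  make_dataset(spec, noise_sigma = 5e-4, seed = 9, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # encoder file carries the 12 joint-angle channels
  enc <- read_mot(file.path(d1, "encoders.mot"))
  expect_equal(ncol(enc$data), 13)  # time + 12
  expect_true(enc$in_degrees)
  # static trial: one second of quiet standing
  st <- read_trc(file.path(d1, "static.trc"))
  expect_gte(n_frames(st) / st$rate, 1)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("encoder channels equal the truth joint coordinates exactly", {
  trial <- make_dataset(gait_spec(n_cycles = 1), noise_sigma = 5e-4, seed = 2)
  expect_identical(trial$encoders,
                   trial$truth$q[, setdiff(coord_names(trial$model),
                                           coord_names(trial$model)[1:6])])
})
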