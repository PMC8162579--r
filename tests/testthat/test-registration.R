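test_that("marker placement inverts the segment pose", {
  # identity segment: world position becomes the local offset
  m <- kinematic_model(
    list(segment("box", mass = 1)),
    list(joint("root", "ground", "box", dofs = free6_dofs())),
    markers = list(a = list(segment = "box", offset = c(0, 0, 0)),
                   b = list(segment = "box", offset = c(0, 0.1, 0)),
                   c = list(segment = "box", offset = c(0.1, 0, 0.1))))
  q <- rep(0, 6)
  placed <- place_markers_at_pose(m, q, cbind(a = c(1, 0, 0)))
  expect_equal(placed$markers$a$offset, c(1, 0, 0), tolerance = 1e-14)
  # segment yawed +90 deg about Z: world (0,1,0) is local (1,0,0)
  q2 <- c(0, 0, 0, pi / 2, 0, 0)
  placed2 <- place_markers_at_pose(m, q2, cbind(a = c(0, 1, 0)))
  expect_equal(placed2$markers$a$offset, c(1, 0, 0), tolerance = 1e-12)
  expect_error(place_markers_at_pose(m, q, cbind(zz = c(0, 0, 0))), "unknown marker")
})

test_that("placement reproduces arbitrary static markers to machine precision", {
  m <- robot_fixture()
  set.seed(30)
  q_pose <- random_robot_pose(m)
  X <- forward_kinematics(m, random_robot_pose(m))$markers
  placed <- place_markers_at_pose(m, q_pose, X)
  expect_lt(max(abs(forward_kinematics(placed, q_pose)$markers - X)), 1e-12)
})

test_that("encoder registration is exact on noise-free data", {
  m <- robot_fixture()
  q_true <- robot_static_pose(m)
  X <- forward_kinematics(m, q_true)$markers
  reg <- encoder_register(m, X, q_true[-(1:6)])
  expect_lt(reg$static_marker_rmse, 1e-9)
  expect_lt(max(abs(reg$static_pose - q_true)), 1e-8)
  for (mn in m$marker_names)
    expect_equal(reg$registered_model$markers[[mn]]$offset,
                 m$markers[[mn]]$offset, tolerance = 1e-9)
  expect_error(encoder_register(m, X, q_true[8:18]), "missing channel")
})

test_that("orientation registration recovers the static pose from markers alone", {
  m <- robot_fixture()
  fd <- robot_frame_definitions()
  q_true <- robot_static_pose(m)
  X <- forward_kinematics(m, q_true)$markers
  reg <- orientation_register(m, X, fd)
  expect_lt(reg$static_marker_rmse, 1e-9)
  expect_lt(max(abs(reg$static_pose - q_true)), 1e-6)
  for (mn in m$marker_names)
    expect_equal(reg$registered_model$markers[[mn]]$offset,
                 m$markers[[mn]]$offset, tolerance = 1e-8)
})

test_that("orientation objective matches a 1-DOF grid scan on a hinge toy", {
  # single hinge, one framed segment; the frame is rotated 7 degrees about
  # the hinge axis, so the best-fit hinge angle is 7 degrees
  m <- planar_chain(1)
  ang <- 7 * pi / 180
  q_true <- rep(0, n_coords(m)); q_true[7] <- ang
  fd <- structure(list(
    frames = list(list(segment = "link1",
                       origin = "tip1",
                       primary = list(label = "x", from = "aux1", to = "tip1"),
                       secondary = list(label = "y", from = "tip1", to = "aux3"))),
    virtual_points = list(), model_frames = NULL), class = "frame_definitions")
  pose0 <- forward_kinematics(m, rep(0, 7))
  fr0 <- frames_from_pose(fd, pose0$markers)
  sp0 <- new_transform(pose0$segment_R$link1, pose0$segment_p$link1)
  fd$model_frames <- list(link1 = t_compose(t_inverse(sp0), fr0$link1$transform))

  X <- forward_kinematics(m, q_true)$markers
  reg <- orientation_register(m, X, fd, free = "q1")
  # brute-force scan of the virtual-point objective over the hinge angle
  frames <- frames_from_pose(fd, X)
  A <- fd$model_frames$link1
  target <- cbind(frames$link1$transform$p,
                  frames$link1$transform$p + 0.1 * frames$link1$transform$R)
  objective <- function(a) {
    q <- reg$static_pose; q[7] <- a
    pose <- forward_kinematics(m, q)
    sp <- new_transform(pose$segment_R$link1, pose$segment_p$link1)
    f <- t_compose(sp, A)
    pts <- cbind(f$p, f$p + 0.1 * f$R)
    sum((pts - target)^2)
  }
  grid <- seq(ang - 0.02, ang + 0.02, by = 1e-5)
  best <- grid[which.min(vapply(grid, objective, numeric(1)))]
  expect_lt(abs(reg$static_pose[7] - best), 1e-4)
  expect_lt(abs(reg$static_pose[7] - ang), 1e-4)
})

test_that("simulated user placement is seeded, unbiased, and sigma-calibrated", {
  m <- robot_fixture()
  same1 <- simulate_user_placement(m, sigma = 0.01, seed = 5)
  same2 <- simulate_user_placement(m, sigma = 0.01, seed = 5)
  for (mn in m$marker_names)
    expect_identical(same1$markers[[mn]]$offset, same2$markers[[mn]]$offset)
  zero <- simulate_user_placement(m, sigma = 0, seed = 5)
  for (mn in m$marker_names)
    expect_equal(zero$markers[[mn]]$offset, m$markers[[mn]]$offset)
  expect_error(simulate_user_placement(m, sigma = -1), "sigma")
  # empirical SD over many draws within 5% of sigma
  draws <- vapply(1:100, function(s) {
    pm <- simulate_user_placement(m, sigma = 0.01, seed = 1000 + s)
    vapply(m$marker_names, function(mn)
      pm$markers[[mn]]$offset - m$markers[[mn]]$offset, numeric(3))
  }, matrix(0, 3, 35))
  expect_equal(stats::sd(draws), 0.01, tolerance = 0.05)
})

test_that("every method zeroes the static marker residual, biased or not", {
  m <- robot_fixture()
  q_true <- robot_static_pose(m)
  X <- forward_kinematics(m, q_true)$markers
  fd <- robot_frame_definitions()
  expect_lt(encoder_register(m, X, q_true[-(1:6)])$static_marker_rmse, 1e-9)
  expect_lt(orientation_register(m, X, fd)$static_marker_rmse, 1e-9)
  for (s in 1:3) {
    manual <- simulate_user_placement(m, sigma = 0.01, seed = 40 + s)
    reg <- user_register(manual, X)
    expect_lt(reg$static_marker_rmse, 1e-9)
    # ... even though the pose itself is biased
    expect_gt(max(abs(reg$static_pose - q_true)), 1e-3)
  }
})

test_that("a zero-error user reproduces the encoder registration", {
  m <- robot_fixture()
  q_true <- robot_static_pose(m)
  X <- forward_kinematics(m, q_true)$markers
  manual <- simulate_user_placement(m, sigma = 0, seed = 1)
  usr <- user_register(manual, X)
  enc <- encoder_register(m, X, q_true[-(1:6)])
  expect_lt(max(abs(usr$static_pose - enc$static_pose)), 1e-6)
  for (mn in m$marker_names)
    expect_equal(usr$registered_model$markers[[mn]]$offset,
                 enc$registered_model$markers[[mn]]$offset, tolerance = 1e-6)
})

test_that("downstream angle error grows monotonically with placement error", {
  # median over seeds of the mean right-leg angle RMSE is nondecreasing in
  # sigma (continuity to the encoder-exact limit at sigma = 0)
  m <- robot_fixture()
  spec <- gait_spec(n_cycles = 1, sample_rate = 25)
  truth <- generate_gait(spec, m)
  series <- synthesize_markers(m, truth, noise_sigma = 0)
  q_true <- robot_static_pose(m)
  X <- forward_kinematics(m, q_true)$markers
  dofs <- right_leg_dofs()
  med <- vapply(c(0, 0.001, 0.005, 0.010), function(sigma) {
    rmses <- vapply(1:10, function(s) {
      manual <- simulate_user_placement(m, sigma = sigma, seed = 500 + s)
      reg <- user_register(manual, X)
      traj <- solve_trajectory(reg$registered_model, series, q0 = reg$static_pose)
      mean(sqrt(colMeans((traj$q[, dofs] - truth$q[, dofs])^2))) * 180 / pi
    }, numeric(1))
    stats::median(rmses)
  }, numeric(1))
  expect_lt(med[1], 1e-4)
  expect_true(all(diff(med) >= 0))
})
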