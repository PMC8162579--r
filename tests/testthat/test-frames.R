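pelvis_def <- list(
  segment = "pelvis",
  origin = c("RASI", "LASI"),
  primary = list(label = "z", from = "LASI", to = "RASI"),
  secondary = list(label = "x", from = "PSISmid", to = c("RASI", "LASI")))

test_that("axis-aligned pelvis construction gives the exact frame", {
  pts <- cbind(RASI = c(0.1, 1, 0), LASI = c(-0.1, 1, 0),
               PSISmid = c(0, 1, -0.1))
  # note: mediolateral direction LASI -> RASI maps onto +z here because the
  # points are laid out with the subject's right along +x; the assigned
  # labels still produce an exact right-handed frame
  def <- list(segment = "pelvis", origin = c("RASI", "LASI"),
              primary = list(label = "x", from = "LASI", to = "RASI"),
              secondary = list(label = "z", from = "PSISmid",
                               to = c("RASI", "LASI")))
  fr <- build_frame(def, pts)
  R <- fr$transform$R
  expect_equal(R[, 1], c(1, 0, 0), tolerance = 1e-14)  # mediolateral
  expect_equal(R[, 3], c(0, 0, 1), tolerance = 1e-14)  # anterior
  expect_equal(R[, 2], c(0, 1, 0), tolerance = 1e-14)  # vertical
  expect_equal(fr$transform$p, c(0, 1, 0), tolerance = 1e-14)
})

test_that("constructed frames are right-handed orthonormal", {
  set.seed(20)
  for (i in 1:10) {
    pts <- cbind(RASI = stats::rnorm(3), LASI = stats::rnorm(3),
                 PSISmid = stats::rnorm(3))
    fr <- tryCatch(build_frame(pelvis_def, pts), error = function(e) NULL)
    if (is.null(fr)) next  # degenerate draw
    R <- fr$transform$R
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("frames are equivariant under rigid rotation of the markers", {
  set.seed(21)
  pts <- cbind(RASI = c(0.1, 1, 0.02), LASI = c(-0.1, 1, 0.01),
               PSISmid = c(0.02, 1.05, -0.12))
  base <- build_frame(pelvis_def, pts)$transform
  for (i in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    Q <- rot_axis_angle(ax, stats::runif(1, -pi, pi))
    fr <- build_frame(pelvis_def, Q %*% pts)$transform
    expect_equal(fr$R, Q %*% base$R, tolerance = 1e-12)
    expect_equal(fr$p, as.numeric(Q %*% base$p), tolerance = 1e-12)
  }
})

test_that("translation and positive scaling do not change the rotation", {
  pts <- cbind(RASI = c(0.1, 1, 0.02), LASI = c(-0.1, 1, 0.01),
               PSISmid = c(0.02, 1.05, -0.12))
  base <- build_frame(pelvis_def, pts)$transform
  shifted <- build_frame(pelvis_def, pts + c(3, -2, 5))$transform
  expect_equal(shifted$R, base$R, tolerance = 1e-14)
  expect_equal(shifted$p, base$p + c(3, -2, 5), tolerance = 1e-12)
  scaled <- build_frame(pelvis_def, 4.2 * pts)$transform
  expect_equal(scaled$R, base$R, tolerance = 1e-12)
})

test_that("missing markers and near-parallel directions are rejected", {
  pts <- cbind(RASI = c(0.1, 1, 0), LASI = c(-0.1, 1, 0))
  expect_error(build_frame(pelvis_def, pts), "missing marker")
  degen <- cbind(RASI = c(0.1, 1, 0), LASI = c(-0.1, 1, 0),
                 PSISmid = c(-0.2, 1, 0))  # collinear with the ASIS axis
  expect_error(build_frame(pelvis_def, degen), "degenerate")
})

test_that("static-trial averaging reduces frame noise", {
  m <- robot_fixture()
  fd <- robot_frame_definitions()
  q <- robot_static_pose(m)
  clean <- forward_kinematics(m, q)$markers
  ref <- frames_from_pose(fd, clean)
  angle_between <- function(Ra, Rb) {
    c_ <- (sum(diag(t(Ra) %*% Rb)) - 1) / 2
    acos(min(1, max(-1, c_))) * 180 / pi
  }
  tN <- 200
  for (s in 1:20) {
    set.seed(200 + s)
    pos <- array(rep(clean, tN), c(3, 35, tN),
                 dimnames = list(NULL, colnames(clean), NULL))
    pos <- pos + array(stats::rnorm(length(pos), 0, 5e-4), dim(pos))
    series <- marker_series((seq_len(tN) - 1) / 200, pos)
    frames <- frames_from_static(m, series, fd)
    devs <- vapply(names(ref), function(seg)
      angle_between(frames[[seg]]$transform$R, ref[[seg]]$transform$R),
      numeric(1))
    expect_lt(max(devs), 0.2)
  }
})

test_that("single-frame static trial equals direct construction", {
  m <- robot_fixture()
  fd <- robot_frame_definitions()
  X <- forward_kinematics(m, robot_static_pose(m))$markers
  series <- marker_series(0, array(X, c(3, 35, 1),
                                   dimnames = list(NULL, colnames(X), NULL)))
  f1 <- frames_from_static(m, series, fd)
  f2 <- frames_from_pose(fd, X)
  for (s in names(f1)) {
    expect_equal(f1[[s]]$transform$R, f2[[s]]$transform$R, tolerance = 1e-14)
    expect_equal(f1[[s]]$transform$p, f2[[s]]$transform$p, tolerance = 1e-14)
  }
})

test_that("fixture frames equal segment poses composed with constant offsets", {
  m <- robot_fixture()
  fd <- robot_frame_definitions()
  set.seed(22)
  q <- random_robot_pose(m)
  pose <- forward_kinematics(m, q)
  frames <- frames_from_pose(fd, pose$markers)
  for (s in names(frames)) {
    sp <- new_transform(pose$segment_R[[s]], pose$segment_p[[s]])
    A <- fd$model_frames[[s]]
    expect_equal(frames[[s]]$transform$R, sp$R %*% A$R, tolerance = 1e-10)
    expect_equal(frames[[s]]$transform$p,
                 as.numeric(sp$R %*% A$p) + sp$p, tolerance = 1e-10)
  }
})
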