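test_that("robot fixture has the documented structure and is deterministic", {
  m <- robot_fixture()
  expect_s3_class(m, "kinematic_model")
  expect_equal(n_coords(m), 18)
  expect_length(m$markers, 35)
  # marker distribution: 3 per foot/shank/thigh + 2 per knee/ankle axis,
  # 4 pelvis, 2 trunk, 3 head
  per_seg <- table(m$marker_segment)
  expect_equal(as.numeric(per_seg[c("pelvis", "torso", "head")]), c(4, 2, 3))
  for (s in c("thigh_r", "thigh_l", "shank_r", "shank_l"))
    expect_equal(unname(per_seg[[s]]), 5)
  for (s in c("foot_r", "foot_l"))
    expect_equal(unname(per_seg[[s]]), 3)

  # determinism: two calls serialize identically
  f1 <- tempfile(); f2 <- tempfile()
  save_model(robot_fixture(), f1)
  save_model(robot_fixture(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fixture limbs are mirror images about the sagittal plane", {
  m <- robot_fixture()
  mirror <- function(v) c(v[1], v[2], -v[3])
  right <- grep("^R", m$marker_names, value = TRUE)
  for (rn in right) {
    ln <- sub("^R", "L", rn)
    if (!(ln %in% m$marker_names)) next
    expect_equal(m$markers[[ln]]$offset, mirror(m$markers[[rn]]$offset),
                 tolerance = 1e-12)
  }
  expect_equal(m$joints$hip_l$frame_in_parent$p,
               mirror(m$joints$hip_r$frame_in_parent$p), tolerance = 1e-12)
  expect_equal(m$segments$thigh_l$mass, m$segments$thigh_r$mass)
})

test_that("model JSON round trip preserves all fields", {
  m <- robot_fixture()
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(coord_names(m2), coord_names(m))
  for (s in names(m$segments)) {
    expect_equal(m2$segments[[s]]$mass, m$segments[[s]]$mass, tolerance = 1e-12)
    expect_equal(m2$segments[[s]]$com_local, m$segments[[s]]$com_local, tolerance = 1e-12)
    expect_equal(m2$segments[[s]]$inertia_local, m$segments[[s]]$inertia_local,
                 tolerance = 1e-12)
  }
  for (mn in m$marker_names)
    expect_equal(m2$markers[[mn]]$offset, m$markers[[mn]]$offset, tolerance = 1e-12)
  for (jn in names(m$joints)) {
    expect_equal(m2$joints[[jn]]$frame_in_parent$p, m$joints[[jn]]$frame_in_parent$p,
                 tolerance = 1e-12)
    expect_equal(m2$joints[[jn]]$frame_in_parent$R, m$joints[[jn]]$frame_in_parent$R,
                 tolerance = 1e-12)
  }
})

test_that("bundled fixture file matches the in-code fixture", {
  path <- system.file("extdata", "robot.model.json", package = "gaitreg")
  m <- load_model(path)
  expect_equal(n_coords(m), 18)
  expect_length(m$markers, 35)
  q <- robot_static_pose(m)
  expect_equal(forward_kinematics(m, q)$markers,
               forward_kinematics(robot_fixture(), q)$markers, tolerance = 1e-12)
})

test_that("a minimal one-segment model has the six root coordinates", {
  m <- kinematic_model(
    list(segment("box", mass = 1)),
    list(joint("root", "ground", "box", dofs = free6_dofs())),
    markers = list(a = list(segment = "box", offset = c(1, 0, 0))))
  expect_equal(n_coords(m), 6)
})

test_that("structural invariants are enforced", {
  mk_ok <- list(a = list(segment = "s1", offset = c(1, 0, 0)))
  base <- list(segment("s1", mass = 1), segment("s2", mass = 1))
  root <- joint("root", "ground", "s1", dofs = free6_dofs())

  # duplicate marker name
  expect_error(kinematic_model(
    list(segment("s1")), list(root),
    markers = list(a = list(segment = "s1", offset = c(0, 0, 0)),
                   a = list(segment = "s1", offset = c(1, 0, 0)))),
    "duplicate marker")

  # non-unit axis
  expect_error(kinematic_model(
    base, list(root, joint("j", "s1", "s2",
                           dofs = list(dof("q", "rotation", c(0, 0, 2))))),
    markers = mk_ok), "unit length")

  # parallel consecutive axes
  expect_error(kinematic_model(
    base, list(root, joint("j", "s1", "s2",
                           dofs = list(dof("qa", "rotation", c(0, 0, 1)),
                                       dof("qb", "rotation", c(0, 0, 1))))),
    markers = mk_ok), "parallel")

  # cyclic / non-tree graph: s2 is a child twice
  expect_error(kinematic_model(
    base, list(root,
               joint("j1", "s1", "s2", dofs = list(dof("q1", "rotation", c(0, 0, 1)))),
               joint("j2", "s2", "s2", dofs = list(dof("q2", "rotation", c(0, 0, 1))))),
    markers = mk_ok), "more than one joint|tree")

  # unattached segment
  expect_error(kinematic_model(
    base, list(root), markers = mk_ok), "not attached")

  # negative mass and asymmetric inertia
  expect_error(kinematic_model(
    list(segment("s1", mass = -1)), list(root), markers = mk_ok), "mass")
  bad_I <- diag(3); bad_I[1, 2] <- 0.5
  expect_error(kinematic_model(
    list(segment("s1", mass = 1, inertia_local = bad_I)), list(root),
    markers = mk_ok), "symmetric")
})

test_that("malformed model files raise parse errors naming the problem", {
  f <- tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(load_model(f), "malformed")
  writeLines('{"schema_version": "1.0", "segments": []}', f)
  expect_error(load_model(f), "joints")
  expect_error(load_model(tempfile()), "does not exist")
})
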