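# Shared builders and independent oracles used across test files.

free6_dofs <- function() {
  list(dof("tx", "translation", c(1, 0, 0)),
       dof("ty", "translation", c(0, 1, 0)),
       dof("tz", "translation", c(0, 0, 1)),
       dof("rz", "rotation", c(0, 0, 1)),
       dof("rx", "rotation", c(1, 0, 0)),
       dof("ry", "rotation", c(0, 1, 0)))
}

# Planar serial chain of `n` unit links hinged about Z, with a marker at the
# tip of each link and three extra non-collinear markers on the first link
# (so IK problems on the chain are well-posed).
planar_chain <- function(n = 2, link = 1) {
  segs <- list(segment("base"))
  jnts <- list(joint("root", "ground", "base", dofs = free6_dofs()))
  mks <- list()
  for (i in seq_len(n)) {
    nm <- paste0("link", i)
    segs <- c(segs, list(segment(nm, mass = 1, com_local = c(link / 2, 0, 0),
                                 inertia_local = diag(1e-3, 3))))
    parent <- if (i == 1) "base" else paste0("link", i - 1)
    jnts <- c(jnts, list(joint(
      paste0("hinge", i), parent, nm,
      frame_in_parent = new_transform(p = c(if (i == 1) 0 else link, 0, 0)),
      dofs = list(dof(paste0("q", i), "rotation", c(0, 0, 1))))))
    mks[[paste0("tip", i)]] <- list(segment = nm, offset = c(link, 0, 0))
  }
  mks[["aux1"]] <- list(segment = "link1", offset = c(0.3, 0.1, 0))
  mks[["aux2"]] <- list(segment = "link1", offset = c(0.6, -0.1, 0.1))
  mks[["aux3"]] <- list(segment = "link1", offset = c(0.2, 0, 0.2))
  kinematic_model(segs, jnts, markers = mks, name = paste0("chain", n))
}

# Independent forward-kinematics oracle: naive 4x4 homogeneous-matrix stack,
# written without reference to the package internals.
naive_fk_markers <- function(model, q) {
  homog <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  rodrigues <- function(axis, ang) {
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  }
  world <- list(ground = diag(4))
  qs <- stats::setNames(as.numeric(q), coord_names(model))
  repeat {
    progressed <- FALSE
    for (jn in names(model$joints)) {
      j <- model$joints[[jn]]
      if (!is.null(world[[j$child]]) || is.null(world[[j$parent]])) next
      Xp <- homog(j$frame_in_parent$R, j$frame_in_parent$p)
      Xc <- homog(j$frame_in_child$R, j$frame_in_child$p)
      Xm <- diag(4)
      for (d in j$dofs) {
        v <- qs[[d$name]]
        Xm <- Xm %*% (if (d$type == "translation")
          homog(diag(3), d$axis * v) else homog(rodrigues(d$axis, v), c(0, 0, 0)))
      }
      world[[j$child]] <- world[[j$parent]] %*% Xp %*% Xm %*% solve(Xc)
      progressed <- TRUE
    }
    if (!progressed) break
  }
  out <- matrix(NA_real_, 3, length(model$marker_names),
                dimnames = list(NULL, model$marker_names))
  for (mn in model$marker_names) {
    m <- model$markers[[mn]]
    w <- world[[m$segment]] %*% c(m$offset, 1)
    out[, mn] <- w[1:3]
  }
  out
}

# Planar double pendulum fixture (massless base, two distributed-mass links
# hanging in -Y, hinges about Z) and its independently derived Lagrangian
# joint torques.
pendulum_params <- function() {
  list(m1 = 1.3, c1 = 0.09, I1 = 0.02, L1 = 0.21,
       m2 = 0.9, c2 = 0.12, I2 = 0.015, g = 9.80665)
}

double_pendulum_model <- function() {
  p <- pendulum_params()
  kinematic_model(
    list(segment("base"),
         segment("link1", mass = p$m1, com_local = c(0, -p$c1, 0),
                 inertia_local = diag(c(0.003, 0.001, p$I1))),
         segment("link2", mass = p$m2, com_local = c(0, -p$c2, 0),
                 inertia_local = diag(c(0.002, 0.001, p$I2)))),
    list(joint("root", "ground", "base", dofs = free6_dofs()),
         joint("h1", "base", "link1",
               dofs = list(dof("q1", "rotation", c(0, 0, 1)))),
         joint("h2", "link1", "link2",
               frame_in_parent = new_transform(p = c(0, -p$L1, 0)),
               dofs = list(dof("q2", "rotation", c(0, 0, 1))))),
    name = "double_pendulum")
}

# Closed-form Lagrangian equations of motion for the double pendulum, in
# terms of absolute link angles a1 = q1, a2 = q1 + q2 measured from the
# downward vertical (positive about +Z).  Derived by hand from the kinetic
# and potential energies; independent of the package's Newton-Euler code.
pendulum_lagrangian_tau <- function(q1, q1d, q1dd, q2, q2d, q2dd) {
  p <- pendulum_params()
  a1 <- q1; a2 <- q1 + q2
  a1d <- q1d; a2d <- q1d + q2d
  a1dd <- q1dd; a2dd <- q1dd + q2dd
  A1 <- p$I1 + p$m1 * p$c1^2 + p$m2 * p$L1^2
  A2 <- p$I2 + p$m2 * p$c2^2
  k <- p$m2 * p$L1 * p$c2
  D <- a1 - a2
  Q1 <- A1 * a1dd + k * cos(D) * a2dd + k * sin(D) * a2d^2 +
    (p$m1 * p$c1 + p$m2 * p$L1) * p$g * sin(a1)
  Q2 <- A2 * a2dd + k * cos(D) * a1dd - k * sin(D) * a1d^2 +
    p$m2 * p$c2 * p$g * sin(a2)
  list(tau1 = Q1 + Q2, tau2 = Q2)
}

# Single-support "stork" model for the static lever-arm closed form: a body
# mass above an ankle hinge, a foot whose COM sits directly below the ankle.
stork_model <- function() {
  kinematic_model(
    list(segment("body", mass = 9, com_local = c(0, 0.3, 0),
                 inertia_local = diag(0.1, 3)),
         segment("foot", mass = 0.4, com_local = c(0, -0.03, 0),
                 inertia_local = diag(0.001, 3))),
    list(joint("root", "ground", "body", dofs = free6_dofs()),
         joint("ankle", "body", "foot",
               frame_in_parent = new_transform(p = c(0, -0.4, 0)),
               dofs = list(dof("ankle_flex", "rotation", c(0, 0, 1))))),
    name = "stork")
}

constant_trajectory <- function(model, q, tN = 21, rate = 200) {
  time <- (seq_len(tN) - 1) / rate
  coordinate_trajectory(time,
                        matrix(rep(q, each = tN), tN, n_coords(model),
                               dimnames = list(NULL, coord_names(model))),
                        rate = rate)
}

# In-range random coordinate vector for the robot fixture, centered on the
# standing pose.
random_robot_pose <- function(model, scale = 0.15) {
  q <- robot_static_pose(model)
  q + stats::rnorm(n_coords(model), 0, scale) *
    c(rep(0.2, 3), rep(0.5, 3), rep(1, 12))
}
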