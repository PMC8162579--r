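# Synthetic experiment generator: a kinematically plausible periodic gait
# for the robot fixture with known joint angles, plus marker data, encoder
# channels, and dynamically consistent single-support ground reactions.
#
# The gait is procedural, not a physics simulation of a controller: pelvis
# advances at constant speed, stance ankles are pinned to the ground, swing
# ankles follow a C2-smooth lift-and-carry path, and the sagittal leg angles
# come from exact planar two-link inverse geometry.  Small periodic
# out-of-sagittal waveforms (hip adduction/rotation, ankle inversion) are
# superimposed.  Because every waveform is exactly periodic in the cycle and
# the pelvis advances one stride per cycle, consecutive ipsilateral
# footfalls are spaced exactly one stride apart by construction.

#' Specify a synthetic gait
#'
#' Defaults are the study conditions: 0.4 m/s walking speed, 0.33 m step
#' length, 200 Hz sampling.  `speed = 0` denotes quiet standing.
#'
#' @param speed Walking speed (m/s).
#' @param step_length Step length (m); stride = 2 steps; cycle duration =
#'   stride / speed.
#' @param sample_rate Sampling rate (Hz).
#' @param n_cycles Number of gait cycles.
#' @param duty Stance fraction of the cycle per foot (0.5-0.9).
#' @param lift Peak swing-foot lift (m).
#' @param hip_add_amp,hip_rot_amp,ankle_inv_amp Amplitudes (rad) of the
#'   out-of-sagittal sinusoids.
#' @param start_x Initial pelvis forward position (m).
#' @return A `gait_spec` object.
#' @export
gait_spec <- function(speed = 0.4, step_length = 0.33, sample_rate = 200,
                      n_cycles = 3, duty = 0.62, lift = 0.03,
                      hip_add_amp = 2 * pi / 180, hip_rot_amp = 2 * pi / 180,
                      ankle_inv_amp = 2 * pi / 180, start_x = 0) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (speed < 0 || step_length <= 0) stop("speed and step_length must be nonnegative")
  if (speed > 0 && (duty <= 0.5 || duty >= 0.9))
    stop("duty factor must lie in (0.5, 0.9)")
  structure(list(speed = speed, step_length = step_length,
                 stride = 2 * step_length,
                 cycle_duration = if (speed > 0) 2 * step_length / speed else Inf,
                 cadence = if (speed > 0) speed / step_length else 0,
                 sample_rate = sample_rate, n_cycles = n_cycles, duty = duty,
                 lift = lift, hip_add_amp = hip_add_amp,
                 hip_rot_amp = hip_rot_amp, ankle_inv_amp = ankle_inv_amp,
                 start_x = start_x),
            class = "gait_spec")
}

# Quintic smoothstep: C2, zero first and second derivatives at both ends.
smoothstep5 <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

# Exact planar two-link leg geometry in the sagittal plane.
# dx: ankle forward of hip; dy: ankle below hip (both m).  Returns hip and
# knee flexion (rad, knee negative when flexed backward).
planar_leg_ik <- function(dx, dy, lt, ls) {
  r2 <- dx^2 + dy^2
  reach <- lt + ls
  if (any(r2 > (reach - 1e-6)^2))
    stop("infeasible gait spec: required hip-ankle distance ",
         format(sqrt(max(r2)), digits = 4), " m exceeds leg length ",
         format(reach, digits = 4), " m")
  ck <- (r2 - lt^2 - ls^2) / (2 * lt * ls)
  qk <- -acos(pmin(1, pmax(-1, ck)))
  # ankle position in the thigh-aligned frame before hip rotation:
  # v = (0, -lt) + Rz(qk) (0, -ls); hip flexion rotates v onto (dx, -dy)
  vx <- ls * sin(qk)
  vy <- -lt - ls * cos(qk)
  qh <- atan2(dx, dy) - atan2(vx, -vy)
  list(hip = qh, knee = qk)
}

leg_phase <- function(t, spec, side) {
  ph <- (t / spec$cycle_duration) %% 1
  if (side == "l") ph <- (ph + 0.5) %% 1
  ph
}

# Ankle-path world x and y for one leg over the cycle phases.
ankle_path <- function(t, spec, side, geom) {
  ph <- leg_phase(t, spec, side)
  cyc <- floor(t / spec$cycle_duration - (if (side == "l") 0.5 else 0))
  # Stance ankle is centered under the hip at mid-stance.
  offset <- if (side == "l") 0.5 else 0
  x_strike <- spec$start_x +
    spec$speed * spec$cycle_duration * (cyc + offset + spec$duty / 2)
  swing <- ph >= spec$duty
  s <- pmax(0, (ph - spec$duty) / (1 - spec$duty))
  x <- x_strike + ifelse(swing, spec$stride * smoothstep5(s), 0)
  y <- geom$ankle_height + ifelse(swing, spec$lift * sin(pi * s)^3, 0)
  list(x = x, y = y, phase = ph)
}

#' Generate the ground-truth gait trajectory
#'
#' @param spec A `gait_spec`.
#' @param model The robot fixture (or a model with the same coordinate set).
#' @return A `coordinate_trajectory` of truth coordinates: root translation
#'   advancing at `spec$speed`, stance feet flat on the ground (y = 0 plane),
#'   swing feet lifted.
#' @export
generate_gait <- function(spec, model) {
  geom <- robot_geometry()
  if (spec$speed == 0) {
    tN <- max(2L, round(spec$n_cycles * spec$sample_rate))
    time <- (seq_len(tN) - 1) / spec$sample_rate
    q0 <- robot_static_pose(model)
    q <- matrix(rep(q0, each = tN), tN, n_coords(model),
                dimnames = list(NULL, coord_names(model)))
    return(coordinate_trajectory(time, q, rate = spec$sample_rate))
  }
  tN <- round(spec$n_cycles * spec$cycle_duration * spec$sample_rate)
  time <- (seq_len(tN) - 1) / spec$sample_rate
  nq <- n_coords(model)
  q <- matrix(0, tN, nq, dimnames = list(NULL, coord_names(model)))
  q[, "pelvis_tx"] <- spec$start_x + spec$speed * time
  q[, "pelvis_ty"] <- geom$pelvis_height

  for (side in c("r", "l")) {
    ap <- ankle_path(time, spec, side, geom)
    dx <- ap$x - q[, "pelvis_tx"]
    dy <- geom$pelvis_height - ap$y
    leg <- planar_leg_ik(dx, dy, geom$thigh_length, geom$shank_length)
    ph <- ap$phase
    q[, paste0("hip_flexion_", side)] <- leg$hip
    q[, paste0("knee_flexion_", side)] <- leg$knee
    q[, paste0("ankle_flexion_", side)] <- -(leg$hip + leg$knee)
    sgn <- if (side == "r") 1 else -1
    q[, paste0("hip_adduction_", side)] <- sgn * spec$hip_add_amp * sin(2 * pi * ph)
    q[, paste0("hip_rotation_", side)] <- sgn * spec$hip_rot_amp * sin(2 * pi * ph + pi / 3)
    q[, paste0("ankle_inversion_", side)] <- sgn * spec$ankle_inv_amp * sin(2 * pi * ph)
  }
  coordinate_trajectory(time, q, rate = spec$sample_rate)
}

#' Neutral standing pose of the robot fixture
#'
#' Feet flat under the hips on the y = 0 ground plane, knees slightly bent
#' (the hip height in [robot_geometry()] is below full leg extension).
#'
#' @param model The robot fixture.
#' @return Named coordinate vector.
#' @export
robot_static_pose <- function(model = robot_fixture()) {
  geom <- robot_geometry()
  q <- stats::setNames(rep(0, n_coords(model)), coord_names(model))
  q["pelvis_ty"] <- geom$pelvis_height
  leg <- planar_leg_ik(0, geom$pelvis_height - geom$ankle_height,
                       geom$thigh_length, geom$shank_length)
  for (side in c("r", "l")) {
    q[paste0("hip_flexion_", side)] <- leg$hip
    q[paste0("knee_flexion_", side)] <- leg$knee
    q[paste0("ankle_flexion_", side)] <- -(leg$hip + leg$knee)
  }
  q
}

#' Synthesize a marker series from truth kinematics
#'
#' Forward-kinematics marker positions plus independent isotropic Gaussian
#' noise per marker per frame; reproducible under `seed`.
#'
#' @param model A `kinematic_model`.
#' @param truth_q A `coordinate_trajectory`.
#' @param noise_sigma Measurement noise SD per axis (m, >= 0).
#' @param seed Optional integer seed.
#' @return A `marker_series`.
#' @export
synthesize_markers <- function(model, truth_q, noise_sigma = 0, seed = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  tN <- nrow(truth_q$q)
  M <- length(model$marker_names)
  pos <- array(NA_real_, c(3, M, tN), dimnames = list(NULL, model$marker_names, NULL))
  for (f in seq_len(tN))
    pos[, , f] <- forward_kinematics(model, truth_q$q[f, ])$markers
  if (noise_sigma > 0) {
    pos <- run_with_seed(seed,
      pos + array(stats::rnorm(length(pos), 0, noise_sigma), dim(pos)))
    dimnames(pos) <- list(NULL, model$marker_names, NULL)
  }
  marker_series(truth_q$time, pos, rate = truth_q$rate)
}

# Smooth support-transfer weight for the right foot over its cycle phase.
right_support_weight <- function(ph, duty) {
  ds <- duty - 0.5  # double-support fraction after each strike
  ramp <- function(u) (1 - cos(pi * pmin(1, pmax(0, u)))) / 2
  w <- ifelse(ph < ds, ramp(ph / ds),
        ifelse(ph < 0.5, 1,
          ifelse(ph < 0.5 + ds, 1 - ramp((ph - 0.5) / ds), 0)))
  w
}

#' Synthesize dynamically consistent ground reactions
#'
#' The whole-body Newton-Euler wrench computed from the truth kinematics is
#' assigned to the stance foot during single support; during double support
#' it is split between the feet by a smooth cosine transition weight.  The
#' center of pressure is solved per foot so the horizontal moment balance is
#' exact on the ground plane, and the vertical free moment carries the
#' remainder.  Running [inverse_dynamics()] on (truth, synthesized GRF)
#' therefore leaves near-zero root residuals during single support.
#'
#' @param model A `kinematic_model`.
#' @param truth_q A `coordinate_trajectory` from [generate_gait()].
#' @param spec The `gait_spec` used to generate `truth_q` (provides the
#'   stance phasing).
#' @param support `"auto"` (phasing from `spec`; standing splits the load
#'   evenly), or `"r"`/`"l"` to assign the whole wrench to one foot (e.g.
#'   single-foot standing).
#' @return Named list with `ground_reaction` objects `r` and `l`.
#' @export
synthesize_grf <- function(model, truth_q, spec, support = "auto") {
  d <- differentiate(truth_q)
  tN <- nrow(truth_q$q)
  g <- model$gravity
  F_tot <- matrix(0, tN, 3); N_tot <- matrix(0, tN, 3)
  ankle_x <- list(r = numeric(tN), l = numeric(tN))
  for (f in seq_len(tN)) {
    kin <- segment_kinematics(model, truth_q$q[f, ], d$qd[f, ], d$qdd[f, ])
    Fs <- c(0, 0, 0); Ns <- c(0, 0, 0)
    for (s in names(model$segments)) {
      seg <- model$segments[[s]]
      pose <- kin$pose
      cw <- pose$segment_p[[s]] + as.numeric(pose$segment_R[[s]] %*% seg$com_local)
      Iw <- pose$segment_R[[s]] %*% seg$inertia_local %*% t(pose$segment_R[[s]])
      w <- kin$omega[[s]]
      fi <- seg$mass * (kin$a_com[[s]] - g)
      Fs <- Fs + fi
      Ns <- Ns + as.numeric(Iw %*% kin$alpha[[s]]) + cross3(w, as.numeric(Iw %*% w)) +
        cross3(cw, fi)
    }
    F_tot[f, ] <- Fs; N_tot[f, ] <- Ns
    ankle_x$r[f] <- kin$pose$segment_p[["foot_r"]][1]
    ankle_x$l[f] <- kin$pose$segment_p[["foot_l"]][1]
  }

  w_r <- if (support == "r") rep(1, tN)
    else if (support == "l") rep(0, tN)
    else if (spec$speed > 0)
      right_support_weight(leg_phase(truth_q$time, spec, "r"), spec$duty)
    else rep(0.5, tN)  # quiet standing: even split

  build_side <- function(w, body, ax) {
    force <- w * F_tot
    nshare <- w * N_tot
    cop <- matrix(0, tN, 3)
    fm <- matrix(0, tN, 3)
    fy <- force[, 2]
    ok <- abs(fy) > 1e-6
    cop[ok, 1] <- nshare[ok, 3] / fy[ok]
    cop[ok, 3] <- -nshare[ok, 1] / fy[ok]
    cop[!ok, 1] <- ax[!ok]
    force[!ok, ] <- 0
    fm_full <- nshare - t(vapply(seq_len(tN), function(f)
      cross3(cop[f, ], force[f, ]), numeric(3)))
    fm[ok, ] <- fm_full[ok, ]
    ground_reaction(truth_q$time, force, cop, fm, body)
  }
  list(r = build_side(w_r, "foot_r", ankle_x$r),
       l = build_side(1 - w_r, "foot_l", ankle_x$l))
}

#' Generate the complete synthetic experiment
#'
#' Builds the robot fixture, a static calibration trial (1 s of quiet
#' standing), a walking trial at the spec'd speed, encoder channels (exact
#' truth joint angles), and dynamically consistent ground reactions.  All
#' randomness flows from the single `seed`.  When `out_dir` is given, the
#' trial is also written to disk as TRC/MOT files plus JSON metadata,
#' deterministically for a given seed.
#'
#' @param spec A `gait_spec`.
#' @param noise_sigma Marker measurement noise SD (m); applied to both the
#'   static and walking trials.
#' @param seed Integer seed.
#' @param out_dir Optional output directory (created if needed).
#' @return A `synthetic_trial`: model, spec, `static_markers` and `markers`
#'   (`marker_series`), `static_q`, `truth` (`coordinate_trajectory`),
#'   `encoders` (named matrix of the 12 joint angles), `grf`, `seed`,
#'   `noise_sigma`, and (if written) `files`.
#' @export
make_dataset <- function(spec = gait_spec(), noise_sigma = 5e-4, seed = 1,
                         out_dir = NULL) {
  model <- robot_fixture()
  static_q <- robot_static_pose(model)
  static_tN <- round(spec$sample_rate)  # 1 s static trial
  static_time <- (seq_len(static_tN) - 1) / spec$sample_rate
  static_traj <- coordinate_trajectory(
    static_time,
    matrix(rep(static_q, each = static_tN), static_tN, n_coords(model),
           dimnames = list(NULL, coord_names(model))),
    rate = spec$sample_rate)

  truth <- generate_gait(spec, model)
  joint_names <- coord_names(model)[-(1:6)]

  static_markers <- synthesize_markers(model, static_traj, noise_sigma,
                                       seed = seed)
  markers <- synthesize_markers(model, truth, noise_sigma,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  grf <- synthesize_grf(model, truth, spec)

  trial <- structure(list(
    model = model, spec = spec,
    static_markers = static_markers, static_q = static_q,
    markers = markers, truth = truth,
    encoders = truth$q[, joint_names, drop = FALSE],
    static_encoders = static_q[joint_names],
    grf = grf, seed = seed, noise_sigma = noise_sigma
  ), class = "synthetic_trial")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_trc(static_markers, fp("static.trc"))
    write_trc(markers, fp("walking.trc"))
    enc <- data.frame(time = truth$time, truth$q[, joint_names] * 180 / pi,
                      check.names = FALSE)
    write_mot(enc, fp("encoders.mot"), name = "encoders", in_degrees = TRUE)
    write_coordinates_mot(truth, model, fp("truth_angles.mot"))
    write_grf_mot(grf, fp("grf.mot"))
    save_model(model, fp("robot.model.json"))
    meta <- list(seed = seed, noise_sigma = noise_sigma,
                 spec = unclass(spec), package_version = "0.1.0")
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), fp("metadata.json"))
    trial$files <- vapply(c("static.trc", "walking.trc", "encoders.mot",
                            "truth_angles.mot", "grf.mot", "robot.model.json",
                            "metadata.json"), fp, character(1))
  }
  trial
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial> seed ", x$seed, ", ", n_frames(x$markers),
      " walking frames @ ", x$spec$sample_rate, " Hz, noise ",
      format(x$noise_sigma * 1000, digits = 3), " mm\n", sep = "")
  invisible(x)
}

#' Decimate a marker series
#'
#' Keeps every `k`-th frame (starting from the first).  Used to run IK at a
#' reduced rate while events and moments stay at the native rate.
#'
#' @param series A `marker_series`.
#' @param k Positive integer decimation factor.
#' @return A `marker_series`.
#' @export
decimate_markers <- function(series, k) {
  keep <- seq(1, n_frames(series), by = k)
  marker_series(series$time[keep], series$pos[, , keep, drop = FALSE],
                names = series$names)
}
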