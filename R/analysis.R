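# Signal processing and the evaluation protocol: zero-phase Butterworth
# filtering, threshold-based gait events, percent-gait-cycle normalization,
# and the RMSE comparisons between registration methods.

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a low-pass Butterworth filter and applies it forward and backward
#' (zero phase lag; effective order is twice `order`).  The signal is
#' reflection-padded at both ends to suppress edge transients.  Defaults are
#' a 4th-order filter with an 8 Hz cutoff.
#'
#' @param x Numeric vector or matrix (columns filtered independently),
#'   uniformly sampled.
#' @param rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz); must satisfy 0 < cutoff < rate/2.
#' @param order Filter order per pass.
#' @return Filtered data, same shape and length as `x`.
#' @export
butterworth_lowpass <- function(x, rate, cutoff = 8, order = 4) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  g <- sum(b) / sum(a)  # DC gain (1 for a low-pass)
  # one pass with steady-state initial conditions anchored at the first sample
  run <- function(v) as.numeric(signal::filter(
    b, a, v, init.x = rep(v[1], length(b) - 1),
    init.y = rep(v[1] * g, length(a) - 1)))
  filt1 <- function(v) {
    n <- length(v)
    p <- min(n - 1, max(24, 3 * (order + 1)))
    head_pad <- 2 * v[1] - v[(p + 1):2]
    tail_pad <- 2 * v[n] - v[(n - 1):(n - p)]
    vp <- c(head_pad, v, tail_pad)
    y <- rev(run(rev(run(vp))))
    y[(p + 1):(p + n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(as.numeric(x))
}

#' Low-pass filter every channel of a marker series
#'
#' @param series A `marker_series` with complete (non-missing) data.
#' @param cutoff,order Passed to [butterworth_lowpass()].
#' @return A filtered `marker_series`.
#' @export
filter_marker_series <- function(series, cutoff = 8, order = 4) {
  pos <- series$pos
  tN <- dim(pos)[3]
  flat <- matrix(pos, nrow = 3 * dim(pos)[2], ncol = tN)
  flat <- t(butterworth_lowpass(t(flat), series$rate, cutoff, order))
  pos2 <- array(flat, dim(pos), dimnames = dimnames(pos))
  marker_series(series$time, pos2, rate = series$rate)
}

#' Detect foot strike and foot off from vertical ground reaction force
#'
#' Foot strike is the rise of the vertical force through
#' `threshold_fraction * body_weight`, foot off the fall through it;
#' contact/flight phases shorter than `min_phase` are removed (debounce),
#' and crossing times are linearly interpolated between samples.
#'
#' @param grf A `ground_reaction`.
#' @param body_weight Total body weight (N).
#' @param threshold_fraction Fraction of body weight (0 < f < 1, default 0.05).
#' @param min_phase Minimum phase duration (s, default 0.05).
#' @return A `gait_events` list: `foot_strike`, `foot_off` (times, s),
#'   `side` (the applied body).  Empty vectors if no crossings.
#' @export
detect_gait_events <- function(grf, body_weight, threshold_fraction = 0.05,
                               min_phase = 0.05) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly between 0 and 1")
  fy <- grf$force[, 2]
  thr <- threshold_fraction * body_weight
  contact <- fy > thr
  n <- length(contact)
  dt <- 1 / grf$rate
  minn <- max(1L, round(min_phase / dt))
  repeat {
    r <- rle(contact)
    short <- which(r$lengths < minn)
    if (length(short) == 0 || length(r$lengths) == 1) break
    k <- short[1]
    i0 <- sum(r$lengths[seq_len(k - 1)]) + 1
    contact[i0:(i0 + r$lengths[k] - 1)] <- !r$values[k]
  }
  strikes <- which(diff(c(FALSE, contact)) == 1)
  offs <- which(diff(c(contact, FALSE)) == -1)
  interp_cross <- function(i, rising) {
    if (rising) {
      if (i == 1) return(grf$time[1])
      a <- fy[i - 1]; b <- fy[i]
      grf$time[i - 1] + (thr - a) / (b - a) * dt
    } else {
      if (i == n) return(grf$time[n])
      a <- fy[i]; b <- fy[i + 1]
      grf$time[i] + (a - thr) / (a - b) * dt
    }
  }
  fs <- vapply(strikes[strikes > 1], interp_cross, numeric(1), rising = TRUE)
  fo <- vapply(offs[offs < n], interp_cross, numeric(1), rising = FALSE)
  structure(list(foot_strike = fs, foot_off = fo, side = grf$applied_body),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> '", x$side, "': ", length(x$foot_strike), " strikes, ",
      length(x$foot_off), " offs\n", sep = "")
  invisible(x)
}

#' Normalize a signal to percent gait cycle
#'
#' Linear interpolation onto 101 equally spaced points spanning one cycle
#' (0 to 100 percent).
#'
#' @param time Sample times (s).
#' @param values Numeric vector or matrix (rows are samples).
#' @param cycle Length-2 numeric: `c(t_strike, t_next_strike)`; must lie
#'   within the sampled time range.
#' @return A 101-row matrix (or length-101 vector) with attribute `percent`.
#' @export
normalize_gait_cycle <- function(time, values, cycle) {
  tol <- 1e-9
  if (cycle[1] < min(time) - tol || cycle[2] > max(time) + tol)
    stop("gait cycle [", cycle[1], ", ", cycle[2],
         "] lies outside the sampled time range")
  grid <- seq(cycle[1], cycle[2], length.out = 101)
  one <- function(v) stats::approx(time, v, xout = grid, rule = 2)$y
  out <- if (is.matrix(values)) apply(values, 2, one) else one(values)
  attr(out, "percent") <- seq(0, 100)
  out
}

#' Root-mean-square error between two aligned series
#'
#' @param a,b Numeric vectors of equal length on the same time base.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b))
    stop("rmse: series have different lengths (", length(a), " vs ", length(b), ")")
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}

#' Right-leg degrees of freedom, in reporting order
#' @return Named character vector mapping report labels to coordinate names.
#' @export
right_leg_dofs <- function() {
  c("Hip flexion" = "hip_flexion_r",
    "Hip adduction" = "hip_adduction_r",
    "Hip rotation" = "hip_rotation_r",
    "Knee flexion" = "knee_flexion_r",
    "Ankle flexion" = "ankle_flexion_r",
    "Ankle inversion" = "ankle_inversion_r")
}

#' Evaluate a registered model against ground truth
#'
#' Runs constrained IK on the walking trial, detects the first full right
#' gait cycle from the vertical ground reaction force, and reports per-DOF
#' right-leg joint-angle RMSE (deg, on the 101-point normalized cycle)
#' against the truth angles, per-frame marker RMSE (mm, mean and SD over the
#' cycle), and -- when `reference_moments` is supplied -- per-DOF joint
#' moment RMSE (N*m) over the right single-support window at native
#' sampling.
#'
#' @param registration A `registration_result` (provides the model and the
#'   static pose used to warm-start IK).
#' @param markers Walking-trial `marker_series`.
#' @param grf Named list of `ground_reaction` objects (needs the right-foot
#'   plate for event detection).
#' @param truth A `coordinate_trajectory` of truth coordinates (rad).
#' @param reference_moments Optional `moment_trajectory` to compare moments
#'   against (the encoder-registered model's moments in the study design).
#' @param compute_moments Compute inverse-dynamics moments (required when
#'   `reference_moments` is given).
#' @param weights Optional IK marker weights.
#' @return An `evaluation` list: `report` (Table-shaped data frame),
#'   `angle_rmse_deg`, `moment_rmse_Nm`, `marker_rmse_mean_mm`,
#'   `marker_rmse_sd_mm`, `cycle`, `single_support`, `traj`, `moments`.
#' @export
evaluate_registration <- function(registration, markers, grf, truth,
                                  reference_moments = NULL,
                                  compute_moments = !is.null(reference_moments),
                                  weights = NULL) {
  model <- registration$registered_model
  traj <- solve_trajectory(model, markers, weights = weights,
                           q0 = registration$static_pose)
  bw <- total_weight(model)

  grf_r <- grf[[which(vapply(grf, function(g) g$applied_body, character(1)) == "foot_r")[1]]]
  grf_l <- grf[[which(vapply(grf, function(g) g$applied_body, character(1)) == "foot_l")[1]]]
  ev_r <- detect_gait_events(grf_r, bw)
  if (length(ev_r$foot_strike) < 2)
    stop("need at least two right foot strikes to define a gait cycle")
  cycle <- ev_r$foot_strike[1:2]

  dofs <- right_leg_dofs()
  est_deg <- traj$q[, dofs, drop = FALSE] * 180 / pi
  tru_deg <- truth$q[, dofs, drop = FALSE] * 180 / pi
  est_n <- normalize_gait_cycle(traj$time, est_deg, cycle)
  tru_n <- normalize_gait_cycle(truth$time, tru_deg, cycle)
  angle_rmse <- vapply(seq_along(dofs), function(i) rmse(est_n[, i], tru_n[, i]),
                       numeric(1))
  names(angle_rmse) <- names(dofs)

  in_cycle <- traj$time >= cycle[1] & traj$time <= cycle[2]
  marker_mean <- mean(traj$residual_rms[in_cycle]) * 1000
  marker_sd <- stats::sd(traj$residual_rms[in_cycle]) * 1000

  # Right single-support window: left foot off -> left foot strike, inside
  # the analyzed cycle.
  ev_l <- detect_gait_events(grf_l, bw)
  off_l <- ev_l$foot_off[ev_l$foot_off > cycle[1] & ev_l$foot_off < cycle[2]]
  str_l <- ev_l$foot_strike[ev_l$foot_strike > cycle[1] & ev_l$foot_strike < cycle[2]]
  single_support <- if (length(off_l) > 0 && length(str_l) > 0)
    c(off_l[1], str_l[str_l > off_l[1]][1]) else c(NA_real_, NA_real_)

  moment_rmse <- rep(NA_real_, length(dofs)); names(moment_rmse) <- names(dofs)
  moments <- NULL
  if (compute_moments) {
    moments <- inverse_dynamics(model, traj, grf)
    if (!is.null(reference_moments) && all(is.finite(single_support))) {
      win <- moments$time >= single_support[1] & moments$time <= single_support[2]
      ref_win <- reference_moments$time >= single_support[1] &
        reference_moments$time <= single_support[2]
      for (i in seq_along(dofs)) {
        a <- moments$moments[win, dofs[i]]
        b <- reference_moments$moments[ref_win, dofs[i]]
        if (length(a) == length(b)) moment_rmse[i] <- rmse(a, b)
      }
    }
  }

  report <- data.frame(
    row.names = c(names(dofs), "Marker error (mm)"),
    angle_rmse_deg = c(angle_rmse, NA),
    moment_rmse_Nm = c(moment_rmse, NA)
  )
  report["Marker error (mm)", "angle_rmse_deg"] <- marker_mean

  structure(list(report = report, angle_rmse_deg = angle_rmse,
                 moment_rmse_Nm = moment_rmse,
                 marker_rmse_mean_mm = marker_mean,
                 marker_rmse_sd_mm = marker_sd,
                 cycle = cycle, single_support = single_support,
                 traj = traj, moments = moments, method = registration$method),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat("<evaluation> method '", x$method, "'\n", sep = "")
  print(round(x$report, 3))
  invisible(x)
}

#' Total weight of a model (N)
#' @param model A `kinematic_model`.
#' @return Sum of segment masses times gravitational acceleration.
#' @export
total_weight <- function(model) {
  sum(vapply(model$segments, function(s) s$mass, numeric(1))) *
    sqrt(sum(model$gravity^2))
}
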