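# Inverse dynamics: net joint moments from a coordinate trajectory and
# measured ground reactions, via a recursive Newton-Euler pass over the
# segment tree (outward velocities/accelerations, inward forces/moments).
# Moments are reported about the joint coordinate axes (generalized forces):
# N*m for rotational dofs, N for the root translations (the "residuals").

#' Construct a ground-reaction series for one plate/foot
#'
#' @param time Time stamps (s), strictly increasing.
#' @param force Frames x 3 matrix of force on the body (N, ground frame).
#' @param cop Frames x 3 matrix, center of pressure (m, ground frame).
#' @param free_moment Frames x 3 matrix of free moment (N*m).
#' @param applied_body Segment name the wrench acts on (the stance foot).
#' @return A `ground_reaction` object.
#' @export
ground_reaction <- function(time, force, cop, free_moment, applied_body) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop("ground reaction time must be strictly increasing")
  force <- as.matrix(force); cop <- as.matrix(cop); free_moment <- as.matrix(free_moment)
  if (!all(is.finite(force))) stop("ground reaction force must be finite")
  structure(list(time = time, force = force, cop = cop,
                 free_moment = free_moment, applied_body = applied_body,
                 rate = if (length(time) > 1) 1 / mean(diff(time)) else NA_real_),
            class = "ground_reaction")
}

#' @export
print.ground_reaction <- function(x, ...) {
  cat("<ground_reaction> ", length(x$time), " frames on '", x$applied_body,
      "'\n", sep = "")
  invisible(x)
}

# Finite-difference derivative of the columns of a matrix.
# Interior: 5-point 4th-order central stencils; one point from each end:
# 3rd-order shifted stencils; ends: 2nd-order one-sided.
fd_matrix <- function(x, dt, order) {
  x <- as.matrix(x)
  tN <- nrow(x)
  if (tN < 5) stop("differentiation requires at least 5 samples")
  out <- matrix(NA_real_, tN, ncol(x), dimnames = dimnames(x))
  i <- 3:(tN - 2)
  if (order == 1) {
    out[i, ] <- (x[i - 2, ] - 8 * x[i - 1, ] + 8 * x[i + 1, ] - x[i + 2, ]) / (12 * dt)
    out[2, ] <- (-2 * x[1, ] - 3 * x[2, ] + 6 * x[3, ] - x[4, ]) / (6 * dt)
    out[tN - 1, ] <- (x[tN - 3, ] - 6 * x[tN - 2, ] + 3 * x[tN - 1, ] + 2 * x[tN, ]) / (6 * dt)
    out[1, ] <- (-3 * x[1, ] + 4 * x[2, ] - x[3, ]) / (2 * dt)
    out[tN, ] <- (3 * x[tN, ] - 4 * x[tN - 1, ] + x[tN - 2, ]) / (2 * dt)
  } else {
    out[i, ] <- (-x[i - 2, ] + 16 * x[i - 1, ] - 30 * x[i, ] + 16 * x[i + 1, ] - x[i + 2, ]) / (12 * dt^2)
    out[2, ] <- (11 * x[1, ] - 20 * x[2, ] + 6 * x[3, ] + 4 * x[4, ] - x[5, ]) / (12 * dt^2)
    out[tN - 1, ] <- (-x[tN - 4, ] + 4 * x[tN - 3, ] + 6 * x[tN - 2, ] - 20 * x[tN - 1, ] + 11 * x[tN, ]) / (12 * dt^2)
    out[1, ] <- (2 * x[1, ] - 5 * x[2, ] + 4 * x[3, ] - x[4, ]) / dt^2
    out[tN, ] <- (2 * x[tN, ] - 5 * x[tN - 1, ] + 4 * x[tN - 2, ] - x[tN - 3, ]) / dt^2
  }
  out
}

#' Differentiate a coordinate trajectory
#'
#' Central differences on the interior (higher-order stencils, see Details)
#' and second-order one-sided differences at the ends.  Intended to be
#' applied after any filtering.
#'
#' @details Interior samples with two neighbors on each side use 5-point
#'   4th-order central stencils; the samples adjacent to the ends use
#'   3rd-order shifted stencils; the end samples use 2nd-order one-sided
#'   formulas.
#'
#' @param traj A `coordinate_trajectory` with at least 5 samples.
#' @return List with `qd` (velocities) and `qdd` (accelerations), matrices
#'   aligned with `traj$q`.
#' @export
differentiate <- function(traj) {
  dt <- 1 / traj$rate
  list(qd = fd_matrix(traj$q, dt, 1), qdd = fd_matrix(traj$q, dt, 2))
}

# Outward pass: world angular velocity/acceleration and COM acceleration of
# every segment, given q, qd, qdd for one frame.  Returns per-segment lists.
segment_kinematics <- function(model, q, qd, qdd, pose = NULL) {
  if (is.null(pose)) pose <- forward_kinematics(model, q)
  omega <- list(ground = c(0, 0, 0))
  alpha <- list(ground = c(0, 0, 0))
  a_origin <- list(ground = c(0, 0, 0))
  a_com <- list()
  for (jn in model$joint_order) {
    j <- model$joints[[jn]]
    par <- j$parent
    wp <- omega[[par]]; ap <- alpha[[par]]; a_op <- a_origin[[par]]
    o_p <- if (par == "ground") c(0, 0, 0) else pose$segment_p[[par]]
    cidx <- which(model$coords$joint == jn)
    rot_idx <- cidx[model$coords$type[cidx] == "rotation"]
    trn_idx <- cidx[model$coords$type[cidx] == "translation"]

    if (length(rot_idx) > 0) {
      p_j <- pose$dof_point[, rot_idx[1]]
    } else {
      p_j <- pose$segment_p[[j$child]]
    }
    r <- p_j - o_p
    a_j <- a_op + cross3(ap, r) + cross3(wp, cross3(wp, r))
    # Root translations: axes fixed in the (non-rotating) parent frame.
    for (k in trn_idx) a_j <- a_j + qdd[k] * pose$dof_axis[, k]

    wc <- wp; ac <- a_j; alc <- ap
    for (k in rot_idx) {
      ax <- pose$dof_axis[, k]
      alc <- alc + qdd[k] * ax + cross3(wc, qd[k] * ax)
      wc <- wc + qd[k] * ax
    }
    o_c <- pose$segment_p[[j$child]]
    r2 <- o_c - p_j
    a_oc <- a_j + cross3(alc, r2) + cross3(wc, cross3(wc, r2))
    omega[[j$child]] <- wc
    alpha[[j$child]] <- alc
    a_origin[[j$child]] <- a_oc
    cw <- as.numeric(pose$segment_R[[j$child]] %*% model$segments[[j$child]]$com_local)
    a_com[[j$child]] <- a_oc + cross3(alc, cw) + cross3(wc, cross3(wc, cw))
  }
  list(pose = pose, omega = omega, alpha = alpha, a_com = a_com)
}

# Inward Newton-Euler pass for one frame.  external: named list per segment
# of list(force, point, moment) in world coordinates.  Returns generalized
# forces for all coordinates.
rnea_frame <- function(model, kin, external = list()) {
  g <- model$gravity
  pose <- kin$pose
  segs <- names(model$segments)
  # reverse topological order over joints gives children before parents
  Fs <- list(); Ns <- list()
  for (jn in rev(model$joint_order)) {
    s <- model$joints[[jn]]$child
    seg <- model$segments[[s]]
    cw <- pose$segment_p[[s]] + as.numeric(pose$segment_R[[s]] %*% seg$com_local)
    Iw <- pose$segment_R[[s]] %*% seg$inertia_local %*% t(pose$segment_R[[s]])
    w <- kin$omega[[s]]
    f_inert <- seg$mass * (kin$a_com[[s]] - g)
    n_inert <- as.numeric(Iw %*% kin$alpha[[s]]) + cross3(w, as.numeric(Iw %*% w)) +
      cross3(cw, f_inert)
    Ftot <- f_inert; Ntot <- n_inert
    ext <- external[[s]]
    if (!is.null(ext)) {
      Ftot <- Ftot - ext$force
      Ntot <- Ntot - (cross3(ext$point, ext$force) + ext$moment)
    }
    # add already-processed children
    for (jc in model$joint_order) {
      if (model$joints[[jc]]$parent == s) {
        cs <- model$joints[[jc]]$child
        Ftot <- Ftot + Fs[[cs]]
        Ntot <- Ntot + Ns[[cs]]
      }
    }
    Fs[[s]] <- Ftot; Ns[[s]] <- Ntot
  }
  tau <- numeric(n_coords(model))
  for (qi in seq_len(n_coords(model))) {
    jn <- model$coords$joint[qi]
    s <- model$joints[[jn]]$child
    ax <- pose$dof_axis[, qi]
    if (model$coords$type[qi] == "rotation") {
      p_k <- pose$dof_point[, qi]
      tau[qi] <- sum(ax * (Ns[[s]] - cross3(p_k, Fs[[s]])))
    } else {
      tau[qi] <- sum(ax * Fs[[s]])
    }
  }
  names(tau) <- coord_names(model)
  tau
}

grf_index <- function(grf, t) {
  idx <- round((t - grf$time[1]) * grf$rate) + 1
  if (idx < 1 || idx > length(grf$time) || abs(grf$time[idx] - t) > 1e-6)
    stop("ground reaction / trajectory time mismatch at t = ", format(t),
         " (alignment error)")
  idx
}

#' Inverse dynamics over a trajectory
#'
#' Recursive Newton-Euler over the segment tree: the outward pass propagates
#' angular velocity/acceleration and COM acceleration from the analytic
#' joint-axis recursion; the inward pass accumulates forces and moments,
#' applying each external wrench at its center of pressure.  Generalized
#' moments are reported about each joint coordinate axis; the root
#' translational entries are the residual forces.
#'
#' @param model A `kinematic_model`.
#' @param traj A `coordinate_trajectory`.
#' @param grf A `ground_reaction` or list of them (may be empty).  Times must
#'   cover the trajectory on the same sampling grid.
#' @param qd,qdd Optional velocity/acceleration matrices; computed from
#'   `traj` by [differentiate()] when omitted (requires >= 5 samples).
#' @return A `moment_trajectory`: `time`, `moments` (frames x coordinates,
#'   named), `rate`.
#' @export
inverse_dynamics <- function(model, traj, grf = list(), qd = NULL, qdd = NULL) {
  if (inherits(grf, "ground_reaction")) grf <- list(grf)
  if (is.null(qd) || is.null(qdd)) {
    d <- differentiate(traj)
    if (is.null(qd)) qd <- d$qd
    if (is.null(qdd)) qdd <- d$qdd
  }
  tN <- nrow(traj$q)
  out <- matrix(NA_real_, tN, n_coords(model),
                dimnames = list(NULL, coord_names(model)))
  for (f in seq_len(tN)) {
    external <- list()
    for (g in grf) {
      idx <- grf_index(g, traj$time[f])
      external[[g$applied_body]] <- list(force = g$force[idx, ],
                                         point = g$cop[idx, ],
                                         moment = g$free_moment[idx, ])
    }
    kin <- segment_kinematics(model, traj$q[f, ], qd[f, ], qdd[f, ])
    out[f, ] <- rnea_frame(model, kin, external)
  }
  structure(list(time = traj$time, moments = out, rate = traj$rate),
            class = "moment_trajectory")
}

#' @export
print.moment_trajectory <- function(x, ...) {
  cat("<moment_trajectory> ", nrow(x$moments), " frames x ", ncol(x$moments),
      " coordinates\n", sep = "")
  invisible(x)
}

grf_col_names <- function(prefix) {
  paste0(prefix, c("_force_vx", "_force_vy", "_force_vz",
                   "_force_px", "_force_py", "_force_pz",
                   "_torque_x", "_torque_y", "_torque_z"))
}

#' Write ground reactions as a MOT file (9 columns per plate)
#'
#' Columns per plate: force vector, center of pressure, free moment
#' (OpenSim external-loads dialect).
#'
#' @param grf_list Named list of `ground_reaction` objects (names become
#'   column prefixes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grf_mot <- function(grf_list, path) {
  if (inherits(grf_list, "ground_reaction")) grf_list <- list(plate1 = grf_list)
  time <- grf_list[[1]]$time
  df <- data.frame(time = time)
  for (nm in names(grf_list)) {
    g <- grf_list[[nm]]
    block <- cbind(g$force, g$cop, g$free_moment)
    colnames(block) <- grf_col_names(nm)
    df <- cbind(df, block)
  }
  attr(df, "applied_body") <- vapply(grf_list, function(g) g$applied_body, character(1))
  hdr_extra <- paste0("appliedBody_", names(grf_list), "=",
                      vapply(grf_list, function(g) g$applied_body, character(1)))
  tbl <- df
  hdr <- c("ground reactions",
           "version=1",
           paste0("nRows=", nrow(tbl)),
           paste0("nColumns=", ncol(tbl)),
           "inDegrees=no",
           hdr_extra,
           "endheader",
           paste(names(tbl), collapse = "\t"))
  rows <- apply(tbl, 1, function(r) paste(num_fmt(as.numeric(r), 8), collapse = "\t"))
  write_lines_atomic(c(hdr, rows), path)
}

#' Read ground reactions from a MOT file written by [write_grf_mot()]
#'
#' @param path MOT file path.
#' @return Named list of `ground_reaction` objects.
#' @export
read_grf_mot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) stop("malformed GRF MOT file '", path, "': missing endheader")
  hdr <- lines[seq_len(end[1] - 1)]
  m <- read_mot(path)
  df <- m$data
  prefixes <- unique(sub("_force_vx$", "", grep("_force_vx$", names(df), value = TRUE)))
  out <- list()
  for (p in prefixes) {
    ab_line <- grep(paste0("^appliedBody_", p, "="), hdr, value = TRUE)
    ab <- if (length(ab_line) > 0) sub(".*=", "", ab_line[1]) else p
    cols <- grf_col_names(p)
    if (!all(cols %in% names(df)))
      stop("GRF MOT file '", path, "' lacks the 9-column block for plate '", p, "'")
    out[[p]] <- ground_reaction(df$time,
                                force = as.matrix(df[, cols[1:3]]),
                                cop = as.matrix(df[, cols[4:6]]),
                                free_moment = as.matrix(df[, cols[7:9]]),
                                applied_body = ab)
  }
  out
}
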