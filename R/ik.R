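# Constrained inverse kinematics: per-frame weighted least-squares fit of
# model markers to observed world positions over the model's generalized
# coordinates.
#
# Solver: damped Gauss-Newton (Levenberg-Marquardt) with the analytic
# geometric Jacobian.  Accepted iterations never increase the objective;
# termination when the gradient infinity-norm drops below `grad_tol`, the
# step below `step_tol`, or after `max_iter` iterations (then flagged
# non-converged rather than returning a silent wrong answer).

#' Solve inverse kinematics for a single frame
#'
#' Minimizes `sum_i w_i || x_i_obs - x_i(q) ||^2` over the generalized
#' coordinates.  Targets containing any non-finite component are treated as
#' missing markers and excluded from the objective for this frame.
#'
#' @param model A `kinematic_model`.
#' @param targets Observed world marker positions: a 3 x M matrix with marker
#'   names as column names, or a named list of 3-vectors.  `NA` components
#'   mark missing markers.
#' @param weights Per-marker nonnegative weights: a single number or a named
#'   vector (default all 1).
#' @param q0 Initial guess (default all zero).
#' @param free Optional subset of coordinates to solve for (names or
#'   indices); the rest stay frozen at `q0`.
#' @param bounds Optional 2 x n matrix (or list with `lower`/`upper`) of soft
#'   per-coordinate bounds; steps are projected onto the box.
#' @param max_iter,grad_tol,step_tol Solver controls.
#' @return An `ik_result`: `q`, per-marker residual distances (m), total
#'   `objective` (m^2, recomputed at the returned `q`), `converged`,
#'   `iterations`.
#' @export
solve_frame <- function(model, targets, weights = NULL, q0 = NULL,
                        free = NULL, bounds = NULL,
                        max_iter = 100, grad_tol = 1e-10, step_tol = 1e-12) {
  if (!is.matrix(targets)) targets <- vapply(targets, as.numeric, numeric(3))
  usable <- colnames(targets)[colSums(!is.finite(targets)) == 0]
  usable <- intersect(usable, model$marker_names)
  if (length(usable) < 3)
    stop("under-determined IK problem: fewer than 3 usable markers")
  # Non-collinearity: centered targets must span a plane.
  X <- targets[, usable, drop = FALSE]
  sv <- svd(X - rowMeans(X))$d
  if (sv[2] < 1e-9)
    stop("under-determined IK problem: usable markers are collinear")

  nq <- n_coords(model)
  q <- if (is.null(q0)) rep(0, nq) else as.numeric(q0)
  if (length(q) != nq) stop("q0 has length ", length(q), ", expected ", nq)

  if (is.null(free)) free <- seq_len(nq)
  if (is.character(free)) free <- model$coord_index[free]
  free <- as.integer(free)

  w <- rep(1, length(usable)); names(w) <- usable
  if (!is.null(weights)) {
    if (length(weights) == 1 && is.null(names(weights))) {
      w[] <- weights
    } else {
      common <- intersect(names(weights), usable)
      w[common] <- weights[common]
    }
  }
  if (any(w < 0)) stop("marker weights must be nonnegative")
  sw3 <- rep(sqrt(w), each = 3)

  lower <- rep(-Inf, nq); upper <- rep(Inf, nq)
  if (!is.null(bounds)) {
    if (is.list(bounds)) { lower <- bounds$lower; upper <- bounds$upper }
    else { lower <- bounds[1, ]; upper <- bounds[2, ] }
  }
  clamp <- function(x) pmin(pmax(x, lower), upper)
  q <- clamp(q)

  resid <- function(qv) {
    pose <- forward_kinematics(model, qv)
    r <- as.vector(pose$markers[, usable, drop = FALSE] - X) * sw3
    list(pose = pose, r = r, f = sum(r^2))
  }

  cur <- resid(q)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- marker_jacobian(model, q, usable, pose = cur$pose)[, free, drop = FALSE] * sw3
    g <- 2 * crossprod(J, cur$r)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    dJ <- diag(JtJ)
    ridge <- 1e-12 * max(dJ, 1)
    accepted <- FALSE
    for (inner in 1:25) {
      H <- JtJ + diag(lambda * dJ + ridge, length(free))
      delta <- tryCatch(solve(H, -crossprod(J, cur$r)),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        q_new <- q
        q_new[free] <- q[free] + as.numeric(delta)
        q_new <- clamp(q_new)
        trial <- resid(q_new)
        if (trial$f <= cur$f) {
          step <- sqrt(sum((q_new - q)^2))
          q <- q_new; cur <- trial
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          if (step < step_tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 4
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE  # no descent direction: at a minimum
      break
    }
  }

  d <- sqrt(colSums((cur$pose$markers[, usable, drop = FALSE] - X)^2))
  residuals <- rep(NA_real_, ncol(targets))
  names(residuals) <- colnames(targets)
  residuals[usable] <- d
  names(q) <- coord_names(model)
  structure(list(q = q, residuals = residuals, objective = cur$f,
                 converged = converged, iterations = iter,
                 n_markers = length(usable)),
            class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat("<ik_result> objective ", format(x$objective, digits = 4), " m^2, ",
      x$iterations, " iterations, converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Solve inverse kinematics over a marker trajectory
#'
#' Frames are solved in order, each warm-started from the previous frame's
#' solution (the first from `q0`, typically the static-trial pose).  Missing
#' markers (NA triplets) are excluded per frame.
#'
#' @param model A `kinematic_model`.
#' @param marker_series A `marker_series`.
#' @param weights,free,... Passed to [solve_frame()].
#' @param q0 Initial guess for the first frame.
#' @return A `coordinate_trajectory`: `time`, `q` (frames x coordinates
#'   matrix, named columns), `rate`, plus per-frame `residual_rms` (m),
#'   `objective`, and `converged`.
#' @export
solve_trajectory <- function(model, marker_series, weights = NULL, q0 = NULL,
                             free = NULL, ...) {
  tN <- n_frames(marker_series)
  nq <- n_coords(model)
  qmat <- matrix(NA_real_, tN, nq, dimnames = list(NULL, coord_names(model)))
  rms <- numeric(tN); obj <- numeric(tN); conv <- logical(tN)
  q_prev <- q0
  for (f in seq_len(tN)) {
    targets <- frame_markers(marker_series, f)
    res <- tryCatch(
      solve_frame(model, targets, weights = weights, q0 = q_prev,
                  free = free, ...),
      error = function(e) stop("IK failed at frame ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    qmat[f, ] <- res$q
    rms[f] <- sqrt(mean(res$residuals[is.finite(res$residuals)]^2))
    obj[f] <- res$objective
    conv[f] <- res$converged
    q_prev <- res$q
  }
  coordinate_trajectory(time = marker_series$time, q = qmat,
                        rate = marker_series$rate,
                        residual_rms = rms, objective = obj, converged = conv)
}

#' Construct a coordinate trajectory
#'
#' @param time Time stamps (s), uniformly sampled.
#' @param q Frames x coordinates matrix (named columns; angles rad,
#'   translations m).
#' @param rate Sample rate (Hz); inferred from `time` when omitted.
#' @param ... Extra fields stored alongside (e.g. solver diagnostics).
#' @return A `coordinate_trajectory` object.
#' @export
coordinate_trajectory <- function(time, q, rate = NULL, ...) {
  q <- as.matrix(q)
  if (length(time) != nrow(q)) stop("time and q have mismatched lengths")
  if (is.null(rate)) rate <- if (length(time) > 1) 1 / mean(diff(time)) else NA_real_
  structure(c(list(time = as.numeric(time), q = q, rate = rate), list(...)),
            class = "coordinate_trajectory")
}

#' @export
print.coordinate_trajectory <- function(x, ...) {
  cat("<coordinate_trajectory> ", nrow(x$q), " frames x ", ncol(x$q),
      " coordinates @ ", format(x$rate, digits = 5), " Hz\n", sep = "")
  invisible(x)
}
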