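# Marker registration: position model markers so they coincide with the
# experimental markers at the static-trial pose.  Three methods are
# implemented: encoder registration (ground-truth joint angles), orientation
# registration (pose matched to marker-derived anatomical frames), and a
# stochastic simulated-user registration (manual placement surrogate).
#
# All three share the same final step: each model marker's local offset is
# recomputed so forward kinematics at the registration pose reproduces the
# experimental markers exactly.  The static marker residual is therefore
# ~zero for every method, regardless of how biased the pose is -- which is
# precisely why static marker error cannot diagnose registration error.

as_static_matrix <- function(static_markers) {
  if (inherits(static_markers, "marker_series")) average_markers(static_markers)
  else if (is.matrix(static_markers)) static_markers
  else vapply(static_markers, as.numeric, numeric(3))
}

run_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Recompute marker offsets so FK at a pose matches given world positions
#'
#' Each marker's local offset becomes the experimental world position mapped
#' through the inverse of its segment's world pose at `q_pose`; forward
#' kinematics at `q_pose` then reproduces the markers to machine precision.
#'
#' @param model A `kinematic_model`.
#' @param q_pose Coordinate vector of the registration pose.
#' @param static_markers 3 x M named matrix (m), `marker_series`, or named
#'   list: experimental marker positions.  Every name must be a model marker.
#' @return The model with updated marker offsets.
#' @export
place_markers_at_pose <- function(model, q_pose, static_markers) {
  X <- as_static_matrix(static_markers)
  unknown <- setdiff(colnames(X), model$marker_names)
  if (length(unknown) > 0)
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  pose <- forward_kinematics(model, q_pose)
  for (mn in colnames(X)) {
    s <- model$marker_segment[[mn]]
    inv <- t_inverse(new_transform(pose$segment_R[[s]], pose$segment_p[[s]]))
    model$markers[[mn]]$offset <- t_apply(inv, X[, mn])
  }
  precompute_model(model)
}

static_rmse <- function(model, q_pose, X) {
  pose <- forward_kinematics(model, q_pose)
  common <- intersect(colnames(X), colnames(pose$markers))
  sqrt(mean(colSums((pose$markers[, common, drop = FALSE] - X[, common, drop = FALSE])^2)))
}

registration_result <- function(registered_model, static_pose, method, rmse) {
  structure(list(registered_model = registered_model, static_pose = static_pose,
                 method = method, static_marker_rmse = rmse),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> method '", x$method, "', static marker RMSE ",
      format(x$static_marker_rmse, digits = 3), " m\n", sep = "")
  invisible(x)
}

# Solve the 6 root coordinates by least-squares pelvis-marker fit with all
# joint angles frozen.  Minimal completion for registration methods that
# know the joint angles but not the whole-body pose.
solve_root_pose <- function(model, X, q0) {
  pelvis_markers <- model$marker_names[model$marker_segment == "pelvis"]
  pelvis_markers <- intersect(pelvis_markers, colnames(X))
  res <- solve_frame(model, X[, pelvis_markers, drop = FALSE], q0 = q0,
                     free = seq_len(6))
  res$q
}

#' Encoder registration
#'
#' The model is posed with the ground-truth joint angles recorded by the
#' robot's encoders during the static trial; the 6 root coordinates, which
#' encoders cannot provide, are solved by a least-squares pelvis-marker fit
#' with the joint angles frozen.  Markers are then placed to match the
#' experimental positions exactly.
#'
#' @param model A `kinematic_model` (nominal marker offsets).
#' @param static_markers Experimental static markers (matrix, series, or
#'   named list).
#' @param encoder_q Named vector supplying every non-root coordinate (rad).
#' @return A `registration_result` with method `"encoder"`.
#' @export
encoder_register <- function(model, static_markers, encoder_q) {
  X <- as_static_matrix(static_markers)
  joint_coords <- coord_names(model)[-(1:6)]
  missing <- setdiff(joint_coords, names(encoder_q))
  if (length(missing) > 0)
    stop("encoder_q is missing channel(s): ", paste(missing, collapse = ", "))
  q <- stats::setNames(rep(0, n_coords(model)), coord_names(model))
  q[joint_coords] <- encoder_q[joint_coords]
  q <- solve_root_pose(model, X, q)
  registered <- place_markers_at_pose(model, q, X)
  registration_result(registered, q, "encoder", static_rmse(registered, q, X))
}

# Virtual frame points: origin + axis_length along each axis of a frame.
frame_points <- function(tf, axis_length = 0.1) {
  cbind(o = tf$p,
        x = tf$p + axis_length * tf$R[, 1],
        y = tf$p + axis_length * tf$R[, 2],
        z = tf$p + axis_length * tf$R[, 3])
}

# Initialize the root coordinates from a target pelvis world pose, assuming
# the fixture's free-joint convention (world-axis translations, then
# intrinsic Z-X-Y rotations, identity joint frames).  Falls back to zeros.
root_guess_from_pelvis <- function(model, pelvis_pose) {
  q <- rep(0, n_coords(model))
  rj <- model$joints[[model$root_joint]]
  axes <- vapply(rj$dofs[4:6], function(d) d$axis, numeric(3))
  std <- identical(unname(axes), unname(cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))))
  if (std && max(abs(rj$frame_in_parent$R - diag(3))) < 1e-12 &&
      max(abs(rj$frame_in_child$R - diag(3))) < 1e-12) {
    q[1:3] <- pelvis_pose$p
    q[4:6] <- euler_zxy_from_rot(pelvis_pose$R)
  }
  q
}

#' Orientation registration
#'
#' The proposed registration method: anatomical reference frames are built
#' from the experimental static markers, the model is posed so that its own
#' (specification-derived) anatomical frames best match them in the
#' least-squares sense, and markers are then placed to match the
#' experimental positions exactly.  Orientation tracking is realized through
#' virtual frame points -- for each framed segment, the frame origin and the
#' points 0.1 m along each frame axis become four unit-weight targets for
#' the marker-based solver (a swappable strategy).
#'
#' @param model A `kinematic_model`.
#' @param static_markers Experimental static markers.
#' @param frame_definitions A `frame_definitions` object with stored
#'   `model_frames` (anatomical-to-segment transforms).
#' @param axis_length Virtual axis point distance from the origin (m).
#' @param free Optional subset of coordinates to solve (names or indices);
#'   useful for partially framed toy models.
#' @return A `registration_result` with method `"orientation"`.
#' @export
orientation_register <- function(model, static_markers, frame_definitions,
                                 axis_length = 0.1, free = NULL) {
  X <- as_static_matrix(static_markers)
  frames <- frames_from_pose(frame_definitions, X)

  aug <- model
  targets <- NULL
  for (seg in names(frames)) {
    A <- frame_definitions$model_frames[[seg]]
    if (is.null(A))
      stop("frame definitions lack a model frame for segment '", seg, "'")
    local_pts <- frame_points(A, axis_length)
    nms <- paste0("__frame_", seg, "_", colnames(local_pts))
    for (i in seq_along(nms))
      aug$markers[[nms[i]]] <- list(segment = seg, offset = local_pts[, i])
    tp <- frame_points(frames[[seg]]$transform, axis_length)
    colnames(tp) <- nms
    targets <- cbind(targets, tp)
  }
  aug <- precompute_model(aug)

  q0 <- rep(0, n_coords(model))
  if (!is.null(frames$pelvis) && !is.null(frame_definitions$model_frames$pelvis)) {
    P <- t_compose(frames$pelvis$transform,
                   t_inverse(frame_definitions$model_frames$pelvis))
    q0 <- root_guess_from_pelvis(model, P)
  }
  res <- solve_frame(aug, targets, q0 = q0, free = free)
  if (!res$converged)
    warning("orientation registration pose solve did not converge")
  q <- res$q
  registered <- place_markers_at_pose(model, q, X)
  registration_result(registered, q, "orientation", static_rmse(registered, q, X))
}

#' Simulate manual (GUI) marker placement
#'
#' Stochastic surrogate for a human positioning model markers by eye: each
#' marker's local offset is perturbed by an independent isotropic Gaussian
#' with standard deviation `sigma` per axis.  Reproducible under `seed`.
#'
#' @param model A `kinematic_model` whose current offsets are treated as
#'   truth unless `true_offsets` is given.
#' @param true_offsets Optional named list of 3-vector offsets to perturb.
#' @param sigma Placement error SD per axis (m, >= 0).
#' @param seed Integer seed (one simulated user per seed).
#' @return The model with perturbed marker offsets.
#' @export
simulate_user_placement <- function(model, true_offsets = NULL, sigma = 0.01,
                                    seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(true_offsets)) {
    for (mn in names(true_offsets)) model$markers[[mn]]$offset <- true_offsets[[mn]]
  }
  run_with_seed(seed, {
    for (mn in model$marker_names) {
      model$markers[[mn]]$offset <- model$markers[[mn]]$offset +
        stats::rnorm(3, 0, sigma)
    }
  })
  precompute_model(model)
}

#' Inject a rigid marker-placement bias on one segment
#'
#' Rotates every marker offset of a segment about the segment origin --
#' a systematic misplacement of the whole marker cloud, as opposed to the
#' independent per-marker scatter of [simulate_user_placement()].  A rigid
#' cloud rotation biases the segment's estimated orientation by
#' approximately the injected rotation, producing near-constant joint-angle
#' offsets downstream.
#'
#' @param model A `kinematic_model`.
#' @param segment Segment name.
#' @param rotation 3x3 rotation matrix applied to the local offsets.
#' @return The model with rotated marker offsets.
#' @export
rotate_segment_markers <- function(model, segment, rotation) {
  if (!(segment %in% names(model$segments)))
    stop("unknown segment: ", segment)
  for (mn in model$marker_names) {
    if (model$markers[[mn]]$segment == segment)
      model$markers[[mn]]$offset <- as.numeric(rotation %*% model$markers[[mn]]$offset)
  }
  precompute_model(model)
}

#' User registration
#'
#' Completes registration for a model whose markers were placed manually
#' (with error): the pose is solved by full-marker least-squares IK using
#' the manual offsets, then markers are repositioned to match the
#' experimental static markers exactly.  The static residual is ~zero even
#' though the pose (and hence the registration) is biased.
#'
#' @param model_with_manual_markers A `kinematic_model` with (possibly
#'   erroneous) manual marker offsets.
#' @param static_markers Experimental static markers.
#' @param weights Optional per-marker IK weights.
#' @return A `registration_result` with method `"user"`.
#' @export
user_register <- function(model_with_manual_markers, static_markers,
                          weights = NULL) {
  model <- model_with_manual_markers
  X <- as_static_matrix(static_markers)
  q0 <- solve_root_pose(model, X, rep(0, n_coords(model)))
  res <- solve_frame(model, X, weights = weights, q0 = q0)
  if (!res$converged)
    warning("user registration pose solve did not converge")
  q <- res$q
  registered <- place_markers_at_pose(model, q, X)
  registration_result(registered, q, "user", static_rmse(registered, q, X))
}
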