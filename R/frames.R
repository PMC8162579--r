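# Anatomical reference frames built from marker subsets.
#
# A frame definition names an origin (marker or marker-pair midpoint), a
# primary direction (kept exact) and a secondary direction (orthogonalized
# against the primary by Gram-Schmidt); the third axis is the cross product
# that completes a right-handed frame.  The secondary direction may also be
# the normal of a three-marker plane (used for the foot).

resolve_point <- function(spec, points) {
  spec <- as.character(spec)
  missing <- setdiff(spec, colnames(points))
  if (length(missing) > 0)
    stop("missing marker(s) for frame construction: ",
         paste(missing, collapse = ", "))
  if (length(spec) == 1) points[, spec] else rowMeans(points[, spec, drop = FALSE])
}

axis_cycle <- c(x = "y", y = "z", z = "x")

#' Build one anatomical frame from marker positions
#'
#' @param definition A frame definition: list with `segment`, `origin`
#'   (marker name(s); midpoint if several), `primary` and `secondary`
#'   (each `list(label, from, to)` for a direction between points, or
#'   `list(label, plane = c(p1, p2, p3))` for a plane normal
#'   `(p2-p1) x (p3-p1)`).  `label` assigns the direction to the frame's
#'   x, y, or z axis; the primary direction is kept exact.
#' @param marker_positions Named 3-column-per-marker matrix (3 x M, columns
#'   named) or named list of 3-vectors, in any common frame.
#' @return An `anatomical_frame`: list with `segment` and `transform`
#'   (a [new_transform()] whose rotation is right-handed orthonormal).
#' @export
build_frame <- function(definition, marker_positions) {
  pts <- marker_positions
  if (!is.matrix(pts)) {
    pts <- vapply(marker_positions, as.numeric, numeric(3))
  }
  origin <- resolve_point(definition$origin, pts)

  dir_of <- function(ax) {
    if (!is.null(ax$plane)) {
      p <- lapply(ax$plane, function(nm) resolve_point(nm, pts))
      cross3(p[[2]] - p[[1]], p[[3]] - p[[1]])
    } else {
      resolve_point(ax$to, pts) - resolve_point(ax$from, pts)
    }
  }
  u <- normalize3(dir_of(definition$primary))
  v <- dir_of(definition$secondary)
  # Reject near-parallel defining directions (< 1 degree subtended).
  sin_angle <- sqrt(sum(cross3(u, normalize3(v))^2))
  if (sin_angle < sin(pi / 180))
    stop("degenerate frame for segment '", definition$segment,
         "': primary and secondary directions subtend less than 1 degree")
  v <- normalize3(v - sum(v * u) * u)

  lp <- definition$primary$label; ls <- definition$secondary$label
  lt <- setdiff(c("x", "y", "z"), c(lp, ls))
  cols <- list()
  cols[[lp]] <- u; cols[[ls]] <- v
  # Complete the right-handed triad: e_x = e_y x e_z (cyclically).
  cols[[lt]] <- cross3(cols[[axis_cycle[[lt]]]], cols[[axis_cycle[[axis_cycle[[lt]]]]]])
  R <- cbind(cols$x, cols$y, cols$z)
  structure(list(segment = definition$segment,
                 transform = new_transform(R, origin)),
            class = "anatomical_frame")
}

# Compute world positions of virtual points (e.g. hip joint centers).
# Model mode: from the known segment pose.  Measured mode: through the
# segment's already-built anatomical frame composed with the stored constant
# anatomical-to-segment transform (the model's reference-frame definition).
virtual_point_world <- function(vp, fd, built_frames, pose = NULL) {
  if (!is.null(pose)) {
    sp <- new_transform(pose$segment_R[[vp$segment]], pose$segment_p[[vp$segment]])
    return(t_apply(sp, vp$local))
  }
  fr <- built_frames[[vp$segment]]
  if (is.null(fr))
    stop("virtual point requires the '", vp$segment, "' frame to be built first")
  A <- fd$model_frames[[vp$segment]]
  if (is.null(A))
    stop("virtual point requires a stored model frame for segment '", vp$segment, "'")
  t_apply(fr$transform, t_apply(t_inverse(A), vp$local))
}

#' Build all defined anatomical frames from one set of marker positions
#'
#' Frames are built in definition order; virtual points (hip joint centers)
#' become available once their base segment's frame has been built.
#'
#' @param fd A `frame_definitions` object (see [robot_frame_definitions()]).
#' @param marker_positions 3 x M named matrix of world marker positions (m).
#' @param model,pose Optional: when supplied, virtual points are taken from
#'   the model's segment poses (model-side construction) instead of being
#'   derived through the pelvis anatomical frame (measured-side).
#' @return Named list of `anatomical_frame` objects, one per framed segment.
#' @export
frames_from_pose <- function(fd, marker_positions, model = NULL, pose = NULL) {
  pts <- marker_positions
  if (!is.matrix(pts)) pts <- vapply(marker_positions, as.numeric, numeric(3))
  frames <- list()
  if (!is.null(pose)) {
    for (nm in names(fd$virtual_points)) {
      pts <- cbind(pts, virtual_point_world(fd$virtual_points[[nm]], fd, frames, pose))
      colnames(pts)[ncol(pts)] <- nm
    }
  }
  pending_vp <- if (is.null(pose)) names(fd$virtual_points) else character(0)
  for (def in fd$frames) {
    frames[[def$segment]] <- build_frame(def, pts)
    if (length(pending_vp) > 0) {
      ready <- pending_vp[vapply(fd$virtual_points[pending_vp],
                                 function(v) !is.null(frames[[v$segment]]), logical(1))]
      for (nm in ready) {
        pts <- cbind(pts, virtual_point_world(fd$virtual_points[[nm]], fd, frames))
        colnames(pts)[ncol(pts)] <- nm
      }
      pending_vp <- setdiff(pending_vp, ready)
    }
  }
  frames
}

#' Anatomical frames from a static calibration trial
#'
#' Marker positions are time-averaged over the static trial (reducing
#' measurement noise by ~1/sqrt(frames)) before frame construction.
#'
#' @param model A `kinematic_model` (used to check marker names).
#' @param static_series A `marker_series` (see [marker_series()]) with at
#'   least one frame.
#' @param definitions A `frame_definitions` object.
#' @return Named list of `anatomical_frame` objects.
#' @export
frames_from_static <- function(model, static_series, definitions) {
  if (n_frames(static_series) < 1) stop("static trial has no frames")
  avg <- average_markers(static_series)
  frames_from_pose(definitions, avg)
}
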