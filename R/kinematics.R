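# Forward kinematics and analytic (geometric) Jacobians.

#' Forward kinematics
#'
#' Computes the world pose of every segment and the world position of every
#' marker for a given coordinate vector.  Pure function of `(model, q)`.
#' Joint motion is composed as intrinsic successive displacements about the
#' declared dof axes.
#'
#' @param model A `kinematic_model`.
#' @param q Numeric coordinate vector of length `n_coords(model)`
#'   (root translations m, root rotations rad, joint angles rad).
#' @return A `pose_solution`: list with `segment_R` / `segment_p` (named lists
#'   of world rotations and origins), `markers` (3 x M matrix of world marker
#'   positions, columns named), and per-dof world axes / points used by the
#'   Jacobian (`dof_axis`, `dof_point`).
#' @export
forward_kinematics <- function(model, q) {
  q <- as.numeric(q)
  nq <- n_coords(model)
  if (length(q) != nq)
    stop("coordinate vector has length ", length(q), ", model expects ", nq)

  seg_R <- list(); seg_p <- list()
  seg_R[["ground"]] <- diag(3); seg_p[["ground"]] <- c(0, 0, 0)
  dof_axis <- matrix(0, 3, nq); dof_point <- matrix(0, 3, nq)

  for (jn in model$joint_order) {
    j <- model$joints[[jn]]
    Rp <- seg_R[[j$parent]]; pp <- seg_p[[j$parent]]
    # Joint frame in world, before joint motion.
    R <- Rp %*% j$frame_in_parent$R
    p <- pp + as.numeric(Rp %*% j$frame_in_parent$p)
    cidx <- which(model$coords$joint == jn)
    for (k in seq_along(j$dofs)) {
      d <- j$dofs[[k]]; qi <- cidx[k]
      a_w <- as.numeric(R %*% d$axis)
      if (d$type == "translation") {
        p <- p + a_w * q[qi]
        dof_axis[, qi] <- a_w
        dof_point[, qi] <- p
      } else {
        dof_axis[, qi] <- a_w
        dof_point[, qi] <- p
        R <- R %*% rot_axis_angle(d$axis, q[qi])
      }
    }
    Xc_inv_R <- t(j$frame_in_child$R)
    seg_R[[j$child]] <- R %*% Xc_inv_R
    seg_p[[j$child]] <- p - as.numeric((R %*% Xc_inv_R) %*% j$frame_in_child$p)
  }

  M <- length(model$marker_names)
  markers <- matrix(NA_real_, 3, M, dimnames = list(NULL, model$marker_names))
  for (s in names(model$seg_markers)) {
    off <- model$seg_markers[[s]]
    markers[, colnames(off)] <- seg_R[[s]] %*% off + seg_p[[s]]
  }

  structure(list(segment_R = seg_R, segment_p = seg_p, markers = markers,
                 dof_axis = dof_axis, dof_point = dof_point),
            class = "pose_solution")
}

#' @export
print.pose_solution <- function(x, ...) {
  cat("<pose_solution> ", length(x$segment_R) - 1, " segments, ",
      ncol(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Analytic marker Jacobian
#'
#' Geometric Jacobian of world marker positions with respect to the
#' generalized coordinates: rotational columns are `axis x (marker - point)`,
#' translational columns are the axis itself; columns for dofs not on the
#' path from ground to the marker's segment are zero.
#'
#' @param model A `kinematic_model`.
#' @param q Coordinate vector, or a precomputed [forward_kinematics()] result
#'   via `pose`.
#' @param marker_subset Character vector of marker names (default: all).
#' @param pose Optional `pose_solution` at `q` to avoid recomputation.
#' @return A `(3*m) x n_coords` matrix; rows are grouped per marker (x, y, z).
#' @export
marker_jacobian <- function(model, q, marker_subset = NULL, pose = NULL) {
  if (is.null(pose)) pose <- forward_kinematics(model, q)
  mks <- marker_subset %||% model$marker_names
  unknown <- setdiff(mks, model$marker_names)
  if (length(unknown) > 0)
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  nq <- n_coords(model)
  J <- matrix(0, 3 * length(mks), nq)
  rot <- model$coords$type == "rotation"
  X <- pose$markers[, mks, drop = FALSE]
  aff <- model$coord_affects[, mks, drop = FALSE]
  for (qi in seq_len(nq)) {
    idx <- which(aff[qi, ])
    if (length(idx) == 0) next
    rows <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
    if (rot[qi]) {
      J[rows, qi] <- cross3_mat(pose$dof_axis[, qi],
                                X[, idx, drop = FALSE] - pose$dof_point[, qi])
    } else {
      J[rows, qi] <- pose$dof_axis[, qi]
    }
  }
  J
}
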