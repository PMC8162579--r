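# Kinematic-chain data model: rigid segments connected by low-DOF joints in a
# tree rooted at the ground, with optical markers attached to segments by
# constant local offsets.

#' Define a rigid segment
#'
#' @param name Segment identifier (unique within a model).
#' @param mass Segment mass in kg (>= 0).
#' @param com_local Position of the center of mass in the segment frame (m).
#' @param inertia_local Symmetric positive-semidefinite 3x3 inertia tensor
#'   about the COM, in the segment frame (kg m^2).
#' @return A `gait_segment` object.
#' @export
segment <- function(name, mass = 0,
                    com_local = c(0, 0, 0),
                    inertia_local = diag(0, 3)) {
  inertia_local <- matrix(as.numeric(inertia_local), 3, 3)
  structure(list(name = name, mass = as.numeric(mass),
                 com_local = as.numeric(com_local),
                 inertia_local = inertia_local),
            class = "gait_segment")
}

#' Define one joint degree of freedom
#'
#' @param name Coordinate name (unique within a model).
#' @param type Either `"rotation"` (about `axis`, rad) or `"translation"`
#'   (along `axis`, m).
#' @param axis Unit 3-vector in the joint frame.
#' @return A dof description list.
#' @export
dof <- function(name, type = c("rotation", "translation"), axis) {
  type <- match.arg(type)
  list(name = name, type = type, axis = as.numeric(axis))
}

#' Define a joint between two segments
#'
#' Joint motion is composed as intrinsic successive displacements about the
#' declared dof axes, applied in order, between a frame fixed in the parent
#' and a frame fixed in the child.  Translational dofs are only permitted in
#' the ground (root) joint, where they precede the rotations.
#'
#' @param name Joint identifier.
#' @param parent,child Segment names; the root joint has parent `"ground"`.
#' @param frame_in_parent,frame_in_child Rigid transforms (see
#'   [new_transform()]) locating the joint frame in the parent and child
#'   segment frames.
#' @param dofs List of [dof()] entries (0 to 6; an empty list is a weld).
#' @return A `gait_joint` object.
#' @export
joint <- function(name, parent, child,
                  frame_in_parent = new_transform(),
                  frame_in_child = new_transform(),
                  dofs = list()) {
  structure(list(name = name, parent = parent, child = child,
                 frame_in_parent = frame_in_parent,
                 frame_in_child = frame_in_child,
                 dofs = dofs),
            class = "gait_joint")
}

#' Assemble and validate a kinematic model
#'
#' Validates all structural invariants: the joint graph is a tree rooted at
#' ground, the root joint is a 6-DOF free joint (three translations followed
#' by three rotations), dof axes are unit length, consecutive axes within a
#' joint are non-parallel, masses are nonnegative, inertia tensors are
#' symmetric positive semidefinite, and marker names are unique model-wide.
#'
#' Generalized coordinates are ordered root translations (m), root rotations
#' (rad), then joint coordinates (rad) in joint declaration order.
#'
#' @param segments List of [segment()] objects.
#' @param joints List of [joint()] objects; the ground joint may appear
#'   anywhere in the list but its coordinates always come first.
#' @param markers Named list; each element is `list(segment =, offset =)`
#'   giving the marker's segment and constant local offset (m).
#' @param gravity Gravity vector in the ground frame (m/s^2).
#' @param name Optional model name.
#' @return A validated `kinematic_model` object.
#' @export
kinematic_model <- function(segments, joints, markers = list(),
                            gravity = c(0, -9.80665, 0),
                            name = "model") {
  seg_names <- vapply(segments, function(s) s$name, character(1))
  if (anyDuplicated(seg_names))
    stop("duplicate segment name: ", seg_names[duplicated(seg_names)][1])
  names(segments) <- seg_names

  for (s in segments) {
    if (s$mass < 0) stop("segment '", s$name, "': mass must be >= 0")
    I <- s$inertia_local
    if (max(abs(I - t(I))) > 1e-9)
      stop("segment '", s$name, "': inertia tensor must be symmetric")
    ev <- eigen((I + t(I)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9)
      stop("segment '", s$name, "': inertia tensor must be positive semidefinite")
  }

  jnt_names <- vapply(joints, function(j) j$name, character(1))
  if (anyDuplicated(jnt_names))
    stop("duplicate joint name: ", jnt_names[duplicated(jnt_names)][1])
  names(joints) <- jnt_names

  ground_joints <- jnt_names[vapply(joints, function(j) j$parent == "ground", logical(1))]
  if (length(ground_joints) != 1)
    stop("model must have exactly one joint with parent 'ground' (found ",
         length(ground_joints), ")")
  root_joint <- ground_joints[1]
  rj <- joints[[root_joint]]
  rtypes <- vapply(rj$dofs, function(d) d$type, character(1))
  if (!identical(rtypes, c(rep("translation", 3), rep("rotation", 3))))
    stop("root joint '", root_joint,
         "' must be a 6-DOF free joint: three translations followed by three rotations")

  for (j in joints) {
    if (j$parent != "ground" && !(j$parent %in% seg_names))
      stop("joint '", j$name, "': unknown parent segment '", j$parent, "'")
    if (!(j$child %in% seg_names))
      stop("joint '", j$name, "': unknown child segment '", j$child, "'")
    for (d in j$dofs) {
      if (abs(sqrt(sum(d$axis^2)) - 1) > 1e-9)
        stop("joint '", j$name, "', dof '", d$name, "': axis must be unit length")
      if (d$type == "translation" && j$name != root_joint)
        stop("joint '", j$name, "': translational dofs are only supported in the root joint")
    }
    if (length(j$dofs) >= 2) {
      for (k in seq_len(length(j$dofs) - 1)) {
        a <- j$dofs[[k]]$axis; b <- j$dofs[[k + 1]]$axis
        if (j$dofs[[k]]$type == "rotation" && j$dofs[[k + 1]]$type == "rotation" &&
            sqrt(sum(cross3(a, b)^2)) < 1e-9)
          stop("joint '", j$name, "': consecutive rotation axes are parallel")
      }
    }
    if (!is_rotation(j$frame_in_parent$R) || !is_rotation(j$frame_in_child$R))
      stop("joint '", j$name, "': joint frames must contain proper rotations")
  }

  # Tree check: each segment is the child of exactly one joint, reachable from
  # ground without cycles.
  child_of <- vapply(joints, function(j) j$child, character(1))
  if (anyDuplicated(child_of))
    stop("segment '", child_of[duplicated(child_of)][1],
         "' is the child of more than one joint (joint graph must be a tree)")
  orphans <- setdiff(seg_names, child_of)
  if (length(orphans) > 0)
    stop("segment(s) not attached by any joint: ", paste(orphans, collapse = ", "))

  # Topological order by BFS from ground.
  joint_order <- character(0)
  remaining <- jnt_names
  while (length(remaining) > 0) {
    nxt <- remaining[vapply(joints[remaining], function(j) {
      j$parent == "ground" || j$parent %in% vapply(joints[joint_order], function(x) x$child, character(1))
    }, logical(1))]
    if (length(nxt) == 0)
      stop("joint graph is not a tree rooted at ground (cycle or disconnected component)")
    joint_order <- c(joint_order, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  # Coordinate ordering: root joint first, then declaration order.
  coord_joints <- c(root_joint, setdiff(jnt_names, root_joint))
  coord_name <- character(0); coord_joint <- character(0)
  coord_type <- character(0); coord_dof <- integer(0)
  for (jn in coord_joints) {
    ds <- joints[[jn]]$dofs
    for (k in seq_along(ds)) {
      coord_name <- c(coord_name, ds[[k]]$name)
      coord_joint <- c(coord_joint, jn)
      coord_type <- c(coord_type, ds[[k]]$type)
      coord_dof <- c(coord_dof, k)
    }
  }
  if (anyDuplicated(coord_name))
    stop("duplicate coordinate name: ", coord_name[duplicated(coord_name)][1])

  # Markers.
  if (length(markers) > 0) {
    if (is.null(names(markers)) || any(names(markers) == ""))
      stop("markers must be a named list")
    if (anyDuplicated(names(markers)))
      stop("duplicate marker name: ", names(markers)[duplicated(names(markers))][1])
    for (mn in names(markers)) {
      m <- markers[[mn]]
      if (!(m$segment %in% seg_names))
        stop("marker '", mn, "': unknown segment '", m$segment, "'")
      if (length(m$offset) != 3)
        stop("marker '", mn, "': offset must be a 3-vector")
      markers[[mn]]$offset <- as.numeric(m$offset)
    }
  }

  model <- structure(list(
    name = name, segments = segments, joints = joints, markers = markers,
    gravity = as.numeric(gravity), root_joint = root_joint,
    joint_order = joint_order,
    coords = data.frame(name = coord_name, joint = coord_joint,
                        type = coord_type, dof = coord_dof,
                        stringsAsFactors = FALSE)
  ), class = "kinematic_model")
  model <- precompute_model(model)
  model
}

# Cached lookups used by the kinematics and dynamics hot loops.
precompute_model <- function(model) {
  seg_names <- names(model$segments)
  parent_joint <- vapply(seg_names, function(s) {
    hit <- vapply(model$joints, function(j) j$child == s, logical(1))
    names(model$joints)[hit]
  }, character(1))
  model$parent_joint <- parent_joint

  coord_idx <- seq_len(nrow(model$coords))
  names(coord_idx) <- model$coords$name
  model$coord_index <- coord_idx

  # Coordinate indices on the path root -> segment (ancestors incl. own joint).
  seg_coords <- list()
  for (s in seg_names) {
    idx <- integer(0)
    cur <- s
    while (cur != "ground") {
      jn <- parent_joint[[cur]]
      idx <- c(which(model$coords$joint == jn), idx)
      cur <- model$joints[[jn]]$parent
    }
    seg_coords[[s]] <- idx
  }
  model$seg_coords <- seg_coords

  # Markers grouped by segment as a 3xM local-offset matrix.
  seg_markers <- list()
  for (s in seg_names) {
    mn <- names(model$markers)[vapply(model$markers, function(m) m$segment == s, logical(1))]
    if (length(mn) > 0) {
      off <- vapply(model$markers[mn], function(m) m$offset, numeric(3))
      seg_markers[[s]] <- matrix(off, nrow = 3, dimnames = list(NULL, mn))
    }
  }
  model$seg_markers <- seg_markers
  model$marker_names <- names(model$markers)
  model$marker_segment <- vapply(model$markers, function(m) m$segment, character(1))

  # coordinate-by-marker incidence (TRUE where the coordinate moves the marker)
  nq <- nrow(model$coords)
  M <- length(model$marker_names)
  aff <- matrix(FALSE, nq, M, dimnames = list(NULL, model$marker_names))
  for (mi in seq_len(M))
    aff[seg_coords[[model$marker_segment[mi]]], mi] <- TRUE
  model$coord_affects <- aff
  model
}

#' Number of generalized coordinates of a model
#' @param model A `kinematic_model`.
#' @return Integer coordinate count (6 root + joint dofs).
#' @export
n_coords <- function(model) nrow(model$coords)

#' Coordinate names of a model, in canonical order
#' @param model A `kinematic_model`.
#' @return Character vector of coordinate names.
#' @export
coord_names <- function(model) model$coords$name

#' @export
print.kinematic_model <- function(x, ...) {
  cat("<kinematic_model> '", x$name, "'\n", sep = "")
  cat("  segments:   ", length(x$segments), "\n")
  cat("  joints:     ", length(x$joints), " (root: ", x$root_joint, ")\n", sep = "")
  cat("  coordinates:", n_coords(x), "\n")
  cat("  markers:    ", length(x$markers), "\n")
  invisible(x)
}

transform_to_json <- function(t) {
  list(rotation = apply(t$R, 1, function(r) as.list(r), simplify = FALSE),
       translation = as.list(t$p))
}

transform_from_json <- function(x, where) {
  if (is.null(x$rotation) || is.null(x$translation))
    stop("malformed transform at ", where, ": need 'rotation' and 'translation'")
  R <- do.call(rbind, lapply(x$rotation, function(r) as.numeric(unlist(r))))
  new_transform(R, as.numeric(unlist(x$translation)))
}

#' Save a kinematic model as JSON
#'
#' The schema is a JSON object with keys `schema_version`, `name`, `gravity`,
#' `segments`, `joints`, and `markers`; see the package vignette for the full
#' field-by-field description.
#'
#' @param model A `kinematic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    schema_version = "1.0",
    name = model$name,
    gravity = as.list(model$gravity),
    segments = lapply(unname(model$segments), function(s) list(
      name = s$name, mass = s$mass, com_local = as.list(s$com_local),
      inertia_local = apply(s$inertia_local, 1, as.list, simplify = FALSE))),
    joints = lapply(names(model$joints), function(jn) {
      j <- model$joints[[jn]]
      list(name = j$name, parent = j$parent, child = j$child,
           frame_in_parent = transform_to_json(j$frame_in_parent),
           frame_in_child = transform_to_json(j$frame_in_child),
           dofs = lapply(j$dofs, function(d)
             list(name = d$name, type = d$type, axis = as.list(d$axis))))
    }),
    markers = lapply(names(model$markers), function(mn) {
      m <- model$markers[[mn]]
      list(name = mn, segment = m$segment, offset = as.list(m$offset))
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Load a kinematic model from JSON
#'
#' @param path Path to a model JSON file conforming to the schema written by
#'   [save_model()] (`schema_version` "1.0").
#' @return A validated `kinematic_model`; all structural invariants are
#'   checked on load.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e)))
  for (key in c("schema_version", "segments", "joints"))
    if (is.null(doc[[key]]))
      stop("model file '", path, "' is missing required key '", key, "'")
  segs <- lapply(doc$segments, function(s) {
    if (is.null(s$name)) stop("segment entry missing 'name' in ", path)
    segment(s$name, mass = s$mass %||% 0,
            com_local = as.numeric(unlist(s$com_local %||% list(0, 0, 0))),
            inertia_local = if (is.null(s$inertia_local)) diag(0, 3) else
              do.call(rbind, lapply(s$inertia_local, function(r) as.numeric(unlist(r)))))
  })
  jnts <- lapply(doc$joints, function(j) {
    if (is.null(j$name)) stop("joint entry missing 'name' in ", path)
    joint(j$name, j$parent, j$child,
          frame_in_parent = transform_from_json(j$frame_in_parent, paste0("joint '", j$name, "'")),
          frame_in_child = transform_from_json(j$frame_in_child, paste0("joint '", j$name, "'")),
          dofs = lapply(j$dofs, function(d)
            dof(d$name, d$type, as.numeric(unlist(d$axis)))))
  })
  mks <- list()
  for (m in doc$markers %||% list()) {
    if (is.null(m$name) || is.null(m$segment))
      stop("marker entry missing 'name' or 'segment' in ", path)
    if (m$name %in% names(mks))
      stop("duplicate marker name '", m$name, "' in ", path)
    mks[[m$name]] <- list(segment = m$segment, offset = as.numeric(unlist(m$offset)))
  }
  kinematic_model(segs, jnts, markers = mks,
                  gravity = as.numeric(unlist(doc$gravity %||% list(0, -9.80665, 0))),
                  name = doc$name %||% "model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
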