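# Canonical child-sized humanoid-robot fixture: 12 lower-extremity DOFs
# (3 per hip, 1 per knee, 2 per ankle) plus a 6-DOF pelvis-to-ground root,
# and 35 optical markers (3 per foot/shank/thigh, 2 per knee/ankle flexion
# axis, 4 pelvis, 2 trunk, 3 head).
#
# The robot's published description does not include link lengths or inertial
# values; the numbers here are documented stand-ins chosen as plausible
# child-robot proportions (leg length ~0.51 m) sized so that a 0.33 m step
# at 0.4 m/s is comfortably within reach.  All values live in
# robot_geometry() so the fixture is reproducible and self-describing.

#' Geometric and inertial constants of the robot fixture
#'
#' @return A named list: segment lengths (m), hip spacing, ankle height,
#'   pelvis (hip-center) standing height, and total mass (kg).
#' @export
robot_geometry <- function() {
  list(
    thigh_length = 0.26,
    shank_length = 0.25,
    ankle_height = 0.04,   # ankle joint center above the sole
    hip_half_spacing = 0.08,
    foot_heel_x = -0.05,   # heel/toe extent in the foot frame
    foot_toe_x = 0.10,
    pelvis_height = 0.485, # standing hip-center height used by the gait generator
                           # (below full extension: bent-knee robot gait, and
                           # keeps the swing leg within reach at 0.33 m steps)
    total_mass = 12.0
  )
}

#' The canonical humanoid-robot fixture model
#'
#' Deterministic: two calls return identical models.  Left and right limbs
#' are mirror images about the sagittal (z = 0) plane.  Trunk and head are
#' welded to the pelvis (0-DOF joints), so the model has exactly
#' 6 + 12 = 18 generalized coordinates and 35 markers.
#'
#' Sign conventions (right-handed, Y up, X forward, Z to the robot's right):
#' positive rotation about Z is flexion (knee flexion is therefore negative),
#' positive rotation about X adducts the right leg and abducts the left, and
#' positive rotation about Y rotates the segment toward external rotation on
#' the left side.
#'
#' @return A validated `kinematic_model`.
#' @export
robot_fixture <- function() {
  g <- robot_geometry()
  lt <- g$thigh_length; ls <- g$shank_length; ha <- g$ankle_height
  hz <- g$hip_half_spacing

  segs <- list(
    segment("pelvis", mass = 2.5, com_local = c(0, 0.02, 0),
            inertia_local = diag(c(0.0104, 0.0137, 0.0074))),
    segment("torso", mass = 4.0, com_local = c(0, 0.12, 0),
            inertia_local = diag(c(0.0408, 0.0173, 0.0365))),
    segment("head", mass = 1.0, com_local = c(0, 0.10, 0),
            inertia_local = diag(c(0.00196, 0.00196, 0.00196))),
    segment("thigh_r", mass = 1.2, com_local = c(0, -lt / 2, 0),
            inertia_local = diag(c(0.00676, 0.0008, 0.00676))),
    segment("shank_r", mass = 0.8, com_local = c(0, -ls / 2, 0),
            inertia_local = diag(c(0.00417, 0.0005, 0.00417))),
    segment("foot_r", mass = 0.25, com_local = c(0.02, -0.025, 0),
            inertia_local = diag(c(0.000154, 0.00057, 0.00052))),
    segment("thigh_l", mass = 1.2, com_local = c(0, -lt / 2, 0),
            inertia_local = diag(c(0.00676, 0.0008, 0.00676))),
    segment("shank_l", mass = 0.8, com_local = c(0, -ls / 2, 0),
            inertia_local = diag(c(0.00417, 0.0005, 0.00417))),
    segment("foot_l", mass = 0.25, com_local = c(0.02, -0.025, 0),
            inertia_local = diag(c(0.000154, 0.00057, 0.00052)))
  )

  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  leg_joints <- function(side, zsign) {
    s <- side
    list(
      joint(paste0("hip_", s), "pelvis", paste0("thigh_", s),
            frame_in_parent = new_transform(p = c(0, 0, zsign * hz)),
            dofs = list(dof(paste0("hip_flexion_", s), "rotation", ez),
                        dof(paste0("hip_adduction_", s), "rotation", ex),
                        dof(paste0("hip_rotation_", s), "rotation", ey))),
      joint(paste0("knee_", s), paste0("thigh_", s), paste0("shank_", s),
            frame_in_parent = new_transform(p = c(0, -lt, 0)),
            dofs = list(dof(paste0("knee_flexion_", s), "rotation", ez))),
      joint(paste0("ankle_", s), paste0("shank_", s), paste0("foot_", s),
            frame_in_parent = new_transform(p = c(0, -ls, 0)),
            dofs = list(dof(paste0("ankle_flexion_", s), "rotation", ez),
                        dof(paste0("ankle_inversion_", s), "rotation", ex)))
    )
  }

  jnts <- c(
    list(joint("ground_pelvis", "ground", "pelvis",
               dofs = list(dof("pelvis_tx", "translation", ex),
                           dof("pelvis_ty", "translation", ey),
                           dof("pelvis_tz", "translation", ez),
                           dof("pelvis_tilt", "rotation", ez),
                           dof("pelvis_list", "rotation", ex),
                           dof("pelvis_rotation", "rotation", ey)))),
    leg_joints("r", +1),
    leg_joints("l", -1),
    list(joint("pelvis_torso", "pelvis", "torso",
               frame_in_parent = new_transform(p = c(-0.02, 0.10, 0))),
         joint("torso_head", "torso", "head",
               frame_in_parent = new_transform(p = c(0, 0.25, 0))))
  )

  mk <- function(seg, name, off) list(list(segment = seg, offset = off)) |> stats::setNames(name)
  leg_markers <- function(side, seg_suffix, zsign) {
    S <- toupper(side)
    c(
      # thigh: 3 tracking + 2 knee-axis (on the knee flexion axis)
      mk(paste0("thigh_", side), paste0(S, "TH1"), c(0.04, -0.10, zsign * 0.03)),
      mk(paste0("thigh_", side), paste0(S, "TH2"), c(0.03, -0.16, zsign * 0.04)),
      mk(paste0("thigh_", side), paste0(S, "TH3"), c(0.05, -0.20, zsign * 0.01)),
      mk(paste0("thigh_", side), paste0(S, "KNL"), c(0, -0.26, zsign * 0.045)),
      mk(paste0("thigh_", side), paste0(S, "KNM"), c(0, -0.26, -zsign * 0.045)),
      # shank: 3 tracking + 2 ankle-axis (on the ankle flexion axis)
      mk(paste0("shank_", side), paste0(S, "SK1"), c(0.03, -0.08, zsign * 0.03)),
      mk(paste0("shank_", side), paste0(S, "SK2"), c(0.02, -0.14, zsign * 0.04)),
      mk(paste0("shank_", side), paste0(S, "SK3"), c(0.04, -0.18, zsign * 0.02)),
      mk(paste0("shank_", side), paste0(S, "ANL"), c(0, -0.25, zsign * 0.035)),
      mk(paste0("shank_", side), paste0(S, "ANM"), c(0, -0.25, -zsign * 0.035)),
      # foot: heel, toe (medial, by the hallux) and fifth-metatarsal head
      # (lateral); spread to maximize the plane-defining triangle area
      mk(paste0("foot_", side), paste0(S, "HEE"), c(-0.05, -0.03, 0)),
      mk(paste0("foot_", side), paste0(S, "TOE"), c(0.09, -0.03, -zsign * 0.01)),
      mk(paste0("foot_", side), paste0(S, "MT5"), c(0.04, -0.03, zsign * 0.04))
    )
  }

  mks <- c(
    mk("pelvis", "RASI", c(0.07, 0.02, 0.07)),
    mk("pelvis", "LASI", c(0.07, 0.02, -0.07)),
    mk("pelvis", "RPSI", c(-0.07, 0.03, 0.04)),
    mk("pelvis", "LPSI", c(-0.07, 0.03, -0.04)),
    mk("torso", "STRN", c(0.05, 0.15, 0)),
    mk("torso", "C7", c(-0.05, 0.22, 0)),
    mk("head", "HDF", c(0.06, 0.08, 0)),
    mk("head", "HDR", c(0, 0.10, 0.06)),
    mk("head", "HDL", c(0, 0.10, -0.06)),
    leg_markers("r", "r", +1),
    leg_markers("l", "l", -1)
  )

  kinematic_model(segs, jnts, markers = mks, name = "robot_fixture")
}

#' Anatomical frame definitions for the robot fixture
#'
#' Kadaba-style constructions from the fixture's marker set: the pelvis frame
#' from the ASIS/PSIS markers, thigh and shank mediolateral axes from the
#' knee- and ankle-flexion-axis markers, thigh longitudinal axis toward the
#' hip joint center (taken from model geometry via the pelvis frame, not a
#' functional method), and foot frames from heel/toe/metatarsal markers.
#' The returned object also carries, per framed segment, the constant
#' anatomical-to-segment transform (`model_frames`) computed once from the
#' fixture's nominal marker offsets, which is what orientation registration
#' matches against.
#'
#' @return A `frame_definitions` list with elements `frames`,
#'   `virtual_points`, and `model_frames`.
#' @export
robot_frame_definitions <- function() {
  g <- robot_geometry()
  defs <- list(
    list(segment = "pelvis",
         origin = c("RASI", "LASI"),
         primary = list(label = "z", from = "LASI", to = "RASI"),
         secondary = list(label = "x", from = c("RPSI", "LPSI"), to = c("RASI", "LASI"))),
    list(segment = "thigh_r",
         origin = c("RKNL", "RKNM"),
         primary = list(label = "z", from = "RKNM", to = "RKNL"),
         secondary = list(label = "y", from = c("RKNL", "RKNM"), to = "R_HJC")),
    list(segment = "shank_r",
         origin = c("RANL", "RANM"),
         primary = list(label = "z", from = "RANM", to = "RANL"),
         secondary = list(label = "y", from = c("RANL", "RANM"), to = c("RKNL", "RKNM"))),
    list(segment = "foot_r",
         origin = "RHEE",
         primary = list(label = "x", from = "RHEE", to = "RTOE"),
         secondary = list(label = "y", plane = c("RHEE", "RMT5", "RTOE"))),
    list(segment = "thigh_l",
         origin = c("LKNL", "LKNM"),
         primary = list(label = "z", from = "LKNL", to = "LKNM"),
         secondary = list(label = "y", from = c("LKNL", "LKNM"), to = "L_HJC")),
    list(segment = "shank_l",
         origin = c("LANL", "LANM"),
         primary = list(label = "z", from = "LANL", to = "LANM"),
         secondary = list(label = "y", from = c("LANL", "LANM"), to = c("LKNL", "LKNM"))),
    list(segment = "foot_l",
         origin = "LHEE",
         primary = list(label = "x", from = "LHEE", to = "LTOE"),
         secondary = list(label = "y", plane = c("LHEE", "LTOE", "LMT5")))
  )

  fd <- structure(list(
    frames = defs,
    # Hip joint centers in pelvis segment coordinates (robot geometry).
    virtual_points = list(
      R_HJC = list(segment = "pelvis", local = c(0, 0, g$hip_half_spacing)),
      L_HJC = list(segment = "pelvis", local = c(0, 0, -g$hip_half_spacing))
    ),
    model_frames = NULL
  ), class = "frame_definitions")

  # Constant anatomical-to-segment transforms, computed from the fixture's
  # nominal marker offsets at the reference pose.  These encode the model's
  # own reference-frame definitions ("technical specifications").
  model <- robot_fixture()
  pose <- forward_kinematics(model, rep(0, n_coords(model)))
  frames <- frames_from_pose(fd, pose$markers, model, pose)
  mf <- list()
  for (seg in names(frames)) {
    sp <- new_transform(pose$segment_R[[seg]], pose$segment_p[[seg]])
    mf[[seg]] <- t_compose(t_inverse(sp), frames[[seg]]$transform)
  }
  fd$model_frames <- mf
  fd
}

#' Save / load frame definitions as JSON
#'
#' @param fd A `frame_definitions` object.
#' @param path File path.
#' @return `path` (save) or a `frame_definitions` object (load).
#' @export
save_frame_definitions <- function(fd, path) {
  doc <- list(
    schema_version = "1.0",
    frames = fd$frames,
    virtual_points = fd$virtual_points,
    model_frames = lapply(fd$model_frames, transform_to_json)
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname save_frame_definitions
#' @export
load_frame_definitions <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fix_pt <- function(x) if (is.list(x)) as.character(unlist(x)) else x
  frames <- lapply(doc$frames, function(f) {
    f$origin <- fix_pt(f$origin)
    for (k in c("primary", "secondary")) {
      if (!is.null(f[[k]]$from)) f[[k]]$from <- fix_pt(f[[k]]$from)
      if (!is.null(f[[k]]$to)) f[[k]]$to <- fix_pt(f[[k]]$to)
      if (!is.null(f[[k]]$plane)) f[[k]]$plane <- fix_pt(f[[k]]$plane)
    }
    f
  })
  vp <- lapply(doc$virtual_points, function(v)
    list(segment = v$segment, local = as.numeric(unlist(v$local))))
  mf <- lapply(doc$model_frames, transform_from_json, where = "model_frames")
  structure(list(frames = frames, virtual_points = vp, model_frames = mf),
            class = "frame_definitions")
}
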