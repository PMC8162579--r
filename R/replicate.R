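# Full study design on synthetic data: generate one experiment, register the
# model with the encoder, orientation, and simulated-user methods, run
# constrained IK (and optionally inverse dynamics) for each registered
# model, and tabulate per-DOF RMSE comparisons.

#' Replicate the registration comparison on a synthetic experiment
#'
#' Generates a synthetic trial, performs encoder registration, orientation
#' registration, and `n_users` seeded simulated-user registrations, then
#' evaluates each registered model against the known joint angles.  Joint
#' moments (when computed) are compared against the encoder-registered
#' model's moments, which stands in for moment ground truth.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_users Number of simulated users (default 5).
#' @param sigma_user Manual marker-placement error SD (m, default 0.010).
#' @param sigma_marker Optical measurement noise SD (m, default 0.0005).
#' @param spec A `gait_spec`.
#' @param ik_decimate Integer: run IK on every k-th frame (events and
#'   moments stay on the native grid).
#' @param compute_moments Compute and compare inverse-dynamics moments.
#' @param include_encoder Evaluate the encoder-registered model (always
#'   required when `compute_moments = TRUE`).
#' @return A `replicate_report`: `report` (Table-shaped data frame),
#'   `evals` (per-method evaluations), `summary` (mean RMSEs, per-DOF
#'   orientation-vs-user comparison), `config`.
#' @export
replicate_study <- function(seed = 1, n_users = 5, sigma_user = 0.010,
                            sigma_marker = 0.0005, spec = gait_spec(),
                            ik_decimate = 4, compute_moments = TRUE,
                            include_encoder = TRUE) {
  if (compute_moments) include_encoder <- TRUE
  trial <- make_dataset(spec, noise_sigma = sigma_marker, seed = seed)
  model <- robot_fixture()
  fd <- robot_frame_definitions()

  walk <- trial$markers
  if (sigma_marker > 0) walk <- filter_marker_series(walk)
  if (ik_decimate > 1) walk <- decimate_markers(walk, ik_decimate)

  regs <- list()
  if (include_encoder)
    regs$encoder <- encoder_register(model, trial$static_markers,
                                     trial$static_encoders)
  regs$orientation <- orientation_register(model, trial$static_markers, fd)
  user_regs <- lapply(seq_len(n_users), function(u) {
    manual <- simulate_user_placement(model, sigma = sigma_user,
                                      seed = seed * 100L + u)
    user_register(manual, trial$static_markers)
  })

  evals <- list()
  ref_moments <- NULL
  if (include_encoder) {
    evals$encoder <- evaluate_registration(regs$encoder, walk, trial$grf,
                                           trial$truth,
                                           compute_moments = compute_moments)
    if (compute_moments) ref_moments <- evals$encoder$moments
  }
  evals$orientation <- evaluate_registration(regs$orientation, walk, trial$grf,
                                             trial$truth,
                                             reference_moments = ref_moments)
  evals$users <- lapply(user_regs, function(r)
    evaluate_registration(r, walk, trial$grf, trial$truth,
                          reference_moments = ref_moments))

  dofs <- names(right_leg_dofs())
  user_angles <- vapply(evals$users, function(e) e$angle_rmse_deg,
                        numeric(length(dofs)))
  user_angle_mean <- rowMeans(user_angles)
  user_angle_sd <- apply(user_angles, 1, stats::sd)
  ori_angle <- evals$orientation$angle_rmse_deg

  report <- data.frame(row.names = c(dofs, "Marker error (mm)"))
  if (include_encoder)
    report$encoder_angle_deg <- c(evals$encoder$angle_rmse_deg, NA)
  report$orientation_angle_deg <- c(ori_angle, NA)
  report$user_angle_mean_deg <- c(user_angle_mean, NA)
  report$user_angle_sd_deg <- c(user_angle_sd, NA)
  if (compute_moments) {
    user_moments <- vapply(evals$users, function(e) e$moment_rmse_Nm,
                           numeric(length(dofs)))
    report$orientation_moment_Nm <- c(evals$orientation$moment_rmse_Nm, NA)
    report$user_moment_mean_Nm <- c(rowMeans(user_moments), NA)
    report$user_moment_sd_Nm <- c(apply(user_moments, 1, stats::sd), NA)
  }
  mk <- "Marker error (mm)"
  if (include_encoder)
    report[mk, "encoder_angle_deg"] <- evals$encoder$marker_rmse_mean_mm
  report[mk, "orientation_angle_deg"] <- evals$orientation$marker_rmse_mean_mm
  report[mk, "user_angle_mean_deg"] <-
    mean(vapply(evals$users, function(e) e$marker_rmse_mean_mm, numeric(1)))
  report[mk, "user_angle_sd_deg"] <-
    mean(vapply(evals$users, function(e) e$marker_rmse_sd_mm, numeric(1)))

  n_better <- sum(ori_angle < user_angle_mean)
  summary <- list(
    n_dofs = length(dofs),
    n_dofs_orientation_better = n_better,
    orientation_mean_angle_rmse_deg = mean(ori_angle),
    user_mean_angle_rmse_deg = mean(user_angle_mean),
    angle_rmse_reduction_pct =
      100 * (1 - mean(ori_angle) / mean(user_angle_mean)),
    orientation_marker_rmse_mm = evals$orientation$marker_rmse_mean_mm,
    user_marker_rmse_mm = report[mk, "user_angle_mean_deg"]
  )
  if (compute_moments) {
    summary$orientation_mean_moment_rmse_Nm <-
      mean(evals$orientation$moment_rmse_Nm)
    summary$user_mean_moment_rmse_Nm <- mean(rowMeans(user_moments))
    summary$moment_rmse_reduction_pct <-
      100 * (1 - summary$orientation_mean_moment_rmse_Nm /
               summary$user_mean_moment_rmse_Nm)
  }

  structure(list(report = report, evals = evals, summary = summary,
                 config = list(seed = seed, n_users = n_users,
                               sigma_user = sigma_user,
                               sigma_marker = sigma_marker,
                               ik_decimate = ik_decimate,
                               spec = unclass(spec))),
            class = "replicate_report")
}

#' @export
print.replicate_report <- function(x, ...) {
  cat("<replicate_report> seed ", x$config$seed, ", ", x$config$n_users,
      " users, sigma_user ", x$config$sigma_user * 1000, " mm\n", sep = "")
  print(round(x$report, 2))
  cat("orientation better than user mean in ",
      x$summary$n_dofs_orientation_better, "/", x$summary$n_dofs,
      " right-leg DOFs\n", sep = "")
  invisible(x)
}

#' Ensemble of study replications
#'
#' Repeats [replicate_study()] over `n_reps` seeds and counts in how many
#' repetitions orientation registration beats the user-registration mean in
#' at least `min_dofs` of the 6 right-leg DOFs.
#'
#' @param n_reps Number of repetitions.
#' @param base_seed Seed of the first repetition (rep i uses
#'   `base_seed + i - 1`).
#' @param min_dofs Per-repetition success threshold (default 5 of 6).
#' @param ... Passed to [replicate_study()] (moments and the encoder
#'   evaluation are skipped by default for speed).
#' @return List with `n_better` (per-rep DOF counts), `successes`,
#'   `n_reps`, and the per-rep summaries.
#' @export
registration_ensemble <- function(n_reps = 10, base_seed = 1, min_dofs = 5, ...) {
  args <- list(...)
  reps <- lapply(seq_len(n_reps), function(i) {
    do.call(replicate_study,
            c(list(seed = base_seed + i - 1L, compute_moments = FALSE,
                   include_encoder = FALSE), args))
  })
  n_better <- vapply(reps, function(r) r$summary$n_dofs_orientation_better,
                     numeric(1))
  list(n_better = n_better,
       successes = sum(n_better >= min_dofs),
       n_reps = n_reps,
       summaries = lapply(reps, function(r) r$summary))
}
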