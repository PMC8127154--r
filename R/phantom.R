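#' Digital head phantom specification
#'
#' A labelled 3D phantom with ellipsoidal grey matter, white matter and CSF
#' compartments and two task ROIs (bilateral auditory cortex, left motor
#' cortex) embedded in grey matter. Tissue parameters are proton density
#' (arbitrary units) and effective transverse relaxation rate R2* (1/s);
#' defaults use literature-order 3 T values (T2*: GM 66 ms, WM 53 ms,
#' CSF 150 ms). The activation table gives the peak task-induced change in
#' R2* (1/s, negative for a BOLD signal increase) per (ROI, condition).
#'
#' @param grid_shape voxels per axis (scalar, >= 16).
#' @param voxel_size isotropic voxel size in mm.
#' @param tissue_params named list \code{gm/wm/csf/background}, each a list
#'   with \code{pd} and \code{t2star} (seconds; ignored for background).
#' @param rois named list of ROI definitions, each with \code{centre}
#'   (fractional coordinates in [0,1]^3) and \code{radius} (fraction of grid).
#' @param activation_table data frame with columns \code{roi},
#'   \code{condition}, \code{amplitude} (peak delta-R2* in 1/s).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = 32L, voxel_size = 4,
                         tissue_params = list(
                           gm = list(pd = 0.80, t2star = 0.066),
                           wm = list(pd = 0.70, t2star = 0.053),
                           csf = list(pd = 1.00, t2star = 0.150),
                           background = list(pd = 0, t2star = NA)),
                         rois = list(
                           auditory = list(centre = rbind(c(0.17, 0.5, 0.45),
                                                          c(0.83, 0.5, 0.45)),
                                           radius = 0.075),
                           motor = list(centre = rbind(c(0.35, 0.42, 0.80)),
                                        radius = 0.08)),
                         activation_table = default_activation_table()) {
  if (grid_shape < 16L) stop("grid_shape must be >= 16 per axis")
  if (tissue_params$background$pd != 0)
    stop("background proton density must be 0")
  for (tis in c("gm", "wm", "csf"))
    if (tissue_params[[tis]]$t2star <= 0)
      stop("t2star must be positive for tissue ", tis)
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
               tissue_params = tissue_params, rois = rois,
               activation_table = activation_table)
  class(spec) <- "phantom_spec"
  spec
}

#' Default task activation table
#'
#' Peak delta-R2* amplitudes (1/s; negative = BOLD signal increase) used by
#' the phantom: the auditory ROI responds to every tone with larger responses
#' to rare Deviant/Novel tones; the motor ROI responds to the button press
#' accompanying Deviant and Novel tones.
#'
#' @return A data frame with columns \code{roi}, \code{condition},
#'   \code{amplitude}.
#' @export
default_activation_table <- function() {
  data.frame(
    roi = c("auditory", "auditory", "auditory", "motor", "motor"),
    condition = c("standard", "deviant", "novel", "deviant", "novel"),
    amplitude = c(-0.06, -0.12, -0.12, -0.08, -0.08),
    stringsAsFactors = FALSE)
}

ellipsoid_mask <- function(n, centre, semi) {
  ax <- (seq_len(n) - centre[1]) / semi[1]
  ay <- (seq_len(n) - centre[2]) / semi[2]
  az <- (seq_len(n) - centre[3]) / semi[3]
  outer(outer(ax^2, ay^2, `+`), az^2, `+`) <= 1
}

#' Build a labelled head phantom
#'
#' Constructs the label volume plus proton-density and R2* maps from a
#' \code{\link{phantom_spec}}. ROIs are spherical connected components carved
#' out of the grey-matter shell; an ROI placed outside grey matter is a
#' configuration error.
#'
#' @param spec a \code{phantom_spec}.
#' @return An object of class \code{head_phantom}: list with \code{labels}
#'   (integer array; 0 background, 1 gm, 2 wm, 3 csf), \code{pd} and
#'   \code{r2star} arrays, \code{gm_mask}, \code{roi_masks} (named list of
#'   logical arrays, subsets of grey matter), \code{voxel_size}, \code{spec}.
#' @export
build_phantom <- function(spec) {
  n <- spec$grid_shape
  ctr <- rep((n + 1) / 2, 3)
  brain <- ellipsoid_mask(n, ctr, c(0.44, 0.46, 0.42) * n)
  wm <- ellipsoid_mask(n, ctr, c(0.24, 0.26, 0.22) * n)
  csf <- ellipsoid_mask(n, ctr, c(0.08, 0.10, 0.07) * n)
  wm <- wm & !csf
  gm <- brain & !wm & !csf
  labels <- array(0L, dim = c(n, n, n))
  labels[gm] <- 1L; labels[wm] <- 2L; labels[csf] <- 3L
  roi_masks <- list()
  for (nm in names(spec$rois)) {
    def <- spec$rois[[nm]]
    m <- array(FALSE, dim = c(n, n, n))
    for (i in seq_len(nrow(def$centre))) {
      c_vox <- def$centre[i, ] * n
      m <- m | ellipsoid_mask(n, c_vox, rep(def$radius * n, 3))
    }
    if (any(m & !gm))
      stop("ROI '", nm, "' extends outside grey matter (",
           sum(m & !gm), " voxels); adjust centre/radius")
    roi_masks[[nm]] <- m
  }
  tp <- spec$tissue_params
  pd <- array(0, dim = c(n, n, n))
  r2 <- array(0, dim = c(n, n, n))
  pd[gm] <- tp$gm$pd;  r2[gm] <- 1 / tp$gm$t2star
  pd[wm] <- tp$wm$pd;  r2[wm] <- 1 / tp$wm$t2star
  pd[csf] <- tp$csf$pd; r2[csf] <- 1 / tp$csf$t2star
  ph <- list(labels = labels, pd = pd, r2star = r2, gm_mask = gm,
             roi_masks = roi_masks, voxel_size = spec$voxel_size, spec = spec)
  class(ph) <- "head_phantom"
  ph
}

#' @export
print.head_phantom <- function(x, ...) {
  n <- dim(x$labels)
  cat("head_phantom:", paste(n, collapse = "x"), "voxels at",
      x$voxel_size, "mm;",
      sum(x$labels == 1L), "gm,", sum(x$labels == 2L), "wm,",
      sum(x$labels == 3L), "csf voxels; ROIs:",
      paste(sprintf("%s=%d", names(x$roi_masks),
                    vapply(x$roi_masks, sum, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a noise-free multi-echo BOLD series over the phantom
#'
#' Per-voxel signal model \eqn{S(TE, t) = PD \exp(-TE (R2^* + \Delta
#' R2^*(t)))}. The task-induced \eqn{\Delta R2^*(t)} in each ROI is the sum
#' over conditions of the peak amplitude times the HRF-convolved event
#' regressor (peak-normalized for an isolated event), so the FID channel
#' (TE = 0) carries no task contrast and the fractional signal change at echo
#' TE is \eqn{1 - \exp(TE \cdot |\Delta R2^*|)} at the response peak.
#'
#' Volumes are evaluated lazily: the object stores per-ROI delta-R2* time
#' courses; use \code{\link{ideal_volume}} or \code{\link{ideal_array}} to
#' materialize images.
#'
#' @param phantom a \code{head_phantom}.
#' @param schedule an \code{oddball_schedule} covering the scan.
#' @param TR repetition time (s).
#' @param TEs echo times (s); must be non-empty.
#' @param n_volumes number of volumes.
#' @param activation_table overrides the phantom's activation table.
#' @param amp_scale scalar gain applied to all activation amplitudes (used
#'   for subject/session variation).
#' @return An object of class \code{ideal_series}.
#' @export
simulate_bold_series <- function(phantom, schedule, TR, TEs, n_volumes,
                                 activation_table = phantom$spec$activation_table,
                                 amp_scale = 1) {
  if (length(TEs) == 0) stop("TE list must be non-empty")
  sched_dur <- max(schedule$events$onset + schedule$events$duration)
  if (sched_dur < TR * n_volumes - TR)
    warning("schedule (", round(sched_dur, 1),
            " s) is shorter than the scan (", TR * n_volumes, " s)")
  rois <- names(phantom$roi_masks)
  delta <- matrix(0, nrow = n_volumes, ncol = length(rois),
                  dimnames = list(NULL, rois))
  at <- activation_table
  for (i in seq_len(nrow(at))) {
    roi <- at$roi[i]
    if (!(roi %in% rois)) stop("activation table references unknown ROI ", roi)
    reg <- condition_regressor(schedule, at$condition[i], TR, n_volumes)
    delta[, roi] <- delta[, roi] + amp_scale * at$amplitude[i] * reg
  }
  s <- list(phantom = phantom, TR = TR, TEs = TEs,
            n_volumes = as.integer(n_volumes), roi_delta = delta,
            amp_scale = amp_scale, activation_table = at)
  class(s) <- "ideal_series"
  s
}

#' Materialize one volume of an ideal series
#'
#' @param series an \code{ideal_series}.
#' @param echo echo index (1-based into \code{series$TEs}).
#' @param vol volume index (1-based).
#' @return 3D numeric array of signal values.
#' @export
ideal_volume <- function(series, echo, vol) {
  te <- series$TEs[echo]
  ph <- series$phantom
  v <- ph$pd * exp(-te * ph$r2star)
  for (roi in colnames(series$roi_delta)) {
    d <- series$roi_delta[vol, roi]
    if (d != 0) {
      m <- ph$roi_masks[[roi]]
      v[m] <- v[m] * exp(-te * d)
    }
  }
  v
}

#' Materialize an ideal series echo as a 4D array
#'
#' @param series an \code{ideal_series}.
#' @param echo echo index.
#' @return 4D array (x, y, z, t).
#' @export
ideal_array <- function(series, echo) {
  d <- dim(series$phantom$pd)
  out <- array(0, dim = c(d, series$n_volumes))
  for (t in seq_len(series$n_volumes))
    out[, , , t] <- ideal_volume(series, echo, t)
  out
}

#' Cohort specification with subject/session variance components
#'
#' Describes a test-retest cohort: each subject has a multiplicative
#' activation gain \eqn{1 + a_i + b_{is}} with \eqn{a_i \sim N(0,
#' \sigma_s^2)} drawn once per subject (shared across sessions) and
#' \eqn{b_{is} \sim N(0, \sigma_e^2)} drawn per session. The analytic
#' ground-truth consistency ICC of the gains is
#' \eqn{\sigma_s^2 / (\sigma_s^2 + \sigma_e^2)}.
#'
#' @param n_subjects number of subjects (>= 2); default 12.
#' @param n_sessions number of sessions (>= 2 for reliability analyses);
#'   default 2.
#' @param subject_amp_sd SD of the subject gain component (fraction of the
#'   mean activation amplitude).
#' @param session_amp_sd SD of the session gain component.
#' @param noise_sd thermal noise SD in signal units (consumed by the
#'   acquisition simulators).
#' @param drift_coeffs polynomial drift coefficients (see
#'   \code{\link{simulate_epi_series}}).
#' @param ar1_rho lag-1 autocorrelation of the acquisition noise, in [0, 1).
#' @param seed RNG seed for cohort draws.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 12L, n_sessions = 2L,
                        subject_amp_sd = 0.2, session_amp_sd = 0.1,
                        noise_sd = 0.005, drift_coeffs = c(0, 0.002, 0.001),
                        ar1_rho = 0.3, seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (n_sessions < 2L) stop("n_sessions must be >= 2 for reliability analyses")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  sp <- list(n_subjects = as.integer(n_subjects),
             n_sessions = as.integer(n_sessions),
             subject_amp_sd = subject_amp_sd, session_amp_sd = session_amp_sd,
             noise_sd = noise_sd, drift_coeffs = drift_coeffs,
             ar1_rho = ar1_rho, seed = as.integer(seed))
  class(sp) <- "cohort_spec"
  sp
}

#' Simulate a cohort of ideal series with variance components
#'
#' Draws per-subject and per-session activation gains, builds one ideal
#' series per subject and session, and records every drawn value in a
#' manifest together with the analytic ground-truth ICC of the gains.
#'
#' @param phantom a \code{head_phantom}.
#' @param cohort a \code{cohort_spec}.
#' @param schedule_factory function(session) returning the
#'   \code{oddball_schedule} for that session (the task design is typically
#'   shared across subjects).
#' @param TR,TEs,n_volumes scan parameters passed to
#'   \code{\link{simulate_bold_series}}.
#' @return A list with \code{ideal} (list of lists, \code{[[subject]]
#'   [[session]]}), \code{manifest} (data frame: subject, session,
#'   subject_effect, session_effect, amp_scale), and \code{truth_icc}.
#' @export
simulate_cohort <- function(phantom, cohort, schedule_factory,
                            TR, TEs, n_volumes) {
  set.seed(cohort$seed)
  a <- stats::rnorm(cohort$n_subjects, 0, cohort$subject_amp_sd)
  b <- matrix(stats::rnorm(cohort$n_subjects * cohort$n_sessions, 0,
                           cohort$session_amp_sd),
              nrow = cohort$n_subjects)
  schedules <- lapply(seq_len(cohort$n_sessions), schedule_factory)
  ideal <- vector("list", cohort$n_subjects)
  rows <- list()
  for (i in seq_len(cohort$n_subjects)) {
    ideal[[i]] <- vector("list", cohort$n_sessions)
    for (s in seq_len(cohort$n_sessions)) {
      g <- 1 + a[i] + b[i, s]
      ideal[[i]][[s]] <- simulate_bold_series(
        phantom, schedules[[s]], TR, TEs, n_volumes, amp_scale = g)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, session = s, subject_effect = a[i],
        session_effect = b[i, s], amp_scale = g)
    }
  }
  truth <- cohort$subject_amp_sd^2 /
    (cohort$subject_amp_sd^2 + cohort$session_amp_sd^2)
  list(ideal = ideal, manifest = do.call(rbind, rows), truth_icc = truth,
       cohort = cohort, schedules = schedules)
}
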