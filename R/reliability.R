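# Two-way consistency ICC(3,1) from an n x k table (rows = targets,
# columns = raters/sessions): mean squares from the two-way model with
# subject and session main effects,
#   ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS),
# BMS = between-target mean square, EMS = residual (interaction) mean square.
icc31_table <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  den <- bms + (k - 1) * ems
  icc <- if (den > 0) (bms - ems) / den else NA_real_
  c(icc = icc, bms = bms, ems = ems)
}

#' Voxel-wise ICC(3,1) test-retest reliability map
#'
#' Consistency-type intra-class correlation per voxel from subject-by-session
#' contrast maps: per voxel, BMS is the between-subject mean square and EMS
#' the residual mean square of the two-way (subject + session) decomposition,
#' and \eqn{ICC(3,1) = (BMS - EMS)/(BMS + (k-1) EMS)}. An ICC of 1 indicates
#' perfect between-session reliability (EMS = 0); values approach -1 when
#' session-by-subject variation dominates and between-subject variance
#' vanishes. Degenerate voxels (zero denominator) are masked out.
#'
#' @param maps array indexed (x, y, z, subject, session), or a matrix
#'   (subjects x sessions) for a single "voxel".
#' @param mask optional logical 3D array restricting the computation.
#' @return An object of class \code{icc_map}: list with \code{icc},
#'   \code{bms}, \code{ems} (3D arrays), \code{mask}, \code{k}. For matrix
#'   input the arrays are length-1.
#' @export
icc31_map <- function(maps, mask = NULL) {
  if (is.matrix(maps)) maps <- array(maps, c(1L, 1L, 1L, dim(maps)))
  if (length(dim(maps)) != 5L)
    stop("maps must be indexed (x, y, z, subject, session)")
  if (anyNA(maps)) stop("missing cells in the subject x session table")
  d <- dim(maps)
  n <- d[4]; k <- d[5]
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 sessions")
  nvox <- prod(d[1:3])
  Y <- matrix(maps, nvox, n * k)  # voxel x (subject, session) col-major
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.vector(mask))
  icc <- bms <- ems <- rep(NA_real_, nvox)
  # vectorized two-way mean squares across voxels
  Yv <- Y[vox, , drop = FALSE]
  subj_means <- matrix(0, length(vox), n)
  sess_means <- matrix(0, length(vox), k)
  for (s in seq_len(k))
    sess_means[, s] <- rowMeans(Yv[, (s - 1L) * n + seq_len(n), drop = FALSE])
  for (i in seq_len(n))
    subj_means[, i] <- rowMeans(Yv[, i + (seq_len(k) - 1L) * n, drop = FALSE])
  gm <- rowMeans(Yv)
  ss_rows <- k * rowSums((subj_means - gm)^2)
  ss_cols <- n * rowSums((sess_means - gm)^2)
  ss_tot <- rowSums((Yv - gm)^2)
  ss_err <- pmax(ss_tot - ss_rows - ss_cols, 0)
  bms_v <- ss_rows / (n - 1)
  ems_v <- ss_err / ((n - 1) * (k - 1))
  den <- bms_v + (k - 1) * ems_v
  icc_v <- ifelse(den > 0, (bms_v - ems_v) / den, NA_real_)
  icc[vox] <- icc_v; bms[vox] <- bms_v; ems[vox] <- ems_v
  valid <- array(FALSE, d[1:3]); valid[vox] <- den > 0
  out <- list(icc = array(icc, d[1:3]), bms = array(bms, d[1:3]),
              ems = array(ems, d[1:3]), mask = valid, k = k, n = n)
  class(out) <- "icc_map"
  out
}

#' Task-network mask and median ICC
#'
#' The network mask is the grey-matter mask intersected with voxels whose
#' session-1 group T-score exceeds a deliberately low threshold (default 1),
#' so that cluster extent differences between modalities do not bias the
#' mask. \code{median_icc} then summarizes the ICC map over that mask.
#'
#' @param session1_group_tmap 3D array of group T-scores from session 1.
#' @param t_threshold threshold applied to the T-map (default 1).
#' @param gm_mask logical grey-matter mask.
#' @return \code{network_mask}: logical 3D array. \code{median_icc}: scalar.
#' @export
network_mask <- function(session1_group_tmap, t_threshold = 1, gm_mask) {
  if (!identical(dim(session1_group_tmap), dim(gm_mask)))
    stop("T-map and grey-matter mask are on different grids")
  m <- gm_mask & !is.na(session1_group_tmap) &
    (session1_group_tmap > t_threshold)
  if (!any(m)) stop("network mask is empty")
  m
}

#' @rdname network_mask
#' @param iccmap an \code{icc_map}.
#' @param mask logical 3D array over which to take the median.
#' @export
median_icc <- function(iccmap, mask) {
  v <- iccmap$icc[mask & iccmap$mask]
  if (length(v) == 0L) stop("no valid ICC voxels inside the mask")
  stats::median(v)
}

#' Intra-voxel reliability for one subject
#'
#' Applies the ICC(3,1) decomposition with the ROI voxels as rows and the
#' sessions as columns, yielding one scalar per subject that measures how
#' consistently the spatial pattern of the contrast within the ROI is
#' reproduced across sessions. Invariant to per-session additive offsets and
#' to a common positive rescaling. Returns NA when the ROI pattern carries no
#' voxel-to-voxel variance.
#'
#' @param session_maps list (or 4D array x,y,z,session) of the subject's
#'   contrast maps across sessions.
#' @param roi logical array with >= 10 voxels.
#' @return Scalar ICC_v (NA when undefined).
#' @export
intravoxel_icc <- function(session_maps, roi) {
  if (is.array(session_maps) && length(dim(session_maps)) == 4L)
    session_maps <- lapply(seq_len(dim(session_maps)[4]),
                           function(s) session_maps[, , , s])
  if (length(session_maps) < 2L) stop("need >= 2 sessions")
  vox <- which(as.vector(roi))
  if (length(vox) < 10L) stop("ROI must contain at least 10 voxels")
  y <- vapply(session_maps, function(m) as.vector(m)[vox],
              numeric(length(vox)))
  r <- icc31_table(y)
  den <- r["bms"] + (ncol(y) - 1) * r["ems"]
  if (!is.finite(r["icc"]) || den <= 0) return(NA_real_)
  unname(r["icc"])
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (midranks for tied |d|; zeros dropped per the standard
# convention). Used for n <= 15.
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = NA_real_, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  # enumerate all sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-12)
  list(statistic = W, p = min(1, p))
}

#' Paired nonparametric and parametric comparisons
#'
#' \code{paired_compare} tests paired samples: the Wilcoxon signed-rank test
#' uses the exact permutation null by full enumeration of sign patterns for
#' n <= 15 and the normal approximation (with continuity correction and
#' tie-corrected variance) otherwise; \code{paired_t} is the standard paired
#' t test. All-zero differences give the degenerate p = 1.
#' \code{spearman_rho} is Pearson correlation on midranks.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 5).
#' @param method \code{"wilcoxon_signed_rank"} or \code{"paired_t"}.
#' @return \code{paired_compare}: list with \code{statistic}, \code{p},
#'   \code{method}, \code{n}. \code{spearman_rho}: scalar rho.
#' @export
paired_compare <- function(values_a, values_b,
                           method = c("wilcoxon_signed_rank", "paired_t")) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  if (length(values_a) < 5L) stop("need at least 5 pairs")
  d <- values_a - values_b
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, method = method,
                n = length(d)))
  if (method == "paired_t") {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                method = method, n = length(d)))
  }
  dz <- d[d != 0]
  n <- length(dz)
  if (n <= 15L) {
    r <- wilcoxon_exact_p(d)
    return(list(statistic = r$statistic, p = r$p, method = method, n = n))
  }
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  list(statistic = W, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = method, n = n)
}

#' @rdname paired_compare
#' @export
spearman_rho <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  stats::cor(rank(values_a), rank(values_b))
}
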