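#' Drop initial non-steady-state volumes
#'
#' @param series 4D array (x, y, z, t) or numeric matrix (t x voxels).
#' @param n number of initial volumes to remove (default 10).
#' @return The series with the first \code{n} volumes removed.
#' @export
drop_initial_volumes <- function(series, n = 10L) {
  if (is.array(series) && length(dim(series)) == 4L) {
    T <- dim(series)[4]
    if (n >= T) stop("cannot drop ", n, " of ", T, " volumes")
    series[, , , (n + 1L):T, drop = FALSE]
  } else {
    T <- nrow(series)
    if (n >= T) stop("cannot drop ", n, " of ", T, " volumes")
    series[(n + 1L):T, , drop = FALSE]
  }
}

#' Voxel-wise T2* from multi-echo mean volumes
#'
#' Log-linear least-squares fit of the temporal-mean signal against echo
#' time over all echoes (including the TE = 0 FID): R2* is minus the slope
#' and T2* = 1/R2*, clamped to [0.005, 0.3] s. Voxels with nonpositive
#' signal at any echo, or with a nonpositive fitted R2*, are excluded from
#' the validity mask (T2* clamps to the upper bound for a zero slope).
#'
#' @param echo_mean_volumes list of 3D arrays, one temporal-mean volume per
#'   echo.
#' @param TEs echo times in seconds (>= 2 echoes).
#' @return A list with \code{t2star} (3D array, seconds) and \code{mask}
#'   (logical array), class \code{t2star_map}.
#' @export
fit_t2star <- function(echo_mean_volumes, TEs) {
  if (length(echo_mean_volumes) < 2L || length(TEs) < 2L)
    stop("need at least 2 echoes")
  d <- dim(echo_mean_volumes[[1]])
  Y <- vapply(echo_mean_volumes, as.vector, numeric(prod(d)))
  mask <- apply(Y > 0, 1, all)
  t2 <- rep(NA_real_, prod(d))
  if (any(mask)) {
    L <- log(Y[mask, , drop = FALSE])
    te <- TEs - mean(TEs)
    slope <- (L %*% te) / sum(te^2)
    r2 <- -as.vector(slope)
    v <- ifelse(r2 <= 0, 0.3, pmin(pmax(1 / r2, 0.005), 0.3))
    t2[mask] <- v
  }
  out <- list(t2star = array(t2, d), mask = array(mask, d), TEs = TEs)
  class(out) <- "t2star_map"
  out
}

#' Optimal combination of multi-echo series
#'
#' Combines per-echo time series into one weighted series. The default
#' \code{te_weighted} scheme uses the matched-filter weights
#' \code{w_e ~ TE_e * exp(-TE_e / T2*)} (so the TE = 0 FID receives weight
#' zero); \code{tsnr_weighted} uses \code{w_e ~ tSNR_e^2}. Weights are
#' normalized to sum to 1 per voxel; voxels where all weights vanish are
#' masked out (returned as zero).
#'
#' @param echo_series list of 4D arrays (x, y, z, t), one per echo.
#' @param TEs echo times in seconds.
#' @param t2star a \code{t2star_map} (required for \code{te_weighted}).
#' @param scheme \code{"te_weighted"} or \code{"tsnr_weighted"}.
#' @return A list with \code{series} (4D array) and \code{mask} (logical
#'   array of voxels with a valid combination).
#' @export
optimal_combine <- function(echo_series, TEs, t2star = NULL,
                            scheme = c("te_weighted", "tsnr_weighted")) {
  scheme <- match.arg(scheme)
  if (length(echo_series) < 2L) stop("need at least 2 echoes to combine")
  d <- dim(echo_series[[1]])
  nvox <- prod(d[1:3]); T <- d[4]
  W <- matrix(0, nvox, length(TEs))
  if (scheme == "te_weighted") {
    if (is.null(t2star)) stop("te_weighted combination requires a t2star map")
    t2 <- as.vector(t2star$t2star)
    t2[!as.vector(t2star$mask)] <- NA
    for (e in seq_along(TEs)) W[, e] <- TEs[e] * exp(-TEs[e] / t2)
  } else {
    for (e in seq_along(TEs)) {
      m <- matrix(echo_series[[e]], nvox, T)
      mu <- rowMeans(m)
      sdv <- sqrt(rowSums((m - mu)^2) / (T - 1))
      tsnr <- ifelse(sdv > 0, mu / sdv, 0)
      W[, e] <- tsnr^2
    }
  }
  W[is.na(W)] <- 0
  tot <- rowSums(W)
  mask <- tot > 0
  W[mask, ] <- W[mask, , drop = FALSE] / tot[mask]
  comb <- matrix(0, nvox, T)
  for (e in seq_along(TEs))
    comb <- comb + W[, e] * matrix(echo_series[[e]], nvox, T)
  list(series = array(comb, d), mask = array(mask, d[1:3]),
       weights = W, scheme = scheme)
}

#' Temporal signal-to-noise ratio map
#'
#' Voxel-wise mean over time divided by the standard deviation of the
#' residuals after polynomial detrending (order 2 by default). Voxels with
#' zero residual variance are set to 0 and excluded from the mask.
#'
#' @param series 4D array (x, y, z, t).
#' @param detrend_order polynomial order removed before computing the
#'   residual SD.
#' @return A list with \code{tsnr} (3D array), \code{mask} (logical) and
#'   \code{detrend_order}, class \code{tsnr_map}.
#' @export
tsnr_map <- function(series, detrend_order = 2L) {
  d <- dim(series)
  T <- d[4]
  if (T < detrend_order + 2L) stop("need at least detrend_order + 2 volumes")
  m <- matrix(series, prod(d[1:3]), T)
  X <- poly_basis(T, detrend_order)
  beta <- t(qr.coef(qr(X), t(m)))
  res <- m - beta %*% t(X)
  sdres <- sqrt(rowSums(res^2) / (T - ncol(X)))
  mu <- rowMeans(m)
  mask <- sdres > 1e-12 * pmax(abs(mu), 1)
  tsnr <- ifelse(mask, mu / sdres, 0)
  tsnr[tsnr < 0] <- 0
  out <- list(tsnr = array(tsnr, d[1:3]), mask = array(mask, d[1:3]),
              detrend_order = as.integer(detrend_order))
  class(out) <- "tsnr_map"
  out
}

#' Percentage-difference map between two tSNR maps
#'
#' \code{100 * (a - b) / (a + b)} on the joint mask; voxels where
#' \code{a + b = 0} are masked out. Values lie in [-100, 100].
#'
#' @param tsnr_a,tsnr_b \code{tsnr_map} objects on the same grid.
#' @return A list with \code{pdiff} (3D array) and \code{mask}.
#' @export
percent_difference_map <- function(tsnr_a, tsnr_b) {
  if (!identical(dim(tsnr_a$tsnr), dim(tsnr_b$tsnr)))
    stop("tSNR maps are on different grids")
  a <- tsnr_a$tsnr; b <- tsnr_b$tsnr
  mask <- tsnr_a$mask & tsnr_b$mask & (a + b) > 0
  p <- array(0, dim(a))
  p[mask] <- pmin(pmax(100 * (a[mask] - b[mask]) / (a[mask] + b[mask]),
                       -100), 100)
  list(pdiff = p, mask = mask)
}

# reflective-boundary 1D convolution along one axis of a 3D/4D array
smooth_axis <- function(x, kern, axis) {
  d <- dim(x)
  n <- d[axis]
  h <- (length(kern) - 1L) / 2L
  if (h == 0L) return(x)
  # half-sample symmetric reflection (conserves total mass for any kernel)
  idx <- c(pmin(pmax(seq(h, 1, by = -1), 1), n), seq_len(n),
           pmin(pmax(seq(n, n - h + 1, by = -1), 1), n))
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, dp[1], prod(dp[-1]))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern))
    out <- out + kern[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
  res <- array(out, dp)
  aperm(res, order(perm))
}

#' Separable Gaussian smoothing
#'
#' Smooths each volume with a separable Gaussian kernel of the given full
#' width at half maximum (per axis, in mm), using reflective boundaries so
#' the volume mean is preserved. \code{fwhm_mm = 0} is the identity.
#'
#' @param series 3D or 4D array.
#' @param fwhm_mm kernel FWHM in millimetres.
#' @param voxel_size voxel size in mm.
#' @return The smoothed array, same shape.
#' @export
smooth_gaussian <- function(series, fwhm_mm = 8, voxel_size = 4) {
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(series)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  h <- max(1L, ceiling(3 * sigma_vox))
  t <- (-h):h
  kern <- exp(-t^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  is3d <- length(dim(series)) == 3L
  x <- if (is3d) array(series, c(dim(series), 1L)) else series
  for (ax in 1:3) x <- smooth_axis(x, kern, ax)
  if (is3d) array(x, dim(series)) else x
}
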