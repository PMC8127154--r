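#' Segmented 3D radial multi-echo trajectory
#'
#' Builds a Looping-Star-style trajectory: spokes are grouped into loops of
#' \code{spokes_per_loop} equally spaced directions along a great circle
#' whose pole is segment-specific; successive loops within a segment reuse
#' the circle, one loop per echo (the echo label of a spoke equals its loop
#' index within the segment). Segment poles and the per-volume segment
#' ordering are pseudo-random under the seed. Each spoke carries
#' \code{samples_per_spoke} samples at radii 0..k_max, with
#' k_max = 1/(2 * nominal_resolution).
#'
#' @param spokes_per_loop spokes per loop (default 24).
#' @param n_echoes echoes = loops per segment (default 3).
#' @param n_segments segments per volume (default 15, giving 72 spokes per
#'   segment and 1080 per volume at the defaults).
#' @param samples_per_spoke readout samples per spoke.
#' @param nominal_resolution nominal spatial resolution in mm (> 0).
#' @param seed RNG seed for segment poles and ordering.
#' @param dead_samples number of receiver dead-time samples missing at the
#'   centre of FID (echo 1) spokes.
#' @return An object of class \code{ls_trajectory}: list with
#'   \code{directions} (n_spokes x 3 unit vectors), \code{segment},
#'   \code{loop}, \code{echo}, \code{within_loop} labels, \code{radii},
#'   \code{k_max}, \code{ordering}, counts and \code{dead_samples}.
#' @export
make_trajectory <- function(spokes_per_loop = 24L, n_echoes = 3L,
                            n_segments = 15L, samples_per_spoke = 16L,
                            nominal_resolution = 3.2, seed = 1L,
                            dead_samples = 2L) {
  if (nominal_resolution <= 0) stop("nominal_resolution must be positive")
  stopifnot(spokes_per_loop >= 1L, n_echoes >= 1L, n_segments >= 1L,
            samples_per_spoke >= 1L)
  set.seed(seed)
  spokes_per_segment <- spokes_per_loop * n_echoes
  n_spokes <- spokes_per_segment * n_segments
  dirs <- matrix(0, n_spokes, 3)
  segment <- integer(n_spokes); loop <- integer(n_spokes)
  within <- integer(n_spokes)
  row <- 0L
  for (s in seq_len(n_segments)) {
    # uniform random pole; orthonormal in-plane frame
    z <- stats::rnorm(3); z <- z / sqrt(sum(z^2))
    a <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * z) * z; u <- u / sqrt(sum(u^2))
    v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
           z[1] * u[2] - z[2] * u[1])
    phase <- stats::runif(1, 0, 2 * pi)
    th <- phase + 2 * pi * (seq_len(spokes_per_loop) - 1) / spokes_per_loop
    circ <- cbind(cos(th)) %*% rbind(u) + cbind(sin(th)) %*% rbind(v)
    for (l in seq_len(n_echoes)) {
      idx <- row + seq_len(spokes_per_loop)
      dirs[idx, ] <- circ
      segment[idx] <- s; loop[idx] <- l; within[idx] <- seq_len(spokes_per_loop)
      row <- row + spokes_per_loop
    }
  }
  k_max <- 1 / (2 * nominal_resolution)
  radii <- if (samples_per_spoke == 1L) 0 else
    k_max * (seq_len(samples_per_spoke) - 1) / (samples_per_spoke - 1)
  traj <- list(directions = dirs, segment = segment, loop = loop,
               echo = loop, within_loop = within,
               spokes_per_loop = as.integer(spokes_per_loop),
               n_echoes = as.integer(n_echoes),
               n_segments = as.integer(n_segments),
               spokes_per_segment = as.integer(spokes_per_segment),
               spokes_per_volume = as.integer(n_spokes),
               samples_per_spoke = as.integer(samples_per_spoke),
               radii = radii, k_max = k_max,
               nominal_resolution = nominal_resolution,
               ordering = sample.int(n_segments),
               dead_samples = as.integer(dead_samples), seed = as.integer(seed))
  class(traj) <- "ls_trajectory"
  traj
}

#' @export
print.ls_trajectory <- function(x, ...) {
  cat("ls_trajectory:", x$spokes_per_loop, "spokes/loop,", x$n_echoes,
      "echoes,", x$n_segments, "segments =>", x$spokes_per_segment,
      "spokes/segment,", x$spokes_per_volume, "spokes/volume;",
      x$samples_per_spoke, "samples/spoke, k_max", signif(x$k_max, 4),
      "cycles/mm\n")
  invisible(x)
}

# Physical k-space coordinates (cycles/mm) of every trajectory sample,
# ordered spoke-major: (spoke 1 samples, spoke 2 samples, ...).
trajectory_points <- function(traj) {
  S <- traj$samples_per_spoke
  n <- traj$spokes_per_volume
  d <- traj$directions[rep(seq_len(n), each = S), , drop = FALSE]
  d * traj$radii[rep(seq_len(S), times = n)]
}

# Nearest Cartesian k-grid node (linear 1-based index into the centered FFT
# grid) for each trajectory sample. DC sits at 0-based index floor(N/2);
# offsets wrap modulo N (the +N/2 and -N/2 nodes coincide for even N).
trajectory_nodes <- function(traj, grid_shape, voxel_size) {
  n <- grid_shape
  dk <- 1 / (n * voxel_size)
  cen <- n %/% 2L
  pts <- trajectory_points(traj)
  off <- round(pts / dk)
  ijk <- (off + cen) %% n   # 0-based
  as.integer(ijk[, 1] + ijk[, 2] * n + ijk[, 3] * n * n + 1L)
}

complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, 0, sd / sqrt(2)),
          imaginary = stats::rnorm(n, 0, sd / sqrt(2)))
}

#' Sample multi-echo radial k-space from an ideal series
#'
#' Forward model consistent with nearest-neighbour gridding: for each volume
#' and echo, the centered 3D DFT of the echo's volume is evaluated at the
#' nearest Cartesian k-grid node of every trajectory sample, plus circular
#' complex white noise of standard deviation \code{noise_sd} (total complex
#' variance \code{noise_sd^2}). Optionally each sample gains
#' \code{interference_amp} times the conjugate of the sample-reversed spoke
#' (echo-in/echo-out interference). The first \code{dead_samples} samples of
#' FID (echo 1) spokes are blanked (receiver dead time) and stored instead,
#' with independent noise of the same level, in \code{reacquired_center}.
#'
#' @param ideal an \code{ideal_series}.
#' @param traj an \code{ls_trajectory}; its echo count must match
#'   \code{length(ideal$TEs)}.
#' @param noise_sd complex noise SD.
#' @param interference_amp echo-in/echo-out interference amplitude
#'   (default 0 = off).
#' @param seed RNG seed.
#' @return An object of class \code{kspace_series}: list with \code{samples}
#'   (complex matrix, rows = spoke-major samples of one volume, cols =
#'   volumes), \code{reacquired_center}, \code{trajectory}, \code{TEs},
#'   \code{grid_shape}, \code{voxel_size}, \code{seed}.
#' @export
sample_kspace <- function(ideal, traj, noise_sd = 0, interference_amp = 0,
                          seed = 1L) {
  if (traj$n_echoes != length(ideal$TEs))
    stop("trajectory has ", traj$n_echoes, " echoes but ideal series has ",
         length(ideal$TEs), " TEs")
  set.seed(seed)
  n <- dim(ideal$phantom$pd)[1]
  nodes <- trajectory_nodes(traj, n, ideal$phantom$voxel_size)
  S <- traj$samples_per_spoke
  echo_of_sample <- traj$echo[rep(seq_len(traj$spokes_per_volume), each = S)]
  n_samp <- length(nodes)
  n_vol <- ideal$n_volumes
  dead <- min(traj$dead_samples, S)
  fid_spokes <- which(traj$echo == 1L)
  dead_idx <- if (dead > 0)
    as.vector(outer(seq_len(dead), (fid_spokes - 1L) * S, `+`)) else integer(0)
  samples <- matrix(complex(real = 0), n_samp, n_vol)
  reac <- matrix(complex(real = 0), length(dead_idx), n_vol)
  # volumes with identical task state share FFTs
  key <- apply(ideal$roi_delta, 1, paste, collapse = ",")
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(n_vol)) {
    if (!is.null(cache[[key[t]]])) {
      base <- cache[[key[t]]]
    } else {
      base <- matrix(complex(real = 0), n_samp, 1)
      for (e in seq_len(traj$n_echoes)) {
        F <- centered_fft3(ideal_volume(ideal, e, t))
        sel <- echo_of_sample == e
        base[sel] <- F[nodes[sel]]
      }
      cache[[key[t]]] <- base
    }
    s <- base
    if (interference_amp > 0) {
      rev_idx <- as.vector(outer(rev(seq_len(S)),
                                 (seq_len(traj$spokes_per_volume) - 1L) * S,
                                 `+`))
      s <- s + interference_amp * Conj(s[rev_idx])
    }
    s <- s + complex_noise(n_samp, noise_sd)
    if (length(dead_idx)) {
      reac[, t] <- base[dead_idx] + complex_noise(length(dead_idx), noise_sd)
      s[dead_idx] <- NA_complex_
    }
    samples[, t] <- s
  }
  ks <- list(samples = samples, reacquired_center = reac,
             dead_idx = dead_idx, trajectory = traj, TEs = ideal$TEs,
             grid_shape = n, voxel_size = ideal$phantom$voxel_size,
             seed = as.integer(seed))
  class(ks) <- "kspace_series"
  ks
}

#' Sample radial k-space from a static volume
#'
#' Single-volume version of \code{\link{sample_kspace}} for arbitrary 3D
#' objects (point sources, smooth test objects): every echo samples the same
#' static volume. Useful for characterizing the acquisition/reconstruction
#' operator (point-spread function, noise floor, linearity).
#'
#' @param vol 3D numeric (or complex) array.
#' @param traj an \code{ls_trajectory}.
#' @param voxel_size voxel size in mm.
#' @param noise_sd complex noise SD.
#' @param interference_amp echo-in/echo-out interference amplitude.
#' @param seed RNG seed.
#' @return A \code{kspace_series} with one volume.
#' @export
sample_kspace_volume <- function(vol, traj, voxel_size, noise_sd = 0,
                                 interference_amp = 0, seed = 1L) {
  set.seed(seed)
  n <- dim(vol)[1]
  nodes <- trajectory_nodes(traj, n, voxel_size)
  S <- traj$samples_per_spoke
  F <- centered_fft3(vol)
  base <- F[nodes]
  s <- base
  if (interference_amp > 0) {
    rev_idx <- as.vector(outer(rev(seq_len(S)),
                               (seq_len(traj$spokes_per_volume) - 1L) * S,
                               `+`))
    s <- s + interference_amp * Conj(s[rev_idx])
  }
  s <- s + complex_noise(length(s), noise_sd)
  dead <- min(traj$dead_samples, S)
  fid_spokes <- which(traj$echo == 1L)
  dead_idx <- if (dead > 0)
    as.vector(outer(seq_len(dead), (fid_spokes - 1L) * S, `+`)) else integer(0)
  reac <- matrix(complex(real = 0), length(dead_idx), 1)
  if (length(dead_idx)) {
    reac[, 1] <- base[dead_idx] + complex_noise(length(dead_idx), noise_sd)
    s[dead_idx] <- NA_complex_
  }
  ks <- list(samples = matrix(s, ncol = 1), reacquired_center = reac,
             dead_idx = dead_idx, trajectory = traj, TEs = rep(NA_real_,
             traj$n_echoes), grid_shape = n, voxel_size = voxel_size,
             seed = as.integer(seed))
  class(ks) <- "kspace_series"
  ks
}

#' Simulate a single-echo EPI-style image series
#'
#' Image-space simulator for the conventional arm: the ideal single-echo
#' series plus a voxel-wise polynomial drift and stationary AR(1) Gaussian
#' noise. The drift is \code{sum_j coeffs[j] * x^(j-1)} with \code{x}
#' spanning [-1, 1] over the run, scaled by the voxel's baseline signal.
#'
#' @param ideal an \code{ideal_series} with a single TE (e.g. 27.5 ms).
#' @param noise_sd marginal noise SD in signal units.
#' @param drift_coeffs polynomial coefficients (constant, linear, ...).
#' @param ar1_rho lag-1 autocorrelation in [0, 1).
#' @param seed RNG seed.
#' @return 4D numeric array (x, y, z, t).
#' @export
simulate_epi_series <- function(ideal, noise_sd = 0, drift_coeffs = 0,
                                ar1_rho = 0, seed = 1L) {
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (length(ideal$TEs) != 1L)
    stop("EPI simulator expects a single-echo ideal series")
  set.seed(seed)
  d <- dim(ideal$phantom$pd)
  T <- ideal$n_volumes
  out <- array(0, dim = c(d, T))
  for (t in seq_len(T)) out[, , , t] <- ideal_volume(ideal, 1L, t)
  nvox <- prod(d)
  mat <- matrix(out, nvox, T)
  base <- ideal$phantom$pd * exp(-ideal$TEs[1] * ideal$phantom$r2star)
  if (any(drift_coeffs != 0)) {
    x <- if (T > 1) seq(-1, 1, length.out = T) else 0
    drift <- rowSums(vapply(seq_along(drift_coeffs),
                            function(j) drift_coeffs[j] * x^(j - 1),
                            numeric(length(x))))
    mat <- mat + as.vector(base) %o% drift
  }
  if (noise_sd > 0) {
    inn_sd <- noise_sd * sqrt(1 - ar1_rho^2)
    e <- matrix(0, nvox, T)
    e[, 1] <- stats::rnorm(nvox, 0, noise_sd)
    if (T > 1) for (t in 2:T)
      e[, t] <- ar1_rho * e[, t - 1] + stats::rnorm(nvox, 0, inn_sd)
    mat <- mat + e
  }
  array(mat, dim = c(d, T))
}
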