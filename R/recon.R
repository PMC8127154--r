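#' Radial density-compensation weights
#'
#' Per-sample weights correcting the oversampling of the k-space centre in a
#' 3D radial trajectory: \code{w = max(|k|, dk/2)^2} (the clamp keeps the
#' centre sample at a positive weight), normalized so the mean weight is 1.
#' \code{dk} is the Cartesian grid spacing implied by the grid the samples
#' will be deposited on.
#'
#' @param traj an \code{ls_trajectory}.
#' @param grid_shape reconstruction grid size per axis.
#' @param voxel_size voxel size in mm.
#' @return Numeric vector of positive weights, one per trajectory sample
#'   (spoke-major ordering), mean 1.
#' @export
density_weights <- function(traj, grid_shape, voxel_size) {
  if (traj$spokes_per_volume < 1L) stop("empty trajectory")
  dk <- 1 / (grid_shape * voxel_size)
  r <- rep(traj$radii, times = traj$spokes_per_volume)
  w <- pmax(r, dk / 2)^2
  w / mean(w)
}

#' Merge dead-time centre reacquisition into a k-space series
#'
#' Fills the blanked receiver dead-time samples of FID spokes with the
#' reacquired centre pass; echo spokes are untouched. With
#' \code{dead_samples = 0} this is the identity.
#'
#' @param k a \code{kspace_series}.
#' @return The series with dead-time gaps filled.
#' @export
merge_center_reacquisition <- function(k) {
  if (length(k$dead_idx) == 0L) return(k)
  if (is.null(k$reacquired_center) || nrow(k$reacquired_center) == 0L)
    stop("dead-time samples present but no reacquired centre data")
  k$samples[k$dead_idx, ] <- k$reacquired_center
  k
}

# Grid one volume of one echo: weighted-mean deposition onto nearest nodes,
# centered inverse FFT. Returns the complex image.
grid_one <- function(samp, nodes, w, grid_shape) {
  ok <- !is.na(samp)
  nodes <- nodes[ok]; samp <- samp[ok]; w <- w[ok]
  num_re <- rowsum(w * Re(samp), nodes)
  num_im <- rowsum(w * Im(samp), nodes)
  den <- rowsum(w, nodes)
  F <- array(complex(real = 0), dim = rep(grid_shape, 3))
  F[as.integer(rownames(den))] <- complex(real = num_re / den,
                                          imaginary = num_im / den)
  centered_ifft3(F)
}

#' Gridding reconstruction of a radial k-space series
#'
#' Density-compensated nearest-neighbour gridding: each sample is deposited
#' on its nearest Cartesian k-grid node; a node's value is the weighted mean
#' of its contributing samples (making full sampling exactly invertible under
#' the matched forward model); unvisited nodes are zero; the image is the
#' magnitude of the centered inverse FFT. Dead-time gaps still present (NA)
#' are excluded from deposition; call
#' \code{\link{merge_center_reacquisition}} first to use the reacquired
#' centre pass.
#'
#' @param k a \code{kspace_series}.
#' @param weights density weights from \code{\link{density_weights}};
#'   computed automatically when \code{NULL}.
#' @param grid_shape reconstruction grid (defaults to the acquisition grid).
#' @return A list of per-echo 4D magnitude arrays (x, y, z, t), one element
#'   per TE.
#' @export
grid_reconstruct <- function(k, weights = NULL, grid_shape = k$grid_shape) {
  traj <- k$trajectory
  if (is.null(weights))
    weights <- density_weights(traj, grid_shape, k$voxel_size)
  nodes <- trajectory_nodes(traj, grid_shape, k$voxel_size)
  S <- traj$samples_per_spoke
  echo_of_sample <- traj$echo[rep(seq_len(traj$spokes_per_volume), each = S)]
  n_vol <- ncol(k$samples)
  out <- vector("list", traj$n_echoes)
  for (e in seq_len(traj$n_echoes)) {
    sel <- which(echo_of_sample == e)
    if (length(sel) == 0L) stop("echo ", e, " has zero spokes")
    vols <- array(0, dim = c(rep(grid_shape, 3), n_vol))
    for (t in seq_len(n_vol)) {
      img <- grid_one(k$samples[sel, t], nodes[sel], weights[sel], grid_shape)
      vols[, , , t] <- Mod(img)
    }
    out[[e]] <- vols
  }
  names(out) <- paste0("echo", seq_len(traj$n_echoes))
  out
}
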