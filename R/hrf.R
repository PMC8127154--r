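#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: the difference of two gamma densities with
#' peak delay 6 s, undershoot delay 16 s, unit dispersions and an undershoot
#' ratio of 1/6, truncated at 32 s and scaled to unit peak.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param length_s kernel length in seconds.
#' @return Numeric vector sampling the kernel at \code{0, dt, 2 dt, ...}.
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Microtime event stream for one condition, convolved with the canonical HRF
# and sampled at volume onset times t_v = (v - 1) * TR.
#
# deviant/novel (and standard, used by the simulator): zero-duration events,
# unit impulses at the nearest microtime bin. silent: rest blocks as boxcar
# epochs of their duration. The HRF has unit peak, so an isolated impulse
# yields a regressor with peak ~1.
condition_regressor <- function(schedule, condition, TR, n_volumes,
                                microtime = 16L) {
  dt <- TR / microtime
  total <- TR * n_volumes
  nbins <- ceiling(total / dt) + ceiling(32 / dt) + 1L
  u <- numeric(nbins)
  ev <- schedule$events
  if (condition == "silent") {
    sel <- ev$trial_type == "rest"
    for (i in which(sel)) {
      b0 <- floor(ev$onset[i] / dt) + 1L
      b1 <- min(nbins, floor((ev$onset[i] + ev$duration[i]) / dt) + 1L)
      if (b0 <= nbins) u[b0:b1] <- 1
    }
  } else {
    sel <- ev$trial_type == condition
    if (condition == "motor") sel <- ev$trial_type %in% c("deviant", "novel")
    for (i in which(sel)) {
      b <- round(ev$onset[i] / dt) + 1L
      if (b >= 1L && b <= nbins) u[b] <- u[b] + 1
    }
  }
  h <- canonical_hrf(dt)
  x <- stats::convolve(u, rev(h), type = "open")[seq_len(nbins)]
  vb <- round((seq_len(n_volumes) - 1) * TR / dt) + 1L
  x[vb]
}

# Discrete cosine drift basis: K = floor(2 * duration / cutoff) functions
# cos(pi k (2v - 1) / (2 n)), k = 1..K, over the n retained volumes.
dct_basis <- function(n, TR, cutoff) {
  K <- floor(2 * n * TR / cutoff)
  if (K < 1L) return(matrix(nrow = n, ncol = 0))
  v <- seq_len(n)
  sapply(seq_len(K), function(k) cos(pi * k * (2 * v - 1) / (2 * n)))
}

#' Build a first-level GLM design matrix
#'
#' Constructs the design for one run: Deviant and Novel tones as
#' zero-duration HRF-convolved events, Silent rest periods as HRF-convolved
#' boxcar epochs, Standard tones deliberately unmodelled (implicit baseline),
#' a discrete-cosine drift basis implementing the high-pass cutoff, optional
#' nuisance columns, and a constant. The first \code{drop} volumes are
#' excluded; regressors are sampled at the retained volume times.
#'
#' @param schedule an \code{oddball_schedule} covering the scan.
#' @param TR repetition time (s).
#' @param n_vols total acquired volumes (before dropping).
#' @param drop initial volumes to exclude (default 10).
#' @param hpf_cutoff high-pass cutoff in seconds (default 128).
#' @param nuisance optional numeric matrix of externally supplied nuisance
#'   regressors (\code{n_vols - drop} rows).
#' @return An object of class \code{fmri_design}: list with \code{X}
#'   (rows = retained volumes), \code{names}, \code{TR}, \code{drop},
#'   \code{hpf_cutoff}, \code{condition_cols}, \code{empty_conditions}.
#' @export
build_design <- function(schedule, TR, n_vols, drop = 10L, hpf_cutoff = 128,
                         nuisance = NULL) {
  n_ret <- n_vols - drop
  if (n_ret < 2L) stop("fewer than 2 retained volumes")
  keep <- (drop + 1L):n_vols
  conds <- c("deviant", "novel", "silent")
  cols <- lapply(conds, function(cc)
    condition_regressor(schedule, cc, TR, n_vols)[keep])
  names(cols) <- conds
  empty <- conds[vapply(cols, function(x) all(x == 0), TRUE)]
  cols <- cols[setdiff(conds, empty)]  # zero columns flagged and dropped
  D <- dct_basis(n_ret, TR, hpf_cutoff)
  dn <- if (ncol(D)) paste0("dct", seq_len(ncol(D))) else character(0)
  X <- if (length(cols)) cbind(do.call(cbind, cols), D) else D
  nm <- c(names(cols), dn)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_ret)
      stop("nuisance matrix must have ", n_ret, " rows")
    X <- cbind(X, nuisance)
    nn <- colnames(nuisance)
    if (is.null(nn)) nn <- paste0("nuis", seq_len(ncol(nuisance)))
    nm <- c(nm, nn)
  }
  X <- cbind(X, 1)
  nm <- c(nm, "constant")
  colnames(X) <- nm
  des <- list(X = X, names = nm, TR = TR, drop = as.integer(drop),
              hpf_cutoff = hpf_cutoff,
              condition_cols = stats::setNames(match(conds, nm), conds),
              empty_conditions = empty)
  class(des) <- "fmri_design"
  des
}

#' @export
print.fmri_design <- function(x, ...) {
  cat("fmri_design:", nrow(x$X), "volumes x", ncol(x$X), "regressors (",
      paste(x$names, collapse = ", "), ")\n")
  if (length(x$empty_conditions))
    cat("  empty conditions:", paste(x$empty_conditions, collapse = ", "), "\n")
  invisible(x)
}
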