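#' Fit a voxel-wise GLM with optional AR(1) prewhitening
#'
#' Ordinary least squares per voxel; with \code{whiten = "ar1"}, the lag-1
#' autocorrelation of the OLS residuals is pooled over the mask, the model
#' rows are Cochrane-Orcutt transformed (first row scaled by
#' \code{sqrt(1 - rho^2)}), and the model is refit; betas, residual variance
#' and degrees of freedom come from the transformed model.
#'
#' @param series 4D array (x, y, z, t) or matrix (t x voxels); rows must
#'   match the design.
#' @param design an \code{fmri_design} (or a plain design matrix).
#' @param whiten \code{"none"} or \code{"ar1"}.
#' @param mask optional logical array/vector restricting the voxels used for
#'   pooling rho (all voxels are always fit).
#' @return An object of class \code{glm_fit}: list with \code{beta}
#'   (regressors x voxels), \code{sigma2}, \code{df}, \code{ar1_rho},
#'   \code{XtXinv}, \code{design}, \code{dims}.
#' @export
fit_glm <- function(series, design, whiten = c("none", "ar1"), mask = NULL) {
  whiten <- match.arg(whiten)
  X <- if (inherits(design, "fmri_design")) design$X else as.matrix(design)
  dims <- NULL
  if (is.array(series) && length(dim(series)) == 4L) {
    dims <- dim(series)[1:3]
    Y <- t(matrix(series, prod(dims), dim(series)[4]))
  } else Y <- as.matrix(series)
  if (nrow(Y) != nrow(X))
    stop("series has ", nrow(Y), " volumes but design has ", nrow(X), " rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rho <- NA_real_
  if (whiten == "ar1") {
    use <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.vector(mask))
    r <- res[, use, drop = FALSE]
    num <- sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
    den <- sum(r^2)
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.99), -0.99)
    Tn <- nrow(X)
    Xs <- rbind(sqrt(1 - rho^2) * X[1, ],
                X[-1, , drop = FALSE] - rho * X[-Tn, , drop = FALSE])
    Ys <- rbind(sqrt(1 - rho^2) * Y[1, ],
                Y[-1, , drop = FALSE] - rho * Y[-Tn, , drop = FALSE])
    qrX <- qr(Xs)
    beta <- qr.coef(qrX, Ys)
    res <- Ys - Xs %*% beta
    X <- Xs
  }
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(X))
  fit <- list(beta = beta, sigma2 = sigma2, df = df, ar1_rho = rho,
              XtXinv = XtXinv,
              design = if (inherits(design, "fmri_design")) design else NULL,
              names = colnames(X), dims = dims)
  class(fit) <- "glm_fit"
  fit
}

#' Named first-level contrast vectors
#'
#' Presets for the interrogated contrasts: (i) Dev + Nov > Silent,
#' (ii) Dev + Nov > all (implicit baseline), (iii) Nov > Dev and Dev > Nov,
#' (iv) Nov > all, (v) Dev > all. Weights over condition columns; all other
#' columns get zero.
#'
#' @param fit a \code{glm_fit} (or regressor name vector).
#' @param name one of \code{"dev+nov>silent"}, \code{"dev+nov>all"},
#'   \code{"nov>dev"}, \code{"dev>nov"}, \code{"nov>all"}, \code{"dev>all"}.
#' @return Numeric contrast vector matching the design columns.
#' @export
contrast_weights <- function(fit, name) {
  nms <- if (inherits(fit, "glm_fit")) fit$names else fit
  c0 <- stats::setNames(numeric(length(nms)), nms)
  w <- switch(name,
    "dev+nov>silent" = c(deviant = 0.5, novel = 0.5, silent = -1),
    "dev+nov>all" = c(deviant = 0.5, novel = 0.5),
    "nov>dev" = c(novel = 1, deviant = -1),
    "dev>nov" = c(deviant = 1, novel = -1),
    "nov>all" = c(novel = 1),
    "dev>all" = c(deviant = 1),
    stop("unknown contrast preset: ", name))
  missing_cond <- setdiff(names(w), nms)
  if (length(missing_cond))
    stop("contrast '", name, "' references conditions absent from the ",
         "design: ", paste(missing_cond, collapse = ", "))
  c0[names(w)] <- w
  unname(c0)
}

#' Voxel-wise contrast T-map
#'
#' \eqn{T = c' \hat\beta / \sqrt{\hat\sigma^2 c' (X'X)^{-1} c}}. Voxels with
#' zero residual variance are masked (T set to NA).
#'
#' @param fit a \code{glm_fit}.
#' @param c contrast weight vector (length = number of regressors), or a
#'   preset name accepted by \code{\link{contrast_weights}}.
#' @return A list with \code{t} (array if the fit carried image dimensions,
#'   else vector), \code{effect} (contrast of betas), \code{df},
#'   \code{contrast}.
#' @export
contrast_tmap <- function(fit, c) {
  if (is.character(c)) c <- contrast_weights(fit, c)
  if (length(c) != nrow(fit$beta))
    stop("contrast has length ", length(c), " but the model has ",
         nrow(fit$beta), " regressors")
  if (all(c == 0)) stop("contrast weights are all zero")
  eff <- as.vector(t(c) %*% fit$beta)
  varc <- as.numeric(t(c) %*% fit$XtXinv %*% c)
  se <- sqrt(fit$sigma2 * varc)
  tv <- ifelse(se > 0, eff / se, NA_real_)
  if (!is.null(fit$dims)) {
    tv <- array(tv, fit$dims)
    eff <- array(eff, fit$dims)
  }
  list(t = tv, effect = eff, df = fit$df, contrast = c)
}

#' Group-level one-sample and paired t-maps
#'
#' Voxel-wise one-sample t across subjects (df = n - 1); the paired version
#' is the one-sample test on the within-subject difference maps. Voxels with
#' zero between-subject variance are masked (NA).
#'
#' @param maps 4D array (x, y, z, subject) of first-level contrast maps.
#' @return A list with \code{t}, \code{mean}, \code{df}, \code{n}.
#' @export
group_ttest <- function(maps) {
  n <- dim(maps)[4]
  if (n < 3L) stop("need at least 3 subjects")
  d <- dim(maps)[1:3]
  m <- matrix(maps, prod(d), n)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (n - 1))
  tv <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  list(t = array(tv, d), mean = array(mu, d), df = n - 1L, n = n)
}

#' @rdname group_ttest
#' @param maps_a,maps_b 4D arrays (x, y, z, subject), matched subject order.
#' @export
paired_group_ttest <- function(maps_a, maps_b) {
  if (!identical(dim(maps_a), dim(maps_b)))
    stop("paired maps must have identical dimensions")
  group_ttest(maps_a - maps_b)
}

#' Sign-flip permutation cluster inference
#'
#' One-sample group inference with cluster-level family-wise error control:
#' voxels exceeding the one-sided Student-t threshold for the cluster-forming
#' p (default .001) are grouped into 6-connected clusters; the corrected p of
#' each observed cluster is the proportion of sign-flip permutations (plus
#' the identity) whose maximum suprathreshold cluster size is at least the
#' observed size.
#'
#' @param maps 4D array (x, y, z, subject) of first-level contrast maps.
#' @param cluster_forming_p one-sided cluster-forming threshold.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed for the flips.
#' @param mask optional logical 3D array.
#' @return A data frame (class \code{cluster_table}) with one row per
#'   observed cluster: \code{cluster}, \code{size}, \code{peak_t},
#'   \code{peak_x/y/z}, \code{p_fwe}; empty when nothing survives the
#'   forming threshold.
#' @export
cluster_inference <- function(maps, cluster_forming_p = 0.001, n_perm = 500L,
                              seed = 1L, mask = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  n <- dim(maps)[4]
  d <- dim(maps)[1:3]
  thr <- stats::qt(1 - cluster_forming_p, df = n - 1L)
  m <- matrix(maps, prod(d), n)
  keep <- if (is.null(mask)) rep(TRUE, prod(d)) else as.vector(mask)
  tstat <- function(mm) {
    mu <- rowMeans(mm)
    sdv <- sqrt(rowSums((mm - mu)^2) / (n - 1))
    ifelse(sdv > 0 & keep, mu / (sdv / sqrt(n)), -Inf)
  }
  tv <- tstat(m)
  supra <- array(tv > thr, d)
  labs <- label_components6(supra)
  ncl <- max(labs)
  if (ncl == 0L)
    return(structure(data.frame(cluster = integer(0), size = integer(0),
                                peak_t = numeric(0), peak_x = integer(0),
                                peak_y = integer(0), peak_z = integer(0),
                                p_fwe = numeric(0)),
                     class = c("cluster_table", "data.frame")))
  sizes <- tabulate(labs[labs > 0], nbins = ncl)
  set.seed(seed)
  max_null <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    tp <- tstat(m * rep(fl, each = nrow(m)))
    sp <- array(tp > thr, d)
    lp <- label_components6(sp)
    max_null[p] <- if (max(lp) > 0L) max(tabulate(lp[lp > 0L])) else 0L
  }
  out <- data.frame(cluster = seq_len(ncl), size = sizes,
                    peak_t = NA_real_, peak_x = NA_integer_,
                    peak_y = NA_integer_, peak_z = NA_integer_,
                    p_fwe = NA_real_)
  tarr <- array(tv, d)
  for (cl in seq_len(ncl)) {
    vox <- which(labs == cl)
    pk <- vox[which.max(tarr[vox])]
    pc <- arrayInd(pk, d)
    out$peak_t[cl] <- tarr[pk]
    out$peak_x[cl] <- pc[1]; out$peak_y[cl] <- pc[2]; out$peak_z[cl] <- pc[3]
    out$p_fwe[cl] <- (1 + sum(max_null >= sizes[cl])) / (n_perm + 1)
  }
  out <- out[order(-out$size), ]
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Percent signal change for a condition in an ROI
#'
#' \eqn{PSC = 100 \cdot \hat\beta_{cond} \cdot h_{peak} / \hat\beta_{const}}
#' averaged over the ROI, where \eqn{h_{peak}} is the maximum of the
#' regressor built for a single isolated zero-duration event at microtime
#' resolution TR/16. Voxels with nonpositive baseline are excluded.
#'
#' @param fit a \code{glm_fit} carrying its design.
#' @param design the \code{fmri_design} used for the fit (defaults to the
#'   one stored in the fit).
#' @param roi logical array (on the fit's grid) or voxel index vector.
#' @param condition condition name (a design column, e.g. \code{"deviant"}).
#' @return Scalar percent signal change averaged over valid ROI voxels.
#' @export
percent_signal_change <- function(fit, design = fit$design, roi, condition) {
  if (is.null(design)) stop("a design is required")
  ci <- match(condition, fit$names)
  if (is.na(ci)) stop("condition '", condition, "' is not a design column")
  k0 <- match("constant", fit$names)
  dt <- design$TR / 16
  h <- canonical_hrf(dt)
  h_peak <- max(h)  # unit-peak kernel: an isolated impulse regressor peaks at 1
  vox <- if (is.logical(roi)) which(as.vector(roi)) else as.integer(roi)
  bc <- fit$beta[ci, vox]
  b0 <- fit$beta[k0, vox]
  ok <- b0 > 0
  if (!any(ok)) stop("nonpositive baseline everywhere in the ROI")
  mean(100 * bc[ok] * h_peak / b0[ok])
}
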