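test_that("the canonical double-gamma HRF has the expected shape", {
  dt <- 0.1
  h <- canonical_hrf(dt)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # peak latency: the positive gamma (shape 6, rate 1) modes at 5 s
  expect_lt(abs((which.max(h) - 1) * dt - 5), dt + 1e-9)
  # exactly one sign change after the peak (the undershoot)
  post <- h[which.max(h):length(h)]
  flips <- sum(diff(sign(post[post != 0])) != 0)
  expect_equal(flips, 1)
})

test_that("design construction: rows, conditions, and the DCT drift basis", {
  sch <- generate_schedule(paradigm_config(seed = 6))
  des <- build_design(sch, TR = 2.648, n_vols = 240, drop = 10)
  expect_equal(nrow(des$X), 230)
  expect_true(all(c("deviant", "novel", "silent", "constant") %in% des$names))
  # DCT size = floor(2 * retained duration / cutoff)
  expect_equal(sum(grepl("^dct", des$names)),
               floor(2 * 230 * 2.648 / 128))
  expect_equal(length(des$empty_conditions), 0)
  # eventless schedule: only drift + constant remain
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   trial_type = character(0), tone_id = character(0))
  empty_sch <- structure(list(events = ev, config = NULL, swap_time = NA,
                              n_tones = 0L), class = "oddball_schedule")
  des0 <- suppressWarnings(build_design(empty_sch, TR = 2.5, n_vols = 100,
                                        drop = 10))
  expect_setequal(des0$empty_conditions, c("deviant", "novel", "silent"))
  expect_true(all(grepl("^dct|^constant$", des0$names)))
  # contrasts referencing dropped conditions fail loudly
  expect_error(contrast_weights(des0$names, "dev+nov>silent"), "absent")
  # nuisance columns are appended with their names
  nui <- matrix(stats::rnorm(90), 90, 1,
                dimnames = list(NULL, "motion1"))
  desn <- suppressWarnings(build_design(sch, TR = 2.5, n_vols = 100,
                                        drop = 10, nuisance = nui))
  expect_true("motion1" %in% desn$names)
})

test_that("GLM estimation matches hand-solved least squares and is exact on noiseless data", {
  # small numeric system against the normal-equations oracle
  set.seed(51)
  X <- cbind(stats::rnorm(6), 1)
  colnames(X) <- c("x", "constant")
  Y <- matrix(stats::rnorm(12), 6, 2)
  fit <- fit_glm(Y, X)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(fit$beta, beta_oracle, ignore_attr = TRUE, tolerance = 1e-12)
  res <- Y - X %*% beta_oracle
  expect_equal(fit$sigma2, colSums(res^2) / 4, tolerance = 1e-12)
  cm <- contrast_tmap(fit, c(1, 0))
  se <- sqrt(fit$sigma2 * solve(t(X) %*% X)[1, 1])
  expect_equal(as.vector(cm$t), as.vector(beta_oracle[1, ] / se),
               tolerance = 1e-12)
  # noiseless data: exact recovery, zero residual variance
  beta_true <- matrix(c(2, -1), 2, 1)
  fit2 <- fit_glm(X %*% beta_true, X)
  expect_equal(as.vector(fit2$beta), c(2, -1), tolerance = 1e-9)
  expect_lt(fit2$sigma2, 1e-20)
  # rank deficiency names the collinear column
  X2 <- cbind(X, dup = X[, 1])
  expect_error(fit_glm(Y, X2), "collinear")
})

test_that("AR(1) prewhitening recovers the pooled autocorrelation", {
  set.seed(52)
  T <- 230; V <- 1000
  X <- cbind(stats::rnorm(T), 1)
  rho <- 0.3
  inn <- matrix(stats::rnorm(T * V, 0, sqrt(1 - rho^2)), T, V)
  E <- matrix(0, T, V)
  E[1, ] <- stats::rnorm(V)
  for (t in 2:T) E[t, ] <- rho * E[t - 1, ] + inn[t, ]
  fit <- fit_glm(E + X %*% matrix(0.5, 2, V), X, whiten = "ar1")
  expect_lt(abs(fit$ar1_rho - rho), 0.05)
})

test_that("contrast maps behave like Student-t statistics", {
  # antisymmetry
  set.seed(53)
  X <- cbind(stats::rnorm(30), 1)
  Y <- matrix(stats::rnorm(30 * 50), 30, 50)
  fit <- fit_glm(Y, X)
  t1 <- contrast_tmap(fit, c(1, 0))$t
  t2 <- contrast_tmap(fit, c(-1, 0))$t
  expect_equal(t1, -t2)
  expect_error(contrast_tmap(fit, c(0, 0)), "all zero")
  # null calibration: empirical 97.5th percentile matches t(df)
  Yn <- matrix(stats::rnorm(30 * 20000), 30, 20000)
  fitn <- fit_glm(Yn, X)
  tn <- contrast_tmap(fitn, c(1, 0))$t
  q_emp <- stats::quantile(tn, 0.975)
  q_th <- stats::qt(0.975, df = fitn$df)
  expect_lt(abs(q_emp / q_th - 1), 0.05)
})

test_that("group tests: masking, pairing antisymmetry, and effect-size calibration", {
  d <- c(4, 4, 4)
  # identical nonzero maps: zero variance -> masked NA
  maps <- array(rep(as.vector(array(1:64, d)), 5), c(d, 5))
  g <- group_ttest(maps)
  expect_true(all(is.na(g$t)))
  expect_error(group_ttest(maps[, , , 1:2, drop = FALSE]), "3 subjects")
  # paired antisymmetry
  set.seed(54)
  a <- array(stats::rnorm(prod(d) * 6), c(d, 6))
  b <- array(stats::rnorm(prod(d) * 6), c(d, 6))
  expect_equal(paired_group_ttest(a, b)$t, -paired_group_ttest(b, a)$t)
  # one-sample t with effect d = 1, n = 12: mean matches the noncentral-t mean
  n <- 12
  m <- array(stats::rnorm(4000 * n, mean = 1, sd = 1), c(40, 10, 10, n))
  gt <- group_ttest(m)
  nu <- n - 1
  expect_mean <- sqrt(n) * sqrt(nu / 2) * gamma((nu - 1) / 2) / gamma(nu / 2)
  se_mc <- stats::sd(gt$t) / sqrt(length(gt$t))
  expect_lt(abs(mean(gt$t) - expect_mean), 4 * se_mc)
})

test_that("high-pass filtering protects betas from slow confounds", {
  ph <- tiny_phantom()
  TR <- 2.5; nv <- 240
  sch <- generate_schedule(paradigm_config(
    initial_silence = 10 * TR, total_duration = TR * nv + 1,
    n_rest_blocks = 6L, seed = 8))
  ids <- simulate_bold_series(ph, sch, TR = TR, TEs = 0.0275, n_volumes = nv,
                              activation_table = modelled_activation())
  ser <- drop_initial_volumes(simulate_epi_series(ids), 10)
  des <- build_design(sch, TR, nv, drop = 10)
  fit <- fit_glm(ser, des)
  vox <- which(ph$roi_masks$auditory)
  b0 <- fit$beta[match("deviant", fit$names), vox]
  tt <- (10:(nv - 1)) * TR
  d <- dim(ser)
  # a slow confound inside the span of the drift basis leaves the condition
  # betas exactly unchanged (orthogonal projection), here period 575 s
  D <- des$X[, grepl("^dct|^constant", des$names), drop = FALSE]
  inspan <- as.vector(D %*% stats::rnorm(ncol(D)))
  ser2 <- ser + array(rep(inspan, each = prod(d[1:3])), d) * 0.05
  b1 <- fit_glm(ser2, des)$beta[match("deviant", fit$names), vox]
  expect_lt(mean(abs(b1 - b0)) / mean(abs(b0)), 0.01)
  # arbitrary-phase sinusoids slower than twice the cutoff are absorbed to
  # at least 90% of their energy by the drift basis
  for (period in c(300, 450, 575)) {
    slow <- sin(2 * pi * tt / period + 0.7)
    resid <- slow - D %*% qr.coef(qr(D), slow)
    expect_lt(sqrt(sum(resid^2) / sum(slow^2)), 0.10)
  }
})

test_that("percent signal change is scale invariant and recovers the manifest", {
  sch <- short_schedule()
  ph <- tiny_phantom()
  TR <- 2.5; nv <- 120
  ids <- simulate_bold_series(ph, sch, TR = TR, TEs = 0.0275, n_volumes = nv,
                              activation_table = modelled_activation())
  ser <- drop_initial_volumes(simulate_epi_series(ids), 10)
  des <- build_design(sch, TR, nv, drop = 10)
  fit <- fit_glm(ser, des)
  roi <- ph$roi_masks$auditory
  psc <- percent_signal_change(fit, des, roi, "deviant")
  manifest_psc <- 100 * (exp(0.0275 * 0.12) - 1)  # TE x |peak delta-R2*|
  expect_lt(abs(psc / manifest_psc - 1), 0.10)
  # doubling all signal amplitudes leaves PSC unchanged
  fit2 <- fit_glm(2 * ser, des)
  expect_equal(percent_signal_change(fit2, des, roi, "deviant"), psc,
               tolerance = 1e-9)
  # zero condition beta gives zero PSC
  ids0 <- simulate_bold_series(ph, sch, TR = TR, TEs = 0.0275,
    n_volumes = nv, activation_table = data.frame(
      roi = "motor", condition = "novel", amplitude = -0.08))
  fit0 <- fit_glm(drop_initial_volumes(simulate_epi_series(ids0), 10), des)
  expect_lt(abs(percent_signal_change(fit0, des, roi, "deviant")), 1e-8)
})

test_that("cluster inference finds a strong synthetic blob and nothing in zero maps", {
  d <- c(16, 16, 16)
  zero <- array(0, c(d, 8))
  tab <- cluster_inference(zero, n_perm = 100, seed = 1)
  expect_equal(nrow(tab), 0)
  # strong blob at a known location on a noise background
  set.seed(55)
  maps <- array(stats::rnorm(prod(d) * 12, 0, 1), c(d, 12))
  blob <- tiny_phantom()$roi_masks$motor  # a single connected blob
  for (s in 1:12) {
    m <- maps[, , , s]
    m[blob] <- m[blob] + 4
    maps[, , , s] <- m
  }
  maps <- smooth_gaussian(maps, fwhm_mm = 8, voxel_size = 8)
  tab2 <- cluster_inference(maps, n_perm = 200, seed = 2)
  sig <- tab2[tab2$p_fwe <= 0.05, ]
  expect_equal(nrow(sig), 1)
  # the significant cluster contains a blob centre voxel
  ctr <- which(blob, arr.ind = TRUE)[1, ]
  tv <- group_ttest(maps)$t
  thr <- stats::qt(1 - 0.001, 11)
  labs <- silentstar:::label_components6(array(tv > thr, d))
  expect_gt(labs[ctr[1], ctr[2], ctr[3]], 0)
})
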