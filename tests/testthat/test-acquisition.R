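test_that("trajectory counts and labels follow the looping structure", {
  tr <- make_trajectory(24, 3, 15, samples_per_spoke = 17,
                        nominal_resolution = 3.2, seed = 1)
  expect_equal(tr$spokes_per_segment, 72)
  expect_equal(tr$spokes_per_volume, 1080)
  expect_equal(tr$echo, tr$loop)
  norms <- sqrt(rowSums(tr$directions^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  # loops within a segment revisit the same circle of directions
  seg1 <- tr$directions[tr$segment == 1, ]
  expect_equal(seg1[1:24, ], seg1[25:48, ])
  # pseudo-random segment ordering is a permutation, reproducible under seed
  expect_setequal(tr$ordering, 1:15)
  tr2 <- make_trajectory(24, 3, 15, samples_per_spoke = 17,
                         nominal_resolution = 3.2, seed = 1)
  expect_identical(tr$ordering, tr2$ordering)
  # minimal configuration
  tr0 <- make_trajectory(1, 1, 1, samples_per_spoke = 4,
                         nominal_resolution = 3.2, seed = 1)
  expect_equal(tr0$spokes_per_volume, 1)
  expect_equal(tr0$echo, 1L)
  expect_error(make_trajectory(1, 1, 1, 4, nominal_resolution = 0),
               "nominal_resolution")
})

test_that("spoke directions cover the sphere without net bias", {
  tr <- make_trajectory(24, 3, 15, samples_per_spoke = 9,
                        nominal_resolution = 8, seed = 2)
  expect_lt(sqrt(sum(colMeans(tr$directions)^2)), 0.05)
})

test_that("forward model gives closed-form samples for simple objects", {
  n <- 16L
  tr <- make_trajectory(12, 1, 20, samples_per_spoke = 9,
                        nominal_resolution = 8, seed = 4, dead_samples = 0)
  # point object at the grid centre (the DC reference voxel): constant modulus
  delta <- array(0, dim = rep(n, 3))
  ctr <- n %/% 2L + 1L
  delta[ctr, ctr, ctr] <- 3
  ks <- sample_kspace_volume(delta, tr, voxel_size = 8)
  expect_true(all(abs(Mod(ks$samples) - 3) < 1e-9))
  # zero object: all samples zero
  ks0 <- sample_kspace_volume(array(0, rep(n, 3)), tr, voxel_size = 8)
  expect_true(all(Mod(ks0$samples) == 0))
  # uniform object: DC node = object sum, off-DC nodes = 0
  ksu <- sample_kspace_volume(array(2, rep(n, 3)), tr, voxel_size = 8)
  nodes <- silentstar:::trajectory_nodes(tr, n, 8)
  dc_node <- (ctr - 1) * (1 + n + n^2) + 1
  at_dc <- nodes == dc_node
  expect_true(all(abs(ksu$samples[at_dc] - 2 * n^3) < 1e-6))
  expect_true(all(Mod(ksu$samples[!at_dc]) < 1e-6))
})

test_that("sampled spectra of real objects are conjugate symmetric", {
  n <- 16L
  set.seed(8)
  vol <- array(stats::rnorm(n^3), rep(n, 3))
  F <- silentstar:::centered_fft3(vol)
  cen <- n %/% 2L
  # F(-k) = conj(F(k)) with indices wrapped modulo n about the DC node
  for (trial in 1:50) {
    k <- sample(0:(n - 1), 3) - cen
    pos <- (k + cen) %% n + 1L
    neg <- (-k + cen) %% n + 1L
    expect_equal(F[pos[1], pos[2], pos[3]],
                 Conj(F[neg[1], neg[2], neg[3]]), tolerance = 1e-9)
  }
})

test_that("complex acquisition noise matches the configured variance", {
  n <- 16L
  tr <- make_trajectory(24, 1, 40, samples_per_spoke = 17,
                        nominal_resolution = 8, seed = 5, dead_samples = 0)
  ks <- sample_kspace_volume(array(0, rep(n, 3)), tr, voxel_size = 8,
                             noise_sd = 0.7, seed = 6)
  v <- mean(Mod(ks$samples)^2)  # complex variance = E|z|^2
  expect_lt(abs(v / 0.49 - 1), 0.05)
})

test_that("dead-time blanking stores the centre samples for reacquisition", {
  ph <- tiny_phantom()
  sch <- short_schedule()
  ids <- simulate_bold_series(ph, sch, TR = 2.5, TEs = c(0, 0.016, 0.032),
                              n_volumes = 3)
  tr <- make_trajectory(6, 3, 8, samples_per_spoke = 7,
                        nominal_resolution = 8, seed = 7, dead_samples = 2)
  ks <- sample_kspace(ids, tr, noise_sd = 0, seed = 8)
  expect_true(all(is.na(ks$samples[ks$dead_idx, ])))
  expect_false(anyNA(ks$samples[-ks$dead_idx, ]))
  # noiseless reacquisition equals the forward-model values
  merged <- merge_center_reacquisition(ks)
  expect_false(anyNA(merged$samples))
  # echo-count mismatch is an error
  tr2 <- make_trajectory(6, 2, 8, samples_per_spoke = 7,
                         nominal_resolution = 8, seed = 7)
  expect_error(sample_kspace(ids, tr2), "echo")
})

test_that("EPI simulator: identity, AR(1) autocorrelation, reproducibility", {
  ph <- tiny_phantom()
  sch <- short_schedule()
  ids <- simulate_bold_series(ph, sch, TR = 2.5, TEs = 0.0275,
                              n_volumes = 40)
  clean <- simulate_epi_series(ids, noise_sd = 0, drift_coeffs = 0)
  for (t in c(1, 20, 40))
    expect_equal(clean[, , , t], ideal_volume(ids, 1, t))
  # reproducible under seed
  a <- simulate_epi_series(ids, noise_sd = 0.01, ar1_rho = 0.3, seed = 9)
  b <- simulate_epi_series(ids, noise_sd = 0.01, ar1_rho = 0.3, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_epi_series(ids, ar1_rho = 1.2), "ar1_rho")
  # lag-1 autocorrelation of pure noise matches rho = 0.3
  sch_long <- generate_schedule(paradigm_config(
    initial_silence = 25, total_duration = 1000, n_rest_blocks = 3L,
    seed = 6))
  ids2 <- simulate_bold_series(ph, sch_long, TR = 2.5, TEs = 0.0275,
                               n_volumes = 400,
    activation_table = data.frame(roi = character(0),
                                  condition = character(0),
                                  amplitude = numeric(0)))
  noisy <- simulate_epi_series(ids2, noise_sd = 0.05, ar1_rho = 0.3,
                               seed = 10)
  d <- dim(noisy)
  m <- matrix(noisy, prod(d[1:3]), d[4])
  vox <- which(as.vector(ph$gm_mask))[1:400]
  e <- m[vox, ] - rowMeans(m[vox, ])
  rho_hat <- sum(e[, -1] * e[, -d[4]]) / sum(e^2)
  expect_lt(abs(rho_hat - 0.3), 0.02)
})
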