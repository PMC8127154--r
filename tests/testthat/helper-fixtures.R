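# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

tiny_phantom <- function() {
  memo("phantom16", function() build_phantom(
    phantom_spec(grid_shape = 16L, voxel_size = 8)))
}

# short run matched to a 120-volume TR 2.5 s scan
short_schedule <- function(seed = 5L) {
  memo(paste0("sched", seed), function() generate_schedule(
    paradigm_config(initial_silence = 25, total_duration = 301,
                    n_rest_blocks = 3L, seed = seed)))
}

# activation restricted to modelled conditions (no Standard response), for
# exact GLM recovery checks free of model mismatch
modelled_activation <- function() {
  data.frame(roi = c("auditory", "auditory", "motor", "motor"),
             condition = c("deviant", "novel", "deviant", "novel"),
             amplitude = c(-0.12, -0.12, -0.08, -0.08),
             stringsAsFactors = FALSE)
}

# smooth test object for gridding oracles (Gaussian blobs, 16^3)
smooth_blob <- function(n = 16L) {
  g <- seq_len(n); ctr <- (n + 1) / 2
  r2 <- outer(outer((g - ctr)^2, (g - ctr)^2, `+`), (g - ctr)^2, `+`)
  r2b <- outer(outer((g - ctr - 3)^2, (g - ctr + 2)^2, `+`),
               (g - ctr - 1)^2, `+`)
  exp(-r2 / (2 * 3^2)) + 0.5 * exp(-r2b / (2 * 2.5^2))
}

# trajectory whose rounded samples visit every Cartesian node of a 16^3 grid
# (radius oversampled to reach the corners; wrapping is consistent between
# the forward model and gridding)
full_coverage_traj <- function() {
  memo("fulltraj", function() make_trajectory(
    spokes_per_loop = 48L, n_echoes = 1L, n_segments = 160L,
    samples_per_spoke = 33L, nominal_resolution = 8 / sqrt(3), seed = 3L,
    dead_samples = 0L))
}

# one cohort draw of the subject x session activation-gain table, via the
# cohort simulator on a minimal scan
cohort_gain_table <- function(seed, n_subjects = 12L, subject_amp_sd = 0.2,
                              session_amp_sd = 0.1) {
  ev <- data.frame(onset = 4.5, duration = 0, trial_type = "deviant",
                   tone_id = "tone_B", stringsAsFactors = FALSE)
  sch <- structure(list(events = ev, config = NULL, swap_time = NA,
                        n_tones = 1L), class = "oddball_schedule")
  co <- cohort_spec(n_subjects = n_subjects, subject_amp_sd = subject_amp_sd,
                    session_amp_sd = session_amp_sd, seed = seed)
  sim <- simulate_cohort(tiny_phantom(), co, function(s) sch,
                         TR = 2.5, TEs = 0.0275, n_volumes = 2)
  m <- sim$manifest
  matrix(m$amp_scale, nrow = n_subjects, byrow = TRUE)
}

# brute-force two-way mean-square ICC(3,1) oracle via stats::aov
icc31_aov_oracle <- function(y) {
  df <- data.frame(v = as.vector(y),
                   subj = factor(rep(seq_len(nrow(y)), ncol(y))),
                   sess = factor(rep(seq_len(ncol(y)), each = nrow(y))))
  ms <- summary(stats::aov(v ~ subj + sess, data = df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (ncol(y) - 1) * ms[3])
}
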