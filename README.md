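# silentstar

Synthetic-data simulation and analysis of **near-silent multi-echo 3D radial
fMRI** ("Looping Star" style) versus **conventional single-echo EPI** during
an auditory oddball task.

MRI acoustic noise is a real confound for auditory experiments: the scanner
can be louder than the stimuli it is supposed to probe. Near-silent radial
sequences sidestep this, but they acquire k-space along spokes, produce a
task-insensitive FID image plus T2\*-weighted echoes, and need gridding
reconstruction and echo combination before a standard event-related
analysis can run. This package implements the full evaluation chain on
simulated data with known ground truth, for methodologists who want to test
the analysis machinery — paradigm statistics, reconstruction operators, GLM
inference, test–retest reliability — without access to scanner data.

## What it implements

* **Oddball paradigm generator** — Standard/Deviant/Novel tones with
  probabilities .84/.09/.07, 80 ms events on a 705 ms slot grid, five
  initial Standards, ≥ 3 Standards between rare-tone onsets, six 10 s rest
  blocks, mid-run Standard↔Deviant identity swap; BIDS-style events TSV I/O
  and a rule-by-rule validator.
* **Digital head phantom** with tissue PD/R2\* maps, auditory and motor
  ROIs, and a TE-dependent BOLD model
  `S = PD · exp(−TE · (R2* + ΔR2*(t)))`, where ΔR2\*(t) follows the
  canonical double-gamma HRF; cohorts add subject/session variance
  components with an analytic ICC ground truth.
* **Acquisition simulators** — a segmented 3D radial multi-echo sampler
  (24 spokes/loop × 3 echoes × 15 segments = 1080 spokes/volume; TEs
  0/16.1/32.2 ms, TR 2.648 s; receiver dead-time centre loss with
  reacquisition) and an EPI-style image-space sampler (TE 27.5 ms,
  TR 2.5 s, polynomial drift, AR(1) noise).
* **Reconstruction** — density-compensated nearest-neighbour gridding
  (`w = max(|k|, Δk/2)²`), exactly invertible on fully sampled data.
* **Multi-echo processing** — log-linear T2\* mapping, TE-weighted /
  tSNR-weighted echo combination, tSNR maps with 2nd-order detrending,
  percentage-difference maps, Gaussian smoothing (8 mm FWHM).
* **GLM** — canonical HRF designs with implicit Standard baseline, 128 s
  DCT high-pass, pooled-ρ AR(1) prewhitening, contrast T-maps, group and
  paired t-tests, sign-flip permutation cluster inference (forming
  threshold p < .001), percent signal change

  `T = c′β̂ / √(σ̂² c′(X′X)⁻¹c)`
* **Reliability** — voxel-wise consistency ICC from two-way mean squares,

  `ICC(3,1) = (BMS − EMS) / (BMS + (k−1)·EMS)`,

  network-mask (T > 1) median ICC, per-subject intra-voxel ICC_v, exact
  (2ⁿ-enumeration) Wilcoxon signed-rank, Spearman correlation.
* **Pipeline orchestration** — `run_pipeline()` runs both arms end to end
  from a single master seed, deterministically, and returns maps, tables
  and a ground-truth manifest.

## Worked example

```r
library(silentstar)

cfg   <- paradigm_config()            # .84/.09/.07, 635 s run
sched <- generate_schedule(cfg, seed = 1)
sched
#> oddball_schedule: 777 tones ( 660 standard, 78 deviant, 39 novel ),
#>   6 rest blocks; swap at 330.725 s
head(sched$events[sched$events$trial_type != "standard", ], 3)
#>     onset duration trial_type   tone_id
#> 6  30.005     0.08    deviant    tone_B
#> 12 34.235     0.08      novel novel_001
#> 19 39.170     0.08    deviant    tone_B
```

777 tones with 78 deviants is a 10.0 % empirical deviant rate for this
seed; pooled over many schedules the rate converges to the configured .09.
`tone_B` identifies the deviant tone before the swap at 330.7 s, after
which it becomes the standard.

```r
fix <- make_fixtures("tiny", seed = 1)   # 16^3 phantom, 60 vols, 4 x 2 cohort
res <- run_pipeline(fix$config)

res$median_icc
#> $ls  [1] 0.0893   # radial arm, median ICC(3,1) in the task network
#> $epi [1] 0.0552   # EPI arm
res$manifest$truth_icc
#> [1] 0.8           # ICC of the underlying activation gains

round(cbind(radial = res$psc$ls[, 1], epi = res$psc$epi[, 1]), 3)
#>      radial   epi
#> [1,]  0.110 0.259
#> [2,]  0.086 0.204
#> [3,]  0.138 0.199
#> [4,]  0.108 0.358
```

The percent-signal-change values (deviant tones, auditory ROI) sit in the
0.1–0.4 % range typical of event-related auditory responses; the radial
arm's values are lower because radial under-sampling blurs the activation.
The voxel-level median ICC is far below the 0.8 gain-level ground truth at
this tiny scale — measurement noise attenuates ICC, which is exactly the
behaviour the reliability analysis is meant to expose.

```r
# the two ICC(3,1) reference cases
icc31_map(cbind(1:6, 1:6))$icc[1]                              # sessions identical
#> [1] 1
icc31_map(cbind(c(1,-1,1,-1,1,-1), c(-1,1,-1,1,-1,1)))$icc[1]  # no subject variance
#> [1] -1
```

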