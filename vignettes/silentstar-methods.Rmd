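---
title: "Simulating near-silent multi-echo radial fMRI versus EPI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating near-silent multi-echo radial fMRI versus EPI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentstar)
```

# Scope

`silentstar` is a synthetic-data laboratory for comparing two fMRI
acquisition strategies during an auditory oddball task: a near-silent
multi-echo 3D radial sequence of the Looping-Star family (spokes grouped
into loops, one refocused echo per loop, segments pseudo-randomly ordered)
and a conventional single-echo gradient-echo EPI acquisition. Because no
human data ship with the package, every analysis runs on a digital phantom
whose ground truth is fully recorded, so each stage — paradigm, acquisition,
reconstruction, echo combination, GLM, reliability — can be checked against
the values that generated the data.

# The oddball paradigm generator

Tones occupy a fixed slot grid of period `tone_duration + isi`
(80 ms + 625 ms = 0.705 s). The run opens with silence (ten repetition
times), then five forced Standard tones; afterwards each eligible slot draws
a non-standard tone with a fixed probability, subject to the constraint that
at least `min_standards_between` (3) Standard tones separate consecutive
non-standard onsets. Six 10-s silent rest blocks interrupt the grid at the
six interior points that divide the post-silence run into seven equal spans.
Halfway through (by tone index) a swap cue exchanges the identities of the
Standard and Deviant tones (`tone_A`/`tone_B`) without changing their roles,
and pauses the stream for one slot (a configuration flag, since the design
leaves the cue's timing behaviour open).

One modelling subtlety: a naive "draw with probability
$q = p_{dev} + p_{nov}$, reject while inside the spacing window" process
does *not* produce long-run non-standard fractions equal to $q$ — the forced
Standards dilute it to $q/(1 + mq)$. The generator therefore draws eligible
slots with the adjusted probability $q^\* = q/(1 - mq)$, which makes the
renewal process's stationary non-standard fraction exactly $q$. The
feasibility bound $q \le 1/(m+1)$ guarantees $q^\* \le 1$. The package
treats the configured probabilities as *marginal* tone-type frequencies,
which is what the acceptance checks measure (pooled fractions over 100
schedules within three standard errors of .09/.07/.84).

# Phantom and BOLD signal model

The phantom is a set of nested ellipsoids (grey matter shell, white matter
core, central CSF) on a 32³ grid at 4 mm — matching the 4 mm analysis
resolution of the study design — with a 16³/8 mm variant for fast tests.
Tissue parameters are proton density and $R_2^* = 1/T_2^*$, with 3 T
literature-order defaults ($T_2^*$: GM 66 ms, WM 53 ms, CSF 150 ms). Two
ROIs are carved from grey matter: a bilateral auditory region and a left
motor region (the button-press hand area).

BOLD is modelled purely as a transient change of the relaxation rate:

$$S(v, TE, t) = PD(v)\,e^{-TE\,(R_2^*(v) + \Delta R_2^*(v,t))}.$$

$\Delta R_2^*(v, t)$ is, per ROI, the sum over conditions of a peak
amplitude (1/s, negative for activation) times the canonical-HRF-convolved
event regressor, peak-normalized for an isolated event. The auditory ROI
responds to every tone (Standards weakly, Deviants/Novels more strongly);
the motor ROI responds to the rare tones only, standing in for the button
press. Default peak amplitudes (−0.06 s⁻¹ Standards, −0.12 s⁻¹ rare tones,
−0.08 s⁻¹ motor) give percent signal changes of roughly 0.2–0.4 % at
TE ≈ 30 ms — typical event-related auditory responses. The study that the
design follows does not quantify its expected per-tone signal change, so
these amplitudes are free parameters of the generator, recorded in every
cohort manifest. Inflow and blood-volume effects are deliberately absent,
and the $TE = 0$ FID channel carries no task contrast by construction — a
property the tests exploit.

Cohorts draw a multiplicative activation gain $1 + a_i + b_{is}$ per subject
$i$ and session $s$, with $a_i \sim N(0, \sigma_s^2)$ shared across sessions
and $b_{is} \sim N(0, \sigma_e^2)$ per session. Defaults
($\sigma_s = 0.2$, $\sigma_e = 0.1$, 12 subjects × 2 sessions) make the
analytic consistency ICC of the gains
$\sigma_s^2/(\sigma_s^2 + \sigma_e^2) = 0.8$.

# Acquisition models

**Radial multi-echo arm.** The trajectory mirrors the published counts — 24
spokes per loop, 3 echoes (so 72 spokes per segment), 15 segments, 1080
spokes per volume, TEs 0/16.1/32.2 ms, TR 2.648 s. The published source
gives counts but not the loop geometry, so each segment's loops lie on a
great circle with a pseudo-random pole, repeated once per echo; this
satisfies the structural invariants (echo = loop index, near-uniform
direction coverage, zero mean direction) without claiming to reproduce the
exact gradient design. The forward model evaluates the centered 3D DFT of
each echo volume *at the nearest Cartesian grid node* of every trajectory
sample (grid convention: DC at 0-based index ⌊N/2⌋; node indices wrap
modulo N, which is exact for the periodic DFT). Sampling at nodes rather
than exact off-grid frequencies makes nearest-neighbour gridding an exact
inverse on fully sampled data, giving the reconstruction a machine-precision
oracle; under-sampling (fewer segments) reproduces the blurring that the
real sequence's acceleration incurs. Receiver dead time blanks the first
`dead_samples` (default 2) centre samples of FID spokes; they are re-measured
in a separate pass with independent noise of the same level, mimicking the
end-of-scan centre reacquisition, and merged before gridding.
Echo-in/echo-out interference is available as an optional term (amplitude ×
conjugate of the sample-reversed spoke) and defaults to off, matching a
pipeline that mitigates it by echo combination rather than filtering.
Complex white noise has total variance `noise_sd²` split between quadratures.

**EPI-style arm.** TE 27.5 ms, TR 2.5 s. Simulated directly in image space:
ideal series + polynomial drift (coefficients applied to time rescaled to
[−1, 1] and scaled by the voxel's baseline) + stationary AR(1) Gaussian
noise (marginal SD `noise_sd`, lag-1 correlation `ar1_rho`). Slice timing,
motion and bias fields are out of scope: synthetic data are generated
motion-free in a common space.

# Reconstruction

Density compensation uses $w = \max(|k|, \Delta k/2)^2$ normalized to unit
mean — the $|k|^2$ growth appropriate for 3D radial sampling, clamped so the
centre sample keeps positive weight. Gridding deposits each sample on its
nearest node; a node's value is the *weighted mean* (not sum) of its
contributors, which is what makes full sampling exactly invertible under
the matched forward model (the alternative sum convention is not, and no
published normalization was stated to follow). Unvisited nodes are zero;
images are magnitudes of the centered inverse FFT. No oversampled grid and
no apodization are used — this is nearest-neighbour gridding, not
convolution gridding, and the exactness oracle depends on that choice.

Consequence worth knowing: with a radius limited to $k_{max}$ the corners of
k-space are never sampled, so sharp-edged objects reconstruct with NRMSE
well above the smooth-object figure (≈0.15 for the tissue phantom at 16³).
That is physics, not a bug; the inversion oracle uses smooth objects and a
corner-reaching (oversampled-radius) trajectory.

# Multi-echo processing

$T_2^*$ comes from a log-linear least-squares fit of the temporal-mean
signal over all echoes including the FID, clamped to [5, 300] ms — fitting
the mean rather than each time point matches the static-$T_2^*$ assumption
of the signal model. The default `te_weighted` combination uses matched
filter weights $w_e \propto TE_e\,e^{-TE_e/T_2^*}$, normalized per voxel;
at $TE = 0$ the weight vanishes, so the FID is effectively excluded — the
published pipeline used the same weighting, and whether its FID contributed
is not stated, so a `tsnr_weighted` alternative ($w_e \propto tSNR_e^2$),
which retains the FID, ships alongside. Under equal thermal noise per echo
the task-insensitive FID necessarily has the highest raw tSNR, so the
te-weighted series is benchmarked against the best *BOLD-sensitive* echo
(which it beats), while the tsnr-weighted scheme is required to match or
beat every single echo including the FID.

tSNR is mean over time divided by the residual SD after second-order
polynomial detrending; adding any zero-mean drift in the span of that basis
leaves the map bit-for-bit unchanged. The between-modality difference map is
$100\,(a - b)/(a + b)$, clamped to [−100, 100]. Smoothing is a separable
Gaussian (FWHM 8 mm by default) with half-sample-symmetric reflection at
the boundaries, chosen because that padding conserves total mass for any
kernel, so constant volumes and volume means are preserved.

# GLM

The canonical HRF is the standard double-gamma (peak 6 s, undershoot 16 s,
unit dispersions, undershoot ratio 1/6, 32 s support) scaled to unit peak.
Designs model Deviant and Novel tones as zero-duration impulses and Silent
rest periods as 10-s boxcars, all convolved at microtime resolution TR/16
and sampled at volume onsets; Standard tones are deliberately unmodelled
(implicit baseline, avoiding over-parameterisation). A discrete-cosine
drift basis of size ⌊2·duration/cutoff⌋ implements the 128 s high-pass;
all-zero condition columns are flagged and dropped so degenerate schedules
stay estimable. The first ten volumes are excluded before sampling.

AR(1) handling replaces full restricted-maximum-likelihood estimation with
a pooled-ρ Cochrane–Orcutt transform: fit OLS, pool the lag-1 residual
autocorrelation over the mask, transform rows (first row scaled by
$\sqrt{1-\rho^2}$), refit. This preserves the AR(1) intent with a closed
form that simulations can verify (ρ̂ recovered within 0.05 at ρ = 0.3,
230 volumes).

On the high-pass "protection" property: a slow confound lying in the span of
the drift basis changes condition betas by exactly nothing (orthogonal
projection), and the basis absorbs ≥ 90 % of the energy of arbitrary-phase
sinusoids slower than twice the cutoff. A stronger amplitude-free claim —
that *any* slow sinusoid leaves betas within 1 % — is not attainable by any
finite-window filter: 1–6 % of the confound's amplitude leaks into the
event betas, which matters because task betas are only ~0.3 % of the mean
signal. The tests therefore assert the two well-posed properties above.

Group inference is a voxel-wise one-sample (or paired) t across subjects.
Cluster-level family-wise error control uses sign-flip permutations: 6-
connected components above the one-sided t threshold for p < .001, corrected
p = proportion of permutations (plus identity) whose maximum cluster size
reaches the observed one. This replaces Gaussian-random-field correction,
whose smoothness estimation is out of scope; permutation is exact under
exchangeability, which the calibration test verifies (family-wise error
within the binomial 95 % interval of 0.05 over 200 global-null replicates at
16³, 12 subjects, n_perm = 100). One-sided tests are used for directional
contrasts; presets cover Dev + Nov > Silent, Dev + Nov > baseline, Nov > Dev
and its reverse, and Nov/Dev > baseline.

Percent signal change is $100\,\hat\beta_{cond}\,h_{peak}/\hat\beta_{const}$
averaged over an ROI, where $h_{peak}$ is the maximum of a single isolated
zero-duration event regressor built at TR/16 — with the unit-peak HRF this
is ≈ 1, so PSC is essentially the condition beta as a percentage of
baseline. The published batch-scaling rule ("dependent on the time-bin") is
under-specified, so this microtime rule is declared rather than inferred.

# Reliability

ICC(3,1) is computed from two-way *mean* squares (between-subject BMS,
residual EMS after removing subject and session main effects):

$$ICC(3,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS}.$$

The source text says "sum of squares", but the cited toolbox and the
Shrout–Fleiss definition use mean squares, and for balanced k = 2 designs
the choice changes values — the mean-square convention is declared and is
what the brute-force ANOVA oracle verifies to 1e-12. Endpoints behave as
described: EMS = 0 gives +1; BMS = 0 gives −1 for k = 2. The network mask
is grey matter ∧ (session-1 group T > 1) — a deliberately low threshold so
cluster-extent differences between modalities do not bias the mask — and
the map is summarized by its median inside that mask. Intra-voxel
reliability applies the same decomposition with ROI voxels as rows and
sessions as columns, one scalar per subject; it is invariant to per-session
additive offsets and common positive rescaling, and undefined for
voxel-constant patterns.

The finite-sample ICC estimator is biased slightly downward (≈ −0.03 at
n = 12, k = 2, ICC 0.8). The recovery test accounts for this exactly: under
normality BMS/EMS is a scaled F(n−1, (n−1)(k−1)) variate, so the expected
value of the estimator is computed by quadrature and the Monte-Carlo mean
over 200 simulated cohorts is required to match it within sampling error,
with the true variance-component ratio inside the central 95 % interval of
the estimates.

Paired modality comparisons: the Wilcoxon signed-rank test enumerates all
2ⁿ sign patterns exactly for n ≤ 15 (for the 12-subject design: all
differences positive gives the exact two-sided p = 2/2¹² ≈ 0.00049) and
falls back to the tie-corrected normal approximation with continuity
correction above; Spearman's rho is Pearson correlation on midranks.

# Pipeline, determinism, and problem sizes

`run_pipeline()` chains every stage for both arms: schedules (one per
modality, shared across subjects and sessions, as in the source design) →
phantom and cohort draws → acquisition → gridding reconstruction →
$T_2^*$/combination (radial arm) → volume dropping → smoothing → first-level
GLM with AR(1) → group maps and sign-flip cluster inference → PSC → ICC maps,
network-mask median ICC, per-subject ICC_v → paired between-modality
comparisons. A single master seed fans out to per-stage seeds through a
stable hash (`stage_seed`), so any stage can be reproduced in isolation and
two runs of the same configuration are identical object-for-object. The
radial arm's k-space noise SD is scaled as `noise_sd · N^{3/2}` so both arms
see comparable image-space noise.

Two problem sizes are built in. The `default` scale mirrors the study
conditions (32³ at 4 mm, 240 volumes, 12 × 2 cohort). The `tiny` scale
(16³ at 8 mm, 60 volumes, 4 × 2 cohort, 3 rest blocks, a reduced trajectory
of 12 spokes/loop × 10 segments) exists so that the entire end-to-end suite
— including two full pipeline runs for the determinism check and a
strong-activation cluster check — completes in a couple of minutes on one
CPU. Statistical calibration tests use whatever size their power demands
(e.g. 200 cluster-inference replicates at 16³, 230-volume AR(1) fits).

# What passing tests do and do not show

The generator emulates: event-driven $\Delta R_2^*$ dynamics with the
correct TE dependence, thermal and AR(1) noise, polynomial drift,
subject/session variance components, radial under-sampling blur, dead-time
centre loss, and the acoustic-design difference expressed as the two
acquisition geometries. It does not emulate: head motion, physiological
noise and pulsation, field inhomogeneity and distortion, slice profiles,
coil sensitivities, inflow, or realistic anatomy. Passing tests therefore
demonstrate that the *analysis machinery* is correct and calibrated on data
whose generative model is known — not that the two modalities would compare
the same way in vivo. Scanner hardware quantities (sound levels) and
human-data statistics are out of scope by design.

# Known limitations

* Nearest-neighbour gridding trades accuracy for testability; convolution
  gridding or iterative reconstruction would blur less at equal sampling.
* The pooled-ρ AR(1) model whitens all voxels with one coefficient.
* The loop geometry is a uniform stand-in satisfying the published counts,
  not the actual gradient waveform design.
* ICC ground truth applies to activation *gains*; voxel-level ICC in the
  imaging pipeline is additionally attenuated by measurement noise, which
  the tiny-scale pipeline makes visible (median ICC well below the gain
  ICC) — a realistic property, not an error.
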