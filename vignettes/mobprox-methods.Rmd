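---
title: "Methods: two-parameter track classification and differential interactome calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-parameter track classification and differential interactome calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(mobprox)
```

mobprox implements two quantitative procedures used to study how a
transcription factor occupies chromatin and which partners it contacts in
live cells: a two-parameter motion classification of single-molecule
tracking (SMT) trajectories, and a differential interactome caller for
TurboID proximity-labeling proteomics. This vignette is the package's own
account of both methods: the models, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the procedures left genuine freedom.

## 1. Single-molecule track classification

### The model

A molecule imaged at 100 Hz (frame interval $\Delta t = 10$ ms) yields a
2D trajectory $(x_k, y_k)$. Its time-averaged mean squared displacement
(TA-MSD) at lag $\tau$ frames,

$$\mathrm{MSD}(\tau) \;=\; \big\langle\, (x_{k+\tau}-x_k)^2 + (y_{k+\tau}-y_k)^2 \,\big\rangle_k ,$$

behaves as $\mathrm{MSD}(\tau) \propto \tau^{\alpha}$ for the motion types
of interest. The anomalous exponent $\alpha$ separates sub-diffusive
(confined, chromatin-bound) motion from free Brownian diffusion and
drift-like (directed) transport. The classifier applies fixed boundaries:

* $\alpha \le 0.7$ — **Confined** (boundary inclusive),
* $0.7 < \alpha < 1$ — **Brownian**,
* $\alpha \ge 1$ — **Directed**.

Two further per-track statistics feed the downstream mobility analysis:
the **radius of confinement** $R_c$, obtained by fitting the
confined-diffusion saturation model

$$\mathrm{MSD}(\tau) \;=\; R_c^2\left(1 - e^{-4 D \tau \Delta t / R_c^2}\right),$$

whose plateau is $R_c^2$; and the **mean frame-to-frame jump**, the average
displacement between consecutive frames.

Localization error matters here: each reported coordinate carries an
independent Gaussian error $\sigma_{loc}$, which adds a constant
$4\sigma_{loc}^2$ to every observed MSD value. At 30 nm precision that
floor is 0.0036 µm², comparable to the one-frame MSD of a slowly diffusing
molecule, and it systematically flattens fitted exponents — pure Brownian
tracks fit around $\alpha \approx 0.85$–$0.95$ rather than exactly 1. This
is not a defect to correct but a property of real SMT data the class
boundaries implicitly assume (see Section 3).

### Pipeline stages and filters

`run_classification()` fixes the stage order: duration filter → per-track
features → butterfly detection and segmentation → segment features →
$\alpha$ classification → confined-jump filter → seeded down-sampling. The
stage order is logged with row counts per stage, since the filters do not
commute in general.

* **Duration filter.** Tracks shorter than five frames (`min_duration = 5`,
  counting localizations, not frame span) are discarded; four points
  cannot support the lag 1–4 MSD window.
* **Butterfly detection.** Tracks mixing confined dwelling with free
  excursions ("butterfly" tracks) betray themselves by a jump far above
  their own average. The default rule flags step $i$ when
  $j_i > \bar j \times (1 + 1.5)$, i.e. 2.5× the track's mean jump. The
  stated rule — a jump exceeding "the average jump plus a threshold of
  1.5" — is ambiguous about units and semantics, so all three readings are
  implemented: `relative` (default; unit-free, robust to magnification),
  `additive_sd` ($\bar j + 1.5\,s_j$) and `absolute` (a length in µm).
  None is asserted to be the original.
* **Segmentation.** A flagged track is split at each outlier step; the
  split displacement belongs to neither segment. Segments re-enter feature
  extraction and classification under their parent's id; segments shorter
  than five frames are discarded, and the parent itself is excluded from
  the final table. Segments are not re-tested for splits (one pass).
* **Confined-jump filter.** Confined rows — whole tracks and confined
  butterfly segments alike — with a mean jump above 100 nm
  (`confined_jump_max_um = 0.1`) are removed: a molecule hopping more than
  a pixel per frame is not chromatin-bound regardless of its fitted
  exponent. Rows of other classes are untouched.
* **Down-sampling.** To compare conditions at matched statistical weight,
  the final table is down-sampled to 20,000 tracks, three times, without
  replacement, from seeded streams `seed + 1..3`. All filters are
  idempotent and the whole pipeline is deterministic given the seed.

### Numerical choices

* The TA-MSD uses **all overlapping pairs** per lag — the standard
  lowest-variance estimator — and, under linking gaps, matches frame
  indices rather than row positions; lags with no pair are omitted.
* $\alpha$ is the least-squares slope of $\log \mathrm{MSD}$ vs
  $\log \tau$ over **lags 1–4** (`alpha_lag_range`). Short tracks dominate
  SMT data, and short lags are where the power law is cleanest before
  confinement saturates the curve; the window is configurable. Lags with
  non-positive MSD are excluded; fewer than two usable lags marks the
  track `fit_ok = FALSE` and it is dropped (and counted) rather than
  guessed at.
* $R_c$ comes from a Levenberg–Marquardt fit (via minpack.lm) of the
  saturation model with both $R_c$ and $D$ free, started at
  $R_c^{(0)} = \sqrt{\max \mathrm{MSD}}$ and
  $D^{(0)} = \mathrm{MSD}(1)/4\Delta t$. If the optimizer fails, the
  fallback is the geometric plateau estimate
  $\sqrt{\overline{\mathrm{MSD}}}$ over the last quartile of lags, flagged
  in the result. For unconfined tracks the model has no plateau and the
  fitted $R_c$ is large and ill-determined — which is harmless, and even
  useful, because the mobility gating only needs "large".
* The mean jump uses **consecutive-frame pairs only**; displacements
  across linking gaps are excluded ("frame-to-frame" is read literally).
  A track with no consecutive pair yields `NA` and is flagged.

### Two-parameter mobility gating

Histone H2B is essentially fully chromatin-incorporated, so its
distribution in the (radius of confinement, mean jump) plane anchors what
"chromatin-like" motion looks like in a given imaging configuration.
`calibrate_gates()` cuts axis-aligned rectangles at marginal percentiles
of the H2B features: **LoMC** (low-mobility chromatin) below the 75th
percentile of both marginals, **HiMC** (high-mobility chromatin) above the
95th. Percentile gates were chosen over density contours because they are
reproducible, parameter-light and anchored to the calibration data; the
defaults 75/95 mark the dense core and sparse tail of the reference
distribution, and `lo_pct < hi_pct` is enforced so the gates stay
disjoint. Gating operates in linear µm space since the thresholds quoted
in nm are linear. Boundaries are inclusive; in the degenerate case where
both gates touch, LoMC wins the tie. `summarize_mobility()` reports
per-replicate gate fractions and their mean ± s.d. (sample s.d., $n-1$)
across the three down-sampled replicates; `compare_conditions()` emits the
tidy long table a standard two-way ANOVA consumes — the ANOVA itself is
deliberately left to standard tools.

## 2. TurboID differential interactome calling

### The procedure

Input is a label-free intensity matrix over the canonical design: bait
groups WT and R35A, controls TurboID-only and noDox, four replicates each.
The stages, in fixed order:

1. **QC filter** — drop potential contaminants, reverse (decoy) hits and
   proteins identified only by a modification site.
2. **Valid-value filter** — keep a protein only if some group has valid
   values in all four of its replicates.
3. **log2 transform.**
4. **Left-shifted imputation** — missing LFQ values are predominantly
   below-detection (left-censored), so each missing cell is drawn from
   $\mathcal N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$, where
   $\mu_s, \sigma_s$ are the observed mean and s.d. of that sample column.
   Imputation is per column (the Perseus convention) and seeded; observed
   cells are bit-identical before and after. `imputation_diagnostics()`
   verifies the realized moments.
5. **Dual-control enrichment** — for each protein, log2 fold change and a
   two-sided two-sample t-test of the bait samples against each control,
   BH-adjusted across all proteins within a comparison. The t-test is
   Student (equal-variance) by default — the conventional choice at
   $n = 4$ — with Welch selectable.
6. **Significance calling** — an interactor must be >2-fold enriched
   (strictly) *and* pass adjusted $p < 0.05$ (strictly) against **both**
   controls.
7. **Differential scoring** — with the per-protein contrast
   $\Delta = \overline{\log_2 \mathrm{WT}} - \overline{\log_2 \mathrm{R35A}}$,
   proteins strictly outside the cohort mean ± 3 s.d. are labelled
   WT- or R35A-preferential.

### Design decisions

* **Pooled bait case.** Whether enrichment against the controls was tested
  per bait or with both bait groups pooled is not fixed by the procedure's
  description; `call_interactors()` pools WT + R35A (eight samples) so
  each protein gets a single log2FC and adjusted p per control, matching
  the one-value-per-control shape of the calls table. Per-bait testing
  remains available through `test_enrichment()` directly.
* **Differential cohort.** The mean and s.d. of $\Delta$ are computed over
  *all* quantified proteins (the population a volcano plot shows), not
  only called interactors; `differential_cohort = "significant"` switches
  to the narrower reading. With a zero-spread cohort nothing is labelled.
* **Single imputation pass.** Both control comparisons and the WT/R35A
  contrast reuse one imputed matrix, so all statistics refer to the same
  completed data.
* Zero pooled variance in a t-test yields $p = 1$ when the means agree and
  the smallest representable p otherwise, flagged `degenerate` rather than
  propagating `NaN`.

## 3. What the synthetic data emulate — and what they do not

The generators exist so that every stage is testable against known ground
truth without any external data; their defaults were fixed once, from
values typical of live-cell SMT and LFQ proteomics, and are not tuned to
any particular dataset.

**Trajectories** (`simulate_tracks()`): mixtures of four motion classes at
$\Delta t = 10$ ms with independent Gaussian localization error
($\sigma_{loc} = 30$ nm by default) and geometric (photobleaching-like)
track lengths, minimum 1, mean 30 frames. Per-class defaults: Brownian
$D = 0.3$ µm²/s (a slow, chromatin-interacting fraction; the tracking
step's 3 µm²/s bound caps plausible values); confined $D = 0.1$ µm²/s,
$R_c = 80$ nm, so confinement saturates the MSD inside the lag 1–4 window;
directed $D = 0.01$ µm²/s with $v = 4$ µm/s, a drift strong enough that
the fitted exponent clears 1 despite the $4\sigma_{loc}^2$ noise floor;
butterfly tracks run confined and switch to directed at 3/4 of the track,
position-continuous at the switch. Confinement is implemented as hard
radial reflection at a circle about the start point — the single-parameter
reading of a "radius of confinement" — with the consequence that true
positions never leave the disk (a harmonic-well picture would only
penalize excursions). The H2B reference is 85% tightly confined
($D = 0.02$ µm²/s, $R_c = 60$ nm) plus a 15% mobile fraction.

Two consequences of these conditions are worth stating because the test
suite depends on them:

* *Localization noise is part of the study conditions.* A noise-free
  Brownian track fits $\alpha$ centred exactly on the 1.0 class boundary,
  so roughly half of such tracks would be labelled Directed no matter how
  well the estimator works; with the realistic 30 nm error the Brownian
  population sits near $\alpha \approx 0.86$, inside its band. Class-recovery
  checks therefore run with the default noise, while estimator-recovery
  checks (mean $\alpha \to 1$) run noise-free.
* *The relative butterfly rule splits long tracks often.* For Gaussian
  steps the probability that a single jump exceeds 2.5× the track mean is
  ≈ 0.7%, so a 1000-frame track is almost surely split at least once
  whatever its class. Track-level class recovery is accordingly scored by
  the majority class among a track's retained rows (its segments, or the
  whole track), with butterfly trues scored by detection. This is the
  natural track-level reading once one accepts that segmentation, not the
  parent label, is what feeds the downstream table.

Not emulated: blinking and gap-closing photophysics, stage drift,
chromatic aberration, 3D motion, state switching other than the single
butterfly changepoint, and any spatial heterogeneity of the nucleus.
Passing tests demonstrate that the estimators and filters do what their
definitions say under these idealized conditions — not that the biological
conclusions drawn from any particular real dataset are correct.

**Proteomics** (`simulate_proteomics()`): per-protein baseline abundance
$\log_2 I \sim \mathcal N(25, 2^2)$ (typical LFQ scale), replicate noise
0.3 on the log2 scale, planted per-group log2 effects, and left-censored
missingness $P(\mathrm{missing}) = \mathrm{logistic}((22 - \log_2 I)/1)$ —
lower-intensity values vanish more often, the MNAR behaviour that
justifies left-shifted imputation. QC flags are planted at 2% each.
Not emulated: peptide-level roll-up, shared peptides, between-run
normalization drift, and correlation between missingness across
replicates.

## 4. Problem sizes and degenerate inputs

The test suite and the acceptance script use deliberately moderate sizes —
hundreds of tracks of 500–1000 frames for classification checks, 500-track
sweeps for the filter checks, 1,000–2,500 protein matrices with ≥ 10,000
imputed cells for the imputation moments — chosen as the smallest scales
at which the Monte-Carlo noise of each check is comfortably below its
tolerance.

Degenerate inputs are contracts, not accidents: empty track sets flow
through every stage and produce empty outputs; constant tracks yield zero
MSD, a failed $\alpha$ fit (flagged, dropped, counted) and $R_c = 0$; a
flat MSD curve takes the $\sqrt{\mathrm{plateau}}$ fallback; a gap-only
track has no consecutive jump and is flagged; all-flagged proteomics
matrices empty with a warning rather than erroring.

## 5. Known limitations

* The $\alpha$/jump thresholds are fixed conventions; no uncertainty is
  propagated through the class labels, and tracks near a boundary are
  assigned, not flagged.
* The $R_c$ fit assumes a single confinement domain per track (or per
  segment); molecules sampling several domains within one segment get an
  effective radius.
* Gates are rectangles; a correlated H2B distribution would be gated more
  tightly by a density contour (config-selectable in principle, not
  implemented).
* The imputation model is unconditionally left-shifted per column; for
  data missing at random it biases fold changes toward zero for
  low-coverage proteins, and the dual-control design only partly cancels
  this.
* The caller treats replicates as independent; batch structure must be
  handled upstream.
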