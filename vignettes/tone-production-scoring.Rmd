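---
title: "Scoring lexical tone production: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lexical tone production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonetrace)
```

## The two accuracy constructs

Experiments on non-native lexical tone learning typically measure
production at two levels that dissociate empirically:

* **Phonetic accuracy**: how close the *shape* of a produced F0 contour is
  to the target contour, regardless of whether the speaker linked it to
  the right word. Measured here on imitation-task trajectories.
* **Phono-lexical accuracy**: whether the speaker produced the *correct
  categorical* tone (and segments) for a lexical item, regardless of
  fine-grained phonetic detail. Measured on picture-naming productions.

`tonetrace` implements both scoring chains plus a synthetic experiment
generator that produces data with known ground truth, so each stage can be
validated end to end without audio.

## Phonetic accuracy: the feature chain

### T-value normalization

Raw F0 (Hz) confounds tone shape with voice register: a bass and a soprano
produce the same tone in disjoint frequency bands. Each speaker's samples
are therefore mapped onto a speaker-relative five-point scale:

$$T = 5 \cdot \frac{\log_{10} x - \log_{10} x_{\min}}
                   {\log_{10} x_{\max} - \log_{10} x_{\min}}$$

where $x_{\min}, x_{\max}$ are the speaker's F0 floor and ceiling. The
transform is logarithmic because pitch perception is; its endpoints are 0
and 5 by construction (the ratio is computed before the scaling so the
anchors are exact in floating point). Design choices:

* **Range scope.** The floor/ceiling are pooled over *both* experiment
  days (per-day ranges are available via `speaker_range(per_day = TRUE)`),
  so a speaker's Day-1 and Day-2 coefficients share one scale.
* **Range timing.** Ranges are estimated from repaired but *untruncated*
  trajectories: the first/last samples carry the contour extremes of rises
  and falls, and estimating the range after edge truncation would
  systematically shrink it and inflate all T-values.
* **Clamping.** Samples outside the supplied range (possible with
  externally supplied or per-day ranges) are clamped to $[0, 5]$ with a
  warning by default; `strict = TRUE` turns this into an error.

### Repair and truncation

Pitch trackers produce missing frames and octave jumps. `repair_contour()`
replaces missing samples and spikes by linear interpolation *in log-F0*
(geometric interpolation in Hz, consistent with the log-domain
normalization). A sample counts as a spike when its ratio to **both**
nearest valid neighbours exceeds `jump_ratio` (default 1.8, just under an
octave); edge samples are flagged against their single neighbour only when
the two following samples agree with each other. This replaces the manual
excursion correction a human rater would perform with an explicit,
configurable rule. The repair is idempotent. Contours with fewer than two
valid samples are irreparable and are routed to the exclusion ledger.
`truncate_edges()` then drops the first and last two of the 20 samples
(edge frames are excursion-prone), leaving 16-point trajectories.

### DCT shape coefficients

Each 16-point T-value contour is summarized by the first three
coefficients of a type-II discrete cosine transform,
$c_k = \sum_{n=0}^{N-1} x_n \cos\!\big(\pi k (n + \tfrac12)/N\big)$,
reported as

* `dct1` $= c_0/N$ — equal to the contour **mean** (T-value units),
* `dct2` $= 2c_1/N$ — related **negatively** to slope (rising contours
  negative, falling positive),
* `dct3` $= 2c_2/N$ — related positively to curvature.

The scaling is a deliberate choice: the DCT basis and normalization are
conventions, and this one makes `dct1` directly interpretable and fixes
the sign of `dct2` to the convention used in the tone-production
literature. Reversing a contour in time negates `dct2` and preserves
`dct1`/`dct3`; the implementation is checked against an independent
double-loop cosine-sum oracle to $10^{-9}$, and against Parseval's
identity under the orthonormal variant of the basis.

### Centroids and tonal distance

The feature vector is $(\mathrm{dct1}, \mathrm{dct2}, \mathrm{dct3},
z(\mathrm{duration}))$, where durations are z-scored against the target
stimulus set (the "normalized duration" dimension is otherwise
under-determined; z-scoring puts it on a scale commensurate with the DCT
terms). Per-tone **centroids** are the arithmetic means of the target
stimuli's vectors — one centroid per tone category, matching the notion
of "the respective tonal centroid" rather than per-item references.
**Tonal distance** is the Euclidean norm from a production's vector to
its target tone's centroid; larger = less target-like. The four
dimensions are equally weighted on their raw scales by default; a
`standardize` switch divides each dimension by its target-set spread
(the right choice when durations vary much more than the DCT terms).

## Level-tone disambiguation by clustering

Mid-level and low-level productions differ only in height and are hard to
label reliably by ear. `cluster_level_contours()` runs agglomerative
clustering (Ward linkage, Euclidean distance between equal-length T-value
contours) cut at $k = 2$, per participant per day; the cluster with the
higher grand-mean T-value is labeled *mid*. T-value contours — not raw Hz
or semitones — are clustered, consistent with the rest of the pipeline
(the choice of input scale in the original GUI-based workflow is not
documented; Ward/Euclidean is fixed here because it is standard,
deterministic and reproducible, with the linkage configurable). Ties on
cluster mean height are broken by lower within-cluster variance, then by
first occurrence, so results are order-invariant. A zero-variance input
set triggers a degenerate-clustering warning, and all contours are
assigned by comparing the grand mean against 0.625 — the midpoint of the
canonical low (Chao 11 → T = 0) and mid (Chao 22 → T = 1.25) heights.
`correspondence_rate()` reports the percentage of rater labels that agree
with the data-driven split, and `reconcile_labels()` replaces the
disagreeing labels, logging every change.

## Phono-lexical scoring

`score_production()` partitions every labeled naming production into
exactly one of five categories (correct, tone-only error, segment error,
non-target, excluded). "Correct" demands exact categorical match of both
the segment string and the tone label — phono-lexical accuracy is
categorical by definition, and no phonetic gradient credit is given.
Uncategorizable tone productions and quality-flagged trials are routed to
*excluded*, never to the error counts. Tone analyses then use only
segmentally correct items (correct + tone-only): errors on other items
say nothing specific about tone-to-meaning linkage. The 12 tone-only
error types are the ordered target→produced pairs in the fixed tone order
rise, fall, mid, low; `tabulate_errors()` keeps zero cells because
downstream count models are zero-heavy. `summarize_accuracy()` computes
percent-correct per speaker over *attempted* (non-excluded) items — the
denominator convention is not fully pinned down by the descriptive tables
it mirrors, so the attempted-items reading is used and documented — and
the tone-only share of each speaker's errors, with zero-error speakers
excluded from that share's group mean (their share is undefined, not
100%).

## The synthetic world

The generator states a world in which the analysis assumptions hold and
distortions are parametric:

* **Targets.** Four tones with Chao specifications 15 (rise), 51 (fall),
  22 (mid), 11 (low) crossed with four segment frames → 16 pseudowords.
  Chao digit $d$ maps to $T = (d-1) \cdot 5/4$, aligning Chao 1/5 with the
  T-scale endpoints. Contours are linear onset→offset plus a single
  raised-cosine curvature term; the default rise carries a mild sagging
  bend (delayed rise, a typical natural realization) while the fall stays
  straight. Durations vary by tone (430/390/400/420 ms), so the duration
  z-score reference has nonzero spread while all members of a tone
  category share one feature vector — a faithful imitation then sits at
  distance exactly 0 from its centroid, which anchors the noiseless
  identity tests.
* **Imitations.** In T-space:
  $\text{imit} = m + \gamma(\text{linear} - m) + \kappa \cdot
  \text{curvature} + \beta \cdot \mathbb{1}[\text{level}] + \varepsilon$,
  with $m$ the target contour mean, slope gain $\gamma \in (0,1]$
  (pitch-range compression), curvature gain $\kappa$, level-tone raise
  $\beta$, and white Gaussian noise $\varepsilon$ (sd $\sigma$, T-units).
  The mean + linear + curvature decomposition is used so that
  $\gamma = \kappa = 1, \beta = 0$ reproduces the target exactly. The
  result converts to Hz through the *imitating speaker's own* range and
  durations get multiplicative log-normal jitter.
* **Naming.** Segments correct with probability `p_segment_correct`
  (default per-day 0.45/0.86, emulating accuracy growth over training);
  the produced tone is a draw from the speaker's row-stochastic 4×4
  confusion matrix. The stock Mandarin-like matrix concentrates low-tone
  errors on mid (low→mid dominance, diagonal 0.59/row-low mass 0.35 on
  mid); the English-like matrix spreads errors uniformly (diagonal 0.70,
  0.10 elsewhere).
* **Cohort.** 21 + 20 speakers over 2 days with per-speaker parameters
  drawn from group distributions (Mandarin $\beta \sim N(0.8, 0.15)$ vs
  English $N(0.2, 0.1)$; $\gamma$ around 0.7–0.75; production noise
  $\sigma = 0.3$), and Bernoulli trial dropout calibrated to the design
  bookkeeping (21/2624 imitation, 4/1312 naming) to exercise the
  exclusion ledger. Everything is a pure function of `(config, seed)`.

What a green test does *not* establish: the generator's contour family is
a specification-driven stand-in, not a reproduction of any measured
stimulus set; noise is white in T-space (real F0 error is temporally
autocorrelated and interacts with segmental perturbation); naming
confusions are stationary across items and days given the per-day
segment accuracy. Green tests certify the *scoring machinery* under a
known world, not the empirical findings of any particular experiment.

## Numerical and statistical choices

* **Parameter recovery** (`recover_imitation_params()`) normalizes with
  the generator's *true* speaker ranges from the ground-truth sidecar.
  This is deliberate: a compressed imitation set ($\gamma < 1$) has
  observed extremes that are themselves compressed, and normalizing by
  them rescales the T axis by $1/\gamma$ — the compression would cancel
  itself and $\gamma$ would be unidentifiable from observed ranges. The
  analysis pipeline, which has no access to true ranges for real
  speakers, uses observed ranges; its distance comparisons are
  within-convention and unaffected.
* **Bootstrap.** Condition means carry percentile bootstrap 95% CIs
  (deterministic given the config seed via per-stage substreams). The
  percentile method is used because distance distributions are skewed
  norms; coverage of the group-difference CI is verified by simulation to
  sit in the 93–97% band under a null world.
* **Confusion recovery checks** use a *simultaneous* 95% band over all 16
  confusion cells (Bonferroni critical value 2.955) rather than per-cell
  1.96 bands: sixteen per-cell 95% bands have roughly
  $0.95^{16} \approx 44\%$ joint coverage, so the per-cell reading would
  reject a correctly implemented sampler about half the time.
* **Degenerate inputs.** Flat voice ranges, all-identical cluster inputs,
  sub-2-valid-sample contours, empty assignment sets, and zero-spread
  reference durations all raise typed conditions
  (`tonetrace_degenerate_range`, `tonetrace_degenerate_clustering`,
  `tonetrace_irreparable_error`, ...) rather than propagating NaNs.

## Known limitations

* No pitch tracking: F0 extraction from audio is upstream (Praat,
  ProsodyPro); the package starts at sampled trajectories.
* No inferential models: group comparisons are descriptive
  (means + bootstrap CIs), not mixed-effects posterior estimates.
* Inter-rater adjudication is represented as a single authoritative label
  column; agreement statistics on real dual ratings are out of scope.
* The octave-jump rule is a proxy for rater judgment; genuine sustained
  octave shifts (halving/doubling over many frames) are not corrected,
  only single-sample spikes.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- run_config(simulate = cohort_config(n_english = 6, n_mandarin = 6),
                  seed = 42, bootstrap_reps = 500)
imit <- run_imitation_analysis(cfg)
head(imit$summary)          # group x tone x day mean distance + 95% CI
naming <- run_naming_analysis(cfg)
naming$summary$groups       # Table-5-style accuracy rows
naming$error_table$mandarin # 4 x 4 target x produced counts
```
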