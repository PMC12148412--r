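---
title: "Melting-curve and stability-score analysis of TPP-TR experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve and stability-score analysis of TPP-TR experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltscore)
```

## The measurement

Temperature-range thermal proteome profiling (TPP-TR) heats aliquots of a
cell extract at a gradient of temperatures (here 37, 41, 44, 47, 50, 53,
56, 59, 63 and 67 °C), pellets the denatured, aggregated fraction, and
quantifies what stays soluble by mass spectrometry. With 10-plex tandem
mass tags, each temperature is one reporter channel (TMT 126–131) of a
single labeled mix, so a protein's reporter profile traces its melting
curve. Comparing conditions — here a resting state, an LPS-primed state
and a nigericin-activated state, with two biological replicates each —
reveals proteins whose thermal stability or abundance changes on
treatment, e.g. through complex assembly, ligand binding or
post-translational modification.

`meltscore` implements the downstream analysis: spectrum quality
filtering, protein roll-up, per-temperature normalization, melting-curve
fitting, bootstrap stability/abundance scoring with FDR control, hit
calling, profile clustering and complex co-melting summaries, plus a
synthetic meltome generator that provides exact ground truth for every
stage.

## Spectrum filtering and roll-up

Two precursor quality measures gate the spectrum-level data:
signal-to-interference (`s2i`, the fraction of the isolation window's
signal belonging to the precursor) and the precursor-to-threshold ratio
(`p2t`, a signal-to-noise proxy). Spectra with `s2i < 0.5` or `p2t < 4`
are discarded; values exactly at a threshold pass, because only
strictly-below values indicate unacceptable coisolation or noise.
Reporter intensities of the surviving spectra are summed per protein,
condition, replicate and channel — the standard TMT roll-up — and a
protein enters a condition's analysis only when observed in at least two
biological replicates there. Filtering happens before roll-up, so a
contaminated spectrum can never leak into a protein total.

## Per-temperature normalization

Total reporter signal falls as temperature rises, because most of the
proteome melts. Each temperature is therefore normalized in an
independent run:

1. per-sample scale factors are the median, across proteins quantified in
   every sample at that temperature, of the ratio to the per-protein
   geometric mean (median-of-ratios, robust to differential behavior of
   individual proteins);
2. scaled intensities are divided by the run level — the median positive
   scaled intensity at that temperature — making each run dimensionless
   and the result invariant to the overall signal level of a temperature;
3. a generalized log transform
   `glog2(x) = log2((x + sqrt(x^2 + c_t^2)) / 2)` stabilizes the variance,
   with the offset `c_t` tied to the noise floor as the 5th percentile of
   the positive scaled intensities of that run (configurable via
   `glog_percentile`).

The transform behaves linearly below `c_t` and logarithmically above it,
so low-intensity channels do not explode in variance. Batch structure —
in this design the replicate index is the only batch — is removed per
protein and temperature by least squares on `norm_value ~ condition +
batch` with treatment coding, subtracting only the batch terms; condition
contrasts are untouched, and proteins whose missingness pattern cannot
support the design are passed through unchanged and flagged.

## The melting curve

The soluble fraction is modeled with a three-parameter sigmoid. The
default, reciprocal-temperature form is

$$f(T) = \frac{1 - \text{plateau}}{1 + e^{-(a/T - b)}} + \text{plateau},$$

which for $a > 0$ decreases monotonically with $T$ and approaches 1 at
low temperature; `plateau` is the residual soluble fraction at high
temperature. A logistic directly in $T$,
$f(T) = (1-\text{plateau})/(1 + e^{aT-b}) + \text{plateau}$, is offered
as an alternative (`form = "linear"`), with the sign convention chosen so
that $a > 0$ again yields melting behavior. Fractions are anchored by
dividing each profile by its value at the lowest gradient temperature, so
$f(37\,°C) = 1$ exactly; a profile with a missing or non-positive
37 °C value is unfittable and flagged.

Fitting uses bounded Levenberg–Marquardt least squares over
$(a, b, \text{plateau})$ with $a > 0$ and $\text{plateau} \in [0, 0.5]$ —
the upper bound guarantees the melting temperature exists whenever the
fit converges — from three starts whose $b$ matches the temperature at
which the observed profile first crosses 0.5 and whose plateau seeds at
the smallest observed fraction. At least five observed points are
required. $R^2$ is computed on the fraction scale and reported as `NA`
for profiles with zero total variance (no transition). The melting
temperature solves $f(T_m) = 0.5$ in closed form: with
$q = \ln(0.5/(0.5 - \text{plateau}))$,

$$T_m = \frac{a}{b - q} \;\text{(reciprocal form)}, \qquad
  T_m = \frac{b + q}{a} \;\text{(linear form)},$$

verified in the tests against a bracketing root-finder to $10^{-9}$ °C
over randomly drawn valid models. Curves are fitted per replicate on raw
(or per-sample-scaled) intensities; per-replicate $T_m$ values are
reported and may be averaged downstream — fitting replicate-averaged
fractions would hide replicate disagreement.

## Bootstrap stability and abundance scores

Differential melting is scored on the log2 comparison ratios
(treatment minus reference on the glog2 scale, replicates paired by
index). A protein is eligible when at least two of the (two lowest
temperatures) × (replicates) cells are measured. In each of 500 bootstrap
iterations, one replicate's ratio is drawn uniformly among the
non-missing values at every temperature; then

* the **abundance draw** is the mean drawn ratio over the two lowest
  temperatures (37 and 41 °C), where essentially nothing has melted, so
  it reads out expression-level change;
* the **stability draw** subtracts the abundance draw from every drawn
  ratio and sums over temperatures — the baseline-corrected area between
  the two melting curves, insensitive to uniform abundance shifts.

The mean and SD of the 500 draws summarize each score. A two-sided
p-value comes from `mean/SD` referred to Student's t with
(number of measured temperatures − 1) degrees of freedom; a zero SD with
a non-zero mean maps to the smallest positive double, with a zero mean to
p = 1. Score averages are standardized proteome-wide into z-scores with
the robust median/MAD center and scale. Two FDRs are attached: the
**global FDR** fits an empirical null N(median, (1.4826·MAD)²) to the z
distribution and converts the two-sided tail p-values to
Benjamini–Hochberg q-values (tracking effect size), and the **local FDR**
is the BH adjustment of the bootstrap t p-values (tracking replicate
reproducibility). The empirical null guards against over- or under-
dispersion of the score distribution; a theoretical N(0,1) null is
available as an option.

Expression scores mirror the abundance readout with a moderated t:
`logfc` is the mean treatment-minus-reference difference at the two
lowest temperatures, the residual variance is shrunk toward the
proteome median with prior degrees of freedom `prior_df = 4` (posterior
variance $(d_0 s_0^2 + d s^2)/(d_0 + d)$, $d_0 + d$ degrees of freedom),
and the z-score is the signed inverse-normal transform of the two-sided
p-value. With `prior_df = 0` the statistic reduces exactly to the pooled
two-sample t-test, which the tests verify. Four prior degrees of freedom
is a deliberately mild shrinkage appropriate for the very small
per-protein sample sizes (typically 4 vs 4 values).

Two hit criteria are provided: the stringent dual cutoff
(`fdr_local < 0.01` **and** `fdr_global < 0.01`, the default) and the
alternative `|z| > 1.96` with `fdr_global < 0.05`, whose cutoff is the
standard-normal two-sided 5 % critical value.

Reproducibility is by construction: each protein's bootstrap stream is
seeded from the run seed combined with a deterministic hash of the
protein identifier, so results are invariant to protein order and
parallel layout.

## Downstream summaries

Hit proteins' per-temperature mean ratio profiles are grouped by
agglomerative hierarchical clustering (Euclidean distance, average
linkage, tree cut at `k = 5` by default), with residual missing cells
row-mean imputed and rows pre-sorted by protein id so ties resolve
deterministically. For complex co-melting, hits are matched against a
user-supplied subunit table (CORUM-format column subset); each complex
with scored members is summarized by its hit fraction, and — as an
extension beyond descriptive matching — a hypergeometric enrichment
p-value with BH adjustment across complexes, verified against exhaustive
combinatorial enumeration in the tests.

## The synthetic meltome generator

`sim_config()` / `simulate_proteome()` emulate the study design: 3
conditions × 2 replicates × the 10-temperature gradient. Per protein the
generator draws a log2-normal base intensity (mean 23, SD 1.5 on the
log2 scale, i.e. a median around 8×10⁶ — the scale of summed reporter
signals), a true melting temperature from N(52 °C, 4 °C) truncated to
[42, 62] °C, a sigmoid slope $a \in [600, 1400]$ (transition width of
roughly 5–10 °C at these $T_m$ values) and a plateau in [0.02, 0.15].
Spiked effects go into the last condition: a $T_m$ shift of |2–5| °C for
a random 5 % of proteins and a log2 fold change of |0.5–1.5| for another
5 %, signs random, with exact bookkeeping returned as the truth table.
Noise is multiplicative log-normal (σ = 0.1 log2 units by default, the
replicate-to-replicate scatter typical of TMT reporter data); missingness
ramps linearly from 0 at 37 °C to 10 % at 67 °C, mimicking low-signal
dropout; per-replicate additive log2 batch offsets are available (zero by
default) so batch removal is exactly testable.

Because all ten temperatures share one labeled mix, the decreasing total
signal with temperature emerges from the melting curves themselves; the
generator deliberately applies no additional per-temperature attenuation
by default. A smooth multiplicative attenuation would be mathematically
unidentifiable from global melting for any analysis working from reporter
intensities alone, so spiking it in would merely bias absolute $T_m$
estimates in a way no method could correct; the `signal_decay` knob
exists for robustness studies of the ratio-based scoring path, which is
exactly invariant to any per-temperature factor.

What the generator does *not* emulate: peptide-level identity and shared
peptides, isotope impurity between channels, coisolation beyond the
scalar `s2i`, intensity-dependent (rather than temperature-dependent)
missingness, and correlated co-melting of complex members. Passing
tests on synthetic data therefore demonstrate the statistical machinery
under the stated model, not robustness to every artifact of real
spectra.

## Statistical design of the test suite

The suite favors independent oracles over re-computation: the bootstrap
is compared with exhaustive enumeration of all $2^{10}$ replicate-choice
combinations; $T_m$ with a root-finder; the hypergeometric tail with
combinatorial enumeration; average linkage with a hand-executed
agglomeration; batch removal against the reference limma implementation;
the moderated t at zero prior df against `t.test`. Stochastic
equivalence checks standardize each deviation by its exact standard
error from the enumeration (for sample SDs, the finite-n variance of
$s^2$ — the asymptotic form degenerates for the near-two-point draw
distributions that arise here) and bound the number of 3-SE exceedances
by its binomial Monte-Carlo tolerance, since over hundreds of
simultaneous checks an exact sampler exceeds 3 SE occasionally by
construction. Calibration and recovery checks run at 2,000 proteins
(null calibration, spiked-hit detection averaged over 5 seeds) and 200
proteins (melting-temperature recovery), sizes at which binomial
tolerances are tight enough to be meaningful while the full suite stays
fast.

## Known limitations

* Melting curves are descriptive here: no significance test on $T_m$
  differences is performed (the stability score plays that role).
* The glog transform compresses ratios for proteins near the noise
  floor, which can leak a small residual stability signal from a pure
  abundance change at low intensities.
* The empirical-null global FDR assumes the bulk of the proteome is
  unchanged; designs where most proteins shift require the theoretical
  null option.
* Batch removal assumes additive batch effects on the glog2 scale and an
  unconfounded design; confounding raises an error rather than a silent
  partial fix.
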