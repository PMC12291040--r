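---
title: "Class modeling for MS/MS drug screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class modeling for MS/MS drug screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcascreen)
```

This vignette records how `simcascreen` models the screening problem,
which numerical choices were genuinely open, and what the shipped tests
do and do not demonstrate. It is written for a reader who wants to
trust (or challenge) the defaults.

## The screening model

Each analyte is one point in an 8-variable space: precursor $m/z$,
retention time (minutes), the $m/z$ values of its three most intense
MS/MS fragments, and the three corresponding neutral losses. Fragments
qualify when their relative intensity — intensity divided by the
base-peak intensity — is at least the threshold (default 10 %,
inclusive); ties in intensity rank by lower $m/z$ and then input order
so the matrix is reproducible. Analytes with fewer than three
qualifying fragments get *missing* slots, never silent zeros;
imputation happens only inside `autoscale_fit()`, as an explicit,
named policy (`mean_impute` by default, `zero_fill` for pipelines that
record absent fragments as null entries).

A SIMCA panel is one principal-component model per drug class, fit to
that class's training rows after class-local autoscaling (each class
is described in its own units — the standard SIMCA convention; global
scaling is available via `scaling = "global"` in `fit_class()`).
Classification is an outlier test: a sample is projected onto a class
model and characterised by its score distance (Hotelling $T^2$, the
Mahalanobis distance from the centre of the score space) and its
orthogonal distance ($Q$, the squared norm of the reconstruction
residual). Verdicts are independent across classes — *soft*
classification — so a sample may be claimed by several structurally
similar classes, exactly one, or none. All three outcomes carry
forensic meaning.

## The acceptance rule

The literature offers several ways to turn $(T^2, Q)$ into a verdict.
The package implements two, selected by `rule =`:

* `"chi2"` (default). The combined distance
  $c = N_h\,T^2/T^2_0 + N_q\,Q/Q_0$ is treated as approximately
  chi-square with $N_h + N_q$ degrees of freedom, where $T^2_0$ and
  $Q_0$ are reference means and $N_h, N_q$ are moment-matched degrees
  of freedom ($N = 2\,\mathrm{mean}^2/\mathrm{var}$, clamped to
  $[1, 250]$). The reported per-sample distance is normalised,
  $d = \sqrt{c/(N_h+N_q)}$, so thresholds are comparable across
  classes and sit near 1.
* `"box"`. Accept iff $T^2 \le T^2_{crit}$ **and** $Q \le Q_{crit}$,
  with $d = \max(T^2/T^2_{crit},\; Q/Q_{crit})$ and threshold 1.

Everywhere — `predict()`, `validate_models()`, `coomans_table()` — a
verdict is the single comparison $d \le d_{threshold}$, so Coomans
quadrants, confusion counts and accepted-class sets can never
disagree.

Two finite-sample refinements matter at screening-panel class sizes
(our defaults exercise classes of 4–22 analytes):

1. **Cross-validated reference distances.** The reference moments
   ($T^2_0$, $Q_0$, $N_h$, $N_q$) are estimated from *cross-validated*
   distances of the class training rows — leave-one-out up to 30 rows,
   deterministic 10-fold above — rather than resubstitution distances.
   A class model fit to $n$ rows in 8 variables reproduces those same
   rows far too well: with resubstitution references the acceptance
   region is calibrated for the training rows and wildly
   anti-conservative for new samples (we measured new-sample acceptance
   near 0.4 at $n = 8$ for a nominal 0.95). With CV references the
   region describes samples the model has not seen.
2. **An F-shaped threshold.** The acceptance quantile uses
   $d_{threshold} = \sqrt{F_{1-\alpha}(\nu,\, n-1)}$ with
   $\nu = N_h + N_q$, not the asymptotic
   $\sqrt{\chi^2_{1-\alpha}(\nu)/\nu}$. The reference moments are
   themselves estimated from $n$ training distances; the F form
   absorbs that estimation uncertainty and converges to the chi-square
   form as $n$ grows. In calibration runs the new-sample acceptance is
   0.95 at large $n$ and intentionally conservative (0.97–0.98) below
   $n \approx 15$ — a small class should be slow to reject its own
   kind, at the documented cost of specificity, which is precisely the
   small-class trade-off screening panels report.

The exploratory PCA limits are the classical ones and are kept
separate from the acceptance rule: $T^2_{crit} =
A(n-1)/(n-A)\,F_{1-\alpha}(A, n-A)$ and the moment-matched scaled
chi-square $Q$ limit ($g\chi^2_{1-\alpha}(h)$ with $g = v/2m$,
$h = 2m^2/v$ from the training $Q$ moments; Jackson–Mudholkar
available via `q_method`). Degenerate cases are pinned: $v = 0$ gives
$Q_{crit} = m$; a full-rank model gives $Q_{crit} = 0$ and the $Q$
term of the combined rule is dropped.

## Component selection

`select_components()` scores each candidate count $A$ by
cross-validated efficiency $\sqrt{\text{sensitivity} \times
\text{specificity}}$: five contiguous venetian-blind cancellation
groups (after sorting by analyte id — deterministic without a seed)
for classes of at least 8 rows, leave-one-out below; sensitivity is
pooled over held-out class rows, specificity is the mean over folds of
the rejection rate of all other-class training rows projected onto the
fold model. The smallest $A$ attaining the maximum efficiency wins
(parsimony tie-break).

One subtlety: *fold models use resubstitution references*. Inside CV
the held-out rejections are the generalisation signal; if each fold
model were CV-corrected internally, every $A$ would calibrate equally
well and the efficiency profile would flatten — the overfitting
penalty that makes efficiency peak at the true dimensionality would
cancel out. The final model, in contrast, uses the CV-corrected
reference described above. The recovery tests (rank-2 fixtures, 20
seeds) exercise exactly this mechanism.

## Neutral-loss reference: a forced choice

With the base peak as the neutral-loss reference *and* the base peak
occupying fragment slot 1 (it always survives a relative-intensity
threshold), the first neutral-loss column is identically zero for
every analyte. A constant column cannot be autoscaled, so a matrix
built that way can never reach PCA or SIMCA. Both knobs are therefore
exposed on `extract_features()`: `nl_reference = "base_peak"` (the
literal reading, kept as the extraction default) or `"precursor"` (the
chemical convention), and `include_base_peak = FALSE` to exclude the
base peak from the ranked slots. Modeling-level defaults
(`run_config()`, and every shipped end-to-end example) use the
precursor reference so the matrix is full rank. Published matrices of
this kind must implicitly have made one of these two choices; the
package makes both available and names the one it uses.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rel_intensity_threshold` | 0.10 | fraction of base peak | conventional cut separating informative fragments from noise; inclusive comparison |
| `train_fraction` | 0.75 | — | conventional 75/25 calibration/validation split; `n_train` overrides with an absolute count (rounding is `ceiling`) |
| `alpha` | 0.05 | — | 95 % confidence limits and acceptance quantile |
| `classes_min` | 4 | analytes | below four analytes a one-class model is little more than its mean; smaller classes still count as non-target in validation |
| `A_max` | 5 | components | search cap for CV selection; additionally capped by fold arithmetic |
| `rule` | `"chi2"` | — | single smooth distance per verdict; `"box"` gives the classical rectangular region |
| `missing_policy` | `"mean_impute"` | — | imputed cells scale to exactly 0 and are variance-neutral; `"zero_fill"` mirrors pipelines that enter nulls |

## The synthetic generator

`generate_panel()` emulates the *statistical geometry* of an NPS
screening panel, not fragmentation chemistry: per class, a precursor
window, a retention-time window, and characteristic neutral losses
whose fragments are generated as precursor − loss. Two realism
features matter for testing:

* **Homologue spread** (`loss_sd`): drug classes are homologue series,
  so characteristic losses vary by a fraction of a dalton to a few
  daltons across a class's members, on top of millidalton measurement
  jitter. Without this the neutral-loss columns carry only jitter that
  the Kennard–Stone split cannot see, and held-out rows land outside
  the training span in those columns — a fixture artefact, not a
  property of real panels. Defaults: 0.5 Da in the nine realistic
  templates, 1.5 Da in the well-separated set, 0 in the raw
  `class_template()` constructor.
* **Shared motifs**: the JWH and PINACA templates share one
  characteristic loss, and cathinones share losses with
  phenethylamines, reproducing the overlapping-class geometry that
  makes Coomans comparisons interesting; `separated_templates()`
  removes all sharing for calibration tests.

The default panel sizes (17, 22, 18, 17, 4, 17, 5, 4, 6 across the
nine modeled classes, plus 49 dispersed background analytes, 159 in
total) deliberately exercise the small-class regime. The
well-separated end-to-end calibration runs instead use 18 analytes per
class: a four-analyte class leaves roughly three training rows after a
75/25 split, and no defensible one-class model of three points in
eight variables achieves 90 % specificity — the shipped realistic
panel shows that regime honestly (wide thresholds, depressed
specificity for the smallest classes) rather than asserting it away.

What passing tests show: on class-structured data of this geometry the
pipeline recovers classes with the advertised error rates, the
acceptance rule is calibrated, and every reported number is consistent
with its definition. What they cannot show: performance on real
instrument data, whose within-class structure (correlated fragment
chemistry, retention drift, intensity nonlinearity) is richer than any
template.

## Numerical conventions

* Eigenvalues are score variances with the $n-1$ denominator;
  `svd()` is the only decomposition used.
* Loading signs are fixed (largest-magnitude element positive) so
  loading plots reproduce across platforms.
* Kennard–Stone is fully deterministic: seed pair = the maximum
  pairwise distance (ties: lowest row indices), then maximin additions
  (ties: lowest row index). It matches a brute-force oracle on every
  tested instance.
* The core pipeline contains no randomness; only the synthetic
  generator and calibration simulations draw random numbers, always
  behind an explicit seed, and the generator restores the caller's RNG
  state.
* Model JSON is written at full double precision; a reloaded panel
  reproduces verdicts bit-for-bit.
* Problem sizes in the shipped tests (e.g. 2000-row calibration
  matrices, 20-seed recovery loops, three end-to-end replicates) were
  chosen so the whole suite runs in well under a minute on one core
  while keeping binomial error bands tight enough to be meaningful.

## Known limitations

* The chi-square/F acceptance approximation is moment-based; for
  heavy-tailed within-class distributions the realised error rate can
  drift from $\alpha$ (the box rule is the robust fallback).
* Classes far below ~8 training rows yield honest but weak models:
  generous thresholds, low specificity. The package warns rather than
  refuses (the floor applies to panel counts, not split counts).
* No spectral-library similarity, adduct handling, isotope patterns or
  raw-file parsing: inputs are centroided peak lists in text formats.
* Retention times are taken as-is; cross-batch RT alignment is out of
  scope and must happen upstream.
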