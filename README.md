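# simcascreen

Per-class SIMCA modeling of UPLC-HRMS/MS features for forensic drug
screening.

New psychoactive substances (NPS) appear faster than spectral libraries
can track them. A practical screening strategy is therefore *class*
recognition rather than compound identification: build one one-class
model per drug class (benzodiazepines, cathinones, fentanyl analogues,
synthetic-cannabinoid subclasses such as JWH and PINACA, ...) from the
MS/MS behaviour of known standards, and ask of every unknown, class by
class, "could this be one of you?". A seized sample can then be flagged
as cathinone-like even when the exact cathinone has never been seen
before — and a sample matching *no* class is itself an informative
verdict.

`simcascreen` implements that workflow end to end for analysts and
chemometricians working from centroided MS/MS peak lists:

* **Feature extraction** — each analyte is summarised by 8 variables:
  precursor *m/z*, retention time, the *m/z* of the three most intense
  fragments above a 10 % relative-intensity threshold, and the three
  corresponding neutral losses. Missing fragment slots are flagged, not
  zero-filled. MGF, MSP and a long CSV peak-list dialect are parsed;
  feature tables round-trip through CSV.
* **Kennard–Stone splitting** — deterministic maximin partitioning of
  the autoscaled matrix into training and test sets (default 75/25).
* **PCA diagnostics** — scores, loadings, Hotelling *T*² (score
  distance) and *Q* residuals (orthogonal distance) with 95 % critical
  limits (F-based *T*² limit; moment-matched χ² *Q* limit), and the
  influence-table backing of the *T*²-vs-*Q* outlier plot.
* **SIMCA class models** — one PCA model per class on class-locally
  autoscaled training rows. The number of components is chosen by
  cross-validated *efficiency* (the geometric mean of sensitivity and
  specificity; five cancellation groups for classes of ≥ 8 analytes,
  leave-one-out below). Acceptance uses a combined distance
  *c* = *N*<sub>h</sub>·*T*²/*T*²₀ + *N*<sub>q</sub>·*Q*/*Q*₀ with
  moment-matched degrees of freedom estimated from cross-validated
  training distances, thresholded at the 1 − α quantile of its
  F-approximation (a box rule — accept iff both *T*² and *Q* are under
  their critical limits — is available). Classification is *soft*: a
  sample may be accepted by several classes, one, or none.
* **Validation and screening** — per-class sensitivity / specificity /
  efficiency reports, Coomans distance tables for comparing
  structurally similar classes, JSON model serialization, a one-call
  `run_pipeline()`, and a CLI (`inst/cli/simcascreen.R`) with
  `synth`, `build-matrix`, `split`, `pca`, `fit`, `predict`, `report`
  and `run` subcommands.
* **Synthetic fixtures** — a seeded generator of NPS-like spectra with
  controllable class structure (precursor/RT windows, characteristic
  neutral-loss motifs with homologue spread, shared losses between
  related classes, missing fragments), so the entire pipeline is
  testable without any instrument data.

## Worked example

Generate a 159-analyte synthetic panel (nine drug classes with
realistic small class sizes plus a dispersed background class), build
the 159 × 8 feature matrix, split it, fit the panel and validate on the
held-out analytes:

```r
library(simcascreen)

panel <- generate_panel(default_templates(), default_panel_sizes(), seed = 7)
fm    <- build_matrix(panel$records, nl_reference = "precursor")
fm
#> <feature_matrix> 159 analytes x 8 variables; 86 missing cells
#> classes: arylcyclohexylamines (4), benzodiazepines (17), cathinones (22),
#>   fentanyls (18), JWH (17), nitazenes (4), other_nps (49),
#>   phenethylamines (6), PINACA (17), tryptamines (5)

sp  <- kennard_stone_split(autoscale_fit(fm)$scaled, 0.75)
fit <- simca(fm[sp$train])
fit
#> SIMCA class models (9 classes, rule = chi2, alpha = 0.05)
#>            class n_train A cv_efficiency d_threshold
#>  benzodiazepines       8 1     1.0000000    1.856535
#>       cathinones      15 1     0.9952267    1.665883
#>        fentanyls      13 1     0.9607689    1.715383
#>              JWH       9 1     0.8819171    1.968480
#>        nitazenes       4 1     0.8660254    3.090646
#>        other_nps      47 4     0.9123653    1.788737
#>  phenethylamines       5 1     0.9912662    2.500334
#>           PINACA      12 1     0.9574271    1.693717
#>      tryptamines       4 2     0.9273154    3.039777
#> not modeled (below floor): arylcyclohexylamines

validate_models(fit, fm[sp$test], set = "test")
#>            class  set TP FN TN FP sensitivity specificity efficiency
#>  benzodiazepines test  9  0 30  0           1       1.000      1.000
#>       cathinones test  7  0 31  1           1       0.969      0.984
#>        fentanyls test  5  0 34  0           1       1.000      1.000
#>              JWH test  8  0 31  0           1       1.000      1.000
#>        nitazenes test  0  0 39  0          NA       1.000         NA
#>        other_nps test  2  0 18 19           1       0.486      0.697
#>  phenethylamines test  1  0 37  1           1       0.974      0.987
#>           PINACA test  5  0 34  0           1       1.000      1.000
#>      tryptamines test  1  0 33  5           1       0.868      0.932
```

Reading the output: every class model accepted all of its own held-out
analytes (sensitivity 1). Specificity is high for the coherent
chemical classes and collapses (0.49) for the deliberately dispersed
`other_nps` background class — a dispersed "class" makes a poor
one-class model, which is why real panels model only chemically
coherent groups. The tiny classes show the expected small-sample
behaviour: arylcyclohexylamines fell below the four-analyte modeling
floor after the split, nitazenes kept no test analytes, and the small
tryptamine model is the least specific of the coherent classes.
`d_threshold` is the acceptance cutoff on the combined distance; it
widens as classes get smaller, reflecting the extra uncertainty of a
model built on few analytes.

Screening unknowns is a `predict()` call — each sample gets an
independent verdict from every class model, so the accepted-class set
can be empty (no known class: possibly no NPS at all) or contain
several structurally similar classes:

```r
unknown <- generate_panel(no_nps_template(), 3, seed = 99)
predict(fit, build_matrix(unknown$records, nl_reference = "precursor"))
#> <simca_pred> 3 samples x 9 class models
#>  sample_id accepted_classes
#> no_nps_001           (none)
#> no_nps_002           (none)
#> no_nps_003           (none)
```

Two-class comparisons (e.g. the structurally related JWH and PINACA
cannabinoid subclasses, which share an indole-alkyl fragment whose
neutral formula C17H14N has monoisotopic mass
`monoisotopic_mass("C17H14N")` = 232.1126 Da) are visualised with
`coomans_table()` / `plot(fit, newdata, classes = c("JWH", "PINACA"))`.

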