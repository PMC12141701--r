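# soxfe

Self-organized explainable feature engineering for two-class EEG
classification.

## What it is for

Given multichannel EEG recording sessions with one of two labels (the
motivating application is violence-versus-rest detection from a 14-channel
consumer headset at 128 Hz), `soxfe` classifies 15-s segments and, at the
same time, explains *which brain lobes* its decision relies on. It is aimed
at researchers doing handcrafted (non-deep) EEG feature engineering who
need a transparent, deterministic pipeline with record-level
cross-validation.

## The method

Five stages, each "self-organized" in the sense that it picks its own best
configuration:

1. **DMPat features.** At each time point, the channel-pair "distance"
   `d(i,j) = sqrt(x_i^2 + x_j^2)` is evaluated over all pairs `i < j`; the
   minimizing and maximizing pairs become integer codes
   `v = (a1-1)*NC + (a2-1)`, histogrammed over the segment into a
   min-distance vector `f1` and a max-distance vector `f2` (length `NC^2`
   = 196), plus their concatenation `f3` (392).
2. **INCA selection.** A diagonal-weight neighborhood component analysis
   ranks all features; every top-`r` prefix for `r = 14..98` is scored by
   tenfold-CV 1-NN (city-block) misclassification, and the loss-minimizing
   `r` is kept.
3. **DLob explainability.** Selected feature indices decode back to channel
   pairs; channels map to eight lobe symbols (FL/FR/OL/OR/PL/PR/TL/TR),
   giving a symbol string (two symbols per feature) summarized by a
   histogram, Shannon entropy, and a transition-count matrix exported as a
   directed cortical-connectome graph (DOT/GraphML/JSON).
4. **tkNN classification.** An ensemble kNN enumerates the full
   4 distances x 3 weights x k=1..10 grid (120 out-of-fold outcome
   vectors), adds iterative majority voting over the top `m = 3..120`
   accuracy-sorted outcomes (118 voted vectors), and greedily keeps the
   most accurate of all 238.
5. **Fusion.** The three branch outcomes are fused by the element-wise
   mode, and the best of `{t1, t2, t3, vote}` is the final outcome,
   reported with accuracy, sensitivity, specificity and geometric mean
   `sqrt(Sen x Spe)`.

Cross-validation is either class-stratified tenfold or leave-one-record-out
(LORO, one fold per recording session — the honest scheme when records are
the independent units). All tie-breaks and seeds are pinned; identical
seeds give byte-identical reports. See the methods vignette
(`vignettes/soxfe-methods.Rmd`) for the conventions, numerics and protocol
choices in detail.

## Worked example

A synthetic dataset with a planted channel-pair contrast (class 1 damps
channels 1–2, class 2 damps channels 7–8), 10 records per class, 8
segments per record:

```r
library(soxfe)
records <- generate_dataset(synth_config(seed = 11))
report <- run_pipeline(records, run_config(cv_scheme = "loro", seed = 11))
report
#> <soxfe_report> 160 segments, loro CV (20 folds)
#>   t1  acc 100.00  sen 100.00  spe 100.00  gm 100.00
#>   t2  acc 100.00  sen 100.00  spe 100.00  gm 100.00
#>   t3  acc 100.00  sen 100.00  spe 100.00  gm 100.00
#>   vot acc 100.00  sen 100.00  spe 100.00  gm 100.00
#>   fot acc 100.00  sen 100.00  spe 100.00  gm 100.00
#>   final outcome: t1 (selected sizes 14/14/14; DLob lengths 28/28/28)
```

Each row is one outcome: the three feature branches (`t1` min-distance,
`t2` max-distance, `t3` merged), the mode-fused vote, and the greedy final
outcome — here every branch separates the planted structure perfectly under
leave-one-record-out CV. The selector kept 14 features per branch (the
smallest size it scans, since the loss is already zero there), so each DLob
string has 28 symbols:

```r
report$branches$f1$dlob$string
#> <dlob_string> 28 symbols (min_distance)
#> OL OR FL FL FL FL FL FR FL OL OL TR OR FR FL FR OR FR PL OR FL PR OL FR FL TL OR TR
report$branches$f1$dlob$entropy
#> [1] 2.602048        # bits
report$branches$f1$outcomes
#> <outcome_set> 238 candidates; best #1 = parameter outcome (cityblock/squared_inverse/k=1), accuracy 100.00%
```

`write_report(report, "out/")` writes `report.json`, a per-segment
prediction table, and one connectome graph file per branch. On null data
(identical gain profiles for both classes) the same pipeline stays at
chance level — see the acceptance tests.

Real data can be loaded from delimited text, EDF, or MATLAB v7.3 files via
`load_record()` / `load_dataset()` with a manifest table (`path`,
`record_id`, `label`), and the whole pipeline is also available from the
shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "soxfe.R", package = "soxfe"))') \
  run --manifest data/manifest.tsv --out out --scheme loro --seed 1
```

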