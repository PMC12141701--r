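---
title: "Methods: distance-pattern features, iterative selection and ensemble voting for two-class EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-pattern features, iterative selection and ensemble voting for two-class EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxfe)
```

## The problem and the pipeline

`soxfe` implements a self-organized, explainable feature-engineering
pipeline for two-class classification of multichannel EEG. The intended
data are recording sessions ("records") from a fixed montage — the default
is the 14-channel consumer headset layout (AF3, F7, F3, FC5, T7, P7, O1,
O2, P8, T8, FC6, F4, F8, AF4) sampled at 128 Hz — with one class label per
record. Records are cut into non-overlapping 15-s segments (1920 samples at
128 Hz), and segments are the classification unit.

The pipeline has five stages:

1. **DMPat feature extraction.** At every time point $t$, the pairwise
   "distance" between channels $i$ and $j$ is
   $d_{ij}(t) = \sqrt{x_i(t)^2 + x_j(t)^2}$ — the norm of the two
   instantaneous amplitudes. Over all pairs $i < j$, the minimizing and
   maximizing pairs are converted to integer codes
   $v = (a_1 - 1)\,\mathrm{NC} + (a_2 - 1)$, and the codes are histogrammed
   over the segment. This gives a min-distance vector $f_1$ and a
   max-distance vector $f_2$, each of length $\mathrm{NC}^2$ (196 for 14
   channels), and their concatenation $f_3$ (length 392).
2. **INCA feature selection.** A diagonal (per-feature) neighborhood
   component analysis ranks the features; for every subset size
   $r \in [14, 98]$ the top-$r$ prefix is scored by tenfold-CV
   misclassification of a 1-NN city-block classifier, and the
   loss-minimizing $r$ is kept (ties to the smallest $r$).
3. **DLob explainability.** Each selected feature index is decoded back to
   its channel pair; both channels map through the montage's channel→lobe
   table to one of eight symbols (FL/FR, OL/OR, PL/PR, TL/TR), giving a
   symbol string of length $2N$ for $N$ selected features, summarized by a
   histogram, its Shannon entropy, and a transition-count matrix exported
   as a directed "cortical connectome" graph.
4. **tkNN classification.** An ensemble kNN enumerates the full
   $4 \times 3 \times 10 = 120$ grid of distance (cityblock, euclidean,
   cosine, spearman) × vote weight (squared inverse, equal, inverse) ×
   $k \in 1..10$, producing 120 out-of-fold prediction vectors under the
   outer CV partition. Iterative majority voting takes the element-wise
   mode of the top $m = 3..120$ accuracy-sorted outcomes (118 voted
   vectors), and a greedy pass keeps the most accurate of all 238.
5. **Fusion.** The three branch outcomes ($f_1$, $f_2$, $f_3$) are fused by
   the element-wise mode, and the best of the four candidates is the final
   outcome. With two classes and three voters the mode always has a strict
   majority.

Accuracy, sensitivity, specificity and the geometric mean
$\sqrt{\text{Sen} \times \text{Spe}}$ are reported in percent, with class 1
("violence" in the motivating application) as the positive class by
default.

## Conventions the math leaves open

Several details of the formulas above are underdetermined; the package
fixes them as follows.

* **Diagonal exclusion.** $d_{ii} = \sqrt{2}\,|x_i|$ names a single
  channel, not a channel pair, so the argmin/argmax run over $i < j$ only.
  Consequently only $\mathrm{NC}(\mathrm{NC}-1)/2$ of the $\mathrm{NC}^2$
  histogram bins can ever be populated; the vectors keep the full
  $\mathrm{NC}^2$ length so codes remain directly decodable.
* **Pair ordering and ties.** The distance matrix is symmetric, so the
  ordered convention $a_1 < a_2$ makes codes unique. Ties in the
  argmin/argmax go to the first pair in row-major upper-triangle scan
  order — deterministic and stable under sample reordering.
* **Decoding.** The feature-index decoder is the exact inverse of the
  encoder: $a_1 = \lfloor v/\mathrm{NC} \rfloor + 1$,
  $a_2 = (v \bmod \mathrm{NC}) + 1$ with $v$ the 0-based code. A
  ceiling/modulo variant is sometimes written for this decoding but is
  inconsistent with the encoder at bin boundaries; the exact inverse is
  used. For merged vectors, indices above $\mathrm{NC}^2$ are folded into
  the max-distance code space first; the lobe lookup is identical in both
  halves.
* **Two symbols per feature.** The second symbol of each DLob token uses
  the *second* decoded channel. (A doubled-first-channel reading would make
  every token a repeated symbol and could never produce mixed tokens.)
* **Histograms are raw counts.** Each of $f_1$, $f_2$ sums to the segment
  length; no cross-segment normalization is applied. Scaling is absorbed by
  the downstream classifier; where scaling matters (cosine/spearman
  distances), it is part of the classifier definition, not the features.
* **Tie-breaking everywhere else.** Vote ties go to the smallest class
  label; accuracy sorting is stable with enumeration-order ties; the greedy
  selections take the first maximum (parameter outcomes before voted ones;
  branches in order $t_1, t_2, t_3$, then the fused vote).

## The NCA variant and its numerics

Classical NCA learns a full linear transform; for feature *selection* the
package uses the diagonal variant: a weight vector $w$ enters a weighted
L1 distance $d_w(x_i, x_j) = \sum_r w_r^2 |x_{ir} - x_{jr}|$, and the
regularized leave-one-out soft-neighbor objective

$$F(w) = \frac{1}{n} \sum_i \sum_{j \ne i,\; y_j = y_i} p_{ij}
  \;-\; \lambda \sum_r w_r^2, \qquad
  p_{ij} = \frac{\exp(-d_w(x_i, x_j)/\sigma)}{\sum_{k \ne i} \exp(-d_w(x_i, x_k)/\sigma)}$$

is maximized. Numerical choices, all deterministic:

* features are z-scored internally (constant features pass through and
  collect no weight);
* $\lambda$ defaults to $1/n$;
* the kernel length scale $\sigma$ is fixed to the **standard deviation**
  of the pairwise distances at the all-ones start. The scale on which
  neighbors differ from one another is the distance spread, not the
  distance mean: a mean-based $\sigma$ leaves the softmax nearly uniform
  once $p$ is large, the data term is then dominated by the ridge penalty,
  and every weight collapses to zero;
* the softmax is computed with a per-row shift (its value is
  shift-invariant), so large distances cannot underflow;
* optimization is full-batch projected gradient ascent from $w = 1$ with
  step-size halving (up to 30 halvings per iteration, growth factor 1.2 on
  acceptance, cap 100 iterations). The projection $w \ge 0$ matters
  because relevance is reported as $w^2$: an unprojected overshoot through
  zero would hand an irrelevant feature a large squared weight;
* returned weights are $w^2$, ranked descending with ascending-index
  tie-breaks.

There is no randomness anywhere in this optimizer; the `seed` argument
drives only the stratified tenfold partition used by the selector's 1-NN
loss.

## Protocol choices

* **Selection is not nested.** The NCA ranking and the subset-size scan see
  the full dataset before the outer validation split, and the tkNN
  outcome accuracies (used for sorting, voting, and the greedy choices) are
  computed on the assembled held-out predictions against the true labels.
  This is the method's published protocol, reproduced faithfully; it is a
  selection-on-validation design, and its accuracies should be read as
  such. The practical consequence is visible in this package's own null
  experiments: on label-free data the greedy maximum over 238 correlated
  candidate outcomes sits systematically above 50% (≈ 55–60% at 160
  segments), and the bias grows as the segment count shrinks.
* **One outer partition for all branches.** The three branches share the
  same CV partition so the fused mode compares aligned held-out
  predictions.
* **Cross-validation.** Tenfold CV is class-stratified with a seeded
  shuffle (fold sizes differ by at most one, overall and per class).
  Leave-one-record-out (LORO) builds one fold per recording session, so no
  record ever spans the split; it is the honest scheme when records, not
  segments, are the independent units.
* **kNN edge cases.** Zero-distance training points (exact duplicates)
  decide a prediction alone with equal weight — this also keeps the
  inverse-distance weights finite. Zero-variance rows under spearman and
  zero vectors under cosine are assigned correlation/similarity 0, i.e.
  distance 1.

## The synthetic generator

The generator emulates the *structure* of the motivating dataset: two
classes, several records per class, records segmented into 15-s windows at
128 Hz on a 14-channel montage. Each channel is stationary AR(1) Gaussian
noise (coefficient 0.9, the strong short-lag autocorrelation of low-pass
EEG; marginal SD 1) multiplied by a per-class, per-channel gain. The
default contrast damps channels 1–2 by ×0.1 in class 1 and channels 7–8 in
class 2: the damped pair usually wins the instantaneous argmin, so the two
classes concentrate their min-distance histograms on different bins (codes
1 and 91). Amplitude structure is the minimal sufficient class signal for
a feature extractor driven by instantaneous amplitudes; the generator makes
no attempt at oscillatory realism.

Default sizes are 10 records per class × 8 segments per record
(160 segments, 20 LORO folds). Eight segments per record mirrors the
roughly 8.6 segments-per-record ratio of the motivating dataset and keeps
the chance-level behavior of the selection-biased final accuracy inside a
±10-point band around 50% (at 2 segments per record the same bias pushes a
null run far above chance purely through the 238-fold greedy maximum). A
full pipeline run at these sizes takes roughly 15–20 s on one CPU; the test
suite uses 3 records × 4 segments (24 segments) where only mechanics, not
recovery, are under test.

What passing tests on this generator do **not** show: robustness to
artifacts, nonstationarity, electrode drift, 1/f spectra, or any
physiological realism — real EEG separability claims require real EEG.

## Input handling

Delimited text (CSV/TSV; channels in rows by default, flag for the
transpose), EDF (via a minimal built-in reader of the fixed-width header
and 16-bit data records; amplitudes are rescaled to physical units, so a
round trip is exact only to the int16 quantization step), and MATLAB v7.3
containers (HDF5, via `rhdf5`; array dimensions are transposed back to the
MATLAB shape; classic v5 files are rejected with a pointer to `-v7.3` or
CSV export). Channel rows are reordered to montage order by name when
names are present, positionally otherwise. No filtering, re-referencing or
artifact rejection is applied anywhere.

## Entropy conventions

String entropy is the standard Shannon entropy of the symbol frequencies,
base 2 by default (base e available); the base is recorded in reports.
Normalized or estimator-corrected entropies are deliberately not
implemented: with eight symbols and strings of length 42–160 the plug-in
estimate is the transparent choice, and any alternative convention can be
derived from the reported histogram.

## Known limitations

* The NCA optimizer is a fixed-budget first-order method; its weight
  *magnitudes* are not comparable across datasets and only the induced
  ranking is contractual.
* Pairwise-distance NCA is $O(n^2 p)$ in memory; at the package's intended
  problem sizes (hundreds of segments) this is a few hundred MB at most,
  but the implementation is not designed for $n \gg 10^3$.
* The spearman distance ranks each feature vector independently per row;
  with very few features rank correlations are coarse and frequently
  degenerate (handled, but of limited discriminative value).
* Selection-on-validation (above) means reported accuracies are optimistic
  on small datasets; the LORO scheme limits, but does not remove, this
  bias.
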