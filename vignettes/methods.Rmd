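---
title: "Methods: composition descriptors, two-step selection and forest classification of anti-inflammatory peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition descriptors, two-step selection and forest classification of anti-inflammatory peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aipforest)
```

`aipforest` classifies peptides as anti-inflammatory (AIP) or not from
sequence alone. This vignette documents the model, the design decisions
behind it, and what the synthetic benchmark does and does not show.

## The descriptors

All three encoders map a validated peptide (uppercase, 20 standard
amino-acid letters, length `L ≥ 5` by default) to a fixed-order numeric
vector, so feature matrices and trained models are portable.

**AAC** is the 20-vector of residue frequencies `N(j)/L`, alphabetical
order A..Y. Rows sum to 1.

**DDE** standardises each of the 400 ordered adjacent-dipeptide
frequencies against a codon-usage null model. With `DC(j) = n_j/(L−1)`,
the expectation under random coding is `TM(j) = (C_{j1}/CN)(C_{j2}/CN)`,
where `C_j` is the number of sense codons for residue `j` and `CN = 61`
for the standard genetic code (stop codons excluded); the binomial-style
variance is `TV(j) = TM(j)(1−TM(j))/(L−1)` and
`DDE(j) = (DC(j)−TM(j))/√TV(j)`. Because every `TM(j)` lies strictly in
(0, 1), `TV` is never zero and no epsilon guard is needed — the test
suite asserts this rather than defending against it. The codon counts
(A = 4, C = 2, …, L = 6, …, W = 1) are exposed through `codon_table()`
and can be overridden, e.g. for non-standard codes.

**GDC** counts ordered residue pairs at positions `(i, i + g)` and
normalises by the pair count. We take a *g*-gap pair to span `g`
positions, so a length-`L` peptide has `L − g` pairs and the minimum
encodable length for gap `g` is `g + 1`: with the supported gap range
`g ∈ {1..4}`, every peptide of the minimum length 5 is encodable,
including `g = 4` (a single pair). The rival convention — `g` skipped
residues between the pair, `L − g − 1` pairs — would make `g = 4`
undefined exactly at the minimum length, which is why it was rejected.
`g = 1` is ordinary adjacent dipeptide composition.

Combined encodings concatenate blocks in the requested order with
prefixed names (`AAC:`, `DDE:`, `GDC1:` …); AAC + DDE + GDC-gap1 gives
20 + 400 + 400 = 820 features.

## Two-step feature selection

Each feature `t` is scored by the ratio of between-group to within-group
variance,

$$S(t) = \frac{S_B^2(t)}{S_W^2(t)}, \quad
S_B^2 = \tfrac{1}{K-1}\sum_i m_i(\bar x_i - \bar x)^2, \quad
S_W^2 = \tfrac{1}{N-K}\sum_i\sum_j (x_{ij} - \bar x_i)^2,$$

which is exactly the one-way ANOVA F statistic (the tests verify
agreement with `stats::anova(lm(...))` to 10 significant digits). Two
degenerate cases need conventions: zero within-group variance with
non-zero between-group variance means the feature separates the classes
perfectly and receives `Inf` (ranked ahead of all finite scores); a
constant feature receives 0. Ties keep the original column order so
rankings are stable.

Incremental feature selection (IFS) then grows the model along the
ranking — subset sizes `step, 2·step, …` up to the full set — and keeps
the subset with the best cross-validated objective (AUC by default;
configurable because a deployment might prefer MCC or accuracy). Ties
break towards the smaller subset. The `step` parameter (default 1,
matching one-at-a-time forward addition) exists because an exact sweep
of hundreds of features under 5-fold cross-validation is expensive;
batched steps trade curve resolution for time without changing the
procedure.

**Honest curve estimation.** A subtle but consequential choice: if
features are ranked once on the full dataset and the leading `k` are
then cross-validated, the test folds have already informed the ranking,
and the IFS curve is biased upwards — markedly above chance even on
label-independent data. `incremental_select()` therefore re-ranks features
by ANOVA *inside each training fold* and evaluates each subset size on
the fold's held-out samples, which restores chance-level behaviour on
null data. The full-data ranking is still what defines the finally
reported optimal feature list (and the features of the deployed model),
which is standard practice: the curve estimates generalisation of the
*procedure*, the full-data ranking is the procedure's output.

## The classifier and its evaluation

The classifier is a probability random forest (via `ranger`) with the
classical WEKA-style defaults: 100 trees, `floor(log2 d) + 1` candidate
features per split, unlimited depth. The `sqrt` rule and explicit
integers are available through `rf_config()` for parity with other
backends. All training is seeded and single-threaded, so results are
bit-reproducible.

Scores are positive-class vote fractions in [0, 1]; the hard decision is
`score ≥ 0.5` (a score of exactly 0.5 is called positive — the boundary
must go somewhere, and the convention is asserted in a test).
Evaluation uses the confusion-matrix measures SN, SP, ACC and MCC
(MCC set to 0 when a denominator factor vanishes, the usual convention
for degenerate confusion matrices) plus the ROC curve swept over all
distinct thresholds. AUC is computed by the trapezoidal rule on the
tie-grouped curve, which makes it identical to the Mann–Whitney
probability with ties counted half; the tests check this equivalence
against an O(n²) pairwise oracle at 1e-12.

Cross-validation is stratified (per-class round-robin after a seeded
shuffle, so fold class proportions differ from global by at most one
sample) and reports *pooled* out-of-fold metrics as the headline number,
with per-fold reports retained; pooled metrics are preferred because
they weight every sample equally and are stable for small folds, but
fold mean ± sd is available via `glance()`/`tidy()` since conventions
differ across studies.

## The synthetic benchmark

`simulate_peptides()` generates the two classes from the simplest
generative family in which the three descriptor types carry
*distinguishable* signal channels:

- **Composition channel** (`effect`): residues i.i.d. from
  `p± = base ± effect·δ`, where δ raises ten amino acids (A–L) by 1/20
  and lowers the other ten. With the uniform default base the
  total-variation distance between class compositions is exactly
  `effect`. Distributions that would leave [0, 1] are rejected with an
  error, never silently renormalised.
- **Transition channel** (`dipeptide_effect`): positives follow a
  first-order Markov chain with transition weights tilted by
  `1 + dipeptide_effect·s(a)s(b)` (`s = ±1` on the two half-alphabets).
  Under the uniform base the chain's stationary distribution stays
  uniform, so this signal is invisible to AAC but visible to DDE and
  GDC — which is what lets the tests demonstrate, qualitatively, that
  dipeptide descriptors outperform plain composition when the
  discriminating information lives in residue *adjacency*.

Lengths are uniform on `length_range` (default 5–30, a typical
bioactive-peptide range whose minimum matches the descriptors' length
requirement). The base composition defaults to uniform for analytic
transparency; a Swiss-Prot-like average composition is available as a
preset.

Because the per-unit-effect information differs between channels — the
transition signal is spread thinly over 400 sparse dipeptide counts —
the channel-separation demonstration uses a stronger tilt (0.5,
transition odds ratio 3) than the composition checks (0.15/0.3).

**What the benchmark does not show.** The generator makes no attempt at
AIP biology: no motifs, terminal preferences, modified residues, or
realistic length/composition distributions. Passing the synthetic checks
demonstrates that the pipeline's machinery is correct and calibrated
(chance-level on null data, monotone signal recovery, channel
attribution), not that any particular real-data performance will be
achieved.

## Problem sizes and runtime choices

The shipped checks run the full pipeline at 200 + 200 peptides with the
820-feature combined encoding, IFS step 200 and 5-fold cross-validation,
with three seeds by three effect levels for the monotonicity check —
sizes at which the whole suite completes in well under a minute on a
single core while keeping Monte-Carlo error on a pooled AUC near 0.03.
The null-calibration band [0.40, 0.60] and the signal-recovery threshold
(AUC ≥ 0.85 at effect 0.3) were fixed with those conditions.

## Known limitations

- Binary classification only; the ANOVA scorer accepts `K ≥ 2` groups in
  principle but the pipeline assumes two classes throughout.
- Comparison descriptors sometimes used alongside these three
  (CKSAAGP, CTriad, grouped compositions, tripeptide composition) are
  not implemented; `encode_peptides()` is the natural extension point.
- Redundancy filtering of input sets (e.g. CD-HIT-style identity
  clustering) is expected to happen upstream.
- The IFS curve's optimal point is still a maximum over correlated
  estimates; with few curve points this residual optimism is small but
  not zero (visible as the null calibration sitting slightly above 0.5
  on some seeds). An outer evaluation loop on truly held-out data, as
  supported by `cmd_evaluate()`, is the remedy when an unbiased final
  estimate matters.
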