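---
title: "Mapping TF networks by combining evidence scores with boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping TF networks by combining evidence scores with boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A transcription-factor (TF) network map assigns to every (TF, gene) pair a
score for the hypothesis that the TF directly and functionally regulates the
gene: it binds the gene's regulatory DNA *and* thereby modulates its
transcription. Expression data after direct TF perturbations carry functional
information but also indirect effects; binding-location experiments
(ChIP-style assays, transposon calling cards) carry direct-binding
information but include many non-functional sites. `tfmapr` treats network
mapping as supervised learning on edges: expression-derived *evidence scores*
are the features, binding-derived 0/1 labels are the targets, and a
gradient-boosted tree classifier learns how to weigh the evidence.

# Evidence scores

Four scores are computed per (TF, gene) edge, each a standard idea in the
field:

* **DE** — the log2 fold-change of the gene after the TF's perturbation
  versus the mean of control samples. Fold-changes with `|LFC| <= tau`
  (default `tau = 0.38`, inclusive at the boundary) are set to 0 to suppress
  measurement noise around zero. For time-course overexpression designs the
  time point with the largest absolute response wins, sign preserved; this
  captures the peak response without modelling kinetics.
* **LASSO** — the signed coefficient of the TF in an L1-penalized regression
  of the gene's profile on all TF profiles, penalty chosen per gene by 5-fold
  cross-validation with the one-standard-error rule (conservative: prefers
  sparser models within one SE of the best CV error).
* **Tree ensemble** — the impurity-based variable importance of the TF in a
  regression forest of the gene on all TF profiles (100 trees). This is the
  package's tree-based nonlinear-association score; any ensemble-of-trees
  regression that yields a nonnegative per-TF importance fills this role.
* **PWM** — a binding-motif score: a position weight matrix is inferred from
  the promoters of the TF's top predicted targets in a preliminary network
  (by default the tree-ensemble score), then scanned over every promoter;
  the edge score is the best log2-odds window against a 0-order background.

Regression-based scores canonicalize sample order internally, so all scores
are invariant to the column order of the input matrix. Self-edges
(a TF regulating itself) are structurally excluded everywhere: they are held
as `NA` and never ranked, trained on, or written out.

## Motif inference choices

No single standard algorithm defines "infer a motif from a promoter set", so
the package commits to a deterministic pipeline: (1) seed with the k-mer
(default k = 7) whose per-sequence coverage in the foreground most exceeds
its coverage in the background, requiring foreground coverage of at least
25%; (2) extend to each candidate width (default 8–12) with
background-frequency flanks and a strong (0.7) anchor on the seed consensus;
(3) refine by EM over a one-occurrence-per-sequence alignment — soft
posterior over window positions, *hard* per-sequence strand choice (soft
strand assignment lets near-palindromic motifs collapse into a strand
mixture that halves the information content at asymmetric positions);
(4) keep the width with the best per-position alignment log-odds. If no
k-mer is meaningfully enriched (coverage ratio < 1.5) the inference returns
a background-frequency matrix rather than refining noise into a sharp but
meaningless motif — scans with such a matrix score ~0 everywhere, i.e. the
feature goes silent instead of hallucinating. The 0-order background is the
simplest defensible null; higher-order backgrounds are out of scope.

# The combiner

A boosted-tree logistic classifier (XGBoost) maps each edge's evidence
vector to the probability that the edge would be supported by a binding
experiment. Missing evidence values pass through as native missing values
and are routed by the trees' default directions, so heterogeneous feature
availability needs no imputation. No class reweighting is applied despite
the low positive rate: the plain logistic objective keeps the predicted
probabilities calibrated against the label base rate, and calibration is a
feature of the output, not a nuisance.

Three training regimes serve three use cases:

* **Generalization** — score TFs that lack binding data. Labeled TFs are
  cross-validated in 10 folds *by TF*: a TF's edges are scored only by
  models that never saw its labels. Folds are stratified by each TF's
  positive-label count (quartile bins, seeded shuffle, round-robin deal), so
  label-rich and label-poor TFs spread evenly. Hyperparameters (depth
  {2,4,6} x learning rate {0.05,0.1,0.3} x rounds {50,200,500}) are tuned by
  5-fold inner CV, also split by TF, maximizing held-out AUPRC with ties
  broken by grid order. Fold assignment is repeated over seeds (default 20)
  and the mean network reported, with the per-seed SD as dispersion.
* **Integration** — fuse expression and binding data for TFs that have both.
  A separate model per TF (or small group) is trained with an intentional
  overfit profile (depth 10, rate 0.3, 1000 rounds, no subsampling) and used
  to score the very edges it was trained on. Overfitting is the control
  knob: it raises the influence of the binding labels on the fused score,
  while the features rank edges within label groups.
* **Cross-trained** — fit on one dataset's features (all labeled TFs),
  apply to another dataset's features with the same column roles.

**Constrained ranking** post-processes an integration network for users who
require every reported edge to be binding-supported: label-1 edges keep
their model score, all other edges are set to exactly 0. By construction
100% of nonzero-score edges are supported by the labels used to constrain
them.

# Evaluation metrics

All curve metrics use per-TF-scaled thresholds: at threshold *t* the edge
budget is `t x (number of evaluable TFs)` — an average of *t* targets per
TF — so networks of different sizes are comparable. Edges are ranked by
absolute score; zero and missing scores are never ranked; ties break
lexicographically by (tf, gene) everywhere a cut is made, making every
metric deterministic.

* **Binding** — percent of top-budget edges supported by binding labels;
  only TFs with binding data are evaluable, and their random expectation
  (the overall positive fraction) is reported alongside.
* **GO** — per TF, the best Bonferroni-adjusted upper-tail hypergeometric
  enrichment among its top-*t* targets, over terms with at most 300
  annotated genes (generic terms excluded) and at least 2 in the universe.
  The curve reports the median of `-log10 p` across TFs exceeding the
  significance cap (`-log10 p > 4`): it compares how specific the best term
  is among TFs that have one. Bonferroni on the adjusted scale is used for
  the cap because it is the more conservative of the common readings; both
  raw and adjusted p are returned. When no TF passes, the curve point is an
  explicit missing value, never 0.
* **GO-directness** — among each TF's thresholded targets annotated with its
  best term, the fraction that is binding-supported; aggregated across TFs
  by mean (headline) with the median also emitted. This separates "enriched
  because of direct targets" from "enrichment bought with indirect edges".
* **PPI** — discretize at *t* = 25 targets per TF (per-TF top-*t*, so every
  TF contributes a comparable set — global cuts would make Jaccard
  similarities incomparable across TF pairs), rank TF pairs by Jaccard
  similarity of target sets, and report the percent of top-*n* pairs
  (n = 10..100) with interaction confidence >= 0.7.
* **AUROC / AUPRC** — midrank-tied rank AUROC and step-interpolated AUPRC,
  for fixed-size comparisons against label networks.

A chance baseline for these metrics is produced by permuting a network's
scores uniformly across all valid (non-self) edges, which preserves the
score multiset exactly while destroying all (TF, gene) structure.

# The synthetic benchmark

Real curated binding networks and perturbation compendia are external
downloads, so the package ships a planted-truth generator that emulates
their structure: a sparse signed regulatory network (Poisson out-degree,
default mean 20; effect magnitudes N(1, 0.25) with random sign), one
perturbation sample per TF plus 3 controls, gene baselines N(0, 1) in log2
units, and N(0, 0.5) observation noise. A deletion sets the perturbed TF's
log2 level to 0 — so, as in real knockout compendia, TFs expressed near the
baseline midpoint yield weak signatures and response strength varies across
TFs; an overexpression pins the level at +2. Binding labels flip planted
edges to 0 with probability 0.3 (false negatives) and non-edges to 1 with
probability 0.01 (false positives), mimicking imperfect binding assays.
Promoters are uniform-random 500-mers carrying each TF's planted motif in
80% of its true targets. Annotation terms are unions of 1–3 TFs' target
sets plus noise genes; strong interactions connect "complex" TF pairs that
share 80% of their targets.

The default conditions — 50 TFs, 500 genes — are the package's reference
benchmark; the test suite also uses a 100-TF variant for training-size
scaling and 6–10-TF fixtures for oracle comparisons. These sizes make the
whole suite run in minutes on one core while leaving every statistical
property measurable.

What the benchmark does *not* emulate: yeast-specific expression
distributions, time-course kinetics, correlated measurement noise, motif
families and cofactor motifs, and annotation incompleteness. Passing tests
demonstrate that the machinery is correct and that the statistical
structure (features informative of truth, labels noisy, fusion coherent) is
exploited — not that real-data accuracy matches any particular study.

# Observed behaviour of integration mode

Two findings from the benchmark are worth stating explicitly. First, when
expression features are strong relative to the labels, cross-validated
generalization can outrank integration against the planted truth —
overfitting the labels is only the right call when the labels add
information the features lack. Second, with the overfit profile a per-TF
model can memorize its training labels even from *uninformative* features
(deep trees separate 500 rows on any continuous column), so randomizing the
features does not collapse the integrated network below the labels' own
accuracy; what randomization removes is precisely the fusion gain — the
feature-driven re-ranking within label groups. Users who want the
randomization control to be diagnostic should compare against the labels'
own accuracy, not against zero.

# Numerical conventions and degenerate inputs

* Written artifacts use 6-significant-digit scores, tab separation, and
  lexicographic (tf, gene) edge order, so repeated runs are byte-identical.
* All randomness flows from a single user seed through derived per-task
  seeds; RNG state is restored after every internal use.
* Constant-expression genes or TFs yield zero coefficients/importances with
  a warning; zero-variance series get Spearman score 0.
* Degenerate label sets (all 0 or all 1) refuse to train, except per-group
  integration, which emits the constant label with a warning rather than
  aborting a 50-group run for one degenerate group.
* Promoters shorter than a motif score as missing; `N` bases contribute 0
  to scan scores.
* Hypergeometric p-values are floored at 1e-300 before `-log10`.

# Limitations

* The LASSO score is weak at small sample counts (one sample per TF): the
  one-SE rule frequently selects the empty model. It is retained because
  the combiner is robust to weak features, but it contributes little below
  ~100 samples.
* GO metrics take the annotation as given; no ancestor propagation is
  performed. Users wanting true-path semantics must pre-propagate.
* Binding labels are consumed as given; no confidence scores are modelled
  except through the constrained-ranking path.
* The motif module is a self-contained inference pipeline, not a wrapper
  around an external motif finder, and uses only 0-order backgrounds.
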