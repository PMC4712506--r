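---
title: "Methods: iterative ensemble-consensus label refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative ensemble-consensus label refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtyperefine)
```

## The problem and the model

Molecular subtype labels for expression cohorts are typically produced by a
single-sample predictor applied once. `subtyperefine` instead treats the
labelling as a latent quantity to be estimated jointly with the features
that discriminate the classes: if a sample's label is wrong, the features
selected from that labelling are slightly wrong, and a diverse classifier
ensemble trained on those features will tend to vote the sample back toward
its true class. Iterating feature selection, balanced ensemble voting and
consensus relabelling is a fixed-point computation on the labelling; the
assumptions are that (i) each class is characterised by a modest set of
up- and down-regulated probes, (ii) the initial labelling is mostly right,
so class-versus-rest statistics computed from it point in the right
direction, and (iii) ensemble members err in sufficiently different ways
that consensus filters individual-member noise.

Samples on which the ensemble cannot agree are not forced into a class:
they are marked `INCONSISTENT` and removed from all subsequent scoring and
training within the phase. This is deliberate — a low-agreement sample
harms feature selection more than its vote is worth, and the inconsistent
pool is itself a finding (candidate mixed or atypical tumours).

## The CM1 score

For a probe $g$ and class $c$ with in-class mean/sd $\mu_{in}, s_{in}$ and
out-of-class (pooled rest) $\mu_{out}, s_{out}$:

$$\mathrm{CM1}(g, c) = \frac{\mu_{in} - \mu_{out}}{s_{in} + s_{out}}$$

The statistic family it belongs to (signal-to-noise-style class separation
scores) admits several spread terms, and the exact denominator is a design
point rather than the method's substance; the loop's behaviour is driven by
the *ranking*, which is stable across variants. We therefore default to the
sum-of-sds form and keep the denominator pluggable (`"pooled"` for the
pooled sd, `"range"` for max − min). Numerical conventions:

* zero denominator with equal means scores 0, so all-constant probes never
  rank;
* zero denominator with separated means scores ±`cap` (default $10^6$) —
  perfectly separated constant probes rank first without overflow;
* ranking ties break by ascending probe id, making selection
  platform-independent;
* only strictly positive scores qualify as "up" and strictly negative as
  "down"; when fewer than `k_up`/`k_down` strict-signed probes exist, the
  list is short (with a warning), never padded.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k_up`, `k_down` | 5, 5 | probes/class | ten signed probes per class; small enough that every feature earns its place, large enough to span a class signature |
| `folds` | 10 | — | standard stratified CV granularity for ~290-sample training sets |
| `runs` | 10 | — | balanced subsets are random; repeats let every large-class sample be voted from several training compositions |
| `refine_threshold` | 0.5 | vote fraction | "at least half" with a uniqueness requirement: exact ties never assign |
| `traintest_threshold` | 2/3 | vote fraction | reclassification of held-out/inconsistent samples demands stronger evidence than in-loop relabelling |
| `kappa_stop` | 0.92 | kappa | well inside the "almost perfect" band (0.81–1); consecutive labellings this similar will not change feature selection materially |
| `max_iterations` | 50 | — | a safety cap; planted-structure cohorts converge in 2–4 iterations |

The balanced subsample takes $m$ = (smallest class size) samples per class,
the smallest class contributing all of its samples. With the five-class
imbalance this package's generator defaults to (smallest class 58), that is
58 × 5 = 290 training samples per run — classifiers over-weight majority
classes otherwise, and the normal-like-sized class would be drowned out.

## Voting and consensus

Within a run, balanced-subset samples receive one out-of-fold prediction
per roster member; every other assigned sample is voted by members trained
once on the whole subset. Both are needed: relabelling is only possible for
samples that receive votes, and only out-of-fold votes are honest for
subset samples. Votes are pooled across the 10 runs (240 votes per sample
with the 24-member roster) and consensus is applied once to the pooled
counts, rather than taking a majority of per-run majorities — pooling uses
all information, has no nested-tie pathologies, and makes the vote totals
an interpretable per-sample evidence weight. A member that fails to train
on a fold abstains (with a warning) and shrinks that sample's vote total;
an abstention is not a "no" vote.

The roster is declared data, not code: 24 members over six families (trees
at several complexities, a one-rule learner, naive Bayes, LDA, multinomial
logistic, linear/RBF SVMs, nearest centroids, k-NN at several k, random
forests, gradient boosting), echoed verbatim into result provenance. The
specific member list is a design choice — the method needs diversity, not
particular algorithms — so the roster is fully configurable, and a reduced
8-member roster (`fast_roster_members()`) spanning five families is
provided for simulation studies where wall-clock time dominates.

## Stopping

Stability requires labels **and** feature set unchanged. The conjunctive
reading is the safe one: labels can be momentarily unchanged while the
feature set still drifts, and stopping then would freeze a transient. Note
an unchanged labelling implies the next feature selection would repeat, so
a fixed point stops after a single iteration. The kappa criterion is
independent: the two-rater Fleiss' kappa between consecutive labellings —
computed over samples assigned in both, so the inconsistent state is never
treated as a rated category — reaching `kappa_stop` ends the loop even if
small label flips persist. Stability is checked before kappa, so a perfect
fixed point reports `labels_and_features_stable` rather than
`kappa_reached`.

## Agreement statistics and survival

Cramér's V, Fleiss' kappa and the adjusted Rand index are implemented from
their definitions (no continuity/bias corrections) and verified in the test
suite against independent brute-force oracles — `chisq.test`, an
alternative algebraic identity for kappa, exhaustive pair enumeration for
ARI — to $10^{-12}$ on 1,000 random instances. For V, all-zero rows or
columns (e.g. an empty inconsistent row) are dropped before both the
$\chi^2$ and the $\min(r,c)-1$ term, since association is undefined over
empty margins. Because published agreement figures for refined-vs-initial
tables rarely state whether the inconsistent row was included, the
`agreement_report()` output carries both variants (`cramers_v`/`ari` over
jointly assigned samples, `_all` over all shared samples).

Kaplan–Meier curves and the $K$-group log-rank test are likewise computed
from the standard formulas (censorings at $t$ leave the risk set after the
events at $t$; the log-rank covariance uses the hypergeometric form with
one group dropped, falling back to a generalized inverse if the reduced
covariance is singular), and are tested against the `survival` package as
an independent oracle. Cox modelling is intentionally out of scope: the
stratification claim the pipeline evaluates is the log-rank p-value.

## What the generator emulates — and what it does not

`generator_spec()` encodes the study conditions the tests run under:
1,000 probes; five classes of sizes 250/200/90/90/58 (the pronounced
imbalance, smallest class 58); five up- and five down-regulated planted
probes per class, disjoint across classes, shifted by ±2 background sd;
i.i.d. Gaussian log-intensity background; exactly `round(0.1·n)` corrupted
initial labels, reassigned to a uniformly random *different* class (a
mislabelling predictor always outputs some subtype, never an inconsistent
state); class-conditional ER/PR/HER2 positivity probabilities following the
expected subtype patterns (luminal ER+, HER2-enriched HER2+, basal-like
triple-negative); class-distinct exponential survival with median survivals
from ~1,000 (basal-like) to ~4,000 days (luminal A) and ~30 % independent
exponential censoring; a stratified 50/50 discovery/validation split.

Real microarray data differ in ways the generator deliberately omits:
probe–probe correlation beyond the planted blocks, heavy-tailed and
batch-structured noise, classes defined by graded continua rather than
clean mean shifts, and label errors that are *systematic* (concentrated
between adjacent subtypes) rather than uniform. Passing tests therefore
demonstrate that the machinery is correct and that the loop converges and
repairs uniform label noise under block-structured signal — not that any
particular cohort's labels would be improved.

## Problem sizes and determinism

End-to-end tests and the acceptance script run the full two-stage pipeline
on the 1,000 × 688 generator default with the 8-member roster — a size
chosen so a single pipeline converges in 2–4 iterations in well under a
minute while preserving the class imbalance and the 10-fold/10-run
structure. Unit tests of the loop use smaller planted cohorts (~150–300
probes, 70–160 samples) and a 3-member roster. Everything is deterministic
given the master seed: per-iteration, per-run, per-fold and per-member
seeds are derived from it by a Lehmer-step schedule, and stochastic members
(random forest, k-NN tie-breaking) are seeded per fit, so two executions
with the same configuration produce identical traces.

## Known limitations

* The roster's member algorithms come from general-purpose R
  implementations; no claim of equivalence with any other suite's versions
  of the same learners is made.
* The consensus rule requires a unique maximal class at the threshold;
  cohorts with genuinely overlapping classes will park many samples as
  inconsistent rather than force a call.
* CM1 scores are raw effect sizes — no moderated variance estimation and
  no multiple-testing calibration — matching the method's design, but
  meaning top lists from very small classes are noisy.
* `full_pipeline()` assumes discovery and validation matrices share the
  probe space; cross-platform mapping is out of scope.
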