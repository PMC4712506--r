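# subtyperefine

Iterative ensemble-consensus refinement of molecular subtype labels for
gene expression cohorts.

Single-sample predictors such as PAM50 assign each breast tumour to one of
five intrinsic subtypes (luminal A, luminal B, HER2-enriched, basal-like,
normal-like), but the labels they produce are noisy: different predictors
agree only moderately, and misassigned samples blur the molecular and
clinical contrasts between subtypes. `subtyperefine` treats an initial
labelling as a starting point, not ground truth, and iteratively refines it
until the labels, the discriminative features behind them, and a
heterogeneous classifier ensemble all agree.

## The method

Each refinement iteration, starting from the current labelling of a
probes × samples expression matrix:

1. **CM1 feature scoring.** Every probe is scored for every class against
   the pooled rest:

   `CM1(probe, class) = (mean_in − mean_out) / (sd_in + sd_out)`

   Positive scores mark up-regulation in the class, negative scores
   down-regulation. Per class, the 5 most positive and 5 most negative
   strictly-signed probes are kept (10 per class; the signed union is the
   classifier feature space).
2. **Balanced ensemble voting.** The smallest class (size *m*) fixes a
   balanced training subset of *m* samples per class. A declared roster of
   heterogeneous classifiers (24 members over six families by default:
   trees, a one-rule learner, naive Bayes, linear/function-based learners,
   nearest neighbours, bagged/boosted meta-learners) votes every sample —
   subset samples through stratified 10-fold cross-validation, all other
   assigned samples through members trained on the full subset. The
   subsampling is repeated 10 times and votes are pooled.
3. **Consensus relabelling.** A sample is relabelled to the unique class
   holding at least half of its pooled votes; otherwise it is marked
   `INCONSISTENT` and excluded from all later scoring and training.
4. **Stopping.** The loop ends when labels and feature set stop changing,
   or when Fleiss' kappa between consecutive labellings reaches 0.92
   ("almost perfect agreement"), with a safety cap on iterations.

After convergence, validation samples and previously inconsistent samples
are reclassified by the refined ensemble under a stricter two-thirds
consensus (failures stay `UNASSIGNED`), merged with the refined discovery
set, and the loop runs once more over everything.

Label quality is evaluated with first-principles implementations of
Cramér's V, Fleiss' kappa (with its six interpretation bands) and the
adjusted Rand index, with clinical marker contingency summaries (ER/PR/HER2)
and Kaplan–Meier / log-rank survival stratification.

A seed-deterministic synthetic-cohort generator (five latent classes with
planted up-/down-regulated probe blocks, an imbalanced design whose
smallest class has 58 samples, a corrupted initial labelling,
class-conditional markers and class-distinct exponential survival) makes
the whole pipeline testable end to end.

## Worked example

```r
library(subtyperefine)

ds <- generate_dataset(generator_spec(seed = 42))        # 1000 x 688 cohort
roster <- build_roster(fast_roster_members())            # 8 fast members
cfg <- refinement_config(seed = 42)

disc <- ds$discovery_ids
res <- full_pipeline(
  ds$expression[, disc],
  ds$initial[ds$initial$sample_id %in% disc, ],
  ds$expression[, ds$validation_ids],
  roster, cfg,
  validation_lab = ds$initial[ds$initial$sample_id %in% ds$validation_ids, ]
)

res
#> <pipeline_result> 3 total iteration(s) (discovery 2, merged 1)
#> final label counts:
#>
#>  Basal   Her2   LumA   LumB Normal
#>     91     89    250    200     58

fin <- res$final_labelling
truth <- ds$truth$label[match(fin$sample_id, ds$truth$sample_id)]
mean(fin$label == truth)                       # 0.999 final agreement
mean(ds$initial$label == ds$truth$label)       # 0.900 before refinement
mean(ds$planted$probe_id %in% res$final_features$union)  # 1.0 recovery

res$agreement$fleiss_kappa                     # 0.864 vs the corrupted input
res$agreement$kappa_band                       # "almost perfect agreement"
```

The refinement corrects essentially all of the 10 % corrupted labels in
three iterations while recovering every planted discriminative probe; the
kappa of ~0.86 against the *initial* labels reflects exactly the corruption
that was repaired.

Result objects have broom-style `tidy()`/`glance()` methods and
`autoplot()` / `plot_contingency()` figures; `cli_main()` (or the installed
`inst/cli/subtyperefine` script) exposes `simulate`, `refine`,
`reclassify`, `pipeline` and `report` subcommands over the same functions.

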