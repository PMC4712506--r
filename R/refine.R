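# The iterative refinement loop: class-balanced subsampling, repeated
# ensemble voting, consensus relabelling with an inconsistent state,
# stability/kappa stopping, and the two-stage discovery -> validation
# workflow.

#' Refinement configuration
#'
#' @param k_up,k_down Per-class signed feature list sizes (default 5 and 5,
#'   i.e. ten probes per class).
#' @param folds Cross-validation folds within each balanced subset
#'   (default 10).
#' @param runs Balanced-subsample repetitions per iteration (default 10);
#'   votes are pooled across runs before consensus.
#' @param refine_threshold Consensus vote fraction during refinement
#'   (default 0.5, "at least half").
#' @param traintest_threshold Consensus vote fraction for reclassification
#'   of validation/inconsistent samples (default 2/3).
#' @param kappa_stop Stop when the two-rater Fleiss' kappa between
#'   consecutive labellings reaches this value (default 0.92).
#' @param max_iterations Safety cap on refinement iterations (default 50).
#' @param denominator CM1 denominator variant, see [cm1_score()].
#' @param seed Master seed; all per-iteration and per-run seeds derive from
#'   it deterministically.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(k_up = 5, k_down = 5, folds = 10, runs = 10,
                              refine_threshold = 0.5,
                              traintest_threshold = 2 / 3,
                              kappa_stop = 0.92, max_iterations = 50,
                              denominator = "sdsum", seed = 1L) {
  for (th in c(refine_threshold, traintest_threshold)) {
    if (th <= 0 || th > 1) abort("thresholds must be in (0, 1]")
  }
  if (kappa_stop < 0 || kappa_stop > 1) abort("kappa_stop must be in [0, 1]")
  if (runs < 1) abort("runs must be >= 1")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(
    k_up = k_up, k_down = k_down, folds = folds, runs = runs,
    refine_threshold = refine_threshold,
    traintest_threshold = traintest_threshold,
    kappa_stop = kappa_stop, max_iterations = max_iterations,
    denominator = denominator, seed = as.integer(seed)
  ), class = "refinement_config")
}

#' Class-balanced training subsample
#'
#' Finds the minimum class size `m` among the assigned samples and returns
#' exactly `m` sample ids per class: the minimum class contributes all its
#' samples, larger classes are drawn uniformly without replacement. With
#' five classes and a smallest class of 58 this reproduces the 58-per-class,
#' 290-sample balanced training set.
#'
#' @param lab Labelling tibble; INCONSISTENT/UNASSIGNED samples are excluded
#'   before balancing.
#' @param seed Integer seed for the uniform draws.
#' @param classes Fixed class list (default: classes present among assigned
#'   samples); a listed class with no assigned sample is an error.
#' @return Character vector of `m * K` sample ids.
#' @export
balance_classes <- function(lab, seed = 1L, classes = NULL) {
  lab <- assigned(lab)
  classes <- classes %||% sort(unique(lab$label))
  sizes <- vapply(classes, function(cl) sum(lab$label == cl), integer(1))
  if (any(sizes == 0)) {
    abort(paste0("class with no assigned samples: ", classes[sizes == 0][1]))
  }
  m <- min(sizes)
  withr::with_seed(seed, {
    unlist(map(classes, function(cl) {
      ids <- lab$sample_id[lab$label == cl]
      if (length(ids) == m) ids else sample(ids, m)
    }), use.names = FALSE)
  })
}

# All classes present with at least `min_n` assigned samples, else an error
# naming the offender.
check_class_support <- function(lab, classes, min_n = 2) {
  lab <- assigned(lab)
  sizes <- vapply(classes, function(cl) sum(lab$label == cl), integer(1))
  if (any(sizes < min_n)) {
    abort(sprintf("class '%s' has %d assigned sample(s), need >= %d",
                  classes[sizes < min_n][1], min(sizes), min_n))
  }
  invisible(sizes)
}

#' One refinement iteration
#'
#' Selects per-class signed feature sets from the currently assigned
#' samples, then for each of `config$runs` runs draws a class-balanced
#' subset, votes subset samples by out-of-fold cross-validation and all
#' other assigned samples by members trained on the full subset, pools the
#' votes across runs, and applies the consensus rule. Samples failing
#' consensus become INCONSISTENT and leave the assigned pool for subsequent
#' iterations.
#'
#' @param x Expression matrix (probes x samples).
#' @param lab Current labelling of the matrix samples.
#' @param roster A `classifier_roster`.
#' @param config A [refinement_config()].
#' @param iteration_seed Seed for this iteration (derive it from the master
#'   seed for reproducibility).
#' @param classes Fixed class list (default: classes among assigned samples).
#' @return An `iteration_record` list: `features`, `labelling_before`,
#'   `labelling_after`, `n_changed`, `n_newly_inconsistent`, `kappa`,
#'   `vote_totals`, and `stop_reason` (filled by [run_refinement()]).
#' @export
refine_iteration <- function(x, lab, roster, config, iteration_seed = 1L,
                             classes = NULL) {
  lab_a <- assigned(lab)
  classes <- classes %||% sort(unique(lab_a$label))
  check_class_support(lab, classes, min_n = 2)

  fs <- select_features(x, lab_a, k_up = config$k_up, k_down = config$k_down,
                        classes = classes, denominator = config$denominator)
  xs <- x[fs$union, , drop = FALSE]

  vms <- vector("list", 2L * config$runs)
  vi <- 0L
  for (r in seq_len(config$runs)) {
    run_seed <- derive_seed(iteration_seed, r)
    subset_ids <- balance_classes(lab_a, seed = derive_seed(run_seed, 1L),
                                  classes = classes)
    sub_lab <- lab_a[lab_a$sample_id %in% subset_ids, , drop = FALSE]
    vi <- vi + 1L
    vms[[vi]] <- crossval_votes(xs[, subset_ids, drop = FALSE], sub_lab,
                                roster, folds = config$folds,
                                seed = derive_seed(run_seed, 2L),
                                classes = classes)
    outside <- setdiff(lab_a$sample_id, subset_ids)
    if (length(outside)) {
      vi <- vi + 1L
      vms[[vi]] <- predict_votes(xs[, subset_ids, drop = FALSE], sub_lab,
                                 xs[, outside, drop = FALSE], roster,
                                 seed = derive_seed(run_seed, 3L),
                                 classes = classes)
    }
  }
  pooled <- pool_votes(vms[seq_len(vi)], classes)
  voted <- consensus(pooled, config$refine_threshold, mode = "refine")

  new_lab <- lab
  idx <- match(voted$sample_id, new_lab$sample_id)
  new_lab$label[idx] <- voted$label

  before_a <- assigned(lab)
  after <- new_lab$label[match(before_a$sample_id, new_lab$sample_id)]
  n_changed <- sum(after != before_a$label)
  n_newly_inconsistent <- sum(after == STATE_INCONSISTENT)

  structure(list(
    features = fs,
    labelling_before = lab,
    labelling_after = new_lab,
    n_changed = n_changed,
    n_newly_inconsistent = n_newly_inconsistent,
    kappa = labelling_kappa(lab, new_lab, classes = classes),
    vote_totals = total_votes(pooled),
    stop_reason = "none"
  ), class = "iteration_record")
}

#' Run the refinement loop to convergence
#'
#' Iterates [refine_iteration()] until (a) the labelling and the selected
#' feature set both stop changing, (b) the two-rater Fleiss' kappa between
#' consecutive labellings reaches `config$kappa_stop`, or (c)
#' `config$max_iterations` is hit (with a warning). An unchanged labelling
#' implies the next feature selection would be identical, so a fixed point
#' stops after a single iteration.
#'
#' @inheritParams refine_iteration
#' @param lab Initial labelling (e.g. the original subtype calls).
#' @return A `refinement_trace`: list with `iterations` (list of
#'   `iteration_record`s), `final_labelling`, `final_features`,
#'   `stop_reason`, `classes`, `config`, `roster`.
#' @export
run_refinement <- function(x, lab, roster, config, classes = NULL) {
  classes <- classes %||% sort(unique(assigned(lab)$label))
  records <- list()
  current <- lab
  prev_fs <- NULL
  stop_reason <- "none"
  for (i in seq_len(config$max_iterations)) {
    rec <- refine_iteration(x, current, roster, config,
                            iteration_seed = derive_seed(config$seed, 17L, i),
                            classes = classes)
    labels_stable <- rec$n_changed == 0
    features_stable <- labels_stable ||
      (!is.null(prev_fs) && feature_sets_equal(rec$features, prev_fs))
    if (labels_stable && features_stable) {
      stop_reason <- "labels_and_features_stable"
    } else if (!is.na(rec$kappa) && rec$kappa >= config$kappa_stop) {
      stop_reason <- "kappa_reached"
    } else if (i == config$max_iterations) {
      stop_reason <- "max_iterations"
      warn(sprintf("refinement stopped at max_iterations = %d without converging",
                   config$max_iterations))
    }
    rec$stop_reason <- stop_reason
    records[[i]] <- rec
    current <- rec$labelling_after
    prev_fs <- rec$features
    if (stop_reason != "none") break
  }
  structure(list(
    iterations = records,
    final_labelling = current,
    final_features = prev_fs,
    stop_reason = stop_reason,
    classes = classes,
    config = config,
    roster = roster
  ), class = "refinement_trace")
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat(sprintf("<refinement_trace> %d iteration(s), stop: %s\n",
              length(x$iterations), x$stop_reason))
  print(tidy(x))
  invisible(x)
}

#' Reclassify held-out or inconsistent samples from a refined training set
#'
#' Per run, draws a class-balanced subset of the refined training samples,
#' trains every roster member on it and votes the target samples; votes are
#' pooled across runs and reduced at the (stricter) train-test consensus
#' threshold, so samples failing it come back UNASSIGNED.
#'
#' @param x Training expression matrix (probes x samples).
#' @param lab Refined labelling of the training samples.
#' @param target_x Expression matrix of the samples to classify (validation
#'   set and/or previously inconsistent samples).
#' @param roster A `classifier_roster`.
#' @param config A [refinement_config()].
#' @param features Optional `feature_set`; default recomputes
#'   [select_features()] from `lab`.
#' @param classes Fixed class list.
#' @return A labelling tibble over the target samples.
#' @export
reclassify <- function(x, lab, target_x, roster, config, features = NULL,
                       classes = NULL) {
  lab_a <- assigned(lab)
  classes <- classes %||% sort(unique(lab_a$label))
  check_class_support(lab, classes, min_n = 2)
  fs <- features %||% select_features(x, lab_a, k_up = config$k_up,
                                      k_down = config$k_down,
                                      classes = classes,
                                      denominator = config$denominator)
  xs <- x[fs$union, , drop = FALSE]
  ts <- target_x[fs$union, , drop = FALSE]
  vms <- map(seq_len(config$runs), function(r) {
    run_seed <- derive_seed(config$seed, 23L, r)
    subset_ids <- balance_classes(lab_a, seed = derive_seed(run_seed, 1L),
                                  classes = classes)
    sub_lab <- lab_a[lab_a$sample_id %in% subset_ids, , drop = FALSE]
    predict_votes(xs[, subset_ids, drop = FALSE], sub_lab, ts, roster,
                  seed = derive_seed(run_seed, 2L), classes = classes)
  })
  pooled <- pool_votes(vms, classes)
  consensus(pooled, config$traintest_threshold, mode = "traintest")
}

#' Full two-stage refinement pipeline
#'
#' Refines the discovery labelling to convergence, reclassifies the
#' validation samples and the discovery samples left inconsistent using the
#' refined feature set and labels under the train-test consensus rule,
#' merges every assigned sample, and refines the merged set again. Reports
#' the final labels, feature set, a final-versus-initial contingency table
#' (with an Inconsistent row when present) and agreement statistics.
#'
#' @param x Discovery expression matrix (probes x samples).
#' @param lab Initial discovery labelling.
#' @param validation_x Optional validation expression matrix sharing the
#'   probe space (`NULL` for none; the pipeline then degenerates to
#'   refinement of the discovery set plus reclassification of its
#'   inconsistent samples).
#' @param roster A `classifier_roster`.
#' @param config A [refinement_config()].
#' @param validation_lab Optional initial labelling of the validation
#'   samples, used only for reporting (contingency/agreement).
#' @return A `pipeline_result`: list with `final_labelling` (all samples),
#'   `final_features`, `discovery_trace`, `merged_trace`, `reclassified`,
#'   `contingency`, `agreement`, `classes`, `config`, `roster`.
#' @export
full_pipeline <- function(x, lab, validation_x = NULL, roster,
                          config = refinement_config(),
                          validation_lab = NULL) {
  classes <- sort(unique(assigned(lab)$label))
  cfg1 <- config
  cfg1$seed <- derive_seed(config$seed, 1L)
  trace1 <- run_refinement(x, lab, roster, cfg1, classes = classes)
  refined <- trace1$final_labelling

  inc_ids <- refined$sample_id[refined$label == STATE_INCONSISTENT]
  target_x <- x[, inc_ids, drop = FALSE]
  if (!is.null(validation_x) && ncol(validation_x) > 0) {
    missing_probes <- setdiff(rownames(x), rownames(validation_x))
    if (length(missing_probes)) {
      abort(sprintf("validation matrix lacks %d probe(s), e.g. '%s'",
                    length(missing_probes), missing_probes[1]))
    }
    target_x <- cbind(target_x, validation_x[rownames(x), , drop = FALSE])
  }

  recl <- NULL
  merged_lab <- assigned(refined)
  merged_x <- x[, merged_lab$sample_id, drop = FALSE]
  if (ncol(target_x) > 0) {
    cfg2 <- config
    cfg2$seed <- derive_seed(config$seed, 2L)
    recl <- reclassify(x[, assigned(refined)$sample_id, drop = FALSE],
                       assigned(refined), target_x, roster, cfg2,
                       features = trace1$final_features, classes = classes)
    recl_a <- assigned(recl)
    merged_lab <- bind_rows(merged_lab, recl_a)
    all_x <- cbind(x, if (!is.null(validation_x) && ncol(validation_x) > 0) {
      validation_x[rownames(x), , drop = FALSE]
    })
    merged_x <- all_x[, merged_lab$sample_id, drop = FALSE]
  }

  cfg3 <- config
  cfg3$seed <- derive_seed(config$seed, 3L)
  trace2 <- run_refinement(merged_x, merged_lab, roster, cfg3,
                           classes = classes)

  # final state over every sample seen: merged-phase outcome, UNASSIGNED for
  # reclassification failures
  final <- trace2$final_labelling
  if (!is.null(recl)) {
    un <- recl[recl$label == STATE_UNASSIGNED, , drop = FALSE]
    final <- bind_rows(final, un)
  }

  initial_all <- lab
  if (!is.null(validation_lab)) initial_all <- bind_rows(lab, validation_lab)
  shared <- intersect(final$sample_id, initial_all$sample_id)
  fin <- final$label[match(shared, final$sample_id)]
  ini <- initial_all$label[match(shared, initial_all$sample_id)]
  row_levels <- c(classes,
                  intersect(c(STATE_INCONSISTENT, STATE_UNASSIGNED), unique(fin)))
  contingency <- contingency_table(fin, ini, row_levels = row_levels,
                                   col_levels = classes)

  structure(list(
    final_labelling = final,
    final_features = trace2$final_features,
    discovery_trace = trace1,
    merged_trace = trace2,
    reclassified = recl,
    contingency = contingency,
    agreement = agreement_report(final, initial_all),
    classes = classes,
    config = config,
    roster = roster
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  n_it <- length(x$discovery_trace$iterations) + length(x$merged_trace$iterations)
  cat(sprintf(
    "<pipeline_result> %d total iteration(s) (discovery %d, merged %d)\n",
    n_it, length(x$discovery_trace$iterations), length(x$merged_trace$iterations)
  ))
  cat("final label counts:\n")
  print(table(x$final_labelling$label))
  invisible(x)
}
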