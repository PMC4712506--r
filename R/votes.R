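# Ensemble voting: out-of-fold cross-validation votes, train-test votes,
# and the consensus reduction to labels.

#' Construct a vote matrix from a per-member prediction log
#'
#' The prediction log is the unit of provenance: one row per (sample,
#' member) vote with the fold it came from; abstentions (member failed to
#' train or predict) carry `NA` predictions and do not count as votes. The
#' vote matrix is always recomputable from the log.
#'
#' @param log Tibble with columns `sample_id`, `member_id`, `fold`,
#'   `predicted_label` (`NA` = abstain).
#' @param classes Class list defining the columns of the count matrix.
#' @param sample_ids Sample universe (rows); defaults to the ids in the log.
#' @param nominal_votes Nominal votes per sample (roster size, times runs
#'   when pooled); stored for the vote-conservation invariant.
#' @return A `vote_matrix` object: list with `counts` (samples x classes
#'   integer matrix), `log`, and `nominal_votes`.
#' @export
vote_matrix <- function(log, classes, sample_ids = NULL, nominal_votes = NA_integer_) {
  sample_ids <- sample_ids %||% unique(log$sample_id)
  cast <- log[!is.na(log$predicted_label), , drop = FALSE]
  bad <- setdiff(unique(cast$predicted_label), classes)
  if (length(bad)) abort(paste0("vote for unknown class: ", bad[1]))
  counts <- table(
    factor(cast$sample_id, levels = sample_ids),
    factor(cast$predicted_label, levels = classes)
  )
  counts <- matrix(as.integer(counts), nrow = length(sample_ids),
                   dimnames = list(sample_ids, classes))
  structure(list(counts = counts, log = log, nominal_votes = nominal_votes),
            class = "vote_matrix")
}

#' @export
print.vote_matrix <- function(x, ...) {
  cat(sprintf("<vote_matrix> %d samples x %d classes, %d logged votes (%d abstentions)\n",
              nrow(x$counts), ncol(x$counts), sum(!is.na(x$log$predicted_label)),
              sum(is.na(x$log$predicted_label))))
  invisible(x)
}

#' Total (non-abstained) votes per sample
#' @param votes A `vote_matrix`.
#' @return Named integer vector.
#' @export
total_votes <- function(votes) {
  rowSums(votes$counts)
}

# Pool several vote matrices over the same class list (sample sets may
# differ); logs are concatenated so conservation still holds.
pool_votes <- function(vms, classes) {
  log <- bind_rows(map(vms, "log"))
  nominal <- sum(map_int(vms, function(v) {
    as.integer(v$nominal_votes %||% NA_integer_)
  }))
  vote_matrix(log, classes, sample_ids = unique(log$sample_id),
              nominal_votes = nominal)
}

# Stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt cyclically over folds, so fold class proportions track
# the overall ones and every class with >= 2 members spans >= 2 folds.
stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  fold_of
}

#' Out-of-fold cross-validation votes
#'
#' Runs stratified k-fold cross-validation of every roster member on the
#' training samples: each sample receives exactly one out-of-fold prediction
#' per member (one vote each, so roster-size votes in total), unless a
#' member fails on a fold, in which case it abstains for that fold's test
#' samples with a warning.
#'
#' @param x Expression matrix (probes x samples) already restricted to the
#'   selected feature union.
#' @param lab Labelling of the training samples; all must carry class labels.
#' @param roster A `classifier_roster`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed driving fold assignment and member randomness.
#' @param classes Class list (default: classes present in `lab`).
#' @return A `vote_matrix` over the training samples.
#' @export
crossval_votes <- function(x, lab, roster, folds = 10, seed = 1L, classes = NULL) {
  if (folds < 2) abort("folds must be >= 2")
  lab_a <- assigned(lab)
  if (nrow(lab_a) < nrow(lab)) abort("all training samples must carry class labels")
  classes <- classes %||% sort(unique(lab_a$label))
  ids <- lab_a$sample_id
  if (!all(ids %in% colnames(x))) abort("labelled samples missing from matrix")
  sizes <- table(lab_a$label)
  if (any(sizes < 2)) {
    abort(sprintf("class '%s' has fewer than 2 training samples",
                  names(sizes)[sizes < 2][1]))
  }
  xt <- t(x[, ids, drop = FALSE])  # samples x features
  y <- factor(lab_a$label, levels = classes)
  fold_of <- stratified_folds(lab_a$label, folds, derive_seed(seed, 101L))

  logs <- vector("list", folds * nrow(roster))
  li <- 0L
  n_ok_members <- 0L
  for (mi in seq_len(nrow(roster))) {
    member_ok <- FALSE
    for (f in seq_len(folds)) {
      test <- fold_of == f
      if (!any(test)) next
      li <- li + 1L
      mseed <- derive_seed(seed, mi, f)
      pred <- tryCatch({
        fit <- fit_member(roster$member_id[mi], roster$family[mi],
                          roster$params[[mi]],
                          xt[!test, , drop = FALSE], y[!test], seed = mseed)
        p <- predict_member(fit, xt[test, , drop = FALSE], seed = mseed)
        member_ok <- TRUE
        p
      }, error = function(e) {
        warn(sprintf("member '%s' abstained on fold %d: %s",
                     roster$member_id[mi], f, conditionMessage(e)))
        rep(NA_character_, sum(test))
      })
      logs[[li]] <- tibble(
        sample_id = ids[test], member_id = roster$member_id[mi],
        fold = f, predicted_label = pred
      )
    }
    if (member_ok) n_ok_members <- n_ok_members + 1L
  }
  if (n_ok_members == 0L) abort("all roster members failed to train")
  vote_matrix(bind_rows(logs[seq_len(li)]), classes, sample_ids = ids,
              nominal_votes = nrow(roster))
}

#' Votes for target samples from members trained on a full training set
#'
#' Each roster member is fitted once on the complete training set and casts
#' one vote per target sample.
#'
#' @param train_x Training expression matrix (probes x samples) restricted to
#'   the feature union.
#' @param train_lab Labelling of the training samples (all assigned).
#' @param target_x Target expression matrix; must contain every training
#'   feature (rows are matched by probe id).
#' @inheritParams crossval_votes
#' @return A `vote_matrix` over the target samples (`fold` logged as 0).
#' @export
predict_votes <- function(train_x, train_lab, target_x, roster, seed = 1L,
                          classes = NULL) {
  lab_a <- assigned(train_lab)
  if (nrow(lab_a) < nrow(train_lab)) abort("all training samples must carry class labels")
  classes <- classes %||% sort(unique(lab_a$label))
  feats <- rownames(train_x)
  missing_feats <- setdiff(feats, rownames(target_x))
  if (length(missing_feats)) {
    abort(sprintf("target matrix lacks %d training feature(s), e.g. '%s'",
                  length(missing_feats), missing_feats[1]))
  }
  ids <- lab_a$sample_id
  xt <- t(train_x[, ids, drop = FALSE])
  tt <- t(target_x[feats, , drop = FALSE])
  y <- factor(lab_a$label, levels = classes)
  target_ids <- colnames(target_x)

  logs <- vector("list", nrow(roster))
  n_ok <- 0L
  for (mi in seq_len(nrow(roster))) {
    mseed <- derive_seed(seed, mi, 0L)
    pred <- tryCatch({
      fit <- fit_member(roster$member_id[mi], roster$family[mi],
                        roster$params[[mi]], xt, y, seed = mseed)
      p <- predict_member(fit, tt, seed = mseed)
      n_ok <- n_ok + 1L
      p
    }, error = function(e) {
      warn(sprintf("member '%s' abstained: %s", roster$member_id[mi],
                   conditionMessage(e)))
      rep(NA_character_, length(target_ids))
    })
    logs[[mi]] <- tibble(
      sample_id = target_ids, member_id = roster$member_id[mi],
      fold = 0L, predicted_label = pred
    )
  }
  if (n_ok == 0L) abort("all roster members failed to train")
  vote_matrix(bind_rows(logs), classes, sample_ids = target_ids,
              nominal_votes = nrow(roster))
}

#' Reduce votes to consensus labels
#'
#' A sample is assigned class `c` iff its votes for `c` reach
#' `ceiling(threshold * total)` — `total` being its non-abstained votes —
#' and `c` is the unique maximally voted class. Otherwise the sample is
#' marked `INCONSISTENT` (refinement mode) or `UNASSIGNED` (train-test
#' mode). Exact ties therefore never assign.
#'
#' @param votes A `vote_matrix`.
#' @param threshold Required vote fraction in `(0, 1]`; 0.5 gives the
#'   at-least-half majority used inside refinement, 2/3 the stricter
#'   train-test rule.
#' @param mode `"refine"` (failures become INCONSISTENT) or `"traintest"`
#'   (failures become UNASSIGNED).
#' @return A labelling tibble over the voted samples.
#' @export
consensus <- function(votes, threshold, mode = c("refine", "traintest")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  counts <- votes$counts
  if (nrow(counts) == 0 || ncol(counts) == 0) abort("empty vote matrix")
  fail_state <- if (mode == "refine") STATE_INCONSISTENT else STATE_UNASSIGNED
  tot <- rowSums(counts)
  need <- ceiling(threshold * tot)
  vmax <- apply(counts, 1, max)
  unique_max <- rowSums(counts == vmax) == 1
  winner <- colnames(counts)[max.col(counts, ties.method = "first")]
  ok <- tot > 0 & vmax >= need & unique_max
  labelling(rownames(counts), ifelse(ok, winner, fail_state),
            classes = colnames(counts))
}

#' Write a per-member prediction log as TSV
#' @param votes A `vote_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vote_log <- function(votes, path) {
  readr::write_tsv(votes$log, path, progress = FALSE)
  invisible(path)
}
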