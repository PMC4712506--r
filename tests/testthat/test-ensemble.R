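# Roster construction, cross-validation and train-test voting, and the
# consensus rule.

test_that("the default roster has 24 members over at least 5 families", {
  roster <- build_roster()
  expect_s3_class(roster, "classifier_roster")
  expect_identical(nrow(roster), 24L)
  expect_gte(length(unique(roster$family)), 5)
  expect_false(anyDuplicated(roster$member_id) > 0)
})

test_that("roster construction validates its inputs", {
  fast <- build_roster(fast_roster_members())
  expect_identical(nrow(fast), 8L)
  expect_gte(length(unique(fast$family)), 5)

  three <- build_roster(default_roster_members()[1:3])
  expect_identical(nrow(three), 3L)

  dup <- default_roster_members()[c(1, 1)]
  expect_error(build_roster(dup), "duplicate member_id")
  expect_error(
    build_roster(list(list(member_id = "a", family = "quantum"),
                      list(member_id = "b", family = "tree"))),
    "unknown family"
  )
  expect_error(build_roster(default_roster_members()[1]), "at least 2")
})

test_that("cross-validation gives every sample one out-of-fold vote per member", {
  ds <- small_dataset(seed = 2, corruption = 0)
  roster <- tiny_roster()
  fs <- select_features(ds$expression, ds$truth)
  vm <- crossval_votes(ds$expression[fs$union, ], ds$truth, roster,
                       folds = 5, seed = 9)
  expect_true(all(total_votes(vm) == nrow(roster)))
  # per-member: exactly one vote per sample
  per <- table(vm$log$sample_id, vm$log$member_id)
  expect_true(all(per == 1))
})

test_that("voting is deterministic under a fixed seed and recomputable from the log", {
  ds <- small_dataset(seed = 2, corruption = 0)
  roster <- tiny_roster()
  fs <- select_features(ds$expression, ds$truth)
  xs <- ds$expression[fs$union, ]
  vm1 <- crossval_votes(xs, ds$truth, roster, folds = 5, seed = 9)
  vm2 <- crossval_votes(xs, ds$truth, roster, folds = 5, seed = 9)
  expect_identical(vm1$counts, vm2$counts)
  expect_identical(vm1$log, vm2$log)
  # conservation: counts rebuild exactly from the prediction log
  rebuilt <- vote_matrix(vm1$log, colnames(vm1$counts),
                         sample_ids = rownames(vm1$counts))
  expect_identical(rebuilt$counts, vm1$counts)
})

test_that("a memorizing member reproduces training labels on separable data", {
  ds <- small_dataset(seed = 4, corruption = 0, effect_size = 4)
  knn_only <- build_roster(list(
    list(member_id = "knn1", family = "knn", params = list(k = 1)),
    list(member_id = "knn1b", family = "knn", params = list(k = 1))
  ))
  fs <- select_features(ds$expression, ds$truth)
  xs <- ds$expression[fs$union, ]
  # target = copies of training samples: 1-NN votes their training labels
  vm <- predict_votes(xs, ds$truth, xs[, 1:10], knn_only, seed = 1)
  lab <- consensus(vm, 0.5, mode = "refine")
  expect_identical(lab$label, ds$truth$label[1:10])
})

test_that("predict_votes rejects a feature-disjoint target matrix", {
  ds <- small_dataset(seed = 4, corruption = 0)
  fs <- select_features(ds$expression, ds$truth)
  xs <- ds$expression[fs$union, ]
  bad <- xs[, 1:4]
  rownames(bad) <- paste0("OTHER_", seq_len(nrow(bad)))
  expect_error(predict_votes(xs, ds$truth, bad, tiny_roster()),
               "lacks")
})

test_that("pooled votes concentrate on true classes for planted test data", {
  ds <- small_dataset(seed = 21, corruption = 0, effect_size = 2,
                      class_sizes = c(A = 20, B = 20, C = 20, D = 20, E = 14),
                      validation_fraction = 0.3)
  fs <- select_features(ds$expression[, ds$discovery_ids],
                        ds$truth[ds$truth$sample_id %in% ds$discovery_ids, ])
  xs <- ds$expression[fs$union, ]
  vm <- predict_votes(xs[, ds$discovery_ids],
                      ds$truth[ds$truth$sample_id %in% ds$discovery_ids, ],
                      xs[, ds$validation_ids], tiny_roster(), seed = 5)
  truth <- ds$truth$label[match(rownames(vm$counts), ds$truth$sample_id)]
  on_truth <- vm$counts[cbind(seq_len(nrow(vm$counts)),
                              match(truth, colnames(vm$counts)))]
  expect_gte(sum(on_truth) / sum(vm$counts), 0.9)
})

test_that("consensus implements the threshold-plus-unique-maximum rule", {
  mk <- function(counts) {
    log <- purrr::map_dfr(seq_along(counts), function(i) {
      tibble::tibble(sample_id = "s1",
                     member_id = paste0("m", i, "_", seq_len(counts[i])),
                     fold = 1L, predicted_label = names(counts)[i])
    })
    vote_matrix(log, names(counts), sample_ids = "s1")
  }
  # 13 of 24 at threshold 0.5: majority assigns
  v <- mk(c(LumA = 13, LumB = 6, Basal = 5))
  expect_identical(consensus(v, 0.5)$label, "LumA")
  # exact 12/12 tie: no unique maximum
  v <- mk(c(LumA = 12, LumB = 12))
  expect_identical(consensus(v, 0.5)$label, "INCONSISTENT")
  # 15 of 24 at two thirds: 15 < ceil(16) fails, train-test mode unassigns
  v <- mk(c(Basal = 15, LumA = 9))
  expect_identical(consensus(v, 2 / 3, mode = "traintest")$label, "UNASSIGNED")
  expect_identical(consensus(v, 0.5, mode = "refine")$label, "Basal")
  expect_error(consensus(v, 0), "threshold")
})

test_that("raising the consensus threshold never assigns a previously failing sample", {
  withr::with_seed(31, {
    for (rep in 1:40) {
      k <- sample(2:5, 1)
      tot <- sample(5:40, 1)
      counts <- as.vector(stats::rmultinom(1, tot, runif(k)))
      names(counts) <- paste0("C", seq_len(k))
      log <- purrr::map_dfr(seq_len(k), function(i) {
        if (counts[i] == 0) return(NULL)
        tibble::tibble(sample_id = "s", member_id = paste0("m", i, "_", seq_len(counts[i])),
                       fold = 1L, predicted_label = names(counts)[i])
      })
      vm <- vote_matrix(log, names(counts), sample_ids = "s")
      thresholds <- sort(runif(3, 0.05, 1))
      states <- vapply(thresholds, function(th) consensus(vm, th)$label, "")
      assigned_flag <- states != "INCONSISTENT"
      # monotone: once unassigned at a lower threshold, never assigned higher up
      expect_true(all(diff(assigned_flag) <= 0))
      for (i in seq_along(thresholds)) {
        if (assigned_flag[i]) {
          expect_gte(counts[states[i]], ceiling(thresholds[i] * sum(counts)))
        }
      }
    }
  })
})
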