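# The refinement loop: balanced subsampling, iteration mechanics, stopping
# semantics, reclassification, and the two-stage pipeline.

test_that("balance_classes reproduces the 58-per-class balanced cohort arithmetic", {
  sizes <- c(LumA = 728, LumB = 600, Her2 = 234, Basal = 233, Normal = 58)
  lab <- labelling(sprintf("s%04d", seq_len(sum(sizes))),
                   rep(names(sizes), times = sizes))
  ids <- balance_classes(lab, seed = 1)
  expect_length(ids, 290)
  picked <- table(lab$label[match(ids, lab$sample_id)])
  expect_true(all(picked == 58))
  # the minimum class contributes every one of its samples
  normals <- lab$sample_id[lab$label == "Normal"]
  expect_setequal(intersect(ids, normals), normals)
})

test_that("balance_classes is an identity on balanced input and seed-sensitive otherwise", {
  lab <- labelling(paste0("s", 1:50), rep(c("A", "B", "C", "D", "E"), each = 10),
                   classes = c("A", "B", "C", "D", "E"))
  expect_setequal(balance_classes(lab, seed = 1), lab$sample_id)

  sizes <- c(A = 30, B = 30, C = 8)
  lab2 <- labelling(paste0("t", seq_len(sum(sizes))),
                    rep(names(sizes), times = sizes),
                    classes = names(sizes))
  i1 <- balance_classes(lab2, seed = 1)
  i2 <- balance_classes(lab2, seed = 2)
  min_ids <- lab2$sample_id[lab2$label == "C"]
  expect_setequal(intersect(i1, min_ids), min_ids)
  expect_setequal(intersect(i2, min_ids), min_ids)
  expect_false(setequal(i1, i2))

  expect_error(balance_classes(lab2, classes = c("A", "B", "C", "Z")),
               "no assigned samples: Z")
})

test_that("one iteration relabels most corrupted samples on planted data", {
  ds <- small_dataset(seed = 6, corruption = 0.1, effect_size = 2,
                      class_sizes = c(A = 30, B = 30, C = 25, D = 25, E = 16),
                      n_probes = 300)
  rec <- refine_iteration(ds$expression, ds$initial, tiny_roster(),
                          tiny_config(seed = 6), iteration_seed = 60)
  corrupted <- ds$truth$sample_id[ds$truth$label != ds$initial$label]
  after <- rec$labelling_after$label[match(corrupted,
                                           rec$labelling_after$sample_id)]
  truth <- ds$truth$label[match(corrupted, ds$truth$sample_id)]
  expect_gte(mean(after == truth), 0.8)
  # vote conservation: every assigned sample gets runs x roster votes
  expect_true(all(rec$vote_totals == 2 * 3))
})

test_that("a clean labelling is a fixed point and stops stable in one iteration", {
  ds <- small_dataset(seed = 9, corruption = 0, effect_size = 4)
  trace <- run_refinement(ds$expression, ds$truth, tiny_roster(),
                          tiny_config(seed = 9))
  expect_identical(length(trace$iterations), 1L)
  expect_identical(trace$stop_reason, "labels_and_features_stable")
  expect_identical(trace$final_labelling, ds$truth)
})

test_that("kappa_stop = 0 forces a kappa_reached stop on a non-fixed-point input", {
  ds <- small_dataset(seed = 10, corruption = 0.15, effect_size = 3)
  trace <- run_refinement(ds$expression, ds$initial, tiny_roster(),
                          tiny_config(seed = 10, kappa_stop = 0))
  expect_identical(length(trace$iterations), 1L)
  expect_identical(trace$stop_reason, "kappa_reached")
})

test_that("max_iterations caps the loop with a warning, not an error", {
  ds <- small_dataset(seed = 12, corruption = 0.15, effect_size = 3)
  expect_warning(
    trace <- run_refinement(ds$expression, ds$initial, tiny_roster(),
                            tiny_config(seed = 12, kappa_stop = 1,
                                        max_iterations = 1)),
    "max_iterations"
  )
  expect_identical(trace$stop_reason, "max_iterations")
})

test_that("refinement is deterministic under a fixed master seed", {
  ds <- small_dataset(seed = 14, corruption = 0.1, effect_size = 3)
  t1 <- run_refinement(ds$expression, ds$initial, tiny_roster(),
                       tiny_config(seed = 14))
  t2 <- run_refinement(ds$expression, ds$initial, tiny_roster(),
                       tiny_config(seed = 14))
  expect_identical(t1$final_labelling, t2$final_labelling)
  expect_identical(tidy(t1), tidy(t2))
  expect_identical(t1$final_features$union, t2$final_features$union)
})

test_that("inconsistent samples leave the assigned pool within a phase", {
  ds <- small_dataset(seed = 16, corruption = 0.1, effect_size = 2,
                      class_sizes = c(A = 20, B = 20, C = 16, D = 16, E = 12),
                      n_probes = 200)
  # add noise-only impostor samples that should fail consensus
  noise <- matrix(rnorm(nrow(ds$expression) * 6),
                  nrow = nrow(ds$expression),
                  dimnames = list(rownames(ds$expression), paste0("noise", 1:6)))
  x <- cbind(ds$expression, noise)
  lab <- labelling(c(ds$initial$sample_id, colnames(noise)),
                   c(ds$initial$label, rep(c("A", "B", "C"), 2)),
                   classes = c("A", "B", "C", "D", "E"))
  trace <- run_refinement(x, lab, tiny_roster(), tiny_config(seed = 16))
  if (length(trace$iterations) >= 2) {
    inc_after_1 <- trace$iterations[[1]]$labelling_after
    inc_ids <- inc_after_1$sample_id[inc_after_1$label == "INCONSISTENT"]
    final <- trace$final_labelling
    expect_true(all(final$label[match(inc_ids, final$sample_id)] ==
                      "INCONSISTENT"))
  }
  expect_true(trace$stop_reason != "none")
})

test_that("reclassify assigns separable targets and rejects most pure noise", {
  ds <- small_dataset(seed = 18, corruption = 0, effect_size = 4,
                      class_sizes = c(A = 14, B = 14, C = 12, D = 12, E = 10),
                      n_probes = 200)
  # targets: copies of training samples plus background-scale noise impostors
  copies <- ds$expression[, 1:8]
  colnames(copies) <- paste0("copy", 1:8)
  noise <- withr::with_seed(181, matrix(
    rnorm(nrow(ds$expression) * 100), nrow = nrow(ds$expression),
    dimnames = list(rownames(ds$expression), paste0("noise", 1:100))
  ))
  out_fast <- suppressWarnings(reclassify(
    ds$expression, ds$truth, cbind(copies, noise),
    build_roster(fast_roster_members()),
    refinement_config(runs = 5, folds = 4, seed = 18)
  ))
  expect_identical(out_fast$label[match(paste0("copy", 1:8), out_fast$sample_id)],
                   ds$truth$label[1:8])
  noise_states <- out_fast$label[grepl("^noise", out_fast$sample_id)]
  expect_gte(mean(noise_states == "UNASSIGNED"), 0.5)
})

test_that("no reclassified sample is assigned below the pooled two-thirds threshold", {
  ds <- small_dataset(seed = 18, corruption = 0, effect_size = 4,
                      class_sizes = c(A = 14, B = 14, C = 12, D = 12, E = 10),
                      n_probes = 200)
  copies <- ds$expression[, 1:8]
  colnames(copies) <- paste0("copy", 1:8)
  noise <- withr::with_seed(182, matrix(
    rnorm(nrow(ds$expression) * 20), nrow = nrow(ds$expression),
    dimnames = list(rownames(ds$expression), paste0("noise", 1:20))
  ))
  out <- reclassify(ds$expression, ds$truth, cbind(copies, noise),
                    tiny_roster(), tiny_config(seed = 18))
  # re-derive the pooled votes reclassify used and check the threshold
  fs <- select_features(ds$expression, ds$truth)
  vms <- purrr::map(1:2, function(r) {
    run_seed <- subtyperefine:::derive_seed(tiny_config(seed = 18)$seed, 23L, r)
    subset_ids <- balance_classes(ds$truth,
                                  seed = subtyperefine:::derive_seed(run_seed, 1L),
                                  classes = c("A", "B", "C", "D", "E"))
    sub_lab <- ds$truth[ds$truth$sample_id %in% subset_ids, ]
    predict_votes(ds$expression[fs$union, subset_ids], sub_lab,
                  cbind(copies, noise)[fs$union, ], tiny_roster(),
                  seed = subtyperefine:::derive_seed(run_seed, 2L),
                  classes = c("A", "B", "C", "D", "E"))
  })
  pooled <- subtyperefine:::pool_votes(vms, c("A", "B", "C", "D", "E"))
  assigned_ids <- out$sample_id[out$label != "UNASSIGNED"]
  for (s in assigned_ids) {
    expect_gte(max(pooled$counts[s, ]),
               ceiling(2 / 3 * sum(pooled$counts[s, ])))
  }
})

test_that("the two-stage pipeline recovers planted labels and reports conservation", {
  ds <- generate_dataset(generator_spec(
    n_probes = 300, class_sizes = c(A = 40, B = 40, C = 30, D = 30, E = 20),
    effect_size = 2, corruption = 0.1, validation_fraction = 0.4, seed = 77
  ))
  disc <- ds$discovery_ids
  res <- full_pipeline(
    ds$expression[, disc], ds$initial[ds$initial$sample_id %in% disc, ],
    ds$expression[, ds$validation_ids], tiny_roster(),
    tiny_config(seed = 77),
    validation_lab = ds$initial[ds$initial$sample_id %in% ds$validation_ids, ]
  )
  fin <- res$final_labelling
  expect_setequal(fin$sample_id, ds$truth$sample_id)
  assigned_fin <- fin[!(fin$label %in% c("INCONSISTENT", "UNASSIGNED")), ]
  truth <- ds$truth$label[match(assigned_fin$sample_id, ds$truth$sample_id)]
  expect_gte(mean(assigned_fin$label == truth), 0.9)
  # contingency row/column sums equal the respective label counts
  expect_equal(unname(rowSums(res$contingency)),
               unname(as.vector(table(factor(fin$label,
                 levels = rownames(res$contingency))))))
  expect_equal(unname(colSums(res$contingency)),
               unname(as.vector(table(factor(ds$initial$label,
                 levels = colnames(res$contingency))))))
  expect_s3_class(glance(res), "tbl_df")
})

test_that("an empty validation set degenerates to refinement of the discovery set", {
  ds <- small_dataset(seed = 20, corruption = 0.1, effect_size = 3)
  res <- full_pipeline(ds$expression, ds$initial, NULL, tiny_roster(),
                       tiny_config(seed = 20))
  trace <- run_refinement(ds$expression, ds$initial, tiny_roster(),
                          {
                            cfg <- tiny_config(seed = 20)
                            cfg$seed <- subtyperefine:::derive_seed(cfg$seed, 1L)
                            cfg
                          })
  aligned <- res$final_labelling[match(trace$final_labelling$sample_id,
                                       res$final_labelling$sample_id), ]
  # discovery-phase assignments survive unless the merged phase reclassified
  expect_setequal(res$final_labelling$sample_id,
                  trace$final_labelling$sample_id)
})
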