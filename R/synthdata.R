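# Seed-deterministic synthetic data generator. Emulates the statistical
# structure the refinement pipeline assumes: a handful of latent classes
# with per-class blocks of up-/down-regulated probes on a Gaussian
# log-intensity background, an imbalanced cohort with one small class, a
# corrupted initial labelling, class-conditional clinical marker
# probabilities, and class-dependent exponential survival.

#' Specification for a synthetic cohort
#'
#' Defaults mirror a downsized five-class cohort with a pronounced class
#' imbalance (the smallest class has 58 samples), 5 up- and 5 down-regulated
#' planted probes per class at effect size 2 background standard deviations,
#' and a 10 percent corrupted initial labelling.
#'
#' @param n_probes Number of probes (default 1000).
#' @param class_sizes Named integer vector of per-class sample counts
#'   (default `c(LumA = 250, LumB = 200, Her2 = 90, Basal = 90, Normal = 58)`).
#' @param n_up,n_down Planted up-/down-regulated probes per class (default 5
#'   each); planted sets are disjoint across classes.
#' @param effect_size Shift of planted probes in units of the background
#'   standard deviation (default 2).
#' @param noise_sd Background standard deviation on the log-intensity scale
#'   (default 1).
#' @param corruption Fraction of samples whose initial label is reassigned
#'   to a uniformly random different class (default 0.1); exactly
#'   `round(corruption * n)` samples are corrupted.
#' @param marker_probs Per-class probabilities of positive ER/PR/HER2 status:
#'   a data frame with columns `class`, `er`, `pr`, `her2`. Defaults follow
#'   the marker patterns expected of the intrinsic subtypes (luminal ER+,
#'   HER2-enriched HER2+, basal-like triple-negative).
#' @param hazards Named per-day exponential death hazards per class.
#'   Defaults give median survivals between roughly 1000 days (basal-like)
#'   and 4000 days (luminal A).
#' @param censoring_rate Target fraction of subjects censored (default 0.3),
#'   realised by independent exponential censoring with the matching rate.
#' @param marker_missing Probability a marker is recorded as unknown
#'   (default 0.02).
#' @param validation_fraction Fraction of samples (stratified by true class)
#'   held out as the validation set (default 0.5).
#' @param seed Integer seed; every draw derives from it.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_probes = 1000,
                           class_sizes = c(LumA = 250, LumB = 200, Her2 = 90,
                                           Basal = 90, Normal = 58),
                           n_up = 5, n_down = 5,
                           effect_size = 2, noise_sd = 1,
                           corruption = 0.1,
                           marker_probs = default_marker_probs(names(class_sizes)),
                           hazards = default_hazards(names(class_sizes)),
                           censoring_rate = 0.3,
                           marker_missing = 0.02,
                           validation_fraction = 0.5,
                           seed = 1L) {
  if (is.null(names(class_sizes)) || anyDuplicated(names(class_sizes))) {
    abort("class_sizes must have unique names")
  }
  if (any(class_sizes < 1)) abort("all class sizes must be positive")
  if (corruption < 0 || corruption >= 1) abort("corruption must be in [0, 1)")
  if (n_up < 0 || n_down < 0) abort("planted probe counts must be non-negative")
  if ((n_up + n_down) * length(class_sizes) > n_probes) {
    abort("planted probes exceed n_probes")
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    abort("validation_fraction must be in [0, 1)")
  }
  structure(list(
    n_probes = n_probes, class_sizes = class_sizes,
    n_up = n_up, n_down = n_down,
    effect_size = effect_size, noise_sd = noise_sd,
    corruption = corruption, marker_probs = marker_probs,
    hazards = hazards, censoring_rate = censoring_rate,
    marker_missing = marker_missing,
    validation_fraction = validation_fraction,
    seed = as.integer(seed)
  ), class = "generator_spec")
}

#' Default class-conditional marker-positivity probabilities
#' @param classes Class names (5 expected; extras recycle the last row).
#' @return Data frame with columns `class`, `er`, `pr`, `her2`.
#' @export
default_marker_probs <- function(classes) {
  base <- data.frame(
    er = c(0.98, 0.97, 0.41, 0.12, 0.81),
    pr = c(0.76, 0.63, 0.21, 0.09, 0.52),
    her2 = c(0.03, 0.09, 0.56, 0.09, 0.08)
  )
  idx <- pmin(seq_along(classes), nrow(base))
  cbind(data.frame(class = classes), base[idx, , drop = FALSE],
        row.names = NULL)
}

#' Default per-day exponential death hazards per class
#' @param classes Class names (5 expected; extras recycle the last value).
#' @return Named numeric vector of hazards (events per day).
#' @export
default_hazards <- function(classes) {
  base <- log(2) / c(4000, 2500, 1200, 1000, 3000)
  setNames(base[pmin(seq_along(classes), length(base))], classes)
}

#' Generate a synthetic cohort
#'
#' Background expression is `Normal(0, noise_sd^2)`; the planted up-probes
#' of class `c` are shifted by `+effect_size * noise_sd` in class-`c`
#' samples and the down-probes by the negative shift. The initial labelling
#' corrupts exactly `round(corruption * n)` true labels to a uniformly
#' random different class (never to a non-class state). Markers and
#' survival are drawn from the class-conditional distributions. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A `synthetic_dataset` list: `expression` (probes x samples
#'   matrix), `truth` and `initial` (labelling tibbles), `clinical`
#'   (tibble), `planted` (tibble `class`, `probe_id`, `direction`),
#'   `discovery_ids`, `validation_ids`, and the `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  classes <- names(spec$class_sizes)
  k <- length(classes)
  n <- sum(spec$class_sizes)
  probe_ids <- sprintf("P%04d", seq_len(spec$n_probes))
  sample_ids <- sprintf("S%04d", seq_len(n))
  true_label <- rep(classes, times = spec$class_sizes)

  # planted probe manifest: disjoint leading blocks, class by class
  per_class <- spec$n_up + spec$n_down
  planted <- map_dfr(seq_len(k), function(i) {
    start <- (i - 1) * per_class
    tibble(
      class = classes[i],
      probe_id = probe_ids[start + seq_len(per_class)],
      direction = rep(c("up", "down"), c(spec$n_up, spec$n_down))
    )
  })

  x <- withr::with_seed(derive_seed(spec$seed, 1L), {
    m <- matrix(rnorm(spec$n_probes * n, sd = spec$noise_sd),
                nrow = spec$n_probes, dimnames = list(probe_ids, sample_ids))
    shift <- spec$effect_size * spec$noise_sd
    for (i in seq_len(k)) {
      in_cl <- true_label == classes[i]
      rows <- planted$probe_id[planted$class == classes[i]]
      dirs <- planted$direction[planted$class == classes[i]]
      m[rows[dirs == "up"], in_cl] <- m[rows[dirs == "up"], in_cl] + shift
      m[rows[dirs == "down"], in_cl] <- m[rows[dirs == "down"], in_cl] - shift
    }
    m
  })

  # corrupted initial labelling: exactly round(corruption * n) reassignments
  n_corrupt <- round(spec$corruption * n)
  initial_label <- true_label
  if (n_corrupt > 0) {
    withr::with_seed(derive_seed(spec$seed, 2L), {
      idx <- sample(n, n_corrupt)
      for (i in idx) {
        others <- setdiff(classes, true_label[i])
        initial_label[i] <- others[sample.int(length(others), 1)]
      }
    })
  }

  clinical <- withr::with_seed(derive_seed(spec$seed, 3L), {
    mp <- spec$marker_probs[match(true_label, spec$marker_probs$class), ,
                            drop = FALSE]
    draw_marker <- function(p) {
      s <- ifelse(runif(n) < p, "+", "-")
      s[runif(n) < spec$marker_missing] <- "unknown"
      s
    }
    lambda <- spec$hazards[true_label]
    death <- rexp(n, rate = lambda)
    cens_frac <- spec$censoring_rate
    if (cens_frac > 0) {
      # exponential censoring with rate mu = lambda * c / (1 - c) yields an
      # expected censored fraction of c within each class
      mu <- lambda * cens_frac / (1 - cens_frac)
      cens <- rexp(n, rate = mu)
    } else {
      cens <- rep(Inf, n)
    }
    tibble(
      sample_id = sample_ids,
      er = draw_marker(mp$er), pr = draw_marker(mp$pr),
      her2 = draw_marker(mp$her2),
      time = round(pmin(death, cens), 1),
      event = as.integer(death <= cens)
    )
  })

  val_ids <- character(0)
  if (spec$validation_fraction > 0) {
    val_ids <- withr::with_seed(derive_seed(spec$seed, 4L), {
      unlist(map(classes, function(cl) {
        ids <- sample_ids[true_label == cl]
        sample(ids, round(spec$validation_fraction * length(ids)))
      }))
    })
  }
  disc_ids <- setdiff(sample_ids, val_ids)

  structure(list(
    expression = x,
    truth = labelling(sample_ids, true_label, classes = classes),
    initial = labelling(sample_ids, initial_label, classes = classes),
    clinical = clinical,
    planted = planted,
    discovery_ids = disc_ids,
    validation_ids = sort(val_ids),
    spec = spec
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d probes x %d samples, %d classes, %d corrupted label(s), %d discovery / %d validation\n",
    nrow(x$expression), ncol(x$expression), length(x$spec$class_sizes),
    sum(x$truth$label != x$initial$label),
    length(x$discovery_ids), length(x$validation_ids)
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits `expression.tsv`, `truth.tsv`, `initial.tsv`, `clinical.tsv` and
#' `planted.tsv` in the formats read back by the package's readers.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_labelling(dataset$truth, file.path(dir, "truth.tsv"))
  write_labelling(dataset$initial, file.path(dir, "initial.tsv"))
  write_clinical(dataset$clinical, file.path(dir, "clinical.tsv"))
  readr::write_tsv(dataset$planted, file.path(dir, "planted.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble(sample_id = dataset$validation_ids),
                   file.path(dir, "validation_ids.tsv"), progress = FALSE)
  invisible(dir)
}
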