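# Independent oracle implementations and small fixture builders used across
# the test files. Oracles deliberately take different algebraic routes than
# the package implementations.

# Fleiss' kappa via the 1 - (disagreement ratio) identity:
# kappa = 1 - (N m^2 - sum(x^2)) / (N m (m-1) sum(p_j (1 - p_j)))
oracle_fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  m <- sum(ratings[1, ])
  p_j <- colSums(ratings) / (n * m)
  denom <- n * m * (m - 1) * sum(p_j * (1 - p_j))
  if (denom == 0) return(NA_real_)
  1 - (n * m^2 - sum(ratings^2)) / denom
}

# Adjusted Rand index by explicit enumeration of all sample pairs and the
# pair-table identity ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)).
oracle_ari <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) ss <- ss + 1
      else if (same_a && !same_b) sd <- sd + 1
      else if (!same_a && same_b) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  denom <- (ss + sd) * (sd + dd) + (ss + ds) * (ds + dd)
  if (denom == 0) return(NA_real_)
  2 * (ss * dd - sd * ds) / denom
}

# Cramer's V via stats::chisq.test on the empty-margin-dropped table.
oracle_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  chi2 <- suppressWarnings(
    unname(stats::chisq.test(tab, correct = FALSE)$statistic)
  )
  sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1)))
}

# Final-vs-initial label counts as printed for the full refined cohort
# (rows: refined calls incl. the inconsistent state; columns: initial calls).
# Row sums 728/600/234/233/144/47 and column sums 721/492/240/331/202 give a
# consistent grand total of 1986.
table1_counts <- function() {
  matrix(as.integer(
    c(563, 94, 1, 12, 58,
      102, 383, 77, 19, 19,
      7, 1, 149, 59, 18,
      0, 0, 0, 230, 3,
      33, 0, 11, 5, 95,
      16, 14, 2, 6, 9)),
    nrow = 6, byrow = TRUE,
    dimnames = list(
      c("LumA", "LumB", "Her2", "Basal", "Normal", "Inconsistent"),
      c("LumA", "LumB", "Her2", "Basal", "Normal")
    )
  )
}

# A small planted five-class cohort for loop-level tests.
small_dataset <- function(seed = 1L, corruption = 0.1, effect_size = 3,
                          class_sizes = c(A = 16, B = 16, C = 14, D = 14, E = 10),
                          n_probes = 150, validation_fraction = 0) {
  generate_dataset(generator_spec(
    n_probes = n_probes, class_sizes = class_sizes,
    effect_size = effect_size, corruption = corruption,
    validation_fraction = validation_fraction, seed = seed
  ))
}

# A cheap, robust three-member roster for loop-level unit tests.
tiny_roster <- function() {
  build_roster(list(
    list(member_id = "knn1", family = "knn", params = list(k = 1)),
    list(member_id = "centroid", family = "function",
         params = list(engine = "centroid", metric = "euclidean")),
    list(member_id = "nb", family = "bayes", params = list(laplace = 0))
  ))
}

# A fast loop configuration for unit tests (acceptance uses the defaults).
tiny_config <- function(seed = 1L, ...) {
  refinement_config(runs = 2, folds = 4, seed = seed, ...)
}
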