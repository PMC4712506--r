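# Agreement statistics between categorical labellings, implemented from
# first principles: Cramer's V, Fleiss' kappa (multi-rater), and the
# adjusted Rand index, plus the six-band kappa interpretation scale.

#' Contingency table of two labellings
#'
#' Cross-tabulates two label vectors over the same samples; rows follow
#' `row_levels` (default: values of `a` in first-appearance order), columns
#' `col_levels`.
#'
#' @param a,b Vectors of labels (predicted, initial), equal length.
#' @param row_levels,col_levels Optional fixed level orders.
#' @return An integer matrix of counts with dimnames.
#' @export
contingency_table <- function(a, b, row_levels = NULL, col_levels = NULL) {
  if (length(a) != length(b)) abort("labellings must cover the same samples")
  row_levels <- row_levels %||% unique(as.character(a))
  col_levels <- col_levels %||% unique(as.character(b))
  tab <- table(factor(a, levels = row_levels), factor(b, levels = col_levels))
  matrix(as.integer(tab), nrow = length(row_levels),
         dimnames = list(row_levels, col_levels))
}

#' Cramer's V association between two categorical labellings
#'
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))` with the plain Pearson
#' chi-squared statistic (no continuity or bias correction) and `r`, `c`
#' counting non-empty rows and columns — all-zero margins (such as an empty
#' "Inconsistent" row) are dropped before computing both the statistic and
#' the degrees-of-freedom term. Ranges from 0 (no association) to 1
#' (complete association); the result is clamped to `[0, 1]` against
#' floating-point drift.
#'
#' @param tab Matrix of non-negative counts (rows: predicted labels,
#'   columns: initial labels).
#' @return A single number in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("counts must be non-negative")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("association undefined: need at least 2 non-empty rows and columns")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v <- sqrt(chi2 / (n * (min(nrow(tab), ncol(tab)) - 1)))
  min(max(v, 0), 1)
}

#' Fleiss' kappa for a subjects-by-categories rating table
#'
#' Chance-corrected multi-rater agreement: `kappa = (Pbar - Pe) / (1 - Pe)`
#' where `Pbar` averages the per-subject pairwise agreement and `Pe` is the
#' chance agreement from the category marginals. Each row holds the counts
#' of raters assigning the subject to each category; the rater count must be
#' constant across subjects and at least 2.
#'
#' Unanimous tables return exactly 1; the degenerate all-one-category table
#' (`Pe = 1`) also returns 1 by convention, with a message, since agreement
#' is perfect even though the chance correction is undefined.
#'
#' @param ratings Integer matrix, subjects x categories.
#' @return A single number `<= 1`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 1) abort("need at least 1 subject")
  raters <- rowSums(ratings)
  if (length(unique(raters)) != 1) {
    abort("raters-per-subject must be constant across subjects")
  }
  n_r <- raters[1]
  if (n_r < 2) abort("need at least 2 raters per subject")
  n <- nrow(ratings)
  p_j <- colSums(ratings) / (n * n_r)
  p_i <- (rowSums(ratings^2) - n_r) / (n_r * (n_r - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    inform("all ratings in a single category: kappa = 1 by convention")
    return(1)
  }
  if (p_bar == 1) return(1)
  (p_bar - p_e) / (1 - p_e)
}

# Two-labelling kappa: Fleiss' kappa on a two-rater table over the samples
# assigned (a class, not INCONSISTENT/UNASSIGNED) in both labellings.
labelling_kappa <- function(lab_prev, lab_curr, classes = NULL) {
  prev <- assigned(lab_prev)
  curr <- assigned(lab_curr)
  shared <- intersect(prev$sample_id, curr$sample_id)
  if (length(shared) == 0) return(NA_real_)
  a <- prev$label[match(shared, prev$sample_id)]
  b <- curr$label[match(shared, curr$sample_id)]
  classes <- classes %||% sort(unique(c(a, b)))
  ratings <- matrix(0L, nrow = length(shared), ncol = length(classes),
                    dimnames = list(shared, classes))
  ratings[cbind(seq_along(shared), match(a, classes))] <-
    ratings[cbind(seq_along(shared), match(a, classes))] + 1L
  ratings[cbind(seq_along(shared), match(b, classes))] <-
    ratings[cbind(seq_along(shared), match(b, classes))] + 1L
  fleiss_kappa(ratings)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-adjusted pairwise partition agreement from the
#' pair-count contingency table; 1 iff the partitions are identical up to
#' label renaming, 0 expected under random labelling.
#'
#' @param labels_a,labels_b Label vectors over the same samples (>= 2).
#' @return A single number `<= 1`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("labellings must cover the same samples")
  }
  n <- length(labels_a)
  if (n < 2) abort("need at least 2 samples")
  tab <- contingency_table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  index <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (index - expected) / (max_index - expected)
}

#' Interpret a kappa value on the six-band agreement scale
#'
#' Bands: `<= 0` poor; `(0, 0.20]` slight; `(0.20, 0.40]` fair;
#' `(0.40, 0.60]` moderate; `(0.60, 0.80]` substantial; `(0.80, 1]` almost
#' perfect agreement.
#'
#' @param kappa Numeric value(s) `<= 1`.
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa > 1 + 1e-12)) abort("kappa cannot exceed 1")
  vapply(kappa, function(k) {
    if (k <= 0) "poor agreement"
    else if (k <= 0.20) "slight agreement"
    else if (k <= 0.40) "fair agreement"
    else if (k <= 0.60) "moderate agreement"
    else if (k <= 0.80) "substantial agreement"
    else "almost perfect agreement"
  }, character(1))
}

#' Agreement report between two labellings
#'
#' Computes Cramer's V, the two-rater Fleiss' kappa (with its
#' interpretation band) and the adjusted Rand index between two labellings
#' over their shared assigned samples, plus both variants of V and ARI with
#' and without the samples one side marks inconsistent/unassigned.
#'
#' @param lab_a,lab_b Labelling tibbles (e.g. refined vs initial).
#' @return A one-row tibble with columns `n_shared`, `cramers_v`,
#'   `fleiss_kappa`, `kappa_band`, `ari`, `cramers_v_all`, `ari_all`,
#'   `n_all` (the `_all` variants keep non-class states as categories).
#' @export
agreement_report <- function(lab_a, lab_b) {
  shared_all <- intersect(lab_a$sample_id, lab_b$sample_id)
  a_all <- lab_a$label[match(shared_all, lab_a$sample_id)]
  b_all <- lab_b$label[match(shared_all, lab_b$sample_id)]
  both <- intersect(assigned(lab_a)$sample_id, assigned(lab_b)$sample_id)
  a <- lab_a$label[match(both, lab_a$sample_id)]
  b <- lab_b$label[match(both, lab_b$sample_id)]
  kap <- labelling_kappa(lab_a, lab_b)
  v_all <- tryCatch(cramers_v(contingency_table(a_all, b_all)),
                    error = function(e) NA_real_)
  v <- tryCatch(cramers_v(contingency_table(a, b)), error = function(e) NA_real_)
  tibble(
    n_shared = length(both),
    cramers_v = v,
    fleiss_kappa = kap,
    kappa_band = if (is.na(kap)) NA_character_ else interpret_kappa(kap),
    ari = if (length(both) >= 2) adjusted_rand_index(a, b) else NA_real_,
    cramers_v_all = v_all,
    ari_all = if (length(shared_all) >= 2) adjusted_rand_index(a_all, b_all) else NA_real_,
    n_all = length(shared_all)
  )
}
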