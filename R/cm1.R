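# CM1 scoring and signed per-class feature selection.

#' CM1 score of one probe for one class
#'
#' Signed class-versus-rest separation statistic for a single expression
#' vector: `(mean_in - mean_out) / (sd_in + sd_out)` with sample standard
#' deviations. Positive scores indicate up-regulation in the class relative
#' to all other samples, negative scores down-regulation. Alternative
#' denominators are available since the statistic's spread term varies
#' between formulations: `"pooled"` uses the pooled standard deviation,
#' `"range"` uses `max(v) - min(v)`.
#'
#' When the denominator is zero the score is 0 if the class means are also
#' equal, and `sign(mean_in - mean_out) * cap` otherwise, so all-constant
#' probes never enter top lists and perfectly separated constant probes do
#' not overflow.
#'
#' @param values Numeric vector of expression values over samples.
#' @param in_class Logical mask, `TRUE` for samples in the class. At least 2
#'   samples in the class and 2 outside are required.
#' @param denominator One of `"sdsum"` (default), `"pooled"`, `"range"`.
#' @param cap Magnitude used for the zero-denominator, separated case
#'   (default `1e6`).
#' @return A single signed numeric score.
#' @export
#' @examples
#' cm1_score(c(1, 2, 3, 7, 8, 9), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
cm1_score <- function(values, in_class,
                      denominator = c("sdsum", "pooled", "range"),
                      cap = 1e6) {
  denominator <- match.arg(denominator)
  if (length(values) != length(in_class)) {
    abort("values and in_class must have equal length")
  }
  n_in <- sum(in_class)
  n_out <- sum(!in_class)
  if (n_in < 2 || n_out < 2) {
    abort("degenerate class: need at least 2 samples in the class and 2 outside")
  }
  num <- mean(values[in_class]) - mean(values[!in_class])
  den <- switch(denominator,
    sdsum = sd(values[in_class]) + sd(values[!in_class]),
    pooled = {
      v_in <- stats::var(values[in_class])
      v_out <- stats::var(values[!in_class])
      sqrt(((n_in - 1) * v_in + (n_out - 1) * v_out) / (n_in + n_out - 2))
    },
    range = max(values) - min(values)
  )
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * cap)
  }
  num / den
}

#' Rank all probes by CM1 score for one class
#'
#' Scores every probe of the matrix for `class_label` versus all other
#' assigned samples pooled, and orders by descending score with ties broken
#' by ascending probe id. Samples in the INCONSISTENT or UNASSIGNED state are
#' excluded before scoring.
#'
#' @param x Expression matrix (probes x samples).
#' @param lab Labelling tibble covering the matrix samples.
#' @param class_label The class scored against the rest.
#' @inheritParams cm1_score
#' @return A tibble with columns `probe_id`, `class`, `score`, `rank`.
#' @export
rank_probes <- function(x, lab, class_label,
                        denominator = c("sdsum", "pooled", "range"),
                        cap = 1e6) {
  denominator <- match.arg(denominator)
  lab <- assigned(lab)
  lab <- lab[lab$sample_id %in% colnames(x), , drop = FALSE]
  in_ids <- lab$sample_id[lab$label == class_label]
  out_ids <- lab$sample_id[lab$label != class_label]
  if (length(in_ids) < 2 || length(out_ids) < 2) {
    abort(sprintf(
      "degenerate class '%s': %d in-class and %d out-of-class assigned samples (need >= 2 each)",
      class_label, length(in_ids), length(out_ids)
    ))
  }
  s_in <- row_stats(x, in_ids)
  s_out <- row_stats(x, out_ids)
  num <- s_in$mean - s_out$mean
  den <- switch(denominator,
    sdsum = s_in$sd + s_out$sd,
    pooled = sqrt(((s_in$n - 1) * s_in$sd^2 + (s_out$n - 1) * s_out$sd^2) /
                    (s_in$n + s_out$n - 2)),
    range = {
      sub <- x[, c(in_ids, out_ids), drop = FALSE]
      apply(sub, 1, max) - apply(sub, 1, min)
    }
  )
  score <- unname(ifelse(den == 0, ifelse(num == 0, 0, sign(num) * cap),
                         num / den))
  out <- tibble(probe_id = rownames(x), class = class_label, score = score)
  out <- out[order(-out$score, out$probe_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Select per-class signed top feature sets
#'
#' For every class in turn, takes the `k_up` highest strictly positive and
#' `k_down` lowest strictly negative CM1 scores (fewer, with a warning, when
#' not enough strictly signed scores exist). Zero scores never qualify. The
#' union preserves first-selection order and is deduplicated.
#'
#' @inheritParams rank_probes
#' @param k_up,k_down Per-class list sizes (defaults 5 and 5, i.e. ten probes
#'   per class).
#' @param classes Class list; defaults to the classes present in `lab`.
#' @return A `feature_set` object: list with `per_class` (tibble `class`,
#'   `probe_id`, `direction`, `score`, `rank`) and `union` (character vector).
#' @export
select_features <- function(x, lab, k_up = 5, k_down = 5,
                            classes = NULL,
                            denominator = c("sdsum", "pooled", "range"),
                            cap = 1e6) {
  denominator <- match.arg(denominator)
  lab <- assigned(lab)
  classes <- classes %||% sort(unique(lab$label))
  per_class <- map_dfr(classes, function(cl) {
    ranked <- rank_probes(x, lab, cl, denominator = denominator, cap = cap)
    up <- ranked[ranked$score > 0, , drop = FALSE]
    up <- head(up, k_up)
    dn <- ranked[ranked$score < 0, , drop = FALSE]
    dn <- dn[order(dn$score, dn$probe_id), , drop = FALSE]
    dn <- head(dn, k_down)
    if (nrow(up) < k_up) {
      warn(sprintf("class '%s': only %d strictly positive score(s) available (requested %d)",
                   cl, nrow(up), k_up))
    }
    if (nrow(dn) < k_down) {
      warn(sprintf("class '%s': only %d strictly negative score(s) available (requested %d)",
                   cl, nrow(dn), k_down))
    }
    bind_rows(
      mutate(up, direction = "up"),
      mutate(dn, direction = "down")
    )[, c("class", "probe_id", "direction", "score", "rank")]
  })
  structure(
    list(
      per_class = per_class,
      union = unique(per_class$probe_id),
      k_up = k_up, k_down = k_down
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> %d classes, %d probes in union (k_up=%d, k_down=%d)\n",
    length(unique(x$per_class$class)), length(x$union), x$k_up, x$k_down
  ))
  invisible(x)
}

#' @export
tidy.feature_set <- function(x, ...) x$per_class

#' Write ranked CM1 scores as TSV
#' @param ranked Tibble from [rank_probes()] (or several, row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ranked, path) {
  readr::write_tsv(ranked[, c("probe_id", "class", "score", "rank")], path,
                   progress = FALSE)
  invisible(path)
}

# Equality of two feature sets as used by the stopping rule: same selected
# probes per class and direction (scores may drift).
feature_sets_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  ka <- a$per_class[order(a$per_class$class, a$per_class$direction, a$per_class$probe_id),
                    c("class", "probe_id", "direction")]
  kb <- b$per_class[order(b$per_class$class, b$per_class$direction, b$per_class$probe_id),
                    c("class", "probe_id", "direction")]
  identical(as.data.frame(ka), as.data.frame(kb))
}
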