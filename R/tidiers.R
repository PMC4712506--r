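# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_tile geom_text labs scale_fill_gradient theme_minimal
#'   scale_y_continuous
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.refinement_trace <- function(x, ...) {
  map_dfr(seq_along(x$iterations), function(i) {
    r <- x$iterations[[i]]
    tibble(
      iteration = i,
      n_assigned = nrow(assigned(r$labelling_after)),
      n_changed = r$n_changed,
      n_newly_inconsistent = r$n_newly_inconsistent,
      n_features = length(r$features$union),
      kappa = r$kappa,
      stop_reason = r$stop_reason
    )
  })
}

#' @export
glance.refinement_trace <- function(x, ...) {
  it <- tidy(x)
  tibble(
    n_iterations = nrow(it),
    stop_reason = x$stop_reason,
    n_assigned = it$n_assigned[nrow(it)],
    n_inconsistent = sum(x$final_labelling$label == STATE_INCONSISTENT),
    n_features = it$n_features[nrow(it)],
    final_kappa = it$kappa[nrow(it)]
  )
}

#' @export
tidy.pipeline_result <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$discovery_trace), phase = "discovery", .before = 1),
    mutate(tidy(x$merged_trace), phase = "merged", .before = 1)
  )
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    n_iterations_discovery = length(x$discovery_trace$iterations),
    n_iterations_merged = length(x$merged_trace$iterations),
    n_final_assigned = nrow(assigned(x$final_labelling)),
    n_inconsistent = sum(x$final_labelling$label == STATE_INCONSISTENT),
    n_unassigned = sum(x$final_labelling$label == STATE_UNASSIGNED),
    n_features = length(x$final_features$union),
    cramers_v = x$agreement$cramers_v,
    fleiss_kappa = x$agreement$fleiss_kappa,
    ari = x$agreement$ari
  )
}

#' @export
tidy.vote_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "class", values_to = "votes")
}

#' Plot the per-iteration progress of a refinement trace
#'
#' Shows label changes, newly inconsistent samples and the consecutive
#' -iteration kappa per iteration.
#'
#' @param object A `refinement_trace`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.refinement_trace <- function(object, ...) {
  it <- tidy(object) |>
    tidyr::pivot_longer(c("n_changed", "n_newly_inconsistent", "kappa"),
                        names_to = "metric", values_to = "value")
  ggplot(it, aes(x = .data$iteration, y = .data$value)) +
    geom_line() + geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "iteration", y = NULL, title = "Refinement progress") +
    theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve` tibble, or the `curves` element of
#'   [survival_stratification()] (with a `class` column for strata).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  p <- if ("class" %in% colnames(object)) {
    ggplot(object, aes(x = .data$time, y = .data$survival,
                       colour = .data$class))
  } else {
    ggplot(object, aes(x = .data$time, y = .data$survival))
  }
  p + geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "time (days)", y = "survival probability") +
    theme_minimal()
}

#' Heat-map style plot of a final-versus-initial contingency table
#'
#' @param tab Contingency matrix as produced by [contingency_table()] or
#'   found in a `pipeline_result`.
#' @return A ggplot object.
#' @export
plot_contingency <- function(tab) {
  df <- as_tibble(as.matrix(tab), rownames = "predicted") |>
    tidyr::pivot_longer(-"predicted", names_to = "initial",
                        values_to = "count")
  df$predicted <- factor(df$predicted, levels = rev(rownames(tab)))
  df$initial <- factor(df$initial, levels = colnames(tab))
  ggplot(df, aes(x = .data$initial, y = .data$predicted,
                 fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "initial label", y = "predicted label") +
    theme_minimal()
}

#' Export a heat-map ordering of probes and samples
#'
#' Orders the selected probes and the samples by average-linkage
#' hierarchical clustering of the feature-restricted expression (correlation
#' distance), the layout a heat map of the refined features would use.
#'
#' @param x Expression matrix (probes x samples).
#' @param features A `feature_set`.
#' @return List with `probe_order` and `sample_order` (character vectors).
#' @export
heatmap_ordering <- function(x, features) {
  xs <- x[features$union, , drop = FALSE]
  dp <- stats::as.dist(1 - stats::cor(t(xs)))
  ds <- stats::as.dist(1 - stats::cor(xs))
  list(
    probe_order = rownames(xs)[stats::hclust(dp, method = "average")$order],
    sample_order = colnames(xs)[stats::hclust(ds, method = "average")$order]
  )
}
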