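# Kaplan-Meier estimation, the K-group log-rank test, and clinical marker
# summaries, computed from the standard formulas. With tied event and
# censoring times, censorings at t leave the risk set after the events at t
# (the usual convention).

#' Kaplan-Meier product-limit survival curve
#'
#' At each distinct event time `t`, survival is multiplied by
#' `1 - d(t)/n(t)` with `d` events and `n` the at-risk count; censored
#' subjects leave the risk set without a drop.
#'
#' @param time Non-negative follow-up times (days).
#' @param event Event indicators (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @return A `km_curve` tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, one row per distinct observed time.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) abort("empty input")
  if (length(time) != length(event)) abort("time and event must have equal length")
  if (any(time < 0)) abort("negative survival time")
  event <- as.integer(as.logical(event))
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1L), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(time = times, n_risk = n_risk, n_event = n_event,
                n_censor = n_censor, survival = surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' K-group log-rank test
#'
#' The standard log-rank statistic: at each distinct event time, the
#' observed event count per group is compared with its hypergeometric
#' expectation under the pooled risk set; the quadratic form of the
#' observed-minus-expected vector against the summed covariance matrix
#' (one group dropped) is chi-squared with K-1 degrees of freedom under the
#' null of identical survival curves.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event observed).
#' @param group Group labels (>= 2 non-empty groups).
#' @return A `logrank_test` list with `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  n <- length(time)
  if (length(event) != n || length(group) != n) {
    abort("time, event and group must have equal length")
  }
  event <- as.integer(as.logical(event))
  group <- as.character(group)
  groups <- sort(unique(group))
  k <- length(groups)
  if (k < 2) abort("need at least 2 groups")
  gidx <- match(group, groups)

  event_times <- sort(unique(time[event == 1L]))
  obs <- setNames(numeric(k), groups)
  expd <- setNames(numeric(k), groups)
  vmat <- matrix(0, k, k, dimnames = list(groups, groups))
  for (t in event_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1L)
    n_g <- vapply(seq_len(k), function(g) sum(at_risk & gidx == g), numeric(1))
    d_g <- vapply(seq_len(k), function(g) sum(time == t & event == 1L & gidx == g),
                  numeric(1))
    obs <- obs + d_g
    expd <- expd + d_t * n_g / n_t
    if (n_t > 1) {
      frac <- n_g / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) * (diag(frac) - outer(frac, frac))
      vmat <- vmat + vt
    }
  }
  if (length(event_times) == 0) {
    warn("no events in any group: log-rank statistic 0, p = 1")
    return(structure(list(statistic = 0, df = k - 1, p_value = 1,
                          observed = obs, expected = expd),
                     class = "logrank_test"))
  }
  u <- (obs - expd)[-k]
  v <- vmat[-k, -k, drop = FALSE]
  stat <- tryCatch(
    drop(t(u) %*% solve(v, u)),
    error = function(e) drop(t(u) %*% MASS::ginv(v) %*% u)
  )
  structure(list(statistic = stat, df = k - 1,
                 p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
                 observed = obs, expected = expd),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-squared = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Per-class clinical marker summary
#'
#' Cross-tabulates each labelling class (including the inconsistent/
#' unassigned states when present) against positive/negative/unknown status
#' of the ER, PR and HER2 markers. Samples missing a marker are tracked
#' under `unknown`, never silently dropped.
#'
#' @param lab Labelling tibble.
#' @param clinical Clinical tibble as from [read_clinical()].
#' @return A tibble with one row per (class, marker) and columns `class`,
#'   `marker`, `positive`, `negative`, `unknown`, `total`.
#' @export
marker_summary <- function(lab, clinical) {
  shared <- intersect(lab$sample_id, clinical$sample_id)
  lb <- lab$label[match(shared, lab$sample_id)]
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  map_dfr(sort(unique(lb)), function(class_label) {
    in_cl <- lb == class_label
    map_dfr(c("er", "pr", "her2"), function(m) {
      v <- cl[[m]][in_cl]
      tibble(
        class = class_label, marker = m,
        positive = sum(v == "+", na.rm = TRUE),
        negative = sum(v == "-", na.rm = TRUE),
        unknown = sum(is.na(v) | v == "unknown"),
        total = sum(in_cl)
      )
    })
  })
}

#' Survival stratification of a labelling
#'
#' Convenience wrapper: joins a labelling with clinical follow-up, drops
#' samples without survival data, and returns per-class KM curves plus the
#' log-rank test across classes.
#'
#' @param lab Labelling tibble (non-class states are kept as their own
#'   stratum only if `include_states = TRUE`).
#' @param clinical Clinical tibble.
#' @param include_states Keep INCONSISTENT/UNASSIGNED samples as strata
#'   (default `FALSE`).
#' @return List with `curves` (tibble of per-class KM curves, column
#'   `class`) and `test` (a `logrank_test`).
#' @export
survival_stratification <- function(lab, clinical, include_states = FALSE) {
  if (!include_states) lab <- assigned(lab)
  shared <- intersect(lab$sample_id, clinical$sample_id)
  lb <- lab$label[match(shared, lab$sample_id)]
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  keep <- !is.na(cl$time) & !is.na(cl$event)
  lb <- lb[keep]; cl <- cl[keep, , drop = FALSE]
  if (length(lb) == 0) abort("no samples with survival data")
  curves <- map_dfr(sort(unique(lb)), function(g) {
    mutate(km_curve(cl$time[lb == g], cl$event[lb == g]), class = g,
           .before = 1)
  })
  list(curves = curves,
       test = logrank_test(cl$time, cl$event, lb))
}

#' Write per-group KM curves as TSV
#' @param curves Tibble from [survival_stratification()]`$curves` or a
#'   single [km_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(curves, path) {
  readr::write_tsv(as_tibble(curves), path, progress = FALSE)
  invisible(path)
}
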