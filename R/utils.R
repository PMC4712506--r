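#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange select group_by summarise ungroup
#'   left_join bind_rows count n distinct pull desc slice rename
#' @importFrom purrr map map_dfr map_chr map_int map_dbl imap walk
#' @importFrom stats pchisq rnorm rexp runif sd setNames predict median
#' @importFrom utils head modifyList
NULL

# Non-class label states; fixed, case-sensitive interchange tokens.
STATE_INCONSISTENT <- "INCONSISTENT"
STATE_UNASSIGNED <- "UNASSIGNED"

#' Default intrinsic subtype class list
#'
#' The five transcriptomic breast cancer groups used throughout as the default
#' class list: luminal A, luminal B, HER2-enriched, basal-like, normal-like.
#'
#' @return Character vector of five class labels.
#' @export
default_classes <- function() {
  c("LumA", "LumB", "Her2", "Basal", "Normal")
}

# Deterministic seed schedule: derive a child seed (< 2^31) from a parent seed
# and a stream of integer offsets, by iterated Lehmer steps. Avoids correlated
# streams when the same parent seeds several consumers.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed %% 2147483647L)
  if (s <= 0) s <- s + 2147483646
  for (o in offs) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
    if (s == 0) s <- 1
  }
  as.integer(s)
}

# Row means / sample sds over a column mask, vectorised over probes.
row_stats <- function(values, cols) {
  x <- values[, cols, drop = FALSE]
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  list(mean = m, sd = sqrt(pmax(v, 0)), n = n)
}
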