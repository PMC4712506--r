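# Classifier roster: a declared, ordered list of heterogeneous ensemble
# members. Member algorithms come from standard packages (rpart, tree, nnet,
# e1071, MASS, class, ranger, xgboost) plus two classic learners implemented
# here (OneR, nearest centroid); the roster itself is plain data so it can be
# echoed verbatim into result provenance.

ROSTER_FAMILIES <- c("tree", "rule", "bayes", "function", "knn", "meta")

#' Build a classifier roster
#'
#' @param members A data frame (or tibble) with columns `member_id`, `family`
#'   and a list-column `params`, or a list of `list(member_id=, family=,
#'   params=)` specs. Defaults to the 24-member roster of
#'   [default_roster_members()].
#' @return A `classifier_roster` tibble with columns `member_id`, `family`,
#'   `params`.
#' @details Families span the categories a heterogeneous classification
#'   suite offers: `"tree"` (recursive partitioning), `"rule"` (one-rule
#'   learner), `"bayes"` (naive Bayes), `"function"` (linear/function-based:
#'   LDA, multinomial logistic, SVM, nearest centroid), `"knn"` (nearest
#'   neighbour) and `"meta"` (bagged/boosted ensembles).
#' @export
build_roster <- function(members = default_roster_members()) {
  if (is.list(members) && !is.data.frame(members)) {
    members <- map_dfr(members, function(m) {
      tibble(member_id = m$member_id, family = m$family,
             params = list(m$params %||% list()))
    })
  }
  members <- as_tibble(members)
  if (!all(c("member_id", "family") %in% colnames(members))) {
    abort("roster members need member_id and family columns")
  }
  if (!"params" %in% colnames(members)) {
    members$params <- rep(list(list()), nrow(members))
  }
  if (nrow(members) < 2) abort("a roster needs at least 2 members")
  if (anyDuplicated(members$member_id)) {
    abort(paste0("duplicate member_id: ",
                 members$member_id[duplicated(members$member_id)][1]))
  }
  bad <- setdiff(unique(members$family), ROSTER_FAMILIES)
  if (length(bad)) {
    abort(paste0("unknown family tag: ", bad[1],
                 " (known: ", paste(ROSTER_FAMILIES, collapse = ", "), ")"))
  }
  structure(members[, c("member_id", "family", "params")],
            class = c("classifier_roster", class(members)))
}

member_spec <- function(member_id, family, ...) {
  list(member_id = member_id, family = family, params = list(...))
}

#' Default 24-member roster specification
#'
#' Twenty-four members over six families, mirroring the breadth of a
#' heterogeneous classification suite: trees at several complexities, a
#' one-rule learner, naive Bayes, linear and kernel function-based learners,
#' nearest-neighbour voters, and bagged/boosted meta-learners.
#'
#' @return A list of member specs consumable by [build_roster()].
#' @export
default_roster_members <- function() {
  list(
    member_spec("rpart_cp01", "tree", engine = "rpart", cp = 0.01),
    member_spec("rpart_cp001", "tree", engine = "rpart", cp = 0.001),
    member_spec("rpart_ms5", "tree", engine = "rpart", cp = 0.005, minsplit = 5),
    member_spec("rpart_d3", "tree", engine = "rpart", cp = 0.01, maxdepth = 3),
    member_spec("tree_dev", "tree", engine = "tree"),
    member_spec("oner_b4", "rule", bins = 4),
    member_spec("oner_b6", "rule", bins = 6),
    member_spec("nb_l0", "bayes", laplace = 0),
    member_spec("nb_l1", "bayes", laplace = 1),
    member_spec("lda", "function", engine = "lda"),
    member_spec("multinom_d0", "function", engine = "multinom", decay = 0),
    member_spec("multinom_d01", "function", engine = "multinom", decay = 0.1),
    member_spec("svm_lin_c1", "function", engine = "svm", kernel = "linear", cost = 1),
    member_spec("svm_lin_c10", "function", engine = "svm", kernel = "linear", cost = 10),
    member_spec("svm_rbf_c1", "function", engine = "svm", kernel = "radial", cost = 1),
    member_spec("centroid_euc", "function", engine = "centroid", metric = "euclidean"),
    member_spec("centroid_cor", "function", engine = "centroid", metric = "correlation"),
    member_spec("knn1", "knn", k = 1),
    member_spec("knn3", "knn", k = 3),
    member_spec("knn5", "knn", k = 5),
    member_spec("knn7", "knn", k = 7),
    member_spec("ranger_100", "meta", engine = "ranger", num_trees = 100),
    member_spec("ranger_300", "meta", engine = "ranger", num_trees = 300),
    member_spec("xgb_40", "meta", engine = "xgboost", nrounds = 40, max_depth = 3)
  )
}

#' Reduced 8-member roster specification
#'
#' A fast roster spanning five families, intended for simulation studies and
#' end-to-end tests where wall-clock time matters more than member count.
#'
#' @return A list of member specs consumable by [build_roster()].
#' @export
fast_roster_members <- function() {
  list(
    member_spec("rpart_cp01", "tree", engine = "rpart", cp = 0.01),
    member_spec("nb_l0", "bayes", laplace = 0),
    member_spec("lda", "function", engine = "lda"),
    member_spec("svm_lin_c1", "function", engine = "svm", kernel = "linear", cost = 1),
    member_spec("centroid_euc", "function", engine = "centroid", metric = "euclidean"),
    member_spec("knn1", "knn", k = 1),
    member_spec("knn5", "knn", k = 5),
    member_spec("ranger_64", "meta", engine = "ranger", num_trees = 64)
  )
}

#' @export
print.classifier_roster <- function(x, ...) {
  cat(sprintf("<classifier_roster> %d members (%s)\n", nrow(x),
              paste(sort(unique(x$family)), collapse = ", ")))
  NextMethod()
}

# --- member fit/predict -----------------------------------------------------
# x: samples x features numeric matrix; y: factor over x's rows.
# Returns an opaque fit; predict_member() maps a matrix to character labels.

fit_member <- function(member_id, family, params, x, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  engine <- params$engine %||% family
  withr::with_seed(seed, switch(family,
    tree = fit_tree(engine, params, x, y),
    rule = fit_oner(params, x, y),
    bayes = list(kind = "nb",
                 model = e1071::naiveBayes(x, y, laplace = params$laplace %||% 0)),
    `function` = fit_function(engine, params, x, y),
    knn = list(kind = "knn", train = x, y = y, k = params$k %||% 1),
    meta = fit_meta(engine, params, x, y, seed),
    abort(paste0("unknown family tag: ", family))
  ))
}

fit_tree <- function(engine, params, x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  if (identical(engine, "tree")) {
    list(kind = "tree", model = tree::tree(.y ~ ., data = df))
  } else {
    ctl <- rpart::rpart.control(
      cp = params$cp %||% 0.01,
      minsplit = params$minsplit %||% 20,
      maxdepth = params$maxdepth %||% 30,
      xval = 0
    )
    list(kind = "rpart",
         model = rpart::rpart(.y ~ ., data = df, method = "class", control = ctl))
  }
}

# OneR: quantile-bin every feature, take per-bin majority class, keep the
# single feature with the lowest training error.
fit_oner <- function(params, x, y) {
  bins <- params$bins %||% 4
  best <- NULL
  best_err <- Inf
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    brk <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(brk) < 2) next
    bin <- findInterval(v, brk, all.inside = TRUE)
    rule <- tapply(y, factor(bin, levels = seq_len(length(brk) - 1)), function(g) {
      if (!length(g)) return(NA_character_)
      names(sort(table(g), decreasing = TRUE))[1]
    })
    pred <- rule[as.character(bin)]
    err <- mean(pred != as.character(y), na.rm = TRUE)
    if (err < best_err) {
      best_err <- err
      best <- list(feature = colnames(x)[j], breaks = brk, rule = rule,
                   fallback = names(sort(table(y), decreasing = TRUE))[1])
    }
  }
  if (is.null(best)) abort("OneR: no feature could be binned")
  c(list(kind = "oner"), best)
}

fit_function <- function(engine, params, x, y) {
  switch(engine,
    lda = list(kind = "lda", model = MASS::lda(x, grouping = y)),
    multinom = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      list(kind = "multinom",
           model = nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                  maxit = 200, decay = params$decay %||% 0,
                                  MaxNWts = 5000))
    },
    svm = list(kind = "svm",
               model = e1071::svm(x, y, kernel = params$kernel %||% "linear",
                                  cost = params$cost %||% 1)),
    centroid = {
      cen <- t(vapply(levels(y), function(cl) colMeans(x[y == cl, , drop = FALSE]),
                      numeric(ncol(x))))
      list(kind = "centroid", centroids = cen,
           metric = params$metric %||% "euclidean")
    },
    abort(paste0("unknown function-family engine: ", engine))
  )
}

fit_meta <- function(engine, params, x, y, seed) {
  switch(engine,
    ranger = list(kind = "ranger",
                  model = ranger::ranger(
                    x = x, y = y,
                    num.trees = params$num_trees %||% 100,
                    num.threads = 1, seed = seed
                  )),
    xgboost = {
      lev <- levels(y)
      model <- xgboost::xgboost(
        data = x, label = as.integer(y) - 1L,
        params = list(objective = "multi:softmax", num_class = length(lev),
                      max_depth = params$max_depth %||% 3, eta = 0.3,
                      nthread = 1),
        nrounds = params$nrounds %||% 40, verbose = 0
      )
      list(kind = "xgb", model = model, levels = lev)
    },
    abort(paste0("unknown meta-family engine: ", engine))
  )
}

predict_member <- function(fit, x, seed = 1L) {
  withr::with_seed(seed, switch(fit$kind,
    rpart = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(fit$model, newdata = df, type = "class"))
    },
    tree = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(fit$model, newdata = df, type = "class"))
    },
    oner = {
      bin <- findInterval(x[, fit$feature], fit$breaks, all.inside = TRUE)
      pred <- unname(fit$rule[as.character(bin)])
      pred[is.na(pred)] <- fit$fallback
      pred
    },
    nb = as.character(predict(fit$model, newdata = x)),
    lda = as.character(predict(fit$model, newdata = x)$class),
    multinom = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(fit$model, newdata = df))
    },
    svm = as.character(predict(fit$model, newdata = x)),
    centroid = {
      d <- if (identical(fit$metric, "correlation")) {
        1 - stats::cor(t(x), t(fit$centroids))
      } else {
        # squared Euclidean distances sample-to-centroid
        outer(rowSums(x^2), rep(1, nrow(fit$centroids))) -
          2 * x %*% t(fit$centroids) +
          outer(rep(1, nrow(x)), rowSums(fit$centroids^2))
      }
      rownames(fit$centroids)[max.col(-d, ties.method = "first")]
    },
    knn = as.character(class::knn(fit$train, x, fit$y, k = fit$k)),
    ranger = as.character(predict(fit$model, data = x, num.threads = 1)$predictions),
    xgb = fit$levels[predict(fit$model, newdata = x) + 1L],
    abort(paste0("unknown fitted member kind: ", fit$kind))
  ))
}
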