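#' Gini impurity of a class distribution
#'
#' `Gini(p) = sum_k p_k (1 - p_k)`, the probability that two draws from the
#' node disagree in class; 0 for a pure node, at most `1 - 1/k` for `k`
#' classes.
#'
#' @param p Vector of class proportions summing to 1.
#' @return The Gini impurity.
#' @examples
#' gini(c(0.5, 0.5)) # 0.5
#' gini(c(0.9, 0.1)) # 0.18
#' @export
gini <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`p` must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  sum(p * (1 - p))
}

#' Importance contribution of a single split node
#'
#' The default ("literal") score is `GI_m - GI_l - GI_r`: the parent's Gini
#' minus the unweighted sum of the two children's. Because it ignores child
#' sample sizes it can be negative for uninformative splits. With
#' `weighted = TRUE` the standard impurity decrease
#' `GI_m - (n_l/n_m) GI_l - (n_r/n_m) GI_r` is used instead, which is
#' non-negative for any split chosen greedily. Both modes are exposed; see
#' the methods vignette for the trade-off.
#'
#' @param node An internal node of a [fit_forest()] tree.
#' @param weighted Use child-size weighting (default `FALSE`).
#' @return The node's importance score.
#' @export
node_importance <- function(node, weighted = FALSE) {
  if (isTRUE(node$leaf)) {
    stop("node importance is defined for internal nodes only",
         call. = FALSE)
  }
  if (weighted) {
    node$gini - (node$left$n / node$n) * node$left$gini -
      (node$right$n / node$n) * node$right$gini
  } else {
    node$gini - node$left$gini - node$right$gini
  }
}

#' Importance of one feature within one tree
#'
#' Sums [node_importance()] over every internal node of `tree` that splits
#' on `feature`; 0 if the feature is never used.
#'
#' @param tree A tree from [fit_forest()] (element of the forest list).
#' @param feature Feature (column) name.
#' @inheritParams node_importance
#' @return The summed score.
#' @export
tree_importance <- function(tree, feature, weighted = FALSE) {
  walk <- function(node) {
    if (isTRUE(node$leaf)) return(0)
    here <- if (node$feature == feature) {
      node_importance(node, weighted = weighted)
    } else 0
    here + walk(node$left) + walk(node$right)
  }
  walk(tree)
}

#' Normalised forest feature importances
#'
#' Per feature, sums [tree_importance()] over every tree, then divides by
#' the grand total so the scores sum to 1.
#'
#' @param forest A forest from [fit_forest()].
#' @inheritParams node_importance
#' @return A `gini_importance` tibble with columns `feature`, `importance`
#'   (normalised), `raw`, sorted by decreasing importance (ties broken by
#'   feature name).
#' @export
forest_importance <- function(forest, weighted = FALSE) {
  if (length(forest) == 0L) stop("empty forest", call. = FALSE)
  features <- attr(forest, "features")
  raw <- vapply(features, function(f) {
    sum(vapply(forest, tree_importance, numeric(1), feature = f,
               weighted = weighted))
  }, numeric(1))
  total <- sum(raw)
  if (total == 0) {
    stop("no informative splits: total importance is zero", call. = FALSE)
  }
  out <- tibble::tibble(feature = features,
                        importance = unname(raw) / total,
                        raw = unname(raw))
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  class(out) <- c("gini_importance", class(out))
  out
}

#' Fit a seeded random forest of CART trees
#'
#' A minimal, deterministic forest builder for importance computation:
#' bootstrap-resampled binary CART trees, `mtry` features considered per
#' split (default `ceiling(sqrt(d))`), greedy weighted-Gini-gain splitting,
#' grown until pure or `max_depth`.
#'
#' @param table Data frame of features plus a binary label column.
#' @param label Name of the binary label column.
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth (default `Inf`).
#' @param mtry Features sampled per split; default `ceiling(sqrt(d))`.
#' @param min_split Minimum node size to attempt a split (default 2).
#' @param bootstrap Resample rows with replacement per tree (default TRUE).
#' @param seed Integer RNG seed.
#' @return A list of trees with attribute `"features"`; input to
#'   [forest_importance()].
#' @export
fit_forest <- function(table, label = "cardio", n_trees = 100,
                       max_depth = Inf, mtry = NULL, min_split = 2,
                       bootstrap = TRUE, seed = 1L) {
  stopifnot(label %in% names(table), nrow(table) >= 2)
  y <- table[[label]]
  if (length(unique(y)) < 2) {
    stop("label has a single class; nothing to split on", call. = FALSE)
  }
  features <- setdiff(names(table), c(label, "id"))
  x <- as.matrix(
    dplyr::mutate(table[features], dplyr::across(dplyr::everything(),
                                                 as.numeric))
  )
  classes <- sort(unique(y))
  yi <- match(y, classes)
  d <- length(features)
  if (is.null(mtry)) mtry <- ceiling(sqrt(d))
  mtry <- max(1L, min(as.integer(mtry), d))

  forest <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(i) {
      idx <- if (bootstrap) {
        sample.int(nrow(x), replace = TRUE)
      } else {
        seq_len(nrow(x))
      }
      .grow_cart(x, yi, idx, n_classes = length(classes),
                 max_depth = max_depth, mtry = mtry,
                 min_split = min_split)
    })
  })
  attr(forest, "features") <- features
  attr(forest, "classes") <- classes
  forest
}

# Gini from class counts (1 - sum p^2 == sum p(1-p)).
.gini_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Recursive CART grower on row subset `idx`; split criterion is weighted
# impurity decrease, the standard greedy rule.
.grow_cart <- function(x, yi, idx, n_classes, max_depth, mtry, min_split,
                       depth = 0L) {
  n <- length(idx)
  counts <- tabulate(yi[idx], nbins = n_classes)
  g <- .gini_counts(counts)
  leaf <- list(leaf = TRUE, n = n, dist = counts / n, gini = g)
  if (g == 0 || n < min_split || depth >= max_depth) return(leaf)

  feat_pool <- sample.int(ncol(x), mtry)
  best <- NULL
  best_score <- g - 1e-12  # require a strict impurity decrease
  for (j in feat_pool) {
    xj <- x[idx, j]
    o <- order(xj)
    xs <- xj[o]
    ys <- yi[idx][o]
    splittable <- which(xs[-n] < xs[-1])
    if (length(splittable) == 0L) next
    # cumulative class counts left of each candidate cut, vectorised
    cum <- vapply(seq_len(n_classes), function(k) cumsum(ys == k),
                  numeric(n))
    cl <- cum[splittable, , drop = FALSE]
    cr <- matrix(counts, length(splittable), n_classes, byrow = TRUE) - cl
    nl <- splittable
    nr <- n - nl
    score <- (nl * (1 - rowSums((cl / nl)^2)) +
                nr * (1 - rowSums((cr / nr)^2))) / n
    w <- which.min(score)
    if (score[w] < best_score) {
      best_score <- score[w]
      i <- splittable[w]
      best <- list(j = j, thr = (xs[i] + xs[i + 1]) / 2)
    }
  }
  if (is.null(best)) return(leaf)
  xj <- x[idx, best$j]
  go_left <- xj <= best$thr
  list(
    leaf = FALSE, n = n, dist = counts / n, gini = g,
    feature = colnames(x)[best$j], threshold = best$thr,
    left = .grow_cart(x, yi, idx[go_left], n_classes, max_depth, mtry,
                      min_split, depth + 1L),
    right = .grow_cart(x, yi, idx[!go_left], n_classes, max_depth, mtry,
                       min_split, depth + 1L)
  )
}

#' Rank cohort features by forest Gini importance
#'
#' Pipeline surface: fits a seeded forest on the cohort (label excluded,
#' `id` ignored) and returns the normalised importance ranking, mirroring
#' an importance table layout of (feature, normalised importance) sorted
#' descending.
#'
#' @inheritParams fit_forest
#' @inheritParams node_importance
#' @return A `gini_importance` tibble (see [forest_importance()]).
#' @export
rank_features <- function(table, label = "cardio", n_trees = 100,
                          max_depth = Inf, seed = 1L, weighted = TRUE) {
  forest <- fit_forest(table, label = label, n_trees = n_trees,
                       max_depth = max_depth, seed = seed)
  forest_importance(forest, weighted = weighted)
}

#' Sum one-hot indicator importances back into their parent feature
#'
#' When a categorical feature (e.g. `gender`) was one-hot expanded before
#' ranking, its indicator columns `gender_1`, `gender_2`, ... are separate
#' rows; this collapses them into a single `gender` row by summing, so the
#' ranking speaks of the clinical feature, not its encoding.
#'
#' @param importance A `gini_importance` tibble.
#' @param parents Character vector of parent feature names.
#' @return The collapsed, re-sorted `gini_importance` tibble.
#' @export
collapse_onehot_importance <- function(importance, parents = "gender") {
  out <- importance
  for (p in parents) {
    hit <- grepl(paste0("^", p, "_"), out$feature)
    if (!any(hit)) next
    merged <- tibble::tibble(feature = p,
                             importance = sum(out$importance[hit]),
                             raw = sum(out$raw[hit]))
    out <- dplyr::bind_rows(out[!hit, , drop = FALSE], merged)
  }
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  class(out) <- c("gini_importance", class(out))
  out
}

#' Select the top-k most important features
#'
#' Returns the `k` features with the largest normalised importance in
#' descending order, ties broken by ascending feature name. The modelling
#' protocol keeps the top 12 of the 14 cardio features (11 raw predictors
#' plus BMI, MAP, PP) as the classifier input.
#'
#' @param importance A `gini_importance` tibble from [forest_importance()].
#' @param k Number of features, `1 <= k <= nrow(importance)`.
#' @return Character vector of `k` feature names.
#' @export
select_top_k <- function(importance, k = 12) {
  if (k < 1 || k > nrow(importance)) {
    stop("`k` must be between 1 and the number of features", call. = FALSE)
  }
  ord <- order(-importance$importance, importance$feature)
  importance$feature[ord][seq_len(k)]
}
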