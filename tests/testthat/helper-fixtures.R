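# Shared fixtures and independent oracles used across test files.

# Gradient of the separable convex quadratic f(w) = sum (w - target)^2.
quad_target <- c(1, -2, 3)
quad_grad <- function(p) list(w = 2 * (p$w - quad_target))
quad_loss <- function(p) sum((p$w - quad_target)^2)

run_optimizer <- function(opt, steps, start = c(5, 5, 5)) {
  p <- list(w = start)
  for (s in seq_len(steps)) {
    out <- optimizer_step(opt, p, quad_grad(p))
    opt <- out$opt
    p <- out$params
  }
  list(params = p, opt = opt)
}

# Hand-built CART nodes (bypassing fit_forest) so importance formulas can
# be checked on known structures.
leaf_node <- function(n, dist) {
  list(leaf = TRUE, n = n, dist = dist, gini = sum(dist * (1 - dist)))
}
split_node <- function(feature, threshold, n, dist, left, right) {
  list(leaf = FALSE, n = n, dist = dist, gini = sum(dist * (1 - dist)),
       feature = feature, threshold = threshold, left = left,
       right = right)
}

# Independent importance oracle: plain recursive traversal accumulating
# per-feature impurity decreases, written without reference to the package
# accumulation code path.
oracle_tree_importance <- function(tree, weighted = FALSE) {
  acc <- new.env()
  visit <- function(nd) {
    if (isTRUE(nd$leaf)) return(invisible(NULL))
    dec <- if (weighted) {
      nd$gini - (nd$left$n / nd$n) * nd$left$gini -
        (nd$right$n / nd$n) * nd$right$gini
    } else {
      nd$gini - nd$left$gini - nd$right$gini
    }
    prev <- mget(nd$feature, envir = acc, ifnotfound = 0)[[1]]
    assign(nd$feature, prev + dec, envir = acc)
    visit(nd$left)
    visit(nd$right)
  }
  visit(tree)
  as.list(acc)
}

# Weighted mean of leaf impurities, for the impurity-conservation law.
oracle_leaf_impurity <- function(tree) {
  total <- 0
  visit <- function(nd) {
    if (isTRUE(nd$leaf)) {
      total <<- total + nd$n * nd$gini
      return(invisible(NULL))
    }
    visit(nd$left)
    visit(nd$right)
  }
  visit(tree)
  total / tree$n
}

# Weighted-node-importance sum, scaled by node mass, for the same law.
oracle_scaled_importance_sum <- function(tree) {
  total <- 0
  visit <- function(nd) {
    if (isTRUE(nd$leaf)) return(invisible(NULL))
    total <<- total + (nd$n / tree$n) *
      (nd$gini - (nd$left$n / nd$n) * nd$left$gini -
         (nd$right$n / nd$n) * nd$right$gini)
    visit(nd$left)
    visit(nd$right)
  }
  visit(tree)
  total
}

# Independent LSTM unroll: a literal transcription of the recurrence with
# no shared code with the package internals.
oracle_lstm_prob <- function(params, x) {
  h_dim <- attr(params, "hidden_dim")
  sig <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, h_dim)
  cc <- rep(0, h_dim)
  for (t in seq_len(nrow(x))) {
    z <- c(h, x[t, ])
    f <- sig(params$Wf %*% z + params$bf)
    i <- sig(params$Wi %*% z + params$bi)
    o <- sig(params$Wo %*% z + params$bo)
    a <- params$Wc %*% z + params$bc
    g <- if (attr(params, "variant") == "softsign") a / (1 + abs(a)) else
      tanh(a)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  sig(sum(params$why * h) + params$bhy)
}
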