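#' Gate and candidate activation functions
#'
#' `sigmoid(x) = 1/(1+exp(-x))` with range (0,1); `tanh` with range (-1,1);
#' `softsign(x) = x/(1+|x|)` with range (-1,1) and heavier tails than tanh,
#' used as the candidate-state activation in the improved cell to speed up
#' convergence.
#'
#' @param name One of `"sigmoid"`, `"tanh"`, `"softsign"`.
#' @param x Numeric vector/matrix.
#' @return The activated values.
#' @examples
#' activation("softsign", 1) # 0.5
#' @export
activation <- function(name, x) {
  switch(name,
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    softsign = x / (1 + abs(x)),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialise LSTM parameters
#'
#' Creates the eight learnable gate parameter groups — weight matrices
#' `Wf`, `Wi`, `Wo`, `Wc`, each `hidden_dim x (hidden_dim + input_dim)`
#' acting on the concatenation `[h_prev, x_t]`, and bias vectors `bf`,
#' `bi`, `bo`, `bc` — plus a sigmoid classification head (`why`, `bhy`)
#' mapping the final hidden state to one logit. Gate matrices are
#' Glorot-uniform initialised; biases start at zero (a forget-gate bias
#' offset is available via `forget_bias`).
#'
#' @param input_dim Dimension of each timestep input.
#' @param hidden_dim Hidden state size.
#' @param variant `"standard"` (tanh candidate) or `"softsign"`.
#' @param seed Integer RNG seed for the initial weights.
#' @param forget_bias Constant added to `bf` at init (default 0, following
#'   the plain cell equations).
#' @return A named list of parameter arrays with class `lstm_params` and
#'   attributes `input_dim`, `hidden_dim`, `variant`.
#' @export
lstm_params <- function(input_dim, hidden_dim, variant = "standard",
                        seed = 1L, forget_bias = 0) {
  stopifnot(input_dim >= 1, hidden_dim >= 1,
            variant %in% c("standard", "softsign"))
  h <- hidden_dim
  z <- hidden_dim + input_dim
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- withr::with_seed(as.integer(seed), list(
    Wf = glorot(h, z), Wi = glorot(h, z), Wo = glorot(h, z),
    Wc = glorot(h, z),
    bf = rep(forget_bias, h), bi = rep(0, h), bo = rep(0, h),
    bc = rep(0, h),
    why = glorot(1, h)[1, ], bhy = 0
  ))
  attr(p, "input_dim") <- as.integer(input_dim)
  attr(p, "hidden_dim") <- as.integer(hidden_dim)
  attr(p, "variant") <- variant
  class(p) <- "lstm_params"
  p
}

#' One LSTM cell step
#'
#' Computes the forget, input and output gates
#' `f,i,o = sigmoid(W [h_prev; x_t] + b)`, the candidate state
#' `g = tanh(.)` (standard) or `softsign(.)` (improved variant), the cell
#' update `C_t = f * C_prev + i * g` and the output
#' `h_t = o * tanh(C_t)`. Accepts a batch: `x_t` may be a
#' `input_dim x B` matrix with matching `h_prev`, `c_prev`.
#'
#' @param params An [lstm_params()] object.
#' @param x_t Input at time t (vector of length `input_dim` or matrix).
#' @param h_prev,c_prev Previous hidden/cell state (vector of length
#'   `hidden_dim` or matrix).
#' @return List `h`, `c`, and `cache` holding all intermediates for
#'   backpropagation.
#' @export
cell_forward <- function(params, x_t, h_prev, c_prev) {
  h_dim <- attr(params, "hidden_dim")
  d <- attr(params, "input_dim")
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = d)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, nrow = h_dim)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, nrow = h_dim)
  if (nrow(x_t) != d || nrow(h_prev) != h_dim) {
    stop("input/state shapes do not match the parameters", call. = FALSE)
  }
  z <- rbind(h_prev, x_t)
  f <- .sigmoid(params$Wf %*% z + params$bf)
  i <- .sigmoid(params$Wi %*% z + params$bi)
  o <- .sigmoid(params$Wo %*% z + params$bo)
  a_c <- params$Wc %*% z + params$bc
  g <- if (attr(params, "variant") == "softsign") {
    a_c / (1 + abs(a_c))
  } else {
    tanh(a_c)
  }
  c_new <- f * c_prev + i * g
  tanh_c <- tanh(c_new)
  h <- o * tanh_c
  list(h = h, c = c_new,
       cache = list(z = z, f = f, i = i, o = o, g = g, a_c = a_c,
                    c_prev = c_prev, c = c_new, tanh_c = tanh_c))
}

# Batched forward over a list of T input matrices (input_dim x B).
.lstm_forward_batch <- function(params, xs) {
  h_dim <- attr(params, "hidden_dim")
  b <- ncol(xs[[1]])
  h <- matrix(0, h_dim, b)
  cc <- matrix(0, h_dim, b)
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    step <- cell_forward(params, xs[[t]], h, cc)
    h <- step$h
    cc <- step$c
    caches[[t]] <- step$cache
  }
  logit <- drop(params$why %*% h) + params$bhy
  list(prob = .sigmoid(logit), logit = logit, h_final = h,
       caches = caches)
}

#' Forward pass over one encoded record
#'
#' Unrolls [cell_forward()] from zero initial states over the sequence and
#' applies the sigmoid head to the final hidden state, returning the
#' predicted disease probability.
#'
#' @param params An [lstm_params()] object.
#' @param x A `T x input_dim` matrix from [encode_record()].
#' @return List with `prob` (scalar in (0,1)), `h_final`, and `caches`
#'   (per-timestep intermediates for [lstm_backward()]).
#' @export
lstm_forward <- function(params, x) {
  if (NROW(x) == 0) stop("empty sequence", call. = FALSE)
  x <- as.matrix(x)
  xs <- lapply(seq_len(nrow(x)), function(t) matrix(x[t, ], ncol = 1))
  out <- .lstm_forward_batch(params, xs)
  out$prob <- drop(out$prob)
  out
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1-y) log(1-p))`, averaged over the batch; probabilities
#' are clipped to `[1e-12, 1 - 1e-12]` for numerical safety.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1).
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(p, y) {
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Backpropagation through time
#'
#' Exact analytic gradients of the mean binary cross-entropy with respect
#' to all eight gate parameter groups and the head, accumulated backwards
#' across timesteps: the head error is pushed into `h_T`, then each step
#' distributes its hidden/cell error into the gate pre-activations
#' (sigmoid derivative `s(1-s)`; candidate derivative `1 - g^2` for tanh or
#' `1/(1+|a|)^2` for softsign) and passes `dh_{t-1}`, `dC_{t-1} = dC_t *
#' f_t` upstream.
#'
#' @param params The [lstm_params()] used in the forward pass.
#' @param forward_out The list returned by [lstm_forward()] (or the
#'   internal batched forward).
#' @param y Binary label(s) matching the forward batch.
#' @return Named list of gradients with the same shapes as `params`.
#' @export
lstm_backward <- function(params, forward_out, y) {
  caches <- forward_out$caches
  h_dim <- attr(params, "hidden_dim")
  softsign <- attr(params, "variant") == "softsign"
  b <- ncol(caches[[1]]$z)
  if (length(y) != b) {
    stop("labels do not match the forward batch", call. = FALSE)
  }
  p <- forward_out$prob
  dlogit <- (p - y) / b

  g <- list(
    Wf = params$Wf * 0, Wi = params$Wi * 0, Wo = params$Wo * 0,
    Wc = params$Wc * 0,
    bf = params$bf * 0, bi = params$bi * 0, bo = params$bo * 0,
    bc = params$bc * 0,
    why = drop(forward_out$h_final %*% dlogit),
    bhy = sum(dlogit)
  )
  dh <- outer(params$why, dlogit)
  dc <- matrix(0, h_dim, b)
  for (t in rev(seq_along(caches))) {
    ch <- caches[[t]]
    d_o <- dh * ch$tanh_c
    da_o <- d_o * ch$o * (1 - ch$o)
    dc <- dc + dh * ch$o * (1 - ch$tanh_c^2)
    d_f <- dc * ch$c_prev
    da_f <- d_f * ch$f * (1 - ch$f)
    d_i <- dc * ch$g
    da_i <- d_i * ch$i * (1 - ch$i)
    d_g <- dc * ch$i
    da_c <- if (softsign) d_g / (1 + abs(ch$a_c))^2 else d_g * (1 - ch$g^2)

    zt <- t(ch$z)
    g$Wf <- g$Wf + da_f %*% zt
    g$Wi <- g$Wi + da_i %*% zt
    g$Wo <- g$Wo + da_o %*% zt
    g$Wc <- g$Wc + da_c %*% zt
    g$bf <- g$bf + rowSums(da_f)
    g$bi <- g$bi + rowSums(da_i)
    g$bo <- g$bo + rowSums(da_o)
    g$bc <- g$bc + rowSums(da_c)

    dz <- t(params$Wf) %*% da_f + t(params$Wi) %*% da_i +
      t(params$Wo) %*% da_o + t(params$Wc) %*% da_c
    dh <- dz[seq_len(h_dim), , drop = FALSE]
    dc <- dc * ch$f
  }
  g
}

#' Compare BPTT gradients to central finite differences
#'
#' Numerically differentiates the mean binary cross-entropy through the
#' forward pass alone (`(L(theta+eps) - L(theta-eps)) / (2 eps)` per
#' coordinate) and compares with [lstm_backward()]. The two paths share no
#' code beyond the forward evaluation, so agreement validates the analytic
#' gradients.
#'
#' @param params [lstm_params()] to check.
#' @param x Encoded input: a `T x input_dim` matrix (single record) or a
#'   list of `input_dim x B` matrices (batch).
#' @param y Matching binary label(s).
#' @param eps Finite-difference step (default 1e-5).
#' @return A tibble with one row per parameter group: `group`,
#'   `rel_error` (L2 norm of the difference over the sum of norms) and
#'   `max_abs_diff`.
#' @export
gradient_check <- function(params, x, y, eps = 1e-5) {
  xs <- if (is.list(x)) x else {
    lapply(seq_len(nrow(x)), function(t) matrix(x[t, ], ncol = 1))
  }
  fwd <- .lstm_forward_batch(params, xs)
  analytic <- lstm_backward(params, fwd, y)
  loss_at <- function(p) {
    bce_loss(.lstm_forward_batch(p, xs)$prob, y)
  }
  groups <- names(analytic)
  rows <- lapply(groups, function(nm) {
    ga <- analytic[[nm]]
    gn <- ga
    for (idx in seq_along(gn)) {
      up <- params
      up[[nm]][idx] <- up[[nm]][idx] + eps
      dn <- params
      dn[[nm]][idx] <- dn[[nm]][idx] - eps
      gn[idx] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    tibble::tibble(
      group = nm,
      rel_error = sqrt(sum((ga - gn)^2)) /
        (sqrt(sum(ga^2)) + sqrt(sum(gn^2)) + 1e-12),
      max_abs_diff = max(abs(ga - gn))
    )
  })
  dplyr::bind_rows(rows)
}

#' Encode a record as an LSTM input sequence
#'
#' The cardio features of one record become a sequence either one feature
#' per timestep in the supplied (importance) order — `per_feature_step`,
#' the default, giving `T = length(features)` scalar inputs — or as a
#' single timestep carrying the whole feature vector (`single_step`).
#' Either encoding is a bijection of the selected feature vector.
#'
#' @param record One-row data frame (or named vector) of features.
#' @param features Ordered character vector of feature names to encode.
#' @param mode `"per_feature_step"` or `"single_step"`.
#' @return A `T x input_dim` numeric matrix.
#' @export
encode_record <- function(record, features,
                          mode = c("per_feature_step", "single_step")) {
  mode <- match.arg(mode)
  if (is.data.frame(record)) record <- unlist(record[1, , drop = TRUE])
  missing <- setdiff(features, names(record))
  if (length(missing) > 0) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.numeric(record[features])
  if (mode == "per_feature_step") {
    matrix(v, ncol = 1)
  } else {
    matrix(v, nrow = 1)
  }
}

# Encode a whole table as a list of T (input_dim x B) matrices.
.encode_batch <- function(table, features,
                          mode = c("per_feature_step", "single_step")) {
  mode <- match.arg(mode)
  m <- t(as.matrix(table[features]))  # d x n
  if (mode == "per_feature_step") {
    lapply(seq_len(nrow(m)), function(t) m[t, , drop = FALSE])
  } else {
    list(m)
  }
}
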