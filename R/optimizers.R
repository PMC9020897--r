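#' Optimizer configuration
#'
#' Bundles the hyperparameters shared by the optimizer family, with the
#' reference defaults: RMSprop `lr = 0.001`, `gamma = 0.9`; Adam `lr = 0.001`,
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`; RAdam `lr = 1e-4`
#' (moment/eps inherited from Adam); Lookahead and R-Lookahead `k = 5`,
#' `alpha_slow = 0.5` with fast-weight learning rate 0.001 (see the
#' methods vignette for that choice).
#'
#' @param lr Learning rate (> 0).
#' @param beta1,beta2 Exponential decay rates of the first/second moment
#'   estimates, in \[0, 1).
#' @param eps Numerical floor added to the adaptive denominator.
#' @param gamma RMSprop squared-gradient decay, in \[0, 1).
#' @param k Lookahead inner (fast-weight) steps per round, >= 1.
#' @param alpha_slow Lookahead slow-weight step size in \[0, 1\].
#' @param reset_inner Reset the inner optimizer's moment state at each
#'   Lookahead round (default FALSE: state persists across rounds).
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-8, gamma = 0.9, k = 5,
                             alpha_slow = 0.5, reset_inner = FALSE) {
  stopifnot(lr > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            eps > 0, gamma >= 0, gamma < 1, k >= 1,
            alpha_slow >= 0, alpha_slow <= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 gamma = gamma, k = as.integer(k),
                 alpha_slow = alpha_slow,
                 reset_inner = isTRUE(reset_inner)),
            class = "optimizer_config")
}

.default_configs <- function(name, cfg = NULL) {
  base <- switch(name,
    sgd = optimizer_config(lr = 0.001),
    rmsprop = optimizer_config(lr = 0.001, gamma = 0.9),
    adam = optimizer_config(lr = 0.001),
    radam = optimizer_config(lr = 1e-4),
    lookahead = optimizer_config(lr = 0.001, k = 5, alpha_slow = 0.5),
    `r-lookahead` = optimizer_config(lr = 0.001, k = 5, alpha_slow = 0.5),
    stop("unknown optimizer: ", name, call. = FALSE)
  )
  if (!is.null(cfg)) base[names(cfg)] <- cfg
  do.call(optimizer_config, base)
}

#' Construct an optimizer by name
#'
#' Returns a stateful optimizer object advanced by [optimizer_step()].
#' Available kinds: `"sgd"`, `"rmsprop"`, `"adam"`, `"radam"`,
#' `"lookahead"` (slow/fast weights around an inner SGD, the classic
#' form) and `"r-lookahead"` (Lookahead whose fast-weight inner optimizer
#' is RAdam). Defaults follow the reference settings (see
#' [optimizer_config()]).
#'
#' @param name Optimizer kind.
#' @param cfg Optional [optimizer_config()] or named list of overrides.
#' @param inner For the Lookahead wrappers: name of the inner fast-weight
#'   optimizer (default `"sgd"` for `lookahead`, `"radam"` for
#'   `r-lookahead`).
#' @return A `cp_optimizer` object.
#' @examples
#' opt <- make_optimizer("r-lookahead")
#' @export
make_optimizer <- function(name, cfg = NULL, inner = NULL) {
  name <- match.arg(name, c("sgd", "rmsprop", "adam", "radam",
                            "lookahead", "r-lookahead"))
  cfg <- .default_configs(name, cfg)
  if (name %in% c("lookahead", "r-lookahead")) {
    if (is.null(inner)) inner <- if (name == "r-lookahead") "radam" else "sgd"
    inner_opt <- make_optimizer(inner, cfg = cfg)
    obj <- list(kind = "lookahead", name = name, cfg = cfg,
                inner = inner_opt, slow = NULL, i = 0L)
  } else {
    obj <- list(kind = name, name = name, cfg = cfg, state = NULL)
  }
  class(obj) <- "cp_optimizer"
  obj
}

#' Lookahead wrapped around RAdam ("R-Lookahead")
#'
#' Convenience constructor for the headline optimizer: `k` RAdam fast steps
#' per round, slow weights moved a fraction `alpha_slow` toward the fast
#' result, fast weights reset to the new slow weights.
#'
#' @inheritParams make_optimizer
#' @return A `cp_optimizer`.
#' @export
make_r_lookahead <- function(cfg = NULL) {
  make_optimizer("r-lookahead", cfg = cfg)
}

.zeros_like <- function(params) lapply(params, function(p) p * 0)

# One update for the non-wrapped kinds; params/grads are flat named lists
# of conformable arrays.
.step_flat <- function(opt, params, grads) {
  cfg <- opt$cfg
  if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient", call. = FALSE)
  }
  if (is.null(opt$state)) {
    opt$state <- list(m = .zeros_like(params), v = .zeros_like(params),
                      t = 0L)
  }
  st <- opt$state
  st$t <- st$t + 1L
  t <- st$t
  upd <- params
  if (opt$kind == "sgd") {
    for (nm in names(params)) upd[[nm]] <- params[[nm]] - cfg$lr * grads[[nm]]
  } else if (opt$kind == "rmsprop") {
    for (nm in names(params)) {
      st$v[[nm]] <- cfg$gamma * st$v[[nm]] + (1 - cfg$gamma) * grads[[nm]]^2
      upd[[nm]] <- params[[nm]] -
        cfg$lr * grads[[nm]] / (sqrt(st$v[[nm]]) + cfg$eps)
    }
  } else if (opt$kind == "adam") {
    for (nm in names(params)) {
      st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
      st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
      mhat <- st$m[[nm]] / (1 - cfg$beta1^t)
      vhat <- st$v[[nm]] / (1 - cfg$beta2^t)
      upd[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
    }
  } else if (opt$kind == "radam") {
    rho_inf <- 2 / (1 - cfg$beta2) - 1
    rho_t <- rho_inf - 2 * t * cfg$beta2^t / (1 - cfg$beta2^t)
    rectified <- rho_t > 4
    r_t <- if (rectified) {
      sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
             ((rho_inf - 4) * (rho_inf - 2) * rho_t))
    } else {
      NA_real_
    }
    for (nm in names(params)) {
      st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
      st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
      mhat <- st$m[[nm]] / (1 - cfg$beta1^t)
      if (rectified) {
        vhat <- st$v[[nm]] / (1 - cfg$beta2^t)
        upd[[nm]] <- params[[nm]] -
          cfg$lr * r_t * mhat / (sqrt(vhat) + cfg$eps)
      } else {
        # variance of the adaptive rate is untrustworthy this early:
        # fall back to plain (bias-corrected) momentum
        upd[[nm]] <- params[[nm]] - cfg$lr * mhat
      }
    }
    st$rho_t <- rho_t
    st$r_t <- r_t
  }
  opt$state <- st
  list(opt = opt, params = upd)
}

#' Advance an optimizer by one gradient step
#'
#' For the plain kinds, applies one canonical update. For the Lookahead
#' wrappers, applies one inner fast-weight step; every `k`-th call
#' completes a round: the slow weights move to
#' `(1 - alpha_slow) * slow + alpha_slow * fast` and the fast weights are
#' reset to them.
#'
#' @param opt A `cp_optimizer` from [make_optimizer()].
#' @param params Flat named list of parameter arrays.
#' @param grads Matching named list of gradients.
#' @return List with updated `opt` and `params`.
#' @export
optimizer_step <- function(opt, params, grads) {
  stopifnot(inherits(opt, "cp_optimizer"))
  if (!identical(names(params), names(grads))) {
    stop("parameter/gradient names do not match", call. = FALSE)
  }
  if (opt$kind != "lookahead") {
    out <- .step_flat(opt, params, grads)
    return(out)
  }
  if (is.null(opt$slow)) opt$slow <- params
  inner_out <- optimizer_step(opt$inner, params, grads)
  opt$inner <- inner_out$opt
  params <- inner_out$params
  opt$i <- opt$i + 1L
  if (opt$i >= opt$cfg$k) {
    a <- opt$cfg$alpha_slow
    for (nm in names(params)) {
      opt$slow[[nm]] <- (1 - a) * opt$slow[[nm]] + a * params[[nm]]
      params[[nm]] <- opt$slow[[nm]]
    }
    opt$i <- 0L
    if (opt$cfg$reset_inner) opt$inner$state <- NULL
  }
  list(opt = opt, params = params)
}

#' Run one full Lookahead round
#'
#' Executes `k` inner fast-weight steps from the current slow weights on
#' the supplied mini-batches, then performs the slow-weight interpolation.
#' `grad_fn(params, batch)` must return gradients shaped like `params`.
#'
#' @param opt A Lookahead-kind `cp_optimizer`.
#' @param params Flat named parameter list (the slow weights).
#' @param grad_fn Function of `(params, batch)` returning gradients.
#' @param batches List of at least `k` mini-batches.
#' @return List with updated `opt` and `params`.
#' @export
lookahead_round <- function(opt, params, grad_fn, batches) {
  stopifnot(opt$kind == "lookahead")
  if (length(batches) < opt$cfg$k) {
    stop("need at least k batches for one round", call. = FALSE)
  }
  for (b in seq_len(opt$cfg$k)) {
    out <- optimizer_step(opt, params, grad_fn(params, batches[[b]]))
    opt <- out$opt
    params <- out$params
  }
  list(opt = opt, params = params)
}

#' RAdam rectification diagnostics
#'
#' Evaluates the simple-moving-average length `rho_t = rho_inf -
#' 2 t beta2^t / (1 - beta2^t)` (with `rho_inf = 2/(1-beta2) - 1`) and the
#' rectification factor `r_t` for a range of steps — the quantities that
#' decide whether RAdam takes its variance-rectified adaptive branch
#' (`rho_t > 4`) or falls back to plain momentum.
#'
#' @param beta2 Second-moment decay rate.
#' @param t_max Number of steps to tabulate.
#' @return Tibble with `t`, `rho_t`, `rectified`, `r_t` (NA while the
#'   momentum branch is active).
#' @export
radam_schedule <- function(beta2 = 0.999, t_max = 10) {
  rho_inf <- 2 / (1 - beta2) - 1
  t <- seq_len(t_max)
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  rectified <- rho_t > 4
  r_t <- rep(NA_real_, t_max)
  r_t[rectified] <- sqrt(
    ((rho_t[rectified] - 4) * (rho_t[rectified] - 2) * rho_inf) /
      ((rho_inf - 4) * (rho_inf - 2) * rho_t[rectified])
  )
  tibble::tibble(t = t, rho_t = rho_t, rectified = rectified, r_t = r_t)
}

#' Serialise / restore optimizer state
#'
#' Round-trips a `cp_optimizer` (including any Lookahead slow weights and
#' nested inner state) through a plain JSON file so that a training
#' trajectory can be resumed bit-identically.
#'
#' @param opt A `cp_optimizer`.
#' @param path File path.
#' @return `save_optimizer()` returns `path` invisibly; `load_optimizer()`
#'   the restored object.
#' @export
save_optimizer <- function(opt, path) {
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(.opt_to_list(opt), path, digits = I(17),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_optimizer
#' @export
load_optimizer <- function(path) {
  .opt_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

.array_to_list <- function(a) list(data = as.numeric(a), dim = dim(a))
.array_from_list <- function(l) {
  if (is.null(l$dim) || length(l$dim) == 0) l$data else
    array(l$data, dim = l$dim)
}

.opt_to_list <- function(opt) {
  out <- list(kind = opt$kind, name = opt$name, cfg = unclass(opt$cfg))
  pack_state <- function(st) {
    if (is.null(st)) return(NULL)
    list(m = lapply(st$m, .array_to_list), v = lapply(st$v, .array_to_list),
         t = st$t)
  }
  if (opt$kind == "lookahead") {
    out$i <- opt$i
    out$slow <- if (is.null(opt$slow)) NULL else
      lapply(opt$slow, .array_to_list)
    out$inner <- .opt_to_list(opt$inner)
  } else {
    out$state <- pack_state(opt$state)
  }
  out
}

.opt_from_list <- function(l) {
  cfg <- do.call(optimizer_config,
                 l$cfg[c("lr", "beta1", "beta2", "eps", "gamma", "k",
                         "alpha_slow", "reset_inner")])
  unpack_state <- function(st) {
    if (is.null(st)) return(NULL)
    list(m = lapply(st$m, .array_from_list),
         v = lapply(st$v, .array_from_list), t = as.integer(st$t))
  }
  if (l$kind == "lookahead") {
    obj <- list(kind = "lookahead", name = l$name, cfg = cfg,
                inner = .opt_from_list(l$inner),
                slow = if (is.null(l$slow)) NULL else
                  lapply(l$slow, .array_from_list),
                i = as.integer(l$i))
  } else {
    obj <- list(kind = l$kind, name = l$name, cfg = cfg,
                state = unpack_state(l$state))
  }
  class(obj) <- "cp_optimizer"
  obj
}
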