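#' Architecture specification of a deep Cox network
#'
#' The default architecture has three hidden layers of 50, 20 and 10 rectified
#' linear units feeding a single linear output, the log relative hazard
#' `h(x)`. An empty `hidden_dims` gives the degenerate linear Cox model
#' `h(x) = beta'x`.
#'
#' @param input_dim Number of input features (>= 1).
#' @param hidden_dims Integer vector of hidden layer widths, default
#'   `c(50, 20, 10)`.
#' @param activation Hidden activation; only `"relu"` is supported.
#' @param dropout Dropout proportion applied to hidden activations during
#'   training, default 0.
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_dim, hidden_dims = c(50L, 20L, 10L),
                         activation = "relu", dropout = 0) {
  if (input_dim < 1L) stop("input_dim must be >= 1")
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) > 0L && any(hidden_dims < 1L)) {
    stop("all hidden dimensions must be >= 1")
  }
  activation <- match.arg(activation, "relu")
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim), hidden_dims = hidden_dims,
                 activation = activation, dropout = dropout),
            class = "network_spec")
}

#' Training configuration
#'
#' @param learning_rate Step size; the canonical search grid is
#'   `c(1e-3, 1e-4, 1e-5)`.
#' @param epochs Number of full-batch passes (>= 0; 0 leaves weights
#'   untouched).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param l2_penalty Weight-decay coefficient on weights (not biases),
#'   default 0.
#' @param seed Integer seed controlling any training-time randomness.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-3, epochs = 500L,
                            optimizer = c("adam", "sgd"), l2_penalty = 0,
                            seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, epochs >= 0, l2_penalty >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, l2_penalty = l2_penalty,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Default learning-rate grid
#' @param learning_rates Learning rates to span, default
#'   `c(1e-3, 1e-4, 1e-5)`.
#' @param ... Further arguments passed to [training_config()] for every grid
#'   point.
#' @return List of `training_config` objects.
#' @export
default_grid <- function(learning_rates = c(1e-3, 1e-4, 1e-5), ...) {
  lapply(learning_rates, function(lr) training_config(learning_rate = lr, ...))
}

#' Initialize a Cox network
#'
#' Weights are drawn from seeded zero-mean normals scaled by
#' `sqrt(2/fan_in)` (the usual variance-preserving scheme for rectified
#' linear units); biases start at zero.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed; the same seed reproduces identical weights.
#' @return A `cox_network`: list with `spec`, `weights` (`W`, `b` per layer)
#'   and `init_seed`.
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- c(spec$input_dim, spec$hidden_dims, 1L)
  set.seed(seed)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(spec = spec, weights = list(W = W, b = b),
                 init_seed = as.integer(seed)),
            class = "cox_network")
}

# forward pass keeping pre-activations and activations for backprop;
# drop_masks: optional list of inverted-dropout masks per hidden layer
.forward <- function(net, x, drop_masks = NULL) {
  W <- net$weights$W; b <- net$weights$b
  L <- length(W)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  a[[1L]] <- x
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      z[[l]] <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
      act <- pmax(z[[l]], 0)
      if (!is.null(drop_masks)) act <- act * drop_masks[[l]]
      a[[l + 1L]] <- act
    }
  }
  z[[L]] <- sweep(a[[L]] %*% W[[L]], 2L, b[[L]], "+")
  list(h = drop(z[[L]]), a = a, z = z)
}

#' Risk scores of a Cox network
#'
#' Evaluates the network's log relative hazard `h(x)` for each sample; the
#' proportional-hazards model is `lambda(t|x) = lambda0(t) exp(h(x))`, so a
#' higher score means a higher predicted hazard.
#'
#' @param net A `cox_network`.
#' @param x Numeric samples x input_dim matrix.
#' @return Named numeric vector of scores (names = rownames of `x`, if any).
#' @export
forward_risk <- function(net, x) {
  stopifnot(inherits(net, "cox_network"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$spec$input_dim) {
    stop("feature count ", ncol(x), " does not match network input_dim ",
         net$spec$input_dim)
  }
  h <- .forward(net, x)$h
  if (!all(is.finite(h))) stop("non-finite risk scores")
  stats::setNames(as.numeric(h), rownames(x))
}

# negative log partial likelihood and its gradient w.r.t. the scores.
# Breslow handling of ties: the risk set of an event at time T_i is
# {j : T_j >= T_i}, identical for tied event times. log-sum-exp is computed
# with max subtraction.
.cox_loss_grad <- function(scores, time, event, normalize = FALSE) {
  n <- length(scores)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]; hs <- scores[ord]; es <- event[ord]
  M <- max(hs)
  w <- exp(hs - M)
  cw <- cumsum(w)
  r <- rle(ts)
  lt <- rep.int(cumsum(r$lengths), r$lengths)  # last index of each tie group
  idx <- which(es == 1L)
  denom_log <- M + log(cw[lt[idx]])
  loss <- -sum(hs[idx] - denom_log)
  acc <- numeric(n)
  if (length(idx) > 0L) {
    g <- lt[idx]
    rs <- rowsum(1 / cw[g], group = g)
    acc[as.integer(rownames(rs))] <- rs[, 1L]
  }
  revcum <- rev(cumsum(rev(acc)))
  grad_sorted <- w * revcum - es
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  if (normalize && length(idx) > 0L) {
    loss <- loss / length(idx)
    grad <- grad / length(idx)
  }
  list(loss = loss, grad = grad)
}

#' Negative log partial likelihood of risk scores
#'
#' The training loss of the Cox network: minus the sum, over uncensored
#' patients i, of `h_i - log(sum over the risk set of exp(h_j))`, where the
#' risk set holds every patient with observed time at least `T_i` (Breslow
#' convention for ties). The log-sum-exp is computed with max subtraction for
#' numerical stability. The loss depends only on differences between scores.
#'
#' @param scores Numeric vector of risk scores, aligned with `s`.
#' @param s A `survival_table` (or list with `time` and `event`).
#' @param normalize Divide by the number of events? Default `FALSE`.
#' @param allow_no_events If no patient is uncensored, return 0 instead of an
#'   error. Default `FALSE`.
#' @return The loss, a single number >= 0.
#' @export
cox_loss <- function(scores, s, normalize = FALSE, allow_no_events = FALSE) {
  if (length(scores) != length(s$time)) {
    stop("scores and survival table have different lengths")
  }
  if (sum(s$event) == 0L) {
    if (allow_no_events) return(0)
    stop("no uncensored patients: partial likelihood undefined")
  }
  .cox_loss_grad(scores, s$time, s$event, normalize = normalize)$loss
}

# backprop of dL/dh through the network; returns weight/bias gradients
.backward <- function(net, fwd, dh, drop_masks = NULL) {
  W <- net$weights$W
  L <- length(W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(dh, ncol = 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(W[[l]])) * (fwd$z[[l - 1L]] > 0)
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[l - 1L]]
    }
  }
  list(W = gW, b = gb)
}

# full-batch training over a list of strata (each: x, time, event).
# The loss is the sum of per-stratum partial likelihoods: risk sets never
# cross stratum boundaries.
.train_strata <- function(net, strata, cfg, freeze_layers = 0L) {
  stopifnot(inherits(net, "cox_network"), inherits(cfg, "training_config"))
  for (st in strata) {
    if (ncol(st$x) != net$spec$input_dim) {
      stop("feature count ", ncol(st$x), " does not match network input_dim ",
           net$spec$input_dim)
    }
    if (sum(st$event) == 0L) stop("a training stratum has no events")
  }
  L <- length(net$weights$W)
  n_hidden <- length(net$spec$hidden_dims)
  if (freeze_layers > n_hidden) {
    stop("cannot freeze ", freeze_layers, " layers: network has ", n_hidden,
         " hidden layers")
  }
  if (cfg$epochs == 0L) {
    net$loss_trace <- numeric(0)
    return(net)
  }
  set.seed(cfg$seed)
  use_dropout <- net$spec$dropout > 0
  # Adam state
  mW <- lapply(net$weights$W, function(w) w * 0)
  vW <- mW
  mb <- lapply(net$weights$b, function(b) b * 0)
  vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    gW <- lapply(net$weights$W, function(w) w * 0)
    gb <- lapply(net$weights$b, function(b) b * 0)
    loss <- 0
    for (st in strata) {
      masks <- NULL
      if (use_dropout && n_hidden > 0L) {
        keep <- 1 - net$spec$dropout
        masks <- lapply(net$spec$hidden_dims, function(d) {
          matrix(stats::rbinom(nrow(st$x) * d, 1L, keep) / keep,
                 nrow = nrow(st$x), ncol = d)
        })
      }
      fwd <- .forward(net, st$x, masks)
      lg <- .cox_loss_grad(fwd$h, st$time, st$event)
      loss <- loss + lg$loss
      bk <- .backward(net, fwd, lg$grad, masks)
      for (l in seq_len(L)) {
        gW[[l]] <- gW[[l]] + bk$W[[l]]
        gb[[l]] <- gb[[l]] + bk$b[[l]]
      }
    }
    if (cfg$l2_penalty > 0) {
      loss <- loss + cfg$l2_penalty *
        sum(vapply(net$weights$W, function(w) sum(w^2), numeric(1L)))
      for (l in seq_len(L)) {
        gW[[l]] <- gW[[l]] + 2 * cfg$l2_penalty * net$weights$W[[l]]
      }
    }
    if (!is.finite(loss)) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate ", cfg$learning_rate, "): aborting")
    }
    trace[epoch] <- loss
    upd <- seq_len(L)
    if (freeze_layers > 0L) upd <- upd[upd > freeze_layers]
    for (l in upd) {
      if (cfg$optimizer == "adam") {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mW_hat <- mW[[l]] / (1 - beta1^epoch)
        vW_hat <- vW[[l]] / (1 - beta2^epoch)
        mb_hat <- mb[[l]] / (1 - beta1^epoch)
        vb_hat <- vb[[l]] / (1 - beta2^epoch)
        net$weights$W[[l]] <- net$weights$W[[l]] -
          cfg$learning_rate * mW_hat / (sqrt(vW_hat) + eps)
        net$weights$b[[l]] <- net$weights$b[[l]] -
          cfg$learning_rate * mb_hat / (sqrt(vb_hat) + eps)
      } else {
        net$weights$W[[l]] <- net$weights$W[[l]] - cfg$learning_rate * gW[[l]]
        net$weights$b[[l]] <- net$weights$b[[l]] - cfg$learning_rate * gb[[l]]
      }
    }
  }
  net$loss_trace <- trace
  net
}

#' Train a Cox network on one cohort
#'
#' Full-batch gradient minimization of [cox_loss()] with the Adam optimizer.
#' Full batches keep the partial likelihood exact: the loss couples samples
#' through shared risk sets, so mini-batching would change the objective.
#' Training is deterministic given the configuration seed.
#'
#' @param net A `cox_network` (e.g. from [init_network()]).
#' @param x Numeric samples x input_dim feature matrix.
#' @param s A `survival_table` aligned with the rows of `x`.
#' @param cfg A `training_config`.
#' @return The trained network, with the per-epoch loss in `$loss_trace`.
#' @export
train_network <- function(net, x, s, cfg) {
  .train_strata(net, list(list(x = x, time = s$time, event = s$event)), cfg)
}

# fold ids stratified by event status: events and censored samples are dealt
# round-robin so every fold gets its share of events
.stratified_folds <- function(event, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (grp in list(which(event == 1L), which(event == 0L))) {
    if (length(grp) > 0L) {
      fold[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
    }
  }
  fold
}

#' Cross-validate training configurations
#'
#' Evaluates every configuration in `grid` by k-fold cross-validation (folds
#' stratified by event status so each fold contains events) and returns the
#' configuration with the largest mean held-out concordance index. Exact ties
#' are broken toward the larger learning rate, which converges in fewer
#' epochs.
#'
#' @param x Samples x features matrix.
#' @param s Aligned `survival_table`.
#' @param spec A `network_spec`.
#' @param grid List of `training_config` objects (see [default_grid()]).
#' @param n_folds Number of folds, default 10.
#' @param seed Seed for the fold assignment.
#' @return List with `best` (the selected config) and `summary` (data frame
#'   of learning rate, mean and sd of held-out C per config).
#' @export
cross_validate_hyperparams <- function(x, s, spec, grid, n_folds = 10L,
                                       seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (sum(s$event) < n_folds) {
    stop("fewer events (", sum(s$event), ") than folds (", n_folds,
         "): reduce n_folds so every fold contains events")
  }
  fold <- .stratified_folds(s$event, n_folds, seed)
  lrs <- vapply(grid, function(g) g$learning_rate, numeric(1L))
  mean_c <- numeric(length(grid))
  sd_c <- numeric(length(grid))
  fold_c_by_cfg <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    cfg <- grid[[gi]]
    cs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      net <- init_network(spec, seed = cfg$seed)
      net <- train_network(net, x[tr, , drop = FALSE],
                           s[tr, , drop = FALSE], cfg)
      sc <- forward_risk(net, x[!tr, , drop = FALSE])
      cs[f] <- concordance_index(sc, s[!tr, , drop = FALSE])
    }
    fold_c_by_cfg[[gi]] <- cs
    mean_c[gi] <- mean(cs)
    sd_c[gi] <- stats::sd(cs)
  }
  # argmax; exact ties resolved toward the larger learning rate
  best <- order(-mean_c, -lrs)[1L]
  list(best = grid[[best]],
       summary = data.frame(learning_rate = lrs, mean_c = mean_c, sd_c = sd_c),
       per_fold_c = fold_c_by_cfg)
}

#' Save / load a Cox network checkpoint
#'
#' The checkpoint is a single JSON file holding the architecture, all weights
#' and the seeds, tagged with a format version. Loading a checkpoint with a
#' different version tag fails loudly.
#'
#' @param net A `cox_network`.
#' @param path Checkpoint file.
#' @return `path` invisibly for `save_network`; the restored `cox_network`
#'   for `load_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "cox_network"))
  payload <- list(
    format = "coxnet-1",
    spec = unclass(net$spec),
    init_seed = net$init_seed,
    W = lapply(net$weights$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = net$weights$b)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "coxnet-1")) {
    stop("unsupported checkpoint format: ",
         if (is.null(p$format)) "<missing>" else p$format)
  }
  spec <- network_spec(p$spec$input_dim,
                       vapply(p$spec$hidden_dims, as.integer, integer(1L)),
                       p$spec$activation, p$spec$dropout)
  W <- lapply(p$W, function(entry) {
    matrix(vapply(entry$data, as.numeric, numeric(1L)),
           nrow = as.integer(entry$dim[[1L]]))
  })
  b <- lapply(p$b, function(v) vapply(v, as.numeric, numeric(1L)))
  structure(list(spec = spec, weights = list(W = W, b = b),
                 init_seed = as.integer(p$init_seed)),
            class = "cox_network")
}
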