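test_that("init_network builds the default 50-20-10 stack reproducibly", {
  net <- init_network(network_spec(100), seed = 3)
  dims <- lapply(net$weights$W, dim)
  expect_identical(dims, list(c(100L, 50L), c(50L, 20L), c(20L, 10L),
                              c(10L, 1L)))
  expect_identical(lengths(net$weights$b), c(50L, 20L, 10L, 1L))
  net2 <- init_network(network_spec(100), seed = 3)
  expect_identical(net$weights, net2$weights)
  # empty hidden stack degenerates to the linear Cox model
  lin <- init_network(network_spec(4, hidden_dims = integer(0)), seed = 1)
  expect_length(lin$weights$W, 1L)
  expect_identical(dim(lin$weights$W[[1]]), c(4L, 1L))
  expect_error(network_spec(0), "input_dim")
})

test_that("forward_risk is the relu composition of the layers", {
  # hand-set weights on a 2-feature, one-hidden-layer net
  net <- init_network(network_spec(2, hidden_dims = 2L), seed = 1)
  net$weights$W[[1]] <- matrix(c(1, -1, 2, 0), 2, 2)
  net$weights$b[[1]] <- c(0.5, -1)
  net$weights$W[[2]] <- matrix(c(1, -2), 2, 1)
  net$weights$b[[2]] <- 0.25
  x <- rbind(c(1, 2), c(-3, 0.5))
  hidden <- pmax(x %*% net$weights$W[[1]] +
                   rep(c(0.5, -1), each = 2), 0)
  expected <- drop(hidden %*% c(1, -2)) + 0.25
  expect_equal(unname(forward_risk(net, x)), expected)

  # zero map
  net0 <- net
  net0$weights$W <- lapply(net0$weights$W, function(w) w * 0)
  net0$weights$b <- lapply(net0$weights$b, function(b) b * 0)
  expect_equal(unname(forward_risk(net0, x)), c(0, 0))

  # permutation equivariance and dimension check
  net3 <- init_network(network_spec(5, hidden_dims = c(4L, 3L)), seed = 2)
  xx <- matrix(rnorm(40), ncol = 5)
  perm <- sample(8)
  expect_equal(unname(forward_risk(net3, xx[perm, ])),
               unname(forward_risk(net3, xx))[perm])
  expect_error(forward_risk(net3, xx[, 1:3]), "input_dim")
})

test_that("cox_loss matches analytic values and is shift invariant", {
  expect_equal(cox_loss(0.7, make_surv(5, 1L)), 0)
  expect_equal(cox_loss(c(1.3, 1.3), make_surv(c(2, 5), c(1L, 1L))), log(2))
  s <- make_surv(c(3, 1, 4, 2, 6, 5), c(1L, 0L, 1L, 1L, 0L, 1L))
  sc <- c(0.3, -1, 2, 0.1, -0.4, 1.2)
  expect_equal(cox_loss(sc, s), cox_loss(sc + 100, s), tolerance = 1e-9)
  expect_error(cox_loss(c(1, 2), make_surv(c(1, 2), c(0L, 0L))),
               "no uncensored")
  expect_equal(cox_loss(c(1, 2), make_surv(c(1, 2), c(0L, 0L)),
                        allow_no_events = TRUE), 0)
})

test_that("cox_loss equals the brute-force partial likelihood on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    inst <- random_instance(sample(3:20, 1))
    s <- make_surv(inst$time, inst$event)
    expect_equal(cox_loss(inst$scores, s),
                 brute_cox_loss(inst$scores, inst$time, inst$event),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  for (rep in 1:10) {
    inst <- random_instance(sample(4:12, 1))
    lg <- coxtransfer:::.cox_loss_grad(inst$scores, inst$time, inst$event)
    ref <- num_grad(function(h) {
      brute_cox_loss(h, inst$time, inst$event)
    }, inst$scores)
    expect_equal(lg$grad, ref, tolerance = 1e-5)
  }
  # backprop: gradient w.r.t. every weight of a small network, with biases
  # jittered off zero so no pre-activation sits exactly on the relu kink
  net <- init_network(network_spec(3, hidden_dims = c(4L, 2L)), seed = 5)
  net$weights$b <- lapply(net$weights$b, function(b) b + 0.1 * seq_along(b))
  x <- matrix(rnorm(18), ncol = 3)
  s <- make_surv(c(1, 3, 2, 5, 4, 6), c(1L, 1L, 0L, 1L, 0L, 1L))
  fwd <- coxtransfer:::.forward(net, x)
  lg <- coxtransfer:::.cox_loss_grad(fwd$h, s$time, s$event)
  bk <- coxtransfer:::.backward(net, fwd, lg$grad)
  loss_at <- function(net) {
    cox_loss(unname(forward_risk(net, x)), s)
  }
  for (l in seq_along(net$weights$W)) {
    w <- net$weights$W[[l]]
    idx <- cbind(c(1, nrow(w)), c(1, ncol(w)))
    for (r in seq_len(nrow(idx))) {
      ref <- num_grad(function(v) {
        n2 <- net; n2$weights$W[[l]][idx[r, 1], idx[r, 2]] <- v
        loss_at(n2)
      }, w[idx[r, 1], idx[r, 2]])
      expect_equal(bk$W[[l]][idx[r, 1], idx[r, 2]], ref, tolerance = 1e-5)
    }
    refb <- num_grad(function(v) {
      n2 <- net; n2$weights$b[[l]][1] <- v
      loss_at(n2)
    }, net$weights$b[[l]][1])
    expect_equal(bk$b[[l]][1], refb, tolerance = 1e-5)
  }
})

test_that("training learns a strongly separable risk and is deterministic", {
  set.seed(21)
  n <- 200
  x <- matrix(rnorm(n * 4), ncol = 4)
  # low-noise accelerated-failure construction: the generating feature itself
  # has concordance > 0.95, so a well-trained net must exceed 0.9
  time <- exp(-2 * x[, 1] + 0.3 * rnorm(n))
  s <- make_surv(time, rep(1L, n))
  expect_gt(concordance_index(x[, 1], s), 0.95)
  spec <- network_spec(4, hidden_dims = c(8L, 4L))
  cfg <- training_config(learning_rate = 1e-2, epochs = 300, seed = 2)
  net <- train_network(init_network(spec, seed = 2), x, s, cfg)
  ci <- concordance_index(forward_risk(net, x), s)
  expect_gt(ci, 0.9)
  # loss decreases overall
  expect_lt(tail(net$loss_trace, 1), net$loss_trace[1])
  # epochs = 0 leaves weights untouched
  net0 <- init_network(spec, seed = 2)
  same <- train_network(net0, x, s, training_config(epochs = 0, seed = 2))
  expect_identical(same$weights, net0$weights)
  # determinism
  net2 <- train_network(init_network(spec, seed = 2), x, s, cfg)
  expect_identical(net$weights, net2$weights)
})

test_that("training aborts on divergence instead of silently returning garbage", {
  set.seed(4)
  x <- matrix(rnorm(30 * 3) * 1e4, ncol = 3)
  s <- make_surv(rexp(30) + 0.1, rep(1L, 30))
  cfg <- training_config(learning_rate = 1e8, epochs = 50, optimizer = "sgd",
                         seed = 1)
  expect_error(train_network(init_network(network_spec(3), seed = 1), x, s, cfg),
               "non-finite")
})

test_that("cross-validation scores the grid and breaks ties toward larger rates", {
  set.seed(8)
  n <- 80
  x <- matrix(rnorm(n * 3), ncol = 3)
  time <- rexp(n, rate = 0.2 * exp(1.5 * x[, 1]))
  s <- make_surv(pmax(time, 1e-8), rbinom(n, 1, 0.8))
  spec <- network_spec(3, hidden_dims = c(4L))
  grid <- default_grid(epochs = 60, seed = 3)
  res <- cross_validate_hyperparams(x, s, spec, grid, n_folds = 4, seed = 3)
  expect_equal(nrow(res$summary), 3L)
  expect_true(res$best$learning_rate %in% res$summary$learning_rate)
  expect_equal(res$summary$mean_c[res$summary$learning_rate ==
                                    res$best$learning_rate],
               max(res$summary$mean_c))
  # only a sane learning rate separates this data: tiny rates barely move
  expect_equal(res$best$learning_rate, 1e-3)
  # single-config grid returned unchanged
  one <- cross_validate_hyperparams(x, s, spec, grid[1], n_folds = 4, seed = 3)
  expect_identical(one$best, grid[[1]])
  # more folds than events errors with advice
  few <- make_surv(c(1, 2, 3, 4, 5, 6), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_error(cross_validate_hyperparams(matrix(rnorm(18), ncol = 3), few,
                                          spec, grid, n_folds = 4),
               "folds")
})

test_that("checkpoints round-trip and reject foreign formats", {
  net <- init_network(network_spec(6, hidden_dims = c(5L, 3L)), seed = 11)
  p <- tempfile(fileext = ".json")
  save_network(net, p)
  back <- load_network(p)
  x <- matrix(rnorm(24), ncol = 6)
  expect_equal(forward_risk(back, x), forward_risk(net, x), tolerance = 1e-12)
  expect_identical(back$spec$hidden_dims, net$spec$hidden_dims)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "coxnet-99"), bad, auto_unbox = TRUE)
  expect_error(load_network(bad), "format")
})
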