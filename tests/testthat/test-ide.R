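test_that("weighted averages match hand-evaluated sums", {
  expect_equal(weighted_average(c(1, 0, 1, 0), 1), 0.5)
  expect_equal(weighted_average(rep(0.7, 5), 0.3), 0.7)
  expect_equal(weighted_average(c(1, 0), 0.5), 1 / 3)
  # array form
  v <- list(array(1, c(2, 1)), array(0, c(2, 1)))
  expect_equal(weighted_average(v, 0.5), array(1 / 3, c(2, 1)))
  expect_error(weighted_average(c(1, 0), 0), "positive")
})

test_that("the clip nonlinearity is idempotent and bounded", {
  x <- array(seq(-2, 3, length.out = 24), c(2, 3, 4))
  y <- eesnn:::clip01(x)
  expect_true(all(y >= 0 & y <= 1))
  expect_identical(eesnn:::clip01(y), y)
  expect_equal(dim(y), dim(x))
})

test_that("fixed-point map reproduces hand-solved cases", {
  # constant map: zero weights, bias 0.3 -> g(alpha) = 0.3 everywhere
  cfg <- scalar_config(H = 1, lambda = 1)
  w <- scalar_weights(cfg, F1 = 0, W1 = 0, b = 0.3)
  xh <- array(0, c(1, 1, 1))
  for (a in c(0, 0.4, 1)) {
    expect_equal(as.numeric(fixed_point_map(array(a, c(1, 1, 1)), xh, w,
                                            cfg)), 0.3)
  }
  eq <- solve_equilibrium(xh, w, cfg)
  expect_equal(as.numeric(eq$alpha[[1]]), 0.3, tolerance = 1e-5)
  expect_true(eq$converged)
  # undamped iteration lands on the constant map's fixed point exactly
  eq1 <- solve_equilibrium(xh, w, cfg, damping = 1)
  expect_identical(as.numeric(eq1$alpha[[1]]), 0.3)
  expect_lte(eq1$iterations, 2)

  # scalar contraction alpha = 0.5 alpha + 0.25 -> alpha* = 0.5
  w2 <- scalar_weights(cfg, F1 = 0, W1 = 0.5, b = 0.25)
  eq2 <- solve_equilibrium(xh, w2, cfg, tol = 1e-10, max_iter = 500)
  expect_equal(as.numeric(eq2$alpha[[1]]), 0.5, tolerance = 1e-8)

  # saturation: affine value 2 clips to 1
  w3 <- scalar_weights(cfg, F1 = 0, W1 = 0, b = 2)
  expect_equal(as.numeric(fixed_point_map(array(0.2, c(1, 1, 1)), xh, w3,
                                          cfg)), 1)
})

test_that("equilibrium rates always stay inside [0, 1]", {
  for (seed in 1:10) {
    cfg <- tiny_config(H = 2, ch = 3, C = 2, S = 2, kernel = c(1, 1),
                       lambda = 1, seed = seed)
    w <- eesnn_init_weights(cfg)
    w$b[[1]][] <- rnorm(3)
    xh <- array(rnorm(4), c(1, 2, 2))
    eq <- solve_equilibrium(xh, w, cfg, max_iter = 50)
    for (l in 1:2) {
      expect_true(all(eq$alpha[[l]] >= 0 & eq$alpha[[l]] <= 1))
    }
  }
})

test_that("contractive nets converge with certificate", {
  set.seed(20)
  for (seed in 1:20) {
    cfg <- tiny_config(H = 2, ch = 3, C = 2, S = 2, kernel = c(1, 1),
                       lambda = 1, seed = seed)
    w <- contractive_weights(cfg, gamma = 0.8)
    w$b[[1]][] <- runif(3, 0.2, 0.5)
    w$b[[2]][] <- runif(3, 0.2, 0.5)
    xh <- array(runif(4, 0.1, 0.4), c(1, 2, 2))
    eq <- solve_equilibrium(xh, w, cfg, tol = 1e-8, max_iter = 500)
    expect_true(eq$converged)
  }
})

test_that("simulated average rates approach the solved equilibrium", {
  closer <- 0
  for (seed in 1:25) {
    set.seed(seed)
    cfg <- tiny_config(H = 2, ch = 3, C = 2, S = 2, kernel = c(1, 1),
                       lambda = 1, seed = seed)
    w <- contractive_weights(cfg, gamma = 0.8)
    w$b[[1]][] <- runif(3, 0.3, 0.6)
    w$b[[2]][] <- runif(3, 0.3, 0.6)
    x <- matrix(runif(4, 0.1, 0.5), 2, 2)
    sim <- simulate_rates(x, w, cfg, steps = 64, checkpoints = c(8, 64))
    xh <- array(0, c(1, 2, 2))
    xh[1, , ] <- x
    eq <- solve_equilibrium(xh, w, cfg, tol = 1e-10, max_iter = 1000)
    e8 <- max(abs(sim$checkpoints[["8"]] - eq$alpha[[1]]))
    e64 <- max(abs(sim$checkpoints[["64"]] - eq$alpha[[1]]))
    if (e64 < e8) closer <- closer + 1
  }
  expect_gte(closer, 24)
})

test_that("implicit gradient matches the closed-form scalar fixed point", {
  # f(a) = w a + c with w = 0.5, c = 0.25: a* = 0.5, dL/dw = a*/(1-w) = 1
  cfg <- scalar_config(H = 1, lambda = 1)
  w <- scalar_weights(cfg, F1 = 0, W1 = 0.5, b = 0.25)
  xh <- array(0, c(1, 1, 1))
  eq <- solve_equilibrium(xh, w, cfg, tol = 1e-12, max_iter = 1000)
  ig <- implicit_gradient(array(1, c(1, 1, 1)), eq$alpha[[1]], xh, w, cfg)
  expect_equal(as.numeric(ig$W1), 1, tolerance = 1e-8)
  expect_equal(as.numeric(ig$b[[1]]), 1 / (1 - 0.5), tolerance = 1e-8)

  # w = 0: no recurrence, direct chain rule d(c)/db = 1
  w0 <- scalar_weights(cfg, F1 = 0, W1 = 0, b = 0.25)
  eq0 <- solve_equilibrium(xh, w0, cfg, tol = 1e-12)
  ig0 <- implicit_gradient(array(1, c(1, 1, 1)), eq0$alpha[[1]], xh, w0,
                           cfg)
  expect_equal(as.numeric(ig0$b[[1]]), 1, tolerance = 1e-8)
})

test_that("equilibrium-loss gradients match finite differences", {
  set.seed(7)
  cfg <- tiny_config(H = 2, ch = 2, C = 2, S = 2, kernel = c(1, 1),
                     lambda = 0.9, seed = 5)
  w <- eesnn_init_weights(cfg)
  w$W1 <- w$W1 * 0.3
  w$F[[2]] <- w$F[[2]] * 0.5
  w$b[[1]] <- c(0.4, 0.5)
  w$b[[2]] <- c(0.45, 0.35)
  x <- matrix(runif(4, 0.2, 0.6), 2, 2)
  lossf <- function(w) {
    eesnn:::ide_loss_grads(x, 1, w, cfg, mode = "solve", tol = 1e-13,
                           max_iter = 2000)$loss
  }
  g <- eesnn:::ide_loss_grads(x, 1, w, cfg, mode = "solve", tol = 1e-13,
                              max_iter = 2000)
  paths <- list(list("F", 1), list("F", 2), list("b", 1), list("b", 2),
                "W1", "W0", "b0")
  for (nm in paths) {
    if (is.list(nm)) {
      v <- w[[nm[[1]]]][[nm[[2]]]]
      ga <- g$grads[[nm[[1]]]][[nm[[2]]]]
    } else {
      v <- w[[nm]]
      ga <- g$grads[[nm]]
    }
    for (i in seq_len(min(3, length(v)))) {
      wp <- w
      if (is.list(nm)) {
        fd <- fd_grad1(function(vv) {
          wp[[nm[[1]]]][[nm[[2]]]] <- vv
          lossf(wp)
        }, v, i)
      } else {
        fd <- fd_grad1(function(vv) {
          wp[[nm]] <- vv
          lossf(wp)
        }, v, i)
      }
      expect_equal(ga[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("equilibrium training reduces loss on a separable batch", {
  set.seed(8)
  cfg <- tiny_config(H = 1, ch = 3, C = 2, S = 4, kernel = c(1, 3),
                     lambda = 0.9, steps = 2, seed = 4)
  w <- eesnn_init_weights(cfg)
  make_x <- function(y) {
    matrix(rnorm(8, 0, 0.2), 2, 4) + if (y == 1) 1.2 else 0
  }
  labs <- rep(c(0L, 1L), each = 6)
  batch <- tibble::tibble(data = lapply(labs, make_x), label = labs)
  st <- NULL
  losses <- numeric(60)
  for (i in 1:60) {
    r <- ide_train_step(batch, w, cfg, st, lr = 5e-3, sim_steps = 20)
    w <- r$weights
    st <- r$opt_state
    losses[i] <- r$loss
  }
  expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
  # most steps decrease the loss
  expect_gte(mean(diff(losses) < 0), 0.7)
})

test_that("zero-weight network has ln(2) loss on a balanced batch", {
  cfg <- tiny_config(H = 1, ch = 2, C = 2, S = 2, kernel = c(1, 1),
                     seed = 3)
  w <- eesnn_init_weights(cfg)
  w$F[[1]] <- w$F[[1]] * 0
  w$W1 <- w$W1 * 0
  w$W0 <- w$W0 * 0
  batch <- tibble::tibble(data = list(matrix(1, 2, 2), matrix(-1, 2, 2)),
                          label = c(1L, 0L))
  g1 <- eesnn:::ide_loss_grads(batch$data[[1]], 1, w, cfg, mode = "solve")
  g0 <- eesnn:::ide_loss_grads(batch$data[[2]], 0, w, cfg, mode = "solve")
  expect_equal((g1$loss + g0$loss) / 2, log(2))
})
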