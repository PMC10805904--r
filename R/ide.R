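#' Discounted weighted average of a sequence
#'
#' Computes `sum(lambda^(t-tau) * v[tau]) / sum(lambda^(t-tau))` over
#' `tau = 1..t`. Applied to a spike train this is the weighted-average
#' firing rate whose limit is the network's equilibrium state; applied to
#' the mapped inputs it gives the averaged input the equilibrium is
#' driven by. With `lambda = 1` it reduces to the plain mean.
#'
#' @param v List of numeric arrays (one per step, identical shapes), or a
#'   numeric vector.
#' @param lambda Discount factor (> 0).
#' @return Array (or scalar) of the weighted average.
#' @examples
#' weighted_average(c(1, 0, 1, 0), 1)
#' weighted_average(c(1, 0), 0.5)
#' @export
weighted_average <- function(v, lambda) {
  if (!is.list(v)) v <- as.list(v)
  if (length(v) == 0L) stop("`v` must be non-empty.", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be positive.", call. = FALSE)
  t <- length(v)
  wts <- lambda^(t - seq_len(t))
  num <- Reduce(`+`, Map(function(x, w) w * x, v, wts))
  num / sum(wts)
}

#' @noRd
clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)  # pmax(0, .) takes attributes from its first argument
  y
}

# forward through the layer maps f2..fH at a given bottom-layer rate;
# returns per-layer rates and pre-clip values (for clip masks)
#' @noRd
rate_chain <- function(alpha1, weights, config) {
  H <- config$hidden_layers
  scale <- config$lif$v_th - config$lif$u_reset
  alpha <- vector("list", H)
  z <- vector("list", H)
  alpha[[1]] <- alpha1
  if (H >= 2) {
    for (l in 2:H) {
      z[[l]] <- (conv2d(alpha[[l - 1]], weights$F[[l]]) + weights$b[[l]]) /
        scale
      alpha[[l]] <- clip01(z[[l]])
    }
  }
  list(alpha = alpha, z = z)
}

#' The equilibrium fixed-point map
#'
#' Applies the clipped affine layer maps in sequence: the bottom-layer
#' rate is pushed up through layers 2..H, then fed back (together with
#' the averaged input) into layer 1, each map being
#' `clip01((linear(input) + bias) / (v_th - u_reset))`. A fixed point of
#' this composite map is the equilibrium weighted-average firing rate of
#' layer 1.
#'
#' @param alpha1 Array of bottom-layer rates in \[0, 1\], shape
#'   (channels, electrode channels, width).
#' @param xhat Averaged input tensor, shape (1, electrode channels,
#'   width).
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @return Array `g(alpha1)`, same shape as `alpha1`, entries in
#'   \[0, 1\].
#' @export
fixed_point_map <- function(alpha1, xhat, weights, config) {
  scale <- config$lif$v_th - config$lif$u_reset
  if (scale <= 0) {
    stop("`v_th - u_reset` must be positive for the rate scaling.",
         call. = FALSE)
  }
  ch <- rate_chain(alpha1, weights, config)
  H <- config$hidden_layers
  z1 <- (conv2d(ch$alpha[[H]], weights$W1) + conv2d(xhat, weights$F[[1]]) +
           weights$b[[1]]) / scale
  clip01(z1)
}

#' Solve for the equilibrium firing-rate state
#'
#' Damped fixed-point (Picard) iteration on [fixed_point_map()]:
#' `alpha <- (1 - damping) * alpha + damping * g(alpha)`. Under the
#' spectral contraction condition (product of the layer operator norms
#' below `v_th - u_reset` per layer) the iteration converges; when it
#' does not converge within `max_iter` the best iterate is returned with
#' `converged = FALSE`.
#'
#' @param xhat Averaged input tensor (1, channels, width).
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param tol Sup-norm residual tolerance on `alpha - g(alpha)`.
#' @param max_iter Maximum iterations.
#' @param damping Damping factor in (0, 1].
#' @return An object of class `equilibrium_state`: list with per-layer
#'   rates `alpha` (layer 1 is the solved fixed point, deeper layers are
#'   propagated from it), `xhat`, `residual`, `iterations`, `converged`.
#' @export
solve_equilibrium <- function(xhat, weights, config, tol = 1e-6,
                              max_iter = 100, damping = 0.5) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  w <- dim(xhat)[3]
  alpha1 <- array(0, c(config$hidden_channels[1], config$input_channels, w))
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- fixed_point_map(alpha1, xhat, weights, config)
    residual <- max(abs(alpha1 - g))
    alpha1 <- (1 - damping) * alpha1 + damping * g
    if (residual <= tol) break
  }
  ch <- rate_chain(alpha1, weights, config)
  structure(list(alpha = ch$alpha, xhat = xhat, residual = residual,
                 iterations = iter, converged = residual <= tol),
            class = "equilibrium_state")
}

# vector-Jacobian product of the composite map g at alpha1 (v given at
# the output of g), plus the clip masks needed to reuse the linearization
#' @noRd
map_vjp <- function(v, chain, z1, xhat, weights, config) {
  H <- config$hidden_layers
  scale <- config$lif$v_th - config$lif$u_reset
  d1 <- (z1 > 0 & z1 < 1) * 1
  gz1 <- v * d1 / scale
  g <- conv_input_grad(weights$W1, gz1)
  if (H >= 2) {
    for (l in H:2) {
      dl <- (chain$z[[l]] > 0 & chain$z[[l]] < 1) * 1
      gzl <- g * dl / scale
      g <- conv_input_grad(weights$F[[l]], gzl)
    }
  }
  g
}

# adjoint pass through the composite map collecting parameter gradients,
# given the adjoint `x` at the map's output
#' @noRd
map_param_grads <- function(x_adj, chain, z1, xhat, weights, config) {
  H <- config$hidden_layers
  scale <- config$lif$v_th - config$lif$u_reset
  kh <- config$kernel_size[1]
  kw <- config$kernel_size[2]
  gF <- lapply(weights$F, function(k) array(0, dim(k)))
  gb <- lapply(weights$b, function(b) numeric(length(b)))
  d1 <- (z1 > 0 & z1 < 1) * 1
  gz1 <- x_adj * d1 / scale
  gW1 <- conv_weight_grad(chain$alpha[[H]], gz1, kh, kw)
  gF[[1]] <- conv_weight_grad(xhat, gz1, kh, kw)
  gb[[1]] <- rowSums(matrix(gz1, dim(gz1)[1]))
  g <- conv_input_grad(weights$W1, gz1)
  if (H >= 2) {
    for (l in H:2) {
      dl <- (chain$z[[l]] > 0 & chain$z[[l]] < 1) * 1
      gzl <- g * dl / scale
      gF[[l]] <- gF[[l]] + conv_weight_grad(chain$alpha[[l - 1]], gzl, kh, kw)
      gb[[l]] <- gb[[l]] + rowSums(matrix(gzl, dim(gzl)[1]))
      g <- conv_input_grad(weights$F[[l]], gzl)
    }
  }
  list(F = gF, b = gb, W1 = gW1)
}

#' Implicit-differentiation gradient at an equilibrium point
#'
#' Given the loss gradient with respect to the bottom-layer equilibrium
#' rate `a*`, solves the adjoint linear system
#' `t(J_g)(x) + t(dL/da*) = 0` for the fixed-point residual map
#' `g_theta(a) = f_theta(a) - a`, then returns the parameter gradients
#' `t(x) . df_theta(a*)/dtheta` for every kernel and bias in the map
#' (feedforward kernels, feedback kernel, hidden biases). The clip
#' nonlinearity's derivative is taken as 1 strictly inside (0, 1) and 0
#' outside and on the boundary.
#'
#' The adjoint system is solved densely (with an LU factorization, and a
#' least-squares fallback flagged in the result if singular) when the
#' state has at most `dense_limit` entries, and by Neumann iteration
#' otherwise.
#'
#' @param loss_grad Array `dL/da*`, same shape as `alpha1_star`.
#' @param alpha1_star Bottom-layer equilibrium rate (from
#'   [solve_equilibrium()] or a simulated weighted average).
#' @param xhat Averaged input tensor.
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param dense_limit Size threshold for the dense solve.
#' @return List with parameter gradients `F`, `b`, `W1`, and a
#'   `least_squares` flag.
#' @export
implicit_gradient <- function(loss_grad, alpha1_star, xhat, weights, config,
                              dense_limit = 512) {
  scale <- config$lif$v_th - config$lif$u_reset
  H <- config$hidden_layers
  chain <- rate_chain(alpha1_star, weights, config)
  z1 <- (conv2d(chain$alpha[[H]], weights$W1) +
           conv2d(xhat, weights$F[[1]]) + weights$b[[1]]) / scale
  n <- length(alpha1_star)
  v <- as.vector(loss_grad)
  shp <- dim(alpha1_star)
  vjp <- function(x) {
    as.vector(map_vjp(array(x, shp), chain, z1, xhat, weights, config))
  }
  ls_flag <- FALSE
  if (n <= dense_limit) {
    jt <- vapply(seq_len(n), function(i) {
      e <- numeric(n)
      e[i] <- 1
      vjp(e)
    }, numeric(n))
    a_mat <- jt - diag(n)
    x <- tryCatch(solve(a_mat, -v), error = function(e) {
      ls_flag <<- TRUE
      qr.coef(qr(a_mat, LAPACK = TRUE), -v)
    })
    x[!is.finite(x)] <- 0
  } else {
    # Neumann iteration for x = t(J_map) x + v, valid under contraction
    x <- v
    for (k in seq_len(500)) {
      x_new <- vjp(x) + v
      if (max(abs(x_new - x)) < 1e-12) {
        x <- x_new
        break
      }
      x <- x_new
    }
  }
  out <- map_param_grads(array(x, shp), chain, z1, xhat, weights, config)
  out$least_squares <- ls_flag
  out
}

#' Simulate weighted-average firing rates
#'
#' Runs the spiking network for `steps` simulation steps under a constant
#' (replicated) input and returns the discounted weighted-average spike
#' rates of every layer, optionally at intermediate checkpoints. These
#' simulated averages are the quantities that converge to the solved
#' equilibrium under the contraction condition.
#'
#' @param x Numeric matrix (channels x samples), presented at every step.
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param steps Number of simulation steps.
#' @param checkpoints Optional integer vector of step counts at which to
#'   record the layer-1 average.
#' @return List with `alpha` (per-layer averages at `steps`) and
#'   `checkpoints` (named list of layer-1 averages).
#' @export
simulate_rates <- function(x, weights, config, steps,
                           checkpoints = NULL) {
  H <- config$hidden_layers
  lam <- config$lif$lambda
  vth <- config$lif$v_th
  xt <- array(0, c(1, nrow(x), ncol(x)))
  xt[1, , ] <- x
  shp <- function(l) c(config$hidden_channels[l], nrow(x), ncol(x))
  u <- lapply(seq_len(H), function(l) array(config$lif$u_reset, shp(l)))
  num <- lapply(seq_len(H), function(l) array(0, shp(l)))
  den <- 0
  sH_prev <- array(0, shp(H))
  cps <- list()
  for (t in seq_len(steps)) {
    num <- lapply(num, function(a) lam * a)
    den <- lam * den + 1
    below <- NULL
    st <- vector("list", H)
    for (l in seq_len(H)) {
      inp <- if (l == 1L) {
        conv2d(xt, weights$F[[1]]) + conv2d(sH_prev, weights$W1) +
          weights$b[[1]]
      } else {
        conv2d(below, weights$F[[l]]) + weights$b[[l]]
      }
      pre <- lam * u[[l]] + inp
      s <- (pre >= vth) * 1
      u[[l]] <- pre - vth * s
      st[[l]] <- s
      num[[l]] <- num[[l]] + s
      below <- s
    }
    sH_prev <- st[[H]]
    if (!is.null(checkpoints) && t %in% checkpoints) {
      cps[[as.character(t)]] <- num[[1]] / den
    }
  }
  list(alpha = lapply(num, function(a) a / den), checkpoints = cps)
}

# loss and full parameter gradients for one window under the equilibrium
# formulation (explicit chain path + implicit fixed-point path)
#' @noRd
ide_loss_grads <- function(x, y, weights, config,
                           mode = c("simulate", "solve"), sim_steps = 30,
                           tol = 1e-6, max_iter = 100,
                           feature_adjoint = NULL) {
  mode <- match.arg(mode)
  lam <- config$lif$lambda
  xs <- map_time(x, config)
  xhat <- weighted_average(xs, lam)
  if (mode == "simulate") {
    if (config$time_setting == "replicate") {
      a1 <- simulate_rates(x, weights, config, sim_steps)$alpha[[1]]
    } else {
      stop("IDE simulation currently requires the 'replicate' setting.",
           call. = FALSE)
    }
  } else {
    eq <- solve_equilibrium(xhat, weights, config, tol = tol,
                            max_iter = max_iter)
    a1 <- eq$alpha[[1]]
  }
  H <- config$hidden_layers
  scale <- config$lif$v_th - config$lif$u_reset
  chain <- rate_chain(a1, weights, config)
  aH <- chain$alpha[[H]]
  z <- sum(weights$W0 * as.vector(aH)) + weights$b0
  loss <- bce_with_logit(z, y)
  gz <- stats::plogis(z) - y
  gW0 <- gz * as.vector(aH)
  gb0 <- gz

  # explicit path: d loss / d theta at fixed a*, through f2..fH
  kh <- config$kernel_size[1]
  kw <- config$kernel_size[2]
  gF <- lapply(weights$F, function(k) array(0, dim(k)))
  gb <- lapply(weights$b, function(b) numeric(length(b)))
  g_alpha <- gz * array(weights$W0, dim(aH))
  if (!is.null(feature_adjoint)) {
    spatial <- prod(dim(aH)[2:3])
    g_alpha <- g_alpha + array(feature_adjoint / spatial, dim(aH))
  }
  if (H >= 2) {
    for (l in H:2) {
      dl <- (chain$z[[l]] > 0 & chain$z[[l]] < 1) * 1
      gzl <- g_alpha * dl / scale
      gF[[l]] <- gF[[l]] + conv_weight_grad(chain$alpha[[l - 1]], gzl, kh, kw)
      gb[[l]] <- gb[[l]] + rowSums(matrix(gzl, dim(gzl)[1]))
      g_alpha <- conv_input_grad(weights$F[[l]], gzl)
    }
  }
  # implicit path through the fixed point
  ig <- implicit_gradient(g_alpha, a1, xhat, weights, config)
  for (l in seq_len(H)) {
    gF[[l]] <- gF[[l]] + ig$F[[l]]
    gb[[l]] <- gb[[l]] + ig$b[[l]]
  }
  if (!is.finite(loss)) {
    stop("non-finite loss in equilibrium training step.", call. = FALSE)
  }
  list(loss = loss, logit = z,
       grads = list(F = gF, b = gb, W1 = ig$W1, W0 = gW0, b0 = gb0))
}

#' One equilibrium (implicit-differentiation) training step
#'
#' Forward: simulate the spiking network and take the discounted
#' weighted-average firing rate as the equilibrium surrogate (or solve
#' the fixed point directly with `mode = "solve"`); the readout is
#' applied to the top-layer average rate. Backward: implicit
#' differentiation of the fixed-point equation, so no unrolled graph is
#' stored. One Adam update is applied.
#'
#' @inheritParams bptt_train_step
#' @param mode `"simulate"` (weighted-average rates after `sim_steps`
#'   steps) or `"solve"` (damped fixed-point iteration).
#' @param sim_steps Simulation steps for `mode = "simulate"`.
#' @return List with `weights`, `opt_state`, `loss` (batch mean).
#' @export
ide_train_step <- function(batch, weights, config, opt_state = NULL,
                           lr = 1e-3, mode = c("simulate", "solve"),
                           sim_steps = 30) {
  ide_train_step_adv(batch, weights, config, opt_state, lr, mode,
                     sim_steps, feature_adjoints = NULL)
}

#' @noRd
ide_train_step_adv <- function(batch, weights, config, opt_state = NULL,
                               lr = 1e-3, mode = c("simulate", "solve"),
                               sim_steps = 30, feature_adjoints = NULL) {
  mode <- match.arg(mode)
  n <- nrow(batch)
  if (is.null(n) || n == 0L) stop("`batch` must be non-empty.", call. = FALSE)
  total <- NULL
  loss <- 0
  for (i in seq_len(n)) {
    fa <- if (is.null(feature_adjoints)) NULL else feature_adjoints[i, ]
    g <- ide_loss_grads(batch$data[[i]], batch$label[i], weights, config,
                        mode = mode, sim_steps = sim_steps,
                        feature_adjoint = fa)
    loss <- loss + g$loss / n
    total <- if (is.null(total)) g$grads else add_grads(total, g$grads)
  }
  total <- scale_grads(total, 1 / n)
  st <- adam_update(weights, total, opt_state, lr)
  list(weights = st$weights, opt_state = st$opt_state, loss = loss)
}
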