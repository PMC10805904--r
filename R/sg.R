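#' Surrogate derivative specification
#'
#' During backpropagation the non-differentiable Heaviside spike function
#' is replaced by a smooth surrogate derivative centered at the firing
#' threshold. Three standard families are supported:
#' * `"piecewise_linear"`: `(1/a) * 1[|u - Vth| <= a/2]` (boxcar);
#' * `"sigmoid"`: the logistic density
#'   `(1/a) * exp((Vth-u)/a) / (1 + exp((Vth-u)/a))^2`;
#' * `"atan"`: `a / (2 * (1 + ((pi/2) * a * (u - Vth))^2))`.
#'
#' All are nonnegative, peak at the threshold, and integrate to 1 over the
#' membrane potential.
#'
#' @param family Surrogate family.
#' @param a Width parameter (> 0). Defaults per family: 2 (`atan`),
#'   0.25 (`sigmoid`), 1 (`piecewise_linear`).
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(family = c("atan", "sigmoid", "piecewise_linear"),
                           a = NULL) {
  family <- match.arg(family)
  if (is.null(a)) {
    a <- switch(family, atan = 2, sigmoid = 0.25, piecewise_linear = 1)
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("`a` must be a positive scalar.", call. = FALSE)
  }
  structure(list(family = family, a = a), class = "surrogate_spec")
}

#' Evaluate a surrogate spike derivative
#'
#' @param u Numeric array of (pre-reset) membrane potentials.
#' @param v_th Firing threshold.
#' @param spec A [surrogate_spec].
#' @return Array of surrogate derivative values, same shape as `u`.
#' @examples
#' surrogate_derivative(1, 1, surrogate_spec("atan", 2))
#' @export
surrogate_derivative <- function(u, v_th, spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  a <- spec$a
  d <- u - v_th
  switch(spec$family,
    piecewise_linear = (abs(d) <= a / 2) / a,
    sigmoid = {
      e <- exp(-d / a)
      e / (a * (1 + e)^2)
    },
    atan = a / (2 * (1 + ((pi / 2) * a * d)^2))
  )
}

# smooth primitive of the surrogate derivative; used by the relaxed
# forward pass for gradient checking
#' @noRd
relaxed_spike <- function(u, v_th, spec) {
  a <- spec$a
  d <- u - v_th
  switch(spec$family,
    piecewise_linear = {
      y <- pmin(1, pmax(0, d / a + 0.5))
      dim(y) <- dim(d)
      y
    },
    sigmoid = stats::plogis(d / a),
    atan = atan((pi / 2) * a * d) / pi + 0.5
  )
}

#' @noRd
bce_with_logit <- function(z, y) {
  # numerically stable binary cross-entropy with logits
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# Backpropagation through the unrolled network (spatial and temporal
# paths), replacing ds/du by the surrogate. The -Vth*s soft-reset term
# participates in the backward pass unless detach_reset.
#
# Returns loss, logit, parameter gradients, the gradient with respect to
# the input window (for saliency), and the time-averaged top-layer
# channel rates (the adversarial feature tap).
#' @noRd
bptt_grad <- function(x, y, weights, config, surrogate,
                      relax = FALSE, detach_reset = FALSE,
                      feature_adjoint = NULL, dlogit = NULL) {
  tr <- eesnn_forward(x, weights, config, relax = relax,
                      surrogate = surrogate)
  H <- config$hidden_layers
  Tn <- config$snn_steps
  lam <- config$lif$lambda
  vth <- config$lif$v_th
  kh <- config$kernel_size[1]
  kw <- config$kernel_size[2]
  shp_H <- dim(tr$spikes[[1]][[H]])
  spatial <- shp_H[2] * shp_H[3]

  z <- tr$readout
  if (is.null(dlogit)) {
    loss <- bce_with_logit(z, y)
    gz <- stats::plogis(z) - y
  } else {
    loss <- NA_real_
    gz <- dlogit
  }

  gF <- lapply(weights$F, function(k) array(0, dim(k)))
  gb <- lapply(weights$b, function(b) numeric(length(b)))
  gW1 <- array(0, dim(weights$W1))
  gW0 <- numeric(length(weights$W0))
  gb0 <- gz * Tn
  w0_arr <- array(weights$W0, shp_H)

  g_s <- lapply(seq_len(Tn), function(t) {
    lapply(seq_len(H), function(l) array(0, dim(tr$spikes[[t]][[l]])))
  })
  for (t in seq_len(Tn)) {
    g_s[[t]][[H]] <- g_s[[t]][[H]] + gz * w0_arr
    gW0 <- gW0 + gz * as.vector(tr$spikes[[t]][[H]])
    if (!is.null(feature_adjoint)) {
      g_s[[t]][[H]] <- g_s[[t]][[H]] +
        array(feature_adjoint / (Tn * spatial), shp_H)
    }
  }

  g_u <- lapply(seq_len(H), function(l) array(0, dim(tr$spikes[[1]][[l]])))
  g_x <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    for (l in rev(seq_len(H))) {
      pre <- tr$pre[[t]][[l]]
      h <- surrogate_derivative(pre, vth, surrogate)
      gs <- g_s[[t]][[l]]
      gu <- g_u[[l]]
      g_pre <- if (detach_reset) gu + gs * h else gu + (gs - vth * gu) * h
      g_u[[l]] <- lam * g_pre
      nch <- dim(g_pre)[1]
      gb[[l]] <- gb[[l]] + rowSums(matrix(g_pre, nch))
      if (l == 1L) {
        gF[[1]] <- gF[[1]] + conv_weight_grad(tr$inputs[[t]], g_pre, kh, kw)
        g_x[[t]] <- conv_input_grad(weights$F[[1]], g_pre)
        if (t >= 2L) {
          gW1 <- gW1 +
            conv_weight_grad(tr$spikes[[t - 1]][[H]], g_pre, kh, kw)
          g_s[[t - 1]][[H]] <- g_s[[t - 1]][[H]] +
            conv_input_grad(weights$W1, g_pre)
        }
      } else {
        gF[[l]] <- gF[[l]] +
          conv_weight_grad(tr$spikes[[t]][[l - 1]], g_pre, kh, kw)
        g_s[[t]][[l - 1]] <- g_s[[t]][[l - 1]] +
          conv_input_grad(weights$F[[l]], g_pre)
      }
    }
  }
  if (any(!vapply(c(gF, list(gW1), gb, list(gW0, gb0)),
                  function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient encountered during backpropagation.",
         call. = FALSE)
  }

  g_input <- if (config$time_setting == "replicate") {
    Reduce(`+`, lapply(g_x, function(g) g[1, , , drop = TRUE]))
  } else {
    do.call(cbind, lapply(g_x, function(g) matrix(g[1, , ], dim(g)[2])))
  }
  dim(g_input) <- c(config$input_channels, config$input_samples)

  feat <- Reduce(`+`, lapply(tr$spikes, function(st) {
    rowSums(matrix(st[[H]], shp_H[1]))
  })) / (Tn * spatial)

  list(loss = loss, logit = z, probability = tr$probability,
       grads = list(F = gF, b = gb, W1 = gW1, W0 = gW0, b0 = gb0),
       g_input = g_input, features = feat, trace = tr)
}

#' One surrogate-gradient BPTT training step
#'
#' Unrolls the network over its simulation steps on every window in the
#' batch, backpropagates the binary cross-entropy through both the
#' spatial (layer) and temporal (step) paths with the surrogate
#' derivative standing in for the spike nonlinearity, and applies one
#' Adam update to all weights.
#'
#' @param batch A segments tibble (columns `data`, `label`); see
#'   [segment_cohort()].
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param surrogate A [surrogate_spec].
#' @param opt_state Optimizer state from a previous call, or `NULL`.
#' @param lr Learning rate.
#' @param detach_reset If `TRUE`, the soft-reset term is excluded from
#'   the backward graph.
#' @param feature_adjoints Optional matrix (one row per batch element) of
#'   extra adjoints on the time-averaged top-layer channel rates; used by
#'   the adversarial trainer.
#' @return List with `weights`, `opt_state`, `loss` (batch mean), and
#'   `features` (batch x top-layer-channels matrix).
#' @export
bptt_train_step <- function(batch, weights, config, surrogate,
                            opt_state = NULL, lr = 1e-3,
                            detach_reset = FALSE,
                            feature_adjoints = NULL) {
  n <- nrow(batch)
  if (is.null(n) || n == 0L) stop("`batch` must be non-empty.", call. = FALSE)
  total <- NULL
  loss <- 0
  feats <- NULL
  for (i in seq_len(n)) {
    fa <- if (is.null(feature_adjoints)) NULL else feature_adjoints[i, ]
    g <- bptt_grad(batch$data[[i]], batch$label[i], weights, config,
                   surrogate, detach_reset = detach_reset,
                   feature_adjoint = fa)
    loss <- loss + g$loss / n
    total <- if (is.null(total)) g$grads else add_grads(total, g$grads)
    feats <- rbind(feats, g$features)
  }
  total <- scale_grads(total, 1 / n)
  st <- adam_update(weights, total, opt_state, lr)
  list(weights = st$weights, opt_state = st$opt_state, loss = loss,
       features = feats)
}
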