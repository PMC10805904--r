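#' EESNN architecture configuration
#'
#' Describes a recurrent convolutional spiking network for EEG windows:
#' `hidden_layers` convolutional layers of LIF neurons on a shared spatial
#' grid (electrode channels x time samples), a feedback convolution from
#' the top hidden layer back into the first layer's input current, and a
#' single non-spiking readout neuron that accumulates the top layer's
#' spikes across simulation steps.
#'
#' Two mappings from EEG time to SNN time steps are supported:
#' * `"replicate"`: the whole window is presented unchanged at each of
#'   `snn_steps` simulation steps (the default, with `snn_steps = 2`);
#' * `"split"`: the window is cut into `t2` consecutive slices, one per
#'   simulation step, so the SNN consumes the window in temporal order.
#'
#' @param input_channels Number of electrode channels C.
#' @param input_samples Samples per window (sampling rate x window length).
#' @param hidden_layers Number of hidden LIF layers H (>= 1).
#' @param hidden_channels Feature channels per hidden layer; scalar or
#'   length-H vector.
#' @param kernel_size Convolution kernel (height, width); both odd.
#' @param lif A [lif_params] shared by all hidden layers.
#' @param time_setting `"replicate"` or `"split"`.
#' @param snn_steps Simulation steps for `"replicate"`.
#' @param t2 Number of time slices for `"split"`; must divide
#'   `input_samples`.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `eesnn_config`.
#' @examples
#' eesnn_config(input_channels = 4, input_samples = 64, hidden_layers = 1)
#' @export
eesnn_config <- function(input_channels,
                         input_samples,
                         hidden_layers = 5,
                         hidden_channels = 32,
                         kernel_size = c(3, 3),
                         lif = lif_params(),
                         time_setting = c("replicate", "split"),
                         snn_steps = 2,
                         t2 = NULL,
                         seed = 1L) {
  time_setting <- match.arg(time_setting)
  stopifnot(hidden_layers >= 1, input_channels >= 1, input_samples >= 1,
            length(kernel_size) == 2, all(kernel_size %% 2 == 1),
            inherits(lif, "lif_params"))
  hidden_channels <- rep_len(as.integer(hidden_channels), hidden_layers)
  if (time_setting == "replicate") {
    stopifnot(snn_steps >= 1)
    t2 <- NULL
  } else {
    if (is.null(t2)) stop("`t2` is required for time_setting = 'split'.",
                          call. = FALSE)
    if (input_samples %% t2 != 0) {
      stop("`t2` must divide `input_samples`.", call. = FALSE)
    }
    snn_steps <- as.integer(t2)
  }
  structure(list(input_channels = as.integer(input_channels),
                 input_samples = as.integer(input_samples),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_channels = hidden_channels,
                 kernel_size = as.integer(kernel_size),
                 lif = lif,
                 time_setting = time_setting,
                 snn_steps = as.integer(snn_steps),
                 t2 = if (is.null(t2)) NULL else as.integer(t2),
                 seed = as.integer(seed)),
            class = "eesnn_config")
}

#' @noRd
map_width <- function(config) {
  if (config$time_setting == "split") {
    config$input_samples %/% config$t2
  } else {
    config$input_samples
  }
}

#' Initialize EESNN weights
#'
#' Kaiming-style fan-in scaled Gaussian initialization for all feedforward
#' kernels `F1..FH`, the feedback kernel `W1`, per-layer biases, and the
#' linear readout, seeded from the configuration.
#'
#' @param config An [eesnn_config].
#' @return An object of class `eesnn_weights`: lists `F` and `b` of length
#'   H, feedback kernel `W1`, readout `W0` and `b0`.
#' @export
eesnn_init_weights <- function(config) {
  stopifnot(inherits(config, "eesnn_config"))
  kh <- config$kernel_size[1]
  kw <- config$kernel_size[2]
  ch <- config$hidden_channels
  H <- config$hidden_layers
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  kaiming <- function(out_ch, in_ch) {
    sd <- sqrt(2 / (in_ch * kh * kw))
    array(stats::rnorm(out_ch * in_ch * kh * kw, 0, sd),
          c(out_ch, in_ch, kh, kw))
  }
  Fs <- vector("list", H)
  bs <- vector("list", H)
  in_ch <- 1L
  for (l in seq_len(H)) {
    Fs[[l]] <- kaiming(ch[l], in_ch)
    bs[[l]] <- numeric(ch[l])
    in_ch <- ch[l]
  }
  W1 <- kaiming(ch[1], ch[H])
  n_feat <- ch[H] * config$input_channels * map_width(config)
  W0 <- stats::rnorm(n_feat, 0, 1 / sqrt(n_feat))
  structure(list(F = Fs, b = bs, W1 = W1, W0 = W0, b0 = 0),
            class = "eesnn_weights")
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Map an EEG window onto SNN simulation steps
#'
#' @param x Numeric matrix (channels x samples) for one window.
#' @param config An [eesnn_config].
#' @return A list of `snn_steps` input tensors of shape
#'   (1, channels, width): identical copies under `"replicate"`,
#'   consecutive time slices under `"split"`.
#' @export
map_time <- function(x, config) {
  stopifnot(inherits(config, "eesnn_config"))
  x <- as.matrix(x)
  if (nrow(x) != config$input_channels || ncol(x) != config$input_samples) {
    stop(sprintf("window is %d x %d but the config expects %d x %d.",
                 nrow(x), ncol(x), config$input_channels,
                 config$input_samples), call. = FALSE)
  }
  if (config$time_setting == "replicate") {
    xt <- array(0, c(1, nrow(x), ncol(x)))
    xt[1, , ] <- x
    rep(list(xt), config$snn_steps)
  } else {
    w <- map_width(config)
    lapply(seq_len(config$t2), function(k) {
      xt <- array(0, c(1, nrow(x), w))
      xt[1, , ] <- x[, (k - 1L) * w + seq_len(w), drop = FALSE]
      xt
    })
  }
}

#' Run the spiking network forward on one EEG window
#'
#' Implements the discrete membrane update of the recurrent architecture:
#' at step t the first layer integrates the leaked membrane, the feedback
#' convolution of the top layer's spikes from step t-1, and the input
#' convolution of the mapped window; each deeper layer integrates the same
#' step's spikes from the layer below. The readout neuron accumulates the
#' weighted top-layer spikes across all steps without spiking or reset;
#' the seizure probability is the logistic of the accumulated potential.
#'
#' @param x Numeric matrix (channels x samples).
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param relax If `TRUE`, replace the Heaviside spike by its smooth
#'   surrogate primitive (see [surrogate_spec()]); used for gradient
#'   checking and saliency, not for inference.
#' @param surrogate A [surrogate_spec] (required when `relax = TRUE`).
#' @return An object of class `eesnn_trace`: per-step per-layer spikes and
#'   pre-reset potentials, the accumulated readout potential, and the
#'   seizure probability.
#' @export
eesnn_forward <- function(x, weights, config, relax = FALSE,
                          surrogate = NULL) {
  stopifnot(inherits(weights, "eesnn_weights"),
            inherits(config, "eesnn_config"))
  if (relax && is.null(surrogate)) {
    stop("`relax = TRUE` requires a surrogate_spec.", call. = FALSE)
  }
  xs <- map_time(x, config)
  H <- config$hidden_layers
  lam <- config$lif$lambda
  vth <- config$lif$v_th
  w <- map_width(config)
  shp <- function(l) c(config$hidden_channels[l], config$input_channels, w)
  u <- lapply(seq_len(H), function(l) array(config$lif$u_reset, shp(l)))
  sH_prev <- array(0, shp(H))
  Tn <- length(xs)
  spikes <- vector("list", Tn)
  pres <- vector("list", Tn)
  acc <- 0
  spike_fn <- if (relax) {
    function(pre) relaxed_spike(pre, vth, surrogate)
  } else {
    function(pre) (pre >= vth) * 1
  }
  for (t in seq_len(Tn)) {
    st <- vector("list", H)
    pt <- vector("list", H)
    below <- NULL
    for (l in seq_len(H)) {
      inp <- if (l == 1L) {
        conv2d(xs[[t]], weights$F[[1]]) + conv2d(sH_prev, weights$W1) +
          weights$b[[1]]
      } else {
        conv2d(below, weights$F[[l]]) + weights$b[[l]]
      }
      pre <- lam * u[[l]] + inp
      if (anyNA(pre) || any(!is.finite(pre))) {
        stop(sprintf("non-finite membrane potential in layer %d, step %d.",
                     l, t), call. = FALSE)
      }
      s <- spike_fn(pre)
      u[[l]] <- pre - vth * s
      st[[l]] <- s
      pt[[l]] <- pre
      below <- s
    }
    sH_prev <- st[[H]]
    acc <- acc + sum(weights$W0 * as.vector(st[[H]])) + weights$b0
    spikes[[t]] <- st
    pres[[t]] <- pt
  }
  structure(list(spikes = spikes, pre = pres, inputs = xs,
                 readout = acc, probability = stats::plogis(acc),
                 config = config),
            class = "eesnn_trace")
}

#' Classify a forward trace
#'
#' @param trace An [eesnn_trace].
#' @param threshold Probability cut in (0, 1); the label is 1 only for
#'   probabilities strictly above it, so at the default 0.5 the rule
#'   coincides with the sign of the accumulated readout potential (an
#'   exactly zero potential gives label 0).
#' @return Integer class label, 0 (non-seizure) or 1 (seizure).
#' @export
predict_label <- function(trace, threshold = 0.5) {
  stopifnot(inherits(trace, "eesnn_trace"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1).", call. = FALSE)
  }
  as.integer(trace$probability > threshold)
}

#' Save / load a trained network checkpoint
#'
#' A checkpoint bundles the weights and their configuration; the
#' round-trip is bit-exact.
#'
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with elements `weights` and `config`.
#' @export
save_checkpoint <- function(weights, config, path) {
  stopifnot(inherits(weights, "eesnn_weights"),
            inherits(config, "eesnn_config"))
  saveRDS(list(weights = weights, config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$weights, "eesnn_weights"),
            inherits(ck$config, "eesnn_config"))
  ck
}
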