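# shared fixtures: tiny seeded networks and on-the-fly file fixtures

# small net with 1x1 kernels (pure channel mixing) for hand-checkable
# dynamics and cheap finite differences
tiny_config <- function(H = 2, ch = 2, C = 2, S = 2, lambda = 0.9,
                        v_th = 1, steps = 2, kernel = c(1, 1), seed = 5) {
  eesnn_config(input_channels = C, input_samples = S, hidden_layers = H,
               hidden_channels = ch, kernel_size = kernel,
               lif = lif_params(lambda = lambda, v_th = v_th),
               snn_steps = steps, seed = seed)
}

# scalar network (one neuron per layer, 1x1 grid) with all weights
# settable directly
scalar_config <- function(H = 1, lambda = 1, v_th = 1, steps = 3) {
  tiny_config(H = H, ch = 1, C = 1, S = 1, lambda = lambda, v_th = v_th,
              steps = steps)
}

scalar_weights <- function(config, F1 = 1, W1 = 0, b = 0, W0 = 1, b0 = 0) {
  w <- eesnn_init_weights(config)
  for (l in seq_along(w$F)) {
    w$F[[l]][] <- F1
    w$b[[l]][] <- b
  }
  w$W1[] <- W1
  w$W0[] <- W0
  w$b0 <- b0
  w
}

# rescale a random net so the product of feedback/feedforward operator
# norms is gamma < 1 (the equilibrium contraction condition); kernels are
# 1x1 so operator norms are matrix 2-norms
contractive_weights <- function(config, gamma = 0.8) {
  w <- eesnn_init_weights(config)
  op2 <- function(k) svd(matrix(k, dim(k)[1]))$d[1]
  norms <- op2(w$W1)
  if (config$hidden_layers >= 2) {
    for (l in 2:config$hidden_layers) norms <- norms * op2(w$F[[l]])
  }
  s <- (gamma / norms)^(1 / config$hidden_layers)
  w$W1 <- w$W1 * s
  if (config$hidden_layers >= 2) {
    for (l in 2:config$hidden_layers) w$F[[l]] <- w$F[[l]] * s
  }
  w
}

# numeric gradient of f at x by central differences, one coordinate
fd_grad1 <- function(f, x, i, eps = 1e-6) {
  xp <- x
  xm <- x
  xp[i] <- xp[i] + eps
  xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# write a minimal EDF file (256-byte header + signal headers + int16
# records) for reader tests
write_edf_fixture <- function(path, data, rate, labels,
                              patient = "test patient") {
  ns <- nrow(data)
  n_samp <- ncol(data)
  stopifnot(n_samp %% rate == 0)
  n_rec <- n_samp / rate
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(patient, 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("", 80)                 # transducer
  for (i in 1:ns) wr("uV", 8)                # physical dimension
  pmin_ <- -3276.8; pmax_ <- 3276.7
  for (i in 1:ns) wr(pmin_, 8)
  for (i in 1:ns) wr(pmax_, 8)
  for (i in 1:ns) wr(-32768, 8)
  for (i in 1:ns) wr(32767, 8)
  for (i in 1:ns) wr("", 80)                 # prefiltering
  for (i in 1:ns) wr(rate, 8)
  for (i in 1:ns) wr("", 32)
  # digital = physical / 0.1 under the chosen scaling
  dig <- round((data - pmin_) / (pmax_ - pmin_) * 65535) - 32768
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * rate + 1):(r * rate)
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
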