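test_that("confusion counts are the standard 2x2 table", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc[, c("TP", "FN", "TN", "FP")]),
               c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FN + perfect$FP, 0L)
  blind <- confusion(rep(1, 5), rep(0, 5))
  expect_equal(c(blind$TP, blind$FN), c(0L, 5L))
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics reproduce the rebalanced-accuracy identity", {
  # perfect classifier: everything 1
  m <- seizure_metrics(list(TP = 5, FN = 0, TN = 20, FP = 0),
                       scores = c(rep(1, 5), rep(0, 20)),
                       labels = c(rep(1, 5), rep(0, 20)))
  expect_equal(unlist(m[, c("sensitivity", "specificity", "gmean",
                            "raccuracy", "auc")]),
               c(sensitivity = 1, specificity = 1, gmean = 1,
                 raccuracy = 1, auc = 1))
  # randomized identity: raccuracy == (sens+spec)/2 under the default r
  set.seed(61)
  for (i in 1:50) {
    cc <- list(TP = sample(1:50, 1), FN = sample(1:50, 1),
               TN = sample(1:50, 1), FP = sample(1:50, 1))
    m <- seizure_metrics(cc)
    expect_equal(m$raccuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$gmean^2, m$sensitivity * m$specificity)
  }
  # empty class: undefined, not zero
  expect_warning(m0 <- seizure_metrics(list(TP = 0, FN = 0, TN = 3,
                                            FP = 1)), "undefined")
  expect_true(is.na(m0$sensitivity))
})

test_that("printed sensitivity and GMean imply the printed RAccuracy", {
  # SNN row: sensitivity 80.82 %, GMean 69.89 % -> RAccuracy 70.63 %
  derive <- function(sens_pct, gmean_pct) {
    sens <- sens_pct / 100
    spec <- (gmean_pct / 100)^2 / sens
    scale <- 1e6
    cc <- list(TP = round(sens * scale), FN = scale - round(sens * scale),
               TN = round(spec * scale), FP = scale - round(spec * scale))
    100 * seizure_metrics(cc)$raccuracy
  }
  expect_equal(derive(80.82, 69.89), 70.63, tolerance = 0.011)
  # ANN row: 56.89 %, 66.58 % -> 67.40 %
  expect_equal(derive(56.89, 66.58), 67.40, tolerance = 0.011)
})

test_that("rank AUC handles separation, ties, and agrees with pROC", {
  labs <- c(rep(1, 4), rep(0, 6))
  expect_equal(eesnn:::auc_rank(c(rep(0.9, 4), rep(0.1, 6)), labs), 1)
  expect_equal(eesnn:::auc_rank(rep(0.5, 10), labs), 0.5)
  set.seed(62)
  scores <- rnorm(40)
  labs2 <- rbinom(40, 1, 0.4)
  expect_equal(eesnn:::auc_rank(scores, labs2),
               as.numeric(pROC::auc(pROC::roc(labs2, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("spiking probability is spikes over neurons times steps", {
  cfg <- scalar_config(H = 1, lambda = 1, steps = 3)
  w <- scalar_weights(cfg, F1 = 1, W1 = 0, b = 0, W0 = 1)
  tr <- eesnn_forward(matrix(0.6, 1, 1), w, cfg)   # spikes 0,1,0
  sp <- spiking_probability(tr)
  expect_equal(sp$average, 1 / 3)
  expect_equal(sp$per_layer$probability, 1 / 3)
  # silent network
  w0 <- scalar_weights(cfg, F1 = 0)
  expect_equal(spiking_probability(eesnn_forward(matrix(0, 1, 1), w0,
                                                 cfg))$average, 0)
  # saturated network spikes every step
  wf <- scalar_weights(cfg, F1 = 5)
  expect_equal(spiking_probability(eesnn_forward(matrix(1, 1, 1), wf,
                                                 cfg))$average, 1)
})

test_that("energy model reproduces the dense-network worked example", {
  # 2.6e10 MACs at 4.6 pJ -> 119.6 mJ (printed as 1.2e2)
  e <- estimate_energy(2.6e10, 0)
  expect_equal(e$energy_mJ, 119.6)
  expect_equal(signif(e$energy_mJ, 2), 120)
  expect_equal(estimate_energy(0, 1)$energy_pJ, 0.9)
  expect_equal(estimate_energy(0, 0)$energy_pJ, 0)
  # linearity
  e1 <- estimate_energy(3e5, 2e4)
  e2 <- estimate_energy(7e5, 5e4)
  e12 <- estimate_energy(1e6, 7e4)
  expect_equal(e1$energy_pJ + e2$energy_pJ, e12$energy_pJ)
  expect_error(estimate_energy(-1, 0), "nonnegative")
})

test_that("operation counts follow spike activity", {
  cfg <- tiny_config(H = 2, ch = 2, C = 2, S = 3, kernel = c(3, 3),
                     steps = 2, seed = 63)
  w <- eesnn_init_weights(cfg)
  # silent network: no ACs, only input and readout MACs remain
  ws <- w
  ws$F <- lapply(ws$F, function(k) k * 0)
  ws$W1 <- ws$W1 * 0
  tr0 <- eesnn_forward(matrix(1, 2, 3), ws, cfg)
  ops0 <- count_ops(ws, cfg, tr0)
  expect_equal(ops0$ac_ops, 0)
  expect_gt(ops0$snn_mac_ops, 0)
  # saturated network: ACs equal the dense synapse count of the
  # spike-driven layers
  wf <- w
  wf$b <- lapply(wf$b, function(b) b + 10)   # every neuron fires always
  trf <- eesnn_forward(matrix(0, 2, 3), wf, cfg)
  expect_equal(spiking_probability(trf)$average, 1)
  opsf <- count_ops(wf, cfg, trf)
  expect_equal(opsf$ac_ops, opsf$mac_ops - opsf$snn_mac_ops)
  # event-driven energy is below dense energy for sparse traces
  tr <- eesnn_forward(matrix(0.5, 2, 3), w, cfg)
  ops <- count_ops(w, cfg, tr)
  expect_lte(estimate_energy(ops$snn_mac_ops, ops$ac_ops)$energy_pJ,
             estimate_energy(ops$mac_ops, 0)$energy_pJ)
})

test_that("a hand-counted scalar feedback synapse fires one accumulate", {
  cfg <- scalar_config(H = 1, lambda = 1, steps = 3)
  w <- scalar_weights(cfg, F1 = 1, W1 = 1e-9, b = 0, W0 = 1)
  tr <- eesnn_forward(matrix(0.6, 1, 1), w, cfg)  # spikes 0,1,0
  ops <- count_ops(w, cfg, tr)
  # only the step-2 spike is consumed (at step 3) by the single feedback
  # synapse
  expect_equal(ops$ac_ops, 1)
})

test_that("saliency maps are shaped, signed, and symmetric", {
  cfg <- tiny_config(H = 1, ch = 2, C = 3, S = 8, kernel = c(3, 3),
                     steps = 2, seed = 64)
  w <- eesnn_init_weights(cfg)
  x <- matrix(rnorm(24), 3, 8)
  expect_error(saliency(x, w, cfg), "surrogate")
  s <- saliency(x, w, cfg, surrogate_spec("sigmoid", 0.5))
  expect_equal(dim(s), c(3, 8))
  # zero-weight network: all-zero map
  w0 <- w
  w0$F <- lapply(w0$F, function(k) k * 0)
  w0$W1 <- w0$W1 * 0
  w0$W0 <- w0$W0 * 0
  expect_true(all(saliency(x, w0, cfg,
                           surrogate_spec("sigmoid", 0.5)) == 0))
  # duplicated input channels receive identical attributions when every
  # weight treats the duplicate rows identically (1x1 kernels act
  # positionwise; the readout must also weight the rows equally)
  cfg1 <- tiny_config(H = 1, ch = 2, C = 2, S = 4, kernel = c(1, 1),
                      steps = 2, seed = 65)
  w1 <- eesnn_init_weights(cfg1)
  w0_arr <- array(w1$W0, c(2, 2, 4))
  w0_arr[, 2, ] <- w0_arr[, 1, ]
  w1$W0 <- as.vector(w0_arr)
  xd <- matrix(rnorm(4), 1, 4)
  s1 <- saliency(rbind(xd, xd), w1, cfg1, surrogate_spec("sigmoid", 0.5))
  expect_equal(s1[1, ], s1[2, ])
})
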