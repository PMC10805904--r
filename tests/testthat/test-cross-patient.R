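test_that("Gaussian augmentation fit matches hand-computed moments", {
  # single segment: covariance is pure ridge, draws reproduce the source
  seg <- matrix(1:6, 2, 3)
  m1 <- fit_stea(list(seg), eps = 0)
  expect_equal(m1$mean, as.vector(seg))
  expect_equal(m1$cov, matrix(0, 6, 6))
  d <- generate_stea(fit_stea(list(seg), eps = 0), 2, seed = 4)
  expect_equal(d$data[[1]], seg, tolerance = 1e-12, ignore_attr = TRUE)

  # two segments differing in one entry by +/- d
  a <- matrix(0, 2, 2)
  b <- a
  b[2, 1] <- 1
  m2 <- fit_stea(list(a, b), eps = 0)
  expect_equal(m2$mean, c(0, 0.5, 0, 0))
  expected_cov <- matrix(0, 4, 4)
  expected_cov[2, 2] <- 0.5  # unbiased 2-sample variance of (0, 1)
  expect_equal(m2$cov, expected_cov)
  expect_error(fit_stea(list(a, matrix(0, 3, 2))), "inconsistent")
})

test_that("covariance estimation is consistent on known Gaussians", {
  set.seed(31)
  d <- 6
  A <- matrix(rnorm(d * d, 0, 0.4), d)
  true_cov <- crossprod(A) + diag(d) * 0.5
  L <- chol(true_cov)
  segs <- lapply(1:500, function(i) {
    matrix(drop(rnorm(d) %*% L), 2, 3)
  })
  m <- fit_stea(segs, eps = 0)
  rel <- norm(m$cov - true_cov, "F") / norm(true_cov, "F")
  expect_lt(rel, 0.15)
})

test_that("augmentation draws are seeded, counted, and CLT-consistent", {
  set.seed(32)
  segs <- lapply(1:20, function(i) matrix(rnorm(8, 2, 1), 2, 4))
  m <- fit_stea(segs)
  expect_equal(nrow(generate_stea(m, 0)), 0)
  d1 <- generate_stea(m, 5, seed = 9)
  d2 <- generate_stea(m, 5, seed = 9)
  expect_identical(d1$data, d2$data)
  expect_true(all(d1$label == 1) && all(d1$synthetic))
  # empirical means within 3 sigma/sqrt(n) for nearly all coordinates
  n <- 4000
  draws <- generate_stea(m, n, seed = 10)
  flat <- t(vapply(draws$data, as.vector, numeric(8)))
  sds <- sqrt(diag(m$cov + diag(m$eps, 8)))
  hit <- abs(colMeans(flat) - m$mean) <= 3 * sds / sqrt(n)
  expect_gte(mean(hit), 0.99)
})

test_that("ratio-targeted augmentation reaches 1:5 and tags draws", {
  set.seed(33)
  segs <- dplyr::bind_rows(
    tibble::tibble(segment_id = sprintf("s%d", 1:4), patient_id = "P01",
                   label = 1L, start_s = 1:4, window_seconds = 1,
                   sampling_rate = 4, synthetic = FALSE,
                   data = lapply(1:4, function(i) matrix(rnorm(8), 2, 4))),
    tibble::tibble(segment_id = sprintf("n%d", 1:40), patient_id = "P01",
                   label = 0L, start_s = 5:44, window_seconds = 1,
                   sampling_rate = 4, synthetic = FALSE,
                   data = lapply(1:40, function(i) matrix(rnorm(8), 2, 4))))
  aug <- augment_stea(segs, target_ratio = 5, seed = 2)
  expect_equal(sum(aug$label == 1), 8)  # ceiling(40/5) = 8 seizure total
  expect_equal(sum(aug$synthetic), 4)
  # already satisfied ratio: unchanged
  expect_identical(augment_stea(aug, target_ratio = 5), aug)
})

test_that("adversarial round with beta = 0 equals the plain trainer", {
  set.seed(34)
  cfg <- tiny_config(H = 1, ch = 3, C = 2, S = 4, kernel = c(1, 3),
                     steps = 2, seed = 12)
  w <- eesnn_init_weights(cfg)
  batch <- tibble::tibble(
    segment_id = sprintf("s%d", 1:6),
    patient_id = rep(c("A", "B"), 3),
    label = rep(c(0L, 1L), each = 3),
    start_s = 1:6, window_seconds = 1, sampling_rate = 4,
    synthetic = FALSE,
    data = lapply(1:6, function(i) matrix(rnorm(8), 2, 4)))
  sp <- surrogate_spec()
  disc <- eesnn:::disc_init(2, 3, seed = 1)
  disc$classes <- c("A", "B")
  adv0 <- adversarial_config(beta = 0)
  r_adv <- adversarial_round(batch, w, disc, adv0, trainer = "sg",
                             config = cfg, surrogate = sp)
  r_plain <- bptt_train_step(batch, w, cfg, sp)
  expect_identical(r_adv$weights, r_plain$weights)
  expect_identical(r_adv$model_loss, r_plain$loss)
})

test_that("single-patient batches skip the discriminator with a warning", {
  cfg <- tiny_config(H = 1, ch = 2, C = 2, S = 2, kernel = c(1, 1),
                     steps = 1, seed = 13)
  w <- eesnn_init_weights(cfg)
  batch <- tibble::tibble(
    segment_id = c("a", "b"), patient_id = c("A", "A"),
    label = c(0L, 1L), start_s = 1:2, window_seconds = 1,
    sampling_rate = 2, synthetic = FALSE,
    data = list(matrix(0.1, 2, 2), matrix(0.5, 2, 2)))
  disc <- eesnn:::disc_init(2, 2, seed = 1)
  disc$classes <- c("A", "B")
  expect_warning(
    adversarial_round(batch, w, disc, adversarial_config(), trainer = "sg",
                      config = cfg, surrogate = surrogate_spec()),
    "single patient")
})

test_that("the discriminator can learn identity-correlated features", {
  set.seed(35)
  n <- 120
  ids <- rep(1:3, each = n / 3)
  feats <- matrix(rnorm(n * 4, 0, 0.3), n, 4) +
    outer(ids, c(1, -1, 0.5, 0))  # identity-coded offsets
  disc <- eesnn:::disc_init(3, 4, seed = 2)
  for (i in 1:200) {
    dg <- eesnn:::disc_loss_grad(disc, feats, ids)
    disc$W <- disc$W - 0.1 * dg$gW
    disc$b <- disc$b - 0.1 * dg$gb
  }
  acc <- mean(eesnn:::disc_predict(disc, feats) == ids)
  expect_gt(acc, 1 / 3 + 0.2)
})

test_that("fine-tuning guards against evaluation leakage", {
  cfg <- tiny_config(H = 1, ch = 2, C = 2, S = 2, kernel = c(1, 1),
                     steps = 1, seed = 14)
  segs <- tibble::tibble(
    segment_id = sprintf("s%d", 1:6), patient_id = "P01",
    label = rep(c(0L, 1L), 3), start_s = 1:6, window_seconds = 1,
    sampling_rate = 2, synthetic = FALSE,
    data = lapply(1:6, function(i) matrix(rnorm(4), 2, 2)))
  fit <- train_detector(segs, cfg, trainer = "sg", epochs = 1,
                        batch_size = 6, seed = 1)
  # zero epochs: unchanged
  same <- finetune(fit, segs[1:2, ], segs[3:6, ], epochs = 0)
  expect_identical(same$weights, fit$weights)
  # shared segment: hard error
  expect_error(finetune(fit, segs[1:3, ], segs[3:6, ], epochs = 1),
               "overlap")
  # disjoint adaptation changes the weights
  adapted <- finetune(fit, segs[1:2, ], segs[3:6, ], epochs = 2,
                      lr = 1e-3)
  expect_false(identical(adapted$weights, fit$weights))
})
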