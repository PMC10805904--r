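# STEA multivariate-Gaussian seizure augmentation, the adversarial
# patient-identity confusion loop, and fine-tune adaptation.

#' Fit a spatio-temporal Gaussian augmentation model
#'
#' Flattens each seizure window (channels x samples) to one long vector,
#' estimates the sample mean and sample covariance across windows, and
#' adds a small ridge `eps * I` to the covariance diagonal. When the
#' flattened dimension exceeds the number of windows the sample
#' covariance is rank-deficient, which the ridge repairs.
#'
#' @param segments A segments tibble (seizure windows), or a list of
#'   channels x samples matrices of identical shape.
#' @param eps Diagonal loading; default `1e-4 * trace(cov) / dim`.
#' @return An object of class `stea_model`.
#' @export
fit_stea <- function(segments, eps = NULL) {
  if (is.data.frame(segments)) {
    mats <- segments$data
    meta <- list(sampling_rate = segments$sampling_rate[1],
                 window_seconds = segments$window_seconds[1])
  } else {
    mats <- segments
    meta <- list(sampling_rate = NA_real_, window_seconds = NA_real_)
  }
  if (length(mats) < 1L) stop("need at least one segment.", call. = FALSE)
  shp <- dim(mats[[1]])
  ok <- vapply(mats, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stop("segments have inconsistent shapes.", call. = FALSE)
  flat <- t(vapply(mats, as.vector, numeric(prod(shp))))
  mu <- colMeans(flat)
  sigma <- if (nrow(flat) == 1L) {
    matrix(0, length(mu), length(mu))
  } else {
    stats::cov(flat)
  }
  if (is.null(eps)) eps <- 1e-4 * sum(diag(sigma)) / length(mu)
  structure(list(mean = mu, cov = sigma, eps = eps, n = nrow(flat),
                 dim = shp, sampling_rate = meta$sampling_rate,
                 window_seconds = meta$window_seconds),
            class = "stea_model")
}

#' Sample synthetic seizure windows from a fitted augmentation model
#'
#' Draws from `N(mean, cov + eps * I)`, reshapes to channels x samples,
#' and returns a segments tibble labeled seizure and tagged synthetic so
#' leakage guards can keep the draws out of any evaluation pool.
#'
#' @param model A [fit_stea()] model.
#' @param count Number of windows to draw (>= 0).
#' @param seed Integer seed; draws are reproducible.
#' @return A segments tibble with `count` rows.
#' @export
generate_stea <- function(model, count, seed = 1L) {
  stopifnot(inherits(model, "stea_model"), count >= 0)
  if (count == 0) return(empty_segments())
  sigma <- model$cov + diag(model$eps, length(model$mean))
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * max(1, max(abs(sigma)))) {
    stop("covariance is not positive semi-definite after regularization.",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- MASS::mvrnorm(count, model$mean, sigma)
  if (count == 1L) draws <- matrix(draws, 1)
  tibble::tibble(
    segment_id = sprintf("stea_%d_%d", seed, seq_len(count)),
    patient_id = "stea_synthetic",
    label = 1L,
    start_s = NA_real_,
    window_seconds = model$window_seconds,
    sampling_rate = model$sampling_rate,
    synthetic = TRUE,
    data = lapply(seq_len(count), function(i) {
      matrix(draws[i, ], model$dim[1], model$dim[2])
    }))
}

#' @noRd
empty_segments <- function() {
  tibble::tibble(segment_id = character(), patient_id = character(),
                 label = integer(), start_s = numeric(),
                 window_seconds = numeric(), sampling_rate = numeric(),
                 synthetic = logical(), data = list())
}

#' Augment training data to a target class ratio
#'
#' Fits [fit_stea()] on the (real) seizure segments and draws synthetic
#' seizure windows until the seizure : non-seizure ratio reaches
#' `1 : target_ratio`. If the ratio is already met, the input is
#' returned unchanged.
#'
#' @param segments Training segments tibble.
#' @param target_ratio Non-seizure windows per seizure window to aim for.
#' @param seed Integer seed.
#' @return The augmented segments tibble.
#' @export
augment_stea <- function(segments, target_ratio = 5, seed = 1L) {
  seiz <- segments[segments$label == 1 & !segments$synthetic, ]
  n0 <- sum(segments$label == 0)
  n1 <- sum(segments$label == 1)
  need <- ceiling(n0 / target_ratio) - n1
  if (need <= 0 || nrow(seiz) == 0) return(segments)
  model <- fit_stea(seiz)
  dplyr::bind_rows(segments, generate_stea(model, need, seed = seed))
}

#' Adversarial training configuration
#'
#' Settings for the patient-identity confusion strategy: a softmax
#' identity discriminator reads the time-averaged top-layer spike rates
#' (one feature per hidden channel), and training alternates `k`
#' discriminator steps (minimizing identity cross-entropy) with one
#' detector step that adds `beta` times a confusion loss - the
#' cross-entropy of the discriminator's output against the uniform
#' identity distribution - pushing the features towards
#' patient-invariance.
#'
#' In addition to the per-batch alternation, [train_detector()] retrains
#' the discriminator on the full training set's features at the start of
#' every epoch (`refresh_steps` full-batch gradient steps), so the
#' confusion gradient always points away from genuinely remaining
#' identity information, and — because the seizure objective keeps
#' optimizing long after invariance peaks — keeps the weights from the
#' epoch at which the refreshed discriminator's in-sample accuracy was
#' lowest (`snapshot = TRUE`).
#'
#' @param beta Confusion weight (>= 0; `beta = 0` recovers the plain
#'   trainer exactly).
#' @param k Discriminator steps per detector step (>= 1).
#' @param disc_lr Discriminator learning rate.
#' @param refresh_steps Full-batch discriminator steps at each epoch
#'   start (0 disables the refresh).
#' @param snapshot Keep the most patient-invariant epoch's weights.
#' @return An object of class `adversarial_config`.
#' @export
adversarial_config <- function(beta = 0.1, k = 1, disc_lr = 0.05,
                               refresh_steps = 150, snapshot = TRUE) {
  stopifnot(beta >= 0, k >= 1, disc_lr > 0, refresh_steps >= 0)
  structure(list(beta = beta, k = as.integer(k), disc_lr = disc_lr,
                 refresh_steps = as.integer(refresh_steps),
                 snapshot = isTRUE(snapshot)),
            class = "adversarial_config")
}

#' @noRd
disc_init <- function(n_classes, n_features, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(W = matrix(stats::rnorm(n_classes * n_features, 0,
                               1 / sqrt(n_features)),
                  n_classes, n_features),
       b = numeric(n_classes), classes = NULL)
}

# softmax cross-entropy loss, parameter gradients, and per-sample
# feature gradients for the identity discriminator
#' @noRd
disc_loss_grad <- function(disc, feats, class_idx) {
  n <- nrow(feats)
  logits <- feats %*% t(disc$W) + matrix(disc$b, n, length(disc$b),
                                         byrow = TRUE)
  m <- apply(logits, 1, max)
  p <- exp(logits - m)
  p <- p / rowSums(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), class_idx)], 1e-12)))
  d <- p
  d[cbind(seq_len(n), class_idx)] <- d[cbind(seq_len(n), class_idx)] - 1
  d <- d / n
  list(loss = loss,
       gW = t(d) %*% feats,
       gb = colSums(d),
       gfeats = d %*% disc$W,
       prob = p)
}

# confusion objective for the detector: cross-entropy between the
# discriminator's output and the uniform distribution over identities.
# Unlike maximizing the discriminator's own loss (which admits degenerate
# optima that merely permute identities), its only optimum is a
# discriminator output that carries no identity information.
#' @noRd
disc_confusion_grad <- function(disc, feats) {
  n <- nrow(feats)
  ncl <- length(disc$b)
  logits <- feats %*% t(disc$W) + matrix(disc$b, n, ncl, byrow = TRUE)
  m <- apply(logits, 1, max)
  p <- exp(logits - m)
  p <- p / rowSums(p)
  loss <- -mean(rowMeans(log(pmax(p, 1e-12))))
  list(loss = loss, gfeats = ((p - 1 / ncl) / n) %*% disc$W)
}

#' @noRd
disc_predict <- function(disc, feats) {
  logits <- feats %*% t(disc$W) + matrix(disc$b, nrow(feats),
                                         length(disc$b), byrow = TRUE)
  max.col(logits, ties.method = "first")
}

#' @noRd
features_of <- function(batch, weights, config) {
  H <- config$hidden_layers
  t(vapply(batch$data, function(x) {
    tr <- eesnn_forward(x, weights, config)
    shp <- dim(tr$spikes[[1]][[H]])
    Reduce(`+`, lapply(tr$spikes, function(st) {
      rowSums(matrix(st[[H]], shp[1]))
    })) / (length(tr$spikes) * shp[2] * shp[3])
  }, numeric(config$hidden_channels[config$hidden_layers])))
}

#' One adversarial alternation round
#'
#' Performs `k` discriminator updates on the batch's extracted features
#' (skipped with a warning if the batch holds a single patient), then
#' one detector update whose objective is the seizure loss plus `beta`
#' times the uniform-target confusion loss, implemented by injecting the
#' scaled confusion feature gradient into the detector's backward pass.
#'
#' @param batch Segments tibble carrying `patient_id`.
#' @param weights,config,surrogate Detector state and settings.
#' @param disc_state Discriminator state from [train_detector()]
#'   internals or a previous round.
#' @param adv An [adversarial_config()].
#' @param trainer `"sg"` or `"ide"`.
#' @param opt_state,lr Detector optimizer state and learning rate.
#' @param ide_mode,ide_sim_steps,detach_reset Trainer pass-through.
#' @return List with updated `weights`, `opt_state`, `disc_state`, and
#'   the two losses (`model_loss`, `disc_loss`).
#' @export
adversarial_round <- function(batch, weights, disc_state, adv,
                              trainer = "sg", config, surrogate = NULL,
                              opt_state = NULL, lr = 1e-3,
                              ide_mode = "simulate", ide_sim_steps = 30,
                              detach_reset = FALSE) {
  stopifnot(inherits(adv, "adversarial_config"))
  class_idx <- match(batch$patient_id, disc_state$classes)
  if (anyNA(class_idx)) {
    # unseen identities (e.g. synthetic augmentation draws) get their own
    # throwaway class slot only if present in `classes`; otherwise skip them
    keep <- !is.na(class_idx)
  } else {
    keep <- rep(TRUE, nrow(batch))
  }
  feats <- features_of(batch, weights, config)
  disc_loss <- NA_real_
  if (length(unique(class_idx[keep])) >= 2) {
    for (i in seq_len(adv$k)) {
      dg <- disc_loss_grad(disc_state, feats[keep, , drop = FALSE],
                           class_idx[keep])
      disc_state$W <- disc_state$W - adv$disc_lr * dg$gW
      disc_state$b <- disc_state$b - adv$disc_lr * dg$gb
      disc_loss <- dg$loss
    }
  } else {
    warning("batch holds a single patient; discriminator step skipped.",
            call. = FALSE)
  }
  fa <- NULL
  if (adv$beta > 0 && any(keep)) {
    dg <- disc_confusion_grad(disc_state, feats[keep, , drop = FALSE])
    fa <- matrix(0, nrow(batch), ncol(feats))
    fa[keep, ] <- adv$beta * dg$gfeats * sum(keep)
  }
  if (trainer == "sg") {
    res <- bptt_train_step(batch, weights, config, surrogate, opt_state,
                           lr, detach_reset, feature_adjoints = fa)
  } else {
    res <- ide_train_step_adv(batch, weights, config, opt_state, lr,
                              mode = ide_mode, sim_steps = ide_sim_steps,
                              feature_adjoints = fa)
  }
  list(weights = res$weights, opt_state = res$opt_state,
       disc_state = disc_state, model_loss = res$loss,
       disc_loss = disc_loss)
}

#' Probe how much patient identity the features still carry
#'
#' Trains a fresh softmax identity classifier on the detector's
#' extracted features (time-averaged top-layer spike rates) for a random
#' `train_fraction` of the segments and reports its accuracy on the
#' held-out remainder. After successful patient-invariant training this
#' accuracy should approach chance (1 / number of patients).
#'
#' @param fit An `eesnn_fit`.
#' @param segments Segments tibble with `patient_id`.
#' @param train_fraction Fraction of segments used to train the probe.
#' @param steps,lr Probe gradient-descent schedule.
#' @param seed Integer seed for the probe split and initialization.
#' @param n_splits Number of random train/test splits to average over;
#'   a single 70/30 split is a noisy estimate of the decodable identity
#'   information, so invariance experiments should average several.
#' @return A list with `accuracy` (mean over splits), `accuracies` (per
#'   split), `chance`, and `n_patients`.
#' @export
identity_probe <- function(fit, segments, train_fraction = 0.7,
                           steps = 300, lr = 0.1, seed = 99L,
                           n_splits = 1L) {
  stopifnot(inherits(fit, "eesnn_fit"), n_splits >= 1)
  segs <- segments
  segs$data <- lapply(segs$data, function(m) m / fit$scale)
  feats <- features_of(segs, fit$weights, fit$config)
  ids <- match(segs$patient_id, sort(unique(segs$patient_id)))
  n_cl <- length(unique(ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  accs <- vapply(seq_len(n_splits), function(k) {
    set.seed(seed + k - 1L)
    tr <- sample(nrow(segs), floor(train_fraction * nrow(segs)))
    disc <- disc_init(n_cl, ncol(feats), seed = seed + k - 1L)
    for (i in seq_len(steps)) {
      dg <- disc_loss_grad(disc, feats[tr, , drop = FALSE], ids[tr])
      disc$W <- disc$W - lr * dg$gW
      disc$b <- disc$b - lr * dg$gb
    }
    mean(disc_predict(disc, feats[-tr, , drop = FALSE]) == ids[-tr])
  }, numeric(1))
  list(accuracy = mean(accs), accuracies = accs, chance = 1 / n_cl,
       n_patients = n_cl)
}

#' Adapt a trained detector on a new patient's data
#'
#' Continues training from the fitted weights on a small set of
#' adaptation segments, with a hard guard that none of them appear in
#' the evaluation pool.
#'
#' @param fit An `eesnn_fit`.
#' @param adaptation Segments tibble used for adaptation.
#' @param eval_segments Segments tibble that will be evaluated on; any
#'   overlap with `adaptation` raises an error.
#' @param epochs Adaptation epochs; 0 returns the fit unchanged.
#' @param batch_size,lr Adaptation schedule.
#' @param seed Integer seed for shuffling.
#' @return The adapted `eesnn_fit`.
#' @export
finetune <- function(fit, adaptation, eval_segments, epochs = 1,
                     batch_size = 16, lr = 1e-4, seed = 1L) {
  stopifnot(inherits(fit, "eesnn_fit"))
  overlap <- intersect(adaptation$segment_id, eval_segments$segment_id)
  if (length(overlap) > 0) {
    stop("adaptation and evaluation segments overlap: ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  if (epochs == 0 || nrow(adaptation) == 0) return(fit)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  adaptation$data <- lapply(adaptation$data, function(m) m / fit$scale)
  weights <- fit$weights
  opt_state <- NULL
  n <- nrow(adaptation)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (st in seq(1L, n, by = batch_size)) {
      batch <- adaptation[idx[st:min(st + batch_size - 1L, n)], ]
      if (fit$trainer == "sg") {
        res <- bptt_train_step(batch, weights, fit$config, fit$surrogate,
                               opt_state, lr)
      } else {
        res <- ide_train_step(batch, weights, fit$config, opt_state, lr)
      }
      weights <- res$weights
      opt_state <- res$opt_state
    }
  }
  fit$weights <- weights
  fit
}
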