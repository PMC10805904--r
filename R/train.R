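# optimizer and high-level training orchestration

#' @noRd
add_grads <- function(a, b) {
  if (is.list(a)) Map(add_grads, a, b) else a + b
}

#' @noRd
scale_grads <- function(g, s) {
  if (is.list(g)) lapply(g, scale_grads, s = s) else g * s
}

#' @noRd
zeros_like <- function(a) {
  if (is.list(a)) lapply(a, zeros_like) else a * 0
}

#' @noRd
adam_update <- function(weights, grads, state = NULL, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  w <- unclass(weights)
  if (is.null(state)) {
    state <- list(t = 0L, m = zeros_like(w), v = zeros_like(w))
  }
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(w, g, m, v) {
    if (is.list(w)) {
      res <- Map(rec, w, g, m, v)
      list(w = lapply(res, `[[`, "w"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(w = w - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
    }
  }
  res <- rec(w, grads, state$m, state$v)
  list(weights = structure(res$w, class = "eesnn_weights"),
       opt_state = list(t = state$t, m = res$m, v = res$v))
}

#' Train a seizure detector
#'
#' End-to-end training on a segments tibble: optional class-ratio
#' rebalancing, optional multivariate-Gaussian seizure augmentation of
#' the training data (never of evaluation data), optional adversarial
#' patient-identity confusion, and mini-batch optimization with either
#' the surrogate-gradient BPTT trainer or the equilibrium
#' (implicit-differentiation) trainer. Segments are rescaled by one
#' global standard deviation estimated from the training data (stored in
#' the fit and re-applied at evaluation) so that input currents are on
#' the scale of the firing threshold.
#'
#' @param segments Segments tibble (see [segment_cohort()]).
#' @param config An [eesnn_config]; its input shape must match the data.
#' @param trainer `"sg"` (surrogate-gradient BPTT) or `"ide"`
#'   (equilibrium / implicit differentiation).
#' @param surrogate A [surrogate_spec] for the SG trainer.
#' @param epochs,batch_size,lr Optimization schedule.
#' @param seed Integer seed governing shuffling, augmentation and
#'   initialization.
#' @param rebalance_ratio If non-`NULL`, subsample non-seizure segments
#'   to this many per seizure segment before training.
#' @param stea If `TRUE`, augment training seizure segments with
#'   [generate_stea()] draws until the seizure:non-seizure ratio reaches
#'   `1:stea_target_ratio`.
#' @param stea_target_ratio Target non-seizure per seizure ratio after
#'   augmentation.
#' @param adversarial An [adversarial_config()] or `NULL`.
#' @param standardize Rescale by the global training standard deviation.
#' @param ide_mode,ide_sim_steps Passed to [ide_train_step()].
#' @param detach_reset Passed to [bptt_train_step()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `eesnn_fit` with elements `weights`,
#'   `config`, `trainer`, `surrogate`, `scale`, `log` (a tibble of
#'   per-batch losses), and discriminator state when adversarial
#'   training was used.
#' @export
train_detector <- function(segments, config,
                           trainer = c("sg", "ide"),
                           surrogate = surrogate_spec(),
                           epochs = 5, batch_size = 16, lr = 1e-3,
                           seed = 1L,
                           rebalance_ratio = NULL,
                           stea = FALSE, stea_target_ratio = 5,
                           adversarial = NULL,
                           standardize = TRUE,
                           ide_mode = "simulate", ide_sim_steps = 30,
                           detach_reset = FALSE,
                           verbose = FALSE) {
  trainer <- match.arg(trainer)
  stopifnot(inherits(config, "eesnn_config"), nrow(segments) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (!is.null(rebalance_ratio)) {
    segments <- rebalance_segments(segments, ratio = rebalance_ratio,
                                   seed = seed)
  }
  if (stea) {
    segments <- augment_stea(segments, target_ratio = stea_target_ratio,
                             seed = seed + 1L)
  }
  scale <- 1
  if (standardize) {
    scale <- stats::sd(unlist(lapply(segments$data, as.vector)))
    if (!is.finite(scale) || scale == 0) scale <- 1
    segments$data <- lapply(segments$data, function(m) m / scale)
  }

  weights <- eesnn_init_weights(config)
  opt_state <- NULL
  disc_state <- NULL
  if (!is.null(adversarial)) {
    ids <- sort(unique(segments$patient_id))
    disc_state <- disc_init(n_classes = length(ids),
                            n_features = config$hidden_channels[
                              config$hidden_layers],
                            seed = seed + 2L)
    disc_state$classes <- ids
  }

  n <- nrow(segments)
  log_rows <- list()
  step_id <- 0L
  best_disc_acc <- Inf
  best_weights <- NULL
  snapshot_from <- max(2L, round(epochs / 5))
  for (ep in seq_len(epochs)) {
    if (!is.null(adversarial) && adversarial$beta > 0 &&
        adversarial$refresh_steps > 0) {
      # retrain the identity discriminator on the whole training set so
      # confusion targets the identity information actually left
      feats_all <- features_of(segments, weights, config)
      cls <- match(segments$patient_id, disc_state$classes)
      for (i in seq_len(adversarial$refresh_steps)) {
        dg <- disc_loss_grad(disc_state, feats_all, cls)
        disc_state$W <- disc_state$W - adversarial$disc_lr * dg$gW
        disc_state$b <- disc_state$b - adversarial$disc_lr * dg$gb
      }
      acc_in <- mean(disc_predict(disc_state, feats_all) == cls)
      if (adversarial$snapshot && ep >= snapshot_from &&
          acc_in < best_disc_acc) {
        best_disc_acc <- acc_in
        best_weights <- weights
      }
    }
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (st in starts) {
      batch <- segments[idx[st:min(st + batch_size - 1L, n)], ]
      step_id <- step_id + 1L
      disc_loss <- NA_real_
      if (!is.null(adversarial)) {
        res <- adversarial_round(batch, weights, disc_state, adversarial,
                                 trainer = trainer, config = config,
                                 surrogate = surrogate,
                                 opt_state = opt_state, lr = lr,
                                 ide_mode = ide_mode,
                                 ide_sim_steps = ide_sim_steps,
                                 detach_reset = detach_reset)
        weights <- res$weights
        opt_state <- res$opt_state
        disc_state <- res$disc_state
        loss <- res$model_loss
        disc_loss <- res$disc_loss
      } else if (trainer == "sg") {
        res <- bptt_train_step(batch, weights, config, surrogate,
                               opt_state, lr, detach_reset)
        weights <- res$weights
        opt_state <- res$opt_state
        loss <- res$loss
      } else {
        res <- ide_train_step(batch, weights, config, opt_state, lr,
                              mode = ide_mode, sim_steps = ide_sim_steps)
        weights <- res$weights
        opt_state <- res$opt_state
        loss <- res$loss
      }
      ep_loss <- ep_loss + loss
      log_rows[[step_id]] <- tibble::tibble(epoch = ep, step = step_id,
                                            loss = loss,
                                            disc_loss = disc_loss)
    }
    if (verbose) {
      message(sprintf("epoch %d: mean loss %.4f", ep,
                      ep_loss / length(starts)))
    }
  }
  selection <- NULL
  if (!is.null(best_weights)) {
    weights <- best_weights
    selection <- list(disc_accuracy = best_disc_acc)
  }
  structure(list(weights = weights, config = config, trainer = trainer,
                 surrogate = surrogate, scale = scale,
                 opt_state = opt_state, disc_state = disc_state,
                 selection = selection,
                 log = dplyr::bind_rows(log_rows)),
            class = "eesnn_fit")
}

#' Evaluate a trained detector on held-out segments
#'
#' Runs the spiking forward pass on every segment (rescaled by the fit's
#' training scale), classifies at the probability threshold, and reports
#' the confusion counts, the derived metrics (sensitivity, specificity,
#' GMean, rebalanced accuracy, AUC), the average spiking probability, and
#' the theoretical energy estimate from the counted synaptic operations.
#'
#' @param fit An `eesnn_fit` from [train_detector()].
#' @param segments Segments tibble to evaluate on.
#' @param threshold Probability threshold for classification.
#' @return An object of class `eesnn_eval`: list with `predictions`
#'   (tibble: segment_id, label, probability, prediction), `confusion`,
#'   `metrics`, `spiking`, and `energy` tibbles.
#' @export
evaluate_detector <- function(fit, segments, threshold = 0.5) {
  stopifnot(inherits(fit, "eesnn_fit"), nrow(segments) >= 1)
  if (any(segments$synthetic)) {
    stop("synthetic (augmented) segments must never enter an evaluation ",
         "pool.", call. = FALSE)
  }
  probs <- numeric(nrow(segments))
  mac <- 0
  ac <- 0
  spike_tot <- 0
  unit_tot <- 0
  for (i in seq_len(nrow(segments))) {
    tr <- eesnn_forward(segments$data[[i]] / fit$scale, fit$weights,
                        fit$config)
    probs[i] <- tr$probability
    ops <- count_ops(fit$weights, fit$config, tr)
    mac <- mac + ops$mac_ops
    ac <- ac + ops$ac_ops
    sp <- spiking_probability(tr)
    spike_tot <- spike_tot + sp$spikes
    unit_tot <- unit_tot + sp$units
  }
  preds <- as.integer(probs > threshold)
  cc <- confusion(segments$label, preds)
  met <- seizure_metrics(cc, scores = probs, labels = segments$label)
  energy <- estimate_energy(mac / nrow(segments), ac / nrow(segments))
  structure(list(
    predictions = tibble::tibble(segment_id = segments$segment_id,
                                 patient_id = segments$patient_id,
                                 label = segments$label,
                                 probability = probs,
                                 prediction = preds),
    confusion = cc,
    metrics = met,
    spiking = tibble::tibble(average_spiking_probability =
                               spike_tot / unit_tot),
    energy = energy), class = "eesnn_eval")
}

#' Leave-one-subject-out cross-patient evaluation
#'
#' Trains one detector per fold on all other patients' segments and
#' evaluates on the held-out patient, optionally adapting on an initial
#' temporal fraction of the held-out patient's segments (which are then
#' excluded from evaluation).
#'
#' @param segments Segments tibble covering several patients.
#' @param config An [eesnn_config].
#' @param finetune_fraction Fraction in \[0, 1) of each test patient's
#'   segments (in temporal order) used for adaptation.
#' @param finetune_epochs Epochs of adaptation training.
#' @param ... Passed to [train_detector()].
#' @return A tibble with one row per fold (test patient, metrics) plus
#'   an `aggregate` attribute with pooled-confusion metrics.
#' @export
run_loso <- function(segments, config, finetune_fraction = 0,
                     finetune_epochs = 1, ...) {
  splits <- make_splits(segments, mode = "leave_one_out",
                        finetune_fraction = finetune_fraction)
  rows <- list()
  pooled <- NULL
  for (k in seq_len(nrow(splits))) {
    fit <- train_detector(splits$train[[k]], config, ...)
    if (finetune_fraction > 0 && nrow(splits$finetune[[k]]) > 0) {
      fit <- finetune(fit, splits$finetune[[k]], splits$eval[[k]],
                      epochs = finetune_epochs)
    }
    ev <- evaluate_detector(fit, splits$eval[[k]])
    pooled <- if (is.null(pooled)) ev$confusion else {
      tibble::tibble(TP = pooled$TP + ev$confusion$TP,
                     FP = pooled$FP + ev$confusion$FP,
                     TN = pooled$TN + ev$confusion$TN,
                     FN = pooled$FN + ev$confusion$FN)
    }
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(fold = k, test_patient = splits$test_patient[k]),
      ev$metrics)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "aggregate") <- seizure_metrics(pooled)
  out
}
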