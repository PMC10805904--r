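# Detection metrics, theoretical neuromorphic energy model, and
# gradient saliency.

#' Confusion counts for binary seizure labels
#'
#' @param labels Integer vector of true labels in \{0, 1\}.
#' @param predictions Integer vector of predicted labels, same length.
#' @return A one-row tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("`labels` and `predictions` differ in length.", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be binary.", call. = FALSE)
  }
  tibble::tibble(TP = sum(labels == 1 & predictions == 1),
                 FP = sum(labels == 0 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FN = sum(labels == 1 & predictions == 0))
}

#' @noRd
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seizure detection metrics
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, their
#' geometric mean (GMean), the class-rebalanced accuracy
#' `(r*TP + TN) / (r*(TP+FN) + TN + FP)`, and (when scores are given)
#' the AUC by the rank (Mann-Whitney) statistic with ties counted 0.5.
#'
#' The rebalancing weight defaults to `r = (TN+FP)/(TP+FN)`, under which
#' the rebalanced accuracy is algebraically the arithmetic mean of
#' sensitivity and specificity; `r` can be overridden.
#'
#' A metric whose denominator class is absent is reported as `NA`
#' ("undefined") with a warning, never as 0. All metrics are on the
#' \[0, 1\] scale.
#'
#' @param counts Confusion counts ([confusion()] output or any list with
#'   `TP`, `FP`, `TN`, `FN`).
#' @param scores Optional numeric classifier scores for the AUC.
#' @param labels Labels aligned with `scores`.
#' @param r Optional rebalancing weight override.
#' @return A one-row tibble: `sensitivity`, `specificity`, `gmean`,
#'   `raccuracy`, `auc`.
#' @export
seizure_metrics <- function(counts, scores = NULL, labels = NULL,
                            r = NULL) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  pos <- TP + FN
  neg <- TN + FP
  if (pos == 0 || neg == 0) {
    warning("a class is empty; dependent metrics are undefined (NA).",
            call. = FALSE)
  }
  sens <- if (pos > 0) TP / pos else NA_real_
  spec <- if (neg > 0) TN / neg else NA_real_
  gmean <- sqrt(sens * spec)
  if (is.null(r)) r <- if (pos > 0) neg / pos else NA_real_
  racc <- (r * TP + TN) / (r * pos + neg)
  auc <- if (!is.null(scores)) {
    stopifnot(length(scores) == length(labels))
    auc_rank(scores, labels)
  } else {
    NA_real_
  }
  tibble::tibble(sensitivity = sens, specificity = spec, gmean = gmean,
                 raccuracy = racc, auc = auc)
}

#' Average spiking probability of a forward trace
#'
#' Total spike count divided by (number of neurons x simulation steps),
#' per layer and as the neuron-weighted average across layers - the
#' sparsity statistic that drives the event-driven energy advantage.
#'
#' @param trace An `eesnn_trace`.
#' @return List with `per_layer` (tibble: layer, neurons, probability),
#'   `average`, and the raw totals `spikes` and `units`.
#' @export
spiking_probability <- function(trace) {
  stopifnot(inherits(trace, "eesnn_trace"))
  Tn <- length(trace$spikes)
  H <- length(trace$spikes[[1]])
  per <- lapply(seq_len(H), function(l) {
    n <- length(trace$spikes[[1]][[l]])
    if (n == 0) stop("layer with zero neurons.", call. = FALSE)
    sp <- sum(vapply(trace$spikes, function(st) sum(st[[l]]), numeric(1)))
    tibble::tibble(layer = l, neurons = n, spikes = sp,
                   probability = sp / (n * Tn))
  })
  per <- dplyr::bind_rows(per)
  list(per_layer = per[, c("layer", "neurons", "probability")],
       average = sum(per$spikes) / (sum(per$neurons) * Tn),
       spikes = sum(per$spikes),
       units = sum(per$neurons) * Tn)
}

#' Theoretical energy estimate from operation counts
#'
#' Energy per 32-bit floating-point operation on a 45 nm CMOS process:
#' 4.6 pJ for a multiply-accumulate (MAC, dense/ANN-style) and 0.9 pJ
#' for an accumulate (AC, event-driven spike-triggered). Total energy is
#' linear in the counts.
#'
#' @param mac_ops,ac_ops Nonnegative operation counts.
#' @param e_mac,e_ac Per-operation energies in pJ.
#' @return A one-row tibble: `mac_ops`, `ac_ops`, `energy_pJ`,
#'   `energy_mJ`.
#' @examples
#' estimate_energy(2.6e10, 0)  # 119.6 mJ
#' @export
estimate_energy <- function(mac_ops, ac_ops, e_mac = 4.6, e_ac = 0.9) {
  if (mac_ops < 0 || ac_ops < 0) {
    stop("operation counts must be nonnegative.", call. = FALSE)
  }
  pj <- e_mac * mac_ops + e_ac * ac_ops
  tibble::tibble(mac_ops = mac_ops, ac_ops = ac_ops,
                 energy_pJ = pj, energy_mJ = pj * 1e-9)
}

#' Count synaptic operations for one forward trace
#'
#' Dense (ANN) mode counts one MAC for every synapse of every layer at
#' every simulation step. Event-driven (SNN) mode counts one AC per
#' synapse per actually-fired presynaptic spike; the input-layer
#' convolution (analog input current) and the readout remain MACs.
#' Feedback synapses are counted from the second step onwards in both
#' modes (the first step has no feedback input). Boundary effects of the
#' same-padding convolutions are counted exactly.
#'
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param trace An `eesnn_trace` from [eesnn_forward()].
#' @return List with `mac_ops` (all-dense total), `ac_ops`
#'   (spike-driven accumulates), and `snn_mac_ops` (the MACs that remain
#'   in event-driven mode: input layer + readout).
#' @export
count_ops <- function(weights, config, trace) {
  H <- config$hidden_layers
  Tn <- length(trace$spikes)
  kh <- config$kernel_size[1]
  kw <- config$kernel_size[2]
  ch <- config$hidden_channels
  grid <- dim(trace$spikes[[1]][[1]])[2:3]
  fan <- function(out_ch) conv_fanout_map(grid[1], grid[2], kh, kw, out_ch)
  # input layer: 1 image channel feeding ch[1] output channels
  input_mac <- sum(fan(ch[1])) * Tn
  readout_mac <- length(weights$W0) * Tn
  dense <- input_mac + readout_mac
  # feedback: ch[H] presynaptic channels into ch[1], steps 2..Tn
  dense <- dense + sum(fan(ch[1])) * ch[H] * max(0, Tn - 1)
  if (H >= 2) {
    for (l in 2:H) {
      dense <- dense + sum(fan(ch[l])) * ch[l - 1] * Tn
    }
  }
  ac <- 0
  fb_fan <- fan(ch[1])
  for (t in seq_len(Tn)) {
    if (t < Tn) {
      sH <- trace$spikes[[t]][[H]]
      pos <- colSums(matrix(sH, dim(sH)[1]))
      ac <- ac + sum(pos * as.vector(fb_fan))
    }
    if (H >= 2) {
      for (l in 2:H) {
        s <- trace$spikes[[t]][[l - 1]]
        pos <- colSums(matrix(s, dim(s)[1]))
        ac <- ac + sum(pos * as.vector(fan(ch[l])))
      }
    }
  }
  list(mac_ops = dense, ac_ops = ac,
       snn_mac_ops = input_mac + readout_mac)
}

#' Gradient saliency map of a window
#'
#' Gradient of the seizure logit (accumulated readout potential) with
#' respect to the input window, computed through the spiking forward
#' pass with the surrogate derivative standing in for the spike
#' nonlinearity, and mapped back onto (channel, time) of the raw
#' segment. Values are signed: positive entries push the decision
#' towards seizure.
#'
#' @param x Numeric matrix (channels x samples).
#' @param weights An [eesnn_weights].
#' @param config An [eesnn_config].
#' @param surrogate A [surrogate_spec]; required for differentiability.
#' @return An object of class `eesnn_saliency`: a channels x samples
#'   matrix of signed importances.
#' @export
saliency <- function(x, weights, config, surrogate = NULL) {
  if (is.null(surrogate)) {
    stop("saliency needs a surrogate_spec (e.g. surrogate_spec('atan')) ",
         "for the backward pass.", call. = FALSE)
  }
  g <- bptt_grad(x, y = NULL, weights, config, surrogate, dlogit = 1)
  structure(g$g_input, class = c("eesnn_saliency", "matrix", "array"))
}
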