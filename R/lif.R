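#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the discrete-time leaky integrate-and-fire (LIF) neuron
#' with subtractive ("soft") reset. At each step the membrane potential is
#' leaked by a factor `lambda`, the input current is integrated, and a
#' binary spike is emitted whenever the pre-reset potential reaches the
#' firing threshold; the threshold is then subtracted from the membrane
#' rather than clamping it to the reset value, so no charge is discarded.
#'
#' @param lambda Leak factor in (0, 1]. `lambda = 1` gives a non-leaky
#'   integrate-and-fire neuron. The leak stands in for the membrane time
#'   constant of the underlying continuous-time model after discretization.
#' @param v_th Firing threshold (potential units), must exceed `u_reset`.
#' @param u_reset Reset baseline (potential units); the membrane starts
#'   here and the soft reset subtracts `v_th` towards it. Default 0.
#' @param tau_m Optional membrane time constant, kept for documentation
#'   only; dynamics are parameterized directly by `lambda`.
#'
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params(lambda = 0.9, v_th = 1)
#' @export
lif_params <- function(lambda = 0.9, v_th = 1, u_reset = 0, tau_m = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(v_th), length(v_th) == 1L, is.finite(v_th),
            is.numeric(u_reset), length(u_reset) == 1L, is.finite(u_reset))
  if (lambda <= 0 || lambda > 1) {
    stop("`lambda` must lie in (0, 1].", call. = FALSE)
  }
  if (v_th <= u_reset) {
    stop("`v_th` must be greater than `u_reset`.", call. = FALSE)
  }
  structure(list(lambda = lambda, v_th = v_th, u_reset = u_reset,
                 tau_m = tau_m),
            class = "lif_params")
}

#' LIF layer state
#'
#' Membrane potentials and the spikes emitted at the current step, one
#' entry per neuron. Spikes are strictly binary.
#'
#' @param u Numeric array of membrane potentials.
#' @param s Numeric array of spikes in \{0, 1\}, same shape as `u`.
#' @return An object of class `lif_state`.
#' @export
lif_state <- function(u, s = array(0, dim(as.array(u)))) {
  u <- as.array(u)
  s <- as.array(s)
  if (!identical(dim(u), dim(s))) {
    stop("`u` and `s` must have identical shapes.", call. = FALSE)
  }
  if (!all(s %in% c(0, 1))) {
    stop("spikes must be exactly 0 or 1.", call. = FALSE)
  }
  structure(list(u = u, s = s), class = "lif_state")
}

#' One discrete LIF update with soft reset
#'
#' Computes the pre-reset potential `lambda * u + input`, emits a spike
#' wherever it reaches the threshold (`>=`, so a potential exactly at
#' threshold fires), and subtracts `v_th` for every spike. The identity
#' `u_new + v_th * s_new == lambda * u_old + input` holds exactly.
#'
#' @param state A [lif_state].
#' @param input_current Numeric array of input currents, same shape as the
#'   state.
#' @param params A [lif_params].
#' @return The updated [lif_state].
#' @examples
#' s <- lif_state(array(0.8, 1))
#' lif_step(s, array(0.6, 1), lif_params(lambda = 0.5, v_th = 1))
#' @export
lif_step <- function(state, input_current, params) {
  stopifnot(inherits(state, "lif_state"), inherits(params, "lif_params"))
  input_current <- as.array(input_current)
  if (!identical(dim(input_current), dim(state$u))) {
    stop("`input_current` shape does not match the state.", call. = FALSE)
  }
  if (!all(is.finite(input_current))) {
    stop("`input_current` contains non-finite values.", call. = FALSE)
  }
  pre <- params$lambda * state$u + input_current
  s <- (pre >= params$v_th) * 1
  lif_state(pre - params$v_th * s, s)
}

#' Run a LIF layer over a spike-train input
#'
#' Iterates [lif_step()] from the zero-membrane initial state over a
#' sequence of input currents and returns the full state sequence.
#'
#' @param inputs List of numeric arrays (one per step, identical shapes).
#' @param params A [lif_params].
#' @return A list of [lif_state] objects, one per step.
#' @examples
#' run_spike_train(rep(list(array(0.6, 1)), 3), lif_params(lambda = 1))
#' @export
run_spike_train <- function(inputs, params) {
  if (!is.list(inputs) || length(inputs) == 0L) {
    stop("`inputs` must be a non-empty list of arrays.", call. = FALSE)
  }
  state <- lif_state(array(params$u_reset, dim(as.array(inputs[[1]]))))
  out <- vector("list", length(inputs))
  for (t in seq_along(inputs)) {
    state <- lif_step(state, inputs[[t]], params)
    out[[t]] <- state
  }
  out
}
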