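#' Spike-timing-dependent plasticity parameters
#'
#' Asymmetric exponential STDP window. With `delta_t = t_pre - t_post`, a
#' presynaptic arrival preceding the postsynaptic spike (`delta_t < 0`)
#' potentiates by `A_plus * exp(delta_t / tau_plus)`; otherwise the synapse
#' depresses by `|A_minus| * exp(-delta_t / tau_minus)`. The depression
#' window (`tau_minus = 18` ms) is deliberately wider than the potentiation
#' window (`tau_plus = 3` ms) so learning sharpens spike order instead of
#' collapsing the population into strict synchrony. Raw window values are
#' scaled by the learning rate `eta` and the weight is clipped to
#' `[w_min, w_max]`.
#'
#' @param a_plus maximum potentiation (window peak)
#' @param a_minus maximum depression; the magnitude is used
#' @param tau_plus potentiation window time constant (ms)
#' @param tau_minus depression window time constant (ms)
#' @param eta learning rate applied to the raw window value
#' @param w_min,w_max weight clip bounds
#' @return an object of class `stdp_params`
#' @export
stdp_params <- function(a_plus = 1, a_minus = -1, tau_plus = 3,
                        tau_minus = 18, eta = 0.2, w_min = 0, w_max = 3) {
  stopifnot(tau_plus > 0, tau_minus > 0, eta > 0, w_max > w_min)
  structure(list(a_plus = a_plus, a_minus = abs(a_minus),
                 tau_plus = tau_plus, tau_minus = tau_minus, eta = eta,
                 w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' Raw STDP weight change for a spike-time difference
#'
#' @param delta_t `t_pre - t_post` (ms); the presynaptic time is the arrival
#'   time of the spike at the synapse. Vectorized.
#' @param params an [stdp_params()]
#' @return raw weight change (unscaled by the learning rate): positive
#'   (potentiation) for `delta_t < 0`, negative (depression) for
#'   `delta_t >= 0`
#' @examples
#' stdp_dw(-3)  # exp(-1), pre leads post by one potentiation time constant
#' stdp_dw(0)   # -1, simultaneous spikes take the depression branch
#' @export
stdp_dw <- function(delta_t, params = stdp_params()) {
  ifelse(delta_t < 0,
         params$a_plus * exp(delta_t / params$tau_plus),
         -params$a_minus * exp(-delta_t / params$tau_minus))
}

#' Nearest-neighbor pairing state
#'
#' Bookkeeping for one plastic synapse under the nearest-neighbor pairing
#' scheme: the most recent unpaired presynaptic arrival and postsynaptic
#' spike. Each spike is used at most once per pairing direction — once a
#' pre event pairs with the stored post spike (or vice versa) the partner
#' is consumed.
#'
#' @param last_pre time of the most recent unconsumed presynaptic arrival
#'   (ms), or `NA`
#' @param last_post time of the most recent unconsumed postsynaptic spike
#'   (ms), or `NA`
#' @return an object of class `pairing_state`
#' @export
pairing_state <- function(last_pre = NA_real_, last_post = NA_real_) {
  structure(list(last_pre = last_pre, last_post = last_post),
            class = "pairing_state")
}

#' Apply one pre or post spike event to a plastic synapse
#'
#' Under nearest-neighbor pairing, a presynaptic arrival pairs with the
#' stored postsynaptic spike (depression, since the arrival follows it) and
#' a postsynaptic spike pairs with the stored presynaptic arrival
#' (potentiation when the arrival came first). The weight update is
#' `w <- clip(w + eta * stdp_dw(t_pre - t_post), w_min, w_max)` and the
#' consumed partner is cleared.
#'
#' @param w current synaptic weight
#' @param pairing a [pairing_state()]
#' @param event `"pre"` (arrival at the synapse) or `"post"`
#' @param t event time (ms); for `"pre"` events this is the arrival time
#'   (emission plus conduction delay)
#' @param params an [stdp_params()]
#' @return list with updated `w` and `pairing`
#' @examples
#' p <- pairing_state()
#' ev <- on_spike_event(0.07, p, "pre", 10)       # nothing to pair yet
#' on_spike_event(ev$w, ev$pairing, "post", 13)$w # 0.07 + 0.2 * exp(-1)
#' @export
on_spike_event <- function(w, pairing, event = c("pre", "post"), t,
                           params = stdp_params()) {
  event <- match.arg(event)
  if (event == "pre") {
    if (!is.na(pairing$last_post)) {
      w <- w + params$eta * stdp_dw(t - pairing$last_post, params)
      pairing$last_post <- NA_real_
    }
    pairing$last_pre <- t
  } else {
    if (!is.na(pairing$last_pre)) {
      w <- w + params$eta * stdp_dw(pairing$last_pre - t, params)
      pairing$last_pre <- NA_real_
    }
    pairing$last_post <- t
  }
  w <- min(max(w, params$w_min), params$w_max)
  list(w = w, pairing = pairing)
}

#' Replay a time-ordered pre/post event train through one synapse
#'
#' Convenience driver over [on_spike_event()]: applies a whole train of
#' events in time order and returns the weight trajectory.
#'
#' @param w0 initial weight
#' @param events data frame with columns `time` (ms) and `side`
#'   (`"pre"`/`"post"`), sorted by time
#' @param params an [stdp_params()]
#' @return list with the final `w`, final `pairing` state, and the numeric
#'   vector `trajectory` of the weight after each event
#' @export
stdp_replay <- function(w0, events, params = stdp_params()) {
  stopifnot(all(diff(events$time) >= 0))
  pairing <- pairing_state()
  w <- w0
  traj <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    r <- on_spike_event(w, pairing, events$side[i], events$time[i], params)
    w <- r$w
    pairing <- r$pairing
    traj[i] <- w
  }
  list(w = w, pairing = pairing, trajectory = traj)
}
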