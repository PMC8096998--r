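#' Izhikevich neuron parameters
#'
#' Parameter quadruple (a, b, c, d) of the two-variable Izhikevich model.
#' `a` sets the recovery time scale, `b` the recovery sensitivity to the
#' membrane potential, `c` the post-spike reset potential (mV) and `d` the
#' post-spike recovery increment. Presets: `"excitatory"` is the regular
#' spiking set (0.02, 0.2, -65, 8) and `"inhibitory"` (0.04, 0.24, -65, 2).
#'
#' @param type preset name, `"excitatory"` or `"inhibitory"`, ignored when
#'   all four values are supplied
#' @param a,b,c,d explicit parameter values overriding the preset
#' @return an object of class `izh_params` (named list)
#' @examples
#' izh_params("excitatory")
#' @export
izh_params <- function(type = c("excitatory", "inhibitory"),
                       a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(a)) {
    type <- match.arg(type)
    p <- switch(type,
      excitatory = list(a = 0.02, b = 0.2, c = -65, d = 8),
      inhibitory = list(a = 0.04, b = 0.24, c = -65, d = 2))
  } else {
    stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
    p <- list(a = a, b = b, c = c, d = d)
  }
  structure(p, class = "izh_params")
}

#' Neuron state
#'
#' Membrane potential `v` (mV) and recovery variable `u` of one Izhikevich
#' unit. The default is the resting state for the supplied parameters
#' (`v = -65`, `u = b * v`).
#'
#' @param v membrane potential (mV)
#' @param u recovery variable; defaults to `b * v` for `params`
#' @param params an [izh_params()] object used for the default `u`
#' @return an object of class `neuron_state`
#' @export
neuron_state <- function(v = -65, u = NULL, params = izh_params()) {
  if (is.null(u)) u <- params$b * v
  structure(list(v = v, u = u), class = "neuron_state")
}

#' Resting state of an Izhikevich neuron
#'
#' Solves the subthreshold fixed point of the two-variable system with zero
#' input: the stable root of `0.04 v^2 + (5 - b) v + 140 = 0` with
#' `u = b v` (for the regular-spiking preset this is `v = -70`,
#' `u = -14`).
#'
#' @param params an [izh_params()]
#' @return a [neuron_state()] at rest
#' @examples
#' izh_rest()$v  # -70 for the excitatory preset
#' @export
izh_rest <- function(params = izh_params()) {
  disc <- (5 - params$b)^2 - 4 * 0.04 * 140
  if (disc < 0) stop("no subthreshold rest state for these parameters")
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  neuron_state(v = v, u = params$b * v, params = params)
}

#' Advance one Izhikevich neuron by one explicit-Euler tick
#'
#' Integrates `v' = 0.04 v^2 + 5 v + 140 - u + I` and `u' = a (b v - u)` by
#' one explicit Euler step of length `dt`, then applies the spike rule: if
#' the membrane exceeds 30 mV a spike is registered and the state resets to
#' `v = c`, `u = u + d`. A state already above 30 mV on entry (e.g. a forced
#' injection) spikes immediately without integrating.
#'
#' @param state a [neuron_state()]
#' @param params an [izh_params()]
#' @param I total input current for this tick
#' @param dt tick length (ms), must be positive
#' @return list with the updated `state` and logical `spiked`
#' @examples
#' st <- neuron_state()
#' step_neuron(st, izh_params(), I = 10, dt = 0.5)
#' @export
step_neuron <- function(state, params, I, dt = 0.5) {
  stopifnot(dt > 0, is.finite(state$v), is.finite(state$u))
  v <- state$v
  u <- state$u
  spiked <- FALSE
  if (v > 30) {
    spiked <- TRUE
  } else {
    vo <- v
    uo <- u
    v <- vo + dt * (0.04 * vo^2 + 5 * vo + 140 - uo + I)
    u <- uo + dt * params$a * (params$b * vo - uo)
    if (!is.finite(v) || !is.finite(u)) {
      stop("numerical instability: non-finite membrane state after update")
    }
    if (v > 30) spiked <- TRUE
  }
  if (spiked) {
    v <- params$c
    u <- u + params$d
  }
  list(state = structure(list(v = v, u = u), class = "neuron_state"),
       spiked = spiked)
}

#' Postsynaptic potential kernel
#'
#' Unit alpha-shaped response `(t/tau) * exp(1 - t/tau)` of the postsynaptic
#' membrane to a single spike arrival at `t = 0`; zero for negative times.
#' The kernel peaks at exactly 1 when `t == tau`.
#'
#' @param t_since time since arrival (ms); vectorized
#' @param tau kernel time constant (ms), default 4
#' @return kernel value(s) in `[0, 1]`
#' @examples
#' psp_kernel(4)       # 1 at the peak
#' psp_kernel(8)       # 2 * exp(-1)
#' @export
psp_kernel <- function(t_since, tau = 4) {
  stopifnot(tau > 0)
  ifelse(t_since < 0, 0, (t_since / tau) * exp(1 - t_since / tau))
}

#' Short-term plasticity parameters
#'
#' Baseline utilization `U`, facilitation recovery `tau_f` (ms) and
#' depression recovery `tau_d` (ms) of the depressing/facilitating synapse
#' model. Between spikes the available resources `x` relax to 1 with time
#' constant `tau_d` and the utilization `u` relaxes to `U` with `tau_f`.
#'
#' @param U baseline utilization fraction, in (0, 1); the default 0.7 puts
#'   the synapse in the strongly depressing regime, in which the response to
#'   a rapid spike train declines from the first spike on
#' @param tau_f facilitation recovery time constant (ms)
#' @param tau_d depression recovery time constant (ms)
#' @return an object of class `stp_params`
#' @export
stp_params <- function(U = 0.7, tau_f = 20, tau_d = 50) {
  stopifnot(U > 0, U < 1, tau_f > 0, tau_d > 0)
  structure(list(U = U, tau_f = tau_f, tau_d = tau_d), class = "stp_params")
}

#' Synapse state constructor
#'
#' One delayed connection: presynaptic and postsynaptic neuron indices,
#' weight `w`, conduction `delay` (ms), short-term-plasticity state
#' (`x` available resources, `u_util` utilization, `t_last` last spike
#' time), whether STDP applies (`plastic`), and the sign carried into
#' transmission (`-1` for inhibitory presynaptic neurons).
#'
#' @param pre,post neuron indices
#' @param w synaptic weight (dimensionless efficacy, `>= 0`)
#' @param delay conduction delay (ms, `>= 1`)
#' @param plastic does STDP apply to this synapse
#' @param sign `+1` (excitatory) or `-1` (inhibitory transmission)
#' @param stp an [stp_params()] used to seed the utilization state
#' @return an object of class `synapse`
#' @export
synapse <- function(pre, post, w, delay, plastic = FALSE, sign = 1L,
                    stp = stp_params()) {
  stopifnot(w >= 0, delay >= 1, sign %in% c(-1L, 1L))
  structure(list(pre = pre, post = post, w = w, delay = delay,
                 x = 1, u_util = stp$U, t_last = -Inf,
                 plastic = plastic, sign = as.integer(sign)),
            class = "synapse")
}

#' Apply a presynaptic spike to a synapse's short-term-plasticity state
#'
#' Decays `x` toward 1 (time constant `tau_d`) and `u_util` toward `U`
#' (time constant `tau_f`) over the interval since the last spike, then
#' applies the spike: the facilitation jump `u <- u + U (1 - u)` first, the
#' transmitted efficacy is recorded as `u * x` with the post-facilitation
#' `u` and pre-depression `x`, and the depression jump `x <- x - u x`
#' follows. The arrival at the postsynaptic site is due at `t + delay`.
#'
#' @param s a [synapse()]
#' @param stp an [stp_params()]
#' @param t presynaptic spike time (ms); must not precede `s$t_last`
#' @return list with the updated `synapse`, the transmitted `efficacy`
#'   (`u * x`), and `arrival` time (`t + s$delay`)
#' @examples
#' s <- synapse(1, 2, w = 0.1, delay = 5, stp = stp_params(U = 0.2))
#' on_presynaptic_spike(s, stp_params(U = 0.2), t = 0)$efficacy  # 0.36
#' @export
on_presynaptic_spike <- function(s, stp, t) {
  if (t < s$t_last) {
    stop("event ordering violation: spike at t = ", t,
         " precedes last synapse event at t = ", s$t_last)
  }
  dte <- t - s$t_last
  x <- 1 - (1 - s$x) * exp(-dte / stp$tau_d)
  u <- stp$U + (s$u_util - stp$U) * exp(-dte / stp$tau_f)
  u <- u + stp$U * (1 - u)
  efficacy <- u * x
  x <- x - u * x
  s$x <- x
  s$u_util <- u
  s$t_last <- t
  list(synapse = s, efficacy = efficacy, arrival = t + s$delay)
}

#' Synaptic input current from past arrivals
#'
#' Sums `w * u * x * psp_kernel(t - t_i)` over all spike arrivals `t_i` at a
#' neuron within the truncation `horizon` (arrivals older than the horizon
#' contribute nothing; the kernel there is below 1e-3 of its peak). The
#' `amp` column of `arrivals` carries the signed product `w * u * x`
#' captured when the presynaptic spike was emitted, negative for inhibitory
#' presynaptic neurons.
#'
#' @param t evaluation time (ms)
#' @param arrivals data frame with columns `time` and `amp`
#' @param tau PSP kernel time constant (ms)
#' @param horizon truncation horizon (ms); `Inf` disables truncation
#' @return the summed current contribution at `t`
#' @export
synaptic_input <- function(t, arrivals, tau = 4, horizon = 40) {
  if (is.null(arrivals) || nrow(arrivals) == 0) return(0)
  dtv <- t - arrivals$time
  keep <- dtv >= 0 & dtv <= horizon
  if (!any(keep)) return(0)
  sum(arrivals$amp[keep] * psp_kernel(dtv[keep], tau))
}

#' Per-neuron background noise specification
#'
#' Each neuron receives a Gaussian noise current standing in for the
#' irrelevant input from surrounding cortex. The baseline mean is drawn
#' once per neuron, uniformly in `[mean_low, mean_high]`; `variance` is the
#' Gaussian variance (the standard deviation used is `sqrt(variance)`);
#' `offset` is an additive, regime-dependent shift applied to the mean of
#' eligible (excitatory, non-detector) neurons. The noise is piecewise
#' constant in time: each neuron holds its deviate for `hold_ms` before
#' redrawing (redraws are phase-staggered across neurons), giving the
#' current a short correlation time as a barrage of synaptic input from
#' slower surrounding tissue would have. `hold_ms` equal to the tick length
#' makes the draws independent across ticks.
#'
#' @param mean_low,mean_high bounds of the per-neuron baseline mean
#' @param variance Gaussian variance of the noise current
#' @param offset additive shift to the mean (regime dependent)
#' @param hold_ms correlation (hold) time of the noise current (ms)
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(mean_low = 1.5, mean_high = 2.0, variance = 1.8,
                       offset = 0, hold_ms = 2) {
  stopifnot(mean_high >= mean_low, variance >= 0, hold_ms > 0)
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 variance = variance, offset = offset, hold_ms = hold_ms),
            class = "noise_spec")
}
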