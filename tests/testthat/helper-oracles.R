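# Independent brute-force oracles used across the test files.

# Full-rescan reference simulator: advances a circuit tick by tick in pure R,
# recomputing every neuron's synaptic input by scanning the complete arrival
# history each tick (no event queue, no per-neuron buffers). Mirrors the
# engine's update equations and RNG discipline so rasters can be compared
# exactly.
simulate_bruteforce <- function(circuit, duration, injections = NULL,
                                offsets = NULL) {
  cfg <- circuit$cfg
  dt <- cfg$dt
  nN <- circuit$n_neurons
  v <- circuit$v; u <- circuit$u
  pa <- circuit$params$a; pb <- circuit$params$b
  pc <- circuit$params$c; pd <- circuit$params$d
  nm <- circuit$noise_mean; nsd <- circuit$noise_sd
  hold <- circuit$noise_hold
  elig <- circuit$offset_eligible
  syn <- circuit$syn
  w <- syn$w; x <- syn$x; uu <- syn$uu; tl <- syn$t_last
  lpre <- syn$last_pre; lpost <- syn$last_post
  stp <- cfg$stp; sp <- cfg$stdp
  tau <- cfg$psp_tau; horizon <- cfg$psp_horizon
  hold_ticks <- max(1L, as.integer(round(cfg$noise$hold_ms / dt)))
  dticks <- pmax(1L, as.integer(floor(syn$delay / dt + 0.5)))
  n_ticks <- as.integer(round(duration / dt))
  t0 <- circuit$time_now
  eff_of <- lapply(seq_len(nN), function(n) which(syn$pre == n))
  aff_of <- lapply(seq_len(nN), function(n) which(syn$post == n & syn$plastic))
  clip <- function(wn) min(max(wn, sp$w_min), sp$w_max)
  # chronological arrival log (append order matches the engine)
  arr_t <- numeric(0); arr_n <- integer(0); arr_a <- numeric(0)
  fut_tick <- integer(0); fut_n <- integer(0); fut_a <- numeric(0)
  fut_s <- integer(0)
  spikes_n <- integer(0); spikes_t <- numeric(0)
  forced_tick <- if (is.null(injections)) integer(0) else
    as.integer(round((injections$time - t0) / dt))
  for (it in 0:(n_ticks - 1)) {
    t <- t0 + it * dt
    abs_tick <- round(t / dt)
    due <- which(fut_tick == it)
    for (q in due) {
      arr_t <- c(arr_t, t); arr_n <- c(arr_n, fut_n[q])
      arr_a <- c(arr_a, fut_a[q])
      s <- fut_s[q]
      if (syn$plastic[s]) {
        if (is.finite(lpost[s])) {
          w[s] <- clip(w[s] + sp$eta *
                         (-sp$a_minus * exp(-(t - lpost[s]) / sp$tau_minus)))
          lpost[s] <- NA_real_
        }
        lpre[s] <- t
      }
    }
    if (length(due)) {
      keep <- setdiff(seq_along(fut_tick), due)
      fut_tick <- fut_tick[keep]; fut_n <- fut_n[keep]
      fut_a <- fut_a[keep]; fut_s <- fut_s[keep]
    }
    off <- 0
    if (!is.null(offsets)) {
      for (i in seq_len(nrow(offsets))) {
        if (t >= offsets$start[i] && t < offsets$end[i]) {
          off <- off + offsets$amount[i]
        }
      }
    }
    I <- numeric(nN)
    for (n in seq_len(nN)) {
      idx <- which(arr_n == n & t - arr_t <= horizon)
      isyn <- 0
      for (q in idx) isyn <- isyn + arr_a[q] * psp_kernel(t - arr_t[q], tau)
      if (((abs_tick + (n - 1)) %% hold_ticks) == 0) hold[n] <- rnorm(1)
      I[n] <- isyn + nm[n] + (if (elig[n]) off else 0) + nsd[n] * hold[n]
    }
    if (length(forced_tick)) {
      fn <- injections$neuron[forced_tick == it]
      v[fn] <- 40
    }
    spiked <- integer(0)
    for (n in seq_len(nN)) {
      spk <- FALSE
      if (v[n] > 30) {
        spk <- TRUE
      } else {
        vo <- v[n]; uo <- u[n]
        v[n] <- vo + dt * (0.04 * vo * vo + 5 * vo + 140 - uo + I[n])
        u[n] <- uo + dt * pa[n] * (pb[n] * vo - uo)
        if (v[n] > 30) spk <- TRUE
      }
      if (spk) {
        v[n] <- pc[n]; u[n] <- u[n] + pd[n]
        spiked <- c(spiked, n)
        spikes_n <- c(spikes_n, n); spikes_t <- c(spikes_t, t)
      }
    }
    for (n in spiked) {
      for (s in eff_of[[n]]) {
        dte <- t - tl[s]
        x[s] <- 1 - (1 - x[s]) * exp(-dte / stp$tau_d)
        uu[s] <- stp$U + (uu[s] - stp$U) * exp(-dte / stp$tau_f)
        uu[s] <- uu[s] + stp$U * (1 - uu[s])
        eff <- uu[s] * x[s]
        x[s] <- x[s] - uu[s] * x[s]
        tl[s] <- t
        fut_tick <- c(fut_tick, it + dticks[s])
        fut_n <- c(fut_n, syn$post[s])
        fut_a <- c(fut_a, syn$sign[s] * w[s] * eff)
        fut_s <- c(fut_s, s)
      }
      for (s in aff_of[[n]]) {
        if (is.finite(lpre[s])) {
          dtt <- lpre[s] - t
          dw <- sp$eta * (if (dtt < 0) sp$a_plus * exp(dtt / sp$tau_plus)
                          else -sp$a_minus * exp(-dtt / sp$tau_minus))
          w[s] <- clip(w[s] + dw)
          lpre[s] <- NA_real_
        }
        lpost[s] <- t
      }
    }
  }
  list(events = data.frame(neuron = spikes_n, time = spikes_t), w = w)
}

# Declarative nearest-neighbor pairing oracle. A postsynaptic spike q pairs
# with the latest presynaptic arrival p < q provided no other post spike
# falls in (p, q); a presynaptic arrival p pairs with the latest post spike
# q < p provided no other pre arrival falls in (q, p). Updates are applied
# chronologically with clipping, like the implementation, but the pairing
# itself is computed from the full trains rather than incremental state.
stdp_oracle_nn <- function(w0, pre, post, params = stdp_params()) {
  ev <- rbind(data.frame(t = pre, side = "pre"),
              data.frame(t = post, side = "post"))
  # pre events processed before post events at equal times
  ev <- ev[order(ev$t, ev$side == "post"), ]
  w <- w0
  for (i in seq_len(nrow(ev))) {
    t <- ev$t[i]
    if (ev$side[i] == "post") {
      cand <- pre[pre < t]
      if (length(cand)) {
        p <- max(cand)
        if (!any(post > p & post < t)) {
          w <- w + params$eta * stdp_dw(p - t, params)
        }
      }
    } else {
      cand <- post[post < t]
      if (length(cand)) {
        q <- max(cand)
        if (!any(pre > q & pre < t)) {
          w <- w + params$eta * stdp_dw(t - q, params)
        }
      }
    }
    w <- min(max(w, params$w_min), params$w_max)
  }
  w
}

# All-to-all pairing count within a cutoff window (for scheme comparison).
all_to_all_pairings <- function(pre, post, cutoff = 100) {
  sum(outer(pre, post, function(p, q) abs(p - q) <= cutoff))
}

# Count of pairings actually used by the nearest-neighbor scheme.
nn_pairing_count <- function(pre, post) {
  n <- 0
  for (t in post) {
    cand <- pre[pre < t]
    if (length(cand) && !any(post > max(cand) & post < t)) n <- n + 1
  }
  for (t in pre) {
    cand <- post[post < t]
    if (length(cand) && !any(pre > max(cand) & pre < t)) n <- n + 1
  }
  n
}

# Brute-force window rescan for rate binning.
bin_rates_oracle <- function(events, t0, duration, bin_width, stride,
                             neurons) {
  starts <- seq(t0, t0 + duration - bin_width, by = stride)
  out <- matrix(0, length(neurons), length(starts))
  for (bi in seq_along(starts)) {
    for (ni in seq_along(neurons)) {
      cnt <- 0
      for (r in seq_len(nrow(events))) {
        if (events$neuron[r] == neurons[ni] &&
            events$time[r] >= starts[bi] &&
            events$time[r] < starts[bi] + bin_width) cnt <- cnt + 1
      }
      out[ni, bi] <- cnt / (bin_width / 1000)
    }
  }
  out
}

# Minimal stand-in trial result for decoder unit tests.
fake_trial <- function(label, events, duration, roles) {
  structure(list(raster = spike_raster(events, t0 = 0, duration = duration,
                                       roles = roles),
                 spec = list(sample = label)),
            class = "trial_result")
}

# Single-neuron response to a volley of arrivals (detector-style, no noise).
detector_fires <- function(w, arrivals, stp = stp_params(), psp_tau = 4,
                           dt = 0.5, params = izh_params(), dur = 120) {
  e1 <- stp$U + stp$U * (1 - stp$U)
  st <- izh_rest(params)
  for (t in seq(0, dur, by = dt)) {
    I <- sum(w * e1 * psp_kernel(t - arrivals, psp_tau))
    r <- step_neuron(st, params, I, dt)
    if (r$spiked) return(TRUE)
    st <- r$state
  }
  FALSE
}
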