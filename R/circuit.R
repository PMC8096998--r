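#' Circuit configuration
#'
#' Sizes, connectivity, delay rules, initial weights and parameter blocks of
#' the working-memory circuit. Defaults are the reference circuit: 24
#' excitatory neurons (15 of them coding/input neurons), 6 inhibitory
#' neurons, all-to-all excitatory connectivity with 4 synapses per ordered
#' pair (delays `R + 3k`, `R ~ U[3, 12]`, `k = 0..3`, so the mean
#' excitatory conduction delay is about 12 ms), excitatory-inhibitory links
#' each present with probability 0.8 and delays `U[1, 20]` ms, initial
#' plastic weights `U[0, 0.14]`, and fixed weights for the
#' excitatory-to-inhibitory (`w_ei`) and inhibitory-to-excitatory (`w_ie`)
#' synapses.
#'
#' @param n_exc,n_inh excitatory / inhibitory neuron counts
#' @param s_ee synapses per ordered excitatory pair
#' @param p_ei directed connection probability between excitatory and
#'   inhibitory neurons (each direction sampled independently)
#' @param w_init length-2 range of initial plastic weights
#' @param n_input number of coding neurons (must not exceed `n_exc`)
#' @param delay_ee_base length-2 range of the per-connection base delay `R`
#' @param delay_ee_step per-synapse delay increment (ms)
#' @param delay_ei length-2 delay range for synapses involving inhibitory
#'   neurons
#' @param w_ei fixed excitatory-to-inhibitory weight
#' @param w_ie fixed inhibitory-to-excitatory weight (applied with negative
#'   sign)
#' @param seed master RNG seed; child seeds for topology, weights and noise
#'   baselines are derived from it so topology is reproducible
#'   independently of the noise realization
#' @param dt integration step (ms)
#' @param noise a [noise_spec()]
#' @param stp an [stp_params()]
#' @param stdp an [stdp_params()]
#' @param psp_tau PSP kernel time constant (ms)
#' @param psp_horizon kernel truncation horizon (ms)
#' @param slot_width rank-order slot width (ms)
#' @param patterns named list of [rank_pattern()] stimuli; one detector is
#'   built per pattern
#' @param detector_base_delay smallest detector afferent delay (ms)
#' @param k_coincident coincident arrivals that must fire a detector
#' @param k_spread spread arrivals that must leave it silent
#' @param detector_margin sensitivity of the detector weight between its
#'   firing and silence bounds (see [solve_detector_weight()])
#' @return an object of class `circuit_config`
#' @export
circuit_config <- function(n_exc = 24, n_inh = 6, s_ee = 4, p_ei = 0.8,
                           w_init = c(0, 0.14), n_input = 15,
                           delay_ee_base = c(3, 12), delay_ee_step = 3,
                           delay_ei = c(1, 20), w_ei = 0.4, w_ie = 1.0,
                           seed = 1L, dt = 0.5, noise = noise_spec(),
                           stp = stp_params(), stdp = stdp_params(),
                           psp_tau = 4, psp_horizon = 40, slot_width = 4,
                           patterns = default_patterns(n_input, slot_width),
                           detector_base_delay = 1, k_coincident = 10,
                           k_spread = 5, detector_margin = 0.55) {
  if (n_input > n_exc) stop("invalid config: n_input (", n_input,
                            ") exceeds n_exc (", n_exc, ")")
  if (n_exc < 2 || n_inh < 0) stop("invalid config: need >= 2 excitatory neurons")
  if (p_ei < 0 || p_ei > 1) stop("invalid config: p_ei must be in [0, 1]")
  if (length(w_init) != 2 || w_init[2] < w_init[1] || w_init[1] < 0) {
    stop("invalid config: w_init must be an increasing nonnegative range")
  }
  if (any(vapply(patterns, function(p) length(p$ranks), 1L) != n_input)) {
    stop("invalid config: every pattern must cover the ", n_input, " coding neurons")
  }
  structure(list(n_exc = n_exc, n_inh = n_inh, s_ee = s_ee, p_ei = p_ei,
                 w_init = w_init, n_input = n_input,
                 delay_ee_base = delay_ee_base, delay_ee_step = delay_ee_step,
                 delay_ei = delay_ei, w_ei = w_ei, w_ie = w_ie,
                 seed = as.integer(seed), dt = dt, noise = noise, stp = stp,
                 stdp = stdp, psp_tau = psp_tau, psp_horizon = psp_horizon,
                 slot_width = slot_width, patterns = patterns,
                 detector_base_delay = detector_base_delay,
                 k_coincident = k_coincident, k_spread = k_spread,
                 detector_margin = detector_margin),
            class = "circuit_config")
}

# detector-weight solutions are deterministic in their parameters; cache them
.detector_weight_cache <- new.env(parent = emptyenv())

detector_weight_for <- function(cfg) {
  key <- paste(cfg$n_input, cfg$k_coincident, cfg$k_spread, cfg$slot_width,
               cfg$stp$U, cfg$stp$tau_f, cfg$stp$tau_d, cfg$psp_tau, cfg$dt,
               cfg$detector_margin, sep = "|")
  if (!is.null(.detector_weight_cache[[key]])) return(.detector_weight_cache[[key]])
  w <- solve_detector_weight(cfg$n_input, cfg$k_coincident, cfg$k_spread,
                             cfg$slot_width, cfg$stp, cfg$psp_tau, cfg$dt,
                             margin = cfg$detector_margin)
  .detector_weight_cache[[key]] <- w
  w
}

#' Build a working-memory circuit
#'
#' Constructs the full network: one read-only detector neuron per stimulus
#' pattern (their afferents are non-plastic and they project nowhere),
#' `n_exc` excitatory neurons of which the first `n_input` are the coding
#' neurons, and `n_inh` inhibitory neurons. Neuron order is detectors,
#' coding, remaining excitatory, inhibitory. Excitatory-excitatory synapse
#' `k` of an ordered pair gets delay `R + delay_ee_step * k` with `R` drawn
#' once per pair; synapses involving inhibitory neurons get `U[1, 20]` ms
#' delays; detector afferents get the polychronization delays of
#' [make_detector()] and a weight solved by [solve_detector_weight()].
#' Per-neuron noise baseline means are drawn once at construction. The
#' circuit is a stateful (environment-backed) object: [run_circuit()]
#' advances it in place.
#'
#' @param cfg a [circuit_config()]
#' @param seed optional override of `cfg$seed`
#' @return an object of class `circuit`
#' @examples
#' circ <- build_circuit(circuit_config(seed = 42))
#' circ
#' @export
build_circuit <- function(cfg = circuit_config(), seed = NULL) {
  stopifnot(inherits(cfg, "circuit_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)
  ss <- sample.int(2147483646L, 3L)

  n_lab <- length(cfg$patterns)
  labels <- names(cfg$patterns)
  n_det <- n_lab
  nN <- n_det + cfg$n_exc + cfg$n_inh
  det_idx <- seq_len(n_det)
  exc_idx <- n_det + seq_len(cfg$n_exc)
  coding_idx <- n_det + seq_len(cfg$n_input)
  inh_idx <- n_det + cfg$n_exc + seq_len(cfg$n_inh)
  roles <- c(rep("detector", n_det),
             rep("coding", cfg$n_input),
             rep("excitatory", cfg$n_exc - cfg$n_input),
             rep("inhibitory", cfg$n_inh))

  pe <- izh_params("excitatory")
  pi_ <- izh_params("inhibitory")
  a <- b <- cc <- d <- numeric(nN)
  is_inh <- seq_len(nN) %in% inh_idx
  a[!is_inh] <- pe$a; b[!is_inh] <- pe$b; cc[!is_inh] <- pe$c; d[!is_inh] <- pe$d
  a[is_inh] <- pi_$a; b[is_inh] <- pi_$b; cc[is_inh] <- pi_$c; d[is_inh] <- pi_$d

  # --- topology stream ---------------------------------------------------
  set.seed(ss[1])
  pairs <- expand.grid(post = exc_idx, pre = exc_idx)[, c("pre", "post")]
  pairs <- pairs[pairs$pre != pairs$post, ]
  n_pairs <- nrow(pairs)
  r_ee <- runif(n_pairs, cfg$delay_ee_base[1], cfg$delay_ee_base[2])
  kk <- rep(seq_len(cfg$s_ee) - 1L, times = n_pairs)
  ee <- data.frame(pre = rep(pairs$pre, each = cfg$s_ee),
                   post = rep(pairs$post, each = cfg$s_ee),
                   delay = rep(r_ee, each = cfg$s_ee) + cfg$delay_ee_step * kk,
                   k = kk, class = "ee", sign = 1L, plastic = TRUE)
  ei_grid <- expand.grid(pre = exc_idx, post = inh_idx)
  ei_keep <- runif(nrow(ei_grid)) < cfg$p_ei
  ei <- ei_grid[ei_keep, , drop = FALSE]
  ei$delay <- runif(nrow(ei), cfg$delay_ei[1], cfg$delay_ei[2])
  ie_grid <- expand.grid(pre = inh_idx, post = exc_idx)
  ie_keep <- runif(nrow(ie_grid)) < cfg$p_ei
  ie <- ie_grid[ie_keep, , drop = FALSE]
  ie$delay <- runif(nrow(ie), cfg$delay_ei[1], cfg$delay_ei[2])

  # --- weight stream -----------------------------------------------------
  set.seed(ss[2])
  ee$w <- runif(nrow(ee), cfg$w_init[1], cfg$w_init[2])
  if (nrow(ei)) { ei$w <- cfg$w_ei; ei$k <- NA_integer_; ei$class <- "ei"
                  ei$sign <- 1L; ei$plastic <- FALSE }
  if (nrow(ie)) { ie$w <- cfg$w_ie; ie$k <- NA_integer_; ie$class <- "ie"
                  ie$sign <- -1L; ie$plastic <- FALSE }

  # --- detector afferents (deterministic) --------------------------------
  w_det <- if (n_det > 0) detector_weight_for(cfg) else NA_real_
  det_list <- list()
  detectors <- list()
  for (i in seq_len(n_det)) {
    spec <- make_detector(cfg$patterns[[i]], cfg$detector_base_delay,
                          weight = w_det)
    detectors[[labels[i]]] <- spec
    det_list[[i]] <- data.frame(pre = coding_idx, post = det_idx[i],
                                delay = spec$delays, k = NA_integer_,
                                class = "det", sign = 1L, plastic = FALSE,
                                w = w_det)
  }
  cols <- c("pre", "post", "delay", "k", "class", "sign", "plastic", "w")
  syn <- rbind(ee[, cols],
               if (nrow(ei)) ei[, cols],
               if (nrow(ie)) ie[, cols],
               do.call(rbind, det_list))
  rownames(syn) <- NULL

  # --- noise stream ------------------------------------------------------
  set.seed(ss[3])
  nm <- numeric(nN)
  nsd <- numeric(nN)
  drawn <- runif(cfg$n_exc + cfg$n_inh, cfg$noise$mean_low, cfg$noise$mean_high)
  nm[c(exc_idx, inh_idx)] <- drawn
  nsd[c(exc_idx, inh_idx)] <- sqrt(cfg$noise$variance)
  nhold <- rnorm(nN)

  circ <- new.env(parent = emptyenv())
  circ$cfg <- cfg
  circ$n_neurons <- nN
  circ$roles <- roles
  circ$labels <- labels
  circ$detector_idx <- stats::setNames(det_idx, labels)
  circ$exc_idx <- exc_idx
  circ$coding_idx <- coding_idx
  circ$inh_idx <- inh_idx
  circ$detectors <- detectors
  circ$v <- rep(-65, nN)
  circ$u <- b * -65
  circ$params <- list(a = a, b = b, c = cc, d = d)
  circ$noise_mean <- nm
  circ$noise_sd <- nsd
  circ$noise_hold <- nhold
  circ$offset_eligible <- seq_len(nN) %in% exc_idx
  circ$syn <- list(pre = as.integer(syn$pre), post = as.integer(syn$post),
                   w = syn$w, delay = syn$delay, sign = as.integer(syn$sign),
                   plastic = syn$plastic, k = syn$k, class = syn$class,
                   x = rep(1, nrow(syn)), uu = rep(cfg$stp$U, nrow(syn)),
                   t_last = rep(-1e30, nrow(syn)),
                   last_pre = rep(NA_real_, nrow(syn)),
                   last_post = rep(NA_real_, nrow(syn)))
  circ$arrivals <- data.frame(time = numeric(0), neuron = integer(0),
                              amp = numeric(0), syn = integer(0))
  circ$time_now <- 0
  class(circ) <- "circuit"
  circ
}

#' @export
print.circuit <- function(x, ...) {
  cfg <- x$cfg
  cat("working-memory circuit:", cfg$n_exc, "excitatory (", cfg$n_input,
      "coding ),", cfg$n_inh, "inhibitory,", length(x$labels),
      "detector(s) [", paste(x$labels, collapse = ", "), "]\n")
  cat("  synapses:", length(x$syn$w), "total,",
      sum(x$syn$plastic), "plastic E-E; t =", x$time_now, "ms\n")
  invisible(x)
}

#' Synapse table of a circuit
#'
#' @param circuit a [build_circuit()] object
#' @param plastic_only keep only the plastic excitatory-excitatory synapses
#' @return data frame with columns `pre`, `post`, `k` (synapse index within
#'   the connection), `class`, `delay`, `w`
#' @export
weight_table <- function(circuit, plastic_only = FALSE) {
  s <- circuit$syn
  tab <- data.frame(pre = s$pre, post = s$post, k = s$k, class = s$class,
                    delay = s$delay, w = s$w)
  if (plastic_only) tab <- tab[s$plastic, ]
  rownames(tab) <- NULL
  tab
}

#' Run a circuit for a stretch of simulated time
#'
#' Advances the circuit tick by tick: synaptic input (kernel-summed
#' arrivals) plus Gaussian noise plus any scheduled mean-current offsets,
#' one Euler step per neuron, spike propagation through the delay queues
#' with short-term-plasticity updates, and nearest-neighbor STDP on the
#' plastic synapses. Scheduled injections force the named neurons over
#' threshold at the given (absolute) times, so downstream synapses see
#' ordinary spikes. All circuit state (membrane, weights, synapse state,
#' pending arrivals, clock) persists, so consecutive calls chain exactly.
#'
#' @param circuit a [build_circuit()] object (modified in place)
#' @param duration stretch length (ms)
#' @param injections `NULL` or data frame with columns `neuron`, `time`
#'   (absolute ms within this stretch)
#' @param offsets `NULL` or data frame with columns `start`, `end`,
#'   `amount`: additive mean-current windows applied to excitatory
#'   (non-detector) neurons
#' @param dt integration step; defaults to the config value
#' @return a `spike_raster` object for the stretch
#' @export
run_circuit <- function(circuit, duration, injections = NULL, offsets = NULL,
                        dt = circuit$cfg$dt) {
  stopifnot(inherits(circuit, "circuit"), duration >= 0)
  t0 <- circuit$time_now
  if (!is.null(injections) && nrow(injections) > 0) {
    if (any(injections$time < t0 - 1e-9) ||
        any(injections$time > t0 + duration + 1e-9)) {
      stop("injection times must fall within the simulated stretch")
    }
  }
  sched <- list(
    forced_neuron = if (is.null(injections)) integer(0) else as.integer(injections$neuron),
    forced_time = if (is.null(injections)) numeric(0) else as.numeric(injections$time),
    off_start = if (is.null(offsets)) numeric(0) else as.numeric(offsets$start),
    off_end = if (is.null(offsets)) numeric(0) else as.numeric(offsets$end),
    off_amount = if (is.null(offsets)) numeric(0) else as.numeric(offsets$amount),
    arr_time = circuit$arrivals$time, arr_neuron = circuit$arrivals$neuron,
    arr_amp = circuit$arrivals$amp, arr_syn = circuit$arrivals$syn)
  par <- list(U = circuit$cfg$stp$U, tau_f = circuit$cfg$stp$tau_f,
              tau_d = circuit$cfg$stp$tau_d, psp_tau = circuit$cfg$psp_tau,
              psp_horizon = circuit$cfg$psp_horizon,
              eta = circuit$cfg$stdp$eta, a_plus = circuit$cfg$stdp$a_plus,
              a_minus = circuit$cfg$stdp$a_minus,
              tau_plus = circuit$cfg$stdp$tau_plus,
              tau_minus = circuit$cfg$stdp$tau_minus,
              w_min = circuit$cfg$stdp$w_min, w_max = circuit$cfg$stdp$w_max,
              hold_ticks = max(1L, as.integer(round(circuit$cfg$noise$hold_ms / dt))))
  nst <- list(v = circuit$v, u = circuit$u, a = circuit$params$a,
              b = circuit$params$b, c = circuit$params$c,
              d = circuit$params$d, noise_mean = circuit$noise_mean,
              noise_sd = circuit$noise_sd, noise_hold = circuit$noise_hold,
              offset_eligible = circuit$offset_eligible)
  out <- engine_run(nst, circuit$syn, par, sched, t0, duration, dt)
  circuit$v <- out$v
  circuit$u <- out$u
  circuit$noise_hold <- out$noise_hold
  circuit$syn$w <- out$w
  circuit$syn$x <- out$x
  circuit$syn$uu <- out$uu
  circuit$syn$t_last <- out$t_last
  circuit$syn$last_pre <- out$last_pre
  circuit$syn$last_post <- out$last_post
  circuit$arrivals <- data.frame(time = out$arr_time, neuron = out$arr_neuron,
                                 amp = out$arr_amp, syn = out$arr_syn)
  circuit$time_now <- out$t_end
  spike_raster(data.frame(neuron = out$spike_neuron, time = out$spike_time),
               t0 = t0, duration = duration, roles = circuit$roles)
}

#' Spike raster
#'
#' Time-stamped spike events of one run: a data frame of `(neuron, time)`
#' pairs, the covered interval `[t0, t0 + duration)` and the per-neuron
#' role labels.
#'
#' @param events data frame with integer `neuron` and numeric `time` (ms)
#' @param t0 start of the covered interval (ms)
#' @param duration covered length (ms)
#' @param roles character vector of per-neuron roles
#' @return an object of class `spike_raster`
#' @export
spike_raster <- function(events, t0 = 0, duration = max(events$time, 0),
                         roles = NULL) {
  events <- events[order(events$time, events$neuron), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, t0 = t0, duration = duration,
                 roles = roles),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("spike_raster: ", nrow(x$events), " events over [", x$t0, ", ",
      x$t0 + x$duration, ") ms\n", sep = "")
  invisible(x)
}

#' Concatenate consecutive rasters
#'
#' @param ... `spike_raster` objects covering consecutive intervals
#' @return one merged `spike_raster`
#' @export
bind_rasters <- function(...) {
  rs <- list(...)
  if (length(rs) == 1 && is.list(rs[[1]]) && !inherits(rs[[1]], "spike_raster")) {
    rs <- rs[[1]]
  }
  events <- do.call(rbind, lapply(rs, function(r) r$events))
  t0 <- rs[[1]]$t0
  dur <- sum(vapply(rs, function(r) r$duration, 1))
  spike_raster(events, t0 = t0, duration = dur, roles = rs[[1]]$roles)
}

#' Spike counts per neuron in a window
#'
#' @param raster a `spike_raster`
#' @param from,to half-open window `[from, to)` in absolute ms; defaults to
#'   the whole raster
#' @param neurons optional neuron subset
#' @return named integer vector of counts (names are neuron indices)
#' @export
spike_counts <- function(raster, from = raster$t0,
                         to = raster$t0 + raster$duration, neurons = NULL) {
  ev <- raster$events
  ev <- ev[ev$time >= from & ev$time < to, , drop = FALSE]
  if (is.null(neurons)) neurons <- sort(unique(ev$neuron))
  counts <- vapply(neurons, function(n) sum(ev$neuron == n), 1L)
  stats::setNames(counts, neurons)
}
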