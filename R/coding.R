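#' Rank-order spike pattern
#'
#' A stimulus is encoded by the firing order of the coding neurons: neuron
#' `i` fires at `rank[i] * slot_width` ms after the cycle start, the ranks
#' being a permutation of `1..n`, so exactly one coding neuron fires in any
#' slot and `n` neurons can represent `n!` distinct stimuli.
#'
#' @param ranks integer permutation of `1..length(ranks)`; `ranks[i]` is the
#'   firing slot of coding neuron `i`
#' @param slot_width slot duration (ms); the minimum distinguishable
#'   inter-spike interval
#' @param label stimulus name
#' @return an object of class `rank_pattern`
#' @examples
#' rank_pattern(c(1, 3, 2), label = "demo")
#' @export
rank_pattern <- function(ranks, slot_width = 4, label = NA_character_) {
  ranks <- as.integer(ranks)
  if (anyDuplicated(ranks) || !setequal(ranks, seq_along(ranks))) {
    stop("ranks must be a permutation of 1..", length(ranks))
  }
  stopifnot(slot_width > 0)
  structure(list(ranks = ranks, slot_width = slot_width, label = label),
            class = "rank_pattern")
}

#' @export
print.rank_pattern <- function(x, ...) {
  cat("rank_pattern", if (!is.na(x$label)) paste0("'", x$label, "'"), "-",
      length(x$ranks), "neurons, slot", x$slot_width, "ms\n")
  cat("  ranks:", x$ranks, "\n")
  invisible(x)
}

#' Encode a rank pattern into a spike schedule
#'
#' Returns one injection time per coding neuron:
#' `cycle_start + rank[i] * slot_width`.
#'
#' @param pattern a [rank_pattern()]
#' @param cycle_start start of the encoding cycle (ms)
#' @return numeric vector of firing times (ms), one per coding neuron
#' @examples
#' encode(rank_pattern(c(1, 3, 2)))  # 4, 12, 8
#' @export
encode <- function(pattern, cycle_start = 0) {
  stopifnot(inherits(pattern, "rank_pattern"))
  cycle_start + pattern$ranks * pattern$slot_width
}

#' Construct a polychronization detector for a target pattern
#'
#' The detector exploits heterogeneous conduction delays: afferent `i` gets
#' delay `max_j(t_j) - t_i + base_delay`, so the spikes of a volley firing
#' in exactly the target order arrive at the detector simultaneously (at
#' `max_t + base_delay`) and drive it over threshold, while any other order
#' spreads the arrivals and the leaky membrane never accumulates enough
#' charge.
#'
#' @param target a [rank_pattern()], or a numeric vector of firing times
#'   (ms) directly
#' @param base_delay smallest afferent delay (ms, `>= 1`)
#' @param weight afferent weight; `NA` until solved (see
#'   [solve_detector_weight()])
#' @param params detector neuron parameters
#' @return an object of class `detector_spec` with fields `target`,
#'   `times`, `delays`, `arrival` (the common arrival time of a matched
#'   volley), `weight` and `params`
#' @examples
#' d <- make_detector(c(2, 1, 0), base_delay = 2)
#' d$delays  # 2 3 4
#' @export
make_detector <- function(target, base_delay = 1, weight = NA_real_,
                          params = izh_params("excitatory")) {
  stopifnot(base_delay >= 1)
  times <- if (inherits(target, "rank_pattern")) encode(target) else as.numeric(target)
  delays <- max(times) - times + base_delay
  structure(list(target = target, times = times, delays = delays,
                 arrival = max(times) + base_delay, weight = weight,
                 params = params),
            class = "detector_spec")
}

#' Arrival times of an arbitrary volley at a detector
#'
#' @param detector a [make_detector()] spec
#' @param times firing times of the volley (ms), one per afferent
#' @return per-afferent arrival times `times + delays`
#' @export
detector_arrivals <- function(detector, times) {
  stopifnot(length(times) == length(detector$delays))
  times + detector$delays
}

#' Solve the afferent weight of a coincidence detector
#'
#' The detector must fire when at least `k_fire` afferent spikes arrive
#' simultaneously but stay silent when `k_silent` arrivals are spread one
#' slot width apart. Each arrival injects a PSP of amplitude
#' `w * e1` where `e1 = (U + U(1-U))` is the transmitted efficacy of a
#' first spike on a rested synapse. The minimal firing weight for each
#' condition is found by bisection on a single simulated Izhikevich neuron
#' and the returned weight is the geometric mean of the two bounds.
#'
#' @param n_afferent number of coding afferents
#' @param k_fire coincident arrivals that must trigger a spike
#' @param k_silent spread arrivals that must not
#' @param slot_width spacing of the spread arrivals (ms)
#' @param stp an [stp_params()] (sets the first-spike efficacy)
#' @param psp_tau PSP kernel time constant (ms)
#' @param dt integration step (ms)
#' @param params detector neuron parameters
#' @param margin position of the returned weight between the firing bound
#'   (0) and the silence bound (1), interpolated on a log scale. Values
#'   near 1 make the detector maximally sensitive to imperfect (jittered)
#'   volleys while still ignoring `k_silent` spread arrivals
#' @param silent_times optional explicit arrival times (ms, relative) of
#'   the worst volley that must stay subthreshold, overriding the default
#'   `k_silent`-spread template
#' @return the solved afferent weight (scalar)
#' @export
solve_detector_weight <- function(n_afferent = 15, k_fire = 10, k_silent = 5,
                                  slot_width = 4, stp = stp_params(),
                                  psp_tau = 4, dt = 0.5,
                                  params = izh_params("excitatory"),
                                  margin = 0.5, silent_times = NULL) {
  stopifnot(k_fire <= n_afferent, k_silent < k_fire)
  e1 <- {u1 <- stp$U + stp$U * (1 - stp$U); u1 * 1}
  fires <- function(w, t_arr) {
    horizon <- 150
    st <- izh_rest(params)
    tt <- seq(0, horizon, by = dt)
    for (t in tt) {
      I <- sum(w * e1 * psp_kernel(t - t_arr, psp_tau))
      r <- step_neuron(st, params, I, dt)
      if (r$spiked) return(TRUE)
      st <- r$state
    }
    FALSE
  }
  min_w <- function(t_arr) {
    lo <- 1e-3
    hi <- 1e3
    if (fires(lo, t_arr)) return(lo)
    if (!fires(hi, t_arr)) stop("detector weight solve failed: no spike at w = 1e3")
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (fires(mid, t_arr)) hi <- mid else lo <- mid
    }
    hi
  }
  w_fire <- min_w(rep(10, k_fire))
  silent_arr <- if (is.null(silent_times)) {
    10 + slot_width * (seq_len(k_silent) - 1)
  } else {
    10 + silent_times - min(silent_times)
  }
  w_silent <- min_w(silent_arr)
  if (w_fire >= w_silent) {
    stop("detector weight infeasible: firing bound ", signif(w_fire, 4),
         " >= silence bound ", signif(w_silent, 4))
  }
  exp((1 - margin) * log(w_fire) + margin * log(w_silent))
}

#' Representational capacity of order versus rate coding
#'
#' With one spike per neuron, `n` neurons can represent `n!` states under
#' rank-order coding but at most `n + 1` states under a rate code.
#'
#' @param n neuron count (`>= 1`)
#' @return named numeric vector `c(order = n!, rate = n + 1)`
#' @examples
#' capacity(3)  # 6 states by order, 4 by rate
#' @export
capacity <- function(n) {
  stopifnot(n >= 1)
  c(order = factorial(n), rate = n + 1)
}

#' Default stimulus patterns
#'
#' The two built-in sample stimuli, `red` and `green`, map to two maximally
#' dissimilar permutations of the coding neurons: the identity order and
#' its reversal (every pairwise firing order is inverted between them, and
#' no two neurons keep the same rank difference, so the two detectors share
#' at most one coincident arrival).
#'
#' @param n_input number of coding neurons
#' @param slot_width slot duration (ms)
#' @return named list of [rank_pattern()] objects
#' @export
default_patterns <- function(n_input = 15, slot_width = 4) {
  list(red = rank_pattern(seq_len(n_input), slot_width, label = "red"),
       green = rank_pattern(rev(seq_len(n_input)), slot_width, label = "green"))
}
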