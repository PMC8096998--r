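#' Delay-match-to-sample trial specification
#'
#' One DMS trial: a preparation period (noise only), a cue period (the
#' sample's rank-order volley injected cyclically on the coding neurons), a
#' stimulus-free delay, and a response period in which a non-specific
#' recall signal (an extra mean current on all excitatory neurons) is
#' applied and the detector spikes are counted over the readout window.
#' The noise regime shifts the excitatory noise mean for the whole trial:
#' `+1.5` in the persistent-activity regime, `-0.3` in the activity-silent
#' regime; the recall offset stacks on top during the response period.
#'
#' @param sample stimulus label (must name a circuit pattern)
#' @param regime `"persistent"` or `"silent"`
#' @param prep_ms,cue_ms,delay_ms,response_ms period durations (ms)
#' @param readout_ms detector counting window at the start of the response
#'   period (ms)
#' @param intertrial_ms unstimulated gap before this trial inside a session
#' @param recall_offset extra mean current during the response period
#' @param regime_offset mean-current shift for the trial; default `+1.5`
#'   (persistent) or `-0.3` (silent)
#' @param seed optional RNG seed applied at trial start
#' @return an object of class `trial_spec`
#' @export
trial_spec <- function(sample, regime = c("persistent", "silent"),
                       prep_ms = 1000, cue_ms = 1000, delay_ms = 3000,
                       response_ms = 500, readout_ms = 500,
                       intertrial_ms = 0, recall_offset = 2.25,
                       regime_offset = NULL, seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(regime_offset)) {
    regime_offset <- if (regime == "persistent") 1.5 else -0.3
  }
  stopifnot(prep_ms >= 0, cue_ms >= 0, delay_ms >= 0, response_ms >= 0,
            readout_ms <= response_ms)
  structure(list(sample = sample, regime = regime, prep_ms = prep_ms,
                 cue_ms = cue_ms, delay_ms = delay_ms,
                 response_ms = response_ms, readout_ms = readout_ms,
                 intertrial_ms = intertrial_ms,
                 recall_offset = recall_offset,
                 regime_offset = regime_offset, seed = seed),
            class = "trial_spec")
}

#' Cue-period injection schedule for a pattern
#'
#' The 15-spike rank-order volley is repeated cyclically over the cue
#' period with cycle length `n_input * slot_width` ms; spikes falling past
#' the cue end are dropped.
#'
#' @param circuit a [build_circuit()] object
#' @param label pattern name
#' @param cue_start,cue_ms cue window (absolute ms)
#' @return data frame with columns `neuron`, `time`
#' @export
cue_schedule <- function(circuit, label, cue_start, cue_ms) {
  pat <- circuit$cfg$patterns[[label]]
  if (is.null(pat)) stop("unknown sample label: ", label)
  cycle <- length(pat$ranks) * pat$slot_width
  starts <- seq(cue_start, cue_start + cue_ms - 1e-9, by = cycle)
  sched <- do.call(rbind, lapply(starts, function(s) {
    data.frame(neuron = circuit$coding_idx, time = encode(pat, s))
  }))
  sched[sched$time < cue_start + cue_ms, , drop = FALSE]
}

#' Run one delay-match-to-sample trial
#'
#' Runs the four periods in order on the same circuit state; weights evolve
#' by STDP throughout. Weight snapshots of the plastic synapses are taken
#' at every period boundary. The recalled label is the detector with the
#' strictly largest spike count in the readout window; equal counts
#' (including the all-zero case) leave the trial unresolved and incorrect.
#'
#' @param circuit a [build_circuit()] object whose patterns include the
#'   sample (modified in place)
#' @param spec a [trial_spec()]
#' @return an object of class `trial_result`: `raster`, `detector_counts`,
#'   `recalled`, `correct`, `weights` (snapshots at period boundaries),
#'   `spec`, `t0`
#' @export
run_trial <- function(circuit, spec) {
  stopifnot(inherits(circuit, "circuit"), inherits(spec, "trial_spec"))
  if (is.null(circuit$cfg$patterns[[spec$sample]])) {
    stop("unknown sample label: ", spec$sample)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  t0 <- circuit$time_now
  t_cue <- t0 + spec$prep_ms
  t_delay <- t_cue + spec$cue_ms
  t_resp <- t_delay + spec$delay_ms
  t_end <- t_resp + spec$response_ms
  regime_win <- data.frame(start = t0, end = t_end,
                           amount = spec$regime_offset)
  recall_win <- data.frame(start = t_resp, end = t_end,
                           amount = spec$recall_offset)
  snap <- function() circuit$syn$w[circuit$syn$plastic]
  weights <- list(initial = snap())
  rs <- list()
  rs$prep <- run_circuit(circuit, spec$prep_ms, offsets = regime_win)
  weights$post_prep <- snap()
  inj <- cue_schedule(circuit, spec$sample, t_cue, spec$cue_ms)
  rs$cue <- run_circuit(circuit, spec$cue_ms, injections = inj,
                        offsets = regime_win)
  weights$post_cue <- snap()
  rs$delay <- run_circuit(circuit, spec$delay_ms, offsets = regime_win)
  weights$post_delay <- snap()
  rs$response <- run_circuit(circuit, spec$response_ms,
                             offsets = rbind(regime_win, recall_win))
  weights$post_response <- snap()
  raster <- bind_rasters(rs)
  counts <- spike_counts(raster, from = t_resp, to = t_resp + spec$readout_ms,
                         neurons = circuit$detector_idx)
  names(counts) <- names(circuit$detector_idx)
  mx <- max(counts)
  recalled <- if (mx > 0 && sum(counts == mx) == 1) {
    names(counts)[which.max(counts)]
  } else {
    NA_character_
  }
  structure(list(raster = raster, detector_counts = counts,
                 recalled = recalled,
                 correct = isTRUE(recalled == spec$sample),
                 weights = weights, spec = spec, t0 = t0),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("trial_result: sample =", x$spec$sample, "regime =", x$spec$regime,
      "\n  detector counts:",
      paste(names(x$detector_counts), x$detector_counts, sep = "=",
            collapse = " "),
      "\n  recalled:", ifelse(is.na(x$recalled), "unresolved", x$recalled),
      "correct:", x$correct, "\n")
  invisible(x)
}

#' Run a session of consecutive trials
#'
#' With `carry_state = TRUE` all trials run on one circuit whose weights
#' and synapse state persist; each trial after the first is preceded by its
#' `intertrial_ms` of unstimulated simulation (regime offset still
#' applied), which is how one memory can interfere with the next. With
#' `carry_state = FALSE` a fresh circuit is built per trial.
#'
#' @param circuit_factory a circuit, or a zero/one-argument function
#'   returning one (called once when carrying state, once per trial with
#'   the trial index otherwise)
#' @param trials list of [trial_spec()] objects
#' @param carry_state persist circuit state across trials
#' @return list of `trial_result` objects
#' @export
run_session <- function(circuit_factory, trials, carry_state = TRUE) {
  if (length(trials) == 0) return(list())
  make <- function(i) {
    if (inherits(circuit_factory, "circuit")) return(circuit_factory)
    if (length(formals(circuit_factory)) == 0) circuit_factory()
    else circuit_factory(i)
  }
  results <- vector("list", length(trials))
  circ <- if (carry_state) make(1L) else NULL
  for (i in seq_along(trials)) {
    sp <- trials[[i]]
    if (!carry_state) circ <- make(i)
    if (carry_state && i > 1 && sp$intertrial_ms > 0) {
      gap <- data.frame(start = circ$time_now,
                        end = circ$time_now + sp$intertrial_ms,
                        amount = sp$regime_offset)
      run_circuit(circ, sp$intertrial_ms, offsets = gap)
    }
    results[[i]] <- run_trial(circ, sp)
  }
  results
}

#' Recall accuracy over a delay x intertrial sweep
#'
#' For every `(delay, intertrial)` cell, runs `reps` two-trial
#' carried-state sessions and scores the second trial of each (the one
#' preceded by the intertrial gap and by a potentially interfering
#' memory). Samples are drawn at random per session. Cue duration is
#' compressed (one-eighth of the standard 1 s by default) to match the
#' continuous-task time scale; delays are taken as given.
#'
#' @param circuit_factory one-argument function (session seed) returning a
#'   fresh circuit
#' @param delays delay durations to test (ms)
#' @param intertrials intertrial intervals to test (ms)
#' @param reps sessions per cell (`>= 1`)
#' @param regime `"persistent"` or `"silent"`
#' @param labels candidate sample labels
#' @param cue_ms compressed cue duration (ms)
#' @param prep_ms preparation period before the first trial of a session
#' @param seed seed for the sweep's sample draws and session seeds
#' @return data frame with one row per cell: `delay_ms`, `intertrial_ms`,
#'   `accuracy`, `n`
#' @export
accuracy_sweep <- function(circuit_factory, delays, intertrials, reps = 20,
                           regime = "persistent",
                           labels = c("red", "green"), cue_ms = 1000,
                           prep_ms = 1000, seed = 1) {
  stopifnot(reps >= 1)
  cells <- expand.grid(delay_ms = delays, intertrial_ms = intertrials,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(match(cells$delay_ms, delays),
                       match(cells$intertrial_ms, intertrials)), ]
  set.seed(seed)
  session_seeds <- matrix(sample.int(2147483646L, nrow(cells) * reps),
                          nrow = nrow(cells))
  acc <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    correct <- logical(reps)
    for (r in seq_len(reps)) {
      sseed <- session_seeds[ci, r]
      set.seed(sseed)
      samples <- sample(labels, 2, replace = TRUE)
      trials <- list(
        trial_spec(samples[1], regime, prep_ms = prep_ms, cue_ms = cue_ms,
                   delay_ms = cells$delay_ms[ci], seed = sseed),
        trial_spec(samples[2], regime, prep_ms = 0, cue_ms = cue_ms,
                   delay_ms = cells$delay_ms[ci],
                   intertrial_ms = cells$intertrial_ms[ci]))
      res <- run_session(function(i) circuit_factory(sseed), trials,
                         carry_state = TRUE)
      correct[r] <- res[[2]]$correct
    }
    acc[ci] <- mean(correct)
  }
  cells$accuracy <- acc
  cells$n <- reps
  rownames(cells) <- NULL
  cells
}
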