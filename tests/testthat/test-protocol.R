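short_spec <- function(sample, regime, seed = NULL, ...) {
  trial_spec(sample, regime, prep_ms = 200, cue_ms = 240, delay_ms = 300,
             response_ms = 200, readout_ms = 200, seed = seed, ...)
}

test_that("cue schedule repeats the volley cyclically inside the cue window", {
  circ <- build_circuit(circuit_config(seed = 1))
  sched <- cue_schedule(circ, "red", cue_start = 1000, cue_ms = 1000)
  expect_true(all(sched$time >= 1000 & sched$time < 2000))
  # 16 full cycles of 60 ms fit in 1 s; the 17th is clipped at the boundary
  n1 <- sum(sched$neuron == circ$coding_idx[1])
  expect_gte(n1, 16)
  # within one cycle the firing order follows the ranks
  first_cycle <- sched[sched$time <= 1060, ]
  ord <- first_cycle$neuron[order(first_cycle$time)]
  expect_equal(circ$cfg$patterns$red$ranks[match(ord, circ$coding_idx)],
               seq_len(sum(sched$time <= 1060)))
})

test_that("unknown sample labels raise a config error", {
  circ <- build_circuit(circuit_config(seed = 1))
  expect_error(run_trial(circ, trial_spec("blue")), "unknown sample")
  expect_error(cue_schedule(circ, "blue", 0, 100), "unknown sample")
})

test_that("a trial returns a complete, internally consistent result", {
  circ <- build_circuit(circuit_config(seed = 2))
  sp <- short_spec("red", "persistent", seed = 11)
  res <- run_trial(circ, sp)
  expect_s3_class(res, "trial_result")
  total <- sp$prep_ms + sp$cue_ms + sp$delay_ms + sp$response_ms
  expect_equal(res$raster$duration, total)
  expect_named(res$detector_counts, c("red", "green"))
  expect_length(res$weights, 5)
  expect_equal(length(res$weights$initial), sum(circ$syn$plastic))
  # weights evolved during the trial
  expect_false(identical(res$weights$initial, res$weights$post_cue))
  # readout rule: strict argmax, ties and silence unresolved
  cnt <- res$detector_counts
  if (max(cnt) > 0 && sum(cnt == max(cnt)) == 1) {
    expect_equal(res$recalled, names(cnt)[which.max(cnt)])
  } else {
    expect_true(is.na(res$recalled))
    expect_false(res$correct)
  }
})

test_that("the cue drives the matching detector and not the other", {
  circ <- build_circuit(circuit_config(seed = 3))
  sp <- trial_spec("green", "silent", prep_ms = 200, cue_ms = 1000,
                   delay_ms = 200, response_ms = 200, readout_ms = 200,
                   seed = 21)
  res <- run_trial(circ, sp)
  ev <- res$raster$events
  cue_from <- 200
  cue_to <- 1200
  green_cue <- sum(ev$neuron == circ$detector_idx["green"] &
                   ev$time >= cue_from & ev$time < cue_to)
  red_cue <- sum(ev$neuron == circ$detector_idx["red"] &
                 ev$time >= cue_from & ev$time < cue_to)
  expect_gte(green_cue, 10)   # one detection per 60 ms volley, ~16 volleys
  expect_equal(red_cue, 0)
})

test_that("empty and degenerate sessions behave", {
  expect_equal(run_session(function(i) NULL, list()), list())
  circ <- build_circuit(circuit_config(seed = 4))
  res <- run_session(circ, list(short_spec("red", "silent", seed = 31)))
  expect_length(res, 1)
  expect_s3_class(res[[1]], "trial_result")
})

test_that("carried state persists across trials, fresh circuits do not", {
  specs <- list(short_spec("red", "silent", seed = 41),
                short_spec("red", "silent"))
  res_carry <- run_session(build_circuit(circuit_config(seed = 5)), specs,
                           carry_state = TRUE)
  # second trial starts where the first left off
  expect_equal(res_carry[[2]]$t0, res_carry[[1]]$t0 + 940)
  # with carried state the second trial inherits learned weights
  expect_equal(res_carry[[2]]$weights$initial,
               res_carry[[1]]$weights$post_response)
  # an intertrial gap advances the clock before the next trial
  gap <- list(short_spec("red", "silent", seed = 43),
              short_spec("red", "silent", intertrial_ms = 100))
  res_gap <- run_session(build_circuit(circuit_config(seed = 5)), gap,
                         carry_state = TRUE)
  expect_equal(res_gap[[2]]$t0, res_gap[[1]]$t0 + 940 + 100)
  res_fresh <- run_session(function(i) build_circuit(circuit_config(seed = 5)),
                           specs, carry_state = FALSE)
  expect_equal(res_fresh[[2]]$t0, 0)
  expect_equal(res_fresh[[2]]$weights$initial,
               res_fresh[[1]]$weights$initial)
})

test_that("regime phenomenology: persistent delay is elevated, silent is not", {
  prep_delay <- function(regime, seed) {
    circ <- build_circuit(circuit_config(seed = seed))
    res <- run_trial(circ, trial_spec(if (seed %% 2) "red" else "green",
                                      regime, seed = 6000 + seed))
    ev <- res$raster$events
    exc <- circ$exc_idx
    c(prep = sum(ev$time < 1000 & ev$neuron %in% exc) / 24,
      delay = sum(ev$time >= 2000 & ev$time < 5000 & ev$neuron %in% exc) /
        24 / 3)
  }
  pers <- vapply(1:10, function(s) prep_delay("persistent", s), c(prep = 1, delay = 1))
  sil <- vapply(1:10, function(s) prep_delay("silent", s), c(prep = 1, delay = 1))
  # persistent activity: delay-period rate well above the preparation rate
  expect_gt(mean(pers["delay", ]) - mean(pers["prep", ]), 2)
  # silent regime: delay activity stays at the low-frequency ground state,
  # far below the persistent-regime delay rate
  expect_lt(mean(sil["delay", ]), 1)
  expect_lt(mean(sil["delay", ]), mean(pers["delay", ]) / 4)
})

test_that("accuracy sweep has the right shape and bounded values", {
  tab <- accuracy_sweep(function(s) build_circuit(circuit_config(seed = s)),
                        delays = c(200, 400), intertrials = c(0, 100),
                        reps = 2, regime = "persistent",
                        cue_ms = 240, prep_ms = 200, seed = 3)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$delay_ms, c(200, 200, 400, 400))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$n == 2))
})
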