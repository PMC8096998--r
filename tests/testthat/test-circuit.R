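test_that("default build has the reference counts, delays and weights", {
  circ <- build_circuit(circuit_config(seed = 1))
  tab <- weight_table(circ)
  ee <- tab[tab$class == "ee", ]
  expect_equal(nrow(ee), 24 * 23 * 4)           # full E-E, 4 synapses/pair
  expect_true(all(circ$syn$plastic[tab$class == "ee"]))
  expect_false(any(circ$syn$plastic[tab$class != "ee"]))
  # no self connections, no I-I connections
  expect_true(all(ee$pre != ee$post))
  inh <- circ$inh_idx
  expect_false(any(tab$pre %in% inh & tab$post %in% inh))
  # delay rule: R + 3k per connection, synapse k offsets visible
  expect_true(all(ee$delay >= 3 & ee$delay <= 12 + 9))
  expect_lt(abs(mean(ee$delay) - 12), 0.3)
  ei <- tab[tab$class %in% c("ei", "ie"), ]
  expect_true(all(ei$delay >= 1 & ei$delay <= 20))
  # initial plastic weights uniform on [0, 0.14]
  expect_true(all(ee$w >= 0 & ee$w <= 0.14))
  expect_lt(abs(mean(ee$w) - 0.07), 0.005)
  # inhibitory synapses transmit with negative sign
  expect_true(all(circ$syn$sign[tab$class == "ie"] == -1L))
})

test_that("invalid configurations are rejected with a config error", {
  expect_error(circuit_config(n_input = 30, n_exc = 24), "n_input")
  expect_error(circuit_config(p_ei = 1.4), "p_ei")
  expect_error(circuit_config(w_init = c(0.2, 0.1)), "w_init")
})

test_that("same seed rebuilds a bitwise-identical circuit", {
  c1 <- build_circuit(circuit_config(seed = 7))
  c2 <- build_circuit(circuit_config(seed = 7))
  expect_identical(c1$syn$w, c2$syn$w)
  expect_identical(c1$syn$delay, c2$syn$delay)
  expect_identical(c1$noise_mean, c2$noise_mean)
  c3 <- build_circuit(circuit_config(seed = 8))
  expect_false(identical(c1$syn$w, c3$syn$w))
})

test_that("zero noise and no input leaves the circuit silent", {
  cfg <- circuit_config(seed = 1, noise = noise_spec(0, 0, 0))
  circ <- build_circuit(cfg)
  r <- run_circuit(circ, 500)
  expect_equal(nrow(r$events), 0)
  # and the plastic weight table is untouched by the silent run
  expect_identical(circ$syn$w, build_circuit(cfg)$syn$w)
})

test_that("default noise drives low-rate irregular ground-state firing", {
  circ <- build_circuit(circuit_config(seed = 3))
  set.seed(99)
  r <- run_circuit(circ, 5000)
  counts <- spike_counts(r, neurons = c(circ$exc_idx, circ$inh_idx))
  rate <- sum(counts) / length(counts) / 5
  expect_gt(rate, 0.05)
  expect_lt(rate, 15)
  # most neurons participate; detectors stay silent without input
  expect_gt(mean(counts > 0), 0.5)
  expect_equal(sum(spike_counts(r, neurons = circ$detector_idx)), 0)
})

test_that("identical seeds and schedules reproduce the raster exactly", {
  run_once <- function() {
    circ <- build_circuit(circuit_config(seed = 5))
    set.seed(17)
    inj <- data.frame(neuron = circ$coding_idx[1:3], time = c(50, 60, 70))
    run_circuit(circ, 400, injections = inj,
                offsets = data.frame(start = 0, end = 400, amount = 1))
  }
  expect_identical(run_once()$events, run_once()$events)
})

test_that("chained runs equal one long run with the same seed stream", {
  c1 <- build_circuit(circuit_config(seed = 5))
  set.seed(23)
  rA <- run_circuit(c1, 300)
  rB <- run_circuit(c1, 300)
  c2 <- build_circuit(circuit_config(seed = 5))
  set.seed(23)
  rAB <- run_circuit(c2, 600)
  expect_identical(rbind(rA$events, rB$events), rAB$events)
  expect_identical(c1$syn$w, c2$syn$w)
  expect_identical(c1$v, c2$v)
})

test_that("event-queue engine matches the full-rescan oracle", {
  fx <- make_fixture("micro-circuit", seed = 6)
  cfg <- fx$config
  c_eng <- build_circuit(cfg)
  c_ora <- build_circuit(cfg)
  inj <- data.frame(neuron = c(2, 3), time = c(40, 90))
  off <- data.frame(start = 0, end = 200, amount = 1.0)
  set.seed(77)
  r_eng <- run_circuit(c_eng, 200, injections = inj, offsets = off)
  set.seed(77)
  r_ora <- simulate_bruteforce(c_ora, 200, injections = inj, offsets = off)
  expect_equal(r_eng$events$neuron, r_ora$events$neuron)
  expect_equal(r_eng$events$time, r_ora$events$time)
  expect_equal(c_eng$syn$w, r_ora$w, tolerance = 1e-12)
})

test_that("spike causality: arrivals never precede emission plus delay", {
  circ <- build_circuit(circuit_config(seed = 9))
  set.seed(5)
  inj <- data.frame(neuron = circ$coding_idx, time = seq(20, 76, by = 4))
  r <- run_circuit(circ, 150, injections = inj)
  arr <- circ$arrivals[circ$arrivals$syn > 0, ]
  expect_gt(nrow(arr), 0)
  ok <- vapply(seq_len(nrow(arr)), function(i) {
    s <- arr$syn[i]
    pre_spikes <- r$events$time[r$events$neuron == circ$syn$pre[s]]
    # arrival time equals emission + conduction delay, up to tick rounding
    any(abs(pre_spikes + circ$syn$delay[s] - arr$time[i]) <= 0.251)
  }, TRUE)
  expect_true(all(ok))
})

test_that("raster utilities: binding, counting, printing", {
  ev1 <- data.frame(neuron = c(1L, 2L), time = c(10, 20))
  ev2 <- data.frame(neuron = 1L, time = 60)
  r1 <- spike_raster(ev1, t0 = 0, duration = 50)
  r2 <- spike_raster(ev2, t0 = 50, duration = 50)
  rb <- bind_rasters(r1, r2)
  expect_equal(rb$duration, 100)
  expect_equal(nrow(rb$events), 3)
  expect_equal(unname(spike_counts(rb, from = 0, to = 50, neurons = 1:2)),
               c(1L, 1L))
  expect_output(print(rb), "spike_raster")
})
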