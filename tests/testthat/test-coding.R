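test_that("rank-order encoding maps ranks to slot times", {
  p <- rank_pattern(c(1, 3, 2), slot_width = 4)
  expect_equal(encode(p), c(4, 12, 8))
  ident <- rank_pattern(1:15)
  expect_equal(encode(ident), seq(4, 60, by = 4))
  expect_equal(encode(ident, cycle_start = 100), 100 + seq(4, 60, by = 4))
  # any valid pattern keeps pairwise gaps of at least one slot
  set.seed(2)
  for (i in 1:10) {
    pat <- rank_pattern(sample(8), slot_width = 4)
    tt <- sort(encode(pat))
    expect_true(all(diff(tt) >= 4))
  }
})

test_that("invalid rank vectors are rejected", {
  expect_error(rank_pattern(c(1, 1, 2)), "permutation")
  expect_error(rank_pattern(c(1, 2, 4)), "permutation")
})

test_that("detector delays equalize matched-volley arrival times", {
  # worked three-neuron example: firing times (2, 1, 0) with base delay 2
  a <- make_detector(c(2, 1, 0), base_delay = 2)
  expect_equal(a$delays, c(2, 3, 4))
  expect_equal(detector_arrivals(a, c(2, 1, 0)), rep(4, 3))
  e <- make_detector(c(3, 0, 2), base_delay = 1)
  expect_equal(e$delays, c(1, 4, 2))
  expect_equal(detector_arrivals(e, c(3, 0, 2)), rep(4, 3))
  # the mismatched pattern spreads its arrivals
  expect_gt(diff(range(detector_arrivals(a, c(3, 0, 2)))), 0)
  # single afferent: delay is just the base delay
  expect_equal(make_detector(5, base_delay = 3)$delays, 3)
  # matched arrivals coincide exactly for arbitrary patterns (symbolic)
  set.seed(4)
  for (i in 1:20) {
    tt <- encode(rank_pattern(sample(10)))
    d <- make_detector(tt, base_delay = 1 + i %% 5)
    expect_equal(max(detector_arrivals(d, tt)) -
                 min(detector_arrivals(d, tt)), 0)
  }
})

test_that("worked detector pair discriminates its two spike trains", {
  fx <- make_fixture("fig3-detector")
  mis_a <- detector_arrivals(fx$a, c(3, 0, 2))
  w <- solve_detector_weight(3, k_fire = 3, k_silent = 2, slot_width = 2,
                             silent_times = mis_a, margin = 0.3)
  expect_true(detector_fires(w, detector_arrivals(fx$a, c(2, 1, 0))))
  expect_false(detector_fires(w, mis_a))
  # and symmetrically for the second detector
  mis_e <- detector_arrivals(fx$e, c(2, 1, 0))
  we <- solve_detector_weight(3, k_fire = 3, k_silent = 2, slot_width = 2,
                              silent_times = mis_e, margin = 0.3)
  expect_true(detector_fires(we, detector_arrivals(fx$e, c(3, 0, 2))))
  expect_false(detector_fires(we, mis_e))
})

test_that("order-code capacity is n! against n+1 for rate coding", {
  expect_equal(capacity(3), c(order = 6, rate = 4))
  expect_equal(capacity(1), c(order = 1, rate = 2))
  expect_equal(capacity(5), c(order = 120, rate = 6))
})

# exhaustive roundtrip over all permutations of a 4-neuron code: a clean
# volley activates exactly its own detector
test_that("every 4-neuron permutation activates only its own detector", {
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  slot <- 4
  times <- perms * slot
  dets <- lapply(seq_len(nrow(perms)),
                 function(i) make_detector(times[i, ], base_delay = 1))
  # worst mismatched volley template: two coincident pairs 8 ms apart
  w <- solve_detector_weight(4, k_fire = 4, k_silent = 3, slot_width = 4,
                             silent_times = c(0, 0, 8, 8), margin = 0.3)
  for (i in seq_len(nrow(perms))) {
    volley <- times[i, ]
    fired <- vapply(dets, function(d)
      detector_fires(w, detector_arrivals(d, volley)), TRUE)
    expect_true(fired[i])
    expect_equal(sum(fired), 1)
  }
})

test_that("own-detector activation survives small jitter better than others", {
  target <- encode(rank_pattern(c(2, 4, 1, 3)))
  others <- list(c(4, 2, 3, 1), c(1, 3, 2, 4), c(3, 1, 4, 2))
  own <- make_detector(target, base_delay = 1)
  other_dets <- lapply(others,
                       function(p) make_detector(encode(rank_pattern(p)), 1))
  w <- solve_detector_weight(4, k_fire = 4, k_silent = 3, slot_width = 4,
                             silent_times = c(0, 0, 8, 8), margin = 0.3)
  set.seed(31)
  own_hits <- other_hits <- 0
  for (i in 1:40) {
    volley <- target + runif(4, -1, 1)
    own_hits <- own_hits + detector_fires(w, detector_arrivals(own, volley))
    other_hits <- other_hits +
      max(vapply(other_dets, function(d)
        detector_fires(w, detector_arrivals(d, volley)), TRUE))
  }
  expect_gt(own_hits, other_hits)
})

test_that("the two built-in stimulus patterns are order-inverted", {
  pats <- default_patterns(15)
  expect_equal(pats$red$ranks, 1:15)
  expect_equal(pats$green$ranks, 15:1)
  # every pairwise firing order is inverted between the two stimuli
  dr <- outer(pats$red$ranks, pats$red$ranks, "-")
  dg <- outer(pats$green$ranks, pats$green$ranks, "-")
  expect_true(all(sign(dr) == -sign(dg)))
})
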