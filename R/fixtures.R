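#' Deterministic test fixtures
#'
#' Emits the small, fully deterministic assets used by the test suite:
#'
#' * `"micro-circuit"`: a 5-neuron circuit (4 excitatory of which 3 coding,
#'   1 inhibitory, 2 synapses per excitatory pair, no detectors) for
#'   brute-force cross-checks of the tick loop;
#' * `"fig3-detector"`: the worked three-neuron detector pair — detector
#'   `a` for firing times (2, 1, 0) ms with afferent delays (2, 3, 4) ms
#'   and detector `e` for (3, 0, 2) ms with delays (1, 4, 2) ms, so a
#'   matched volley arrives simultaneously at its own detector only;
#' * `"stdp-pair-train"`: alternating pre/post spike events with their
#'   spike-time differences and the expected raw weight changes from the
#'   asymmetric exponential window;
#' * `"rate-raster"`: a hand-built 10-spike raster for window-binning
#'   checks.
#'
#' @param name fixture name
#' @param seed RNG seed (where the fixture has random content)
#' @param dir optional directory; when given, the fixture is also written
#'   out as plain-text files
#' @return the fixture object (list; see details above)
#' @export
make_fixture <- function(name = c("micro-circuit", "fig3-detector",
                                  "stdp-pair-train", "rate-raster"),
                         seed = 1L, dir = NULL) {
  name <- match.arg(name)
  fx <- switch(name,
    "micro-circuit" = {
      cfg <- circuit_config(n_exc = 4, n_inh = 1, s_ee = 2, n_input = 3,
                            patterns = list(), seed = seed)
      list(config = cfg, circuit = build_circuit(cfg))
    },
    "fig3-detector" = {
      a <- make_detector(c(2, 1, 0), base_delay = 2)
      e <- make_detector(c(3, 0, 2), base_delay = 1)
      list(a = a, e = e)
    },
    "stdp-pair-train" = {
      set.seed(seed)
      gaps <- round(runif(8, 1, 12))
      t_pre <- cumsum(40 + gaps)
      side_first <- rep(c("pre", "post"), length.out = 8)
      events <- do.call(rbind, lapply(seq_along(gaps), function(i) {
        first <- t_pre[i]
        data.frame(time = c(first, first + gaps[i]),
                   side = if (side_first[i] == "pre") c("pre", "post")
                          else c("post", "pre"))
      }))
      events <- events[order(events$time), ]
      rownames(events) <- NULL
      delta <- ifelse(side_first == "pre", -gaps, gaps)
      expected <- data.frame(delta_t = delta, dw = stdp_dw(delta))
      list(events = events, expected = expected)
    },
    "rate-raster" = {
      ev <- data.frame(neuron = c(1L, 1L, 2L, 2L, 2L, 3L, 1L, 3L, 2L, 1L),
                       time = c(50, 250, 250, 400, 650, 700, 710, 820,
                                910, 990))
      list(raster = spike_raster(ev, t0 = 0, duration = 1000,
                                 roles = rep("excitatory", 3)))
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    switch(name,
      "micro-circuit" = write.table(weight_table(fx$circuit),
                                    file.path(dir, "micro_circuit_synapses.tsv"),
                                    sep = "\t", row.names = FALSE, quote = FALSE),
      "fig3-detector" = write.table(
        data.frame(detector = rep(c("a", "e"), each = 3),
                   afferent = rep(1:3, 2),
                   firing_ms = c(fx$a$times, fx$e$times),
                   delay_ms = c(fx$a$delays, fx$e$delays)),
        file.path(dir, "fig3_detector.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE),
      "stdp-pair-train" = {
        write.table(fx$events, file.path(dir, "stdp_events.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.table(fx$expected, file.path(dir, "stdp_expected.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      },
      "rate-raster" = write.table(fx$raster$events,
                                  file.path(dir, "rate_raster.tsv"),
                                  sep = "\t", row.names = FALSE,
                                  quote = FALSE))
  }
  fx
}
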