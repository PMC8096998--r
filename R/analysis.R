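#' Sliding-window firing rates
#'
#' Counts spikes per neuron in half-open windows `[t, t + bin_width)` tiled
#' across the raster at the given stride (full windows only) and converts
#' to Hz.
#'
#' @param raster a `spike_raster`
#' @param bin_width window length (ms)
#' @param stride window spacing (ms)
#' @param neurons neuron indices to include (must be non-empty); defaults
#'   to every neuron the raster knows about
#' @return an object of class `rate_matrix`: `rates` (neurons x bins, Hz),
#'   `bins` (window centers, ms), `neurons`, `bin_width`, `stride`
#' @export
bin_rates <- function(raster, bin_width = 500, stride = 200,
                      neurons = NULL) {
  stopifnot(bin_width > 0, stride > 0)
  if (is.null(neurons)) {
    neurons <- if (!is.null(raster$roles)) seq_along(raster$roles)
               else sort(unique(raster$events$neuron))
  }
  if (length(neurons) == 0) stop("empty neuron subset")
  starts <- seq(raster$t0, raster$t0 + raster$duration - bin_width,
                by = stride)
  if (length(starts) == 0) stop("raster shorter than one bin")
  ev <- raster$events[raster$events$neuron %in% neurons, , drop = FALSE]
  nmap <- match(ev$neuron, neurons)
  rates <- vapply(starts, function(s) {
    idx <- ev$time >= s & ev$time < s + bin_width
    tabulate(nmap[idx], nbins = length(neurons)) / (bin_width / 1000)
  }, numeric(length(neurons)))
  rates <- matrix(rates, nrow = length(neurons))
  structure(list(rates = rates, bins = starts + bin_width / 2,
                 neurons = neurons, bin_width = bin_width, stride = stride),
            class = "rate_matrix")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer trials (", length(idx),
           ") than folds (", k, ")")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' SVM decoding accuracy over time
#'
#' For every time bin, fits a linear-kernel support vector machine on the
#' per-trial firing-rate vectors of the excitatory neurons (detectors and
#' inhibitory neurons are excluded by default: the detectors would leak the
#' label directly) under stratified k-fold cross-validation, and reports
#' the mean held-out accuracy. With two stimulus classes the chance level
#' is 50%.
#'
#' @param trials list of `trial_result` objects
#' @param labels class label per trial; defaults to each trial's sample
#' @param bin_width,stride rate-binning parameters (ms)
#' @param cv_folds cross-validation folds
#' @param seed RNG seed for the fold assignment
#' @param neurons neuron subset fed to the decoder; defaults to all
#'   excitatory (coding + non-coding) neurons
#' @return an object of class `decoding_curve`: `bins` (ms), `accuracy`
#'   (fraction per bin), `n_trials`, `cv_folds`, `chance`
#' @export
decode_over_time <- function(trials, labels = NULL, bin_width = 500,
                             stride = 200, cv_folds = 5, seed = 1,
                             neurons = NULL) {
  if (is.null(labels)) {
    labels <- vapply(trials, function(tr) tr$spec$sample, "")
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes to decode")
  if (is.null(neurons)) {
    roles <- trials[[1]]$raster$roles
    neurons <- which(roles %in% c("coding", "excitatory"))
  }
  rms <- lapply(trials, function(tr) {
    rm <- bin_rates(tr$raster, bin_width, stride, neurons)
    rm$rates
  })
  n_bins <- ncol(rms[[1]])
  stopifnot(all(vapply(rms, ncol, 1L) == n_bins))
  bins <- bin_rates(trials[[1]]$raster, bin_width, stride, neurons)$bins
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  acc <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    X <- t(vapply(rms, function(r) r[, b], numeric(length(neurons))))
    hits <- 0
    for (f in seq_len(cv_folds)) {
      tr_i <- fold != f
      fit <- e1071::svm(X[tr_i, , drop = FALSE], y[tr_i], kernel = "linear",
                        scale = FALSE)
      pred <- predict(fit, X[!tr_i, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr_i])
    }
    acc[b] <- hits / length(y)
  }
  structure(list(bins = bins, accuracy = acc, n_trials = length(trials),
                 cv_folds = cv_folds, chance = 1 / nlevels(y)),
            class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat("decoding_curve:", length(x$bins), "bins,", x$n_trials, "trials,",
      x$cv_folds, "-fold CV, chance =", x$chance, "\n")
  cat("  accuracy range:", round(min(x$accuracy), 3), "-",
      round(max(x$accuracy), 3), "\n")
  invisible(x)
}

#' Histogram and summary of the plastic weight distribution
#'
#' Histogram over the plastic excitatory-excitatory weights only, with the
#' summary statistics used to characterize learning: the mean weight, the
#' fraction above a high threshold and the fraction below a low one. A
#' freshly built default circuit has mean close to 0.07 (uniform initial
#' weights on `[0, 0.14]`); after a cue period the distribution becomes
#' strongly right-skewed, most weights near zero and a small tail above
#' 0.2.
#'
#' @param circuit a [build_circuit()] object, or a bare numeric vector of
#'   weights (e.g. a stored snapshot)
#' @param edges increasing histogram break points; weights are clipped to
#'   the STDP bounds so the default edges span them
#' @param threshold high-weight threshold for `frac_above`
#' @param low low-weight threshold for `frac_below`
#' @return an object of class `weight_histogram`: `counts`, `edges`,
#'   `mids`, `n`, `mean`, `frac_above`, `frac_below`
#' @export
weight_histogram <- function(circuit, edges = NULL, threshold = 0.2,
                             low = 0.02) {
  w <- if (inherits(circuit, "circuit")) {
    circuit$syn$w[circuit$syn$plastic]
  } else {
    as.numeric(circuit)
  }
  if (is.null(edges)) {
    top <- if (inherits(circuit, "circuit")) circuit$cfg$stdp$w_max
           else max(w, threshold)
    edges <- seq(0, top, length.out = 26)
  }
  stopifnot(all(diff(edges) > 0))
  h <- graphics::hist(w, breaks = edges, plot = FALSE, include.lowest = TRUE,
                      right = FALSE)
  structure(list(counts = h$counts, edges = edges, mids = h$mids,
                 n = length(w), mean = mean(w),
                 frac_above = mean(w > threshold),
                 frac_below = mean(w < low)),
            class = "weight_histogram")
}

#' @export
print.weight_histogram <- function(x, ...) {
  cat("weight_histogram:", x$n, "plastic weights, mean =",
      signif(x$mean, 3), "\n  fraction above threshold:",
      signif(x$frac_above, 3), "; fraction below low mark:",
      signif(x$frac_below, 3), "\n")
  invisible(x)
}
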