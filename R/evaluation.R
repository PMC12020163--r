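# Evaluation suite: average precision, expected calibration error,
# positive-acquisition curves, gain-over-random, paired Wilcoxon tests and
# the stable-significance iteration.

#' Average precision
#'
#' Area under the precision-recall curve by the step-wise formula
#' `sum_k (R_k - R_{k-1}) P_k` over descending-score thresholds, with tied
#' scores grouped into a single threshold. Robust under heavy class
#' imbalance; a random ranking scores about the positive prevalence.
#'
#' @param scores Real-valued ranking scores (higher = more positive).
#' @param labels Binary labels (both classes present).
#' @return Scalar in `[0, 1]`.
#' @examples
#' averagePrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)) # (1 + 2/3) / 2
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    .input_error("scores and labels must have equal length")
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    .input_error("average precision is undefined for single-class labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # last position of each distinct-score group
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  prec <- tp / last
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Expected calibration error
#'
#' Predicted-class confidence `max(p, 1 - p)` is partitioned into
#' `nBins` equal-width bins over `[0, 1]`; the ECE is the bin-weighted
#' mean absolute gap between per-bin accuracy and per-bin mean
#' confidence. Zero for a perfectly calibrated classifier; empty bins
#' contribute nothing.
#'
#' @param probs Predictive positive-class probabilities in `[0, 1]`.
#' @param labels Binary labels.
#' @param nBins Number of equal-width confidence bins.
#' @return Scalar in `[0, 1]`.
#' @export
expectedCalibrationError <- function(probs, labels, nBins = 10L) {
  labels <- as.numeric(labels)
  if (length(probs) != length(labels))
    .input_error("probs and labels must have equal length")
  if (any(probs < 0 | probs > 1))
    .input_error("probs must lie in [0, 1]")
  conf <- pmax(probs, 1 - probs)
  pred <- as.numeric(probs >= 0.5)
  acc <- as.numeric(pred == labels)
  bin <- pmin(pmax(ceiling(conf * nBins), 1L), nBins)
  ece <- 0
  n <- length(probs)
  for (b in unique(bin)) {
    in_b <- bin == b
    ece <- ece + sum(in_b) / n * abs(mean(acc[in_b]) - mean(conf[in_b]))
  }
  ece
}

#' Cumulative positive-acquisition curve
#'
#' Running count of acquired positive labels over the iterations of one
#' run: how quickly an acquisition strategy discovers the rare actives in
#' the pool.
#'
#' @param history An [ALHistory-class].
#' @return data.frame with columns `iteration` and `cumPositives`
#'   (nondecreasing).
#' @export
cumulativePositiveCurve <- function(history) {
  stopifnot(is(history, "ALHistory"))
  a <- history@acquisitions
  if (!nrow(a)) .input_error("history contains no acquisitions")
  agg <- tapply(a$label, a$iteration, sum)
  data.frame(iteration = as.integer(names(agg)),
             cumPositives = cumsum(as.numeric(agg)), row.names = NULL)
}

#' Iterations needed to recover a fraction of the positives
#'
#' Smallest iteration whose cumulative positive count reaches
#' `ceiling(fraction * totalPositives)`; `NA` if never reached.
#'
#' @param curve Output of [cumulativePositiveCurve()], or a numeric
#'   vector of cumulative counts (iteration = position).
#' @param totalPositives Number of positives in the pool at iteration 0.
#' @param fraction Target fraction in `(0, 1]`.
#' @return Integer iteration or `NA`.
#' @export
iterationsToFraction <- function(curve, totalPositives, fraction = 0.7) {
  if (totalPositives <= 0) .input_error("totalPositives must be positive")
  if (fraction <= 0 || fraction > 1)
    .config_error("fraction must lie in (0, 1]")
  if (is.data.frame(curve)) {
    counts <- curve$cumPositives
    iters <- curve$iteration
  } else {
    counts <- as.numeric(curve)
    iters <- seq_along(counts)
  }
  need <- ceiling(fraction * totalPositives)
  hit <- which(counts >= need)
  if (!length(hit)) return(NA_integer_)
  as.integer(iters[hit[1]])
}

#' Tidy metric traces from a collection of runs
#'
#' Flattens run histories into the tidy long format used by the
#' comparison operations: one row per (arm, task, seed, iteration,
#' metric). Metrics: `avg_precision` and `ece` on the evaluation grid,
#' `cum_positives` at every iteration.
#'
#' @param histories An [ALHistory-class] or list of them.
#' @return data.frame with columns `arm`, `task`, `seed`, `iteration`,
#'   `metric`, `value`.
#' @export
metricTraces <- function(histories) {
  if (is(histories, "ALHistory")) histories <- list(histories)
  out <- lapply(histories, function(h) {
    stopifnot(is(h, "ALHistory"))
    ev <- h@evals
    rows <- list()
    if (nrow(ev)) {
      rows$ap <- data.frame(arm = h@arm, task = h@task, seed = h@runSeed,
                            iteration = ev$iteration, metric = "avg_precision",
                            value = ev$avgPrecision)
      rows$ece <- data.frame(arm = h@arm, task = h@task, seed = h@runSeed,
                             iteration = ev$iteration, metric = "ece",
                             value = ev$ece)
    }
    if (nrow(h@acquisitions)) {
      cp <- cumulativePositiveCurve(h)
      rows$cp <- data.frame(arm = h@arm, task = h@task, seed = h@runSeed,
                            iteration = cp$iteration, metric = "cum_positives",
                            value = cp$cumPositives)
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Paired per-(task, seed) values of two arms at one iteration/metric.
.paired_values <- function(traces, armA, armB, iteration, metric) {
  sel <- traces$metric == metric & traces$iteration == iteration
  a <- traces[sel & traces$arm == armA, ]
  b <- traces[sel & traces$arm == armB, ]
  if (!nrow(a) || !nrow(b))
    .input_error(sprintf("no '%s' values for both arms at iteration %d",
                         metric, iteration))
  key_a <- paste(a$task, a$seed)
  key_b <- paste(b$task, b$seed)
  common <- intersect(key_a, key_b)
  if (length(common) < length(key_a) || length(common) < length(key_b))
    .input_error("arms are not paired: (task, seed) units differ")
  list(a = a$value[match(common, key_a)], b = b$value[match(common, key_b)])
}

# One-sided / two-sided signed-rank p-value; 1 when all differences are 0.
.wilcox_p <- function(a, b, alternative) {
  d <- a - b
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                      alternative = alternative)$p.value)
}

#' Paired Wilcoxon signed-rank comparison of two arms
#'
#' Compares two acquisition arms at one iteration using the paired
#' per-(task, seed) values of a metric. Pairing follows the replication
#' design: tasks x seeds units with identical initial sets across arms.
#'
#' @param traces Tidy traces from [metricTraces()].
#' @param armA,armB Arm names; `alternative = "greater"` tests armA >
#'   armB.
#' @param iteration Iteration on both arms' evaluation grids.
#' @param metric Metric name (default `"avg_precision"`).
#' @param alternative `"greater"` or `"two.sided"`.
#' @return A [ComparisonResult-class].
#' @export
wilcoxonAt <- function(traces, armA, armB, iteration,
                       metric = "avg_precision", alternative = "greater") {
  pv <- .paired_values(traces, armA, armB, iteration, metric)
  if (length(pv$a) < 6)
    .input_error(sprintf("need >= 6 paired observations, found %d",
                         length(pv$a)))
  if (all(pv$a == pv$b))
    .input_error("degenerate test: all paired differences are zero")
  p <- .wilcox_p(pv$a, pv$b, alternative)
  winner <- if (mean(pv$a - pv$b) >= 0) armA else armB
  new("ComparisonResult", iteration = as.integer(iteration), pValue = p,
      winner = winner)
}

# Scan from the right: smallest index i such that p[j] < alpha for all
# j >= i; NA if the last point is not significant.
.stable_from <- function(p, alpha) {
  ok <- p < alpha
  if (!length(ok) || !ok[length(ok)]) return(NA_integer_)
  bad <- which(!ok)
  if (!length(bad)) return(1L)
  as.integer(max(bad) + 1L)
}

#' Stable-significance iteration
#'
#' Smallest evaluation-grid iteration from which arm A remains
#' significantly better than arm B (one-sided paired signed-rank p-value
#' below `alpha`) at every subsequent grid point. Transient onsets of
#' significance that are later lost do not count.
#'
#' @param traces Tidy traces from [metricTraces()].
#' @param armA,armB Arm names (tests armA > armB).
#' @param metric Metric name.
#' @param alpha Significance level.
#' @return Iteration value, or `NA` if significance is never stable.
#' @export
stableSignificanceIteration <- function(traces, armA, armB,
                                        metric = "avg_precision",
                                        alpha = 0.05) {
  sel <- traces$metric == metric & traces$arm %in% c(armA, armB)
  grid <- sort(unique(traces$iteration[sel]))
  if (length(grid) < 2)
    .input_error("evaluation grid must contain at least 2 points")
  p <- vapply(grid, function(it) {
    pv <- .paired_values(traces, armA, armB, it, metric)
    .wilcox_p(pv$a, pv$b, "greater")
  }, numeric(1))
  i <- .stable_from(p, alpha)
  if (is.na(i)) NA_integer_ else as.integer(grid[i])
}

#' Mean paired gain of an arm over its random baseline
#'
#' Per-iteration mean of the paired per-(task, seed) differences between
#' an acquisition arm and the uniform baseline, with a standard-error
#' band.
#'
#' @param traces Tidy traces from [metricTraces()].
#' @param arm Acquisition arm.
#' @param baseline Baseline arm (default `"uniform"`).
#' @param metric Metric name.
#' @return data.frame with columns `iteration`, `meanGain`, `se`, `n`.
#' @export
gainOverRandom <- function(traces, arm, baseline = "uniform",
                           metric = "avg_precision") {
  sel <- traces$metric == metric & traces$arm %in% c(arm, baseline)
  g_arm <- sort(unique(traces$iteration[sel & traces$arm == arm]))
  g_base <- sort(unique(traces$iteration[sel & traces$arm == baseline]))
  if (!identical(g_arm, g_base))
    .input_error("arm and baseline evaluation grids do not match")
  rows <- lapply(g_arm, function(it) {
    pv <- .paired_values(traces, arm, baseline, it, metric)
    d <- pv$a - pv$b
    data.frame(iteration = it, meanGain = mean(d),
               se = stats::sd(d) / sqrt(length(d)), n = length(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
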