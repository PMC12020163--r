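# Evaluation metrics and paired comparisons.

# Independent step-wise AP: walk descending distinct thresholds and
# accumulate precision at each recall increment.
brute_ap <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0
  prev_rec <- 0
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

test_that("average precision matches hand-computed examples", {
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  # perfect ranking
  expect_equal(averagePrecision(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  # ties grouped: all scores equal collapses to prevalence
  expect_equal(averagePrecision(rep(1, 10), rep(c(1, 0), c(3, 7))), 0.3)
  expect_error(averagePrecision(1:4, rep(1, 4)), class = "molal_input_error")
})

test_that("average precision agrees with brute force on random instances", {
  set.seed(50)
  for (i in 1:500) {
    n <- sample(3:40, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5 else runif(n)
    expect_equal(averagePrecision(scores, labels), brute_ap(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("random rankings score near the prevalence", {
  set.seed(51)
  n <- 20000
  pi_ <- 0.15
  labels <- rbinom(n, 1, pi_)
  ap <- averagePrecision(runif(n), labels)
  se <- sqrt(pi_ * (1 - pi_) / n)
  expect_lt(abs(ap - pi_), 3 * se + 0.01)
})

test_that("expected calibration error matches its worked examples", {
  expect_equal(expectedCalibrationError(rep(1, 5), rep(1, 5)), 0)
  # 4 points at p = 0.8 with labels 1,1,1,0: one bin, |0.75 - 0.8|
  expect_equal(expectedCalibrationError(rep(0.8, 4), c(1, 1, 1, 0)), 0.05,
               tolerance = 1e-12)
  set.seed(52)
  p <- runif(200)
  y <- rbinom(200, 1, 0.5)
  e <- expectedCalibrationError(p, y)
  expect_gte(e, 0)
  expect_lte(e, 1)
})

test_that("a perfectly calibrated predictor has vanishing ECE", {
  set.seed(53)
  n <- 1e5
  p <- runif(n)
  y <- rbinom(n, 1, p)
  expect_lt(expectedCalibrationError(p, y), 0.02)
})

test_that("cumulative positive curves count acquisitions correctly", {
  h <- new("ALHistory", arm = "bald", task = "t", runSeed = 1L,
           acquisitions = data.frame(iteration = 1:3, index = 1:3,
                                     id = letters[1:3], label = c(1, 0, 1),
                                     score = runif(3), labeledSize = 101:103,
                                     poolSize = 99:97),
           evals = data.frame(), config = list(), seedTrail = data.frame(),
           status = "completed")
  cp <- cumulativePositiveCurve(h)
  expect_equal(cp$cumPositives, c(1, 1, 2))
  expect_false(is.unsorted(cp$cumPositives))
})

test_that("iterations-to-fraction scans the curve correctly", {
  expect_equal(iterationsToFraction(c(1, 1, 2, 3), 4, 0.5), 3)
  expect_true(is.na(iterationsToFraction(c(1, 1, 2, 3), 4, 1.0)))
  expect_equal(iterationsToFraction(c(0, 0, 5), 5, 1.0), 3)
  expect_error(iterationsToFraction(c(1, 2), 0, 0.5),
               class = "molal_input_error")
})

make_traces <- function(values_a, values_b, metric = "avg_precision",
                        iterations = NULL, n_seeds = NULL) {
  # values_*: matrix seeds x iterations (or vector for one iteration)
  va <- as.matrix(values_a); vb <- as.matrix(values_b)
  if (is.null(iterations)) iterations <- seq_len(ncol(va))
  rows <- list()
  for (s in seq_len(nrow(va))) for (j in seq_len(ncol(va))) {
    rows[[length(rows) + 1]] <- data.frame(
      arm = c("a", "b"), task = "t", seed = s, iteration = iterations[j],
      metric = metric, value = c(va[s, j], vb[s, j]))
  }
  do.call(rbind, rows)
}

test_that("paired Wilcoxon comparisons behave at the extremes", {
  set.seed(54)
  noise <- matrix(rnorm(20, sd = 1e-3), 20, 1)
  tr <- make_traces(0.5 + abs(noise) + 0.1, 0.5 - abs(noise))
  res <- wilcoxonAt(tr, "a", "b", iteration = 1)
  expect_lt(res@pValue, 0.05)
  expect_identical(res@winner, "a")
  # identical paired samples: degenerate
  tr0 <- make_traces(matrix(0.5, 10, 1), matrix(0.5, 10, 1))
  expect_error(wilcoxonAt(tr0, "a", "b", 1), "degenerate")
  # too few pairs
  tr5 <- make_traces(matrix(runif(5), 5, 1), matrix(runif(5), 5, 1))
  expect_error(wilcoxonAt(tr5, "a", "b", 1), "6 paired")
})

test_that("signed-rank rejection rate matches a permutation oracle", {
  # paired shift of known size: compare power at alpha = 0.05 against a
  # brute-force sign-flip permutation test on the same data
  set.seed(55)
  n_pairs <- 8
  n_rep <- 120
  shift <- 0.6
  rej_w <- rej_perm <- 0
  for (r in seq_len(n_rep)) {
    d <- rnorm(n_pairs, mean = shift)
    a <- d; b <- rep(0, n_pairs)
    p_w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               alternative = "greater")$p.value)
    # exact permutation distribution of the signed-rank statistic
    rk <- rank(abs(d))
    obs <- sum(rk[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n_pairs))
    stat <- as.matrix(signs) %*% rk
    p_perm <- mean(stat >= obs)
    rej_w <- rej_w + (p_w < 0.05)
    rej_perm <- rej_perm + (p_perm < 0.05)
  }
  se <- sqrt(0.5 * 0.5 / n_rep) # conservative MC standard error
  expect_lt(abs(rej_w - rej_perm) / n_rep, 3 * se)
})

test_that("stable significance ignores transient onsets", {
  # right-to-left scan over a constructed p-value sequence
  expect_equal(molal:::.stable_from(c(0.2, 0.01, 0.2, 0.01, 0.01), 0.05), 4L)
  expect_equal(molal:::.stable_from(c(0.01, 0.01), 0.05), 1L)
  expect_true(is.na(molal:::.stable_from(c(0.01, 0.01, 0.2), 0.05)))

  set.seed(56)
  n_seeds <- 12
  eps <- matrix(abs(rnorm(n_seeds * 4, sd = 1e-3)), n_seeds, 4)
  # arm a clearly above b from grid point 3 onwards, equal-noise before
  va <- cbind(matrix(rnorm(n_seeds * 2, sd = 0.1), n_seeds, 2),
              0.6 + eps[, 3:4])
  vb <- cbind(va[, 1:2], matrix(0.4, n_seeds, 2))
  tr <- make_traces(va, vb, iterations = c(0, 10, 20, 30))
  expect_equal(stableSignificanceIteration(tr, "a", "b"), 20)
  # significance achieved then lost at the final point: never the onset
  va2 <- cbind(0.9 + eps[, 1, drop = FALSE], vb[, 2:3],
               vb[, 4, drop = FALSE])
  tr2 <- make_traces(va2, vb, iterations = c(0, 10, 20, 30))
  expect_true(is.na(stableSignificanceIteration(tr2, "a", "b")))
})

test_that("gain over random pairs correctly and detects offsets", {
  set.seed(57)
  base <- matrix(runif(30), 10, 3)
  tr_same <- make_traces(base, base)
  tr_same$arm[tr_same$arm == "b"] <- "uniform"
  g0 <- gainOverRandom(tr_same, "a")
  expect_equal(g0$meanGain, rep(0, 3))
  tr_off <- make_traces(base + 0.05, base)
  tr_off$arm[tr_off$arm == "b"] <- "uniform"
  g5 <- gainOverRandom(tr_off, "a")
  expect_equal(g5$meanGain, rep(0.05, 3), tolerance = 1e-12)
  expect_true(all(g5$n == 10))
  # unpaired grids refused
  tr_bad <- tr_off[!(tr_off$arm == "uniform" & tr_off$iteration == 3), ]
  expect_error(gainOverRandom(tr_bad, "a"), class = "molal_input_error")
})
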