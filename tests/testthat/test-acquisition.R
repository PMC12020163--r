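# Acquisition functions against literal brute-force oracles.

# Literal evaluation of the BALD decomposition for one point: entropy of
# the mean predictive distribution minus mean per-draw entropy.
brute_bald <- function(p1) {
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  H <- function(p) {
    p <- clip(p)
    -(p * log(p) + (1 - p) * log(1 - p))
  }
  H(mean(p1)) - mean(H(p1))
}

# Literal double-loop evaluation of the EPIG estimator for a pool point
# against a target set: 2x2 joint from paired draws, KL against the
# product of marginals, averaged over targets.
brute_epig <- function(p_pool, Q) {
  T_ <- length(p_pool)
  contrib <- numeric(ncol(Q))
  for (j in seq_len(ncol(Q))) {
    q <- Q[, j]
    joint <- matrix(0, 2, 2)
    for (t in seq_len(T_)) {
      pp <- c(1 - p_pool[t], p_pool[t])
      qq <- c(1 - q[t], q[t])
      joint <- joint + outer(pp, qq) / T_
    }
    marg_p <- c(1 - mean(p_pool), mean(p_pool))
    marg_q <- c(1 - mean(q), mean(q))
    kl <- 0
    for (a in 1:2) for (b in 1:2) {
      if (joint[a, b] > 0) {
        num <- max(joint[a, b], 1e-12)
        den <- max(marg_p[a], 1e-12) * max(marg_q[b], 1e-12)
        kl <- kl + joint[a, b] * (log(num) - log(den))
      }
    }
    contrib[j] <- kl
  }
  mean(contrib)
}

test_that("uniform scores are the reciprocal pool size", {
  expect_equal(uniformScores(4)@scores, rep(0.25, 4))
  expect_equal(uniformScores(1)@scores, 1.0)
  for (n in c(3, 17, 100))
    expect_equal(sum(uniformScores(n)@scores), 1)
  expect_error(uniformScores(0), class = "molal_input_error")
})

test_that("BALD matches its analytic spot-check and brute force", {
  # T = 2 with p in {0.9, 0.1}: H(0.5) - (H(0.9) + H(0.1)) / 2
  post <- posteriorSamples(matrix(c(0.9, 0.1), nrow = 2))
  expected <- log(2) - (-(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_equal(baldScores(post)@scores, expected, tolerance = 1e-12)
  expect_equal(baldScores(post)@scores, 0.3680, tolerance = 5e-4)

  # agreement: exactly zero
  post0 <- posteriorSamples(matrix(0.7, nrow = 5, ncol = 3))
  expect_identical(baldScores(post0)@scores, rep(0, 3))

  set.seed(1)
  for (rep_ in 1:50) {
    T_ <- sample(2:30, 1)
    n <- sample(1:8, 1)
    p1 <- matrix(runif(T_ * n), T_, n)
    got <- baldScores(posteriorSamples(p1))@scores
    ref <- vapply(seq_len(n), function(i) brute_bald(p1[, i]), numeric(1))
    expect_equal(got, ref, tolerance = 1e-10)
    expect_true(all(got >= -1e-9 & got <= log(2) + 1e-9))
  }
})

test_that("EPIG matches its analytic spot-check and brute force", {
  # T = 2, pool p in {0.9, 0.1}, single target with the same draws:
  # joint [[0.41, 0.09], [0.09, 0.41]] against the uniform product
  pp <- posteriorSamples(matrix(c(0.9, 0.1), nrow = 2))
  sc <- epigScores(pp, pp)
  J <- matrix(c(0.41, 0.09, 0.09, 0.41), 2)
  expect_equal(sc@scores, sum(J * log(J / 0.25)), tolerance = 1e-12)
  expect_equal(round(sc@scores, 4), 0.2218)

  # pool draws identical: zero for any target set
  pool0 <- posteriorSamples(matrix(0.8, 4, 2))
  tgt <- posteriorSamples(matrix(runif(8), 4, 2))
  expect_identical(epigScores(pool0, tgt)@scores, rep(0, 2))

  # target draws constant: zero regardless of pool disagreement
  pool_var <- posteriorSamples(matrix(c(0.9, 0.1, 0.5, 0.2), 4, 1))
  tgt0 <- posteriorSamples(matrix(0.3, 4, 3))
  expect_equal(epigScores(pool_var, tgt0)@scores, 0, tolerance = 1e-12)

  set.seed(2)
  for (rep_ in 1:20) {
    T_ <- sample(2:15, 1)
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    P <- matrix(runif(T_ * n), T_, n)
    Q <- matrix(runif(T_ * m), T_, m)
    got <- epigScores(posteriorSamples(P), posteriorSamples(Q))@scores
    ref <- vapply(seq_len(n), function(i) brute_epig(P[, i], Q), numeric(1))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("EPIG per-target contributions are symmetric in pool and target", {
  set.seed(3)
  P <- matrix(runif(12), 6, 2)
  Q <- matrix(runif(6), 6, 1)
  a <- epigScores(posteriorSamples(P[, 1, drop = FALSE]),
                  posteriorSamples(Q))@scores
  b <- epigScores(posteriorSamples(Q),
                  posteriorSamples(P[, 1, drop = FALSE]))@scores
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("unpaired pool/target draws are refused", {
  p4 <- posteriorSamples(matrix(runif(8), 4, 2))
  p5 <- posteriorSamples(matrix(runif(10), 5, 2))
  expect_error(epigScores(p4, p5), class = "molal_input_error")
  expect_match(tryCatch(epigScores(p4, p5), error = conditionMessage),
               "not paired")
})

test_that("selection takes the argmax, breaks ties by seed, samples uniformly", {
  sc <- new("AcquisitionScores", scores = c(0.1, 0.9, 0.5), name = "bald",
            logBase = "nat")
  expect_identical(selectNext(sc, 1, seed = 1), 2L)
  expect_setequal(selectNext(sc, 3, seed = 1), 1:3)

  ties <- new("AcquisitionScores", scores = rep(0.3, 10), name = "epig",
              logBase = "nat")
  pick1 <- selectNext(ties, 1, seed = 4)
  expect_identical(selectNext(ties, 1, seed = 4), pick1)
  picks <- vapply(1:40, function(s) selectNext(ties, 1, seed = s), integer(1))
  expect_gt(length(unique(picks)), 3) # ties actually randomised

  unif <- uniformScores(10)
  expect_identical(selectNext(unif, 2, seed = 9), selectNext(unif, 2, seed = 9))
  expect_error(selectNext(unif, 11, seed = 1), class = "molal_config_error")
})
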