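# Active-learning loop: bookkeeping invariants, determinism, pairing.

small_cfg <- function(acq, n_iter = 8, seed = 1) {
  alConfig(acquisition = acq, task = "active", nIterations = n_iter,
           initialSize = 20L, evalEvery = 4L, targetSampleSize = 20L,
           runSeed = seed, bnn = bnnConfig(hiddenDim = 16L, epochs = 5L))
}

test_that("labeled-set arithmetic and pool shrinkage are exact", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 1)
  h <- runActiveLearning(prob$tab, prob$features, spl, small_cfg("bald"))
  a <- h@acquisitions
  expect_equal(nrow(a), 8)
  expect_equal(a$labeledSize, 20 + seq_len(8))
  expect_equal(diff(a$poolSize), rep(-1, 7))
  expect_false(anyDuplicated(a$index) > 0)
  expect_identical(h@status, "completed")
  # final labeled size invariant: initial + i * batch
  expect_equal(a$labeledSize[8], 28)
})

test_that("no test-set index is ever acquired and pool labels exist", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 2)
  for (acq in c("uniform", "epig")) {
    h <- runActiveLearning(prob$tab, prob$features, spl, small_cfg(acq))
    expect_length(intersect(h@acquisitions$index, prob$splits@test), 0)
    expect_false(anyNA(h@acquisitions$label))
  }
})

test_that("uniform-arm acquisition sequences are reproducible bit-for-bit", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 3)
  h1 <- runActiveLearning(prob$tab, prob$features, spl, small_cfg("uniform"))
  h2 <- runActiveLearning(prob$tab, prob$features, spl, small_cfg("uniform"))
  expect_identical(h1@acquisitions$index, h2@acquisitions$index)
  expect_identical(h1@evals, h2@evals)
  h3 <- runActiveLearning(prob$tab, prob$features, spl,
                          small_cfg("uniform", seed = 9))
  expect_false(identical(h1@acquisitions$index, h3@acquisitions$index))
})

test_that("evaluation happens on the configured grid", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 4)
  h <- runActiveLearning(prob$tab, prob$features, spl,
                         small_cfg("uniform", n_iter = 10))
  expect_equal(h@evals$iteration, c(0, 4, 8, 10))
  expect_true(all(h@evals$ece >= 0 & h@evals$ece <= 1))
  expect_true(all(is.na(h@evals$avgPrecision) |
                    (h@evals$avgPrecision >= 0 & h@evals$avgPrecision <= 1)))
})

test_that("the run truncates cleanly when the pool is exhausted", {
  prob <- tiny_al_problem(n = 150)
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 5)
  n_pool <- length(spl@pool)
  cfg <- small_cfg("uniform", n_iter = n_pool + 10)
  h <- runActiveLearning(prob$tab, prob$features, spl, cfg)
  expect_identical(h@status, "pool_exhausted")
  expect_equal(nrow(h@acquisitions), n_pool)
})

test_that("uniform acquisition is a uniform permutation prefix of the pool", {
  # first-pick distribution over many seeds: chi-square not rejected
  prob <- tiny_al_problem(n = 120, seed = 8)
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 10, seed = 1)
  n_pool <- length(spl@pool)
  cfg0 <- alConfig(acquisition = "uniform", task = "active", nIterations = 1L,
                   initialSize = 10L, evalEvery = 10L, runSeed = 1L,
                   bnn = bnnConfig(hiddenDim = 8L, epochs = 2L))
  picks <- vapply(1:400, function(s) {
    cfg0@runSeed <- as.integer(s)
    runActiveLearning(prob$tab, prob$features, spl, cfg0)@acquisitions$index[1]
  }, integer(1))
  counts <- table(factor(picks, levels = spl@pool))
  p <- suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.01)
})

test_that("run matrices share initial sets across arms within a seed", {
  prob <- tiny_al_problem()
  hs <- runMatrix(prob$tab, prob$features, prob$splits,
                  acquisitions = c("uniform", "bald"), seeds = 1:2,
                  config = small_cfg("uniform", n_iter = 4))
  expect_length(hs, 4)
  # identical initial sets across arms: same labeled size trajectory and
  # disjoint-from-test acquisition, plus equal eval grids
  tr <- metricTraces(hs)
  grids <- tapply(tr$iteration[tr$metric == "avg_precision"],
                  tr$arm[tr$metric == "avg_precision"],
                  function(x) paste(sort(unique(x)), collapse = ","))
  expect_length(unique(grids), 1)
  expect_error(runMatrix(prob$tab, prob$features, prob$splits,
                         acquisitions = "bald", seeds = integer(0)),
               class = "molal_config_error")
})

test_that("histories serialise and round-trip losslessly", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 6)
  h <- runActiveLearning(prob$tab, prob$features, spl, small_cfg("bald"))
  path <- tempfile(fileext = ".json")
  writeHistory(h, path)
  back <- readHistory(path)
  expect_equal(back@acquisitions, h@acquisitions, tolerance = 0)
  expect_equal(back@evals, h@evals, tolerance = 0)
  expect_identical(back@arm, h@arm)
  expect_identical(back@status, h@status)
  expect_identical(back@runSeed, h@runSeed)
})

test_that("acquisition scores can be logged to CSV", {
  prob <- tiny_al_problem()
  spl <- makeInitialPool(prob$tab, prob$splits, "active", 20, seed = 7)
  log <- tempfile(fileext = ".csv")
  runActiveLearning(prob$tab, prob$features, spl, small_cfg("uniform"),
                    logFile = log)
  lg <- read.csv(log)
  expect_equal(nrow(lg), 8)
  expect_named(lg, c("iteration", "poolIndex", "moleculeId", "score",
                     "acquired"))
})
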