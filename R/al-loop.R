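# The active-learning loop: train, score pool, acquire, reveal, retrain.

#' Create an active-learning run configuration
#'
#' @param acquisition `"uniform"`, `"bald"` or `"epig"`.
#' @param featureKind Expected provenance of the feature matrix.
#' @param task Task name (`NA` = take it from the split object).
#' @param nIterations Number of acquisition iterations.
#' @param batchSize Points acquired per iteration (no diversity
#'   correction is applied for batches > 1).
#' @param initialSize Balanced initial labeled-set size.
#' @param targetSampleSize Number M of target points drawn from the test
#'   set per iteration for the EPIG estimator.
#' @param evalEvery Evaluation grid spacing; iteration 0 and the final
#'   iteration are always evaluated.
#' @param runSeed Seed from which every stage seed of the run is derived.
#' @param bnn A [BnnConfig-class] for the per-iteration retraining.
#' @param inferenceDropout Dropout rate for the stochastic forward passes
#'   (default 0.5, the reference setting for Monte-Carlo sampling; `NA` =
#'   training rate).
#' @return An [ALConfig-class].
#' @export
alConfig <- function(acquisition = "epig", featureKind = "synthetic",
                     task = NA_character_, nIterations = 100L, batchSize = 1L,
                     initialSize = 100L, targetSampleSize = 100L,
                     evalEvery = 10L, runSeed = 1L, bnn = bnnConfig(),
                     inferenceDropout = 0.5) {
  new("ALConfig", acquisition = acquisition, featureKind = featureKind,
      task = as.character(task), nIterations = as.integer(nIterations),
      batchSize = as.integer(batchSize), initialSize = as.integer(initialSize),
      targetSampleSize = as.integer(targetSampleSize),
      evalEvery = as.integer(evalEvery), runSeed = as.integer(runSeed),
      bnn = bnn, inferenceDropout = inferenceDropout)
}

.config_snapshot <- function(config) {
  b <- config@bnn
  list(acquisition = config@acquisition, featureKind = config@featureKind,
       task = config@task, nIterations = config@nIterations,
       batchSize = config@batchSize, initialSize = config@initialSize,
       targetSampleSize = config@targetSampleSize,
       evalEvery = config@evalEvery, runSeed = config@runSeed,
       inferenceDropout = config@inferenceDropout,
       bnn = list(inputDim = b@inputDim, hiddenDim = b@hiddenDim,
                  nHidden = b@nHidden, dropoutP = b@dropoutP,
                  learningRate = b@learningRate, weightDecay = b@weightDecay,
                  epochs = b@epochs, batchSize = b@batchSize,
                  lrCycle = b@lrCycle, nForwardPasses = b@nForwardPasses,
                  posWeight = b@posWeight, standardize = b@standardize))
}

#' Run one active-learning experiment
#'
#' Executes the pool-based loop: (1) train the MC-dropout network on the
#' current labeled set; (2) draw T stochastic forward passes over the pool
#' (and, for EPIG, over M target points sampled from the test set, in the
#' same call so that pool and target share each pass's dropout mask); (3)
#' score the pool with the configured acquisition function; (4) select the
#' batch; (5) reveal the selected labels from the table (simulated oracle)
#' and move the points into the labeled set; (6) on the evaluation grid,
#' measure average precision and expected calibration error of the
#' Monte-Carlo mean prediction on the fixed test set. Repeats for
#' `nIterations` or until the pool is exhausted (clean truncation). The
#' entire run is reproducible from `config@runSeed`; with the uniform
#' baseline, the model is only trained at evaluation points since scores
#' do not depend on it.
#'
#' @param table A [MoleculeTable-class] (labels are the simulated oracle).
#' @param features A [FeatureMatrix-class] aligned with `table`.
#' @param splits A [SplitIndices-class] with initial/pool filled in.
#' @param config An [ALConfig-class].
#' @param logFile Optional CSV path; one row per acquired point
#'   (iteration, pool index, molecule id, score, acquired flag) is
#'   appended.
#' @param checkpointDir Optional directory; the partial history is
#'   flushed there every 25 iterations.
#' @return An [ALHistory-class].
#' @export
runActiveLearning <- function(table, features, splits, config,
                              logFile = NULL, checkpointDir = NULL) {
  stopifnot(is(table, "MoleculeTable"), is(splits, "SplitIndices"),
            is(config, "ALConfig"))
  x <- .feature_values(features)
  if (nrow(x) != length(table))
    .input_error("features and molecule table are not aligned")
  if (is(features, "FeatureMatrix") && features@kind != config@featureKind)
    .config_error(sprintf("feature kind '%s' does not match config ('%s')",
                          features@kind, config@featureKind))
  task <- if (is.na(config@task)) splits@task else config@task
  if (is.na(task) || !task %in% taskNames(table))
    .config_error("no valid task: set config@task or use makeInitialPool()")
  y <- table@labels[, task]
  labeled <- splits@initial
  pool <- splits@pool
  if (!length(labeled)) .config_error("splits carry no initial set")
  if (!length(pool)) .input_error("pool is empty")
  if (length(intersect(c(labeled, pool), splits@test)))
    .input_error("initial/pool overlap the test set")
  if (anyNA(y[pool]))
    .input_error("pool contains molecules without a label for the task")

  acq <- config@acquisition
  run_seed <- config@runSeed
  n_iter <- config@nIterations
  eval_grid <- unique(c(seq(0L, n_iter, by = config@evalEvery), n_iter))
  test_eval <- splits@test[!is.na(y[splits@test])]
  inf_p <- if (is.na(config@inferenceDropout)) NULL else config@inferenceDropout
  Tn <- config@bnn@nForwardPasses

  acq_rows <- vector("list", n_iter)
  eval_rows <- list()
  seed_rows <- list()
  status <- "completed"
  note_seed <- function(i, stage, s) {
    seed_rows[[length(seed_rows) + 1]] <<- data.frame(
      iteration = i, stage = stage, seed = s)
  }

  for (i in 0:n_iter) {
    model <- NULL
    need_model <- acq != "uniform" || i %in% eval_grid
    if (need_model) {
      s_train <- deriveSeed(run_seed, acq, "train", i)
      note_seed(i, "train", s_train)
      cfg_b <- config@bnn
      cfg_b@seed <- s_train
      model <- tryCatch(trainBnn(x[labeled, , drop = FALSE], y[labeled],
                                 cfg_b),
                        error = function(e) e)
      if (inherits(model, "error")) {
        warning(sprintf("training failed at iteration %d: %s; aborting with partial history",
                        i, conditionMessage(model)))
        status <- sprintf("diverged_at_%d", i)
        break
      }
    }
    if (i %in% eval_grid && length(test_eval) && !is.null(model)) {
      s_eval <- deriveSeed(run_seed, acq, "eval", i)
      note_seed(i, "eval", s_eval)
      post <- mcPredict(model, x[test_eval, , drop = FALSE], T = Tn,
                        dropoutActive = TRUE, seed = s_eval, dropoutP = inf_p)
      pbar <- meanPrediction(post)
      y_test <- y[test_eval]
      ap <- if (length(unique(y_test)) < 2) NA_real_ else
        averagePrecision(pbar, y_test)
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        iteration = i, avgPrecision = ap,
        ece = expectedCalibrationError(pbar, y_test),
        labeledSize = length(labeled))
    }
    if (i == n_iter) break
    if (!length(pool)) {
      status <- "pool_exhausted"
      break
    }
    b <- min(config@batchSize, length(pool))
    s_pred <- deriveSeed(run_seed, acq, "predict", i)
    sc <- switch(acq,
      uniform = uniformScores(length(pool)),
      bald = {
        note_seed(i, "predict", s_pred)
        baldScores(mcPredict(model, x[pool, , drop = FALSE], T = Tn,
                             dropoutActive = TRUE, seed = s_pred,
                             dropoutP = inf_p))
      },
      epig = {
        if (!length(test_eval))
          .input_error("EPIG requires a labeled test set to sample targets from")
        m_t <- min(config@targetSampleSize, length(test_eval))
        s_target <- deriveSeed(run_seed, acq, "target", i)
        note_seed(i, "target", s_target)
        targets <- .with_seed(s_target, sample(test_eval, m_t))
        note_seed(i, "predict", s_pred)
        post <- mcPredict(model, x[c(pool, targets), , drop = FALSE], T = Tn,
                          dropoutActive = TRUE, seed = s_pred, dropoutP = inf_p)
        p1 <- post@probs[, , 2, drop = FALSE]
        dim(p1) <- dim(post@probs)[1:2]
        epigScores(posteriorSamples(p1[, seq_along(pool), drop = FALSE]),
                   posteriorSamples(p1[, length(pool) + seq_len(m_t),
                                       drop = FALSE]))
      })
    s_sel <- deriveSeed(run_seed, acq, "select", i)
    note_seed(i, "select", s_sel)
    sel <- selectNext(sc, b, seed = s_sel)
    chosen <- pool[sel]
    if (any(chosen %in% splits@test))
      stop("internal leakage: selected a test-set index") # never reachable
    acq_rows[[i + 1]] <- data.frame(
      iteration = i + 1L, index = chosen, id = table@ids[chosen],
      label = y[chosen], score = sc@scores[sel],
      labeledSize = length(labeled) + b, poolSize = length(pool) - b)
    labeled <- c(labeled, chosen)
    pool <- pool[-sel]
    if (!is.null(logFile)) {
      utils::write.table(
        data.frame(iteration = i + 1L, poolIndex = chosen,
                   moleculeId = table@ids[chosen], score = sc@scores[sel],
                   acquired = TRUE),
        logFile, sep = ",", row.names = FALSE,
        col.names = !file.exists(logFile), append = file.exists(logFile))
    }
    if (!is.null(checkpointDir) && (i + 1L) %% 25L == 0L) {
      h <- .make_history(config, task, acq_rows, eval_rows, seed_rows,
                         "checkpoint")
      writeHistory(h, file.path(checkpointDir,
                                sprintf("%s_%s_%d_checkpoint.json", acq, task,
                                        run_seed)))
    }
  }
  .make_history(config, task, acq_rows, eval_rows, seed_rows, status)
}

.make_history <- function(config, task, acq_rows, eval_rows, seed_rows,
                          status) {
  acq_df <- do.call(rbind, Filter(Negate(is.null), acq_rows))
  if (is.null(acq_df))
    acq_df <- data.frame(iteration = integer(0), index = integer(0),
                         id = character(0), label = numeric(0),
                         score = numeric(0), labeledSize = integer(0),
                         poolSize = integer(0))
  eval_df <- if (length(eval_rows)) do.call(rbind, eval_rows) else
    data.frame(iteration = integer(0), avgPrecision = numeric(0),
               ece = numeric(0), labeledSize = integer(0))
  seed_df <- if (length(seed_rows)) do.call(rbind, seed_rows) else
    data.frame(iteration = integer(0), stage = character(0),
               seed = integer(0))
  rownames(acq_df) <- rownames(eval_df) <- rownames(seed_df) <- NULL
  new("ALHistory", arm = config@acquisition, task = task,
      runSeed = config@runSeed, acquisitions = acq_df, evals = eval_df,
      config = .config_snapshot(config), seedTrail = seed_df,
      status = status)
}

#' Run a matrix of active-learning experiments
#'
#' Cross-product of acquisition arms, tasks and replication seeds, with
#' the pairing contract required for signed-rank comparisons: within each
#' (task, seed) cell every arm shares the identical initial set and pool
#' (drawn once from the shared train/test split), while stage seeds
#' (initialisation, dropout masks) differ across arms.
#'
#' @param table A [MoleculeTable-class].
#' @param features A [FeatureMatrix-class] aligned with `table`.
#' @param splits A [SplitIndices-class] with train/test filled in (the
#'   test set is identical for all runs).
#' @param acquisitions Character vector of arms.
#' @param tasks Task names (default: all tasks of `table`).
#' @param seeds Integer replication seeds.
#' @param config Template [ALConfig-class]; its acquisition/task/runSeed
#'   fields are overridden per run.
#' @return Named list of [ALHistory-class] objects, keyed
#'   `arm|task|seed`.
#' @export
runMatrix <- function(table, features, splits, acquisitions,
                      tasks = NULL, seeds, config = alConfig()) {
  if (!length(seeds)) .config_error("at least one seed is required")
  if (!length(acquisitions)) .config_error("at least one acquisition arm is required")
  if (is.null(tasks))
    tasks <- if (!is.na(splits@task)) splits@task else taskNames(table)
  out <- list()
  for (task in tasks) {
    for (seed in seeds) {
      spl <- makeInitialPool(table, splits, task,
                             initialSize = config@initialSize, seed = seed)
      for (acq in acquisitions) {
        cfg <- config
        cfg@acquisition <- acq
        cfg@task <- task
        cfg@runSeed <- as.integer(seed)
        out[[paste(acq, task, seed, sep = "|")]] <-
          runActiveLearning(table, features, spl, cfg)
      }
    }
  }
  out
}
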