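# Scaffold-based train/test splitting and initial/pool construction.

#' Scaffold-based train/test split
#'
#' Groups molecules by canonical Bemis-Murcko scaffold, sorts groups by
#' descending size (ties broken by lexicographic scaffold string) and
#' assigns them greedily to the training set -- prioritising larger groups
#' -- until it holds at least `1 - testFraction` of the molecules; the
#' remaining groups form the test set. No scaffold ever crosses the
#' boundary, so the test set probes generalisation to unseen chemotypes.
#' Acyclic molecules (empty scaffold) form one shared group.
#'
#' The assignment is fully deterministic; `seed` is only recorded in the
#' returned object for provenance.
#'
#' @param table A [MoleculeTable-class] with parseable SMILES.
#' @param testFraction Target fraction of molecules in the test set.
#' @param seed Integer seed recorded with the split.
#' @param scaffolds Optional precomputed scaffold strings (one per
#'   molecule, as returned by [murckoScaffolds()]), to avoid recomputing
#'   them across repeated splits.
#' @return A [SplitIndices-class] with `train` and `test` filled in.
#' @export
scaffoldSplit <- function(table, testFraction = 0.2, seed = 1L,
                          scaffolds = NULL) {
  stopifnot(is(table, "MoleculeTable"))
  if (testFraction <= 0 || testFraction >= 1)
    .config_error("testFraction must lie in (0, 1)")
  scaf <- if (is.null(scaffolds)) murckoScaffolds(table) else scaffolds
  if (length(scaf) != length(table))
    .input_error("scaffolds must have one entry per molecule")
  groups <- split(seq_along(scaf), scaf)
  if (length(groups) < 2)
    .input_error("all molecules share a single scaffold; split impossible")
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups), method = "radix")
  groups <- groups[ord]
  n <- length(scaf)
  target <- (1 - testFraction) * n
  train <- integer(0)
  cut_at <- 0L
  for (g in seq_along(groups)) {
    train <- c(train, groups[[g]])
    cut_at <- g
    if (length(train) >= target) break
  }
  test <- sort(unlist(groups[seq_along(groups) > cut_at], use.names = FALSE))
  if (!length(test))
    .input_error("largest scaffold groups already cover the dataset; split impossible")
  new("SplitIndices", train = sort(as.integer(train)), test = as.integer(test),
      seed = as.integer(seed),
      params = list(testFraction = testFraction, method = "scaffold"))
}

#' Random train/test split
#'
#' Uniform split for feature spaces without chemical structure (synthetic
#' feature spaces, precomputed embeddings without SMILES).
#'
#' @param n Number of rows.
#' @param testFraction Fraction assigned to the test set.
#' @param seed Integer seed.
#' @return A [SplitIndices-class] with `train` and `test` filled in.
#' @export
randomSplit <- function(n, testFraction = 0.2, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    .config_error("testFraction must lie in (0, 1)")
  n_test <- max(1L, round(testFraction * n))
  test <- sort(.with_seed(deriveSeed(seed, "random_split"),
                          sample.int(n, n_test)))
  new("SplitIndices", train = setdiff(seq_len(n), test), test = test,
      seed = as.integer(seed),
      params = list(testFraction = testFraction, method = "random"))
}

#' Balanced initial set and acquisition pool
#'
#' Draws the initial labeled set -- `initialSize/2` positives and
#' `initialSize/2` negatives, uniformly at random from the training set
#' under the given seed -- and defines the pool as the remaining training
#' molecules with a non-missing label for the task (a pool point must be
#' labelable).
#'
#' @param table A [MoleculeTable-class].
#' @param splits A [SplitIndices-class] with `train`/`test` filled in.
#' @param task Task name the run will operate on.
#' @param initialSize Total size of the balanced initial set (even).
#' @param seed Integer seed for the random draw.
#' @return A [SplitIndices-class] with `initial` and `pool` filled in.
#' @export
makeInitialPool <- function(table, splits, task, initialSize = 100L,
                            seed = 1L) {
  stopifnot(is(table, "MoleculeTable"), is(splits, "SplitIndices"))
  if (!task %in% taskNames(table))
    .config_error(sprintf("unknown task '%s'", task))
  if (initialSize %% 2 != 0)
    .config_error("initialSize must be even (balanced positives/negatives)")
  half <- initialSize %/% 2
  y <- table@labels[, task]
  train_lab <- splits@train[!is.na(y[splits@train])]
  pos <- train_lab[y[train_lab] == 1]
  neg <- train_lab[y[train_lab] == 0]
  if (length(pos) < half)
    .input_error(sprintf(
      "insufficient positives for task '%s': need %d, found %d", task, half,
      length(pos)))
  if (length(neg) < half)
    .input_error(sprintf(
      "insufficient negatives for task '%s': need %d, found %d", task, half,
      length(neg)))
  initial <- .with_seed(deriveSeed(seed, "initial", task), {
    c(sample(pos, half), sample(neg, half))
  })
  initial <- sort(as.integer(initial))
  pool <- sort(setdiff(train_lab, initial))
  new("SplitIndices", train = splits@train, test = splits@test,
      initial = initial, pool = as.integer(pool), task = task,
      seed = as.integer(seed),
      params = c(splits@params, list(initialSize = as.integer(initialSize))))
}
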