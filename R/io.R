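# JSON serialisation of splits and run histories.

#' Write a split manifest
#'
#' Serialises a [SplitIndices-class] to JSON (index lists plus the seed
#' and parameters used).
#'
#' @param splits A [SplitIndices-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeSplit <- function(splits, path) {
  stopifnot(is(splits, "SplitIndices"))
  obj <- list(train = splits@train, test = splits@test,
              initial = splits@initial, pool = splits@pool,
              task = splits@task, seed = splits@seed, params = splits@params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path JSON file written by [writeSplit()].
#' @return A [SplitIndices-class].
#' @export
readSplit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SplitIndices", train = as.integer(obj$train),
      test = as.integer(obj$test),
      initial = as.integer(obj$initial %||% integer(0)),
      pool = as.integer(obj$pool %||% integer(0)),
      task = as.character(obj$task %||% NA_character_),
      seed = as.integer(obj$seed %||% NA_integer_),
      params = as.list(obj$params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run history
#'
#' Serialises an [ALHistory-class] to a JSON manifest (configuration
#' snapshot, acquisition record, evaluation table, seed trail) at full
#' numeric precision, so reading it back reproduces the history exactly.
#'
#' @param history An [ALHistory-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeHistory <- function(history, path) {
  stopifnot(is(history, "ALHistory"))
  obj <- list(arm = history@arm, task = history@task,
              runSeed = history@runSeed, status = history@status,
              config = history@config, acquisitions = history@acquisitions,
              evals = history@evals, seedTrail = history@seedTrail)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a run history
#'
#' @param path JSON file written by [writeHistory()].
#' @return An [ALHistory-class].
#' @export
readHistory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x, template) {
    if (is.null(x) || !length(x)) return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cl in names(template))
      df[[cl]] <- methods::as(df[[cl]], class(template[[cl]]))
    df[names(template)]
  }
  acq_t <- data.frame(iteration = integer(0), index = integer(0),
                      id = character(0), label = numeric(0),
                      score = numeric(0), labeledSize = integer(0),
                      poolSize = integer(0))
  eval_t <- data.frame(iteration = integer(0), avgPrecision = numeric(0),
                       ece = numeric(0), labeledSize = integer(0))
  seed_t <- data.frame(iteration = integer(0), stage = character(0),
                       seed = integer(0))
  new("ALHistory", arm = obj$arm, task = obj$task,
      runSeed = as.integer(obj$runSeed), status = obj$status,
      config = obj$config,
      acquisitions = as_df(obj$acquisitions, acq_t),
      evals = as_df(obj$evals, eval_t),
      seedTrail = as_df(obj$seedTrail, seed_t))
}

#' Write tidy metric traces to CSV
#'
#' @param traces data.frame from [metricTraces()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}
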