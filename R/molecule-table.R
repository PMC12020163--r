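# MoleculeTable construction and CSV round-trip.

#' Construct a MoleculeTable
#'
#' @param ids Character identifiers (unique). Defaults to `mol_<i>`.
#' @param smiles Character SMILES strings; `NA` is allowed for synthetic
#'   feature spaces without chemical structures.
#' @param labels Numeric vector (single task) or matrix with entries in
#'   `{0, 1, NA}`.
#' @param taskNames Task names; defaults to the label column names or
#'   `task_<j>`.
#' @return A [MoleculeTable-class].
#' @examples
#' moleculeTable(smiles = c("CCO", "c1ccccc1"), labels = c(1, 0))
#' @export
moleculeTable <- function(smiles, labels, ids = NULL, taskNames = NULL) {
  smiles <- as.character(smiles)
  if (is.null(dim(labels))) labels <- matrix(as.numeric(labels), ncol = 1)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  if (is.null(taskNames)) {
    taskNames <- colnames(labels)
    if (is.null(taskNames))
      taskNames <- paste0("task_", seq_len(ncol(labels)))
  }
  colnames(labels) <- taskNames
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smiles))
  new("MoleculeTable", ids = as.character(ids), smiles = smiles,
      labels = labels)
}

#' Read a molecule table from CSV
#'
#' Reads a CSV with a SMILES column and one or more binary label columns
#' (the Tox21/ClinTox layout). Empty cells and `"NA"` are treated as
#' missing labels. Rows whose SMILES cannot be parsed are dropped with a
#' logged count.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param smilesColumn Name of the SMILES column.
#' @param taskColumns Character vector of label column names; default: all
#'   columns except the SMILES and id columns.
#' @param idColumn Optional name of an identifier column.
#' @return A [MoleculeTable-class] containing only rows with parseable
#'   SMILES.
#' @export
readMoleculeTable <- function(path, smilesColumn = "smiles",
                              taskColumns = NULL, idColumn = NULL) {
  if (!file.exists(path)) .input_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  if (!smilesColumn %in% names(df))
    .config_error(sprintf("SMILES column '%s' not present in %s",
                          smilesColumn, path))
  if (is.null(taskColumns))
    taskColumns <- setdiff(names(df), c(smilesColumn, idColumn))
  missing_cols <- setdiff(taskColumns, names(df))
  if (length(missing_cols))
    .config_error(sprintf("label column(s) not present: %s",
                          paste(missing_cols, collapse = ", ")))
  if (!is.null(idColumn) && !idColumn %in% names(df))
    .config_error(sprintf("id column '%s' not present", idColumn))
  labels <- as.matrix(df[, taskColumns, drop = FALSE])
  storage.mode(labels) <- "double"
  ok_vals <- labels[!is.na(labels)]
  if (length(ok_vals) && !all(ok_vals %in% c(0, 1)))
    .input_error("label columns must contain only 0, 1 or missing cells")

  smiles <- as.character(df[[smilesColumn]])
  parsed <- .parse_smiles(smiles)
  n_bad <- sum(!parsed$valid)
  if (n_bad > 0)
    message(sprintf("readMoleculeTable: dropped %d row(s) with unparseable SMILES", n_bad))
  keep <- parsed$valid
  if (!any(keep)) .input_error("no rows with parseable SMILES")
  ids <- if (!is.null(idColumn)) as.character(df[[idColumn]])[keep] else
    paste0("mol_", which(keep))
  moleculeTable(smiles = smiles[keep],
                labels = labels[keep, , drop = FALSE],
                ids = ids, taskNames = taskColumns)
}

#' Write a molecule table to CSV
#'
#' Missing labels are written as empty cells, so that
#' `readMoleculeTable(writeMoleculeTable(x))` reproduces labels and missing
#' mask exactly.
#'
#' @param table A [MoleculeTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeMoleculeTable <- function(table, path) {
  stopifnot(is(table, "MoleculeTable"))
  df <- data.frame(id = table@ids, smiles = table@smiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table@labels, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Single-task view of a multitask table
#'
#' Restricts a table to one task, keeping only molecules whose label for
#' that task is not missing. Multitask data are handled as independent
#' per-task active-learning runs.
#'
#' @param table A [MoleculeTable-class].
#' @param task Task name.
#' @return A one-task [MoleculeTable-class] without missing labels.
#' @export
singleTaskView <- function(table, task) {
  stopifnot(is(table, "MoleculeTable"))
  if (!task %in% taskNames(table))
    .config_error(sprintf("unknown task '%s'; available: %s", task,
                          paste(taskNames(table), collapse = ", ")))
  y <- table@labels[, task]
  keep <- which(!is.na(y))
  if (!length(keep))
    .input_error(sprintf("task '%s' has no non-missing labels", task))
  new("MoleculeTable", ids = table@ids[keep], smiles = table@smiles[keep],
      labels = table@labels[keep, task, drop = FALSE])
}
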