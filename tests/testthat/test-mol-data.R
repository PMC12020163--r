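# Molecule tables, CSV round-trip, scaffold splitting, initial/pool sets.

test_that("CSV reading maps blanks to missing and validates labels", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("smiles,tox", "CCO,1", "c1ccccc1,0", "CCN,"), path)
  tab <- readMoleculeTable(path, smilesColumn = "smiles",
                           taskColumns = "tox")
  expect_equal(length(tab), 3)
  expect_equal(sum(is.na(labelMatrix(tab))), 1)
  expect_equal(labelMatrix(tab)[1:2, "tox"], c(1, 0), ignore_attr = TRUE)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("smiles,tox", "CCO,2"), bad)
  expect_error(readMoleculeTable(bad, taskColumns = "tox"),
               class = "molal_input_error")
  expect_error(readMoleculeTable(path, smilesColumn = "nope"),
               class = "molal_config_error")
})

test_that("rows with unparseable SMILES are dropped with a logged count", {
  path <- write_fixture_csv(tempfile(fileext = ".csv"), with_invalid = TRUE)
  expect_message(tab <- readMoleculeTable(path, idColumn = "id"),
                 "dropped 1 row")
  expect_equal(length(tab), 20)
  expect_false("broken" %in% moleculeIds(tab))
})

test_that("molecule tables round-trip through CSV exactly", {
  tab <- fixtureMolecules()
  path <- tempfile(fileext = ".csv")
  writeMoleculeTable(tab, path)
  back <- readMoleculeTable(path, idColumn = "id")
  expect_identical(moleculeIds(back), moleculeIds(tab))
  expect_identical(smilesOf(back), smilesOf(tab))
  expect_identical(labelMatrix(back), labelMatrix(tab))
})

test_that("label values other than 0/1/missing are rejected at construction", {
  expect_error(moleculeTable(smiles = "CCO", labels = 2), "0 or 1")
  expect_error(moleculeTable(smiles = c("CCO", "CCN"), labels = c(0, 1),
                             ids = c("a", "a")), "unique")
})

test_that("scaffold split follows the greedy larger-groups-first rule", {
  tab <- fixtureMolecules()
  scafs <- murckoScaffolds(tab)
  sp <- scaffoldSplit(tab, testFraction = 0.2, seed = 1)

  # independent application of the greedy rule
  groups <- split(seq_along(scafs), scafs)
  ord <- order(-lengths(groups), names(groups), method = "radix")
  groups <- groups[ord]
  train_ref <- integer(0)
  g <- 0
  while (length(train_ref) < 0.8 * length(scafs)) {
    g <- g + 1
    train_ref <- c(train_ref, groups[[g]])
  }
  expect_setequal(sp@train, train_ref)
  expect_setequal(sp@test, setdiff(seq_along(scafs), train_ref))
  expect_true(length(sp@test) / length(scafs) >= 0.1)
  expect_true(length(sp@test) / length(scafs) <= 0.3)
  # no scaffold crosses the boundary
  expect_length(intersect(scafs[sp@train], scafs[sp@test]), 0)
})

test_that("molecules sharing a scaffold always land on the same side", {
  tab <- fixtureMolecules()
  scafs <- murckoScaffolds(tab)
  sp <- scaffoldSplit(tab, 0.3, seed = 2)
  for (s in unique(scafs)) {
    members <- which(scafs == s)
    expect_true(all(members %in% sp@train) || all(members %in% sp@test))
  }
})

test_that("a single shared scaffold makes the split impossible", {
  tab <- moleculeTable(smiles = c("c1ccccc1C", "c1ccccc1CC", "c1ccccc1O"),
                       labels = c(1, 0, 1))
  expect_error(scaffoldSplit(tab, 0.2), "single scaffold")
})

test_that("initial sets are balanced, seeded and pool excludes missing labels", {
  n <- 400
  y <- rep(c(1, 0), c(120, 280))
  y[c(5, 200)] <- NA
  tab <- moleculeTable(smiles = rep(NA_character_, n), labels = y,
                       taskNames = "tox")
  sp <- new("SplitIndices", train = 1:320, test = 321:400L)
  spl <- makeInitialPool(tab, sp, "tox", initialSize = 100, seed = 7)
  expect_length(spl@initial, 100)
  expect_equal(sum(y[spl@initial] == 1), 50)
  expect_equal(sum(y[spl@initial] == 0), 50)
  # pool = labeled train molecules not in the initial set
  labeled_train <- sp@train[!is.na(y[sp@train])]
  expect_setequal(c(spl@initial, spl@pool), labeled_train)
  expect_length(intersect(spl@initial, spl@pool), 0)
  # determinism
  spl2 <- makeInitialPool(tab, sp, "tox", initialSize = 100, seed = 7)
  expect_identical(spl2@initial, spl@initial)
  spl3 <- makeInitialPool(tab, sp, "tox", initialSize = 100, seed = 8)
  expect_false(identical(spl3@initial, spl@initial))
})

test_that("initial-set shortfalls are reported by class", {
  y <- rep(c(1, 0), c(30, 270))
  tab <- moleculeTable(smiles = rep(NA_character_, 300), labels = y,
                       taskNames = "tox")
  sp <- new("SplitIndices", train = 1:300, test = integer(0))
  err <- tryCatch(makeInitialPool(tab, sp, "tox", 100, 1), error = identity)
  expect_s3_class(err, "molal_input_error")
  expect_match(conditionMessage(err), "positives.*need 50.*found 30")
})

test_that("single-task views drop missing rows and validate the task", {
  tab <- fixtureMolecules()
  v <- singleTaskView(tab, "task_b")
  expect_equal(length(v), sum(!is.na(labelMatrix(tab)[, "task_b"])))
  expect_identical(taskNames(v), "task_b")
  expect_false(anyNA(labelMatrix(v)))
  expect_error(singleTaskView(tab, "task_z"), class = "molal_config_error")
  all_missing <- moleculeTable(smiles = c("CCO", "CCN"),
                               labels = matrix(NA_real_, 2, 1,
                                               dimnames = list(NULL, "t")))
  expect_error(singleTaskView(all_missing, "t"), class = "molal_input_error")
})

test_that("multitask views match the missingness rate at scale", {
  n <- 20000
  lab <- generateMultitaskLabels(n, nTasks = 4, activeRate = 0.0624,
                                 missingRate = 0.2056, seed = 11)
  tab <- moleculeTable(smiles = rep(NA_character_, n), labels = lab)
  for (task in taskNames(tab)[1:2]) {
    v <- singleTaskView(tab, task)
    frac <- length(v) / n
    se <- sqrt(0.2056 * (1 - 0.2056) / n)
    expect_lt(abs(frac - (1 - 0.2056)), 4 * se)
  }
})

test_that("split manifests round-trip through JSON", {
  tab <- fixtureMolecules()
  sp <- scaffoldSplit(tab, 0.2, seed = 3)
  path <- tempfile(fileext = ".json")
  writeSplit(sp, path)
  back <- readSplit(path)
  expect_identical(back@train, sp@train)
  expect_identical(back@test, sp@test)
})
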