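# Shared fixtures built in code at test time.

# CSV of the packaged fixture molecules plus one unparseable SMILES row.
write_fixture_csv <- function(path, with_invalid = FALSE) {
  tab <- fixtureMolecules()
  df <- data.frame(id = moleculeIds(tab), smiles = smilesOf(tab),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(labelMatrix(tab)))
  if (with_invalid)
    df <- rbind(df, data.frame(id = "broken", smiles = "C1CC",
                               task_a = 1, task_b = 0))
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Small synthetic AL problem shared by the loop tests.
tiny_al_problem <- function(n = 300, seed = 5) {
  spec <- syntheticSpec(n = n, d = 8, nPosClusters = 3, prevalence = 0.2,
                        seed = seed)
  gs <- generateFeatureSpace(spec)
  tab <- moleculeTable(smiles = rep(NA_character_, n), labels = gs$labels,
                       taskNames = "active")
  splits <- randomSplit(n, 0.2, seed = seed)
  list(tab = tab, features = gs$features, splits = splits)
}

tiny_bnn <- function(epochs = 10, seed = 1) {
  bnnConfig(hiddenDim = 32L, epochs = as.integer(epochs), seed = as.integer(seed))
}
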