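# Synthetic feature spaces and multitask label matrices.
#
# The generator emulates the statistical structure that drives
# representation-dependent active learning: a "structured" space in which
# the minority positives form distinct tight clusters displaced from the
# negative mass (the signature of a well-organised learned embedding),
# versus a "scattered" space in which positives are drawn from the
# negative mixture with only a small mean shift, producing heavy class
# overlap (the signature of a poorly structured fingerprint space). The
# two regimes share every other generator choice, isolating
# representation quality as the experimental variable.

#' Create a synthetic feature-space specification
#'
#' Defaults describe the reference study conditions: n = 2000 points in
#' d = 16 dimensions, 6.8% positives, 10 positive clusters at separation 6
#' (centroid displacement in units of the within-cluster standard
#' deviation).
#'
#' @param n,d Points and feature dimension.
#' @param regime `"structured"` or `"scattered"`.
#' @param nPosClusters Number of positive clusters; also the number of
#'   negative mixture components (must not exceed `d`).
#' @param separation Displacement of each positive cluster from its
#'   anchoring negative component, in within-cluster standard deviations.
#' @param prevalence Positive fraction (0, 0.5).
#' @param nTasks,missingRate Multitask label settings (used by
#'   [generateMultitaskLabels()]).
#' @param seed Integer seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(n = 2000L, d = 16L, regime = "structured",
                          nPosClusters = 10L, separation = 6,
                          prevalence = 0.068, nTasks = 1L, missingRate = 0,
                          seed = 1L) {
  new("SyntheticSpec", n = as.integer(n), d = as.integer(d), regime = regime,
      nPosClusters = as.integer(nPosClusters), separation = separation,
      prevalence = prevalence, nTasks = as.integer(nTasks),
      missingRate = missingRate, seed = as.integer(seed))
}

# Within-cluster standard deviation of the positive clusters. Equal to the
# negative components' unit sd, so the structured and scattered regimes
# differ only in where the positives sit, never in their local scale, and
# separation 0 makes the structured positives exactly the negative mixture.
.POS_SD <- 1
# Spread of the negative mixture component centres per coordinate.
.NEG_CENTER_SD <- 2

#' Generate a synthetic feature space with binary labels
#'
#' Negatives are drawn from an isotropic Gaussian mixture
#' (`nPosClusters` components, unit within-component standard deviation,
#' centres spread to fill the space). In the `structured` regime the
#' `round(prevalence * n)` positives form distinct Gaussian clusters
#' (unit sd, tight relative to the extent of the space), each anchored at
#' one negative component and displaced by `separation` within-cluster
#' standard deviations along one of a set of random mutually orthogonal
#' directions; in the `scattered` regime the positives are drawn from the
#' negative components themselves with a small mean shift of
#' `separation / 4` along the same directions, producing heavy class
#' overlap. Deterministic under `spec@seed`.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A list with elements `features` (a [FeatureMatrix-class] of
#'   kind `"synthetic"`) and `labels` (0/1 vector).
#' @export
generateFeatureSpace <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  n <- spec@n; d <- spec@d; k <- spec@nPosClusters
  n_pos <- round(spec@prevalence * n)
  if (n_pos < k)
    .input_error(sprintf(
      "prevalence * n = %d is smaller than nPosClusters = %d", n_pos, k))
  n_neg <- n - n_pos
  .with_seed(deriveSeed(spec@seed, "features", spec@regime), {
    centers <- matrix(stats::rnorm(k * d, sd = .NEG_CENTER_SD), k, d)
    # random orthonormal displacement directions (QR of a Gaussian matrix)
    u <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
    comp_neg <- sample.int(k, n_neg, replace = TRUE)
    xneg <- centers[comp_neg, , drop = FALSE] +
      matrix(stats::rnorm(n_neg * d), n_neg, d)
    comp_pos <- sample.int(k, n_pos, replace = TRUE)
    if (spec@regime == "structured") {
      disp <- spec@separation * .POS_SD
      pos_centers <- centers + disp * t(u)
      xpos <- pos_centers[comp_pos, , drop = FALSE] +
        matrix(stats::rnorm(n_pos * d, sd = .POS_SD), n_pos, d)
    } else {
      shift <- (spec@separation / 4) * .POS_SD
      pos_centers <- centers + shift * t(u)
      xpos <- pos_centers[comp_pos, , drop = FALSE] +
        matrix(stats::rnorm(n_pos * d), n_pos, d)
    }
    x <- rbind(xneg, xpos)
    y <- c(rep(0, n_neg), rep(1, n_pos))
    perm <- sample.int(n)
    list(features = new("FeatureMatrix", values = x[perm, , drop = FALSE],
                        kind = "synthetic"),
         labels = y[perm])
  })
}

#' Generate a Tox21-like multitask label matrix with missing values
#'
#' Each cell is independently missing with probability `missingRate`;
#' non-missing cells are active with probability `rate_k / (1 -
#' missingRate)`, where the per-task rates `rate_k` are evenly spaced
#' across `activeRate * (1 +/- jitter)` (and then randomly assigned to
#' tasks), so that the overall active fraction of all cells is
#' `activeRate` in expectation while individual tasks vary -- mirroring
#' multitask toxicity panels whose per-task active rates span roughly 2%
#' to 12% around an overall 6.24%, with 20.56% of measurements missing.
#'
#' @param n Number of molecules.
#' @param nTasks Number of tasks.
#' @param activeRate Overall fraction of active cells among all cells.
#' @param missingRate Fraction of missing cells.
#' @param jitter Relative half-width of the per-task active-rate spread
#'   (0 = identical rates).
#' @param seed Integer seed.
#' @return An n x nTasks matrix with entries 0, 1 or `NA` and task names
#'   `task_01`, `task_02`, ...
#' @export
generateMultitaskLabels <- function(n, nTasks = 12L, activeRate = 0.0624,
                                    missingRate = 0.2056, jitter = 0.68,
                                    seed = 1L) {
  if (activeRate < 0 || activeRate >= 1 || missingRate < 0 || missingRate >= 1)
    .input_error("activeRate and missingRate must lie in [0, 1)")
  if (jitter < 0 || jitter >= 1) .config_error("jitter must lie in [0, 1)")
  rates <- if (nTasks == 1) activeRate else
    seq(activeRate * (1 - jitter), activeRate * (1 + jitter),
        length.out = nTasks)
  cond <- rates / (1 - missingRate)
  if (any(cond >= 1))
    .input_error("activeRate incompatible with missingRate (conditional rate >= 1)")
  .with_seed(deriveSeed(seed, "multitask_labels"), {
    rates <- sample(rates)
    lab <- matrix(NA_real_, n, nTasks)
    for (j in seq_len(nTasks)) {
      obs <- stats::runif(n) >= missingRate
      lab[obs, j] <- as.numeric(stats::runif(sum(obs)) <
                                  rates[j] / (1 - missingRate))
    }
    colnames(lab) <- sprintf("task_%02d", seq_len(nTasks))
    lab
  })
}

#' Packaged fixture of drug-like molecules
#'
#' A stable table of 20 hand-curated, valid drug-like SMILES spanning
#' more than six distinct Bemis-Murcko scaffolds, with fixed synthetic
#' binary labels on two tasks (`task_a` complete, `task_b` with missing
#' cells). Used throughout the test suite for scaffold splitting and
#' fingerprint checks; the labels carry no chemical meaning.
#'
#' @return A [MoleculeTable-class] of 20 molecules.
#' @export
fixtureMolecules <- function() {
  smiles <- c(
    aspirin        = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol    = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen      = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    benzamide      = "NC(=O)c1ccccc1",
    caffeine       = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    theobromine    = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
    naproxen       = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    naphthalenol   = "Oc1ccc2ccccc2c1",
    diazepam       = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
    tryptamine     = "NCCc1c[nH]c2ccccc12",
    melatonin      = "COc1ccc2[nH]cc(CCNC(C)=O)c2c1",
    quinoline      = "c1ccc2ncccc2c1",
    quinaldine     = "Cc1ccc2ccccc2n1",
    nicotinamide   = "NC(=O)c1cccnc1",
    metronidazole  = "Cc1ncc(n1CCO)[N+](=O)[O-]",
    cyclohexanol   = "OC1CCCCC1",
    methylcyclohex = "CC1CCCCC1",
    piperine_core  = "C1CCNCC1",
    benzophenone   = "O=C(c1ccccc1)c1ccccc1",
    glycerol       = "OCC(O)CO"
  )
  task_a <- c(1, 0, 0, 0, 1, 1, 0, 0, 1, 0,
              1, 0, 0, 0, 1, 0, 0, 1, 0, 1)
  task_b <- c(1, 0, NA, 0, 1, NA, 0, 1, 1, 0,
              NA, 0, 1, 0, 1, NA, 0, 1, 0, NA)
  moleculeTable(smiles = unname(smiles), ids = names(smiles),
                labels = cbind(task_a = task_a, task_b = task_b))
}
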