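# molal — Bayesian active learning for molecular property prediction

`molal` is an R package for pool-based Bayesian active learning (AL) on
binary molecular property tasks such as toxicity screening. Labeling
compounds is expensive; AL spends the labeling budget where it matters by
letting the model choose which pool molecule to label next. The package
implements the complete pipeline:

* **Model** — a Monte-Carlo-dropout Bayesian neural network (one
  batch-normalized input block, a residual block, a single logit head)
  over ECFP fingerprints, precomputed embeddings, or synthetic features;
  trained with Adam, weight decay, and cosine-annealing warm restarts
  (compiled RcppArmadillo core, bit-for-bit reproducible from seeds).
* **Uncertainty** — T stochastic forward passes with dropout active,
  one shared dropout mask per pass so that all points see the same
  sampled submodel φ⁽ᵗ⁾ (the paired draws the EPIG estimator requires).
* **Acquisition** — BALD, the mutual information between a candidate's
  label and the model parameters,
  `BALD(x) = H[E_t p(y|x,φ_t)] − E_t H[p(y|x,φ_t)]`;
  EPIG, the expected information a candidate's label carries about the
  labels of target points x* drawn from the test distribution,
  `EPIG(x) = E_{x*} KL[ p(y, y*|x, x*) ‖ p(y|x) p(y*|x*) ]`;
  and the uniform random baseline `1/|pool|`.
* **Data handling** — molecule tables from CSV (SMILES + binary label
  columns with missing cells), Bemis–Murcko scaffold train/test splitting
  (greedy, larger scaffold groups first, no scaffold crosses the
  boundary), balanced initial sets, per-task views of multitask panels.
* **Evaluation** — average precision, expected calibration error (10
  equal-width confidence bins), cumulative positive-acquisition curves,
  iterations-to-fraction, gain-over-random, paired Wilcoxon signed-rank
  comparisons, and the stable-significance iteration.
* **Synthetic data** — a generator contrasting a *structured* feature
  space (minority positives in distinct clusters, the signature of a good
  pretrained embedding) with a *scattered* one (heavy class overlap, the
  signature of a weak fingerprint space), plus Tox21-like multitask label
  matrices with missing cells.

See the methods vignette (`vignettes/bayesian-active-learning.Rmd`) for
the model, the estimators, all defaults and the design rationale.

## Worked example

```r
library(molal)

## a structured synthetic feature space (2000 molecules, 16 features)
spec <- syntheticSpec(seed = 7)
space <- generateFeatureSpace(spec)
table <- moleculeTable(smiles = rep(NA_character_, spec@n),
                       labels = space$labels, taskNames = "active")

separability(space$features, space$labels)
#> SeparabilityReport: Fisher 0.0227 | Davies-Bouldin 9.2264 | purity 0.9826 (k = 10)

## splits: 80:20 train/test, balanced 100-molecule initial set
splits <- randomSplit(spec@n, testFraction = 0.2, seed = 1)
splits <- makeInitialPool(table, splits, task = "active",
                          initialSize = 100, seed = 1)
splits
#> SplitIndices: 1600 train / 400 test; 100 initial / 1500 pool for task active

## a short EPIG run (25 acquisitions, evaluation every 5 iterations)
cfg <- alConfig(acquisition = "epig", task = "active", nIterations = 25,
                evalEvery = 5, runSeed = 1, bnn = bnnConfig(epochs = 30))
hist <- runActiveLearning(table, space$features, splits, cfg)
hist
#> ALHistory [epig / active / seed 1]: 25 acquisitions, 6 evaluations (completed)
tail(hist@evals, 3)
#>   iteration avgPrecision       ece labeledSize
#> 4        15    0.8529459 0.1856891         115
#> 5        20    0.9524949 0.1529064         120
#> 6        25    0.9587984 0.1526252         125
sum(hist@acquisitions$label)
#> [1] 6
```

Reading the output: the structured space has high local class purity
(0.98), so uncertainty estimates are informative; test average precision
climbs from mid-0.8 to 0.96 within 25 acquisitions while calibration
error falls; and 6 of the 25 acquired molecules are actives — about four
times the pool prevalence (~4%), the positive-enrichment behaviour that
makes information-seeking acquisition useful in screening.

For chemistry-backed runs, start from `readMoleculeTable()` +
`featurizeEcfp()` (or `loadEmbeddings()`) and `scaffoldSplit()`;
`runMatrix()` runs the acquisition × task × seed grid with paired initial
sets, and `metricTraces()` / `wilcoxonAt()` /
`stableSignificanceIteration()` compare the arms. A thin command-line
wrapper (`inst/scripts/molal.R`) exposes `simulate`, `split`, `run` and
`evaluate` subcommands over YAML configs.

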