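# S4 classes for the active-learning pipeline.

#' MoleculeTable: SMILES plus a compound-by-task binary label matrix
#'
#' The central input container: opaque molecule identifiers, SMILES strings
#' (may be `NA` for synthetic feature spaces without chemical structures),
#' and a compound x task label matrix with entries in `{0, 1, NA}` where
#' `NA` marks a missing measurement.
#'
#' @slot ids Character vector of unique molecule identifiers.
#' @slot smiles Character vector of SMILES strings (or `NA`).
#' @slot labels Numeric matrix (rows = molecules, columns = tasks) with
#'   entries 0, 1 or `NA`; column names are the task names.
#' @export
setClass("MoleculeTable",
         slots = c(ids = "character", smiles = "character", labels = "matrix"))

setValidity("MoleculeTable", function(object) {
  n <- length(object@ids)
  if (length(object@smiles) != n)
    return("ids and smiles must have equal length")
  if (nrow(object@labels) != n)
    return("labels must have one row per molecule")
  if (anyDuplicated(object@ids))
    return("ids must be unique")
  if (is.null(colnames(object@labels)) || anyDuplicated(colnames(object@labels)))
    return("labels must have unique column (task) names")
  vals <- object@labels[!is.na(object@labels)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    return("every non-missing label must be exactly 0 or 1")
  TRUE
})

#' Train/test/initial/pool index sets
#'
#' Holds the scaffold-based train/test partition and, after
#' [makeInitialPool()], the balanced initial labeled set and the acquisition
#' pool for one task. All indices are 1-based row indices into the
#' originating [MoleculeTable].
#'
#' @slot train,test,initial,pool Integer index vectors.
#' @slot task Task name the initial/pool sets were built for (`NA` before
#'   [makeInitialPool()]).
#' @slot seed Integer seed used to draw the initial set.
#' @slot params List of the parameters used (test fraction, initial size).
#' @export
setClass("SplitIndices",
         slots = c(train = "integer", test = "integer", initial = "integer",
                   pool = "integer", task = "character", seed = "integer",
                   params = "list"),
         prototype = prototype(initial = integer(0), pool = integer(0),
                               task = NA_character_, seed = NA_integer_,
                               params = list()))

setValidity("SplitIndices", function(object) {
  if (length(intersect(object@train, object@test)))
    return("train and test must be disjoint")
  if (length(intersect(object@initial, object@pool)))
    return("initial and pool must be disjoint")
  if (!all(object@initial %in% object@train) || !all(object@pool %in% object@train))
    return("initial and pool must be subsets of train")
  TRUE
})

#' Feature matrix with provenance
#'
#' An n x d numeric feature matrix tagged with its provenance:
#' `"ecfp"` (binary hashed circular-substructure fingerprints),
#' `"embedding"` (precomputed, e.g. pooled transformer output) or
#' `"synthetic"` (generated feature space).
#'
#' @slot values Numeric matrix, one row per molecule.
#' @slot kind One of `"ecfp"`, `"embedding"`, `"synthetic"`.
#' @export
setClass("FeatureMatrix", slots = c(values = "matrix", kind = "character"))

setValidity("FeatureMatrix", function(object) {
  if (!object@kind %in% c("ecfp", "embedding", "synthetic"))
    return("kind must be one of 'ecfp', 'embedding', 'synthetic'")
  if (!is.numeric(object@values))
    return("values must be numeric")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  if (object@kind == "ecfp" && !all(object@values %in% c(0, 1)))
    return("ecfp features must be binary")
  TRUE
})

#' Posterior predictive samples from stochastic forward passes
#'
#' A T x n x 2 array of class probabilities, one slice per Monte-Carlo
#' dropout forward pass; `probs[t, i, 2]` is the positive-class probability
#' of point i under sampled submodel t.
#'
#' @slot probs Numeric array of dimension T x n x 2.
#' @export
setClass("PosteriorSamples", slots = c(probs = "array"))

setValidity("PosteriorSamples", function(object) {
  d <- dim(object@probs)
  if (length(d) != 3 || d[3] != 2)
    return("probs must be a T x n x 2 array")
  if (d[1] < 1) return("at least one forward pass required")
  if (any(object@probs < 0 | object@probs > 1))
    return("probabilities must lie in [0, 1]")
  s <- object@probs[, , 1, drop = FALSE] + object@probs[, , 2, drop = FALSE]
  if (any(abs(s - 1) > 1e-6))
    return("class probabilities must sum to 1 within 1e-6")
  TRUE
})

#' Acquisition scores for a candidate pool
#'
#' @slot scores Numeric score per pool point (natural-log units for
#'   information-based scores).
#' @slot name One of `"uniform"`, `"bald"`, `"epig"`.
#' @slot logBase Entropy base; always `"nat"`.
#' @export
setClass("AcquisitionScores",
         slots = c(scores = "numeric", name = "character", logBase = "character"),
         prototype = prototype(logBase = "nat"))

setValidity("AcquisitionScores", function(object) {
  if (!object@name %in% c("uniform", "bald", "epig"))
    return("name must be one of 'uniform', 'bald', 'epig'")
  if (any(!is.finite(object@scores)))
    return("scores must be finite")
  if (object@name %in% c("bald", "epig") && any(object@scores < -1e-9))
    return("bald/epig scores must be nonnegative up to rounding")
  TRUE
})

#' Bayesian neural network configuration
#'
#' Architecture and training hyper-parameters of the MC-dropout network:
#' one input layer (linear, batch-norm, ReLU, dropout), `nHidden` residual
#' blocks, and a single-logit output layer; trained with Adam, weight decay
#' and a cosine-annealing learning-rate schedule with warm restarts every
#' `lrCycle` epochs. Create with [bnnConfig()].
#'
#' @slot inputDim Feature dimension (`NA` = inferred at fit time).
#' @slot hiddenDim Hidden width.
#' @slot nHidden Number of residual blocks.
#' @slot dropoutP Dropout probability used during training.
#' @slot learningRate,weightDecay,epochs,batchSize,lrCycle Optimiser
#'   settings.
#' @slot nForwardPasses Default number of stochastic forward passes T.
#' @slot posWeight Positive-class weight in the cross-entropy (1 = none).
#' @slot standardize Standardise features to zero mean / unit variance
#'   using training-set statistics before the first layer.
#' @slot seed Integer seed controlling init, shuffling and dropout masks.
#' @export
setClass("BnnConfig",
         slots = c(inputDim = "integer", hiddenDim = "integer",
                   nHidden = "integer", dropoutP = "numeric",
                   learningRate = "numeric", weightDecay = "numeric",
                   epochs = "integer", batchSize = "integer",
                   lrCycle = "integer", nForwardPasses = "integer",
                   posWeight = "numeric", standardize = "logical",
                   seed = "integer"))

setValidity("BnnConfig", function(object) {
  if (object@dropoutP < 0 || object@dropoutP >= 1)
    return("dropoutP must satisfy 0 <= p < 1")
  if (object@nForwardPasses < 2)
    return("nForwardPasses must be at least 2")
  counts <- c(object@hiddenDim, object@nHidden, object@epochs,
              object@batchSize, object@lrCycle)
  if (any(counts < 1)) return("all counts must be positive")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@weightDecay < 0) return("weightDecay must be nonnegative")
  TRUE
})

#' Trained MC-dropout network handle
#'
#' Returned by [trainBnn()]; consumed by [mcPredict()]. Holds the fitted
#' weights, batch-norm running statistics, optional feature standardisation
#' and the per-epoch training-loss trace.
#'
#' @slot params List of weight matrices and batch-norm parameters.
#' @slot config The [BnnConfig-class] used.
#' @slot center,scale Standardisation vectors (length 0 when disabled).
#' @slot lossTrace Mean training loss per epoch.
#' @export
setClass("BnnModel",
         slots = c(params = "list", config = "BnnConfig", center = "numeric",
                   scale = "numeric", lossTrace = "numeric"))

#' Active-learning run configuration
#'
#' Create with [alConfig()].
#'
#' @slot acquisition `"uniform"`, `"bald"` or `"epig"`.
#' @slot featureKind Provenance expected of the feature matrix.
#' @slot task Task (label column) the run operates on.
#' @slot nIterations Number of acquisition iterations.
#' @slot batchSize Points acquired per iteration.
#' @slot initialSize Size of the balanced initial labeled set.
#' @slot targetSampleSize Number M of target points drawn (per iteration)
#'   from the test set for the EPIG estimator.
#' @slot evalEvery Evaluation grid spacing in iterations.
#' @slot runSeed Integer seed from which all stage seeds are derived.
#' @slot bnn The [BnnConfig-class] for the per-iteration retraining.
#' @slot inferenceDropout Dropout rate for the stochastic forward passes
#'   (`NA` = same as the training rate).
#' @export
setClass("ALConfig",
         slots = c(acquisition = "character", featureKind = "character",
                   task = "character", nIterations = "integer",
                   batchSize = "integer", initialSize = "integer",
                   targetSampleSize = "integer", evalEvery = "integer",
                   runSeed = "integer", bnn = "BnnConfig",
                   inferenceDropout = "numeric"))

setValidity("ALConfig", function(object) {
  if (!object@acquisition %in% c("uniform", "bald", "epig"))
    return("acquisition must be 'uniform', 'bald' or 'epig'")
  if (object@nIterations < 1) return("nIterations must be >= 1")
  if (object@evalEvery < 1) return("evalEvery must be >= 1")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  TRUE
})

#' History of one active-learning run
#'
#' Per-iteration record of acquisitions (pool index, revealed label, score,
#' labeled-set size, pool size), the evaluation-metric table, the full
#' configuration snapshot and the derived-seed trail.
#'
#' @slot arm Acquisition name.
#' @slot task Task name.
#' @slot runSeed Run seed.
#' @slot acquisitions data.frame: iteration, index, id, label, score,
#'   labeledSize, poolSize.
#' @slot evals data.frame: iteration, avgPrecision, ece, labeledSize.
#' @slot config List snapshot of the [ALConfig-class].
#' @slot seedTrail data.frame: iteration, stage, seed.
#' @slot status `"completed"`, `"pool_exhausted"` or `"diverged_at_<i>"`.
#' @export
setClass("ALHistory",
         slots = c(arm = "character", task = "character", runSeed = "integer",
                   acquisitions = "data.frame", evals = "data.frame",
                   config = "list", seedTrail = "data.frame",
                   status = "character"))

setValidity("ALHistory", function(object) {
  a <- object@acquisitions
  if (nrow(a)) {
    if (anyDuplicated(a$index))
      return("acquired indices must be globally unique across the run")
    if (is.unsorted(a$iteration))
      return("acquisitions must be ordered by iteration")
  }
  TRUE
})

#' Feature-space class-separability report
#'
#' @slot fisherRatio Squared distance between class means over the summed
#'   traces of the class covariance matrices.
#' @slot daviesBouldin Two-cluster Davies-Bouldin index (classes as
#'   clusters, Euclidean distance).
#' @slot classPurity Mean fraction of each point's k nearest neighbours
#'   (excluding itself) sharing its label.
#' @slot kNeighbors Neighbourhood size used for the purity.
#' @export
setClass("SeparabilityReport",
         slots = c(fisherRatio = "numeric", daviesBouldin = "numeric",
                   classPurity = "numeric", kNeighbors = "integer"))

setValidity("SeparabilityReport", function(object) {
  if (!is.finite(object@fisherRatio) || object@fisherRatio < 0)
    return("fisherRatio must be finite and nonnegative")
  if (!is.finite(object@daviesBouldin) || object@daviesBouldin < 0)
    return("daviesBouldin must be finite and nonnegative")
  if (object@classPurity < 0 || object@classPurity > 1)
    return("classPurity must lie in [0, 1]")
  TRUE
})

#' Result of a paired Wilcoxon comparison between two arms
#'
#' @slot iteration Iteration the comparison was made at.
#' @slot pValue Signed-rank p-value.
#' @slot winner Name of the arm favoured by the paired differences.
#' @slot stableFrom Iteration from which significance is stable (`NA`
#'   unless produced by [stableSignificanceIteration()]).
#' @export
setClass("ComparisonResult",
         slots = c(iteration = "integer", pValue = "numeric",
                   winner = "character", stableFrom = "integer"),
         prototype = prototype(stableFrom = NA_integer_))

setValidity("ComparisonResult", function(object) {
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    return("pValue must lie in (0, 1]")
  TRUE
})

#' Synthetic feature-space specification
#'
#' Defines the generator of [generateFeatureSpace()]: an n x d feature
#' space whose minority positives either form distinct tight clusters
#' displaced from the negative mass (`regime = "structured"`) or are drawn
#' from the negative mixture with a small mean shift producing heavy
#' overlap (`regime = "scattered"`).
#'
#' @slot n,d Number of points and feature dimension.
#' @slot regime `"structured"` or `"scattered"`.
#' @slot nPosClusters Number of positive clusters (equals the number of
#'   negative mixture components).
#' @slot separation Centroid displacement in units of the within-cluster
#'   standard deviation.
#' @slot prevalence Positive-class fraction (0 < prevalence < 0.5).
#' @slot nTasks,missingRate Multitask label-matrix settings.
#' @slot seed Integer seed.
#' @export
setClass("SyntheticSpec",
         slots = c(n = "integer", d = "integer", regime = "character",
                   nPosClusters = "integer", separation = "numeric",
                   prevalence = "numeric", nTasks = "integer",
                   missingRate = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!object@regime %in% c("structured", "scattered"))
    return("regime must be 'structured' or 'scattered'")
  if (object@prevalence <= 0 || object@prevalence >= 0.5)
    return("prevalence must satisfy 0 < prevalence < 0.5")
  if (object@separation < 0) return("separation must be nonnegative")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  if (object@nPosClusters < 1) return("nPosClusters must be >= 1")
  if (object@nPosClusters > object@d)
    return("nPosClusters must not exceed d (orthogonal displacements)")
  TRUE
})
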