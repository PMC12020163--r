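# Generics, accessors and show methods.

#' @rdname MoleculeTable-class
#' @param object,x A `MoleculeTable`.
#' @export
setGeneric("taskNames", function(x) standardGeneric("taskNames"))

#' @rdname MoleculeTable-class
#' @export
setMethod("taskNames", "MoleculeTable", function(x) colnames(x@labels))

#' @rdname MoleculeTable-class
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname MoleculeTable-class
#' @export
setMethod("moleculeIds", "MoleculeTable", function(x) x@ids)

#' @rdname MoleculeTable-class
#' @export
setGeneric("smilesOf", function(x) standardGeneric("smilesOf"))

#' @rdname MoleculeTable-class
#' @export
setMethod("smilesOf", "MoleculeTable", function(x) x@smiles)

#' @rdname MoleculeTable-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname MoleculeTable-class
#' @export
setMethod("labelMatrix", "MoleculeTable", function(x) x@labels)

setMethod("show", "MoleculeTable", function(object) {
  lab <- object@labels
  cat("MoleculeTable with", length(object@ids), "molecules and",
      ncol(lab), "task(s)\n")
  cat("  tasks:", paste(colnames(lab), collapse = ", "), "\n")
  cat(sprintf("  missing labels: %.2f%%\n", 100 * mean(is.na(lab))))
})

#' Number of molecules / feature rows
#' @param x A `MoleculeTable` or `FeatureMatrix`.
#' @export
setMethod("length", "MoleculeTable", function(x) length(x@ids))

#' Subset a MoleculeTable by row
#' @param x A `MoleculeTable`.
#' @param i Integer or logical row index.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "MoleculeTable", function(x, i, j, ..., drop = FALSE) {
  new("MoleculeTable", ids = x@ids[i], smiles = x@smiles[i],
      labels = x@labels[i, , drop = FALSE])
})

#' @rdname FeatureMatrix-class
#' @param x A `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureKind", "FeatureMatrix", function(x) x@kind)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureDim", "FeatureMatrix", function(x) ncol(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d x %d\n", object@kind,
              nrow(object@values), ncol(object@values)))
})

#' @rdname PosteriorSamples-class
#' @param x A `PosteriorSamples`.
#' @export
setGeneric("nPasses", function(x) standardGeneric("nPasses"))

#' @rdname PosteriorSamples-class
#' @export
setMethod("nPasses", "PosteriorSamples", function(x) dim(x@probs)[1])

#' @rdname PosteriorSamples-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname PosteriorSamples-class
#' @export
setMethod("nPoints", "PosteriorSamples", function(x) dim(x@probs)[2])

#' Positive-class probability draws
#'
#' The T x n matrix of positive-class probabilities, one row per
#' stochastic forward pass.
#' @param x A `PosteriorSamples`.
#' @export
setGeneric("positiveProbs", function(x) standardGeneric("positiveProbs"))

#' @rdname positiveProbs
#' @export
setMethod("positiveProbs", "PosteriorSamples", function(x) x@probs[, , 2])

#' Monte-Carlo mean prediction
#'
#' Per-point positive-class probability averaged over the T passes.
#' @param x A `PosteriorSamples`.
#' @export
setGeneric("meanPrediction", function(x) standardGeneric("meanPrediction"))

#' @rdname meanPrediction
#' @export
setMethod("meanPrediction", "PosteriorSamples", function(x) {
  p <- x@probs[, , 2, drop = FALSE]
  dim(p) <- dim(x@probs)[1:2]
  colMeans(p)
})

setMethod("show", "PosteriorSamples", function(object) {
  d <- dim(object@probs)
  cat(sprintf("PosteriorSamples: T = %d passes over %d points\n", d[1], d[2]))
})

setMethod("show", "SplitIndices", function(object) {
  cat("SplitIndices:", length(object@train), "train /", length(object@test),
      "test")
  if (length(object@initial))
    cat(";", length(object@initial), "initial /", length(object@pool),
        "pool for task", object@task)
  cat("\n")
})

setMethod("show", "AcquisitionScores", function(object) {
  cat(sprintf("AcquisitionScores [%s]: %d pool points (%s)\n", object@name,
              length(object@scores), object@logBase))
})

setMethod("show", "BnnModel", function(object) {
  cfg <- object@config
  cat(sprintf("BnnModel: %d -> %d (x%d residual block%s) -> 1 logit; final loss %.4f\n",
              cfg@inputDim, cfg@hiddenDim, cfg@nHidden,
              if (cfg@nHidden == 1) "" else "s",
              utils::tail(object@lossTrace, 1)))
})

setMethod("show", "ALHistory", function(object) {
  cat(sprintf("ALHistory [%s / %s / seed %d]: %d acquisitions, %d evaluations (%s)\n",
              object@arm, object@task, object@runSeed,
              nrow(object@acquisitions), nrow(object@evals), object@status))
})

setMethod("show", "SeparabilityReport", function(object) {
  cat(sprintf("SeparabilityReport: Fisher %.4f | Davies-Bouldin %.4f | purity %.4f (k = %d)\n",
              object@fisherRatio, object@daviesBouldin, object@classPurity,
              object@kNeighbors))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult at iteration %d: p = %.4g, winner = %s\n",
              object@iteration, object@pValue, object@winner))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec [%s]: n = %d, d = %d, %d positive cluster(s), separation %.1f, prevalence %.3f\n",
              object@regime, object@n, object@d, object@nPosClusters,
              object@separation, object@prevalence))
})
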