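# MC-dropout Bayesian neural network: configuration, training, prediction.

#' Create a BNN configuration
#'
#' Defaults follow the reference hyper-parameter set for this
#' architecture: hidden width 128, one residual block, dropout 0.3, Adam
#' with learning rate 1e-3 and weight decay 1e-2, cosine-annealing
#' learning-rate schedule restarting every 10 epochs, 110 epochs, batch
#' size 16, and T = 20 stochastic forward passes at prediction time.
#'
#' @param inputDim Feature dimension (`NA` = inferred when fitting).
#' @param hiddenDim Hidden width.
#' @param nHidden Number of residual blocks.
#' @param dropoutP Training dropout probability.
#' @param learningRate,weightDecay Adam settings.
#' @param epochs,batchSize Training schedule. Batches of size 1 are
#'   dropped to avoid degenerate batch-normalization statistics.
#' @param lrCycle Cosine-annealing warm-restart cycle length in epochs.
#' @param nForwardPasses Default number of stochastic forward passes T.
#' @param posWeight Positive-class weight in the cross-entropy (1 = plain
#'   unweighted loss).
#' @param standardize Standardise inputs with training-set statistics.
#' @param seed Integer seed (initialisation, shuffling, dropout masks).
#' @return A [BnnConfig-class].
#' @export
bnnConfig <- function(inputDim = NA_integer_, hiddenDim = 128L, nHidden = 1L,
                      dropoutP = 0.3, learningRate = 1e-3, weightDecay = 1e-2,
                      epochs = 110L, batchSize = 16L, lrCycle = 10L,
                      nForwardPasses = 20L, posWeight = 1, standardize = FALSE,
                      seed = 1L) {
  new("BnnConfig", inputDim = as.integer(inputDim),
      hiddenDim = as.integer(hiddenDim), nHidden = as.integer(nHidden),
      dropoutP = dropoutP, learningRate = learningRate,
      weightDecay = weightDecay, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lrCycle = as.integer(lrCycle),
      nForwardPasses = as.integer(nForwardPasses), posWeight = posWeight,
      standardize = standardize, seed = as.integer(seed))
}

.feature_values <- function(features) {
  if (is(features, "FeatureMatrix")) features@values else as.matrix(features)
}

#' Train the MC-dropout network
#'
#' Fits the feed-forward architecture -- linear, batch-norm, ReLU, dropout;
#' `nHidden` residual blocks (linear, batch-norm, skip connection, ReLU,
#' dropout); final one-logit linear layer -- with binary cross-entropy on
#' logits, Adam with weight decay, and cosine-annealing warm restarts.
#' Training is reproducible bit-for-bit given `config@seed`.
#'
#' @param features A [FeatureMatrix-class] or numeric matrix.
#' @param labels Binary vector with at least 2 examples per class.
#' @param config A [BnnConfig-class].
#' @return A [BnnModel-class].
#' @export
trainBnn <- function(features, labels, config = bnnConfig()) {
  x <- .feature_values(features)
  y <- as.numeric(labels)
  if (length(y) != nrow(x))
    .input_error("labels must have one entry per feature row")
  if (anyNA(y)) .input_error("training labels must not be missing")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    .input_error("at least 2 examples per class are required")
  if (is.na(config@inputDim)) config@inputDim <- ncol(x)
  if (config@inputDim != ncol(x))
    .config_error(sprintf("feature dimension %d does not match inputDim %d",
                          ncol(x), config@inputDim))
  center <- scale_ <- numeric(0)
  if (config@standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  fit <- .bnn_train_cpp(x, y, config@hiddenDim, config@nHidden,
                        config@dropoutP, config@learningRate,
                        config@weightDecay, config@epochs, config@batchSize,
                        config@lrCycle, config@posWeight, config@seed)
  if (isTRUE(fit$diverged))
    .input_error(sprintf("training loss became non-finite at epoch %d",
                         fit$epoch))
  loss <- as.numeric(fit$loss_trace)
  fit$loss_trace <- NULL
  fit$diverged <- NULL
  new("BnnModel", params = fit, config = config, center = center,
      scale = scale_, lossTrace = loss)
}

#' Monte-Carlo dropout prediction
#'
#' Runs `T` stochastic forward passes with dropout active at inference
#' time. One dropout mask per layer is sampled for each pass and shared
#' across all input rows, so a pass corresponds to a single sampled
#' submodel; points predicted in the same call therefore share the same
#' sequence of sampled submodels (paired draws), which the EPIG estimator
#' relies on. Batch-normalization always runs in inference mode with the
#' stored running statistics.
#'
#' @param model A [BnnModel-class].
#' @param features A [FeatureMatrix-class] or numeric matrix.
#' @param T Number of stochastic forward passes.
#' @param dropoutActive Keep dropout on at inference (MC dropout). With
#'   `FALSE` all passes are identical deterministic predictions.
#' @param seed Integer seed for the dropout masks.
#' @param dropoutP Inference dropout rate; `NULL` uses the training rate.
#' @return A [PosteriorSamples-class] (T x n x 2 class probabilities).
#' @export
mcPredict <- function(model, features, T = model@config@nForwardPasses,
                      dropoutActive = TRUE, seed = 1L, dropoutP = NULL) {
  stopifnot(is(model, "BnnModel"))
  x <- .feature_values(features)
  if (ncol(x) != model@config@inputDim)
    .config_error(sprintf("feature dimension %d does not match the model (%d)",
                          ncol(x), model@config@inputDim))
  if (dropoutActive && T < 2) {
    warning("T < 2 with dropout active: no uncertainty can be estimated")
  }
  if (is.null(dropoutP)) dropoutP <- model@config@dropoutP
  if (length(model@center))
    x <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  p1 <- .bnn_predict_cpp(model@params, x, as.integer(T), dropoutActive,
                         dropoutP, as.integer(seed))
  posteriorSamples(p1)
}

#' Construct PosteriorSamples from positive-class draws
#'
#' @param p1 T x n matrix of positive-class probabilities.
#' @return A [PosteriorSamples-class].
#' @export
posteriorSamples <- function(p1) {
  p1 <- as.matrix(p1)
  probs <- array(0, dim = c(nrow(p1), ncol(p1), 2))
  probs[, , 1] <- 1 - p1
  probs[, , 2] <- p1
  new("PosteriorSamples", probs = probs)
}
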