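# Acquisition functions: uniform baseline, BALD, EPIG; batch selection.
#
# BALD(x) = H[ E_t p(y|x, phi_t) ] - E_t H[ p(y|x, phi_t) ]  (mutual
# information between the unknown label and the model parameters), and
# EPIG(x) = E_{x*} KL[ p(y, y*|x, x*) || p(y|x) p(y*|x*) ]  (mutual
# information between the candidate's label and the label of a random
# target point), both estimated from T Monte-Carlo dropout draws. All
# entropies are in natural log (nats); selection is base-invariant.

.CLIP <- 1e-12

# Shannon entropy of Bernoulli(p) in nats, probabilities clipped.
.bentropy <- function(p) {
  p <- pmin(pmax(p, .CLIP), 1 - .CLIP)
  -(p * log(p) + (1 - p) * log1p(-p))
}

#' Uniform (random) acquisition scores
#'
#' The random-sampling baseline: every pool point receives the same score
#' `1 / nPool`.
#'
#' @param nPool Pool size.
#' @return An [AcquisitionScores-class] of name `"uniform"`.
#' @export
uniformScores <- function(nPool) {
  if (nPool < 1) .input_error("empty pool")
  new("AcquisitionScores", scores = rep(1 / nPool, nPool), name = "uniform",
      logBase = "nat")
}

#' BALD acquisition scores
#'
#' Bayesian Active Learning by Disagreement: the mutual information
#' between a candidate's unknown label and the model parameters, computed
#' as the entropy of the mean predictive distribution minus the mean
#' per-draw entropy. Zero when all draws agree (no epistemic uncertainty);
#' bounded above by ln 2 for binary labels.
#'
#' @param post A [PosteriorSamples-class] over the pool (T >= 2).
#' @return An [AcquisitionScores-class] of name `"bald"`.
#' @export
baldScores <- function(post) {
  stopifnot(is(post, "PosteriorSamples"))
  if (nPasses(post) < 2) .input_error("BALD requires T >= 2 draws")
  p1 <- post@probs[, , 2, drop = FALSE]
  dim(p1) <- dim(post@probs)[1:2]
  pbar <- colMeans(p1)
  scores <- .bentropy(pbar) - colMeans(.bentropy(p1))
  # exact zero when all draws for a point are identical
  same <- apply(p1, 2, function(v) max(v) - min(v) == 0)
  scores[same] <- 0
  new("AcquisitionScores", scores = scores, name = "bald", logBase = "nat")
}

#' EPIG acquisition scores
#'
#' Expected Predictive Information Gain: for each pool point, the mutual
#' information between its unknown label and the label of a random target
#' point, averaged over the target set. The joint distribution is
#' estimated from paired draws, `joint[c, c*] = (1/T) sum_t p(y = c | x,
#' phi_t) p(y* = c* | x*, phi_t)`; the per-target contribution is the KL
#' divergence of the joint from the product of its marginals (with `0 log
#' 0 = 0`). Pool and target samples must come from the same T sampled
#' submodels, i.e. from the same [mcPredict()] call or the same dropout
#' seed -- unpaired draws destroy the correlation EPIG measures.
#'
#' @param postPool [PosteriorSamples-class] over the pool.
#' @param postTarget [PosteriorSamples-class] over the M target points,
#'   paired draw-for-draw with `postPool`.
#' @return An [AcquisitionScores-class] of name `"epig"`.
#' @export
epigScores <- function(postPool, postTarget) {
  stopifnot(is(postPool, "PosteriorSamples"), is(postTarget, "PosteriorSamples"))
  Tn <- nPasses(postPool)
  if (Tn != nPasses(postTarget))
    .input_error(sprintf(
      "pool draws (T = %d) and target draws (T = %d) are not paired",
      Tn, nPasses(postTarget)))
  if (Tn < 2) .input_error("EPIG requires T >= 2 draws")
  P <- postPool@probs[, , 2, drop = FALSE]   # T x n
  dim(P) <- dim(postPool@probs)[1:2]
  Q <- postTarget@probs[, , 2, drop = FALSE] # T x m
  dim(Q) <- dim(postTarget@probs)[1:2]
  # 2 x 2 joint for every (pool, target) pair via cross-products over T
  J11 <- crossprod(P, Q) / Tn            # n x m
  J10 <- crossprod(P, 1 - Q) / Tn
  J01 <- crossprod(1 - P, Q) / Tn
  J00 <- crossprod(1 - P, 1 - Q) / Tn
  pbar <- colMeans(P)                    # length n
  qbar <- colMeans(Q)                    # length m
  # 0 log 0 = 0 falls out of multiplying by J; marginals clipped as in BALD
  kl_term <- function(J, pq)
    J * (log(pmax(J, .CLIP)) - log(pmax(pq, .CLIP^2)))
  M11 <- outer(pbar, qbar)
  M10 <- outer(pbar, 1 - qbar)
  M01 <- outer(1 - pbar, qbar)
  M00 <- outer(1 - pbar, 1 - qbar)
  kl <- kl_term(J11, M11) + kl_term(J10, M10) + kl_term(J01, M01) +
    kl_term(J00, M00)
  scores <- rowMeans(kl)
  # exact zero when the pool point's draws are all identical
  same <- apply(P, 2, function(v) max(v) - min(v) == 0)
  scores[same] <- 0
  scores[scores < 0] <- 0
  new("AcquisitionScores", scores = scores, name = "epig", logBase = "nat")
}

#' Select the next point(s) to label
#'
#' For information-based scores, the `batchSize` highest-scoring pool
#' indices with ties broken uniformly at random under `seed`; for the
#' uniform baseline, `batchSize` indices drawn uniformly without
#' replacement under `seed`.
#'
#' @param scores An [AcquisitionScores-class].
#' @param batchSize Number of points to select.
#' @param seed Integer seed (tie-breaking / uniform sampling).
#' @return Integer vector of pool-relative indices.
#' @export
selectNext <- function(scores, batchSize = 1L, seed = 1L) {
  stopifnot(is(scores, "AcquisitionScores"))
  n <- length(scores@scores)
  if (n == 0) .input_error("empty pool")
  if (batchSize > n)
    .config_error(sprintf("batchSize %d exceeds pool size %d", batchSize, n))
  if (scores@name == "uniform") {
    return(.with_seed(deriveSeed(seed, "uniform_select"),
                      sample.int(n, batchSize)))
  }
  tie <- .with_seed(deriveSeed(seed, "tie_break"), stats::runif(n))
  order(-scores@scores, tie)[seq_len(batchSize)]
}
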