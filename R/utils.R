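# Internal condition helpers and the seed-derivation rule.

.config_error <- function(msg) {
  stop(structure(class = c("molal_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.input_error <- function(msg) {
  stop(structure(class = c("molal_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a stage seed from a run seed
#'
#' All randomness in the package flows from a single run seed through this
#' rule: the run seed and an arbitrary list of stage labels (strings or
#' integers, e.g. `"train"`, iteration number) are folded into a 31-bit
#' integer with a polynomial rolling hash modulo the Mersenne prime
#' 2^31 - 1. Distinct stages of one run, and the same stage across runs,
#' therefore receive reproducible but unrelated seeds.
#'
#' @param seed Integer run seed.
#' @param ... Stage labels (coerced to character).
#' @return An integer in `[1, 2^31 - 1]`, usable with [set.seed()].
#' @examples
#' deriveSeed(1, "train", 10)
#' @export
deriveSeed <- function(seed, ...) {
  p <- 2147483647
  h <- as.numeric(seed) %% p
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "\r")
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% p
  as.integer(h + 1)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

.is_count <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x) && x > 0
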