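#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cmdscale kmeans lm coef rnorm runif dist sd
#' @importFrom utils read.table write.table head tail
NULL

# Consistent condition helpers: every user-facing error carries a class so
# callers (and tests) can match on the failure kind rather than the message.
tf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tadfam_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

tf_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "tadfam_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is fanned out to per-stage seeds by hashing the
#' stage name, so any stage can be re-run in isolation and reproduce the
#' full-pipeline result.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 10007 * h) %% (2^31 - 1))
}

# Signed cube root (needed for the TM-score d0 formula at short lengths).
cbrt <- function(x) sign(x) * abs(x)^(1/3)
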