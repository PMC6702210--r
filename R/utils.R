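#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rbinom rbeta rpois rnorm runif dnorm pnorm pchisq
#'   setNames median approx complete.cases
#' @importFrom utils head combn
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream child seed, kept below 2^31 - 1.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i)) %% 2147483647)
}

check_fraction <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}
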