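# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global random-number generator seeded at `seed`
#' (Mersenne-Twister), restoring the caller's RNG state afterwards so that
#' seeded package operations never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a stream of sub-seeds from one master seed, kept below 2^31.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Format a hazard ratio with its 95% confidence interval
#'
#' Renders `exp(beta)` and the Wald 95% CI `exp(beta +/- z * se)` in the
#' conventional "HR (lo-hi)" display used in prognostic tables, with two
#' decimals.
#'
#' @param beta Log hazard ratio.
#' @param se Standard error of `beta`.
#' @param digits Decimals to print (default 2).
#' @return A character string such as `"1.72 (1.21-2.44)"`.
#' @examples
#' formatHR(0.542, 0.178)
#' @export
formatHR <- function(beta, se, digits = 2) {
  z <- stats::qnorm(0.975)
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "-", fmt, ")"),
          exp(beta), exp(beta - z * se), exp(beta + z * se))
}

#' Convert counts to whole-number percentages
#'
#' Used by the class-correlation tables: each count is expressed as a
#' percentage of the total, rounded to the nearest integer.
#'
#' @param counts Non-negative numeric vector of counts.
#' @return Numeric vector of percentages on the 0-100 scale.
#' @examples
#' pctOfTotal(c(484, 584))
#' @export
pctOfTotal <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) return(rep(NA_real_, length(counts)))
  round(100 * counts / total)
}

# Simple structured log line; all exclusion/fallback reporting funnels here.
tkLog <- function(...) {
  message("[tksig] ", ...)
}
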