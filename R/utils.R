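# Internal helpers shared across modules.

#' Evaluate an expression with a private RNG state
#'
#' Seeds the generator, runs `code`, and restores whatever random state the
#' caller had, so no simulation leaks global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_rng <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Round half away from zero
#'
#' Plain half-up rounding (0.5 rounds to 1), unlike [base::round()]'s
#' round-half-even. Used wherever a reported integer percentage is derived
#' from a fraction.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(14.977) # 15
#' round_half_up(0.5)    # 1
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv`; degenerate at exactly 1 when cv = 0 so noiseless runs are exact.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("exocargo_config_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("exocargo_parse_error", "error")))
}
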