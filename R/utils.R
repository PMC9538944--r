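## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All user-facing validation errors in the package carry a condition class
#' (`fishbcf_invalid_input`, `fishbcf_insufficient_data`,
#' `fishbcf_config_error`, `fishbcf_schema_error`) so callers can handle them
#' programmatically.
#' @noRd
stop_fishbcf <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fishbcf_error")))
}

stop_invalid <- function(msg) stop_fishbcf(msg, "fishbcf_invalid_input")
stop_insufficient <- function(msg) stop_fishbcf(msg, "fishbcf_insufficient_data")
stop_config <- function(msg) stop_fishbcf(msg, "fishbcf_config_error")
stop_schema <- function(msg) stop_fishbcf(msg, "fishbcf_schema_error")

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_invalid(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_invalid(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  invisible(x)
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive an independent substream seed from a master seed
#'
#' Deterministic fan-out so that adding replicates or components does not
#' perturb draws already assigned to existing ones.
#' @noRd
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

#' Lognormal parameters for mean 1 and a given coefficient of variation
#' @noRd
lnorm_pars <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Multiplicative lognormal noise factors with mean 1
#' @noRd
rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  p <- lnorm_pars(cv)
  stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}
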