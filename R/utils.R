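# Internal helpers shared across modules.

#' @importFrom stats pnorm qnorm pt rnorm dnorm var sd quantile setNames
#'   p.adjust pbinom pf lm coef vcov residuals model.matrix complete.cases
#'   cor rbinom runif
#' @importFrom utils read.csv head type.convert modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scoped seeding: set the RNG inside the calling frame, restore on exit.
#' All exported stochastic operations accept `seed = NULL` (use current RNG
#' state) or an integer (reproducible, caller's RNG untouched).
#' @noRd
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

#' Derive a stage seed from a master seed, staying below 2^31.
#' @noRd
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 1000003 * k) %% 2147483629)
}

#' Format a double losslessly for text output.
#' @noRd
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Clamp p-values into (0, 1] as the StatMap contract requires.
#' @noRd
clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
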