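#' @useDynLib scqpcr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree dist hclust p.adjust prcomp rnorm runif sd t.test var
#' @importFrom utils read.csv write.csv
NULL

# Experimental groups, in cohort order. Controls first, then post-surgery days.
GROUP_LEVELS <- c("littermate_control", "surgical_control", "day1", "day3", "day7")
CONTROL_GROUPS <- c("littermate_control", "surgical_control")
POST_GROUPS <- c("day1", "day3", "day7")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage consumes its own RNG stream so that toggling one stage
#' cannot perturb the draws of another. The stage seed is a deterministic
#' 31-bit hash of the stage name mixed with the global seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

# Stable assertion helper producing uniform error messages.
fail_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
  invisible(TRUE)
}
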