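`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of a pipeline run draws its seed deterministically
#' from the global seed and the stage name, so stages can be re-run in
#' isolation and still reproduce the full-run results.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# sample standard deviation guarded against zero variance
sd_strict <- function(x, what = "values") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("zero variance in %s; cannot standardize", what)
  s
}
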