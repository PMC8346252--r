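# Shared validation helpers and deterministic seed derivation.

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_invalid(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(name, " must be TRUE or FALSE")
  invisible(x)
}

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are derived by hashing the pair (global seed, stage name) so
#' that adding or removing a pipeline stage does not reshuffle the randomness
#' of the others. The hash is a 31-bit polynomial rolling hash, so any derived
#' seed is a valid R integer seed.
#'
#' @param global_seed single integer seed for the whole run.
#' @param stage_name character scalar naming the stage.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, stage_name) {
  check_scalar_number(global_seed, "global_seed")
  if (!is.character(stage_name) || length(stage_name) != 1L)
    stop_invalid("stage_name must be a single string")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(global_seed) %% m
  for (code in utf8ToInt(stage_name)) h <- (h * 31 + code) %% m
  as.integer(h)
}

# Run code with a locally-set RNG seed, restoring any prior RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
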