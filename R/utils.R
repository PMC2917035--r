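# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so seeded operations never perturb the global RNG stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

stop_validation <- function(...) {
  stop(structure(
    class = c("pathscore_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("pathscore_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_unique <- function(ids, what) {
  if (anyDuplicated(ids))
    stop_validation("duplicate ", what, ": ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(ids)
}

# scalar count >= min
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_validation(name, " must be an integer >= ", min)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_validation(name, " must be a positive number")
  as.numeric(x)
}

#' @noRd
msg <- function(...) {
  if (isTRUE(getOption("pathscore.verbose", TRUE))) message("[pathscore] ", ...)
}
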