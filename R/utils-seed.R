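#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores, so seeded
#' package functions never disturb the global random stream. A `NULL` seed
#' evaluates the expression against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a stage- and sample-specific sub-seed from a master seed
#'
#' Folds arbitrary label strings into a 31-bit integer and mixes it with the
#' master seed, so each pipeline stage and sample gets an independent,
#' reproducible stream. Re-running one stage never shifts another stage's
#' draws.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stage/sample.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(777, "fcm", "SC001", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  labels <- paste(vapply(list(...), function(x) paste(as.character(x),
    collapse = "_"), character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  s <- (abs(master) %% m)
  out <- (s * 48271 + h * 16807 + 12345) %% m
  as.integer(out + 1L)
}
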