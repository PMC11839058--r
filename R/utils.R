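# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG, evaluates `expr`, and restores whatever RNG state
#' existed before the call, so seeded operations leave no global trace.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# scalar checks used in argument validation
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# djb2 string hash, used to fingerprint run configurations in logs;
# the output location is not part of a run's identity
config_hash <- function(x) {
  x$out_dir <- NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(json))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
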