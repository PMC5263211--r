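# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named random substream seed
#'
#' All randomness in the package flows from one user seed; independent
#' stages (genotype simulation, trial noise, training-set sampling, ...)
#' draw from named substreams so that changing one stage's consumption
#' does not perturb the others. The derived seed is kept below 2^31-1.
#'
#' @param seed integer master seed.
#' @param name character substream label.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v) * 131)
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a fraction %s, got %s", name,
                 if (open) "strictly in (0, 1)" else "in [0, 1]",
                 format(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok) {
    stop(sprintf("`%s` must be an integer >= %d, got %s", name, min,
                 format(x)), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_nonneg <- function(x, name) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  if (!ok) stop(sprintf("`%s` must be a non-negative number", name), call. = FALSE)
  invisible(x)
}

# align a named vector of responses with the rows of a matrix; errors list
# the offending identifiers so data problems surface with context
align_ids <- function(ids_needed, ids_have, what) {
  missing <- setdiff(ids_needed, ids_have)
  if (length(missing)) {
    stop(sprintf("%s missing for %d id(s): %s", what, length(missing),
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
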