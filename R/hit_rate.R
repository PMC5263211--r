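#' Top/bottom selection hit rates
#'
#' Fraction of the observed best (worst) `fraction` of lines that the
#' predictions also place in the predicted best (worst) `fraction` — the
#' practically relevant question of whether a selection method identifies
#' the lines a breeder would advance or discard. Ties are broken by line
#' id for reproducibility.
#'
#' @param predicted,observed named numeric vectors over identical lines.
#' @param fraction selected fraction, in (0, 0.5].
#' @return named vector `c(best = ..., worst = ...)` of proportions.
#' @examples
#' x <- stats::setNames(1:10, paste0("L", 1:10))
#' top_bottom_hit_rate(x, x, 0.2) # perfect prediction: both 1
#' @export
top_bottom_hit_rate <- function(predicted, observed, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  }
  ids <- names(predicted)
  if (is.null(ids) || is.null(names(observed)) ||
      !setequal(ids, names(observed))) {
    stop("predicted and observed must cover identical named lines",
         call. = FALSE)
  }
  observed <- observed[ids]
  n <- length(ids)
  k <- floor(fraction * n + 1e-9)
  if (k < 1L) {
    stop(sprintf("fraction %.3f selects zero of %d lines", fraction, n),
         call. = FALSE)
  }
  top <- function(x) ids[order(-x, ids)][seq_len(k)]
  bottom <- function(x) ids[order(x, ids)][seq_len(k)]
  c(best = length(intersect(top(predicted), top(observed))) / k,
    worst = length(intersect(bottom(predicted), bottom(observed))) / k)
}
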