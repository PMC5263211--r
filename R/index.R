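#' Scale predictions over the selection candidates
#'
#' Centers the predictions to mean zero and normalizes their spread:
#' division by the standard deviation by default (the index-selection
#' convention, unit-consistent weights) or by the variance via
#' `method = "variance"`. Only the selection candidates themselves enter
#' the scaling.
#'
#' @param preds numeric vector (>= 2 distinct values).
#' @param method `"sd"` (default) or `"variance"`.
#' @return scaled vector, names preserved.
#' @export
scale_predictions <- function(preds, method = c("sd", "variance")) {
  method <- match.arg(method)
  stopifnot(is.numeric(preds), length(preds) >= 2L)
  s <- stats::sd(preds)
  if (!is.finite(s) || s < 1e-12) {
    stop("cannot scale constant predictions", call. = FALSE)
  }
  centered <- preds - mean(preds)
  if (method == "sd") centered / s else centered / s^2
}

#' Heritability-weighted merge of GBLUP and KBLUP predictions
#'
#' Builds the genomic assisted selection index
#' `GEBV_index = scaled(GBLUP) * w_gblup + scaled(KBLUP) * w_kblup`,
#' where the weights default to the heritabilities estimated from the
#' respective fits' shrinkage ratios. An explicit `w_gblup` (e.g. from
#' [adjusted_gblup_weight()] after marker pre-selection) overrides the
#' default; `w_kblup` always stays the KBLUP heritability.
#'
#' @param gblup_preds,kblup_preds named prediction vectors over the same
#'   candidate lines.
#' @param h2_gblup,h2_kblup heritabilities in [0, 1] used as weights.
#' @param w_gblup optional override of the GBLUP weight.
#' @param method scaling convention passed to [scale_predictions()].
#' @return data.frame of class `gas_index`: `line_id`, `gblup_scaled`,
#'   `kblup_scaled`, `w_gblup`, `w_kblup`, `gebv_index` (candidate order
#'   of `gblup_preds`).
#' @export
heritability_index <- function(gblup_preds, kblup_preds, h2_gblup, h2_kblup,
                               w_gblup = NULL, method = c("sd", "variance")) {
  ids <- names(gblup_preds)
  if (is.null(ids) || is.null(names(kblup_preds))) {
    stop("predictions must be named by line id", call. = FALSE)
  }
  if (!setequal(ids, names(kblup_preds))) {
    bad <- c(setdiff(ids, names(kblup_preds)),
             setdiff(names(kblup_preds), ids))
    stop(sprintf("line id mismatch between prediction sets: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  for (h in c(h2_gblup, h2_kblup)) {
    if (!is.numeric(h) || h < 0 || h > 1) {
      stop("heritability weights must lie in [0, 1]", call. = FALSE)
    }
  }
  gs <- scale_predictions(gblup_preds, method)
  ks <- scale_predictions(kblup_preds[ids], method)
  wg <- w_gblup %||% h2_gblup
  wk <- h2_kblup
  out <- data.frame(line_id = ids,
                    gblup_scaled = as.numeric(gs),
                    kblup_scaled = as.numeric(ks),
                    w_gblup = wg, w_kblup = wk,
                    gebv_index = as.numeric(gs * wg + ks * wk),
                    stringsAsFactors = FALSE)
  class(out) <- c("gas_index", "data.frame")
  out
}

#' Adjusted GBLUP index weight after marker pre-selection
#'
#' `w_gblup = h2_gblup / (1 - |r|)` where `r` is the correlation between
#' the GBLUP and KBLUP predictions of the selection candidates. Inflates
#' the genomic weight when the two sources disagree, compensating the
#' heritability drop caused by marker selection; used only in the
#' marker-selected index variant.
#'
#' @param h2_gblup GBLUP heritability, strictly in (0, 1).
#' @param r_gblup_kblup correlation between the two prediction sets,
#'   `|r| < 1`.
#' @return the adjusted weight.
#' @examples
#' adjusted_gblup_weight(0.4, 0.5) # 0.8
#' @export
adjusted_gblup_weight <- function(h2_gblup, r_gblup_kblup) {
  if (!is.numeric(h2_gblup) || h2_gblup <= 0 || h2_gblup >= 1) {
    stop("h2_gblup must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(r_gblup_kblup) || abs(r_gblup_kblup) >= 1) {
    stop("|r| must be < 1 (weight unbounded otherwise)", call. = FALSE)
  }
  h2_gblup / (1 - abs(r_gblup_kblup))
}
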