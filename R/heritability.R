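#' Convert between heritability and the shrinkage ratio
#'
#' The shrinkage ratio of the mixed model, `lambda2 = sigma2_e / sigma2_g`,
#' relates to heritability through `lambda2 = 1/h2 - 1`, equivalently
#' `h2 = 1 / (1 + lambda2)` (the Hofheinz approximation). The two
#' functions are exact inverses.
#'
#' @param lambda2 shrinkage ratio, >= 0.
#' @param h2 heritability, strictly in (0, 1).
#' @return the converted value.
#' @examples
#' h2_from_lambda(1)    # 0.5
#' lambda_from_h2(0.25) # 3
#' @export
h2_from_lambda <- function(lambda2) {
  if (!is.numeric(lambda2) || any(lambda2 < 0)) {
    stop("lambda2 must be non-negative", call. = FALSE)
  }
  1 / (1 + lambda2)
}

#' @rdname h2_from_lambda
#' @export
lambda_from_h2 <- function(h2) {
  if (!is.numeric(h2) || any(h2 <= 0) || any(h2 >= 1)) {
    stop("h2 must lie strictly in (0, 1)", call. = FALSE)
  }
  1 / h2 - 1
}

#' Piepho-Moehring heritability from BLUE differences
#'
#' `h2 = sigma2_g / (sigma2_g + MVD / 2)` where MVD is the mean variance
#' of a difference of two line BLUEs.
#'
#' @param sigma2_g genetic variance, >= 0.
#' @param mvd mean variance of a difference of the BLUEs, > 0.
#' @return heritability in [0, 1].
#' @export
heritability_piepho <- function(sigma2_g, mvd) {
  if (!is.numeric(sigma2_g) || sigma2_g < 0) {
    stop("sigma2_g must be non-negative", call. = FALSE)
  }
  if (!is.numeric(mvd) || mvd <= 0) stop("mvd must be positive", call. = FALSE)
  sigma2_g / (sigma2_g + mvd / 2)
}

#' Cullis heritability from BLUP differences
#'
#' `h2 = 1 - VD_BLUP / (2 sigma2_g)` with VD_BLUP the mean variance of a
#' difference of two line BLUPs, clipped at zero.
#'
#' @param vd_blup mean variance of a difference of the BLUPs, >= 0.
#' @param sigma2_g genetic variance, > 0.
#' @return heritability in [0, 1].
#' @export
heritability_cullis <- function(vd_blup, sigma2_g) {
  if (!is.numeric(sigma2_g) || sigma2_g <= 0) {
    stop("sigma2_g must be positive", call. = FALSE)
  }
  if (!is.numeric(vd_blup) || vd_blup < 0) {
    stop("vd_blup must be non-negative", call. = FALSE)
  }
  max(0, 1 - vd_blup / (2 * sigma2_g))
}

#' Forward trials exceeding a heritability threshold
#'
#' Retains trials whose heritability is strictly larger than `h2_min`
#' (default 0.3), the conventional quality gate before across-trial
#' combination.
#'
#' @param reports data.frame with columns `trial_id` and the chosen
#'   heritability column.
#' @param h2_min threshold (strict inequality).
#' @param column which heritability to gate on (default `"h2_piepho"`).
#' @return character vector of retained trial ids (possibly empty).
#' @export
filter_trials <- function(reports, h2_min = 0.3, column = "h2_piepho") {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L,
            all(c("trial_id", column) %in% names(reports)))
  reports$trial_id[reports[[column]] > h2_min]
}
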