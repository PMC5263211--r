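#' Sign-change marker pre-selection
#'
#' Compares marker effects estimated separately on the training
#' population (multi-environment data) and on the preliminary yield
#' trial. Markers whose effect changes sign between the two fits are
#' taken to introduce noise rather than signal and are removed before
#' rebuilding the marker and relationship matrices. Zero effects carry no
#' sign evidence and are retained by default.
#'
#' @param u_train,u_pyt named marker-effect vectors from two
#'   [fit_rrblup()] fits on the same panel.
#' @param zero_rule `"retain"` (default) or `"drop"` markers with a zero
#'   effect in either fit.
#' @return character vector of retained marker ids (possibly empty);
#'   attribute `fraction_removed`.
#' @export
select_markers_sign <- function(u_train, u_pyt,
                                zero_rule = c("retain", "drop")) {
  zero_rule <- match.arg(zero_rule)
  if (is.null(names(u_train)) || is.null(names(u_pyt))) {
    stop("marker effects must be named", call. = FALSE)
  }
  if (!setequal(names(u_train), names(u_pyt))) {
    stop("the two fits must cover the same marker panel", call. = FALSE)
  }
  u_pyt <- u_pyt[names(u_train)]
  prod <- u_train * u_pyt
  keep <- prod > 0
  if (zero_rule == "retain") keep <- keep | prod == 0
  retained <- names(u_train)[keep]
  attr(retained, "fraction_removed") <- 1 - mean(keep)
  retained
}

#' Sign discordance after refitting on the selected panel
#'
#' Refits both RR-BLUP models on a retained marker panel and reports the
#' fraction of markers whose effects still disagree in sign — a
#' diagnostic of how much disagreement was removable noise versus linkage
#' structure, not a further filter.
#'
#' @param y_train,markers_train training response and marker rows.
#' @param y_pyt,markers_pyt preliminary-trial response and marker rows.
#' @param retained marker ids to refit on (nonempty).
#' @param fixed_train optional fixed-effect design for the training fit.
#' @return the discordant fraction in [0, 1].
#' @export
refit_sign_fraction <- function(y_train, markers_train, y_pyt, markers_pyt,
                                retained, fixed_train = NULL) {
  if (!length(retained)) {
    stop("empty marker panel: nothing to refit", call. = FALSE)
  }
  f1 <- fit_rrblup(y_train, markers_train[, retained, drop = FALSE],
                   fixed_design = fixed_train)
  f2 <- fit_rrblup(y_pyt, markers_pyt[, retained, drop = FALSE])
  mean(f1$u * f2$u[names(f1$u)] < 0)
}
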