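#' Quality-control filtering of a marker panel
#'
#' Removes markers failing any of three criteria: call rate below
#' `call_rate_min`, minor allele frequency below `maf_min`, or a missing
#' fraction above `missing_max`. Defaults follow common GBS practice
#' (call rate 90%, MAF 0.05, 10% missing). The line set is unchanged.
#'
#' @param markers lines x markers matrix coded -1/0/+1 with `NA` missing.
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param maf_min minimum minor allele frequency (computed on observed
#'   dosages).
#' @param missing_max maximum fraction of missing calls.
#' @return the filtered matrix; attribute `qc_removed` holds per-criterion
#'   counts (markers may fail several criteria at once).
#' @examples
#' m <- matrix(c(1, -1, 1, NA, 1, 1, 1, 1), 4, 2,
#'             dimnames = list(paste0("L", 1:4), c("ok", "mono")))
#' qc_filter_markers(m, maf_min = 0.05)
#' @export
qc_filter_markers <- function(markers, call_rate_min = 0.90,
                              maf_min = 0.05, missing_max = 0.10) {
  stopifnot(is.matrix(markers), ncol(markers) >= 1L)
  assert_fraction(call_rate_min, "call_rate_min", open = FALSE)
  assert_fraction(maf_min, "maf_min", open = FALSE)
  assert_fraction(missing_max, "missing_max", open = FALSE)

  miss <- colMeans(is.na(markers))
  p <- colMeans(markers + 1, na.rm = TRUE) / 2 # +1 allele frequency
  maf <- pmin(p, 1 - p)

  fail_call <- (1 - miss) < call_rate_min
  fail_maf <- maf < maf_min
  fail_miss <- miss > missing_max
  keep <- !(fail_call | fail_maf | fail_miss)
  if (!any(keep)) {
    stop("empty marker panel: all markers removed by QC", call. = FALSE)
  }
  out <- markers[, keep, drop = FALSE]
  attr(out, "qc_removed") <- c(call_rate = sum(fail_call),
                               maf = sum(fail_maf),
                               missing = sum(fail_miss),
                               total = sum(!keep))
  out
}

#' Impute missing genotype calls
#'
#' `method = "mean"` replaces each missing entry by its marker's observed
#' mean. `method = "em"` iterates the multivariate-normal conditional
#' expectation of the missing entries given the observed ones (markers as
#' variables, lines as samples), starting from mean imputation and
#' re-estimating the mean vector and covariance each sweep until the
#' imputed values stabilize. Both are deterministic; on non-convergence
#' the EM variant falls back to mean imputation with a warning. Imputed
#' values are clipped to [-1, 1].
#'
#' The EM variant forms the markers x markers covariance, so it is meant
#' for panels of modest size (a few hundred markers); the default
#' throughout the package is marker-mean imputation.
#'
#' @param markers lines x markers matrix with `NA` missing.
#' @param method `"mean"` or `"em"`.
#' @param tol convergence tolerance on the largest change of any imputed
#'   value between sweeps.
#' @param max_iter maximum EM sweeps.
#' @return the completed matrix (no missing entries).
#' @export
impute_missing <- function(markers, method = c("mean", "em"),
                           tol = 1e-6, max_iter = 50L) {
  method <- match.arg(method)
  stopifnot(is.matrix(markers))
  if (!anyNA(markers)) return(markers)

  na_idx <- is.na(markers)
  col_mean <- colMeans(markers, na.rm = TRUE)
  col_mean[is.nan(col_mean)] <- 0 # fully missing marker (pre-QC input)
  mean_imp <- markers
  mean_imp[na_idx] <- rep(col_mean, each = nrow(markers))[na_idx]
  if (method == "mean") return(mean_imp)

  x <- mean_imp
  lines_na <- which(rowSums(na_idx) > 0L)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(x)
    s <- stats::cov(x)
    diag(s) <- diag(s) + 1e-8 * mean(diag(s)) # ridge for near-singular blocks
    delta <- 0
    for (i in lines_na) {
      mis <- which(na_idx[i, ])
      obs <- which(!na_idx[i, ])
      new <- if (length(obs)) {
        mu[mis] + s[mis, obs, drop = FALSE] %*%
          solve(s[obs, obs, drop = FALSE], x[i, obs] - mu[obs])
      } else {
        mu[mis]
      }
      delta <- max(delta, max(abs(new - x[i, mis])))
      x[i, mis] <- new
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MVN-EM imputation did not converge in ", max_iter,
            " iterations; falling back to marker-mean imputation",
            call. = FALSE)
    return(mean_imp)
  }
  x[na_idx] <- pmin(1, pmax(-1, x[na_idx]))
  x
}
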