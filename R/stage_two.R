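# Stage two: across-trial combination of one year's MET BLUEs.
#
# Model: blue_ij = mu + line_i + trial_j + (line:trial)_ij + e_ij with
# fixed line and trial effects and a random interaction. Because stage
# one delivers exactly one BLUE per line x trial cell, each interaction
# effect appears in a single record and the marginal covariance is
# diagonal: Var(blue_ij) = s2_gt + se_ij^2, the residual variance being
# fixed at the squared stage-one standard errors (inverse-squared-SE
# weighting). REML on s2_gt is therefore a smooth 1-D problem.

#' Across-trial BLUEs for one year's multi-environment trials
#'
#' Combines per-trial BLUEs into per-line across-trial BLUEs with a
#' weighted fixed-line / fixed-trial / random-interaction model (see
#' Details in the package vignette). Lines observed in a single trial are
#' estimable but flagged `low_info`.
#'
#' @param blues BLUE table rows (columns `line_id`, `trial_id`, `blue`,
#'   `se`) for >= 2 trials of one year.
#' @return data.frame `line_id`, `blue`, `se`, `weight`, `n_trials`,
#'   `low_info`; attributes `sigma2_gt` (interaction variance) and `mvd`
#'   (mean variance of a difference of the line BLUEs).
#' @export
across_trial_blues <- function(blues) {
  stopifnot(is.data.frame(blues),
            all(c("line_id", "trial_id", "blue", "se") %in% names(blues)))
  trials <- sort(unique(blues$trial_id))
  if (length(trials) < 2L) {
    stop("across-trial combination needs at least 2 trials", call. = FALSE)
  }
  if (any(blues$se <= 0)) stop("standard errors must be positive", call. = FALSE)
  lines <- sort(unique(blues$line_id))
  n <- nrow(blues)
  nl <- length(lines)

  X <- cbind(`(Intercept)` = rep(1, n),
             contr_sum_cols(blues$line_id, lines, "g"),
             contr_sum_cols(blues$trial_id, trials, "t"))
  if (qr(X)$rank < ncol(X)) {
    stop("line/trial design not of full rank (disconnected trials?)",
         call. = FALSE)
  }
  se2 <- blues$se^2
  y <- blues$blue

  crit <- function(ls) {
    v <- exp(ls) + se2
    w <- 1 / v
    A <- crossprod(X, X * w)
    b <- solve(A, crossprod(X, y * w))
    r <- y - X %*% b
    0.5 * (sum(log(v)) +
             as.numeric(determinant(A, logarithm = TRUE)$modulus) +
             sum(w * r^2))
  }
  opt <- stats::optimize(crit, c(-14, 8), tol = 1e-9)
  s2gt <- exp(opt$minimum)
  if (opt$minimum < -13.9) s2gt <- 0

  v <- s2gt + se2
  w <- 1 / v
  A <- crossprod(X, X * w)
  b <- drop(solve(A, crossprod(X, y * w)))
  C <- solve(A)

  # L maps coefficients to per-line BLUEs mu + g_i (sum-to-zero lines)
  L <- matrix(0, nl, ncol(X), dimnames = list(lines, colnames(X)))
  L[, 1L] <- 1
  for (i in seq_len(nl - 1L)) L[i, paste0("g", lines[i])] <- 1
  L[nl, grep("^g", colnames(X))] <- -1

  est <- drop(L %*% b)
  Vb <- L %*% C %*% t(L)
  se_line <- sqrt(pmax(diag(Vb), 0))
  n_trials <- as.numeric(table(blues$line_id)[lines])

  dv <- diag(Vb)
  mvd <- 2 * (nl * sum(dv) - sum(Vb)) / (nl * (nl - 1L))

  out <- data.frame(line_id = lines, blue = est, se = se_line,
                    weight = 1 / se_line^2, n_trials = n_trials,
                    low_info = n_trials < 2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma2_gt") <- s2gt
  attr(out, "mvd") <- mvd
  out
}

#' Kinship-enhanced BLUP of preliminary-trial breeding values
#'
#' Applies the GBLUP machinery to the adjusted BLUEs of the unreplicated
#' selection candidates themselves (grand mean as the only fixed effect):
#' relationship information is borrowed across relatives to shrink and
#' stabilize single-plot values. The trial heritability follows from the
#' fitted shrinkage ratio as `h2 = 1 / (1 + lambda2)`.
#'
#' @param pyt_blues BLUE table from [adjust_spatial()] of one PYT; check
#'   entries are dropped (checks are named varieties, not selection
#'   candidates).
#' @param K kinship covering all phenotyped candidate lines.
#' @return list of class `gas_kblup`: `fit` (the underlying `gas_fit`),
#'   `bv` (named breeding values, mean + genetic effect, for the
#'   candidates), `h2`.
#' @export
kblup <- function(pyt_blues, K) {
  stopifnot(is.data.frame(pyt_blues),
            all(c("line_id", "blue") %in% names(pyt_blues)))
  cand <- pyt_blues[!(pyt_blues$is_check %||% FALSE), , drop = FALSE]
  y <- stats::setNames(cand$blue, cand$line_id)
  fit <- fit_gblup(y, K)
  structure(list(fit = fit,
                 bv = fit$pred[cand$line_id],
                 h2 = fit$h2),
            class = "gas_kblup")
}

#' @export
print.gas_kblup <- function(x, ...) {
  cat(sprintf("<gas_kblup> %d candidates, h2 = %.3f\n", length(x$bv), x$h2))
  invisible(x)
}
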