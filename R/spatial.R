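# Stage one: check-based spatial adjustment of a single trial.
#
# Replicated check plots identify additive row and column effects and the
# plot error variance; subtracting the estimated trends from every plot
# turns each unreplicated test plot into a BLUE with a propagated SE.

# sum-to-zero contrast columns for the levels `lev` evaluated at `x`
contr_sum_cols <- function(x, lev, prefix) {
  k <- length(lev)
  if (k < 2L) return(NULL)
  m <- matrix(0, length(x), k - 1L,
              dimnames = list(NULL, paste0(prefix, lev[-k])))
  for (j in seq_len(k - 1L)) m[x == lev[j], j] <- 1
  m[x == lev[k], ] <- -1
  m
}

# expand fitted sum-to-zero coefficients back to one effect per level
expand_sum_effects <- function(coefs, lev) {
  if (is.null(coefs)) return(stats::setNames(rep(0, length(lev)), lev))
  eff <- c(coefs, -sum(coefs))
  stats::setNames(eff, lev)
}

#' Spatial adjustment of a trial from its replicated checks
#'
#' Fits `check_mean + row + col` (sum-to-zero row and column effects) to
#' the check plots of one trial by least squares, estimates the plot
#' error variance from the check residuals, and subtracts the fitted
#' row/column trends from every plot. Unreplicated test lines yield one
#' adjusted value each (their BLUE); the SE propagates both the plot
#' error and the estimation error of the subtracted trend,
#' `se^2 = sigma2_e + Var(row_hat + col_hat)`, taken from the check-model
#' coefficient covariance. Checks yield their adjusted mean with SE
#' `sqrt(sigma2_e / reps)`.
#'
#' Rows or columns containing no check plot are unadjustable: their
#' effect is set to 0 with a warning. If the checks provide too few
#' degrees of freedom for the full model the fit degrades to a
#' single-axis model (whichever of rows/cols has fewer levels), then to
#' check means only; the reduction is logged via `message()`.
#'
#' @param trial plot records of a single trial (columns `line_id`,
#'   `trial_id`, `year`, `row`, `col`, `is_check`, and the trait).
#' @param trait trait column name, `"yield"` or `"protein"`.
#' @return a BLUE table: data.frame with `line_id`, `trial_id`, `year`,
#'   `blue`, `se`, `weight` (= 1/se^2), `is_check`; attributes
#'   `sigma2_e`, `row_effects`, `col_effects`, `model`.
#' @export
adjust_spatial <- function(trial, trait = "yield") {
  stopifnot(is.data.frame(trial), trait %in% names(trial))
  if (length(unique(trial$trial_id)) != 1L) {
    stop("adjust_spatial() works on a single trial; split by trial_id first",
         call. = FALSE)
  }
  if (anyDuplicated(trial[, c("row", "col")])) {
    stop("duplicated (row, col) positions within the trial", call. = FALSE)
  }
  chk <- trial[trial$is_check, , drop = FALSE]
  if (nrow(chk) < 2L) {
    stop("trial has no replicated check plots", call. = FALSE)
  }
  y <- chk[[trait]]
  check_lev <- sort(unique(chk$line_id))
  row_lev <- sort(unique(chk$row))
  col_lev <- sort(unique(chk$col))

  Xc <- matrix(0, nrow(chk), length(check_lev),
               dimnames = list(NULL, check_lev))
  Xc[cbind(seq_len(nrow(chk)), match(chk$line_id, check_lev))] <- 1
  Xr <- contr_sum_cols(chk$row, row_lev, "r@")
  Xk <- contr_sum_cols(chk$col, col_lev, "c@")

  single_axis <- if (length(row_lev) <= length(col_lev)) "rows" else "cols"
  builds <- list(`rows+cols` = cbind(Xc, Xr, Xk))
  builds[[single_axis]] <- if (single_axis == "rows") cbind(Xc, Xr) else
    cbind(Xc, Xk)
  builds$means <- Xc
  model <- NULL
  for (nm in names(builds)) {
    X <- builds[[nm]]
    if (!is.null(X) && nrow(X) - qr(X)$rank >= 2L) {
      model <- nm
      break
    }
  }
  if (is.null(model)) stop("too few check plots to estimate an error variance",
                           call. = FALSE)
  if (model != "rows+cols") {
    message(sprintf("trial %s: check plots support only the '%s' model",
                    trial$trial_id[1L], model))
  }

  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("aliased spatial effects set to 0 (sparse check layout)",
            call. = FALSE)
    cf[is.na(cf)] <- 0
  }
  df <- nrow(X) - fit$rank
  sigma2_e <- sum(fit$residuals^2) / df
  ok <- !is.na(fit$coefficients)
  Cmat <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X),
                                                      colnames(X)))
  Cmat[ok, ok] <- sigma2_e * solve(crossprod(X[, ok, drop = FALSE]))

  has_rows <- model %in% c("rows+cols", "rows") && !is.null(Xr)
  has_cols <- model %in% c("rows+cols", "cols") && !is.null(Xk)
  r_coef <- if (has_rows) cf[colnames(Xr)] else NULL
  c_coef <- if (has_cols) cf[colnames(Xk)] else NULL

  all_rows <- sort(unique(trial$row))
  all_cols <- sort(unique(trial$col))
  row_eff <- stats::setNames(rep(0, length(all_rows)), all_rows)
  col_eff <- stats::setNames(rep(0, length(all_cols)), all_cols)
  row_eff[as.character(row_lev)] <- expand_sum_effects(r_coef, row_lev)
  col_eff[as.character(col_lev)] <- expand_sum_effects(c_coef, col_lev)

  uncovered_r <- if (has_rows) setdiff(all_rows, row_lev) else integer(0)
  uncovered_c <- if (has_cols) setdiff(all_cols, col_lev) else integer(0)
  if (length(uncovered_r) || length(uncovered_c)) {
    warning(sprintf("no check in %d row(s)/%d col(s); their effects set to 0",
                    length(uncovered_r), length(uncovered_c)), call. = FALSE)
  }

  # variance of the subtracted trend per plot, from the coefficient
  # covariance (sum-to-zero expansion: the dropped level is minus the sum)
  Lp <- matrix(0, nrow(trial), ncol(X),
               dimnames = list(NULL, colnames(X)))
  axis_rows <- function(values, lev, prefix) {
    last <- lev[length(lev)]
    for (i in seq_len(nrow(trial))) {
      v <- values[i]
      if (!(v %in% lev)) next
      if (v == last) {
        Lp[i, paste0(prefix, lev[-length(lev)])] <<- -1
      } else {
        Lp[i, paste0(prefix, v)] <<- 1
      }
    }
  }
  if (has_rows) axis_rows(trial$row, row_lev, "r@")
  if (has_cols) axis_rows(trial$col, col_lev, "c@")
  var_adj <- rowSums((Lp %*% Cmat) * Lp)

  adj <- trial[[trait]] - row_eff[as.character(trial$row)] -
    col_eff[as.character(trial$col)]

  is_chk <- trial$is_check
  out_test <- data.frame(line_id = trial$line_id[!is_chk],
                         trial_id = trial$trial_id[1L],
                         year = trial$year[1L],
                         blue = adj[!is_chk],
                         se = sqrt(sigma2_e + var_adj[!is_chk]),
                         is_check = FALSE,
                         stringsAsFactors = FALSE)
  adj_chk <- adj[is_chk]
  chk_mean <- tapply(adj_chk, chk$line_id, mean)
  chk_n <- tapply(adj_chk, chk$line_id, length)
  out_chk <- data.frame(line_id = names(chk_mean),
                        trial_id = trial$trial_id[1L],
                        year = trial$year[1L],
                        blue = as.numeric(chk_mean),
                        se = sqrt(sigma2_e / as.numeric(chk_n)),
                        is_check = TRUE,
                        stringsAsFactors = FALSE)
  out <- rbind(out_test, out_chk)
  out$weight <- 1 / out$se^2
  rownames(out) <- NULL
  attr(out, "sigma2_e") <- sigma2_e
  attr(out, "row_effects") <- row_eff
  attr(out, "col_effects") <- col_eff
  attr(out, "model") <- model
  out
}

#' Per-trial heritability report
#'
#' Summarizes a stage-one BLUE table into the two standard heritability
#' measures. The genetic variance is the variance of the adjusted test
#' BLUEs in excess of their mean squared SE; the mean variance of a BLUE
#' difference for unreplicated entries is twice the mean squared SE
#' (Piepho-Moehring route), and the BLUP prediction-error variance under
#' the shrinkage model gives `VD_BLUP = 2 s2g v / (s2g + v)` (Cullis
#' route), with `v` the mean squared SE.
#'
#' @param blues a BLUE table from [adjust_spatial()].
#' @return one-row data.frame: `trial_id`, `sigma2_g`, `sigma2_e`, `mvd`,
#'   `h2_piepho`, `vd_blup`, `h2_cullis`.
#' @export
trial_report <- function(blues) {
  s2e <- attr(blues, "sigma2_e")
  stopifnot(!is.null(s2e))
  test <- blues[!blues$is_check, , drop = FALSE]
  v <- mean(test$se^2)
  s2g <- max(0, stats::var(test$blue) - v)
  mvd <- 2 * v
  h2p <- heritability_piepho(s2g, mvd)
  if (s2g > 0) {
    pev <- s2g * v / (s2g + v)
    vd <- 2 * pev
    h2c <- heritability_cullis(vd, s2g)
  } else {
    vd <- NA_real_
    h2c <- 0
  }
  data.frame(trial_id = blues$trial_id[1L],
             sigma2_g = s2g, sigma2_e = s2e, mvd = mvd,
             h2_piepho = h2p, vd_blup = vd, h2_cullis = h2c,
             stringsAsFactors = FALSE)
}

#' Stage-one analysis of every trial in a plot table
#'
#' Convenience wrapper: splits plot records by trial, runs
#' [adjust_spatial()] and [trial_report()] on each.
#'
#' @param trials plot records for one or more trials.
#' @param trait trait column name.
#' @return list with `blues` (one combined BLUE table, trial attributes
#'   dropped) and `reports` (one row per trial).
#' @export
stage_one <- function(trials, trait = "yield") {
  parts <- split(trials, trials$trial_id)
  blues <- vector("list", length(parts))
  reports <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    bt <- adjust_spatial(parts[[i]], trait)
    blues[[i]] <- bt
    reports[[i]] <- trial_report(bt)
  }
  list(blues = do.call(rbind, blues),
       reports = do.call(rbind, reports))
}
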