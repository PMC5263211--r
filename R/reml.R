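# Spectral REML for single-variance-component mixed models
#
# Model: y = X b + g + e,  g ~ N(0, G s2g),  e ~ N(0, I s2e).
# With G = U D U' the rotated data have diagonal covariance
# s2g * (D + delta I), delta = s2e / s2g, so the REML criterion profiles
# to a smooth 1-D function of log(delta) evaluated in O(n p^2) per point
# after one eigendecomposition (the EMMA device). delta equals the
# shrinkage ratio lambda^2 = s2e / s2g, from which h2 = 1 / (1 + lambda^2).

reml_eigen <- function(y, X, eig, lower = -14, upper = 14, tol = 1e-10) {
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("singular fixed-effect design matrix", call. = FALSE)
  }
  if (n - p < 2L) stop("not enough residual degrees of freedom", call. = FALSE)

  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  crit <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (d + delta)
    A <- crossprod(Xt, Xt * w)
    b <- solve(A, crossprod(Xt, yt * w))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(d + delta)) +
             as.numeric(determinant(A, logarithm = TRUE)$modulus) + (n - p))
  }

  opt <- stats::optimize(crit, c(lower, upper), tol = tol)
  ldelta <- opt$minimum
  boundary <- (ldelta - lower < 1e-3) || (upper - ldelta < 1e-3)
  delta <- exp(ldelta)

  w <- 1 / (d + delta)
  A <- crossprod(Xt, Xt * w)
  b <- drop(solve(A, crossprod(Xt, yt * w)))
  r <- drop(yt - Xt %*% b)
  s2g <- sum(w * r^2) / (n - p)
  # alpha = s2g * V^{-1} (y - X b); BLUPs are K[, train] %*% alpha
  alpha <- drop(U %*% (w * r))

  list(delta = delta, sigma2_g = s2g, sigma2_e = delta * s2g,
       b = stats::setNames(b, colnames(X)), alpha = alpha,
       log_likelihood = -opt$objective, boundary = boundary)
}

# shared construction of a gas_fit object
new_gas_fit <- function(method, core, extra = list()) {
  structure(c(list(method = method,
                   sigma2_g = core$sigma2_g,
                   sigma2_e = core$sigma2_e,
                   lambda2 = core$delta,
                   h2 = 1 / (1 + core$delta),
                   fixed_effects = core$b,
                   log_likelihood = core$log_likelihood,
                   boundary = core$boundary),
              extra),
            class = "gas_fit")
}

#' @export
print.gas_fit <- function(x, ...) {
  cat(sprintf("<gas_fit:%s> s2g=%.4g s2e=%.4g lambda2=%.4g h2=%.3f%s\n",
              x$method, x$sigma2_g, x$sigma2_e, x$lambda2, x$h2,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

default_design <- function(y) {
  matrix(1, length(y), 1L, dimnames = list(names(y), "(Intercept)"))
}

#' GBLUP: genomic best linear unbiased prediction
#'
#' Fits `y = X b + g + e` with `g ~ N(0, K s2g)` by REML (one
#' eigendecomposition of the training block of `K`, 1-D optimization of
#' the profiled criterion on the variance ratio). Genetic effects are
#' predicted for every line in `K`, including lines without phenotypes,
#' through their genomic relationship with the phenotyped lines.
#'
#' @param y named numeric vector of line phenotypes (e.g. stage-one or
#'   stage-two BLUEs); names must appear in `rownames(K)`.
#' @param K a [genomic_relationship()] result or a plain symmetric
#'   relationship matrix with line ids as dimnames.
#' @param fixed_design optional fixed-effect design matrix (rows aligned
#'   with `y`); defaults to an intercept. Must be full column rank.
#' @return a `gas_fit` with variance components `sigma2_g`, `sigma2_e`,
#'   the shrinkage ratio `lambda2 = sigma2_e / sigma2_g`, the heritability
#'   `h2 = 1 / (1 + lambda2)`, fixed effects, genetic effects `g` for all
#'   lines in `K`, and `pred = mu + g` where `mu` is the mean fixed-effect
#'   contribution of the training lines. A constant response yields a
#'   zero-genetic-variance fit (`h2 = 0`) flagged via `zero_variance`.
#' @examples
#' K <- diag(4); dimnames(K) <- list(paste0("L", 1:4), paste0("L", 1:4))
#' y <- c(L1 = 1, L2 = 2, L3 = 3, L4 = 4)
#' fit <- fit_gblup(y, K)
#' fit$h2
#' @export
fit_gblup <- function(y, K, fixed_design = NULL) {
  Km <- as_kinship(K)
  ids <- names(y)
  if (is.null(ids)) stop("`y` must be a named vector of line phenotypes",
                         call. = FALSE)
  align_ids(ids, rownames(Km), "kinship entries")
  X <- fixed_design %||% default_design(y)
  stopifnot(nrow(X) == length(y))

  all_ids <- rownames(Km)
  if (stats::sd(y) < 1e-12) {
    g <- stats::setNames(numeric(length(all_ids)), all_ids)
    fit <- structure(list(method = "gblup", sigma2_g = 0,
                          sigma2_e = stats::var(y) + 1e-12, lambda2 = Inf,
                          h2 = 0, fixed_effects = c(`(Intercept)` = mean(y)),
                          log_likelihood = NA_real_, boundary = TRUE,
                          zero_variance = TRUE, g = g,
                          mu = mean(y), pred = g + mean(y),
                          train_ids = ids),
                     class = "gas_fit")
    return(fit)
  }

  Koo <- Km[ids, ids, drop = FALSE]
  eig <- eigen(Koo, symmetric = TRUE)
  core <- reml_eigen(y, X, eig)
  g_all <- drop(Km[, ids, drop = FALSE] %*% core$alpha)
  names(g_all) <- all_ids
  mu <- mean(drop(X %*% core$b))
  new_gas_fit("gblup", core,
              list(g = g_all, mu = mu, pred = mu + g_all,
                   train_ids = ids, zero_variance = FALSE))
}

#' RR-BLUP: ridge-regression marker-effect estimation
#'
#' Fits `y = X b + Z u + e` with `u ~ N(0, I s2u)` for all markers
#' jointly. Marker codes are recoded to dosages and centered by twice the
#' training allele frequency; the REML problem is solved through a single
#' eigendecomposition of the n x n marker cross-product, and marker
#' effects are recovered by back-rotation. The line-scale genetic variance
#' `sigma2_g = c * sigma2_u` (with `c = 2 * sum(p(1-p))`, the kinship
#' normalizer) makes `lambda2` and `h2` directly comparable with
#' [fit_gblup()] on `K` built from the same markers.
#'
#' @param y named numeric vector of line phenotypes (>= 10 lines).
#' @param markers complete lines x markers matrix covering all lines in
#'   `y`.
#' @param fixed_design optional fixed-effect design (default intercept).
#' @return a `gas_fit` with marker effects `u`, allele frequencies `p`
#'   used for centering, fitted genetic values `g = W u`, and
#'   `pred = mu + g` for the training lines.
#' @export
fit_rrblup <- function(y, markers, fixed_design = NULL) {
  ids <- names(y)
  if (is.null(ids)) stop("`y` must be a named vector", call. = FALSE)
  if (length(y) < 10L) stop("RR-BLUP requires at least 10 lines", call. = FALSE)
  align_ids(ids, rownames(markers), "marker rows")
  if (anyNA(markers)) stop("markers must be complete", call. = FALSE)
  Z <- markers[ids, , drop = FALSE]
  X <- fixed_design %||% default_design(y)
  stopifnot(nrow(X) == length(y))

  dosage <- Z + 1
  p <- colMeans(dosage) / 2
  cnorm <- 2 * sum(p * (1 - p))
  if (cnorm < 1e-12) stop("all markers monomorphic", call. = FALSE)
  W <- sweep(dosage, 2L, 2 * p)

  G <- tcrossprod(W)
  eig <- eigen(G, symmetric = TRUE)
  core <- reml_eigen(y, X, eig)
  u <- drop(crossprod(W, core$alpha))
  names(u) <- colnames(Z)
  g <- drop(W %*% u)
  names(g) <- ids
  mu <- mean(drop(X %*% core$b))

  # report variances on the line (kinship) scale: K = G / cnorm
  core_line <- core
  core_line$sigma2_g <- core$sigma2_g * cnorm
  core_line$delta <- core$delta / cnorm
  fit <- new_gas_fit("rrblup", core_line,
                     list(u = u, p = p, cnorm = cnorm,
                          sigma2_u = core$sigma2_g,
                          g = g, mu = mu, pred = mu + g,
                          train_ids = ids, zero_variance = FALSE))
  fit
}

#' Genomic estimated breeding values for new lines
#'
#' Applies the marker effects of an [fit_rrblup()] fit to a new marker
#' panel: `GEBV = mu + W_new u`, centering the new panel with the
#' training allele frequencies. The new panel must carry exactly the
#' markers used in the fit (after any marker selection).
#'
#' @param markers_new complete lines x markers matrix.
#' @param fit a `gas_fit` from [fit_rrblup()].
#' @return named numeric vector of GEBVs, in the row order of
#'   `markers_new`.
#' @export
predict_gebv <- function(markers_new, fit) {
  stopifnot(inherits(fit, "gas_fit"))
  if (fit$method != "rrblup") {
    stop("predict_gebv() needs an RR-BLUP fit with marker effects",
         call. = FALSE)
  }
  have <- colnames(markers_new)
  need <- names(fit$u)
  if (!setequal(have, need)) {
    bad <- c(setdiff(need, have), setdiff(have, need))
    stop(sprintf("marker id mismatch (%d discrepant): %s", length(bad),
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(markers_new)) stop("markers must be complete", call. = FALSE)
  Z <- markers_new[, need, drop = FALSE]
  W <- sweep(Z + 1, 2L, 2 * fit$p)
  stats::setNames(drop(fit$mu + W %*% fit$u), rownames(markers_new))
}
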