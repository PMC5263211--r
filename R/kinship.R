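#' Genomic relationship matrix
#'
#' Computes the marker-based kinship `K = W W' / (2 * sum(p_k * (1 - p_k)))`
#' where the -1/0/+1 codes are recoded to 0/1/2 dosages, `p_k` is the
#' frequency of the counted allele, and `W` centers the dosages by
#' `2 * p_k` (VanRaden-type normalization as used by Endelman & Jannink's
#' A.mat). For fully inbred panels the mean diagonal is close to 2.
#'
#' @param markers complete lines x markers matrix coded -1/0/+1.
#' @return a `gas_grm`: list with `K` (symmetric lines x lines matrix),
#'   `allele_freqs` (named per-marker `p_k`), and `min_eigenvalue`
#'   (smallest eigenvalue of `K`, reported for positive-definiteness
#'   diagnostics). A message is emitted if the mean diagonal falls outside
#'   the sanity band [0.5, 2.5].
#' @examples
#' z <- rbind(L1 = c(1, -1), L2 = c(1, 1))
#' colnames(z) <- c("M1", "M2")
#' genomic_relationship(z)$K
#' @export
genomic_relationship <- function(markers) {
  stopifnot(is.matrix(markers))
  if (anyNA(markers)) {
    stop("markers must be complete; impute missing values first", call. = FALSE)
  }
  if (nrow(markers) < 2L) stop("need at least 2 lines", call. = FALSE)

  dosage <- markers + 1
  p <- colMeans(dosage) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom < 1e-12) {
    stop("all markers monomorphic: kinship normalizer is zero", call. = FALSE)
  }
  w <- sweep(dosage, 2L, 2 * p)
  k <- tcrossprod(w) / denom
  k <- (k + t(k)) / 2

  mean_diag <- mean(diag(k))
  if (mean_diag < 0.5 || mean_diag > 2.5) {
    message(sprintf("kinship mean diagonal %.2f outside the usual [0.5, 2.5]",
                    mean_diag))
  }
  structure(list(K = k,
                 allele_freqs = stats::setNames(p, colnames(markers)),
                 min_eigenvalue = min(eigen(k, symmetric = TRUE,
                                            only.values = TRUE)$values)),
            class = "gas_grm")
}

#' @export
print.gas_grm <- function(x, ...) {
  cat(sprintf("<gas_grm> %d lines, %d markers; mean diag %.3f, min eigen %.2e\n",
              nrow(x$K), length(x$allele_freqs), mean(diag(x$K)),
              x$min_eigenvalue))
  invisible(x)
}

#' @export
as.matrix.gas_grm <- function(x, ...) x$K

# accept either a gas_grm or a plain symmetric matrix wherever a kinship
# is needed
as_kinship <- function(K) {
  if (inherits(K, "gas_grm")) return(K$K)
  stopifnot(is.matrix(K), nrow(K) == ncol(K), !is.null(rownames(K)))
  K
}
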