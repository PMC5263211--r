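#' Simulate multi-family inbred genotypes
#'
#' Lines are built as recombination mosaics of two inbred parental
#' haplotypes per family (no explicit linkage map; switch points follow a
#' Markov chain along the marker index, ~10 blocks per line). Parents are
#' drawn marker-wise from population allele frequencies spread over
#' (0.05, 0.95), so families share long haplotype stretches and the panel
#' carries the relatedness gradients kinship-based methods exploit.
#' A small residual heterozygosity (2%) mimics F4-derived material; check
#' varieties are appended as unrelated inbred lines.
#'
#' Genotypes are coded -1/+1 for the two homozygotes and 0 for
#' heterozygotes; missing calls (rate `config$missing_rate`) are `NA`.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (lines x markers) with `line_id` rownames and
#'   `marker_id` colnames; attributes `family` (integer vector, `NA` for
#'   checks) and `is_check` (logical vector).
#' @examples
#' g <- simulate_genotypes(sim_config(n_lines_per_year = 20, n_years = 2,
#'                                    n_markers = 50, pyt_rows = 6,
#'                                    pyt_cols = 8))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genotypes"))

  m <- config$n_markers
  n_test <- config$n_years * config$n_lines_per_year
  n_chk <- config$n_checks
  n <- n_test + n_chk

  p <- stats::runif(m, 0.05, 0.95) # population frequency of the +1 allele
  het_rate <- 0.02
  switch_prob <- min(0.5, 10 / m) # ~10 parental blocks per line

  draw_parent <- function() ifelse(stats::runif(m) < p, 1, -1)

  fam <- rep_len(seq_len(config$n_families), n_test)
  parents <- lapply(seq_len(config$n_families),
                    function(f) list(draw_parent(), draw_parent()))

  geno <- matrix(0, nrow = n, ncol = m,
                 dimnames = list(
                   c(sprintf("L%04d", seq_len(n_test)),
                     sprintf("CHK%d", seq_len(n_chk))),
                   sprintf("M%04d", seq_len(m))))

  for (i in seq_len(n_test)) {
    pr <- parents[[fam[i]]]
    # mosaic: which parent contributes each marker (flip parity chain)
    start <- sample(0:1, 1L)
    flips <- stats::runif(m - 1) < switch_prob
    state <- (cumsum(c(start, flips)) %% 2L) + 1L
    gi <- ifelse(state == 1L, pr[[1]], pr[[2]])
    gi[stats::runif(m) < het_rate] <- 0
    geno[i, ] <- gi
  }
  for (j in seq_len(n_chk)) {
    # unrelated inbreds, own private parents
    geno[n_test + j, ] <- draw_parent()
  }

  if (config$missing_rate > 0) {
    geno[stats::runif(n * m) < config$missing_rate] <- NA
  }

  attr(geno, "family") <- stats::setNames(
    c(fam, rep(NA_integer_, n_chk)), rownames(geno))
  attr(geno, "is_check") <- stats::setNames(
    c(rep(FALSE, n_test), rep(TRUE, n_chk)), rownames(geno))
  geno
}

#' Construct true breeding values from marker effects
#'
#' The exact linear genetic model: `true_bv = Z[, qtl] %*% effects` per
#' trait, with no scaling or noise. Used by [simulate_true_values()] and
#' directly in tests.
#'
#' @param genotypes complete (-1/0/+1) marker matrix.
#' @param qtl_indices integer marker indices carrying effects.
#' @param qtl_effects numeric matrix `length(qtl_indices)` x traits.
#' @return matrix of breeding values (lines x traits).
#' @export
truth_from_effects <- function(genotypes, qtl_indices, qtl_effects) {
  qtl_effects <- as.matrix(qtl_effects)
  stopifnot(!anyNA(genotypes), length(qtl_indices) == nrow(qtl_effects),
            all(qtl_indices >= 1), all(qtl_indices <= ncol(genotypes)))
  bv <- genotypes[, qtl_indices, drop = FALSE] %*% qtl_effects
  rownames(bv) <- rownames(genotypes)
  bv
}

#' Simulate true breeding values for two correlated traits
#'
#' Samples `n_qtl` markers and draws additive effects from a bivariate
#' normal with correlation `trait_cor` (yield-like and protein-like
#' traits). Effects are rescaled so the realized genetic variance across
#' lines is exactly 1 per trait, which makes the later phenotype
#' simulation attain the target heritabilities through the identity
#' `s2e = (1 - h2) / h2`.
#'
#' @param genotypes complete marker matrix from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return a `truth_set`: list with `line_ids`, `true_bv` (lines x 2
#'   matrix, columns `yield`, `protein`), `qtl_indices`, `qtl_effects`,
#'   and `is_check`.
#' @export
simulate_true_values <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(genotypes)) {
    stop("genotypes must be complete (impute before simulating truth)",
         call. = FALSE)
  }
  if (config$n_qtl > ncol(genotypes)) {
    stop("configuration error: n_qtl exceeds the number of markers",
         call. = FALSE)
  }
  set.seed(substream_seed(config$seed, "truth"))

  qtl <- sort(sample.int(ncol(genotypes), config$n_qtl))
  rho <- config$trait_cor
  a1 <- stats::rnorm(config$n_qtl)
  a2 <- rho * a1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(config$n_qtl)
  eff <- cbind(yield = a1, protein = a2)

  bv <- truth_from_effects(genotypes, qtl, eff)
  sds <- apply(bv, 2, stats::sd)
  if (any(sds < 1e-10)) {
    stop("degenerate QTL draw: a trait has zero genetic variance", call. = FALSE)
  }
  eff <- sweep(eff, 2, sds, "/")
  bv <- sweep(bv, 2, sds, "/")
  colnames(bv) <- c("yield", "protein")

  structure(list(line_ids = rownames(genotypes),
                 true_bv = bv,
                 qtl_indices = qtl,
                 qtl_effects = eff,
                 is_check = attr(genotypes, "is_check") %||%
                   stats::setNames(rep(FALSE, nrow(genotypes)),
                                   rownames(genotypes))),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d lines, %d QTL, traits: %s\n",
              length(x$line_ids), length(x$qtl_indices),
              paste(colnames(x$true_bv), collapse = ", ")))
  invisible(x)
}
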