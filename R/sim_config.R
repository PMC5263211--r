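#' Configuration for the breeding-program simulator
#'
#' Describes a multi-year line breeding program: each year a new cohort of
#' inbred lines is tested in a single unreplicated preliminary yield trial
#' (PYT) with replicated checks on a row-by-column field grid, and a
#' selected fraction of the cohort is retested the following year in
#' replicated multi-environment trials (MET) across several locations.
#' Two traits of contrasting heritability are simulated: a yield-like,
#' low-heritability trait and a protein-like, high-heritability trait.
#'
#' True breeding values are standardized to unit genetic variance; the
#' per-trial residual variance is derived from the target heritability via
#' the single-trial identity h2 = s2g / (s2g + s2e).
#'
#' @param n_lines_per_year new test lines entering each year's PYT.
#' @param n_years number of program years.
#' @param n_families number of bi-parental families the lines descend from.
#' @param n_markers biallelic SNP markers.
#' @param n_qtl markers carrying additive effects (<= `n_markers`).
#' @param h2_yield,h2_protein target single-trial heritabilities, strictly
#'   in (0, 1).
#' @param trait_cor genetic correlation between the two traits' QTL effects.
#' @param var_gxe variance of the line-by-trial interaction in METs.
#' @param n_met_locations MET trials (locations) per year.
#' @param pyt_rows,pyt_cols PYT field grid dimensions; the grid must hold
#'   `n_lines_per_year + n_checks * check_reps` plots.
#' @param n_checks number of replicated check varieties.
#' @param check_reps check plots per check variety in a PYT.
#' @param met_check_reps check plots per check variety in each MET trial.
#' @param spatial_row_sd,spatial_col_sd standard deviations of additive row
#'   and column field trends (trait units).
#' @param carry_fraction fraction of each PYT cohort advanced to the next
#'   year's MET, in (0, 1].
#' @param missing_rate fraction of genotype calls set missing.
#' @param select_on how lines are advanced from PYT to MET: `"observed"`
#'   uses the raw PYT yield phenotype (reproduces selection-induced bias),
#'   `"true"` uses the true breeding value, `"random"` selects at random.
#' @param seed master seed; every stochastic stage draws from a named
#'   substream of it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_lines_per_year = 40, n_years = 3, n_markers = 100,
#'                   pyt_rows = 8, pyt_cols = 9)
#' cfg$h2_yield
#' @export
sim_config <- function(n_lines_per_year = 120L,
                       n_years = 6L,
                       n_families = 25L,
                       n_markers = 600L,
                       n_qtl = 100L,
                       h2_yield = 0.3,
                       h2_protein = 0.7,
                       trait_cor = 0.3,
                       var_gxe = 0.25,
                       n_met_locations = 3L,
                       pyt_rows = 12L,
                       pyt_cols = 14L,
                       n_checks = 4L,
                       check_reps = 10L,
                       met_check_reps = 8L,
                       spatial_row_sd = 0.5,
                       spatial_col_sd = 0.5,
                       carry_fraction = 0.4,
                       missing_rate = 0,
                       select_on = c("observed", "true", "random"),
                       seed = 1L) {
  cfg <- list(
    n_lines_per_year = assert_count(n_lines_per_year, "n_lines_per_year"),
    n_years          = assert_count(n_years, "n_years"),
    n_families       = assert_count(n_families, "n_families"),
    n_markers        = assert_count(n_markers, "n_markers"),
    n_qtl            = assert_count(n_qtl, "n_qtl"),
    h2_yield         = assert_fraction(h2_yield, "h2_yield"),
    h2_protein       = assert_fraction(h2_protein, "h2_protein"),
    trait_cor        = trait_cor,
    var_gxe          = assert_nonneg(var_gxe, "var_gxe"),
    n_met_locations  = assert_count(n_met_locations, "n_met_locations"),
    pyt_rows         = assert_count(pyt_rows, "pyt_rows"),
    pyt_cols         = assert_count(pyt_cols, "pyt_cols"),
    n_checks         = assert_count(n_checks, "n_checks"),
    check_reps       = assert_count(check_reps, "check_reps", min = 2L),
    met_check_reps   = assert_count(met_check_reps, "met_check_reps", min = 2L),
    spatial_row_sd   = assert_nonneg(spatial_row_sd, "spatial_row_sd"),
    spatial_col_sd   = assert_nonneg(spatial_col_sd, "spatial_col_sd"),
    carry_fraction   = carry_fraction,
    missing_rate     = missing_rate,
    select_on        = match.arg(select_on),
    seed             = assert_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(trait_cor) || abs(trait_cor) > 1) {
    stop("`trait_cor` must be in [-1, 1]", call. = FALSE)
  }
  if (cfg$n_qtl > cfg$n_markers) {
    stop("configuration error: n_qtl must not exceed n_markers", call. = FALSE)
  }
  capacity <- cfg$pyt_rows * cfg$pyt_cols
  demand <- cfg$n_lines_per_year + cfg$n_checks * cfg$check_reps
  if (capacity < demand) {
    stop(sprintf(paste0("configuration error: PYT grid %dx%d holds %d plots ",
                        "but %d are required"),
                 cfg$pyt_rows, cfg$pyt_cols, capacity, demand), call. = FALSE)
  }
  if (!is.numeric(carry_fraction) || carry_fraction <= 0 || carry_fraction > 1) {
    stop("configuration error: carry_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d years x %d lines/year, %d families, %d markers (%d QTL)\n",
              x$n_years, x$n_lines_per_year, x$n_families, x$n_markers, x$n_qtl))
  cat(sprintf("  h2: yield %.2f, protein %.2f; var_gxe %.2f; carry %.2f (%s)\n",
              x$h2_yield, x$h2_protein, x$var_gxe, x$carry_fraction, x$select_on))
  cat(sprintf("  PYT grid %dx%d, %d checks x %d reps; %d MET locations\n",
              x$pyt_rows, x$pyt_cols, x$n_checks, x$check_reps,
              x$n_met_locations))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# trait means on their field scales (dt/ha, %); genetic sd is 1 by
# construction, so these just anchor the intercepts
trait_means <- c(yield = 60, protein = 14)

# residual sd for a target single-trial h2 with unit genetic variance
residual_sd_for_h2 <- function(h2) sqrt((1 - h2) / h2)
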