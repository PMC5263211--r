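# Field-trial phenotype simulation: a shared plot engine generates
# row x column grids with replicated checks; PYTs hold each test line once,
# METs replicate a cohort across locations with line-by-trial interaction.

# Check placement on an R x C grid: greedily covers every row and column
# with at least one check plot whenever n_plots >= max(R, C) (geometric
# feasibility), then fills least-occupied rows/columns with randomized
# tie-breaks (a regular pattern would disconnect or alias the row-column
# design). Deterministic under the caller's RNG state.
place_checks <- function(rows, cols, n_plots) {
  stopifnot(n_plots <= rows * cols)
  used <- matrix(FALSE, rows, cols)
  row_cover <- rep(FALSE, rows)
  col_cover <- rep(FALSE, cols)
  col_count <- rep(0L, cols)
  out <- matrix(0L, n_plots, 2L)
  shuffle <- function(x) if (length(x) > 1L) sample(x) else x
  for (i in seq_len(n_plots)) {
    cand_r <- c(shuffle(which(!row_cover)),
                order(rowSums(used) + stats::runif(rows)))
    placed <- FALSE
    for (r in cand_r) {
      free_c <- which(!used[r, ])
      if (!length(free_c)) next
      uncov <- free_c[!col_cover[free_c]]
      pool <- if (length(uncov)) uncov else free_c
      pool <- pool[col_count[pool] == min(col_count[pool])]
      cc <- if (length(pool) > 1L) sample(pool, 1L) else pool
      used[r, cc] <- TRUE
      row_cover[r] <- TRUE
      col_cover[cc] <- TRUE
      col_count[cc] <- col_count[cc] + 1L
      out[i, ] <- c(r, cc)
      placed <- TRUE
      break
    }
    if (!placed) stop("internal error: no free cell for check placement")
  }
  data.frame(row = out[, 1L], col = out[, 2L])
}

# One trial's plot records. `gxe` is a named per-line deviation (0 for PYT).
simulate_field_trial <- function(truth, lines, trial_id, year, stage,
                                 rows, cols, n_checks, check_reps,
                                 h2 = c(yield = 0.3, protein = 0.7),
                                 trial_effect = c(yield = 0, protein = 0),
                                 gxe = NULL,
                                 row_sd = 0, col_sd = 0) {
  check_ids <- truth$line_ids[truth$is_check][seq_len(n_checks)]
  n_cp <- n_checks * check_reps
  n_cells <- rows * cols
  if (n_cells < length(lines) + n_cp) {
    stop(sprintf("configuration error: grid %dx%d too small for %d plots",
                 rows, cols, length(lines) + n_cp), call. = FALSE)
  }
  chk <- place_checks(rows, cols, n_cp)
  # randomize which variety sits on which check plot: a deterministic
  # assignment would confound variety with the row/column pattern
  chk$line_id <- sample(rep(check_ids, length.out = n_cp))

  cell_key <- function(r, c) (r - 1L) * cols + c
  free <- setdiff(seq_len(n_cells), cell_key(chk$row, chk$col))
  test_cells <- sample(free, length(lines)) # random layout of test lines
  tst <- data.frame(row = (test_cells - 1L) %/% cols + 1L,
                    col = (test_cells - 1L) %% cols + 1L,
                    line_id = lines)

  plots <- rbind(cbind(chk, is_check = TRUE),
                 cbind(tst, is_check = FALSE))

  row_eff <- stats::rnorm(rows, 0, row_sd)
  col_eff <- stats::rnorm(cols, 0, col_sd)
  gxe <- gxe %||% stats::setNames(numeric(length(truth$line_ids)),
                                  truth$line_ids)

  out <- data.frame(line_id = plots$line_id,
                    trial_id = trial_id, year = year, stage = stage,
                    row = plots$row, col = plots$col,
                    is_check = plots$is_check,
                    stringsAsFactors = FALSE)
  for (tr in c("yield", "protein")) {
    e <- stats::rnorm(nrow(plots), 0, residual_sd_for_h2(h2[[tr]]))
    out[[tr]] <- trait_means[[tr]] + trial_effect[[tr]] +
      truth$true_bv[plots$line_id, tr] + gxe[plots$line_id] +
      row_eff[plots$row] + col_eff[plots$col] + e
  }
  rownames(out) <- NULL
  out
}

#' Simulate one year's unreplicated preliminary yield trial
#'
#' Each test line occupies a single plot on a `pyt_rows` x `pyt_cols`
#' grid; `n_checks` check varieties are replicated `check_reps` times and
#' spread so every row and column carries a check when geometrically
#' feasible. Phenotypes are `mean + true_bv + row + col + residual`, with
#' additive row/column trends of the configured magnitude and residual
#' variance set by the target single-trial heritability.
#'
#' @param truth a `truth_set` from [simulate_true_values()].
#' @param config a [sim_config()].
#' @param lines line ids tested (default: the first
#'   `n_lines_per_year` non-check lines).
#' @param year trial year.
#' @return plot-level `data.frame` (columns `line_id`, `trial_id`, `year`,
#'   `stage`, `row`, `col`, `is_check`, `yield`, `protein`).
#' @export
simulate_pyt <- function(truth, config, lines = NULL, year = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  lines <- lines %||%
    utils::head(truth$line_ids[!truth$is_check], config$n_lines_per_year)
  align_ids(lines, truth$line_ids, "true breeding values")
  set.seed(substream_seed(config$seed, paste0("pyt-", year)))
  year_eff <- stats::rnorm(2, 0, 0.5)
  simulate_field_trial(truth, lines,
                       trial_id = sprintf("PYT_y%02d", year),
                       year = year, stage = "PYT",
                       rows = config$pyt_rows, cols = config$pyt_cols,
                       n_checks = config$n_checks,
                       check_reps = config$check_reps,
                       h2 = c(yield = config$h2_yield,
                              protein = config$h2_protein),
                       trial_effect = c(yield = year_eff[1],
                                        protein = year_eff[2]),
                       row_sd = config$spatial_row_sd,
                       col_sd = config$spatial_col_sd)
}

#' Simulate one year's multi-environment trials
#'
#' The cohort is replicated across `n_met_locations` trials, each laid out
#' on its own grid with replicated checks. Phenotypes follow
#' `mean + true_bv + trial + line:trial + spatial + residual`; the
#' line-by-trial interaction has variance `var_gxe` and is drawn
#' independently per location, the residual variance follows the target
#' heritability.
#'
#' @inheritParams simulate_pyt
#' @return plot-level `data.frame` as in [simulate_pyt()], one block per
#'   location.
#' @export
simulate_met <- function(truth, config, lines = NULL, year = 2L) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  lines <- lines %||%
    utils::head(truth$line_ids[!truth$is_check], config$n_lines_per_year)
  align_ids(lines, truth$line_ids, "true breeding values")
  set.seed(substream_seed(config$seed, paste0("met-", year)))

  n_cp <- config$n_checks * config$met_check_reps
  n_cells <- length(lines) + n_cp
  rows <- max(2L, floor(sqrt(n_cells)))
  cols <- ceiling(n_cells / rows)

  out <- vector("list", config$n_met_locations)
  for (j in seq_len(config$n_met_locations)) {
    t_eff <- stats::rnorm(2, 0, 0.5)
    gxe <- stats::setNames(
      stats::rnorm(length(truth$line_ids), 0, sqrt(config$var_gxe)),
      truth$line_ids)
    out[[j]] <- simulate_field_trial(
      truth, lines,
      trial_id = sprintf("MET_y%02d_l%d", year, j),
      year = year, stage = "MET",
      rows = rows, cols = cols,
      n_checks = config$n_checks, check_reps = config$met_check_reps,
      h2 = c(yield = config$h2_yield, protein = config$h2_protein),
      trial_effect = c(yield = t_eff[1], protein = t_eff[2]),
      gxe = gxe,
      row_sd = config$spatial_row_sd, col_sd = config$spatial_col_sd)
  }
  do.call(rbind, out)
}

#' Simulate a complete multi-year breeding program
#'
#' Year `t` tests a fresh cohort of `n_lines_per_year` lines in a PYT; a
#' `carry_fraction` of the cohort — selected on the observed PYT yield by
#' default, reproducing selection-induced bias — is retested the next year
#' in METs. Families span cohorts, so training populations from earlier
#' years are genetically related to later selection candidates. Line
#' identifiers are stable across stages and the whole dataset is
#' deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return a `gas_program`: list with `config`, `genotypes`, `truth`,
#'   `trials` (plot records for all PYTs and METs), `cohorts`
#'   (`line_id`, `pyt_year`) and `met_lines` (list: MET year -> line ids).
#' @examples
#' prog <- simulate_program(sim_config(n_lines_per_year = 30, n_years = 3,
#'                                     n_markers = 80, pyt_rows = 6,
#'                                     pyt_cols = 10, seed = 7))
#' table(prog$trials$stage)
#' @export
simulate_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  geno_complete <- if (anyNA(geno)) impute_missing(geno, "mean") else geno
  truth <- simulate_true_values(geno_complete, config)

  nly <- config$n_lines_per_year
  test_ids <- truth$line_ids[!truth$is_check]
  cohorts <- data.frame(line_id = test_ids,
                        pyt_year = rep(seq_len(config$n_years), each = nly),
                        stringsAsFactors = FALSE)

  n_carry <- max(2L, round(config$carry_fraction * nly))
  trials <- vector("list", 2L * config$n_years)
  met_lines <- list()
  for (t in seq_len(config$n_years)) {
    cohort <- cohorts$line_id[cohorts$pyt_year == t]
    pyt <- simulate_pyt(truth, config, lines = cohort, year = t)
    trials[[2L * t - 1L]] <- pyt

    if (t < config$n_years) {
      obs <- pyt[!pyt$is_check, c("line_id", "yield")]
      sel <- switch(config$select_on,
        observed = obs$line_id[order(-obs$yield, obs$line_id)][seq_len(n_carry)],
        true = cohort[order(-truth$true_bv[cohort, "yield"],
                            cohort)][seq_len(n_carry)],
        random = {
          set.seed(substream_seed(config$seed, paste0("carry-", t)))
          sort(sample(cohort, n_carry))
        })
      met_lines[[as.character(t + 1L)]] <- sel
      trials[[2L * t]] <- simulate_met(truth, config, lines = sel,
                                       year = t + 1L)
    }
  }

  structure(list(config = config,
                 genotypes = geno,
                 truth = truth,
                 trials = do.call(rbind, trials[!vapply(trials, is.null,
                                                        logical(1))]),
                 cohorts = cohorts,
                 met_lines = met_lines),
            class = "gas_program")
}

#' @export
print.gas_program <- function(x, ...) {
  cat(sprintf("<gas_program> %d years, %d lines, %d markers, %d trials\n",
              x$config$n_years, nrow(x$cohorts), ncol(x$genotypes),
              length(unique(x$trials$trial_id))))
  invisible(x)
}
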