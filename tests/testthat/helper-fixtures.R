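# Shared fixtures: small configurations, a cached simulated program, and
# a hand-built toy trial grid with known spatial effects.

quick_config <- function(...) {
  args <- list(n_lines_per_year = 40L, n_years = 2L, n_families = 8L,
               n_markers = 120L, n_qtl = 50L,
               pyt_rows = 8L, pyt_cols = 11L,
               n_checks = 3L, check_reps = 8L, met_check_reps = 6L,
               seed = 101L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# memoised fixtures (simulating a multi-year program is the expensive part)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# a 5-year program large enough for the genomic comparison machinery
comparison_program <- function() {
  fixture("comparison_program", function() {
    simulate_program(sim_config(
      n_lines_per_year = 60L, n_years = 5L, n_families = 15L,
      n_markers = 200L, n_qtl = 80L, pyt_rows = 10L, pyt_cols = 11L,
      carry_fraction = 0.6, seed = 42L))
  })
}

comparison_analysis <- function() {
  fixture("comparison_analysis", function() {
    suppressWarnings(suppressMessages(
      prepare_program_analysis(comparison_program(), "yield")))
  })
}

# toy trial on an r x c grid: known additive row/column effects, one check
# variety replicated in every row/column, test lines on the free plots,
# zero noise unless a residual vector is supplied
make_toy_grid <- function(row_eff = c(2, 0, 0, -2),
                          col_eff = c(0, 0, 0, 0),
                          n_checks_per_row = 3L,
                          bv = NULL, mu = 10, resid = NULL) {
  r <- length(row_eff)
  cc <- length(col_eff)
  set.seed(7)
  pos <- place_checks(r, cc, r * n_checks_per_row)
  key <- paste(pos$row, pos$col)
  all_pos <- expand.grid(row = seq_len(r), col = seq_len(cc))
  free <- all_pos[!(paste(all_pos$row, all_pos$col) %in% key), ]
  n_test <- nrow(free)
  bv <- bv %||% seq_len(n_test)
  d <- rbind(
    data.frame(line_id = "CHK1", row = pos$row, col = pos$col,
               is_check = TRUE, g = 0),
    data.frame(line_id = sprintf("T%02d", seq_len(n_test)),
               row = free$row, col = free$col, is_check = FALSE, g = bv))
  d$trial_id <- "TOY"
  d$year <- 1L
  d$stage <- "PYT"
  resid <- resid %||% numeric(nrow(d))
  d$yield <- mu + d$g + row_eff[d$row] + col_eff[d$col] + resid
  d$protein <- d$yield
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
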