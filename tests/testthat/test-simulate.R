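# synthetic data module: genotypes, truth, trials, program assembly

test_that("genotype simulation is deterministic with the right shape and codes", {
  cfg <- quick_config(n_lines_per_year = 20L, n_years = 1L, n_markers = 50L,
                      pyt_rows = 7L, pyt_cols = 7L, seed = 1L)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(20L + cfg$n_checks, 50L))
  expect_true(all(g1 %in% c(-1, 0, 1)))
  # inbred-like: heterozygote frequency at most 5%
  expect_lte(mean(g1 == 0), 0.05)
})

test_that("families share haplotypes: within-family similarity beats the panel mean", {
  cfg <- quick_config(n_lines_per_year = 60L, n_years = 1L, n_families = 6L,
                      n_markers = 300L, pyt_rows = 10L, pyt_cols = 10L,
                      seed = 2L)
  g <- simulate_genotypes(cfg)
  fam <- attr(g, "family")
  test <- !attr(g, "is_check")
  cors <- stats::cor(t(g[test, ]))
  same <- outer(fam[test], fam[test], "==")
  diag(same) <- NA
  expect_gt(mean(cors[same & !is.na(same)]),
            mean(cors[upper.tri(cors)]))
  # and the kinship inherits the block pattern
  K <- genomic_relationship(g[test, ])$K
  diag(K) <- NA
  expect_gt(mean(K[same & !is.na(same)], na.rm = TRUE),
            mean(K[!same & !is.na(same)], na.rm = TRUE))
})

test_that("realized allele frequencies are spread over the interval", {
  g <- simulate_genotypes(quick_config(n_lines_per_year = 80L,
                                       pyt_rows = 10L, pyt_cols = 12L,
                                       n_markers = 400L, seed = 3L))
  p <- colMeans(g + 1) / 2
  expect_gt(mean(p > 0.05 & p < 0.95), 0.9)
  expect_gt(stats::sd(p), 0.15)
})

test_that("true breeding values reconstruct exactly from QTL effects", {
  cfg <- quick_config(seed = 4L)
  g <- simulate_genotypes(cfg)
  truth <- simulate_true_values(g, cfg)
  expect_equal(unname(truth$true_bv),
               unname(g[, truth$qtl_indices] %*% truth$qtl_effects),
               tolerance = 1e-12)
  # unit genetic variance by construction (within 10% trivially)
  expect_equal(unname(apply(truth$true_bv, 2, stats::var)), c(1, 1),
               tolerance = 1e-8)
  # null genetics and single-locus cases
  expect_equal(unname(truth_from_effects(g, c(1L, 5L),
                                         matrix(0, 2, 1))[, 1]),
               rep(0, nrow(g)))
  one <- truth_from_effects(g, 3L, matrix(1, 1, 1))
  expect_equal(unname(one[, 1]), unname(g[, 3L]))
})

test_that("n_qtl larger than the panel is a configuration error", {
  cfg <- quick_config(seed = 5L)
  g <- simulate_genotypes(cfg)
  expect_error(sim_config(n_qtl = 200L, n_markers = 100L), "n_qtl")
  cfg2 <- cfg
  cfg2$n_qtl <- ncol(g) + 1L
  expect_error(simulate_true_values(g, cfg2), "n_qtl")
})

test_that("PYT layout: counts, uniqueness, and check coverage", {
  cfg <- quick_config(n_checks = 3L, check_reps = 8L, seed = 6L)
  g <- simulate_genotypes(cfg)
  truth <- simulate_true_values(g, cfg)
  p <- simulate_pyt(truth, cfg)
  expect_equal(sum(p$is_check), 24L) # n_checks * check_reps
  tst <- p[!p$is_check, ]
  expect_equal(anyDuplicated(tst$line_id), 0L)
  expect_equal(anyDuplicated(p[, c("row", "col")]), 0L)
  chk <- p[p$is_check, ]
  # 24 check plots on an 8 x 11 grid: feasible to cover all rows and cols
  expect_setequal(unique(chk$row), seq_len(cfg$pyt_rows))
  expect_setequal(unique(chk$col), seq_len(cfg$pyt_cols))
  expect_error(simulate_pyt(truth, cfg,
                            lines = truth$line_ids[!truth$is_check]),
               "grid")
})

test_that("without spatial trends and noise the PYT reproduces the breeding values", {
  cfg <- quick_config(h2_yield = 0.999, spatial_row_sd = 0,
                      spatial_col_sd = 0, seed = 7L)
  g <- simulate_genotypes(cfg)
  truth <- simulate_true_values(g, cfg)
  p <- simulate_pyt(truth, cfg)
  tst <- p[!p$is_check, ]
  bv <- truth$true_bv[tst$line_id, "yield"]
  expect_gt(stats::cor(tst$yield, bv), 0.995)
  expect_lt(max(abs((tst$yield - mean(tst$yield)) - (bv - mean(bv)))), 0.2)
})

test_that("noiseless MET per-trial BLUEs correlate 1 with truth", {
  cfg <- quick_config(h2_yield = 0.999, var_gxe = 0, spatial_row_sd = 0,
                      spatial_col_sd = 0, seed = 8L)
  g <- simulate_genotypes(cfg)
  truth <- simulate_true_values(g, cfg)
  m <- simulate_met(truth, cfg, lines = utils::head(truth$line_ids, 30L))
  s1 <- suppressMessages(suppressWarnings(stage_one(m, "yield")))
  for (tid in unique(s1$blues$trial_id)) {
    b <- s1$blues[s1$blues$trial_id == tid & !s1$blues$is_check, ]
    expect_gt(stats::cor(b$blue, truth$true_bv[b$line_id, "yield"]), 0.99)
  }
})

test_that("line-by-trial interaction decorrelates trials monotonically", {
  mean_cor <- function(vg) {
    r <- vapply(1:4, function(s) {
      cfg <- quick_config(var_gxe = vg, h2_yield = 0.9, spatial_row_sd = 0,
                          spatial_col_sd = 0, n_met_locations = 2L,
                          seed = 100L + s)
      g <- simulate_genotypes(cfg)
      truth <- simulate_true_values(g, cfg)
      m <- simulate_met(truth, cfg, lines = utils::head(truth$line_ids, 40L))
      tst <- m[!m$is_check, ]
      wide <- stats::reshape(tst[, c("line_id", "trial_id", "yield")],
                             idvar = "line_id", timevar = "trial_id",
                             direction = "wide")
      stats::cor(wide[[2L]], wide[[3L]])
    }, 0)
    mean(r)
  }
  cors <- vapply(c(0, 1, 4), mean_cor, 0)
  expect_true(all(diff(cors) < 0))
})

test_that("realized single-trial heritability is centred on the target", {
  # Piepho-Moehring h2 estimated per replicate trial is individually noisy
  # (unreplicated entries, error df limited by the checks), so the band is
  # asserted for the replicate mean; squared accuracy against the true
  # breeding values is the stable realized-heritability measure.
  h2s <- vapply(1:20, function(s) {
    cfg <- sim_config(n_lines_per_year = 400L, n_years = 1L,
                      n_markers = 150L, n_qtl = 60L,
                      pyt_rows = 18L, pyt_cols = 28L,
                      n_checks = 4L, check_reps = 25L, seed = 300L + s)
    g <- simulate_genotypes(cfg)
    truth <- simulate_true_values(g, cfg)
    p <- simulate_pyt(truth, cfg)
    bt <- suppressMessages(suppressWarnings(adjust_spatial(p, "yield")))
    trial_report(bt)$h2_piepho
  }, 0)
  expect_gt(mean(h2s), 0.15)
  expect_lt(mean(h2s), 0.45)
  expect_true(all(h2s >= 0 & h2s <= 0.8))
})

test_that("realized heritability converges to the configured value at large n", {
  cfg <- sim_config(n_lines_per_year = 2000L, n_years = 1L,
                    n_markers = 300L, n_qtl = 100L,
                    pyt_rows = 42L, pyt_cols = 50L,
                    n_checks = 4L, check_reps = 20L,
                    spatial_row_sd = 0, spatial_col_sd = 0, seed = 11L)
  g <- simulate_genotypes(cfg)
  truth <- simulate_true_values(g, cfg)
  p <- simulate_pyt(truth, cfg)
  tst <- p[!p$is_check, ]
  realized <- stats::cor(tst$yield, truth$true_bv[tst$line_id, "yield"])^2
  expect_lt(abs(realized - cfg$h2_yield), 0.05)
})

test_that("program assembly: cohorts, carry-over, selection and determinism", {
  cfg <- quick_config(n_lines_per_year = 30L, n_years = 3L,
                      pyt_rows = 8L, pyt_cols = 8L,
                      carry_fraction = 1.0, seed = 12L)
  prog <- simulate_program(cfg)
  expect_equal(length(unique(prog$cohorts$line_id)), 90L)
  # carry_fraction = 1: every PYT line (except the final cohort) is retested
  for (t in 1:2) {
    cohort <- prog$cohorts$line_id[prog$cohorts$pyt_year == t]
    expect_setequal(prog$met_lines[[as.character(t + 1L)]], cohort)
  }
  prog2 <- simulate_program(cfg)
  expect_identical(prog$trials, prog2$trials)
  expect_identical(prog$genotypes, prog2$genotypes)

  # truncation selection on the true value raises the MET cohort mean
  cfg_sel <- quick_config(n_lines_per_year = 30L, n_years = 2L,
                          pyt_rows = 8L, pyt_cols = 8L,
                          carry_fraction = 0.5, select_on = "true",
                          seed = 13L)
  ps <- simulate_program(cfg_sel)
  sel <- ps$met_lines[["2"]]
  cohort <- ps$cohorts$line_id[ps$cohorts$pyt_year == 1L]
  expect_gt(mean(ps$truth$true_bv[sel, "yield"]),
            mean(ps$truth$true_bv[cohort, "yield"]))
  expect_error(sim_config(carry_fraction = 0), "carry_fraction")
  expect_error(sim_config(carry_fraction = 1.2), "carry_fraction")
})
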