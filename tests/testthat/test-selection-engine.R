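# prediction scaling, heritability index, adjusted weight, sign-change
# marker selection, training designs, hit rates

test_that("scaling centers and normalizes by the chosen convention", {
  x <- c(a = 1, b = 2, c = 3)
  s <- scale_predictions(x)
  expect_equal(unname(s), c(-1, 0, 1), tolerance = 1e-4)
  expect_equal(unname(round(s, 4)), c(-1, 0, 1)) # sd of 1,2,3 is exactly 1
  expect_lt(abs(mean(scale_predictions(rnorm(50)))), 1e-12)
  # affine invariance
  set.seed(71)
  z <- rnorm(30)
  expect_equal(scale_predictions(3.7 * z + 11), scale_predictions(z),
               tolerance = 1e-10)
  # literal division by the variance is available for fidelity
  expect_equal(unname(scale_predictions(c(1, 2, 3) * 2, "variance")),
               c(-0.5, 0, 0.5))
  expect_error(scale_predictions(rep(4, 5)), "constant")
})

test_that("the heritability index is exact bookkeeping of its components", {
  set.seed(72)
  ids <- sprintf("L%02d", 1:40)
  gp <- stats::setNames(rnorm(40), ids)
  kp <- stats::setNames(rnorm(40), ids)
  idx <- heritability_index(gp, kp, h2_gblup = 0.35, h2_kblup = 0.12)
  expect_equal(idx$gebv_index,
               idx$gblup_scaled * idx$w_gblup + idx$kblup_scaled * idx$w_kblup)
  expect_lt(abs(mean(idx$gblup_scaled)), 1e-12)
  expect_lt(abs(mean(idx$kblup_scaled)), 1e-12)
  # degenerate KBLUP weight reduces to the GBLUP ranking
  idx0 <- heritability_index(gp, kp, h2_gblup = 0.4, h2_kblup = 0)
  expect_equal(stats::cor(idx0$gebv_index, gp[idx0$line_id],
                          method = "spearman"), 1)
  # exact cancellation
  idxc <- heritability_index(gp, stats::setNames(-gp, ids),
                             h2_gblup = 0.3, h2_kblup = 0.3)
  expect_equal(idxc$gebv_index, rep(0, 40), tolerance = 1e-12)
  expect_error(heritability_index(gp, kp[-1], 0.3, 0.3), "mismatch")
})

test_that("the adjusted GBLUP weight follows the closed form", {
  expect_equal(adjusted_gblup_weight(0.4, 0.5), 0.8)
  expect_equal(adjusted_gblup_weight(0.4, 0), 0.4) # reduces to plain h2
  expect_equal(adjusted_gblup_weight(0.4, -0.5),
               adjusted_gblup_weight(0.4, 0.5)) # absolute value
  expect_error(adjusted_gblup_weight(0.4, 1), "unbounded")
  expect_error(adjusted_gblup_weight(1.2, 0.2), "strictly")
})

test_that("sign-change selection keeps agreeing markers", {
  u <- c(m1 = 0.5, m2 = -0.2, m3 = 0.1, m4 = 0)
  expect_equal(select_markers_sign(u, u), names(u), ignore_attr = TRUE)
  expect_equal(attr(select_markers_sign(u, u), "fraction_removed"), 0)
  # total disagreement empties the panel and downstream construction fails
  v <- -u[c("m1", "m2", "m3")]
  retained <- select_markers_sign(u[1:3], v)
  expect_length(retained, 0L)
  g <- matrix(1, 4, 3, dimnames = list(paste0("L", 1:4), names(u)[1:3]))
  expect_error(genomic_relationship(g[, retained, drop = FALSE]))
  # zero effects: retained by default, droppable by rule
  w <- c(m1 = 1, m2 = 1, m3 = 1, m4 = 1)
  expect_true("m4" %in% select_markers_sign(u, w))
  expect_false("m4" %in% select_markers_sign(u, w, zero_rule = "drop"))
  expect_error(select_markers_sign(u, u[1:2]), "same marker panel")
})

test_that("independent effects disagree in sign for about half the markers", {
  set.seed(73)
  n <- 100L
  m <- 400L
  z <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("L%03d", 1:n), sprintf("M%03d", 1:m)))
  y1 <- stats::setNames(rnorm(n), rownames(z))
  y2 <- stats::setNames(rnorm(n), rownames(z))
  f1 <- fit_rrblup(y1, z)
  f2 <- fit_rrblup(y2, z)
  retained <- select_markers_sign(f1$u, f2$u)
  frac <- attr(retained, "fraction_removed")
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
})

test_that("refitting orthogonal noise-free markers never flips a sign", {
  # Hadamard columns are mutually orthogonal and orthogonal to the
  # intercept, so dropping markers leaves the others' effects untouched
  h2m <- matrix(c(1, 1, 1, -1), 2)
  H <- h2m
  for (i in 1:3) H <- kronecker(H, h2m)
  z <- H[, 2:11]
  dimnames(z) <- list(sprintf("L%02d", 1:16), sprintf("M%02d", 1:10))
  u_a <- c(3, -2, 1.5, -1, 2, 1, -1.5, 0.5, 1, -2)
  u_b <- u_a * c(1, 1, 1, 1, 1, -1, -1, 1, 1, 1) # two flipped signs
  ya <- stats::setNames(drop(z %*% u_a), rownames(z))
  yb <- stats::setNames(drop(z %*% u_b), rownames(z))
  fa <- fit_rrblup(ya, z)
  fb <- fit_rrblup(yb, z)
  retained <- select_markers_sign(fa$u, fb$u)
  expect_setequal(retained, colnames(z)[-(6:7)])
  expect_equal(refit_sign_fraction(ya, z, yb, z, retained), 0)
})

test_that("a single retained marker gives a degenerate 0/1 fraction", {
  set.seed(74)
  z <- matrix(sample(c(-1, 1), 12 * 5, replace = TRUE), 12, 5,
              dimnames = list(sprintf("L%02d", 1:12), sprintf("M%02d", 1:5)))
  y1 <- stats::setNames(z[, 1] + rnorm(12, 0, 0.1), rownames(z))
  y2 <- stats::setNames(z[, 1] + rnorm(12, 0, 0.1), rownames(z))
  fr <- refit_sign_fraction(y1, z, y2, z, "M01")
  expect_true(fr %in% c(0, 1))
  expect_error(refit_sign_fraction(y1, z, y2, z, character(0)), "empty")
})

test_that("sign selection reduces discordance on correlated signal", {
  fracs <- vapply(1:3, function(s) {
    cfg <- quick_config(n_lines_per_year = 60L, n_markers = 200L,
                        n_families = 8L, pyt_rows = 9L, pyt_cols = 10L,
                        seed = 800L + s)
    g <- simulate_genotypes(cfg)
    truth <- simulate_true_values(g, cfg)
    ids <- rownames(g)[!attr(g, "is_check")]
    set.seed(s)
    bv <- truth$true_bv[ids, "yield"]
    y1 <- stats::setNames(bv + rnorm(length(ids), 0, 1.5), ids)
    y2 <- stats::setNames(bv + rnorm(length(ids), 0, 1.5), ids)
    f1 <- fit_rrblup(y1, g[ids, ])
    f2 <- fit_rrblup(y2, g[ids, ])
    retained <- select_markers_sign(f1$u, f2$u)
    pre <- attr(retained, "fraction_removed")
    post <- refit_sign_fraction(y1, g[ids, ], y2, g[ids, ], retained)
    post - pre
  }, 0)
  expect_lt(mean(fracs), 0)
})

test_that("two-tailed sampling takes the distribution extremes deterministically", {
  pheno <- data.frame(line_id = c("w", "x", "y", "z"), year = 1,
                      value = c(1, 5, 3, 9))
  ts <- two_tailed_sample(pheno, 2L)
  expect_setequal(ts$sampled_ids, c("z", "w"))
  # ties broken by line id
  pheno2 <- data.frame(line_id = c("b", "a", "c", "d"), year = 1,
                       value = c(2, 2, 0, 5))
  expect_setequal(two_tailed_sample(pheno2, 2L)$sampled_ids, c("d", "c"))
  # random mode is reproducible under the seed
  pheno3 <- data.frame(line_id = sprintf("L%02d", 1:12),
                       year = rep(1:2, each = 6), value = rnorm(12))
  r1 <- two_tailed_sample(pheno3, 3L, mode = "random", seed = 5L)
  r2 <- two_tailed_sample(pheno3, 3L, mode = "random", seed = 5L)
  expect_identical(r1$sampled_ids, r2$sampled_ids)
  expect_error(two_tailed_sample(pheno, 7L), "fewer")
})

test_that("the two-tailed pair maximizes the variance over all equal-size subsets", {
  vals <- c(3.2, -1.5, 0.7, 9.1, 4.4, -2.8)
  pheno <- data.frame(line_id = sprintf("L%d", 1:6), year = 1, value = vals)
  tt <- two_tailed_sample(pheno, 2L)
  v_tt <- stats::var(pheno$value[pheno$line_id %in% tt$sampled_ids])
  all_pairs <- utils::combn(6, 2)
  v_all <- apply(all_pairs, 2, function(ix) stats::var(vals[ix]))
  expect_equal(v_tt, max(v_all))
  # for larger subsets two-tailed dominates the random expectation (the
  # maximum over all subsets is not guaranteed beyond pairs)
  tt4 <- two_tailed_sample(pheno, 4L)
  v_tt4 <- stats::var(pheno$value[pheno$line_id %in% tt4$sampled_ids])
  v4 <- apply(utils::combn(6, 4), 2, function(ix) stats::var(vals[ix]))
  expect_gte(v_tt4, mean(v4))
})

test_that("three-year combinations enumerate correctly at fixed size", {
  set.seed(76)
  pheno <- data.frame(line_id = sprintf("L%03d", 1:350),
                      year = rep(1:5, each = 70), value = rnorm(350))
  designs <- three_year_training_sets(pheno, selection_year = 5L,
                                      lines_per_year = 60L)
  expect_length(designs, 4L) # C(4, 3)
  for (d in designs) {
    expect_length(d$sampled_ids, 180L)
    expect_length(attr(d, "combo"), 3L)
  }
  # 3 remaining years: a single combination
  d3 <- three_year_training_sets(pheno[pheno$year < 5, ], 4L,
                                 lines_per_year = 10L)
  expect_length(d3, 1L)
  expect_error(three_year_training_sets(pheno[pheno$year < 4, ], 3L),
               ">= 3")
})

test_that("hit rates: perfect, anti and domain behaviour", {
  x <- stats::setNames(1:10, sprintf("L%02d", 1:10))
  for (q in c(0.1, 0.2, 0.5)) {
    expect_equal(unname(top_bottom_hit_rate(x, x, q)), c(1, 1))
  }
  anti <- top_bottom_hit_rate(stats::setNames(-as.numeric(x), names(x)),
                              x, 0.5)
  expect_equal(unname(anti), c(0, 0))
  expect_error(top_bottom_hit_rate(x, x, 0.6), "0.5")
  expect_error(top_bottom_hit_rate(x, x, 0), "0.5")
  expect_error(top_bottom_hit_rate(x, x[-1], 0.2), "identical")
  expect_error(top_bottom_hit_rate(x, x, 0.05), "zero")
})
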