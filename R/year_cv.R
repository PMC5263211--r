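#' Year-fold and leave-one-year-out cross-validation curves
#'
#' Reproduces the two evaluation geometries used to study training
#' population design:
#'
#' * `"year_fold"` — every MET year is a fold; its lines form the
#'   selection population and the training population samples
#'   `sizes` lines from each remaining year, either at random or
#'   two-tailed. Both design arms of a fold share the identical selection
#'   population.
#' * `"loyo"` — leave one year out entirely; the training population
#'   samples a `fractions` proportion of each remaining year's lines.
#'
#' GBLUP models with year fixed effects are fitted per fold and the
#' accuracy is the Pearson correlation between predictions and the fold
#' year's across-trial MET BLUEs.
#'
#' @param program a `gas_program`.
#' @param sizes lines per training year for the year-fold geometry.
#' @param fractions sampling proportions for the leave-one-year-out
#'   geometry.
#' @param geometry one or both of `"year_fold"`, `"loyo"`.
#' @param trait trait analyzed.
#' @param seed sampling seed.
#' @param analysis optional precomputed [prepare_program_analysis()].
#' @return data.frame `geometry`, `fold_year`, `size` (lines/year or
#'   fraction), `design`, `accuracy`, `n_train`, `n_validation`.
#' @export
year_fold_cv <- function(program, sizes = c(20L, 40L, 60L),
                         fractions = seq(0.2, 0.9, by = 0.1),
                         geometry = c("year_fold", "loyo"),
                         trait = "yield", seed = NULL, analysis = NULL) {
  geometry <- match.arg(geometry, several.ok = TRUE)
  seed <- seed %||% program$config$seed %||% 1L
  an <- analysis %||% prepare_program_analysis(program, trait)
  mb <- an$met_blues
  years <- sort(unique(mb$year))
  if (length(years) < 2L) {
    stop("cross-validation needs at least 2 MET years", call. = FALSE)
  }
  Km <- an$K
  rows <- list()

  fit_acc <- function(train, valid) {
    y_tr <- stats::setNames(train$blue, train$line_id)
    fit <- fit_gblup(y_tr, Km, fixed_design = year_design(train$year))
    stats::cor(fit$pred[valid$line_id], valid$blue)
  }

  for (fy in years) {
    valid <- mb[mb$year == fy, , drop = FALSE]
    pool <- mb[mb$year != fy, , drop = FALSE]
    pheno <- data.frame(line_id = pool$line_id, year = pool$year,
                        value = pool$blue, stringsAsFactors = FALSE)
    year_sizes <- table(pool$year)

    if ("year_fold" %in% geometry) {
      for (n in sizes) {
        if (n > min(year_sizes)) {
          warning(sprintf(
            "fold %s: %d lines/year exceeds smallest year (%d); skipped",
            fy, n, min(year_sizes)), call. = FALSE)
          next
        }
        for (dsg in c("random", "two_tailed")) {
          ts <- two_tailed_sample(pheno, n, mode = dsg,
                                  seed = substream_seed(seed,
                                                        paste0("yf-", fy)))
          train <- pool[pool$line_id %in% ts$sampled_ids, , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            geometry = "year_fold", fold_year = fy, size = n, design = dsg,
            accuracy = fit_acc(train, valid),
            n_train = nrow(train), n_validation = nrow(valid),
            stringsAsFactors = FALSE)
        }
      }
    }
    if ("loyo" %in% geometry) {
      for (fr in fractions) {
        ns <- floor(fr * min(year_sizes))
        if (ns < 2L) {
          warning(sprintf("fold %s: fraction %.2f leaves < 2 lines; skipped",
                          fy, fr), call. = FALSE)
          next
        }
        for (dsg in c("random", "two_tailed")) {
          ts <- two_tailed_sample(pheno, ns, mode = dsg,
                                  seed = substream_seed(seed,
                                                        paste0("loyo-", fy)))
          train <- pool[pool$line_id %in% ts$sampled_ids, , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            geometry = "loyo", fold_year = fy, size = fr, design = dsg,
            accuracy = fit_acc(train, valid),
            n_train = nrow(train), n_validation = nrow(valid),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
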