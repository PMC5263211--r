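#' Sample a training population per year
#'
#' `mode = "two_tailed"` deterministically takes the `ceil(n/2)` highest
#' and `floor(n/2)` lowest lines of each year's phenotype distribution
#' (ties broken by line id), maximizing the training phenotypic variance;
#' `mode = "random"` samples uniformly without replacement under the
#' given seed.
#'
#' @param pheno data.frame with `line_id`, `year`, `value`.
#' @param n_per_year lines sampled from each year.
#' @param mode `"two_tailed"` or `"random"`.
#' @param seed integer seed for the random mode (substreamed per year).
#' @return list of class `gas_training_design`: `design`,
#'   `lines_per_year`, `years`, `by_year` (list of ids), `sampled_ids`.
#' @export
two_tailed_sample <- function(pheno, n_per_year,
                              mode = c("two_tailed", "random"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("line_id", "year", "value") %in% names(pheno)))
  n_per_year <- assert_count(n_per_year, "n_per_year")
  years <- sort(unique(pheno$year))
  by_year <- vector("list", length(years))
  names(by_year) <- as.character(years)
  for (yy in years) {
    d <- pheno[pheno$year == yy, , drop = FALSE]
    if (nrow(d) < n_per_year) {
      stop(sprintf("year %s has %d lines, fewer than n_per_year = %d",
                   yy, nrow(d), n_per_year), call. = FALSE)
    }
    ids <- if (mode == "two_tailed") {
      ord <- d$line_id[order(-d$value, d$line_id)]
      n_top <- ceiling(n_per_year / 2)
      n_bot <- floor(n_per_year / 2)
      c(utils::head(ord, n_top),
        if (n_bot > 0) rev(utils::tail(ord, n_bot)) else character(0))
    } else {
      set.seed(substream_seed(seed, paste0("sample-", yy)))
      sample(d$line_id, n_per_year)
    }
    by_year[[as.character(yy)]] <- ids
  }
  structure(list(design = mode, lines_per_year = n_per_year,
                 years = years, by_year = by_year,
                 sampled_ids = unlist(by_year, use.names = FALSE)),
            class = "gas_training_design")
}

#' @export
print.gas_training_design <- function(x, ...) {
  cat(sprintf("<gas_training_design:%s> %d lines (%d/year from years %s)\n",
              x$design, length(x$sampled_ids), x$lines_per_year,
              paste(x$years, collapse = ", ")))
  invisible(x)
}

#' All three-year training populations for one selection year
#'
#' Enumerates every 3-subset of the years available for training (the
#' years in which the selection population's lines do not occur) and
#' samples `lines_per_year` lines from each year of the combination —
#' with 4 remaining years this yields 4 training populations of
#' `3 * lines_per_year` lines, the fixed-size design used for comparing
#' selection methods.
#'
#' @param pheno data.frame `line_id`, `year`, `value` of candidate
#'   training lines.
#' @param selection_year the year being predicted (excluded from
#'   training).
#' @param lines_per_year lines drawn per training year (default 60).
#' @param design sampling mode, see [two_tailed_sample()].
#' @param seed seed for random sampling.
#' @return named list of `gas_training_design` objects, one per year
#'   combination; each carries attribute `combo` (its years).
#' @export
three_year_training_sets <- function(pheno, selection_year,
                                     lines_per_year = 60L,
                                     design = c("two_tailed", "random"),
                                     seed = 1L) {
  design <- match.arg(design)
  years <- setdiff(sort(unique(pheno$year)), selection_year)
  if (length(years) < 3L) {
    stop(sprintf("need >= 3 non-selection years, have %d", length(years)),
         call. = FALSE)
  }
  combos <- utils::combn(years, 3L, simplify = FALSE)
  out <- vector("list", length(combos))
  names(out) <- vapply(combos, paste, "", collapse = "+")
  for (i in seq_along(combos)) {
    sub <- pheno[pheno$year %in% combos[[i]], , drop = FALSE]
    ts <- two_tailed_sample(sub, lines_per_year, mode = design, seed = seed)
    attr(ts, "combo") <- combos[[i]]
    out[[i]] <- ts
  }
  out
}
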