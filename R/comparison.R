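# End-to-end method comparison on a simulated (or loaded) program:
# stage-one adjustment -> trial filter -> stage-two MET BLUEs ->
# phenotypic BLUP / KBLUP / GBLUP / heritability index / marker-selected
# index, evaluated by correlating predictions for retested lines with
# their next-year across-trial MET BLUEs.

year_design <- function(years_vec) {
  lev <- sort(unique(years_vec))
  X <- cbind(`(Intercept)` = rep(1, length(years_vec)))
  if (length(lev) > 1L) X <- cbind(X, contr_sum_cols(years_vec, lev, "y"))
  X
}

#' Prepare a program for prediction and comparison
#'
#' Runs marker QC and imputation, builds the genomic relationship matrix,
#' performs the stage-one spatial adjustment of every trial, applies the
#' heritability filter to the MET trials (if fewer than two trials of a
#' year pass, all of that year's trials are kept with a warning so the
#' year remains analyzable), and computes stage-two across-trial BLUEs
#' per MET year.
#'
#' @param program a `gas_program` (or a compatible list with `genotypes`
#'   and `trials`).
#' @param trait `"yield"` or `"protein"`.
#' @param h2_min strict heritability threshold for forwarding MET trials.
#' @param maf_min,call_rate_min,missing_max QC thresholds, see
#'   [qc_filter_markers()].
#' @return list of class `gas_analysis`: `markers`, `K`, `reports`
#'   (per-trial heritabilities), `pyt_blues` (list PYT year -> BLUE
#'   table), `met_blues` (data.frame `line_id`, `year`, `blue`),
#'   `trait`.
#' @export
prepare_program_analysis <- function(program, trait = "yield", h2_min = 0.3,
                                     maf_min = 0.05, call_rate_min = 0.90,
                                     missing_max = 0.10) {
  trials <- program$trials
  stopifnot(is.data.frame(trials), trait %in% names(trials))
  markers <- qc_filter_markers(program$genotypes, call_rate_min, maf_min,
                               missing_max)
  if (anyNA(markers)) markers <- impute_missing(markers, "mean")
  K <- genomic_relationship(markers)

  parts <- split(trials, trials$trial_id)
  blues <- lapply(parts, adjust_spatial, trait = trait)
  reports <- do.call(rbind, lapply(blues, trial_report))
  rownames(reports) <- NULL
  stage_of <- vapply(parts, function(p) p$stage[1L], "")
  year_of <- vapply(parts, function(p) p$year[1L], 0)

  pyt_blues <- list()
  for (tid in names(parts)[stage_of == "PYT"]) {
    pyt_blues[[as.character(year_of[[tid]])]] <- blues[[tid]]
  }

  met_ids <- names(parts)[stage_of == "MET"]
  met_blues <- NULL
  for (yy in sort(unique(year_of[met_ids]))) {
    ids_year <- met_ids[year_of[met_ids] == yy]
    rep_year <- reports[reports$trial_id %in% ids_year, , drop = FALSE]
    keep <- filter_trials(rep_year, h2_min)
    if (length(keep) < 2L) {
      warning(sprintf(
        "MET year %s: %d trial(s) pass h2 > %.2f; using all %d trials",
        yy, length(keep), h2_min, length(ids_year)), call. = FALSE)
      keep <- ids_year
    }
    byear <- do.call(rbind, blues[keep])
    at <- across_trial_blues(byear[!byear$is_check, , drop = FALSE])
    met_blues <- rbind(met_blues,
                       data.frame(line_id = at$line_id, year = yy,
                                  blue = at$blue,
                                  stringsAsFactors = FALSE))
  }
  structure(list(markers = markers, K = K, reports = reports,
                 pyt_blues = pyt_blues, met_blues = met_blues,
                 trait = trait),
            class = "gas_analysis")
}

#' Compare selection methods by across-year prediction accuracy
#'
#' For every selection year `t` whose PYT cohort is retested in MET year
#' `t + 1`, predicts the retested lines by each requested method and
#' correlates the predictions with the next-year across-trial MET BLUEs:
#'
#' * `blup` — the line's own adjusted PYT value (conventional phenotypic
#'   selection);
#' * `kblup` — kinship-enhanced BLUP of the whole PYT cohort;
#' * `gblup` — genomic prediction trained on the MET BLUEs of
#'   three-year training populations in which the candidates never occur
#'   (their phenotypes from both the PYT year and the MET are excluded
#'   from training by construction);
#' * `index` — heritability-weighted merge of the scaled GBLUP and KBLUP
#'   predictions;
#' * `index_marker_sel` — the index after sign-change marker
#'   pre-selection on the GBLUP side, with the GBLUP weight inflated by
#'   `h2 / (1 - |r|)`.
#'
#' @param program a `gas_program`.
#' @param methods subset of
#'   `c("blup", "kblup", "gblup", "index", "index_marker_sel")`.
#' @param trait trait analyzed.
#' @param lines_per_year training lines sampled per year (capped at the
#'   smallest year size with a message).
#' @param design training sampling mode, see [two_tailed_sample()].
#' @param h2_min MET trial heritability gate.
#' @param seed seed for random training sampling.
#' @param analysis optional precomputed [prepare_program_analysis()]
#'   result (must match `trait`).
#' @return list of class `gas_comparison`: `results` (one row per
#'   selection year x training combination x method with the fold
#'   accuracy), `predictions` (per fold: named prediction vectors and the
#'   observed BLUEs, for hit-rate analysis), `summary` (mean +/- SE per
#'   method).
#' @export
run_method_comparison <- function(program,
                                  methods = c("blup", "kblup", "gblup",
                                              "index", "index_marker_sel"),
                                  trait = "yield",
                                  lines_per_year = 60L,
                                  design = c("two_tailed", "random"),
                                  h2_min = 0.3,
                                  seed = NULL,
                                  analysis = NULL) {
  design <- match.arg(design)
  if (!length(methods)) stop("empty method list", call. = FALSE)
  methods <- match.arg(methods, c("blup", "kblup", "gblup", "index",
                                  "index_marker_sel"), several.ok = TRUE)
  seed <- seed %||% program$config$seed %||% 1L
  an <- analysis %||% prepare_program_analysis(program, trait, h2_min)
  stopifnot(identical(an$trait, trait))

  met_years <- sort(unique(an$met_blues$year))
  pyt_years <- as.integer(names(an$pyt_blues))
  needs_genomic <- any(methods %in% c("gblup", "index", "index_marker_sel"))

  results <- list()
  predictions <- list()
  Km <- an$K

  for (t in sort(pyt_years)) {
    if (!((t + 1L) %in% met_years)) next
    pyt_bt <- an$pyt_blues[[as.character(t)]]
    cohort <- pyt_bt$line_id[!pyt_bt$is_check]
    obs_all <- an$met_blues[an$met_blues$year == t + 1L, , drop = FALSE]
    cand <- intersect(cohort, obs_all$line_id)
    if (length(cand) < 5L) {
      warning(sprintf("selection year %d: only %d retested lines; skipped",
                      t, length(cand)), call. = FALSE)
      next
    }
    observed <- stats::setNames(
      obs_all$blue[match(cand, obs_all$line_id)], cand)

    fold_preds <- list(observed = observed)
    add_row <- function(combo, method, pred) {
      results[[length(results) + 1L]] <<- data.frame(
        selection_year = t, combo = combo, method = method,
        accuracy = stats::cor(pred[cand], observed),
        n = length(cand), stringsAsFactors = FALSE)
    }

    blup_pred <- stats::setNames(
      pyt_bt$blue[match(cand, pyt_bt$line_id)], cand)
    if ("blup" %in% methods) {
      add_row(NA_character_, "blup", blup_pred)
      fold_preds$blup <- blup_pred
    }

    kb <- NULL
    if (any(methods %in% c("kblup", "index", "index_marker_sel"))) {
      kb <- kblup(pyt_bt, Km)
      if ("kblup" %in% methods) {
        add_row(NA_character_, "kblup", kb$bv)
        fold_preds$kblup <- kb$bv[cand]
      }
    }

    run_genomic <- needs_genomic
    if (needs_genomic) {
      train_pool <- an$met_blues[an$met_blues$year != t + 1L, , drop = FALSE]
      train_pool <- train_pool[!(train_pool$line_id %in% cohort), ,
                               drop = FALSE]
      if (length(unique(train_pool$year)) < 3L) {
        warning(sprintf(
          "selection year %d: %d training year(s) < 3; genomic methods skipped",
          t, length(unique(train_pool$year))), call. = FALSE)
        run_genomic <- FALSE
      }
    }
    if (run_genomic) {
      sizes <- table(train_pool$year)
      lpy <- min(lines_per_year, min(sizes))
      if (lpy < lines_per_year) {
        message(sprintf(
          "selection year %d: training lines per year capped at %d", t, lpy))
      }
      designs <- three_year_training_sets(
        data.frame(line_id = train_pool$line_id, year = train_pool$year,
                   value = train_pool$blue, stringsAsFactors = FALSE),
        selection_year = t + 1L, lines_per_year = lpy, design = design,
        seed = substream_seed(seed, paste0("train-", t)))

      for (ci in seq_along(designs)) {
        ts <- designs[[ci]]
        combo <- names(designs)[ci]
        tr <- train_pool[train_pool$line_id %in% ts$sampled_ids, ,
                         drop = FALSE]
        y_tr <- stats::setNames(tr$blue, tr$line_id)
        X_tr <- year_design(tr$year)

        gfit <- fit_gblup(y_tr, Km, fixed_design = X_tr)
        g_pred <- gfit$pred[cand]
        if ("gblup" %in% methods) {
          add_row(combo, "gblup", g_pred)
          fold_preds[[paste0("gblup@", combo)]] <- g_pred
        }
        if ("index" %in% methods) {
          idx <- heritability_index(g_pred, kb$bv[cand],
                                    h2_gblup = gfit$h2, h2_kblup = kb$h2)
          pred <- stats::setNames(idx$gebv_index, idx$line_id)
          add_row(combo, "index", pred)
          fold_preds[[paste0("index@", combo)]] <- pred
        }
        if ("index_marker_sel" %in% methods) {
          u_tr <- fit_rrblup(y_tr, an$markers, fixed_design = X_tr)$u
          y_pyt <- stats::setNames(
            pyt_bt$blue[!pyt_bt$is_check],
            pyt_bt$line_id[!pyt_bt$is_check])
          u_py <- fit_rrblup(y_pyt, an$markers)$u
          retained <- select_markers_sign(u_tr, u_py)
          if (length(retained) < 2L) {
            warning(sprintf(
              "selection year %d, combo %s: marker selection left %d markers",
              t, combo, length(retained)), call. = FALSE)
            next
          }
          K_sel <- genomic_relationship(
            an$markers[, retained, drop = FALSE])
          gfit_sel <- fit_gblup(y_tr, K_sel, fixed_design = X_tr)
          gs_pred <- gfit_sel$pred[cand]
          r <- stats::cor(gs_pred, kb$bv[cand])
          h2g <- min(max(gfit_sel$h2, 1e-6), 1 - 1e-6)
          wg <- adjusted_gblup_weight(h2g, max(-0.999, min(0.999, r)))
          idx <- heritability_index(gs_pred, kb$bv[cand],
                                    h2_gblup = h2g, h2_kblup = kb$h2,
                                    w_gblup = wg)
          pred <- stats::setNames(idx$gebv_index, idx$line_id)
          add_row(combo, "index_marker_sel", pred)
          fold_preds[[paste0("index_marker_sel@", combo)]] <- pred
        }
      }
    }
    predictions[[as.character(t)]] <- fold_preds
  }

  if (!length(results)) {
    stop("no usable selection year / MET year pair in the program",
         call. = FALSE)
  }
  res <- do.call(rbind, results)
  structure(list(results = res,
                 predictions = predictions,
                 summary = summarize_comparison(res)),
            class = "gas_comparison")
}

#' Summarize fold accuracies per method
#'
#' @param results the `results` data.frame of a [run_method_comparison()].
#' @return data.frame `method`, `mean_accuracy`, `se`, `n_folds`.
#' @export
summarize_comparison <- function(results) {
  stopifnot(all(c("method", "accuracy") %in% names(results)))
  agg <- split(results$accuracy, results$method)
  out <- data.frame(
    method = names(agg),
    mean_accuracy = vapply(agg, mean, 0),
    se = vapply(agg, function(a) stats::sd(a) / sqrt(length(a)), 0),
    n_folds = vapply(agg, length, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$mean_accuracy), , drop = FALSE]
}

#' @export
print.gas_comparison <- function(x, ...) {
  cat("<gas_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Hit-rate curves for a method comparison
#'
#' Averages [top_bottom_hit_rate()] over all folds of a comparison for a
#' grid of selected fractions.
#'
#' @param comparison a [run_method_comparison()] result.
#' @param fractions selected fractions in (0, 0.5].
#' @return data.frame `method`, `fraction`, `best`, `worst` (mean
#'   proportions over folds).
#' @export
comparison_hit_rates <- function(comparison,
                                 fractions = seq(0.1, 0.5, by = 0.1)) {
  stopifnot(inherits(comparison, "gas_comparison"))
  rows <- list()
  for (fold in comparison$predictions) {
    obs <- fold$observed
    for (nm in setdiff(names(fold), "observed")) {
      method <- sub("@.*$", "", nm)
      pred <- fold[[nm]][names(obs)]
      for (q in fractions) {
        hr <- top_bottom_hit_rate(pred, obs, q)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, fraction = q,
          best = hr[["best"]], worst = hr[["worst"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(best, worst) ~ method + fraction, d, mean)
  agg[order(agg$method, agg$fraction), , drop = FALSE]
}
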