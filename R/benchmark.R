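# sample a training config from the hyperparameter search space
# (log-uniform rates/penalties, uniform dropout, integer-uniform sizes)
.sample_train_cfg <- function(model, seed, epochs, batch_size = Inf,
                              hidden_range = c(128L, 512L),
                              layer_range = c(1L, 3L)) {
  .with_seed(seed, {
    lu <- function(lo, hi) exp(stats::runif(1L, log(lo), log(hi)))
    train_config(model = model,
                 hidden = sample(hidden_range[1L]:hidden_range[2L], 1L),
                 n_layers = sample(layer_range[1L]:layer_range[2L], 1L),
                 lr = lu(1e-5, 1e-2), l2 = lu(1e-7, 1e-5),
                 input_dropout = stats::runif(1L, 0, 0.5),
                 recurrent_dropout = stats::runif(1L, 0, 0.5),
                 epochs = epochs, batch_size = batch_size, seed = seed)
  })
}

.sample_svm_hp <- function(seed) {
  .with_seed(seed, {
    lu <- function(lo, hi) exp(stats::runif(1L, log(lo), log(hi)))
    svm_hyperparams(kernel = sample(c("linear", "radial"), 1L),
                    cost = lu(1e-3, 1e3), gamma = lu(1e-3, 1e3),
                    epsilon = lu(1e-3, 1))
  })
}

# forecast the test subjects of one split with any supported model kind
.forecast_test <- function(kind, fitobj, test_cohort, svm_k = 1L,
                           raw_means = NULL) {
  if (kind %in% c("minimalrnn", "lss"))
    return(forecast_cohort(fitobj, test_cohort))
  rows <- lapply(test_cohort$subjects, function(s) {
    sp <- split_timepoints(s)
    if (!length(sp$target_slots)) return(NULL)
    horizon <- s$grid_months[max(sp$target_slots)] -
      s$grid_months[max(sp$input_slots)]
    if (horizon <= 0L) return(NULL)
    if (kind == "constant")
      constant_forecast(s, horizon, input_slots = sp$input_slots,
                        means = raw_means)
    else svm_forecast(fitobj, s, svm_k, horizon,
                      input_slots = sp$input_slots)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Repeated-split benchmark of a forecasting model
#'
#' Runs the full evaluation protocol: the cohort is split into
#' train/validation/test subject sets at 18:1:1 over `n_repeats` repeats
#' with disjoint test blocks; per repeat the model is fitted on the
#' training subjects (optionally with a seeded random hyperparameter search
#' scored on the validation subjects), test subjects' first-half timepoints
#' are used to forecast their second half, and diagnosis mAUC/BCA plus
#' ADAS-Cog13 and ventricles/ICV MAEs are computed on observed months.
#' Results are averaged across repeats; per-split vectors are kept for
#' paired testing ([compare_benchmarks()]). Fully deterministic given
#' `seed`.
#'
#' @param x an `ad_cohort` (raw scale, monthly grid).
#' @param model `"minimalrnn"`, `"lss"`, `"constant"` or `"svm"`.
#' @param fill filling strategy for the sequence models.
#' @param n_repeats number of repeated splits (up to 20).
#' @param seed master seed; all training, search and split randomness
#'   derives from it.
#' @param train_cfg base [train_config()] for the sequence models (its seed
#'   field is re-derived per repeat).
#' @param search_budget number of random hyperparameter draws per repeat
#'   (0 = use `train_cfg` / default SVM hyperparameters as-is).
#' @param resolution grid interval in months (1, 3 or 6); coarse-grid
#'   forecasts are interpolated back to monthly.
#' @param svm_k requested input-timepoint count for the SVM harness.
#' @param keep_models if `TRUE`, keep the fitted model of each repeat.
#' @return an `eval_report`: per-split metric table, summary (mean, sd),
#'   split plans and configuration.
#' @export
run_benchmark <- function(x, model = c("minimalrnn", "lss", "constant",
                                       "svm"),
                          fill = c("model", "forward", "linear"),
                          n_repeats = 20L, seed = 1L,
                          train_cfg = train_config(), search_budget = 0L,
                          resolution = 1L, svm_k = 1L,
                          keep_models = FALSE) {
  model <- match.arg(model)
  fill <- match.arg(fill)
  if (resolution > 1L) x <- regrid_cohort(x, resolution)
  plans <- make_split_plan(x, n_repeats, seed)
  per_split <- list()
  models <- list()

  for (k in seq_len(n_repeats)) {
    plan <- plans[[k]]
    tryCatch(error = function(e)
      stop("benchmark repeat ", k, " (seed ", seed + 7919L * k,
           ") failed: ", conditionMessage(e), call. = FALSE), {
    train <- cohort_subset(x, plan$train)
    val <- cohort_subset(x, plan$val)
    test <- cohort_subset(x, plan$test)
    rep_seed <- seed + 7919L * k
    fitobj <- NULL
    raw_means <- NULL

    if (model %in% c("minimalrnn", "lss")) {
      cfgs <- if (search_budget > 0L) {
        lapply(seq_len(search_budget), function(i)
          .sample_train_cfg(model, rep_seed + i,
                            epochs = train_cfg$epochs,
                            batch_size = train_cfg$batch_size))
      } else {
        cfg <- train_cfg
        cfg$model <- model
        cfg$seed <- rep_seed
        list(cfg)
      }
      best <- NULL
      for (cfg in cfgs) {
        fit <- train_progression_model(train, fill, cfg, val_cohort = val)
        sc <- .val_composite(fit, val)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, fit = fit)
      }
      fitobj <- best$fit
    } else if (model == "svm") {
      hps <- if (search_budget > 0L)
        lapply(seq_len(search_budget), function(i)
          .sample_svm_hp(rep_seed + i))
      else list(svm_hyperparams())
      best <- NULL
      for (hp in hps) {
        fit <- fit_svm_grid(train, hp)
        fc_val <- .forecast_test("svm", fit, val, svm_k = svm_k)
        ev <- evaluate_forecasts(fc_val, val)
        sc <- (if (is.na(ev$mauc)) 0 else ev$mauc) -
          sum(c(ev$ventricles_mae * 100, ev$adas_mae / 10), na.rm = TRUE)
        if (is.null(best) || sc > best$score) best <- list(score = sc,
                                                           fit = fit)
      }
      fitobj <- best$fit
    } else {
      raw_means <- fit_fallback_means(train)
    }

    fc <- .forecast_test(model, fitobj, test, svm_k = svm_k,
                         raw_means = raw_means)
    ev <- evaluate_forecasts(fc, test)
    per_split[[k]] <- data.frame(
      repeat_index = k, mauc = ev$mauc, bca = ev$bca,
      adas_mae = ev$adas_mae, ventricles_mae = ev$ventricles_mae,
      n_dx = ev$n_dx, n_adas = ev$n_adas, n_vent = ev$n_vent,
      n_train = length(plan$train), n_test = length(plan$test))
    if (keep_models) models[[k]] <- fitobj
      })
  }

  tab <- do.call(rbind, c(per_split, list(make.row.names = FALSE)))
  metrics <- c("mauc", "bca", "adas_mae", "ventricles_mae")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(tab[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(metrics, function(m) stats::sd(tab[[m]], na.rm = TRUE),
                numeric(1L)), row.names = NULL)
  structure(
    list(model = model, fill = fill, per_split = tab, summary = summary,
         plans = plans, seed = seed, resolution = resolution,
         n_repeats = n_repeats, search_budget = search_budget,
         models = if (keep_models) models else NULL,
         package_version = as.character(utils::packageVersion("adprogress"))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$model,
      if (x$model %in% c("minimalrnn", "lss")) paste0(" (", x$fill,
                                                      " filling)"),
      ", ", x$n_repeats, " repeats, seed ", x$seed, "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s %.4g +/- %.2g\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Paired comparison of two benchmark reports
#'
#' Corrected resampled t-tests per metric between two [run_benchmark()]
#' reports produced from the same split plans, with Benjamini-Hochberg FDR
#' decisions across the metrics.
#'
#' @param a,b `eval_report`s with identical `plans`.
#' @param q FDR level.
#' @return data.frame with mean difference (a - b), t, p and FDR decision
#'   per metric.
#' @export
compare_benchmarks <- function(a, b, q = 0.05) {
  stopifnot(identical(a$plans, b$plans))
  metrics <- c("mauc", "bca", "adas_mae", "ventricles_mae")
  n_train <- a$per_split$n_train[1L]
  n_test <- a$per_split$n_test[1L]
  res <- lapply(metrics, function(m) {
    sa <- a$per_split[[m]]
    sb <- b$per_split[[m]]
    keep <- !is.na(sa) & !is.na(sb)      # splits where both models scored
    if (sum(keep) < 2L)
      return(list(t = NA_real_, p = NA_real_, mean_diff = NA_real_,
                  df = NA_integer_))
    corrected_resampled_ttest(sa[keep], sb[keep], n_train, n_test)
  })
  p <- vapply(res, `[[`, numeric(1L), "p")
  dec <- fdr_adjust(p, q)
  data.frame(metric = metrics,
             mean_diff = vapply(res, `[[`, numeric(1L), "mean_diff"),
             t = vapply(res, `[[`, numeric(1L), "t"),
             p = p, p_adjusted = dec$adjusted, significant = dec$reject,
             row.names = NULL)
}

#' Performance as a function of the number of input timepoints
#'
#' Applies one trained model to the same test subjects using only the first
#' 1, 2, 3 or 4 input timepoints; subjects with fewer than `max(k_list)`
#' input timepoints are discarded so the subject set is identical across
#' conditions.
#'
#' @param model a fitted `progression_model`.
#' @param x test `ad_cohort` (raw scale).
#' @param k_list input-timepoint counts to sweep.
#' @return list with `per_k` (metric data.frame per k) and `subject_ids`.
#' @export
run_input_timepoint_sweep <- function(model, x, k_list = 1:4) {
  kmax <- max(k_list)
  eligible <- names(x$subjects)[vapply(x$subjects, function(s) {
    sp <- split_timepoints(s)
    length(sp$input_slots) >= kmax && length(sp$target_slots) > 0L
  }, logical(1L))]
  if (!length(eligible)) stop("no subject has ", kmax, " input timepoints")
  xe <- cohort_subset(x, eligible)
  per_k <- lapply(k_list, function(k) {
    fc <- forecast_cohort(model, xe, input_k = k)
    ev <- evaluate_forecasts(fc, xe)
    data.frame(k = k, mauc = ev$mauc, bca = ev$bca, adas_mae = ev$adas_mae,
               ventricles_mae = ev$ventricles_mae, n_dx = ev$n_dx)
  })
  list(per_k = do.call(rbind, c(per_k, list(make.row.names = FALSE))),
       subject_ids = eligible)
}

#' Input-feature ablation of a trained model
#'
#' Re-scores a trained model on test inputs in which one feature at a time
#' is replaced everywhere by its dataset mean (continuous markers: the
#' training mean, i.e. 0 on the z-scale; diagnosis: the training class
#' frequency vector). Ground-truth targets are never altered. Emits one row
#' per ablated feature plus a no-ablation row.
#'
#' @param model a fitted `progression_model`.
#' @param x test `ad_cohort` (raw scale).
#' @return data.frame with 23 ablation rows + 1 baseline row of metrics.
#' @export
run_feature_ablation <- function(model, x) {
  schema <- x$schema
  ablate <- function(feature) {
    xa <- x
    xa$subjects <- lapply(xa$subjects, function(s) {
      if (feature == "DX") {
        rows <- which(s$observed[, 1L])
        if (length(rows))
          s$values[rows, .dx_cols] <- matrix(model$means$dx_freq,
                                             length(rows), 3L, byrow = TRUE)
      } else {
        j <- match(feature, schema$continuous)
        rows <- which(s$observed[, 1L + j])
        if (length(rows))
          s$values[rows, 3L + j] <- model$norm_stats$mean[j]
      }
      s
    })
    xa
  }
  features <- c("none", "DX", schema$continuous)
  rows <- lapply(features, function(f) {
    xin <- if (f == "none") x else ablate(f)
    fc <- forecast_cohort(model, xin)
    ev <- evaluate_forecasts(fc, x)       # truth always unablated
    data.frame(ablated = f, mauc = ev$mauc, bca = ev$bca,
               adas_mae = ev$adas_mae, ventricles_mae = ev$ventricles_mae)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Temporal-resolution sweep
#'
#' Runs [run_benchmark()] at 1-, 3- and 6-month grid intervals (observed
#' data assigned to the nearest slot; coarse-grid forecasts linearly
#' interpolated to monthly before scoring).
#'
#' @inheritParams run_benchmark
#' @param resolutions grid intervals to sweep.
#' @return named list of `eval_report`s.
#' @export
run_resolution_sweep <- function(x, resolutions = c(1L, 3L, 6L), ...) {
  stats::setNames(lapply(resolutions, function(r)
    run_benchmark(x, resolution = r, ...)),
    paste0("res", resolutions))
}
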