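#' Multiclass AUC (mean of one-vs-rest AUCs)
#'
#' For each diagnosis class, the two-class AUC of that class against the
#' rest, using the predicted probability of the class as the score (tied
#' scores contribute 1/2, via midranks); the result is the unweighted mean
#' over the three classes. A class absent from the labels has no defined
#' AUC; the mean is then taken over the defined classes with a warning.
#'
#' @param probs n x 3 matrix of class probabilities (columns NC, MCI, AD).
#' @param labels length-n true classes (`"NC"`/`"MCI"`/`"AD"`).
#' @return scalar in \[0, 1\].
#' @export
mauc <- function(probs, labels) {
  probs <- rbind(probs)
  labels <- as.character(labels)
  stopifnot(nrow(probs) == length(labels), ncol(probs) == 3L)
  aucs <- vapply(seq_len(3L), function(c) {
    pos <- labels == dx_levels()[c]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(probs[, c])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
  if (anyNA(aucs)) {
    warning("class(es) absent from labels; mAUC averaged over ",
            sum(!is.na(aucs)), " defined class(es)")
  }
  mean(aucs, na.rm = TRUE)
}

#' Balanced class accuracy
#'
#' Mean over the three classes of (sensitivity + specificity) / 2, computed
#' one-vs-rest on hard class assignments. Classes absent from the labels are
#' skipped with a warning.
#'
#' @param pred_labels predicted classes (e.g. argmax of the probability
#'   rows); @param labels true classes.
#' @return scalar in \[0, 1\].
#' @export
bca <- function(pred_labels, labels) {
  pred_labels <- as.character(pred_labels)
  labels <- as.character(labels)
  stopifnot(length(pred_labels) == length(labels))
  per_class <- vapply(dx_levels(), function(c) {
    pos <- labels == c
    if (sum(pos) == 0L || sum(!pos) == 0L) return(NA_real_)
    sens <- mean(pred_labels[pos] == c)
    spec <- mean(pred_labels[!pos] != c)
    (sens + spec) / 2
  }, numeric(1L))
  if (anyNA(per_class)) {
    warning("class(es) absent from labels; BCA averaged over ",
            sum(!is.na(per_class)), " defined class(es)")
  }
  mean(per_class, na.rm = TRUE)
}

#' Mean absolute error over observed entries
#'
#' @param pred,truth numeric vectors aligned to the observed ground-truth
#'   months. Returns `NA` when there is nothing to score (excluded from
#'   averages upstream).
#' @export
mae <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  keep <- !is.na(pred) & !is.na(truth)
  if (!any(keep)) return(NA_real_)
  mean(abs(pred[keep] - truth[keep]))
}

#' Corrected resampled t-test for repeated random splits
#'
#' Paired t-test across K repeated train/test splits with the variance
#' inflated by (1/K + n_test/n_train) to account for overlapping training
#' sets; two-sided p-value from the t distribution with K-1 degrees of
#' freedom. As n_test/n_train -> 0 it reduces to the classical paired
#' t-test.
#'
#' @param scores_a,scores_b per-split scores of the two models (same
#'   splits, same order).
#' @param n_train,n_test subject counts of the training and test sets.
#' @return list with `t`, `p`, `mean_diff`, `df`.
#' @export
corrected_resampled_ttest <- function(scores_a, scores_b, n_train, n_test) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  k <- length(scores_a)
  d <- scores_a - scores_b
  v <- stats::var(d)
  m <- mean(d)
  if (v == 0) {
    if (m == 0) return(list(t = 0, p = 1, mean_diff = 0, df = k - 1L))
    warning("zero variance with nonzero mean difference")
    return(list(t = sign(m) * Inf, p = 0, mean_diff = m, df = k - 1L))
  }
  tt <- m / sqrt((1 / k + n_test / n_train) * v)
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = k - 1L), mean_diff = m,
       df = k - 1L)
}

#' Benjamini-Hochberg FDR decisions
#'
#' @param pvalues vector of p-values; @param q FDR level.
#' @return list with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical decisions at level `q`).
#' @export
fdr_adjust <- function(pvalues, q = 0.05) {
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

# feature indices within the continuous block
.idx_adas13 <- 3L
.idx_vent <- 11L
.idx_icv <- 17L

# Align a forecast table with observed ground truth.
# Returns dx/adas/vent scoring tables with absolute and relative months.
.forecast_tables <- function(forecasts, x, norm_stats = NULL,
                             z_scale = FALSE) {
  dx_rows <- list(); adas_rows <- list(); vent_rows <- list()
  for (id in unique(forecasts$subject_id)) {
    fc <- forecasts[forecasts$subject_id == id, , drop = FALSE]
    s <- x$subjects[[id]]
    if (is.null(s)) stop("forecast subject not in cohort: ", id)
    last_input <- min(fc$month) - 1L
    slots <- which(s$grid_months %in% fc$month)
    for (t in slots) {
      mth <- s$grid_months[t]
      row <- fc[fc$month == mth, , drop = FALSE][1L, ]
      rel <- mth - last_input
      if (s$observed[t, 1L]) {
        truec <- dx_levels()[which.max(s$values[t, .dx_cols])]
        dx_rows[[length(dx_rows) + 1L]] <- data.frame(
          subject_id = id, month = mth, rel_month = rel, true = truec,
          p_NC = row$p_NC, p_MCI = row$p_MCI, p_AD = row$p_AD)
      }
      if (s$observed[t, 1L + .idx_adas13]) {
        tr <- s$values[t, 3L + .idx_adas13]
        pr <- row[["ADAS13"]]
        if (z_scale) {
          tr <- (tr - norm_stats$mean[.idx_adas13]) /
            norm_stats$sd[.idx_adas13]
          pr <- (pr - norm_stats$mean[.idx_adas13]) /
            norm_stats$sd[.idx_adas13]
        }
        adas_rows[[length(adas_rows) + 1L]] <- data.frame(
          subject_id = id, month = mth, rel_month = rel, pred = pr,
          true = tr)
      }
      if (z_scale) {
        if (s$observed[t, 1L + .idx_vent]) {
          tr <- (s$values[t, 3L + .idx_vent] - norm_stats$mean[.idx_vent]) /
            norm_stats$sd[.idx_vent]
          pr <- (row[["Ventricles"]] - norm_stats$mean[.idx_vent]) /
            norm_stats$sd[.idx_vent]
          vent_rows[[length(vent_rows) + 1L]] <- data.frame(
            subject_id = id, month = mth, rel_month = rel, pred = pr,
            true = tr)
        }
      } else if (s$observed[t, 1L + .idx_vent] &&
                 s$observed[t, 1L + .idx_icv]) {
        tr <- s$values[t, 3L + .idx_vent] / s$values[t, 3L + .idx_icv]
        pr <- if ("ventricles_icv" %in% names(row)) row[["ventricles_icv"]]
          else row[["Ventricles"]] / row[["ICV"]]
        vent_rows[[length(vent_rows) + 1L]] <- data.frame(
          subject_id = id, month = mth, rel_month = rel, pred = pr,
          true = tr)
      }
    }
  }
  bindr <- function(l) if (length(l))
    do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL
  list(dx = bindr(dx_rows), adas = bindr(adas_rows), vent = bindr(vent_rows))
}

.dx_argmax <- function(tab)
  dx_levels()[max.col(as.matrix(tab[, c("p_NC", "p_MCI", "p_AD")]),
                      ties.method = "first")]

#' Score a forecast table against a cohort's observed future
#'
#' Evaluation follows the TADPOLE conventions: diagnosis by multiclass AUC
#' and balanced class accuracy over all (subject, month) pairs with an
#' observed diagnosis; ADAS-Cog13 by MAE on the raw score; ventricular
#' volume by MAE as a fraction of intracranial volume (both measured at the
#' same visit). Only observed ground-truth months are scored.
#'
#' @param forecasts forecast table ([forecast_cohort()] or a baseline's).
#' @param x the `ad_cohort` holding the ground truth (raw scale).
#' @param norm_stats,z_scale internal: score the continuous targets on the
#'   z-normalized scale instead (used for validation model selection).
#' @return list with `mauc`, `bca`, `adas_mae`, `ventricles_mae`, counts
#'   `n_dx`, `n_adas`, `n_vent`, and the per-entry scoring `tables`.
#' @export
evaluate_forecasts <- function(forecasts, x, norm_stats = NULL,
                               z_scale = FALSE) {
  tb <- .forecast_tables(forecasts, x, norm_stats, z_scale)
  out <- list(mauc = NA_real_, bca = NA_real_, adas_mae = NA_real_,
              ventricles_mae = NA_real_,
              n_dx = 0L, n_adas = 0L, n_vent = 0L, tables = tb)
  if (!is.null(tb$dx) && nrow(tb$dx)) {
    probs <- as.matrix(tb$dx[, c("p_NC", "p_MCI", "p_AD")])
    out$mauc <- suppressWarnings(mauc(probs, tb$dx$true))
    out$bca <- suppressWarnings(bca(.dx_argmax(tb$dx), tb$dx$true))
    out$n_dx <- nrow(tb$dx)
  }
  if (!is.null(tb$adas)) {
    out$adas_mae <- mae(tb$adas$pred, tb$adas$true)
    out$n_adas <- nrow(tb$adas)
  }
  if (!is.null(tb$vent)) {
    out$ventricles_mae <- mae(tb$vent$pred, tb$vent$true)
    out$n_vent <- nrow(tb$vent)
  }
  out
}

#' Breakdown of forecast performance by diagnostic trajectory group
#'
#' Subjects are grouped by the pair (diagnosis at the last input timepoint
#' with an observed diagnosis, diagnosis at the last timepoint with an
#' observed diagnosis): stable NC-S/MCI-S/AD, progressive NC-P/MCI-P
#' (movement along NC -> MCI -> AD), and MCI-R (reverted to NC). Subjects
#' lacking an observed diagnosis in either half are excluded, as are AD
#' reverters (rare). Within groups, diagnosis is scored by plain accuracy of
#' the argmax prediction (the groups are single-class, so AUC is
#' undefined), plus the two MAEs.
#'
#' @inheritParams evaluate_forecasts
#' @return data.frame with one row per group: subject count, diagnosis
#'   accuracy, ADAS-Cog13 MAE and ventricles/ICV MAE.
#' @export
group_breakdown <- function(forecasts, x) {
  tb <- .forecast_tables(forecasts, x)
  groups <- c("NC-S", "NC-P", "MCI-R", "MCI-S", "MCI-P", "AD")
  assign_group <- function(s) {
    sp <- split_timepoints(s)
    in_dx <- sp$input_slots[s$observed[sp$input_slots, 1L]]
    tg_dx <- sp$target_slots[s$observed[sp$target_slots, 1L]]
    if (!length(in_dx) || !length(tg_dx)) return(NA_character_)
    a <- which.max(s$values[max(in_dx), .dx_cols])
    b <- which.max(s$values[max(tg_dx), .dx_cols])
    if (a == 1L) return(if (b == 1L) "NC-S" else "NC-P")
    if (a == 2L) return(c("MCI-R", "MCI-S", "MCI-P")[b])
    if (b == 3L) "AD" else NA_character_       # AD reverters excluded
  }
  grp <- vapply(x$subjects[unique(forecasts$subject_id)], assign_group,
                character(1L))
  stat <- function(tab, f) {
    if (is.null(tab)) return(rep(NA_real_, length(groups)))
    g <- grp[tab$subject_id]
    vapply(groups, function(gr) {
      sub <- tab[!is.na(g) & g == gr, , drop = FALSE]
      if (!nrow(sub)) NA_real_ else f(sub)
    }, numeric(1L))
  }
  data.frame(
    group = groups,
    n_subjects = vapply(groups, function(gr) sum(grp == gr, na.rm = TRUE),
                        integer(1L)),
    dx_accuracy = stat(tb$dx, function(s) mean(.dx_argmax(s) == s$true)),
    adas_mae = stat(tb$adas, function(s) mae(s$pred, s$true)),
    ventricles_mae = stat(tb$vent, function(s) mae(s$pred, s$true)),
    row.names = NULL)
}

#' Breakdown of forecast performance by yearly horizon
#'
#' Observed target months are bucketed by years since the last input
#' timepoint (months 1-12 = year 1, 13-24 = year 2, ...), and each metric
#' is computed per bucket; empty buckets are reported as `NA`.
#'
#' @inheritParams evaluate_forecasts
#' @param max_years number of yearly buckets.
#' @return data.frame with one row per year.
#' @export
yearly_breakdown <- function(forecasts, x, max_years = 6L) {
  tb <- .forecast_tables(forecasts, x)
  year_of <- function(rel) ceiling(rel / 12)
  out <- data.frame(year = seq_len(max_years), n_dx = 0L,
                    mauc = NA_real_, bca = NA_real_,
                    adas_mae = NA_real_, ventricles_mae = NA_real_)
  for (y in seq_len(max_years)) {
    if (!is.null(tb$dx)) {
      sub <- tb$dx[year_of(tb$dx$rel_month) == y, , drop = FALSE]
      if (nrow(sub)) {
        out$n_dx[y] <- nrow(sub)
        probs <- as.matrix(sub[, c("p_NC", "p_MCI", "p_AD")])
        out$mauc[y] <- suppressWarnings(mauc(probs, sub$true))
        out$bca[y] <- suppressWarnings(bca(.dx_argmax(sub), sub$true))
      }
    }
    if (!is.null(tb$adas)) {
      sub <- tb$adas[year_of(tb$adas$rel_month) == y, , drop = FALSE]
      if (nrow(sub)) out$adas_mae[y] <- mae(sub$pred, sub$true)
    }
    if (!is.null(tb$vent)) {
      sub <- tb$vent[year_of(tb$vent$rel_month) == y, , drop = FALSE]
      if (nrow(sub)) out$ventricles_mae[y] <- mae(sub$pred, sub$true)
    }
  }
  out
}
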