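#' Constant-prediction baseline
#'
#' Predicts every future month to equal the last observed value of each
#' variable (the diagnosis as a degenerate probability vector on the last
#' observed label). Needs no training. Variables never observed in the input
#' fall back to the supplied training means (reference marginals if none are
#' given). Forecasting from a constant forecast changes nothing
#' (idempotence), and a zero horizon yields an empty table.
#'
#' @param traj a `subject_trajectory` (raw scale).
#' @param horizon_months months to forecast beyond the last input timepoint.
#' @param input_slots optional grid slots to use as input (default all
#'   observed timepoints).
#' @param means optional `fill_means` on the raw scale for never-observed
#'   variables.
#' @return forecast table with the same columns as [forecast()].
#' @export
constant_forecast <- function(traj, horizon_months, input_slots = NULL,
                              means = NULL) {
  if (is.null(input_slots)) input_slots <- which(rowSums(traj$observed) > 0L)
  t_in <- if (length(input_slots)) max(input_slots) else 1L
  obs <- traj$observed[seq_len(t_in), , drop = FALSE]
  vals <- traj$values[seq_len(t_in), , drop = FALSE]
  ref <- .adni_reference()
  fallback_cont <- if (is.null(means)) stats::setNames(ref$mean, ref$name)
    else means$cont
  fallback_dx <- if (is.null(means)) rep(1 / 3, 3L) else means$dx_freq

  dx_obs <- which(obs[, 1L])
  p <- if (length(dx_obs)) vals[max(dx_obs), .dx_cols] else fallback_dx
  g <- vapply(seq_len(.n_cont), function(j) {
    o <- which(obs[, 1L + j])
    if (length(o)) vals[max(o), 3L + j] else unname(fallback_cont[j])
  }, numeric(1L))

  if (horizon_months <= 0L) {
    out <- data.frame(subject_id = character(), month = numeric(),
                      p_NC = numeric(), p_MCI = numeric(), p_AD = numeric())
    for (nm in ref$name) out[[nm]] <- numeric()
    return(out)
  }
  months <- traj$grid_months[t_in] + seq_len(horizon_months)
  out <- data.frame(subject_id = traj$subject_id, month = months,
                    p_NC = p[1L], p_MCI = p[2L], p_AD = p[3L],
                    matrix(g, length(months), .n_cont, byrow = TRUE),
                    check.names = FALSE)
  colnames(out)[6:27] <- ref$name
  out
}

#' Enumerate sliding training windows for the horizon-grid models
#'
#' For a subject with `v` timepoints on the 6-month schedule, an input
#' window of `k` consecutive timepoints and a target exactly
#' `horizon_steps` 6-month steps after the window end: all such (window,
#' target) pairs, i.e. `max(0, v - (k - 1) - horizon_steps)` samples. A
#' 10-visit subject yields 9/8/7 samples for 6/12/18-month horizons at
#' k = 1.
#'
#' @param subject_visits number of 6-month timepoints `v`.
#' @param k_input window length `k` (1-4).
#' @param horizon_steps horizon in 6-month steps (1-10).
#' @return data.frame with `input_start`, `input_end`, `target` slot
#'   indices (zero rows when no sample fits).
#' @export
enumerate_training_samples <- function(subject_visits, k_input,
                                       horizon_steps) {
  n <- max(0L, subject_visits - (k_input - 1L) - horizon_steps)
  if (n == 0L)
    return(data.frame(input_start = integer(), input_end = integer(),
                      target = integer()))
  start <- seq_len(n)
  data.frame(input_start = start, input_end = start + k_input - 1L,
             target = start + k_input - 1L + horizon_steps)
}

#' Concatenated design vector over input timepoints
#'
#' 23 features per timepoint (the diagnosis as one numeric feature - the
#' probability-weighted class index, so a hard NC/MCI/AD label maps to
#' 1/2/3 and linear-filled soft labels interpolate - plus the 22 continuous
#' markers), concatenated oldest-first over `k_input` timepoints: length
#' `23 * k_input` (46 for two timepoints, 69 for three).
#'
#' @param filled T x 25 filled value matrix (linear filling, z-scale).
#' @param slots integer vector of `k_input` consecutive slot indices.
#' @return numeric vector of length `23 * length(slots)`.
#' @export
build_design_vector <- function(filled, slots) {
  as.numeric(vapply(slots, function(t) {
    dx_num <- sum(filled[t, .dx_cols] * (1:3)) / max(sum(filled[t, .dx_cols]),
                                                     1e-12)
    c(dx_num, filled[t, .cont_cols()])
  }, numeric(23L)))
}

#' Hyperparameters for the horizon-grid SVM/SVR models
#'
#' Search space: linear or RBF kernel; penalty 1e-3 to 1e3; gamma 1e-3 to
#' 1e3; epsilon (regression only) 1e-3 to 1.
#'
#' @param kernel `"radial"` or `"linear"`; @param cost penalty C;
#' @param gamma RBF width; @param epsilon SVR tube width.
#' @export
svm_hyperparams <- function(kernel = "radial", cost = 1, gamma = 0.05,
                            epsilon = 0.1) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 epsilon = epsilon), class = "svm_hyperparams")
}

# regrid a cohort at a new resolution from its observed grid rows
regrid_cohort <- function(x, resolution) {
  subs <- lapply(x$subjects, function(s) {
    keep <- which(rowSums(s$observed) > 0L)
    dx <- rep(NA_character_, length(keep))
    odx <- s$observed[keep, 1L]
    dx[odx] <- dx_levels()[max.col(s$values[keep, .dx_cols, drop = FALSE],
                                   ties.method = "first")][odx]
    g <- s$values[keep, .cont_cols(), drop = FALSE]
    g[!s$observed[keep, .mask_cont_cols(), drop = FALSE]] <- NA
    colnames(g) <- x$schema$continuous
    visits <- data.frame(month = s$grid_months[keep], DX = dx, g,
                         check.names = FALSE)
    build_monthly_grid(visits, x$schema, resolution,
                       subject_id = s$subject_id)
  })
  cohort(unname(subs), x$schema)
}

#' Fit the full horizon grid of SVM/SVR models
#'
#' One classifier (diagnosis) or regressor (ADAS-Cog13, ventricles/ICV) per
#' (target, input-timepoints, horizon) cell: 3 targets x 4 window lengths x
#' 10 horizons (6, 12, ..., 60 months) = 120 models. Subjects are placed on
#' a 6-month grid, linear-filled and z-normalized; all available windows of
#' every training subject contribute samples. The classifier emits
#' pairwise-coupled class probabilities so multiclass AUC is computable.
#' Cells whose training set is empty (or single-class for the classifier)
#' are marked unavailable and fall back at prediction time.
#'
#' @param x training `ad_cohort` (raw scale, any resolution).
#' @param hp an [svm_hyperparams()].
#' @param k_values,horizon_steps grid axes (defaults 1:4 and 1:10).
#' @return an `svm_grid` object.
#' @export
fit_svm_grid <- function(x, hp = svm_hyperparams(), k_values = 1:4,
                         horizon_steps = 1:10) {
  x6 <- regrid_cohort(x, 6L)
  norm_stats <- fit_norm_stats(x6)
  x6n <- znormalize(x6, norm_stats)
  means <- fit_fallback_means(x6n)

  # per-subject filled matrices + target observations
  prep <- lapply(x6n$subjects, function(s) {
    filled <- linear_fill(s, means)
    ratio_obs <- s$observed[, 1L + .idx_vent] & s$observed[, 1L + .idx_icv]
    ratio <- ifelse(ratio_obs,
                    (s$values[, 3L + .idx_vent] * norm_stats$sd[.idx_vent] +
                       norm_stats$mean[.idx_vent]) /
                      (s$values[, 3L + .idx_icv] * norm_stats$sd[.idx_icv] +
                         norm_stats$mean[.idx_icv]),
                    NA_real_)
    list(filled = filled, obs = s$observed, ratio = ratio,
         n_slots = nrow(filled))
  })
  ratio_all <- unlist(lapply(prep, `[[`, "ratio"))
  ratio_mean <- mean(ratio_all, na.rm = TRUE)
  ratio_sd <- stats::sd(ratio_all, na.rm = TRUE)
  if (!is.finite(ratio_sd) || ratio_sd == 0) ratio_sd <- 1

  targets <- c("diagnosis", "adas13", "ventricles")
  models <- list()
  for (target in targets) {
    models[[target]] <- list()
    for (k in k_values) {
      models[[target]][[k]] <- vector("list", max(horizon_steps))
      for (h in horizon_steps) {
        Xs <- list(); ys <- list()
        for (p in prep) {
          win <- enumerate_training_samples(p$n_slots, k, h)
          for (i in seq_len(nrow(win))) {
            tgt <- win$target[i]
            y <- switch(target,
              diagnosis = if (p$obs[tgt, 1L])
                dx_levels()[which.max(p$filled[tgt, .dx_cols])] else NA,
              adas13 = if (p$obs[tgt, 1L + .idx_adas13])
                p$filled[tgt, 3L + .idx_adas13] else NA,
              ventricles = if (!is.na(p$ratio[tgt]))
                (p$ratio[tgt] - ratio_mean) / ratio_sd else NA)
            if (is.na(y)) next
            Xs[[length(Xs) + 1L]] <- build_design_vector(
              p$filled, win$input_start[i]:win$input_end[i])
            ys[[length(ys) + 1L]] <- y
          }
        }
        fit <- NULL
        if (length(ys)) {
          X <- do.call(rbind, Xs)
          if (target == "diagnosis") {
            y <- factor(unlist(ys), levels = dx_levels())
            if (nlevels(droplevels(y)) >= 2L) {
              fit <- e1071::svm(X, droplevels(y), kernel = hp$kernel,
                                cost = hp$cost, gamma = hp$gamma,
                                probability = TRUE, scale = FALSE)
            }
          } else {
            fit <- e1071::svm(X, unlist(ys), type = "eps-regression",
                              kernel = hp$kernel, cost = hp$cost,
                              gamma = hp$gamma, epsilon = hp$epsilon,
                              scale = FALSE)
          }
        }
        if (!is.null(fit)) models[[target]][[k]][[h]] <- fit
      }
    }
  }
  structure(list(models = models, hp = hp, k_values = k_values,
                 horizon_steps = horizon_steps, norm_stats = norm_stats,
                 means = means, ratio_mean = ratio_mean,
                 ratio_sd = ratio_sd),
            class = "svm_grid")
}

#' @export
print.svm_grid <- function(x, ...) {
  n_cells <- sum(vapply(x$models, function(m)
    sum(lengths(lapply(m, function(k) k)) > 0), numeric(1L)))
  cat("<svm_grid> ", length(x$models), " targets x ",
      length(x$k_values), " window lengths x ", length(x$horizon_steps),
      " horizons = ",
      length(x$models) * length(x$k_values) * length(x$horizon_steps),
      " model slots\n", sep = "")
  invisible(x)
}

#' Forecast a subject with the horizon-grid models
#'
#' Predicts at 6, 12, ..., 60 months after the last input timepoint with
#' the model of the requested window length (falling back to the largest
#' window the subject's input supports), linearly interpolates intermediate
#' months (diagnosis probability vectors renormalized) and forward-fills
#' beyond month 60.
#'
#' @param fit an [fit_svm_grid()] object.
#' @param traj a `subject_trajectory` (raw scale, any resolution).
#' @param k_requested requested number of input timepoints (1-4).
#' @param horizon_months months to forecast.
#' @param input_slots optional grid slots (on `traj`'s grid) forming the
#'   input.
#' @return forecast table with columns `subject_id`, `month`, `p_NC`,
#'   `p_MCI`, `p_AD`, `ADAS13`, `ventricles_icv`.
#' @export
svm_forecast <- function(fit, traj, k_requested, horizon_months,
                         input_slots = NULL) {
  if (horizon_months <= 0L) stop("horizon_months must be positive")
  if (is.null(input_slots)) input_slots <- which(rowSums(traj$observed) > 0L)
  t_in <- max(input_slots)
  # input portion on a 6-month grid
  sub <- .truncate_traj(traj, t_in)
  mini <- cohort(list(sub), adni_schema())
  s6 <- regrid_cohort(mini, 6L)$subjects[[1L]]
  s6n <- .normalize_traj(s6, fit$norm_stats)
  filled <- linear_fill(s6n, fit$means)
  v_avail <- nrow(filled)
  kk <- max(1L, min(k_requested, v_avail))
  slots <- (v_avail - kk + 1L):v_avail
  xvec <- rbind(build_design_vector(filled, slots))

  # anchors at the last input month
  obs <- s6n$observed
  dx_obs <- which(obs[, 1L])
  anchor_p <- if (length(dx_obs)) s6n$values[max(dx_obs), .dx_cols]
    else fit$means$dx_freq
  ao <- which(obs[, 1L + .idx_adas13])
  anchor_adas <- if (length(ao))
    s6n$values[max(ao), 3L + .idx_adas13] * fit$norm_stats$sd[.idx_adas13] +
      fit$norm_stats$mean[.idx_adas13]
  else fit$norm_stats$mean[.idx_adas13]
  ro <- which(obs[, 1L + .idx_vent] & obs[, 1L + .idx_icv])
  anchor_ratio <- if (length(ro)) {
    vr <- s6n$values[max(ro), 3L + .idx_vent] * fit$norm_stats$sd[.idx_vent] +
      fit$norm_stats$mean[.idx_vent]
    ir <- s6n$values[max(ro), 3L + .idx_icv] * fit$norm_stats$sd[.idx_icv] +
      fit$norm_stats$mean[.idx_icv]
    vr / ir
  } else fit$ratio_mean

  hsteps <- fit$horizon_steps
  P <- matrix(NA_real_, length(hsteps), 3L)
  adas <- rep(NA_real_, length(hsteps))
  ratio <- rep(NA_real_, length(hsteps))
  for (h in hsteps) {
    m_dx <- fit$models$diagnosis[[kk]][[h]]
    if (!is.null(m_dx)) {
      pr <- attr(stats::predict(m_dx, xvec, probability = TRUE),
                 "probabilities")
      p3 <- stats::setNames(rep(0, 3L), dx_levels())
      p3[colnames(pr)] <- pr[1L, ]
      P[h, ] <- p3
    } else P[h, ] <- if (h > 1L) P[h - 1L, ] else anchor_p
    m_a <- fit$models$adas13[[kk]][[h]]
    adas[h] <- if (!is.null(m_a))
      stats::predict(m_a, xvec) * fit$norm_stats$sd[.idx_adas13] +
        fit$norm_stats$mean[.idx_adas13]
    else if (h > 1L) adas[h - 1L] else anchor_adas
    m_v <- fit$models$ventricles[[kk]][[h]]
    ratio[h] <- if (!is.null(m_v))
      stats::predict(m_v, xvec) * fit$ratio_sd + fit$ratio_mean
    else if (h > 1L) ratio[h - 1L] else anchor_ratio
  }

  last_month <- traj$grid_months[t_in]
  grid_months <- 6L * hsteps
  out_rel <- seq_len(horizon_months)
  interp <- function(anchor, ys) {
    f <- stats::approx(c(0L, grid_months), c(anchor, ys),
                       xout = pmin(out_rel, max(grid_months)))$y
    f        # months beyond the last grid month carry its value forward
  }
  pmat <- vapply(1:3, function(j) interp(anchor_p[j], P[, j]),
                 numeric(length(out_rel)))
  pmat <- pmax(pmat, 0)
  pmat <- pmat / rowSums(pmat)
  data.frame(subject_id = traj$subject_id, month = last_month + out_rel,
             p_NC = pmat[, 1L], p_MCI = pmat[, 2L], p_AD = pmat[, 3L],
             ADAS13 = interp(anchor_adas, adas),
             ventricles_icv = interp(anchor_ratio, ratio))
}
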