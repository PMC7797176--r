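# shared fixture builders (everything generated in code at test time)

ref_tab <- adprogress:::.adni_reference()
marker_names <- ref_tab$name

# visits data.frame with all markers NA except those supplied
make_visits <- function(months, dx = NULL, ...) {
  n <- length(months)
  df <- data.frame(month = months,
                   DX = if (is.null(dx)) rep(NA_character_, n) else dx)
  for (nm in marker_names) df[[nm]] <- rep(NA_real_, n)
  supplied <- list(...)
  for (nm in names(supplied)) df[[nm]] <- supplied[[nm]]
  df
}

make_traj <- function(months, dx = NULL, ..., resolution = 1L, id = "s1") {
  build_monthly_grid(make_visits(months, dx, ...), adni_schema(),
                     resolution, subject_id = id)
}

# a dense trajectory: every marker observed at every visit
make_full_traj <- function(months, dx, id = "s1", seed = 1L) {
  set.seed(seed)
  args <- stats::setNames(
    lapply(seq_along(marker_names), function(j)
      ref_tab$mean[j] + ref_tab$sd[j] * stats::rnorm(length(months), 0, 0.3)),
    marker_names)
  do.call(make_traj, c(list(months = months, dx = dx, id = id), args))
}

# small simulated cohort with adjustable observation rates
sim_small <- function(n = 30L, seed = 1L, observed = NULL, ...) {
  rates <- if (is.null(observed)) NULL
    else c(DX = observed, stats::setNames(rep(observed, 22L), marker_names))
  simulate_cohort(sim_config(n_subjects = n, seed = seed,
                             missing_rates = rates, ...))
}

# brute-force one-vs-rest AUC by counting all positive/negative pairs
oracle_mauc <- function(probs, labels) {
  per <- vapply(1:3, function(c) {
    s <- probs[, c]
    pos <- which(labels == dx_levels()[c])
    neg <- which(labels != dx_levels()[c])
    if (!length(pos) || !length(neg)) return(NA_real_)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    tot / (length(pos) * length(neg))
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

# teacher-forced one-step-ahead error on the z-scale, consuming inputs with
# the same filling strategy the model was trained under
one_step_zmae <- function(m, x) {
  mean(unlist(lapply(x$subjects, function(s) {
    sn <- adprogress:::.normalize_traj(s, m$norm_stats)
    filled <- fill_trajectory(sn, m$means, m$strategy)
    h <- rep(list(numeric(m$params$hidden)), m$params$n_layers)
    preds <- matrix(NA_real_, nrow(filled), 25)
    for (t in seq_len(nrow(filled))) {
      v <- filled[t, ]
      for (l in seq_along(h)) {
        h[[l]] <- if (m$params$type == "lss")
          lss_step(h[[l]], v, m$params$layers[[l]])
        else minimal_rnn_step(h[[l]], v, m$params$layers[[l]])
        v <- h[[l]]
      }
      p <- predict_next(h[[length(h)]], m$params)
      if (t < nrow(filled)) preds[t + 1, ] <- c(p$probs, p$cont)
    }
    abs(preds[-1, 4:25] - sn$values[-1, 4:25])
  })))
}

# z-scale MAE across all 22 markers at observed target months
overall_zmae <- function(model, fc, test_cohort) {
  st <- model$norm_stats
  tot <- 0; n <- 0
  for (id in unique(fc$subject_id)) {
    s <- test_cohort$subjects[[id]]
    f <- fc[fc$subject_id == id, , drop = FALSE]
    for (t in which(s$grid_months %in% f$month)) {
      row <- f[f$month == s$grid_months[t], , drop = FALSE][1, ]
      for (j in 1:22) if (s$observed[t, 1 + j]) {
        tot <- tot + abs(row[[marker_names[j]]] - s$values[t, 3 + j]) /
          st$sd[j]
        n <- n + 1
      }
    }
  }
  tot / n
}
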