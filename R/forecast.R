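# normalize / truncate helpers ------------------------------------------------

.normalize_traj <- function(traj, stats) {
  g <- traj$values[, .cont_cols(), drop = FALSE]
  traj$values[, .cont_cols()] <- sweep(sweep(g, 2L, stats$mean), 2L,
                                       stats$sd, "/")
  traj
}

.truncate_traj <- function(traj, t_last) {
  traj$grid_months <- traj$grid_months[seq_len(t_last)]
  traj$values <- traj$values[seq_len(t_last), , drop = FALSE]
  traj$observed <- traj$observed[seq_len(t_last), , drop = FALSE]
  traj$visit_record <- traj$visit_record[traj$visit_record$slot <= t_last, ,
                                         drop = FALSE]
  traj
}

.clamp_fill <- function(x) pmin(pmax(x, -.fill_clip), .fill_clip)

# advance all layers one step; returns list(H = hidden list, xhat = 25-vec)
.step_all <- function(model, H, x) {
  v <- x
  for (l in seq_len(model$params$n_layers)) {
    H[[l]] <- if (model$params$type == "minimalrnn")
      minimal_rnn_step(H[[l]], v, model$params$layers[[l]])
    else lss_step(H[[l]], v, model$params$layers[[l]])
    v <- H[[l]]
  }
  p <- predict_next(H[[model$params$n_layers]], model$params)
  list(H = H, xhat = c(p$probs, p$cont))
}

#' Run a trained model over a trajectory, filling missing inputs
#'
#' Scans the input timepoints in order. At each step the input vector takes
#' observed entries where available and the model's one-step-ahead
#' prediction elsewhere (first-timepoint gaps are pre-filled with the
#' training means). On feature-complete data the filled sequence equals the
#' input and the scan reduces to teacher forcing; when every feature is
#' missing the scan reduces to pure recursive forecasting.
#'
#' @param model a [train_progression_model()] fit.
#' @param traj a `subject_trajectory` on the raw scale.
#' @return list with `filled` (T x 25 matrix, z-scale), `preds` (T x 25;
#'   row t is the model's prediction of timepoint t, rows 2..T), and `H`
#'   (final hidden state per layer).
#' @export
model_fill_forward <- function(model, traj) {
  traj <- .normalize_traj(traj, model$norm_stats)
  filled <- fill_trajectory(traj, model$means, "model")
  m25 <- .expand_mask(traj$observed)
  tt <- nrow(filled)
  H <- rep(list(numeric(model$params$hidden)), model$params$n_layers)
  preds <- matrix(NA_real_, tt, 25L)
  xhat <- NULL
  for (t in seq_len(tt)) {
    x <- filled[t, ]
    if (t > 1L) {
      x[!m25[t, ]] <- .clamp_fill(xhat[!m25[t, ]])
      preds[t, ] <- xhat
    }
    filled[t, ] <- x
    s <- .step_all(model, H, x)
    H <- s$H; xhat <- s$xhat
  }
  list(filled = filled, preds = preds, H = H)
}

#' Forecast a subject's future months
#'
#' Consumes the subject's input timepoints (missing entries handled by the
#' model's filling strategy), then autoregresses: each predicted vector (3
#' diagnosis probabilities + 22 continuous markers) is fed back as the next
#' input, for any horizon. Models on a coarse grid (3- or 6-month
#' resolution) are linearly interpolated to a monthly resolution, diagnosis
#' probabilities renormalized. Continuous outputs are returned on the raw
#' scale.
#'
#' @param model a `progression_model`.
#' @param traj a `subject_trajectory` on the raw scale.
#' @param horizon_months number of months to forecast beyond the last input
#'   timepoint (> 0).
#' @param input_slots optional integer vector of grid slots to use as input
#'   (default: all timepoints carrying an observation); later observations
#'   are ignored.
#' @return data.frame with columns `subject_id`, `month` (absolute grid
#'   month), `p_NC`, `p_MCI`, `p_AD`, and one column per continuous marker.
#' @export
forecast <- function(model, traj, horizon_months, input_slots = NULL) {
  if (horizon_months <= 0L) stop("horizon_months must be positive")
  res <- traj$resolution
  if (is.null(input_slots)) {
    input_slots <- which(rowSums(traj$observed) > 0L)
    if (!length(input_slots)) input_slots <- 1L
  }
  t_in <- max(input_slots)
  work <- .truncate_traj(.normalize_traj(traj, model$norm_stats), t_in)
  filled <- fill_trajectory(work, model$means, model$strategy)
  m25 <- .expand_mask(work$observed)

  H <- rep(list(numeric(model$params$hidden)), model$params$n_layers)
  xhat <- NULL
  for (t in seq_len(t_in)) {
    x <- filled[t, ]
    if (model$strategy == "model" && t > 1L)
      x[!m25[t, ]] <- .clamp_fill(xhat[!m25[t, ]])
    filled[t, ] <- x
    s <- .step_all(model, H, x)
    H <- s$H; xhat <- s$xhat
  }

  n_steps <- ceiling(horizon_months / res)
  preds <- matrix(NA_real_, n_steps, 25L)
  preds[1L, ] <- xhat
  for (k in seq_len(n_steps - 1L) + 1L) {
    s <- .step_all(model, H, .clamp_fill(xhat))
    H <- s$H; xhat <- s$xhat
    preds[k, ] <- xhat
  }

  last_month <- work$grid_months[t_in]
  grid_pred_months <- last_month + res * seq_len(n_steps)
  out_months <- last_month + seq_len(horizon_months)
  if (res == 1L) {
    vals <- preds[seq_len(horizon_months), , drop = FALSE]
  } else {
    anchor <- filled[t_in, ]
    xs <- c(last_month, grid_pred_months)
    ys <- rbind(anchor, preds)
    vals <- vapply(seq_len(25L), function(j)
      stats::approx(xs, ys[, j], xout = out_months)$y,
      numeric(length(out_months)))
    p <- pmax(vals[, .dx_cols, drop = FALSE], 0)
    vals[, .dx_cols] <- p / rowSums(p)
  }
  cont <- sweep(sweep(vals[, .cont_cols(), drop = FALSE], 2L,
                      model$norm_stats$sd, "*"), 2L,
                model$norm_stats$mean, "+")
  out <- data.frame(subject_id = traj$subject_id, month = out_months,
                    p_NC = vals[, 1L], p_MCI = vals[, 2L],
                    p_AD = vals[, 3L], cont, check.names = FALSE)
  colnames(out)[6:27] <- names(model$norm_stats$mean)
  out
}

#' Forecast every evaluable subject of a cohort
#'
#' Applies the evaluation protocol: each subject's first half of timepoints
#' is the input, and forecasts run monthly to the subject's last timepoint.
#' Subjects with no target timepoint (a single visit) are excluded.
#'
#' @param model a `progression_model` (or a baseline supported by
#'   [constant_forecast()] / [svm_forecast()] via their own drivers).
#' @param x an `ad_cohort` on the raw scale.
#' @param input_k optional: use only the first `input_k` input timepoints
#'   (subjects with fewer than `input_k` input timepoints are dropped, so
#'   the same subjects are comparable across `input_k` settings).
#' @return a forecast table (rows from [forecast()], subjects concatenated).
#' @export
forecast_cohort <- function(model, x, input_k = NULL) {
  rows <- lapply(x$subjects, function(s) {
    sp <- split_timepoints(s)
    if (!length(sp$target_slots)) return(NULL)
    slots <- sp$input_slots
    if (!is.null(input_k)) {
      if (length(slots) < input_k) return(NULL)
      slots <- slots[seq_len(input_k)]
    }
    horizon <- s$grid_months[max(sp$target_slots)] -
      s$grid_months[max(slots)]
    if (horizon <= 0L) return(NULL)
    forecast(model, s, horizon, input_slots = slots)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Save / load a fitted progression model
#'
#' Single-file JSON checkpoint holding the named weight arrays, training
#' config, filling strategy, normalization statistics and fallback means.
#'
#' @param model a `progression_model`; @param path file path.
#' @export
save_model <- function(model, path) {
  enc <- function(w) list(dim = dim(w) %||% length(w), data = as.numeric(w))
  obj <- list(
    schema_version = 1L,
    type = model$params$type, hidden = model$params$hidden,
    n_layers = model$params$n_layers, in_dim = model$params$in_dim,
    strategy = model$strategy,
    cfg = unclass(model$cfg),
    layers = lapply(model$params$layers, function(l) lapply(l, enc)),
    heads = lapply(model$params$heads, enc),
    norm_mean = as.list(model$norm_stats$mean),
    norm_sd = as.list(model$norm_stats$sd),
    means_cont = as.list(model$means$cont),
    means_dx = model$means$dx_freq,
    resolution = model$resolution)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dec <- function(e) {
    w <- as.numeric(unlist(e$data))
    d <- unlist(e$dim)
    if (length(d) == 2L) dim(w) <- d
    w
  }
  params <- structure(
    list(type = obj$type, hidden = as.integer(obj$hidden),
         n_layers = as.integer(obj$n_layers), in_dim = as.integer(obj$in_dim),
         layers = lapply(obj$layers, function(l) lapply(l, dec)),
         heads = lapply(obj$heads, dec)),
    class = "model_params")
  ns <- structure(list(mean = unlist(obj$norm_mean),
                       sd = unlist(obj$norm_sd)), class = "norm_stats")
  means <- structure(list(cont = unlist(obj$means_cont),
                          dx_freq = as.numeric(unlist(obj$means_dx))),
                     class = "fill_means")
  cfg <- obj$cfg
  class(cfg) <- "train_config"
  structure(list(params = params, cfg = cfg, strategy = obj$strategy,
                 norm_stats = ns, means = means,
                 resolution = as.integer(obj$resolution)),
            class = "progression_model")
}
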