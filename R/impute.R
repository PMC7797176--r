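#' Fallback means from the training cohort
#'
#' The imputation fallback for entries with no past observation: for each
#' continuous marker, the mean over all observed entries pooling training
#' subjects and timepoints; for the diagnosis, the empirical class-frequency
#' 3-vector. When filling is applied after z-normalization (the package
#' default), the continuous fallback means are ~0 by construction.
#'
#' @param x training `ad_cohort`.
#' @return list of class `fill_means` with `cont` (named 22-vector) and
#'   `dx_freq` (3-vector over NC/MCI/AD).
#' @export
fit_fallback_means <- function(x) {
  if (length(x$subjects) == 0L) stop("empty training cohort")
  vals <- do.call(rbind, lapply(x$subjects, function(s) s$values))
  obs <- do.call(rbind, lapply(x$subjects, function(s) s$observed))
  cont <- vapply(seq_len(.n_cont), function(j)
    mean(vals[obs[, 1L + j], 3L + j]), numeric(1L))
  names(cont) <- x$schema$continuous
  never <- which(is.nan(cont))
  if (length(never))
    stop("feature(s) never observed in training cohort: ",
         paste(x$schema$continuous[never], collapse = ", "))
  dx_rows <- vals[obs[, 1L], .dx_cols, drop = FALSE]
  if (nrow(dx_rows) == 0L)
    stop("diagnosis never observed in training cohort")
  dx_freq <- colMeans(dx_rows)
  structure(list(cont = cont, dx_freq = dx_freq), class = "fill_means")
}

# fill one column: leading gap -> fallback, interior per `interior`
# ("locf" or "linear"), trailing gap -> last observed value
.fill_column <- function(v, obs_idx, fallback, interior = "locf") {
  n <- length(v)
  out <- rep(fallback, n)
  if (length(obs_idx) == 0L) return(out)
  first <- obs_idx[1L]
  last <- obs_idx[length(obs_idx)]
  if (interior == "linear" && length(obs_idx) > 1L) {
    out[first:last] <- stats::approx(obs_idx, v[obs_idx],
                                     xout = first:last,
                                     method = "linear")$y
  } else {
    filled <- v[obs_idx]
    idx <- findInterval(first:last, obs_idx)
    out[first:last] <- filled[idx]
  }
  if (last < n) out[(last + 1L):n] <- v[last]
  out
}

# strategy core shared by forward_fill / linear_fill
.fill_values <- function(traj, means, interior, dx_interior) {
  values <- traj$values
  obs <- traj$observed
  filled <- matrix(0, nrow(values), ncol(values))
  dx_idx <- which(obs[, 1L])
  for (d in .dx_cols) {
    filled[, d] <- .fill_column(values[, d], dx_idx, means$dx_freq[d],
                                dx_interior)
  }
  for (j in seq_len(.n_cont)) {
    filled[, 3L + j] <- .fill_column(values[, 3L + j], which(obs[, 1L + j]),
                                     means$cont[j], interior)
  }
  filled
}

#' Forward filling (last observation carried forward)
#'
#' Each missing entry is replaced by the most recent observed value of the
#' same feature; entries before the first observation fall back to the
#' training means ([fit_fallback_means()]). The diagnosis one-hot vector is
#' carried forward as a hard label. The observation mask is not modified:
#' losses and metrics keep using the original mask.
#'
#' @param traj a `subject_trajectory`; @param means a `fill_means`.
#' @return T x 25 filled value matrix.
#' @export
forward_fill <- function(traj, means) {
  .fill_values(traj, means, interior = "locf", dx_interior = "locf")
}

#' Linear filling (interpolation between observations)
#'
#' Interior gaps are linearly interpolated per feature between the previous
#' and next observed values; trailing gaps have no future observation and
#' fall back to forward filling; leading gaps fall back to the training
#' means. The diagnosis is interpolated on its one-hot coordinates, yielding
#' soft class vectors, unless `dx = "carry"` requests hard carry-forward.
#'
#' @inheritParams forward_fill
#' @param dx `"interpolate"` (soft one-hot interpolation, default) or
#'   `"carry"` (hard label carry-forward).
#' @return T x 25 filled value matrix.
#' @export
linear_fill <- function(traj, means, dx = c("interpolate", "carry")) {
  dx <- match.arg(dx)
  .fill_values(traj, means, interior = "linear",
               dx_interior = if (dx == "interpolate") "linear" else "locf")
}

#' Apply a filling strategy to a trajectory
#'
#' Dispatcher used by training and forecasting. For `"model"` filling only
#' the first timepoint is pre-filled with the training means (as for forward
#' filling); every later missing entry is supplied by the sequence model
#' itself during its forward pass (see [model_fill_forward()]).
#'
#' @inheritParams forward_fill
#' @param strategy `"forward"`, `"linear"` or `"model"`.
#' @return T x 25 matrix; for `"model"`, missing entries beyond the first
#'   timepoint are left `NA` for the model to fill.
#' @export
fill_trajectory <- function(traj, means,
                            strategy = c("forward", "linear", "model")) {
  strategy <- match.arg(strategy)
  if (strategy == "forward") return(forward_fill(traj, means))
  if (strategy == "linear") return(linear_fill(traj, means))
  values <- traj$values
  m25 <- .expand_mask(traj$observed)
  fallback <- c(means$dx_freq, means$cont)
  values[1L, !m25[1L, ]] <- fallback[!m25[1L, ]]
  values
}
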