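#' Training configuration for the sequence models
#'
#' The search space used by the benchmark harness spans input and recurrent
#' dropout rates 0-0.5, L2 weight penalty 1e-7 to 1e-5, learning rate 1e-5 to
#' 1e-2, 1-3 hidden layers and hidden sizes 128-512; defaults here are scaled
#' to synthetic desk-size cohorts.
#'
#' @param model `"minimalrnn"` or `"lss"`.
#' @param hidden hidden-state size; @param n_layers stacked layers.
#' @param lr Adam learning rate; @param l2 L2 penalty on weight matrices
#'   (biases exempt).
#' @param input_dropout dropout rate on the input vector, resampled per
#'   timepoint; @param recurrent_dropout dropout on the previous hidden state
#'   inside the gate/state update, one mask per sequence (variational style).
#' @param epochs training epochs (full passes); @param batch_size subjects
#'   per gradient step (`Inf` = full batch).
#' @param lr_decay multiplicative learning-rate decay applied each epoch.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param stop_grad_fill if `TRUE`, gradients do not flow through
#'   model-filled input entries (ablation switch; default `FALSE`,
#'   end-to-end training).
#' @param val_every if > 0 and a validation cohort is supplied to
#'   [train_progression_model()], score the validation subjects every this
#'   many epochs and keep the best snapshot (composite: mAUC minus the
#'   z-scale MAEs of ADAS-Cog13 and ventricle volume).
#' @return a `train_config` list.
#' @export
train_config <- function(model = c("minimalrnn", "lss"), hidden = 32L,
                         n_layers = 1L, lr = 5e-3, l2 = 1e-6,
                         input_dropout = 0, recurrent_dropout = 0,
                         epochs = 50L, batch_size = Inf, lr_decay = 1,
                         seed = 1L, stop_grad_fill = FALSE, val_every = 0L) {
  structure(list(model = match.arg(model), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), lr = lr, l2 = l2,
                 input_dropout = input_dropout,
                 recurrent_dropout = recurrent_dropout,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 lr_decay = lr_decay, seed = as.integer(seed),
                 stop_grad_fill = isTRUE(stop_grad_fill),
                 val_every = as.integer(val_every)),
            class = "train_config")
}

# Stack a cohort into padded arrays for batched scans.
# X[25, N, T] inputs (pre-filled per strategy; model strategy leaves later
# missing entries 0), OBS[25, N, T] observation indicators (diagnosis mask on
# all three one-hot rows), FILL[25, N, T] entries the model must fill,
# ALIVE[N, T] within-sequence indicators.
.stack_cohort <- function(x, means, strategy) {
  subs <- x$subjects
  n <- length(subs)
  lens <- vapply(subs, function(s) length(s$grid_months), integer(1L))
  tmax <- max(lens)
  X <- array(0, c(25L, n, tmax))
  OBS <- array(0, c(25L, n, tmax))
  FILL <- array(0, c(25L, n, tmax))
  ALIVE <- matrix(0, n, tmax)
  for (i in seq_len(n)) {
    s <- subs[[i]]
    ti <- lens[i]
    filled <- fill_trajectory(s, means, strategy)
    filled[is.na(filled)] <- 0
    m25 <- .expand_mask(s$observed) * 1
    X[, i, seq_len(ti)] <- t(filled)
    OBS[, i, seq_len(ti)] <- t(m25)
    ALIVE[i, seq_len(ti)] <- 1
    if (strategy == "model" && ti > 1L)
      FILL[, i, 2:ti] <- t(1 - m25[2:ti, , drop = FALSE])
  }
  list(X = X, OBS = OBS, FILL = FILL, ALIVE = ALIVE, n = n, tmax = tmax,
       lens = lens)
}

# Model-filled (and autoregressed) inputs are clamped to this range on the
# z-scale: far outside any plausible marker value, so it never binds on
# realistic imputations, but it bounds the prediction-feedback loop, which
# for the purely linear state-space cell would otherwise be free to diverge
# on long mostly-missing grids.
.fill_clip <- 10

# Batched forward/backward pass (backpropagation through time).
# Returns mean-per-subject masked loss and, if want_grads, gradients in the
# same structure as params. With strategy "model", missing inputs at step t
# are the model's own predictions from step t-1 and gradients flow through
# them unless stop_grad. `dropout` is NULL (inference) or
# list(Din = [25,N,T] scaled input masks, R = list of [d,N] scaled masks).
.fb <- function(params, data, strategy, dropout = NULL,
                stop_grad = FALSE, want_grads = TRUE, keep_preds = FALSE) {
  L <- params$n_layers
  d <- params$hidden
  n <- data$n; tmax <- data$tmax
  mf <- strategy == "model"
  hd <- params$heads

  H <- lapply(seq_len(L), function(l) matrix(0, d, n))   # h_0 = 0
  st <- vector("list", tmax)                             # stored intermediates
  PRED <- if (keep_preds) array(NA_real_, c(25L, n, tmax)) else NULL
  loss <- 0
  xhat <- NULL

  for (t in seq_len(tmax)) {
    Xt <- data$X[, , t, drop = FALSE]; dim(Xt) <- c(25L, n)
    if (mf && t > 1L) {
      Ft <- data$FILL[, , t, drop = FALSE]; dim(Ft) <- c(25L, n)
      Xt <- Xt + Ft * pmin(pmax(xhat, -.fill_clip), .fill_clip)
    }
    Xin <- if (!is.null(dropout)) dropout$Din[, , t] * Xt else Xt
    rec <- list(X = Xt, Xin = Xin, layers = vector("list", L))
    V <- Xin
    for (l in seq_len(L)) {
      Hprev <- H[[l]]
      ly <- params$layers[[l]]
      if (params$type == "minimalrnn") {
        U <- tanh(ly$Wu %*% V + ly$bu)
        Hd <- if (!is.null(dropout)) dropout$R[[l]] * Hprev else Hprev
        Fg <- stats::plogis(ly$Uh %*% Hd + ly$Uu %*% U + ly$bf)
        Hnew <- Fg * Hprev + (1 - Fg) * U
        rec$layers[[l]] <- list(V = V, U = U, Fg = Fg, Hd = Hd,
                                Hprev = Hprev, H = Hnew)
      } else {
        Hd <- if (!is.null(dropout)) dropout$R[[l]] * Hprev else Hprev
        Hnew <- ly$A %*% Hd + ly$B %*% V + ly$b
        rec$layers[[l]] <- list(V = V, Hd = Hd, Hprev = Hprev, H = Hnew)
      }
      H[[l]] <- Hnew
      V <- Hnew
    }
    Z <- hd$Ws %*% V + hd$bs
    P <- .softmax(Z)
    G <- hd$Wg %*% V + hd$bg
    rec$P <- P; rec$G <- G
    st[[t]] <- rec
    xhat <- rbind(P, G)
    if (keep_preds && t < tmax) PRED[, , t + 1L] <- xhat

    if (t < tmax) {           # loss for predicting timepoint t+1
      Xtar <- data$X[, , t + 1L, drop = FALSE]; dim(Xtar) <- c(25L, n)
      Otar <- data$OBS[, , t + 1L, drop = FALSE]; dim(Otar) <- c(25L, n)
      wdx <- Otar[1L, ] * data$ALIVE[, t + 1L]
      loss <- loss - sum(wdx * colSums(Xtar[.dx_cols, , drop = FALSE] *
                                         log(pmax(P, 1e-12))))
      wct <- Otar[.cont_cols(), , drop = FALSE] *
        rep(data$ALIVE[, t + 1L], each = .n_cont)
      loss <- loss + sum(wct * abs(G - Xtar[.cont_cols(), , drop = FALSE])) /
        .n_cont
    }
  }
  loss <- loss / n
  if (!want_grads)
    return(list(loss = loss, H = H, preds = PRED))

  zero_like <- function(p) lapply(p, function(w) w * 0)
  gl <- lapply(params$layers, zero_like)
  gh <- zero_like(hd)
  dHcarry <- lapply(seq_len(L), function(l) matrix(0, d, n))
  dXhat_pending <- NULL        # grad wrt xhat produced at t, consumed at t-1

  for (t in rev(seq_len(tmax))) {
    rec <- st[[t]]
    # ---- head gradients at time t (predicting t+1) ----
    dZ <- matrix(0, 3L, n); dG <- matrix(0, .n_cont, n)
    have_head <- FALSE
    if (t < tmax) {
      Xtar <- data$X[, , t + 1L, drop = FALSE]; dim(Xtar) <- c(25L, n)
      Otar <- data$OBS[, , t + 1L, drop = FALSE]; dim(Otar) <- c(25L, n)
      wdx <- Otar[1L, ] * data$ALIVE[, t + 1L]
      dZ <- sweep(rec$P - Xtar[.dx_cols, , drop = FALSE], 2L, wdx, "*") / n
      wct <- Otar[.cont_cols(), , drop = FALSE] *
        rep(data$ALIVE[, t + 1L], each = .n_cont)
      dG <- wct * sign(rec$G - Xtar[.cont_cols(), , drop = FALSE]) /
        (.n_cont * n)
      have_head <- TRUE
    }
    if (mf && !stop_grad && !is.null(dXhat_pending)) {
      # clamp jacobian: no gradient where the filled value was clipped
      xhat_here <- rbind(rec$P, rec$G)
      dXhat_pending <- dXhat_pending * (abs(xhat_here) < .fill_clip)
      dP <- dXhat_pending[.dx_cols, , drop = FALSE]
      # softmax jacobian for a generic upstream gradient
      dZ <- dZ + rec$P * sweep(dP, 2L, colSums(rec$P * dP))
      dG <- dG + dXhat_pending[.cont_cols(), , drop = FALSE]
      have_head <- TRUE
    }
    dV <- matrix(0, d, n)
    if (have_head) {
      gh$Ws <- gh$Ws + dZ %*% t(rec$layers[[L]]$H)
      gh$bs <- gh$bs + rowSums(dZ)
      gh$Wg <- gh$Wg + dG %*% t(rec$layers[[L]]$H)
      gh$bg <- gh$bg + rowSums(dG)
      dV <- t(hd$Ws) %*% dZ + t(hd$Wg) %*% dG
    }
    dHcarry[[L]] <- dHcarry[[L]] + dV
    # ---- cell gradients, top layer down ----
    for (l in rev(seq_len(L))) {
      dH <- dHcarry[[l]]
      rl <- rec$layers[[l]]
      ly <- params$layers[[l]]
      if (params$type == "minimalrnn") {
        dF <- dH * (rl$Hprev - rl$U)
        dU <- dH * (1 - rl$Fg)
        dA <- dF * rl$Fg * (1 - rl$Fg)
        dU <- dU + t(ly$Uu) %*% dA
        dHprev <- dH * rl$Fg + t(ly$Uh) %*% dA
        if (!is.null(dropout)) {
          dHprev <- dH * rl$Fg + dropout$R[[l]] * (t(ly$Uh) %*% dA)
        }
        dZu <- dU * (1 - rl$U^2)
        gl[[l]]$Wu <- gl[[l]]$Wu + dZu %*% t(rl$V)
        gl[[l]]$bu <- gl[[l]]$bu + rowSums(dZu)
        gl[[l]]$Uh <- gl[[l]]$Uh + dA %*% t(rl$Hd)
        gl[[l]]$Uu <- gl[[l]]$Uu + dA %*% t(rl$U)
        gl[[l]]$bf <- gl[[l]]$bf + rowSums(dA)
        dVl <- t(ly$Wu) %*% dZu
      } else {
        dHprev <- t(ly$A) %*% dH
        if (!is.null(dropout)) dHprev <- dropout$R[[l]] * dHprev
        gl[[l]]$A <- gl[[l]]$A + dH %*% t(rl$Hd)
        gl[[l]]$B <- gl[[l]]$B + dH %*% t(rl$V)
        gl[[l]]$b <- gl[[l]]$b + rowSums(dH)
        dVl <- t(ly$B) %*% dH
      }
      dHcarry[[l]] <- dHprev
      if (l > 1L) dHcarry[[l - 1L]] <- dHcarry[[l - 1L]] + dVl
      else {
        dXin <- dVl
        dXt <- if (!is.null(dropout)) dropout$Din[, , t] * dXin else dXin
        if (mf && !stop_grad && t > 1L) {
          Ft <- data$FILL[, , t, drop = FALSE]; dim(Ft) <- c(25L, n)
          dXhat_pending <- Ft * dXt
        } else dXhat_pending <- NULL
      }
    }
  }
  grads <- list(layers = gl, heads = gh)
  list(loss = loss, grads = grads, H = H, preds = PRED)
}

# one Adam update in place; L2 applied to weight matrices only
.adam_step <- function(params, grads, state, lr, l2,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v, is_bias) {
    if (!is_bias && l2 > 0) g <- g + l2 * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^state$t)
    vh <- v / (1 - b2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  upd_group <- function(pg, gg, mg, vg) {
    for (nm in names(pg)) {
      r <- walk(pg[[nm]], gg[[nm]], mg[[nm]], vg[[nm]],
                is_bias = is.null(dim(pg[[nm]])))
      pg[[nm]] <- r$p; mg[[nm]] <- r$m; vg[[nm]] <- r$v
    }
    list(p = pg, m = mg, v = vg)
  }
  for (l in seq_along(params$layers)) {
    r <- upd_group(params$layers[[l]], grads$layers[[l]],
                   state$m$layers[[l]], state$v$layers[[l]])
    params$layers[[l]] <- r$p
    state$m$layers[[l]] <- r$m; state$v$layers[[l]] <- r$v
  }
  r <- upd_group(params$heads, grads$heads, state$m$heads, state$v$heads)
  params$heads <- r$p; state$m$heads <- r$m; state$v$heads <- r$v
  list(params = params, state = state)
}

.adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(w) w * 0)
  z <- list(layers = lapply(params$layers, zero_like),
            heads = zero_like(params$heads))
  list(t = 0L, m = z, v = z)
}

.make_dropout <- function(cfg, d, L, n, tmax) {
  if (cfg$input_dropout <= 0 && cfg$recurrent_dropout <= 0) return(NULL)
  pin <- cfg$input_dropout; pr <- cfg$recurrent_dropout
  Din <- array(1, c(25L, n, tmax))
  if (pin > 0)
    Din[] <- (array(stats::runif(25L * n * tmax), c(25L, n, tmax)) >= pin) /
      (1 - pin)
  R <- lapply(seq_len(L), function(l) {
    if (pr > 0) matrix((stats::runif(d * n) >= pr) / (1 - pr), d, n)
    else matrix(1, d, n)
  })
  list(Din = Din, R = R)
}

#' Train a progression model on a cohort
#'
#' Minimizes the masked multi-task loss ([sequence_loss()]) summed over
#' training subjects (mean per subject) plus an L2 weight penalty, with Adam
#' and backpropagation through time; the initial hidden state is zero. Under
#' the `"model"` filling strategy, missing inputs at step t are replaced by
#' the model's own prediction from step t-1 within the same forward pass,
#' with gradients flowing through the filled values (disable with
#' `stop_grad_fill` in the config). Training is deterministic given the
#' config seed.
#'
#' @param x training `ad_cohort` (raw scale; normalization statistics and
#'   fallback means are fitted from it unless supplied).
#' @param strategy `"forward"`, `"linear"` or `"model"` filling.
#' @param cfg a [train_config()].
#' @param val_cohort optional validation cohort (raw scale) used for
#'   best-snapshot selection when `cfg$val_every > 0`.
#' @param norm_stats,means optionally precomputed [fit_norm_stats()] /
#'   [fit_fallback_means()] (must then match the training subjects).
#' @return an object of class `progression_model` carrying the fitted
#'   parameters, config, strategy, normalization statistics and fallback
#'   means.
#' @export
train_progression_model <- function(x, strategy = c("forward", "linear",
                                                    "model"),
                                    cfg = train_config(), val_cohort = NULL,
                                    norm_stats = NULL, means = NULL) {
  strategy <- match.arg(strategy)
  if (!x$normalized) {
    if (is.null(norm_stats)) norm_stats <- fit_norm_stats(x)
    x <- znormalize(x, norm_stats)
  } else norm_stats <- x$norm_stats
  if (is.null(means)) means <- fit_fallback_means(x)
  data <- .stack_cohort(x, means, strategy)
  if (sum(data$OBS[, , -1L]) == 0)
    stop("no observed targets beyond the first timepoint; cannot train")

  params <- init_model(cfg$model, cfg$hidden, cfg$n_layers, in_dim = 25L,
                       seed = cfg$seed)
  state <- .adam_init(params)
  lr <- cfg$lr
  best <- NULL
  history <- numeric(0L)

  model_obj <- function(p) structure(
    list(params = p, cfg = cfg, strategy = strategy,
         norm_stats = norm_stats, means = means,
         resolution = x$resolution),
    class = "progression_model")

  .with_seed(cfg$seed + 1L, {
    nb <- if (is.finite(cfg$batch_size))
      ceiling(data$n / cfg$batch_size) else 1L
    for (ep in seq_len(cfg$epochs)) {
      idx_all <- if (nb > 1L) sample.int(data$n) else seq_len(data$n)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        idx <- idx_all[seq.int(b, length(idx_all), by = nb)]
        bdata <- if (nb > 1L) {
          bt <- max(data$lens[idx])    # trim padding to this batch
          list(X = data$X[, idx, seq_len(bt), drop = FALSE],
               OBS = data$OBS[, idx, seq_len(bt), drop = FALSE],
               FILL = data$FILL[, idx, seq_len(bt), drop = FALSE],
               ALIVE = data$ALIVE[idx, seq_len(bt), drop = FALSE],
               n = length(idx), tmax = bt)
        } else data
        dr <- .make_dropout(cfg, cfg$hidden, cfg$n_layers, bdata$n,
                            bdata$tmax)
        r <- .fb(params, bdata, strategy, dropout = dr,
                 stop_grad = cfg$stop_grad_fill)
        if (!is.finite(r$loss))
          stop("training diverged (loss not finite); try a lower ",
               "learning rate")
        up <- .adam_step(params, r$grads, state, lr, cfg$l2)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + r$loss * bdata$n / data$n
      }
      history[ep] <- ep_loss
      lr <- lr * cfg$lr_decay
      if (!is.null(val_cohort) && cfg$val_every > 0L &&
          (ep %% cfg$val_every == 0L || ep == cfg$epochs)) {
        sc <- .val_composite(model_obj(params), val_cohort)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, params = params)
      }
    }
  })
  if (!is.null(best)) params <- best$params
  out <- model_obj(params)
  out$loss_history <- history
  out$final_loss <- history[length(history)]
  out
}

#' @export
print.progression_model <- function(x, ...) {
  cat("<progression_model> ", x$params$type, " (", x$strategy,
      " filling), ", x$params$n_layers, " layer(s) x ", x$params$hidden,
      " units", sep = "")
  if (length(x$final_loss)) cat("; final training loss ",
                                signif(x$final_loss, 4), sep = "")
  cat("\n")
  invisible(x)
}

# validation composite: mAUC minus z-scale MAEs of the two continuous
# forecast targets, over the validation subjects' second-half timepoints
.val_composite <- function(model, val_cohort) {
  fc <- forecast_cohort(model, val_cohort)
  if (is.null(fc) || nrow(fc) == 0L) return(-Inf)
  ev <- evaluate_forecasts(fc, val_cohort, norm_stats = model$norm_stats,
                           z_scale = TRUE)
  mauc_v <- if (is.na(ev$mauc)) 0 else ev$mauc
  mauc_v - sum(c(ev$adas_mae, ev$ventricles_mae), na.rm = TRUE)
}
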