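#' Initialize parameters for a sequence model
#'
#' Two architectures share one interface. The minimal gated RNN transforms
#' the 25-dimensional input (3 one-hot diagnosis + 22 continuous markers)
#' with a tanh embedding and mixes it into the hidden state through a single
#' forget gate, so the new state is a coordinatewise convex combination of
#' the old state and the transformed input. The linear state-space (LSS)
#' model is its full linearization: the state update is strictly affine with
#' no gate and no nonlinearity. Both read out the next timepoint through a
#' softmax head (3 diagnosis probabilities) and an affine head (22
#' continuous predictions).
#'
#' Layers may be stacked: each layer's hidden state is the next layer's
#' input; the output heads read the top layer.
#'
#' @param type `"minimalrnn"` or `"lss"`.
#' @param hidden hidden-state size per layer.
#' @param n_layers number of stacked layers (1-3).
#' @param in_dim input dimension (25 for the standard schema).
#' @param seed integer seed for the weight draw.
#' @return a `model_params` list with per-layer weights and output heads.
#' @export
init_model <- function(type = c("minimalrnn", "lss"), hidden = 32L,
                       n_layers = 1L, in_dim = 25L, seed = 1L) {
  type <- match.arg(type)
  stopifnot(n_layers >= 1L, hidden >= 1L)
  .with_seed(seed, {
    glorot <- function(r, c) matrix(stats::runif(r * c, -1, 1) *
                                      sqrt(6 / (r + c)), r, c)
    layers <- lapply(seq_len(n_layers), function(l) {
      d_in <- if (l == 1L) in_dim else hidden
      if (type == "minimalrnn") {
        list(Wu = glorot(hidden, d_in), bu = numeric(hidden),
             Uh = glorot(hidden, hidden), Uu = glorot(hidden, hidden),
             bf = numeric(hidden))
      } else {
        list(A = diag(hidden) * 0.9 + glorot(hidden, hidden) * 0.1,
             B = glorot(hidden, d_in), b = numeric(hidden))
      }
    })
    heads <- list(Ws = glorot(3L, hidden), bs = numeric(3L),
                  Wg = glorot(.n_cont, hidden), bg = numeric(.n_cont))
    structure(list(type = type, hidden = as.integer(hidden),
                   n_layers = as.integer(n_layers),
                   in_dim = as.integer(in_dim),
                   layers = layers, heads = heads),
              class = "model_params")
  })
}

#' @export
print.model_params <- function(x, ...) {
  np <- sum(vapply(unlist(c(x$layers, list(x$heads)), recursive = FALSE),
                   length, integer(1L)))
  cat("<model_params> ", x$type, ": ", x$n_layers, " layer(s) x ",
      x$hidden, " hidden units, ", np, " parameters\n", sep = "")
  invisible(x)
}

#' One minimal-RNN cell update
#'
#' `u = tanh(Wu x + bu)`; forget gate `f = sigmoid(Uh h_prev + Uu u + bf)`;
#' `h = f * h_prev + (1 - f) * u` (elementwise). With all weights and biases
#' zero this reduces to `h = 0.5 * h_prev`; a large positive gate bias gives
#' `h ~ h_prev` (perfect memory).
#'
#' @param h_prev hidden vector (or matrix, columns = batch).
#' @param x input vector (or matrix).
#' @param layer list with `Wu`, `bu`, `Uh`, `Uu`, `bf`.
#' @return updated hidden state, same shape as `h_prev`.
#' @export
minimal_rnn_step <- function(h_prev, x, layer) {
  h_prev <- as.matrix(h_prev); x <- as.matrix(x)
  if (nrow(x) != ncol(layer$Wu) || nrow(h_prev) != ncol(layer$Uh))
    stop("shape mismatch in minimal_rnn_step")
  u <- tanh(layer$Wu %*% x + layer$bu)
  f <- stats::plogis(layer$Uh %*% h_prev + layer$Uu %*% u + layer$bf)
  h <- f * h_prev + (1 - f) * u
  if (ncol(h) == 1L) drop(h) else h
}

#' One linear state-space update
#'
#' `h = A h_prev + B x + b`: strictly linear, no gate, no nonlinearity.
#'
#' @param h_prev hidden vector (or matrix); @param x input vector (or
#'   matrix); @param layer list with `A`, `B`, `b`.
#' @export
lss_step <- function(h_prev, x, layer) {
  h_prev <- as.matrix(h_prev); x <- as.matrix(x)
  if (nrow(x) != ncol(layer$B) || nrow(h_prev) != ncol(layer$A))
    stop("shape mismatch in lss_step")
  h <- layer$A %*% h_prev + layer$B %*% x + layer$b
  if (ncol(h) == 1L) drop(h) else h
}

# numerically stable column softmax
.softmax <- function(z) {
  z <- as.matrix(z)
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Predict the next timepoint from a hidden state
#'
#' Softmax head for the 3-class diagnosis probabilities and affine head for
#' the 22 continuous markers, read from the (top-layer) hidden state.
#'
#' @param h hidden vector or matrix (columns = batch).
#' @param params a [init_model()] object.
#' @return list with `probs` (3-simplex) and `cont` (22-vector), or the
#'   matrix equivalents for batched input.
#' @export
predict_next <- function(h, params) {
  h <- as.matrix(h)
  p <- .softmax(params$heads$Ws %*% h + params$heads$bs)
  g <- params$heads$Wg %*% h + params$heads$bg
  if (ncol(h) == 1L) list(probs = drop(p), cont = drop(g))
  else list(probs = p, cont = g)
}

#' Masked multi-task sequence loss
#'
#' For predictions aligned one step ahead of the inputs: the cross-entropy
#' of the predicted diagnosis probabilities against the observed one-hot
#' diagnosis, plus the mean absolute error over the 22 continuous markers
#' (masked entries contribute nothing; the MAE term is normalized by the 22
#' predicted continuous variables). Missing targets are simply not scored.
#' The two terms are weighted equally.
#'
#' @param pred numeric matrix, one row per predicted timepoint, 25 columns
#'   (3 class probabilities then 22 continuous predictions).
#' @param target matching matrix of ground-truth values (one-hot diagnosis +
#'   continuous), rows aligned with `pred`.
#' @param observed matching T x 23 logical mask (diagnosis counted once).
#' @return scalar loss.
#' @export
sequence_loss <- function(pred, target, observed) {
  pred <- rbind(pred); target <- rbind(target); observed <- rbind(observed)
  stopifnot(nrow(pred) == nrow(target), nrow(pred) == nrow(observed),
            ncol(pred) == 25L, ncol(observed) == 23L)
  if (!any(observed)) stop("no observed target anywhere in the sequence")
  ce <- 0
  for (t in which(observed[, 1L])) {
    p <- pmax(pred[t, .dx_cols], 1e-12)
    ce <- ce - sum(target[t, .dx_cols] * log(p))
  }
  err <- abs(pred[, .cont_cols(), drop = FALSE] -
               target[, .cont_cols(), drop = FALSE])
  err[!observed[, .mask_cont_cols(), drop = FALSE]] <- 0
  ce + sum(err) / .n_cont
}
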