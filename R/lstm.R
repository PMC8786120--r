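# A minimal LSTM implemented from first principles. The recurrence is the
# standard cell:
#
#   c_t = z_f (.) c_{t-1} + z_i (.) z          (long-term memory)
#   h_t = z_o (.) tanh(c_t)                    (short-term output)
#   y_t = sigmoid(W' h_t)                      (scalar readout)
#
# with sigmoid-activated gates z_f (forget), z_i (input), z_o (output) and a
# tanh-activated candidate z, all driven by the concatenation [h_{t-1}, x_t]
# through one weight matrix W (columns ordered input|forget|output|candidate)
# plus bias b. Because the readout is sigmoid-bounded, series are min-max
# scaled into [0.1, 0.9] before training (see forecast.R).
#
# Gradients are exact backpropagation through time, batched over training
# windows so each epoch is a handful of dense matrix products.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialise LSTM parameters
#'
#' Small uniform weights scaled by 1/sqrt(fan-in); gate biases zero except
#' the forget gate, initialised to 1 so early training starts from a
#' remember-by-default cell.
#'
#' @param input_size input dimension per time step (1 for a scalar series).
#' @param hidden number of hidden units.
#' @param seed integer seed for the initial weights.
#' @return list of class `mw_lstm_params` with `W` ((input+hidden) x 4*hidden),
#'   `b` (4*hidden), `Wy` (hidden x 1), `hidden`, `input_size`.
#' @export
lstm_init <- function(input_size, hidden, seed) {
  k <- input_size + hidden
  s0 <- 1 / sqrt(k)
  par <- with_seed(as.integer(seed), {
    list(W = matrix(stats::runif(k * 4 * hidden, -s0, s0), k, 4 * hidden),
         b = c(rep(0, hidden), rep(1, hidden), rep(0, 2 * hidden)),
         Wy = matrix(stats::runif(hidden, -s0, s0), hidden, 1))
  })
  par$hidden <- as.integer(hidden)
  par$input_size <- as.integer(input_size)
  class(par) <- "mw_lstm_params"
  par
}

#' One LSTM cell update from explicit gate values
#'
#' The pure memory-update map: `c = zf*cprev + zi*z`, `h = zo*tanh(c)`,
#' `y = sigmoid(drop(Wy %*% h))`. Exposed separately from [lstm_step()] so
#' gate-level identities (pure memory, pure write) can be exercised
#' directly.
#'
#' @param z candidate vector (tanh-activated current information).
#' @param zf,zi,zo forget/input/output gate vectors in (0,1).
#' @param cprev previous cell state vector.
#' @param Wy readout matrix (hidden x 1), optional; if missing `y` is NULL.
#' @return list with `c`, `h`, and `y`.
#' @export
lstm_cell <- function(z, zf, zi, zo, cprev, Wy = NULL) {
  c_new <- zf * cprev + zi * z
  h <- zo * tanh(c_new)
  y <- if (is.null(Wy)) NULL else sigmoid(drop(crossprod(Wy, h)))
  list(c = c_new, h = h, y = y)
}

#' One LSTM time step from input and parameters
#'
#' Computes the four gate pre-activations from `[h_prev, x]`, applies the
#' activations (sigmoid gates, tanh candidate) and advances the cell via
#' [lstm_cell()].
#'
#' @param x input vector (length `input_size`).
#' @param state list with `h` and `c` vectors (length `hidden`).
#' @param params an [lstm_init()] parameter set.
#' @return list with `state` (new `h`, `c`) and scalar `y`.
#' @export
lstm_step <- function(x, state, params) {
  H <- params$hidden
  if (length(x) != params$input_size || length(state$h) != H) {
    stop("input/state shapes inconsistent with parameters", call. = FALSE)
  }
  a <- drop(c(state$h, x) %*% params$W) + params$b
  zi <- sigmoid(a[1:H])
  zf <- sigmoid(a[(H + 1):(2 * H)])
  zo <- sigmoid(a[(2 * H + 1):(3 * H)])
  z <- tanh(a[(3 * H + 1):(4 * H)])
  out <- lstm_cell(z, zf, zi, zo, state$c, params$Wy)
  list(state = list(h = out$h, c = out$c), y = out$y)
}

# Batched forward pass. X is an array (batch x T x input). Returns final
# sigmoid outputs and per-step caches for backpropagation.
lstm_forward <- function(X, params) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]; H <- params$hidden
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, params$input_size)
    a <- sweep(cbind(h, xt) %*% params$W, 2L, params$b, "+")
    zi <- sigmoid(a[, 1:H, drop = FALSE])
    zf <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    zo <- sigmoid(a[, (2 * H + 1):(3 * H), drop = FALSE])
    z <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    cprev <- cc; hprev <- h
    cc <- zf * cprev + zi * z
    tc <- tanh(cc)
    h <- zo * tc
    cache[[t]] <- list(xt = xt, hprev = hprev, cprev = cprev,
                       zi = zi, zf = zf, zo = zo, z = z, tc = tc)
  }
  y <- sigmoid(h %*% params$Wy)
  list(y = y, h = h, cache = cache)
}

# Mean-squared-error loss over the batch and exact BPTT gradients.
lstm_loss_grad <- function(X, target, params) {
  fw <- lstm_forward(X, params)
  B <- dim(X)[1L]; H <- params$hidden
  err <- fw$y - target
  loss <- mean(err^2)
  du <- (2 * err / B) * fw$y * (1 - fw$y)
  dWy <- crossprod(fw$h, du)
  dh <- du %*% t(params$Wy)
  dc <- matrix(0, B, H)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  db <- numeric(length(params$b))
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    dzo <- dh * cc$tc
    dc <- dc + dh * cc$zo * (1 - cc$tc^2)
    dzi <- dc * cc$z
    dz <- dc * cc$zi
    dzf <- dc * cc$cprev
    dc_prev <- dc * cc$zf
    da <- cbind(dzi * cc$zi * (1 - cc$zi),
                dzf * cc$zf * (1 - cc$zf),
                dzo * cc$zo * (1 - cc$zo),
                dz * (1 - cc$z^2))
    dW <- dW + crossprod(cbind(cc$hprev, cc$xt), da)
    db <- db + colSums(da)
    dh <- da %*% t(params$W[1:H, , drop = FALSE])
    dc <- dc_prev
  }
  list(loss = loss, dW = dW, db = db, dWy = dWy)
}

#' Finite-difference gradient of the LSTM training loss
#'
#' Central differences on every parameter entry; the independent check used
#' to validate the analytic backpropagation-through-time gradients.
#'
#' @param X batch array (batch x T x input).
#' @param target batch x 1 matrix of targets in (0,1).
#' @param params parameter set.
#' @param eps finite-difference step.
#' @return list with numeric gradients `dW`, `db`, `dWy`.
#' @export
lstm_numeric_grad <- function(X, target, params, eps = 1e-6) {
  loss_at <- function(p) mean((lstm_forward(X, p)$y - target)^2)
  out <- list()
  for (nm in c("W", "b", "Wy")) {
    g <- params[[nm]]
    for (k in seq_along(g)) {
      p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - eps
      g[k] <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    }
    out[[paste0("d", nm)]] <- g
  }
  out
}
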