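# Forecaster on top of the LSTM cell. Three numerical devices make the
# sigmoid-readout cell usable for tonnage-scale trending series:
#   1. trend normalisation — a log-linear trend is fitted by OLS and the
#      LSTM models the (stationary) multiplicative residual; the sigmoid
#      readout cannot emit values above the training range, which a growing
#      counterfactual continuation requires;
#   2. min-max scaling of the residual into (0, 1);
#   3. checkpoint selection by recursive validation on the series tail,
#      across several random restarts, averaging the best few models.
# Training is full-batch Adam on sliding windows with exact BPTT gradients.

#' Forecaster configuration
#'
#' Defaults are sized for a short monthly history (~72 points): a 12-month
#' lag window so one full seasonal cycle is visible per training example, a
#' small hidden layer, full-batch Adam, and model selection by recursive
#' validation on the last months of the series.
#'
#' @param window lag length in months (>= 1).
#' @param hidden hidden units (>= 1).
#' @param epochs maximum training epochs per restart.
#' @param learning_rate Adam step size.
#' @param patience epochs without a new best training loss before an early
#'   stop (only used when the series is too short for validation-based
#'   selection).
#' @param scale_bounds 2-vector: the interval the detrended series is
#'   min-max scaled into; must lie strictly inside (0, 1) because the
#'   readout is a sigmoid.
#' @param detrend `"loglinear"` (default: multiplicative residuals around a
#'   fitted exponential trend; falls back to `"linear"` if the series has
#'   nonpositive values), `"linear"` (additive residuals around an OLS
#'   line; exactly affine-equivariant), or `"none"`.
#' @param restarts number of random weight initialisations.
#' @param topk forecasts of the best `topk` restarts (by validation error)
#'   are averaged.
#' @param seed integer seed (mandatory) controlling weight initialisation.
#' @return list of class `mw_forecast_cfg`.
#' @export
forecast_config <- function(window = 12L, hidden = 10L, epochs = 700L,
                            learning_rate = 0.015, patience = 200L,
                            scale_bounds = c(0.1, 0.9),
                            detrend = c("loglinear", "linear", "none"),
                            restarts = 5L, topk = 3L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  detrend <- match.arg(detrend)
  if (window < 1L || hidden < 1L) stop("window and hidden must be >= 1", call. = FALSE)
  if (scale_bounds[1] <= 0 || scale_bounds[2] >= 1 || diff(scale_bounds) <= 0) {
    stop("scale_bounds must satisfy 0 < lo < hi < 1", call. = FALSE)
  }
  if (restarts < 1L || topk < 1L) stop("restarts and topk must be >= 1", call. = FALSE)
  structure(list(window = as.integer(window), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 patience = as.integer(patience), scale_bounds = scale_bounds,
                 detrend = detrend, restarts = as.integer(restarts),
                 topk = as.integer(min(topk, restarts)), seed = as.integer(seed)),
            class = "mw_forecast_cfg")
}

scale_series <- function(x, lo, hi, bounds) {
  if (hi == lo) return(rep(mean(bounds), length(x)))  # constant series
  bounds[1] + diff(bounds) * (x - lo) / (hi - lo)
}

unscale_series <- function(u, lo, hi, bounds) {
  if (hi == lo) return(rep(lo, length(u)))
  lo + (u - bounds[1]) * (hi - lo) / diff(bounds)
}

# Fit the trend component; returns residual series and an extrapolator.
fit_trend <- function(x, kind) {
  n <- length(x); tt <- seq_len(n)
  if (kind == "loglinear" && any(x <= 0)) kind <- "linear"
  switch(kind,
    none = list(kind = "none", resid = x, at = function(t) rep(0, length(t)),
                combine = function(trend, r) r),
    linear = {
      co <- stats::coef(stats::lm(x ~ tt))
      list(kind = "linear", resid = x - (co[1] + co[2] * tt),
           at = function(t) co[1] + co[2] * t,
           combine = function(trend, r) trend + r)
    },
    loglinear = {
      co <- stats::coef(stats::lm(log(x) ~ tt))
      tr <- exp(co[1] + co[2] * tt)
      list(kind = "loglinear", resid = x / tr,
           at = function(t) exp(co[1] + co[2] * t),
           combine = function(trend, r) trend * r)
    })
}

make_windows <- function(u, w) {
  n <- length(u) - w
  X <- array(0, c(n, w, 1L))
  for (k in seq_len(n)) X[k, , 1L] <- u[k:(k + w - 1L)]
  list(X = X, y = matrix(u[(w + 1L):length(u)], n, 1L))
}

# Recursive multi-step prediction in scaled space.
recursive_predict <- function(params, buf, w, horizon) {
  out <- numeric(horizon)
  for (k in seq_len(horizon)) {
    X1 <- array(utils::tail(buf, w), c(1L, w, 1L))
    yk <- lstm_forward(X1, params)$y[1L, 1L]
    out[k] <- yk
    buf <- c(buf, yk)
  }
  out
}

# One Adam training run from a given init seed. When val_h > 0, every 5th
# epoch the current parameters are scored by recursive forecasts over the
# held-out tail (two 4-step origins when val_h = 8) and the best checkpoint
# is returned; otherwise best-training-loss with patience.
train_restart <- function(u, cfg, init_seed, val_h) {
  n <- length(u)
  utr <- if (val_h > 0) u[seq_len(n - val_h)] else u
  dat <- make_windows(utr, cfg$window)
  par <- lstm_init(1L, cfg$hidden, init_seed)
  m <- list(W = par$W * 0, b = par$b * 0, Wy = par$Wy * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(score = Inf, par = par, loss = Inf)
  trace <- numeric(0)
  stall <- 0L
  val_score <- function(p) {
    origins <- seq.int(n - val_h, n - 4L, by = 4L)
    mean(vapply(origins, function(o) {
      pv <- recursive_predict(p, u[seq_len(o)], cfg$window, 4L)
      mean((pv - u[(o + 1L):(o + 4L)])^2)
    }, numeric(1)))
  }
  for (e in seq_len(cfg$epochs)) {
    g <- lstm_loss_grad(dat$X, dat$y, par)
    trace <- c(trace, g$loss)
    if (val_h > 0) {
      if (e %% 5L == 0L) {
        sc <- val_score(par)
        if (sc < best$score) best <- list(score = sc, par = par, loss = g$loss)
      }
    } else {
      if (g$loss < best$loss) {
        best <- list(score = g$loss, par = par, loss = g$loss)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    for (nm in c("W", "b", "Wy")) {
      gn <- g[[paste0("d", nm)]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gn
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gn^2
      par[[nm]] <- par[[nm]] -
        cfg$learning_rate * (m[[nm]] / (1 - b1^e)) / (sqrt(v[[nm]] / (1 - b2^e)) + eps)
    }
  }
  best$trace <- trace
  best
}

#' Fit the LSTM forecaster to a monthly series
#'
#' The series is detrended (see [forecast_config()]), the residual is
#' min-max scaled into `cfg$scale_bounds`, and the LSTM is trained by
#' full-batch Adam on sliding windows with next-value targets, with exact
#' backpropagation-through-time gradients. When the series is long enough,
#' the last 8 months are held out of the training windows and each
#' restart's checkpoints are scored by their recursive forecasts over that
#' tail; the best `cfg$topk` restarts are kept and their forecasts
#' averaged. Deterministic given `cfg$seed`.
#'
#' @param series an `mw_monthly` series (or numeric vector) of length
#'   greater than `cfg$window + 4`.
#' @param cfg an [forecast_config()].
#' @return object of class `mw_forecaster` holding the selected parameter
#'   sets, trend and scaling constants, the scaled history buffer, calendar
#'   position, and the training `loss_trace` of the best restart.
#' @export
fit_forecaster <- function(series, cfg) {
  stopifnot(inherits(cfg, "mw_forecast_cfg"))
  if (inherits(series, "mw_monthly") ||
      (is.data.frame(series) && "value" %in% names(series))) {
    series <- as_monthly_series(series)
    x <- series$value
    last_ym <- c(series$year[nrow(series)], series$month[nrow(series)])
  } else {
    x <- as.numeric(series)
    last_ym <- NULL
  }
  n <- length(x)
  if (n <= cfg$window + 4L) {
    stop("series too short for the configured window", call. = FALSE)
  }
  trend <- fit_trend(x, cfg$detrend)
  r <- trend$resid
  lo <- min(r); hi <- max(r)
  u <- scale_series(r, lo, hi, cfg$scale_bounds)
  val_h <- if (n >= cfg$window + 16L) 8L else if (n >= cfg$window + 9L) 4L else 0L
  runs <- lapply(seq_len(cfg$restarts), function(rr) {
    train_restart(u, cfg, (cfg$seed * 131L + rr) %% 2147483647L, val_h)
  })
  sel <- order(vapply(runs, `[[`, numeric(1), "score"))[seq_len(cfg$topk)]
  structure(list(models = lapply(runs[sel], `[[`, "par"),
                 loss = runs[[sel[1L]]]$loss,
                 loss_trace = runs[[sel[1L]]]$trace,
                 val_error = runs[[sel[1L]]]$score,
                 trend = trend, lo = lo, hi = hi, cfg = cfg,
                 n_train = n, u = u, last_ym = last_ym),
            class = "mw_forecaster")
}

#' Forecast future months
#'
#' Recursive multi-step prediction: each one-step-ahead prediction is fed
#' back as the newest input. The selected restarts' predictions are
#' averaged in scaled space, inverse-scaled, recombined with the
#' extrapolated trend, and clipped at 0.
#'
#' @param object a fitted `mw_forecaster`.
#' @param horizon number of months ahead (>= 0).
#' @param ... unused.
#' @return If the training series carried a calendar, an `mw_monthly`
#'   series continuing it; otherwise a numeric vector. `horizon = 0` gives
#'   an empty result. The training loss trace is attached as attribute
#'   `loss_trace`.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' @rdname forecast
#' @export
forecast.mw_forecaster <- function(object, horizon, ...) {
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  cfg <- object$cfg
  uo <- if (horizon > 0) {
    per_model <- vapply(object$models,
                        function(p) recursive_predict(p, object$u, cfg$window, horizon),
                        numeric(horizon))
    rowMeans(matrix(per_model, nrow = horizon))
  } else numeric(0)
  r <- unscale_series(uo, object$lo, object$hi, cfg$scale_bounds)
  tt <- object$n_train + seq_len(horizon)
  vals <- pmax(object$trend$combine(object$trend$at(tt), r), 0)
  res <- if (!is.null(object$last_ym) && horizon > 0) {
    idx <- object$last_ym[1L] * 12L + (object$last_ym[2L] - 1L) + seq_len(horizon)
    monthly_series(idx %/% 12L, idx %% 12L + 1L, vals)
  } else vals
  attr(res, "loss_trace") <- object$loss_trace
  res
}

seasonal_naive_forecast <- function(x, horizon, period = 12L) {
  n <- length(x)
  if (n < period) stop("series shorter than one period", call. = FALSE)
  x[n - period + ((seq_len(horizon) - 1L) %% period) + 1L]
}

sarima_forecast <- function(x, horizon, period = 12L) {
  xt <- stats::ts(x, frequency = period)
  fit <- tryCatch(
    stats::arima(xt, order = c(1L, 0L, 0L),
                 seasonal = list(order = c(0L, 1L, 1L), period = period),
                 method = "CSS-ML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::arima(xt, order = c(0L, 1L, 1L),
                   seasonal = list(order = c(0L, 1L, 0L), period = period)),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(seasonal_naive_forecast(x, horizon, period))
  as.numeric(stats::predict(fit, n.ahead = horizon)$pred)
}

#' Forecast-accuracy metrics
#'
#' MAE, RMSE and MAPE (percent). MAPE is computed over months with nonzero
#' actuals only; if any actual is zero a warning is raised and those months
#' are excluded (NaN if all are zero).
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return named numeric vector `mae`, `rmse`, `mape`.
#' @export
forecast_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  err <- predicted - actual
  nz <- actual != 0
  if (!all(nz)) warning("zero actuals excluded from MAPE")
  mape <- if (any(nz)) 100 * mean(abs(err[nz] / actual[nz])) else NaN
  c(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), mape = mape)
}

#' Compare forecasting models on a holdout
#'
#' Splits the series into head and tail, fits each candidate on the head
#' and scores its `holdout`-step forecast against the tail: the LSTM, a
#' seasonal-naive repeater (same month last year), and a seasonal ARIMA
#' baseline (via [stats::arima()]).
#'
#' @param series an `mw_monthly` series or numeric vector.
#' @param holdout number of final months held out; must be positive and
#'   less than half the series length.
#' @param cfg an [forecast_config()] for the LSTM candidate.
#' @param models character subset of `c("lstm", "seasonal_naive", "sarima")`.
#' @return data.frame with one row per model: `model`, `mae`, `rmse`,
#'   `mape`.
#' @export
compare_models <- function(series, holdout, cfg,
                           models = c("lstm", "seasonal_naive", "sarima")) {
  x <- if (is.numeric(series)) as.numeric(series) else as_monthly_series(series)$value
  n <- length(x)
  if (holdout < 1L || holdout >= n / 2) {
    stop("holdout must be >= 1 and < half the series length", call. = FALSE)
  }
  head_x <- x[seq_len(n - holdout)]
  tail_x <- x[(n - holdout + 1L):n]
  preds <- list()
  for (mdl in models) {
    preds[[mdl]] <- switch(mdl,
      lstm = as.numeric(forecast(fit_forecaster(head_x, cfg), holdout)),
      seasonal_naive = seasonal_naive_forecast(head_x, holdout),
      sarima = sarima_forecast(head_x, holdout),
      stop("unknown model: ", mdl, call. = FALSE))
  }
  out <- do.call(rbind, lapply(names(preds), function(nm) {
    mt <- forecast_metrics(tail_x, preds[[nm]])
    data.frame(model = nm, mae = mt[["mae"]], rmse = mt[["rmse"]],
               mape = mt[["mape"]])
  }))
  rownames(out) <- NULL
  out
}
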