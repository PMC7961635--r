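# Real-time filtering and differentiation: a circular buffer of M
# samples per channel, a windowed-sinc low-pass FIR, and a smoothing
# spline (smoothing level chosen by generalized cross-validation each
# step) evaluated, together with its first two derivatives, at the
# delayed time t_d = t - D/fs. Four hyper-parameters: memory M, cutoff
# fc, spline order Ns and lag D.

#' Filter configuration
#'
#' @param M buffer memory (samples).
#' @param fc low-pass cutoff (Hz), `0 < fc < fs/2`.
#' @param Ns spline order (3 = cubic; the only order currently
#'   implemented, matching the default used for gait).
#' @param D evaluation lag (samples), `0 <= D < M`.
#' @param fs sampling frequency (Hz).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(M = 35, fc = 6, Ns = 3, D = 14, fs = 100) {
  if (!(fc > 0 && fc < fs / 2)) stop("need 0 < fc < fs/2")
  if (!(D >= 0 && D < M)) stop("need 0 <= D < M")
  if (M < Ns + 2) stop("need M >= Ns + 2")
  if (Ns != 3) stop("only cubic smoothing splines (Ns = 3) are implemented")
  structure(list(M = as.integer(M), fc = fc, Ns = as.integer(Ns),
                 D = as.integer(D), fs = fs), class = "filter_config")
}

#' Design a windowed-sinc low-pass FIR kernel
#'
#' Length-`M` sinc kernel tapered by a Hamming window and normalized to
#' unit DC gain; symmetric, hence linear-phase.
#'
#' @param M kernel length (samples).
#' @param fc cutoff frequency (Hz).
#' @param fs sampling frequency (Hz).
#' @return numeric vector of `M` coefficients summing to 1.
#' @export
design_fir <- function(M, fc, fs) {
  if (!(fc > 0 && fc < fs / 2)) stop("need 0 < fc < fs/2")
  n <- seq_len(M) - 1
  m <- (M - 1) / 2
  x <- 2 * fc / fs * (n - m)
  h <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / (M - 1))
  k <- h * w
  k / sum(k)
}

# zero-phase 'same' convolution of a symmetric kernel. The signal is
# extended by odd (point) reflection about its endpoints before
# convolving, so every output has full kernel support; point reflection
# preserves value and slope continuity at the ends, which keeps the
# edge bias small enough for spline differentiation near (not at) the
# window edges.
fir_same <- function(y, kernel) {
  M <- length(kernel)
  n <- length(y)
  c0 <- (M + 1) %/% 2
  pl <- c0 - 1
  pr <- M - c0
  if (n <= max(pl, pr)) stop("signal shorter than half the kernel")
  left <- if (pl > 0) 2 * y[1] - y[(pl + 1):2] else numeric(0)
  right <- if (pr > 0) 2 * y[n] - y[(n - 1):(n - pr)] else numeric(0)
  yp <- c(left, y, right)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(yp[i:(i + M - 1)] * kernel)
  out
}

# GCV cubic smoothing spline value + first two derivatives at x_out.
# Falls back to an exact cubic polynomial fit for degenerate windows
# (near-constant signal, or GCV failure on tiny samples).
spline_eval <- function(x, y, x_out) {
  if (stats::sd(y) < 1e-12 * (1 + max(abs(y)))) {
    return(c(value = mean(y), d1 = 0, d2 = 0))
  }
  fit <- tryCatch(
    stats::smooth.spline(x, y, cv = FALSE, all.knots = TRUE,
                         keep.data = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    xc <- x - mean(x)
    co <- stats::coef(stats::lm(y ~ xc + I(xc^2) + I(xc^3)))
    co[is.na(co)] <- 0
    xo <- x_out - mean(x)
    return(c(value = co[1] + co[2] * xo + co[3] * xo^2 + co[4] * xo^3,
             d1 = co[2] + 2 * co[3] * xo + 3 * co[4] * xo^2,
             d2 = 2 * co[3] + 6 * co[4] * xo))
  }
  c(value = stats::predict(fit, x_out)$y,
    d1 = stats::predict(fit, x_out, deriv = 1)$y,
    d2 = stats::predict(fit, x_out, deriv = 2)$y)
}

#' Create a real-time filter
#'
#' @param config a [filter_config()].
#' @param channels number of signal channels (filtered independently).
#' @param channel_names optional channel names.
#' @return object of class `rt_filter` holding the (initially empty)
#'   circular buffer.
#' @export
rt_filter <- function(config, channels, channel_names = NULL) {
  structure(list(
    config = config,
    kernel = design_fir(config$M, config$fc, config$fs),
    buffer = matrix(NA_real_, nrow = config$M, ncol = channels),
    times = rep(NA_real_, config$M),
    count = 0L,
    channel_names = channel_names %||% paste0("ch", seq_len(channels))),
    class = "rt_filter")
}

#' Push a sample and evaluate the filter
#'
#' Appends one frame to the circular buffer. Once the buffer holds `M`
#' samples, the window is FIR-filtered, a GCV smoothing spline is fitted
#' to the filtered window, and its value and first two derivatives are
#' returned at the delayed time `t_d = t - D/fs`. Before that the status
#' is `"warming_up"`.
#'
#' @param filt an [rt_filter()].
#' @param t sample timestamp (s); samples must arrive at constant `fs`.
#' @param x numeric vector (one value per channel).
#' @return list with the updated `filter` and `output` (`NULL` while
#'   warming up, else a `filter_output` with `t_d`, `value`, `d1`, `d2`).
#' @export
push_and_evaluate <- function(filt, t, x) {
  cfg <- filt$config
  x <- as.numeric(x)
  if (length(x) != ncol(filt$buffer)) stop("channel count mismatch")
  if (filt$count < cfg$M) {
    filt$count <- filt$count + 1L
    filt$buffer[filt$count, ] <- x
    filt$times[filt$count] <- t
  } else {
    filt$buffer <- rbind(filt$buffer[-1, , drop = FALSE], x)
    filt$times <- c(filt$times[-1], t)
  }
  if (filt$count < cfg$M) {
    return(list(filter = filt, output = NULL, status = "warming_up"))
  }
  t_d <- t - cfg$D / cfg$fs
  vals <- matrix(NA_real_, nrow = 3, ncol = ncol(filt$buffer),
                 dimnames = list(c("value", "d1", "d2"),
                                 filt$channel_names))
  for (ci in seq_len(ncol(filt$buffer))) {
    yf <- fir_same(filt$buffer[, ci], filt$kernel)
    vals[, ci] <- spline_eval(filt$times, yf, t_d)
  }
  out <- structure(list(t_d = t_d, value = vals["value", ],
                        d1 = vals["d1", ], d2 = vals["d2", ]),
                   class = "filter_output")
  list(filter = filt, output = out, status = "ok")
}

#' Run the real-time filter over a full signal
#'
#' Convenience wrapper feeding samples one by one; returns one row per
#' produced output (the first `M - 1` samples only warm the buffer up).
#'
#' @param config a [filter_config()].
#' @param time vector of timestamps at constant `fs`.
#' @param X numeric matrix, samples x channels.
#' @return list of data.frames `value`, `d1`, `d2`, each with a `t_d`
#'   column followed by one column per channel.
#' @export
filter_stream <- function(config, time, X) {
  X <- as.matrix(X)
  filt <- rt_filter(config, ncol(X), colnames(X))
  rows <- list()
  for (i in seq_along(time)) {
    st <- push_and_evaluate(filt, time[i], X[i, ])
    filt <- st$filter
    if (!is.null(st$output)) rows[[length(rows) + 1]] <- st$output
  }
  pack <- function(field) {
    df <- do.call(rbind, lapply(rows, function(o)
      c(o$t_d, o[[field]])))
    df <- as.data.frame(df)
    names(df) <- c("t_d", filt$channel_names)
    df
  }
  list(value = pack("value"), d1 = pack("d1"), d2 = pack("d2"))
}

#' Offline (whole-trial) reference filter
#'
#' The non-causal comparator for tuning and testing: zero-phase low-pass
#' (the same symmetric windowed-sinc kernel, centered) over the whole
#' trial, followed by one GCV smoothing spline per channel over all
#' samples. Returns values and first/second derivatives at the original
#' sample times.
#'
#' @param time vector of timestamps (uniform).
#' @param X numeric matrix, samples x channels.
#' @param fc cutoff (Hz).
#' @param Ns spline order (3).
#' @param kernel_length FIR length used for the zero-phase pass.
#' @return list of matrices `value`, `d1`, `d2` (samples x channels) plus
#'   `time`.
#' @export
offline_reference <- function(time, X, fc = 6, Ns = 3, kernel_length = 35) {
  X <- as.matrix(X)
  if (nrow(X) < kernel_length)
    stop("trial shorter than the filter warm-up window")
  if (Ns != 3) stop("only cubic splines (Ns = 3) are implemented")
  fs <- 1 / stats::median(diff(time))
  kernel <- design_fir(kernel_length, fc, fs)
  out <- list(value = X * NA, d1 = X * NA, d2 = X * NA, time = time)
  for (ci in seq_len(ncol(X))) {
    yf <- fir_same(X[, ci], kernel)
    if (stats::sd(yf) < 1e-12 * (1 + max(abs(yf)))) {
      out$value[, ci] <- mean(yf); out$d1[, ci] <- 0; out$d2[, ci] <- 0
      next
    }
    fit <- stats::smooth.spline(time, yf, cv = FALSE, keep.data = FALSE)
    out$value[, ci] <- stats::predict(fit, time)$y
    out$d1[, ci] <- stats::predict(fit, time, deriv = 1)$y
    out$d2[, ci] <- stats::predict(fit, time, deriv = 2)$y
  }
  out
}

#' Grid search for the filter memory and lag
#'
#' Runs the real-time filter over `X` for every `(M, D)` grid point and
#' scores coordinate, speed and acceleration RMSE against a comparator
#' (analytic truth or [offline_reference()] output), aligned at the
#' delayed evaluation times. The selected point minimizes acceleration
#' RMSE — the quantity that dominates downstream inverse dynamics — with
#' ties broken toward smaller `M`, then smaller `D`.
#'
#' @param time,X the signal (uniform sampling).
#' @param truth list with matrices `value`, `d1`, `d2` aligned with
#'   `time` (e.g. analytic derivatives, or an offline reference).
#' @param M_grid,D_grid integer grids; `D >= M` entries are skipped.
#' @param fc,Ns,fs fixed filter parameters.
#' @return list with `M`, `D`, and `rmse` (data.frame with one row per
#'   evaluated grid point: M, D, rmse_q, rmse_u, rmse_a).
#' @export
tune_hyperparameters <- function(time, X, truth, M_grid, D_grid,
                                 fc = 6, Ns = 3, fs = 100) {
  X <- as.matrix(X)
  if (length(M_grid) == 0 || length(D_grid) == 0) stop("empty grid")
  rows <- list()
  for (M in sort(unique(as.integer(M_grid)))) {
    for (D in sort(unique(as.integer(D_grid)))) {
      if (D >= M || M < Ns + 2) next
      cfg <- filter_config(M = M, fc = fc, Ns = Ns, D = D, fs = fs)
      res <- filter_stream(cfg, time, X)
      # output i corresponds to input sample (M - 1 + i) - D
      idx_out <- seq_len(nrow(res$value))
      idx_truth <- (cfg$M - 1 + idx_out) - cfg$D
      keep <- idx_truth >= 1 & idx_truth <= nrow(X)
      rmse <- function(field, tf) {
        est <- as.matrix(res[[field]][keep, -1, drop = FALSE])
        ref <- truth[[tf]][idx_truth[keep], , drop = FALSE]
        sqrt(mean((est - ref)^2))
      }
      rows[[length(rows) + 1]] <- data.frame(
        M = M, D = D, rmse_q = rmse("value", "value"),
        rmse_u = rmse("d1", "d1"), rmse_a = rmse("d2", "d2"))
    }
  }
  if (length(rows) == 0) stop("grid contained no valid (M, D) points")
  tab <- do.call(rbind, rows)
  ord <- order(tab$rmse_a, tab$M, tab$D)
  best <- tab[ord[1], ]
  list(M = best$M, D = best$D, rmse = tab)
}
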