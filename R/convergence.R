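#' Scalar observable time series
#'
#' Uniformly spaced scalar observations with a time step in femtoseconds.
#' The module is unit-agnostic in the observable: the label is echoed in
#' outputs, never interpreted.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param dt time between observations in fs (> 0).
#' @param label observable name/units for reporting.
#' @return An object of class `md_timeseries`.
#' @export
time_series <- function(values, dt = 1, label = "observable") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("time series needs at least 2 values")
  if (!(dt > 0)) stop("dt must be > 0")
  if (any(!is.finite(values))) stop("non-finite values in time series")
  structure(list(values = values, dt = dt, label = label),
            class = "md_timeseries")
}

#' Read a two-column (time, value) CSV as a time series
#'
#' The time step is inferred from the first two time entries unless given
#' explicitly. Units are the caller's concern.
#'
#' @param path CSV path with header and columns time, value.
#' @param dt optional explicit time step (fs); overrides the file.
#' @param label observable label.
#' @export
read_series_csv <- function(path, dt = NULL, label = NULL) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("series CSV must have two columns (time, value)")
  if (is.null(dt)) dt <- diff(tab[[1]])[1]
  time_series(tab[[2]], dt = dt,
              label = if (is.null(label)) names(tab)[2] else label)
}

#' Normalized autocorrelation function
#'
#' ACF(k) = C(k)/C(0) with C(k) the mean-removed lag-k autocovariance using
#' the biased 1/N normalization (the standard choice when integrating the
#' ACF to a correlation time).
#'
#' @param series an `md_timeseries` (or numeric vector).
#' @param max_lag largest lag, in samples (< N).
#' @return data.frame with columns `lag` (samples), `lag_fs`, `acf`.
#' @export
acf_series <- function(series, max_lag = NULL) {
  if (!inherits(series, "md_timeseries")) series <- time_series(series)
  x <- series$values
  N <- length(x)
  if (stats::var(x) == 0) stop("degenerate series: zero variance")
  if (is.null(max_lag)) max_lag <- min(N - 1L, 2000L)
  max_lag <- as.integer(max_lag)
  if (max_lag >= N) stop("max_lag must be smaller than the series length")
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  data.frame(lag = 0:max_lag, lag_fs = (0:max_lag) * series$dt, acf = rho)
}

#' Standard error of the mean via the autocorrelation function
#'
#' Computes the statistical inefficiency
#' g = 1 + 2 * sum_k (1 - k/N) ACF(k), truncating the sum at the first lag
#' with a negative ACF (conservative first-negative-crossing rule), and
#' reports sem = s * sqrt(g/N), the integrated autocorrelation time
#' tau_int = g * dt / 2, and the effective sample count N/g.
#'
#' @inheritParams acf_series
#' @return An `md_error_estimate` list: mean, sem, method = "acf", g,
#'   tau_int_fs, n_eff, truncation_lag.
#' @export
sem_acf <- function(series, max_lag = NULL) {
  if (!inherits(series, "md_timeseries")) series <- time_series(series)
  x <- series$values
  N <- length(x)
  ac <- acf_series(series, max_lag)
  rho <- ac$acf[-1] # lags 1..max_lag
  neg <- which(rho < 0)
  K <- if (length(neg)) neg[1] - 1L else length(rho)
  g <- if (K >= 1) {
    k <- seq_len(K)
    1 + 2 * sum((1 - k / N) * rho[k])
  } else 1
  s <- stats::sd(x)
  structure(list(mean = mean(x), sem = s * sqrt(g / N), method = "acf",
                 g = g, tau_int_fs = g * series$dt / 2, n_eff = N / g,
                 truncation_lag = K, n = N, label = series$label),
            class = "md_error_estimate")
}

#' @export
print.md_error_estimate <- function(x, ...) {
  cat(sprintf("%s: mean = %.6g, sem = %.3g (%s)\n",
              x$label %||% "observable", x$mean, x$sem, x$method))
  if (x$method == "acf") {
    cat(sprintf("  g = %.3g, tau_int = %.3g fs, n_eff = %.4g of %d\n",
                x$g, x$tau_int_fs, x$n_eff, x$n))
  } else {
    cat(sprintf("  n_blocks = %d, block_size = %d samples\n",
                x$n_blocks, x$block_size))
  }
  invisible(x)
}

#' Standard error of the mean by block averaging
#'
#' Splits the series into `n_blocks` contiguous equal-length blocks (any
#' tail remainder is dropped) and reports the standard deviation of block
#' means divided by sqrt(n_blocks), with the (n_blocks - 1) denominator in
#' the block-mean variance.
#'
#' @inheritParams acf_series
#' @param n_blocks number of blocks, in [2, N/2].
#' @return An `md_error_estimate` list: mean, sem, method = "block",
#'   n_blocks, block_size.
#' @export
block_sem <- function(series, n_blocks) {
  if (!inherits(series, "md_timeseries")) series <- time_series(series)
  x <- series$values
  N <- length(x)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2 || n_blocks > N) stop("n_blocks must be in [2, N]")
  bs <- N %/% n_blocks
  use <- bs * n_blocks
  bm <- colMeans(matrix(x[seq_len(use)], nrow = bs, ncol = n_blocks))
  structure(list(mean = mean(x), sem = stats::sd(bm) / sqrt(n_blocks),
                 method = "block", n_blocks = n_blocks, block_size = bs,
                 n = N, label = series$label),
            class = "md_error_estimate")
}

#' Block-size scan with automatic plateau selection
#'
#' Evaluates the block-averaging SEM over a (by default logarithmically
#' spaced) set of block counts and selects the plateau estimate: walking
#' from small to large blocks, the first window of three consecutive SEM
#' values that pairwise differ by less than 10 percent marks convergence,
#' and the plateau SEM is the median of that window. If no window
#' qualifies, the median of the three largest-block SEMs is returned with
#' `converged = FALSE`.
#'
#' @inheritParams acf_series
#' @param block_counts integer vector of block counts; default is ~24
#'   log-spaced values between N/4 and 4.
#' @return List with `curve` (data.frame n_blocks, block_size, sem),
#'   `plateau_sem`, `plateau_block_size`, `converged`.
#' @export
block_scan <- function(series, block_counts = NULL) {
  if (!inherits(series, "md_timeseries")) series <- time_series(series)
  N <- length(series$values)
  if (is.null(block_counts)) {
    hi <- max(4, N %/% 4)
    block_counts <- unique(round(10^seq(log10(hi), log10(4),
                                        length.out = 24)))
  }
  block_counts <- sort(unique(as.integer(block_counts)), decreasing = TRUE)
  block_counts <- block_counts[block_counts >= 2 & block_counts <= N %/% 2]
  if (length(block_counts) < 3) {
    stop("insufficient data: need at least 3 valid block counts")
  }
  sems <- vapply(block_counts, function(nb) block_sem(series, nb)$sem,
                 numeric(1))
  sizes <- N %/% block_counts
  # ordered by increasing block size already (decreasing n_blocks)
  plateau <- NA_real_; pbs <- NA_integer_; converged <- FALSE
  rel <- function(a, b) {
    if (a == 0 && b == 0) 0 else abs(a - b) / max(abs(a), abs(b))
  }
  for (t in seq_len(length(sems) - 2)) {
    w <- sems[t:(t + 2)]
    if (rel(w[1], w[2]) < 0.10 && rel(w[2], w[3]) < 0.10 &&
        rel(w[1], w[3]) < 0.10) {
      plateau <- stats::median(w)
      pbs <- sizes[t]
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    last <- sems[(length(sems) - 2):length(sems)]
    plateau <- stats::median(last)
    pbs <- sizes[length(sizes) - 2]
  }
  list(curve = data.frame(n_blocks = block_counts, block_size = sizes,
                          sem = sems),
       plateau_sem = plateau, plateau_block_size = pbs,
       converged = converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
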