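#' Unwrap periodic trajectories
#'
#' Reconstructs continuous Cartesian paths from wrapped coordinates by
#' accumulating minimum-image frame-to-frame displacements. Valid whenever
#' no tracked atom moves more than half the minimal cell height between
#' consecutive stored frames; larger jumps are ambiguous and raise an
#' error (use a smaller frame_skip).
#'
#' @param traj an `md_trajectory` with a periodic cell.
#' @param indices 1-based atom indices to track (default all).
#' @return Array of dim (n_frames, n_atoms_tracked, 3), Angstrom.
#' @export
unwrap_trajectory <- function(traj, indices = seq_len(n_atoms(traj))) {
  indices <- as.integer(indices)
  nf <- n_frames(traj)
  na <- length(indices)
  U <- array(0, dim = c(nf, na, 3))
  U[1, , ] <- traj$frames[[1]]$positions[indices, , drop = FALSE]
  if (nf == 1) return(U)
  for (f in 2:nf) {
    cell <- frame_cell(traj, f)
    hh <- half_min_cell_height(cell)
    d <- min_image(traj$frames[[f]]$positions[indices, , drop = FALSE] -
                   traj$frames[[f - 1]]$positions[indices, , drop = FALSE],
                   cell)
    if (is.finite(hh) && any(rowSums(d^2) >= hh^2 * (1 - 1e-9))) {
      stop("unwrap ambiguity at frame ", f,
           ": per-frame displacement exceeds half the cell height; ",
           "store frames more often (smaller frame_skip)")
    }
    U[f, , ] <- U[f - 1, , ] + d
  }
  U
}

#' Windowed mean-square displacement
#'
#' Time-origin-averaged MSD on unwrapped paths:
#' M(tau) = < |r(t0 + tau) - r(t0)|^2 > over all origins t0 (stride
#' `origin_stride`) and all selected atoms. Lag 0 is included with value 0.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to average over (`md_selection`, element vector,
#'   or indices).
#' @param max_lag largest lag in frames (< number of frames).
#' @param origin_stride origin spacing in frames (1 = every origin,
#'   maximal averaging).
#' @return An `md_msd` list: `lag_fs`, `msd` (Angstrom^2), `n_origins`,
#'   `mode`, `dt_fs`, `n_atoms`.
#' @export
msd_windowed <- function(traj, selection = select_all(), max_lag = NULL,
                         origin_stride = 1) {
  idx <- resolve_selection(traj, selection)
  if (!length(idx)) stop("empty selection for MSD")
  nf <- n_frames(traj)
  if (is.null(max_lag)) max_lag <- nf - 1L
  max_lag <- as.integer(max_lag)
  if (max_lag >= nf) stop("max_lag must be smaller than the frame count")
  U <- unwrap_trajectory(traj, idx)
  msd <- numeric(max_lag + 1L)
  nor <- integer(max_lag + 1L)
  nor[1] <- length(seq(1L, nf, by = origin_stride))
  for (tau in seq_len(max_lag)) {
    org <- seq(1L, nf - tau, by = origin_stride)
    d <- U[org + tau, , , drop = FALSE] - U[org, , , drop = FALSE]
    msd[tau + 1L] <- mean(d * d) * 3 # mean over squared norm components
    nor[tau + 1L] <- length(org)
  }
  structure(list(lag_fs = (0:max_lag) * traj$timestep, msd = msd,
                 n_origins = nor, mode = "windowed",
                 dt_fs = traj$timestep, n_atoms = length(idx)),
            class = "md_msd")
}

#' Single-origin mean-square displacement
#'
#' MSD measured from the first frame only, the fast but noisier
#' alternative to the windowed scheme.
#'
#' @inheritParams msd_windowed
#' @export
msd_single_origin <- function(traj, selection = select_all(),
                              max_lag = NULL) {
  idx <- resolve_selection(traj, selection)
  if (!length(idx)) stop("empty selection for MSD")
  nf <- n_frames(traj)
  if (is.null(max_lag)) max_lag <- nf - 1L
  U <- unwrap_trajectory(traj, idx)
  msd <- vapply(0:max_lag, function(tau) {
    d <- U[1L + tau, , , drop = FALSE] - U[1L, , , drop = FALSE]
    mean(d * d) * 3
  }, numeric(1))
  structure(list(lag_fs = (0:max_lag) * traj$timestep, msd = msd,
                 n_origins = rep(1L, max_lag + 1L), mode = "single_origin",
                 dt_fs = traj$timestep, n_atoms = length(idx)),
            class = "md_msd")
}

#' Einstein-relation diffusion coefficient with sub-window SEM
#'
#' Fits M(t) ~ 2 d D t + b by least squares. The fit interval is split
#' into `n_subwindows` contiguous equal sub-intervals, each fitted
#' independently; the headline D is the mean of the sub-window estimates
#' and sem_D their standard deviation over sqrt(n_subwindows). With a
#' single sub-window the result is exactly the global least-squares fit
#' (sem reported as 0 and flagged). Lags are fs, MSD Angstrom^2; D is
#' returned in Angstrom^2/ps.
#'
#' @param msd an `md_msd`.
#' @param d dimensionality of the diffusive motion (1, 2 or 3).
#' @param fit_range length-2 numeric, fs interval of lags to fit
#'   (default: all available lag times).
#' @param n_subwindows number of independent sub-window fits (>= 1).
#' @return An `md_diffusion` list: `D_A2_per_ps`, `sem_D`, `intercept_A2`,
#'   `d`, `fit_range_fs`, `n_subwindows`, `D_sub`, `sem_defined`.
#' @export
fit_diffusion <- function(msd, d = 3, fit_range = NULL, n_subwindows = 5) {
  stopifnot(d %in% 1:3)
  n_subwindows <- as.integer(n_subwindows)
  if (n_subwindows < 1) stop("n_subwindows must be >= 1")
  if (is.null(fit_range)) fit_range <- range(msd$lag_fs)
  sel <- which(msd$lag_fs >= fit_range[1] & msd$lag_fs <= fit_range[2])
  if (length(sel) < 2L * n_subwindows) {
    stop("fit range must contain at least 2 lag points per sub-window")
  }
  groups <- split(sel, ceiling(seq_along(sel) / (length(sel) / n_subwindows)))
  fits <- lapply(groups, function(ix) {
    t <- msd$lag_fs[ix]
    if (stats::var(t) == 0) stop("degenerate sub-window: constant lag time")
    stats::coef(stats::lm(msd$msd[ix] ~ t))
  })
  slopes <- vapply(fits, `[[`, numeric(1), 2L)       # A^2 / fs
  intercepts <- vapply(fits, `[[`, numeric(1), 1L)   # A^2
  D_sub <- slopes / (2 * d) * 1000                   # A^2 / ps
  D <- mean(D_sub)
  sem <- if (n_subwindows > 1) stats::sd(D_sub) / sqrt(n_subwindows) else 0
  structure(list(D_A2_per_ps = D, sem_D = sem,
                 intercept_A2 = mean(intercepts), d = d,
                 fit_range_fs = fit_range, n_subwindows = n_subwindows,
                 D_sub = unname(D_sub),
                 sem_defined = n_subwindows > 1),
            class = "md_diffusion")
}

#' @export
print.md_diffusion <- function(x, ...) {
  cat(sprintf("D = %.4g +/- %.2g A^2/ps (d = %d, %d sub-windows, fit %g-%g fs)\n",
              x$D_A2_per_ps, x$sem_D, x$d, x$n_subwindows,
              x$fit_range_fs[1], x$fit_range_fs[2]))
  if (!x$sem_defined) cat("  (single sub-window: SEM undefined, reported 0)\n")
  invisible(x)
}
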