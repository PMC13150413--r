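#' Rotation/translation/permutation-invariant structure descriptors
#'
#' The built-in descriptor is a per-structure histogram of all pairwise
#' interatomic distances over [0, r_max], normalized by the number of
#' pairs. It is invariant under rigid motions and atom reordering, which
#' makes it a cheap, dependency-free stand-in for the environment
#' descriptors (e.g. SOAP) usually used to fingerprint configurations;
#' any external backend producing one row per structure can be plugged in
#' through [fps_rank()], which only sees the matrix.
#'
#' @param structures an `md_trajectory` or list of `md_frame`s.
#' @param r_max histogram range in Angstrom.
#' @param n_bins number of histogram bins (descriptor length).
#' @return An `md_descriptors` numeric matrix (structures x n_bins) with
#'   attribute `descriptor_id`.
#' @export
pair_histogram_descriptors <- function(structures, r_max = 8, n_bins = 64) {
  frames <- if (inherits(structures, "md_trajectory")) structures$frames
            else structures
  if (!length(frames)) stop("no structures given")
  bw <- r_max / n_bins
  rows <- t(vapply(frames, function(fr) {
    n <- nrow(fr$positions)
    if (n < 2) {
      warning("single-atom structure: pair-distance descriptor is all zero")
      return(numeric(n_bins))
    }
    d <- as.numeric(stats::dist(fr$positions))
    d <- d[d < r_max]
    tabulate(pmin(floor(d / bw) + 1L, n_bins), nbins = n_bins) /
      (n * (n - 1) / 2)
  }, numeric(n_bins)))
  structure(rows, class = c("md_descriptors", "matrix"),
            descriptor_id = sprintf("pairhist(r_max=%g,n_bins=%d)",
                                    r_max, n_bins))
}

#' Farthest-point-sampling ranking of structures
#'
#' Greedy max-min selection in descriptor space: starting from
#' `start_index`, repeatedly select the structure with the largest minimal
#' Euclidean distance to the already-selected set. Exact ties are broken
#' toward the lowest structure index, so the ranking is deterministic.
#' `min_dist_trace[k]` is that maximal minimal distance at selection k
#' (NA for the start structure).
#'
#' @param desc descriptor matrix (one row per structure); an
#'   `md_descriptors` or any numeric matrix.
#' @param n number of structures to rank (1 <= n <= rows).
#' @param start_index 1-based index of the first selected structure.
#' @return An `md_fps` list: `order` (length n, 1-based structure
#'   indices), `min_dist_trace`, `start_index`.
#' @export
fps_rank <- function(desc, n, start_index = 1) {
  X <- unclass(desc)
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(X)
  n <- as.integer(n)
  if (n < 1 || n > N) stop("n must be in [1, number of structures]")
  if (start_index < 1 || start_index > N) stop("start_index out of range")
  order_out <- integer(n)
  trace <- rep(NA_real_, n)
  order_out[1] <- start_index
  if (n == 1) {
    return(structure(list(order = order_out, min_dist_trace = trace,
                          start_index = start_index), class = "md_fps"))
  }
  dist_to <- function(i) sqrt(colSums((t(X) - X[i, ])^2))
  min_d <- dist_to(start_index)
  min_d[start_index] <- -Inf
  for (k in 2:n) {
    best <- which.max(min_d) # first index wins exact ties
    order_out[k] <- best
    trace[k] <- min_d[best]
    min_d <- pmin(min_d, dist_to(best))
    min_d[best] <- -Inf
  }
  structure(list(order = order_out, min_dist_trace = trace,
                 start_index = start_index), class = "md_fps")
}

#' Diversity-convergence curve of an FPS ranking
#'
#' Emits the min-distance trace versus selection rank, normalized to the
#' first measured distance, and reports the smallest rank at which the
#' trace has fallen to a fraction `f` of its initial value — the point
#' beyond which additional structures add little diversity.
#'
#' @param res an `md_fps`.
#' @param f convergence fraction (default 0.05).
#' @return List with `curve` (data.frame k, min_dist, normalized) and
#'   `convergence_k` (NA if the trace never falls below `f`).
#' @export
diversity_curve <- function(res, f = 0.05) {
  tr <- res$min_dist_trace
  n <- length(tr)
  if (n < 2) stop("FPS result holds fewer than 2 selections")
  d0 <- tr[2]
  normalized <- if (d0 > 0) tr / d0 else ifelse(is.na(tr), NA, 0)
  conv <- if (d0 == 0) 2L else {
    below <- which(!is.na(tr) & tr <= f * d0)
    if (length(below)) below[1] else NA_integer_
  }
  list(curve = data.frame(k = seq_len(n), min_dist = tr,
                          normalized = normalized),
       convergence_k = conv)
}
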