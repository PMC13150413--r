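#' DBSCAN clustering of selected atoms in one frame
#'
#' Runs DBSCAN on the minimum-image distance matrix of the selected atoms,
#' so clusters straddling a periodic boundary are found intact. A core
#' point has at least `min_samples` points (itself included) within `eps`;
#' clusters are the connected components of the core points, plus border
#' points attached to the cluster of their lowest-index core neighbor;
#' everything else is an outlier. Cluster ids are assigned by ascending
#' minimal member index, so labels are deterministic and permutation
#' consistent.
#'
#' Two size conventions are always reported: the headline
#' `avg_size_excl_outliers` averages true cluster sizes only (outliers are
#' not clusters), while `avg_size_incl_outliers` counts each outlier as a
#' size-1 cluster.
#'
#' @param frame an `md_frame`.
#' @param cell an `md_cell`.
#' @param selection atoms to cluster.
#' @param eps DBSCAN distance cutoff in Angstrom (> 0).
#' @param min_samples minimum points (self-inclusive) for a core point.
#' @return An `md_cluster_frame` list: `labels` (0 = outlier, otherwise
#'   cluster id, aligned with the selected atom order), `sizes`,
#'   `n_clusters`, `avg_size_excl_outliers` (NaN when no clusters),
#'   `avg_size_incl_outliers`, `n_outliers`.
#' @export
cluster_frame <- function(frame, cell, selection, eps, min_samples = 2) {
  if (!(eps > 0)) stop("eps must be > 0")
  min_samples <- as.integer(min_samples)
  if (min_samples < 1) stop("min_samples must be >= 1")
  idx <- resolve_selection(frame, selection)
  if (!length(idx)) stop("empty selection for clustering")
  n <- length(idx)
  D <- distance_matrix(frame, cell, idx)
  adj <- D <= eps
  ncount <- rowSums(adj) # includes self (diagonal distance 0)
  core <- ncount >= min_samples
  labels <- integer(n)
  if (any(core)) {
    gi <- igraph::graph_from_adjacency_matrix(
      adj[core, core, drop = FALSE] * 1, mode = "undirected", diag = FALSE)
    comp <- igraph::components(gi)$membership
    core_idx <- which(core)
    labels[core_idx] <- comp
    # border points: non-core with a core neighbor; deterministic
    # attachment to the cluster of the lowest-index core neighbor
    for (i in which(!core)) {
      nb <- core_idx[adj[i, core_idx]]
      if (length(nb)) labels[i] <- labels[min(nb)]
    }
    # relabel by ascending minimal member index
    first_seen <- vapply(seq_len(max(labels)), function(cl) {
      m <- which(labels == cl)
      if (length(m)) min(m) else NA_integer_
    }, integer(1))
    new_id <- integer(max(labels))
    new_id[order(first_seen)] <- seq_len(max(labels))
    labels[labels > 0] <- new_id[labels[labels > 0]]
  }
  sizes <- if (any(labels > 0)) as.integer(table(labels[labels > 0]))
           else integer(0)
  n_out <- sum(labels == 0)
  structure(list(labels = labels, atom_indices = idx, sizes = sizes,
                 n_clusters = length(sizes),
                 avg_size_excl_outliers =
                   if (length(sizes)) mean(sizes) else NaN,
                 avg_size_incl_outliers =
                   if (length(sizes) || n_out)
                     mean(c(sizes, rep(1L, n_out))) else NaN,
                 n_outliers = n_out),
            class = "md_cluster_frame")
}

#' Cluster-dynamics time series
#'
#' Applies [cluster_frame()] to every frame and reports per-frame series
#' of cluster count, average sizes (both outlier conventions) and outlier
#' count, plus trajectory means. Frames whose cluster count exceeds the
#' modal (most frequent) count are flagged as fragmentation events.
#'
#' @inheritParams cluster_frame
#' @param traj an `md_trajectory`.
#' @param n_workers frame-parallel workers.
#' @return An `md_cluster_series` list: `per_frame` (data.frame),
#'   `mean_n_clusters`, `mean_size_excl`, `mean_size_incl`,
#'   `modal_n_clusters`, `fragmented_frames`, `frames` (list of
#'   `md_cluster_frame`).
#' @export
cluster_timeseries <- function(traj, selection, eps, min_samples = 2,
                               n_workers = 1) {
  res <- frame_map(seq_len(n_frames(traj)), function(f) {
    cluster_frame(traj$frames[[f]], frame_cell(traj, f), selection,
                  eps, min_samples)
  }, n_workers)
  pf <- data.frame(
    frame = seq_along(res),
    n_clusters = vapply(res, `[[`, numeric(1), "n_clusters"),
    avg_size_excl = vapply(res, `[[`, numeric(1), "avg_size_excl_outliers"),
    avg_size_incl = vapply(res, `[[`, numeric(1), "avg_size_incl_outliers"),
    n_outliers = vapply(res, `[[`, numeric(1), "n_outliers"))
  tab <- table(pf$n_clusters)
  modal <- as.integer(names(tab)[which.max(tab)])
  structure(list(per_frame = pf,
                 mean_n_clusters = mean(pf$n_clusters),
                 mean_size_excl = mean(pf$avg_size_excl, na.rm = TRUE),
                 mean_size_incl = mean(pf$avg_size_incl, na.rm = TRUE),
                 modal_n_clusters = modal,
                 fragmented_frames = pf$frame[pf$n_clusters > modal],
                 frames = res),
            class = "md_cluster_series")
}

#' @export
print.md_cluster_series <- function(x, ...) {
  cat(sprintf(
    "clusters: mean count %.3g, mean size %.3g (excl. outliers) / %.3g (incl.), %d frames, %d fragmentation events\n",
    x$mean_n_clusters, x$mean_size_excl, x$mean_size_incl,
    nrow(x$per_frame), length(x$fragmented_frames)))
  invisible(x)
}
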