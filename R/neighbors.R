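#' Cutoff neighbor search between two selections
#'
#' Returns all pairs (i in `idx_a`, j in `idx_b`, i != j) whose
#' minimum-image distance is at or below `cutoff` (closed interval). When
#' the two index sets overlap, each unordered pair is reported once. The
#' output is ordered by ascending i then j, so results are deterministic.
#'
#' @param frame an `md_frame`.
#' @param cell an `md_cell`.
#' @param idx_a,idx_b integer vectors of 1-based atom indices.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return data.frame with columns `i`, `j`, `distance`.
#' @export
neighbor_pairs <- function(frame, cell, idx_a, idx_b, cutoff) {
  if (!(cutoff > 0)) stop("cutoff must be > 0")
  idx_a <- as.integer(idx_a); idx_b <- as.integer(idx_b)
  N <- nrow(frame$positions)
  if (any(c(idx_a, idx_b) < 1L) || any(c(idx_a, idx_b) > N)) {
    stop("atom index out of range")
  }
  if (all(cell$periodic) && cutoff > half_min_cell_height(cell)) {
    warning("cutoff exceeds half the minimal cell height; ",
            "only nearest images are counted")
  }
  ii <- rep(idx_a, times = length(idx_b))
  jj <- rep(idx_b, each = length(idx_a))
  d <- min_image(frame$positions[jj, , drop = FALSE] -
                 frame$positions[ii, , drop = FALSE], cell)
  dist <- sqrt(rowSums(d^2))
  keep <- dist <= cutoff & ii != jj
  inA <- logical(N); inA[idx_a] <- TRUE
  inB <- logical(N); inB[idx_b] <- TRUE
  # the reversed copy of (i, j) is generated iff j is a center and i a
  # neighbor candidate; keep the i < j representative in that case
  dup <- inA[jj] & inB[ii]
  keep <- keep & (!dup | ii < jj)
  ii <- ii[keep]; jj <- jj[keep]; dist <- dist[keep]
  o <- order(ii, jj)
  data.frame(i = ii[o], j = jj[o], distance = dist[o])
}

# Pairwise min-image distance matrix between selected atoms of one frame.
distance_matrix <- function(frame, cell, idx = seq_len(nrow(frame$positions))) {
  n <- length(idx)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  d <- min_image(frame$positions[idx[jj], , drop = FALSE] -
                 frame$positions[idx[ii], , drop = FALSE], cell)
  matrix(sqrt(rowSums(d^2)), n, n)
}
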