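# Independent brute-force oracles used to validate the fast paths.
# These deliberately re-derive each quantity with the most literal
# algorithm available and share no code with the package internals.

# minimum-image displacement: reduce into the central cell by integer
# lattice translations, then exhaustive search over the 27 images
oracle_min_image <- function(d, cell) {
  H <- cell$vectors
  per <- cell$periodic
  Hi <- solve(H)
  shifts <- expand.grid(a = if (per[1]) -1:1 else 0,
                        b = if (per[2]) -1:1 else 0,
                        c = if (per[3]) -1:1 else 0)
  t(apply(matrix(d, ncol = 3), 1, function(v) {
    f <- as.numeric(v %*% Hi)
    f[per] <- f[per] - round(f[per])
    v0 <- as.numeric(f %*% H)
    best <- v0; bn <- sum(v0^2)
    for (s in seq_len(nrow(shifts))) {
      cand <- v0 + as.numeric(as.matrix(shifts[s, ]) %*% H)
      n2 <- sum(cand^2)
      if (n2 < bn) { best <- cand; bn <- n2 }
    }
    best
  }))
}

# quadratic pair search (unordered representative for overlapping sets)
oracle_pairs <- function(pos, cell, idx_a, idx_b, cutoff) {
  out <- NULL
  for (i in idx_a) {
    for (j in idx_b) {
      if (i == j) next
      dd <- sqrt(sum(oracle_min_image(pos[j, ] - pos[i, ], cell)^2))
      if (dd <= cutoff) {
        if (j %in% idx_a && i %in% idx_b && i >= j) next
        out <- rbind(out, data.frame(i = i, j = j, distance = dd))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  }
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  out
}

# literal greedy max-min FPS, recomputing all distances at every step
oracle_fps <- function(X, n, start = 1) {
  N <- nrow(X)
  sel <- start
  for (k in 2:n) {
    best_i <- NA; best_d <- -1
    for (i in seq_len(N)) {
      if (i %in% sel) next
      dmin <- min(vapply(sel, function(s) sqrt(sum((X[i, ] - X[s, ])^2)),
                         numeric(1)))
      if (dmin > best_d) { best_d <- dmin; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# triple-loop hydrogen-bond enumeration with the same geometric criteria
oracle_hbonds <- function(frame, cell, d_HA_cut = 2.5, angle_cut = 130,
                          dh_cut = 1.2) {
  pos <- frame$positions
  os <- which(frame$elements == "O")
  hs <- which(frame$elements == "H")
  bonds <- NULL
  for (h in hs) {
    dists <- vapply(os, function(o) {
      sqrt(sum(oracle_min_image(pos[o, ] - pos[h, ], cell)^2))
    }, numeric(1))
    near <- which(dists <= dh_cut)
    if (!length(near)) next
    don <- os[near[which.min(dists[near])]]
    for (a in os) {
      if (a == don) next
      vHA <- as.numeric(oracle_min_image(pos[a, ] - pos[h, ], cell))
      rHA <- sqrt(sum(vHA^2))
      if (rHA > d_HA_cut) next
      vHD <- as.numeric(oracle_min_image(pos[don, ] - pos[h, ], cell))
      cosang <- sum(vHA * vHD) / (rHA * sqrt(sum(vHD^2)))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= angle_cut) {
        bonds <- rbind(bonds, data.frame(donor = don, hydrogen = h,
                                         acceptor = a))
      }
    }
  }
  if (is.null(bonds)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  }
  bonds <- bonds[order(bonds$donor, bonds$hydrogen, bonds$acceptor), ]
  rownames(bonds) <- NULL
  bonds
}

# connected components of the eps-threshold graph, isolated vertices as
# outliers (equivalent to DBSCAN at min_samples = 2)
oracle_cluster_components <- function(frame, cell, eps) {
  pos <- frame$positions
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt(sum(oracle_min_image(pos[j, ] - pos[i, ], cell)^2))
      if (dd <= eps) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  memb <- igraph::components(g)$membership
  isolated <- rowSums(adj) == 0
  memb[isolated] <- 0L
  # relabel surviving components by first appearance
  ids <- unique(memb[memb > 0])
  relab <- memb
  for (k in seq_along(ids)) relab[memb == ids[k]] <- k
  relab
}

random_triclinic_cell <- function() {
  repeat {
    H <- matrix(stats::runif(9, -2, 10), 3, 3)
    diag(H) <- stats::runif(3, 8, 14)
    if (abs(det(H)) > 200) return(cell_geometry(H))
  }
}

write_tmp_xyz <- function(lines) {
  path <- tempfile(fileext = ".xyz")
  writeLines(lines, path)
  path
}
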