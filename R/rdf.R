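#' Partial radial distribution function
#'
#' Histograms minimum-image A-B distances per frame and normalizes each
#' bin by the ideal-gas shell expectation, so an uncorrelated system gives
#' g(r) = 1. Self pairs (the same atom appearing in both selections) are
#' excluded, and the cross density is corrected for that exclusion: the
#' expected ordered-pair count per frame and bin is
#' (N_A * N_B - |A intersect B|) / V * V_shell, which is symmetric in A
#' and B, so prdf(A, B) equals prdf(B, A) bin-wise. Normalization uses the
#' per-frame cell volume, so NPT trajectories are handled correctly.
#'
#' @param traj an `md_trajectory` with a periodic cell.
#' @param sel_a,sel_b selections (see [select_elements()]); custom
#'   index-based selections are fully supported.
#' @param r_max histogram range in Angstrom; under full periodicity values
#'   beyond half the minimal cell height trigger a warning (only nearest
#'   images are counted there).
#' @param bin_width bin width in Angstrom (default 0.05).
#' @param n_bins alternative to `bin_width`: number of bins over
#'   `[0, r_max]`.
#' @param keep_frames retain the per-frame g(r) stack (for frame-wise RDF
#'   animation/output).
#' @param n_workers frame-parallel workers; results are independent of the
#'   worker count.
#' @return An `md_rdf` list: `bin_edges`, `r` (bin centers), `g`,
#'   `g_per_frame` (matrix frames x bins or NULL), `n_frames`, `pair`.
#' @export
prdf <- function(traj, sel_a, sel_b, r_max, bin_width = 0.05, n_bins = NULL,
                 keep_frames = FALSE, n_workers = 1) {
  if (!(r_max > 0)) stop("r_max must be > 0")
  if (!is.null(n_bins)) {
    if (n_bins < 10) stop("n_bins must be >= 10")
    bin_width <- r_max / n_bins
  }
  n_bins <- as.integer(round(r_max / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  ia <- resolve_selection(traj, sel_a)
  ib <- resolve_selection(traj, sel_b)
  n_cross <- length(ia) * length(ib) - length(intersect(ia, ib))
  if (n_cross <= 0) stop("selections define zero cross pairs")
  cell1 <- frame_cell(traj, 1)
  if (all(cell1$periodic) && r_max > half_min_cell_height(cell1)) {
    warning("r_max exceeds half the minimal cell height; ",
            "g(r) beyond that range counts nearest images only")
  }
  ii <- rep(ia, times = length(ib))
  jj <- rep(ib, each = length(ia))
  keep_pairs <- ii != jj
  ii <- ii[keep_pairs]; jj <- jj[keep_pairs]
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  per_frame <- function(f) {
    cell <- frame_cell(traj, f)
    pos <- traj$frames[[f]]$positions
    d <- min_image(pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE], cell)
    r <- sqrt(rowSums(d^2))
    r <- r[r < r_max]
    counts <- tabulate(pmin(floor(r / bin_width) + 1L, n_bins), nbins = n_bins)
    expected <- n_cross / cell_volume(cell) * shell_vol
    counts / expected
  }
  gf <- frame_map(seq_len(n_frames(traj)), per_frame, n_workers)
  G <- do.call(rbind, gf)
  structure(list(bin_edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = colMeans(G),
                 g_per_frame = if (keep_frames) G else NULL,
                 n_frames = n_frames(traj),
                 pair = list(a = sel_a, b = sel_b)),
            class = "md_rdf")
}

#' @export
print.md_rdf <- function(x, ...) {
  cat(sprintf("md_rdf: %d bins, width %.3g A, %d frames; first peak %.3g A\n",
              length(x$g), diff(x$bin_edges[1:2]), x$n_frames,
              x$r[which.max(x$g)]))
  invisible(x)
}

#' First minimum of a radial distribution function
#'
#' Smooths g(r) with a 5-bin moving average (shrinking at the edges),
#' locates the first local maximum at r > `search_from`, and returns the
#' bin center of the first local minimum after it. To reject plateaus and
#' bin noise, the minimum must be at least 1 percent of the first peak
#' height below the peak.
#'
#' @param rdf an `md_rdf`.
#' @param search_from ignore structure below this radius (Angstrom);
#'   skips the excluded-volume region.
#' @return r_min in Angstrom.
#' @export
first_minimum <- function(rdf, search_from = 2.0) {
  g <- rdf$g
  n <- length(g)
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 2):min(n, i + 2)
    mean(g[w])
  }, numeric(1))
  start <- which(rdf$r > search_from)[1]
  if (is.na(start)) stop("no RDF bins beyond search_from")
  pk <- NA_integer_
  for (i in max(start, 2):(n - 1)) {
    if (sm[i] >= sm[i - 1] && sm[i] > sm[i + 1]) { pk <- i; break }
  }
  if (is.na(pk)) stop("no RDF maximum found: g is monotone in range")
  for (i in (pk + 1):(n - 1)) {
    if (sm[i] <= sm[i - 1] && sm[i] < sm[i + 1] &&
        (sm[pk] - sm[i]) > 0.01 * sm[pk]) {
      return(rdf$r[i])
    }
  }
  stop("no RDF minimum found after the first peak")
}

#' Bondi-style van der Waals radii (Angstrom)
#'
#' Published single-value vdW radii for common elements, used by the vdW
#' coordination mode. Override entries via the `override` argument of
#' [coordination_number()].
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, He = 1.40, Li = 1.82, Be = 1.53, B = 1.92, C = 1.70,
    N = 1.55, O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73,
    Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
    K = 2.75, Ca = 2.31, Ti = 2.15, Fe = 2.04, Ni = 1.63, Cu = 1.40,
    Zn = 1.39, Br = 1.85, Kr = 2.02, Ag = 1.72, I = 1.98, Xe = 2.16,
    Pt = 1.75, Au = 1.66)
}

#' Coordination numbers with fixed, dynamic or van der Waals cutoffs
#'
#' Per frame, the coordination number is the mean over center atoms of the
#' number of neighbor atoms within the cutoff (minimum-image distances;
#' distances exactly at the cutoff count as coordinated). Modes:
#' `fixed` uses the given cutoff; `dynamic` computes the center-neighbor
#' PRDF over the whole trajectory once and uses its first minimum;
#' `vdw` uses a per-pair cutoff (r_vdw(A) + r_vdw(B)) * vdw_scale.
#'
#' @param traj an `md_trajectory`.
#' @param centers,neighbors selections.
#' @param mode one of "fixed", "dynamic", "vdw".
#' @param cutoff fixed-mode cutoff in Angstrom.
#' @param vdw_scale scale factor on the vdW radii sum (default 1.0).
#' @param r_max,bin_width RDF parameters for dynamic mode (default r_max =
#'   half the minimal cell height).
#' @param search_from passed to [first_minimum()] in dynamic mode.
#' @param override named numeric vector of vdW radii overriding the
#'   shipped table.
#' @param n_workers frame-parallel workers.
#' @return An `md_coordination` list: `mean_cn`, `per_frame_cn`,
#'   `cutoff_used` (Angstrom; NA in vdw mode where it is per-pair),
#'   `cutoff_mode`.
#' @export
coordination_number <- function(traj, centers, neighbors,
                                mode = c("fixed", "dynamic", "vdw"),
                                cutoff = NULL, vdw_scale = 1.0,
                                r_max = NULL, bin_width = 0.05,
                                search_from = 2.0, override = NULL,
                                n_workers = 1) {
  mode <- match.arg(mode)
  ic <- resolve_selection(traj, centers)
  im <- resolve_selection(traj, neighbors)
  if (!length(ic) || !length(im)) stop("empty selection")
  elements <- traj$frames[[1]]$elements
  cut_used <- NA_real_
  if (mode == "fixed") {
    if (is.null(cutoff) || !(cutoff > 0)) stop("fixed mode needs cutoff > 0")
    cut_used <- cutoff
  } else if (mode == "dynamic") {
    if (is.null(r_max)) r_max <- half_min_cell_height(frame_cell(traj, 1))
    rdf <- prdf(traj, centers, neighbors, r_max = r_max,
                bin_width = bin_width, n_workers = n_workers)
    cut_used <- first_minimum(rdf, search_from = search_from)
  } else {
    tab <- vdw_radii()
    if (!is.null(override)) tab[names(override)] <- override
    need <- unique(elements[c(ic, im)])
    missing_el <- setdiff(need, names(tab))
    if (length(missing_el)) {
      stop("no vdW radius for element(s): ", paste(missing_el, collapse = ","))
    }
  }
  ii <- rep(ic, times = length(im))
  jj <- rep(im, each = length(ic))
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  pair_cut <- if (mode == "vdw") {
    tab <- vdw_radii()
    if (!is.null(override)) tab[names(override)] <- override
    (tab[elements[ii]] + tab[elements[jj]]) * vdw_scale
  } else rep(cut_used, length(ii))
  per_frame <- function(f) {
    cell <- frame_cell(traj, f)
    pos <- traj$frames[[f]]$positions
    d <- min_image(pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE], cell)
    r <- sqrt(rowSums(d^2))
    sum(r <= pair_cut) / length(ic)
  }
  cns <- unlist(frame_map(seq_len(n_frames(traj)), per_frame, n_workers))
  structure(list(mean_cn = mean(cns), per_frame_cn = cns,
                 cutoff_used = cut_used, cutoff_mode = mode),
            class = "md_coordination")
}

#' @export
print.md_coordination <- function(x, ...) {
  cat(sprintf("CN = %.4g (%s cutoff%s, %d frames)\n", x$mean_cn,
              x$cutoff_mode,
              if (is.finite(x$cutoff_used))
                sprintf(" %.3g A", x$cutoff_used) else "",
              length(x$per_frame_cn)))
  invisible(x)
}
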