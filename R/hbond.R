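#' Assign covalent hydrogens to donor atoms
#'
#' Each hydrogen is attached to its nearest donor-candidate atom within
#' `dh_cut` (minimum-image distances). Hydrogens with no donor inside the
#' cutoff stay unassigned. Exact distance ties are broken deterministically
#' toward the lower donor index and flagged with a warning.
#'
#' @param frame an `md_frame`.
#' @param cell an `md_cell`.
#' @param donors donor-candidate selection (e.g. `select_elements("O")`).
#' @param hydrogens hydrogen selection (default element "H").
#' @param dh_cut covalent D-H cutoff in Angstrom (default 1.2).
#' @return List with `h_donor` (named integer vector: donor index per
#'   hydrogen, NA if unassigned) and `by_donor` (list donor index ->
#'   hydrogen indices).
#' @export
assign_covalent_hydrogens <- function(frame, cell, donors,
                                      hydrogens = select_elements("H"),
                                      dh_cut = 1.2) {
  if (!(dh_cut > 0)) stop("dh_cut must be > 0")
  id <- resolve_selection(frame, donors)
  ih <- resolve_selection(frame, hydrogens)
  if (!length(id)) stop("empty donor selection")
  h_donor <- rep(NA_integer_, length(ih))
  names(h_donor) <- ih
  for (k in seq_along(ih)) {
    d <- min_image(frame$positions[id, , drop = FALSE] -
                   matrix(frame$positions[ih[k], ], length(id), 3,
                          byrow = TRUE), cell)
    r <- sqrt(rowSums(d^2))
    ok <- which(r <= dh_cut)
    if (!length(ok)) next
    rmin <- min(r[ok])
    best <- ok[r[ok] <= rmin + 1e-12]
    if (length(best) > 1) {
      warning("hydrogen ", ih[k], " equidistant from donors ",
              paste(id[best], collapse = ","), "; lower index chosen")
    }
    h_donor[k] <- id[min(best)]
  }
  by_donor <- split(ih[!is.na(h_donor)], h_donor[!is.na(h_donor)])
  list(h_donor = h_donor, by_donor = by_donor)
}

#' Geometric hydrogen-bond detection in one frame
#'
#' A hydrogen bond D-H...A is assigned when the minimum-image H...A
#' distance is at most `d_HA_cut`, the internal D-H...A angle (180 degrees
#' = linear, computed from minimum-image vectors) is at least `angle_cut`,
#' and the acceptor is not the hydrogen's own donor. Bond lists are sorted
#' by (donor, hydrogen, acceptor), so identical frames give identical
#' output regardless of input atom order.
#'
#' @inheritParams assign_covalent_hydrogens
#' @param acceptors acceptor selection.
#' @param d_HA_cut H...A distance cutoff in Angstrom (default 2.5).
#' @param angle_cut D-H...A angle cutoff in degrees (default 130).
#' @return data.frame with columns donor, hydrogen, acceptor, d_HA,
#'   angle_DHA.
#' @export
find_hbonds <- function(frame, cell, donors, acceptors,
                        hydrogens = select_elements("H"),
                        d_HA_cut = 2.5, angle_cut = 130, dh_cut = 1.2) {
  if (!(d_HA_cut > 0) || !(angle_cut >= 0)) stop("cutoffs must be positive")
  ia <- resolve_selection(frame, acceptors)
  if (!length(ia)) stop("empty acceptor selection")
  asg <- assign_covalent_hydrogens(frame, cell, donors, hydrogens, dh_cut)
  hs <- as.integer(names(asg$h_donor))[!is.na(asg$h_donor)]
  ds <- as.integer(unname(asg$h_donor[!is.na(asg$h_donor)]))
  out <- list()
  for (k in seq_along(hs)) {
    h <- hs[k]; don <- ds[k]
    acc <- ia[ia != don]
    if (!length(acc)) next
    vHA <- min_image(frame$positions[acc, , drop = FALSE] -
                     matrix(frame$positions[h, ], length(acc), 3,
                            byrow = TRUE), cell)
    rHA <- sqrt(rowSums(vHA^2))
    near <- which(rHA <= d_HA_cut & rHA > 0)
    if (!length(near)) next
    vHD <- as.numeric(min_image(frame$positions[don, , drop = FALSE] -
                                frame$positions[h, , drop = FALSE], cell))
    nHD <- sqrt(sum(vHD^2))
    cosang <- (vHA[near, , drop = FALSE] %*% vHD) /
      (rHA[near] * nHD)
    # internal angle at H between H->D and H->A; linear D-H...A gives 180
    ang <- acos(pmin(1, pmax(-1, as.numeric(cosang)))) * 180 / pi
    ok <- which(ang >= angle_cut)
    if (!length(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      donor = don, hydrogen = h, acceptor = acc[near[ok]],
      d_HA = rHA[near[ok]], angle_DHA = ang[ok])
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), d_HA = numeric(),
                      angle_DHA = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond network statistics over a trajectory
#'
#' Counts hydrogen bonds per frame, reports the average number of bonds
#' per molecule, and builds the per-frame network graph (molecules as
#' vertices, bonds as edges) to count connected components. A molecule is
#' identified with its donor-candidate heavy atom (e.g. the water oxygen).
#' With `per_molecule = "both"` (default) each bond counts for its donor
#' and its acceptor molecule, i.e. the average is 2 x bonds / molecules,
#' the convention under which bulk water gives roughly 3.8 bonds per
#' molecule; `"donated"` counts bonds once.
#'
#' @inheritParams find_hbonds
#' @param traj an `md_trajectory`.
#' @param per_molecule counting convention, "both" or "donated".
#' @param n_workers frame-parallel workers.
#' @return An `md_hbond_stats` list: `per_frame_counts`,
#'   `avg_per_molecule`, `std_per_molecule` (std across frames),
#'   `components_per_frame`, `n_molecules`, `bonds` (list of per-frame
#'   bond data.frames).
#' @export
hbond_stats <- function(traj, donors, acceptors,
                        hydrogens = select_elements("H"),
                        d_HA_cut = 2.5, angle_cut = 130, dh_cut = 1.2,
                        per_molecule = c("both", "donated"),
                        n_workers = 1) {
  per_molecule <- match.arg(per_molecule)
  id <- resolve_selection(traj, donors)
  if (!length(id)) stop("no molecules: empty donor selection")
  n_mol <- length(id)
  per_frame <- function(f) {
    fr <- traj$frames[[f]]
    cell <- frame_cell(traj, f)
    bonds <- find_hbonds(fr, cell, donors, acceptors, hydrogens,
                         d_HA_cut, angle_cut, dh_cut)
    # molecule graph: vertices are donor-candidate atoms
    g <- igraph::make_empty_graph(n = n_mol, directed = FALSE)
    ed <- rbind(match(bonds$donor, id), match(bonds$acceptor, id))
    ed <- ed[, !is.na(ed[1, ]) & !is.na(ed[2, ]), drop = FALSE]
    if (ncol(ed)) g <- igraph::add_edges(g, as.vector(ed))
    list(count = nrow(bonds),
         components = igraph::components(g)$no,
         bonds = bonds)
  }
  res <- frame_map(seq_len(n_frames(traj)), per_frame, n_workers)
  counts <- vapply(res, `[[`, numeric(1), "count")
  mult <- if (per_molecule == "both") 2 else 1
  pm <- mult * counts / n_mol
  structure(list(per_frame_counts = counts,
                 avg_per_molecule = mean(pm),
                 std_per_molecule = if (length(pm) > 1) stats::sd(pm) else 0,
                 components_per_frame = vapply(res, `[[`, numeric(1),
                                               "components"),
                 n_molecules = n_mol,
                 per_molecule_mode = per_molecule,
                 bonds = lapply(res, `[[`, "bonds")),
            class = "md_hbond_stats")
}

#' @export
print.md_hbond_stats <- function(x, ...) {
  cat(sprintf(
    "H-bonds: %.3g +/- %.2g per molecule (%s, %d molecules, %d frames)\n",
    x$avg_per_molecule, x$std_per_molecule, x$per_molecule_mode,
    x$n_molecules, length(x$per_frame_counts)))
  invisible(x)
}
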