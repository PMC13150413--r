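#' Volumetric atomic density over the cell
#'
#' Wraps every selected atom of every frame into the cell, bins it on a
#' regular fractional-coordinate grid (half-open [0, 1) voxels, so a
#' position exactly on a voxel boundary lands in the higher-index voxel),
#' and normalizes the histogram to a probability density per Angstrom^3:
#' sum(density * voxel_volume) = 1.
#'
#' @param traj an `md_trajectory` with a periodic cell (or a finite
#'   bounding cell for non-periodic data).
#' @param selection atoms to accumulate.
#' @param grid_shape integer length-3, voxels per axis (each >= 2).
#' @return An `md_density` list: `counts` (nx x ny x nz array), `density`
#'   (per Angstrom^3), `cell`, `grid_shape`, `n_samples`.
#' @export
density_grid <- function(traj, selection = select_all(),
                         grid_shape = c(50, 50, 50)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  if (any(grid_shape < 2)) stop("grid dimensions must be >= 2")
  idx <- resolve_selection(traj, selection)
  if (!length(idx)) stop("empty selection for density")
  cell <- frame_cell(traj, 1)
  if (cell_volume(cell) <= 0) {
    stop("cell has no finite volume: provide a bounding cell")
  }
  sb <- .solve_basis(cell)
  counts <- array(0L, dim = grid_shape)
  for (f in seq_len(n_frames(traj))) {
    frac <- traj$frames[[f]]$positions[idx, , drop = FALSE] %*% sb$Hi
    frac <- frac - floor(frac) # wrap into [0, 1)
    vox <- floor(sweep(frac, 2, grid_shape, `*`)) + 1L
    vox <- pmin(vox, matrix(grid_shape, nrow(vox), 3, byrow = TRUE))
    for (k in seq_len(nrow(vox))) {
      counts[vox[k, 1], vox[k, 2], vox[k, 3]] <-
        counts[vox[k, 1], vox[k, 2], vox[k, 3]] + 1L
    }
  }
  n_samples <- length(idx) * n_frames(traj)
  voxel_vol <- cell_volume(cell) / prod(grid_shape)
  structure(list(counts = counts,
                 density = counts / (n_samples * voxel_vol),
                 cell = cell, grid_shape = grid_shape,
                 n_samples = n_samples),
            class = "md_density")
}

#' Project a 3D density onto an axis plane
#'
#' Integrates the volumetric density along the axis orthogonal to the
#' requested plane (sum weighted by the voxel extent), yielding a 2D map
#' that integrates to 1 over the plane.
#'
#' @param grid an `md_density`.
#' @param plane one of "XY", "XZ", "YZ".
#' @return Matrix of projected density (per Angstrom^2) with attributes
#'   `plane` and `pixel_area`.
#' @export
project_density <- function(grid, plane = c("XY", "XZ", "YZ")) {
  plane <- match.arg(plane)
  ax <- switch(plane, XY = 3L, XZ = 2L, YZ = 1L)
  lens <- sqrt(rowSums(grid$cell$vectors^2))
  dvox <- lens / grid$grid_shape # voxel extent per axis
  proj <- apply(grid$density, setdiff(1:3, ax), sum) * dvox[ax]
  # pixel area defined so the projection integrates to exactly 1 over the
  # plane for any (also non-orthogonal) cell
  voxel_vol <- cell_volume(grid$cell) / prod(grid$grid_shape)
  structure(proj, plane = plane, pixel_area = voxel_vol / dvox[ax])
}

#' Write a density grid as a Gaussian cube file
#'
#' Plain-text cube format; axis vectors are written in Angstrom with
#' negative voxel counts, the conventional flag that the file is in
#' Angstrom rather than Bohr. No atoms are listed.
#'
#' @param grid an `md_density`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("volumetric atomic probability density",
               "generated by mdpost (units: Angstrom, 1/Angstrom^3)"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0L, 0, 0, 0), con)
  ax <- grid$cell$vectors / grid$grid_shape
  for (i in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f",
                       -grid$grid_shape[i], ax[i, 1], ax[i, 2], ax[i, 3]),
               con)
  }
  d <- grid$density
  for (ix in seq_len(dim(d)[1])) {
    for (iy in seq_len(dim(d)[2])) {
      v <- d[ix, iy, ]
      lines <- split(v, ceiling(seq_along(v) / 6))
      writeLines(vapply(lines, function(z) {
        paste(sprintf("%13.5e", z), collapse = " ")
      }, character(1)), con)
    }
  }
  invisible(path)
}
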