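#' Simulation cell geometry
#'
#' A cell is a 3x3 lattice matrix (rows are the cell vectors, in Angstrom)
#' together with three per-axis periodicity flags. All distances in the
#' package are Cartesian Angstrom; fractional coordinates are only used
#' internally for image bookkeeping.
#'
#' @param vectors 3x3 numeric matrix; row i is cell vector a_i in Angstrom.
#' @param periodic logical length-3, periodicity flag per axis.
#' @return An object of class `md_cell`.
#' @examples
#' cell <- cell_geometry(diag(3) * 10, periodic = c(TRUE, TRUE, TRUE))
#' cubic_cell(12.4453)
#' @export
cell_geometry <- function(vectors, periodic = c(TRUE, TRUE, TRUE)) {
  vectors <- matrix(as.numeric(vectors), nrow = 3, ncol = 3)
  periodic <- as.logical(rep_len(periodic, 3L))
  if (any(!is.finite(vectors))) stop("cell vectors must be finite")
  lens <- sqrt(rowSums(vectors^2))
  if (any(periodic & lens == 0)) {
    stop("periodic axis has a zero-length cell vector")
  }
  if (all(periodic) && abs(det(vectors)) <= 0) {
    stop("periodic cell has non-positive volume (singular lattice matrix)")
  }
  structure(list(vectors = vectors, periodic = periodic), class = "md_cell")
}

#' @rdname cell_geometry
#' @param L box edge length in Angstrom.
#' @export
cubic_cell <- function(L) cell_geometry(diag(3) * L)

#' @rdname cell_geometry
#' @export
nonperiodic_cell <- function() {
  cell_geometry(diag(3) * 0 + diag(3), periodic = c(FALSE, FALSE, FALSE))
}

#' @export
print.md_cell <- function(x, ...) {
  cat("md_cell: pbc =", paste(ifelse(x$periodic, "T", "F"), collapse = " "), "\n")
  print(round(x$vectors, 6))
  invisible(x)
}

cell_volume <- function(cell) abs(det(cell$vectors))

is_orthorhombic <- function(cell) {
  H <- cell$vectors
  all(abs(H[row(H) != col(H)]) < 1e-10)
}

#' Half the minimal cell height
#'
#' The largest distance up to which the single-nearest-image convention is
#' guaranteed unambiguous under full periodicity. Height along axis i is
#' V / |a_j x a_k|.
#'
#' @param cell an `md_cell`.
#' @return Numeric scalar in Angstrom (Inf for fully non-periodic cells).
#' @export
half_min_cell_height <- function(cell) {
  per <- cell$periodic
  if (!any(per)) return(Inf)
  H <- cell$vectors
  V <- abs(det(.solve_basis(cell)$H2)) # volume of the completed basis
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  H2 <- .solve_basis(cell)$H2
  h <- vapply(1:3, function(i) {
    jk <- setdiff(1:3, i)
    V / sqrt(sum(cr(H2[jk[1], ], H2[jk[2], ])^2))
  }, numeric(1))
  min(h[per]) / 2
}

# Complete aperiodic zero rows with unit axes so the basis is invertible;
# the rounding shift is zeroed on those axes so results are unaffected.
.solve_basis <- function(cell) {
  H2 <- cell$vectors
  for (ax in which(!cell$periodic)) {
    if (sum(H2[ax, ]^2) == 0) H2[ax, ax] <- 1
  }
  Hi <- tryCatch(solve(H2), error = function(e) {
    stop("singular cell matrix with periodic flags set")
  })
  list(H2 = H2, Hi = Hi)
}

#' Minimum-image displacement
#'
#' Maps displacement vectors to their nearest periodic image. For diagonal
#' (orthorhombic) cells, rounding the fractional coordinates is exact for
#' any input displacement; for general triclinic cells the rounded image is
#' refined by an exhaustive search over the 27 neighboring images, which is
#' exact whenever the minimum image lies within one neighbor shell.
#'
#' @param d numeric n x 3 matrix (or length-3 vector) of raw displacements
#'   in Angstrom.
#' @param cell an `md_cell`.
#' @return n x 3 matrix of minimum-image displacements; non-periodic axes
#'   are left untouched.
#' @examples
#' cell <- cubic_cell(10)
#' min_image(c(8, 0, 0), cell)  # -> (-2, 0, 0)
#' @export
min_image <- function(d, cell) {
  d <- if (is.matrix(d)) d else matrix(d, ncol = 3)
  storage.mode(d) <- "double"
  per <- cell$periodic
  if (!any(per)) return(d)
  sb <- .solve_basis(cell)
  H2 <- sb$H2
  frac <- d %*% sb$Hi
  shift <- round(frac)
  shift[, !per] <- 0
  cand <- d - shift %*% H2
  if (is_orthorhombic(cell)) return(cand)
  # triclinic: refine over the 27 (or fewer, with partial pbc) images
  steps <- lapply(1:3, function(ax) if (per[ax]) -1:1 else 0L)
  combos <- as.matrix(expand.grid(steps[[1]], steps[[2]], steps[[3]]))
  best <- cand
  bestn <- rowSums(cand^2)
  for (k in seq_len(nrow(combos))) {
    s <- combos[k, ]
    if (all(s == 0)) next
    off <- as.numeric(s %*% H2)
    cs <- sweep(cand, 2, -off) # cand + s %*% H2
    n2 <- rowSums(cs^2)
    upd <- n2 < bestn - 1e-15
    if (any(upd)) {
      best[upd, ] <- cs[upd, , drop = FALSE]
      bestn[upd] <- n2[upd]
    }
  }
  best
}

#' @rdname min_image
#' @param p,q points (n x 3 or length-3), displacement taken as q - p.
#' @export
min_image_displacement <- function(p, q, cell) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  q <- if (is.matrix(q)) q else matrix(q, ncol = 3)
  min_image(q - p, cell)
}

#' @rdname min_image
#' @export
min_image_distance <- function(p, q, cell) {
  sqrt(rowSums(min_image_displacement(p, q, cell)^2))
}

# Wrap Cartesian positions into the cell (fractional coordinates in [0,1)
# on periodic axes).
wrap_positions <- function(pos, cell) {
  per <- cell$periodic
  if (!any(per)) return(pos)
  sb <- .solve_basis(cell)
  frac <- pos %*% sb$Hi
  shift <- floor(frac)
  shift[, !per] <- 0
  pos - shift %*% sb$H2
}
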