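#' Trajectory and frame containers
#'
#' A frame holds an N x 3 Cartesian position matrix (Angstrom), a character
#' vector of element symbols, and an optional timestamp in femtoseconds. A
#' trajectory is an ordered list of frames sharing one atom count and
#' element ordering, plus a cell (shared, or one per frame for NPT runs)
#' and the time step in fs between stored frames.
#'
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param elements character vector of length N.
#' @param time optional timestamp in fs.
#' @return `md_frame` / `md_trajectory` objects.
#' @export
md_frame <- function(positions, elements, time = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  elements <- as.character(elements)
  if (nrow(positions) != length(elements)) {
    stop("positions and elements disagree on atom count")
  }
  if (any(!is.finite(positions))) stop("non-finite positions")
  structure(list(positions = positions, elements = elements, time = time),
            class = "md_frame")
}

#' @rdname md_frame
#' @param frames list of `md_frame`.
#' @param cell an `md_cell`, or a list of `md_cell` (one per frame).
#' @param timestep fs between stored frames (> 0).
#' @export
md_trajectory <- function(frames, cell, timestep = 1) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  if (!(timestep > 0)) stop("timestep must be > 0")
  n <- nrow(frames[[1]]$positions)
  el <- frames[[1]]$elements
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$positions) != n ||
        !identical(frames[[k]]$elements, el)) {
      stop("inconsistent atom count or element ordering at frame ", k)
    }
  }
  cells <- NULL
  if (is.list(cell) && !inherits(cell, "md_cell")) {
    if (length(cell) != length(frames)) {
      stop("per-frame cell list must match frame count")
    }
    cells <- cell
    cell <- cell[[1]]
  }
  structure(list(frames = frames, cell = cell, cells = cells,
                 timestep = timestep),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, dt = %g fs\n",
              n_frames(x), n_atoms(x), x$timestep))
  cat("elements:", paste(names(table(x$frames[[1]]$elements)),
                         table(x$frames[[1]]$elements),
                         sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @rdname md_frame
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname md_frame
#' @export
n_atoms <- function(traj) nrow(traj$frames[[1]]$positions)

#' @rdname md_frame
#' @param k frame index (1-based).
#' @export
frame_cell <- function(traj, k) {
  if (!is.null(traj$cells)) traj$cells[[k]] else traj$cell
}

.parse_lattice <- function(comment) {
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(m) < 2) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(trimws(m[2]), "[[:space:]]+")[[1]]))
  if (length(v) != 9 || any(is.na(v))) return(NULL)
  matrix(v, nrow = 3, byrow = TRUE) # row-major: a1 a2 a3
}

.parse_pbc <- function(comment) {
  m <- regmatches(comment, regexec('pbc="([^"]+)"', comment))[[1]]
  if (length(m) < 2) return(NULL)
  toks <- toupper(strsplit(trimws(m[2]), "[[:space:]]+")[[1]])
  if (length(toks) != 3) return(NULL)
  toks %in% c("T", "TRUE", "1")
}

#' Read an (extended-)XYZ trajectory
#'
#' Reads a multi-frame plain or extended XYZ file. Lattice vectors and
#' periodic flags are taken from the `Lattice="..."` and `pbc="..."`
#' fields of the comment line when present; frames without lattice
#' information get a non-periodic cell. Per-atom lines are parsed as
#' element symbol followed by three Cartesian coordinates (extra columns
#' are ignored). Coordinates are never wrapped on input.
#'
#' @param path file path.
#' @param frame_skip keep every `frame_skip`-th frame starting at the
#'   first (>= 1).
#' @param timestep time in fs between *stored* frames of the returned
#'   trajectory, i.e. the file's frame spacing times `frame_skip` is the
#'   caller's responsibility; the value given here is attached as-is.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, frame_skip = 1, timestep = 1) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  frame_skip <- as.integer(frame_skip)
  if (frame_skip < 1) stop("frame_skip must be >= 1")
  lines <- readLines(path)
  frames <- list()
  cells <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop("parse error at frame ", fidx, ": bad atom count header")
    }
    if (i + 1L + nat > length(lines)) {
      stop("parse error at frame ", fidx, ": truncated frame")
    }
    comment <- lines[i + 1L]
    at <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(at), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad)) {
      stop("parse error at frame ", fidx, ": malformed atom line ", bad[1])
    }
    el <- vapply(toks, `[`, "", 1L)
    # guard against a declared count swallowing the next frame header
    looks_numeric <- suppressWarnings(!is.na(as.numeric(el)))
    if (any(looks_numeric)) {
      stop("parse error at frame ", fidx,
           ": atom count mismatch (numeric token where element expected)")
    }
    pos <- matrix(suppressWarnings(as.numeric(vapply(
      toks, function(tk) tk[2:4], character(3)))), ncol = 3, byrow = TRUE)
    if (any(is.na(pos))) {
      stop("parse error at frame ", fidx, ": non-numeric coordinate")
    }
    lat <- .parse_lattice(comment)
    pbc <- .parse_pbc(comment)
    cell <- if (!is.null(lat)) {
      cell_geometry(lat, if (!is.null(pbc)) pbc else c(TRUE, TRUE, TRUE))
    } else {
      nonperiodic_cell()
    }
    frames[[length(frames) + 1L]] <- md_frame(pos, el)
    cells[[length(cells) + 1L]] <- cell
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  nat0 <- nrow(frames[[1]]$positions)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$positions) != nat0) {
      stop("inconsistent atom count across frames (frame ", k, ")")
    }
  }
  keep <- seq(1L, length(frames), by = frame_skip)
  frames <- frames[keep]
  cells <- cells[keep]
  same <- all(vapply(cells, function(cl) {
    identical(cl$periodic, cells[[1]]$periodic) &&
      max(abs(cl$vectors - cells[[1]]$vectors)) < 1e-12
  }, logical(1)))
  md_trajectory(frames, if (same) cells[[1]] else cells, timestep = timestep)
}

#' Write a trajectory as extended XYZ
#'
#' Writes `Lattice`, `Properties=species:S:1:pos:R:3` and `pbc` fields;
#' coordinates are printed with 8 decimals so a read/write/read round trip
#' preserves positions to well under 1e-6 Angstrom.
#'
#' @param traj an `md_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    fr <- traj$frames[[k]]
    cell <- frame_cell(traj, k)
    lat <- paste(sprintf("%.10g", as.numeric(t(cell$vectors))), collapse = " ")
    pbc <- paste(ifelse(cell$periodic, "T", "F"), collapse = " ")
    writeLines(as.character(nrow(fr$positions)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3 pbc="%s"', lat, pbc), con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f",
                       fr$elements, fr$positions[, 1],
                       fr$positions[, 2], fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Atom selections
#'
#' Selections name a subset of atoms either by element symbol, by explicit
#' 1-based atom indices, or as all atoms. `resolve_selection()` turns a
#' selection into a sorted vector of unique 1-based indices against a
#' trajectory (or a single frame).
#'
#' @param ... element symbols (character) for `select_elements`, or atom
#'   indices (integer) for `select_indices`.
#' @return An `md_selection`.
#' @examples
#' select_elements("O")
#' select_indices(c(1, 4, 7))
#' @export
select_elements <- function(...) {
  el <- as.character(unlist(list(...)))
  if (!length(el)) stop("element selection must name at least one symbol")
  structure(list(mode = "elements", elements = el), class = "md_selection")
}

#' @rdname select_elements
#' @export
select_indices <- function(...) {
  idx <- as.integer(unlist(list(...)))
  if (!length(idx)) stop("index selection must contain at least one index")
  structure(list(mode = "indices", indices = idx), class = "md_selection")
}

#' @rdname select_elements
#' @export
select_all <- function() structure(list(mode = "all"), class = "md_selection")

#' @rdname select_elements
#' @param x object to coerce: an `md_selection` (returned as-is), a
#'   character vector (element selection), or a numeric vector (indices).
#' @export
as_selection <- function(x) {
  if (inherits(x, "md_selection")) return(x)
  if (is.character(x)) return(select_elements(x))
  if (is.numeric(x)) return(select_indices(x))
  stop("cannot interpret object of class ", class(x)[1], " as a selection")
}

#' @rdname select_elements
#' @param traj an `md_trajectory` or `md_frame`.
#' @param spec an `md_selection` (or something `as_selection()` accepts).
#' @export
resolve_selection <- function(traj, spec) {
  spec <- as_selection(spec)
  elements <- if (inherits(traj, "md_frame")) traj$elements
              else traj$frames[[1]]$elements
  N <- length(elements)
  idx <- switch(spec$mode,
    all = seq_len(N),
    elements = {
      out <- which(elements %in% spec$elements)
      if (!length(out)) {
        warning("selection matches zero atoms (elements: ",
                paste(spec$elements, collapse = ","), ")")
      }
      out
    },
    indices = {
      ii <- sort(unique(spec$indices))
      if (any(ii < 1L | ii > N)) {
        stop("selection index out of range [1, ", N, "]")
      }
      ii
    },
    stop("unknown selection mode")
  )
  as.integer(idx)
}
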