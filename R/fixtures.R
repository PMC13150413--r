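# Seeded synthetic inputs with analytic ground truth. Every generator
# restores the caller's RNG state on exit and is bit-reproducible for a
# fixed seed (R's default Mersenne-Twister stream).

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Stationary AR(1) time series with known statistical inefficiency
#'
#' x_{t+1} = phi x_t + eps, eps ~ N(0, sigma^2), started from the
#' stationary distribution N(0, sigma^2 / (1 - phi^2)). The analytic
#' statistical inefficiency is g = (1 + phi) / (1 - phi) and the lag-k
#' autocorrelation phi^k.
#'
#' @param n series length.
#' @param phi AR coefficient, |phi| < 1.
#' @param sigma innovation standard deviation.
#' @param seed RNG seed.
#' @param dt time step in fs.
#' @return An `md_timeseries` with attribute `g_true`.
#' @export
make_ar1 <- function(n, phi = 0.9, sigma = 1, seed = 1, dt = 1) {
  if (abs(phi) >= 1) stop("|phi| must be < 1 for a stationary AR(1)")
  x <- .with_seed(seed, {
    e <- stats::rnorm(n, sd = sigma)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, sd = sigma / sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
    x
  })
  ts <- time_series(x, dt = dt, label = sprintf("ar1(phi=%g)", phi))
  attr(ts, "g_true") <- (1 + phi) / (1 - phi)
  ts
}

#' Periodic Brownian-walker trajectory with known diffusion coefficient
#'
#' Independent Gaussian steps per axis with variance 2 D dt per axis
#' (dt in ps), wrapped into a cubic periodic box. The unwrapped paths are
#' attached for round-trip testing.
#'
#' @param n_atoms number of walkers.
#' @param n_frames number of stored frames.
#' @param D true self-diffusion coefficient, Angstrom^2/ps.
#' @param dt time between frames, fs.
#' @param box cubic box edge, Angstrom.
#' @param seed RNG seed.
#' @param element element symbol for the walkers.
#' @return An `md_trajectory` with attributes `D_true` (Angstrom^2/ps) and
#'   `paths_unwrapped` (frames x atoms x 3 array).
#' @export
make_brownian <- function(n_atoms = 64, n_frames = 500, D = 0.23, dt = 10,
                          box = 20, seed = 1, element = "O") {
  step_sd <- sqrt(2 * D * dt / 1000) # per-axis, Angstrom
  if (D > 0 && !(step_sd < box / 4)) {
    stop("step too large relative to the box (would break unwrapping): ",
         "reduce D*dt or enlarge the box")
  }
  cell <- cubic_cell(box)
  U <- .with_seed(seed, {
    start <- matrix(stats::runif(n_atoms * 3, 0, box), ncol = 3)
    steps <- array(stats::rnorm((n_frames - 1) * n_atoms * 3, sd = step_sd),
                   dim = c(n_frames - 1, n_atoms, 3))
    U <- array(0, dim = c(n_frames, n_atoms, 3))
    U[1, , ] <- start
    for (f in 2:n_frames) U[f, , ] <- U[f - 1, , ] + steps[f - 1, , ]
    U
  })
  frames <- lapply(seq_len(n_frames), function(f) {
    md_frame(wrap_positions(matrix(U[f, , ], ncol = 3), cell),
             rep(element, n_atoms))
  })
  traj <- md_trajectory(frames, cell, timestep = dt)
  attr(traj, "D_true") <- D
  attr(traj, "paths_unwrapped") <- U
  traj
}

#' Simple-cubic lattice frame/trajectory
#'
#' n x n x n atoms at spacing `a` in a periodic cubic box of edge n*a,
#' where every atom has exactly 6 nearest neighbors at distance `a`.
#' Optional Gaussian jitter broadens the RDF peaks while keeping the shell
#' structure.
#'
#' @param a lattice constant, Angstrom.
#' @param n repetitions per axis.
#' @param element element symbol.
#' @param jitter per-coordinate Gaussian displacement sd, Angstrom.
#' @param n_frames number of (independently jittered) frames.
#' @param seed RNG seed used when jitter > 0 or n_frames > 1.
#' @return An `md_trajectory`.
#' @export
make_lattice <- function(a = 3, n = 3, element = "Ar", jitter = 0,
                         n_frames = 1, seed = 1) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  pos0 <- as.matrix(g) * a
  cell <- cubic_cell(n * a)
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(f) {
    pos <- pos0
    if (jitter > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos0), sd = jitter), ncol = 3)
    }
    md_frame(pos, rep(element, nrow(pos0)))
  }))
  md_trajectory(frames, cell, timestep = 1)
}

.water_h_pair <- function(o, dir, d_OH = 0.96, hoh = 104.5) {
  # two hydrogens around direction `dir` in the plane spanned with a
  # perpendicular axis
  dir <- dir / sqrt(sum(dir^2))
  perp <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(0, -dir[3], dir[2])
  perp <- perp / sqrt(sum(perp^2))
  half <- hoh / 2 * pi / 180
  h1 <- o + d_OH * (cos(half) * dir + sin(half) * perp)
  h2 <- o + d_OH * (cos(half) * dir - sin(half) * perp)
  rbind(h1, h2)
}

#' Constructed water dimer with exact hydrogen-bond geometry
#'
#' Donor water at the origin with one O-H bond along +x; the acceptor
#' oxygen is placed so the H...A distance is exactly `d_HA` and the
#' D-H...A angle exactly `angle_dha` degrees (180 = linear). The
#' acceptor's own hydrogens point away from the donor. Atom order:
#' O_d H H O_a H H.
#'
#' @param d_HA H...acceptor distance, Angstrom.
#' @param angle_dha D-H...A angle, degrees.
#' @param d_OH covalent O-H length, Angstrom.
#' @param box edge of the (non-periodic) bounding cube, Angstrom.
#' @return An `md_frame` with attribute `cell`.
#' @export
make_water_dimer <- function(d_HA = 1.85, angle_dha = 180, d_OH = 0.96,
                             box = 30) {
  od <- c(box / 2, box / 2, box / 2)
  h1 <- od + c(d_OH, 0, 0)
  # second donor hydrogen, off-axis
  h2 <- od + d_OH * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)
  th <- angle_dha * pi / 180
  u <- c(-cos(th), sin(th), 0) # angle at H between H->O_d (-x) and H->O_a
  oa <- h1 + d_HA * u
  ha <- .water_h_pair(oa, u, d_OH)
  pos <- rbind(od, h1, h2, oa, ha)
  fr <- md_frame(pos, c("O", "H", "H", "O", "H", "H"))
  attr(fr, "cell") <- cell_geometry(diag(3) * box,
                                    periodic = c(FALSE, FALSE, FALSE))
  fr
}

#' Linear hydrogen-bonded water chain
#'
#' n waters with oxygens on the x axis at spacing `d_OO`; each molecule
#' donates one perfectly linear hydrogen bond to the next (D-H...A =
#' 180 degrees, H...A = d_OO - d_OH). Atom order per molecule: O H H.
#'
#' @param n number of molecules (>= 2).
#' @param d_OO O-O spacing, Angstrom.
#' @param d_OH covalent O-H length, Angstrom.
#' @param box bounding cube edge, Angstrom.
#' @return An `md_frame` with attribute `cell`.
#' @export
make_water_chain <- function(n = 4, d_OO = 2.8, d_OH = 0.96, box = 40) {
  stopifnot(n >= 2)
  pos <- NULL
  el <- character(0)
  off <- c(5, box / 2, box / 2)
  up <- c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)
  for (k in seq_len(n)) {
    o <- off + c((k - 1) * d_OO, 0, 0)
    hb <- o + c(d_OH, 0, 0)   # donating H, toward the next molecule
    h2 <- o + d_OH * up       # spectator H
    pos <- rbind(pos, o, hb, h2)
    el <- c(el, "O", "H", "H")
  }
  fr <- md_frame(pos, el)
  attr(fr, "cell") <- cell_geometry(diag(3) * box,
                                    periodic = c(FALSE, FALSE, FALSE))
  fr
}

#' Random water box
#'
#' Places `n_mol` rigid waters with uniformly random positions (rejecting
#' O-O contacts below `min_OO`) and orientations in a periodic cubic box.
#' Used for oracle-equivalence tests of the hydrogen-bond machinery, not
#' as a physical water model.
#'
#' @param n_mol number of molecules.
#' @param box cubic box edge, Angstrom.
#' @param min_OO rejection threshold for O-O distances, Angstrom.
#' @param seed RNG seed.
#' @param n_frames number of independent frames.
#' @return An `md_trajectory`; atom order per molecule O H H.
#' @export
make_water_box <- function(n_mol = 64, box = 12.4453, min_OO = 2.4,
                           seed = 1, n_frames = 1) {
  cell <- cubic_cell(box)
  mk_frame <- function() {
    os <- matrix(NA_real_, n_mol, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_mol) {
      tries <- tries + 1L
      if (tries > 200000L) stop("failed to place molecules; lower density")
      cand <- stats::runif(3, 0, box)
      if (placed > 0) {
        d <- min_image(os[seq_len(placed), , drop = FALSE] -
                       matrix(cand, placed, 3, byrow = TRUE), cell)
        if (min(rowSums(d^2)) < min_OO^2) next
      }
      placed <- placed + 1L
      os[placed, ] <- cand
    }
    pos <- NULL
    for (m in seq_len(n_mol)) {
      v <- stats::rnorm(3)
      hh <- .water_h_pair(os[m, ], v / sqrt(sum(v^2)))
      pos <- rbind(pos, os[m, ], hh)
    }
    md_frame(pos, rep(c("O", "H", "H"), n_mol))
  }
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(f) mk_frame()))
  md_trajectory(frames, cell, timestep = 1)
}

#' Gaussian point clumps with known memberships
#'
#' k isotropic Gaussian clumps of `n_per` atoms with standard deviation
#' `spread`, centered `sep` apart on a line (wrapped into a periodic box
#' sized to hold them). Ground-truth memberships are attached.
#'
#' @param k number of clumps.
#' @param n_per atoms per clump.
#' @param spread per-coordinate sd within a clump, Angstrom.
#' @param sep center-to-center spacing, Angstrom.
#' @param seed RNG seed.
#' @param element element symbol.
#' @param center offset applied to all positions before wrapping (use to
#'   push a clump across the periodic boundary).
#' @return An `md_frame` with attributes `cell` and `membership`.
#' @export
make_clustered_points <- function(k = 3, n_per = 10, spread = 0.5, sep = 8,
                                  seed = 1, element = "Pt", center = c(0, 0, 0)) {
  if (sep < 4 * spread) {
    warning("clumps may overlap: sep < 4 * spread")
  }
  L <- max(sep * (k + 1), 20)
  cell <- cubic_cell(L)
  pos <- .with_seed(seed, {
    centers <- cbind(sep * (seq_len(k)), L / 2, L / 2)
    do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per * 3, sd = spread), ncol = 3) +
        matrix(centers[i, ], n_per, 3, byrow = TRUE)
    }))
  })
  pos <- wrap_positions(pos + matrix(center, nrow(pos), 3, byrow = TRUE),
                        cell)
  fr <- md_frame(pos, rep(element, nrow(pos)))
  attr(fr, "cell") <- cell
  attr(fr, "membership") <- rep(seq_len(k), each = n_per)
  fr
}

#' Uniform ideal-gas trajectory
#'
#' Uniformly random, uncorrelated positions in a periodic cubic box; the
#' exact reference for RDF normalization (g(r) = 1) and density
#' uniformity.
#'
#' @param n_atoms atoms per frame.
#' @param n_frames number of frames.
#' @param box cubic box edge, Angstrom.
#' @param seed RNG seed.
#' @param element element symbol.
#' @return An `md_trajectory`.
#' @export
make_uniform_gas <- function(n_atoms = 500, n_frames = 50, box = 15,
                             seed = 1, element = "Ar") {
  cell <- cubic_cell(box)
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(f) {
    md_frame(matrix(stats::runif(n_atoms * 3, 0, box), ncol = 3),
             rep(element, n_atoms))
  }))
  md_trajectory(frames, cell, timestep = 1)
}
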