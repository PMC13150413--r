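test_that("two isolated atoms give a single occupied RDF bin", {
  cell <- cubic_cell(10)
  fr <- md_frame(matrix(c(1, 1, 1, 4.12, 1, 1), 2, 3, byrow = TRUE),
                 c("O", "O"))
  tr <- md_trajectory(list(fr), cell)
  r <- prdf(tr, select_all(), select_all(), r_max = 5, bin_width = 0.05)
  hot <- which(r$g > 0)
  expect_length(hot, 1)
  expect_true(r$bin_edges[hot] <= 3.12 && 3.12 < r$bin_edges[hot + 1])
})

test_that("RDF normalization gives g = 1 for an ideal gas", {
  gas <- make_uniform_gas(n_atoms = 300, n_frames = 20, box = 15, seed = 8)
  r <- prdf(gas, select_all(), select_all(), r_max = 5, bin_width = 0.05)
  sel <- r$r >= 2
  expect_true(all(abs(r$g[sel] - 1) < 0.05))
  expect_true(mean(r$g[sel]) > 0.98 && mean(r$g[sel]) < 1.02)
  # custom index subsets share the same normalization logic
  half <- sort(sample(1:300, 150))
  rh <- prdf(gas, select_indices(half), select_indices(half),
             r_max = 5, bin_width = 0.1)
  expect_lt(abs(mean(rh$g[rh$r >= 2]) - 1), 0.05)
})

test_that("RDF is symmetric in its selections and keeps per-frame stacks", {
  gas <- make_uniform_gas(n_atoms = 60, n_frames = 4, box = 12, seed = 5)
  a <- select_indices(1:25)
  b <- select_indices(20:60)
  rab <- prdf(gas, a, b, r_max = 5, keep_frames = TRUE)
  rba <- prdf(gas, b, a, r_max = 5, keep_frames = TRUE)
  expect_identical(rab$g, rba$g)
  expect_equal(dim(rab$g_per_frame), c(4L, length(rab$g)))
  expect_equal(colMeans(rab$g_per_frame), rab$g)
})

test_that("the simple-cubic first shell holds 6 neighbors by RDF integration", {
  lat <- make_lattice(a = 3, n = 5)
  r <- prdf(lat, select_all(), select_all(), r_max = 7, bin_width = 0.05)
  expect_equal(r$r[which(r$g > 0)[1]], 3.025) # first peak bin contains a = 3
  rho <- (125 - 1) / 15^3
  shells <- 4 / 3 * pi * diff(r$bin_edges^3)
  cn <- sum((r$g * rho * shells)[r$r <= 3.6])
  expect_equal(cn, 6, tolerance = 1e-10)
})

test_that("first_minimum finds the inter-peak minimum of analytic curves", {
  edges <- seq(0, 6, by = 0.05)
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  g <- 1 + exp(-(r_mid - 2.8)^2 / 0.05) - 0.5 * exp(-(r_mid - 3.4)^2 / 0.05)
  rdf <- structure(list(bin_edges = edges, r = r_mid, g = g), class = "md_rdf")
  expect_lt(abs(first_minimum(rdf, search_from = 2) - 3.4), 0.051)

  # strictly increasing g: no minimum
  mono <- structure(list(bin_edges = edges, r = r_mid, g = r_mid),
                    class = "md_rdf")
  expect_error(first_minimum(mono), "monotone|no RDF")

  # two peaks: the minimum between them is returned, not the global one
  g2 <- exp(-(r_mid - 2.5)^2 / 0.1) + 2 * exp(-(r_mid - 4.5)^2 / 0.1)
  rdf2 <- structure(list(bin_edges = edges, r = r_mid, g = g2),
                    class = "md_rdf")
  got <- first_minimum(rdf2, search_from = 2)
  expect_true(got > 2.5 && got < 4.5)
  brute <- r_mid[r_mid > 2.5 & r_mid < 4.5][which.min(g2[r_mid > 2.5 &
                                                           r_mid < 4.5])]
  expect_lt(abs(got - brute), 0.2)
})

test_that("coordination numbers agree with lattice geometry and the oracle", {
  lat <- make_lattice(a = 3, n = 4)
  cn <- coordination_number(lat, select_all(), select_all(), "fixed",
                            cutoff = 3.6)
  expect_identical(cn$mean_cn, 6)

  # water dimer O-O at ~2.81 A within a 3.5 A cutoff
  fr <- make_water_dimer()
  tr <- md_trajectory(list(fr), attr(fr, "cell"))
  cnd <- coordination_number(tr, select_elements("O"), select_elements("O"),
                             "fixed", cutoff = 3.5)
  expect_equal(cnd$mean_cn, 1.0)

  # random box vs literal per-atom count
  set.seed(10)
  cell <- cubic_cell(12)
  pos <- matrix(runif(300, 0, 12), ncol = 3)
  frr <- md_frame(pos, rep("Ar", 100))
  trr <- md_trajectory(list(frr), cell)
  got <- coordination_number(trr, select_all(), select_all(), "fixed",
                             cutoff = 3)$mean_cn
  want <- mean(vapply(1:100, function(i) {
    sum(vapply(setdiff(1:100, i), function(j) {
      sqrt(sum(oracle_min_image(pos[j, ] - pos[i, ], cell)^2)) <= 3
    }, logical(1)))
  }, numeric(1)))
  expect_equal(got, want)
})

test_that("dynamic cutoffs come from the RDF first minimum", {
  lat <- make_lattice(a = 3, n = 4, jitter = 0.08, n_frames = 4, seed = 2)
  cn <- coordination_number(lat, select_all(), select_all(), "dynamic",
                            r_max = 5.5, search_from = 2.5)
  # cutoff falls between the first (a = 3) and second (a*sqrt(2) = 4.24) shells
  expect_true(cn$cutoff_used > 3.2 && cn$cutoff_used < 4.2)
  expect_equal(cn$mean_cn, 6, tolerance = 1e-10)
})

test_that("vdW-based cutoffs use the radii sum and honor overrides", {
  fr <- make_water_dimer()
  tr <- md_trajectory(list(fr), attr(fr, "cell"))
  # O-O cutoff = (1.52 + 1.52) * scale
  cn1 <- coordination_number(tr, select_elements("O"), select_elements("O"),
                             "vdw", vdw_scale = 1.0)
  expect_equal(cn1$mean_cn, 1.0)
  cn0 <- coordination_number(tr, select_elements("O"), select_elements("O"),
                             "vdw", vdw_scale = 0.9)
  expect_equal(cn0$mean_cn, 0)
  cno <- coordination_number(tr, select_elements("O"), select_elements("O"),
                             "vdw", vdw_scale = 0.9,
                             override = c(O = 1.7))
  expect_equal(cno$mean_cn, 1.0)
})
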