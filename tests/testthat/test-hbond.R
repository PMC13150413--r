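test_that("covalent hydrogens attach to their nearest donor", {
  fr <- make_water_dimer()
  cell <- attr(fr, "cell")
  asg <- assign_covalent_hydrogens(fr, cell, select_elements("O"))
  expect_equal(sort(asg$by_donor[["1"]]), c(2L, 3L))
  expect_equal(sort(asg$by_donor[["4"]]), c(5L, 6L))

  # lone hydrogen far from every oxygen stays unassigned
  pos <- rbind(c(5, 5, 5), c(8, 5, 5))
  lone <- md_frame(pos, c("O", "H"))
  asg2 <- assign_covalent_hydrogens(lone, nonperiodic_cell(),
                                    select_elements("O"))
  expect_true(is.na(asg2$h_donor[["2"]]))

  # exactly equidistant donors: deterministic tie to the lower index
  tie <- md_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0)),
                  c("O", "O", "H"))
  expect_warning(
    asg3 <- assign_covalent_hydrogens(tie, nonperiodic_cell(),
                                      select_elements("O"), dh_cut = 1.5),
    "equidistant")
  expect_equal(unname(asg3$h_donor[["3"]]), 1L)

  # random box mapping equals the brute-force nearest-donor search
  tr <- make_water_box(n_mol = 20, box = 10, seed = 4)
  fr <- tr$frames[[1]]
  asg4 <- assign_covalent_hydrogens(fr, tr$cell, select_elements("O"))
  os <- which(fr$elements == "O")
  for (h in which(fr$elements == "H")) {
    d <- vapply(os, function(o) {
      sqrt(sum(oracle_min_image(fr$positions[o, ] - fr$positions[h, ],
                                tr$cell)^2))
    }, numeric(1))
    expect_equal(unname(asg4$h_donor[[as.character(h)]]),
                 os[which.min(d)])
  }
})

test_that("constructed dimer geometries give exact bond counts", {
  fr <- make_water_dimer(d_HA = 1.85, angle_dha = 180)
  cell <- attr(fr, "cell")
  b <- find_hbonds(fr, cell, select_elements("O"), select_elements("O"))
  expect_equal(nrow(b), 1)
  expect_equal(b$donor, 1)
  expect_equal(b$acceptor, 4)
  expect_equal(b$d_HA, 1.85, tolerance = 1e-10)
  expect_equal(b$angle_DHA, 180, tolerance = 1e-6)

  bent <- make_water_dimer(d_HA = 1.85, angle_dha = 90)
  b90 <- find_hbonds(bent, attr(bent, "cell"), select_elements("O"),
                     select_elements("O"), angle_cut = 130)
  expect_equal(nrow(b90), 0)
})

test_that("bond sets match the triple-loop oracle on random water boxes", {
  for (s in 1:2) {
    tr <- make_water_box(n_mol = 64, box = 12.4453, seed = s)
    fr <- tr$frames[[1]]
    got <- find_hbonds(fr, tr$cell, select_elements("O"),
                       select_elements("O"))
    want <- oracle_hbonds(fr, tr$cell)
    expect_equal(got$donor, want$donor)
    expect_equal(got$hydrogen, want$hydrogen)
    expect_equal(got$acceptor, want$acceptor)
  }
})

test_that("loosening either cutoff never removes a bond", {
  tr <- make_water_box(n_mol = 40, box = 11, seed = 7)
  fr <- tr$frames[[1]]
  key <- function(b) paste(b$donor, b$hydrogen, b$acceptor)
  tight <- find_hbonds(fr, tr$cell, select_elements("O"),
                       select_elements("O"), d_HA_cut = 2.2,
                       angle_cut = 140)
  wider_d <- find_hbonds(fr, tr$cell, select_elements("O"),
                         select_elements("O"), d_HA_cut = 2.8,
                         angle_cut = 140)
  wider_a <- find_hbonds(fr, tr$cell, select_elements("O"),
                         select_elements("O"), d_HA_cut = 2.2,
                         angle_cut = 120)
  expect_true(all(key(tight) %in% key(wider_d)))
  expect_true(all(key(tight) %in% key(wider_a)))
})

test_that("bond detection is independent of atom input order", {
  tr <- make_water_box(n_mol = 16, box = 9, seed = 12)
  fr <- tr$frames[[1]]
  perm <- sample(seq_along(fr$elements))
  fr2 <- md_frame(fr$positions[perm, ], fr$elements[perm])
  b1 <- find_hbonds(fr, tr$cell, select_elements("O"), select_elements("O"))
  b2 <- find_hbonds(fr2, tr$cell, select_elements("O"), select_elements("O"))
  # map permuted indices back and compare canonical sets
  inv <- order(perm)
  remapped <- data.frame(donor = perm[b2$donor], hydrogen = perm[b2$hydrogen],
                         acceptor = perm[b2$acceptor])
  remapped <- remapped[order(remapped$donor, remapped$hydrogen,
                             remapped$acceptor), ]
  expect_equal(remapped$donor, b1$donor)
  expect_equal(remapped$acceptor, b1$acceptor)
})

test_that("network statistics follow hand-enumerated graphs", {
  # ideal dimer, 3 identical frames: 1 bond / 2 molecules, both-partner
  fr <- make_water_dimer()
  tr <- md_trajectory(rep(list(fr), 3), attr(fr, "cell"))
  st <- hbond_stats(tr, select_elements("O"), select_elements("O"))
  expect_equal(st$avg_per_molecule, 1.0)
  expect_equal(st$std_per_molecule, 0)
  expect_equal(st$components_per_frame, rep(1, 3))

  # donated-only convention halves the count
  std <- hbond_stats(tr, select_elements("O"), select_elements("O"),
                     per_molecule = "donated")
  expect_equal(std$avg_per_molecule, 0.5)

  # 4-molecule chain: 3 bonds, 1 component, avg 1.5 per molecule
  ch <- make_water_chain(4)
  trc <- md_trajectory(list(ch), attr(ch, "cell"))
  stc <- hbond_stats(trc, select_elements("O"), select_elements("O"))
  expect_equal(stc$per_frame_counts, 3)
  expect_equal(stc$avg_per_molecule, 1.5)
  expect_equal(stc$components_per_frame, 1)

  # bond-free box: all stats zero, one component per molecule
  far <- md_frame(rbind(c(1, 1, 1), c(1.96, 1, 1), c(1, 1.96, 1),
                        c(20, 20, 20), c(20.96, 20, 20), c(20, 20.96, 20)),
                  rep(c("O", "H", "H"), 2))
  trf <- md_trajectory(list(far), cubic_cell(50))
  stf <- hbond_stats(trf, select_elements("O"), select_elements("O"))
  expect_equal(stf$avg_per_molecule, 0)
  expect_equal(stf$components_per_frame, 2)

  # tree bound: edges >= vertices - components
  tr2 <- make_water_box(n_mol = 32, box = 10.5, seed = 3)
  st2 <- hbond_stats(tr2, select_elements("O"), select_elements("O"))
  expect_gte(st2$per_frame_counts[1],
             st2$n_molecules - st2$components_per_frame[1])
})
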