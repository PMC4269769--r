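test_that("region_spec defaults to the published regions and validates", {
  rs <- region_spec()
  expect_setequal(rs$I, c(111:113, 122:125, 162:165))
  expect_setequal(rs$II, 32:35)
  expect_setequal(rs$III, c(45:48, 58:61))
  expect_error(region_spec(I = 1:3, II = 3:5, III = 7:9), "disjoint")
  expect_error(region_spec(I = integer(0), II = 2, III = 3), "non-empty")
})

test_that("bending_angle reproduces hand-computed geometries", {
  # collinear with region II between I and III: 180 degrees
  st <- ca_structure(rbind(c(-5, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  rs <- region_spec(I = 1L, II = 2L, III = 3L)
  expect_equal(bending_angle(st, rs), 180)
  # right angle at the vertex
  st2 <- ca_structure(rbind(c(4, 0, 0), c(0, 0, 0), c(0, 7, 0)))
  expect_equal(bending_angle(st2, rs), 90)
  # hand-placed multi-residue regions: oracle from the normalised dot product
  xyz <- rbind(c(1, 2, 0), c(3, 2, 1), c(0, 0, 0), c(0, 0, 2), c(-2, 4, 1),
               c(-1, 5, 3))
  st3 <- ca_structure(xyz)
  rs3 <- region_spec(I = 1:2, II = 3:4, III = 5:6)
  c1 <- colMeans(xyz[1:2, ]); c2 <- colMeans(xyz[3:4, ]); c3 <- colMeans(xyz[5:6, ])
  v1 <- c1 - c2; v3 <- c3 - c2
  oracle <- acos(sum(v1 * v3) / sqrt(sum(v1^2) * sum(v3^2))) * 180 / pi
  expect_equal(bending_angle(st3, rs3), oracle, tolerance = 1e-12)
  # missing region residue is named in the error
  expect_error(bending_angle(st, region_spec(I = 1L, II = 2L, III = 9L)), "9")
})

test_that("radius_of_gyration matches simple closed forms and modes", {
  one <- ca_structure(matrix(c(4, 4, 4), 1, 3))
  expect_equal(radius_of_gyration(one), 0)
  two <- ca_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1)
  expect_equal(radius_of_gyration(two), 1)   # equal masses: weighting cancels
  # unequal masses shift the centre towards the heavy atom
  atoms <- two$atoms; atoms$mass <- c(3, 1)
  heavy <- structure3d(atoms, two$xyz)
  expect_equal(radius_of_gyration(heavy), sqrt((3 * 0.5^2 + 1.5^2) / 4))
  tpl <- toy_template()
  expect_equal(radius_of_gyration(tpl, "calpha", mass_weighted = FALSE),
               radius_of_gyration(select_atoms(tpl, elety = "CA"),
                                  mass_weighted = FALSE))
})

test_that("angle and Rg are rigid-motion invariant", {
  tpl <- toy_template()
  regions <- attr(tpl, "hinge_info")$regions
  R <- rotation_matrix(c(0, 1, 1), 1.9)
  moved <- structure3d(tpl$atoms, sweep(tpl$xyz %*% t(R), 2L, c(-8, 2, 13), "+"))
  attr(moved, "hinge_info") <- attr(tpl, "hinge_info")
  expect_equal(bending_angle(moved, regions), bending_angle(tpl, regions),
               tolerance = 1e-10)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(tpl),
               tolerance = 1e-10)
})

test_that("landscape probabilities normalise and free energies are min-shifted", {
  tpl <- toy_template()
  ens <- sample_hinge_ensemble(tpl, angle_spec(110, 8), n = 400, seed = 3)
  regions <- attr(tpl, "hinge_info")$regions
  g <- free_energy_landscape(ens, regions)
  expect_equal(sum(g$P), 1, tolerance = 1e-12)
  expect_equal(min(g$F, na.rm = TRUE), 0)
  expect_true(all(is.na(g$F[g$P == 0])))
  expect_true(all(g$F[!is.na(g$F)] >= 0))
  tab <- landscape_table(g)
  expect_equal(sum(tab$P), 1, tolerance = 1e-12)
})

test_that("two-bin occupancy (0.8, 0.2) gives a ln 4 free-energy gap", {
  tpl <- toy_template()
  s1 <- set_hinge_angle(tpl, 101)   # bin (100, 102]
  s2 <- set_hinge_angle(tpl, 139)
  ens <- conformation_ensemble(list(s1, s2), weights = c(0.8, 0.2))
  regions <- attr(tpl, "hinge_info")$regions
  g <- free_energy_landscape(ens, regions)
  occupied <- sort(g$F[g$P > 0])
  expect_length(occupied, 2L)
  expect_equal(occupied[2] - occupied[1], log(4), tolerance = 1e-12)
  # flat landscape: equal weights over distinct bins all sit at F = 0
  flat <- conformation_ensemble(lapply(c(90, 110, 130, 150),
                                       function(a) set_hinge_angle(tpl, a)))
  gf <- free_energy_landscape(flat, regions)
  expect_true(all(abs(gf$F[gf$P > 0]) < 1e-12))
})

test_that("the landscape recovers the generating angle distribution", {
  tpl <- toy_template()
  spec <- angle_spec(110, 8)
  n <- 2000
  ens <- sample_hinge_ensemble(tpl, spec, n = n, seed = 12)
  regions <- attr(tpl, "hinge_info")$regions
  g <- free_energy_landscape(ens, regions)
  expect_lt(abs(landscape_mode(g)$angle - 110), 2)
  # mean and sd of the landscape coordinates within 3 sigma Monte-Carlo error
  expect_lt(abs(mean(g$coords$angle) - 110), 3 * 8 / sqrt(n))
  expect_lt(abs(sd(g$coords$angle) - 8), 3 * 8 / sqrt(2 * (n - 1)))
})

test_that("project_structures matches landscape inputs and flags bad numbering", {
  tpl <- toy_template()
  regions <- attr(tpl, "hinge_info")$regions
  ens <- sample_hinge_ensemble(tpl, angle_spec(120, 6), n = 5, seed = 2)
  g <- free_energy_landscape(ens, regions)
  pr <- project_structures(list(own = ens), regions)
  expect_equal(pr$angle, g$coords$angle, tolerance = 1e-12)
  expect_equal(pr$rg, g$coords$rg, tolerance = 1e-12)
  ref <- set_hinge_angle(tpl, 97.25)
  one <- project_structures(list(ref = ref), regions)
  expect_equal(nrow(one), 1L)
  expect_equal(one$angle, 97.25, tolerance = 1e-6)
  bad <- project_structures(list(tiny = ca_structure(matrix(rnorm(9), 3, 3))),
                            regions)
  expect_false(is.na(bad$error))
  expect_true(is.na(bad$angle))
})

test_that("contact_map uses a strict cutoff, is symmetric, monotone in cutoff", {
  # residues 1-2 at exactly 8.0 A, residues 1-3 at 7.9 A
  st <- ca_structure(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 7.9, 0)))
  ens <- conformation_ensemble(list(st))
  cm <- contact_map(ens, cutoff = 8)
  expect_equal(cm["1", "2"], 0)   # exactly 8 A is not a contact
  expect_equal(cm["1", "3"], 1)
  expect_equal(diag(cm), c(`1` = 1, `2` = 1, `3` = 1))
  expect_equal(cm, t(cm))
  cm_wide <- contact_map(ens, cutoff = 8.0001)
  expect_true(all(cm_wide >= cm))
})

test_that("contact_map equals the brute-force oracle and rigid ensembles are 0/1", {
  tpl <- toy_template()
  ens <- conformation_ensemble(lapply(c(100, 140),
                                      function(a) set_hinge_angle(tpl, a)))
  cm <- contact_map(ens, cutoff = 8)
  ca <- which(tpl$atoms$elety == "CA")
  for (i in c(1, 10, 25)) for (j in c(5, 20, 34)) {
    frac <- mean(vapply(1:2, function(k) {
      xyz <- ens$xyz[ca, , k]
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 8
    }, logical(1)))
    if (i == j) frac <- 1
    expect_equal(unname(cm[i, j]), frac)
  }
  rigid <- conformation_ensemble(list(tpl, tpl, tpl))
  expect_true(all(contact_map(rigid, 8) %in% c(0, 1)))
})

test_that("ss_occupancy scores an ideal alpha-helix as helix fraction 1", {
  helix <- build_peptide(14, phi = -57, psi = -47)
  occ <- ss_occupancy(helix, mode = "backbone")
  interior <- occ$resno >= 4 & occ$resno <= 10
  expect_true(all(occ$helix[interior] == 1))
  expect_true(all(occ$sheet == 0))
})

test_that("extended chains score no secondary structure; fractions bounded", {
  ext <- build_peptide(12, phi = 180, psi = 180)
  occ <- ss_occupancy(ext, mode = "backbone")
  expect_true(all(occ$helix == 0))
  expect_true(all(occ$sheet == 0))
  expect_true(all(occ$helix + occ$sheet <= 1))
})

test_that("calpha fallback works and backbone mode rejects CA-only input", {
  tpl <- toy_template()
  ca_only <- select_atoms(tpl, elety = "CA")
  expect_error(ss_occupancy(ca_only, mode = "backbone"), "calpha")
  occ <- ss_occupancy(ca_only, mode = "calpha")
  # helical subdomain residues carry the helix label
  expect_gt(mean(occ$helix[occ$resno <= 18]), 0.5)
  expect_true(all(occ$helix + occ$sheet <= 1))
})
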