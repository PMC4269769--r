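test_that("noe_check is self-consistent and matches brute force", {
  tpl <- toy_template()
  ens <- conformation_ensemble(lapply(c(100, 120, 140),
                                      function(a) set_hinge_angle(tpl, a)))
  noe <- synth_noe(tpl, contact_cutoff = 8, padding = 0.5)
  rep <- noe_check(ens, noe, tolerance = 0.5)
  # per-structure brute-force oracle
  ca <- which(tpl$atoms$elety == "CA")
  resno <- tpl$atoms$resno[ca]
  for (k in 1:3) {
    st <- get_structure(ens, k)
    ok <- vapply(seq_len(nrow(noe)), function(r) {
      i <- ca[which(resno == noe$resno_i[r])]
      j <- ca[which(resno == noe$resno_j[r])]
      d <- sqrt(sum((st$xyz[i, ] - st$xyz[j, ])^2))
      d <= noe$upper[r] + 0.5 && d >= noe$lower[r]
    }, logical(1))
    expect_equal(rep$per_structure$fulfilled_pct[k], 100 * mean(ok))
  }
  # fulfilled + violated = 100 exactly
  expect_equal(rep$per_structure$fulfilled_pct + rep$per_structure$violated_pct,
               rep(100, 3))
  # the generating structure fulfils 100% of its own restraints
  self <- noe_check(conformation_ensemble(list(tpl)), noe, tolerance = 0)
  expect_equal(self$per_structure$fulfilled_pct, 100)
})

test_that("unattainable bounds give 0% and unresolvable atoms are reported", {
  tpl <- toy_template()
  ens <- conformation_ensemble(list(tpl))
  impossible <- noe_table(c(1L, 2L), "CA", c(30L, 31L), "CA",
                          upper = c(0.2, 0.2))
  rep <- noe_check(ens, impossible, tolerance = 0)
  expect_equal(rep$per_structure$fulfilled_pct, 0)
  mixed <- noe_table(c(1L, 2L), c("CA", "CB"), c(5L, 6L), "CA", upper = 20)
  rep2 <- noe_check(ens, mixed)
  expect_equal(nrow(rep2$excluded), 1L)
  expect_equal(rep2$per_structure$n_checked, 1L)
  only_bad <- noe_table(1L, "CB", 5L, "CB", upper = 20)
  expect_error(noe_check(ens, only_bad), "no NOE restraint resolvable")
})

test_that("r6-averaged NOE mode reports an ensemble-level fulfilment", {
  tpl <- toy_template()
  ens <- conformation_ensemble(lapply(c(110, 130),
                                      function(a) set_hinge_angle(tpl, a)))
  noe <- synth_noe(tpl, contact_cutoff = 8, padding = 2.0)
  rep <- noe_check(ens, noe, r6_average = TRUE)
  expect_true(is.numeric(rep$ensemble_fulfilled_pct))
  expect_gte(rep$ensemble_fulfilled_pct, 0)
  expect_lte(rep$ensemble_fulfilled_pct, 100)
})

test_that("debye_profile matches the two-point and single-scatterer closed forms", {
  s <- c(0, seq(0.01, 0.5, length.out = 40))
  d <- 7.3
  two <- ca_structure(rbind(c(0, 0, 0), c(0, 0, d)))
  p <- debye_profile(two, s, form_factor = "point")
  expected <- ifelse(s == 0, 4, 2 * (1 + sin(s * d) / (s * d)))
  expect_equal(p$intensity, expected, tolerance = 1e-12)
  one <- ca_structure(matrix(c(1, 2, 3), 1, 3))
  p1 <- debye_profile(one, s, form_factor = "residue", r_eff = 3)
  expect_equal(p1$intensity, exp(-0.5 * (s * 3)^2)^2, tolerance = 1e-12)
  expect_error(debye_profile(two, c(0.2, 0.1)), "strictly increasing")
  expect_error(debye_profile(two, -0.1), "non-negative")
})

test_that("dense bead sphere approximates the analytic sphere form factor", {
  R <- 10
  g <- seq(-R, R, by = 1.4)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, ]
  ball <- ca_structure(pts)
  s <- seq(0.02, 0.29, length.out = 25)   # sR < 3
  p <- debye_profile(ball, s, form_factor = "point")
  x <- s * R
  oracle <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  ratio <- (p$intensity / nrow(pts)^2) / oracle
  expect_lt(max(abs(ratio - 1)), 0.05)
})

test_that("debye profile is invariant under rigid-body motion", {
  tpl <- select_atoms(toy_template(), elety = "CA")
  s <- seq(0.01, 0.4, length.out = 30)
  a <- debye_profile(tpl, s)
  R <- rotation_matrix(c(1, 1, 1), 2.2)
  moved <- structure3d(tpl$atoms, sweep(tpl$xyz %*% t(R), 2L, c(10, -5, 3), "+"))
  b <- debye_profile(moved, s)
  expect_lt(max(abs(a$intensity - b$intensity) / a$intensity), 1e-10)
})

test_that("ensemble_profile is the weighted mean of member profiles", {
  tpl <- toy_template()
  s1 <- set_hinge_angle(tpl, 100); s2 <- set_hinge_angle(tpl, 150)
  s <- seq(0.01, 0.4, length.out = 25)
  p1 <- debye_profile(s1, s); p2 <- debye_profile(s2, s)
  # identical members: equals the single-structure profile
  same <- ensemble_profile(conformation_ensemble(list(s1, s1)), s)
  expect_equal(same$intensity, p1$intensity, tolerance = 1e-12)
  # weights (1, 0): equals the first member
  w10 <- ensemble_profile(conformation_ensemble(list(s1, s2), weights = c(1, 0)), s)
  expect_equal(w10$intensity, p1$intensity, tolerance = 1e-12)
  # general weights: brute-force average
  w <- c(0.3, 0.7)
  mix <- ensemble_profile(conformation_ensemble(list(s1, s2), weights = w), s)
  expect_equal(mix$intensity, 0.3 * p1$intensity + 0.7 * p2$intensity,
               tolerance = 1e-12)
})

test_that("chi2_fit closed-form scale behaves on exact data", {
  s <- seq(0.01, 0.4, length.out = 50)
  calc <- debye_profile(select_atoms(toy_template(), elety = "CA"), s)
  self <- saxs_profile(s, calc$intensity, sigma = 0.02 * calc$intensity)
  fit <- chi2_fit(calc, self)
  expect_equal(fit$chi2, 0, tolerance = 1e-20)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  doubled <- saxs_profile(s, 2 * calc$intensity)
  fit2 <- chi2_fit(calc, doubled)
  expect_equal(fit2$scale, 2, tolerance = 1e-12)
  expect_equal(fit2$chi2, 0, tolerance = 1e-20)
  bad <- saxs_profile(s, calc$intensity, sigma = rep(0, 50))
  expect_error(chi2_fit(calc, bad), "sigma contains zeros")
})

test_that("chi2 is about 1 under matched Gaussian noise (20 seeds, 100 points)", {
  tpl <- toy_template()
  ens <- conformation_ensemble(lapply(c(100, 125, 150),
                                      function(a) set_hinge_angle(tpl, a)))
  s <- seq(0.01, 0.45, length.out = 100)
  calc <- ensemble_profile(ens, s)
  chis <- vapply(1:20, function(seed) {
    chi2_fit(calc, synth_saxs(ens, s, noise_frac = 0.02, seed = seed))$chi2
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 0.15)
  expect_true(all(chis > 0.5 & chis < 1.6))
})

test_that("fit_constant recovers an additive offset", {
  s <- seq(0.01, 0.4, length.out = 60)
  calc <- debye_profile(select_atoms(toy_template(), elety = "CA"), s)
  shifted <- saxs_profile(s, 1.5 * calc$intensity + 7)
  fit <- chi2_fit(calc, shifted, fit_constant = TRUE)
  expect_equal(fit$scale, 1.5, tolerance = 1e-8)
  expect_equal(fit$constant, 7, tolerance = 1e-6)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
})

test_that("chi2_fit interpolates calculated profiles onto the experimental grid", {
  tpl <- select_atoms(toy_template(), elety = "CA")
  fine <- debye_profile(tpl, seq(0.005, 0.45, length.out = 400))
  coarse_s <- seq(0.01, 0.4, length.out = 30)
  exact <- debye_profile(tpl, coarse_s)
  fit <- chi2_fit(fine, exact)
  expect_lt(fit$chi2, 1e-4)   # linear-interpolation error only
  outside <- debye_profile(tpl, seq(0.05, 0.2, length.out = 50))
  expect_error(chi2_fit(outside, exact), "does not cover")
})

test_that("compare_models ranks the generating ensemble first", {
  tpl <- toy_template()
  truth <- conformation_ensemble(lapply(c(100, 110, 120),
                                        function(a) set_hinge_angle(tpl, a)))
  decoy <- conformation_ensemble(lapply(c(150, 160, 170),
                                        function(a) set_hinge_angle(tpl, a)))
  s <- seq(0.01, 0.45, length.out = 80)
  exp_prof <- synth_saxs(truth, s, noise_frac = 0.02, seed = 8)
  tab <- compare_models(list(truth = truth, decoy = decoy), exp_prof)
  expect_equal(tab$name[1], "truth")
  expect_lt(tab$chi2[1], tab$chi2[2])
  # single candidate and scale invariance of the ranking
  one <- compare_models(list(only = truth), exp_prof)
  expect_equal(nrow(one), 1L)
  scaled <- saxs_profile(exp_prof$s, 10 * exp_prof$intensity,
                         sigma = 10 * exp_prof$sigma)
  tab2 <- compare_models(list(truth = truth, decoy = decoy), scaled)
  expect_equal(tab2$name, tab$name)
  expect_equal(tab2$chi2, tab$chi2, tolerance = 1e-9)
  expect_error(compare_models(list(truth), exp_prof), "named")
})
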