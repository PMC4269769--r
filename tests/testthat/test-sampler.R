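# Small protocol used throughout: 4 replicas, 6 frames/replica/cycle.
small_protocol <- function(n_cycles = 6L, discard = 2L) {
  annealing_protocol(n_cycles = n_cycles, steps_per_cycle = 30L,
                     discard_cycles = discard, collect_fraction = 0.2,
                     collect_interval = 1L, equilibration_steps = 30L)
}

test_that("annealing protocol bookkeeping reproduces the published numbers", {
  proto <- annealing_protocol()  # 50 cycles, 100 sweeps, discard 20, 20% window
  ps <- protocol_summary(proto, n_replicas = 16L)
  expect_equal(ps$frames_per_replica_per_cycle, 20L)
  expect_equal(ps$n_structures, 9600L)
  expect_equal(ps$ns_per_cycle, 8)
})

test_that("annealing protocol validates its fields", {
  expect_error(annealing_protocol(n_cycles = 10, discard_cycles = 10), "< n_cycles")
  expect_error(annealing_protocol(collect_fraction = 0), "\\(0, 1\\]")
  expect_error(annealing_protocol(t_low = 400, t_high = 300), ">= t_low")
  expect_error(annealing_protocol(steps_per_cycle = 10, collect_fraction = 0.3,
                                  collect_interval = 2L), "whole number")
})

test_that("cycle temperature ramps to t_high and holds t_low in the window", {
  proto <- annealing_protocol(steps_per_cycle = 100L)
  temps <- vapply(1:100, function(s) repave:::cycle_temperature(proto, s),
                  numeric(1))
  expect_equal(max(temps), 400)
  expect_equal(temps[81:100], rep(300, 20))      # collection window at t_low
  expect_equal(which.max(temps), 40)             # heat then cool
})

test_that("metropolis sampling of a two-state system matches Boltzmann", {
  de <- 2000   # J/mol
  temp <- 300
  p2_exact <- exp(-de / (repave::R_GAS * temp)) /
    (1 + exp(-de / (repave::R_GAS * temp)))
  set.seed(123)
  n <- 1e6
  state <- 1L
  visits2 <- 0L
  for (i in seq_len(n)) {
    delta <- if (state == 1L) de else -de
    if (metropolis_accept(delta, temp)) state <- 3L - state
    if (state == 2L) visits2 <- visits2 + 1L
  }
  expect_lt(abs(visits2 / n - p2_exact), 0.02)
})

test_that("sampling is seed-reproducible and emits convergence traces", {
  tpl <- toy_template()
  ff <- toy_forcefield(tpl)
  r1 <- run_unrestrained_sampling(tpl, ff, small_protocol(), n_replicas = 4L,
                                  seed = 5L)
  r2 <- run_unrestrained_sampling(tpl, ff, small_protocol(), n_replicas = 4L,
                                  seed = 5L)
  expect_identical(r1$ensemble$xyz, r2$ensemble$xyz)
  expect_equal(n_structures(r1$ensemble), 4L * 4L * 6L)
  # Rg trace: one row per collected frame, per-cycle log with acceptance
  expect_equal(nrow(r1$trace), n_structures(r1$ensemble))
  expect_true(all(c("cycle", "step", "replica", "rg") %in% names(r1$trace)))
  expect_true(all(is.finite(r1$trace$rg)))
  expect_true(all(r1$log$acceptance >= 0 & r1$log$acceptance <= 1))
})

test_that("restrained run with alpha = 0 reproduces the unrestrained trajectory", {
  tpl <- toy_template()
  ff <- toy_forcefield(tpl)
  data <- synth_rdc(tpl, toy_tensor(), noise_sd = 0.5, seed = 1)
  zero <- rdc_restraint(data, restraint_schedule(alpha_max = 0),
                        tensor_mode = "fixed",
                        tensor = saupe_tensor(matrix(0, 3, 3)))
  a <- run_restrained_sampling(tpl, ff, zero, small_protocol(), n_replicas = 4L,
                               seed = 9L)
  b <- run_unrestrained_sampling(tpl, ff, small_protocol(), n_replicas = 4L,
                                 seed = 9L)
  expect_identical(a$ensemble$xyz, b$ensemble$xyz)
})

test_that("alpha = 0 ensembles are statistically indistinguishable from unrestrained", {
  tpl <- toy_template()
  ff <- toy_forcefield(tpl)
  regions <- attr(tpl, "hinge_info")$regions
  data <- synth_rdc(tpl, toy_tensor(), noise_sd = 0.5, seed = 1)
  zero <- rdc_restraint(data, restraint_schedule(alpha_max = 0),
                        tensor_mode = "fixed",
                        tensor = saupe_tensor(matrix(0, 3, 3)))
  # one frame per replica per cycle to limit autocorrelation
  proto <- annealing_protocol(n_cycles = 12L, steps_per_cycle = 30L,
                              discard_cycles = 2L, collect_fraction = 0.2,
                              collect_interval = 6L, equilibration_steps = 30L)
  angles_of <- function(ens) {
    vapply(seq_len(n_structures(ens)),
           function(k) bending_angle(get_structure(ens, k), regions), numeric(1))
  }
  ang_a <- unlist(lapply(1:5, function(s) {
    angles_of(run_restrained_sampling(tpl, ff, zero, proto, n_replicas = 4L,
                                      seed = s)$ensemble)
  }))
  ang_b <- unlist(lapply(1:5, function(s) {
    angles_of(run_unrestrained_sampling(tpl, ff, proto, n_replicas = 4L,
                                        seed = 100L + s)$ensemble)
  }))
  expect_gt(suppressWarnings(ks.test(ang_a, ang_b)$p.value), 0.01)
})

test_that("a flat hinge potential samples a broader angle distribution", {
  tpl <- toy_template()
  regions <- attr(tpl, "hinge_info")$regions
  data <- synth_rdc(set_hinge_angle(tpl, 95), toy_tensor(), noise_sd = 0.3,
                    seed = 4)
  flat_ff <- toy_forcefield(tpl, hinge = list(type = "flat"))
  restr <- rdc_restraint(data, tensor_mode = "fixed", tensor = toy_tensor())
  free <- run_unrestrained_sampling(tpl, flat_ff, small_protocol(),
                                    n_replicas = 4L, seed = 2L)
  held <- run_restrained_sampling(tpl, flat_ff, restr, small_protocol(),
                                  n_replicas = 4L, seed = 2L)
  ang <- function(run) vapply(seq_len(n_structures(run$ensemble)), function(k) {
    bending_angle(get_structure(run$ensemble, k), regions)
  }, numeric(1))
  expect_gt(sd(ang(free)), sd(ang(held)))
})

test_that("restraining lowers the ensemble Q-factor on the restraining data", {
  tpl <- toy_template()
  truth <- set_hinge_angle(tpl, 95)
  data <- synth_rdc(truth, toy_tensor(), noise_sd = 0.3, seed = 4)
  ff <- toy_forcefield(tpl)
  restr <- rdc_restraint(data, tensor_mode = "fixed", tensor = toy_tensor())
  held <- run_restrained_sampling(tpl, ff, restr, small_protocol(),
                                  n_replicas = 4L, seed = 3L, start_angle = 130)
  free <- run_unrestrained_sampling(tpl, ff, small_protocol(), n_replicas = 4L,
                                    seed = 3L, start_angle = 130)
  mean_calc <- function(ens) {
    acc <- 0
    for (k in seq_len(n_structures(ens))) {
      acc <- acc + back_calc_rdc(get_structure(ens, k), toy_tensor(), data,
                                 reconstruct_h = FALSE)$calc
    }
    acc / n_structures(ens)
  }
  q_held <- rdc_q_factor(mean_calc(held$ensemble), data$value)
  q_free <- rdc_q_factor(mean_calc(free$ensemble), data$value)
  expect_lte(q_held, q_free)
})

test_that("misconfigured move sizes trigger the low-acceptance warning", {
  tpl <- toy_template()
  stiff <- toy_forcefield(tpl, hinge = list(type = "harmonic", angle0 = 120,
                                            k = 20000))
  proto <- annealing_protocol(t_low = 300, t_high = 300, n_cycles = 1L,
                              steps_per_cycle = 50L, discard_cycles = 0L,
                              collect_fraction = 0.2, equilibration_steps = 0L)
  expect_warning(
    run_unrestrained_sampling(tpl, stiff, proto, n_replicas = 2L, seed = 1L,
                              move_sd = 1000),
    "acceptance rate")
})

test_that("toy force field is rigid-motion invariant with exact decomposition", {
  tpl <- toy_template()
  ff <- toy_forcefield(tpl)
  bent <- set_hinge_angle(tpl, 80)
  e <- ff$energy(bent$xyz, components = TRUE)
  expect_equal(e$total, e$elastic + e$hinge + e$repulsion, tolerance = 1e-12)
  expect_lt(e$elastic, 1e-12)   # hinge moves keep subdomains rigid
  R <- rotation_matrix(c(2, 1, -1), 0.7)
  moved <- sweep(bent$xyz %*% t(R), 2L, c(3, -4, 5), "+")
  expect_equal(ff$energy(moved), e$total, tolerance = 1e-8)
})

test_that("rdc_restraint bundle validates tensor mode", {
  data <- rdc_table(1:6, "N", "H", rnorm(6))
  expect_error(rdc_restraint(data, tensor_mode = "fixed"), "requires a tensor")
  b <- rdc_restraint(data, tensor_mode = "steric", order_scale = 2e-3)
  expect_equal(b$order_scale, 2e-3)
})
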