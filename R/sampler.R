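# Metropolis Monte Carlo simulated-annealing sampler over the hinge model.
#
# The restrained-MD engine is replaced by Metropolis MC over the hinge degree
# of freedom: a move rotates the hairpin rigidly about the hinge axis, and is
# accepted on the hybrid energy E_total = E_ff + E_rdc (+ E_cs) at the cycle's
# current temperature. "Steps" are MC sweeps; the time-based protocol maps
# proportionally (default 1 sweep = 5 ps, so a 500 ps cycle is 100 sweeps and
# the 5 ps collection interval is 1 sweep). Move sizes are auto-tuned during
# the discarded cycles only and frozen afterwards, preserving detailed balance
# in the collected ensemble.

#' Gas constant in J mol^-1 K^-1
#' @export
R_GAS <- 8.314462618

#' Metropolis acceptance decision
#'
#' Accepts with probability min(1, exp(-delta_e / (R T))); always consumes one
#' uniform variate so trajectories with identical energies are identical.
#'
#' @param delta_e energy change in J/mol.
#' @param temperature temperature in K.
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  runif(1) < exp(-delta_e / (R_GAS * temperature))
}

#' Simulated-annealing protocol
#'
#' Defaults mirror the published protocol: 50 cycles between 300 and 400 K,
#' 500 ps per cycle with the final 100 ps (20%) equilibrated at the base
#' temperature and sampled every 5 ps, first 20 cycles discarded. Under the
#' default 5 ps-per-sweep mapping a cycle is 100 sweeps with 20 collected
#' frames per replica.
#'
#' @param t_low,t_high temperature bounds in K.
#' @param n_cycles annealing cycles.
#' @param steps_per_cycle MC sweeps per cycle.
#' @param discard_cycles initial cycles excluded from the ensemble.
#' @param collect_fraction final fraction of each cycle, held at `t_low`, from
#'   which structures are collected.
#' @param collect_interval sweeps between collected frames.
#' @param equilibration_steps sweeps of initial equilibration at `t_low`
#'   (the force-constant ramp spans this phase).
#' @param ps_per_step physical-time bookkeeping: picoseconds represented by
#'   one sweep (default 5).
#' @return object of class `annealing_protocol`.
#' @export
annealing_protocol <- function(t_low = 300, t_high = 400, n_cycles = 50L,
                               steps_per_cycle = 100L, discard_cycles = 20L,
                               collect_fraction = 0.2, collect_interval = 1L,
                               equilibration_steps = 100L, ps_per_step = 5) {
  if (discard_cycles >= n_cycles) stop("discard_cycles must be < n_cycles")
  if (collect_fraction <= 0 || collect_fraction > 1) {
    stop("collect_fraction must lie in (0, 1]")
  }
  if (t_high < t_low) stop("t_high must be >= t_low")
  window <- round(steps_per_cycle * collect_fraction)
  if (window < 1L || window %% collect_interval != 0L) {
    stop("collection window must hold a whole number of collection intervals")
  }
  out <- list(t_low = t_low, t_high = t_high, n_cycles = as.integer(n_cycles),
              steps_per_cycle = as.integer(steps_per_cycle),
              discard_cycles = as.integer(discard_cycles),
              collect_fraction = collect_fraction,
              collect_interval = as.integer(collect_interval),
              equilibration_steps = as.integer(equilibration_steps),
              ps_per_step = ps_per_step)
  class(out) <- "annealing_protocol"
  out
}

#' Bookkeeping summary of an annealing protocol
#' @param protocol an [annealing_protocol()].
#' @param n_replicas replica count.
#' @return list with `frames_per_replica_per_cycle`, `n_structures` (size of
#'   the composed ensemble), and `ns_per_cycle` (total sampling per cycle
#'   across replicas, in nanoseconds).
#' @export
protocol_summary <- function(protocol, n_replicas) {
  window <- round(protocol$steps_per_cycle * protocol$collect_fraction)
  frames <- window %/% protocol$collect_interval
  kept <- protocol$n_cycles - protocol$discard_cycles
  list(frames_per_replica_per_cycle = frames,
       n_structures = n_replicas * kept * frames,
       ns_per_cycle = protocol$steps_per_cycle * protocol$ps_per_step *
         n_replicas / 1000)
}

# Temperature at sweep `step` (1-based) within a cycle: linear heat to t_high,
# linear cool back, then hold at t_low for the collection window.
cycle_temperature <- function(protocol, step) {
  L <- protocol$steps_per_cycle
  hold <- round(L * protocol$collect_fraction)
  ramp <- L - hold
  up <- ceiling(ramp / 2)
  down <- ramp - up
  if (step <= up) {
    protocol$t_low + (protocol$t_high - protocol$t_low) * step / up
  } else if (step <= ramp) {
    protocol$t_high - (protocol$t_high - protocol$t_low) * (step - up) / down
  } else {
    protocol$t_low
  }
}

#' Coarse-grained force field for the hinge model
#'
#' Stands in for the molecular-mechanics term of the hybrid energy. Three
#' parts: an elastic network over C-alpha pairs within each rigid subdomain
#' (built from template distances; exactly constant under hinge moves, kept as
#' a correctness check), a hinge-angle potential, and a soft excluded-volume
#' repulsion between core and hairpin C-alphas. All terms in J/mol; invariant
#' under global rotation/translation.
#'
#' The default hinge potential is harmonic about the template's own bending
#' angle with k = 1 J mol^-1 deg^-2 (thermal spread of roughly 35 degrees at 300 K, a hairpin with large-amplitude motions about its own preferred orientation), so
#' the bare force field has a conformational preference of its own that
#' restraints must override -- the situation the replica-averaged method is
#' built for. Pass `list(type = "flat")` for a free hinge.
#'
#' @param template a [build_hinge_template()] structure.
#' @param k_spring elastic constant, J mol^-1 A^-2.
#' @param spring_cutoff network cutoff in Angstrom.
#' @param hinge `list(type = "flat")` or
#'   `list(type = "harmonic", angle0 = degrees, k = J mol^-1 deg^-2)`;
#'   `angle0 = NULL` means the template's measured bending angle.
#' @param k_rep repulsion constant, J mol^-1 A^-2.
#' @param rep_dist onset distance of the soft repulsion in Angstrom.
#' @return object of class `toy_forcefield` with an `$energy(xyz)` function.
#' @export
toy_forcefield <- function(template, k_spring = 500, spring_cutoff = 10,
                           hinge = list(type = "harmonic", angle0 = NULL, k = 1),
                           k_rep = 200, rep_dist = 4.0) {
  info <- attr(template, "hinge_info")
  if (is.null(info)) stop("template lacks hinge_info")
  if (hinge$type == "harmonic" && is.null(hinge$angle0)) {
    hinge$angle0 <- bending_angle(template, info$regions)
  }
  atoms <- template$atoms
  ca <- which(atoms$elety == "CA")
  resno <- atoms$resno[ca]
  nc <- info$topology$n_core; nh <- info$topology$n_hinge
  grp <- ifelse(resno <= nc + nh, 1L, 2L)
  # elastic network within each rigid group
  pairs <- NULL
  xyz0 <- template$xyz
  for (g in 1:2) {
    idx <- ca[grp == g]
    if (length(idx) < 2L) next
    d <- as.matrix(stats::dist(xyz0[idx, , drop = FALSE]))
    sel <- which(upper.tri(d) & d < spring_cutoff, arr.ind = TRUE)
    pairs <- rbind(pairs, cbind(idx[sel[, 1]], idx[sel[, 2]],
                                d[sel]))
  }
  core_ca <- ca[grp == 1L]
  hp_ca <- ca[grp == 2L]
  regions <- info$regions
  ca_r1 <- ca[resno %in% regions$I]
  ca_r2 <- ca[resno %in% regions$II]
  ca_r3 <- ca[resno %in% regions$III]
  energy <- function(xyz, components = FALSE) {
    e_el <- 0
    if (!is.null(pairs)) {
      dv <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
      e_el <- k_spring * sum((sqrt(rowSums(dv^2)) - pairs[, 3])^2)
    }
    e_hinge <- 0
    if (hinge$type == "harmonic") {
      c1 <- colMeans(xyz[ca_r1, , drop = FALSE])
      c2 <- colMeans(xyz[ca_r2, , drop = FALSE])
      c3 <- colMeans(xyz[ca_r3, , drop = FALSE])
      ang <- angle_at(c1, c2, c3) * 180 / pi
      e_hinge <- hinge$k * (ang - hinge$angle0)^2
    }
    dmat <- sqrt(outer(rowSums(xyz[core_ca, , drop = FALSE]^2),
                       rowSums(xyz[hp_ca, , drop = FALSE]^2), "+") -
                   2 * xyz[core_ca, , drop = FALSE] %*%
                   t(xyz[hp_ca, , drop = FALSE]))
    viol <- pmax(0, rep_dist - dmat)
    e_rep <- k_rep * sum(viol^2)
    if (components) {
      list(total = e_el + e_hinge + e_rep, elastic = e_el,
           hinge = e_hinge, repulsion = e_rep)
    } else {
      e_el + e_hinge + e_rep
    }
  }
  out <- list(energy = energy, info = info)
  class(out) <- "toy_forcefield"
  out
}

#' RDC restraint bundle for the sampler
#' @param data an [rdc_table()] of experimental couplings.
#' @param schedule a [restraint_schedule()].
#' @param d_max dipolar constant in Hz.
#' @param tensor_mode `"svd"` (refit each replica's tensor to the data every
#'   update interval, the default), `"fixed"` (use `tensor` throughout), or
#'   `"steric"` (structure-based prediction from each replica's shape).
#' @param tensor a [saupe_tensor()] for `"fixed"` mode.
#' @param order_scale medium order parameter for `"steric"` mode.
#' @return object of class `rdc_restraint`.
#' @export
rdc_restraint <- function(data, schedule = restraint_schedule(),
                          d_max = DMAX_NH,
                          tensor_mode = c("svd", "fixed", "steric"),
                          tensor = NULL, order_scale = 1e-3) {
  tensor_mode <- match.arg(tensor_mode)
  if (tensor_mode == "fixed" && is.null(tensor)) {
    stop("fixed tensor mode requires a tensor")
  }
  out <- list(data = data, schedule = schedule, d_max = d_max,
              tensor_mode = tensor_mode, tensor = tensor,
              order_scale = order_scale)
  class(out) <- "rdc_restraint"
  out
}

# Replica tensor according to the bundle's mode.
replica_tensor <- function(bundle, structure) {
  switch(bundle$tensor_mode,
         fixed = bundle$tensor,
         svd = svd_fit_tensor(structure, bundle$data, bundle$d_max)$tensor,
         steric = steric_tensor(structure, order_scale = bundle$order_scale))
}

# Internal sampler engine shared by the restrained and unrestrained entry
# points. Replicas are parametrised by the rigid rotation delta of the hairpin
# about the hinge axis relative to the template.
run_sampler <- function(template, forcefield, restraint, protocol, n_replicas,
                        seed, start_angle = NULL, move_sd = 8) {
  info <- attr(template, "hinge_info")
  if (is.null(info)) stop("template lacks hinge_info")
  start <- if (is.null(start_angle)) template else
    set_hinge_angle(template, start_angle)
  base_xyz <- start$xyz
  mob <- info$mobile_atoms
  pivot <- info$pivot
  axis <- info$axis
  atoms <- template$atoms
  rel0 <- sweep(base_xyz[mob, , drop = FALSE], 2L, pivot)

  coords_at <- function(delta) {
    xyz <- base_xyz
    xyz[mob, ] <- sweep(rel0 %*% t(rotation_matrix(axis, delta)), 2L, pivot, "+")
    xyz
  }

  restrained <- !is.null(restraint)
  if (restrained) {
    map <- match_rdc_records(start, restraint$data)
    if (!all(map$ok)) {
      warning(sum(!map$ok), " RDC record(s) unmatched in topology; excluded")
    }
    ridx <- which(map$ok)
    d_exp <- restraint$data$value[ridx]
    nrec <- length(ridx)
    if (nrec == 0L) stop("no RDC record matches the topology")
    sched <- restraint$schedule
    if (sched$ramp_steps == 0L) sched$ramp_steps <- protocol$equilibration_steps
  }

  replica_d <- function(xyz, S) {
    r <- xyz[map$b[ridx], , drop = FALSE] - xyz[map$a[ridx], , drop = FALSE]
    u <- r / sqrt(rowSums(r^2))
    restraint$d_max * rowSums((u %*% unclass(S)) * u)
  }

  set.seed(seed)
  M <- n_replicas
  deltas <- rep(0, M)
  xyzs <- lapply(deltas, coords_at)
  e_ff <- vapply(xyzs, forcefield$energy, numeric(1))
  tensors <- NULL
  D <- NULL
  if (restrained) {
    tensors <- lapply(xyzs, function(x)
      replica_tensor(restraint, structure3d(atoms, x)))
    D <- t(vapply(seq_len(M), function(m) replica_d(xyzs[[m]], tensors[[m]]),
                  numeric(nrec)))
    if (nrec == 1L) D <- matrix(D, nrow = M)
  }
  rdc_energy <- function(dbar, alpha) {
    if (!restrained) return(0)
    alpha * sum((dbar - d_exp)^2)
  }

  move_sd_rad <- move_sd * pi / 180
  global_step <- 0L
  collected <- list()
  trace_rows <- list()
  log_rows <- list()
  ca_idx <- which(atoms$elety == "CA")
  ca_mass <- atoms$mass[ca_idx]

  run_phase <- function(n_steps, temp_fn, cycle_id, collect_from = Inf,
                        tune = FALSE) {
    acc <- 0L; tries <- 0L
    for (s in seq_len(n_steps)) {
      global_step <<- global_step + 1L
      temp <- temp_fn(s)
      alpha <- if (restrained) scheduled_alpha(sched, global_step, temp) else 0
      if (restrained &&
          global_step %% sched$tensor_update_interval == 0L &&
          restraint$tensor_mode != "fixed") {
        for (m in seq_len(M)) {
          tensors[[m]] <<- replica_tensor(restraint, structure3d(atoms, xyzs[[m]]))
          D[m, ] <<- replica_d(xyzs[[m]], tensors[[m]])
        }
      }
      for (m in seq_len(M)) {
        prop <- deltas[m] + rnorm(1, 0, move_sd_rad)
        xyz_new <- coords_at(prop)
        e_ff_new <- forcefield$energy(xyz_new)
        if (restrained) {
          d_new <- replica_d(xyz_new, tensors[[m]])
          dbar_new <- colMeans(D) + (d_new - D[m, ]) / M
          e_rdc_new <- rdc_energy(dbar_new, alpha)
          e_rdc_old <- rdc_energy(colMeans(D), alpha)
          delta_e <- (e_ff_new + e_rdc_new) - (e_ff[m] + e_rdc_old)
        } else {
          delta_e <- e_ff_new - e_ff[m]
        }
        tries <- tries + 1L
        if (metropolis_accept(delta_e, temp)) {
          acc <- acc + 1L
          deltas[m] <<- prop
          xyzs[[m]] <<- xyz_new
          e_ff[m] <<- e_ff_new
          if (restrained) D[m, ] <<- d_new
        }
      }
      if (tune && tries >= M) {
        # crude adaptation during discarded phases only
        rate <- acc / tries
        if (s %% 20L == 0L) {
          if (rate < 0.2) move_sd_rad <<- move_sd_rad * 0.8
          if (rate > 0.5) move_sd_rad <<- move_sd_rad * 1.25
        }
      }
      if (s >= collect_from &&
          (s - collect_from) %% protocol$collect_interval == 0L) {
        for (m in seq_len(M)) {
          st <- structure3d(atoms, xyzs[[m]], model_id = length(collected) + 1L)
          collected[[length(collected) + 1L]] <<- st
          xyz_ca <- xyzs[[m]][ca_idx, , drop = FALSE]
          cm <- colSums(xyz_ca * ca_mass) / sum(ca_mass)
          trace_rows[[length(trace_rows) + 1L]] <<- c(
            cycle = cycle_id, step = s, replica = m,
            rg = sqrt(sum(ca_mass * rowSums(sweep(xyz_ca, 2, cm)^2)) / sum(ca_mass)))
        }
      }
    }
    rate <- if (tries > 0) acc / tries else NA_real_
    if (!is.na(rate) && rate < 0.01) {
      warning(sprintf("acceptance rate %.2f%% in cycle %s: move size likely misconfigured",
                      100 * rate, cycle_id))
    }
    e_rdc_now <- if (restrained) {
      rdc_energy(colMeans(D), if (restrained) scheduled_alpha(sched, global_step, temp_fn(n_steps)) else 0)
    } else 0
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      cycle = cycle_id, acceptance = rate,
      e_ff_mean = mean(e_ff), e_rdc = e_rdc_now,
      move_sd_deg = move_sd_rad * 180 / pi)
    invisible(NULL)
  }

  # equilibration at t_low (force-constant ramp spans this phase)
  if (protocol$equilibration_steps > 0L) {
    run_phase(protocol$equilibration_steps, function(s) protocol$t_low,
              cycle_id = 0L, tune = TRUE)
  }
  window <- round(protocol$steps_per_cycle * protocol$collect_fraction)
  for (cyc in seq_len(protocol$n_cycles)) {
    discard <- cyc <= protocol$discard_cycles
    collect_from <- if (discard) Inf else
      protocol$steps_per_cycle - window + protocol$collect_interval
    run_phase(protocol$steps_per_cycle,
              function(s) cycle_temperature(protocol, s),
              cycle_id = cyc, collect_from = collect_from, tune = discard)
  }

  ens <- conformation_ensemble(collected)
  attr(ens, "hinge_info") <- info
  trace <- as.data.frame(do.call(rbind, trace_rows))
  list(ensemble = ens, log = do.call(rbind, log_rows), trace = trace,
       final_move_sd = move_sd_rad * 180 / pi)
}

#' Replica-averaged restrained sampling
#'
#' Runs the annealing protocol with Metropolis MC under the hybrid energy
#' E_total = E_ff + E_rdc: per-replica alignment tensors are refreshed every
#' `tensor_update_interval` steps, the force constant follows the ramp /
#' high-temperature schedule, and the ensemble is composed solely from the
#' base-temperature collection windows of the post-discard cycles (so the
#' default 16-replica, 50-cycle protocol yields 16 x 30 x 20 = 9600
#' structures).
#'
#' @param template a [build_hinge_template()] structure.
#' @param forcefield a [toy_forcefield()].
#' @param restraint an [rdc_restraint()] bundle.
#' @param protocol an [annealing_protocol()].
#' @param n_replicas replica count (default 16).
#' @param seed RNG seed.
#' @param start_angle optional initial bending angle in degrees (default: the
#'   template's).
#' @param move_sd initial proposal width in degrees (auto-tuned during
#'   discarded cycles, frozen afterwards).
#' @return list with `ensemble` ([conformation_ensemble()]), `log` (per-cycle
#'   acceptance and energy terms), `trace` (per-collected-frame radius of
#'   gyration for convergence monitoring) and `final_move_sd`.
#' @export
run_restrained_sampling <- function(template, forcefield, restraint, protocol,
                                    n_replicas = 16L, seed = 1L,
                                    start_angle = NULL, move_sd = 8) {
  stopifnot(inherits(restraint, "rdc_restraint"))
  run_sampler(template, forcefield, restraint, protocol, n_replicas, seed,
              start_angle, move_sd)
}

#' Unrestrained control sampling
#'
#' Identical protocol with every restraint term removed; with the same seed it
#' reproduces a restrained run whose force constant is exactly zero.
#'
#' @inheritParams run_restrained_sampling
#' @return as [run_restrained_sampling()].
#' @export
run_unrestrained_sampling <- function(template, forcefield, protocol,
                                      n_replicas = 16L, seed = 1L,
                                      start_angle = NULL, move_sd = 8) {
  run_sampler(template, forcefield, NULL, protocol, n_replicas, seed,
              start_angle, move_sd)
}
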