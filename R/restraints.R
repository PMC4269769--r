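# Replica-averaged pseudoenergies.
#
# The hybrid energy is E_total = E_ff + E_rdc (+ E_cs), where the RDC term
# penalises the deviation of the replica-averaged back-calculated couplings
# from experiment,
#     E_rdc = alpha * sum_k ( <D_calc,k>_replicas - D_exp,k )^2 ,
# in J/mol with alpha in J mol^-1 Hz^-2, and the chemical-shift term applies
# the same quadratic form over rotating sub-groups of replicas (the MUMO
# scheme, group size 4 by default, to limit over-fitting). Sums run over
# records; deviations are unweighted by default (per-record error weighting is
# optional). Gradients treat each replica's alignment tensor as constant
# between its periodic updates.

#' Bundle replicas into a replica state
#'
#' @param replicas list of [structure3d()] objects sharing one topology.
#' @param tensors optional list of per-replica [saupe_tensor()] objects
#'   (recycled if a single tensor is given).
#' @param step integer step counter (drives chemical-shift group rotation).
#' @return object of class `replica_state`.
#' @export
replica_state <- function(replicas, tensors = NULL, step = 0L) {
  if (length(replicas) < 1L) stop("need at least one replica")
  ref <- replicas[[1L]]$atoms
  for (s in replicas) {
    if (!identical(s$atoms[c("resno", "elety")], ref[c("resno", "elety")])) {
      stop("replicas must share one topology")
    }
  }
  if (!is.null(tensors)) {
    if (inherits(tensors, "saupe_tensor")) tensors <- list(tensors)
    if (length(tensors) == 1L) tensors <- rep(tensors, length(replicas))
    if (length(tensors) != length(replicas)) {
      stop("one alignment tensor per replica required")
    }
  }
  out <- list(replicas = replicas, tensors = tensors, step = as.integer(step))
  class(out) <- "replica_state"
  out
}

#' Restraint force-constant schedule
#'
#' @param alpha_max maximum force constant in J mol^-1 Hz^-2 (default 1000,
#'   the calibrated optimum for RDC restraints).
#' @param ramp_steps length of the initial linear ramp from zero (the
#'   equilibration phase).
#' @param high_t_scale fraction of `alpha_max` applied at high temperature
#'   (default 0.10).
#' @param t_high_threshold temperature (K) at and above which the scaled
#'   constant applies (default 350, midpoint of the 300-400 K annealing
#'   window).
#' @param tensor_update_interval steps between alignment-tensor refreshes
#'   (default 250).
#' @return object of class `restraint_schedule`.
#' @export
restraint_schedule <- function(alpha_max = 1000, ramp_steps = 0,
                               high_t_scale = 0.10, t_high_threshold = 350,
                               tensor_update_interval = 250L) {
  if (high_t_scale <= 0 || high_t_scale > 1) stop("high_t_scale must be in (0, 1]")
  if (alpha_max < 0 || ramp_steps < 0) stop("alpha_max and ramp_steps must be >= 0")
  out <- list(alpha_max = alpha_max, ramp_steps = as.integer(ramp_steps),
              high_t_scale = high_t_scale, t_high_threshold = t_high_threshold,
              tensor_update_interval = as.integer(tensor_update_interval))
  class(out) <- "restraint_schedule"
  out
}

#' Scheduled restraint force constant
#'
#' During the ramp the constant grows linearly from zero to `alpha_max`;
#' afterwards it equals `alpha_max` at base temperature and
#' `high_t_scale * alpha_max` once the temperature reaches the high-T
#' threshold.
#'
#' @param schedule a [restraint_schedule()].
#' @param step step counter (>= 0); ramp steps count from 0.
#' @param temperature current temperature in K.
#' @return force constant in J mol^-1 Hz^-2.
#' @export
scheduled_alpha <- function(schedule, step, temperature) {
  stopifnot(inherits(schedule, "restraint_schedule"), step >= 0)
  if (schedule$ramp_steps > 0 && step < schedule$ramp_steps) {
    return(schedule$alpha_max * step / schedule$ramp_steps)
  }
  if (temperature >= schedule$t_high_threshold) {
    return(schedule$high_t_scale * schedule$alpha_max)
  }
  schedule$alpha_max
}

# Matched RDC records: per record, atom indices (a, b) in the shared topology,
# or NA when unmatched. H reconstruction is not used here: the restraint needs
# explicit coordinates to act on.
match_rdc_records <- function(structure, records) {
  n <- nrow(records)
  ia <- integer(n); ib <- integer(n)
  for (k in seq_len(n)) {
    ia[k] <- atom_index(structure, records$resno[k], records$atom_a[k])
    ib[k] <- atom_index(structure, records$resno[k], records$atom_b[k])
  }
  list(a = ia, b = ib, ok = !is.na(ia) & !is.na(ib))
}

#' Replica-averaged RDC restraint energy and gradients
#'
#' E = alpha * sum_k (<D_calc,k> - D_exp,k)^2 with <.> the mean over replicas,
#' each replica back-calculated under its own alignment tensor (held fixed for
#' the gradient, matching the periodic-update protocol). Records whose atoms
#' cannot be matched in the topology are reported in `$rejected`, never
#' silently dropped.
#'
#' @param state a [replica_state()] with tensors set.
#' @param data an [rdc_table()].
#' @param alpha force constant in J mol^-1 Hz^-2.
#' @param d_max dipolar constant in Hz.
#' @param gradients compute per-replica coordinate gradients (J mol^-1 / A).
#' @param error_weighted divide deviations by per-record errors (default
#'   FALSE: the pseudoenergy is unweighted).
#' @return list with `energy` (J/mol), `calc_mean` (Hz per record, NA for
#'   rejected), `gradients` (list of n_atoms x 3 matrices, one per replica,
#'   when requested), and `rejected` (data.frame of unmatched records).
#' @export
rdc_restraint_energy <- function(state, data, alpha, d_max = DMAX_NH,
                                 gradients = TRUE, error_weighted = FALSE) {
  stopifnot(inherits(state, "replica_state"))
  if (is.null(state$tensors)) stop("replica state carries no alignment tensors")
  if (nrow(data) == 0L) stop("empty RDC table")
  M <- length(state$replicas)
  map <- match_rdc_records(state$replicas[[1L]], data)
  ok <- map$ok
  rejected <- data[!ok, , drop = FALSE]
  idx <- which(ok)
  nrec <- length(idx)
  if (nrec == 0L) stop("no RDC record matches the topology")
  wt <- if (error_weighted) 1 / pmax(data$error[idx], 1e-6) else rep(1, nrec)
  d_per_replica <- matrix(0, M, nrec)
  u_list <- vector("list", M)
  invlen_list <- vector("list", M)
  for (m in seq_len(M)) {
    xyz <- state$replicas[[m]]$xyz
    r <- xyz[map$b[idx], , drop = FALSE] - xyz[map$a[idx], , drop = FALSE]
    len <- sqrt(rowSums(r^2))
    if (any(len < 1e-8)) stop("zero-length internuclear vector in replica ", m)
    u <- r / len
    S <- unclass(state$tensors[[m]])
    d_per_replica[m, ] <- d_max * rowSums((u %*% S) * u)
    u_list[[m]] <- u
    invlen_list[[m]] <- 1 / len
  }
  dbar <- colMeans(d_per_replica)
  dev <- (dbar - data$value[idx]) * wt
  energy <- alpha * sum(dev^2)
  out <- list(energy = energy,
              calc_mean = { v <- rep(NA_real_, nrow(data)); v[idx] <- dbar; v },
              rejected = rejected)
  if (gradients) {
    na <- nrow(state$replicas[[1L]]$xyz)
    coef <- 2 * alpha * dev * wt / M       # per record
    grads <- vector("list", M)
    for (m in seq_len(M)) {
      g <- matrix(0, na, 3L)
      u <- u_list[[m]]
      S <- unclass(state$tensors[[m]])
      su <- u %*% S
      usu <- rowSums(su * u)
      # d(u'Su)/dr = (2/|r|) (S u - (u'Su) u)
      gr <- 2 * invlen_list[[m]] * (su - usu * u) * (coef * d_max)
      for (k in seq_len(nrec)) {
        g[map$b[idx[k]], ] <- g[map$b[idx[k]], ] + gr[k, ]
        g[map$a[idx[k]], ] <- g[map$a[idx[k]], ] - gr[k, ]
      }
      grads[[m]] <- g
    }
    out$gradients <- grads
  }
  out
}

# ---- chemical shifts ---------------------------------------------------------

#' Simple local-geometry chemical-shift predictor
#'
#' Deliberately simple, fully documented model used as the default pluggable
#' predictor: delta = random-coil value + coefficient * cos(theta_i), where
#' theta_i is the virtual bond angle at C-alpha i (formed with the two
#' flanking C-alphas). Terminal residues take the random-coil value. The model
#' is smooth with an exact analytic gradient, so ground-truth recovery tests
#' are exact; any predictor honouring the same contract (fields `nuclei` and
#' `predict(structure, resno, nucleus, gradient)`) can be plugged in instead.
#'
#' @param coefficients named numeric vector of ppm coefficients per nucleus.
#' @param random_coil named numeric vector of random-coil shifts (ppm).
#' @return object of class `shift_predictor`.
#' @export
shift_predictor_curvature <- function(
    coefficients = c(HN = 0.8, HA = -0.6, CA = 2.5, CB = -1.2, CO = 1.8, N = 4.0),
    random_coil = c(HN = 8.30, HA = 4.35, CA = 52.5, CB = 19.0, CO = 177.5, N = 119.5)) {
  nuclei <- intersect(names(coefficients), names(random_coil))
  pred <- function(structure, resno, nucleus, gradient = FALSE) {
    if (!nucleus %in% nuclei) stop("nucleus not supported by predictor: ", nucleus)
    i0 <- atom_index(structure, resno, "CA")
    im <- atom_index(structure, resno - 1L, "CA")
    ip <- atom_index(structure, resno + 1L, "CA")
    rc <- random_coil[[nucleus]]
    cf <- coefficients[[nucleus]]
    if (anyNA(c(i0, im, ip))) {
      res <- list(value = rc, atoms = integer(0),
                  grad = matrix(0, 0, 3))
      return(res)
    }
    p0 <- structure$xyz[i0, ]; pm <- structure$xyz[im, ]; pp <- structure$xyz[ip, ]
    a <- pm - p0; b <- pp - p0
    la <- vnorm(a); lb <- vnorm(b)
    ct <- sum(a * b) / (la * lb)
    value <- rc + cf * ct
    out <- list(value = value, atoms = c(im, i0, ip))
    if (gradient) {
      dct_da <- b / (la * lb) - ct * a / la^2
      dct_db <- a / (la * lb) - ct * b / lb^2
      out$grad <- cf * rbind(dct_da, -(dct_da + dct_db), dct_db)
    }
    out
  }
  out <- list(nuclei = nuclei, predict = pred)
  class(out) <- "shift_predictor"
  out
}

#' Chemical-shift restraint specification
#' @param nuclei subset of the predictor's nuclei to restrain.
#' @param group_size replicas per averaging group (default 4; must divide the
#'   replica count).
#' @param predictor a shift predictor honouring the pluggable contract.
#' @return object of class `cs_spec`.
#' @export
cs_spec <- function(nuclei = c("HN", "CA"), group_size = 4L,
                    predictor = shift_predictor_curvature()) {
  if (!all(nuclei %in% predictor$nuclei)) {
    stop("predictor does not support nuclei: ",
         paste(setdiff(nuclei, predictor$nuclei), collapse = ", "))
  }
  out <- list(nuclei = nuclei, group_size = as.integer(group_size),
              predictor = predictor)
  class(out) <- "cs_spec"
  out
}

# Deterministic rotating group assignment: replicas are rotated by the step
# counter and chunked; every replica lands in exactly one group.
cs_groups <- function(n_replicas, group_size, step) {
  if (n_replicas %% group_size != 0L) {
    stop("group size must divide the replica count")
  }
  shift <- step %% n_replicas
  order <- ((seq_len(n_replicas) - 1L + shift) %% n_replicas) + 1L
  split(order, rep(seq_len(n_replicas %/% group_size), each = group_size))
}

#' Chemical-shift restraint energy over rotating replica groups
#'
#' E = beta * sum_groups sum_obs (<delta_calc>_group - delta_exp)^2, the MUMO
#' scheme: shifts are averaged over small rotating groups (default 4 of 16)
#' rather than all replicas, limiting over-fitting. Group membership rotates
#' deterministically with the state's step counter.
#'
#' @param state a [replica_state()].
#' @param spec a [cs_spec()].
#' @param observed data.frame with columns `resno`, `nucleus`, `value` (ppm).
#' @param beta force constant in J mol^-1 ppm^-2.
#' @param gradients compute per-replica coordinate gradients.
#' @return list with `energy`, `gradients` (when requested) and `groups`.
#' @export
cs_restraint_energy <- function(state, spec, observed, beta, gradients = TRUE) {
  stopifnot(inherits(state, "replica_state"), inherits(spec, "cs_spec"))
  bad <- setdiff(unique(observed$nucleus), spec$predictor$nuclei)
  if (length(bad) > 0L) {
    stop("nucleus absent from predictor: ", paste(bad, collapse = ", "))
  }
  M <- length(state$replicas)
  groups <- cs_groups(M, spec$group_size, state$step)
  obs <- observed[observed$nucleus %in% spec$nuclei, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observed shifts match the restrained nuclei")
  na <- nrow(state$replicas[[1L]]$xyz)
  energy <- 0
  grads <- if (gradients) lapply(seq_len(M), function(i) matrix(0, na, 3L)) else NULL
  for (grp in groups) {
    gsize <- length(grp)
    for (r in seq_len(nrow(obs))) {
      preds <- lapply(grp, function(m) {
        spec$predictor$predict(state$replicas[[m]], obs$resno[r],
                               obs$nucleus[r], gradient = gradients)
      })
      mean_val <- mean(vapply(preds, `[[`, numeric(1), "value"))
      dev <- mean_val - obs$value[r]
      energy <- energy + beta * dev^2
      if (gradients) {
        coef <- 2 * beta * dev / gsize
        for (gi in seq_along(grp)) {
          p <- preds[[gi]]
          if (length(p$atoms) > 0L) {
            grads[[grp[gi]]][p$atoms, ] <- grads[[grp[gi]]][p$atoms, ] + coef * p$grad
          }
        }
      }
    }
  }
  out <- list(energy = energy, groups = groups)
  if (gradients) out$gradients <- grads
  out
}
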