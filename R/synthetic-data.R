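# Synthetic two-subdomain hinge proteins with known ground truth.
#
# The toy protein is a coarse-grained chain with one C-alpha bead per residue
# (3.8 Angstrom spacing) plus pseudo N and H atoms fixed in each residue's
# local frame, so N-H RDC vectors rotate rigidly with their subdomain. Two
# idealised helical subdomains (a "globular" core and a hairpin stand-in) are
# joined by a straight hinge; the bending angle between the subdomains is the
# single default degree of freedom.

#' Define a hinge-protein topology
#' @param n_core residues in the globular subdomain (>= 4).
#' @param n_hairpin residues in the hairpin subdomain (>= 4).
#' @param n_hinge linker residues (>= 1).
#' @return object of class `hinge_topology`.
#' @export
hinge_topology <- function(n_core = 20L, n_hairpin = 10L, n_hinge = 4L) {
  n_core <- as.integer(n_core); n_hairpin <- as.integer(n_hairpin)
  n_hinge <- as.integer(n_hinge)
  if (n_hinge < 1L) stop("hinge must contain at least one residue")
  if (n_core < 4L || n_hairpin < 4L) {
    stop("subdomains need >= 4 residues for non-collinear (helical) geometry")
  }
  if (n_core + n_hairpin + n_hinge < 12L) stop("total residues must be >= 12")
  out <- list(n_core = n_core, n_hairpin = n_hairpin, n_hinge = n_hinge,
              n_total = n_core + n_hairpin + n_hinge)
  class(out) <- "hinge_topology"
  out
}

#' Truncated-normal hinge-angle distribution
#' @param mean_angle mean bending angle in degrees, in (0, 180).
#' @param sd_angle standard deviation in degrees (> 0).
#' @return object of class `angle_spec`; the law is a normal truncated to
#'   (0, 180) degrees.
#' @export
angle_spec <- function(mean_angle, sd_angle) {
  if (mean_angle <= 0 || mean_angle >= 180) stop("mean angle must lie in (0, 180)")
  if (sd_angle <= 0) stop("sd must be positive")
  out <- list(mean = mean_angle, sd = sd_angle)
  class(out) <- "angle_spec"
  out
}

# Helical C-alpha trace: n beads around an axis through `origin` along unit
# vector `axis`, starting at axial offset `offset`. radius/rise/turn give a
# 3.8 Angstrom C-alpha spacing (canonical alpha-helix trace values).
helical_trace <- function(n, origin, axis, perp1, perp2, offset = 0,
                          radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1L
  t(vapply(i, function(k) {
    origin + (offset + rise * k) * axis +
      radius * (cos(turn * k) * perp1 + sin(turn * k) * perp2)
  }, numeric(3)))
}

# Orthonormal frame per residue from C-alpha neighbours restricted to the same
# rigid group, so pseudo N/H placements co-rotate with their subdomain.
residue_frames <- function(ca, group) {
  n <- nrow(ca)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3); e3 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- i; hi <- i
    if (i > 1L && group[i - 1L] == group[i]) lo <- i - 1L
    if (i < n && group[i + 1L] == group[i]) hi <- i + 1L
    t1 <- ca[hi, ] - ca[lo, ]
    if (vnorm(t1) < 1e-9) t1 <- c(1, 0, 0)
    a <- unit_vec(t1)
    # curvature direction within the group, else a fixed fallback
    aux <- NULL
    if (hi > i && lo < i) aux <- ca[lo, ] + ca[hi, ] - 2 * ca[i, ]
    if (is.null(aux) || vnorm(aux) < 1e-6) aux <- c(0, 0, 1)
    b <- aux - sum(aux * a) * a
    if (vnorm(b) < 1e-6) {
      aux <- c(0, 1, 0)
      b <- aux - sum(aux * a) * a
    }
    b <- unit_vec(b)
    e1[i, ] <- a
    e2[i, ] <- b
    e3[i, ] <- c(a[2] * b[3] - a[3] * b[2],
                 a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
  }
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Build a hinge-protein template structure
#'
#' Deterministic coarse-grained template: core and hairpin are rigid idealised
#' helical C-alpha traces joined by a straight hinge, with pseudo N and H
#' atoms per residue. The default bending angle (between the subdomain
#' centroids seen from the hinge centroid) is 120 degrees.
#'
#' @param topology a [hinge_topology()].
#' @param bend_angle initial bending angle in degrees.
#' @param seed unused source of randomness kept for interface symmetry; the
#'   construction is deterministic.
#' @return a [structure3d()] carrying a `hinge_info` attribute (rigid-group
#'   assignment, pivot, rotation axis, toy region definitions).
#' @export
build_hinge_template <- function(topology = hinge_topology(), bend_angle = 120,
                                 seed = 1L) {
  stopifnot(inherits(topology, "hinge_topology"))
  if (bend_angle <= 0 || bend_angle >= 180) stop("bend angle must lie in (0, 180)")
  nc <- topology$n_core; nh <- topology$n_hinge; np <- topology$n_hairpin
  spacing <- 3.8
  # hinge beads along +x, centred at the origin
  hx <- (seq_len(nh) - (nh + 1) / 2) * spacing
  ca_hinge <- cbind(hx, 0, 0)
  # core helix along -x, residue nc adjacent to the hinge start
  core_axis <- c(-1, 0, 0)
  core_start <- c(min(hx) - spacing, 0, 0)
  ca_core <- helical_trace(nc, core_start, core_axis, c(0, 1, 0), c(0, 0, 1))
  ca_core <- ca_core[rev(seq_len(nc)), , drop = FALSE]  # residue 1 farthest out
  # hairpin helix from the hinge end, axis at the requested construction angle
  beta <- bend_angle * pi / 180
  u3 <- c(-cos(beta), sin(beta), 0)
  p1 <- c(-u3[2], u3[1], 0)                  # in-plane perpendicular
  p2 <- c(0, 0, 1)
  hp_start <- c(max(hx), 0, 0) + spacing * u3
  ca_hairpin <- helical_trace(np, hp_start, u3, p1, p2)
  ca <- rbind(ca_core, ca_hinge, ca_hairpin)
  # rigid groups: 1 = core + hinge (static), 2 = hairpin (mobile)
  group <- c(rep(1L, nc + nh), rep(2L, np))
  fr <- residue_frames(ca, group)
  n_res <- nrow(ca)
  # pseudo N and H fixed in the residue frame
  n_pos <- ca + 1.46 * (-0.50 * fr$e1 + 0.87 * fr$e2)
  nh_dir <- -0.30 * fr$e1 + 0.60 * fr$e2 + 0.74 * fr$e3
  nh_dir <- nh_dir / sqrt(rowSums(nh_dir^2))
  h_pos <- n_pos + 1.02 * nh_dir
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(n_res), each = 3L),
    resid = "ALA",
    elety = rep(c("N", "H", "CA"), times = n_res),
    element = rep(c("N", "H", "C"), times = n_res),
    mass = rep(c(14.007, 1.008, 12.011), times = n_res),
    stringsAsFactors = FALSE
  )
  xyz <- matrix(0, 3L * n_res, 3L)
  xyz[seq(1, 3 * n_res, 3), ] <- n_pos
  xyz[seq(2, 3 * n_res, 3), ] <- h_pos
  xyz[seq(3, 3 * n_res, 3), ] <- ca
  st <- structure3d(atoms, xyz)
  regions <- region_spec(I = seq_len(nc),
                         II = nc + seq_len(nh),
                         III = nc + nh + seq_len(np))
  mobile_atoms <- which(atoms$resno > nc + nh)
  info <- list(topology = topology, regions = regions,
               mobile_atoms = mobile_atoms,
               pivot = colMeans(ca_hinge), axis = c(0, 0, 1))
  attr(st, "hinge_info") <- info
  st <- set_hinge_angle(st, bend_angle)
  achieved <- bending_angle(st, regions)
  if (abs(achieved - bend_angle) > 1e-6) {
    stop("degenerate construction: could not realise the requested bend angle")
  }
  st
}

#' Set the bending angle of a hinge-protein structure
#'
#' Rotates the hairpin subdomain rigidly about the hinge axis (through the
#' hinge C-alpha centroid) so that the measured bending angle
#' ([bending_angle()] on the structure's own regions) equals `angle` to 1e-8
#' degrees. Subdomain-internal geometry is untouched.
#'
#' @param structure a template from [build_hinge_template()] (or a structure
#'   derived from one; requires the `hinge_info` attribute).
#' @param angle target bending angle in degrees, in (0, 180).
#' @return the rotated [structure3d()] with updated `hinge_info`.
#' @export
set_hinge_angle <- function(structure, angle) {
  info <- attr(structure, "hinge_info")
  if (is.null(info)) stop("structure lacks hinge_info; build it with build_hinge_template()")
  if (angle <= 0 || angle >= 180) stop("target angle must lie in (0, 180)")
  xyz <- structure$xyz
  mob <- info$mobile_atoms
  pivot <- info$pivot
  regions <- info$regions
  ca_idx <- which(structure$atoms$elety == "CA")
  res_of_ca <- structure$atoms$resno[ca_idx]
  c1 <- centroid(xyz[ca_idx, , drop = FALSE], which(res_of_ca %in% regions$I))
  c2 <- centroid(xyz[ca_idx, , drop = FALSE], which(res_of_ca %in% regions$II))
  v1 <- c1 - c2
  rel <- sweep(xyz[mob, , drop = FALSE], 2L, pivot)
  ca3_local <- which(structure$atoms$elety[mob] == "CA" &
                       structure$atoms$resno[mob] %in% regions$III)
  angle_after <- function(delta) {
    R <- rotation_matrix(info$axis, delta)
    c3 <- colMeans(rel[ca3_local, , drop = FALSE] %*% t(R)) + pivot
    v3 <- c3 - c2
    acos(max(-1, min(1, sum(v1 * v3) / (vnorm(v1) * vnorm(v3))))) * 180 / pi
  }
  # bracket the root on a grid, then polish
  grid <- seq(-pi, pi, length.out = 361)
  vals <- vapply(grid, angle_after, numeric(1)) - angle
  sgn <- sign(vals)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (length(cross) == 0L) {
    stop("target bending angle ", angle, " is unreachable for this geometry")
  }
  k <- cross[which.min(abs(grid[cross]))]
  delta <- stats::uniroot(function(d) angle_after(d) - angle,
                          lower = grid[k], upper = grid[k + 1L],
                          tol = 1e-12)$root
  R <- rotation_matrix(info$axis, delta)
  xyz[mob, ] <- sweep(rel %*% t(R), 2L, pivot, "+")
  out <- structure3d(structure$atoms, xyz, structure$model_id)
  info$angle <- angle
  attr(out, "hinge_info") <- info
  out
}

# Truncated-normal sampler on (lo, hi) by rejection; fine for the sd regimes
# used here (acceptance ~1 when the bulk of the normal is inside the window).
rtrunc_normal <- function(n, mean, sd, lo = 0, hi = 180) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw > lo & draw < hi])
  }
  out[seq_len(n)]
}

#' Sample an ensemble of hinge conformations
#'
#' Draws `n` bending angles i.i.d. from a truncated normal on (0, 180) degrees
#' and applies each to the template; subdomain-internal coordinates are
#' unchanged across the ensemble.
#'
#' @param template from [build_hinge_template()].
#' @param spec an [angle_spec()].
#' @param n number of structures (>= 1).
#' @param seed RNG seed (one stream per call; no global state is left behind).
#' @return a [conformation_ensemble()] with uniform weights; the drawn angles
#'   are attached as attribute `"angles"`.
#' @export
sample_hinge_ensemble <- function(template, spec, n, seed = 1L) {
  stopifnot(inherits(spec, "angle_spec"))
  if (n < 1L) stop("n must be >= 1")
  angles <- with_local_seed(seed, rtrunc_normal(n, spec$mean, spec$sd))
  structures <- lapply(angles, function(a) set_hinge_angle(template, a))
  ens <- conformation_ensemble(structures)
  attr(ens, "angles") <- angles
  attr(ens, "hinge_info") <- attr(template, "hinge_info")
  ens
}

# Run expr under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate synthetic RDCs from a structure and a known alignment tensor
#'
#' Forward model: value = back-calculated coupling + Gaussian(0, noise_sd).
#' Residues without a resolvable N-H vector are skipped with a warning.
#'
#' @param structure a [structure3d()] with N and H atoms (pseudo-atoms allowed).
#' @param tensor generating [saupe_tensor()].
#' @param d_max dipolar constant in Hz.
#' @param noise_sd Gaussian noise level in Hz (also stored as the record
#'   error).
#' @param seed RNG seed.
#' @return an [rdc_table()] with medium label "synthetic".
#' @export
synth_rdc <- function(structure, tensor, d_max = DMAX_NH, noise_sd = 0.5,
                      seed = 1L) {
  resnos <- sort(unique(structure$atoms$resno))
  records <- rdc_table(resnos, "N", "H", 0, error = max(noise_sd, 0))
  bc <- back_calc_rdc(structure, tensor, records, d_max, reconstruct_h = FALSE)
  ok <- !is.na(bc$calc)
  if (any(!ok)) {
    warning(sum(!ok), " residue(s) lack an N-H vector; skipped")
  }
  values <- bc$calc[ok]
  if (noise_sd > 0) {
    values <- values + with_local_seed(seed, rnorm(length(values), 0, noise_sd))
  }
  rdc_table(resnos[ok], "N", "H", values, error = noise_sd)
}

#' Derive synthetic NOE upper bounds from a reference conformation
#'
#' One restraint per C-alpha pair at sequence separation >= 3 whose reference
#' distance is below `contact_cutoff`; the upper bound is the reference
#' distance plus `padding`, so the reference fulfills all its own restraints.
#'
#' @param reference a [structure3d()].
#' @param contact_cutoff distance cutoff in Angstrom (default 6, the NOE
#'   detection range).
#' @param padding slack added to the bound in Angstrom.
#' @return a [noe_table()].
#' @export
synth_noe <- function(reference, contact_cutoff = 6, padding = 0.5) {
  if (contact_cutoff <= 0) stop("cutoff must be positive")
  ca <- which(reference$atoms$elety == "CA")
  resno <- reference$atoms$resno[ca]
  xyz <- reference$xyz[ca, , drop = FALSE]
  n <- length(ca)
  ri <- integer(0); rj <- integer(0); d <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (abs(resno[j] - resno[i]) < 3L) next
      dij <- vnorm(xyz[i, ] - xyz[j, ])
      if (dij < contact_cutoff) {
        ri <- c(ri, resno[i]); rj <- c(rj, resno[j]); d <- c(d, dij)
      }
    }
  }
  if (length(ri) == 0L) {
    stop("no C-alpha pair within the cutoff; no restraints generated")
  }
  noe_table(ri, "CA", rj, "CA", upper = d + padding, lower = 0)
}

#' Generate a noisy synthetic SAXS profile from an ensemble
#'
#' The ensemble-averaged Debye profile is perturbed by multiplicative Gaussian
#' noise; reported uncertainties are `noise_frac` times the clean intensity.
#' With `noise_frac = 0` the profile is exact and carries no sigma column.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param s_grid increasing, positive momentum-transfer grid (1/Angstrom).
#' @param noise_frac relative noise level.
#' @param seed RNG seed.
#' @param form_factor `"residue"` (default) or `"point"`; see [debye_profile()].
#' @return a [saxs_profile()].
#' @export
synth_saxs <- function(ensemble, s_grid, noise_frac = 0.02, seed = 1L,
                       form_factor = "residue") {
  clean <- ensemble_profile(ensemble, s_grid, form_factor = form_factor)
  if (noise_frac == 0) return(clean)
  eps <- with_local_seed(seed, rnorm(length(s_grid), 0, noise_frac))
  saxs_profile(s_grid, clean$intensity * (1 + eps),
               sigma = noise_frac * clean$intensity)
}
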