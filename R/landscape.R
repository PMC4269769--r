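# Ensemble characterisation: interdomain bending angle, radius of gyration,
# free-energy landscape on the (angle, Rg) plane, reference-structure
# projection, contact maps and secondary-structure occupancy.

#' Define the three residue regions used for the bending angle
#'
#' Region I marks the globular subdomain, region II the hinge (the angle
#' vertex) and region III the distal loop of the mobile subdomain. The
#' defaults are the Josephin-domain definitions (author residue numbering):
#' I = 111-113, 122-125, 162-165; II = 32-35; III = 45-48, 58-61.
#'
#' @param I,II,III integer vectors of residue numbers; disjoint, non-empty.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(I = c(111:113, 122:125, 162:165),
                        II = 32:35,
                        III = c(45:48, 58:61)) {
  I <- as.integer(I); II <- as.integer(II); III <- as.integer(III)
  if (length(I) == 0L || length(II) == 0L || length(III) == 0L) {
    stop("all three regions must be non-empty")
  }
  if (length(intersect(I, II)) || length(intersect(I, III)) ||
      length(intersect(II, III))) {
    stop("regions must be disjoint")
  }
  out <- list(I = I, II = II, III = III)
  class(out) <- "region_spec"
  out
}

#' Toy-protein region definitions for a hinge topology
#'
#' Maps the three-region scheme onto the synthetic hinge protein: region I is
#' the globular core, region II the hinge linker, region III the hairpin.
#'
#' @param topology a [hinge_topology()].
#' @return a [region_spec()].
#' @export
hinge_regions <- function(topology) {
  stopifnot(inherits(topology, "hinge_topology"))
  nc <- topology$n_core; nh <- topology$n_hinge
  region_spec(I = seq_len(nc), II = nc + seq_len(nh),
              III = nc + nh + seq_len(topology$n_hairpin))
}

region_centroids <- function(structure, regions) {
  ca <- which(structure$atoms$elety == "CA")
  resno <- structure$atoms$resno[ca]
  cent <- function(rr) {
    idx <- ca[resno %in% rr]
    if (length(idx) < length(rr)) {
      missing <- setdiff(rr, resno)
      stop("missing C-alpha for region residue(s): ",
           paste(missing, collapse = ", "))
    }
    colMeans(structure$xyz[idx, , drop = FALSE])
  }
  list(c1 = cent(regions$I), c2 = cent(regions$II), c3 = cent(regions$III))
}

#' Interdomain bending angle of a structure
#'
#' Angle, in degrees, at the unweighted C-alpha centroid of region II (hinge)
#' between the vectors pointing to the C-alpha centroids of regions I
#' (globular subdomain) and III (distal loop). Lies in [0, 180].
#'
#' @param structure a [structure3d()] containing C-alpha atoms for every
#'   region residue.
#' @param regions a [region_spec()].
#' @return bending angle in degrees.
#' @export
bending_angle <- function(structure, regions) {
  stopifnot(inherits(regions, "region_spec"))
  ce <- region_centroids(structure, regions)
  angle_at(ce$c1, ce$c2, ce$c3) * 180 / pi
}

#' Radius of gyration
#'
#' Rg = sqrt(sum w_i |r_i - rbar|^2 / sum w_i). The default uses all atoms,
#' mass-weighted (the convention for heavy-atom Rg values when hydrogens are
#' absent); `selection = "calpha"` with `mass_weighted = FALSE` gives the
#' C-alpha-only unweighted variant.
#'
#' @param structure a [structure3d()].
#' @param selection `"all"` or `"calpha"`.
#' @param mass_weighted logical (default TRUE).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, selection = c("all", "calpha"),
                               mass_weighted = TRUE) {
  selection <- match.arg(selection)
  keep <- if (selection == "calpha") structure$atoms$elety == "CA" else
    rep(TRUE, nrow(structure$atoms))
  if (!any(keep)) stop("empty selection")
  xyz <- structure$xyz[keep, , drop = FALSE]
  w <- if (mass_weighted) structure$atoms$mass[keep] else rep(1, sum(keep))
  cm <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2L, cm)^2)
  sqrt(sum(w * d2) / sum(w))
}

ensemble_coordinates <- function(ensemble, regions, rg_selection = "calpha",
                                 rg_mass_weighted = FALSE) {
  nm <- n_structures(ensemble)
  ang <- numeric(nm); rg <- numeric(nm)
  for (k in seq_len(nm)) {
    st <- get_structure(ensemble, k)
    ang[k] <- bending_angle(st, regions)
    rg[k] <- radius_of_gyration(st, rg_selection, rg_mass_weighted)
  }
  data.frame(model = ensemble$model_ids, angle = ang, rg = rg,
             weight = ensemble$weights)
}

#' Free-energy landscape over (bending angle, radius of gyration)
#'
#' Weighted 2-D histogram of the two reaction coordinates, converted to free
#' energies F = -ln P in units of k_B T and shifted so the minimum is zero.
#' Empty bins are masked (F = NA), not clamped.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param regions a [region_spec()].
#' @param angle_breaks bin edges in degrees; default 2-degree bins covering
#'   the observed range.
#' @param rg_breaks bin edges in Angstrom; default 0.25-Angstrom bins.
#' @param rg_selection,rg_mass_weighted passed to [radius_of_gyration()];
#'   defaults give the C-alpha Rg used for landscape work.
#' @return object of class `landscape_grid`: list with `angle_breaks`,
#'   `rg_breaks`, `P` (probabilities summing to one), `F` (k_B T, min 0,
#'   NA in empty bins), and `coords` (per-structure angle/Rg table).
#' @export
free_energy_landscape <- function(ensemble, regions, angle_breaks = NULL,
                                  rg_breaks = NULL, rg_selection = "calpha",
                                  rg_mass_weighted = FALSE) {
  co <- ensemble_coordinates(ensemble, regions, rg_selection, rg_mass_weighted)
  pad_breaks <- function(x, width) {
    lo <- floor(min(x) / width) * width
    hi <- ceiling(max(x) / width) * width
    if (hi <= lo) hi <- lo + width
    seq(lo, hi, by = width)
  }
  if (is.null(angle_breaks)) angle_breaks <- pad_breaks(co$angle, 2)
  if (is.null(rg_breaks)) rg_breaks <- pad_breaks(co$rg, 0.25)
  if (min(co$angle) < min(angle_breaks) || max(co$angle) > max(angle_breaks)) {
    stop("angle bins do not cover the observed range")
  }
  if (min(co$rg) < min(rg_breaks) || max(co$rg) > max(rg_breaks)) {
    stop("Rg bins do not cover the observed range")
  }
  ia <- findInterval(co$angle, angle_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ir <- findInterval(co$rg, rg_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  P <- matrix(0, length(angle_breaks) - 1L, length(rg_breaks) - 1L)
  for (k in seq_len(nrow(co))) {
    P[ia[k], ir[k]] <- P[ia[k], ir[k]] + co$weight[k]
  }
  P <- P / sum(P)
  F <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  F[occ] <- -log(P[occ])
  F <- F - min(F, na.rm = TRUE)
  out <- list(angle_breaks = angle_breaks, rg_breaks = rg_breaks,
              P = P, F = F, coords = co)
  class(out) <- "landscape_grid"
  out
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d bins, %d occupied, F range [0, %.2f] kT\n",
              nrow(x$P), ncol(x$P), sum(x$P > 0), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Location of the landscape's free-energy minimum
#' @param grid a `landscape_grid`.
#' @return list with `angle` and `rg` (bin midpoints of the mode).
#' @export
landscape_mode <- function(grid) {
  idx <- which(grid$P == max(grid$P), arr.ind = TRUE)[1, ]
  am <- (grid$angle_breaks[idx[1]] + grid$angle_breaks[idx[1] + 1L]) / 2
  rm_ <- (grid$rg_breaks[idx[2]] + grid$rg_breaks[idx[2] + 1L]) / 2
  list(angle = am, rg = rm_)
}

#' Export a landscape grid as a long-format table
#' @param grid a `landscape_grid`.
#' @return data.frame with columns angle_lo, angle_hi, rg_lo, rg_hi, P, F
#'   (occupied bins only).
#' @export
landscape_table <- function(grid) {
  na <- length(grid$angle_breaks) - 1L
  nr <- length(grid$rg_breaks) - 1L
  idx <- which(grid$P > 0, arr.ind = TRUE)
  data.frame(
    angle_lo = grid$angle_breaks[idx[, 1]],
    angle_hi = grid$angle_breaks[idx[, 1] + 1L],
    rg_lo = grid$rg_breaks[idx[, 2]],
    rg_hi = grid$rg_breaks[idx[, 2] + 1L],
    P = grid$P[idx],
    F = grid$F[idx]
  )
}

#' Project reference structures onto the landscape coordinates
#'
#' Computes (bending angle, Rg) for each model of each named input so
#' reference structures can be overlaid on a [free_energy_landscape()].
#'
#' @param references named list of [structure3d()] or
#'   [conformation_ensemble()] objects sharing the region residue numbering.
#' @param regions a [region_spec()].
#' @param rg_selection,rg_mass_weighted passed to [radius_of_gyration()].
#' @return data.frame with columns `name`, `model`, `angle`, `rg`, `error`
#'   (NA on success; per-structure message when numbering does not resolve).
#' @export
project_structures <- function(references, regions, rg_selection = "calpha",
                               rg_mass_weighted = FALSE) {
  if (is.null(names(references)) || any(names(references) == "")) {
    stop("references must be a named list")
  }
  rows <- list()
  for (nm in names(references)) {
    obj <- references[[nm]]
    ens <- if (inherits(obj, "structure3d")) {
      conformation_ensemble(list(obj))
    } else obj
    for (k in seq_len(n_structures(ens))) {
      st <- get_structure(ens, k)
      res <- tryCatch({
        data.frame(name = nm, model = st$model_id,
                   angle = bending_angle(st, regions),
                   rg = radius_of_gyration(st, rg_selection, rg_mass_weighted),
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(name = nm, model = st$model_id, angle = NA_real_,
                   rg = NA_real_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Residue-residue contact frequency map
#'
#' Entry (i, j) is the fraction of structures in which the C-alpha atoms of
#' residues i and j are strictly closer than `cutoff` (a pair at exactly the
#' cutoff is not a contact). Symmetric with unit diagonal; computed on
#' individual structures, not on the average structure.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param cutoff contact distance in Angstrom (default 8).
#' @return square matrix with residue numbers as dimnames.
#' @export
contact_map <- function(ensemble, cutoff = 8) {
  ca <- which(ensemble$atoms$elety == "CA")
  resno <- ensemble$atoms$resno[ca]
  n <- length(ca)
  nm <- n_structures(ensemble)
  acc <- matrix(0, n, n)
  for (k in seq_len(nm)) {
    xyz <- ensemble$xyz[ca, , k, drop = TRUE]
    d <- as.matrix(stats::dist(xyz))
    acc <- acc + (d < cutoff)
  }
  out <- acc / nm
  diag(out) <- 1
  dimnames(out) <- list(resno, resno)
  out
}

# ---- secondary structure ----------------------------------------------------

# Kabsch-Sander electrostatic hydrogen-bond energy (kcal/mol) between donor
# amide (N-H of residue i) and acceptor carbonyl (C=O of residue j).
ks_hbond_energy <- function(N, H, C, O) {
  q1q2f <- 0.084 * 332
  r_on <- vnorm(O - N); r_ch <- vnorm(C - H)
  r_oh <- vnorm(O - H); r_cn <- vnorm(C - N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(0)  # clash: not a valid H-bond
  q1q2f * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Hydrogen-bond matrix: hb[i, j] TRUE when donor i -> acceptor j with
# Kabsch-Sander energy < -0.5 kcal/mol.
ks_hbond_matrix <- function(structure) {
  resnos <- sort(unique(structure$atoms$resno))
  n <- length(resnos)
  pos <- function(r, nm) {
    i <- atom_index(structure, r, nm)
    if (is.na(i)) NULL else structure$xyz[i, ]
  }
  hb <- matrix(FALSE, n, n)
  for (ii in seq_len(n)) {
    Ni <- pos(resnos[ii], "N")
    Hi <- pos(resnos[ii], "H")
    if (is.null(Hi)) {
      hpos <- reconstruct_amide_h(structure, resnos[ii])
      if (!is.null(hpos)) Hi <- hpos
    }
    if (is.null(Ni) || is.null(Hi)) next
    for (jj in seq_len(n)) {
      if (abs(ii - jj) < 2L) next
      Cj <- pos(resnos[jj], "C")
      Oj <- pos(resnos[jj], "O")
      if (is.null(Cj) || is.null(Oj)) next
      hb[ii, jj] <- ks_hbond_energy(Ni, Hi, Cj, Oj) < -0.5
    }
  }
  dimnames(hb) <- list(resnos, resnos)
  hb
}

# DSSP-style assignment restricted to helix (H: two consecutive i->i+4 turns,
# pooled with G: 3-10 helix from i->i+3 turns) and strand (E: parallel or
# antiparallel bridges). Returns a character vector over residues
# ("H", "E" or "-"); helix takes priority over strand.
assign_ss_backbone <- function(structure) {
  hb <- ks_hbond_matrix(structure)       # hb[donor, acceptor]
  n <- nrow(hb)
  if (n < 5L) return(rep("-", n))
  turn4 <- rep(FALSE, n); turn3 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i + 4L <= n && hb[i + 4L, i]) turn4[i] <- TRUE
    if (i + 3L <= n && hb[i + 3L, i]) turn3[i] <- TRUE
  }
  ss <- rep("-", n)
  # bridges -> strand
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i + 1L, j]) || (hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[j, i] && hb[i, j]) || (hb[j + 1L, i - 1L] && hb[i + 1L, j - 1L])
      if (par || anti) ss[i] <- "E"
    }
  }
  # alpha helix: residues i+1..i+4 of two consecutive 4-turns
  for (i in seq_len(n - 1L)) {
    if (turn4[i] && i > 1L && turn4[i - 1L]) {
      ss[i:min(n, i + 3L)] <- "H"
    }
  }
  # 3-10 helix (pooled into the helix class)
  for (i in seq_len(n - 1L)) {
    if (turn3[i] && i > 1L && turn3[i - 1L] &&
        all(ss[i:min(n, i + 2L)] %in% c("-", "H"))) {
      ss[i:min(n, i + 2L)] <- "H"
    }
  }
  ss
}

# C-alpha-only fallback: virtual torsion of four consecutive C-alphas;
# helical trace torsions cluster near +50 degrees, extended strands near 180.
assign_ss_calpha <- function(structure) {
  ca <- which(structure$atoms$elety == "CA")
  xyz <- structure$xyz[ca, , drop = FALSE]
  n <- nrow(xyz)
  ss <- rep("-", n)
  if (n < 4L) return(ss)
  tor <- rep(NA_real_, n)
  for (i in 2:(n - 2L)) {
    tor[i] <- torsion(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ]) * 180 / pi
  }
  ss[!is.na(tor) & tor > 20 & tor < 80] <- "H"
  ss[!is.na(tor) & abs(tor) > 140] <- "E"
  ss
}

#' Per-residue secondary-structure occupancy over an ensemble
#'
#' Full-backbone mode assigns helix (alpha and 3-10 pooled) and strand via the
#' Kabsch-Sander hydrogen-bond energy criterion
#' (E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol, bond when
#' E < -0.5); the C-alpha-only mode falls back to virtual-torsion classes.
#'
#' @param ensemble a [conformation_ensemble()] (a single [structure3d()] is
#'   promoted to an ensemble of one).
#' @param mode `"backbone"` (requires N, CA, C, O; H is reconstructed when
#'   absent) or `"calpha"`.
#' @return data.frame with `resno`, `helix`, `sheet` fractions in [0, 1].
#' @export
ss_occupancy <- function(ensemble, mode = c("backbone", "calpha")) {
  mode <- match.arg(mode)
  if (inherits(ensemble, "structure3d")) {
    ensemble <- conformation_ensemble(list(ensemble))
  }
  have <- unique(ensemble$atoms$elety)
  if (mode == "backbone" && !all(c("N", "CA", "C", "O") %in% have)) {
    stop("backbone mode needs N, CA, C and O atoms; use mode = \"calpha\" for C-alpha traces")
  }
  resnos <- sort(unique(ensemble$atoms$resno))
  helix <- sheet <- rep(0, length(resnos))
  nm <- n_structures(ensemble)
  for (k in seq_len(nm)) {
    st <- get_structure(ensemble, k)
    ss <- if (mode == "backbone") assign_ss_backbone(st) else assign_ss_calpha(st)
    helix <- helix + (ss == "H")
    sheet <- sheet + (ss == "E")
  }
  data.frame(resno = resnos, helix = helix / nm, sheet = sheet / nm)
}
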