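# Saupe alignment tensors and RDC back-calculation.
#
# Convention: D = d_max * t(u) %*% S %*% u, with u the unit internuclear
# vector and S the traceless symmetric order matrix. The dipolar constant
# d_max is a single configurable scalar; for backbone N-H vectors at the
# 1.02 Angstrom bond-length convention the magnitude is ~21.7 kHz, and the
# medium order parameter (typically ~1e-3 for steric alignment) is carried
# inside S, so observed couplings come out in the usual few-Hz range.

#' Dipolar interaction constant for backbone N-H (Hz)
#'
#' Magnitude of the static dipolar coupling constant at the 1.02 Angstrom
#' N-H bond-length convention. The sign convention is absorbed into the
#' alignment tensor; the constant cancels in Q-factors.
#' @export
DMAX_NH <- 21700

#' Construct a Saupe alignment tensor
#'
#' @param S 3x3 real symmetric traceless matrix (enforced to machine
#'   precision; trace is projected out, asymmetry is an error).
#' @return object of class `saupe_tensor` (a 3x3 matrix).
#' @export
saupe_tensor <- function(S) {
  S <- as.matrix(S)
  stopifnot(all(dim(S) == c(3L, 3L)))
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("Saupe tensor must be symmetric")
  }
  S <- (S + t(S)) / 2
  S <- S - diag(3) * sum(diag(S)) / 3
  class(S) <- c("saupe_tensor", "matrix")
  S
}

#' Build a Saupe tensor from its five independent components
#' @param sxx,syy diagonal components (szz = -sxx-syy).
#' @param sxy,sxz,syz off-diagonal components.
#' @return a [saupe_tensor()].
#' @export
saupe_from_components <- function(sxx, syy, sxy, sxz, syz) {
  saupe_tensor(matrix(c(sxx, sxy, sxz,
                        sxy, syy, syz,
                        sxz, syz, -sxx - syy), 3, 3, byrow = TRUE))
}

#' Axially symmetric Saupe tensor along an axis
#' @param szz principal order value along `axis`.
#' @param axis principal axis (default z).
#' @return a [saupe_tensor()].
#' @export
saupe_axial <- function(szz, axis = c(0, 0, 1)) {
  u <- unit_vec(axis)
  saupe_tensor(szz * (3 * tcrossprod(u) - diag(3)) / 2)
}

#' Eigen-decomposition summary of a Saupe tensor
#'
#' Eigenvalues are ordered by decreasing absolute value (|Szz| >= |Syy| >=
#' |Sxx|); ties are broken by sign (positive first) so principal-axis labels
#' are deterministic. Rhombicity is (Sxx - Syy)/Szz, zero for axial symmetry.
#'
#' @param tensor a [saupe_tensor()].
#' @return list with `values` (Szz, Syy, Sxx), `axes` (columns: z, y, x),
#'   `magnitude` (Szz) and `rhombicity`.
#' @export
saupe_principal <- function(tensor) {
  e <- eigen(unclass(tensor), symmetric = TRUE)
  ord <- order(-abs(e$values), -sign(e$values))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in 1:3) if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  list(values = vals, axes = vecs, magnitude = vals[1],
       rhombicity = if (abs(vals[1]) > 0) (vals[3] - vals[2]) / vals[1] else 0)
}

# ---- atom lookup / amide H reconstruction ----------------------------------

# Index of atom `elety` in residue `resno`; NA if absent.
atom_index <- function(structure, resno, elety) {
  hit <- which(structure$atoms$resno == resno & structure$atoms$elety == elety)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Reconstruct a missing amide hydrogen
#'
#' Places H at 1.02 Angstrom from N along the in-plane bisector of
#' C(i-1)-N(i)-CA(i), pointing away from both neighbours (the standard
#' geometric reconstruction for backbone amides).
#'
#' @param structure a [structure3d()] with backbone N, CA and preceding C.
#' @param resno residue number.
#' @return 3-vector position of the reconstructed H, or `NULL` when the
#'   required anchors are missing (first residue, chain breaks).
#' @export
reconstruct_amide_h <- function(structure, resno) {
  i_n <- atom_index(structure, resno, "N")
  i_ca <- atom_index(structure, resno, "CA")
  i_cp <- atom_index(structure, resno - 1L, "C")
  if (anyNA(c(i_n, i_ca, i_cp))) return(NULL)
  n <- structure$xyz[i_n, ]
  d <- unit_vec(n - structure$xyz[i_cp, ]) + unit_vec(n - structure$xyz[i_ca, ])
  n + 1.02 * unit_vec(d)
}

# Resolve the two atom positions of an RDC record; reconstructs amide H when
# allowed. Returns NULL when the record cannot be matched.
rdc_vector_endpoints <- function(structure, resno, atom_a, atom_b,
                                 reconstruct_h = TRUE) {
  get_pos <- function(name) {
    i <- atom_index(structure, resno, name)
    if (!is.na(i)) return(structure$xyz[i, ])
    if (reconstruct_h && name %in% c("H", "HN")) {
      return(reconstruct_amide_h(structure, resno))
    }
    NULL
  }
  pa <- get_pos(atom_a)
  pb <- get_pos(atom_b)
  if (is.null(pa) || is.null(pb)) return(NULL)
  list(a = pa, b = pb)
}

# Unit internuclear vectors for a set of records: n x 3 matrix with NA rows
# for unmatched records.
rdc_unit_vectors <- function(structure, records, reconstruct_h = TRUE) {
  n <- nrow(records)
  u <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    ep <- rdc_vector_endpoints(structure, records$resno[k], records$atom_a[k],
                               records$atom_b[k], reconstruct_h)
    if (is.null(ep)) next
    r <- ep$b - ep$a
    len <- vnorm(r)
    if (len < 1e-8) stop("zero-length internuclear vector at residue ", records$resno[k])
    u[k, ] <- r / len
  }
  u
}

# ---- back-calculation ------------------------------------------------------

#' Back-calculate RDCs for a structure under a given alignment tensor
#'
#' Computes D = d_max * u' S u for each requested record. Values are invariant
#' under a global rotation applied simultaneously to structure and tensor.
#' When experimental values are present in `records`, fit diagnostics
#' (Q-factor and RMSD in Hz) are reported.
#'
#' @param structure a [structure3d()].
#' @param tensor a [saupe_tensor()].
#' @param records an [rdc_table()] naming which (residue, atom pair) couplings
#'   to predict; the `value` column, if finite, is used for diagnostics.
#' @param d_max dipolar constant in Hz (default [DMAX_NH]).
#' @param reconstruct_h rebuild missing amide H geometrically (default TRUE).
#' @return list with `calc` (Hz, NA for unmatched records), `q_factor`,
#'   `rmsd` (both NA when no experimental values), and `unmatched` (indices).
#' @export
back_calc_rdc <- function(structure, tensor, records, d_max = DMAX_NH,
                          reconstruct_h = TRUE) {
  stopifnot(inherits(tensor, "saupe_tensor"))
  u <- rdc_unit_vectors(structure, records, reconstruct_h)
  S <- unclass(tensor)
  calc <- d_max * rowSums((u %*% S) * u)
  unmatched <- which(is.na(calc))
  ok <- !is.na(calc) & is.finite(records$value)
  q <- rmsd <- NA_real_
  if (any(ok)) {
    dev <- calc[ok] - records$value[ok]
    rmsd <- sqrt(mean(dev^2))
    denom <- sqrt(mean(records$value[ok]^2))
    q <- if (denom > 0) rmsd / denom else 0
  }
  list(calc = calc, q_factor = q, rmsd = rmsd, unmatched = unmatched)
}

#' RDC Q-factor
#' @param calc,exp numeric vectors of calculated and experimental couplings.
#' @return RMS(calc - exp) / RMS(exp).
#' @export
rdc_q_factor <- function(calc, exp) {
  ok <- is.finite(calc) & is.finite(exp)
  sqrt(mean((calc[ok] - exp[ok])^2)) / sqrt(mean(exp[ok]^2))
}

# Design matrix mapping the 5 tensor components (sxx, syy, sxy, sxz, syz)
# to u' S u for unit vectors in rows of u.
saupe_design_matrix <- function(u) {
  cbind(u[, 1]^2 - u[, 3]^2,
        u[, 2]^2 - u[, 3]^2,
        2 * u[, 1] * u[, 2],
        2 * u[, 1] * u[, 3],
        2 * u[, 2] * u[, 3])
}

#' Fit a Saupe tensor to experimental RDCs by singular value decomposition
#'
#' Least-squares solution for the five independent tensor components given a
#' structure and measured couplings; the standard tensor-determination route.
#' Rank-deficient design matrices trigger a conditioning warning and the
#' minimum-norm solution is returned.
#'
#' @param structure a [structure3d()].
#' @param records an [rdc_table()] with experimental values.
#' @param d_max dipolar constant in Hz.
#' @param reconstruct_h rebuild missing amide H (default TRUE).
#' @return list with `tensor` ([saupe_tensor()]), `calc` (fitted couplings for
#'   usable records, Hz), `q_factor`, `rmsd`, `used` (record indices entering
#'   the fit) and `unmatched`.
#' @export
svd_fit_tensor <- function(structure, records, d_max = DMAX_NH,
                           reconstruct_h = TRUE) {
  u <- rdc_unit_vectors(structure, records, reconstruct_h)
  usable <- which(!is.na(u[, 1]) & is.finite(records$value))
  if (length(usable) < 5L) {
    stop("underdetermined: need >= 5 usable RDC records, have ", length(usable))
  }
  uu <- u[usable, , drop = FALSE]
  d <- records$value[usable]
  if (all(d == 0)) {
    # 0-coupling degenerate case: zero tensor, Q undefined
    warning("all experimental RDCs are zero; returning zero tensor")
    return(list(tensor = saupe_tensor(matrix(0, 3, 3)),
                calc = rep(0, length(usable)), q_factor = NA_real_,
                rmsd = 0, used = usable, unmatched = which(is.na(u[, 1]))))
  }
  A <- d_max * saupe_design_matrix(uu)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos)) {
    warning("rank-deficient RDC design matrix (rank ", sum(pos),
            " of 5); returning minimum-norm solution")
  }
  dinv <- ifelse(pos, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * crossprod(sv$u, d))
  tensor <- saupe_from_components(coef[1], coef[2], coef[3], coef[4], coef[5])
  calc <- as.vector(A %*% coef)
  dev <- calc - d
  rmsd <- sqrt(mean(dev^2))
  list(tensor = tensor, calc = calc,
       q_factor = rmsd / sqrt(mean(d^2)), rmsd = rmsd,
       used = usable, unmatched = which(is.na(u[, 1])))
}

#' Steric-obstruction prediction of the alignment tensor
#'
#' Simplified structure-based alignment model for uncharged planar media:
#' the molecule is placed between parallel planar barriers a distance
#' `spacing` apart; for each orientation of the barrier normal (quasi-uniform
#' grid of `n_grid` directions in the molecular frame) the sterically allowed
#' fraction of positions is max(0, 1 - L/spacing), where L is the molecular
#' extent along the normal. The order matrix is the allowed-fraction-weighted
#' second moment of the normal direction, made traceless, times a scalar
#' medium order parameter that accounts for the weak overall alignment.
#'
#' @param structure a [structure3d()] (>= 3 non-collinear atoms).
#' @param spacing barrier spacing in Angstrom; default twice the largest
#'   molecular extent, so every orientation remains allowed but oblong shapes
#'   are progressively disfavoured.
#' @param n_grid number of orientations (default 5000).
#' @param order_scale scalar medium order parameter (default 1e-3, the weak
#'   alignment regime of phage/bicelle media).
#' @return a [saupe_tensor()].
#' @export
steric_tensor <- function(structure, spacing = NULL, n_grid = 5000,
                          order_scale = 1e-3) {
  xyz <- structure$xyz
  if (nrow(xyz) < 3L) stop("steric tensor needs >= 3 atoms")
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  dirs <- fibonacci_sphere(n_grid)
  proj <- xyz %*% t(dirs)                       # n_atoms x n_grid
  extent <- apply(proj, 2L, max) - apply(proj, 2L, min)
  if (max(extent) < 1e-9) stop("degenerate geometry: all atoms coincide")
  if (is.null(spacing)) spacing <- 2 * max(extent)
  w <- pmax(0, 1 - extent / spacing)
  if (sum(w) <= 0) stop("barrier spacing excludes every orientation")
  m2 <- crossprod(dirs * w, dirs) / sum(w)      # weighted <n n'>
  saupe_tensor(order_scale * (m2 - diag(3) / 3))
}
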