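#' @importFrom stats rnorm runif sd setNames approx aggregate
#' @importFrom utils read.table write.table head tail
NULL

# ---- structural data model -------------------------------------------------

#' Create a single structure
#'
#' A `structure3d` couples an atom metadata table with one set of Cartesian
#' coordinates. It is the unit stored inside a [conformation_ensemble()].
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based residue
#'   number as in the PDB), `resid` (3-letter residue name), `elety` (PDB atom
#'   name), `element` (element symbol) and `mass` (atomic mass units).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param model_id integer model identifier.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, model_id = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  required <- c("chain", "resno", "resid", "elety", "element", "mass")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("a structure needs at least one atom")
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L) {
    stop("coordinate matrix must be n_atoms x 3")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("atom masses must be positive")
  }
  if (any(atoms$resno < 1L)) stop("residue indices must be >= 1")
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  out <- list(atoms = atoms, xyz = xyz, model_id = as.integer(model_id))
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d residues, model %d\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), x$model_id))
  invisible(x)
}

#' Number of atoms in a structure or ensemble
#' @param x a `structure3d` or `conformation_ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "structure3d")) return(nrow(x$atoms))
  if (inherits(x, "conformation_ensemble")) return(nrow(x$atoms))
  stop("unsupported type")
}

#' Build a conformation ensemble from structures
#'
#' An ordered, optionally weighted collection of structures sharing one
#' topology (identical atom count and metadata). Coordinates are stored as an
#' `n_atoms x 3 x n_models` array.
#'
#' @param structures list of [structure3d()] objects with identical topology.
#' @param weights optional non-negative per-structure weights; normalised to
#'   sum to one. Default uniform.
#' @return `conformation_ensemble` object with fields `atoms`, `xyz` (3-d
#'   array), `weights` and `model_ids`.
#' @export
conformation_ensemble <- function(structures, weights = NULL) {
  if (length(structures) < 1L) stop("ensemble must contain at least one structure")
  ref <- structures[[1L]]
  if (!inherits(ref, "structure3d")) stop("expected a list of structure3d objects")
  na <- nrow(ref$atoms)
  meta_cols <- c("chain", "resno", "resid", "elety", "element")
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    if (nrow(s$atoms) != na ||
        !identical(s$atoms[meta_cols], ref$atoms[meta_cols])) {
      stop("inconsistent topology at model ", k)
    }
  }
  xyz <- array(0, dim = c(na, 3L, length(structures)))
  for (k in seq_along(structures)) xyz[, , k] <- structures[[k]]$xyz
  model_ids <- vapply(structures, function(s) s$model_id, integer(1))
  new_ensemble(ref$atoms, xyz, weights, model_ids)
}

new_ensemble <- function(atoms, xyz, weights = NULL, model_ids = NULL) {
  nm <- dim(xyz)[3L]
  if (is.null(weights)) {
    weights <- rep(1 / nm, nm)
  } else {
    if (length(weights) != nm) stop("one weight per structure required")
    if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative and not all zero")
    weights <- weights / sum(weights)
  }
  if (is.null(model_ids)) model_ids <- seq_len(nm)
  out <- list(atoms = atoms, xyz = xyz, weights = weights,
              model_ids = as.integer(model_ids))
  class(out) <- "conformation_ensemble"
  out
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<conformation_ensemble> %d structures x %d atoms\n",
              n_structures(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of structures in an ensemble
#' @param ensemble a `conformation_ensemble`.
#' @return integer count.
#' @export
n_structures <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  dim(ensemble$xyz)[3L]
}

#' Extract one structure from an ensemble
#' @param ensemble a `conformation_ensemble`.
#' @param i model index (1-based position in the ensemble).
#' @return a [structure3d()].
#' @export
get_structure <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  i <- as.integer(i)
  if (i < 1L || i > n_structures(ensemble)) stop("model index out of range")
  structure3d(ensemble$atoms, ensemble$xyz[, , i, drop = TRUE],
              model_id = ensemble$model_ids[i])
}

#' Apply an atom selection to a structure or ensemble
#'
#' @param x `structure3d` or `conformation_ensemble`.
#' @param elety optional character vector of atom names to keep (e.g. "CA").
#' @param chain optional chain identifier(s) to keep.
#' @return object of the same class restricted to the selected atoms.
#' @export
select_atoms <- function(x, elety = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(x$atoms))
  if (!is.null(elety)) keep <- keep & x$atoms$elety %in% elety
  if (!is.null(chain)) keep <- keep & x$atoms$chain %in% chain
  if (!any(keep)) stop("selection removes all atoms")
  if (inherits(x, "structure3d")) {
    return(structure3d(x$atoms[keep, , drop = FALSE],
                       x$xyz[keep, , drop = FALSE], x$model_id))
  }
  if (inherits(x, "conformation_ensemble")) {
    return(new_ensemble(
      {
        a <- x$atoms[keep, , drop = FALSE]; rownames(a) <- NULL; a
      },
      x$xyz[keep, , , drop = FALSE], x$weights, x$model_ids))
  }
  stop("unsupported type")
}

# ---- PDB -------------------------------------------------------------------

element_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38)
  m <- tab[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

element_from_name <- function(elety) {
  # first alphabetic character of the stripped atom name; covers protein atoms
  e <- sub("^[0-9']*", "", trimws(elety))
  substr(e, 1L, 1L)
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM record at line %d of %s: too short", i, path))
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    vals <- suppressWarnings(as.numeric(coords))
    if (any(is.na(vals))) {
      stop(sprintf("malformed ATOM record at line %d of %s: non-numeric coordinates",
                   i, path))
    }
  }
  invisible(length(idx))
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' MODEL/ENDMDL blocks each become one structure; a single-model file yields an
#' ensemble of size one with weight 1. Alternate locations other than '' / 'A'
#' are dropped so the topology is deterministic. Parsing is delegated to
#' \pkg{bio3d} after a line-level format check that reports the offending line
#' number on malformed ATOM records.
#'
#' @param path PDB file.
#' @param elety optional atom-name filter applied on read (e.g. `"CA"`).
#' @param chain optional chain filter.
#' @return a [conformation_ensemble()] with uniform weights, coordinates in
#'   Angstrom.
#' @export
read_pdb_ensemble <- function(path, elety = NULL, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM") & (is.na(at$alt) | at$alt %in% c("", "A"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  at <- at[keep, , drop = FALSE]
  # column indices of kept atoms in bio3d's flat xyz layout (x1,y1,z1,x2,...)
  flat_idx <- as.vector(t(outer(which(keep), c(2L, 1L, 0L),
                                function(i, o) 3L * i - o)))
  xyz <- xyz[, flat_idx, drop = FALSE]
  elesy <- at$elesy
  bad <- is.na(elesy) | trimws(elesy) == ""
  if (any(bad)) elesy[bad] <- element_from_name(at$elety[bad])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resid = at$resid,
    elety = at$elety,
    element = trimws(elesy),
    stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  structures <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    mk <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    structures[[k]] <- structure3d(atoms, mk, model_id = k)
  }
  ens <- conformation_ensemble(structures)
  if (!is.null(elety) || !is.null(chain)) {
    ens <- select_atoms(ens, elety = elety, chain = chain)
  }
  ens
}

#' Write an ensemble as a MODEL-delimited PDB file
#'
#' Round-trips with [read_pdb_ensemble()]: topology exactly, coordinates to the
#' PDB format precision of 1e-3 Angstrom.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  nm <- n_structures(ensemble)
  na <- nrow(ensemble$atoms)
  flat <- matrix(0, nrow = nm, ncol = 3L * na)
  for (k in seq_len(nm)) flat[k, ] <- as.vector(t(ensemble$xyz[, , k]))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = if (nm == 1L) flat[1L, ] else flat,
      type = rep("ATOM", na),
      resno = ensemble$atoms$resno,
      resid = ensemble$atoms$resid,
      eleno = seq_len(na),
      elety = ensemble$atoms$elety,
      chain = ensemble$atoms$chain,
      elesy = ensemble$atoms$element
    )
    TRUE
  }, error = function(e) {
    stop("failed to write PDB to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

# ---- RDC tables ------------------------------------------------------------

#' Create an RDC record table
#' @param resno integer residue numbers.
#' @param atom_a,atom_b atom names of the coupled pair (e.g. "N", "H").
#' @param value couplings in Hz.
#' @param error per-record uncertainty in Hz (default 1).
#' @param medium alignment-medium label.
#' @return data.frame of class `rdc_table`.
#' @export
rdc_table <- function(resno, atom_a, atom_b, value, error = 1.0, medium = "synthetic") {
  df <- data.frame(resno = as.integer(resno), atom_a = atom_a, atom_b = atom_b,
                   value = as.numeric(value), error = as.numeric(error),
                   medium = medium, stringsAsFactors = FALSE)
  if (any(df$atom_a == df$atom_b)) stop("atom_a and atom_b must differ")
  if (any(!is.finite(df$value))) stop("non-finite RDC value")
  if (any(df$error < 0)) stop("negative RDC error")
  class(df) <- c("rdc_table", "data.frame")
  df
}

#' Read an RDC table
#'
#' Whitespace-delimited dialect: columns `residue atom_a atom_b value [error]
#' [medium]`; lines starting with `#` and blank lines are skipped. A missing
#' error column defaults to 1.0 Hz.
#'
#' @param path input file.
#' @return an [rdc_table()].
#' @export
read_rdc_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  raw <- trimws(lines)
  keep <- raw != "" & !startsWith(raw, "#")
  rows <- which(keep)
  if (length(rows) == 0L) stop("RDC table is empty: ", path)
  parts <- strsplit(raw[keep], "[ \t]+")
  n <- length(parts)
  out <- data.frame(resno = integer(n), atom_a = character(n),
                    atom_b = character(n), value = numeric(n),
                    error = numeric(n), medium = character(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    p <- parts[[k]]
    if (length(p) < 4L) {
      stop(sprintf("RDC parse error at line %d of %s: expected >= 4 columns", rows[k], path))
    }
    resno <- suppressWarnings(as.integer(p[1]))
    value <- suppressWarnings(as.numeric(p[4]))
    if (is.na(resno) || is.na(value)) {
      stop(sprintf("RDC parse error at line %d of %s: non-numeric field", rows[k], path))
    }
    err <- if (length(p) >= 5L) suppressWarnings(as.numeric(p[5])) else 1.0
    if (is.na(err)) stop(sprintf("RDC parse error at line %d of %s: bad error field", rows[k], path))
    out$resno[k] <- resno
    out$atom_a[k] <- p[2]
    out$atom_b[k] <- p[3]
    out$value[k] <- value
    out$error[k] <- err
    out$medium[k] <- if (length(p) >= 6L) p[6] else "unknown"
  }
  rdc_table(out$resno, out$atom_a, out$atom_b, out$value, out$error, out$medium)
}

#' Write an RDC table in the package dialect
#' @param rdc an [rdc_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(rdc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue atom_a atom_b value_hz error_hz medium", con)
  writeLines(sprintf("%d\t%s\t%s\t%.6f\t%.6f\t%s", rdc$resno, rdc$atom_a,
                     rdc$atom_b, rdc$value, rdc$error, rdc$medium), con)
  invisible(path)
}

# ---- NOE tables ------------------------------------------------------------

#' Create an NOE restraint table
#' @param resno_i,atom_i,resno_j,atom_j atom addresses of the restrained pair.
#' @param upper upper distance bound in Angstrom.
#' @param lower lower bound in Angstrom (default 0).
#' @return data.frame of class `noe_table`.
#' @export
noe_table <- function(resno_i, atom_i, resno_j, atom_j, upper, lower = 0) {
  df <- data.frame(resno_i = as.integer(resno_i), atom_i = atom_i,
                   resno_j = as.integer(resno_j), atom_j = atom_j,
                   lower = as.numeric(lower), upper = as.numeric(upper),
                   stringsAsFactors = FALSE)
  if (any(df$lower < 0)) stop("lower bounds must be >= 0")
  if (any(df$upper <= df$lower)) stop("upper bound must exceed lower bound")
  class(df) <- c("noe_table", "data.frame")
  df
}

#' Read an NOE restraint table
#'
#' Dialect: `residue_i atom_i residue_j atom_j upper [lower]`, '#' comments.
#' @param path input file.
#' @return a [noe_table()].
#' @export
read_noe_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- trimws(readLines(path, warn = FALSE))
  keep <- raw != "" & !startsWith(raw, "#")
  rows <- which(keep)
  parts <- strsplit(raw[keep], "[ \t]+")
  n <- length(parts)
  if (n == 0L) stop("NOE table is empty: ", path)
  ri <- integer(n); rj <- integer(n); ai <- character(n); aj <- character(n)
  up <- numeric(n); lo <- numeric(n)
  for (k in seq_len(n)) {
    p <- parts[[k]]
    if (length(p) < 5L) stop(sprintf("NOE parse error at line %d of %s", rows[k], path))
    ri[k] <- suppressWarnings(as.integer(p[1])); ai[k] <- p[2]
    rj[k] <- suppressWarnings(as.integer(p[3])); aj[k] <- p[4]
    up[k] <- suppressWarnings(as.numeric(p[5]))
    lo[k] <- if (length(p) >= 6L) suppressWarnings(as.numeric(p[6])) else 0
    if (anyNA(c(ri[k], rj[k], up[k], lo[k]))) {
      stop(sprintf("NOE parse error at line %d of %s: non-numeric field", rows[k], path))
    }
  }
  noe_table(ri, ai, rj, aj, up, lo)
}

#' Write an NOE restraint table
#' @param noe a [noe_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_noe_table <- function(noe, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue_i atom_i residue_j atom_j upper_A lower_A", con)
  writeLines(sprintf("%d\t%s\t%d\t%s\t%.4f\t%.4f", noe$resno_i, noe$atom_i,
                     noe$resno_j, noe$atom_j, noe$upper, noe$lower), con)
  invisible(path)
}

# ---- SAXS profiles ---------------------------------------------------------

#' Create a SAXS profile
#' @param s momentum transfer grid in 1/Angstrom, strictly increasing.
#' @param intensity positive intensities.
#' @param sigma optional positive per-point uncertainties.
#' @return object of class `saxs_profile`.
#' @export
saxs_profile <- function(s, intensity, sigma = NULL) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) != length(intensity)) stop("s and intensity lengths differ")
  if (length(s) > 1L && any(diff(s) <= 0)) stop("s grid must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s)) stop("sigma length mismatch")
  }
  out <- list(s = s, intensity = intensity, sigma = sigma)
  class(out) <- "saxs_profile"
  out
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, s in [%.4g, %.4g] 1/A%s\n",
              length(x$s), min(x$s), max(x$s),
              if (is.null(x$sigma)) ", no sigma" else ""))
  invisible(x)
}

#' Read a 3-column SAXS profile (.dat)
#'
#' Columns `s I [sigma]`; header/comment lines (non-numeric first field, or
#' starting with '#') are tolerated and skipped. The grid is validated to be
#' strictly increasing.
#'
#' @param path input file.
#' @return a [saxs_profile()]; `sigma` is `NULL` for 2-column files.
#' @export
read_saxs_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- trimws(readLines(path, warn = FALSE))
  keep <- raw != "" & !startsWith(raw, "#")
  parts <- strsplit(raw[keep], "[ \t]+")
  svals <- c(); ivals <- c(); gvals <- c(); has_sigma <- TRUE
  for (p in parts) {
    v <- suppressWarnings(as.numeric(p))
    if (length(v) < 2L || anyNA(v[1:2])) next   # header line
    svals <- c(svals, v[1]); ivals <- c(ivals, v[2])
    if (length(v) >= 3L && !is.na(v[3])) gvals <- c(gvals, v[3]) else has_sigma <- FALSE
  }
  if (length(svals) == 0L) stop("no data rows in SAXS file: ", path)
  if (any(diff(svals) <= 0)) stop("SAXS format error: s grid not strictly increasing in ", path)
  saxs_profile(svals, ivals, if (has_sigma && length(gvals) == length(svals)) gvals else NULL)
}

#' Write a SAXS profile as 3-column text
#' @param profile a [saxs_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# s(1/A)  I(s)  sigma", con)
  if (is.null(profile$sigma)) {
    writeLines(sprintf("%.6e %.6e", profile$s, profile$intensity), con)
  } else {
    writeLines(sprintf("%.6e %.6e %.6e", profile$s, profile$intensity, profile$sigma), con)
  }
  invisible(path)
}
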