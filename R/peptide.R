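# Idealised all-backbone peptide builder (N, H, CA, C, O per residue) used to
# construct reference geometries for hydrogen-bond based secondary-structure
# assignment.

#' Build an idealised poly-alanine backbone at fixed dihedrals
#'
#' Places N, H, CA, C, O for each residue with standard bond lengths and
#' angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, N-H 1.02 Angstrom)
#' using the given backbone dihedrals. The amide H lies in the peptide plane,
#' trans to the carbonyl O. An ideal alpha-helix is phi = -57, psi = -47.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees (scalars or per-residue
#'   vectors).
#' @param omega peptide-bond dihedral in degrees (default 180, trans).
#' @return a [structure3d()] with atoms N, H, CA, C, O per residue (no H on
#'   residue 1).
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, omega = 180) {
  if (n_res < 2L) stop("need at least 2 residues")
  deg <- pi / 180
  phi <- rep_len(phi, n_res) * deg
  psi <- rep_len(psi, n_res) * deg
  omega <- rep_len(omega, n_res) * deg
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231; b_nh <- 1.02
  a_ncac <- 111.2 * deg; a_cacn <- 116.2 * deg; a_cnca <- 121.7 * deg
  a_caco <- 120.8 * deg; a_cnh <- 119.5 * deg
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; H <- N
  has_h <- rep(TRUE, n_res); has_h[1] <- FALSE
  # seed the first residue
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  C[1, ] <- CA[1, ] + b_cac * c(-cos(a_ncac), sin(a_ncac), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_cn, a_cacn, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_nca, a_cnca, omega[i - 1])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], b_cac, a_ncac, phi[i])
      # O(i-1): trans to N(i) across the carbonyl (torsion N(i)-CA-C-O = 180)
      O[i - 1, ] <- place_atom(N[i, ], CA[i - 1, ], C[i - 1, ], b_co, a_caco, pi)
      # H(i): in the peptide plane, trans to O(i-1)
      H[i, ] <- place_atom(O[i - 1, ], C[i - 1, ], N[i, ], b_nh, a_cnh, pi)
    }
  }
  # last carbonyl O from psi of the final residue
  O[n_res, ] <- place_atom(N[n_res, ], CA[n_res, ], C[n_res, ], b_co, a_caco,
                           psi[n_res] + pi)
  names_per_res <- lapply(seq_len(n_res), function(i) {
    if (has_h[i]) c("N", "H", "CA", "C", "O") else c("N", "CA", "C", "O")
  })
  elety <- unlist(names_per_res)
  resno <- rep(seq_len(n_res), times = lengths(names_per_res))
  element <- substr(elety, 1, 1)
  atoms <- data.frame(chain = "A", resno = resno, resid = "ALA", elety = elety,
                      element = element, mass = element_mass(element),
                      stringsAsFactors = FALSE)
  xyz <- matrix(0, length(elety), 3)
  row <- 1L
  for (i in seq_len(n_res)) {
    for (nm in names_per_res[[i]]) {
      xyz[row, ] <- switch(nm, N = N[i, ], H = H[i, ], CA = CA[i, ],
                           C = C[i, ], O = O[i, ])
      row <- row + 1L
    }
  }
  structure3d(atoms, xyz)
}
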