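# Shared builders for the test suite.

# Small deterministic hinge template (34 residues, 102 atoms).
toy_template <- function(bend = 120) {
  build_hinge_template(hinge_topology(20L, 10L, 4L), bend_angle = bend)
}

# A generic non-degenerate Saupe tensor in the weak-alignment range.
toy_tensor <- function() {
  saupe_from_components(4e-4, -2e-4, 1e-4, 3e-4, -2.5e-4)
}

# Random traceless symmetric tensor with components ~ order 1e-4.
random_tensor <- function() {
  v <- runif(5, -5e-4, 5e-4)
  saupe_from_components(v[1], v[2], v[3], v[4], v[5])
}

# Minimal hand-built structure: CA-only chain at given coordinates.
ca_structure <- function(xyz, resno = seq_len(nrow(xyz)), model_id = 1L) {
  atoms <- data.frame(chain = "A", resno = as.integer(resno), resid = "ALA",
                      elety = "CA", element = "C", mass = 12.011,
                      stringsAsFactors = FALSE)
  structure3d(atoms, xyz, model_id)
}

# Replica state of m hinge conformations at the given angles, all under one
# fixed tensor.
toy_replica_state <- function(angles, tensor = toy_tensor(), step = 0L,
                              template = toy_template()) {
  reps <- lapply(angles, function(a) set_hinge_angle(template, a))
  replica_state(reps, tensors = tensor, step = step)
}

# Central finite-difference gradient of f (scalar) wrt the coordinates of
# replica m in state, at atoms rows `rows`.
fd_gradient <- function(f, state, m, rows, h = 1e-5) {
  g <- matrix(0, length(rows), 3L)
  for (ri in seq_along(rows)) {
    for (d in 1:3) {
      sp <- state; sm <- state
      sp$replicas[[m]]$xyz[rows[ri], d] <- sp$replicas[[m]]$xyz[rows[ri], d] + h
      sm$replicas[[m]]$xyz[rows[ri], d] <- sm$replicas[[m]]$xyz[rows[ri], d] - h
      g[ri, d] <- (f(sp) - f(sm)) / (2 * h)
    }
  }
  g
}
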