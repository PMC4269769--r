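---
title: "Replica-averaged restrained ensembles of hinge proteins: methods and parameter choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replica-averaged restrained ensembles of hinge proteins: methods and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repave)
```

This vignette documents the model implemented by `repave`, the meaning, units
and defaults of every load-bearing parameter, and the numerical choices made
where the underlying methodology leaves freedom. It is a methods reference,
not a tutorial; see the README for a worked example.

## 1. The model

### Hybrid energy

The sampler works on a hybrid energy

$$E_\mathrm{total} = E_\mathrm{FF} + E_\mathrm{RDC} \;(+\, E_\mathrm{CS}),$$

where $E_\mathrm{FF}$ is a molecular-mechanics stand-in (Section 3) and the
restraint terms act on **replica averages**: with $M$ simultaneous copies of
the system,

$$E_\mathrm{RDC} = \alpha \sum_k \left( \langle D^\mathrm{calc}_k
\rangle_\mathrm{replicas} - D^\mathrm{exp}_k \right)^2 ,$$

in J mol$^{-1}$ with $\alpha$ in J mol$^{-1}$ Hz$^{-2}$. Restraining the
average rather than each copy lets individual replicas fluctuate while the
ensemble reproduces the data — the defining property of replica-averaged
restraints. The sum convention (one sum over records, not a per-record
energy) is adopted and fixed here; `rdc_restraint_energy()` reports the
rejected (topology-unmatched) records explicitly rather than dropping them.

Back-calculation uses the standard convention
$D = d_\mathrm{max}\, \hat u^\mathsf{T} S\, \hat u$ with $\hat u$ the unit
internuclear vector and $S$ the traceless symmetric Saupe matrix. The dipolar
constant is a single configurable scalar, `DMAX_NH = 21700` Hz (backbone N–H
at the 1.02 Å bond-length convention). It cancels in Q-factors; the weak
overall alignment of the medium is carried inside $S$ as a scalar order
parameter of order $10^{-3}$, so couplings come out in the usual few-Hz range.

### Alignment tensors

Two tensor routes are provided:

- `svd_fit_tensor()` solves the five independent components by least squares
  (singular value decomposition of the design matrix over records). It is
  exact on noiseless data. Rank-deficient designs warn and return the
  minimum-norm solution; an all-zero data vector is reported as the
  0-coupling degenerate case (zero tensor, undefined Q).
- `steric_tensor()` is a simplified obstruction model for uncharged planar
  media: the molecule sits between parallel planar barriers at spacing $L_0$;
  for each barrier-normal orientation $\hat n$ (quasi-uniform Fibonacci grid,
  default 5000 directions) the allowed fraction of positions is
  $\max(0, 1 - L(\hat n)/L_0)$ with $L(\hat n)$ the molecular extent along
  $\hat n$. The order matrix is the allowed-fraction-weighted second moment of
  $\hat n$, made traceless, times the scalar order parameter. The default
  spacing is twice the largest molecular extent, so every orientation remains
  allowed but oblong shapes are progressively disfavoured. The model
  preserves the shape-to-tensor covariance the method needs
  ($S(R x) = R\,S(x)\,R^\mathsf{T}$ to grid tolerance) without reproducing
  any particular published predictor.

Eigenvalues of a tensor are ordered by decreasing absolute value with ties
broken by sign (positive first), so principal-axis labels are deterministic.

### Chemical-shift restraints (MUMO scheme)

`cs_restraint_energy()` applies the same quadratic form over **rotating
groups** of replicas (default group size 4), rather than the full replica
average, limiting over-fitting of a local observable. Group membership rotates
deterministically with the state's step counter and partitions the replicas
exactly. The shift predictor is pluggable (fields `nuclei` and
`predict(structure, resno, nucleus, gradient)`); the default,
`shift_predictor_curvature()`, is a deliberately simple, fully documented
model — random-coil value plus a coefficient times the cosine of the virtual
Cα bond angle at the residue — chosen because it is smooth with an exact
analytic gradient, making ground-truth recovery tests exact. It is a
curvature model rather than a backbone-dihedral model: the coarse-grained
chain carries no φ/ψ dihedrals, and the virtual bond angle is the natural
local-geometry analogue. The CS force constant β (J mol$^{-1}$ ppm$^{-2}$) is
required configuration with no default claim of fidelity.

### Force-constant schedule

`restraint_schedule()` implements: linear ramp from zero over `ramp_steps`
(default: the equilibration phase), full `alpha_max` at base temperature, and
`high_t_scale × alpha_max` once the temperature reaches `t_high_threshold`.
Defaults: `alpha_max = 1000` J mol$^{-1}$ Hz$^{-2}$ (the calibrated optimum
for RDC restraints of this form), `high_t_scale = 0.10`, threshold 350 K (the
midpoint of the 300–400 K annealing window; the methodology defines "high
temperatures" only loosely, so the threshold is exposed). Per-replica
alignment tensors are refreshed every `tensor_update_interval = 250` steps
and held fixed in between; gradients treat the tensor as a constant, matching
that update protocol.

## 2. The sampling protocol

`annealing_protocol()` defaults encode the published protocol structure:
50 cycles between 300 and 400 K, 100 sweeps per cycle under the default
mapping of 1 sweep ≡ 5 ps (500 ps per cycle), the final 20% of each cycle
(100 ps) held at the base temperature with one frame collected per sweep
(5 ps), and the first 20 cycles discarded. With 16 replicas this composes
exactly $16 \times 30 \times 20 = 9600$ structures and 8 ns of nominal
sampling per cycle across replicas. The within-cycle temperature profile
(linear heat to `t_high`, linear cool, hold at `t_low` for the collection
window) is a choice; the methodology specifies only the endpoints.

Molecular dynamics is replaced by Metropolis Monte Carlo over the hinge
degree of freedom: a move rotates the hairpin rigidly about the hinge axis.
Two properties are maintained deliberately:

- **Detailed balance in the collected ensemble.** Move sizes are auto-tuned
  only during equilibration and the discarded cycles, then frozen.
- **Exact code-path equivalence at α = 0.** `metropolis_accept()` always
  consumes one uniform variate, so a restrained run with zero force constant
  reproduces the unrestrained trajectory bit for bit at equal seeds (tested).

An acceptance rate below 1% over a cycle triggers a diagnostic warning
(move size misconfigured). Convergence monitoring follows the ensemble-method
practice: the sampler emits a per-frame radius-of-gyration trace and a
per-cycle log of acceptance rates and energy terms.

## 3. The synthetic hinge protein and the toy force field

`build_hinge_template()` constructs a coarse-grained chain — one Cα bead per
residue at 3.8 Å spacing plus pseudo N and H atoms fixed in each residue's
local frame — with two idealised helical subdomains (radius 2.3 Å, rise
1.5 Å, 100° turn) joined by a straight hinge. Because the N–H vectors are
rigid in their subdomain frame, RDCs are sensitive to the hinge angle exactly
as in a real two-domain protein. The generator's purpose is ground truth:
every downstream stage is testable offline with known parameters. It does
**not** emulate side chains, realistic Ramachandran statistics, solvent, or
any specific protein's geometry.

`toy_forcefield()` supplies $E_\mathrm{FF}$: an elastic network over Cα pairs
within each rigid subdomain (exactly constant under hinge moves — kept as a
correctness check), a soft core–hairpin excluded-volume repulsion, and a
hinge-angle potential. The default hinge potential is **harmonic about the
template's own bending angle with k = 1 J mol⁻¹ deg⁻²**: at 300 K this gives
a thermal spread of roughly 35°, i.e. a hairpin undergoing large-amplitude
motions about a preferred orientation. The rationale is methodological: the
bare force field must have a conformational preference of its own that the
restraints override — the situation replica-averaged restraining is built
for. A stiffer default (k of order 10) would let the force-field minimum
compete with the data term at the default α; a flat default
(`hinge = list(type = "flat")`, available) would make the unrestrained
control a pure random walk with no preference to correct against, weakening
the restrained-versus-unrestrained comparison.

Parameter recovery (tested, seeds fixed in advance): synthetic RDCs computed
as ensemble averages over a 95° hinge ensemble, sampling started at 130°,
recover a mean bending angle within 5° of 95° on every seed while the
unrestrained control stays near the 120° force-field basin.

## 4. Validation modules

- **NOE** (`noe_check()`): a restraint is fulfilled in a structure iff the
  distance lies in `[lower, upper + tolerance]`; default tolerance 0.5 Å.
  Fulfilled and violated percentages sum to exactly 100 per structure
  (per-structure checking is the default; $r^{-6}$ ensemble averaging is an
  option). Unresolvable restraints are excluded from denominators and
  reported.
- **SAXS** (`debye_profile()`, `chi2_fit()`): the Debye sum with the
  $\sin(x)/x \to 1$ limits handled analytically; default one dummy Gaussian
  scattering centre per residue ($f(s) = e^{-(s\,r_\mathrm{eff})^2/2}$,
  $r_\mathrm{eff} = 3$ Å), with a `"point"` mode for closed-form oracles.
  χ² uses the closed-form least-squares multiplicative scale; an additive
  constant (buffer-subtraction ambiguity) is behind a flag. Hydration-layer
  and excluded-volume fitting are out of scope.

## 5. Landscape analysis

The bending angle is measured at the **region II (hinge) centroid** between
vectors to the region I (globular) and region III (distal loop) centroids —
the hinge-as-vertex reading is the only geometrically sensible one and is
fixed here. "Centres of mass of the Cα atoms" is read as unweighted Cα
centroids. `region_spec()` defaults to the Josephin-domain definitions
(I = 111–113, 122–125, 162–165; II = 32–35; III = 45–48, 58–61, author
numbering); `hinge_regions()` maps the scheme onto the synthetic protein.

`free_energy_landscape()` histograms (angle, Rg) with default bins of 2° ×
0.25 Å (no binning is prescribed by the methodology), converts to
$F = -\ln P$ in $k_\mathrm{B}T$ units shifted so the minimum is zero, and
masks empty bins as `NA` rather than clamping them. Radius of gyration is
offered both heavy-atom mass-weighted (default) and Cα-only unweighted, since
published Rg values rarely state the convention; contact maps use a strict
`< 8 Å` Cα cutoff computed on individual structures. Secondary structure is a
Kabsch–Sander subset: hydrogen bonds by the electrostatic energy
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal mol$^{-1}$ with a $-0.5$ threshold; helix classes H and G are pooled,
strand E via bridge patterns; turns/bends are out of scope. A Cα-only
virtual-torsion fallback handles coarse-grained input.

## 6. Numerical choices

- **Exact hinge placement.** `set_hinge_angle()` root-finds the rigid
  rotation that makes the *measured* bending angle equal the target
  (bracketing grid + `uniroot`, tolerance $10^{-12}$), rather than rotating
  by the nominal angle difference: the helical-subdomain centroids do not lie
  exactly in the rotation plane, so the naive rotation is biased by a few
  tenths of a degree.
- **Cached couplings in the sampler.** Each replica's back-calculated RDC
  vector is cached and the replica average updated in O(records) per move;
  tensors are recomputed only at the update interval.
- **SVD with explicit conditioning.** Singular values below
  $\max(\dim) \cdot \epsilon \cdot \sigma_1$ are treated as zero
  (minimum-norm solution plus warning).
- **Fibonacci sphere** for orientation grids: quasi-uniform, deterministic,
  no RNG involvement.
- **Seeding discipline.** Every generator takes an explicit seed and restores
  the caller's RNG state (`with_local_seed`), so library calls never perturb
  user-level reproducibility.

## 7. Problem sizes and costs

The default toy protein has 34 residues (102 atoms). On one CPU: a full
16-replica, 50-cycle protocol run collects its 9600 structures in ~25 s; the
5-seed parameter-recovery experiment takes ~15 s; the test suite runs in
about two minutes. Memory stays far below 1 GiB throughout.

## 8. Limitations

- The sampler explores only the hinge degree of freedom by default;
  subdomain-internal fluctuations are frozen. This is deliberate (known
  ground truth) but means Q-factors on synthetic data are optimistic relative
  to all-atom ensembles.
- The steric alignment model ignores electrostatics; charged media (e.g.
  phage at low salt) are outside its validity. Whether salt screening should
  be modelled is exposed to the caller, not guessed.
- The CS predictor is a local-curvature toy; it shares only the *contract*
  with trained predictors.
- χ² uncertainties across ensembles can be estimated by block bootstrap over
  structures, but no claim is made that this reproduces any published ±
  values, whose resampling scheme is unstated.
- Analyses of multi-chain crystal structures require an explicit chain
  selection (`read_pdb_ensemble(..., chain = )`); no default chain choice is
  made on the caller's behalf.
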