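---
title: "Methods: matrix-product-state emulation of variational quantum eigensolvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix-product-state emulation of variational quantum eigensolvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mpsvqe` emulates variational quantum eigensolver (VQE) calculations for
molecular electronic structure on a classical computer, using a matrix
product state (MPS) in place of the exponentially large statevector. This
vignette is the package's own account of the underlying methods: the
models, the algorithms, the tunable parameters, the numerical choices made
where the design was genuinely open, and what the validation suite does and
does not demonstrate.

## The simulation model

An $n$-qubit state is stored as a chain of rank-3 site tensors
$B^{i_k}_{\alpha_{k-1}\alpha_k}$ (physical index $i_k \in \{0,1\}$, virtual
bond indices $\alpha$) together with the singular-value spectrum
$\lambda_{\alpha_k}$ of every internal bond. The tensors are kept
*right-canonical*: $\sum_{i,\alpha_k} B^{i*}_{\alpha'\alpha_k}
B^{i}_{\alpha\alpha_k} = \delta_{\alpha\alpha'}$ at every site, which makes
expectation values computable with a single left-to-right transfer
contraction opened by $\lambda^2$ at the leftmost non-identity site and
closed for free by canonicity. Memory scales with the bond dimension $D$
(the retained Schmidt rank) rather than $2^n$.

One-qubit gates contract directly into a site tensor and preserve the
canonical gauge exactly. A two-qubit gate on adjacent sites follows the
standard sequence: contract the two sites with the gate, weight the left
bond by the incoming $\lambda$, singular-value-decompose the resulting
two-site matrix, truncate, and rebuild the two site tensors. Two numerical
choices matter here:

* **Division-free left tensor.** The new left tensor is rebuilt by
  contracting the *unweighted* two-site tensor with the right factor
  ($B_1 = C\,V$), never by dividing the left singular vectors by the old
  $\lambda$. The division form is algebraically equivalent but amplifies
  roundoff when $\lambda$ entries are tiny; it is used in the test suite
  only as an identity check where $\lambda$ is safely large.
* **Renormalized truncation.** After truncation to
  $\min(D, \#\{\sigma > \tau\,\sigma_1\})$ values (never fewer than one),
  the retained spectrum is renormalized to unit 2-norm and the discarded
  weight $\sum_{\text{dropped}}\sigma^2$ is accumulated. Renormalization
  keeps the state normalized after every gate, which in turn keeps the
  variational bound $E \ge E_{\mathrm{FCI}}$ a testable property of every
  run. Whether to renormalize is a genuine free choice; the discarded
  weight is always logged so the fidelity loss remains visible.

Long-range two-qubit gates are compiled to nearest-neighbour form by
`compile_adjacent()`, which wraps them in there-and-back SWAP ladders
(`CNOT(0,3)` becomes `SWAP(0,1) SWAP(1,2) CNOT(2,3) SWAP(1,2) SWAP(0,1)`),
and `simplify_circuit()` then cancels adjacent inverse gate pairs — in
long ansatz circuits consecutive Pauli-exponential fragments share their
support, so most of the SWAP scaffolding annihilates. Both passes are
unitarily equivalent to the input circuit and are checked against a dense
statevector oracle implemented independently of the tensor-network code.

Qubit 0 is the leftmost MPS site and the most significant bit of dense
state indices, everywhere.

## SVD backends

The two-site re-factorization is the computational hotspot, so the SVD
backend is selectable per run:

* **reference** — the platform LAPACK routine;
* **jacobi** — a native one-sided (Hestenes) Jacobi SVD: sweeps over all
  column pairs apply plane rotations until every pair satisfies
  $|a_i^H a_j| \le \tau \lVert a_i\rVert \lVert a_j\rVert$ (default
  $\tau = 10^{-14}\sqrt{m}$, at most 30 sweeps; convergence is declared
  when a full sweep applies no rotation). The rotation parameters follow
  the classical closed forms
  $\tau = (a_i^Ta_i - a_j^Ta_j)/(2a_i^Ta_j)$,
  $t = \mathrm{sign}(\tau)/(|\tau| + \sqrt{1+\tau^2})$,
  $c = 1/\sqrt{1+t^2}$, $s = tc$, with $\mathrm{sign}(0) := +1$ (equal
  column norms get the 45-degree rotation). Complex matrices are handled
  with a phase pre-rotation on one column of the pair so the working inner
  product is real. Pair ordering within a sweep is cyclic lexicographic,
  fixed for determinism. Singular values are the converged column norms,
  U the normalized columns, V the accumulated rotations.
* **cross** — the cross-product baseline (eigendecomposition of $A^HA$
  with back-solved U). Its condition number is squared in the intermediate
  step, so singular values below $\sqrt{\varepsilon}\,\sigma_1$ lose all
  relative accuracy; the benchmark suite demonstrates this degradation on
  condition-number-$10^9$ matrices where the Jacobi backend stays accurate.

## From molecule to qubits

The chemistry layer is native to the package: contracted Cartesian
Gaussian integrals (s, p and 6d shells) via the McMurchie–Davidson scheme
with a series/downward-recursion Boys function, a DIIS-accelerated
restricted Hartree–Fock solver, and AO-to-MO transformation, with optional
active-space reduction that folds frozen orbitals into the effective
one-body term and core energy. The built-in basis sets (STO-3G, 6-31G,
6-31G(d), cc-pVDZ for H and C) cover the systems treated here; the
H2/STO-3G mean field reproduces the textbook values to the printed digits
and H2/cc-pVDZ full CI lands within basis-convention noise of published
values.

The second-quantized Hamiltonian
$\hat H = \sum h^p_q a_p^\dagger a_q + \tfrac12\sum g^{pq}_{rs}
a_p^\dagger a_q^\dagger a_r a_s$ is mapped to Pauli strings by the
Jordan–Wigner transformation in the interleaved spin-orbital ordering
($\alpha_0, \beta_0, \alpha_1, \dots$); like strings are merged and
coefficients below a cutoff (default $10^{-12}$ Hartree) dropped. The
implementation works in the $X^xZ^z$ bit-mask frame with exact phase
bookkeeping and is cross-checked against dense matrices and an independent
determinant-space (Slater–Condon) full CI oracle. Exact ground-state
energies for validation come from a matrix-free Lanczos iteration on the
qubit Hamiltonian (up to 20 qubits) with an extended-precision Rayleigh
quotient polish.

**Measurement-circuit counting.** Each non-identity Pauli term requires
one measurement circuit. For the alternating hydrogen chains the published
circuit counts are reproduced (to 1–3% across 6–50 atoms) when the
Hamiltonian is expressed over symmetrically orthogonalized (Löwdin) local
orbitals with a drop tolerance of $3\times10^{-8}$ Hartree, and
`term_count_scaling()` adopts exactly that convention; in the canonical MO
basis, spatial parity symmetry cancels roughly half the strings and the
counts come out very different. The published counts themselves grow with
a log–log slope of about 1.75 between 12 and 50 atoms, approaching the
often-quoted $N^{1.5}$ only at larger sizes; the acceptance suite asserts
agreement with the published counts and with the slope they imply, not
with the asymptotic exponent applied outside its regime.

## Ansatz construction and compilation

`build_uccsd()` enumerates all spin-conserving singles and doubles from a
closed-shell reference. Excitations related by a global spin flip share
one variational parameter; the shared partner's generator carries the
fermionic reordering parity of the flipped index pairs (a relative minus
sign whenever the occupied or virtual spatial indices coincide), which is
exactly what singlet pairing requires — without it a two-electron UCCSD
cannot reach FCI, which is the property test that guards this.

The antihermitian generators $T - T^\dagger$ are Jordan–Wigner expanded to
Pauli strings with imaginary coefficients $ic$, and each term is compiled
by the standard staircase: basis pre-rotations (H for X, $R_x(\pi/2)$ for
Y), a CNOT ladder onto the last support qubit, $R_z(-2c\theta)$, and the
inverse ladder/rotations — $2(w-1)$ CNOTs for a weight-$w$ string, and the
count identity $\mathrm{CNOTs} = \sum_P 2(w_P - 1) + 3\,\#\mathrm{SWAPs}$
is asserted in the tests. A single first-order Trotter step concatenates
the fragments in a fixed deterministic order (singles before doubles, each
sorted by orbital indices, the strings of one excitation in canonical
label order). The ordering is a free choice; for H2/STO-3G reversing it
moves the optimum by less than $10^{-6}$ Hartree, and the residual
ordering dependence is acknowledged for larger systems.

**Symmetry screening.** Optionally (`screen_ints`), double excitations
whose two-electron integral numerators $(ia|jb)$, $(ib|ja)$ both vanish
are dropped before compilation. Such amplitudes are zero by point-group
symmetry, so removing them leaves the variational minimum unchanged while
shrinking the circuit severalfold; the ethane and cc-pVDZ protocols use
this. Singles are never screened.

For hydrogen chains the package also implements the windowed
generalized-excitation pool: GSD operators over every 5 consecutive
spatial orbitals (stride 1), Jordan–Wigner transformed, every Pauli-Z
deleted, strings with an even number of Pauli-Ys discarded (the
Hamiltonian is real), deduplicated preserving first occurrence, and
compiled as a single pass $\prod_j \exp(i\theta_j P_j)$ in pool order (no
adaptive iteration).

## The VQE driver

`optimize_vqe()` minimizes the MPS-evaluated energy with BOBYQA
(derivative-free trust region; `minqa`), starting from the Hartree–Fock
point $\theta = 0$ for production runs — random starts are reserved for
the one-shot mode, which draws $\theta \sim U[-\pi,\pi]$ from a seed,
evaluates once, and reports whether the bond cap saturated. Key defaults:
initial trust radius 0.1 rad, final radius `rhoend` $10^{-6}$ (the
convergence threshold), at most $\max(300p, 10p^2)$ evaluations for $p$
parameters. For machine-precision targets a coordinate-Newton polish
(central differences, step $10^{-4}$) drives the parameters to the
quadratic minimum; with `rhoend` $10^{-10}$ plus polish the H2/STO-3G
curve agrees with FCI at the $10^{-15}$ Hartree level, which is the
roundoff floor of the energy evaluation itself (Pauli-term sums are
accumulated in extended precision for exactly this reason).

`bond_dimension_scan()` implements the bond-dimension selection rule:
optimize at each $D$ in an ascending list and select the smallest $D$ with
$|E_{D_i} - E_{D_{i+1}}| < 10^{-3}$ Hartree, slightly stricter than
chemical accuracy ($1.6\times10^{-3}$ Hartree).

## DMET

The embedding driver partitions Löwdin-orthogonalized local orbitals into
user-defined fragments (localization choice: symmetric orthogonalization
is deterministic and standard embedding practice). For each fragment the
bath comes from the SVD of the fragment block of the occupied orbitals:
entangled occupied orbitals (singular value $> 10^{-6}$) contribute their
normalized environment tails as bath orbitals — at most one per fragment
orbital — while the remaining fully-environment orbitals are frozen and
their closed-shell density folded into the embedding one-body term as
$J - K/2$. A global chemical potential $\mu$ on the fragment diagonal is
root-found (bracketed on $[-0.5, 0.5]$ Hartree, expanding on failure)
until the summed fragment electron numbers match the molecule to
$10^{-5}$; this electron-number-only self-consistency is deliberate (no
correlation-potential fitting). Fragment energies contract the measured
1- and 2-RDMs with the bare one-body integrals plus *half* the folded
environment potential, first index restricted to fragment orbitals
($P^A_{pqrs} = \langle a_p^\dagger a_q^\dagger a_r a_s\rangle$ convention,
chemists' integrals); the printed summation limits of the fragment-energy
expression are ambiguous, so the implementation is pinned instead by the
whole-molecule-fragment limit, which must (and does) reproduce the
fragment solver's full-system energy to machine precision. Fragment
solvers: dense exact ground state, or MPS-VQE — in the latter case the
embedding space is first canonicalized by an internal closed-shell RHF so
the UCCSD reference is the embedded mean-field determinant, and the RDMs
are measured as Jordan–Wigner ladder expectations and rotated back.

## Study systems and problem sizes

The generators produce every geometry used by the validation suite, and
their defaults are the study conditions: H2 dissociation grids (0.5–2.5 Å
in 0.1 Å steps, 21 points — the published grid is not printed, so this
choice is stated in every report), alternating hydrogen chains with the
six-decimal separations 0.741441/1.322943 Å, regular hydrogen rings, and
ethane with R(C–C) = 1.512 Å, R(C–H) = 1.153 Å. Only the ethane bond
lengths are published; the H–C–C angles are taken tetrahedral
(109.4712°). That assumption is the main reproduction risk for the
torsional barrier: with it, exact diagonalization in the (6e,6o)/6-31G(d)
active space gives a barrier of 0.185 eV and UCCSD-MPS-VQE matches that
to ~$10^{-5}$ Hartree per conformer, while the published reduced-space
value is 0.20 eV. The gap is a model-assumption (geometry/active-space
convention) difference, not a solver error, and the package reports the
barrier as computed. The full 32-qubit STO-3G barrier (published 0.29 eV)
is outside the desk-scale tier and is not attempted by the default suite.

Desk-scale sizes used throughout: up to 10-qubit random-circuit fuzzing
against the dense oracle, 12-qubit ethane and hydrogen-chain VQE, 20-qubit
H2/cc-pVDZ (where the determinant-CI oracle replaces dense
diagonalization), chains to 50 atoms (100 qubits) for Hamiltonian
combinatorics only. What passing these tests shows is that the simulator,
compiler, chemistry and embedding layers are internally exact or
variationally controlled at oracle scale; it does not exercise
thousand-qubit one-shot evolution, many-core parallel scheduling, or
basis sets beyond those listed.

## Known limitations

Jordan–Wigner only (no Bravyi–Kitaev/parity mappings); restricted
closed-shell references only; no point-group reduction of the excitation
list beyond the integral-based screening described above (published
variational-parameter counts that imply additional symmetry screening are
not reproduced); one-shot DMET with chemical-potential fitting only; MPS
snapshots serialize to a JSON container (documented, not a public
exchange format); the dense oracles stop at 16–20 qubits by design. The
cross-product SVD backend is intentionally present as a numerical
baseline and should not be used for production runs.
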