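---
title: "Methods: tight-binding ground states with fluctuating-charge embedding and linear-response spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tight-binding ground states with fluctuating-charge embedding and linear-response spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dftbfq)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic fixtures do and do not emulate, and the numerical choices made
where the design was genuinely open.

## 1. The ground-state model

### Tight binding with self-consistent charges

The electronic structure layer is second-order density-functional tight
binding. A minimal valence basis (s and p shells) is assumed; the
zeroth-order Hamiltonian $H^0_{\mu\nu}$ and overlap $S_{\mu\nu}$ are not
computed from a functional but read from distance-gridded two-center tables
(the `.skf` "simple" dialect) and assembled by the Slater–Koster rotation
rules. Writing the Mulliken charge fluctuation of atom $\alpha$ as
$\Delta q_\alpha = \sum_{\mu\in\alpha}(PS)_{\mu\mu} - n^0_\alpha$ (excess
*electron* population relative to the neutral atom), the total energy is

$$E = \sum_{\mu\nu} P_{\mu\nu} H^0_{\mu\nu}
    + \tfrac12 \sum_{\alpha\beta} \gamma_{\alpha\beta}
      \Delta q_\alpha \Delta q_\beta + E^{\mathrm{rep}}.$$

$\gamma_{\alpha\beta}(R)$ is the interaction of two exponentially decaying
spherical charge fluctuations with decay constants $\tau = \tfrac{16}{5}U$:
the analytic closed form $1/R$ minus a short-range exponential correction,
so that $\gamma(0) = U$ (the Hubbard parameter) and $\gamma \to 1/R$ at long
range. Both limits are asserted in the test suite. Stationarity of $E$
under the density matrix gives the self-consistent Hamiltonian

$$H_{\mu\nu} = H^0_{\mu\nu} + \tfrac12 S_{\mu\nu}
  \big[(\gamma\,\Delta q)_\alpha + (\gamma\,\Delta q)_\beta\big],
  \qquad \mu\in\alpha,\ \nu\in\beta ,$$

which the package verifies literally: a finite-difference derivative of the
implemented energy functional with respect to density-matrix elements must
reproduce every Hamiltonian element to $10^{-6}$, *including* the Mulliken
and environment chains below. That test is the arbiter of all sign
conventions in the package.

### The fluctuating-charge environment

Each classical atom carries a charge $q_i$ with an electronegativity
$\chi_i$ (hartree/e) and chemical hardness $\eta_i$ (hartree/e²). Charges
minimize

$$F(q,\lambda) = \chi\cdot q + \tfrac12 q^{\mathsf T} J q + q\cdot V
  + \sum_f \lambda_f \Big(\sum_{i\in f} q_i - Q_f\Big),$$

one Lagrange multiplier per molecular fragment fixing its total charge
$Q_f$. At the minimum the instantaneous electronegativity
$\chi_i + (Jq)_i + V_i$ is constant within each fragment —
electronegativity equalization — which the suite checks on every solve.
The stationary conditions form a symmetric KKT system
$M\,[q;\lambda] = [-(\chi+V);\,Q]$; $M$ depends on geometry only and is
factorized once per frame, with the right-hand side updated along the SCF.

The off-diagonal kernel $J(r)$ is a genuine design choice; we adopt
the **Ohno form**
$J_{ij}(r) = \bar\eta\,/\sqrt{1+\bar\eta^2 r^2}$, $\bar\eta =
(\eta_i+\eta_j)/2$ — the standard choice of the charge-equilibration
literature: finite (equal to the hardness) at contact and Coulombic at long
range. A bare-Coulomb kernel is available behind the `kernel` selector for
analytic cross-checks. All MM–MM pairs interact, also across fragments
(standard FQ practice; only the *constraints* are per-fragment).

### The QM–MM bridge

The density fluctuation of a QM atom is contracted to a point Mulliken
charge, so the QM–MM kernel is bare Coulomb $1/r$, with a hard floor at
0.5 bohr (closer contact means the partition has put an MM atom inside the
QM region — an input error, not a regime to damp through). An Ohno-damped
variant is available behind `embedding.kernel` for robustness studies.

Two sign conventions meet here and are easy to get wrong: $\Delta q$ counts
excess *electrons*, while $q_i$ are true charges. The potential the QM
region generates at MM site $i$ is therefore
$V_i = \sum_\alpha (-\Delta q_\alpha)/r_{\alpha i}$, and the embedding
potential $v_{\mathrm{emb},\alpha} = \sum_i q_i/r_{\alpha i}$ of the FQ
charges enters the electron Hamiltonian with a **minus** sign:

$$H_{\mu\nu} \mathrel{+}= -\tfrac12 S_{\mu\nu}
 (v_{\mathrm{emb},\alpha}+v_{\mathrm{emb},\beta}).$$

This is the unique pair of signs under which the finite-difference
Hamiltonian oracle passes; with it, the coupled SCF minimizes the joint
functional in $(P, q)$, and the coupled total energy is variationally below
the frozen-environment ($q=0$) energy — also asserted.

Because the QM–MM interaction uses only the potential of the *fluctuation*
$\Delta q$ (not the reference density), absolute solvation energies exclude
a permanent-core electrostatic contribution; solvent *shifts* of
excitations, the quantity the method targets, are unaffected.

The FQ system is re-solved every SCF cycle from the current (not yet
converged) $\Delta q$ — the fully self-consistent "charges-in-SCF" scheme.
At convergence the state is self-consistent both ways: re-solving FQ moves
no charge, rebuilding the Hamiltonian moves no orbital energy (tested).

## 2. Linear response

Excitations are obtained in the Casida formalism over the single-orbital
transition basis $(i,a)$ with Mulliken transition charges
$q^{ia}_\alpha = \tfrac12\sum_{\mu\in\alpha}
[c_{\mu i}(Sc_a)_\mu + c_{\mu a}(Sc_i)_\mu]$. The coupling matrix uses the
ground-state $\gamma$ (the usual approximation for systems without strong
charge transfer):

$$K_{ia,jb} = \sum_{\alpha\beta} q^{ia}_\alpha\,\gamma_{\alpha\beta}\,
  q^{jb}_\beta .$$

The environment contributes the screening of each transition density by the
relaxing FQ charges,

$$K^{\mathrm{FQ}}_{ia,jb} = -(V^{ia})^{\mathsf T} M^{-1} V^{jb},
  \qquad V^{ia}_i = \sum_\alpha q^{ia}_\alpha / r_{\alpha i},$$

with zeros on the constraint rows of the KKT solve: fragment total charges
cannot change in response. $K^{\mathrm{FQ}}$ is negative semidefinite on
that subspace — the polarizable environment can only stabilize a transition
density — which is why the FQ layer systematically red-shifts
diagonal-dominant excitations. The implementation realizes it with one
factorized solve per transition-basis column and is pinned by two
independent oracles: the dense KKT inverse, and direct numerical
minimization of the charge functional under the perturbing potential.

Since the coupling enters the $A$ and $B$ response blocks identically
(singlet response, no exact exchange), $A-B$ is diagonal and the default
solver is the half-size Hermitian form

$$\big[\Delta\varepsilon^2
  + 4\sqrt{\Delta\varepsilon}\,(K+K^{\mathrm{FQ}})\,
  \sqrt{\Delta\varepsilon}\big]F = \omega^2 F .$$

The full two-block non-Hermitian solver is retained behind
`response.solver = "full"` purely as a cross-check; the suite requires
agreement to $10^{-9}$ on ensembles of randomly jittered systems. A
negative $\omega^2$ root is reported as an instability, never silently
clipped.

**Oscillator strengths.** Transition dipoles are point-charge (Mulliken)
dipoles, consistent with the monopole treatment everywhere else:
$\mu_I = \sum_\alpha R_\alpha q^I_\alpha$ with
$q^I = \sum_{ia}\sqrt{\Delta\varepsilon_{ia}/\omega_I}\,F^I_{ia}\,q^{ia}$,
and $f_I = \tfrac23\,\omega_I\,|\mu_I|^2$ in atomic units. This
normalization is chosen so the independent-particle limit reproduces the
single-orbital $f_{ia} = \tfrac23\Delta\varepsilon_{ia}|d_{ia}|^2$ used by
the intensity filter; it omits the spin factor some codes fold in, which is
immaterial for the (normalized) spectra the package produces and is stated
here so absolute intensities are interpreted correctly.

**Intensity selection.** The transition basis may be truncated to pairs
with single-orbital oscillator strength above a threshold before the
response solve (`response.f_threshold`, default 0 = no filter). Threshold
sets are nested, so retained bases are contained in one another and, by
eigenvalue interlacing, every retained root decreases monotonically toward
its unfiltered value as the threshold goes to zero — both asserted. An
empty retained basis is an error advising a lower threshold, not a silent
fallback.

## 3. Spectra and convergence diagnostics

Stick spectra (excitation energy in eV, oscillator strength) are convolved
with **area-normalized Gaussians**: $\sigma = \mathrm{fwhm}/(2\sqrt{2\ln2})$,
each stick scaled by its $f$, so the integral over a wide-enough grid equals
the summed oscillator strength (checked to 1%) and the intensity unit is
oscillator strength per eV. Default fwhm 0.3 eV; grid 1–8 eV in 0.005 eV
steps, all overridable. A grid that fails to cover every stick by
$3\sigma$ triggers a warning, since area is then silently truncated.

Frame averaging is the pointwise mean of the **raw** per-frame spectra;
max-normalization, when requested, is applied after averaging (average
first, normalize last — the other order weights noisy weak frames up; a
switch is deliberately not hidden in the default path, both orders are
available via `normalize_spectrum()`).

Convergence of ensemble quantities (e.g. the first excitation energy per
frame) is monitored with running means and Student-t confidence intervals
(default level 0.99, normality assumed — the construction is a package
choice, stated rather than inherited). The half-width must shrink as
$n^{-1/2}$; the suite fits the log–log slope over $10^4$ synthetic Gaussian
frames and requires $-0.5 \pm 0.1$.

## 4. The toy fixture world

Nothing in the package requires external parameter files. The fixtures
module generates:

* **Toy `.skf` tables** — smooth analytic channel shapes
  $V(r) = c\,e^{-\zeta r}(1 + r/2)$ with element-wise prefactors and decay
  constants, written in the simple dialect and read back by the ordinary
  parser (round-trip asserted to $10^{-12}$). The defaults (hydrogen-like
  s element, oxygen-like s+p element; decays ≈ 1.4–1.5 bohr⁻¹, table to
  19 bohr) were fixed so that the toy water chromophore is closed-shell,
  the overlap matrix stays positive definite at bonding distances, the
  integrals decay below $10^{-10}$ at the table end, and the bright
  excitation lands in the visible/UV window where solvated chromophores
  absorb. The repulsive block stores the exact cubic $k(r_c-r)^3$ as its
  spline, so spline evaluation is testable against a closed form.
* **Water clusters** — one rigid 3-site water (the QM chromophore stand-in)
  surrounded by $n$ rigid waters placed by seeded rejection sampling with a
  2.5 bohr intermolecular floor; each solvent water is one MM fragment with
  $Q=0$.
* **Snapshot ensembles** — per-atom Gaussian jitter (default σ = 0.05 bohr)
  around the base frame; frame 0 is the unjittered base. The default
  amplitude produces sub-0.03 Å displacements: enough to break symmetry and
  broaden the ensemble spectrum, small enough never to re-bond the cluster.

What the fixtures *emulate*: the layered solute/solvent partition, the
configurational broadening of ensemble spectra, the mutual-polarization red
shift. What they do *not* emulate: real electronic structure (the channel
shapes are not fits to any published parameter set), liquid-state solvent
structure (rejection-sampled placement is not molecular dynamics), and
anharmonic/vibronic structure. Passing tests therefore demonstrate the
correctness of the machinery — limits, symmetries, variational identities,
oracle agreement — not the accuracy of any published parameterization on
real chromophores.

The FQ parameter set shipped for the fixtures (χ_O = 0.18, χ_H = 0.02,
η_O = 0.60, η_H = 0.65 a.u.) is of the magnitude used by
charge-equilibration water models and is a documented toy set, editable in
the config; no claim is made of reproducing any published FQ
parameterization.

## 5. Numerical choices

* **Table interpolation**: local cubic through the 4 grid points nearest
  the query distance; exact at grid nodes, $O(h^4)$ off-grid. Distances
  beyond the table evaluate to exactly 0 — the tables are built to decay,
  and extrapolation artifacts are worse than a hard tail.
* **SCF**: linear mixing on $\Delta q$ (default 0.2); convergence requires
  both max $|\Delta q|$ change < 1e-7 and energy change < 1e-9 hartree
  (defaults chosen so the property tests are insensitive to tightening);
  hard cap 200 iterations, with the iteration history attached to the
  non-convergence error. Aufbau double occupation only; odd electron
  counts are rejected up front.
* **Generalized eigenproblem**: Cholesky reduction of $S$ followed by a
  dense symmetric `eigen()`; appropriate at desk scale and free of
  iterative-solver tolerances.
* **FQ solve**: one pivoted factorization of the KKT matrix per frame,
  reused for every SCF cycle and every response column; coincident MM
  sites are detected and reported by atom pair before factorization.
* **Units**: atomic units internally, everywhere; Å and eV only at file
  boundaries, through a single constants table whose inversions are tested
  to machine precision. Atom indices are 1-based both in partition files
  (chemistry convention) and in R.
* **Problem sizes**: the shipped tests and the acceptance script run on
  clusters of ≤ 11 molecules, 20-frame ensembles, and ≤ 100 requested
  states capped by the toy basis (8–72 single-orbital pairs). These sizes
  were chosen as the smallest at which every asserted property is
  non-trivial (ensembles broad enough for CI scaling, bases large enough
  for filter-convergence sequences).

## 6. Known limitations

s/p shells only (no d rotations); closed-shell singlets; no third-order
charge term; electrostatic-only coupling — no Pauli repulsion or
dispersion between layers, so short-contact partitions rely on the kernel
floor rather than physics; no forces, no periodicity; the transition
dipole is monopole-based, so intensities of Rydberg-like or very diffuse
states are outside the model's reach. Absolute solvation energies exclude
the permanent-core electrostatic term by construction (see §1).
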