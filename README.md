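# dftbfq

Absorption spectra of solvated chromophores from a polarizable QM/MM method:
a **self-consistent-charge density-functional tight-binding (SCC-DFTB)**
ground state mutually polarized with a classical **fluctuating-charge (FQ)**
environment, extended to **linear response** (Casida formalism) and to
ensemble-averaged spectra over snapshot geometries.

The package is aimed at method developers and students of polarizable
embedding: every ingredient — Slater–Koster assembly, charge equilibration,
the QM↔MM electrostatic bridge, the response coupling, spectral
post-processing — is an inspectable R function with property-based tests,
and a deterministic toy-fixture generator makes the whole pipeline runnable
without any external parameter set.

## The model

**Ground state.** In SCC-DFTB the valence density is expanded about a
reference density; the energy to second order in the atomic Mulliken charge
fluctuations Δq is

```
E = Σ_μν P_μν H⁰_μν  +  ½ Σ_αβ γ_αβ Δq_α Δq_β  +  E_rep
```

where `H⁰` and the overlap `S` come from distance-tabulated two-center
integrals (.skf tables, rotated by the Slater–Koster rules), `γ_αβ` is the
charge-fluctuation kernel (on-site limit = Hubbard U, Coulomb tail 1/R) and
`E_rep` is a short-range pair repulsion.

**FQ environment.** Each classical atom carries a charge `q_i` with
electronegativity χ and hardness η; charges equilibrate by minimizing

```
F(q, λ) = χ·q + ½ qᵀ J q + q·V + Σ_f λ_f (Σ_{i∈f} q_i − Q_f)
```

(`J` = Ohno-shielded Coulomb kernel, `V` = potential of the QM Mulliken
charges at the FQ sites). The resulting charges re-enter the DFTB
Hamiltonian through a point-charge embedding potential: mutual polarization,
iterated to joint self-consistency inside the SCF.

**Response.** Excitations come from the Casida problem with Mulliken
transition charges `q^ia`, the γ coupling
`K_{ia,jb} = Σ_αβ q^ia_α γ_αβ q^jb_β`, and the FQ screening correction
`K^FQ = −Vᵀ M⁻¹ V` (negative semidefinite: the polarizable environment can
only stabilize transition densities). Oscillator strengths use point-charge
transition dipoles; sticks are convolved with area-normalized Gaussians
(fwhm, default 0.3 eV) and averaged over snapshot ensembles with Student-t
confidence-interval convergence diagnostics.

## Worked example

Generate a self-contained toy workspace (one QM water as chromophore
stand-in, 10 FQ waters, 20 jittered snapshots), run the coupled ground state
and the ensemble spectrum:

```r
library(dftbfq)
ws  <- make_fixture_workspace("demo", n_solvent = 10, n_frames = 20, seed = 1)
rep <- run_ground(ws)
rep$energies_hartree
#> total -4.161768 = band -3.833692 + gamma2 0.020423 + repulsive 0.162340
#>                  + fq -0.504471 + coupling -0.006367      (32 SCF cycles)

res <- run_spectrum(ws)
res$spectrum$grid_ev[which.max(res$spectrum$intensity)]
#> 4.470        # ensemble band maximum, eV
tail(res$convergence, 1)
#>  n mean_first_energy_ev ci99_energy_ev
#> 20             1.658232     0.04882519
```

`band` is the zeroth-order electronic energy, `gamma2` the second-order
charge-fluctuation term, `fq` the internal energy of the equilibrated
solvent charges and `coupling` the QM–MM electrostatic interaction — its
negative sign, and the red shift of the bright band relative to the bare
solute (−0.04 eV on this workspace), are the mutual-polarization effects the
method exists to capture. Per-frame stick spectra, the averaged profile and
the convergence table are written as CSV into the workspace's `out/`
directory.

A thin command-line driver with `ground`, `spectrum`, `fixtures` and
`selftest` subcommands ships in `inst/cli/dftbfq.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dftbfq.R", package="dftbfq"))')" selftest
```

## Scope and limits

s/p shells only (H, C, N, O class elements); closed-shell singlets;
electrostatic-only QM–MM coupling (no Pauli repulsion or dispersion); no
third-order (DFTB3) term, spin polarization, gradients or periodic systems.
See the methods vignette (`vignettes/dftb-fq-methods.Rmd`) for the model
derivation, numerical choices and known limitations.
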