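---
title: "Quasiparticle self-consistent GW-BSE: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasiparticle self-consistent GW-BSE: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gwbse` computes charged (quasiparticle) and neutral (optical) excitations of
closed-shell molecules from many-body perturbation theory. The chain is

1. **Mean field.** A restricted HF or Kohn–Sham determinant defines orbitals
   $\phi_n$ and energies $\varepsilon_n$. Supported references: HF, LDA
   (Slater exchange + PW92 correlation), PBE, and PBEH40 (PBE with the
   exact-exchange fraction raised to 0.40). PBEH40 is the default qsGW
   starting point because its eigenvalue spectrum is already close to the
   qsGW fixed point, which shortens the self-consistency.

2. **Screening.** The RPA polarizability is assembled in imaginary time from
   the resolution-of-identity (RI) representation of the Coulomb interaction,
   $$P_{PQ}(i\tau) = -2\sum_{ia} B^P_{ia} B^Q_{ia}
     e^{-(\varepsilon_a-\varepsilon_i)|\tau|},$$
   cosine-transformed to the imaginary-frequency axis, and screened through
   the Dyson equation $W(i\omega) = (1 - vP(i\omega))^{-1}v$. In the
   orthonormalized Coulomb-metric auxiliary space used throughout, $v$ is the
   identity. The zero-frequency interaction entering the BSE kernel is
   obtained by quadrature of the imaginary-time polarizability,
   $P(0) = \int d\tau\, P(i\tau)$, followed by the same Dyson inversion.

3. **Self-energy.** $\Sigma = iGW$ is evaluated in the space-time fashion:
   $W(i\tau)-v$ by an inverse cosine transform, then particle and hole
   branches
   $$\Sigma^{p/h}_{pq}(\tau) = \sum_{m\in \mathrm{virt/occ}}
     e^{-|\varepsilon_m-\mu|\tau}\, \big[\mathbf B_m^\top\,
     (W(i\tau)-v)\,\mathbf B_m\big]_{pq},$$
   with $\mu$ the mid-gap chemical potential. Even/odd combinations are
   sine/cosine transformed to $\Sigma_c(i\omega)$; the exchange part
   $\Sigma_x$ is static.

4. **Quasiparticles.**
   * *G0W0 / evGW*: the diagonal self-energy is analytically continued to the
     real axis (conjugate-symmetrized Thiele continued fraction) and the
     quasiparticle equation
     $\varepsilon = \varepsilon_{\rm ref} + \Sigma_x + \mathrm{Re}\,
     \Sigma_c(\varepsilon) - v_{xc}^{\rm eff}$ is solved by Newton iteration,
     with the linearized ($Z$-factor) solution as start and fallback. evGW
     repeats this, rebuilding the screening from the updated energies, until
     the HOMO moves by less than 3 meV between cycles; the first cycle is
     exactly G0W0.
   * *qsGW*: the static Hermitian effective Hamiltonian
     $$H_{\rm eff} = h + J[D] + \Sigma_x[D] +
       \tfrac12\big(\Sigma_c(0) + \Sigma_c(0)^\top\big)$$
     is diagonalized and rebuilt — orbitals, density, screening and
     self-energy all refresh each cycle — until the density matrix is
     stationary. This is the "static limit + discard the anti-Hermitian
     part" construction; its fixed point does not depend on the mean-field
     starting functional, which the acceptance script verifies directly.

5. **BSE.** With quasiparticle energies and the static screened interaction,
   the singlet particle-hole problem
   $$A_{ia,jb} = \delta_{ij}\delta_{ab}(\varepsilon_a-\varepsilon_i)
     + 2(ia|jb) - W_{ij,ab}(0),\qquad
     B_{ia,jb} = 2(ia|jb) - W_{ib,aj}(0)$$
   is solved for the lowest roots of the paired eigenproblem
   $(A\pm B)$ by a matrix-free Davidson algorithm. Replacing $W\to v$ on an
   HF reference reproduces TD-HF exactly — this limit pins every spin and
   prefactor convention against an independently constructed dense TD-HF and
   is enforced in the test-suite rather than assumed.

6. **Analysis.** Length-gauge oscillator strengths
   $f_S = \tfrac23\,\Omega_S \sum_{u}\big|\sqrt2\sum_{ia}(X+Y)_{ia}
   d^u_{ia}\big|^2$ (dipole origin at the center of nuclear charge),
   dominant transitions with weights $X_{ia}^2$ under the normalization
   $\sum(X^2-Y^2)=1$ (an $|X+Y|^2$ variant is available via
   `weightType = "xpy2"`), and fragment-resolved exciton character from
   Löwdin populations of the hole and electron orbitals. A state is labeled
   CT when the off-diagonal (hole fragment ≠ electron fragment) weight
   exceeds 0.5 (configurable), local when the diagonal weight does.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `nGridPoints` | 16 | — | imaginary time and frequency nodes |
| `epsS` | 5e-3 | — | relative Coulomb-metric eigenvalue cutoff of the RI |
| `qsgwConvDensity` | 5e-9 | — | Frobenius stationarity of the density matrix |
| `evgwConvHomo` | 3 meV | Ha internally | evGW stop on the HOMO change |
| `davidsonTol` | 1e-5 | Ha | per-root eigenvalue convergence of the BSE solver |
| `phCutoff` | Inf | Ha | particle-hole transition-energy cutoff (1.5 is the large-system setting) |
| `mixing` | 0.3 | — | linear fallback mixing of H_eff |
| `accel` | "diis" | — | qsGW accelerator |

# Numerical choices

**Imaginary grids.** Nodes and weights are exponential-sum quadrature rules
optimized per energy range: geometric initialization, derivative-free search
over (offset, ratio), then an iteratively reweighted Levenberg–Marquardt
polish toward the minimax solution, with collapsed nodes respawned in the
widest gap. Transform matrices (cos/sin time→frequency, cos frequency→time)
are per-row Lawson (reweighted least-squares) fits of the analytic kernel
pair $e^{-\Delta\tau} \leftrightarrow 2\Delta/(\Delta^2+\omega^2)$. Every
rule and transform stores a *certified* maximum error measured on a dense
verification mesh that is independent of the fit mesh; downstream tests
compare routes at multiples of these certified errors instead of guessed
tolerances. At 16 points the time quadrature reaches a relative error below
1e-6 over three decades of transition energies.

**Grid energy range.** The self-energy integrand carries products of
Green's-function and screened-interaction poles, so the certified range must
cover $|\varepsilon-\mu| + \Omega_m$ and not merely the particle-hole gaps; a
Gershgorin bound on the direct-RPA pole energies extends the upper limit.
Ranges are padded, log-rounded and cached so that all four starting points of
a starting-point-independence experiment share identical rules.

**Analytic continuation.** The Thiele continued fraction is built on the
conjugate-symmetrized node set ($\Sigma(\bar z)=\bar\Sigma(z)$), which
substantially reduces the sensitivity of real-axis evaluations to the
few-parts-in-10^6 noise the grid transforms leave in $\Sigma_c(i\omega)$;
exactly rational or constant inputs terminate the fraction early and are
reproduced to machine precision. Degenerate continued-fraction steps trigger
one node-thinning retry before raising an error.

**Integrals.** One- and two-electron integrals over contracted Cartesian
Gaussians are evaluated by McMurchie–Davidson recursions in C++ with a
downward/upward stable Boys function. AO normalization is taken from the raw
overlap diagonal, which normalizes every Cartesian component exactly. The
SCF uses exact four-center integrals (the systems in scope are small); RI
enters in the screening and correlation machinery. The exchange self-energy
and Hartree term inside the GW loops also use exact integrals, which makes
the $W\!\to\!v$ limit of qsGW coincide with HF to machine accuracy. The
auxiliary basis is an even-tempered family per atom (`auto-basic`/`good`/
`verygood` with progression 3.0/2.5/2.0); metric eigenvalues below
`epsS` times the largest are discarded, which removes near-linear
dependencies while keeping the fitted interaction positive semidefinite.

**Kohn–Sham quadrature.** Becke-partitioned atomic grids
(Murray–Handy–Laming radial maps, Gauss–Legendre × uniform spherical product
shells, 50 radial × 288 angular points per atom). The xc potential matrices
are built from the functional energy densities via fourth-order central
finite differences in $(\rho, |\nabla\rho|^2)$ — a robustness choice that
keeps the functional definitions short; the differentiation error
(~1e-10 relative) is far below the grid error.

**Degeneracies.** The SCF initial guess fills degenerate orbital groups
evenly — plain aufbau through a degenerate shell (the N2 π system) otherwise
locks the SCF into a symmetry-broken, higher-energy solution. The Davidson
solvers track three roots beyond the requested window so interior members of
degenerate multiplets cannot be silently skipped; initialization is
deterministic (lowest-gap unit vectors), there is no randomness anywhere in
the solvers, and subspaces are thick-restarted from the current Ritz vectors
when they exceed 20× the tracked roots.

**qsGW convergence.** DIIS (Pulay) extrapolation on $H_{\rm eff}$ is the
default accelerator; plain linear mixing (0.3) is the fallback and remains
available via `accel = "linear"`, but needs several times more cycles at the
5e-9 density threshold. Convergence is declared on the stationarity of the
*unaccelerated* map — the distance between the current density and the
density the bare $H_{\rm eff}$ would produce — with an internal safety factor
0.4, so that one further raw cycle provably stays below the nominal 5e-9
threshold even when the raw map is only marginally contractive. A secondary
criterion (max eigenvalue change < 1e-7 Ha) guards symmetry-locked densities
such as minimal-basis H2, whose density is stationary from the first cycle
while the spectrum still moves.

**Effective xc bookkeeping.** `MeanFieldSolution` stores the pure
density-functional part of the xc matrix (zero for HF) and the
exact-exchange fraction $a$ separately; quasiparticle equations subtract
$v_{xc}^{\rm eff} = v_{xc} + a\,\Sigma_x$. This keeps both limits exact: for
HF the correction reduces to $\Sigma_c$, for pure functionals to
$\Sigma_x + \Sigma_c - v_{xc}$.

# What the fixtures do and do not show

The built-in fixtures (H2, a 100 Å-separated H2 dimer, H2O/6-31G, N2,
ethylene, formaldehyde; deterministic hardcoded geometries) exercise every
code path: degenerate multiplets (N2), charge-transfer vs local block
structure (the far dimer), symmetry-forced dark states, and the
starting-point-independence experiment (water from LDA/PBE/PBEH40/HF).
They are small — tens of basis functions, tens to ~50 particle-hole pairs —
so passing tests demonstrate *correctness of the formalism and its numerics*,
not accuracy for chromophore-scale systems: minimal bases exaggerate
particle-hole truncation effects (the 1.5 Ha cutoff shifts the lowest water
excitation by ~0.1 eV here, where in extended π systems the same cutoff is a
10–20 meV effect), and absolute excitation energies in STO-3G/6-31G carry
basis-set errors of an eV scale. For the exactly degenerate far-dimer pair of
local excitations, any eigensolver may return delocalized symmetric/
antisymmetric combinations; the non-interacting-limit test therefore asserts
block purity (purely local or purely CT weight ≥ 0.99), which is the
physically meaningful statement.

# Problem sizes

The test-suite and the acceptance script run water/6-31G (13 basis functions,
40 particle-hole pairs, ~170 retained auxiliary functions) through four full
qsGW-BSE chains, dense-oracle comparisons on all fixtures up to ~50 pairs,
and a 200-pair randomized paired eigenproblem against dense diagonalization.
These sizes were chosen so that every iterative result can be cross-checked
against an exact dense or sum-over-states route in the same run.

# Limitations

* Closed shells only; open-shell inputs are rejected, never spin-averaged.
* Gaussian bases built in for H, C, N, O (STO-3G, 6-31G); no relativistic
  corrections — appropriate for the light-element fixtures.
* RPA screening only (no vertex), static BSE kernel, no solvation or
  environment embedding, no geometry optimization.
* The dense oracles refuse systems beyond 500 particle-hole pairs by design;
  they are a verification surface, not a production path.
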