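# gwbse — quasiparticle self-consistent GW and Bethe–Salpeter excited states in R

`gwbse` computes optical excitation energies of small closed-shell molecules
with many-body perturbation theory, for people who want a self-contained,
inspectable implementation of the full qsGW-BSE chain rather than a black box:

1. a restricted HF or Kohn–Sham reference (LDA, PBE, or the 40 %-exact-exchange
   hybrid PBEH40) from a built-in Gaussian integral engine
   (McMurchie–Davidson, Rcpp);
2. quasiparticle energies from the GW approximation, Σ = iGW, in three
   flavours: one-shot G0W0, eigenvalue-self-consistent evGW, and
   quasiparticle self-consistent qsGW;
3. singlet neutral excitations from the static-kernel Bethe–Salpeter equation
   (BSE) solved by a matrix-free paired Davidson algorithm;
4. oscillator strengths, dominant particle–hole transitions, and
   fragment-resolved local vs charge-transfer exciton character.

The GW part uses the low-scaling space-time formulation: the RPA
polarizability is assembled in imaginary time,
P(iτ) = −2 Σᵢₐ Bᵢₐ Bᵢₐᵀ e^−(εₐ−εᵢ)|τ|, cosine-transformed to the imaginary
frequency axis, screened through the Dyson equation W(iω) = (1 − vP)⁻¹ v, and
contracted with the Green's function into Σc(iτ). Quadrature nodes, weights
and transform matrices are least-squares-optimized exponential-sum rules with
measured ("certified") error bounds. For G0W0/evGW the diagonal self-energy is
continued to the real axis with a conjugate-symmetrized Thiele/Padé model; for
qsGW the static Hermitian effective Hamiltonian

    H_eff = h + J[D] + Σx[D] + ½(Σc(0) + Σc(0)ᵀ)

is re-diagonalized (DIIS-accelerated) until the density matrix is stationary
to 5×10⁻⁹ (Frobenius). The converged result is independent of the mean-field
starting point; removing that dependence is the point of the method.
Two-electron integrals enter through global resolution-of-identity density
fitting with an even-tempered auxiliary basis, regularized by discarding
Coulomb-metric eigenvalues below ε_s = 5×10⁻³ of the largest.

## Worked example

```r
library(gwbse)

fx <- makeFixture("h2o")                       # built-in geometry + basis
res <- runGWBSE(fx$molecule, basis = fx$basis, # 6-31G
                reference = "PBEH40", method = "qsgw", nRoots = 6)
res$qp
#> QPSolution [qsGW]: HOMO-LUMO gap = 17.9722 eV, 18 iterations, converged
print(res$report)
#> Exciton report [BSE], 6 states
#> S1     9.1590 eV  f =  0.01569  local    5->6 (1.00)
#> S2    11.4860 eV  f =  0.00000  local    5->7 (0.99)
#> S3    11.8087 eV  f =  0.12013  local    4->6 (0.99)
#> S4    14.2980 eV  f =  0.10597  local    4->7 (0.97)
#> S5    16.2094 eV  f =  0.42915  local    3->6 (0.97)
#> S6    19.9037 eV  f =  0.25427  local    3->7 (0.97)
```

Each line is one singlet exciton: energy Ω in eV, length-gauge oscillator
strength f, local/CT classification from Löwdin fragment populations, and the
dominant occupied→virtual transitions with their normalized X² weights (here
state S1 is the HOMO→LUMO excitation, as expected for water).

A thin command-line wrapper drives the same pipeline from a shell:

```sh
Rscript inst/cli/gwbse.R --xyz mol.xyz --basis sto-3g --reference PBEH40 \
        --method qsgw --out run      # writes run_spectrum.csv, run_report.json
```

## Scope

Closed-shell molecules, Gaussian bases (built-in STO-3G and 6-31G for H/C/N/O),
non-relativistic, gas phase. Geometry optimization, solvation, open shells,
periodic systems and beyond-RPA vertex corrections are out of scope. The
methods vignette (`vignettes/qsgw-bse.Rmd`) documents the model, the numerical
choices and the limitations in detail.
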