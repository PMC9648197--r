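Package: gwbse
Title: Quasiparticle Self-Consistent GW and Bethe-Salpeter Excited States for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular excited-state calculations for small closed-shell molecules
    by many-body perturbation theory: G0W0, eigenvalue-self-consistent GW (evGW)
    and quasiparticle self-consistent GW (qsGW) quasiparticle energies built on a
    low-scaling imaginary-time/imaginary-frequency formulation of the random-phase
    approximation screening, followed by the static-kernel Bethe-Salpeter equation
    (BSE) for singlet neutral excitations, solved with a matrix-free paired Davidson
    algorithm.  Includes a self-contained Gaussian-integral engine
    (McMurchie-Davidson), restricted Hartree-Fock and Kohn-Sham references (LDA,
    PBE, PBEH40), global resolution-of-identity density fitting with Coulomb-metric
    regularization, Pade analytic continuation of the self-energy, oscillator
    strengths, and fragment-resolved local versus charge-transfer exciton analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
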