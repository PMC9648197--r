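# Central S4 data model.  Heavy numerical payloads (three-index tensors, grids
# of matrices) live in plain list/array slots; validity methods check the
# structural invariants that downstream algebra relies on.

#' Molecule: atoms, Cartesian coordinates and charge state
#'
#' Coordinates are stored in Angstrom; all integral routines convert to atomic
#' units internally.  Only closed-shell molecules (multiplicity 1, even number
#' of electrons) are representable.
#'
#' @slot symbols element symbols, one per atom
#' @slot coords numeric matrix (n_atoms x 3), Angstrom
#' @slot charge integer total charge
#' @slot multiplicity integer spin multiplicity, must be 1
#' @export
setClass("Molecule", representation(
  symbols = "character", coords = "matrix",
  charge = "integer", multiplicity = "integer"))

setValidity("Molecule", function(object) {
  if (nrow(object@coords) != length(object@symbols))
    return("number of coordinate rows must equal number of symbols")
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (object@multiplicity != 1L)
    return("only closed-shell molecules (multiplicity 1) are supported")
  ne <- sum(elementZ(object@symbols)) - object@charge
  if (ne %% 2 != 0) return("electron count must be even for a closed shell")
  TRUE
})

#' Basis specification
#' @slot primaryName primary (orbital) basis identifier
#' @slot auxiliaryName auxiliary fitting basis identifier ("auto" for the
#'   even-tempered set generated from the primary basis)
#' @slot frozenCore logical; freeze core orbitals in correlated steps
#' @export
setClass("BasisSpec", representation(
  primaryName = "character", auxiliaryName = "character",
  frozenCore = "logical"))

#' Converged mean-field (HF or Kohn-Sham) reference
#'
#' @slot moCoeff AO -> MO coefficient matrix (columns orthonormal under the
#'   overlap metric)
#' @slot moEnergy orbital energies, Hartree
#' @slot occupations 0/2 occupation numbers per MO
#' @slot fock AO-basis Fock/Kohn-Sham matrix
#' @slot vxc AO-basis xc-potential matrix, density-functional part only
#'   (zero matrix for HF); the exact-exchange admixture is carried separately
#'   in \code{exchangeFraction}
#' @slot exchangeFraction fraction of exact exchange in the reference
#'   (1 for HF, 0.4 for PBEH40, 0 for LDA/PBE)
#' @slot referenceTag one of HF, LDA, PBE, PBEH40
#' @slot energy total SCF energy, Hartree
#' @slot backend integral context (basis, overlap, core Hamiltonian, ERI
#'   machinery) reused by all downstream modules
#' @export
setClass("MeanFieldSolution", representation(
  moCoeff = "matrix", moEnergy = "numeric", occupations = "numeric",
  fock = "matrix", vxc = "matrix", exchangeFraction = "numeric",
  referenceTag = "character", energy = "numeric", backend = "list"))

setValidity("MeanFieldSolution", function(object) {
  if (!object@referenceTag %in% c("HF", "LDA", "PBE", "PBEH40"))
    return("referenceTag must be HF, LDA, PBE or PBEH40")
  if (!all(object@occupations %in% c(0, 2)))
    return("occupations must be 0 or 2 (restricted closed shell)")
  S <- object@backend$S
  if (!is.null(S)) {
    dev <- max(abs(crossprod(object@moCoeff, S %*% object@moCoeff) -
                   diag(ncol(object@moCoeff))))
    if (dev > 1e-8) return("MO coefficients not orthonormal under overlap")
  }
  TRUE
})

#' Atom-to-fragment partition for exciton character analysis
#' @slot atomToFragment character vector, fragment label per atom
#' @slot fragmentLabels ordered unique labels
#' @export
setClass("FragmentPartition", representation(
  atomToFragment = "character", fragmentLabels = "character"))

setValidity("FragmentPartition", function(object) {
  if (!all(object@atomToFragment %in% object@fragmentLabels))
    return("every atom label must appear in fragmentLabels")
  TRUE
})

#' Three-center resolution-of-identity tensor in the orthonormalized
#' Coulomb-metric auxiliary space
#'
#' \code{bTensor[P, p, q]} satisfies (pq|rs) ~ sum_P B[P,p,q] B[P,r,s]; in this
#' representation the bare Coulomb interaction is the identity matrix over the
#' retained auxiliary directions.
#'
#' @slot bTensor array (n_aux_kept x nbf x nbf)
#' @slot nAuxKept retained auxiliary dimension after metric thresholding
#' @slot metricSpectrum eigenvalues of the raw Coulomb metric
#' @slot epsS relative eigenvalue threshold used for the truncation
#' @export
setClass("FittedIntegrals", representation(
  bTensor = "array", nAuxKept = "integer", metricSpectrum = "numeric",
  epsS = "numeric"))

setValidity("FittedIntegrals", function(object) {
  d <- dim(object@bTensor)
  if (length(d) != 3) return("bTensor must be a 3-index array")
  if (d[1] != object@nAuxKept) return("leading dimension must equal nAuxKept")
  if (d[2] != d[3]) return("orbital dimensions must agree")
  TRUE
})

#' Imaginary-time / imaginary-frequency quadrature and transform grids
#'
#' Nodes and weights are least-squares optimized so that the exponential
#' kernel exp(-delta*tau) integrates and cosine/sine-transforms accurately for
#' all transition energies delta inside \code{energyRange}.
#'
#' @slot tauPoints,tauWeights imaginary-time nodes/weights (atomic units)
#' @slot omegaPoints,omegaWeights imaginary-frequency nodes/weights
#' @slot cosTauToOmega matrix mapping f(tau_k) -> 2*Int cos(w t) f(t) dt
#' @slot sinTauToOmega matrix mapping f(tau_k) -> 2*Int sin(w t) f(t) dt
#' @slot cosOmegaToTau matrix mapping g(w_j) -> (1/pi)*Int cos(w t) g(w) dw
#' @slot energyRange covered transition-energy interval [delta_min, delta_max]
#' @slot certifiedError named numeric: measured max relative errors of the
#'   quadrature and each transform over energyRange
#' @export
setClass("ImaginaryGrid", representation(
  tauPoints = "numeric", tauWeights = "numeric",
  omegaPoints = "numeric", omegaWeights = "numeric",
  cosTauToOmega = "matrix", sinTauToOmega = "matrix",
  cosOmegaToTau = "matrix", energyRange = "numeric",
  certifiedError = "numeric"))

setValidity("ImaginaryGrid", function(object) {
  if (any(diff(object@tauPoints) <= 0) || any(diff(object@omegaPoints) <= 0))
    return("grid nodes must be strictly increasing")
  if (any(object@tauWeights <= 0)) return("tau weights must be positive")
  if (length(object@energyRange) != 2 ||
      object@energyRange[1] <= 0 ||
      object@energyRange[2] <= object@energyRange[1])
    return("energyRange must be 0 < min < max")
  TRUE
})

#' RPA polarizability and screened Coulomb interaction on the imaginary axis
#'
#' All matrices live in the orthonormalized auxiliary space of a
#' \linkS4class{FittedIntegrals}, in which the bare interaction v is the
#' identity.
#'
#' @slot pTau list of P(i tau_k) matrices (negative semidefinite)
#' @slot wOmega list of W(i omega_j) matrices
#' @slot wStatic W(omega = 0)
#' @slot vMatrix bare interaction (identity in this metric)
#' @slot meta list: grid used, quadrature-error estimate for the static limit
#' @export
setClass("ScreenedInteraction", representation(
  pTau = "list", wOmega = "list", wStatic = "matrix", vMatrix = "matrix",
  meta = "list"))

#' GW self-energy in MO basis on the imaginary grids
#' @slot sigmaX static exchange self-energy matrix
#' @slot sigmaCTauP,sigmaCTauH particle/hole branches of Sigma_c(i tau) (lists)
#' @slot sigmaCOmega complex array (n_omega x n x n) of Sigma_c(i omega)
#' @slot sigmaStatic Hermitized Sigma_c(omega = 0)
#' @export
setClass("SelfEnergy", representation(
  sigmaX = "matrix", sigmaCTauP = "list", sigmaCTauH = "list",
  sigmaCOmega = "array", sigmaStatic = "matrix"))

#' Quasiparticle solution from G0W0, evGW or qsGW
#' @slot qpEnergy quasiparticle energies, Hartree
#' @slot effHamiltonian static effective Hamiltonian (MO basis of the
#'   reference for qsGW; diagonal for G0W0/evGW)
#' @slot qpCoeff eigenvectors over the reference MOs
#' @slot moCoeff AO-basis orbitals of the quasiparticle states
#' @slot densityMatrix AO-basis density matrix from the occupied QP orbitals
#' @slot occupations 0/2 per state
#' @slot history data.frame: per-iteration gap and convergence norm
#' @slot methodTag one of G0W0, evGW, qsGW
#' @slot converged logical
#' @slot backend integral context inherited from the mean field
#' @export
setClass("QPSolution", representation(
  qpEnergy = "numeric", effHamiltonian = "matrix", qpCoeff = "matrix",
  moCoeff = "matrix", densityMatrix = "matrix", occupations = "numeric",
  history = "data.frame", methodTag = "character", converged = "logical",
  backend = "list"))

setValidity("QPSolution", function(object) {
  if (!object@methodTag %in% c("G0W0", "evGW", "qsGW"))
    return("methodTag must be G0W0, evGW or qsGW")
  TRUE
})

#' Matrix-free BSE/TD-HF particle-hole operator
#'
#' Exposes (A+B) and (A-B) actions on trial vectors in the active
#' particle-hole space without materializing the full matrices.
#'
#' @slot qpEnergy quasiparticle (or orbital) energies
#' @slot pairs integer matrix (n_pairs x 2) of (occ, virt) indices
#' @slot gaps transition energies of the active pairs
#' @slot bOV,bOO,bVV MO-blocked RI tensors
#' @slot wStatic W(0) in auxiliary space (identity in TDHF mode)
#' @slot mode one of BSE, TDHF, TDA
#' @slot nOcc,nVirt active window sizes
#' @export
setClass("BSEOperator", representation(
  qpEnergy = "numeric", pairs = "matrix", gaps = "numeric",
  bOV = "array", bOO = "array", bVV = "array", wStatic = "matrix",
  mode = "character", nOcc = "integer", nVirt = "integer"))

setValidity("BSEOperator", function(object) {
  if (!object@mode %in% c("BSE", "TDHF", "TDA"))
    return("mode must be BSE, TDHF or TDA")
  if (nrow(object@pairs) == 0) return("active particle-hole space is empty")
  TRUE
})

#' Converged exciton (neutral excitation) eigenpairs
#' @slot omegas excitation energies, Hartree, ascending
#' @slot xCoeff,yCoeff excitation/de-excitation components (n_pairs x n_roots),
#'   normalized X'X - Y'Y = I
#' @slot residualNorms final residual norm per root
#' @slot pairs the active particle-hole index map
#' @slot mode solver mode tag
#' @slot iterations subspace iterations used
#' @slot subspaceHistory subspace size per iteration
#' @export
setClass("ExcitonSolution", representation(
  omegas = "numeric", xCoeff = "matrix", yCoeff = "matrix",
  residualNorms = "numeric", pairs = "matrix", mode = "character",
  iterations = "integer", subspaceHistory = "integer"))

setValidity("ExcitonSolution", function(object) {
  if (is.unsorted(object@omegas)) return("omegas must be sorted ascending")
  TRUE
})

# ------------------------------------------------------------------ printing
setMethod("show", "Molecule", function(object) {
  cat("Molecule:", length(object@symbols), "atoms (",
      paste(object@symbols, collapse = " "), "), charge",
      object@charge, "\n")
})

setMethod("show", "MeanFieldSolution", function(object) {
  occ <- object@occupations > 0
  gap <- (min(object@moEnergy[!occ]) - max(object@moEnergy[occ])) * HARTREE_EV
  cat(sprintf("MeanFieldSolution [%s]: E = %.8f Ha, HOMO-LUMO gap = %.3f eV\n",
              object@referenceTag, object@energy, gap))
})

setMethod("show", "QPSolution", function(object) {
  occ <- object@occupations > 0
  gap <- (min(object@qpEnergy[!occ]) - max(object@qpEnergy[occ])) * HARTREE_EV
  cat(sprintf("QPSolution [%s]: HOMO-LUMO gap = %.4f eV, %d iterations, %s\n",
              object@methodTag, gap, nrow(object@history),
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "ExcitonSolution", function(object) {
  cat(sprintf("ExcitonSolution [%s]: %d states, lowest = %.4f eV\n",
              object@mode, length(object@omegas),
              object@omegas[1] * HARTREE_EV))
})

setMethod("show", "FittedIntegrals", function(object) {
  cat(sprintf("FittedIntegrals: %d auxiliary functions kept (eps_s = %g)\n",
              object@nAuxKept, object@epsS))
})

setMethod("show", "ImaginaryGrid", function(object) {
  cat(sprintf(
    "ImaginaryGrid: %d tau / %d omega points, range [%g, %g] Ha, max certified error %.2e\n",
    length(object@tauPoints), length(object@omegaPoints),
    object@energyRange[1], object@energyRange[2],
    max(object@certifiedError)))
})
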