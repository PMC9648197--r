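# Independent dense/sum-over-states reference routes used by the test-suite.
# These deliberately avoid the production code paths: dense eigensolves
# instead of Davidson, spectral (pole) representations instead of
# imaginary-grid quadrature, exact four-center integrals instead of RI where
# noted.  All refuse systems above a small dense-size guard.

.denseGuard <- function(npair, maxPairs = 500L) {
  if (npair > maxPairs)
    stop("dense oracle refused for ", npair, " particle-hole pairs (guard ",
         maxPairs, ")", call. = FALSE)
}

#' Dense generalized eigensolution of a paired (A, B) problem
#'
#' Full-spectrum solve of the BSE-structure problem via the symmetric
#' reduction (A-B)^(1/2)(A+B)(A-B)^(1/2); returns all roots and normalized
#' (X, Y) with X'X - Y'Y = I.
#'
#' @param A,B dense symmetric matrices
#' @return list: omegas, X, Y
#' @export
densePairedSolve <- function(A, B) {
  .denseGuard(nrow(A))
  Am <- A - B; Ap <- A + B
  sq <- .matSqrt(Am)
  ev <- .eigAsc(sq$half %*% Ap %*% sq$half)
  if (min(ev$values) <= 0)
    stop("paired problem is not positive definite", call. = FALSE)
  om <- sqrt(ev$values)
  W <- ev$vectors * rep(sqrt(om), each = nrow(A))
  Xp <- sq$half %*% sweep(W, 2, om, `/`)
  Xm <- sq$invhalf %*% W
  list(omegas = om, X = (Xp + Xm) / 2, Y = (Xp - Xm) / 2)
}

#' Direct-RPA pole decomposition of the screened interaction
#'
#' Diagonalizes the direct-RPA (Hartree-kernel) problem in the particle-hole
#' space and returns the excitation energies and auxiliary-space residue
#' vectors V_m with
#'   Wc(i w) = - sum_m 4 V_m V_m' / (w^2 + Omega_m^2).
#'
#' @param energies orbital energies
#' @param occ,virt index windows
#' @param bOV RI block (nP x nocc x nvirt)
#' @return list: omegas (RPA poles), V (nP x n_pairs residue matrix)
#' @export
rpaPoles <- function(energies, occ, virt, bOV) {
  gaps <- .phGaps(energies, occ, virt)
  .denseGuard(length(gaps))
  nP <- dim(bOV)[1]
  b <- matrix(bOV, nP, length(gaps))
  sqg <- sqrt(gaps)
  C2 <- (sqg %o% sqg) * (diag(gaps, nrow = length(gaps)) + 4 * crossprod(b))
  ev <- .eigAsc(C2)
  if (min(ev$values) <= 0)
    stop("direct-RPA problem not positive definite", call. = FALSE)
  list(omegas = sqrt(ev$values), V = b %*% (sqg * ev$vectors))
}

#' Sum-over-states polarizability on the imaginary-frequency axis
#'
#' @param energies,occ,virt,bOV as in \code{rpaPoles}
#' @param omega imaginary-frequency value (real number, i*omega implied)
#' @return symmetric negative-semidefinite matrix P(i omega)
#' @export
sosPolarizability <- function(energies, occ, virt, bOV, omega) {
  gaps <- .phGaps(energies, occ, virt)
  nP <- dim(bOV)[1]
  b <- matrix(bOV, nP, length(gaps))
  p <- -4 * gaps / (gaps^2 + omega^2)
  M <- b %*% (p * t(b))
  (M + t(M)) / 2
}

#' Spectral (pole-sum) screened interaction
#'
#' @param poles result of \code{rpaPoles}
#' @param omega imaginary frequency (real number)
#' @return Wc(i omega) = W - v from the pole expansion
#' @export
wcSpectral <- function(poles, omega) {
  s <- -4 / (omega^2 + poles$omegas^2)
  M <- poles$V %*% (s * t(poles$V))
  (M + t(M)) / 2
}

#' Sum-over-states closed form of the correlation self-energy
#'
#' Evaluates the GW correlation self-energy from the spectral representation
#' of W (full direct-RPA diagonalization):
#'   Sigma_c[p,q](z) = sum_m (2/Omega_m) [ sum_i V^m_pi V^m_qi/(z - e_i + Om)
#'                                        + sum_a V^m_pa V^m_qa/(z - e_a - Om) ]
#' where z is the (complex) frequency on the absolute energy scale.
#'
#' @param poles result of \code{rpaPoles}
#' @param bFull full MO RI tensor (nP x n x n)
#' @param energies orbital energies
#' @param occ,virt index windows
#' @param z complex frequency (absolute scale; use mu + i*w for the
#'   imaginary axis)
#' @param p,q element indices (defaults: diagonal p)
#' @return complex value Sigma_c[p,q](z)
#' @export
sosSigmaC <- function(poles, bFull, energies, occ, virt, z, p, q = p) {
  nP <- dim(bFull)[1]
  # V^m_{p,n} = sum_P bFull[P,p,n] V_m[P]
  Bp <- matrix(bFull[, p, ], nP, dim(bFull)[3])
  Bq <- if (q == p) Bp else matrix(bFull[, q, ], nP, dim(bFull)[3])
  Vp <- crossprod(poles$V, Bp)  # n_poles x nmo
  Vq <- if (q == p) Vp else crossprod(poles$V, Bq)
  out <- 0 + 0i
  for (m in seq_along(poles$omegas)) {
    Om <- poles$omegas[m]
    out <- out + (2 / Om) *
      (sum(Vp[m, occ] * Vq[m, occ] / (z - energies[occ] + Om)) +
       sum(Vp[m, virt] * Vq[m, virt] / (z - energies[virt] - Om)))
  }
  out
}

#' Brute-force G0W0 quasiparticle energy from the spectral self-energy
#'
#' Solves the diagonal quasiparticle equation with the sum-over-states
#' self-energy (no imaginary grids, no analytic continuation): an independent
#' oracle for the production G0W0 route.
#'
#' @param mf a \linkS4class{MeanFieldSolution}
#' @param state MO index
#' @param epsS metric threshold for the RI tensor
#' @return quasiparticle energy (Hartree)
#' @export
g0w0Spectral <- function(mf, state, epsS = 5e-3) {
  occ <- which(mf@occupations > 0)
  virt <- which(mf@occupations == 0)
  fitted <- buildFittedIntegrals(mf@backend$ctx, epsS)
  bMO <- transformToMO(fitted, mf@moCoeff, occ, virt)
  poles <- rpaPoles(mf@moEnergy, occ, virt, bMO$bOV)
  D <- mf@backend$density
  Kx <- .buildJK(mf@backend$jk, D)$K
  C <- mf@moCoeff
  sx <- diag(-0.5 * crossprod(C, Kx %*% C))[state]
  vxcEff <- diag(crossprod(C, mf@vxc %*% C))[state] +
    mf@exchangeFraction * sx
  eRef <- mf@moEnergy[state]
  f <- function(e)
    eRef + sx + Re(sosSigmaC(poles, bMO$bFull, mf@moEnergy, occ, virt,
                             complex(real = e), state)) - vxcEff - e
  e <- eRef
  for (it in 1:200) {
    fe <- f(e)
    if (abs(fe) < 1e-10) break
    fp <- (f(e + 1e-6) - f(e - 1e-6)) / 2e-6
    step <- -fe / fp
    if (!is.finite(step) || abs(step) > 0.5) step <- sign(fe) * 0.05
    e <- e + step
  }
  e
}

#' Independent dense TD-HF construction from RI integrals
#'
#' Builds the singlet TD-HF A/B matrices by the textbook formulas
#' A = D + 2(ia|jb) - (ij|ab), B = 2(ia|jb) - (ib|aj) from either the fitted
#' RI integrals or exact four-center MO integrals, and solves the dense
#' paired problem.
#'
#' @param mf an HF \linkS4class{MeanFieldSolution}
#' @param integrals "ri" (reconstructed fitted integrals) or "exact"
#'   (four-center tensor)
#' @param epsS metric threshold when \code{integrals = "ri"}
#' @return list: omegas, X, Y, A, B
#' @export
denseTDHF <- function(mf, integrals = c("ri", "exact"), epsS = 5e-3) {
  integrals <- match.arg(integrals)
  occ <- which(mf@occupations > 0)
  virt <- which(mf@occupations == 0)
  no <- length(occ); nv <- length(virt)
  .denseGuard(no * nv)
  C <- mf@moCoeff
  n <- nrow(C)
  if (integrals == "ri") {
    eri <- .riReconstruct(buildFittedIntegrals(mf@backend$ctx, epsS))
  } else {
    eri <- .eri4(mf@backend$ctx)
  }
  # AO -> MO transform of the needed blocks (small systems: full transform)
  eriM <- matrix(eri, n * n, n * n)
  Cm <- kronecker(C, C)
  eriMO <- array(crossprod(Cm, eriM %*% Cm), c(ncol(C), ncol(C),
                                               ncol(C), ncol(C)))
  e <- mf@moEnergy
  A <- matrix(0, no * nv, no * nv)
  B <- matrix(0, no * nv, no * nv)
  idx <- function(i, a) (a - 1) * no + i
  for (i in seq_len(no)) for (a in seq_len(nv))
    for (j in seq_len(no)) for (b in seq_len(nv)) {
      I <- idx(i, a); J <- idx(j, b)
      gi <- occ[i]; ga <- virt[a]; gj <- occ[j]; gb <- virt[b]
      A[I, J] <- 2 * eriMO[gi, ga, gj, gb] - eriMO[gi, gj, ga, gb] +
        (I == J) * (e[ga] - e[gi])
      B[I, J] <- 2 * eriMO[gi, ga, gj, gb] - eriMO[gi, gb, ga, gj]
    }
  sol <- densePairedSolve(A, B)
  c(sol, list(A = A, B = B))
}

#' Bundle of dense oracle quantities for a mean-field solution
#'
#' @param mf a \linkS4class{MeanFieldSolution}
#' @param epsS metric threshold
#' @return list: rpa poles, dense TDHF solution, RI blocks
#' @export
denseOracles <- function(mf, epsS = 5e-3) {
  occ <- which(mf@occupations > 0)
  virt <- which(mf@occupations == 0)
  .denseGuard(length(occ) * length(virt))
  fitted <- buildFittedIntegrals(mf@backend$ctx, epsS)
  bMO <- transformToMO(fitted, mf@moCoeff, occ, virt)
  list(poles = rpaPoles(mf@moEnergy, occ, virt, bMO$bOV),
       tdhf = if (mf@referenceTag == "HF") denseTDHF(mf, "ri", epsS),
       bMO = bMO, fitted = fitted, occ = occ, virt = virt)
}
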