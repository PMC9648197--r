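# RPA polarizability on the imaginary-time axis, cosine transform to the
# imaginary-frequency axis, the Dyson-screened interaction W, and its
# zero-frequency limit obtained by quadrature of P(i tau).
#
# Spin convention (closed shell, spin-summed):
#   P_PQ(i tau) = -2 sum_ia B[P,ia] B[Q,ia] exp(-(e_a - e_i)|tau|)
# whose cosine transform is the sum-over-states form
#   P_PQ(i w)  = -4 sum_ia B[P,ia] B[Q,ia] (e_a - e_i)/((e_a - e_i)^2 + w^2).
# The factor convention is pinned operationally by the TD-HF equivalence test
# of the BSE module rather than assumed.

# particle-hole gap vector for an energy/occupation pattern
.phGaps <- function(energies, occ, virt) {
  gaps <- rep(energies[virt], each = length(occ)) - energies[occ]
  if (length(gaps) && min(gaps) <= 0)
    stop("non-positive HOMO-LUMO gap: metallic case unsupported",
         call. = FALSE)
  gaps
}

#' RPA polarizability in imaginary time
#'
#' @param energies orbital (or quasiparticle) energies, Hartree
#' @param occ,virt occupied/virtual index vectors
#' @param bOV RI tensor block (nP x nocc x nvirt)
#' @param grid an \linkS4class{ImaginaryGrid} covering the gap range
#' @return list of negative-semidefinite symmetric matrices, one per tau node
#' @export
polarizabilityTau <- function(energies, occ, virt, bOV, grid) {
  nP <- dim(bOV)[1]
  if (length(occ) == 0 || length(virt) == 0)
    return(lapply(grid@tauPoints, function(t) matrix(0, nP, nP)))
  gaps <- .phGaps(energies, occ, virt)
  if (min(gaps) < grid@energyRange[1] * (1 - 1e-9) ||
      max(gaps) > grid@energyRange[2] * (1 + 1e-9))
    stop("grid energy range does not cover the particle-hole gaps",
         call. = FALSE)
  Bm <- matrix(bOV, nP, length(gaps))  # columns indexed by (i,a)
  lapply(grid@tauPoints, function(tau) {
    M <- -2 * tcrossprod(Bm * rep(exp(-gaps * tau / 2), each = nP))
    (M + t(M)) / 2
  })
}

# cosine-transform a list of symmetric tau matrices to the omega nodes
.cosTransform <- function(pTau, grid) {
  G <- grid@cosTauToOmega
  lapply(seq_len(nrow(G)), function(j) {
    M <- Reduce(`+`, Map(`*`, pTau, G[j, ]))
    (M + t(M)) / 2
  })
}

#' Screened interaction W(i omega) from the Dyson equation
#'
#' In the orthonormalized auxiliary metric the bare interaction is the
#' identity, so W = (1 - P)^(-1).
#'
#' @param pOmega list of symmetric P(i omega) matrices
#' @return list of symmetric W(i omega) matrices
#' @export
screenedInteractionOmega <- function(pOmega) {
  lapply(pOmega, function(P) {
    A <- diag(nrow(P)) - P
    sv <- svd(A, nu = 0, nv = 0)$d
    if (min(sv) < 1e-12 * max(sv))
      stop("(1 - vP) is numerically singular; smallest singular value ",
           format(min(sv)), call. = FALSE)
    W <- solve(A)
    (W + t(W)) / 2
  })
}

#' Static screened interaction from the time-domain polarizability
#'
#' P(omega=0) is the full imaginary-time integral of P(i tau), evaluated with
#' the even-function quadrature 2*sum_k w_k P(i tau_k); W(0) then follows from
#' the Dyson equation.
#'
#' @param pTau list of P(i tau) matrices
#' @param grid the \linkS4class{ImaginaryGrid} the nodes belong to
#' @return list with \code{w0}, \code{p0} and \code{quadError} (certified
#'   relative quadrature error propagated to P(0))
#' @export
staticScreenedInteraction <- function(pTau, grid) {
  P0 <- Reduce(`+`, Map(`*`, pTau, 2 * grid@tauWeights))
  P0 <- (P0 + t(P0)) / 2
  W0 <- screenedInteractionOmega(list(P0))[[1]]
  list(w0 = W0, p0 = P0,
       quadError = unname(grid@certifiedError["quad_tau"] * max(abs(P0))))
}

#' Build the full screening stack for a set of orbital energies
#'
#' Convenience driver: P(i tau) -> P(i omega) -> W(i omega), plus the static
#' limit W(0) via the time-integration route.
#'
#' @param energies orbital or quasiparticle energies (Hartree)
#' @param occ,virt active-window index vectors
#' @param bOV RI block (nP x nocc x nvirt)
#' @param grid an \linkS4class{ImaginaryGrid}
#' @return a \linkS4class{ScreenedInteraction}
#' @export
buildScreening <- function(energies, occ, virt, bOV, grid) {
  pTau <- polarizabilityTau(energies, occ, virt, bOV, grid)
  pOmega <- .cosTransform(pTau, grid)
  wOmega <- screenedInteractionOmega(pOmega)
  st <- staticScreenedInteraction(pTau, grid)
  nP <- dim(bOV)[1]
  new("ScreenedInteraction", pTau = pTau, wOmega = wOmega, wStatic = st$w0,
      vMatrix = diag(nP),
      meta = list(grid = grid, pOmega = pOmega, p0 = st$p0,
                  quadError = st$quadError))
}
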