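# Singlet closed-shell Bethe-Salpeter (and TD-HF / TDA) particle-hole
# operator.  Matrix elements over active pairs (i,a), (j,b):
#   A = delta_ij delta_ab (e_a - e_i) + 2 (ia|jb) - W_{ij,ab}(0)
#   B = 2 (ia|jb) - W_{ib,aj}(0)
# with the static screened interaction W(0); in TDHF mode W(0) is replaced by
# the bare interaction (identity in the orthonormalized auxiliary metric).
# The operator exposes (A+B) and (A-B) actions on trial vectors without
# materializing the full matrices.

# resolve energies/orbitals/backend from a QP or mean-field solution
.stateOf <- function(x) {
  if (is(x, "QPSolution"))
    list(e = x@qpEnergy, C = x@moCoeff, occw = which(x@occupations > 0),
         virtw = which(x@occupations == 0), backend = x@backend)
  else if (is(x, "MeanFieldSolution"))
    list(e = x@moEnergy, C = x@moCoeff, occw = which(x@occupations > 0),
         virtw = which(x@occupations == 0), backend = x@backend)
  else stop("expected a QPSolution or MeanFieldSolution", call. = FALSE)
}

#' Build the matrix-free BSE/TDHF/TDA operator
#'
#' For mode "BSE" the static screened interaction W(0) is rebuilt from the
#' spectrum of \code{qp} (quasiparticle energies and rotated orbitals); for
#' mode "TDHF" the bare interaction is used, which together with an HF
#' reference reproduces time-dependent Hartree-Fock.  Pairs with transition
#' energy above \code{phCutoff} are excluded from the active space.
#'
#' @param qp a \linkS4class{QPSolution} (or, for TDHF, a HF
#'   \linkS4class{MeanFieldSolution})
#' @param config settings from \code{gwConfig}
#' @param mode "BSE", "TDHF" or "TDA"
#' @param phCutoff particle-hole transition-energy cutoff in Hartree
#' @return a \linkS4class{BSEOperator}
#' @export
buildBSEOperator <- function(qp, config = gwConfig(),
                             mode = c("BSE", "TDHF", "TDA"),
                             phCutoff = config$phCutoff) {
  mode <- match.arg(mode)
  stt <- .stateOf(qp)
  ctx <- stt$backend$ctx
  fitted <- stt$backend$setup$fitted
  if (is.null(fitted)) fitted <- buildFittedIntegrals(ctx, config$epsS)
  occ <- stt$occw; virt <- stt$virtw
  bMO <- transformToMO(fitted, stt$C, occ, virt)
  gapsAll <- .phGaps(stt$e, occ, virt)
  nP <- dim(fitted@bTensor)[1]
  if (mode == "TDHF") {
    w0 <- diag(nP)
  } else {
    grid <- .gridFor(stt$e, occ, virt, config$nGridPoints)
    pT <- polarizabilityTau(stt$e, occ, virt, bMO$bOV, grid)
    w0 <- staticScreenedInteraction(pT, grid)$w0
  }
  sel <- which(gapsAll <= phCutoff)
  if (length(sel) == 0) stop("active particle-hole space is empty",
                             call. = FALSE)
  no <- length(occ); nv <- length(virt)
  pairIdx <- cbind(rep(seq_len(no), nv), rep(seq_len(nv), each = no))
  new("BSEOperator", qpEnergy = stt$e,
      pairs = pairIdx[sel, , drop = FALSE], gaps = gapsAll[sel],
      bOV = bMO$bOV, bOO = bMO$bOO, bVV = bMO$bVV, wStatic = w0,
      mode = mode, nOcc = as.integer(no), nVirt = as.integer(nv))
}

# scatter active-pair vector into the (occ x virt) matrix
.pairToMat <- function(op, t) {
  T <- matrix(0, op@nOcc, op@nVirt)
  T[op@pairs] <- t
  T
}

# kernel contractions on one trial vector; returns list(v, wd, wx) pieces
.kernelPieces <- function(op, t) {
  T <- .pairToMat(op, t)
  nP <- dim(op@bOV)[1]; no <- op@nOcc; nv <- op@nVirt
  Bov <- matrix(op@bOV, nP, no * nv)
  # bare term (ia|jb): same for A and B blocks
  vvec <- as.vector(Bov %*% as.vector(T))
  Vt <- matrix(crossprod(Bov, vvec), no, nv)
  # direct screened term W_{ij,ab}
  U <- array(0, c(nP, no, nv))
  for (Q in seq_len(nP))
    U[Q, , ] <- T %*% t(matrix(op@bVV[Q, , ], nv, nv))
  V2 <- array(op@wStatic %*% matrix(U, nP, no * nv), c(nP, no, nv))
  X1 <- matrix(aperm(op@bOO, c(1, 3, 2)), nP * no, no)
  Wd <- crossprod(X1, matrix(aperm(V2, c(1, 2, 3)), nP * no, nv))
  # exchange-type screened term W_{ib,aj}
  R <- array(0, c(nP, nv, nv))
  for (Q in seq_len(nP))
    R[Q, , ] <- crossprod(matrix(op@bOV[Q, , ], no, nv), T)  # [a, b]
  R2 <- array(op@wStatic %*% matrix(R, nP, nv * nv), c(nP, nv, nv))
  X2 <- matrix(aperm(op@bOV, c(1, 3, 2)), nP * nv, no)
  Wx <- crossprod(X2, matrix(aperm(R2, c(1, 3, 2)), nP * nv, nv))
  list(V = Vt, Wd = Wd, Wx = Wx, T = T)
}

#' Apply (A+B) or (A-B) to trial columns
#'
#' Matrix-free evaluation via three-index contractions; cost is linear in the
#' number of trial columns.
#'
#' @param op a \linkS4class{BSEOperator}
#' @param trial matrix of trial vectors (active pairs x n_trial)
#' @param which "plus" for (A+B), "minus" for (A-B)
#' @return matrix of contracted columns
#' @export
applyKernelColumns <- function(op, trial, which = c("plus", "minus")) {
  which <- match.arg(which)
  trial <- as.matrix(trial)
  out <- matrix(0, nrow(trial), ncol(trial))
  for (j in seq_len(ncol(trial))) {
    kp <- .kernelPieces(op, trial[, j])
    M <- if (which == "plus") 4 * kp$V - kp$Wd - kp$Wx
         else -kp$Wd + kp$Wx
    res <- op@gaps * trial[, j] + M[op@pairs]
    if (any(!is.finite(res)))
      stop("NaN in kernel contraction (", which, " case)", call. = FALSE)
    out[, j] <- res
  }
  out
}

# TDA action: A t = ((A+B) + (A-B))/2
.applyA <- function(op, trial)
  (applyKernelColumns(op, trial, "plus") +
     applyKernelColumns(op, trial, "minus")) / 2

# dense materialization of A and B from the same blocks (guarded; used for
# small systems and by the iterative solver's subspace seeding diagnostics)
#' Materialize dense A and B matrices of the operator
#'
#' Only available below a size guard; intended for diagnostics and
#' cross-checks on small active spaces.
#'
#' @param op a \linkS4class{BSEOperator}
#' @param maxPairs size guard on the active space
#' @return list with dense \code{A} and \code{B}
#' @export
denseBSEMatrices <- function(op, maxPairs = 500L) {
  npair <- nrow(op@pairs)
  if (npair > maxPairs)
    stop("dense materialization refused for ", npair,
         " pairs (guard ", maxPairs, ")", call. = FALSE)
  Ap <- applyKernelColumns(op, diag(npair), "plus")
  Am <- applyKernelColumns(op, diag(npair), "minus")
  list(A = (Ap + Am) / 2, B = (Ap - Am) / 2)
}
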