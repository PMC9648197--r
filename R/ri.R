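# Global resolution-of-identity (density fitting) with Coulomb-metric
# eigenvalue regularization.  The three-center tensor is expressed directly in
# the orthonormalized retained metric subspace, in which the bare Coulomb
# interaction is the identity matrix; discarding small metric eigenvalues
# removes near-linear-dependencies of the auxiliary set while preserving
# positive semidefiniteness of the fitted interaction.

#' Build the regularized three-center RI tensor
#'
#' Diagonalizes the auxiliary Coulomb metric (P|Q), discards eigendirections
#' with eigenvalue below \code{epsS} times the largest eigenvalue, and returns
#' B[P,p,q] in the orthonormalized retained subspace, so that
#' (pq|rs) ~ sum_P B[P,p,q] B[P,r,s].
#'
#' @param x a \linkS4class{MeanFieldSolution}, or an integral context from
#'   \code{integralContext}
#' @param epsS relative metric eigenvalue threshold (>= 0); the default is the
#'   regularization strength used throughout the package
#' @return a \linkS4class{FittedIntegrals}
#' @export
buildFittedIntegrals <- function(x, epsS = 5e-3) {
  ctx <- if (is(x, "MeanFieldSolution")) x@backend$ctx else x
  if (epsS < 0) stop("epsS must be >= 0", call. = FALSE)
  met <- .auxMetric(ctx)
  ev <- eigen(met$J, symmetric = TRUE)  # descending
  lam <- ev$values
  if (min(lam) < -1e-8 * max(lam))
    stop("auxiliary Coulomb metric is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(lam)), "); broken auxiliary set",
         call. = FALSE)
  keep <- lam >= max(epsS * max(lam), 1e-13 * max(lam))
  nk <- sum(keep)
  Wmat <- ev$vectors[, keep, drop = FALSE] *
    rep(1 / sqrt(lam[keep]), each = nrow(met$J))
  t3 <- .eri3(ctx, met$anrm)
  naux <- dim(t3)[1]
  n <- dim(t3)[2]
  B <- crossprod(Wmat, matrix(t3, naux, n * n))
  new("FittedIntegrals", bTensor = array(B, c(nk, n, n)),
      nAuxKept = as.integer(nk), metricSpectrum = lam, epsS = epsS)
}

#' Transform the RI tensor to MO-blocked form
#'
#' @param fitted a \linkS4class{FittedIntegrals}
#' @param moCoeff AO->MO coefficient matrix from the same primary basis
#' @param occ,virt column indices of the occupied / virtual MOs of the active
#'   window (either may be empty)
#' @return list with \code{bFull} (nP x nmo x nmo), \code{bOV}, \code{bOO},
#'   \code{bVV} blocks and the index vectors
#' @export
transformToMO <- function(fitted, moCoeff, occ, virt) {
  B <- fitted@bTensor
  nP <- dim(B)[1]; n <- dim(B)[2]
  if (nrow(moCoeff) != n)
    stop("moCoeff dimension does not match the fitted tensor", call. = FALSE)
  nmo <- ncol(moCoeff)
  bFull <- array(0, c(nP, nmo, nmo))
  for (P in seq_len(nP))
    bFull[P, , ] <- crossprod(moCoeff, matrix(B[P, , ], n, n) %*% moCoeff)
  list(bFull = bFull,
       bOV = bFull[, occ, virt, drop = FALSE],
       bOO = bFull[, occ, occ, drop = FALSE],
       bVV = bFull[, virt, virt, drop = FALSE],
       occ = occ, virt = virt)
}

# reconstruct (pq|rs) from the fitted tensor (small-system diagnostics)
.riReconstruct <- function(fitted) {
  B <- fitted@bTensor
  nP <- dim(B)[1]; n <- dim(B)[2]
  M <- crossprod(matrix(B, nP, n * n))
  array(M, c(n, n, n, n))
}
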