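# GW self-energy in the space-time formulation.
#
# G(i tau) is diagonal in the (current) MO basis with exponential decay away
# from the chemical potential mu; W(i tau) - v is obtained from W(i omega) by
# the fitted inverse cosine transform.  The correlation self-energy is
# assembled as full MO matrices on the positive-tau branch for particles and
# holes separately,
#   Sp_k = sum_a exp(-(e_a-mu) tau_k) * Ba' Wc(tau_k) Ba
#   Sh_k = sum_i exp(-(mu-e_i) tau_k) * Bi' Wc(tau_k) Bi
# from which
#   Sigma_c(i w) = Int_0^inf [cos(w t)(Sp-Sh) + i sin(w t)(Sp+Sh)] dt
# and the static limit Sigma_c(0) = Int_0^inf (Sp-Sh) dt by tau quadrature.

#' Static exchange self-energy from the RI tensor
#'
#' Sigma_x[p,q] = - sum_i sum_P B[P,p,i] B[P,q,i] over occupied i.
#'
#' @param bFull MO-basis RI tensor (nP x n x n)
#' @param occ occupied MO indices
#' @return symmetric exchange self-energy matrix
#' @export
sigmaExchange <- function(bFull, occ) {
  n <- dim(bFull)[2]
  if (length(occ) == 0) return(matrix(0, n, n))
  nP <- dim(bFull)[1]
  X <- matrix(aperm(bFull[, , occ, drop = FALSE], c(1, 3, 2)),
              nP * length(occ), n)
  -crossprod(X)
}

# W(i tau) - v on the tau nodes from the W(i omega) stack
.wcTau <- function(wOmega, grid) {
  nP <- nrow(wOmega[[1]])
  wc <- lapply(wOmega, function(W) W - diag(nP))
  M <- grid@cosOmegaToTau
  lapply(seq_len(nrow(M)), function(k) {
    A <- Reduce(`+`, Map(`*`, wc, M[k, ]))
    (A + t(A)) / 2
  })
}

#' Correlation self-energy branches on the imaginary-time nodes
#'
#' @param energies current orbital/quasiparticle energies
#' @param mu chemical potential (mid-gap)
#' @param bFull MO-basis RI tensor
#' @param wcTau list of W(i tau) - v matrices on the tau nodes
#' @param grid the \linkS4class{ImaginaryGrid}
#' @param occ,virt index vectors (Green's-function split at mu)
#' @return list with \code{Sp}, \code{Sh}: lists of symmetric matrices per node
#' @export
sigmaCTau <- function(energies, mu, bFull, wcTau, grid, occ, virt) {
  nP <- dim(bFull)[1]; n <- dim(bFull)[2]
  Bm <- matrix(bFull, nP, n * n)
  branch <- function(idx, expo) {
    if (length(idx) == 0)
      return(lapply(grid@tauPoints, function(t) matrix(0, n, n)))
    Xi <- matrix(aperm(bFull[, , idx, drop = FALSE], c(1, 3, 2)),
                 nP * length(idx), n)
    lapply(seq_along(grid@tauPoints), function(k) {
      Y <- wcTau[[k]] %*% Bm
      Yi <- matrix(aperm(array(Y, c(nP, n, n))[, , idx, drop = FALSE],
                         c(1, 3, 2)), nP * length(idx), n)
      ee <- rep(exp(-expo(energies[idx]) * grid@tauPoints[k]), each = nP)
      M <- crossprod(Xi, Yi * ee)
      (M + t(M)) / 2
    })
  }
  list(Sp = branch(virt, function(e) e - mu),
       Sh = branch(occ, function(e) mu - e))
}

#' Correlation self-energy on the imaginary-frequency nodes
#'
#' @param sct result of \code{sigmaCTau}
#' @param grid the grid carrying the sine/cosine transform fits
#' @return complex array (n_omega x n x n)
#' @export
sigmaCOmega <- function(sct, grid) {
  n <- nrow(sct$Sp[[1]])
  nw <- nrow(grid@cosTauToOmega)
  out <- array(0 + 0i, c(nw, n, n))
  for (j in seq_len(nw)) {
    ev <- Reduce(`+`, Map(`*`, Map(`-`, sct$Sp, sct$Sh),
                          grid@cosTauToOmega[j, ])) / 2
    od <- Reduce(`+`, Map(`*`, Map(`+`, sct$Sp, sct$Sh),
                          grid@sinTauToOmega[j, ])) / 2
    out[j, , ] <- ev + 1i * od
  }
  out
}

#' Static (zero-frequency) correlation self-energy
#'
#' @param sct result of \code{sigmaCTau}
#' @param grid grid carrying the tau quadrature weights
#' @return real symmetric matrix Sigma_c(0)
#' @export
sigmaCStatic <- function(sct, grid) {
  M <- Reduce(`+`, Map(`*`, Map(`-`, sct$Sp, sct$Sh), grid@tauWeights))
  (M + t(M)) / 2
}

# ------------------------------------------------------ analytic continuation

#' Thiele/Pade rational continuation of a frequency series
#'
#' Builds a continued-fraction interpolant through (z_j, f_j) sampled on the
#' imaginary axis and returns a callable model usable at complex or real
#' frequencies.  Degenerate continued-fraction steps trigger an automatic
#' node-thinning retry before failing.
#'
#' @param z complex sample points (i omega_j)
#' @param f complex sample values
#' @return function(zeval) evaluating the rational model
#' @export
analyticContinuation <- function(z, f, symmetrize = TRUE) {
  if (length(z) < 2 || max(abs(f)) == 0) {
    c0 <- if (length(f)) f[1] else 0 + 0i
    return(function(zz) rep(c0, length(zz)))
  }
  if (symmetrize) {
    # enforce the Schwarz reflection Sigma(conj z) = conj Sigma(z): stabilizes
    # evaluation on the real axis against noise in the sampled values
    z <- c(rev(Conj(z)), z)
    f <- c(rev(Conj(f)), f)
  }
  scale <- max(abs(f))
  thiele <- function(z, f) {
    n <- length(z)
    g <- matrix(0 + 0i, n, n)
    g[1, ] <- f
    order <- n
    for (i in 2:n) {
      num <- g[i - 1, i - 1] - g[i - 1, i:n]
      den <- g[i - 1, i:n]
      if (max(abs(num)) < 1e-12 * scale) {
        # remaining differences vanish: the fraction terminates early
        # (constant tails, exactly rational input)
        order <- i - 1
        break
      }
      if (any(abs(den) < 1e-300) || any(!is.finite(abs(num / den))))
        return(NULL)
      g[i, i:n] <- num / (den * (z[i:n] - z[i - 1]))
      scale <- max(abs(g[i, i:n]))
    }
    diag(g)[seq_len(order)]
  }
  a <- thiele(z, f)
  if (is.null(a)) {
    keep <- seq(1, length(z), by = 2)
    z <- z[keep]; f <- f[keep]
    a <- thiele(z, f)
    if (is.null(a))
      stop("degenerate continued fraction in analytic continuation",
           call. = FALSE)
  }
  n <- length(a)
  zs <- z[seq_len(n)]
  function(zz) {
    vapply(zz, function(x) {
      # backward evaluation of the continued fraction
      acc <- 0 + 0i
      if (n > 1) for (i in n:2) acc <- a[i] * (x - zs[i - 1]) / (1 + acc)
      a[1] / (1 + acc)
    }, complex(1))
  }
}

#' Solve the diagonal quasiparticle equation for one state
#'
#' Newton iteration on e = eRef + Re[Sigma_x + Sigma_c(e) - vxc] with the
#' linearized (Z-factor) solution as the starting point and fallback.
#'
#' @param eRef reference orbital energy
#' @param sx diagonal exchange self-energy element
#' @param vxcEff effective xc potential element to subtract (for a hybrid this
#'   already contains the exact-exchange admixture)
#' @param acModel callable from \code{analyticContinuation}; evaluated at
#'   e - mu
#' @param mu chemical potential used when the self-energy was sampled
#' @param maxIter Newton step cap
#' @return list: \code{e} (QP energy), \code{eLin} (linearized), \code{z}
#'   (renormalization factor), \code{converged}
#' @export
solveQpDiagonal <- function(eRef, sx, vxcEff, acModel, mu, maxIter = 100L) {
  sig <- function(e) Re(acModel(complex(real = e - mu)))
  h <- 1e-5
  dsig <- function(e) (sig(e + h) - sig(e - h)) / (2 * h)
  s0 <- sig(eRef)
  z <- 1 / (1 - dsig(eRef))
  if (!is.finite(z) || z <= 0 || z > 1.5) z <- 1
  eLin <- eRef + z * (sx + s0 - vxcEff)
  e <- eLin
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    fval <- eRef + sx + sig(e) - vxcEff - e
    if (abs(fval) < 1e-10) { converged <- TRUE; break }
    slope <- dsig(e) - 1
    step <- -fval / slope
    if (!is.finite(step) || abs(step) > 1) step <- sign(fval) * 0.1
    e <- e + step
  }
  if (!converged) e <- eLin
  list(e = e, eLin = eLin, z = z, converged = converged)
}
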