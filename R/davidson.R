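# Paired Davidson solver for the (A, B) generalized eigenproblem
#   A X + B Y =  Omega X,   B X + A Y = -Omega Y
# in the symmetric-subspace reduction: with projected matrices
# M+ = V'(A+B)V and M- = V'(A-B)V (both positive definite for the systems in
# scope), the subspace problem  T M+ T w = Omega^2 w,  T = (M-)^(1/2),
# yields X+Y = V T w / Omega and X-Y = V T^(-1) w with the normalization
# (X+Y)'(X-Y) = 1, i.e. X'X - Y'Y = 1 per root.  Everything is deterministic:
# initialization from the lowest-gap unit vectors, no randomness anywhere.

.matSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  mx <- max(e$values)
  if (mx <= 0 || min(e$values) < -1e-10 * mx)
    stop("projected (A-B) block is not positive definite", call. = FALSE)
  v <- pmax(e$values, 1e-14 * mx)  # shield exactly-degenerate directions
  list(half = e$vectors %*% (sqrt(v) * t(e$vectors)),
       invhalf = e$vectors %*% ((1 / sqrt(v)) * t(e$vectors)))
}

.orthonormalize <- function(V, add, tol = 1e-10) {
  for (j in seq_len(ncol(add))) {
    v <- add[, j]
    for (rep in 1:2) if (ncol(V) > 0) v <- v - V %*% crossprod(V, v)
    nv <- sqrt(sum(v^2))
    if (nv > tol) V <- cbind(V, v / nv)
  }
  V
}

# generic operator interface so tests can plug in explicit matrices
.opInfo <- function(op) {
  if (is(op, "BSEOperator")) {
    list(n = nrow(op@pairs), gaps = op@gaps,
         plus = function(Tm) applyKernelColumns(op, Tm, "plus"),
         minus = function(Tm) applyKernelColumns(op, Tm, "minus"),
         A = function(Tm) .applyA(op, Tm))
  } else if (is.list(op) && !is.null(op$A) && !is.null(op$B)) {
    Ap <- op$A + op$B; Am <- op$A - op$B
    list(n = nrow(op$A), gaps = diag(op$A),
         plus = function(Tm) Ap %*% Tm, minus = function(Tm) Am %*% Tm,
         A = function(Tm) op$A %*% Tm)
  } else stop("unsupported operator", call. = FALSE)
}

#' Davidson solver for the lowest BSE eigenpairs
#'
#' Iterative subspace solution of the paired (A, B) problem via the reduced
#' symmetric formulation; residual-preconditioned expansion, deterministic
#' initialization from the lowest-gap unit vectors, thick restart when the
#' subspace exceeds \code{20 * nRoots}.
#'
#' @param op a \linkS4class{BSEOperator}, or \code{list(A=, B=)} with dense
#'   matrices (diagnostics)
#' @param nRoots number of lowest excitations to converge
#' @param tol eigenvalue convergence threshold, Hartree
#' @param maxIter subspace iteration cap
#' @return an \linkS4class{ExcitonSolution}
#' @export
davidsonSolve <- function(op, nRoots, tol = 1e-5, maxIter = 100L) {
  oi <- .opInfo(op)
  n <- oi$n
  if (nRoots > n)
    stop("nRoots exceeds the active particle-hole space", call. = FALSE)
  # track a few roots beyond the requested window so interior members of
  # degenerate multiplets cannot be skipped
  nTrack <- min(n, nRoots + 3L)
  nInit <- min(n, nTrack + 4L)
  seed <- order(oi$gaps)[seq_len(nInit)]
  V <- matrix(0, n, nInit)
  V[cbind(seed, seq_len(nInit))] <- 1
  ApV <- oi$plus(V)
  AmV <- oi$minus(V)
  omOld <- rep(Inf, nTrack)
  hist <- integer()
  iterUsed <- 0L
  res <- NULL
  for (iter in seq_len(maxIter)) {
    iterUsed <- iter
    hist <- c(hist, ncol(V))
    Mp <- crossprod(V, ApV); Mp <- (Mp + t(Mp)) / 2
    Mm <- crossprod(V, AmV); Mm <- (Mm + t(Mm)) / 2
    Tsq <- .matSqrt(Mm)
    Smat <- Tsq$half %*% Mp %*% Tsq$half
    ev <- .eigAsc(Smat)
    if (min(ev$values) <= 0)
      stop("reduced problem lost positive definiteness", call. = FALSE)
    om <- sqrt(ev$values[seq_len(min(nTrack, ncol(V)))])
    W <- ev$vectors[, seq_along(om), drop = FALSE] *
      rep(sqrt(om), each = ncol(V))  # |w| = sqrt(Omega)
    XpS <- Tsq$half %*% sweep(W, 2, om, `/`)
    XmS <- Tsq$invhalf %*% W
    Xp <- V %*% XpS
    Xm <- V %*% XmS
    RXp <- ApV %*% XpS   # (A+B) Xp
    RXm <- AmV %*% XmS   # (A-B) Xm
    Rp <- RXp - sweep(Xm, 2, om, `*`)
    Rm <- RXm - sweep(Xp, 2, om, `*`)
    rnorm <- sqrt(colSums(Rp^2) + colSums(Rm^2))
    dOm <- abs(om - omOld[seq_along(om)])
    omOld <- c(om, rep(Inf, nTrack - length(om)))
    if (length(om) == nTrack && all(dOm < tol)) {
      res <- list(om = om, Xp = Xp, Xm = Xm, rnorm = rnorm)
      break
    }
    # restart or expand
    if (ncol(V) > 20L * nTrack) {
      V <- .orthonormalize(matrix(0, n, 0), cbind(Xp, Xm))
      ApV <- oi$plus(V)
      AmV <- oi$minus(V)
      next
    }
    add <- matrix(0, n, 0)
    for (r in seq_along(om)) {
      if (dOm[r] < tol && rnorm[r] < sqrt(tol)) next
      den1 <- oi$gaps - om[r]
      den1[abs(den1) < 1e-3] <- sign(den1[abs(den1) < 1e-3] + 1e-12) * 1e-3
      add <- cbind(add, Rp[, r] / den1, Rm[, r] / den1)
    }
    Vnew <- .orthonormalize(V, add)
    if (ncol(Vnew) == ncol(V)) {  # stagnation: thick restart
      V <- .orthonormalize(matrix(0, n, 0), cbind(Xp, Xm))
      ApV <- oi$plus(V)
      AmV <- oi$minus(V)
      next
    }
    fresh <- (ncol(V) + 1):ncol(Vnew)
    ApV <- cbind(ApV, oi$plus(Vnew[, fresh, drop = FALSE]))
    AmV <- cbind(AmV, oi$minus(Vnew[, fresh, drop = FALSE]))
    V <- Vnew
    res <- list(om = om, Xp = Xp, Xm = Xm, rnorm = rnorm)
  }
  X <- (res$Xp + res$Xm) / 2
  Y <- (res$Xp - res$Xm) / 2
  ord <- order(res$om)[seq_len(nRoots)]
  pairs <- if (is(op, "BSEOperator")) op@pairs
           else cbind(seq_len(n), rep(1L, n))
  new("ExcitonSolution", omegas = res$om[ord],
      xCoeff = X[, ord, drop = FALSE], yCoeff = Y[, ord, drop = FALSE],
      residualNorms = res$rnorm[ord], pairs = pairs,
      mode = if (is(op, "BSEOperator")) op@mode else "BSE",
      iterations = iterUsed, subspaceHistory = hist)
}

#' Tamm-Dancoff solver: Hermitian Davidson on A alone
#'
#' @inheritParams davidsonSolve
#' @return an \linkS4class{ExcitonSolution} with Y = 0
#' @export
solveTDA <- function(op, nRoots, tol = 1e-5, maxIter = 100L) {
  oi <- .opInfo(op)
  n <- oi$n
  if (nRoots > n)
    stop("nRoots exceeds the active particle-hole space", call. = FALSE)
  nTrack <- min(n, nRoots + 3L)
  nInit <- min(n, nTrack + 4L)
  seed <- order(oi$gaps)[seq_len(nInit)]
  V <- matrix(0, n, nInit)
  V[cbind(seed, seq_len(nInit))] <- 1
  AV <- oi$A(V)
  omOld <- rep(Inf, nTrack)
  hist <- integer(); iterUsed <- 0L
  X <- NULL; om <- NULL; rnorm <- NULL
  for (iter in seq_len(maxIter)) {
    iterUsed <- iter
    hist <- c(hist, ncol(V))
    H <- crossprod(V, AV)
    ev <- .eigAsc(H)
    nGot <- min(nTrack, ncol(V))
    om <- ev$values[seq_len(nGot)]
    X <- V %*% ev$vectors[, seq_len(nGot), drop = FALSE]
    Rs <- AV %*% ev$vectors[, seq_len(nGot), drop = FALSE] -
      sweep(X, 2, om, `*`)
    rnorm <- sqrt(colSums(Rs^2))
    dOm <- abs(om - omOld[seq_along(om)])
    omOld <- c(om, rep(Inf, nTrack - length(om)))
    if (length(om) == nTrack && all(dOm < tol)) break
    if (ncol(V) > 20L * nTrack) {
      V <- .orthonormalize(matrix(0, n, 0), X)
      AV <- oi$A(V)
      next
    }
    add <- matrix(0, n, 0)
    for (r in seq_along(om)) {
      if (dOm[r] < tol) next
      den <- oi$gaps - om[r]
      den[abs(den) < 1e-3] <- sign(den[abs(den) < 1e-3] + 1e-12) * 1e-3
      add <- cbind(add, Rs[, r] / den)
    }
    Vnew <- .orthonormalize(V, add)
    if (ncol(Vnew) == ncol(V)) break
    fresh <- (ncol(V) + 1):ncol(Vnew)
    AV <- cbind(AV, oi$A(Vnew[, fresh, drop = FALSE]))
    V <- Vnew
  }
  ord <- order(om)[seq_len(nRoots)]
  pairs <- if (is(op, "BSEOperator")) op@pairs
           else cbind(seq_len(n), rep(1L, n))
  new("ExcitonSolution", omegas = om[ord], xCoeff = X[, ord, drop = FALSE],
      yCoeff = matrix(0, n, nRoots), residualNorms = rnorm[ord],
      pairs = pairs, mode = "TDA", iterations = iterUsed,
      subspaceHistory = hist)
}
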