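# Restricted closed-shell HF / Kohn-Sham reference calculations.
#
# Exchange-correlation functionals are implemented as energy densities
# f(rho, gamma) with gamma = |grad rho|^2; the potential ingredients
# df/drho and df/dgamma are obtained by high-order central finite differences,
# which keeps the functional definitions short and hard to get wrong.  The
# LDA tag uses Slater exchange + PW92 correlation; PBEH40 is PBE with a 0.40
# exact-exchange admixture.

.CX <- 0.75 * (3 / pi)^(1 / 3)

.ecPW92 <- function(rs) {
  A <- 0.0310907; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  srs <- sqrt(rs)
  den <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log(1 + 1 / den)
}

# energy densities per volume; rho is the total closed-shell density
.fxcLDA <- function(rho, gamma) {
  rs <- (3 / (4 * pi * pmax(rho, 1e-300)))^(1 / 3)
  -.CX * rho^(4 / 3) + rho * .ecPW92(rs)
}

.fxcPBEx <- function(rho, gamma) {
  kappa <- 0.804; mu <- 0.2195149727645171
  kf <- (3 * pi^2 * rho)^(1 / 3)
  s2 <- gamma / (4 * kf^2 * rho^2)
  Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  -.CX * rho^(4 / 3) * Fx
}

.fxcPBEc <- function(rho, gamma) {
  gam <- (1 - log(2)) / pi^2
  beta <- 0.06672455060314922
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  ec <- .ecPW92(rs)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- gamma / (4 * ks^2 * rho^2)
  Aa <- beta / gam / (exp(-ec / gam) - 1)
  H <- gam * log(1 + beta / gam * t2 * (1 + Aa * t2) /
                   (1 + Aa * t2 + Aa^2 * t2^2))
  rho * (ec + H)
}

# functional table: energy density and exact-exchange fraction
.functionals <- list(
  HF = list(a = 1.0, f = NULL, gga = FALSE),
  LDA = list(a = 0.0, f = function(r, g) .fxcLDA(r, g), gga = FALSE),
  PBE = list(a = 0.0, f = function(r, g) .fxcPBEx(r, g) + .fxcPBEc(r, g),
             gga = TRUE),
  PBEH40 = list(a = 0.4,
                f = function(r, g) 0.6 * .fxcPBEx(r, g) + .fxcPBEc(r, g),
                gga = TRUE))

# ------------------------------------------------------------ molecular grid

.gaussLegendre <- function(n) {
  # Golub-Welsch on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

# Becke-partitioned atomic grids: Murray-Handy-Laming radial mapping,
# Gauss-Legendre x uniform-phi spherical product shells
.buildMolGrid <- function(mol, nrad = 50L, ntheta = 12L) {
  pos <- mol@coords / BOHR_ANGSTROM
  nat <- nrow(pos)
  rb <- .bragg[mol@symbols] / BOHR_ANGSTROM
  glr <- .gaussLegendre(ntheta)
  nphi <- 2L * ntheta
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- glr$x
  st <- sqrt(1 - ct^2)
  dirs <- cbind(c(outer(st, cos(phi))), c(outer(st, sin(phi))),
                rep(ct, nphi))
  wang <- rep(glr$w, nphi) * (2 * pi / nphi)
  pts <- NULL; wts <- NULL; owner <- NULL
  for (A in seq_len(nat)) {
    q <- seq_len(nrad) / (nrad + 1)
    r <- rb[A] * q^2 / (1 - q)^2
    wr <- (2 * rb[A] * q / (1 - q)^3) / (nrad + 1) * r^2
    p <- dirs[rep(seq_len(nrow(dirs)), nrad), ] *
      r[rep(seq_len(nrad), each = nrow(dirs))]
    p <- sweep(p, 2, pos[A, ], `+`)
    w <- rep(wr, each = nrow(dirs)) * rep(wang, nrad)
    pts <- rbind(pts, p)
    wts <- c(wts, w)
    owner <- c(owner, rep(A, length(w)))
  }
  if (nat > 1) {
    # Becke cell weights
    dAt <- matrix(0, nrow(pts), nat)
    for (A in seq_len(nat))
      dAt[, A] <- sqrt(rowSums(sweep(pts, 2, pos[A, ])^2))
    Rab <- as.matrix(stats::dist(pos))
    P <- matrix(1, nrow(pts), nat)
    for (A in seq_len(nat)) for (B in seq_len(nat)) {
      if (A == B) next
      mu <- (dAt[, A] - dAt[, B]) / Rab[A, B]
      for (k in 1:3) mu <- 1.5 * mu - 0.5 * mu^3
      P[, A] <- P[, A] * 0.5 * (1 - mu)
    }
    wts <- wts * P[cbind(seq_len(nrow(pts)), owner)] / rowSums(P)
  }
  keep <- wts > 1e-14
  list(points = pts[keep, , drop = FALSE], weights = wts[keep])
}

# df/drho and df/dgamma by 4th-order central differences
.xcDerivs <- function(f, rho, gamma) {
  d4 <- function(g, x, h) {
    (8 * (g(x + h) - g(x - h)) - (g(x + 2 * h) - g(x - 2 * h))) / (12 * h)
  }
  hr <- pmax(rho, 1e-8) * 1e-5
  vr <- d4(function(r) f(r, gamma), rho, hr)
  hg <- pmax(gamma, 1e-8) * 1e-5
  vg <- d4(function(g) f(rho, g), gamma, hg)
  list(vrho = vr, vgamma = vg)
}

# xc energy and AO-basis potential matrix on the grid
.xcBuild <- function(fun, bg, w, D) {
  val <- bg$val
  rho <- rowSums((val %*% D) * val)
  gx <- 2 * rowSums((bg$dx %*% D) * val)
  gy <- 2 * rowSums((bg$dy %*% D) * val)
  gz <- 2 * rowSums((bg$dz %*% D) * val)
  gamma <- gx^2 + gy^2 + gz^2
  live <- rho > 1e-11
  n <- ncol(val)
  if (!any(live)) return(list(exc = 0, vxc = matrix(0, n, n)))
  r <- rho[live]; g <- gamma[live]; wl <- w[live]
  exc <- sum(wl * fun$f(r, g))
  dv <- .xcDerivs(fun$f, r, g)
  vr <- dv$vrho
  Vl <- val[live, , drop = FALSE]
  vxc <- crossprod(Vl, Vl * (wl * vr))
  if (fun$gga) {
    cgx <- wl * 2 * dv$vgamma * gx[live]
    cgy <- wl * 2 * dv$vgamma * gy[live]
    cgz <- wl * 2 * dv$vgamma * gz[live]
    M <- crossprod(bg$dx[live, , drop = FALSE], Vl * cgx) +
         crossprod(bg$dy[live, , drop = FALSE], Vl * cgy) +
         crossprod(bg$dz[live, , drop = FALSE], Vl * cgz)
    vxc <- vxc + M + t(M)
  }
  list(exc = exc, vxc = (vxc + t(vxc)) / 2)
}

# --------------------------------------------------------------- SCF driver

# density with electrons distributed evenly over degenerate orbital groups
.guessDensity <- function(C, e, nocc, tol = 1e-7) {
  occ <- numeric(length(e))
  groups <- cumsum(c(TRUE, diff(e) > tol))
  left <- 2 * nocc
  for (g in unique(groups)) {
    idx <- which(groups == g)
    take <- min(left, 2 * length(idx))
    occ[idx] <- take / length(idx)
    left <- left - take
    if (left <= 0) break
  }
  C %*% (occ * t(C))
}

# Coulomb/exchange contraction matrices from the exact 4-center tensor
.jkMats <- function(ctx) {
  eri <- .eri4(ctx)
  n <- ctx$nbf
  Jm <- matrix(eri, n * n, n * n)
  Km <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)
  list(Jm = Jm, Km = Km, n = n)
}

.buildJK <- function(jk, D) {
  d <- as.vector(D)
  list(J = matrix(jk$Jm %*% d, jk$n, jk$n),
       K = matrix(jk$Km %*% d, jk$n, jk$n))
}

#' Run the mean-field (HF or Kohn-Sham) reference calculation
#'
#' Restricted closed-shell SCF with DIIS acceleration and a deterministic
#' core-Hamiltonian initial guess.  PBEH40 is the PBE hybrid with the
#' exact-exchange fraction raised to 0.40.
#'
#' @param mol a \linkS4class{Molecule} (closed shell)
#' @param basis a \linkS4class{BasisSpec} or primary basis name
#' @param referenceTag one of "HF", "LDA", "PBE", "PBEH40"
#' @param convEnergy,convOrb SCF convergence thresholds (Hartree / DIIS error)
#' @param maxIter maximum SCF cycles
#' @param verbose print per-iteration lines
#' @return a \linkS4class{MeanFieldSolution}
#' @export
runMeanField <- function(mol, basis, referenceTag = "HF",
                         convEnergy = 1e-10, convOrb = 1e-8,
                         maxIter = 200L, verbose = FALSE) {
  referenceTag <- toupper(referenceTag)
  fun <- .functionals[[referenceTag]]
  if (is.null(fun))
    stop("referenceTag must be one of HF, LDA, PBE, PBEH40", call. = FALSE)
  validObject(mol)
  ctx <- integralContext(mol, basis)
  jk <- .jkMats(ctx)
  S <- ctx$S
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    stop("primary overlap matrix is near-singular", call. = FALSE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  h <- ctx$hcore
  nocc <- ctx$nelec / 2
  grid <- NULL; bg <- NULL
  if (!is.null(fun$f)) {
    grid <- .buildMolGrid(mol)
    bg <- .evalBasis(ctx, grid$points)
  }
  # core guess with even filling of degenerate groups (plain aufbau through
  # a degenerate shell breaks spatial symmetry and can trap the SCF in a
  # symmetry-broken higher-energy solution)
  Fp <- t(X) %*% h %*% X
  ev <- .eigAsc(Fp)
  C <- X %*% ev$vectors
  D <- .guessDensity(C, ev$values, nocc)
  Eold <- 0
  diisF <- list(); diisE <- list()
  a <- fun$a
  for (it in seq_len(maxIter)) {
    JK <- .buildJK(jk, D)
    vxcM <- matrix(0, ctx$nbf, ctx$nbf)
    exc <- 0
    if (!is.null(fun$f)) {
      xb <- .xcBuild(fun, bg, grid$weights, D)
      vxcM <- xb$vxc
      exc <- xb$exc
    }
    Fm <- h + JK$J - 0.5 * a * JK$K + vxcM
    E <- sum(D * h) + 0.5 * sum(D * JK$J) - 0.25 * a * sum(D * JK$K) +
      exc + ctx$enuc
    err <- t(X) %*% (Fm %*% D %*% S - S %*% D %*% Fm) %*% X
    emax <- max(abs(err))
    if (verbose)
      message(sprintf("SCF %s iter %2d  E = %.10f  dE = %.2e  |err| = %.2e",
                      referenceTag, it, E, E - Eold, emax))
    if (abs(E - Eold) < convEnergy && emax < convOrb) {
      Eold <- E
      break
    }
    Eold <- E
    # DIIS
    diisF[[length(diisF) + 1]] <- Fm
    diisE[[length(diisE) + 1]] <- err
    if (length(diisF) > 8) { diisF <- diisF[-1]; diisE <- diisE[-1] }
    m <- length(diisF)
    if (m > 1) {
      Bm <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m)
        Bm[i, j] <- sum(diisE[[i]] * diisE[[j]])
      Bm[m + 1, 1:m] <- Bm[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(Bm, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        Fm <- matrix(0, ctx$nbf, ctx$nbf)
        for (i in 1:m) Fm <- Fm + cf[i] * diisF[[i]]
      }
    }
    Fp <- t(X) %*% Fm %*% X
    ev <- .eigAsc((Fp + t(Fp)) / 2)
    C <- X %*% ev$vectors
    D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    if (it == maxIter)
      stop("SCF failed to converge in ", maxIter, " iterations",
           call. = FALSE)
  }
  # final orbitals from the converged (un-extrapolated) Fock matrix
  JK <- .buildJK(jk, D)
  vxcM <- matrix(0, ctx$nbf, ctx$nbf)
  exc <- 0
  if (!is.null(fun$f)) {
    xb <- .xcBuild(fun, bg, grid$weights, D)
    vxcM <- xb$vxc
    exc <- xb$exc
  }
  Fm <- h + JK$J - 0.5 * a * JK$K + vxcM
  Fp <- t(X) %*% Fm %*% X
  ev <- .eigAsc((Fp + t(Fp)) / 2)
  C <- X %*% ev$vectors
  D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  E <- sum(D * h) + 0.5 * sum(D * JK$J) - 0.25 * a * sum(D * JK$K) +
    exc + ctx$enuc
  occ <- c(rep(2, nocc), rep(0, ctx$nbf - nocc))
  backend <- list(ctx = ctx, jk = jk, X = X, S = ctx$S, hcore = h,
                  density = D, grid = grid, basisGrid = bg,
                  functional = referenceTag)
  new("MeanFieldSolution", moCoeff = C, moEnergy = ev$values,
      occupations = occ, fock = Fm, vxc = vxcM, exchangeFraction = a,
      referenceTag = referenceTag, energy = E, backend = backend)
}
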