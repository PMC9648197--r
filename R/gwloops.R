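# G0W0, eigenvalue-self-consistent GW (evGW) and quasiparticle self-consistent
# GW (qsGW) drivers.
#
# Design notes:
# * the exchange self-energy and the Hartree term are evaluated with exact
#   four-center integrals (available for the small systems in scope); the RI
#   tensor serves the correlation/screening machinery.  With screening
#   disabled (W = v) the qsGW fixed point is then exactly the HF solution.
# * the static Hermitian effective Hamiltonian is
#     H_eff = h + J[D] + Sigma_x[D] + (Sigma_c(0) + Sigma_c(0)')/2,
#   assembled in a fixed Loewdin-orthonormalized AO basis so that linear
#   mixing across iterations is well defined.
# * imaginary grids are rebuilt from the current transition-energy range via
#   a padded cache, so successive iterations and different starting points
#   share identical quadrature rules.

#' GW/BSE configuration defaults
#'
#' All thresholds in atomic units unless noted.
#'
#' @param nGridPoints imaginary time/frequency nodes (default 16)
#' @param epsS auxiliary metric threshold (default 5e-3)
#' @param evgwConvHomo evGW stop: HOMO change between cycles, Hartree
#'   (default 3 meV)
#' @param qsgwConvDensity qsGW stop: Frobenius norm of the density-matrix
#'   change (default 5e-9)
#' @param maxCycles self-consistency cap
#' @param mixing linear mixing weight on the new effective Hamiltonian
#'   (used at startup and whenever DIIS extrapolation is not applicable)
#' @param screening "rpa" or "none" (W = v; exchange-only diagnostic limit)
#' @param phCutoff particle-hole transition-energy cutoff for the BSE space,
#'   Hartree (Inf keeps all pairs; 1.5 is the large-system setting)
#' @param davidsonTol eigenvalue convergence of the BSE solver, Hartree
#' @param nRoots number of excitons to converge
#' @param accel qsGW convergence accelerator: "diis" (Pulay extrapolation on
#'   the effective Hamiltonian, default) or "linear" mixing only
#' @return named list of settings
#' @export
gwConfig <- function(nGridPoints = 16L, epsS = 5e-3,
                     evgwConvHomo = 3e-3 / HARTREE_EV,
                     qsgwConvDensity = 5e-9, maxCycles = 50L, mixing = 0.3,
                     screening = c("rpa", "none"), phCutoff = Inf,
                     davidsonTol = 1e-5, nRoots = 6L,
                     accel = c("diis", "linear")) {
  list(nGridPoints = as.integer(nGridPoints), epsS = epsS,
       evgwConvHomo = evgwConvHomo, qsgwConvDensity = qsgwConvDensity,
       maxCycles = as.integer(maxCycles), mixing = mixing,
       screening = match.arg(screening), phCutoff = phCutoff,
       davidsonTol = davidsonTol, nRoots = as.integer(nRoots),
       accel = match.arg(accel))
}

# shared setup: RI tensor, windows, exact-exchange machinery
.gwSetup <- function(mf, config) {
  ctx <- mf@backend$ctx
  fitted <- buildFittedIntegrals(ctx, config$epsS)
  occ <- which(mf@occupations > 0)
  virt <- which(mf@occupations == 0)
  list(ctx = ctx, fitted = fitted, occ = occ, virt = virt,
       jk = mf@backend$jk, X = mf@backend$X, S = ctx$S, h = ctx$hcore)
}

.midgap <- function(e, occ, virt) (max(e[occ]) + min(e[virt])) / 2

# Gershgorin upper bound on the direct-RPA pole energies; the self-energy
# integrand carries exponents (e - mu) + Omega_m, so the grid range must
# cover them
.rpaPoleBound <- function(gaps, bOV) {
  nP <- dim(bOV)[1]
  b <- matrix(bOV, nP, length(gaps))
  vabs <- abs(crossprod(b))
  sq <- sqrt(gaps)
  rs <- gaps^2 + 4 * sq * (vabs %*% sq)
  sqrt(max(rs))
}

# grid for the current spectrum: covers ph gaps, |e - mu|, and the
# self-energy product exponents |e - mu| + Omega
.gridFor <- function(e, occ, virt, n, bOV = NULL) {
  mu <- .midgap(e, occ, virt)
  gap <- min(e[virt]) - max(e[occ])
  dmin <- gap / 2
  dmax <- max(max(e[virt]) - min(e[occ]), max(abs(e - mu)))
  if (!is.null(bOV))
    dmax <- max(abs(e - mu)) + .rpaPoleBound(.phGaps(e, occ, virt), bOV)
  .cachedGrid(n, dmin, dmax)
}

# screening stack + Wc(i tau) for a set of energies/orbitals
.screenStack <- function(e, C, setup, config) {
  bMO <- transformToMO(setup$fitted, C, setup$occ, setup$virt)
  grid <- .gridFor(e, setup$occ, setup$virt, config$nGridPoints, bMO$bOV)
  if (config$screening == "none") {
    nP <- dim(setup$fitted@bTensor)[1]
    nt <- length(grid@tauPoints)
    zero <- lapply(seq_len(nt), function(k) matrix(0, nP, nP))
    return(list(grid = grid, bMO = bMO, wcTau = zero,
                scr = NULL))
  }
  scr <- buildScreening(e, setup$occ, setup$virt, bMO$bOV, grid)
  list(grid = grid, bMO = bMO, wcTau = .wcTau(scr@wOmega, grid), scr = scr)
}

# ------------------------------------------------------------- evGW / G0W0

#' Eigenvalue-self-consistent GW (and its one-shot G0W0 limit)
#'
#' Orbitals stay fixed at the mean-field reference; all quasiparticle
#' energies (occupied and virtual) are updated each cycle and the screening
#' is rebuilt from the updated energies.  The first cycle is exactly G0W0.
#'
#' @param mf a converged \linkS4class{MeanFieldSolution}
#' @param config settings from \code{gwConfig}
#' @param maxCycles override of \code{config$maxCycles} (1 for G0W0)
#' @param methodTag label stored in the result
#' @param verbose print per-iteration lines
#' @return a \linkS4class{QPSolution}
#' @export
runEvGW <- function(mf, config = gwConfig(), maxCycles = config$maxCycles,
                    methodTag = if (maxCycles == 1L) "G0W0" else "evGW",
                    verbose = FALSE) {
  setup <- .gwSetup(mf, config)
  occ <- setup$occ; virt <- setup$virt
  C <- mf@moCoeff
  eRef <- mf@moEnergy
  D <- mf@backend$density
  # exact-exchange and xc pieces of the reference (orbitals fixed)
  Kx <- .buildJK(setup$jk, D)$K
  sxDiag <- diag(-0.5 * crossprod(C, Kx %*% C))
  vxcDiag <- diag(crossprod(C, mf@vxc %*% C)) +
    mf@exchangeFraction * sxDiag
  e <- eRef
  hist <- data.frame()
  converged <- FALSE
  damping <- 1.0
  gapPrev <- NA_real_
  oscCount <- 0L
  for (cycle in seq_len(maxCycles)) {
    st <- .screenStack(e, C, setup, config)
    mu <- .midgap(e, occ, virt)
    sct <- sigmaCTau(e, mu, st$bMO$bFull, st$wcTau, st$grid, occ, virt)
    scw <- sigmaCOmega(sct, st$grid)
    eNew <- e
    for (n in seq_along(e)) {
      acm <- analyticContinuation(1i * st$grid@omegaPoints, scw[, n, n])
      eNew[n] <- solveQpDiagonal(eRef[n], sxDiag[n], vxcDiag[n], acm, mu)$e
    }
    dHomo <- abs(max(eNew[occ]) - max(e[occ]))
    e <- e + damping * (eNew - e)
    gap <- min(e[virt]) - max(e[occ])
    hist <- rbind(hist, data.frame(iter = cycle, gap_eV = gap * HARTREE_EV,
                                   conv = dHomo))
    if (verbose)
      message(sprintf("%s cycle %d: gap = %.4f eV, dHOMO = %.2e Ha",
                      methodTag, cycle, gap * HARTREE_EV, dHomo))
    if (cycle > 1 && !is.na(gapPrev)) {
      if (sign(gap - gapPrev) != sign(gapPrev - hist$gap_eV[max(1, cycle - 2)] /
                                        HARTREE_EV)) {
        oscCount <- oscCount + 1L
        if (oscCount >= 4L) damping <- 0.5
      }
    }
    gapPrev <- gap
    if (maxCycles == 1L || dHomo < config$evgwConvHomo) {
      converged <- TRUE
      break
    }
  }
  qpC <- diag(length(e))
  new("QPSolution", qpEnergy = e, effHamiltonian = diag(e), qpCoeff = qpC,
      moCoeff = C, densityMatrix = D,
      occupations = mf@occupations, history = hist, methodTag = methodTag,
      converged = converged,
      backend = c(mf@backend, list(setup = setup, config = config,
                                   meanField = mf)))
}

#' One-shot perturbative G0W0
#'
#' @inheritParams runEvGW
#' @return a \linkS4class{QPSolution} with method tag G0W0
#' @export
runG0W0 <- function(mf, config = gwConfig(), verbose = FALSE)
  runEvGW(mf, config, maxCycles = 1L, methodTag = "G0W0", verbose = verbose)

# ------------------------------------------------------------------- qsGW

#' Quasiparticle self-consistent GW
#'
#' Iterates the static Hermitian effective Hamiltonian
#' H_eff = h + J[D] + Sigma_x[D] + sym(Sigma_c(0)) to a stationary density
#' matrix.  Orbitals and energies are re-derived each cycle by diagonalizing
#' the (linearly mixed) H_eff; the screening and self-energy are rebuilt from
#' the updated spectrum every cycle.  The converged result is independent of
#' the mean-field starting point up to the numerical noise of the grids.
#'
#' @inheritParams runEvGW
#' @return a \linkS4class{QPSolution} with method tag qsGW
#' @export
runQsGW <- function(mf, config = gwConfig(), verbose = FALSE) {
  setup <- .gwSetup(mf, config)
  occ <- setup$occ; virt <- setup$virt
  nocc <- length(occ)
  X <- setup$X
  C <- mf@moCoeff
  e <- mf@moEnergy
  D <- mf@backend$density
  hist <- data.frame()
  converged <- FALSE
  Hprev <- NULL
  Horth <- NULL
  diisH <- list()
  diisR <- list()
  ePrev <- e
  for (cycle in seq_len(config$maxCycles)) {
    st <- .screenStack(e, C, setup, config)
    mu <- .midgap(e, occ, virt)
    Corth <- crossprod(X, setup$S %*% C)  # orthonormal-basis orbitals
    if (config$screening == "none") {
      scStat <- matrix(0, length(e), length(e))
    } else {
      sct <- sigmaCTau(e, mu, st$bMO$bFull, st$wcTau, st$grid, occ, virt)
      scStat <- sigmaCStatic(sct, st$grid)
    }
    JK <- .buildJK(setup$jk, D)
    Horth <- crossprod(X, (setup$h + JK$J - 0.5 * JK$K) %*% X) +
      Corth %*% scStat %*% t(Corth)
    Horth <- (Horth + t(Horth)) / 2
    # stationarity of the raw (unaccelerated) map: distance between the
    # current density and the density the bare H_eff would produce; the
    # internal safety factor keeps one further raw cycle below the nominal
    # threshold even when the raw map is only marginally contractive
    evRaw <- .eigAsc(Horth)
    CRaw <- X %*% evRaw$vectors
    DRaw <- 2 * tcrossprod(CRaw[, seq_len(nocc), drop = FALSE])
    dFix <- sqrt(sum((DRaw - D)^2))
    dEFix <- max(abs(evRaw$values - e))
    if (dFix < 0.4 * config$qsgwConvDensity && dEFix < 1e-7) {
      C <- CRaw
      e <- evRaw$values
      D <- DRaw
      gap <- min(e[virt]) - max(e[occ])
      hist <- rbind(hist, data.frame(iter = cycle, gap_eV = gap * HARTREE_EV,
                                     conv = dFix))
      if (verbose)
        message(sprintf("qsGW cycle %d: stationary (|dD| = %.2e)",
                        cycle, dFix))
      converged <- TRUE
      break
    }
    if (config$accel == "diis" && !is.null(Hprev)) {
      # Pulay extrapolation on the H_eff fixed point: residual = H_out - H_in
      diisH[[length(diisH) + 1]] <- Horth
      diisR[[length(diisR) + 1]] <- Horth - Hprev
      if (length(diisH) > 8) { diisH <- diisH[-1]; diisR <- diisR[-1] }
      m <- length(diisH)
      Huse <- NULL
      if (m > 1) {
        Bm <- matrix(0, m + 1, m + 1)
        for (i in 1:m) for (j in 1:m) Bm[i, j] <- sum(diisR[[i]] * diisR[[j]])
        Bm[m + 1, 1:m] <- Bm[1:m, m + 1] <- -1
        cf <- tryCatch(solve(Bm, c(rep(0, m), -1))[1:m],
                       error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          Huse <- matrix(0, nrow(Horth), ncol(Horth))
          for (i in 1:m) Huse <- Huse + cf[i] * diisH[[i]]
        }
      }
      if (is.null(Huse))
        Huse <- (1 - config$mixing) * Hprev + config$mixing * Horth
    } else {
      Huse <- if (is.null(Hprev)) Horth
              else (1 - config$mixing) * Hprev + config$mixing * Horth
    }
    Hprev <- Huse
    ev <- .eigAsc(Huse)
    CorthNew <- ev$vectors
    e <- ev$values
    C <- X %*% CorthNew
    Dnew <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    dD <- sqrt(sum((Dnew - D)^2))
    D <- Dnew
    gap <- min(e[virt]) - max(e[occ])
    hist <- rbind(hist, data.frame(iter = cycle, gap_eV = gap * HARTREE_EV,
                                   conv = dFix))
    if (verbose)
      message(sprintf("qsGW cycle %d: gap = %.4f eV, |dD| = %.2e, raw |dD| = %.2e",
                      cycle, gap * HARTREE_EV, dD, dFix))
  }
  Corth <- crossprod(X, setup$S %*% C)
  effH <- crossprod(Corth, Horth %*% Corth)
  qpC <- crossprod(mf@moCoeff, setup$S %*% C)
  new("QPSolution", qpEnergy = e, effHamiltonian = effH, qpCoeff = qpC,
      moCoeff = C, densityMatrix = D, occupations = mf@occupations,
      history = hist, methodTag = "qsGW", converged = converged,
      backend = c(mf@backend, list(setup = setup, config = config,
                                   meanField = mf)))
}

#' Serialize a quasiparticle solution to JSON
#'
#' Writes energies (Hartree and eV), occupations, the per-iteration history
#' and method metadata.
#'
#' @param qp a \linkS4class{QPSolution}
#' @param path output file
#' @export
writeQPSolutionJSON <- function(qp, path) {
  jsonlite::write_json(list(
    method = qp@methodTag,
    converged = qp@converged,
    qp_energy_Ha = qp@qpEnergy,
    qp_energy_eV = qp@qpEnergy * HARTREE_EV,
    occupations = qp@occupations,
    homo_lumo_gap_eV = homoLumoGap(qp) * HARTREE_EV,
    history = qp@history), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
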