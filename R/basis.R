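# Shell construction, even-tempered auxiliary generation and the integral
# context shared by SCF, RI and all downstream modules.  Positions are
# converted to Bohr here; contraction coefficients get primitive norms folded
# in, and the final per-AO normalization is taken from the raw overlap (or
# Coulomb-metric) diagonal, which normalizes every Cartesian component exactly.

.dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

.primNorm <- function(a, l)
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.dfact(2 * l - 1))

#' Basis specification constructor
#' @param primaryName primary basis identifier (see \code{availableBases()})
#' @param auxiliaryName auxiliary set: "auto-basic", "auto-good" or
#'   "auto-verygood" even-tempered families (increasing density)
#' @param frozenCore logical
#' @return a \linkS4class{BasisSpec}
#' @export
basisSpec <- function(primaryName = "sto-3g", auxiliaryName = "auto-good",
                      frozenCore = FALSE) {
  new("BasisSpec", primaryName = tolower(primaryName),
      auxiliaryName = tolower(auxiliaryName), frozenCore = frozenCore)
}

# expand the element shell library onto the atoms of a molecule
.buildShells <- function(mol, basisName) {
  lib <- .basis_library[[tolower(basisName)]]
  if (is.null(lib))
    stop("unknown primary basis '", basisName, "'", call. = FALSE)
  shells <- list()
  for (at in seq_along(mol@symbols)) {
    sym <- mol@symbols[at]
    esh <- lib[[sym]]
    if (is.null(esh))
      stop("basis ", basisName, " has no data for element ", sym,
           call. = FALSE)
    for (sh in esh) {
      coefs <- sh$coefs * vapply(sh$exps, .primNorm, 1.0, l = sh$l)
      shells[[length(shells) + 1]] <- list(
        l = sh$l, center = mol@coords[at, ] / BOHR_ANGSTROM,
        exps = sh$exps, coefs = coefs, atom = at)
    }
  }
  shells
}

# even-tempered auxiliary shells spanning the primary product-exponent range
.buildAuxShells <- function(mol, basisName, quality = "good") {
  beta <- switch(quality, basic = 3.0, good = 2.5, verygood = 2.0,
                 stop("auxiliary quality must be basic/good/verygood"))
  lib <- .basis_library[[tolower(basisName)]]
  shells <- list()
  for (at in seq_along(mol@symbols)) {
    sym <- mol@symbols[at]
    esh <- lib[[sym]]
    allE <- unlist(lapply(esh, `[[`, "exps"))
    pE <- unlist(lapply(esh[vapply(esh, `[[`, 0L, "l") == 1L], `[[`, "exps"))
    lmax <- max(vapply(esh, `[[`, 0L, "l"))
    lauxMax <- if (lmax == 0) 1L else 2L
    for (laux in 0:lauxMax) {
      emax <- if (laux == 0) 2 * max(allE)
              else 2 * max(if (length(pE)) pE else allE)
      emin <- min(allE)
      nexp <- max(2L, ceiling(log(emax / emin) / log(beta)) + 1L)
      exps <- emin * beta^(seq_len(nexp) - 1)
      for (a in exps) {
        shells[[length(shells) + 1]] <- list(
          l = laux, center = mol@coords[at, ] / BOHR_ANGSTROM,
          exps = a, coefs = .primNorm(a, laux), atom = at)
      }
    }
  }
  shells
}

.flattenShells <- function(shells) {
  list(l = vapply(shells, `[[`, 0L, "l"),
       centers = do.call(rbind, lapply(shells, `[[`, "center")),
       nprim = vapply(shells, function(s) length(s$exps), 0L),
       exps = unlist(lapply(shells, `[[`, "exps")),
       coefs = unlist(lapply(shells, `[[`, "coefs")))
}

.ncart <- function(l) (l + 1) * (l + 2) / 2

# atom index per AO (cartesian component) for a shell list
.aoAtoms <- function(shells)
  unlist(lapply(shells, function(s) rep(s$atom, .ncart(s$l))))

#' Build the integral context for a molecule/basis combination
#'
#' Computes normalized overlap, kinetic, nuclear-attraction and dipole
#' integrals and keeps the flattened shell data for on-demand two-electron
#' integral evaluation.  The dipole origin is the center of nuclear charge.
#'
#' @param mol a \linkS4class{Molecule}
#' @param basis a \linkS4class{BasisSpec} or a primary basis name
#' @return list with fields S, T, V, hcore, dipole (list x/y/z), nbf, nelec,
#'   shells, aux shells, normalization vectors and molecule metadata
#' @export
integralContext <- function(mol, basis) {
  if (is.character(basis)) basis <- basisSpec(basis)
  validObject(mol)
  shells <- .buildShells(mol, basis@primaryName)
  quality <- sub("^auto-", "", basis@auxiliaryName)
  auxShells <- .buildAuxShells(mol, basis@primaryName, quality)
  fl <- .flattenShells(shells)
  pos <- mol@coords / BOHR_ANGSTROM
  Z <- elementZ(mol@symbols)
  origin <- colSums(pos * Z) / sum(Z)
  one <- cppOneElectron(fl$l, fl$centers, fl$nprim, fl$exps, fl$coefs,
                        pos, as.numeric(Z), origin)
  nrm <- 1 / sqrt(diag(one$S))
  sc <- function(M) M * outer(nrm, nrm)
  ctx <- list(
    molecule = mol, basis = basis, shells = shells, auxShells = auxShells,
    flat = fl, flatAux = .flattenShells(auxShells),
    norm = nrm, nbf = length(nrm), nelec = sum(Z) - mol@charge,
    atomPos = pos, atomZ = Z, aoAtom = .aoAtoms(shells),
    S = sc(one$S), T = sc(one$T), V = sc(one$V),
    dipole = list(x = sc(one$Dx), y = sc(one$Dy), z = sc(one$Dz)),
    enuc = {
      en <- 0
      n <- nrow(pos)
      if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
        en <- en + Z[i] * Z[j] / sqrt(sum((pos[i, ] - pos[j, ])^2))
      en
    })
  ctx$hcore <- ctx$T + ctx$V
  ctx
}

# exact four-center ERI tensor, normalized; guarded against large systems
.eri4 <- function(ctx, maxBasis = 40L) {
  if (ctx$nbf > maxBasis)
    stop("four-center tensor requested for ", ctx$nbf,
         " basis functions; dense route is guarded to <= ", maxBasis,
         call. = FALSE)
  fl <- ctx$flat
  eri <- cppERI4(fl$l, fl$centers, fl$nprim, fl$exps, fl$coefs)
  n <- ctx$nbf
  nr <- ctx$norm
  eri * outer(outer(nr, nr), outer(nr, nr))
}

# raw auxiliary Coulomb metric and normalized three-center tensor
.auxMetric <- function(ctx) {
  fa <- ctx$flatAux
  J <- cppERI2(fa$l, fa$centers, fa$nprim, fa$exps, fa$coefs)
  anrm <- 1 / sqrt(diag(J))
  list(J = J * outer(anrm, anrm), anrm = anrm)
}

.eri3 <- function(ctx, anrm) {
  fa <- ctx$flatAux
  fl <- ctx$flat
  t3 <- cppERI3(fa$l, fa$centers, fa$nprim, fa$exps, fa$coefs,
                fl$l, fl$centers, fl$nprim, fl$exps, fl$coefs)
  t3 * outer(anrm, outer(ctx$norm, ctx$norm))
}

# basis values (and gradients) on grid points, for the xc quadrature;
# primary bases carry only s and p shells
.evalBasis <- function(ctx, pts) {
  np <- nrow(pts)
  n <- ctx$nbf
  val <- matrix(0, np, n)
  dx <- matrix(0, np, n); dy <- matrix(0, np, n); dz <- matrix(0, np, n)
  off <- 0
  for (sh in ctx$shells) {
    rx <- pts[, 1] - sh$center[1]
    ry <- pts[, 2] - sh$center[2]
    rz <- pts[, 3] - sh$center[3]
    r2 <- rx^2 + ry^2 + rz^2
    g <- 0; gp <- 0  # radial part and its exponent-weighted derivative factor
    for (k in seq_along(sh$exps)) {
      e <- exp(-sh$exps[k] * r2) * sh$coefs[k]
      g <- g + e
      gp <- gp - 2 * sh$exps[k] * e
    }
    if (sh$l == 0) {
      val[, off + 1] <- g
      dx[, off + 1] <- rx * gp
      dy[, off + 1] <- ry * gp
      dz[, off + 1] <- rz * gp
      off <- off + 1
    } else if (sh$l == 1) {
      comp <- list(rx, ry, rz)
      for (c1 in 1:3) {
        v <- comp[[c1]] * g
        val[, off + c1] <- v
        dx[, off + c1] <- comp[[c1]] * rx * gp + (c1 == 1) * g
        dy[, off + c1] <- comp[[c1]] * ry * gp + (c1 == 2) * g
        dz[, off + c1] <- comp[[c1]] * rz * gp + (c1 == 3) * g
      }
      off <- off + 3
    } else {
      stop("grid evaluation implemented for s/p primary shells only")
    }
  }
  sweepN <- function(M) sweep(M, 2, ctx$norm, `*`)
  list(val = sweepN(val), dx = sweepN(dx), dy = sweepN(dy), dz = sweepN(dz))
}
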