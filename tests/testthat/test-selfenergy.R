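# Exchange and correlation self-energy, analytic continuation and the
# diagonal quasiparticle equation.

test_that("zero occupied space gives a zero exchange self-energy", {
  b <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  expect_equal(sigmaExchange(b, integer(0)), matrix(0, 4, 4))
})

test_that("RI exchange matrix matches the backend exchange operator", {
  mf <- cachedMF("h2", "HF")
  occ <- which(mf@occupations > 0)
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, which(mf@occupations == 0))
  sx <- sigmaExchange(bMO$bFull, occ)
  D <- mf@backend$density
  Kmo <- crossprod(mf@moCoeff,
                   gwbse:::.buildJK(mf@backend$jk, D)$K %*% mf@moCoeff)
  eriErr <- max(abs(gwbse:::.riReconstruct(fit) -
                      gwbse:::.eri4(mf@backend$ctx)))
  expect_lt(max(abs(sx - (-0.5 * Kmo))), 20 * eriErr)
  expect_lt(max(abs(sx - t(sx))), 1e-12)
})

test_that("W = v (no screening) gives a vanishing correlation self-energy", {
  mf <- cachedMF("h2", "HF")
  occ <- 1L; virt <- 2L
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
  grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
  nP <- dim(fit@bTensor)[1]
  wcZero <- lapply(grid@tauPoints, function(t) matrix(0, nP, nP))
  sct <- sigmaCTau(mf@moEnergy, 0, bMO$bFull, wcZero, grid, occ, virt)
  expect_true(all(vapply(sct$Sp, function(m) max(abs(m)) == 0, TRUE)))
  expect_true(all(vapply(sct$Sh, function(m) max(abs(m)) == 0, TRUE)))
  expect_equal(sigmaCStatic(sct, grid), matrix(0, 2, 2))
})

test_that("analytic continuation is exact for constants and single poles", {
  om <- exp(seq(log(0.1), log(30), length.out = 16))
  mc <- analyticContinuation(1i * om, rep(2.5 + 0i, 16))
  expect_equal(Re(mc(0.3)), 2.5, tolerance = 1e-12)
  mp <- analyticContinuation(1i * om, 1 / (1i * om + 2.0))
  expect_equal(Re(mp(1.0)), 1 / 3, tolerance = 1e-8)
})

test_that("tau-route Sigma_c agrees with the sum-over-states closed form", {
  for (name in c("h2", "n2")) {
    mf <- cachedMF(name, "HF")
    occ <- which(mf@occupations > 0); virt <- which(mf@occupations == 0)
    fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
    bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
    grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
    scr <- buildScreening(mf@moEnergy, occ, virt, bMO$bOV, grid)
    poles <- rpaPoles(mf@moEnergy, occ, virt, bMO$bOV)
    mu <- gwbse:::.midgap(mf@moEnergy, occ, virt)
    sct <- sigmaCTau(mf@moEnergy, mu, bMO$bFull,
                     gwbse:::.wcTau(scr@wOmega, grid), grid, occ, virt)
    scw <- sigmaCOmega(sct, grid)
    homo <- max(occ)
    for (j in c(1, 8, 16)) {
      ref <- sosSigmaC(poles, bMO$bFull, mf@moEnergy, occ, virt,
                       complex(real = mu, imaginary = grid@omegaPoints[j]),
                       homo)
      expect_lt(abs(scw[j, homo, homo] - ref), 1e-6)
    }
  }
})

test_that("diagonal QP equation: exact limits", {
  # Sigma_c = 0 and vxcEff = Sigma_x: the reference energy is unchanged
  ac0 <- analyticContinuation(1i * c(1, 2, 4, 8), rep(0 + 0i, 4))
  r <- solveQpDiagonal(-0.5, sx = -0.3, vxcEff = -0.3, ac0, mu = 0)
  expect_equal(r$e, -0.5, tolerance = 1e-10)
  # constant Sigma_c = c: e = eRef + sx + c - vxc exactly
  acC <- analyticContinuation(1i * c(1, 2, 4, 8), rep(0.07 + 0i, 4))
  r2 <- solveQpDiagonal(-0.5, sx = -0.3, vxcEff = -0.25, acC, mu = 0)
  expect_equal(r2$e, -0.5 - 0.3 + 0.07 + 0.25, tolerance = 1e-9)
  expect_true(r2$converged)
})

test_that("G0W0 HOMO matches the brute-force spectral oracle within 5 meV", {
  mf <- cachedMF("h2o", "PBE")
  qp <- memo("g0w0_h2o_pbe", runG0W0(mf))
  homo <- max(which(mf@occupations > 0))
  oracle <- memo("g0w0_oracle_h2o_pbe", g0w0Spectral(mf, homo))
  expect_lt(abs(qpEnergies(qp)[homo] - oracle), 5e-3 / 27.211386)
})

test_that("analytic continuation to the real axis matches SOS below the gap", {
  mf <- cachedMF("h2", "HF")
  occ <- 1L; virt <- 2L
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
  grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
  scr <- buildScreening(mf@moEnergy, occ, virt, bMO$bOV, grid)
  poles <- rpaPoles(mf@moEnergy, occ, virt, bMO$bOV)
  mu <- gwbse:::.midgap(mf@moEnergy, occ, virt)
  sct <- sigmaCTau(mf@moEnergy, mu, bMO$bFull,
                   gwbse:::.wcTau(scr@wOmega, grid), grid, occ, virt)
  scw <- sigmaCOmega(sct, grid)
  acm <- analyticContinuation(1i * grid@omegaPoints, scw[, 1, 1])
  for (er in seq(-0.8, -0.35, by = 0.05)) {
    ref <- Re(sosSigmaC(poles, bMO$bFull, mf@moEnergy, occ, virt,
                        complex(real = er), 1))
    expect_lt(abs(Re(acm(er - mu)) - ref), 1e-6)
  }
})
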