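# evGW / G0W0 / qsGW self-consistency drivers.

test_that("a huge evGW threshold returns after one cycle, identical to G0W0", {
  mf <- cachedMF("h2", "HF")
  ev1 <- runEvGW(mf, gwConfig(evgwConvHomo = 1.0))
  g0 <- runG0W0(mf)
  expect_equal(nrow(ev1@history), 1L)
  expect_equal(ev1@qpEnergy, g0@qpEnergy, tolerance = 1e-12)
})

test_that("with W frozen to v, evGW gives HF-like eigenvalues from any start", {
  for (ref in c("HF", "PBE")) {
    mf <- cachedMF("h2", ref)
    qp <- runEvGW(mf, gwConfig(screening = "none"))
    expect_lte(nrow(qp@history), 2L)
    # e = e_ref + Sigma_x - vxc_eff: exchange-only (Koopmans-like) spectrum
    occ <- which(mf@occupations > 0)
    D <- mf@backend$density
    Kx <- gwbse:::.buildJK(mf@backend$jk, D)$K
    C <- mf@moCoeff
    sx <- diag(-0.5 * crossprod(C, Kx %*% C))
    vx <- diag(crossprod(C, mf@vxc %*% C)) + mf@exchangeFraction * sx
    expect_equal(qp@qpEnergy, mf@moEnergy + sx - vx, tolerance = 1e-8)
  }
})

test_that("evGW reduces the starting-point dependence relative to G0W0", {
  gapsEv <- vapply(c("PBE", "PBEH40"), function(r)
    homoLumoGap(cachedEvGW(r)), 1.0)
  gapsG0 <- vapply(c("PBE", "PBEH40"), function(r)
    homoLumoGap(memo(paste0("g0w0_h2o_", r), runG0W0(cachedMF("h2o", r)))),
    1.0)
  expect_lt(abs(diff(gapsEv)), abs(diff(gapsG0)))
})

test_that("qsGW converges on fixtures within 20 cycles and reaches its
          density fixed point", {
  qp <- cachedQsGW("PBEH40")
  expect_true(qp@converged)
  expect_lte(nrow(qp@history), 20L)
  expect_lt(utils::tail(qp@history$conv, 1), 5e-9)
})

test_that("one extra qsGW cycle leaves the density stationary (< 5e-9)", {
  qp <- cachedQsGW("PBEH40")
  cfg <- gwConfig()
  setup <- qp@backend$setup
  occ <- setup$occ; virt <- setup$virt
  X <- setup$X
  C <- qp@moCoeff
  e <- qp@qpEnergy
  D <- qp@densityMatrix
  st <- gwbse:::.screenStack(e, C, setup, cfg)
  mu <- gwbse:::.midgap(e, occ, virt)
  sct <- sigmaCTau(e, mu, st$bMO$bFull, st$wcTau, st$grid, occ, virt)
  scStat <- sigmaCStatic(sct, st$grid)
  JK <- gwbse:::.buildJK(setup$jk, D)
  Corth <- crossprod(X, setup$S %*% C)
  H <- crossprod(X, (setup$h + JK$J - 0.5 * JK$K) %*% X) +
    Corth %*% scStat %*% t(Corth)
  ev <- gwbse:::.eigAsc((H + t(H)) / 2)
  Cn <- X %*% ev$vectors
  Dn <- 2 * tcrossprod(Cn[, seq_along(occ), drop = FALSE])
  expect_lt(sqrt(sum((Dn - D)^2)), 5e-9)
})

test_that("qsGW effective Hamiltonian is Hermitian and diagonal at the
          fixed point", {
  qp <- cachedQsGW("PBEH40")
  H <- qp@effHamiltonian
  expect_lt(max(abs(H - t(H))), 1e-10)
  offd <- H - diag(diag(H))
  expect_lt(max(abs(offd)), 1e-5)
  expect_equal(diag(H), qp@qpEnergy, tolerance = 1e-5)
})

test_that("with screening disabled qsGW converges to HF from any start", {
  mfHF <- cachedMF("h2o", "HF")
  for (ref in c("HF", "PBE")) {
    qp <- runQsGW(cachedMF("h2o", ref), gwConfig(screening = "none"))
    expect_true(qp@converged)
    expect_equal(qp@qpEnergy, mfHF@moEnergy, tolerance = 5e-7)
  }
})

test_that("qsGW orbital rotations stay orthonormal and aufbau-filled", {
  qp <- cachedQsGW("PBE")
  S <- qp@backend$ctx$S
  C <- qp@moCoeff
  expect_lt(max(abs(crossprod(C, S %*% C) - diag(ncol(C)))), 1e-9)
  expect_lt(max(abs(crossprod(qp@qpCoeff) - diag(ncol(C)))), 1e-9)
  occ <- which(qp@occupations > 0)
  expect_true(max(qp@qpEnergy[occ]) <
                min(qp@qpEnergy[qp@occupations == 0]))
})
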