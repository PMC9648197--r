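# RPA polarizability, screened interaction and the static time-integration
# route, checked against closed forms and sum-over-states.

twoLevel <- function() {
  list(e = c(0, 0.5), occ = 1L, virt = 2L,
       bOV = array(0.1, c(1, 1, 1)),
       grid = memo("grid_twolevel", buildGrids(12, c(0.2, 1.2))))
}

test_that("no particle-hole pairs means zero polarizability", {
  tl <- twoLevel()
  p <- polarizabilityTau(tl$e, integer(0), tl$virt,
                         array(0, c(3, 0, 1)), tl$grid)
  expect_true(all(vapply(p, function(m) max(abs(m)) == 0, TRUE)))
})

test_that("two-level P(itau) matches the exponential closed form", {
  tl <- twoLevel()
  p <- polarizabilityTau(tl$e, tl$occ, tl$virt, tl$bOV, tl$grid)
  for (k in seq_along(tl$grid@tauPoints))
    expect_equal(p[[k]][1, 1],
                 -2 * 0.01 * exp(-0.5 * tl$grid@tauPoints[k]),
                 tolerance = 1e-12)
})

test_that("metallic (non-positive-gap) input is rejected", {
  tl <- twoLevel()
  expect_error(polarizabilityTau(c(0.5, 0.2), 1, 2, tl$bOV, tl$grid),
               "metallic|gap")
})

test_that("P = 0 gives W = v exactly", {
  W <- screenedInteractionOmega(list(matrix(0, 4, 4)))[[1]]
  expect_equal(W, diag(4), tolerance = 1e-14)
  st <- staticScreenedInteraction(
    lapply(1:12, function(k) matrix(0, 3, 3)),
    memo("grid_twolevel", buildGrids(12, c(0.2, 1.2))))
  expect_equal(st$w0, diag(3), tolerance = 1e-14)
})

test_that("two-level static screening matches the closed-form algebra", {
  tl <- twoLevel()
  # P00(w=0) = -4 * 0.01 * 0.5 / 0.25 = -0.08; W00 = 1/(1 + 0.08)
  P0 <- sosPolarizability(tl$e, tl$occ, tl$virt, tl$bOV, 0)
  expect_equal(P0[1, 1], -0.08, tolerance = 1e-14)
  W0 <- screenedInteractionOmega(list(P0))[[1]]
  expect_equal(W0[1, 1], 1 / 1.08, tolerance = 1e-14)
  # time-integrated route within the grid's certified error
  p <- polarizabilityTau(tl$e, tl$occ, tl$virt, tl$bOV, tl$grid)
  st <- staticScreenedInteraction(p, tl$grid)
  expect_lt(abs(st$p0[1, 1] + 0.08),
            10 * tl$grid@certifiedError[["quad_tau"]] * 0.08 + 1e-12)
})

test_that("cosine-transformed P(iw) matches sum-over-states on water", {
  mf <- cachedMF("h2o", "HF")
  occ <- which(mf@occupations > 0); virt <- which(mf@occupations == 0)
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
  grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
  scr <- memo("scr_h2o_hf", buildScreening(mf@moEnergy, occ, virt,
                                           bMO$bOV, grid))
  tol <- 10 * grid@certifiedError[["cos_tw"]]
  for (j in c(1, 8, 16)) {
    Pref <- sosPolarizability(mf@moEnergy, occ, virt, bMO$bOV,
                              grid@omegaPoints[j])
    expect_lt(max(abs(scr@meta$pOmega[[j]] - Pref)),
              tol * max(abs(Pref)) + 1e-10)
  }
})

test_that("screening matrices are symmetric, P NSD and v - W PSD", {
  scr <- memo("scr_h2o_hf", {
    mf <- cachedMF("h2o", "HF")
    occ <- which(mf@occupations > 0); virt <- which(mf@occupations == 0)
    fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
    bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
    grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
    buildScreening(mf@moEnergy, occ, virt, bMO$bOV, grid)
  })
  for (k in seq_along(scr@pTau)) {
    M <- scr@pTau[[k]]
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_lte(max(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               1e-10)
  }
  for (j in seq_along(scr@wOmega)) {
    W <- scr@wOmega[[j]]
    expect_lt(max(abs(W - t(W))), 1e-12)
    ev <- eigen(diag(nrow(W)) - W, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("static route equals the direct omega = 0 route on fixtures", {
  for (name in c("h2", "h2o")) {
    mf <- cachedMF(name, "HF")
    occ <- which(mf@occupations > 0); virt <- which(mf@occupations == 0)
    fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
    bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
    grid <- gwbse:::.gridFor(mf@moEnergy, occ, virt, 16L, bMO$bOV)
    p <- polarizabilityTau(mf@moEnergy, occ, virt, bMO$bOV, grid)
    st <- staticScreenedInteraction(p, grid)
    P0 <- sosPolarizability(mf@moEnergy, occ, virt, bMO$bOV, 0)
    W0 <- screenedInteractionOmega(list(P0))[[1]]
    expect_lt(max(abs(st$w0 - W0)), 1e-6)
  }
})

test_that("doubling the grid size does not move W(0) beyond certified error", {
  mf <- cachedMF("h2", "HF")
  occ <- which(mf@occupations > 0); virt <- which(mf@occupations == 0)
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, virt)
  rng <- c(0.5, 2)
  g1 <- buildGrids(8, rng)
  g2 <- buildGrids(16, rng)
  w1 <- staticScreenedInteraction(
    polarizabilityTau(mf@moEnergy, occ, virt, bMO$bOV, g1), g1)$w0
  w2 <- staticScreenedInteraction(
    polarizabilityTau(mf@moEnergy, occ, virt, bMO$bOV, g2), g2)$w0
  expect_lt(max(abs(w1 - w2)),
            10 * g1@certifiedError[["quad_tau"]] + 1e-10)
})
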