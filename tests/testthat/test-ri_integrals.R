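# Resolution-of-identity tensor: metric regularization, reconstruction
# accuracy against the exact four-center oracle, MO transforms.

test_that("fitted integrals reconstruct the exact ERIs within RI error", {
  mf <- cachedMF("h2", "HF")
  ctx <- mf@backend$ctx
  fit <- buildFittedIntegrals(ctx, epsS = 0)
  eriRI <- gwbse:::.riReconstruct(fit)
  eriEx <- gwbse:::.eri4(ctx)
  # (11|11) within the (measured) RI accuracy of this auxiliary family
  expect_lt(abs(eriRI[1, 1, 1, 1] - eriEx[1, 1, 1, 1]), 2e-3)
  expect_lt(max(abs(eriRI - eriEx)), 5e-3)
  # symmetry B[P,p,q] = B[P,q,p]
  expect_equal(fit@bTensor, aperm(fit@bTensor, c(1, 3, 2)), tolerance = 1e-12)
})

test_that("eps_s = 1 keeps only the largest metric eigendirection", {
  mf <- cachedMF("h2", "HF")
  fit <- buildFittedIntegrals(mf@backend$ctx, epsS = 1.0)
  expect_equal(fit@nAuxKept, 1L)
})

test_that("denser auxiliary families monotonically reduce the RI error", {
  fx <- makeFixture("h2o")
  errs <- vapply(c("auto-basic", "auto-good", "auto-verygood"), function(q) {
    ctx <- integralContext(fx$molecule, basisSpec(fx$basis, q))
    max(abs(gwbse:::.riReconstruct(buildFittedIntegrals(ctx, 0)) -
              gwbse:::.eri4(ctx)))
  }, 1.0)
  expect_true(errs[1] > errs[2] && errs[2] > errs[3])
})

test_that("discarding metric directions only lowers reconstructed (pq|pq)", {
  mf <- cachedMF("h2o", "HF")
  full <- gwbse:::.riReconstruct(buildFittedIntegrals(mf@backend$ctx, 0))
  cut <- gwbse:::.riReconstruct(buildFittedIntegrals(mf@backend$ctx, 1e-2))
  n <- dim(full)[1]
  for (p in seq_len(n)) for (q in seq_len(n)) {
    expect_lte(cut[p, q, p, q], full[p, q, p, q] + 1e-12)
    expect_gte(cut[p, q, p, q], -1e-10)  # fitted operator stays PSD
  }
})

test_that("MO transform is exact and respects window conventions", {
  mf <- cachedMF("h2", "HF")
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  n <- dim(fit@bTensor)[2]
  # identity coefficients: blocks are slices of the input tensor
  bI <- transformToMO(fit, diag(n), occ = 1, virt = 2)
  expect_equal(bI$bFull, fit@bTensor, tolerance = 1e-12)
  expect_equal(drop(bI$bOV), fit@bTensor[, 1, 2], tolerance = 1e-12)
  # true MO transform contracted back equals full-tensor transform
  C <- mf@moCoeff
  bM <- transformToMO(fit, C, occ = 1, virt = 2)
  P <- dim(fit@bTensor)[1]
  direct <- sapply(seq_len(P), function(k)
    crossprod(C[, 1], matrix(fit@bTensor[k, , ], n, n) %*% C[, 2]))
  expect_equal(drop(bM$bOV), as.numeric(direct), tolerance = 1e-12)
  # empty occupied window: empty block, no error
  b0 <- transformToMO(fit, C, occ = integer(0), virt = 1:2)
  expect_equal(dim(b0$bOV), c(P, 0L, 2L))
})

test_that("degenerate-orbital rotations leave summed OV weights invariant", {
  mf <- cachedMF("h2_dimer_far", "HF")
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  C <- mf@moCoeff
  b1 <- transformToMO(fit, C, occ = 1:2, virt = 3:4)
  # rotate the two (nearly) degenerate occupied orbitals
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  C2 <- C
  C2[, 1:2] <- C[, 1:2] %*% R
  b2 <- transformToMO(fit, C2, occ = 1:2, virt = 3:4)
  expect_equal(sum(b1$bOV^2), sum(b2$bOV^2), tolerance = 1e-10)
})

test_that("fitted exchange energy tracks the backend within measured RI error", {
  mf <- cachedMF("h2o", "HF")
  occ <- which(mf@occupations > 0)
  fit <- buildFittedIntegrals(mf@backend$ctx, 5e-3)
  bMO <- transformToMO(fit, mf@moCoeff, occ, which(mf@occupations == 0))
  sx <- sigmaExchange(bMO$bFull, occ)
  exRI <- sum(diag(sx)[occ])
  D <- mf@backend$density
  exExact <- -0.25 * sum(D * gwbse:::.buildJK(mf@backend$jk, D)$K)
  eriErr <- max(abs(gwbse:::.riReconstruct(fit) - gwbse:::.eri4(mf@backend$ctx)))
  expect_lt(abs(exRI - exExact), 100 * eriErr)
})

test_that("a broken (non-PSD) metric raises a hard error", {
  fit <- cachedMF("h2", "HF")
  expect_error(buildFittedIntegrals(fit@backend$ctx, epsS = -1), "epsS")
})
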