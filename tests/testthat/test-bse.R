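# BSE operator, matrix-free kernel applications and the paired Davidson
# solver (plus its Tamm-Dancoff variant).

test_that("1x1 paired problem has the closed-form solution", {
  sol <- davidsonSolve(list(A = matrix(1.0, 1, 1), B = matrix(0.2, 1, 1)),
                       nRoots = 1, tol = 1e-10)
  expect_equal(sol@omegas, sqrt(0.96), tolerance = 1e-10)
  expect_equal(colSums(sol@xCoeff^2) - colSums(sol@yCoeff^2), 1,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("B = 0 with diagonal A returns the diagonal and unit vectors", {
  A <- diag(c(0.3, 0.5, 0.9))
  sol <- davidsonSolve(list(A = A, B = matrix(0, 3, 3)), nRoots = 3,
                       tol = 1e-10)
  expect_equal(sol@omegas, c(0.3, 0.5, 0.9), tolerance = 1e-10)
  expect_equal(abs(sol@xCoeff), diag(3), tolerance = 1e-6)
  tda <- solveTDA(list(A = A, B = matrix(0, 3, 3)), nRoots = 3, tol = 1e-10)
  expect_equal(tda@omegas, sol@omegas, tolerance = 1e-8)
})

test_that("Davidson matches dense diagonalization on a 200-pair model", {
  set.seed(42)  # fixed-seed randomized positive-definite model
  n <- 200
  M1 <- matrix(rnorm(n * n, sd = 0.02), n, n)
  A <- diag(seq(0.5, 3, length.out = n)) + crossprod(M1)
  B <- crossprod(matrix(rnorm(n * n, sd = 0.05), n, n)) * 0.05
  sol <- davidsonSolve(list(A = A, B = B), nRoots = 6, tol = 1e-9,
                       maxIter = 200)
  ref <- densePairedSolve(A, B)
  expect_equal(sol@omegas, ref$omegas[1:6], tolerance = 1e-8)
})

test_that("kernel application is linear and matches the dense materialization", {
  mf <- cachedMF("h2o", "HF")
  op <- cachedTDHFOp("h2o")
  n <- nrow(op@pairs)
  set.seed(7)
  t1 <- rnorm(n); t2 <- rnorm(n)
  a1 <- applyKernelColumns(op, cbind(t1), "plus")
  a2 <- applyKernelColumns(op, cbind(t2), "plus")
  a12 <- applyKernelColumns(op, cbind(2 * t1 - 3 * t2), "plus")
  expect_equal(drop(a12), drop(2 * a1 - 3 * a2), tolerance = 1e-12)
  dm <- memo("dense_tdhf_h2o_op", denseBSEMatrices(op))
  expect_equal(drop(a1), drop((dm$A + dm$B) %*% t1), tolerance = 1e-10)
  am <- applyKernelColumns(op, cbind(t1), "minus")
  expect_equal(drop(am), drop((dm$A - dm$B) %*% t1), tolerance = 1e-10)
})

test_that("unit trial on one pair with zeroed interactions returns the gap", {
  mf <- cachedMF("h2", "HF")
  op <- buildBSEOperator(mf, mode = "TDHF")
  # zero every two-electron ingredient: kernel reduces to the gap diagonal
  op@bOV[] <- 0; op@bOO[] <- 0; op@bVV[] <- 0
  t0 <- matrix(1, 1, 1)
  expect_equal(drop(applyKernelColumns(op, t0, "plus")), op@gaps,
               tolerance = 1e-14)
  sol <- davidsonSolve(op, nRoots = 1, tol = 1e-9)
  expect_equal(sol@omegas, op@gaps, tolerance = 1e-8)
})

test_that("TDHF mode equals an independent dense TD-HF implementation", {
  for (name in c("h2o", "n2")) {
    sol <- cachedTDHFDav(name)
    ref <- cachedTDHFDense(name)
    expect_equal(sol@omegas, ref$omegas[1:4], tolerance = 1e-6)
  }
})

test_that("RI-TDHF agrees with exact-integral TD-HF at the RI error scale", {
  mf <- cachedMF("h2o", "HF")
  ri <- cachedTDHFDense("h2o")
  ex <- denseTDHF(mf, "exact")
  # ~mHa: the even-tempered RI error scale measured on this fixture
  expect_lt(max(abs(ri$omegas[1:6] - ex$omegas[1:6])), 5e-3)
})

test_that("particle-hole cutoff shifts the lowest excitation upward by a
          small fraction of the excitation energy", {
  qp <- cachedQsGW("PBEH40")
  opFull <- memo("op_bse_h2o", buildBSEOperator(qp, mode = "BSE"))
  solFull <- memo("bse_full_h2o", davidsonSolve(opFull, 1, tol = 1e-7))
  opCut <- buildBSEOperator(qp, mode = "BSE", phCutoff = 1.5)
  expect_lt(nrow(opCut@pairs), nrow(opFull@pairs))
  solCut <- davidsonSolve(opCut, 1, tol = 1e-7)
  shift <- solCut@omegas[1] - solFull@omegas[1]
  expect_gte(shift, -1e-6)           # removing pairs cannot lower the root
  # small molecule + small basis: every virtual matters, so the truncation
  # effect is larger than in extended systems but still < 2% of the root
  expect_lt(shift / solFull@omegas[1], 0.02)
})

test_that("TDA roots bound the full solution from above on water", {
  qp <- cachedQsGW("PBEH40")
  op <- memo("op_bse_h2o", buildBSEOperator(qp, mode = "BSE"))
  full <- memo("bse6_h2o", davidsonSolve(op, 6, tol = 1e-7, maxIter = 200))
  tda <- solveTDA(op, 6, tol = 1e-7, maxIter = 200)
  expect_true(all(tda@omegas >= full@omegas - 1e-7))
  expect_equal(max(abs(tda@yCoeff)), 0)
})

test_that("full-spectrum TDA equals dense eigenvalues of A", {
  mf <- cachedMF("h2", "HF")
  op <- buildBSEOperator(mf, mode = "TDHF")
  dm <- denseBSEMatrices(op)
  n <- nrow(op@pairs)
  tda <- solveTDA(op, n, tol = 1e-10)
  expect_equal(tda@omegas, sort(eigen(dm$A, symmetric = TRUE)$values),
               tolerance = 1e-8)
})

test_that("empty active space and oversized dense requests are refused", {
  qp <- cachedQsGW("PBEH40")
  expect_error(buildBSEOperator(qp, mode = "BSE", phCutoff = 1e-4), "empty")
  op <- memo("op_bse_h2o", buildBSEOperator(qp, mode = "BSE"))
  expect_error(denseBSEMatrices(op, maxPairs = 10L), "refused")
  expect_error(davidsonSolve(op, nRoots = 10000), "exceeds")
})
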