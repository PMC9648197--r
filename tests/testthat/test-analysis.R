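# Oscillator strengths, dominant transitions and fragment-resolved
# local/charge-transfer decomposition.

test_that("single-pair oscillator strength follows the length-gauge formula", {
  # craft a one-pair exciton with Omega = 0.5, X = 1, Y = 0 and a unit
  # transition dipole along z
  ex <- new("ExcitonSolution", omegas = 0.5,
            xCoeff = matrix(1, 1, 1), yCoeff = matrix(0, 1, 1),
            residualNorms = 0, pairs = cbind(1L, 1L), mode = "BSE",
            iterations = 1L, subspaceHistory = 1L)
  state <- cachedMF("h2", "HF")
  ctx <- state@backend$ctx
  dz <- crossprod(state@moCoeff, ctx$dipole$z %*% state@moCoeff)[1, 2]
  f <- oscillatorStrengths(ex, state)
  expect_equal(f, 2 / 3 * 0.5 * 2 * dz^2, tolerance = 1e-12)
  expect_gte(f, 0)
})

test_that("centrosymmetric dimer has dark (g) and bright (u) states", {
  mf <- cachedMF("h2_dimer_far", "HF")
  op <- memo("op_dimer", buildBSEOperator(mf, mode = "TDHF"))
  ex <- memo("ex_dimer", davidsonSolve(op, 4, tol = 1e-9, maxIter = 200))
  f <- oscillatorStrengths(ex, mf)
  expect_true(all(f >= -1e-12))
  # non-interacting pair of identical chromophores: oscillator strength is
  # carried by (at most) one of each nearly degenerate pair
  expect_lt(min(f[1:2]), 1e-6)
})

test_that("oscillator strengths agree between Davidson and dense eigenvectors", {
  mf <- cachedMF("h2o", "HF")
  op <- cachedTDHFOp("h2o")
  sol <- cachedTDHFDav("h2o")
  dm <- memo("dense_tdhf_h2o_op", denseBSEMatrices(op))
  dsol <- densePairedSolve(dm$A, dm$B)
  exD <- new("ExcitonSolution", omegas = dsol$omegas[1:4],
             xCoeff = dsol$X[, 1:4], yCoeff = dsol$Y[, 1:4],
             residualNorms = rep(0, 4), pairs = op@pairs, mode = "TDHF",
             iterations = 1L, subspaceHistory = 1L)
  f1 <- oscillatorStrengths(sol, mf)
  f2 <- oscillatorStrengths(exD, mf)
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("dominant transitions: weights, symmetry and sign invariance", {
  mf <- cachedMF("h2", "HF")
  op <- buildBSEOperator(mf, mode = "TDHF")
  ex <- davidsonSolve(op, 1, tol = 1e-9)
  tr <- dominantTransitions(ex, mf)[[1]]
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$weight, 1.0, tolerance = 1e-10)
  # sign flip of the eigenvector leaves weights unchanged
  ex2 <- ex
  ex2@xCoeff <- -ex2@xCoeff; ex2@yCoeff <- -ex2@yCoeff
  expect_equal(dominantTransitions(ex2, mf)[[1]]$weight, tr$weight)
  # two degenerate non-interacting pairs mix 50/50
  mfd <- cachedMF("h2_dimer_far", "HF")
  opd <- memo("op_dimer", buildBSEOperator(mfd, mode = "TDHF"))
  exd <- memo("ex_dimer", davidsonSolve(opd, 4, tol = 1e-9, maxIter = 200))
  trd <- dominantTransitions(exd, mfd, threshold = 0.05)[[3]]
  expect_true(all(abs(trd$weight - trd$weight[1]) < 0.02) || nrow(trd) == 1)
})

test_that("fragment weights: defaults, normalization and the far-dimer limit", {
  mf <- cachedMF("h2o", "HF")
  ex <- cachedTDHFDav("h2o")
  fc <- fragmentCharacter(ex, mf, defineFragments(mf@backend$ctx$molecule))
  for (s in seq_along(fc)) {
    expect_equal(sum(fc[[s]]$weights), 1, tolerance = 1e-6)
    expect_equal(fc[[s]]$classification, "local")
    expect_equal(unname(fc[[s]]$weights[1, 1]), 1, tolerance = 1e-6)
  }
  # two H2 at 100 A: every low state is purely local or purely CT
  mfd <- cachedMF("h2_dimer_far", "HF")
  part <- defineFragments(mfd@backend$ctx$molecule,
                          list(A = c(1, 2), B = c(3, 4)))
  exd <- memo("ex_dimer", {
    opd <- buildBSEOperator(mfd, mode = "TDHF")
    davidsonSolve(opd, 4, tol = 1e-9, maxIter = 200)
  })
  fcd <- fragmentCharacter(exd, mfd, part)
  for (s in seq_along(fcd)) {
    W <- fcd[[s]]$weights
    purity <- max(sum(diag(W)), sum(W) - sum(diag(W)))
    expect_gte(purity, 0.99)
    expect_equal(sum(W), 1, tolerance = 1e-6)
  }
  # fragment labels reordered: same weights up to permutation
  partR <- defineFragments(mfd@backend$ctx$molecule,
                           list(B = c(3, 4), A = c(1, 2)))
  fcr <- fragmentCharacter(exd, mfd, partR)
  for (s in seq_along(fcd))
    expect_equal(fcd[[s]]$weights[c("A", "B"), c("A", "B")],
                 fcr[[s]]$weights[c("A", "B"), c("A", "B")],
                 tolerance = 1e-12)
})

test_that("the report layer never changes the solver energies", {
  mf <- cachedMF("h2o", "HF")
  ex <- cachedTDHFDav("h2o")
  rep <- excitonReport(ex, mf)
  expect_identical(vapply(rep$states, `[[`, 0, "omega_Ha"),
                   as.vector(ex@omegas))
  # writers produce parseable artifacts
  csv <- tempfile(fileext = ".csv")
  writeSpectrumCSV(rep, csv)
  df <- read.csv(csv)
  expect_equal(df$omega_eV, ex@omegas * 27.211386, tolerance = 1e-8)
  js <- tempfile(fileext = ".json")
  writeReportJSON(rep, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$states), 4L)
})

test_that("config files parse and map onto solver settings", {
  cfgFile <- tempfile(fileext = ".toml")
  writeLines(c("[system]", 'basis = "sto-3g"', 'reference = "PBE"',
               "[gw]", "n_grid_points = 12", "eps_s = 1e-3",
               'screening = "rpa"',
               "[bse]", "n_roots = 3", "davidson_tol = 1e-6"), cfgFile)
  rc <- readRunConfig(cfgFile)
  expect_equal(rc$system$reference, "PBE")
  cfg <- gwbse:::.configFrom(rc)
  expect_equal(cfg$nGridPoints, 12L)
  expect_equal(cfg$epsS, 1e-3)
  expect_equal(cfg$nRoots, 3L)
  expect_equal(cfg$davidsonTol, 1e-6)
})
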