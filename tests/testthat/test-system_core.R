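# Molecule model, XYZ input, fragments and the mean-field reference.

test_that("XYZ reading preserves geometry and rejects malformed files", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0", "H 0.0 0.0 0.74"), xyz)
  mol <- loadMolecule(xyz)
  expect_s4_class(mol, "Molecule")
  expect_equal(length(mol@symbols), 2L)
  expect_equal(sqrt(sum((mol@coords[1, ] - mol@coords[2, ])^2)), 0.74)

  bad <- tempfile(fileext = ".xyz")
  writeLines(c("3", "count mismatch", "H 0 0 0", "H 0 0 0.74"), bad)
  expect_error(loadMolecule(bad), "declared")

  bad2 <- tempfile(fileext = ".xyz")
  writeLines(c("not_a_count", "", "H 0 0 0"), bad2)
  expect_error(loadMolecule(bad2), "atom count")

  bad3 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "H 0 xx 0"), bad3)
  expect_error(loadMolecule(bad3), "parse")

  bad4 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "Xq 0 0 0"), bad4)
  expect_error(loadMolecule(bad4), "element")
})

test_that("molecule invariants: closed shell only, matching dimensions", {
  expect_error(newMolecule("H", rbind(c(0, 0, 0)), multiplicity = 3L),
               "multiplicity")
  expect_error(newMolecule(c("H", "H", "H"),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "even")
  fx <- makeFixture("h2o")
  expect_equal(length(fx$molecule@symbols), 3L)
  expect_equal(fx$molecule@charge, 0L)
  expect_equal(fx$molecule@multiplicity, 1L)
})

test_that("fixture registry is deterministic and guarded", {
  expect_error(makeFixture("benzene"), "unknown fixture")
  f1 <- makeFixture("h2")
  expect_equal(sqrt(sum((f1$molecule@coords[1, ] -
                           f1$molecule@coords[2, ])^2)), 0.74)
  expect_setequal(fixtureNames(),
                  c("h2", "h2_dimer_far", "h2o", "n2", "ethylene",
                    "formaldehyde"))
})

test_that("fragment partitions cover every atom exactly once", {
  mol <- makeFixture("h2o")$molecule
  p0 <- defineFragments(mol)
  expect_equal(p0@fragmentLabels, "ALL")
  expect_equal(p0@atomToFragment, rep("ALL", 3))

  dim4 <- makeFixture("h2_dimer_far")$molecule
  p2 <- defineFragments(dim4, list(A = c(1, 2), B = c(3, 4)))
  expect_equal(p2@fragmentLabels, c("A", "B"))
  expect_error(defineFragments(dim4, list(A = c(1, 2), B = 4)), "unmapped|cover")
})

test_that("H2 HF total energy matches an independent SCF implementation", {
  mf <- cachedMF("h2", "HF")
  expect_equal(mf@energy, oracleSCFh2(0.74), tolerance = 1e-8)
})

test_that("mean-field invariants hold for every reference", {
  mol <- makeFixture("h2o")$molecule
  for (ref in c("HF", "PBE")) {
    mf <- cachedMF("h2o", ref)
    S <- mf@backend$ctx$S
    C <- mf@moCoeff
    expect_lt(max(abs(crossprod(C, S %*% C) - diag(ncol(C)))), 1e-10)
    D <- mf@backend$density
    expect_equal(sum(D * S), mf@backend$ctx$nelec, tolerance = 1e-10)
    # Fock diagonal in MO basis at convergence
    Fmo <- crossprod(C, mf@fock %*% C)
    expect_lt(max(abs(Fmo - diag(diag(Fmo)))), 1e-6)
  }
})

test_that("HF stores a zero xc-potential matrix and full exact exchange", {
  mf <- cachedMF("h2", "HF")
  expect_equal(max(abs(mf@vxc)), 0)
  expect_equal(mf@exchangeFraction, 1.0)
})

test_that("re-running the mean field reproduces energies deterministically", {
  fx <- makeFixture("h2")
  m1 <- runMeanField(fx$molecule, fx$basis, "HF")
  m2 <- runMeanField(fx$molecule, fx$basis, "HF")
  expect_equal(m1@energy, m2@energy, tolerance = 1e-12)
  expect_equal(m1@moEnergy, m2@moEnergy, tolerance = 1e-12)
})

test_that("PBEH40 gap lies strictly between the PBE and HF gaps", {
  gPBE <- homoLumoGap(cachedMF("h2o", "PBE"))
  gH40 <- homoLumoGap(cachedMF("h2o", "PBEH40"))
  gHF <- homoLumoGap(cachedMF("h2o", "HF"))
  expect_true(gPBE < gH40 && gH40 < gHF)
})

test_that("open-shell and unknown-reference inputs are rejected", {
  mol <- makeFixture("h2o")$molecule
  expect_error(runMeanField(mol, "6-31g", "B3LYP"), "referenceTag")
  molIon <- newMolecule(mol@symbols, mol@coords, charge = 0L)
  expect_error(newMolecule(mol@symbols, mol@coords, charge = 1L), "even")
})
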