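# 2D descriptors, conformers and the 3D block.

test_that("topological descriptors match hand-derived values", {
  d <- compute2D("O=C1CCC(O1)Cc1ccc(c(c1)O)O")  # dihydroxy-PVL
  expect_equal(d$mw, 208.21, tolerance = 0.01)
  expect_identical(d$hbd, 2L)
  expect_identical(d$rotb, 2L)

  phenol <- compute2D("Oc1ccccc1")
  expect_equal(phenol$psa, 20.23, tolerance = 0.01)

  benzene <- compute2D("c1ccccc1")
  expect_identical(benzene$hbd, 0L)
  expect_identical(benzene$rotb, 0L)
  expect_equal(benzene$psa, 0)
})

test_that("unparseable SMILES is reported with the offending string", {
  expect_error(compute2D("not(a(smiles"), "not\\(a\\(smiles")
  expect_error(canonicalSmiles("xx$yy"), "xx\\$yy")
})

test_that("sulfation and glucuronidation increase polarity monotonically", {
  cores <- list(
    buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'")),
    buildScaffold("PVL", "gamma-valerolactone", "4'"),
    buildScaffold("PVA", "4-hydroxy-5-phenylvaleric-acid", c("3'", "4'")))
  for (core in cores) {
    d0 <- compute2D(core@smiles)
    for (ev in c("sulfate", "glucuronide")) {
      conj <- conjugateMetabolite(core, ev, core@hydroxylation[1])
      d1 <- compute2D(conj@smiles)
      expect_gt(d1$psa, d0$psa)
      expect_gt(d1$mw, d0$mw)
      expect_gte(d1$hba, d0$hba)
    }
  }
})

test_that("conformer embedding is deterministic and charge-neutral", {
  cf1 <- embedConformer("C")
  expect_identical(length(cf1@elements), 5L)  # methane: C + 4 H
  expect_equal(sum(cf1@charges), 0, tolerance = 1e-9)

  smi <- "O=C1CCC(O1)Cc1ccc(c(c1)O)O"
  a <- embedConformer(smi)
  b <- embedConformer(smi)
  expect_identical(a@coords, b@coords)
  expect_identical(a@charges, b@charges)

  expect_error(embedConformer("((bad"), "bad")
})

test_that("dipole of a centro-symmetric molecule is near zero", {
  cf <- embedConformer("c1ccccc1")
  d3 <- compute3D(cf)
  expect_lt(d3["dipole"], 0.3)
})

test_that("grid volume agrees with the analytic sphere-union oracle", {
  vol1 <- pvlBBB:::.vdwVolume("C", matrix(c(0, 0, 0), 1, 3), grid = 0.2)
  ref1 <- sphereUnionVolume(c(0, 0, 0), 1.70)
  expect_lt(abs(vol1 - ref1) / ref1, 0.05)

  # two overlapping C spheres 1.5 A apart
  ctr2 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  vol2 <- pvlBBB:::.vdwVolume(c("C", "C"), ctr2, grid = 0.2)
  ref2 <- sphereUnionVolume(ctr2, c(1.70, 1.70))
  expect_lt(abs(vol2 - ref2) / ref2, 0.05)

  # three spheres: C-O overlapping pair plus a distant H
  ctr3 <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(8, 0, 0))
  vol3 <- pvlBBB:::.vdwVolume(c("C", "O", "H"), ctr3, grid = 0.2)
  ref3 <- sphereUnionVolume(ctr3, c(1.70, 1.52, 1.20))
  expect_lt(abs(vol3 - ref3) / ref3, 0.05)
})

test_that("glucuronidation strictly increases molecular volume", {
  for (core in list(
    buildScaffold("PVL", "gamma-valerolactone", "4'"),
    buildScaffold("PVA", "4-hydroxy-5-phenylvaleric-acid", "3'"))) {
    conj <- conjugateMetabolite(core, "glucuronide", core@hydroxylation[1])
    v0 <- compute3D(embedConformer(core@smiles))["volume"]
    v1 <- compute3D(embedConformer(conj@smiles))["volume"]
    expect_gt(v1, v0)
  }
})

test_that("descriptor tables have fixed shape and flag failures", {
  expect_warning(
    ds <- computeDescriptors(c("CCO", "definitely-not-smiles", "c1ccccc1")),
    "failed")
  expect_identical(nrow(ds@values), 2L)
  expect_identical(nrow(ds@failures), 1L)
  expect_match(ds@failures$error, "SMILES")
  expect_identical(colnames(ds@values), c("id", DESCRIPTOR_NAMES))

  empty <- computeDescriptors(character(0))
  expect_identical(nrow(empty@values), 0L)

  # rerun produces byte-identical output files
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  ds2 <- computeDescriptors(c("CCO", "c1ccccc1"))
  ds3 <- computeDescriptors(c("CCO", "c1ccccc1"))
  writeDescriptors(ds2, f1)
  writeDescriptors(ds3, f2)
  expect_identical(readLines(f1), readLines(f2))
})
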