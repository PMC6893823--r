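# Scaffold construction, conjugation chemistry and naming.

test_that("scaffold construction gives the right formulas and masses", {
  m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'"))
  expect_identical(m@formula, "C11H12O4")
  expect_equal(m@avgMass, 208.21, tolerance = 0.01)

  base <- buildScaffold("PVL", "gamma-valerolactone")
  expect_identical(base@formula, "C11H12O2")

  pva <- buildScaffold("PVA", "4-hydroxy-5-phenylvaleric-acid")
  expect_identical(pva@systematicName, "4-hydroxy-5-phenylvaleric acid")
  expect_identical(pva@conjugationClass, "unconjugated PVA")
})

test_that("invalid scaffold and conjugation requests error cleanly", {
  expect_error(buildScaffold("PVL", "delta-valerolactone"),
               "backbone_variant")
  m <- buildScaffold("PVL", "gamma-valerolactone", "4'")
  expect_error(conjugateMetabolite(m, "sulfate", "3'"),
               "not a hydroxylated")
  s <- conjugateMetabolite(m, "sulfate", "4'")
  expect_error(conjugateMetabolite(s, "methyl", "4'"), "already conjugated")
})

test_that("conjugation adds the exact moiety mass and updates the name", {
  deltas <- c(sulfate = 79.95682, glucuronide = 176.03209,
              methyl = 14.01565)
  m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'"))
  for (ev in names(deltas)) {
    conj <- conjugateMetabolite(m, ev, "3'")
    expect_equal(conj@monoMass - m@monoMass, unname(deltas[ev]),
                 tolerance = 1e-3, label = paste("mono delta", ev))
  }
  s <- conjugateMetabolite(m, "sulfate", "3'")
  expect_identical(s@systematicName,
                   "5-(4'-hydroxyphenyl)-gamma-valerolactone-3'-sulfate")
  expect_identical(s@formula, "C11H12O7S")
})

test_that("mass deltas are consistent with formula recomputation", {
  # the delta must equal the difference of the masses computed de novo
  # from the two structures, not just a stored constant
  cores <- list(
    buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'", "5'")),
    buildScaffold("PVA", "4-hydroxy-5-phenylvaleric-acid", "4'"))
  for (core in cores) {
    for (ev in c("sulfate", "glucuronide", "methyl")) {
      pos <- core@hydroxylation[1]
      conj <- conjugateMetabolite(core, ev, pos)
      ref <- pvlBBB:::.CONJ_MONO_DELTA[[ev]]
      expect_equal(conj@monoMass - core@monoMass, ref, tolerance = 1e-3)
      expect_equal(conj@avgMass - core@avgMass,
                   pvlBBB:::.CONJ_AVG_DELTA[[ev]], tolerance = 2e-3)
    }
  }
})

test_that("conjugation class is a deterministic function of the events", {
  m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'", "5'"))
  sm <- conjugateMetabolite(conjugateMetabolite(m, "sulfate", "3'"),
                            "methyl", "4'")
  expect_identical(sm@conjugationClass, "PVL-sulfate")
  ss <- conjugateMetabolite(conjugateMetabolite(m, "sulfate", "3'"),
                            "sulfate", "4'")
  expect_identical(ss@conjugationClass, "PVL-disulfate")
  gm <- conjugateMetabolite(conjugateMetabolite(m, "glucuronide", "4'"),
                            "methyl", "3'")
  expect_identical(gm@conjugationClass, "PVL-glucuronide")
  sg <- conjugateMetabolite(conjugateMetabolite(m, "sulfate", "3'"),
                            "glucuronide", "4'")
  expect_identical(sg@conjugationClass, "PVL-sulfate-glucuronide")
  expect_identical(
    buildScaffold("PVA", "5-phenylvaleric-acid")@conjugationClass,
    "unconjugated PVA")
})

test_that("SMILES round-trip through canonicalisation", {
  m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "5'"))
  expect_identical(m@smiles, canonicalSmiles(m@smiles))
  g <- conjugateMetabolite(m, "glucuronide", "3'")
  expect_identical(g@smiles, canonicalSmiles(g@smiles))
})

test_that("systematic names parse back to the same structure", {
  m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'"))
  s <- conjugateMetabolite(conjugateMetabolite(m, "sulfate", "3'"),
                           "methyl", "4'")
  p <- parseSystematicName(s@systematicName)
  expect_identical(p@smiles, s@smiles)
  expect_identical(p@conjugationClass, s@conjugationClass)
})
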