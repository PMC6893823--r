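# Library enumeration, the pinned manifest, and the fixture generator.

test_that("default enumeration is deterministic and matches the manifest", {
  lib1 <- enumerateLibrary()
  lib2 <- enumerateLibrary()
  expect_identical(libraryManifest(lib1), libraryManifest(lib2))

  man <- libraryManifest(lib1)
  expect_identical(nrow(man), 67L)
  expect_false(anyDuplicated(man$id) > 0)
  expect_false(anyDuplicated(man$smiles) > 0)
  expect_true(all(man$class %in% conjugationClasses()))
  expect_setequal(unique(man$class), conjugationClasses())

  pinned <- cachedManifest()
  expect_identical(man[c("id", "systematic_name", "class", "smiles",
                         "formula")],
                   pinned[c("id", "systematic_name", "class", "smiles",
                            "formula")])
  expect_equal(man$mono_mass, pinned$mono_mass, tolerance = 1e-4)
})

test_that("reading the pinned manifest verifies the name/structure bijection", {
  # readManifest reconstructs every entry from its systematic name and
  # stops unless the stored canonical SMILES matches
  lib <- cachedLibrary()
  expect_identical(length(lib), 67L)
  for (m in lib@entries)
    expect_identical(parseSystematicName(m@systematicName)@smiles,
                     m@smiles)
})

test_that("a grammar without conjugation yields only unconjugated cores", {
  g <- list(version = "test", scaffolds = list(list(
    kind = "PVL", backbone = "gamma-valerolactone",
    hydroxylation_patterns = list(list("3'", "4'"), list("3'")),
    heavy_multisets = list(list()))))
  lib <- enumerateLibrary(g)
  expect_identical(length(lib), 2L)
  for (m in lib@entries) {
    expect_identical(nrow(m@conjugations), 0L)
    expect_identical(m@conjugationClass, "unconjugated PVL")
  }
})

test_that("symmetric ring positions deduplicate to one entry", {
  g <- list(version = "test", scaffolds = list(list(
    kind = "PVL", backbone = "gamma-valerolactone",
    hydroxylation_patterns = list(list("3'", "5'")),
    heavy_multisets = list(list("sulfate")))))
  lib <- enumerateLibrary(g)
  # 3'-sulfate and 5'-sulfate on the symmetric 3',5' core are the same
  # molecule
  expect_identical(length(lib), 1L)
  expect_identical(lib@entries[[1]]@conjugationClass, "PVL-sulfate")
})

test_that("random phenolic fixtures are reproducible and valid", {
  a <- randomPhenolic(1)
  b <- randomPhenolic(1)
  expect_identical(a@smiles, b@smiles)
  expect_false(identical(randomPhenolic(2)@smiles,
                         randomPhenolic(3)@smiles))

  p0 <- list(kinds = c("PVL", "PVA"), max_oh = 3,
             p_conj = c(sulfate = 0, glucuronide = 0, methyl = 0))
  for (s in 1:5)
    expect_identical(nrow(randomPhenolic(s, p0)@conjugations), 0L)

  for (s in 1:300) {
    m <- randomPhenolic(s)
    expect_identical(m@smiles, canonicalSmiles(m@smiles))
    expect_true(validObject(m))
  }
})

test_that("random generation does not disturb the global RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(randomPhenolic(5))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
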