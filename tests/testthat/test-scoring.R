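# Lipinski, star count and BBB score.

toyVector <- function(...) {
  # a complete descriptor row, defaulting to values inside every default
  # BBB range
  base <- data.frame(id = "toy", mw = 200, hbd = 1, hba = 3, psa = 50,
                     logp = 1.5, logbb = -0.3, caco2 = -4.5, mdck = -4.5,
                     dipole = 5, volume = 200, rotb = 3, logkhsa = 0)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("Lipinski counts strict threshold violations", {
  expect_identical(
    lipinskiViolations(data.frame(mw = 600, logp = 6, hbd = 6, hba = 11)),
    4L)
  expect_identical(
    lipinskiViolations(data.frame(mw = 208.21, logp = 1.35, hbd = 2,
                                  hba = 4)), 0L)
  # boundary values do not violate
  expect_identical(
    lipinskiViolations(data.frame(mw = 500, logp = 5, hbd = 5, hba = 10)),
    0L)
})

test_that("star count flags descriptors outside the drug ranges", {
  expect_identical(countStars(toyVector(), warn = FALSE), 0L)
  expect_identical(countStars(toyVector(psa = 300), warn = FALSE), 1L)
  expect_identical(countStars(toyVector(psa = 300, mw = 1000),
                              warn = FALSE), 2L)
  expect_warning(countStars(toyVector()), "skips")
})

test_that("BBB score counts descriptors strictly inside their intervals", {
  st <- bbbScore(toyVector())
  expect_identical(st@scores$bbb_score, 12L)

  off <- toyVector(mw = 1e4, hbd = 99, hba = 99, psa = 1e4, logp = 99,
                   logbb = 99, caco2 = 99, mdck = 99, dipole = 99,
                   volume = 1e4, rotb = 99, logkhsa = 99)
  expect_identical(bbbScore(off)@scores$bbb_score, 0L)

  # boundary value counts as outside
  expect_identical(bbbScore(toyVector(psa = 60))@scores$bbb_score, 11L)
})

test_that("incomplete descriptor input is rejected with field names", {
  v <- toyVector()
  v$dipole <- NULL
  v$logkhsa <- NULL
  expect_error(bbbScore(v), "dipole")
  expect_error(bbbScore(v), "logkhsa")
})

test_that("vectorized BBB score equals the brute-force oracle", {
  ds <- cachedDescriptors()
  st <- bbbScore(ds)
  expect_identical(st@scores$bbb_score,
                   bruteBBBScore(ds@values, defaultBBBRanges()))
})

test_that("score is monotone under range widening and narrowing", {
  ds <- cachedDescriptors()
  base <- defaultBBBRanges()
  s0 <- bbbScore(ds, base)@scores$bbb_score

  widen <- base@table
  span <- widen$hi - widen$lo
  widen$lo <- widen$lo - 0.25 * span
  widen$hi <- widen$hi + 0.25 * span
  s_wide <- bbbScore(ds, rangeTable(widen))@scores$bbb_score
  expect_true(all(s_wide >= s0))

  narrow <- base@table
  narrow$lo <- narrow$lo + 0.25 * span
  narrow$hi <- narrow$hi - 0.25 * span
  s_narrow <- bbbScore(ds, rangeTable(narrow))@scores$bbb_score
  expect_true(all(s_narrow <= s0))
})

test_that("score is invariant to descriptor column order", {
  ds <- cachedDescriptors()
  v <- ds@values
  shuffled <- v[, c("id", rev(DESCRIPTOR_NAMES))]
  expect_identical(bbbScore(shuffled)@scores$bbb_score,
                   bbbScore(v)@scores$bbb_score)
})

test_that("heavy conjugates carry stars and rank below unconjugated PVLs", {
  ds <- cachedDescriptors()
  man <- cachedManifest()
  st <- bbbScore(ds)
  ranked <- rankLibrary(st, cachedLibrary())
  expect_identical(nrow(ranked), 67L)

  merged <- merge(st@scores, man[c("id", "class")], by = "id")
  sg <- merged$class %in% c("PVL-sulfate-glucuronide",
                            "PVA-sulfate-glucuronide")
  expect_true(all(merged$stars[sg] >= 1))

  uncj <- merged$bbb_score[merged$class == "unconjugated PVL"]
  heavy <- merged$bbb_score[merged$class %in%
    c("PVL-glucuronide", "PVL-sulfate-glucuronide", "PVL-disulfate")]
  expect_gt(min(uncj), max(heavy))
})

test_that("all-equal scores rank by name within class order", {
  s <- data.frame(id = c("b", "a", "c"), lipinski = 0L, stars = 0L,
                  bbb_score = 5L, stringsAsFactors = FALSE)
  flags <- matrix(rep(c(rep(TRUE, 5), rep(FALSE, 7)), 3), nrow = 3,
                  byrow = TRUE, dimnames = list(NULL, DESCRIPTOR_NAMES))
  st <- new("ScoreTable", scores = s, passFlags = flags)
  out <- rankLibrary(st)
  expect_identical(out$id, c("a", "b", "c"))
})
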