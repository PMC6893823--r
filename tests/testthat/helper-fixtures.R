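# Shared fixtures and independent oracles. Expensive objects (the
# 67-entry library and its descriptor table) are computed once per test run
# and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

cachedLibrary <- function() {
  if (is.null(.fixtures$lib)) .fixtures$lib <- pvlLibrary()
  .fixtures$lib
}

cachedManifest <- function() {
  if (is.null(.fixtures$man))
    .fixtures$man <- libraryManifest(cachedLibrary())
  .fixtures$man
}

cachedDescriptors <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- computeDescriptors(cachedLibrary())
  .fixtures$ds
}

# the five metabolites reported to pass every BBB descriptor range
fiveMaxScoreNames <- c(
  "4-hydroxy-5-phenylvaleric acid",
  "5-(4'-hydroxyphenyl)-gamma-valerolactone-3'-methoxy",
  "5-(3'-hydroxyphenyl)-gamma-valerolactone-4'-methoxy",
  "5-(4'-hydroxyphenyl)-gamma-valerolactone",
  "5-(3'-hydroxyphenyl)-gamma-valerolactone")

heavyConjugateClasses <- c(
  "PVL-glucuronide", "PVL-sulfate-glucuronide", "PVL-disulfate",
  "PVA-glucuronide", "PVA-sulfate-glucuronide")

# Brute-force BBB score oracle: explicit per-molecule, per-descriptor loop.
bruteBBBScore <- function(values, rangeTable) {
  t <- rangeTable@table
  out <- integer(nrow(values))
  for (i in seq_len(nrow(values))) {
    n <- 0L
    for (d in DESCRIPTOR_NAMES) {
      row <- t[t$descriptor == d, ]
      x <- values[[d]][i]
      if (x > row$lo && x < row$hi) n <- n + 1L
    }
    out[i] <- n
  }
  out
}

# Brute-force silhouette oracle (definition-level implementation).
bruteSilhouette <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Analytic union volume of up to three spheres assuming no triple overlap:
# sum of spheres minus pairwise lens volumes.
sphereUnionVolume <- function(centers, radii) {
  centers <- matrix(centers, ncol = 3)
  v <- sum(4 / 3 * pi * radii^3)
  n <- length(radii)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      r1 <- radii[i]; r2 <- radii[j]
      if (dd < r1 + r2) {
        lens <- pi * (r1 + r2 - dd)^2 *
          (dd^2 + 2 * dd * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * dd)
        v <- v - lens
      }
    }
  }
  v
}

# closed-form eigenvalues of a symmetric 2x2 matrix
eigen2x2 <- function(a, b, d) {
  tr <- a + d
  disc <- sqrt((a - d)^2 + 4 * b^2)
  c((tr + disc) / 2, (tr - disc) / 2)
}
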