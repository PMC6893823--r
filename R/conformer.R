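# Single-conformer 3D descriptors: dipole moment from partial charges and
# grid-counted van der Waals volume.

# Bondi van der Waals radii (Angstrom) for the elements occurring in
# phenolic metabolites.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85)

# Debye per elementary charge * Angstrom
.DEBYE_PER_EA <- 4.80320427

#' Embed a deterministic 3D conformer with partial charges
#'
#' Builds one reproducible 3D conformation in three fully deterministic
#' steps: (1) a 2D structure layout with explicit hydrogens; (2) a seeded
#' out-of-plane displacement of every atom (a small linear-congruential
#' stream derived from \code{seed}, default 2019) to break planarity; (3)
#' force-field energy minimisation (MMFF94, falling back to UFF when MMFF94
#' parameters are unavailable). Partial charges are assigned by the
#' electronegativity-equalisation method (EEM); the tiny residual from
#' charge printing precision is redistributed uniformly so charges sum
#' exactly to the net formal charge. Identical \code{(smiles, seed)} input
#' gives byte-identical coordinates. The resulting structure is one
#' reasonable local-minimum conformer, not a global conformer search.
#'
#' @param smiles a single SMILES string.
#' @param seed integer conformer seed (default 2019).
#' @return a \code{\link{Conformer}}.
#' @examples
#' \donttest{
#' cf <- embedConformer("C")  # methane: 5 atoms, net charge 0
#' nrow(cf@coords)
#' }
#' @export
embedConformer <- function(smiles, seed = 2019L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  seed <- as.integer(seed)
  flat <- .ob_convert_quietly("SMI", "MOL2", smiles,
    options = data.frame(names = c("gen2D", "h"), args = c("", "")))
  if (!nzchar(flat))
    stop("2D layout failed for SMILES: '", smiles, "'", call. = FALSE)
  for (attempt in 0:2) {
    jittered <- .jitter_mol2_z(flat, seed + attempt)
    out <- .minimize_mol2(jittered, "MMFF94")
    if (!.geometry_ok(out)) out <- .minimize_mol2(jittered, "UFF")
    if (.geometry_ok(out)) {
      at <- .parse_mol2_atoms(out)
      q <- at$charge
      net <- round(sum(q))
      q <- q + (net - sum(q)) / length(q)
      return(new("Conformer", smiles = smiles, elements = at$element,
                 coords = as.matrix(at[c("x", "y", "z")]), charges = q,
                 seed = seed))
    }
  }
  stop("3D embedding failed for SMILES: '", smiles, "'", call. = FALSE)
}

# Deterministic uniform stream in [0,1): Lehmer linear-congruential
# generator, independent of R's RNG state.
.lcg_uniform <- function(n, seed) {
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  x <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    x[i] <- s / 2147483647
  }
  x
}

# Displace the z coordinates of a planar mol2 layout by +-0.5 A.
.jitter_mol2_z <- function(text, seed) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  b <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  idx <- (a + 1L):(b - 1L)
  z <- (.lcg_uniform(length(idx), seed) - 0.5)
  lines[idx] <- vapply(seq_along(idx), function(k) {
    p <- strsplit(trimws(lines[idx[k]]), "[[:space:]]+")[[1]]
    p[5] <- sprintf("%.4f", as.numeric(p[5]) + z[k])
    paste(p, collapse = " ")
  }, character(1))
  paste(lines, collapse = "\n")
}

.minimize_mol2 <- function(mol2, ff) {
  .ob_convert_quietly("MOL2", "MOL2", mol2,
    options = data.frame(
      names = c("minimize", "ff", "steps", "partialcharge"),
      args = c("", ff, "1500", "eem")))
}

# sanity: all bonds shorter than 2.2 A, no non-bonded overlap below 0.7 A
.geometry_ok <- function(mol2) {
  if (!nzchar(mol2)) return(FALSE)
  ok <- try({
    at <- .parse_mol2_atoms(mol2)
    co <- as.matrix(at[c("x", "y", "z")])
    bd <- .parse_mol2_bonds(mol2)
    bl <- if (nrow(bd)) sqrt(rowSums((co[bd[, 1], , drop = FALSE] -
                                      co[bd[, 2], , drop = FALSE])^2))
          else numeric(0)
    mind <- if (nrow(co) > 1L) {
      d <- as.matrix(stats::dist(co))
      diag(d) <- Inf
      min(d)
    } else Inf
    all(is.finite(co)) && all(bl < 2.2) && all(bl > 0.7) && mind > 0.65
  }, silent = TRUE)
  isTRUE(ok)
}

.parse_mol2_bonds <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  b <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  rows <- lines[(b + 1L):length(lines)]
  rows <- rows[nzchar(trimws(rows)) & !grepl("^@", rows)]
  if (!length(rows)) return(matrix(integer(0), 0, 2))
  out <- do.call(rbind, lapply(strsplit(trimws(rows), "[[:space:]]+"),
                               function(x)
                                 suppressWarnings(as.integer(x[2:3]))))
  out[stats::complete.cases(out), , drop = FALSE]
}

# Minimal reader for the @<TRIPOS>ATOM block of a mol2 record (element,
# coordinates, partial charge). Only used on Open Babel's own output.
.parse_mol2_atoms <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  b <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  if (is.na(a) || is.na(b) || b <= a + 1L)
    stop("malformed mol2 output", call. = FALSE)
  rows <- lines[(a + 1L):(b - 1L)]
  f <- strsplit(trimws(rows), "[[:space:]]+")
  data.frame(
    element = vapply(f, function(x) sub("\\..*$", "", x[6]), character(1)),
    x = vapply(f, function(x) as.numeric(x[3]), numeric(1)),
    y = vapply(f, function(x) as.numeric(x[4]), numeric(1)),
    z = vapply(f, function(x) as.numeric(x[5]), numeric(1)),
    charge = vapply(f, function(x) as.numeric(x[9]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Dipole moment and van der Waals volume of a conformer
#'
#' The dipole moment is \eqn{|\sum_i q_i r_i|} over the partial charges,
#' converted to Debye (origin-independent for neutral molecules). The
#' volume is the van der Waals union volume counted on a cubic grid
#' (default spacing 0.2 Angstrom) with Bondi radii.
#'
#' @param conformer a \code{\link{Conformer}}.
#' @param grid grid spacing in Angstrom.
#' @return named numeric vector \code{c(dipole = , volume = )} in Debye and
#'   Angstrom^3.
#' @export
compute3D <- function(conformer, grid = 0.2) {
  stopifnot(is(conformer, "Conformer"))
  r <- conformer@coords
  q <- conformer@charges
  mu <- sqrt(sum(colSums(r * q)^2)) * .DEBYE_PER_EA
  c(dipole = mu, volume = .vdwVolume(conformer@elements, r, grid))
}

.vdwVolume <- function(elements, coords, grid = 0.2) {
  rad <- .VDW_RADII[elements]
  if (anyNA(rad))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(rad)]), collapse = ", "), call. = FALSE)
  pad <- max(rad) + grid
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = grid)
  gy <- seq(lo[2], hi[2], by = grid)
  gz <- seq(lo[3], hi[3], by = grid)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  inside <- logical(nx * ny * nz)
  # per atom, mark grid points within its sphere (sub-box restricted)
  for (i in seq_along(rad)) {
    ri2 <- rad[i]^2
    ix <- which(abs(gx - coords[i, 1]) <= rad[i])
    iy <- which(abs(gy - coords[i, 2]) <= rad[i])
    iz <- which(abs(gz - coords[i, 3]) <= rad[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - coords[i, 1])^2
    dy2 <- (gy[iy] - coords[i, 2])^2
    dz2 <- (gz[iz] - coords[i, 3])^2
    sub <- outer(dx2, dy2, "+")
    for (k in seq_along(iz)) {
      hit <- sub + dz2[k] <= ri2
      if (any(hit)) {
        idx <- (iz[k] - 1L) * nx * ny +
          rep((iy - 1L) * nx, each = length(ix)) + ix
        inside[idx[hit]] <- TRUE
      }
    }
  }
  sum(inside) * grid^3
}
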