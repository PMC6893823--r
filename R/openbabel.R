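# Thin wrappers around the Open Babel toolkit (via ChemmineOB/ChemmineR).
# All SMILES parsing, canonicalisation, formula/mass computation and
# substructure matching in the package funnels through these helpers so that
# input errors are reported uniformly.

#' Canonicalise SMILES strings
#'
#' Converts one or more SMILES strings to Open Babel canonical SMILES.
#' Canonical SMILES is the identity key used throughout the package: two
#' structures are the same metabolite iff their canonical SMILES agree.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalSmiles(c("OCC", "CCO"))
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  vapply(smiles, function(s) {
    out <- .ob_convert_quietly("SMI", "CAN", s)
    can <- sub("[ \t].*$", "", trimws(out))
    if (!nzchar(can))
      stop("unparseable SMILES: '", s, "'", call. = FALSE)
    can
  }, character(1), USE.NAMES = FALSE)
}

# convertFormat with stderr noise suppressed; returns "" on failure
.ob_convert_quietly <- function(from, to, input, options = NULL) {
  out <- try(suppressWarnings(
    if (is.null(options)) ChemmineOB::convertFormat(from, to, input)
    else ChemmineOB::convertFormat(from, to, input, options = options)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return("")
  out
}

# SDFset from SMILES with uniform error reporting
.ob_sdfset <- function(smiles) {
  if (is.null(names(smiles)))
    names(smiles) <- sprintf("mol%03d", seq_along(smiles))
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  if (inherits(sdf, "try-error"))
    stop("unparseable SMILES among: ",
         paste(sQuote(smiles), collapse = ", "), call. = FALSE)
  sdf
}

# Open Babel bulk properties: formula, MW, logP (atomic contribution),
# TPSA (fragment contribution), HBD/HBA counts.
.ob_props <- function(smiles) {
  sdf <- .ob_sdfset(smiles)
  p <- ChemmineR::propOB(sdf)
  p$mono_mass <- as.numeric(ChemmineR::exactMassOB(sdf))
  p
}

# Rotatable bonds: acyclic single bonds between two non-terminal,
# non-triple-bonded heavy atoms (hydroxyl/terminal groups excluded).
.ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.ob_rotb <- function(smiles) {
  vapply(smiles, function(s) {
    n <- try(ChemmineOB::forEachMol("SMILES", s, function(m)
      ChemmineOB::smartsSearch_OB(list(m), .ROTB_SMARTS,
                                  uniqueMatches = TRUE)), silent = TRUE)
    if (inherits(n, "try-error"))
      stop("unparseable SMILES: '", s, "'", call. = FALSE)
    as.numeric(n[[1]])
  }, numeric(1), USE.NAMES = FALSE)
}
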