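#' @import methods
NULL

# ---------------------------------------------------------------------------
# Metabolite
# ---------------------------------------------------------------------------

#' Metabolite: a PVL/PVA structure with its conjugation state
#'
#' A single phenyl-gamma-valerolactone (PVL) or phenylvaleric acid (PVA)
#' metabolite: scaffold identity (backbone + ring hydroxylation pattern),
#' the phase-II conjugation events installed on it, and derived chemistry
#' (canonical SMILES, Hill formula, average and monoisotopic mass).
#'
#' @slot id character, unique identifier within a library.
#' @slot systematicName character, e.g.
#'   \code{"5-(4'-hydroxyphenyl)-gamma-valerolactone-3'-sulfate"}.
#' @slot kind \code{"PVL"} or \code{"PVA"}.
#' @slot backbone backbone variant, one of
#'   \code{"gamma-valerolactone"}, \code{"5-phenylvaleric-acid"},
#'   \code{"4-hydroxy-5-phenylvaleric-acid"}.
#' @slot hydroxylation character vector of ring positions carrying a
#'   phenolic hydroxyl on the unconjugated scaffold (subset of
#'   \code{c("3'", "4'", "5'")}).
#' @slot conjugations data.frame with columns \code{kind}
#'   (sulfate/glucuronide/methyl) and \code{position}.
#' @slot smiles canonical SMILES (the identity key).
#' @slot formula Hill-notation molecular formula.
#' @slot avgMass average molecular mass, g/mol.
#' @slot monoMass monoisotopic mass, Da.
#' @slot conjugationClass one of the ten conjugation-class labels, see
#'   \code{\link{conjugationClasses}}.
#' @seealso \code{\link{buildScaffold}}, \code{\link{conjugateMetabolite}}
#' @export
setClass("Metabolite", representation(
  id = "character",
  systematicName = "character",
  kind = "character",
  backbone = "character",
  hydroxylation = "character",
  conjugations = "data.frame",
  smiles = "character",
  formula = "character",
  avgMass = "numeric",
  monoMass = "numeric",
  conjugationClass = "character"
))

setValidity("Metabolite", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("PVL", "PVA"))
    msg <- c(msg, "kind must be 'PVL' or 'PVA'")
  if (anyDuplicated(object@hydroxylation))
    msg <- c(msg, "hydroxylation positions must be distinct")
  if (!all(object@hydroxylation %in% c("3'", "4'", "5'")))
    msg <- c(msg, "hydroxylation positions must be among 3', 4', 5'")
  cj <- object@conjugations
  if (nrow(cj)) {
    if (!all(cj$kind %in% c("sulfate", "glucuronide", "methyl")))
      msg <- c(msg, "unknown conjugation kind")
    if (!all(cj$position %in% object@hydroxylation))
      msg <- c(msg, "conjugation positions must be hydroxylated scaffold positions")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MetaboliteLibrary
# ---------------------------------------------------------------------------

#' MetaboliteLibrary: an ordered, deduplicated set of metabolites
#'
#' Container for an enumerated metabolite library (the default library holds
#' the 67 PVL/PVA metabolites reported to circulate in humans). Entries are
#' unique by canonical SMILES and ordered by (conjugation class, name).
#'
#' @slot version manifest version string.
#' @slot provenanceNote free-text provenance of the composition.
#' @slot entries list of \code{\link{Metabolite}} objects.
#' @seealso \code{\link{enumerateLibrary}}, \code{\link{pvlLibrary}}
#' @export
setClass("MetaboliteLibrary", representation(
  version = "character",
  provenanceNote = "character",
  entries = "list"
))

setValidity("MetaboliteLibrary", function(object) {
  msg <- character(0)
  if (!all(vapply(object@entries, is, logical(1), "Metabolite")))
    msg <- c(msg, "entries must all be Metabolite objects")
  ids <- vapply(object@entries, function(m) m@id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "entry ids must be unique")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Conformer
# ---------------------------------------------------------------------------

#' Conformer: a single 3D embedding with partial charges
#'
#' One deterministic 3D conformation of a molecule, with per-atom partial
#' charges from an electronegativity-equalisation scheme. Used for the
#' dipole-moment and van der Waals volume descriptors.
#'
#' @slot smiles the SMILES the conformer was built from.
#' @slot elements character vector of element symbols (explicit hydrogens).
#' @slot coords numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @slot charges numeric vector of partial charges, elementary charge units;
#'   the residual rounding charge is redistributed so the sum equals the net
#'   formal charge exactly.
#' @slot seed integer seed recorded for provenance.
#' @export
setClass("Conformer", representation(
  smiles = "character",
  elements = "character",
  coords = "matrix",
  charges = "numeric",
  seed = "integer"
))

setValidity("Conformer", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (nrow(object@coords) != length(object@elements))
    msg <- c(msg, "coords rows must match elements")
  if (length(object@charges) != length(object@elements))
    msg <- c(msg, "charges must match elements")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DescriptorSet
# ---------------------------------------------------------------------------

#' The twelve descriptor names of the BBB panel
#'
#' Column order of every descriptor table produced by the package:
#' molecular weight (\code{mw}, g/mol), hydrogen-bond donors/acceptors
#' (\code{hbd}, \code{hba}), topological polar surface area (\code{psa},
#' Angstrom^2), octanol/water partition coefficient (\code{logp}),
#' brain/blood partition coefficient (\code{logbb}), predicted Caco-2 and
#' MDCK permeability (\code{caco2}, \code{mdck}, log10 cm/s), dipole moment
#' (\code{dipole}, Debye), van der Waals volume (\code{volume}, Angstrom^3),
#' rotatable bonds (\code{rotb}) and serum-albumin binding (\code{logkhsa}).
#' @export
DESCRIPTOR_NAMES <- c("mw", "hbd", "hba", "psa", "logp", "logbb",
                      "caco2", "mdck", "dipole", "volume", "rotb", "logkhsa")

#' DescriptorSet: descriptor vectors for a set of molecules
#'
#' One row per molecule, the twelve \code{\link{DESCRIPTOR_NAMES}} columns in
#' fixed order, plus per-descriptor provenance of the predictor used.
#'
#' @slot values data.frame with column \code{id} followed by the twelve
#'   descriptor columns.
#' @slot methods named character vector: descriptor -> method/provenance tag.
#' @slot seed integer conformer seed used for the 3D descriptors.
#' @slot failures data.frame (id, error) of molecules whose descriptors
#'   could not be computed; their rows are excluded from \code{values}.
#' @export
setClass("DescriptorSet", representation(
  values = "data.frame",
  methods = "character",
  seed = "integer",
  failures = "data.frame"
))

setValidity("DescriptorSet", function(object) {
  v <- object@values
  need <- c("id", DESCRIPTOR_NAMES)
  if (!identical(colnames(v)[seq_along(need)], need))
    return(sprintf("values must start with columns: %s",
                   paste(need, collapse = ", ")))
  num <- v[DESCRIPTOR_NAMES]
  bad <- vapply(num, function(x) any(!is.finite(x)), logical(1))
  if (any(bad))
    return(paste("non-finite descriptor values in:",
                 paste(names(bad)[bad], collapse = ", ")))
  if (any(v$mw <= 0)) return("mw must be positive")
  cnt <- c("hbd", "hba", "rotb")
  if (any(vapply(num[cnt], function(x)
    any(x < 0 | x != round(x)), logical(1))))
    return("hbd/hba/rotb must be non-negative integers")
  TRUE
})

# ---------------------------------------------------------------------------
# RangeTable
# ---------------------------------------------------------------------------

#' RangeTable: per-descriptor numeric intervals
#'
#' Descriptor intervals used by \code{\link{bbbScore}} (the twelve-entry BBB
#' permeability table) and \code{\link{countStars}} (drug-likeness 95%
#' ranges). A value passes an interval iff it is strictly inside
#' \code{(lo, hi)}; boundary hits count as outside.
#'
#' @slot table data.frame with columns \code{descriptor}, \code{lo},
#'   \code{hi}, \code{provenance} (one of \code{"paper"},
#'   \code{"vendor-doc"}, \code{"literature-default"}).
#' @seealso \code{\link{defaultBBBRanges}}, \code{\link{defaultDrugRanges}}
#' @export
setClass("RangeTable", representation(table = "data.frame"))

setValidity("RangeTable", function(object) {
  t <- object@table
  need <- c("descriptor", "lo", "hi", "provenance")
  if (!all(need %in% colnames(t)))
    return(paste("range table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(t$descriptor)) return("duplicate descriptor entries")
  if (any(t$lo >= t$hi)) return("every interval must have lo < hi")
  if (!all(t$provenance %in% c("paper", "vendor-doc", "literature-default")))
    return("provenance must be paper/vendor-doc/literature-default")
  TRUE
})

# ---------------------------------------------------------------------------
# ScoreTable
# ---------------------------------------------------------------------------

#' ScoreTable: drug-likeness and BBB permeation scores
#'
#' Per-metabolite Lipinski violation count, reduced star count (descriptors
#' outside drug-likeness 95% ranges), BBB score (count of the twelve
#' descriptors strictly inside their BBB ranges, 0-12), and the
#' per-descriptor pass flags behind the BBB score.
#'
#' @slot scores data.frame with columns \code{id}, \code{lipinski},
#'   \code{stars}, \code{bbb_score}.
#' @slot passFlags logical matrix, one row per molecule, one column per BBB
#'   descriptor.
#' @export
setClass("ScoreTable", representation(
  scores = "data.frame",
  passFlags = "matrix"
))

setValidity("ScoreTable", function(object) {
  s <- object@scores
  need <- c("id", "lipinski", "stars", "bbb_score")
  if (!all(need %in% colnames(s)))
    return(paste("scores needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@passFlags) != nrow(s))
    return("passFlags rows must match scores rows")
  if (!all(s$bbb_score == rowSums(object@passFlags)))
    return("bbb_score must equal the number of TRUE pass flags")
  if (any(s$bbb_score < 0 | s$bbb_score > 12))
    return("bbb_score must lie in [0, 12]")
  if (any(s$lipinski < 0 | s$lipinski > 4))
    return("lipinski violations must lie in [0, 4]")
  TRUE
})

# ---------------------------------------------------------------------------
# ChemSpaceResult
# ---------------------------------------------------------------------------

#' ChemSpaceResult: PCA of the standardized descriptor space
#'
#' Principal component analysis of the z-scored descriptor matrix, with
#' orthonormal loadings, non-increasing explained-variance fractions, and
#' (optionally) silhouette statistics quantifying how well the scores
#' cluster by conjugation class.
#'
#' @slot scores metabolite x component score matrix.
#' @slot loadings descriptor x component loading matrix (orthonormal
#'   columns).
#' @slot explainedVariance fraction of variance per component; sums to 1
#'   over all components.
#' @slot classes factor of conjugation classes (empty if not supplied).
#' @slot silhouette list with per-class mean silhouette widths and the
#'   overall mean (empty until \code{\link{classSeparation}} is run).
#' @export
setClass("ChemSpaceResult", representation(
  scores = "matrix",
  loadings = "matrix",
  explainedVariance = "numeric",
  classes = "factor",
  silhouette = "list"
))

setValidity("ChemSpaceResult", function(object) {
  msg <- character(0)
  L <- object@loadings
  if (ncol(L) > 0) {
    g <- crossprod(L)
    if (max(abs(g - diag(ncol(L)))) > 1e-8)
      msg <- c(msg, "loadings columns must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) && any(diff(ev) > 1e-12))
    msg <- c(msg, "explained-variance fractions must be non-increasing")
  if (length(msg)) msg else TRUE
})
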