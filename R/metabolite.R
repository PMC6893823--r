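# Scaffold assembly, phase-II conjugation and systematic naming for
# phenyl-gamma-valerolactone (PVL) and phenylvaleric acid (PVA) metabolites.

.RING_POSITIONS <- c("3'", "4'", "5'")

# Exact and average mass deltas of the three phase-II events:
# sulfation +SO3, glucuronidation +C6H8O6, methylation +CH2.
.CONJ_MONO_DELTA <- c(sulfate = 79.95682, glucuronide = 176.03209,
                      methyl = 14.01565)
.CONJ_AVG_DELTA <- c(sulfate = 80.063, glucuronide = 176.124,
                     methyl = 14.027)

# SMILES fragments installed at a ring position (replacing the phenolic H/OH;
# the fragment includes the phenolic oxygen). Glucuronide is written without
# stereocentres: the descriptors computed by this package are
# stereo-insensitive. "%d" is a fresh ring-closure digit.
.SUBSTITUENT_SMILES <- c(
  hydroxyl = "O",
  methyl = "OC",
  sulfate = "OS(=O)(=O)O",
  glucuronide = "OC%dOC(C(=O)O)C(O)C(O)C%dO"
)

.BACKBONES <- list(
  PVL = c("gamma-valerolactone"),
  PVA = c("5-phenylvaleric-acid", "4-hydroxy-5-phenylvaleric-acid")
)

#' The ten conjugation-class labels
#'
#' The class legend used throughout: six PVL classes (unconjugated, methoxy,
#' sulfate, glucuronide, sulfate-glucuronide, disulfate) and four PVA
#' classes (unconjugated, sulfate, glucuronide, sulfate-glucuronide).
#' Sulfate and glucuronide classes include their methoxylated variants:
#' when a sulfate or glucuronide is present, additional methylation does not
#' change the class.
#'
#' @return character vector of the ten class labels, in legend order.
#' @export
conjugationClasses <- function() {
  c("unconjugated PVL", "PVL-sulfate", "PVL-glucuronide",
    "PVL-sulfate-glucuronide", "PVL-disulfate", "PVL-methoxy",
    "unconjugated PVA", "PVA-sulfate", "PVA-glucuronide",
    "PVA-sulfate-glucuronide")
}

# ---------------------------------------------------------------------------
# SMILES assembly
# ---------------------------------------------------------------------------

# Assemble a raw SMILES from backbone + per-position substituents.
# `subs` is a named list over ring positions; values are substituent keys
# ("hydroxyl"/"methyl"/"sulfate"/"glucuronide") or NA for an unsubstituted H.
.assembleSmiles <- function(backbone, subs) {
  digit <- 3L  # ring-closure digits 1 (lactone) and 2 (benzene) are taken
  seg <- function(pos) {
    key <- subs[[pos]]
    if (is.null(key) || is.na(key)) return("c")
    frag <- .SUBSTITUENT_SMILES[[key]]
    if (grepl("%d", frag, fixed = TRUE)) {
      frag <- gsub("%d", as.character(digit), frag, fixed = TRUE)
      digit <<- digit + 1L
    }
    paste0("c(", frag, ")")
  }
  ring <- paste0("c2c", seg("3'"), seg("4'"), seg("5'"), "c2")
  stem <- switch(backbone,
    "gamma-valerolactone" = "O=C1CCC(O1)C",
    "5-phenylvaleric-acid" = "OC(=O)CCCC",
    "4-hydroxy-5-phenylvaleric-acid" = "OC(=O)CCC(O)C",
    stop("unknown backbone_variant: '", backbone, "'", call. = FALSE))
  paste0(stem, ring)
}

# Substituent state per ring position given hydroxylation + conjugations.
.positionStates <- function(hydroxylation, conjugations) {
  subs <- setNames(vector("list", 3L), .RING_POSITIONS)
  for (p in hydroxylation) subs[[p]] <- "hydroxyl"
  if (nrow(conjugations)) {
    for (i in seq_len(nrow(conjugations)))
      subs[[conjugations$position[i]]] <- conjugations$kind[i]
  }
  subs
}

# ---------------------------------------------------------------------------
# Systematic naming
# ---------------------------------------------------------------------------

.arylPrefix <- function(freeOH) {
  if (length(freeOH) == 0L) return("phenyl")
  pos <- sort(freeOH)
  stem <- c("hydroxy", "dihydroxy", "trihydroxy")[length(pos)]
  paste0(paste(pos, collapse = ","), "-", stem, "phenyl")
}

.conjSuffix <- function(conjugations) {
  if (nrow(conjugations) == 0L) return("")
  ord <- order(conjugations$position, conjugations$kind, method = "radix")
  cj <- conjugations[ord, , drop = FALSE]
  lab <- c(sulfate = "sulfate", glucuronide = "glucuronide",
           methyl = "methoxy")[cj$kind]
  paste0("-", paste(paste0(cj$position, "-", lab), collapse = "-"))
}

.systematicName <- function(kind, backbone, hydroxylation, conjugations) {
  conjugated <- if (nrow(conjugations)) conjugations$position else character(0)
  freeOH <- setdiff(hydroxylation, conjugated)
  prefix <- .arylPrefix(freeOH)
  wrapped <- if (prefix == "phenyl") "phenyl" else paste0("(", prefix, ")")
  core <- switch(backbone,
    "gamma-valerolactone" = paste0("5-", wrapped, "-gamma-valerolactone"),
    "5-phenylvaleric-acid" = paste0("5-", wrapped, "valeric acid"),
    "4-hydroxy-5-phenylvaleric-acid" =
      paste0("4-hydroxy-5-", wrapped, "valeric acid"))
  paste0(core, .conjSuffix(conjugations))
}

#' Parse a systematic metabolite name back into a structure
#'
#' Inverts the package's naming convention: the aryl prefix gives the free
#' phenolic hydroxyls, the suffixes give the conjugation events, and the
#' core gives the backbone. Reconstructs the metabolite and returns it; the
#' canonical SMILES of the result equals that of the named structure (the
#' name/structure bijection on the library).
#'
#' @param name a systematic name produced by this package, e.g.
#'   \code{"5-(4'-hydroxyphenyl)-gamma-valerolactone-3'-sulfate"}.
#' @return a \code{\link{Metabolite}}.
#' @export
parseSystematicName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- name
  backbone <- if (grepl("gamma-valerolactone", x)) {
    kind <- "PVL"; "gamma-valerolactone"
  } else if (grepl("^4-hydroxy-5-", x)) {
    kind <- "PVA"; "4-hydroxy-5-phenylvaleric-acid"
  } else if (grepl("valeric acid", x)) {
    kind <- "PVA"; "5-phenylvaleric-acid"
  } else stop("unrecognised name: '", name, "'", call. = FALSE)

  # aryl prefix -> free hydroxyl positions
  freeOH <- character(0)
  m <- regmatches(x, regexec("\\(([0-9',]+)-(?:di|tri)?hydroxyphenyl\\)", x))[[1]]
  if (length(m) == 2L) freeOH <- strsplit(m[2], ",")[[1]]

  # suffixes -> conjugation events
  conj <- data.frame(kind = character(0), position = character(0),
                     stringsAsFactors = FALSE)
  suffix_re <- "([345]')-(sulfate|glucuronide|methoxy)"
  tail <- sub(".*(valeric acid|valerolactone)", "", x)
  for (mm in regmatches(tail, gregexpr(suffix_re, tail))[[1]]) {
    parts <- regmatches(mm, regexec(suffix_re, mm))[[1]]
    kindm <- c(sulfate = "sulfate", glucuronide = "glucuronide",
               methoxy = "methyl")[parts[3]]
    conj <- rbind(conj, data.frame(kind = unname(kindm),
                                   position = parts[2],
                                   stringsAsFactors = FALSE))
  }
  hydroxylation <- sort(union(freeOH, conj$position))
  m0 <- buildScaffold(kind, backbone, hydroxylation)
  for (i in seq_len(nrow(conj)))
    m0 <- conjugateMetabolite(m0, conj$kind[i], conj$position[i])
  m0
}

# ---------------------------------------------------------------------------
# Class assignment
# ---------------------------------------------------------------------------

#' Assign the conjugation class of a metabolite
#'
#' Deterministic function of the scaffold kind and the multiset of
#' conjugation events: one sulfate (no glucuronide) is a sulfate conjugate,
#' one glucuronide a glucuronide conjugate, one of each a
#' sulfate-glucuronide, two sulfates a disulfate, methyl-only a methoxy
#' conjugate, none unconjugated. Methylation on top of a sulfate or
#' glucuronide does not change the class (methoxy-sulfates class with the
#' sulfates, methoxy-glucuronides with the glucuronides).
#'
#' @param metabolite a \code{\link{Metabolite}}.
#' @return a single class label.
#' @export
assignConjugationClass <- function(metabolite) {
  stopifnot(is(metabolite, "Metabolite"))
  cj <- metabolite@conjugations
  nS <- sum(cj$kind == "sulfate")
  nG <- sum(cj$kind == "glucuronide")
  nM <- sum(cj$kind == "methyl")
  k <- metabolite@kind
  if (nS == 0 && nG == 0) {
    if (nM == 0) return(paste("unconjugated", k))
    return(paste0(k, "-methoxy"))
  }
  if (nS >= 1 && nG >= 1) return(paste0(k, "-sulfate-glucuronide"))
  if (nS >= 2) return(paste0(k, "-disulfate"))
  if (nG >= 2) return(paste0(k, "-diglucuronide"))
  if (nS == 1) return(paste0(k, "-sulfate"))
  paste0(k, "-glucuronide")
}

# ---------------------------------------------------------------------------
# Constructors
# ---------------------------------------------------------------------------

# Shared: build a Metabolite from structural state, computing chemistry via
# Open Babel.
.makeMetabolite <- function(kind, backbone, hydroxylation, conjugations,
                            id = NA_character_) {
  subs <- .positionStates(hydroxylation, conjugations)
  raw <- .assembleSmiles(backbone, subs)
  can <- canonicalSmiles(raw)
  p <- .ob_props(can)
  m <- new("Metabolite",
    id = id,
    systematicName = .systematicName(kind, backbone, hydroxylation,
                                     conjugations),
    kind = kind,
    backbone = backbone,
    hydroxylation = sort(as.character(hydroxylation)),
    conjugations = conjugations,
    smiles = can,
    formula = p$formula,
    avgMass = p$MW,
    monoMass = p$mono_mass,
    conjugationClass = "")
  m@conjugationClass <- assignConjugationClass(m)
  m
}

#' Build an unconjugated PVL/PVA scaffold
#'
#' Constructs the unconjugated metabolite for a backbone variant and ring
#' hydroxylation pattern, with formula and masses computed from the
#' structure.
#'
#' @param kind \code{"PVL"} or \code{"PVA"}.
#' @param backbone one of \code{"gamma-valerolactone"} (PVL),
#'   \code{"5-phenylvaleric-acid"} or
#'   \code{"4-hydroxy-5-phenylvaleric-acid"} (PVA).
#' @param hydroxylation character vector of ring positions from
#'   \code{c("3'", "4'", "5'")} (may be empty).
#' @return a \code{\link{Metabolite}}.
#' @examples
#' m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'"))
#' m@formula   # C11H12O4
#' @export
buildScaffold <- function(kind, backbone, hydroxylation = character(0)) {
  kind <- match.arg(kind, c("PVL", "PVA"))
  if (!backbone %in% .BACKBONES[[kind]])
    stop("unknown backbone_variant '", backbone, "' for kind ", kind,
         call. = FALSE)
  if (!all(hydroxylation %in% .RING_POSITIONS))
    stop("hydroxylation must be a subset of {3', 4', 5'}", call. = FALSE)
  empty <- data.frame(kind = character(0), position = character(0),
                      stringsAsFactors = FALSE)
  .makeMetabolite(kind, backbone, hydroxylation, empty)
}

#' Install a phase-II conjugate on a metabolite
#'
#' Installs a sulfate, glucuronide or methyl group on a free phenolic
#' hydroxyl. The monoisotopic mass increases by the exact moiety mass
#' (SO3 +79.957, C6H8O6 +176.032, CH2 +14.016 Da) and the systematic name
#' is updated (remaining free hydroxyls in the aryl prefix, the conjugate as
#' a positional suffix).
#'
#' @param metabolite a \code{\link{Metabolite}}.
#' @param kind \code{"sulfate"}, \code{"glucuronide"} or \code{"methyl"}.
#' @param position ring position label; must carry a free phenolic hydroxyl.
#' @return the conjugated \code{\link{Metabolite}}.
#' @examples
#' m <- buildScaffold("PVL", "gamma-valerolactone", c("3'", "4'"))
#' s <- conjugateMetabolite(m, "sulfate", "3'")
#' s@systematicName
#' @export
conjugateMetabolite <- function(metabolite, kind, position) {
  stopifnot(is(metabolite, "Metabolite"))
  kind <- match.arg(kind, c("sulfate", "glucuronide", "methyl"))
  if (!position %in% metabolite@hydroxylation)
    stop("position ", position, " is not a hydroxylated ring position",
         call. = FALSE)
  cj <- metabolite@conjugations
  if (position %in% cj$position)
    stop("position ", position, " is already conjugated", call. = FALSE)
  cj <- rbind(cj, data.frame(kind = kind, position = position,
                             stringsAsFactors = FALSE))
  .makeMetabolite(metabolite@kind, metabolite@backbone,
                  metabolite@hydroxylation, cj, id = metabolite@id)
}

# ---------------------------------------------------------------------------
# Show methods and accessors
# ---------------------------------------------------------------------------

setMethod("show", "Metabolite", function(object) {
  cat("Metabolite:", object@systematicName, "\n")
  cat("  class:  ", object@conjugationClass, "\n")
  cat("  smiles: ", object@smiles, "\n")
  cat(sprintf("  formula: %s  (avg %.2f g/mol, mono %.4f Da)\n",
              object@formula, object@avgMass, object@monoMass))
})

setMethod("show", "MetaboliteLibrary", function(object) {
  cat("MetaboliteLibrary v", object@version, " with ",
      length(object@entries), " metabolites\n", sep = "")
  tab <- table(factor(vapply(object@entries,
                             function(m) m@conjugationClass, character(1)),
                      levels = conjugationClasses()))
  for (cl in names(tab)) cat(sprintf("  %-26s %d\n", cl, tab[[cl]]))
})

#' @describeIn MetaboliteLibrary number of metabolites
#' @param x a \code{MetaboliteLibrary}
#' @export
setMethod("length", "MetaboliteLibrary", function(x) length(x@entries))

#' Library entries as a manifest data.frame
#'
#' @param library a \code{\link{MetaboliteLibrary}}.
#' @return data.frame with columns id, systematic_name, class, smiles,
#'   formula, avg_mass, mono_mass.
#' @export
libraryManifest <- function(library) {
  stopifnot(is(library, "MetaboliteLibrary"))
  if (length(library@entries) == 0L)
    return(data.frame(id = character(0), systematic_name = character(0),
                      class = character(0), smiles = character(0),
                      formula = character(0), avg_mass = numeric(0),
                      mono_mass = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(library@entries, function(m)
    data.frame(id = m@id, systematic_name = m@systematicName,
               class = m@conjugationClass, smiles = m@smiles,
               formula = m@formula, avg_mass = m@avgMass,
               mono_mass = m@monoMass, stringsAsFactors = FALSE)))
}

#' Extract entries from a library
#' @param x a \code{MetaboliteLibrary}
#' @param i index or id
#' @export
setMethod("[[", "MetaboliteLibrary", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@entries, function(m) m@id, character(1))
    i <- match(i, ids)
  }
  x@entries[[i]]
})
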