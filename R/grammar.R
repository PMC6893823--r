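# Library enumeration: a scaffold + conjugation grammar generates the
# metabolite library. The packaged default grammar reconstructs the 67
# PVL/PVA metabolites reported to circulate in humans.

.HEAVY_LABELS <- c("none", "sulfate", "glucuronide", "sulfate+glucuronide",
                   "disulfate")

.heavyLabel <- function(multiset) {
  nS <- sum(multiset == "sulfate"); nG <- sum(multiset == "glucuronide")
  if (nS == 0 && nG == 0) "none"
  else if (nS == 1 && nG == 0) "sulfate"
  else if (nS == 0 && nG == 1) "glucuronide"
  else if (nS == 1 && nG == 1) "sulfate+glucuronide"
  else if (nS == 2 && nG == 0) "disulfate"
  else paste(sort(multiset), collapse = "+")
}

#' Load a grammar configuration
#'
#' Reads a YAML grammar: scaffold blocks (kind, backbone, hydroxylation
#' patterns) with the allowed heavy-conjugation multisets (sulfate,
#' glucuronide, sulfate+glucuronide, disulfate) and methylation rules
#' (maximum methyl count, whether methylation requires a catechol-adjacent
#' hydroxyl, and which heavy multisets it may accompany).
#'
#' @param path YAML file; defaults to the packaged grammar.
#' @return grammar list, validated.
#' @seealso \code{\link{enumerateLibrary}}
#' @export
readGrammarConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "grammar_default.yaml", package = "pvlBBB",
                        mustWork = TRUE)
  g <- yaml::read_yaml(path)
  if (is.null(g$scaffolds) || !length(g$scaffolds))
    stop("grammar has no scaffold blocks", call. = FALSE)
  for (blk in g$scaffolds) {
    if (!blk$kind %in% c("PVL", "PVA"))
      stop("grammar: unknown kind ", blk$kind, call. = FALSE)
    if (!blk$backbone %in% .BACKBONES[[blk$kind]])
      stop("grammar: unknown backbone_variant '", blk$backbone, "'",
           call. = FALSE)
  }
  g
}

#' The default library grammar
#'
#' @return the packaged grammar describing the 67-metabolite reconstruction.
#' @export
defaultGrammar <- function() readGrammarConfig()

# Distinct assignments of a heavy multiset onto free positions: a list of
# data.frames (kind, position). Identical events are interchangeable.
.heavyAssignments <- function(multiset, positions) {
  if (length(multiset) == 0L)
    return(list(data.frame(kind = character(0), position = character(0),
                           stringsAsFactors = FALSE)))
  if (length(positions) < length(multiset)) return(list())
  k <- length(multiset)
  combos <- utils::combn(positions, k, simplify = FALSE)
  out <- list()
  perms <- unique(.permutations(multiset))
  for (pos in combos) {
    for (pm in perms) {
      out[[length(out) + 1L]] <-
        data.frame(kind = pm, position = pos, stringsAsFactors = FALSE)
    }
  }
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# positions eligible for methylation: free, and (if required) adjacent to
# another hydroxylated ring position (the catechol substrate of
# catechol-O-methyltransferase). Adjacent pairs are 3'/4' and 4'/5'.
.methylEligible <- function(hydroxylation, taken, requireCatechol) {
  free <- setdiff(hydroxylation, taken)
  if (!requireCatechol) return(free)
  adj <- list("3'" = "4'", "4'" = c("3'", "5'"), "5'" = "4'")
  free[vapply(free, function(p) any(adj[[p]] %in% hydroxylation),
              logical(1))]
}

#' Enumerate a metabolite library from a grammar
#'
#' Expands every scaffold block of the grammar over its hydroxylation
#' patterns and allowed conjugation multisets, deduplicates by canonical
#' SMILES (positional symmetry of the 3'/5' ring positions makes some
#' raw variants identical), and returns the entries ordered by
#' (conjugation class, systematic name). Enumeration is deterministic and
#' order-stable.
#'
#' @param grammar a grammar list from \code{\link{readGrammarConfig}};
#'   defaults to the packaged grammar, which yields the 67-entry library.
#' @param verbose message about removed duplicates.
#' @return a \code{\link{MetaboliteLibrary}}.
#' @examples
#' \donttest{
#' lib <- enumerateLibrary()
#' length(lib)  # 67
#' }
#' @export
enumerateLibrary <- function(grammar = defaultGrammar(), verbose = FALSE) {
  entries <- list()
  for (blk in grammar$scaffolds) {
    meth <- blk$methyl
    if (is.null(meth)) meth <- list(max = 0)
    maxM <- if (is.null(meth$max)) 0L else as.integer(meth$max)
    reqCat <- isTRUE(meth$requires_catechol)
    companions <- if (is.null(meth$companions)) character(0)
                  else unlist(meth$companions)
    heavies <- if (is.null(blk$heavy_multisets)) list(character(0))
               else lapply(blk$heavy_multisets, function(x)
                 as.character(unlist(x)))
    patterns <- lapply(blk$hydroxylation_patterns, function(x)
      as.character(unlist(x)))
    for (pat in patterns) {
      for (hm in heavies) {
        for (asg in .heavyAssignments(hm, pat)) {
          entries[[length(entries) + 1L]] <-
            list(kind = blk$kind, backbone = blk$backbone, hydroxylation = pat,
                 conj = asg)
          if (maxM >= 1L && .heavyLabel(hm) %in% companions) {
            for (mp in .methylEligible(pat, asg$position, reqCat)) {
              conj2 <- rbind(asg, data.frame(kind = "methyl", position = mp,
                                             stringsAsFactors = FALSE))
              entries[[length(entries) + 1L]] <-
                list(kind = blk$kind, backbone = blk$backbone,
                     hydroxylation = pat, conj = conj2)
            }
          }
        }
      }
    }
  }
  mets <- lapply(entries, function(e)
    .makeMetabolite(e$kind, e$backbone, e$hydroxylation, e$conj))
  smi <- vapply(mets, function(m) m@smiles, character(1))
  nm0 <- vapply(mets, function(m) m@systematicName, character(1))
  # among 3'/5'-symmetric duplicates keep the conventionally-named variant
  # (lowest ring locants sort first)
  pre <- order(smi, nm0, method = "radix")
  mets <- mets[pre]; smi <- smi[pre]
  dup <- duplicated(smi)
  if (any(dup) && verbose)
    message("enumerateLibrary: removed ", sum(dup),
            " duplicate structures (ring-position symmetry)")
  mets <- mets[!dup]
  cls <- vapply(mets, function(m) m@conjugationClass, character(1))
  nm <- vapply(mets, function(m) m@systematicName, character(1))
  ord <- order(match(cls, conjugationClasses()), nm, method = "radix")
  mets <- mets[ord]
  for (i in seq_along(mets)) mets[[i]]@id <- sprintf("M%03d", i)
  ver <- if (is.null(grammar$version)) "unversioned" else grammar$version
  note <- if (is.null(grammar$provenance_note)) "" else grammar$provenance_note
  new("MetaboliteLibrary", version = ver, provenanceNote = note,
      entries = mets)
}

#' The packaged 67-metabolite library
#'
#' Loads the pinned manifest of the 67 circulating PVL/PVA metabolites
#' shipped with the package. The manifest is a reconstruction from the
#' metabolite naming scheme and conjugation-class legend (the identity of
#' the 67 compounds is not printed in full anywhere; see the provenance
#' note). \code{rebuild = TRUE} re-enumerates from the grammar instead of
#' reading the pinned CSV; the two agree entry-for-entry.
#'
#' @param rebuild re-enumerate from the default grammar instead of reading
#'   the pinned manifest file.
#' @return a \code{\link{MetaboliteLibrary}}.
#' @export
pvlLibrary <- function(rebuild = FALSE) {
  if (rebuild) return(enumerateLibrary())
  path <- system.file("extdata", "manifest_v1.csv", package = "pvlBBB",
                      mustWork = TRUE)
  readManifest(path)
}

#' Read / write a manifest CSV
#'
#' The manifest format has columns id, systematic_name, class, smiles,
#' formula, avg_mass, mono_mass. Reading reconstructs full
#' \code{\link{Metabolite}} objects by re-parsing each systematic name and
#' verifying the stored canonical SMILES.
#'
#' @param path CSV file path.
#' @return \code{readManifest}: a \code{\link{MetaboliteLibrary}}.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mets <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- parseSystematicName(df$systematic_name[i])
    if (!identical(m@smiles, df$smiles[i]))
      stop("manifest row ", df$id[i],
           ": stored SMILES does not match its systematic name",
           call. = FALSE)
    m@id <- df$id[i]
    mets[[i]] <- m
  }
  new("MetaboliteLibrary", version = "1.0",
      provenanceNote = paste(
        "Reconstruction of the 67 circulating flavan-3-ol metabolites from",
        "the PVL/PVA naming scheme and conjugation-class legend; no",
        "compound-level listing of the 67 is available, so the composition",
        "is a curated reconstruction."),
      entries = mets)
}

#' @rdname readManifest
#' @param library a \code{\link{MetaboliteLibrary}} to write.
#' @return \code{writeManifest}: the path, invisibly.
#' @export
writeManifest <- function(library, path) {
  df <- libraryManifest(library)
  df$avg_mass <- round(df$avg_mass, 4)
  df$mono_mass <- round(df$mono_mass, 5)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  smi <- file.path(dirname(path),
                   sub("\\.csv$", ".smi", basename(path)))
  writeLines(paste(df$smiles, df$id, sep = "\t"), smi)
  invisible(path)
}

#' Random phenolic fixture generator
#'
#' Draws a random (but seed-reproducible) phenolic metabolite: a PVL or PVA
#' scaffold bearing 0-3 ring hydroxyls, each optionally conjugated. This is
#' the property-test fixture generator; it deliberately samples beyond the
#' curated library (any position pattern, any conjugation mix) to exercise
#' structural edge cases.
#'
#' @param seed integer seed; identical seed + params give an identical
#'   structure.
#' @param params list: \code{kinds} (scaffold kinds to draw from),
#'   \code{max_oh} (0-3), \code{p_conj} named probabilities for sulfate /
#'   glucuronide / methyl per hydroxyl (the remainder stays free).
#' @return a \code{\link{Metabolite}}.
#' @examples
#' m <- randomPhenolic(1)
#' identical(m@smiles, randomPhenolic(1)@smiles)  # TRUE
#' @export
randomPhenolic <- function(seed,
                           params = list(
                             kinds = c("PVL", "PVA"),
                             max_oh = 3,
                             p_conj = c(sulfate = 0.25, glucuronide = 0.2,
                                        methyl = 0.15))) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  kind <- sample(params$kinds, 1L)
  backbone <- if (kind == "PVL") "gamma-valerolactone"
              else sample(.BACKBONES$PVA, 1L)
  nOH <- sample(0:min(3, params$max_oh), 1L)
  pattern <- sort(sample(.RING_POSITIONS, nOH))
  p <- params$p_conj
  pFree <- max(0, 1 - sum(p))
  m <- buildScaffold(kind, backbone, pattern)
  for (pos in pattern) {
    ev <- sample(c(names(p), "free"), 1L, prob = c(p, pFree))
    if (ev != "free") m <- conjugateMetabolite(m, ev, pos)
  }
  m
}
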