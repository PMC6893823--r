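# End-to-end orchestration: enumerate -> descriptors -> scores ->
# chemical-space analysis -> window census -> report.

#' Build a pipeline run configuration
#'
#' Collects the file-based inputs of a screening run. Any path left NULL
#' falls back to the packaged default. The seed is recorded in the report
#' and drives every stochastic element of the run (the descriptor stage
#' itself is deterministic; the seed also feeds the silhouette permutation
#' test).
#'
#' @param grammar path to a grammar YAML (NULL = packaged default).
#' @param manifest path to a manifest CSV to load instead of enumerating
#'   (NULL = enumerate from the grammar).
#' @param qspr path to a QSPR config YAML (NULL = packaged default).
#' @param bbbRanges,drugRanges paths to range-table YAMLs (NULL = packaged
#'   defaults).
#' @param seed integer seed.
#' @param combinedPCA analyse PVLs and PVAs in one PCA instead of the
#'   default separate analyses.
#' @return a RunConfig list.
#' @export
pipelineConfig <- function(grammar = NULL, manifest = NULL, qspr = NULL,
                           bbbRanges = NULL, drugRanges = NULL,
                           seed = 2019L, combinedPCA = FALSE) {
  for (p in c(grammar, manifest, qspr, bbbRanges, drugRanges))
    if (!is.null(p) && !file.exists(p))
      stop("config file does not exist: ", p, call. = FALSE)
  list(grammar = grammar, manifest = manifest, qspr = qspr,
       bbbRanges = bbbRanges, drugRanges = drugRanges,
       seed = as.integer(seed), combinedPCA = isTRUE(combinedPCA))
}

# md5 of the canonicalized JSON form of the config (provenance hash)
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline
#'
#' Executes every stage on one configuration: library enumeration (or
#' manifest load), the twelve-descriptor table, Lipinski / star / BBB
#' scoring, per-family PCA with class-separation silhouettes, the logBB
#' window census, and the ranked report. All tables are written as CSV and
#' the run report as JSON; identical config + seed reproduce identical
#' outputs. Partial outputs are kept when a stage fails.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param verbose log stage progress.
#' @return the run report, invisibly (a list; also written to
#'   \code{report.json}).
#' @examples
#' \donttest{
#' rep <- runPipeline(outDir = tempfile("pvlrun"))
#' rep$census$percent_inside
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = "pvlbbb-run",
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[pvlBBB] ", ...)
  hash <- .configHash(config)

  say("stage 1/5: metabolite library")
  lib <- if (!is.null(config$manifest)) readManifest(config$manifest)
         else enumerateLibrary(if (is.null(config$grammar)) defaultGrammar()
                               else readGrammarConfig(config$grammar))
  writeManifest(lib, file.path(outDir, "manifest.csv"))
  man <- libraryManifest(lib)

  say("stage 2/5: descriptor table (", length(lib), " molecules)")
  qspr <- loadQsprConfig(config$qspr)
  ds <- computeDescriptors(lib, qspr = qspr, seed = config$seed)
  writeDescriptors(ds, file.path(outDir, "descriptors.csv"))

  say("stage 3/5: scoring")
  bbbR <- if (is.null(config$bbbRanges)) defaultBBBRanges()
          else readRangeTable(config$bbbRanges)
  drugR <- if (is.null(config$drugRanges)) defaultDrugRanges()
           else readRangeTable(config$drugRanges)
  st <- bbbScore(ds, bbbR, drugR)
  ranked <- rankLibrary(st, lib)
  scored <- cbind(st@scores, as.data.frame(st@passFlags))
  utils::write.csv(scored, file.path(outDir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ranked, file.path(outDir, "ranked.csv"),
                   row.names = FALSE)

  say("stage 4/5: chemical-space analysis")
  classes <- man$class[match(ds@values$id, man$id)]
  kinds <- ifelse(grepl("PVA", classes), "PVA", "PVL")
  pca_out <- list()
  groups <- if (config$combinedPCA) list(all = rep(TRUE, nrow(ds@values)))
            else list(pvl = kinds == "PVL", pva = kinds == "PVA")
  for (gname in names(groups)) {
    keep <- groups[[gname]]
    if (sum(keep) < 3L) next
    z <- suppressWarnings(
      standardizeDescriptors(ds@values[keep, DESCRIPTOR_NAMES]))
    pc <- pcaDescriptors(z, classes = factor(classes[keep]))
    rownames(pc@scores) <- ds@values$id[keep]
    sep <- tryCatch(suppressWarnings(classSeparation(pc)),
                    error = function(e) NULL)
    utils::write.csv(data.frame(id = rownames(pc@scores),
                                class = classes[keep], pc@scores),
                     file.path(outDir, paste0("pca_", gname,
                                              "_scores.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(descriptor = rownames(pc@loadings),
                                pc@loadings),
                     file.path(outDir, paste0("pca_", gname,
                                              "_loadings.csv")),
                     row.names = FALSE)
    pca_out[[gname]] <- list(
      explained_variance = pc@explainedVariance,
      silhouette = if (is.null(sep)) NULL
                   else list(overall = sep$overall,
                             per_class = as.list(sep$per_class)))
  }

  say("stage 5/5: logBB window census")
  census <- logbbWindowCensus(ds, classes = classes)
  census$outside_by_class <- as.list(census$outside_by_class)

  report <- list(
    provenance = list(package = "pvlBBB",
                      version = as.character(utils::packageVersion("pvlBBB")),
                      config_hash = hash, seed = config$seed),
    library = list(version = lib@version, n = length(lib),
                   classes = as.list(table(man$class))),
    descriptor_table = "descriptors.csv",
    failures = ds@failures,
    scores = "scores.csv",
    top_ranked = utils::head(ranked, 10),
    pca = pca_out,
    census = census[c("percent_inside", "n_inside", "n_total",
                      "outside_by_class")])
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null",
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, file.path(outDir, "report.json"))
  invisible(report)
}
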