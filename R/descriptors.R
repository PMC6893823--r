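# Assembly of the full twelve-descriptor panel.

#' Compute the twelve-descriptor panel
#'
#' Computes, for every molecule, the full descriptor vector used by the BBB
#' screen: the topological block (\code{\link{compute2D}}), the predicted
#' block from the configured QSPR models (logBB, Caco-2, MDCK, logKhsa) and
#' the single-conformer 3D block (dipole, volume). Per-molecule failures
#' are recorded in the result's \code{failures} slot and the run continues.
#'
#' @param x a \code{\link{MetaboliteLibrary}}, a character vector of SMILES,
#'   or a single \code{\link{Metabolite}}.
#' @param qspr QSPR config from \code{\link{loadQsprConfig}}.
#' @param seed conformer seed (recorded; the builder is deterministic).
#' @param grid volume grid spacing, Angstrom.
#' @param ids optional ids when \code{x} is a character vector.
#' @return a \code{\link{DescriptorSet}} with one row per molecule, columns
#'   in the fixed \code{\link{DESCRIPTOR_NAMES}} order.
#' @examples
#' \donttest{
#' ds <- computeDescriptors("O=C1CCC(O1)Cc1ccc(O)cc1")
#' ds@values$psa
#' }
#' @export
setGeneric("computeDescriptors", function(x, qspr = loadQsprConfig(),
                                          seed = 2019L, grid = 0.2,
                                          ids = NULL)
  standardGeneric("computeDescriptors"))

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", "character",
  function(x, qspr, seed, grid, ids) {
    if (is.null(ids)) ids <- sprintf("mol%03d", seq_along(x))
    stopifnot(length(ids) == length(x), !anyDuplicated(ids))
    rows <- vector("list", length(x))
    fails <- data.frame(id = character(0), error = character(0),
                        stringsAsFactors = FALSE)
    for (i in seq_along(x)) {
      row <- tryCatch(.descriptorRow(x[i], qspr, seed, grid),
                      error = function(e) conditionMessage(e))
      if (is.character(row)) {
        fails <- rbind(fails, data.frame(id = ids[i], error = row,
                                         stringsAsFactors = FALSE))
      } else {
        rows[[i]] <- cbind(data.frame(id = ids[i],
                                      stringsAsFactors = FALSE), row)
      }
    }
    if (nrow(fails))
      warning("descriptor computation failed for ",
              nrow(fails), " molecule(s): ",
              paste(fails$id, collapse = ", "), call. = FALSE)
    values <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(values))
      values <- cbind(data.frame(id = character(0)),
                      as.data.frame(matrix(numeric(0), 0, 12,
                        dimnames = list(NULL, DESCRIPTOR_NAMES))))
    rownames(values) <- NULL
    new("DescriptorSet", values = values, methods = .descriptorMethods(),
        seed = as.integer(seed), failures = fails)
  })

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", "Metabolite",
  function(x, qspr, seed, grid, ids) {
    computeDescriptors(x@smiles, qspr = qspr, seed = seed, grid = grid,
                       ids = if (is.na(x@id)) NULL else x@id)
  })

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", "MetaboliteLibrary",
  function(x, qspr, seed, grid, ids) {
    smi <- vapply(x@entries, function(m) m@smiles, character(1))
    ids <- vapply(x@entries, function(m) m@id, character(1))
    computeDescriptors(smi, qspr = qspr, seed = seed, grid = grid, ids = ids)
  })

.descriptorRow <- function(smiles, qspr, seed, grid) {
  d2 <- compute2D(smiles)
  bb <- predictLogBB(d2$logp, d2$psa, qspr$logbb)
  cp <- predictCellPermeability(d2$psa, d2$logp, qspr)
  kh <- predictLogKhsa(d2$logp, d2$rotb, qspr$logkhsa)
  cf <- embedConformer(smiles, seed = seed)
  d3 <- compute3D(cf, grid = grid)
  data.frame(mw = d2$mw, hbd = d2$hbd, hba = d2$hba, psa = d2$psa,
             logp = d2$logp, logbb = bb$logbb, caco2 = cp$caco2,
             mdck = cp$mdck, dipole = unname(d3["dipole"]),
             volume = unname(d3["volume"]), rotb = d2$rotb,
             logkhsa = kh)[, DESCRIPTOR_NAMES]
}

.descriptorMethods <- function() c(
  mw = "standard atomic masses (Open Babel)",
  hbd = "H-bond donor count (Open Babel)",
  hba = "H-bond acceptor count (Open Babel)",
  psa = "Ertl fragment-contribution topological PSA",
  logp = "Wildman-Crippen atomic-contribution logP",
  logbb = "linear regression in logP and PSA (config: logbb)",
  caco2 = "linear QSPR in PSA and logP (config: caco2)",
  mdck = "affine map of caco2 (config: mdck)",
  dipole = "EEM point charges, single deterministic conformer",
  volume = "van der Waals union volume, cubic grid",
  logkhsa = "linear QSPR in logP and rotb (config: logkhsa)",
  rotb = "acyclic single-bond SMARTS count")

setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet:", nrow(object@values), "molecules x",
      length(DESCRIPTOR_NAMES), "descriptors (seed ", object@seed, ")\n")
  if (nrow(object@failures))
    cat("  failures:", paste(object@failures$id, collapse = ", "), "\n")
  if (nrow(object@values)) print(utils::head(object@values, 4))
})

#' Write a descriptor table to CSV
#'
#' Fixed column order (id + the twelve descriptors); reruns at the same
#' seed/config produce byte-identical files.
#'
#' @param descriptors a \code{\link{DescriptorSet}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeDescriptors <- function(descriptors, path) {
  stopifnot(is(descriptors, "DescriptorSet"))
  v <- descriptors@values
  num <- vapply(v, is.numeric, logical(1))
  v[num] <- lapply(v[num], function(x) sprintf("%.6g", x))
  utils::write.csv(v, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
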