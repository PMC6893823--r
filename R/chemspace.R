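# Chemical-space analysis: PCA of the standardized descriptor matrix,
# silhouette statistics for conjugation-class clustering, and the logBB
# window census.

#' Z-score a descriptor matrix
#'
#' Centers and scales every column to mean 0 and standard deviation 1
#' using the population-sd convention (divisor n). Constant columns carry
#' no information on this scale and are dropped with a warning.
#'
#' @param x numeric matrix or data.frame (>= 2 rows).
#' @return standardized matrix; dropped column names in attribute
#'   \code{"dropped"}.
#' @examples
#' standardizeDescriptors(cbind(a = c(1, 2, 3)))  # -1.2247, 0, 1.2247
#' @export
standardizeDescriptors <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2L)
    stop("standardization needs at least 2 rows", call. = FALSE)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  const <- sd_pop == 0
  if (any(const))
    warning("dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(m[, !const, drop = FALSE], 2, mu[!const]), 2,
             sd_pop[!const], "/")
  attr(z, "dropped") <- colnames(m)[const]
  z
}

#' Principal component analysis of descriptor space
#'
#' Eigendecomposition of the covariance matrix of the (standardized) input.
#' Loadings are orthonormal; each component's sign is fixed so its
#' largest-magnitude loading is positive; explained-variance fractions are
#' reported over all components and sum to 1.
#'
#' @param x standardized numeric matrix (rows = molecules).
#' @param nComponents number of components to keep in scores/loadings
#'   (default all); more than the matrix rank is truncated with a warning.
#' @param classes optional factor of conjugation classes, stored for
#'   plotting/silhouette analysis.
#' @return a \code{\link{ChemSpaceResult}}.
#' @export
pcaDescriptors <- function(x, nComponents = NULL, classes = NULL) {
  m <- as.matrix(x)
  cv <- stats::cov(m)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(nComponents)) nComponents <- rank
  if (nComponents > rank) {
    warning("requested ", nComponents, " components but rank is ", rank,
            "; truncating", call. = FALSE)
    nComponents <- rank
  }
  L <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  # deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(m)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- sweep(m, 2, colMeans(m)) %*% L
  rownames(scores) <- rownames(m)
  if (is.null(classes)) classes <- factor(character(0))
  new("ChemSpaceResult", scores = scores, loadings = L,
      explainedVariance = ev / sum(ev), classes = as.factor(classes),
      silhouette = list())
}

#' Silhouette statistics for class separation
#'
#' Quantifies how well the score space clusters by conjugation class:
#' mean silhouette width per class and overall, computed on the first two
#' components with Euclidean distance. Classes with fewer than two members
#' cannot have a silhouette and are excluded with a warning.
#'
#' @param x a \code{\link{ChemSpaceResult}} or a score matrix.
#' @param classes factor of class labels (taken from the result if absent).
#' @param nComponents number of leading components used (default 2).
#' @return list with \code{overall} (mean silhouette width),
#'   \code{per_class} (named numeric) and \code{n_used}.
#' @export
classSeparation <- function(x, classes = NULL, nComponents = 2L) {
  scores <- if (is(x, "ChemSpaceResult")) x@scores else as.matrix(x)
  if (is.null(classes) && is(x, "ChemSpaceResult")) classes <- x@classes
  classes <- factor(classes)
  stopifnot(length(classes) == nrow(scores))
  keep_lv <- names(which(table(classes) >= 2L))
  if (length(setdiff(levels(droplevels(classes)), keep_lv)))
    warning("excluding singleton class(es): ",
            paste(setdiff(levels(droplevels(classes)), keep_lv),
                  collapse = ", "), call. = FALSE)
  keep <- classes %in% keep_lv
  cl <- droplevels(classes[keep])
  if (nlevels(cl) < 2L)
    stop("need at least two classes with >= 2 members", call. = FALSE)
  sc <- scores[keep, seq_len(min(nComponents, ncol(scores))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(cl), stats::dist(sc))
  sw <- sil[, "sil_width"]
  list(overall = mean(sw),
       per_class = tapply(sw, cl, mean),
       n_used = sum(keep))
}

#' Permutation test for conjugation-class clustering
#'
#' Compares the observed overall silhouette width against the null
#' distribution obtained by shuffling class labels: the testable form of
#' "the classes cluster in descriptor space".
#'
#' @param x \code{\link{ChemSpaceResult}} or score matrix.
#' @param classes class factor.
#' @param nPermutations number of label shuffles (default 999).
#' @param seed RNG seed.
#' @param nComponents leading components used (default 2).
#' @return list: observed silhouette, permutation quantiles, empirical
#'   p-value, and the permuted values.
#' @export
silhouettePermutationTest <- function(x, classes = NULL,
                                      nPermutations = 999L, seed = 1L,
                                      nComponents = 2L) {
  scores <- if (is(x, "ChemSpaceResult")) x@scores else as.matrix(x)
  if (is.null(classes) && is(x, "ChemSpaceResult")) classes <- x@classes
  obs <- suppressWarnings(
    classSeparation(scores, classes, nComponents)$overall)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPermutations), function(i)
    suppressWarnings(
      classSeparation(scores, sample(classes), nComponents)$overall),
    numeric(1))
  list(observed = obs,
       q95 = stats::quantile(perm, 0.95, names = FALSE),
       p_value = (1 + sum(perm >= obs)) / (1 + nPermutations),
       permuted = perm)
}

#' Census of the logBB CNS window
#'
#' Fraction of molecules whose predicted logBB lies strictly inside the
#' CNS window (default -3.00 to 1.20), with the class breakdown of the
#' molecules outside it.
#'
#' @param x \code{\link{DescriptorSet}} or data.frame with a logbb column.
#' @param classes optional class labels (same order as rows).
#' @param window numeric length-2 open interval.
#' @return list: \code{fraction_inside}, \code{percent_inside},
#'   \code{n_inside}, \code{n_total}, \code{outside} (data.frame id,
#'   class, logbb), \code{outside_by_class} (table).
#' @export
logbbWindowCensus <- function(x, classes = NULL, window = c(-3.00, 1.20)) {
  v <- .descriptorValues(x)
  stopifnot("logbb" %in% colnames(v))
  if (nrow(v) == 0L)
    return(list(fraction_inside = NA_real_, percent_inside = NA_real_,
                n_inside = 0L, n_total = 0L,
                outside = data.frame(id = character(0),
                                     class = character(0),
                                     logbb = numeric(0)),
                outside_by_class = table(character(0))))
  inside <- .strictlyInside(v$logbb, window[1], window[2])
  ids <- if ("id" %in% colnames(v)) v$id
         else sprintf("mol%03d", seq_len(nrow(v)))
  if (is.null(classes)) classes <- rep(NA_character_, nrow(v))
  outside <- data.frame(id = ids[!inside],
                        class = as.character(classes)[!inside],
                        logbb = v$logbb[!inside], stringsAsFactors = FALSE)
  list(fraction_inside = mean(inside),
       percent_inside = 100 * mean(inside),
       n_inside = sum(inside), n_total = length(inside),
       outside = outside,
       outside_by_class = table(outside$class))
}

setMethod("show", "ChemSpaceResult", function(object) {
  ev <- object@explainedVariance
  cat("ChemSpaceResult:", nrow(object@scores), "molecules,",
      ncol(object@scores), "components kept\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(ev, 4)), collapse = ", "),
      if (length(ev) > 4) "...\n" else "\n")
})

#' Scatter plot of the first two components by conjugation class
#'
#' @param x a \code{\link{ChemSpaceResult}} with classes.
#' @param main plot title.
#' @return invisibly, the per-class plotting symbols used.
#' @export
plotChemSpace <- function(x, main = "Descriptor space (PCA)") {
  stopifnot(is(x, "ChemSpaceResult"), ncol(x@scores) >= 2)
  cl <- droplevels(x@classes)
  pch <- seq_len(nlevels(cl)) %% 25
  ev <- x@explainedVariance
  graphics::plot(x@scores[, 1], x@scores[, 2], pch = pch[as.integer(cl)],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * ev[2]), main = main)
  graphics::legend("topright", legend = levels(cl), pch = pch, cex = 0.7)
  invisible(setNames(pch, levels(cl)))
}
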