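# Drug-likeness and BBB permeation scoring.

# Coerce scoring input to the values data.frame of a DescriptorSet.
.descriptorValues <- function(x) {
  if (is(x, "DescriptorSet")) return(x@values)
  if (is.data.frame(x)) return(x)
  stop("expected a DescriptorSet or data.frame", call. = FALSE)
}

#' Lipinski rule-of-five violations
#'
#' Counts the violated rules among mw > 500, logp > 5, hbd > 5, hba > 10.
#' Boundary values (e.g. mw exactly 500) do not violate.
#'
#' @param x a \code{\link{DescriptorSet}} or data.frame with columns mw,
#'   logp, hbd, hba.
#' @return integer vector of violation counts (0-4).
#' @examples
#' lipinskiViolations(data.frame(mw = 600, logp = 6, hbd = 6, hba = 11))
#' @export
lipinskiViolations <- function(x) {
  v <- .descriptorValues(x)
  need <- c("mw", "logp", "hbd", "hba")
  if (!all(need %in% colnames(v)))
    stop("missing descriptor columns: ",
         paste(setdiff(need, colnames(v)), collapse = ", "), call. = FALSE)
  as.integer((v$mw > 500) + (v$logp > 5) + (v$hbd > 5) + (v$hba > 10))
}

#' Reduced star count (drug-likeness non-compliance)
#'
#' Counts, per molecule, how many descriptors fall outside their
#' 95%-of-known-drugs interval (strictly-inside convention: boundary hits
#' count as outside). Runs over the descriptors present in the range
#' table; panel descriptors absent from the table are skipped with a
#' warning, which is why the packaged default is a "reduced" star count.
#'
#' @param x a \code{\link{DescriptorSet}} or descriptor data.frame.
#' @param drugRanges a \code{\link{RangeTable}}.
#' @param warn warn about skipped descriptors.
#' @return integer vector of star counts.
#' @export
countStars <- function(x, drugRanges = defaultDrugRanges(), warn = TRUE) {
  v <- .descriptorValues(x)
  t <- drugRanges@table
  have <- intersect(t$descriptor, colnames(v))
  skipped <- setdiff(intersect(DESCRIPTOR_NAMES, colnames(v)), have)
  if (length(skipped) && warn)
    warning("star count skips descriptors without drug ranges: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  stars <- integer(nrow(v))
  for (d in have) {
    row <- t[t$descriptor == d, ]
    stars <- stars + as.integer(!.strictlyInside(v[[d]], row$lo, row$hi))
  }
  stars
}

#' BBB permeation score (0-12)
#'
#' For each molecule, counts how many of the twelve panel descriptors fall
#' strictly inside their BBB-permeability interval. A complete score table
#' is returned: the 0-12 BBB score with its per-descriptor pass flags,
#' Lipinski violations and the reduced star count.
#'
#' @param x a \code{\link{DescriptorSet}} or descriptor data.frame with an
#'   \code{id} column and the twelve descriptor columns.
#' @param bbbRanges twelve-entry \code{\link{RangeTable}}.
#' @param drugRanges range table for the star count.
#' @param warn passed to \code{\link{countStars}}.
#' @return a \code{\link{ScoreTable}}.
#' @examples
#' \donttest{
#' ds <- computeDescriptors(pvlLibrary())
#' st <- bbbScore(ds)
#' table(st@scores$bbb_score)
#' }
#' @export
bbbScore <- function(x, bbbRanges = defaultBBBRanges(),
                     drugRanges = defaultDrugRanges(), warn = FALSE) {
  v <- .descriptorValues(x)
  t <- bbbRanges@table
  missing_ranges <- setdiff(DESCRIPTOR_NAMES, t$descriptor)
  if (length(missing_ranges))
    stop("BBB range table must cover all twelve descriptors; missing: ",
         paste(missing_ranges, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(DESCRIPTOR_NAMES, colnames(v))
  if (length(missing_cols))
    stop("descriptor input is incomplete; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  flags <- matrix(FALSE, nrow(v), length(DESCRIPTOR_NAMES),
                  dimnames = list(NULL, DESCRIPTOR_NAMES))
  for (d in DESCRIPTOR_NAMES) {
    row <- t[t$descriptor == d, ]
    flags[, d] <- .strictlyInside(v[[d]], row$lo, row$hi)
  }
  ids <- if ("id" %in% colnames(v)) v$id
         else sprintf("mol%03d", seq_len(nrow(v)))
  scores <- data.frame(
    id = ids,
    lipinski = lipinskiViolations(v),
    stars = countStars(v, drugRanges, warn = warn),
    bbb_score = as.integer(rowSums(flags)),
    stringsAsFactors = FALSE)
  new("ScoreTable", scores = scores, passFlags = flags)
}

#' Rank a library by BBB score
#'
#' Descending BBB score; ties broken by (conjugation class, systematic
#' name) in legend order, giving the bar-chart ordering of the screen's
#' final report.
#'
#' @param scoreTable a \code{\link{ScoreTable}}.
#' @param library the corresponding \code{\link{MetaboliteLibrary}} (used
#'   for class/name tie-breaks; optional).
#' @return data.frame: id, systematic_name, class, bbb_score, lipinski,
#'   stars, ordered.
#' @export
rankLibrary <- function(scoreTable, library = NULL) {
  stopifnot(is(scoreTable, "ScoreTable"))
  s <- scoreTable@scores
  if (!is.null(library)) {
    man <- libraryManifest(library)
    s <- merge(s, man[c("id", "systematic_name", "class")], by = "id",
               sort = FALSE)
    ord <- order(-s$bbb_score, match(s$class, conjugationClasses()),
                 method = "radix",
                 s$systematic_name)
  } else {
    s$systematic_name <- NA_character_
    s$class <- NA_character_
    ord <- order(-s$bbb_score, s$id, method = "radix")
  }
  out <- s[ord, c("id", "systematic_name", "class", "bbb_score",
                  "lipinski", "stars")]
  rownames(out) <- NULL
  out
}

setMethod("show", "ScoreTable", function(object) {
  s <- object@scores
  cat("ScoreTable:", nrow(s), "molecules\n")
  cat("  BBB score distribution:\n")
  print(table(s$bbb_score))
})
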