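## Rank-based single-sample cell-type enrichment scores used as DE design
## covariates (keratinocyte, melanocyte, skeletal muscle by default).

#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file (tab-separated: set name, description,
#'   gene ids).
#' @return Named list of character vectors; empty sets are rejected.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors of gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  if (any(lengths(sets) == 0L)) stop("refusing to write an empty gene set")
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Single-sample signature score
#'
#' Mean within-sample expression rank of the signature genes, rescaled by
#' `G + 1` (G = number of genes in the column) to lie in (0, 1); ties are
#' broken by average rank, so the score is invariant under any strictly
#' increasing transform of the expression column. A random set on
#' exchangeable data scores 0.5 in expectation; a set occupying the top |S|
#' ranks scores `(G - (|S| - 1) / 2) / (G + 1)`, the maximum.
#'
#' @param expr named numeric vector: one sample's expression over all genes.
#' @param geneSet character vector of signature gene ids.
#' @return The raw score, or `NA` (with a warning) when no signature gene is
#'   present in the column.
#' @export
scoreSignature <- function(expr, geneSet) {
  if (is.null(names(expr))) stop("'expr' must be named by gene id")
  present <- intersect(geneSet, names(expr))
  if (length(present) == 0L) {
    warning("no signature gene present in the expression column")
    return(NA_real_)
  }
  r <- rank(expr, ties.method = "average")
  mean(r[present]) / (length(expr) + 1)
}

#' Score all samples against all cell-type signatures
#'
#' Applies [scoreSignature()] per sample and cell type, then rescales each
#' cell type linearly to `[0, 1]` across samples (skipped, with a message,
#' when fewer than two distinct raw scores exist).
#'
#' @param normalized gene x sample matrix of normalized expression.
#' @param signatures named list of gene sets (cell type -> gene ids).
#' @param rescale rescale per cell type to `[0, 1]` (default TRUE).
#' @return Numeric matrix, samples x cell types, with an attribute
#'   `"rescaled"` (logical per cell type).
#' @export
scoreCellTypes <- function(normalized, signatures, rescale = TRUE) {
  m <- as.matrix(normalized)
  if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
  raw <- vapply(signatures, function(set)
    apply(m, 2L, function(col) scoreSignature(stats::setNames(col,
      rownames(m)), set)),
    numeric(ncol(m)))
  raw <- matrix(raw, nrow = ncol(m),
    dimnames = list(colnames(m), names(signatures)))
  did <- rep(FALSE, ncol(raw))
  names(did) <- colnames(raw)
  if (rescale) {
    for (j in seq_len(ncol(raw))) {
      v <- raw[, j]
      rng <- range(v, na.rm = TRUE)
      if (is.finite(diff(rng)) && diff(rng) > 0) {
        raw[, j] <- (v - rng[1L]) / diff(rng)
        did[j] <- TRUE
      } else {
        message("cell type '", colnames(raw)[j],
          "': fewer than two distinct scores; rescaling skipped")
      }
    }
  }
  attr(raw, "rescaled") <- did
  raw
}
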