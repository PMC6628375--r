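## Normalization (median-of-ratios size factors, TPM), expression filtering
## and PCA quality control.

.assayCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' DESeq-convention size factors: for each sample, the median over genes of
#' the ratio of its count to the gene's geometric mean across samples,
#' computed over genes with strictly positive counts in all samples.
#'
#' @param counts integer matrix (genes x samples) or a SummarizedExperiment
#'   with a `counts` assay.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(10, 30), s2 = c(20, 60))
#' computeSizeFactors(m)   # 1/sqrt(2), sqrt(2)
#' @export
computeSizeFactors <- function(counts) {
  m <- .assayCounts(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  logg <- rowMeans(log(m))
  ok <- is.finite(logg)
  if (!any(ok))
    stop("no gene has positive counts in every sample; ",
      "apply filterExpressed() or provide deeper data")
  sf <- apply(m, 2L, function(col) {
    exp(stats::median(log(col[ok]) - logg[ok]))
  })
  sf
}

#' Transcripts-per-million normalization
#'
#' `tpm[g, j] = 1e6 * (c[g, j] / L[g]) / sum_g(c[g, j] / L[g])`. Requires a
#' gene effective length for every gene; no imputation is attempted.
#'
#' @param counts gene x sample count matrix.
#' @param lengths positive numeric vector of gene effective lengths (bases),
#'   parallel to the rows.
#' @return Matrix of TPM values; every column sums to 1e6.
#' @export
computeTPM <- function(counts, lengths) {
  m <- .assayCounts(counts)
  if (length(lengths) != nrow(m))
    stop("need one effective length per gene")
  if (any(!is.finite(lengths) | lengths <= 0))
    stop("gene effective lengths must be positive")
  rate <- m / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with all-zero counts; cannot form TPM")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Filter to expressed genes of allowed biotypes
#'
#' Keeps genes whose total count over all samples reaches `minTotal` (a soft
#' filter of 10 reads in total per gene by default, with the boundary read as
#' `>=`) and whose biotype is in `biotypes`; sense-intronic lncRNAs are
#' excluded by default as likely misannotated coding isoforms.
#'
#' @param se a SummarizedExperiment with a `counts` assay and a `biotype`
#'   column in `rowData`, or a plain matrix (then supply `biotype`).
#' @param minTotal minimum row sum, default 10.
#' @param biotypes allowed biotypes.
#' @param biotype biotype vector when `se` is a matrix.
#' @return The filtered object, same class as the input. Idempotent.
#' @export
filterExpressed <- function(se, minTotal = 10,
    biotypes = c("protein_coding", "lincRNA", "antisense"),
    biotype = NULL) {
  stopifnot(minTotal >= 0)
  m <- .assayCounts(se)
  if (is.null(biotype)) {
    if (is(se, "SummarizedExperiment"))
      biotype <- SummarizedExperiment::rowData(se)$biotype
    else stop("supply 'biotype' for a plain matrix")
  }
  keep <- rowSums(m) >= minTotal & biotype %in% biotypes
  if (!any(keep)) warning("no genes pass the expression filter")
  if (is(se, "SummarizedExperiment")) se[keep, ]
  else se[keep, , drop = FALSE]
}

#' PCA quality control of samples
#'
#' Principal component analysis of `log2(x + 1)` of a normalized expression
#' matrix, with genes centered, for visual/quantitative separation of
#' condition and breed.
#'
#' @param normalized gene x sample matrix of normalized expression.
#' @param nComponents number of components to return (default 2).
#' @return A list with `scores` (samples x components), `varExplained`
#'   (fraction of total variance per component) and `sdev`.
#' @export
pcaQC <- function(normalized, nComponents = 2) {
  m <- as.matrix(normalized)
  if (ncol(m) < 2L) stop("need at least two samples")
  x <- log2(m + 1)
  if (all(apply(x, 1L, stats::sd) == 0))
    stop("constant expression matrix; PCA undefined")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
    varExplained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
    sdev = p$sdev)
}
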