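#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width reduce
#' @importFrom IRanges IRanges
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Gene models as pooled exon sets
#'
#' A `GeneAnnotation` stores, for each gene, the pool of exons over all of its
#' transcripts (deduplicated, one strand, one chromosome) together with the
#' gene biotype. It is the coordinate backbone for meta-transcript
#' construction, expression filtering by biotype, and exon-level intersection
#' of cross-species alignments.
#'
#' @slot exons [GenomicRanges::GRangesList] named by gene id; each element
#'   holds the exons of one gene (single seqname and strand).
#' @slot biotype named character vector, parallel to `exons`; values such as
#'   `"protein_coding"`, `"lincRNA"`, `"antisense"`, `"sense_intronic"`.
#'
#' @seealso [readGTF()], [buildMetaTranscript()], [intersectAnnotation()]
#' @export
setClass("GeneAnnotation",
  slots = c(exons = "GRangesList", biotype = "character"))

setValidity("GeneAnnotation", function(object) {
  ex <- object@exons
  bt <- object@biotype
  msgs <- character()
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msgs <- c(msgs, "gene ids (names of 'exons') must be present and unique")
  if (length(bt) != length(ex) || !identical(names(bt), names(ex)))
    msgs <- c(msgs, "'biotype' must be named parallel to 'exons'")
  nchrom <- vapply(ex, function(g) length(unique(as.character(seqnames(g)))),
    integer(1))
  nstr <- vapply(ex, function(g) length(unique(as.character(strand(g)))),
    integer(1))
  if (any(nchrom > 1))
    msgs <- c(msgs, paste0("gene(s) with exons on multiple chromosomes: ",
      paste(head(names(ex)[nchrom > 1], 3), collapse = ", ")))
  if (any(nstr > 1))
    msgs <- c(msgs, paste0("gene(s) with exons on both strands: ",
      paste(head(names(ex)[nstr > 1], 3), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneAnnotation
#'
#' @param exons a named [GenomicRanges::GRangesList] of exons per gene.
#' @param biotype character vector of gene biotypes, either named by gene id
#'   or parallel to `exons`.
#' @return A [GeneAnnotation-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' GeneAnnotation(ex, c(g1 = "lincRNA"))
#' @export
GeneAnnotation <- function(exons, biotype) {
  if (is.null(names(biotype))) names(biotype) <- names(exons)
  biotype <- biotype[names(exons)]
  new("GeneAnnotation", exons = exons, biotype = biotype)
}

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@exons), "genes\n")
  tb <- table(object@biotype)
  cat("biotypes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

#' Differential expression results
#'
#' A `DEResults` object is a [S4Vectors::DataFrame] with one row per gene and
#' the columns `baseMean` (mean of size-factor-normalized counts), `lfcMLE`
#' and `lfcShrunk` (log2 fold change, maximum likelihood and normal-prior MAP
#' estimate), `lfcSE` (standard error of the MLE, log2 scale), `pvalue`
#' (two-sided Wald), `padj` (Benjamini-Hochberg) and `status`
#' (`"up"`/`"down"`/`"ns"`).
#'
#' @seealso [runDE()], [callDE()]
#' @export
setClass("DEResults", contains = "DFrame")

setValidity("DEResults", function(object) {
  need <- c("baseMean", "lfcMLE", "lfcShrunk", "lfcSE", "pvalue", "padj",
    "status")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  ok <- stats::complete.cases(object$pvalue, object$padj)
  if (any(object$padj[ok] < object$pvalue[ok] - 1e-12))
    return("padj must be >= pvalue")
  TRUE
})

setMethod("show", "DEResults", function(object) {
  cat("DEResults:", nrow(object), "genes;",
    sum(object$status == "up"), "up,",
    sum(object$status == "down"), "down\n")
  callNextMethod()
})

#' Co-expression module set
#'
#' Result of signed weighted co-expression analysis: a gene-to-module
#' partition ("grey" marks unassigned genes), per-module eigengenes (first
#' principal component of the standardized module submatrix, unit norm),
#' module-trait Pearson correlations, and per-gene significance (GS, gene vs
#' trait) and module membership (MM, gene vs own eigengene).
#'
#' @slot labels named character vector mapping gene id to module color.
#' @slot eigengenes numeric matrix, samples x modules (unit-norm columns).
#' @slot varExplained numeric, fraction of module variance carried by the
#'   eigengene, named by module.
#' @slot moduleTrait data.frame with columns `module`, `r`, `pvalue` (NULL
#'   until [moduleTrait()] is run).
#' @slot geneSignificance named numeric, per-gene trait correlation.
#' @slot moduleMembership named numeric, per-gene correlation with own ME.
#' @seealso [detectModules()], [runCoexpression()]
#' @export
setClass("ModuleSet",
  slots = c(labels = "character", eigengenes = "matrixOrNULL",
    varExplained = "numeric", moduleTrait = "ANY",
    geneSignificance = "numeric", moduleMembership = "numeric"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@labels)))
    return("'labels' must be named by gene id")
  if (!is.null(object@eigengenes)) {
    mods <- setdiff(unique(object@labels), "grey")
    if (!all(mods %in% colnames(object@eigengenes)))
      return("every non-grey module needs an eigengene column")
  }
  TRUE
})

setMethod("show", "ModuleSet", function(object) {
  tb <- sort(table(object@labels), decreasing = TRUE)
  cat("ModuleSet:", length(object@labels), "genes in",
    sum(names(tb) != "grey"), "modules (+grey)\n")
  print(head(tb, 10))
})

#' Cross-species orthology calls
#'
#' A [S4Vectors::DataFrame] with one row per query gene: `query`, `aligned`,
#' `identity` (matching bases / alignment columns), primary locus
#' (`targetChrom`, `targetStart`, `targetEnd`, `targetStrand`),
#' `matchedGene` (target gene with maximal exon overlap, or NA) and `class`
#' (`annotated_ortholog`, `novel_aligned`, `below_identity`, `unaligned`).
#'
#' @seealso [classifyOrthology()]
#' @export
setClass("OrthologyCalls", contains = "DFrame")

setValidity("OrthologyCalls", function(object) {
  need <- c("query", "aligned", "identity", "matchedGene", "class")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  okcls <- c("annotated_ortholog", "novel_aligned", "below_identity",
    "unaligned")
  if (!all(object$class %in% okcls))
    return("invalid orthology class")
  bad <- object$class == "annotated_ortholog" & is.na(object$matchedGene)
  if (any(bad))
    return("annotated_ortholog calls require a matched target gene")
  TRUE
})

setMethod("show", "OrthologyCalls", function(object) {
  cat("OrthologyCalls:", nrow(object), "queries\n")
  print(table(object$class))
})
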