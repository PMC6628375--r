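## Hypergeometric over-representation of module mRNAs against GO-BP gene
## sets, and guilt-by-association transfer of enriched terms to module
## lncRNAs.

#' Over-representation analysis of one module
#'
#' Upper-tail hypergeometric test of the overlap between a module's mRNAs
#' and each gene set, over a fixed universe (all genes that entered the
#' co-expression analysis): `p = P(X >= k)` with `k` the overlap, `K` the
#' set size within the universe, `n` the module size within the universe and
#' `N` the universe size. BH adjustment is applied across terms within the
#' module. Long non-coding query genes should be excluded by the caller
#' (gene sets describe mRNA function); term membership outside the universe
#' is ignored.
#'
#' @param moduleGenes character vector of the module's mRNA ids.
#' @param geneSets named list of gene sets (e.g. from [readGMT()]).
#' @param universe character vector of background gene ids; must contain
#'   the module genes.
#' @param topN when not NULL, return only the `topN` most significant terms.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `pvalue`, `qvalue`,
#'   sorted by p-value.
#' @export
runORA <- function(moduleGenes, geneSets, universe, topN = NULL) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  if (!all(moduleGenes %in% universe))
    stop("module genes must be contained in the universe")
  mod <- unique(moduleGenes)
  N <- length(universe); n <- length(mod)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, mod))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- bhAdjust(out$pvalue)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(topN)) out <- utils::head(out, topN)
  out
}

#' Over-representation for every trait-associated module
#'
#' Runs [runORA()] for each non-grey module, restricted to mRNA genes.
#'
#' @param mset a [ModuleSet-class].
#' @param geneSets named list of gene sets.
#' @param universe background gene ids (typically all genes that entered
#'   co-expression).
#' @param mrnaIds ids of protein-coding genes; module and universe are
#'   intersected with them before testing.
#' @param topN per-module cap on reported terms (default 10, the usual
#'   reporting depth).
#' @return Named list of per-module ORA tables.
#' @export
moduleORA <- function(mset, geneSets, universe, mrnaIds, topN = 10) {
  uni <- intersect(universe, mrnaIds)
  lab <- mset@labels
  mods <- setdiff(unique(lab), "grey")
  stats::setNames(lapply(mods, function(mod) {
    genes <- intersect(names(lab)[lab == mod], uni)
    runORA(genes, geneSets, uni, topN = topN)
  }), mods)
}

#' Guilt-by-association term transfer to a lncRNA
#'
#' A lncRNA inherits the significantly enriched terms (`q < qCut`) of the
#' co-expression module it belongs to, annotated with the module's direction
#' of trait correlation. Grey (unassigned) lncRNAs inherit nothing.
#'
#' @param lncId lncRNA gene id.
#' @param mset a [ModuleSet-class] with the module-trait table filled.
#' @param oraTables named list of per-module ORA tables
#'   (see [moduleORA()]).
#' @param qCut significance threshold on the BH q-value, default 0.05.
#' @return data.frame with `term`, `qvalue`, `module`, `traitCor`;
#'   zero rows (with a message) for grey or unassigned lncRNAs or modules
#'   without significant terms.
#' @export
guiltByAssociation <- function(lncId, mset, oraTables, qCut = 0.05) {
  empty <- data.frame(term = character(), qvalue = numeric(),
    module = character(), traitCor = numeric())
  mod <- mset@labels[lncId]
  if (is.na(mod) || mod == "grey") {
    message("lncRNA '", lncId, "' is unassigned (grey); no terms inherited")
    return(empty)
  }
  tab <- oraTables[[mod]]
  if (is.null(tab)) return(empty)
  sig <- tab[!is.na(tab$qvalue) & tab$qvalue < qCut, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  mt <- mset@moduleTrait
  r <- if (!is.null(mt) && mod %in% mt$module)
    mt$r[mt$module == mod] else NA_real_
  data.frame(term = sig$term, qvalue = sig$qvalue, module = mod,
    traitCor = r, row.names = NULL)
}
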