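## Signed weighted co-expression network: soft-threshold selection, signed
## adjacency, topological overlap, module detection by average-linkage
## clustering with a constant-height cut and eigengene merging, module-trait
## statistics, and hub extraction.

.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
  "black", "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
  "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
  "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
  "darkgrey", "orange", "darkorange", "white", "skyblue", "saddlebrown",
  "steelblue", "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
  "mediumorchid")

#' Variance filter for network input
#'
#' Keeps the `targetN` genes with the highest variance of `log2(x + 1)` over
#' samples; ties are broken deterministically by gene id.
#'
#' @param normalized gene x sample matrix (TPM or normalized counts).
#' @param targetN number of genes to retain.
#' @param log2Input compute variance on `log2(x + 1)` (default TRUE).
#' @return The reduced matrix (row order by gene id among selected genes).
#' @export
varianceFilter <- function(normalized, targetN, log2Input = TRUE) {
  m <- as.matrix(normalized)
  stopifnot(targetN <= nrow(m), targetN >= 1)
  x <- if (log2Input) log2(m + 1) else m
  v <- apply(x, 1L, stats::var)
  o <- order(-v, rownames(m))
  keep <- sort(o[seq_len(targetN)])
  m[keep, , drop = FALSE]
}

#' Signed adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta` with Pearson correlation: perfectly
#' anti-correlated genes get weight 0, uncorrelated genes `0.5^beta`.
#'
#' @param expr gene x sample matrix.
#' @param beta soft-thresholding power (>= 1), default 7.
#' @return Symmetric gene x gene matrix with unit diagonal, values in
#'   `[0, 1]`.
#' @export
signedAdjacency <- function(expr, beta = 7) {
  stopifnot(beta >= 1, ncol(expr) >= 3)
  x <- as.matrix(expr)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s) present; apply varianceFilter() first")
  a <- ((1 + stats::cor(t(x))) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, computes the whole-network connectivity
#' `k_i = sum_{j != i} a_ij`, the scale-free topology fit (R^2 of
#' `log10 p(k)` on `log10 k` over occupied connectivity bins) and the mean
#' connectivity. Recommends the smallest power reaching `rsqCut`, falling
#' back to the best-fitting power; an explicit `beta` overrides the
#' recommendation (the cohort analysis this package was built around fixes
#' the power at 7).
#'
#' @param expr gene x sample matrix.
#' @param grid candidate powers.
#' @param rsqCut fit threshold, default 0.8.
#' @param beta optional override returned as the recommendation.
#' @param nBins connectivity bins for the fit, default 10.
#' @return A list: `table` (data.frame beta / fitRsq / slope /
#'   meanConnectivity) and `recommended`.
#' @export
pickSoftThreshold <- function(expr, grid = c(1:10, 12, 14, 16, 20),
    rsqCut = 0.8, beta = NULL, nBins = 10) {
  stopifnot(length(grid) >= 1)
  x <- as.matrix(expr)
  cormat <- (1 + stats::cor(t(x))) / 2
  diag(cormat) <- NA
  rows <- lapply(grid, function(b) {
    a <- cormat^b
    k <- rowSums(a, na.rm = TRUE)
    data.frame(beta = b, fitRsq = .scaleFreeFit(k, nBins)$rsq,
      slope = .scaleFreeFit(k, nBins)$slope, meanConnectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  rec <- if (!is.null(beta)) beta
    else if (any(tab$fitRsq >= rsqCut, na.rm = TRUE))
      tab$beta[which(tab$fitRsq >= rsqCut)[1L]]
    else tab$beta[which.max(tab$fitRsq)]
  list(table = tab, recommended = rec)
}

.scaleFreeFit <- function(k, nBins = 10) {
  if (stats::sd(k) == 0) {
    warning("degenerate connectivity distribution; all genes identical?")
    return(list(rsq = NA_real_, slope = NA_real_))
  }
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  use <- !is.na(pk) & pk > 0 & mk > 0
  if (sum(use) < 3L) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[use]) ~ log10(mk[use]))
  list(rsq = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{j != i} a_ij`; `TOM_ii = 1`. Shared-neighbor similarity used
#' as the clustering basis.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with unit diagonal.
#' @return TOM matrix, same shape, values in `[0, 1]`.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  stopifnot(nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1 + 1e-12)
    stop("adjacency values must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`; branches are cut at
#' a constant height (the `cutQuantile` quantile of the merge heights,
#' default 0.90), clusters below `minSize` are set aside as `grey`, and
#' modules whose eigengenes correlate above `mergeCor` are merged. Module
#' labels are color names assigned by decreasing module size.
#'
#' @param tom TOM (or any similarity in `[0, 1]` with unit diagonal) with
#'   gene dimnames.
#' @param expr gene x sample matrix used for eigengene merging; when NULL
#'   the merge step is skipped.
#' @param minSize minimum module size (>= 3), default 10.
#' @param cutQuantile quantile of merge heights at which the tree is cut.
#' @param mergeCor eigengene-correlation merge threshold, default 0.85.
#' @return A [ModuleSet-class] (eigengenes filled when `expr` given).
#' @export
detectModules <- function(tom, expr = NULL, minSize = 10,
    cutQuantile = 0.90, mergeCor = 0.85) {
  stopifnot(minSize >= 3)
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM must carry gene dimnames")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- stats::quantile(hc$height, cutQuantile)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= minSize]
  lab <- ifelse(raw %in% as.integer(keep), as.character(raw), "grey")
  names(lab) <- genes
  if (!is.null(expr) && length(keep) > 1L) {
    lab <- .mergeByEigengene(lab, expr, mergeCor)
  }
  lab <- .colorize(lab)
  mods <- setdiff(unique(lab), "grey")
  me <- NULL; ve <- numeric()
  if (!is.null(expr) && length(mods)) {
    mes <- lapply(mods, function(mod)
      moduleEigengene(expr[names(lab)[lab == mod], , drop = FALSE]))
    me <- vapply(mes, `[[`, numeric(ncol(expr)), "eigengene")
    dimnames(me) <- list(colnames(expr), mods)
    ve <- stats::setNames(vapply(mes, `[[`, numeric(1), "varExplained"),
      mods)
  }
  new("ModuleSet", labels = lab, eigengenes = me, varExplained = ve,
    moduleTrait = NULL, geneSignificance = numeric(),
    moduleMembership = numeric())
}

.mergeByEigengene <- function(lab, expr, mergeCor) {
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2L) return(lab)
    me <- vapply(mods, function(mod)
      moduleEigengene(expr[names(lab)[lab == mod], ,
        drop = FALSE])$eigengene, numeric(ncol(expr)))
    cm <- stats::cor(me)
    diag(cm) <- -Inf
    best <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    if (cm[best[1L], best[2L]] <= mergeCor) return(lab)
    lab[lab == mods[best[2L]]] <- mods[best[1L]]
  }
}

.colorize <- function(lab) {
  tb <- table(lab)
  tb <- tb[order(-tb, names(tb))]           # size, then label: deterministic
  mods <- setdiff(names(tb), "grey")
  pal <- c(.MODULE_COLORS,
    paste0("module", seq_len(max(0, length(mods) - length(.MODULE_COLORS)))))
  map <- stats::setNames(pal[seq_along(mods)], mods)
  map["grey"] <- "grey"
  stats::setNames(unname(map[lab]), names(lab))
}

#' Module eigengene
#'
#' First principal component of the gene-standardized (zero-mean,
#' unit-variance per gene) module submatrix, unit norm, with its sign
#' oriented so that it correlates non-negatively with the mean standardized
#' module profile.
#'
#' @param moduleExpr gene x sample matrix restricted to one module
#'   (>= 2 genes).
#' @return A list: `eigengene` (length-samples unit vector) and
#'   `varExplained` (fraction of module variance on the first component).
#' @export
moduleEigengene <- function(moduleExpr) {
  m <- as.matrix(moduleExpr)
  if (nrow(m) < 2L) stop("a module needs at least two genes")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance gene inside module")
  z <- (m - rowMeans(m)) / sds
  sv <- svd(t(z), nu = 1L, nv = 0L)
  if (all(sv$d == 0)) stop("singular module submatrix")
  me <- sv$u[, 1L]
  if (stats::cor(me, colMeans(z)) < 0) me <- -me
  list(eigengene = stats::setNames(me, colnames(m)),
    varExplained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a clinical trait
#' (binary 0 = normal / 1 = tumor, or continuous), with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param me eigengene matrix (samples x modules) or [ModuleSet-class].
#' @param trait numeric vector, one value per sample.
#' @return data.frame with `module`, `r`, `pvalue`; also stored in the
#'   ModuleSet when one is passed (returned invisibly updated via value).
#' @export
moduleTrait <- function(me, trait) {
  obj <- NULL
  if (is(me, "ModuleSet")) { obj <- me; me <- me@eigengenes }
  if (is.null(me)) stop("no eigengenes available")
  if (length(trait) != nrow(me)) stop("trait length must match samples")
  if (stats::sd(trait) == 0) stop("constant trait; correlation undefined")
  n <- nrow(me)
  if (n < 3L) stop("need at least three samples")
  r <- as.numeric(stats::cor(me, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  tab <- data.frame(module = colnames(me), r = r, pvalue = p,
    row.names = NULL)
  if (!is.null(obj)) { obj@moduleTrait <- tab; return(obj) }
  tab
}

#' Gene significance and module membership
#'
#' GS is the Pearson correlation of each gene's profile with the trait; MM
#' is its correlation with its own module's eigengene (NA for grey genes).
#'
#' @param expr gene x sample matrix.
#' @param mset a [ModuleSet-class] with eigengenes.
#' @param trait per-sample trait vector.
#' @return The ModuleSet with `geneSignificance` and `moduleMembership`
#'   filled.
#' @export
geneModuleStatistics <- function(expr, mset, trait) {
  x <- as.matrix(expr)
  lab <- mset@labels
  gs <- as.numeric(stats::cor(t(x), trait))
  names(gs) <- rownames(x)
  mm <- rep(NA_real_, nrow(x)); names(mm) <- rownames(x)
  for (mod in setdiff(unique(lab), "grey")) {
    g <- names(lab)[lab == mod]
    mm[g] <- as.numeric(stats::cor(t(x[g, , drop = FALSE]),
      mset@eigengenes[, mod]))
  }
  mset@geneSignificance <- gs
  mset@moduleMembership <- mm
  mset
}

#' Hub genes
#'
#' Genes with both high trait significance and high module membership,
#' `|GS| > threshold` and `|MM| > threshold` (strict), grouped by module.
#'
#' @param mset a [ModuleSet-class] with GS/MM filled
#'   (see [geneModuleStatistics()]).
#' @param threshold strict cutoff, default 0.5.
#' @return Named list (module -> character vector of hub gene ids).
#' @export
hubGenes <- function(mset, threshold = 0.5) {
  gs <- mset@geneSignificance; mm <- mset@moduleMembership
  if (!length(gs) || !length(mm))
    stop("GS/MM not computed; run geneModuleStatistics() first")
  lab <- mset@labels
  hubs <- !is.na(gs) & !is.na(mm) & abs(gs) > threshold &
    abs(mm) > threshold
  mods <- setdiff(unique(lab), "grey")
  stats::setNames(lapply(mods, function(mod)
    names(lab)[lab == mod & hubs[names(lab)]]), mods)
}

#' Overlay DE lncRNAs on trait-associated modules
#'
#' Partitions a set of DE lncRNAs into those belonging to significantly
#' trait-associated modules with positive correlation, negative correlation,
#' or neither (grey or non-significant module), and reports the percentage
#' of the DE set covered by significant modules (both one-decimal rounding
#' and truncation of the percentage are reported, as the two conventions
#' differ at the first decimal).
#'
#' @param deGenes character vector of DE lncRNA ids.
#' @param mset a [ModuleSet-class] with the module-trait table filled.
#' @param alpha module-trait significance threshold, default 0.05.
#' @return A list: `inPositive`, `inNegative`, `elsewhere` (counts),
#'   `total`, `pctRounded`, `pctTruncated`, and the per-gene assignment.
#' @export
deModuleOverlay <- function(deGenes, mset, alpha = 0.05) {
  mt <- mset@moduleTrait
  if (is.null(mt)) stop("module-trait table missing; run moduleTrait()")
  sigPos <- mt$module[mt$pvalue < alpha & mt$r > 0]
  sigNeg <- mt$module[mt$pvalue < alpha & mt$r < 0]
  lab <- mset@labels[deGenes]
  lab[is.na(lab)] <- "grey"
  cls <- ifelse(lab %in% sigPos, "positive",
    ifelse(lab %in% sigNeg, "negative", "elsewhere"))
  nPos <- sum(cls == "positive"); nNeg <- sum(cls == "negative")
  tot <- length(deGenes)
  pct <- if (tot) 100 * (nPos + nNeg) / tot else 0
  list(inPositive = nPos, inNegative = nNeg,
    elsewhere = tot - nPos - nNeg, total = tot,
    pctRounded = round(pct, 1), pctTruncated = floor(pct * 10) / 10,
    assignment = stats::setNames(cls, deGenes))
}

#' Run the co-expression stage end to end
#'
#' Variance filter, signed adjacency at the configured power, TOM, module
#' detection, eigengenes, module-trait statistics and GS/MM, in one call.
#'
#' @param normalized gene x sample expression matrix (TPM or normalized
#'   counts).
#' @param trait per-sample trait vector (0 = normal, 1 = tumor).
#' @param targetN variance-filter size (default: all genes).
#' @param beta soft power, default 7.
#' @param minSize,cutQuantile,mergeCor see [detectModules()].
#' @param log2Input correlate `log2(x + 1)` (default TRUE) or raw values.
#' @return A [ModuleSet-class] with all slots filled.
#' @export
runCoexpression <- function(normalized, trait, targetN = nrow(normalized),
    beta = 7, minSize = 10, cutQuantile = 0.90, mergeCor = 0.85,
    log2Input = TRUE) {
  m <- varianceFilter(normalized, targetN, log2Input = log2Input)
  x <- if (log2Input) log2(as.matrix(m) + 1) else as.matrix(m)
  a <- signedAdjacency(x, beta)
  tom <- tomSimilarity(a)
  mset <- detectModules(tom, expr = x, minSize = minSize,
    cutQuantile = cutQuantile, mergeCor = mergeCor)
  if (!is.null(mset@eigengenes)) mset <- moduleTrait(mset, trait)
  geneModuleStatistics(x, mset, trait)
}
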