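## Orchestration: one config drives simulate -> filter -> cell types -> DE
## -> co-expression -> orthology -> enrichment and produces a consolidated
## report with every output stamped by config hash and seed.

#' Default pipeline configuration
#'
#' All stage parameters with their cohort-analysis defaults: expression
#' filter of 10 total reads, DE thresholds `|lfcShrunk| > 1.5` and
#' `padj < 0.05`, orthology identity screen 0.70, hub GS/MM cutoff 0.5,
#' soft-thresholding power 7. The config round-trips through YAML.
#'
#' @param seed RNG seed (propagated to the simulation).
#' @param ... overrides for any default entry.
#' @return A named list.
#' @export
pipelineConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    minTotal = 10,
    biotypes = c("protein_coding", "lincRNA", "antisense"),
    lfcThreshold = 1.5,
    alpha = 0.05,
    minIdentity = 0.70,
    hubThreshold = 0.5,
    beta = 7,
    minModuleSize = 10,
    cutQuantile = 0.90,
    mergeCor = 0.85,
    coexprTargetN = 600,
    oraQ = 0.05,
    moduleTraitCor = c(0.7, -0.7, 0),
    stages = c("simulate", "filter", "celltypes", "de", "coexpress",
      "ortho", "enrich"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config a config list (for writing).
#' @return The config list (reading) or `path` invisibly (writing).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipelineConfig(seed = cfg$seed %||% 1)
  base[names(cfg)] <- cfg
  base
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.stamp <- function(path, hash, seed) {
  lines <- readLines(path)
  writeLines(c(paste0("# melanolnc config=", hash, " seed=", seed), lines),
    path)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes the stages in dependency order: cohort simulation, expression
#' filtering, cell-type scoring, differential expression, co-expression
#' modules with trait statistics and hubs, orthology classification of DE
#' lncRNAs, and guilt-by-association enrichment. Writes TSV artifacts
#' stamped with the config hash and seed, and returns a report.
#'
#' @param config a list from [pipelineConfig()] or a YAML path.
#' @param outdir output directory.
#' @return A report list: `deCounts` (up/down/total, totals-consistent),
#'   `moduleTrait`, `orthoClasses`, `enrichmentTop`, `overlay`,
#'   `configHash`, `seed`, `files`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  seed <- config$seed
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
      row.names = FALSE)
    .stamp(path, hash, seed)
    files[[name]] <<- path
    path
  }

  ## simulate
  scfg <- simulationConfig(seed = seed,
    moduleTraitCor = config$moduleTraitCor)
  sim <- .simulateCohort(scfg)
  se <- sim$se
  counts <- SummarizedExperiment::assay(se, "counts")
  st <- sim$sampleTable
  emit(data.frame(gene_id = rownames(counts), counts,
    check.names = FALSE), "counts.tsv")
  emit(st, "samples.tsv")

  ## filter
  sef <- filterExpressed(se, minTotal = config$minTotal,
    biotypes = config$biotypes)
  countsF <- SummarizedExperiment::assay(sef, "counts")
  if (nrow(countsF) == 0L)
    stop("stage 'filter' produced no genes; upstream simulation too sparse")

  ## normalization + cell types
  sf <- computeSizeFactors(countsF)
  norm <- sweep(countsF, 2L, sf, "/")
  scores <- scoreCellTypes(norm, sim$signatures)
  st2 <- cbind(st, scores[rownames(st), , drop = FALSE])
  emit(data.frame(sample = rownames(scores), scores), "celltype_scores.tsv")

  ## differential expression
  de <- runDE(countsF, st2, cellTypes = colnames(scores),
    sizeFactors = sf, lfcThreshold = config$lfcThreshold,
    alpha = config$alpha)
  emit(data.frame(gene_id = rownames(de), as.data.frame(de)),
    "de_results.tsv")
  up <- sum(de$status == "up"); down <- sum(de$status == "down")
  deCounts <- list(up = up, down = down, total = up + down)
  stopifnot(deCounts$total == deCounts$up + deCounts$down)

  ## co-expression
  trait <- as.integer(st2$condition == "tumor")
  mset <- runCoexpression(norm, trait,
    targetN = min(config$coexprTargetN, nrow(norm)),
    beta = config$beta, minSize = config$minModuleSize,
    cutQuantile = config$cutQuantile, mergeCor = config$mergeCor)
  emit(data.frame(gene_id = names(moduleLabels(mset)),
    module = unname(moduleLabels(mset))), "modules.tsv")
  mt <- moduleTraitTable(mset)
  if (!is.null(mt)) emit(mt, "module_trait.tsv")

  ## DE lncRNAs on modules
  bt <- SummarizedExperiment::rowData(sef)$biotype
  lnc <- rownames(sef)[bt %in% c("lincRNA", "antisense")]
  deLnc <- rownames(de)[de$status != "ns" & rownames(de) %in% lnc]
  overlay <- deModuleOverlay(deLnc, mset, alpha = config$alpha)

  ## orthology of DE lncRNAs (simulated queries stand in for them)
  ortho <- simulateOrthology(scfg)
  calls <- classifyOrthology(geneIds(ortho$queryAnn), ortho$alignments,
    ortho$targetAnn, minIdentity = config$minIdentity)
  emit(as.data.frame(calls), "orthology_calls.tsv")
  orthoClasses <- as.list(table(calls$class))

  ## enrichment + hubs
  mrna <- rownames(sef)[bt == "protein_coding"]
  universe <- names(moduleLabels(mset))
  ora <- moduleORA(mset, sim$goSets, universe, mrna, topN = 10)
  oraTab <- do.call(rbind, lapply(names(ora), function(m)
    cbind(module = m, ora[[m]])))
  if (!is.null(oraTab)) emit(oraTab, "enrichment.tsv")
  hubs <- hubGenes(mset, threshold = config$hubThreshold)

  report <- list(deCounts = deCounts, moduleTrait = mt,
    orthoClasses = orthoClasses,
    enrichmentTop = ora, overlay = overlay[c("inPositive", "inNegative",
      "elsewhere", "total", "pctRounded")],
    hubs = lapply(hubs, length),
    configHash = hash, seed = seed, files = files)
  jsonlite::write_json(report[c("deCounts", "orthoClasses", "overlay",
    "configHash", "seed")], file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  report
}
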