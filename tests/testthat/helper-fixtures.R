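## Shared fixture builders and independent oracle implementations.
## Oracles are deliberately naive (loops, closed forms, enumeration) and
## never call the package functions they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## small GeneAnnotation: one or two genes with known exons
mkAnn <- function() {
  ex <- GRangesList(
    g1 = GRanges("chr1", IRanges(c(101, 301), c(200, 350)), "+"),
    g2 = GRanges("chr2", IRanges(c(501, 801), c(600, 900)), "-"))
  GeneAnnotation(ex, c(g1 = "lincRNA", g2 = "protein_coding"))
}

writeGtfLines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtfExon <- function(chrom, start, end, strand, gene, biotype = "lincRNA",
    tx = paste0(gene, ".t1")) {
  paste(chrom, "src", "exon", start, end, ".", strand, ".",
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      gene, tx, biotype), sep = "\t")
}

samLine <- function(qname, flag, rname, pos, cigar, seq = "*",
    tags = character()) {
  paste(c(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq, "*", tags),
    collapse = "\t")
}

writeSamLines <- function(body, sq = "@SQ\tSN:hs1\tLN:100000") {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sq, body), path)
  path
}

## ---- oracles ----

## BH by its definition: padj_i = min over k with p_(k) >= p_i of m*p_(k)/k
naiveBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  stepup <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  adj[o] <- stepup
  adj
}

## TOM by triple loop
naiveTOM <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

## upper-tail hypergeometric by exact combinatorial sum
naiveHyper <- function(k, K, N, n) {
  tot <- 0
  for (i in k:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

## interval overlap bases by all-pairs scan over closed 1-based intervals
naiveOverlapBases <- function(qs, qe, ss, se) {
  tot <- 0L
  for (i in seq_along(qs)) for (j in seq_along(ss)) {
    lo <- max(qs[i], ss[j]); hi <- min(qe[i], se[j])
    if (hi >= lo) tot <- tot + (hi - lo + 1L)
  }
  tot
}

## independent BED12 re-parser (string -> absolute 0-based half-open blocks)
naiveParseBed12 <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  cs <- as.integer(f[2])
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  starts <- as.integer(strsplit(f[12], ",")[[1]])
  data.frame(chrom = f[1], start = cs + starts, end = cs + starts + sizes,
    strand = f[6], name = f[4])
}

## direct NB log-likelihood maximization (the GLM oracle)
optimNB <- function(y, X, sf, alpha) {
  nll <- function(b) {
    mu <- exp(drop(X %*% b) + log(sf))
    -sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  b0 <- rep(0, ncol(X))
  fit <- stats::optim(b0, nll, method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

## small simulated cohort used by several files (cheap: ~500 genes)
smallCohort <- function(seed = 42, ...) {
  cfg <- simulationConfig(seed = seed,
    nGenes = c(protein_coding = 300, lincRNA = 100, antisense = 60,
      sense_intronic = 20), ...)
  sim <- simulateCounts(cfg)
  sef <- filterExpressed(sim$se)
  cnt <- assay(sef, "counts")
  st <- as.data.frame(colData(sef))
  sf <- computeSizeFactors(cnt)
  list(cfg = cfg, sim = sim, se = sef, counts = cnt, st = st, sf = sf,
    norm = sweep(cnt, 2, sf, "/"))
}
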