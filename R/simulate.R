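## Seeded synthetic-cohort generator: NB counts under the multi-factor
## design with cell-type mixing that confounds condition, latent-factor
## co-expression modules, cell-type marker signatures, GO-BP-like gene
## sets, and dog-to-human spliced alignments with controlled CIGAR
## identities. Every planted fact is recorded in a ground-truth object.

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort. Defaults mirror the canine
#' oral-melanoma cohort the package was built around: 52 samples from 39
#' dogs of three breeds (13 matched normal/tumor pairs, 26 tumor-only, with
#' Labrador retrievers nearly lacking controls), NB counts
#' (`variance = mu + alpha * mu^2`, log-normal dispersions around 0.1),
#' planted log2 fold changes, condition-confounded cell-type mixing
#' (tumors melanocyte-heavy, normals keratinocyte/muscle-heavy), and three
#' latent co-expression modules, two of them condition-linked with opposite
#' signs.
#'
#' @slot nPairs matched normal/tumor individuals (default 13).
#' @slot nTumorOnly tumor-only individuals (default 26).
#' @slot breedDogs named integer, dogs per breed (default
#'   GRET 16, LABR 13, PODL 10).
#' @slot pairsByBreed named integer, matched pairs per breed (default
#'   GRET 6, LABR 1, PODL 6).
#' @slot nGenes named integer, genes per biotype.
#' @slot fracDE fraction of genes with a planted condition effect.
#' @slot lfcDist planted log2-fold-change distribution:
#'   `list(type = "uniform", min, max)` (magnitude, random sign) or
#'   `list(type = "point", value)` (signed).
#' @slot dispMeanlog,dispSdlog log-normal dispersion model (defaults
#'   `log(0.1)`, 0.5).
#' @slot baseMeanlog,baseSdlog log-normal base-mean model.
#' @slot sizeFactorRange range of true size factors (geometric mean
#'   normalized to 1).
#' @slot nModules,moduleSizeRange,moduleLoading,moduleTraitCor latent
#'   co-expression modules: count, size range, log2-scale factor loading,
#'   and per-module correlation of the latent factor with condition.
#' @slot markersPerType,mixNormal,mixTumor,mixConc,cellEffect cell-type
#'   signatures: markers per type, Dirichlet mixing weights by condition,
#'   Dirichlet concentration, and log2 expression shift per unit proportion.
#' @slot breedEffectFrac,breedEffectSd,sexEffectFrac,sexEffectSd nuisance
#'   covariate effects.
#' @slot lengthMeanlog,lengthSdlog exon-length model for the synthetic
#'   annotation.
#' @slot goNoiseTerms number of random background gene sets.
#' @slot nOrthoQueries,orthoConservedFrac,orthoAnnotatedFrac,
#'   orthoIdentityRange,orthoSubFrac,orthoSubIdentityRange,orthoDecoyFrac
#'   orthology scenario: query count, conserved fraction, fraction of
#'   conserved loci overlapping an annotated target gene, identity ranges
#'   above/below the screen, fraction of non-conserved queries aligned
#'   below threshold, and fraction of queries with a secondary decoy.
#' @slot seed mandatory RNG seed (R Mersenne-Twister, inversion normals).
#' @export
setClass("SimulationConfig", slots = c(
  nPairs = "integer", nTumorOnly = "integer",
  breedDogs = "integer", pairsByBreed = "integer",
  nGenes = "integer", fracDE = "numeric", lfcDist = "list",
  dispMeanlog = "numeric", dispSdlog = "numeric",
  baseMeanlog = "numeric", baseSdlog = "numeric",
  sizeFactorRange = "numeric",
  nModules = "integer", moduleSizeRange = "integer",
  moduleLoading = "numeric", moduleTraitCor = "numeric",
  markersPerType = "integer", mixNormal = "numeric", mixTumor = "numeric",
  mixConc = "numeric", cellEffect = "numeric",
  breedEffectFrac = "numeric", breedEffectSd = "numeric",
  sexEffectFrac = "numeric", sexEffectSd = "numeric",
  lengthMeanlog = "numeric", lengthSdlog = "numeric",
  goNoiseTerms = "integer",
  nOrthoQueries = "integer", orthoConservedFrac = "numeric",
  orthoAnnotatedFrac = "numeric", orthoIdentityRange = "numeric",
  orthoSubFrac = "numeric", orthoSubIdentityRange = "numeric",
  orthoDecoyFrac = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  fr <- c(object@fracDE, object@orthoConservedFrac,
    object@orthoAnnotatedFrac, object@orthoSubFrac, object@orthoDecoyFrac)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "a single integer seed is mandatory")
  if (sum(object@nGenes) < 1L) msgs <- c(msgs, "need at least one gene")
  if (object@nPairs + object@nTumorOnly < 1L)
    msgs <- c(msgs, "need at least one sample")
  if (sum(object@breedDogs) != object@nPairs + object@nTumorOnly)
    msgs <- c(msgs, "breedDogs must sum to nPairs + nTumorOnly")
  if (sum(object@pairsByBreed) != object@nPairs)
    msgs <- c(msgs, "pairsByBreed must sum to nPairs")
  if (any(object@pairsByBreed > object@breedDogs[names(object@pairsByBreed)]))
    msgs <- c(msgs, "pairsByBreed cannot exceed breedDogs")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed mandatory integer seed.
#' @param nPairs,nTumorOnly,breedDogs,pairsByBreed,nGenes,fracDE,lfcDist
#'   cohort structure and planted effects; see
#'   [SimulationConfig-class] for meanings and defaults.
#' @param dispMeanlog,dispSdlog,baseMeanlog,baseSdlog,sizeFactorRange
#'   NB count model.
#' @param nModules,moduleSizeRange,moduleLoading,moduleTraitCor latent
#'   modules.
#' @param markersPerType,mixNormal,mixTumor,mixConc,cellEffect cell types.
#' @param breedEffectFrac,breedEffectSd,sexEffectFrac,sexEffectSd nuisance
#'   effects.
#' @param lengthMeanlog,lengthSdlog,goNoiseTerms annotation and gene sets.
#' @param nOrthoQueries,orthoConservedFrac,orthoAnnotatedFrac,
#'   orthoIdentityRange,orthoSubFrac,orthoSubIdentityRange,orthoDecoyFrac
#'   orthology scenario.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed,
    nPairs = 13, nTumorOnly = 26,
    breedDogs = c(GRET = 16, LABR = 13, PODL = 10),
    pairsByBreed = c(GRET = 6, LABR = 1, PODL = 6),
    nGenes = c(protein_coding = 1500, lincRNA = 300, antisense = 150,
      sense_intronic = 50),
    fracDE = 0.10,
    lfcDist = list(type = "uniform", min = 1, max = 3),
    dispMeanlog = log(0.1), dispSdlog = 0.5,
    baseMeanlog = log(100), baseSdlog = 1,
    sizeFactorRange = c(0.5, 2),
    nModules = 3, moduleSizeRange = c(50, 150), moduleLoading = 0.7,
    moduleTraitCor = c(0.7, -0.7, 0),
    markersPerType = 30,
    mixNormal = c(keratinocyte = 0.5, melanocyte = 0.2,
      skeletal_muscle = 0.3),
    mixTumor = c(keratinocyte = 0.1, melanocyte = 0.8,
      skeletal_muscle = 0.1),
    mixConc = 10, cellEffect = 2,
    breedEffectFrac = 0.05, breedEffectSd = 0.5,
    sexEffectFrac = 0.05, sexEffectSd = 0.5,
    lengthMeanlog = log(400), lengthSdlog = 0.4,
    goNoiseTerms = 20,
    nOrthoQueries = 150, orthoConservedFrac = 1 / 3,
    orthoAnnotatedFrac = 0.2, orthoIdentityRange = c(0.72, 0.98),
    orthoSubFrac = 0.3, orthoSubIdentityRange = c(0.45, 0.65),
    orthoDecoyFrac = 0.1) {
  new("SimulationConfig",
    nPairs = as.integer(nPairs), nTumorOnly = as.integer(nTumorOnly),
    breedDogs = stats::setNames(as.integer(breedDogs), names(breedDogs)),
    pairsByBreed = stats::setNames(as.integer(pairsByBreed),
      names(pairsByBreed)),
    nGenes = stats::setNames(as.integer(nGenes), names(nGenes)),
    fracDE = fracDE, lfcDist = lfcDist,
    dispMeanlog = dispMeanlog, dispSdlog = dispSdlog,
    baseMeanlog = baseMeanlog, baseSdlog = baseSdlog,
    sizeFactorRange = sizeFactorRange,
    nModules = as.integer(nModules),
    moduleSizeRange = as.integer(moduleSizeRange),
    moduleLoading = moduleLoading,
    moduleTraitCor = rep_len(moduleTraitCor, nModules),
    markersPerType = as.integer(markersPerType),
    mixNormal = mixNormal, mixTumor = mixTumor, mixConc = mixConc,
    cellEffect = cellEffect,
    breedEffectFrac = breedEffectFrac, breedEffectSd = breedEffectSd,
    sexEffectFrac = sexEffectFrac, sexEffectSd = sexEffectSd,
    lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
    goNoiseTerms = as.integer(goNoiseTerms),
    nOrthoQueries = as.integer(nOrthoQueries),
    orthoConservedFrac = orthoConservedFrac,
    orthoAnnotatedFrac = orthoAnnotatedFrac,
    orthoIdentityRange = orthoIdentityRange,
    orthoSubFrac = orthoSubFrac,
    orthoSubIdentityRange = orthoSubIdentityRange,
    orthoDecoyFrac = orthoDecoyFrac,
    seed = as.integer(seed))
}

.setSeed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection")
}

## safe subset sampling: never the sample(length-1) trap, never over-draws
.samp <- function(pool, k) {
  k <- min(k, length(pool))
  if (k <= 0L) return(pool[0])
  pool[sample.int(length(pool), k)]
}

.rdirichlet1 <- function(w, conc) {
  g <- ifelse(w > 0, stats::rgamma(length(w), shape = w * conc), 0)
  if (sum(g) == 0) return(w)
  g / sum(g)
}

## One deterministic pass building the whole cohort; simulateCounts() and
## simulateSignatures() are views of this object, so the emitted files and
## the ground truth cannot drift apart.
.simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  methods::validObject(cfg)
  .setSeed(cfg@seed)
  breeds <- names(cfg@breedDogs)

  ## ---- samples ----
  dogs <- data.frame(breed = rep(breeds, cfg@breedDogs))
  dogs$individual <- sprintf("dog%03d", seq_len(nrow(dogs)))
  dogs$sex <- unlist(lapply(cfg@breedDogs,
    function(k) rep_len(c("female", "male"), k)), use.names = FALSE)
  paired <- unlist(lapply(breeds, function(b) {
    i <- which(dogs$breed == b)
    i[seq_len(cfg@pairsByBreed[b])]
  }))
  dogs$paired <- seq_len(nrow(dogs)) %in% paired
  st <- rbind(
    data.frame(individual = dogs$individual, breed = dogs$breed,
      sex = dogs$sex, condition = "tumor"),
    data.frame(individual = dogs$individual[dogs$paired],
      breed = dogs$breed[dogs$paired], sex = dogs$sex[dogs$paired],
      condition = "normal"))
  st$sample <- paste0(st$individual, "_", substr(st$condition, 1, 1))
  st <- st[order(st$individual, st$condition), ]
  rownames(st) <- st$sample
  n <- nrow(st)
  tumor <- as.integer(st$condition == "tumor")

  ## ---- cell-type proportions (condition-confounded) ----
  types <- names(cfg@mixNormal)
  props <- t(vapply(seq_len(n), function(j) {
    w <- if (tumor[j] == 1L) cfg@mixTumor else cfg@mixNormal
    .rdirichlet1(w, cfg@mixConc)
  }, numeric(length(types))))
  dimnames(props) <- list(st$sample, types)

  ## ---- genes ----
  G <- sum(cfg@nGenes)
  gid <- sprintf("SIMG%05d", seq_len(G))
  biotype <- rep(names(cfg@nGenes), cfg@nGenes)
  base <- stats::rlnorm(G, cfg@baseMeanlog, cfg@baseSdlog)
  disp <- stats::rlnorm(G, cfg@dispMeanlog, cfg@dispSdlog)

  ## markers, modules and planted-DE genes are mutually disjoint so every
  ## planted fact has a single cause
  pcIdx <- which(biotype == "protein_coding")
  markers <- list()
  used <- integer()
  for (t in types) {
    pool <- setdiff(pcIdx, used)
    pick <- sort(.samp(pool, cfg@markersPerType))
    markers[[t]] <- gid[pick]
    used <- c(used, pick)
  }
  modSizes <- if (cfg@nModules > 0)
    sample(seq(cfg@moduleSizeRange[1L], cfg@moduleSizeRange[2L]),
      cfg@nModules, replace = TRUE) else integer()
  moduleOf <- rep(NA_character_, G)
  for (m in seq_len(cfg@nModules)) {
    pool <- setdiff(seq_len(G), used)
    pick <- sort(.samp(pool, modSizes[m]))
    moduleOf[pick] <- paste0("L", m)
    used <- c(used, pick)
  }
  dePick <- sort(.samp(setdiff(seq_len(G), used),
    round(cfg@fracDE * G)))
  nDE <- length(dePick)
  trueLfc <- rep(0, G)
  if (nDE > 0) {
    trueLfc[dePick] <- switch(cfg@lfcDist$type,
      point = cfg@lfcDist$value,
      uniform = stats::runif(nDE, cfg@lfcDist$min, cfg@lfcDist$max) *
        sample(c(-1, 1), nDE, replace = TRUE),
      stop("unknown lfcDist type '", cfg@lfcDist$type, "'"))
  }
  isDE <- trueLfc != 0

  ## nuisance effects
  breedBeta <- matrix(0, G, length(breeds), dimnames = list(gid, breeds))
  hit <- stats::runif(G) < cfg@breedEffectFrac
  for (b in breeds[-1L])
    breedBeta[hit, b] <- stats::rnorm(sum(hit), 0, cfg@breedEffectSd)
  sexBeta <- rep(0, G)
  hs <- stats::runif(G) < cfg@sexEffectFrac
  sexBeta[hs] <- stats::rnorm(sum(hs), 0, cfg@sexEffectSd)

  ## ---- latent module factors ----
  sCond <- if (stats::sd(tumor) > 0) (tumor - mean(tumor)) / stats::sd(tumor)
    else rep(0, n)
  factors <- matrix(0, n, max(cfg@nModules, 1L))
  inducedLfc <- rep(0, cfg@nModules)
  for (m in seq_len(cfg@nModules)) {
    rho <- cfg@moduleTraitCor[m]
    factors[, m] <- rho * sCond + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    inducedLfc[m] <- if (stats::sd(tumor) > 0)
      cfg@moduleLoading * rho / stats::sd(tumor) else 0
  }

  ## a gene in a condition-linked module has a real condition effect; record
  ## it as truth so discoveries there are not miscounted as false positives
  for (m in seq_len(cfg@nModules)) {
    g <- which(moduleOf == paste0("L", m))
    if (abs(inducedLfc[m]) > 0) {
      trueLfc[g] <- trueLfc[g] + inducedLfc[m]
      isDE[g] <- TRUE
    }
  }

  ## ---- size factors (geometric mean 1) ----
  sf <- stats::runif(n, cfg@sizeFactorRange[1L], cfg@sizeFactorRange[2L])
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- st$sample

  ## ---- counts ----
  sexNum <- as.integer(st$sex == "male")
  log2mu <- matrix(rep(log2(base), n), G, n)
  ## module-induced condition effects enter through the latent factors, so
  ## only the direct (planted) part is added here
  direct <- trueLfc
  for (m in seq_len(cfg@nModules)) {
    g <- which(moduleOf == paste0("L", m))
    direct[g] <- direct[g] - inducedLfc[m]
  }
  log2mu <- log2mu + outer(direct, tumor)
  for (b in breeds)
    log2mu <- log2mu + outer(breedBeta[, b], as.integer(st$breed == b))
  log2mu <- log2mu + outer(sexBeta, sexNum)
  for (t in types) {
    g <- match(markers[[t]], gid)
    log2mu[g, ] <- log2mu[g, ] +
      cfg@cellEffect * matrix(rep(props[, t], length(g)), length(g),
        n, byrow = TRUE)
  }
  for (m in seq_len(cfg@nModules)) {
    g <- which(moduleOf == paste0("L", m))
    log2mu[g, ] <- log2mu[g, ] + cfg@moduleLoading *
      matrix(rep(factors[, m], length(g)), length(g), n, byrow = TRUE)
  }
  mu <- sweep(2^log2mu, 2L, sf, "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / disp), G, n,
    dimnames = list(gid, st$sample))

  ## ---- annotation with consistent effective lengths ----
  nexon <- sample(1:3, G, replace = TRUE)
  exlen <- lapply(seq_len(G), function(g)
    pmax(50L, round(stats::rlnorm(nexon[g], cfg@lengthMeanlog,
      cfg@lengthSdlog))))
  chrom <- paste0("chr", 1 + (seq_len(G) - 1L) %% 38L)
  strand <- sample(c("+", "-"), G, replace = TRUE)
  offset <- stats::setNames(rep(1L, 38L), paste0("chr", 1:38))
  exons <- vector("list", G)
  for (g in seq_len(G)) {
    pos <- offset[chrom[g]]
    starts <- integer(nexon[g]); ends <- integer(nexon[g])
    for (e in seq_len(nexon[g])) {
      starts[e] <- pos
      ends[e] <- pos + exlen[[g]][e] - 1L
      pos <- ends[e] + sample(200:2000, 1L)
    }
    offset[chrom[g]] <- pos + 1000L
    exons[[g]] <- GRanges(chrom[g], IRanges(starts, ends),
      strand = strand[g])
  }
  ann <- GeneAnnotation(stats::setNames(GRangesList(exons), gid),
    stats::setNames(biotype, gid))
  efflen <- vapply(exlen, sum, numeric(1))

  ## ---- GO-BP-like gene sets ----
  goSets <- list()
  for (m in seq_len(cfg@nModules)) {
    core <- gid[which(moduleOf == paste0("L", m) &
      biotype == "protein_coding")]
    if (length(core) >= 2L) {
      extra <- .samp(setdiff(gid[pcIdx], core),
        max(1L, round(length(core) / 2)))
      goSets[[paste0("BP_module_L", m)]] <- sort(c(core, extra))
    }
  }
  for (i in seq_len(cfg@goNoiseTerms))
    goSets[[sprintf("BP_random_%02d", i)]] <-
      sort(.samp(gid[pcIdx], 30L))

  rowdat <- DataFrame(biotype = biotype, length = efflen,
    isDE = isDE, trueLfc = trueLfc, module = moduleOf, row.names = gid)
  propDf <- as.data.frame(props)
  names(propDf) <- paste0("prop_", names(propDf))   # avoid clashing with
  coldat <- DataFrame(st, trueSizeFactor = sf, propDf,  # score covariates
    row.names = st$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rowdat, colData = coldat)
  truth <- list(isDE = stats::setNames(isDE, gid),
    trueLfc = stats::setNames(trueLfc, gid),
    module = stats::setNames(moduleOf, gid),
    moduleFactors = factors, inducedLfc = inducedLfc,
    sizeFactors = sf, cellProps = props, markers = markers,
    dispersion = stats::setNames(disp, gid), seed = cfg@seed)
  list(se = se, truth = truth, annotation = ann, signatures = markers,
    goSets = goSets, sampleTable = st)
}

#' Simulate the cohort count matrix
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list with `se` (a SummarizedExperiment: `counts` assay,
#'   biotype/length/planted-truth rowData, sample covariates and true
#'   cell proportions in colData), `truth` (ground-truth list), and
#'   `annotation` (the matching synthetic [GeneAnnotation-class]).
#'   Deterministic given `cfg@seed`.
#' @export
simulateCounts <- function(cfg) {
  sim <- .simulateCohort(cfg)
  sim[c("se", "truth", "annotation")]
}

#' Simulate cell-type signatures and gene sets
#'
#' Marker gene sets for the three cell types planted in the count model
#' (each marker's log2 expression rises by `cellEffect` per unit of its
#' type's true mixing proportion), plus GO-BP-like sets marking the latent
#' modules and random background sets. Consistent with [simulateCounts()]
#' at the same seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list: `signatures` (cell type -> marker ids), `trueProps`
#'   (samples x cell types), `goSets` (named list of gene sets).
#' @export
simulateSignatures <- function(cfg) {
  if (any(cfg@markersPerType < 1L)) stop("empty marker set requested")
  sim <- .simulateCohort(cfg)
  list(signatures = sim$signatures, trueProps = sim$truth$cellProps,
    goSets = sim$goSets)
}

## Compose an extended CIGAR achieving a requested identity for a query of
## length qlen, with nIntrons N gaps; identity 1 yields pure =/N.
.cigarForIdentity <- function(qlen, identity, nIntrons = 0L,
    intronLen = 1000L) {
  stopifnot(identity > 0, identity <= 1)
  if (identity == 1) {
    i <- 0L; d <- 0L
  } else {
    room <- floor((1 - identity) * qlen / 3)
    i <- min(sample(0:2, 1L) * max(1L, qlen %/% 200L), room)
    d <- min(sample(0:2, 1L) * max(1L, qlen %/% 200L), room)
  }
  C <- qlen + d
  m <- min(round(identity * C), qlen - i)
  x <- qlen - i - m
  segs <- max(nIntrons + 1L, 1L)
  mseg <- diff(round(seq(0, m, length.out = segs + 1L)))
  ops <- character()
  mids <- list(if (x > 0) paste0(x, "X"), if (i > 0) paste0(i, "I"),
    if (d > 0) paste0(d, "D"))
  for (s in seq_len(segs)) {
    half <- c(floor(mseg[s] / 2), ceiling(mseg[s] / 2))
    mid <- mids[[((s - 1L) %% 3L) + 1L]]
    if (!is.null(mid) && all(half > 0)) {
      ops <- c(ops, paste0(half[1L], "="), mid, paste0(half[2L], "="))
      mids[((s - 1L) %% 3L) + 1L] <- list(NULL)
    } else if (mseg[s] > 0) {
      ops <- c(ops, paste0(mseg[s], "="))
    }
    if (s < segs) ops <- c(ops, paste0(intronLen, "N"))
  }
  leftover <- unlist(mids[!vapply(mids, is.null, TRUE)])
  if (length(leftover)) {
    nops <- length(ops)
    ops <- c(ops[-nops], leftover, ops[nops])
  }
  paste(ops, collapse = "")
}

#' Simulate a cross-species orthology scenario
#'
#' Generates a query annotation (the lncRNA side), a target annotation, and
#' a spliced-alignment table: conserved queries carry a primary alignment
#' whose CIGAR reproduces a chosen identity (a mix of `=`, `X`, `I`, `D`
#' and `N` operations), a fraction of those land on annotated target genes,
#' non-conserved queries are either unaligned or aligned below the identity
#' screen, and a fraction of aligned queries get a secondary decoy record.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list: `queryAnn`, `targetAnn` ([GeneAnnotation-class]),
#'   `alignments` (table as from [readAlignments()]), `truth` (data.frame
#'   per query: class, identity, targetGene).
#' @export
simulateOrthology <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (any(cfg@orthoIdentityRange <= 0 | cfg@orthoIdentityRange > 1))
    stop("requested identities must lie in (0, 1]")
  .setSeed(cfg@seed + 1L)
  nq <- cfg@nOrthoQueries
  qid <- sprintf("QLNC%04d", seq_len(nq))
  qbt <- sample(c("lincRNA", "antisense"), nq, replace = TRUE)

  ## query gene models
  qex <- vector("list", nq)
  qpos <- stats::setNames(rep(1L, 5L), paste0("cq", 1:5))
  nexon <- sample(1:3, nq, replace = TRUE)
  for (q in seq_len(nq)) {
    ch <- paste0("cq", 1 + (q - 1L) %% 5L)
    strand <- sample(c("+", "-"), 1L)
    pos <- qpos[ch]
    starts <- integer(); ends <- integer()
    for (e in seq_len(nexon[q])) {
      len <- sample(150:600, 1L)
      starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
      pos <- pos + len + sample(200:2000, 1L)
    }
    qpos[ch] <- pos + 1000L
    qex[[q]] <- GRanges(ch, IRanges(starts, ends), strand = strand)
  }
  queryAnn <- GeneAnnotation(stats::setNames(GRangesList(qex), qid),
    stats::setNames(qbt, qid))
  qlen <- vapply(qex, function(g) sum(width(g)), numeric(1))

  nCons <- round(cfg@orthoConservedFrac * nq)
  consIdx <- sort(sample(nq, nCons))
  nAnnot <- round(cfg@orthoAnnotatedFrac * nCons)
  annotIdx <- if (nCons) consIdx[seq_len(nAnnot)] else integer()
  rest <- setdiff(seq_len(nq), consIdx)
  nSub <- round(cfg@orthoSubFrac * length(rest))
  subIdx <- if (length(rest)) sort(sample(rest, nSub)) else integer()

  tpos <- stats::setNames(rep(1e6, 5L), paste0("hs", 1:5))
  alns <- list(); tgenes <- list(); tbt <- character()
  truth <- data.frame(query = qid, class = "unaligned",
    identity = NA_real_, targetGene = NA_character_)
  mkAln <- function(q, identity, primary = TRUE) {
    ch <- paste0("hs", 1 + (q - 1L) %% 5L)
    strand <- sample(c("+", "-"), 1L)
    cg <- .cigarForIdentity(qlen[q], identity,
      nIntrons = sample(0:2, 1L))
    pos <- as.integer(tpos[ch])
    ops <- parseCigar(cg)
    tpos[ch] <<- pos + .cigarRefLength(ops) + sample(5000:20000, 1L)
    list(rec = data.frame(qname = qid[q], target = ch, pos = pos,
      strand = strand, cigar = cg, primary = primary, nm = NA_integer_,
      qlen = .cigarQueryLength(ops)), blocks = alignmentBlocks(ch, pos,
      cg, strand))
  }
  for (q in consIdx) {
    idy <- stats::runif(1, cfg@orthoIdentityRange[1L],
      cfg@orthoIdentityRange[2L])
    a <- mkAln(q, idy)
    alns[[length(alns) + 1L]] <- a$rec
    truth$identity[q] <- cigarIdentity(a$rec$cigar, NA)
    if (q %in% annotIdx) {
      tg <- paste0("HGENE", sprintf("%04d", q))
      tgenes[[tg]] <- a$blocks          # target exons = alignment blocks
      tbt[tg] <- "lincRNA"
      truth$class[q] <- "annotated_ortholog"
      truth$targetGene[q] <- tg
    } else {
      truth$class[q] <- "novel_aligned"
    }
  }
  for (q in subIdx) {
    idy <- stats::runif(1, cfg@orthoSubIdentityRange[1L],
      cfg@orthoSubIdentityRange[2L])
    a <- mkAln(q, idy)
    alns[[length(alns) + 1L]] <- a$rec
    truth$identity[q] <- cigarIdentity(a$rec$cigar, NA)
    truth$class[q] <- "below_identity"
  }
  aligned <- c(consIdx, subIdx)
  nDecoy <- round(cfg@orthoDecoyFrac * length(aligned))
  for (q in utils::head(aligned, nDecoy)) {
    a <- mkAln(q, stats::runif(1, 0.3, 0.6), primary = FALSE)
    alns[[length(alns) + 1L]] <- a$rec
  }
  ## background target genes away from any alignment
  for (i in 1:10) {
    ch <- paste0("hs", 1 + (i - 1L) %% 5L)
    pos <- as.integer(tpos[ch]) + 50000L * i
    tg <- sprintf("HBG%03d", i)
    tgenes[[tg]] <- GRanges(ch, IRanges(pos, pos + 500L),
      strand = sample(c("+", "-"), 1L))
    tbt[tg] <- "protein_coding"
  }
  targetAnn <- GeneAnnotation(GRangesList(tgenes), tbt)
  alignments <- S4Vectors::DataFrame(do.call(rbind, c(alns,
    list(.samEmpty()))))
  list(queryAnn = queryAnn, targetAnn = targetAnn,
    alignments = alignments, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Materializes counts (TSV), sample metadata (TSV), the synthetic
#' annotation (GTF), signature and GO-BP-like gene sets (GMT), orthology
#' inputs (query/target GTF and SAM), and the ground truth (JSON).
#'
#' @param cfg a [SimulationConfig-class].
#' @param outdir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- .simulateCohort(cfg)
  ortho <- simulateOrthology(cfg)
  p <- function(f) file.path(outdir, f)
  cnt <- SummarizedExperiment::assay(sim$se, "counts")
  utils::write.table(data.frame(gene_id = rownames(cnt), cnt,
    check.names = FALSE), p("counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sim$se)),
    p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeGTF(sim$annotation, p("annotation.gtf"))
  writeGMT(sim$signatures, p("celltype_signatures.gmt"))
  writeGMT(sim$goSets, p("go_bp.gmt"))
  writeGTF(ortho$queryAnn, p("ortho_query.gtf"))
  writeGTF(ortho$targetAnn, p("ortho_target.gtf"))
  writeSAM(ortho$alignments, p("ortho_alignments.sam"))
  truth <- sim$truth
  truth$cellProps <- as.data.frame(truth$cellProps)
  truth$moduleFactors <- NULL
  jsonlite::write_json(c(truth, list(orthology = ortho$truth)),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(stats::setNames(
    p(c("counts.tsv", "samples.tsv", "annotation.gtf",
      "celltype_signatures.gmt", "go_bp.gmt", "ortho_query.gtf",
      "ortho_target.gtf", "ortho_alignments.sam", "ground_truth.json")),
    c("counts", "samples", "annotation", "signatures", "go", "orthoQuery",
      "orthoTarget", "orthoAln", "truth")))
}
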