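## Negative-binomial GLM differential expression with a multi-factor design
## (~ sex + cell_types + breed + condition), Wald tests on the MLE, a
## normal-prior MAP shrinkage of log2 fold changes, BH correction and
## strict-threshold DE calling; breed-specific calls via a breed:condition
## interaction.

#' Build the multi-factor design matrix
#'
#' Dummy-codes `~ sex + cell_types + breed + condition`
#' (optionally `+ breed:condition`), with the condition term last.
#' Reference levels: `normal` condition, alphabetically first sex and breed.
#' Cell-type scores enter unstandardized in `[0, 1]`.
#'
#' @param sampleTable data.frame with factors `condition`
#'   (`normal`/`tumor`), `breed`, `sex`, and one numeric column per cell
#'   type named in `cellTypes` (set `cellTypes = NULL` to omit them).
#' @param cellTypes names of the cell-type score columns.
#' @param interaction add `breed:condition` terms (default FALSE).
#' @return A list: `X` (model matrix), `condIdx` (column index of the
#'   tumor-vs-normal coefficient), `interaction` flag.
#' @export
buildDesign <- function(sampleTable,
    cellTypes = c("keratinocyte", "melanocyte", "skeletal_muscle"),
    interaction = FALSE) {
  st <- as.data.frame(sampleTable)
  for (v in c("condition", "breed", "sex"))
    if (!v %in% names(st)) stop("sampleTable lacks column '", v, "'")
  st$condition <- stats::relevel(factor(st$condition), ref = "normal")
  if (nlevels(st$condition) < 2L)
    stop("'condition' needs both normal and tumor samples")
  st$breed <- factor(st$breed)
  st$sex <- factor(st$sex)
  ## single-level nuisance factors carry no information; drop them
  keepFac <- c("sex", "breed")[c(nlevels(st$sex) > 1L,
    nlevels(st$breed) > 1L)]
  miss <- setdiff(cellTypes, names(st))
  if (length(miss))
    stop("cell-type score column(s) missing from sampleTable: ",
      paste(miss, collapse = ", "))
  rhs <- c(intersect("sex", keepFac), cellTypes,
    intersect("breed", keepFac), "condition",
    if (interaction && "breed" %in% keepFac) "breed:condition")
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(fml, data = st)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is not full rank; covariates are confounded ",
      "(e.g. breed identical to condition)")
  list(X = X, condIdx = match("conditiontumor", colnames(X)),
    interaction = interaction, sampleTable = st)
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per-gene NB dispersion (`variance = mu + alpha * mu^2`) estimated by
#' moments on size-factor-normalized counts residualized on the design:
#' `alpha = max(alphaMin, (s2 - mbar) / mbar^2)` with `s2` the
#' design-residual variance (denominator `n - p`) and `mbar` the mean
#' normalized count. With `trend = TRUE` (default) the raw estimates are
#' shrunk halfway (in log space) toward a log-log linear trend of dispersion
#' on mean fitted across genes, stabilizing gene-wise noise at moderate
#' sample sizes.
#'
#' @param counts gene x sample count matrix (filtered; all-zero rows are an
#'   error).
#' @param sizeFactors per-sample size factors.
#' @param design design list from [buildDesign()] or a model matrix.
#' @param alphaMin lower bound, default 1e-8.
#' @param trend apply trend shrinkage (default TRUE).
#' @return Named numeric vector of dispersions, one per gene.
#' @export
estimateDispersion <- function(counts, sizeFactors, design,
    alphaMin = 1e-8, trend = TRUE) {
  m <- .assayCounts(counts)
  if (any(rowSums(m) == 0))
    stop("all-zero count row(s); apply filterExpressed() first")
  X <- if (is.list(design)) design$X else design
  k <- sweep(m, 2L, sizeFactors, "/")
  n <- ncol(k); p <- ncol(X)
  if (n <= p) stop("need more samples than design coefficients")
  H <- X %*% solve(crossprod(X), t(X))
  fit <- k %*% t(H)
  s2 <- rowSums((k - fit)^2) / (n - p)
  mbar <- rowMeans(k)
  raw <- pmax(alphaMin, (s2 - mbar) / mbar^2)
  if (trend && nrow(m) >= 20L) {
    use <- raw > alphaMin * 10
    if (sum(use) >= 10L) {
      tr <- stats::lm(log(raw[use]) ~ log(mbar[use]))
      pred <- cbind(1, log(mbar)) %*% stats::coef(tr)
      raw <- pmax(alphaMin, exp(0.5 * log(raw) + 0.5 * pred[, 1L]))
    }
  }
  stats::setNames(as.numeric(raw), rownames(m))
}

#' Fit one negative-binomial GLM by IRLS
#'
#' Maximizes the NB log-likelihood with log link and `log(sizeFactors)`
#' offset for a single gene at fixed dispersion, by iteratively reweighted
#' least squares (Fisher scoring, weights `mu / (1 + alpha * mu)`).
#' Convergence when the largest coefficient change drops below `tol`
#' (default 1e-6) within `maxIter` (default 100) iterations.
#'
#' @param y integer count vector (one gene).
#' @param X model matrix.
#' @param sizeFactors per-sample size factors.
#' @param alpha NB dispersion.
#' @param tol,maxIter convergence controls.
#' @return A list: `coef` (natural-log scale), `cov` (inverse Fisher
#'   information), `converged`, `mu` (fitted means), `iter`.
#' @export
fitNBGLM <- function(y, X, sizeFactors, alpha, tol = 1e-6, maxIter = 100L) {
  off <- log(sizeFactors)
  beta <- tryCatch(
    qr.coef(qr(X), log(pmax(y, 0.5) / sizeFactors)),
    error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta) + off
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtWX <- crossprod(X, w * X)
    newbeta <- tryCatch(solve(XtWX, crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(newbeta) || any(!is.finite(newbeta))) break
    newbeta <- pmin(pmax(drop(newbeta), -30), 30)
    delta <- max(abs(newbeta - beta))
    beta <- newbeta
    if (delta < tol) { converged <- TRUE; break }
  }
  ## small-sample correction: Fisher-information covariance is known to be
  ## anticonservative at moderate n; scale by n / (n - p)
  dfc <- length(y) / max(1, length(y) - ncol(X))
  cov <- tryCatch(solve(XtWX) * dfc, error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(coef = beta, cov = cov, converged = converged,
    mu = pmax(exp(drop(X %*% beta) + off), 1e-10), iter = it)
}

#' Two-sided Wald p-value
#'
#' `p = 2 * Phi(-|coef / se|)`.
#'
#' @param coef coefficient estimate(s).
#' @param se standard error(s), positive.
#' @return p-value(s) in `[0, 1]`.
#' @export
waldTest <- function(coef, se) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  2 * stats::pnorm(-abs(coef / se))
}

#' Normal-prior MAP shrinkage of log2 fold changes
#'
#' Posterior-mode estimate under a zero-centered normal prior:
#' `lfcShrunk = lfcMLE * tau2 / (tau2 + se^2)`. The prior variance is
#' adaptive, `tau2 = max(0, mean(lfcMLE^2) - mean(se^2))` (second moment of
#' the MLEs minus average squared standard error), so well-measured genes
#' (`se -> 0`) keep their MLE while noisy genes are pulled toward zero. An
#' approximation in the spirit of heavy-tailed-prior shrinkage, not a clone
#' of it.
#'
#' @param lfcMLE vector of MLE log2 fold changes.
#' @param se vector of their standard errors (log2 scale).
#' @param tau2 prior variance; estimated from the data when NULL.
#' @return Shrunken log2 fold changes, with the prior variance attached as
#'   attribute `"tau2"`.
#' @export
shrinkLFC <- function(lfcMLE, se, tau2 = NULL) {
  ok <- is.finite(lfcMLE) & is.finite(se)
  if (is.null(tau2))
    tau2 <- max(0, mean(lfcMLE[ok]^2) - mean(se[ok]^2))
  fac <- ifelse(se == 0, 1, tau2 / (tau2 + se^2))
  out <- lfcMLE * fac
  attr(out, "tau2") <- tau2
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p vector of p-values in `[0, 1]` (NAs tolerated).
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Call differential-expression status
#'
#' Strict thresholds as printed in the field's convention adopted here:
#' `up` iff `lfcShrunk > lfcThreshold` and `padj < alpha`; `down`
#' symmetric; everything else (including `lfcShrunk == lfcThreshold`
#' exactly, and NA statistics) is `ns`.
#'
#' @param lfcShrunk shrunken log2 fold changes.
#' @param padj BH-adjusted p-values.
#' @param lfcThreshold effect-size threshold, default 1.5 (log2).
#' @param alpha adjusted-p threshold, default 0.05.
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
callDE <- function(lfcShrunk, padj, lfcThreshold = 1.5, alpha = 0.05) {
  stopifnot(lfcThreshold > 0, alpha > 0)
  status <- rep("ns", length(lfcShrunk))
  sig <- !is.na(padj) & padj < alpha
  status[sig & lfcShrunk > lfcThreshold] <- "up"
  status[sig & lfcShrunk < -lfcThreshold] <- "down"
  status
}

#' Run the differential-expression analysis
#'
#' Size factors (computed when not given), per-gene dispersion, NB GLM fits,
#' Wald test on the condition coefficient, adaptive normal-prior shrinkage,
#' BH adjustment and strict-threshold calling, in one pass.
#'
#' @param counts filtered gene x sample count matrix (or
#'   SummarizedExperiment with a `counts` assay).
#' @param sampleTable per-sample covariates (see [buildDesign()]).
#' @param cellTypes cell-type score columns to adjust for; NULL to omit.
#' @param sizeFactors optional pre-computed size factors.
#' @param lfcThreshold,alpha calling thresholds (defaults 1.5 and 0.05).
#' @param shrink apply [shrinkLFC()] before calling (default TRUE; when
#'   FALSE the MLE is used for thresholding).
#' @param dispTrend trend-shrink dispersions (default TRUE).
#' @return A [DEResults-class] with per-gene `baseMean`, `lfcMLE`,
#'   `lfcShrunk`, `lfcSE`, `pvalue`, `padj`, `status`, `converged`.
#' @export
runDE <- function(counts, sampleTable,
    cellTypes = c("keratinocyte", "melanocyte", "skeletal_muscle"),
    sizeFactors = NULL, lfcThreshold = 1.5, alpha = 0.05,
    shrink = TRUE, dispTrend = TRUE) {
  m <- .assayCounts(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
  des <- buildDesign(sampleTable, cellTypes = cellTypes)
  disp <- estimateDispersion(m, sizeFactors, des, trend = dispTrend)
  ln2 <- log(2)
  res <- t(vapply(seq_len(nrow(m)), function(g) {
    fit <- fitNBGLM(m[g, ], des$X, sizeFactors, disp[g])
    b <- fit$coef[des$condIdx]
    se <- sqrt(fit$cov[des$condIdx, des$condIdx])
    c(lfc = b / ln2, se = se / ln2, conv = as.numeric(fit$converged))
  }, numeric(3)))
  lfc <- res[, 1L]; se <- res[, 2L]
  conv <- res[, 3L] == 1 & is.finite(se) & se > 0
  pv <- rep(NA_real_, nrow(m))
  pv[conv] <- waldTest(lfc[conv], se[conv])
  shr <- if (shrink) as.numeric(shrinkLFC(lfc[conv], se[conv])) else
    lfc[conv]
  lfcShrunk <- rep(NA_real_, nrow(m)); lfcShrunk[conv] <- shr
  padj <- rep(NA_real_, nrow(m)); padj[conv] <- bhAdjust(pv[conv])
  out <- DataFrame(
    baseMean = rowMeans(sweep(m, 2L, sizeFactors, "/")),
    lfcMLE = lfc, lfcShrunk = lfcShrunk, lfcSE = se,
    pvalue = pv, padj = padj,
    status = callDE(lfcShrunk, padj, lfcThreshold, alpha),
    converged = conv, row.names = rownames(m))
  metadata(out) <- list(sizeFactors = sizeFactors, dispersions = disp,
    lfcThreshold = lfcThreshold, alpha = alpha,
    tau2 = if (shrink) attr(shrinkLFC(lfc[conv], se[conv]), "tau2") else NA)
  new("DEResults", out)
}

#' Breed-specific differential expression via interaction contrasts
#'
#' Fits the interaction design `~ sex + cell_types + breed + condition +
#' breed:condition` and extracts the per-breed tumor-vs-normal contrast for
#' the target and the comparison breed. A gene is breed-specific iff it is
#' significant and large in the target breed (`padj < alpha` and
#' `|lfcShrunk| > lfcThreshold`) while not significant in the other breed
#' (`padj >= alpha`).
#'
#' @param counts filtered count matrix.
#' @param sampleTable per-sample covariates.
#' @param targetBreed,otherBreed breed labels to contrast.
#' @param cellTypes cell-type covariates (see [buildDesign()]).
#' @param design optional pre-built design list; must contain
#'   `breed:condition` interaction columns.
#' @param sizeFactors,lfcThreshold,alpha as in [runDE()].
#' @return A [S4Vectors::DataFrame] with per-breed lfc/padj columns and a
#'   logical `breedSpecific`; a breed lacking tumor or normal samples yields
#'   a warning and an empty result.
#' @export
breedSpecificDE <- function(counts, sampleTable, targetBreed, otherBreed,
    cellTypes = c("keratinocyte", "melanocyte", "skeletal_muscle"),
    design = NULL, sizeFactors = NULL, lfcThreshold = 1.5, alpha = 0.05) {
  m <- .assayCounts(counts)
  st <- as.data.frame(sampleTable)
  emptyOut <- function() DataFrame(lfcTarget = numeric(),
    lfcShrunkTarget = numeric(), seTarget = numeric(),
    padjTarget = numeric(), lfcOther = numeric(), seOther = numeric(),
    padjOther = numeric(), breedSpecific = logical())
  tab <- table(factor(st$breed), factor(st$condition,
    levels = c("normal", "tumor")))
  for (b in c(targetBreed, otherBreed)) {
    if (!b %in% rownames(tab)) stop("unknown breed '", b, "'")
    if (any(tab[b, ] == 0)) {
      warning("breed '", b, "' lacks ",
        ifelse(tab[b, "normal"] == 0, "normal", "tumor"),
        " samples and is excluded from the breed-specific comparison")
      return(emptyOut())
    }
  }
  ## any further breed without both conditions cannot enter the
  ## interaction fit; drop its samples
  incomplete <- rownames(tab)[apply(tab == 0, 1L, any)]
  if (length(incomplete)) {
    warning("breed(s) without both conditions dropped from the ",
      "interaction fit: ", paste(incomplete, collapse = ", "))
    keep <- !st$breed %in% incomplete
    st <- droplevels(st[keep, , drop = FALSE])
    m <- m[, keep, drop = FALSE]
    if (!is.null(sizeFactors)) sizeFactors <- sizeFactors[keep]
    design <- NULL                 # a supplied design no longer matches
  }
  if (is.null(design)) {
    design <- buildDesign(st, cellTypes = cellTypes, interaction = TRUE)
  } else if (!any(grepl(":", colnames(design$X), fixed = TRUE))) {
    stop("design has no breed:condition interaction terms; ",
      "breed-specific calls require the interaction design")
  }
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
  X <- design$X
  refBreed <- levels(design$sampleTable$breed)[1L]
  contrastFor <- function(breed) {
    cvec <- stats::setNames(rep(0, ncol(X)), colnames(X))
    cvec["conditiontumor"] <- 1
    if (breed != refBreed) {
      ic <- paste0("breed", breed, ":conditiontumor")
      if (!ic %in% colnames(X)) stop("missing interaction column ", ic)
      cvec[ic] <- 1
    }
    cvec
  }
  disp <- estimateDispersion(m, sizeFactors, design)
  ln2 <- log(2)
  cT <- contrastFor(targetBreed); cO <- contrastFor(otherBreed)
  res <- t(vapply(seq_len(nrow(m)), function(g) {
    fit <- fitNBGLM(m[g, ], X, sizeFactors, disp[g])
    est <- function(cv) {
      b <- sum(cv * fit$coef)
      v <- drop(t(cv) %*% fit$cov %*% cv)
      c(b / ln2, sqrt(v) / ln2)
    }
    c(est(cT), est(cO), as.numeric(fit$converged))
  }, numeric(5)))
  ok <- res[, 5L] == 1 & is.finite(res[, 2L]) & is.finite(res[, 4L])
  pT <- pO <- shrT <- rep(NA_real_, nrow(m))
  pT[ok] <- waldTest(res[ok, 1L], res[ok, 2L])
  pO[ok] <- waldTest(res[ok, 3L], res[ok, 4L])
  shrT[ok] <- as.numeric(shrinkLFC(res[ok, 1L], res[ok, 2L]))
  padjT <- padjO <- rep(NA_real_, nrow(m))
  padjT[ok] <- bhAdjust(pT[ok]); padjO[ok] <- bhAdjust(pO[ok])
  specific <- !is.na(padjT) & !is.na(padjO) &
    padjT < alpha & abs(shrT) > lfcThreshold & padjO >= alpha
  DataFrame(lfcTarget = res[, 1L], lfcShrunkTarget = shrT,
    seTarget = res[, 2L], padjTarget = padjT,
    lfcOther = res[, 3L], seOther = res[, 4L], padjOther = padjO,
    breedSpecific = specific, row.names = rownames(m))
}
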