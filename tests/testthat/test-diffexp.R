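test_that("dispersion estimation handles the canonical cases", {
  set.seed(8)
  n <- 52
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  sf <- rep(1, n)
  ## Poisson genes: near-zero dispersion
  pois <- t(replicate(60, rpois(n, 200)))
  rownames(pois) <- paste0("p", 1:60)
  aP <- estimateDispersion(pois, sf, X, trend = FALSE)
  expect_lte(median(aP), 0.01)
  ## planted alpha = 0.2
  nb <- t(replicate(60, rnbinom(n, mu = 200, size = 1 / 0.2)))
  rownames(nb) <- paste0("n", 1:60)
  aN <- estimateDispersion(nb, sf, X, trend = FALSE)
  expect_gte(median(aN), 0.1)
  expect_lte(median(aN), 0.4)
  ## constant normalized counts -> floor
  const <- matrix(5, 1, n, dimnames = list("c", NULL))
  expect_equal(unname(estimateDispersion(const, sf, X, trend = FALSE)),
    1e-8)
  expect_error(estimateDispersion(matrix(0, 1, n), sf, X), "all-zero")
})

test_that("NB GLM recovers the closed-form two-group fold change", {
  n <- 40
  X <- cbind(`(Intercept)` = 1, group = rep(c(0, 1), each = n / 2))
  y <- c(rep(100, n / 2), rep(400, n / 2))
  fit <- fitNBGLM(y, X, rep(1, n), alpha = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["group"]) / log(2), 2, tolerance = 1e-6)
  ## confounded design is refused upstream
  st <- data.frame(condition = rep(c("normal", "tumor"), each = 4),
    breed = rep(c("A", "B"), each = 4), sex = "female")
  expect_error(buildDesign(st, cellTypes = NULL), "not full rank")
})

test_that("IRLS matches direct likelihood maximization on 50 genes", {
  set.seed(17)
  n <- 30
  X <- cbind(1, rep(c(0, 1), each = n / 2), rnorm(n))
  sf <- runif(n, 0.7, 1.4)
  worst <- 0
  for (g in 1:50) {
    alpha <- rlnorm(1, log(0.1), 0.4)
    beta <- c(log(150), rnorm(1, 0, 0.8), rnorm(1, 0, 0.3))
    mu <- exp(drop(X %*% beta) + log(sf))
    y <- rnbinom(n, mu = mu, size = 1 / alpha)
    if (sum(y) == 0) next
    fit <- fitNBGLM(y, X, sf, alpha)
    ref <- optimNB(y, X, sf, alpha)
    worst <- max(worst, max(abs(fit$coef - ref)))
  }
  expect_lt(worst, 1e-4)
})

test_that("Wald p-values follow the normal closed form", {
  expect_equal(waldTest(0, 1), 1)
  expect_equal(waldTest(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(waldTest(-3, 1.5), waldTest(3, 1.5))
  expect_error(waldTest(1, 0), "positive")
})

test_that("lFC shrinkage behaves like a normal-prior posterior mode", {
  lfc <- c(2, 2, 0.5, -3)
  se <- c(0, 10, 0.2, 0.5)
  shr <- shrinkLFC(lfc, se, tau2 = 1)
  expect_equal(shr[1], 2)                        # se = 0 keeps the MLE
  expect_lt(abs(shr[2]), 0.05)                   # se -> inf kills it
  expect_true(all(abs(shr) <= abs(lfc) + 1e-12))
  ## MSE improvement over the whole gene set on simulation
  set.seed(30)
  mses <- replicate(20, {
    true <- c(rep(0, 150), runif(50, -3, 3))
    se <- sqrt(rlnorm(200, log(0.2), 0.6))
    mle <- true + rnorm(200, 0, se)
    shr <- as.numeric(shrinkLFC(mle, se))
    c(mean((shr - true)^2), mean((mle - true)^2))
  })
  expect_lte(mean(mses[1, ]), mean(mses[2, ]))
})

test_that("BH agrees with its brute-force definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.037), 0.037)
  set.seed(12)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), naiveBH(p), tolerance = 1e-12)
  }
})

test_that("DE calling applies strict thresholds as printed", {
  lfc <- c(1.5, 3.79, -2, 2, NA)
  padj <- c(1e-4, 2.7e-8, 0.049, 0.05, 0.01)
  st <- callDE(lfc, padj)
  expect_equal(st, c("ns", "up", "down", "ns", "ns"))
  ## the reported fold change for lFC 3.79 is ~13.8x
  expect_equal(2^3.79, 13.83, tolerance = 0.01)
})

test_that("runDE output satisfies the DEResults invariants", {
  cohort <- smallCohort(seed = 23)
  sigs <- simulateSignatures(cohort$cfg)
  sc <- scoreCellTypes(cohort$norm, sigs$signatures)
  de <- runDE(cohort$counts, cbind(cohort$st, sc[rownames(cohort$st), ]),
    sizeFactors = cohort$sf)
  expect_s4_class(de, "DEResults")
  ok <- !is.na(de$padj)
  expect_true(all(de$padj[ok] >= de$pvalue[ok] - 1e-12))
  up <- de$status == "up"
  expect_true(all(de$lfcShrunk[up] > 1.5 & de$padj[up] < 0.05))
  dn <- de$status == "down"
  expect_true(all(de$lfcShrunk[dn] < -1.5 & de$padj[dn] < 0.05))
})

test_that("breed-specific calls need the interaction and both conditions", {
  cohort <- smallCohort(seed = 24)
  sigs <- simulateSignatures(cohort$cfg)
  sc <- scoreCellTypes(cohort$norm, sigs$signatures)
  st2 <- cbind(cohort$st, sc[rownames(cohort$st), ])
  noInt <- buildDesign(st2, interaction = FALSE)
  expect_error(breedSpecificDE(cohort$counts[1:5, ], st2, "PODL", "GRET",
    design = noInt), "interaction")
  ## LABR has one matched pair by default; drop its normal to trigger the
  ## exclusion path
  drop <- rownames(st2)[st2$breed == "LABR" & st2$condition == "normal"]
  keep <- setdiff(rownames(st2), drop)
  expect_warning(out <- breedSpecificDE(cohort$counts[1:5, keep],
    st2[keep, ], "LABR", "GRET"), "lacks normal")
  expect_equal(nrow(out), 0L)
})

test_that("a planted poodle-only effect is flagged poodle-specific", {
  ## planted global DE genes keep the adaptive shrinkage prior realistic
  cohort <- smallCohort(seed = 25, fracDE = 0.15, nModules = 0)
  cnt <- cohort$counts
  st <- cohort$st
  sigs <- simulateSignatures(cohort$cfg)
  sc <- scoreCellTypes(cohort$norm, sigs$signatures)
  st2 <- cbind(st, sc[rownames(st), ])
  ## plant a strong PODL-only down-regulation into a null non-marker gene
  tgt <- setdiff(rownames(cnt)[!cohort$sim$truth$isDE[rownames(cnt)]],
    unlist(sigs$signatures))[1]
  podlT <- st$breed == "PODL" & st$condition == "tumor"
  cnt[tgt, podlT] <- rpois(sum(podlT), pmax(0.2,
    cnt[tgt, podlT] / 2^6))
  res <- breedSpecificDE(cnt, st2, "PODL", "GRET", sizeFactors = cohort$sf)
  expect_true(res[tgt, "breedSpecific"])
  expect_lt(res[tgt, "lfcShrunkTarget"], -1.5)
  expect_gte(res[tgt, "padjOther"], 0.05)
  ## a globally DE gene is not breed-specific
  glob <- setdiff(rownames(cnt)[!cohort$sim$truth$isDE[rownames(cnt)]],
    c(tgt, unlist(sigs$signatures)))[1]
  allT <- st$condition == "tumor"
  cnt[glob, allT] <- rpois(sum(allT), cnt[glob, allT] * 2^3)
  res2 <- breedSpecificDE(cnt, st2, "PODL", "GRET",
    sizeFactors = cohort$sf)
  expect_false(res2[glob, "breedSpecific"])
})
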