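mkExpr <- function(nGenes = 30, nSamples = 20, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(nGenes * nSamples, 3, 1), nGenes, nSamples,
    dimnames = list(paste0("g", seq_len(nGenes)),
      paste0("s", seq_len(nSamples))))
}

## two planted blocks with within-correlation ~rho, across exactly-0 factors
blockExpr <- function(n1 = 20, n2 = 20, nBg = 0, nSamples = 30, rho = 0.8,
    seed = 1) {
  set.seed(seed)
  f1 <- as.numeric(scale(rnorm(nSamples)))
  f2 <- as.numeric(scale(resid(lm(rnorm(nSamples) ~ f1))))
  lam <- sqrt(rho)
  mk <- function(n, f) if (n > 0)
    t(replicate(n, lam * f + sqrt(1 - lam^2) * rnorm(nSamples)))
  x <- do.call(rbind, Filter(Negate(is.null), list(mk(n1, f1), mk(n2, f2),
    if (nBg > 0) matrix(rnorm(nBg * nSamples), nBg, nSamples))))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- paste0("s", seq_len(nSamples))
  x
}

test_that("variance filter is deterministic and drops constant genes", {
  x <- mkExpr(20, 10, seed = 2)
  x["g5", ] <- 3                       # constant
  expect_identical(varianceFilter(x, 20), x)
  r <- varianceFilter(x, 10)
  expect_false("g5" %in% rownames(r))
  expect_identical(varianceFilter(x, 10), r)
})

test_that("signed adjacency maps correlation to [0,1] as defined", {
  s <- c(1, -2, 3, -1, 2, 0.5)
  x <- rbind(a = s, b = 2 * s + 3, c = -s, d = c(1, 1, -2, -1, 2, -1))
  a <- signedAdjacency(x, beta = 7)
  expect_equal(a["a", "b"], 1)               # cor +1
  expect_equal(a["a", "c"], 0)               # cor -1
  expect_equal(unname(diag(a)), rep(1, 4))
  expect_true(all(a >= 0 & a <= 1))
  ## cor 0 at beta 7 -> 0.5^7
  z <- rbind(p = c(1, -1, 1, -1), q = c(1, 1, -1, -1))
  expect_equal(signedAdjacency(z, 7)["p", "q"], 0.5^7)
  expect_error(signedAdjacency(rbind(x, e = rep(1, 6)), 7),
    "zero-variance")
})

test_that("soft-threshold table is monotone and honours the override", {
  x <- blockExpr(15, 15, 20, seed = 3)
  ps <- pickSoftThreshold(x, grid = c(1, 3, 5, 7, 9))
  expect_true(all(diff(ps$table$meanConnectivity) < 0))
  expect_true(all(c("beta", "fitRsq", "meanConnectivity") %in%
    colnames(ps$table)))
  expect_equal(nrow(ps$table), 5L)
  expect_equal(pickSoftThreshold(x, grid = 7)$recommended, 7)
  expect_equal(pickSoftThreshold(x, beta = 7)$recommended, 7)
})

test_that("TOM matches the brute-force triple loop", {
  expect_equal(tomSimilarity(diag(5)), diag(5))
  ones <- matrix(1, 4, 4)
  expect_equal(tomSimilarity(ones), ones)
  set.seed(9)
  for (i in 1:5) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tomSimilarity(a)
    expect_equal(tom, naiveTOM(a), tolerance = 1e-12)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted blocks exactly", {
  for (seed in 1:10) {
    x <- blockExpr(25, 30, 40, rho = 0.8, seed = seed)
    tom <- tomSimilarity(signedAdjacency(x, 7))
    mset <- detectModules(tom, expr = x, minSize = 5)
    lab <- moduleLabels(mset)
    truth <- c(rep("b1", 25), rep("b2", 30), rep("bg", 40))
    planted <- truth != "bg"
    expect_equal(length(setdiff(unique(lab[planted]), "grey")), 2L)
    expect_equal(mclust::adjustedRandIndex(lab[planted], truth[planted]), 1)
  }
  ## min size larger than everything -> all grey
  x <- blockExpr(10, 10, 0, seed = 99)
  tom <- tomSimilarity(signedAdjacency(x, 7))
  allgrey <- detectModules(tom, minSize = 50)
  expect_true(all(moduleLabels(allgrey) == "grey"))
})

test_that("module labels partition genes and colors are deterministic", {
  x <- blockExpr(20, 15, 30, seed = 7)
  tom <- tomSimilarity(signedAdjacency(x, 7))
  m1 <- detectModules(tom, expr = x, minSize = 5)
  m2 <- detectModules(tom, expr = x, minSize = 5)
  expect_identical(moduleLabels(m1), moduleLabels(m2))
  expect_setequal(names(moduleLabels(m1)), rownames(x))
  ## larger module gets the earlier color
  tb <- table(moduleLabels(m1))
  mods <- setdiff(names(tb), "grey")
  expect_equal(mods[order(match(mods, c("turquoise", "blue", "brown")))],
    mods[order(-tb[mods])])
})

test_that("module eigengene matches brute-force SVD and orientation", {
  set.seed(21)
  for (i in 1:5) {
    x <- blockExpr(12, 0, 0, nSamples = 18, rho = 0.7, seed = i)
    me <- moduleEigengene(x)
    z <- t(scale(t(x)))
    sv <- svd(t(z))
    ref <- sv$u[, 1]
    if (cor(ref, colMeans(z)) < 0) ref <- -ref
    expect_equal(unname(me$eigengene), ref, tolerance = 1e-10)
    expect_equal(me$varExplained, sv$d[1]^2 / sum(sv$d^2))
    ## global sign flip of the data leaves the oriented ME's relation to
    ## the mean profile intact
    me2 <- moduleEigengene(-x)
    expect_gte(cor(me2$eigengene, colMeans(t(scale(t(-x))))), 0)
  }
  ## identical profiles: ME proportional to the profile, varExplained 1
  prof <- rnorm(10)
  same <- rbind(a = prof, b = prof, c = prof) + 5
  meS <- moduleEigengene(same)
  expect_equal(abs(cor(meS$eigengene, prof)), 1, tolerance = 1e-10)
  expect_equal(meS$varExplained, 1)
})

test_that("module-trait statistics follow the t closed form", {
  me <- cbind(m1 = c(0, 0, 1, 1, 0, 1), m2 = rnorm(6))
  trait <- c(0, 0, 1, 1, 0, 1)
  mt <- moduleTrait(me, trait)
  expect_equal(mt$r[1], 1)
  expect_equal(mt$pvalue[1], 0)
  ## r symmetric under trait flip
  mtF <- moduleTrait(me, 1 - trait)
  expect_equal(mtF$r, -mt$r)
  expect_equal(mtF$pvalue, mt$pvalue)
  expect_error(moduleTrait(me, rep(1, 6)), "constant trait")
  ## n = 52, r = 0.64: p in the 1e-7 order of magnitude
  r <- 0.64; n <- 52
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  expect_lt(p, 1e-5)
  expect_gt(p, 1e-9)
})

test_that("hub genes require both |GS| and |MM| strictly above 0.5", {
  x <- blockExpr(20, 20, 10, nSamples = 24, rho = 0.85, seed = 12)
  trait <- as.numeric(x[1, ] > median(x[1, ]))
  tom <- tomSimilarity(signedAdjacency(x, 7))
  mset <- detectModules(tom, expr = x, minSize = 5)
  mset <- moduleTrait(mset, trait)
  mset <- geneModuleStatistics(x, mset, trait)
  hubs <- hubGenes(mset)
  gs <- mset@geneSignificance; mm <- mset@moduleMembership
  for (mod in names(hubs)) for (g in hubs[[mod]]) {
    expect_gt(abs(gs[g]), 0.5)
    expect_gt(abs(mm[g]), 0.5)
  }
  ## boundary: exactly 0.5 is excluded
  mset@geneSignificance[] <- 0.5
  expect_equal(sum(lengths(hubGenes(mset))), 0L)
})

test_that("DE/module overlay partitions and reports both roundings", {
  labels <- setNames(c(rep("yellow", 3), rep("brown", 3), rep("grey", 4)),
    paste0("g", 1:10))
  mset <- new("ModuleSet", labels = labels, eigengenes = NULL,
    varExplained = numeric(), moduleTrait = data.frame(
      module = c("yellow", "brown"), r = c(0.64, -0.90),
      pvalue = c(6e-7, 8e-20)), geneSignificance = numeric(),
    moduleMembership = numeric())
  ov <- deModuleOverlay(paste0("g", 1:10), mset)
  expect_equal(ov$inPositive, 3L)
  expect_equal(ov$inNegative, 3L)
  expect_equal(ov$inPositive + ov$inNegative + ov$elsewhere, ov$total)
  ## no significant module
  mset@moduleTrait$pvalue <- c(0.5, 0.9)
  ov0 <- deModuleOverlay(paste0("g", 1:10), mset)
  expect_equal(ov0$inPositive + ov0$inNegative, 0L)
  expect_equal(ov0$elsewhere, 10L)
})
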