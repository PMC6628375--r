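test_that("meta-transcripts take the exon union with strand-aware sequence", {
  ex <- GRangesList(
    gU = GRanges("chr1", IRanges(c(101, 151), c(200, 250)), "+"),
    gD = GRanges("chr1", IRanges(c(101, 301), c(200, 400)), "-"))
  ann <- GeneAnnotation(ex, c(gU = "lincRNA", gD = "lincRNA"))
  mtU <- buildMetaTranscript(ann, "gU")
  expect_equal(length(mtU$blocks), 1L)         # overlapping exons merge
  expect_equal(start(mtU$blocks), 101L)
  expect_equal(end(mtU$blocks), 250L)
  mtD <- buildMetaTranscript(ann, "gD")
  expect_equal(length(mtD$blocks), 2L)
  expect_equal(mtD$length, 200L)
  ## minus-strand sequence = reverse complement of plus extraction
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")))
  sq <- buildMetaTranscript(ann, "gD", genome)$sequence
  fw <- Biostrings::xscat(
    Biostrings::subseq(genome[["chr1"]], 101, 200),
    Biostrings::subseq(genome[["chr1"]], 301, 400))
  expect_equal(as.character(sq),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      as.character(fw)))))
})

test_that("CIGAR identity implements matches over alignment columns", {
  expect_equal(cigarIdentity("100="), 1)
  expect_equal(cigarIdentity("50=10X40="), 0.9)
  expect_equal(cigarIdentity("50=5I45="), 95 / 100)
  expect_equal(cigarIdentity("50=1000N50="), 1)
  expect_equal(cigarIdentity("10S50=10X40=5H"), 90 / 100)  # clips excluded
  expect_equal(cigarIdentity("40=10D50="), 90 / 100)
  ## identity("k=") = 1 for any k; X replacing = never increases identity
  for (k in c(1, 7, 500)) expect_equal(cigarIdentity(paste0(k, "=")), 1)
  prev <- 1
  for (x in c(0, 5, 20, 45)) {
    idy <- cigarIdentity(sprintf("%d=%s50=", 50 - x,
      if (x > 0) paste0(x, "X") else ""))
    expect_lte(idy, prev)
    prev <- idy
  }
  ## plain M needs the edit-distance tag
  expect_error(cigarIdentity("100M"), "edit-distance")
  expect_equal(cigarIdentity("90M5I5D", nm = 12), (100 - 12) / 100)
  expect_error(cigarIdentity("10M10="), "mixed")
})

test_that("alignment projection splits blocks at introns only", {
  b <- alignmentBlocks("hs1", 1001, "50=100N50=", "+")
  expect_equal(start(b), c(1001L, 1151L))
  expect_equal(end(b), c(1050L, 1200L))
  ## no N: one block spanning the reference-consuming length
  one <- alignmentBlocks("hs1", 501, "30=5I20=10D40=", "+")
  expect_equal(length(one), 1L)
  expect_equal(sum(width(one)), 30 + 20 + 10 + 40)
  ## conservation: total block length = reference-consuming ops
  set.seed(11)
  for (i in 1:20) {
    ops <- paste0(sample(5:50, 6, TRUE),
      c("=", "X", "I", "N", "D", "="), collapse = "")
    blocks <- alignmentBlocks("hs1", 1000, ops, "+")
    pc <- parseCigar(ops)
    expect_equal(sum(width(blocks)),
      sum(pc$len[pc$op %in% c("M", "=", "X", "D")]))
  }
})

test_that("split, strand-aware intersection agrees with the naive scan", {
  ## query inside an intron of the only candidate gene: no overlap
  ann <- GeneAnnotation(GRangesList(
    gi = GRanges("hs1", IRanges(c(1001, 2001), c(1100, 2100)), "+")),
    c(gi = "lincRNA"))
  qIntron <- GRanges("hs1", IRanges(1500, 1600), "+")
  expect_equal(nrow(intersectAnnotation(qIntron, ann)), 0L)
  ## but the unsplit gene span does overlap
  expect_equal(intersectAnnotation(qIntron, ann, split = FALSE)$gene, "gi")
  ## opposite strand excluded under -s semantics
  qAnti <- GRanges("hs1", IRanges(1050, 1080), "-")
  expect_equal(nrow(intersectAnnotation(qAnti, ann)), 0L)
  expect_equal(intersectAnnotation(qAnti, ann, sameStrand = FALSE)$gene,
    "gi")
  ## random fixtures vs all-pairs scan
  set.seed(31)
  for (i in 1:100) {
    qs <- sort(sample(1:5000, 3)); qw <- sample(20:200, 3, TRUE)
    q <- reduce(GRanges("hs1", IRanges(qs, width = qw), "+"))
    es <- sort(sample(1:5000, 4)); ew <- sample(20:200, 4, TRUE)
    annR <- GeneAnnotation(GRangesList(
      gR = reduce(GRanges("hs1", IRanges(es, width = ew), "+"))),
      c(gR = "lincRNA"))
    got <- intersectAnnotation(q, annR)
    exp <- naiveOverlapBases(start(q), end(q),
      start(exonsByGene(annR)[["gR"]]), end(exonsByGene(annR)[["gR"]]))
    if (exp == 0) expect_equal(nrow(got), 0L)
    else expect_equal(got$overlapBases, exp)
  }
})

test_that("classification is total, boundary-inclusive and deterministic", {
  ann <- GeneAnnotation(GRangesList(
    gA = GRanges("hs1", IRanges(1001, 1100), "+"),
    gB = GRanges("hs1", IRanges(1001, 1100), "+")),
    c(gA = "lincRNA", gB = "lincRNA"))
  mkaln <- function(qname, cigar, primary = TRUE, pos = 1001)
    S4Vectors::DataFrame(qname = qname, target = "hs1", pos = pos,
      strand = "+", cigar = cigar, primary = primary, nm = NA_integer_,
      qlen = 100L)
  aln <- rbind(
    mkaln("qExact", "70=30X"),            # identity exactly 0.70: retained
    mkaln("qLow", "61=39X"),              # 0.61: below the screen
    mkaln("qSecondary", "100=", primary = FALSE),
    mkaln("qNovel", "100=", pos = 9001))
  calls <- classifyOrthology(c("qExact", "qLow", "qSecondary", "qNovel",
    "qMissing"), aln, ann)
  cls <- setNames(calls$class, calls$query)
  expect_equal(unname(cls["qExact"]), "annotated_ortholog")
  expect_equal(unname(cls["qLow"]), "below_identity")
  expect_equal(unname(cls["qSecondary"]), "unaligned")  # only a secondary
  expect_equal(unname(cls["qNovel"]), "novel_aligned")
  expect_equal(unname(cls["qMissing"]), "unaligned")
  ## total function: one class per query, counts conserve
  expect_equal(nrow(calls), 5L)
  expect_equal(sum(table(calls$class)), 5L)
  ## tie on overlap bases -> lexicographically smallest gene id
  expect_equal(calls$matchedGene[calls$query == "qExact"], "gA")
  ## lowering the screen rescues the 0.61 alignment
  low <- classifyOrthology("qLow", aln, ann, minIdentity = 0.6)
  expect_equal(low$class, "annotated_ortholog")
})

test_that("simulated orthology truth is re-derivable from the emitted files", {
  cfg <- simulationConfig(seed = 19)
  o <- simulateOrthology(cfg)
  prim <- primaryAlignments(o$alignments)
  ## identity 1 emits pure =/N; requested identities reproduce within 0.01
  for (i in seq_len(nrow(prim))) {
    idy <- cigarIdentity(prim$cigar[i])
    tr <- o$truth$identity[o$truth$query == prim$qname[i]]
    expect_lt(abs(idy - tr), 0.01)
  }
  calls <- classifyOrthology(o$truth$query, o$alignments, o$targetAnn)
  expect_equal(calls$class, o$truth$class)
  ok <- o$truth$class == "annotated_ortholog"
  expect_equal(calls$matchedGene[ok], o$truth$targetGene[ok])
  ## decoy secondaries exist and are ignored
  expect_gt(sum(!o$alignments$primary), 0)
})

test_that("an identity-1 request yields only match and intron operations", {
  cfg <- simulationConfig(seed = 4, orthoIdentityRange = c(1, 1),
    orthoSubFrac = 0)
  o <- simulateOrthology(cfg)
  prim <- primaryAlignments(o$alignments)
  for (cg in prim$cigar) {
    ops <- unique(parseCigar(cg)$op)
    expect_true(all(ops %in% c("=", "N")))
  }
  expect_error(simulationConfig(seed = 1,
    orthoIdentityRange = c(0, 0.5)) |> simulateOrthology(),
    "identities")
})
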