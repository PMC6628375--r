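test_that("GTF reading applies the coordinate convention and pools exons", {
  path <- writeGtfLines(c(
    gtfExon("chr1", 101, 200, "+", "gA"),
    gtfExon("chr1", 101, 200, "+", "gA", tx = "gA.t2"),  # shared exon
    gtfExon("chr1", 301, 350, "+", "gA", tx = "gA.t2"),
    gtfExon("chr2", 501, 600, "-", "gB", biotype = "protein_coding")))
  ann <- readGTF(path)
  expect_setequal(geneIds(ann), c("gA", "gB"))
  exA <- exonsByGene(ann)[["gA"]]
  expect_equal(length(exA), 2L)              # identical exon stored once
  expect_equal(start(sort(exA)), c(101L, 301L))
  expect_equal(end(sort(exA)), c(200L, 350L))
  expect_equal(width(sort(exA)), c(100L, 50L))
  expect_equal(unname(geneBiotype(ann)["gB"]), "protein_coding")
})

test_that("GTF validation rejects malformed input with a line number", {
  bad <- writeGtfLines(c(gtfExon("chr1", 101, 200, "+", "g1"),
    "chr1\tsrc\texon\tnot_a_number"))
  expect_error(readGTF(bad), "line 2")
  inv <- writeGtfLines(gtfExon("chr1", 300, 200, "+", "g1"))
  expect_error(readGTF(inv), "end < start")
  both <- writeGtfLines(c(gtfExon("chr1", 101, 200, "+", "g1"),
    gtfExon("chr1", 301, 400, "-", "g1")))
  expect_error(readGTF(both), "both strands")
})

test_that("GTF round trip preserves coordinates exactly", {
  ann <- mkAnn()
  path <- tempfile(fileext = ".gtf")
  writeGTF(ann, path)
  back <- readGTF(path)
  for (g in geneIds(ann)) {
    a <- sort(exonsByGene(ann)[[g]]); b <- sort(exonsByGene(back)[[g]])
    expect_equal(start(a), start(b))
    expect_equal(end(a), end(b))
    expect_equal(as.character(strand(a)), as.character(strand(b)))
  }
  expect_equal(geneBiotype(back)[geneIds(ann)], geneBiotype(ann))
})

test_that("BED12 lines carry correct block arithmetic", {
  b <- GRanges("chr1", IRanges(c(101, 301), c(200, 350)), "+")
  f <- strsplit(bed12Line(b, "x"), "\t")[[1]]
  expect_equal(f[1:4], c("chr1", "100", "350", "x"))
  expect_equal(as.integer(f[10]), 2L)
  expect_equal(f[11], "100,50,")
  expect_equal(f[12], "0,200,")
  single <- strsplit(bed12Line(GRanges("chr1", IRanges(11, 20), "+"),
    "s"), "\t")[[1]]
  expect_equal(as.integer(single[10]), 1L)
  expect_equal(single[12], "0,")
  over <- GRanges("chr1", IRanges(c(101, 150), c(200, 250)), "+")
  expect_error(bed12Line(over, "bad"), "overlap")
})

test_that("BED12 round trip reconstructs random block sets", {
  set.seed(7)
  for (i in 1:50) {
    nb <- sample(1:5, 1)
    starts <- sort(sample(seq(1, 5000, by = 10), nb))
    widths <- sample(20:80, nb, replace = TRUE)
    ## enforce disjoint blocks
    for (k in seq_len(nb - 1))
      starts[k + 1] <- max(starts[k + 1], starts[k] + widths[k] + 1)
    blocks <- GRanges("chrZ", IRanges(starts, width = widths),
      sample(c("+", "-"), 1))
    line <- bed12Line(blocks, paste0("f", i))
    ## independent re-parse from the raw string
    parsed <- naiveParseBed12(line)
    expect_equal(parsed$start, start(blocks) - 1L)
    expect_equal(parsed$end, end(blocks))
    ## and through the file reader
    path <- tempfile(fileext = ".bed")
    writeLines(line, path)
    back <- readBed12(path)[[paste0("f", i)]]
    expect_equal(start(back), start(blocks))
    expect_equal(end(back), end(blocks))
  }
})

test_that("SAM parsing is flag- and strand-faithful and validates CIGARs", {
  path <- writeSamLines(c(
    samLine("q1", 0, "hs1", 100, "50=10X40="),
    samLine("q1", 256, "hs1", 900, "100M"),             # secondary
    samLine("q2", 16, "hs1", 200, "30=1000N70="),
    samLine("q3", 2048, "hs1", 300, "60=40S"),          # supplementary
    samLine("q4", 4, "*", 0, "*")))                     # unmapped: dropped
  aln <- readAlignments(path)
  expect_equal(nrow(aln), 4L)
  expect_equal(aln$primary, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(aln$strand[aln$qname == "q2"], "-")
  expect_equal(nrow(primaryAlignments(aln)[
    primaryAlignments(aln)$qname == "q1", ]), 1L)
  bad <- writeSamLines(samLine("q9", 0, "hs1", 1, "50Q"))
  expect_error(readAlignments(bad), "unknown CIGAR operation")
  mismatch <- writeSamLines(samLine("q8", 0, "hs1", 1, "10=",
    seq = "ACGTACGTACGTACGT"))
  expect_error(readAlignments(mismatch), "does not match sequence length")
})

test_that("PAF parsing honours tp tags and 0-based starts", {
  path <- tempfile(fileext = ".paf")
  writeLines(c(
    paste("q1", 100, 0, 100, "+", "hs1", 1e6, 999, 1099, 95, 100, 60,
      "tp:A:P", "cg:Z:100=", sep = "\t"),
    paste("q1", 100, 0, 100, "-", "hs2", 1e6, 5000, 5100, 60, 100, 0,
      "tp:A:S", "cg:Z:100=", sep = "\t")), path)
  aln <- readAlignments(path)
  expect_equal(aln$primary, c(TRUE, FALSE))
  expect_equal(aln$pos[1], 1000L)            # 0-based 999 -> 1-based 1000
  expect_equal(aln$strand, c("+", "-"))
})

test_that("SAM writer round trips through the reader", {
  cfg <- simulationConfig(seed = 3)
  o <- simulateOrthology(cfg)
  path <- tempfile(fileext = ".sam")
  writeSAM(o$alignments, path)
  back <- readAlignments(path)
  ord <- order(back$qname, back$cigar)
  ord0 <- order(o$alignments$qname, o$alignments$cigar)
  for (col in c("qname", "target", "pos", "strand", "cigar", "primary"))
    expect_equal(back[[col]][ord], o$alignments[[col]][ord0])
})
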