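## Cross-species lncRNA orthology: meta-transcript construction from pooled
## exons, CIGAR-based sequence identity, projection of spliced alignments to
## target blocks, strand-aware split-exon intersection, and classification.

#' Build a gene's meta-transcript
#'
#' Projects all exons of a gene (pooled over transcripts) onto the genome
#' and takes their interval union, yielding one representative
#' "meta-transcript" per gene; when a genome is supplied the spliced
#' sequence is extracted (reverse-complemented for minus-strand genes).
#'
#' @param ann a [GeneAnnotation-class].
#' @param geneId gene to build.
#' @param genome optional named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @return A list: `geneId`, `blocks` (sorted disjoint [GRanges]), `length`
#'   (spliced length in bases), `sequence` ([Biostrings::DNAString] or NULL).
#' @export
buildMetaTranscript <- function(ann, geneId, genome = NULL) {
  if (!geneId %in% geneIds(ann)) stop("unknown gene '", geneId, "'")
  ex <- ann@exons[[geneId]]
  if (length(ex) == 0L) stop("gene '", geneId, "' has no exons")
  blocks <- reduce(sort(ex))
  seqv <- NULL
  if (!is.null(genome)) {
    chrom <- as.character(seqnames(blocks))[1L]
    if (!chrom %in% names(genome))
      stop("chromosome '", chrom, "' absent from genome")
    pieces <- Biostrings::DNAStringSet(vapply(seq_along(blocks),
      function(i) as.character(Biostrings::subseq(genome[[chrom]],
        start(blocks)[i], end(blocks)[i])), ""))
    seqv <- Biostrings::DNAString(paste(as.character(pieces),
      collapse = ""))
    if (as.character(strand(blocks))[1L] == "-")
      seqv <- Biostrings::reverseComplement(seqv)
  }
  list(geneId = geneId, blocks = blocks, length = sum(width(blocks)),
    sequence = seqv)
}

#' Sequence identity from a CIGAR string
#'
#' Identity = matching bases / alignment columns. With extended CIGARs the
#' matching bases are the `=` operations; alignment columns are
#' `{=, X, M, I, D}` (indels are alignment columns; intron skips `N` and
#' clips `S`/`H` are not). With plain `M` CIGARs the match count is
#' recovered from the edit-distance tag:
#' `matches = sum(M) + sum(I) + sum(D) - NM`.
#'
#' @param cigar CIGAR string.
#' @param nm edit-distance tag value, required when the CIGAR uses `M`.
#' @return Identity in `[0, 1]`.
#' @examples
#' cigarIdentity("50=10X40=")      # 0.9
#' cigarIdentity("50=1000N50=")    # 1.0
#' @export
cigarIdentity <- function(cigar, nm = NA) {
  ops <- parseCigar(cigar)
  colOps <- c("=", "X", "M", "I", "D")
  columns <- sum(ops$len[ops$op %in% colOps])
  if (columns == 0L) stop("CIGAR has no aligned columns: '", cigar, "'")
  if (any(ops$op == "M")) {
    if (any(ops$op %in% c("=", "X")))
      stop("mixed M and =/X operations are not supported")
    if (is.na(nm))
      stop("CIGAR uses M without an edit-distance tag; ",
        "an extended (=/X) CIGAR or an NM tag is required")
    matches <- sum(ops$len[ops$op %in% c("M", "I", "D")]) - nm
  } else {
    matches <- sum(ops$len[ops$op == "="])
  }
  matches / columns
}

#' Project an alignment onto target blocks
#'
#' Walks the CIGAR from the 1-based target start: `M`/`=`/`X`/`D` extend the
#' current block on the target, `N` closes it and skips the intron, `I` and
#' clips advance only the query. The result is the BED12-style block set of
#' the alignment on the target.
#'
#' @param target target sequence name.
#' @param pos 1-based leftmost target position.
#' @param cigar CIGAR string.
#' @param strand alignment strand (`"+"`/`"-"`).
#' @return A [GenomicRanges::GRanges] of blocks (1-based closed), ready for
#'   [bed12Line()].
#' @examples
#' alignmentBlocks("hs1", 1001, "50=100N50=", "+")
#' @export
alignmentBlocks <- function(target, pos, cigar, strand = "+") {
  ops <- parseCigar(cigar)
  cur <- pos          # current target coordinate (1-based, next base)
  bstart <- NA_integer_
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(bstart)) bstart <- cur
      cur <- cur + len
    } else if (op == "N") {
      if (!is.na(bstart)) {
        starts <- c(starts, bstart); ends <- c(ends, cur - 1L)
        bstart <- NA_integer_
      }
      cur <- cur + len
    }                                 # I, S, H, P: query-only / no-op
  }
  if (!is.na(bstart)) {
    starts <- c(starts, bstart); ends <- c(ends, cur - 1L)
  }
  GRanges(target, IRanges(starts, ends), strand = strand)
}

#' Strand-aware split intersection with an annotation
#'
#' Counts overlap bases between query blocks and the exon blocks of each
#' annotated gene — split semantics: a query block inside an intron
#' contributes nothing — restricted to the matching strand by default.
#'
#' @param queryBlocks [GenomicRanges::GRanges] of alignment blocks.
#' @param ann target [GeneAnnotation-class].
#' @param sameStrand require matching strand (default TRUE).
#' @param split count overlap against exon blocks only (default TRUE);
#'   when FALSE the gene span (first to last exon) is used.
#' @return data.frame with `gene` and `overlapBases`, sorted by decreasing
#'   overlap then gene id; zero-overlap genes are omitted.
#' @export
intersectAnnotation <- function(queryBlocks, ann, sameStrand = TRUE,
    split = TRUE) {
  ex <- unlist(ann@exons, use.names = FALSE)
  gid <- rep(names(ann@exons), lengths(ann@exons))
  if (!split) {
    rng <- unlist(range(ann@exons), use.names = FALSE)
    gid <- names(ann@exons)
    ex <- rng
  }
  hits <- GenomicRanges::findOverlaps(queryBlocks, ex,
    ignore.strand = !sameStrand)
  if (length(hits) == 0L)
    return(data.frame(gene = character(), overlapBases = integer()))
  ov <- width(GenomicRanges::pintersect(
    queryBlocks[S4Vectors::queryHits(hits)],
    ex[S4Vectors::subjectHits(hits)], ignore.strand = !sameStrand))
  tot <- tapply(ov, gid[S4Vectors::subjectHits(hits)], sum)
  out <- data.frame(gene = names(tot), overlapBases = as.integer(tot))
  out[order(-out$overlapBases, out$gene), , drop = FALSE]
}

#' Classify queries into orthology classes
#'
#' For every query gene: `unaligned` when it has no primary alignment;
#' `below_identity` when the primary alignment's CIGAR identity falls below
#' `minIdentity` (the screen is inclusive: identity exactly at the threshold
#' is retained); otherwise `annotated_ortholog` to the target gene with
#' maximal exon-overlap bases (ties broken by lexicographically smallest
#' gene id) or `novel_aligned` when no annotated exon is touched.
#'
#' @param queryIds character vector of query gene ids (defines the universe;
#'   queries absent from `aln` are `unaligned`).
#' @param aln alignment table as from [readAlignments()].
#' @param targetAnn target-species [GeneAnnotation-class].
#' @param minIdentity identity screen, default 0.70.
#' @param sameStrand,split intersection semantics, see
#'   [intersectAnnotation()].
#' @return An [OrthologyCalls-class] with one row per query.
#' @export
classifyOrthology <- function(queryIds, aln, targetAnn, minIdentity = 0.70,
    sameStrand = TRUE, split = TRUE) {
  prim <- primaryAlignments(aln)
  rows <- lapply(queryIds, function(q) {
    rec <- prim[prim$qname == q, , drop = FALSE]
    if (nrow(rec) == 0L)
      return(data.frame(query = q, aligned = FALSE, identity = NA_real_,
        targetChrom = NA_character_, targetStart = NA_integer_,
        targetEnd = NA_integer_, targetStrand = NA_character_,
        matchedGene = NA_character_, class = "unaligned"))
    if (nrow(rec) > 1L) {           # defensive: keep best-identity primary
      ids <- vapply(seq_len(nrow(rec)), function(i)
        cigarIdentity(rec$cigar[i], rec$nm[i]), numeric(1))
      rec <- rec[which.max(ids), , drop = FALSE]
    }
    idy <- cigarIdentity(rec$cigar[1L], rec$nm[1L])
    blocks <- alignmentBlocks(rec$target[1L], rec$pos[1L], rec$cigar[1L],
      rec$strand[1L])
    base <- data.frame(query = q, aligned = TRUE, identity = idy,
      targetChrom = rec$target[1L], targetStart = min(start(blocks)),
      targetEnd = max(end(blocks)), targetStrand = rec$strand[1L],
      matchedGene = NA_character_, class = "novel_aligned")
    if (idy < minIdentity) { base$class <- "below_identity"; return(base) }
    ov <- intersectAnnotation(blocks, targetAnn, sameStrand = sameStrand,
      split = split)
    if (nrow(ov)) {
      base$matchedGene <- ov$gene[1L]
      base$class <- "annotated_ortholog"
    }
    base
  })
  new("OrthologyCalls", DataFrame(do.call(rbind, rows)))
}
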