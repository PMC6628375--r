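## Readers/writers for GTF, BED12, SAM and PAF plus CIGAR utilities.
## Internal coordinates follow the Bioconductor convention (1-based, closed,
## via GRanges); BED12 and PAF are converted at the boundary.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
.QUERY_OPS <- c("M", "I", "S", "=", "X")
.REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string into operations and lengths
#'
#' @param cigar a single CIGAR string, e.g. `"50=10X40="`.
#' @return A data.frame with columns `op` and `len`.
#' @examples
#' parseCigar("50=1000N50=")
#' @export
parseCigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  m <- gregexpr("[0-9]+[A-Za-z=]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR string: '", cigar, "'")
  op <- substring(toks, nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  bad <- !op %in% CIGAR_OPS
  if (any(bad))
    stop("unknown CIGAR operation '", op[bad][1L], "' in '", cigar, "'")
  if (any(len <= 0L))
    stop("CIGAR operation lengths must be positive in '", cigar, "'")
  data.frame(op = op, len = len)
}

.cigarQueryLength <- function(ops) sum(ops$len[ops$op %in% .QUERY_OPS])
.cigarRefLength <- function(ops) sum(ops$len[ops$op %in% .REF_OPS])

.readTextLines <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read gene models from a GTF file
#'
#' Reads exon features from an Ensembl-dialect GTF (attributes must carry
#' `gene_id` and `gene_biotype`), pools exons per gene over all transcripts,
#' deduplicates identical exons, and validates that each gene lives on a
#' single chromosome and strand.
#'
#' @param path path to a GTF file (plain or gzip).
#' @return A [GeneAnnotation-class].
#' @details A light pre-scan rejects malformed lines (wrong field count,
#'   non-numeric or inverted coordinates) with the offending line number;
#'   parsing itself is delegated to [rtracklayer::import()].
#' @export
readGTF <- function(path) {
  lines <- .readTextLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  flds <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(flds)
  if (any(nf != 9L))
    stop("GTF parse error at line ", lineno[which(nf != 9L)[1L]],
      ": expected 9 tab-separated fields, got ", nf[nf != 9L][1L])
  st <- suppressWarnings(as.numeric(vapply(flds, `[[`, "", 4L)))
  en <- suppressWarnings(as.numeric(vapply(flds, `[[`, "", 5L)))
  if (anyNA(st) || anyNA(en))
    stop("GTF parse error at line ", lineno[which(is.na(st) | is.na(en))[1L]],
      ": non-numeric coordinates")
  if (any(en < st))
    stop("GTF validation error at line ", lineno[which(en < st)[1L]],
      ": end < start")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features found in '", path, "'")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF attributes must contain gene_id for every exon")
  bt <- gr$gene_biotype
  if (is.null(bt)) stop("GTF attributes must contain gene_biotype")
  ex <- GenomicRanges::split(GenomicRanges::granges(gr), gr$gene_id)
  ex <- unique(ex)                        # identical exons stored once
  btg <- vapply(split(bt, gr$gene_id), function(v) v[1L], "")
  GeneAnnotation(ex, btg[names(ex)])
}

#' Write a GeneAnnotation to GTF
#'
#' Emits one exon line per stored exon, with a single synthetic transcript id
#' per gene (the exon pool is transcript-agnostic). Coordinates round-trip
#' exactly through [readGTF()].
#'
#' @param ann a [GeneAnnotation-class].
#' @param path output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
writeGTF <- function(ann, path) {
  ex <- unlist(ann@exons, use.names = FALSE)
  gid <- rep(names(ann@exons), lengths(ann@exons))
  mcols(ex)$source <- "melanolnc"
  mcols(ex)$type <- "exon"
  mcols(ex)$gene_id <- gid
  mcols(ex)$transcript_id <- paste0(gid, ".meta")
  mcols(ex)$gene_biotype <- unname(ann@biotype[gid])
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

.checkBlocks <- function(blocks) {
  if (length(blocks) == 0L) stop("no blocks")
  if (length(unique(as.character(seqnames(blocks)))) != 1L ||
      length(unique(as.character(strand(blocks)))) != 1L)
    stop("blocks must share one chromosome and strand")
  o <- order(start(blocks))
  blocks <- blocks[o]
  if (length(blocks) > 1L &&
      any(start(blocks)[-1L] <= end(blocks)[-length(blocks)]))
    stop("blocks overlap or touch; expected disjoint sorted blocks")
  blocks
}

#' Format genomic blocks as a BED12 line
#'
#' @param blocks a [GenomicRanges::GRanges] of sorted, disjoint blocks on one
#'   chromosome and strand (1-based, closed, as usual for GRanges).
#' @param name feature name (column 4).
#' @param score BED score (column 5), default 0.
#' @return A single BED12-formatted string (0-based half-open on output).
#' @examples
#' b <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 301), c(200, 350)), "+")
#' bed12Line(b, "x")   # blockSizes "100,50", blockStarts "0,200"
#' @export
bed12Line <- function(blocks, name, score = 0) {
  blocks <- .checkBlocks(blocks)
  chrom <- as.character(seqnames(blocks))[1L]
  str <- as.character(strand(blocks))[1L]
  if (str == "*") str <- "+"
  cs <- start(blocks)[1L] - 1L            # to 0-based
  ce <- end(blocks)[length(blocks)]
  paste(chrom, cs, ce, name, score, str, cs, ce, "0", length(blocks),
    paste0(paste(width(blocks), collapse = ","), ","),
    paste0(paste(start(blocks) - 1L - cs, collapse = ","), ","),
    sep = "\t")
}

#' Write a BED12 file
#'
#' @param blockList a [GenomicRanges::GRangesList], one element of blocks per
#'   feature; names are used as feature names.
#' @param path output path.
#' @param scores optional numeric vector of scores.
#' @return `path`, invisibly.
#' @seealso [bed12Line()], [readBed12()]
#' @export
writeBed12 <- function(blockList, path, scores = NULL) {
  if (is.null(names(blockList))) stop("blockList must be named")
  if (is.null(scores)) scores <- rep(0, length(blockList))
  lines <- mapply(bed12Line, as.list(blockList), names(blockList), scores)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file into per-feature blocks
#'
#' @param path path to a BED12 file.
#' @return A named [GenomicRanges::GRangesList]: per feature, the absolute
#'   block coordinates (1-based closed).
#' @export
readBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(mcols(gr)$blocks))
    mcols(gr)$blocks <- IRanges::IRangesList(lapply(width(gr), function(w)
      IRanges::IRanges(1L, w)))
  out <- GRangesList(lapply(seq_along(gr), function(i) {
    rel <- mcols(gr)$blocks[[i]]
    GRanges(seqnames(gr)[i],
      IRanges::shift(rel, start(gr)[i] - 1L),
      strand = strand(gr)[i])
  }))
  names(out) <- mcols(gr)$name
  out
}

## --- SAM / PAF ------------------------------------------------------------

.samTag <- function(tags, key) {
  hit <- grep(paste0("^", key, ":[Ai]:"), tags, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", key, ":[Ai]:"), "", hit[1L])
}

#' Read spliced alignments from SAM or PAF text
#'
#' Parses a SAM (text) or PAF file into a flat alignment table. SAM records
#' flagged secondary (0x100) or supplementary (0x800) and PAF records with a
#' `tp:A:S`/`tp:A:I` tag are marked non-primary; unmapped SAM records
#' (0x4 or CIGAR `*`) are dropped.
#'
#' @param path path to the alignment file (plain or gzip).
#' @param format `"auto"` (by extension), `"sam"` or `"paf"`.
#' @return A [S4Vectors::DataFrame] with columns `qname`, `target`, `pos`
#'   (1-based leftmost target position), `strand`, `cigar`, `primary`
#'   (logical), `nm` (edit distance tag, NA when absent) and `qlen`
#'   (query bases consumed by the CIGAR).
#' @export
readAlignments <- function(path, format = c("auto", "sam", "paf")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.paf$", base, ignore.case = TRUE)) "paf" else "sam"
  }
  lines <- .readTextLines(path)
  if (format == "sam") .parseSam(lines) else .parsePaf(lines)
}

.parseSam <- function(lines) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("SAM parse error: fewer than 11 fields")
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) != 0L || f[6L] == "*") return(NULL)
    ops <- parseCigar(f[6L])
    if (f[10L] != "*" && .cigarQueryLength(ops) != nchar(f[10L]))
      stop("query-consuming CIGAR length does not match sequence length ",
        "for '", f[1L], "'")
    nm <- .samTag(f[-(1:11)], "NM")
    data.frame(qname = f[1L], target = f[3L], pos = as.integer(f[4L]),
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      cigar = f[6L],
      primary = bitwAnd(flag, 256L) == 0L && bitwAnd(flag, 2048L) == 0L,
      nm = if (is.na(nm)) NA_integer_ else as.integer(nm),
      qlen = .cigarQueryLength(ops))
  })
  S4Vectors::DataFrame(do.call(rbind, c(recs,
    list(.samEmpty()))))
}

.samEmpty <- function() {
  data.frame(qname = character(), target = character(), pos = integer(),
    strand = character(), cigar = character(), primary = logical(),
    nm = integer(), qlen = integer())
}

.parsePaf <- function(lines) {
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("PAF parse error: fewer than 12 fields")
    tags <- if (length(f) > 12L) f[-(1:12)] else character()
    cg <- grep("^cg:Z:", tags, value = TRUE)
    cigar <- if (length(cg)) sub("^cg:Z:", "", cg[1L]) else NA_character_
    if (!is.na(cigar)) parseCigar(cigar)   # validates ops
    tp <- .samTag(tags, "tp")
    nm <- grep("^NM:i:", tags, value = TRUE)
    data.frame(qname = f[1L], target = f[6L],
      pos = as.integer(f[8L]) + 1L,        # PAF is 0-based
      strand = f[5L], cigar = cigar,
      primary = is.na(tp) || tp == "P",
      nm = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1L]))
           else NA_integer_,
      qlen = as.integer(f[2L]))
  })
  S4Vectors::DataFrame(do.call(rbind, c(recs, list(.samEmpty()))))
}

#' Keep only primary alignments
#'
#' With multiple mappings per query, only the primary alignment is retained
#' for orthology assessment.
#'
#' @param aln alignment table from [readAlignments()].
#' @return The subset of rows with `primary == TRUE`.
#' @export
primaryAlignments <- function(aln) aln[aln$primary, , drop = FALSE]

#' Write alignments as SAM text
#'
#' Minimal SAM writer used to materialize simulated alignments; emits `@SQ`
#' headers for every target sequence and an `NM:i` tag when present.
#'
#' @param aln alignment table (columns as from [readAlignments()]).
#' @param path output path.
#' @param targetLengths optional named integer vector of target sequence
#'   lengths for the `@SQ` headers; defaults to the rightmost mapped base.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(aln, path, targetLengths = NULL) {
  aln <- as.data.frame(aln)
  reflen <- vapply(aln$cigar, function(cg) .cigarRefLength(parseCigar(cg)),
    integer(1))
  if (is.null(targetLengths)) {
    ends <- aln$pos + reflen - 1L
    targetLengths <- vapply(split(ends, aln$target), max, numeric(1))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(targetLengths), "\tLN:",
      as.integer(targetLengths)))
  flag <- ifelse(aln$primary, 0L, 256L) + ifelse(aln$strand == "-", 16L, 0L)
  body <- paste(aln$qname, flag, aln$target, aln$pos, 60L, aln$cigar,
    "*", 0L, 0L, "*", "*", sep = "\t")
  has_nm <- !is.na(aln$nm)
  body[has_nm] <- paste0(body[has_nm], "\tNM:i:", aln$nm[has_nm])
  writeLines(c(hdr, body), path)
  invisible(path)
}
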