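## Read filtering, a built-in exact unique mapper for clean synthetic reads,
## SAM ingest for externally aligned data, and per-position allele pileups.

#' Filter and quality-trim reads
#'
#' Drops reads containing N, trims 3' bases below the quality threshold, and
#' drops reads shorter than \code{min_len} after trimming.
#'
#' @param reads ReadSet data.frame (id, seq, qual, mate).
#' @param qual_threshold Phred score below which trailing bases are trimmed.
#' @param min_len minimum surviving read length.
#' @return filtered ReadSet.
#' @export
filter_reads <- function(reads, qual_threshold = 20, min_len = 30) {
  if (nrow(reads) == 0) return(reads)
  keep <- !grepl("N", reads$seq, fixed = TRUE)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0) return(reads)
  n <- nchar(reads$qual)
  # only reads whose final base is low-quality need trimming
  last_q <- utf8ToInt(paste(substring(reads$qual, n, n), collapse = "")) - 33L
  trim <- which(last_q < qual_threshold & n > 0)
  for (i in trim) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    hi <- which(q >= qual_threshold)
    keep_to <- if (length(hi)) max(hi) else 0L
    reads$seq[i] <- substr(reads$seq[i], 1, keep_to)
    reads$qual[i] <- substr(reads$qual[i], 1, keep_to)
  }
  reads <- reads[nchar(reads$seq) >= min_len, , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

# exact full-length placements of a set of equal-or-mixed-width sequences
# against one genome; returns data.table(seq_id, chrom, start, strand)
.exact_placements <- function(genome, seqs) {
  res <- vector("list", 0)
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      L <- length(subj)
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt)) {
        st <- IRanges::start(unlist(m))
        res[[length(res) + 1L]] <- data.table::data.table(
          seq_id = idx[rep(seq_along(cnt), cnt)], chrom = ch,
          start = st, strand = "+")
      }
      mrc <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      cnt <- S4Vectors::elementNROWS(mrc)
      if (sum(cnt)) {
        erc <- IRanges::end(unlist(mrc))
        res[[length(res) + 1L]] <- data.table::data.table(
          seq_id = idx[rep(seq_along(cnt), cnt)], chrom = ch,
          start = L - erc + 1L, strand = "-")
      }
    }
  }
  if (length(res) == 0)
    return(data.table::data.table(seq_id = integer(0), chrom = character(0),
                                  start = integer(0), strand = character(0)))
  data.table::rbindlist(res)
}

.placements_to_alignments <- function(reads, seqs, plc) {
  seq_id <- NULL # R CMD check
  # uniqueness on distinct (chrom, start, strand) placements per sequence
  plc <- unique(plc, by = c("seq_id", "chrom", "start", "strand"))
  nh <- plc[, .N, by = seq_id]
  uniq <- nh$seq_id[nh$N == 1L]
  plc1 <- plc[plc$seq_id %in% uniq, ]
  map <- match(reads$seq, seqs)
  hit <- match(map, plc1$seq_id)
  ok <- !is.na(hit)
  al <- data.frame(
    id = reads$id[ok], mate = reads$mate[ok],
    chrom = plc1$chrom[hit[ok]], start = plc1$start[hit[ok]],
    strand = plc1$strand[hit[ok]], width = nchar(reads$seq[ok]),
    seq = ifelse(plc1$strand[hit[ok]] == "-", revcomp(reads$seq[ok]),
                 reads$seq[ok]),
    nhits = rep(1L, sum(ok)), unique = rep(TRUE, sum(ok)),
    stringsAsFactors = FALSE)
  rownames(al) <- NULL
  al
}

#' Map reads by exact unique full-length matching
#'
#' A read is reported iff its full sequence (or its reverse complement)
#' occurs exactly once in the genome; reads matching several loci are
#' excluded as multi-mappers, reads matching none are unmapped. Designed for
#' error-free synthetic reads; real alignments should be ingested with
#' \code{\link{read_sam}}.
#'
#' @param genome named \code{DNAStringSet}.
#' @param reads ReadSet data.frame.
#' @return AlignmentSet: data.frame(id, mate, chrom, start (1-based), strand,
#'   width, seq, nhits, unique) with \code{seq} in reference orientation.
#' @export
map_reads <- function(genome, reads) {
  if (length(genome) == 0) stopf("empty genome")
  if (nrow(reads) == 0)
    return(data.frame(id = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      strand = character(0), width = integer(0),
                      seq = character(0), nhits = integer(0),
                      unique = logical(0)))
  seqs <- unique(reads$seq)
  seqs <- seqs[!grepl("[^ACGT]", seqs)]
  plc <- .exact_placements(genome, seqs)
  .placements_to_alignments(reads, seqs, plc)
}

#' Map hybrid reads against both parental references
#'
#' The two parental haplotypes differ only by substitutions, so they share
#' one coordinate system; a read carrying either parent's alleles is placed
#' by taking the union of its exact placements on the two references, with
#' uniqueness judged on distinct (chrom, start, strand) loci. This is the
#' package's mismatch-tolerant stand-in for aligning hybrid reads to a single
#' reference.
#'
#' @param genome_a,genome_b the two parental references (same names/lengths).
#' @param reads ReadSet.
#' @return AlignmentSet as in \code{\link{map_reads}}.
#' @export
map_reads_hybrid <- function(genome_a, genome_b, reads) {
  if (length(genome_a) == 0 || length(genome_b) == 0) stopf("empty genome")
  if (nrow(reads) == 0) return(map_reads(genome_a, reads))
  seqs <- unique(reads$seq)
  seqs <- seqs[!grepl("[^ACGT]", seqs)]
  plc <- data.table::rbindlist(list(.exact_placements(genome_a, seqs),
                                    .exact_placements(genome_b, seqs)))
  .placements_to_alignments(reads, seqs, plc)
}

# aligned reference length from a CIGAR string (M/=/X/D/N consume reference)
.cigar_ref_len <- function(cigar, fallback) {
  if (cigar == "*") return(fallback)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0) return(NA_integer_)
  n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "=", "X", "D", "N")])
}

#' Read alignments from a SAM file
#'
#' Minimal SAM ingest: primary mapped records are converted to the internal
#' AlignmentSet (1-based starts); records below the MAPQ floor are flagged
#' non-unique. Unmapped, secondary and supplementary records are skipped.
#'
#' @param path SAM file with a header.
#' @param mapq_floor records with MAPQ below this are flagged non-unique.
#' @return AlignmentSet data.frame.
#' @export
read_sam <- function(path, mapq_floor = 20) {
  ln <- readLines(path)
  hdr <- grepl("^@", ln)
  if (!any(hdr) || !hdr[1])
    stopf("SAM file %s is missing a header", path)
  rec_lines <- which(!hdr)
  out <- vector("list", length(rec_lines))
  for (i in seq_along(rec_lines)) {
    lno <- rec_lines[i]
    f <- strsplit(ln[lno], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stopf("malformed SAM record at line %d of %s", lno, path)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos))
      stopf("malformed SAM record at line %d of %s", lno, path)
    if (bitwAnd(flag, 4L) > 0) next       # unmapped
    if (bitwAnd(flag, 256L) > 0) next     # secondary
    if (bitwAnd(flag, 2048L) > 0) next    # supplementary
    w <- .cigar_ref_len(f[6], nchar(f[10]))
    if (is.na(w)) stopf("malformed CIGAR at line %d of %s", lno, path)
    mate <- if (bitwAnd(flag, 64L) > 0) 1L else if (bitwAnd(flag, 128L) > 0) 2L else 0L
    out[[i]] <- data.frame(
      id = f[1], mate = mate, chrom = f[3], start = pos,
      strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
      width = w, seq = f[10], nhits = NA_integer_,
      unique = !is.na(mapq) && mapq >= mapq_floor,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(id = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      strand = character(0), width = integer(0),
                      seq = character(0), nhits = integer(0),
                      unique = logical(0)))
  do.call(rbind, out)
}

#' Build a per-position allele pileup
#'
#' Counts A/C/G/T observations from unique alignments at the requested
#' positions (or at every covered position). The read base is taken as
#' aligned, mismatches included, with no realignment.
#'
#' @param alignments AlignmentSet; only rows with \code{unique = TRUE} are
#'   consumed.
#' @param positions optional data.frame(chrom, pos) restricting the pileup.
#' @param seqlengths optional named lengths used to validate positions.
#' @return Pileup: data.frame(chrom, pos, A, C, G, T).
#' @export
build_pileup <- function(alignments, positions = NULL, seqlengths = NULL) {
  al <- alignments[alignments$unique, , drop = FALSE]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0))
  if (nrow(al) == 0) return(empty)
  if (!is.null(positions) && !is.null(seqlengths)) {
    bad <- positions$pos < 1 | positions$pos > seqlengths[positions$chrom]
    if (any(bad))
      stopf("position %s:%d outside chromosome", positions$chrom[bad][1],
            positions$pos[bad][1])
  }
  res <- vector("list", 0)
  for (ch in unique(al$chrom)) {
    a <- al[al$chrom == ch, , drop = FALSE]
    if (is.null(positions)) {
      cov <- IRanges::reduce(IRanges::IRanges(a$start, a$start + a$width - 1L))
      pos <- unlist(lapply(seq_along(cov), function(i)
        IRanges::start(cov)[i]:IRanges::end(cov)[i]))
    } else {
      pos <- positions$pos[positions$chrom == ch]
    }
    if (length(pos) == 0) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(pos, pos),
                                IRanges::IRanges(a$start, a$start + a$width - 1L))
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    off <- pos[qi] - a$start[si] + 1L
    base <- substring(a$seq[si], off, off)
    dt <- data.table::data.table(pos = pos[qi], base = base)
    dt <- dt[dt$base %in% c("A", "C", "G", "T"), ]
    tab <- data.table::dcast(dt[, .N, by = c("pos", "base")],
                             pos ~ base, value.var = "N", fill = 0L)
    for (b in c("A", "C", "G", "T"))
      if (!b %in% names(tab)) tab[[b]] <- 0L
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch, pos = tab$pos, A = tab$A, C = tab$C, G = tab$G, T = tab$T,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write an AlignmentSet as TSV
#' @param alignments AlignmentSet.
#' @param path output file.
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
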