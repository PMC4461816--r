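## Breakpoint detection at fine bin resolution, local greedy assembly of
## junction-spanning contigs, split alignment to the reference, and junction
## classification (microhomology / blunt / insertion, inversion orientation,
## chimeric-gene potential).

#' Detect breakpoints from fine-binned copy segments
#'
#' Emits one breakpoint per copy-state transition, placed at the boundary
#' between the two bins flanking the transition.
#'
#' @param segments CopySegment table from \code{\link{segment_profile}} on a
#'   fine-binned (<= 1000 bp) profile.
#' @return data.frame(chrom, pos, left_state, right_state).
#' @export
detect_breakpoints <- function(segments) {
  out <- lapply(unique(segments$chrom), function(ch) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) < 2)
      return(data.frame(chrom = character(0), pos = integer(0),
                        left_state = integer(0), right_state = integer(0)))
    i <- seq_len(nrow(s) - 1L)
    data.frame(chrom = ch, pos = s$end[i],
               left_state = s$state[i], right_state = s$state[i + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract reads around a breakpoint, including their mates
#'
#' Returns every read whose alignment start falls within \code{radius} of
#' the breakpoint, together with its mate wherever the mate maps (or fails
#' to map - junction-spanning mates are typically unmapped and carry the
#' junction sequence).
#'
#' @param alignments AlignmentSet of the sample.
#' @param reads full ReadSet of the sample (mates share the id).
#' @param chrom,pos breakpoint location.
#' @param radius window half-width in bp (default 2000).
#' @return ReadSet subset with an extra logical column \code{mapped}.
#' @export
extract_breakpoint_reads <- function(alignments, reads, chrom, pos,
                                     radius = 2000) {
  lo <- max(1, pos - radius)
  hi <- pos + radius
  sel <- alignments$chrom == chrom & alignments$start >= lo &
    alignments$start <= hi & alignments$unique
  ids <- unique(alignments$id[sel])
  out <- reads[reads$id %in% ids, , drop = FALSE]
  mapped_keys <- paste(alignments$id, alignments$mate)
  out$mapped <- paste(out$id, out$mate) %in% mapped_keys
  rownames(out) <- NULL
  out
}

#' Greedy local assembly from exact suffix-prefix overlaps
#'
#' Builds maximal contigs by repeatedly extending a seed read with reads
#' whose prefix matches the contig's suffix exactly over at least
#' \code{min_overlap} bases; both orientations are considered. Intended for
#' error-free or very-low-error reads around a breakpoint. Contigs shorter
#' than twice the longest read length, or supported by fewer than
#' \code{min_reads} distinct reads, are discarded.
#'
#' @param reads ReadSet (the \code{seq} column is used).
#' @param min_overlap minimum exact overlap in bp (>= 15).
#' @param min_reads minimum distinct supporting reads per contig.
#' @param seeds optional character vector of sequences to seed contigs from
#'   (e.g. unmapped junction-spanning mates); defaults to all reads.
#' @param max_len safety cap on contig length.
#' @return data.frame(contig, support); zero rows when no junction-scale
#'   contig can be built.
#' @export
assemble_local <- function(reads, min_overlap = 31, min_reads = 2,
                           seeds = NULL, max_len = 20000) {
  if (min_overlap < 15) stopf("min_overlap must be >= 15")
  seqs <- unique(reads$seq[!grepl("[^ACGT]", reads$seq)])
  seqs <- seqs[nchar(seqs) > min_overlap]
  if (length(seqs) == 0)
    return(data.frame(contig = character(0), support = integer(0)))
  read_len_max <- max(nchar(seqs))
  pool <- c(seqs, revcomp(seqs))
  n_fwd <- length(seqs)
  K <- min_overlap
  # hash: K-prefix -> pool indices
  pref_env <- new.env(hash = TRUE, parent = emptyenv())
  pref <- substr(pool, 1, K)
  for (i in seq_along(pool)) {
    p <- pref[i]
    pref_env[[p]] <- c(pref_env[[p]], i)
  }
  used <- logical(length(pool))
  mark_used <- function(i) {
    used[i] <<- TRUE
    j <- if (i <= n_fwd) i + n_fwd else i - n_fwd
    used[j] <<- TRUE
  }

  # one rightwards extension step: longest-extension-first among overlaps >= K
  extend_right_once <- function(contig) {
    n <- nchar(contig)
    for (v in K:min(read_len_max - 1L, n)) {
      key <- substr(contig, n - v + 1L, n - v + K)
      cand <- pref_env[[key]]
      if (is.null(cand)) next
      for (ci in cand) {
        L <- nchar(pool[ci])
        if (L <= v) next
        if (v == K || substr(pool[ci], 1, v) == substr(contig, n - v + 1L, n)) {
          return(paste0(contig, substr(pool[ci], v + 1L, L)))
        }
      }
    }
    NULL
  }
  extend_right <- function(contig) {
    repeat {
      if (nchar(contig) >= max_len) break
      nxt <- extend_right_once(contig)
      if (is.null(nxt)) break
      contig <- nxt
    }
    contig
  }
  # reads fully contained in the contig (either orientation) support it
  mark_contained <- function(contig) {
    n <- nchar(contig)
    hits <- integer(0)
    if (n < K) return(0L)
    for (j in 1:(n - K + 1L)) {
      key <- substr(contig, j, j + K - 1L)
      cand <- pref_env[[key]]
      if (is.null(cand)) next
      for (ci in cand) {
        L <- nchar(pool[ci])
        if (j + L - 1L <= n &&
            substr(contig, j, j + L - 1L) == pool[ci]) {
          hits <- c(hits, ci)
          mark_used(ci)
        }
      }
    }
    canon <- ifelse(hits > n_fwd, hits - n_fwd, hits)
    length(unique(canon))
  }

  seed_seqs <- if (is.null(seeds)) pool[seq_len(n_fwd)] else
    unique(seeds[!grepl("[^ACGT]", seeds)])
  contigs <- character(0)
  support <- integer(0)
  for (s in seed_seqs) {
    si <- match(s, pool)
    if (!is.na(si) && used[si]) next
    if (nchar(s) <= K) next
    ctg <- extend_right(s)
    ctg <- revcomp(extend_right(revcomp(ctg)))
    sup <- mark_contained(ctg)
    contigs <- c(contigs, ctg)
    support <- c(support, sup)
  }
  keep <- support >= min_reads & nchar(contigs) >= 2L * read_len_max
  contigs <- contigs[keep]
  support <- support[keep]
  if (length(contigs) == 0)
    return(data.frame(contig = character(0), support = integer(0)))
  # canonical orientation + drop contigs contained in longer ones
  canon <- pmin(contigs, revcomp(contigs))
  o <- order(-nchar(canon))
  canon <- canon[o]; support <- support[o]
  dup <- duplicated(canon)
  for (i in seq_along(canon)) {
    if (dup[i]) next
    for (j in seq_len(i - 1L)) {
      if (dup[j]) next
      if (grepl(canon[i], canon[j], fixed = TRUE) ||
          grepl(revcomp(canon[i]), canon[j], fixed = TRUE)) {
        dup[i] <- TRUE
        break
      }
    }
  }
  data.frame(contig = canon[!dup], support = support[!dup],
             stringsAsFactors = FALSE)
}

#' Precompute string caches for anchoring contigs on a genome
#'
#' When a second haplotype is supplied (same chromosome names and lengths,
#' differing only by substitutions), anchoring and extension accept a base
#' matching either haplotype, so contigs assembled from hybrid reads are not
#' broken at SNPs.
#'
#' @param genome named \code{DNAStringSet}.
#' @param genome_alt optional second haplotype.
#' @return an opaque index object reusable across
#'   \code{\link{split_align}} / \code{\link{chain_contig}} calls.
#' @export
genome_index <- function(genome, genome_alt = NULL) {
  idx <- list(dna = genome,
              str = stats::setNames(as.character(genome), names(genome)),
              rcdna = Biostrings::reverseComplement(genome),
              rcstr = stats::setNames(
                as.character(Biostrings::reverseComplement(genome)),
                names(genome)))
  if (!is.null(genome_alt)) {
    stopifnot(identical(names(genome_alt), names(genome)))
    idx$dna2 <- genome_alt
    idx$str2 <- stats::setNames(as.character(genome_alt), names(genome_alt))
    idx$rcdna2 <- Biostrings::reverseComplement(genome_alt)
    idx$rcstr2 <- stats::setNames(
      as.character(Biostrings::reverseComplement(genome_alt)),
      names(genome_alt))
  }
  idx
}

# first index at which `con` differs from both reference haplotypes, 0 if
# it matches throughout
.first_mismatch2 <- function(ref1, ref2, con) {
  rc <- charToRaw(con)
  d <- charToRaw(ref1) != rc
  if (!is.null(ref2)) d <- d & (charToRaw(ref2) != rc)
  w <- which(d)
  if (length(w)) w[1] else 0L
}

# longest exact match of the contig prefix anywhere in the genome (either
# strand, either haplotype); returns placement(s) with maximal matched length
.prefix_anchor <- function(contig, idx, min_anchor) {
  p0 <- Biostrings::DNAString(substr(contig, 1, min_anchor))
  n <- nchar(contig)
  best <- list()
  best_len <- 0L
  two <- !is.null(idx$str2)
  consider <- function(s, ch, rcspace) {
    chr_str <- if (rcspace) idx$rcstr[[ch]] else idx$str[[ch]]
    chr_str2 <- if (!two) NULL else if (rcspace) idx$rcstr2[[ch]] else idx$str2[[ch]]
    L <- nchar(chr_str)
    avail <- min(n, L - s + 1L)
    ref_seg <- substr(chr_str, s, s + avail - 1L)
    ref_seg2 <- if (two) substr(chr_str2, s, s + avail - 1L) else NULL
    con_seg <- substr(contig, 1, avail)
    mm <- .first_mismatch2(ref_seg, ref_seg2, con_seg)
    len <- if (mm == 0L) avail else mm - 1L
    pl <- if (!rcspace)
      list(chrom = ch, start = s, end = s + len - 1L, strand = "+", len = len)
    else
      # rc-space [s, s+len-1] -> fwd-space [L-s-len+2, L-s+1]
      list(chrom = ch, start = L - (s + len - 1L) + 1L, end = L - s + 1L,
           strand = "-", len = len)
    if (len > best_len) { best <<- list(pl); best_len <<- len }
    else if (len == best_len) best[[length(best) + 1L]] <<- pl
  }
  for (ch in names(idx$dna)) {
    starts <- IRanges::start(Biostrings::matchPattern(p0, idx$dna[[ch]]))
    if (two) starts <- union(starts,
      IRanges::start(Biostrings::matchPattern(p0, idx$dna2[[ch]])))
    for (s in starts) consider(s, ch, rcspace = FALSE)
    starts <- IRanges::start(Biostrings::matchPattern(p0, idx$rcdna[[ch]]))
    if (two) starts <- union(starts,
      IRanges::start(Biostrings::matchPattern(p0, idx$rcdna2[[ch]])))
    for (s in starts) consider(s, ch, rcspace = TRUE)
  }
  if (best_len < min_anchor) return(NULL)
  best
}

# among equally long placements, prefer the one whose junction-side
# coordinate is nearest the hint; flag a surviving tie as ambiguous
.pick_placement <- function(cands, side, hint) {
  if (is.null(cands)) return(NULL)
  if (length(cands) == 1L) return(c(cands[[1]], list(ambiguous = FALSE)))
  if (!is.null(hint)) {
    d <- vapply(cands, function(p) {
      if (p$chrom != hint$chrom) return(Inf)
      jpos <- if (side == "prefix") {
        if (p$strand == "+") p$end else p$start
      } else {
        if (p$strand == "+") p$start else p$end
      }
      abs(jpos - hint$pos)
    }, 0)
    if (sum(d == min(d)) == 1L)
      return(c(cands[[which.min(d)]], list(ambiguous = FALSE)))
  }
  c(cands[[1]], list(ambiguous = TRUE))
}

#' Decompose a contig into reference segments and the junctions between them
#'
#' Walks the contig left to right: anchors the longest exact prefix match,
#' then repeatedly locates the next reference segment by suffix-anchoring a
#' chunk just beyond the current segment and extending it maximally. Each
#' adjacent segment pair defines one junction whose contig overlap (or gap)
#' gives its chemistry. Contigs assembled across several closely spaced
#' junctions are thereby resolved into all of them.
#'
#' @param contig contig sequence.
#' @param genome named \code{DNAStringSet} reference.
#' @param min_anchor minimum anchor length in bp.
#' @param mh_max largest junction overlap searched for (>= the microhomology
#'   band maximum).
#' @param max_gap largest insertion searched for between segments.
#' @param hint optional list(chrom, pos) to break placement ties.
#' @param genome_alt optional second haplotype (see
#'   \code{\link{genome_index}}).
#' @param .idx optional \code{\link{genome_index}} for repeated calls.
#' @return list of segments, each list(chrom, start, end, strand, len,
#'   ambiguous, c_start, c_end); a single segment means the contig is
#'   reference-concordant. NULL when no anchor of \code{min_anchor} exists.
#' @export
chain_contig <- function(contig, genome, min_anchor = 30, mh_max = 20,
                         max_gap = 200, hint = NULL, genome_alt = NULL,
                         .idx = NULL) {
  idx <- if (is.null(.idx)) genome_index(genome, genome_alt) else .idx
  n <- nchar(contig)
  if (n < 2 * min_anchor) return(NULL)
  flip <- function(s) if (s == "+") "-" else "+"
  # extend a placement rightwards along the contig by direct base comparison
  # (a base matching either haplotype continues the match)
  extend_fwd <- function(seg) {
    chr_str <- idx$str[[seg$chrom]]
    chr_str2 <- if (is.null(idx$str2)) NULL else idx$str2[[seg$chrom]]
    L <- nchar(chr_str)
    ref_at <- function(str, p) {
      if (seg$strand == "+") substr(str, p, p) else comp_base(substr(str, p, p))
    }
    repeat {
      if (seg$c_end >= n) break
      p <- if (seg$strand == "+") seg$end + 1L else seg$start - 1L
      if (p < 1L || p > L) break
      cb <- substr(contig, seg$c_end + 1L, seg$c_end + 1L)
      ok <- cb == ref_at(chr_str, p) ||
        (!is.null(chr_str2) && cb == ref_at(chr_str2, p))
      if (!ok) break
      seg$c_end <- seg$c_end + 1L
      seg$len <- seg$len + 1L
      if (seg$strand == "+") seg$end <- seg$end + 1L else seg$start <- seg$start - 1L
    }
    seg
  }
  a1 <- .pick_placement(.prefix_anchor(contig, idx, min_anchor), "prefix", hint)
  if (is.null(a1)) return(NULL)
  a1$c_start <- 1L
  a1$c_end <- a1$len
  segs <- list(a1)
  repeat {
    cur <- segs[[length(segs)]]
    if (n - cur$c_end < min_anchor) break
    chunk_start <- max(cur$c_start + 1L, cur$c_end - mh_max + 1L)
    chunk_end <- min(n, cur$c_end + max_gap + 2L * min_anchor)
    chunk <- substr(contig, chunk_start, chunk_end)
    if (nchar(chunk) < min_anchor) break
    sac <- .prefix_anchor(revcomp(chunk), idx, min_anchor)
    if (is.null(sac)) break
    sac <- lapply(sac, function(p) { p$strand <- flip(p$strand); p })
    s2 <- .pick_placement(sac, "suffix", hint)
    s2$c_end <- chunk_end
    s2$c_start <- chunk_end - s2$len + 1L
    if (s2$c_start <= cur$c_start) break
    s2 <- extend_fwd(s2)
    segs[[length(segs) + 1L]] <- s2
  }
  segs
}

#' Junctions encoded by a chained contig
#'
#' @param segs segment chain from \code{\link{chain_contig}}.
#' @param contig the contig sequence the chain was computed from.
#' @param mh_min minimum overlap classified as microhomology.
#' @return junction data.frame (zero rows for a concordant contig).
#' @export
chain_junctions <- function(segs, contig, mh_min = 2) {
  out <- NULL
  if (is.null(segs) || length(segs) < 2) {
    return(data.frame(
      chrom_left = character(0), pos_left = integer(0),
      side_left = character(0), strand_left = character(0),
      chrom_right = character(0), pos_right = integer(0),
      side_right = character(0), strand_right = character(0),
      type = character(0), mh_len = integer(0), ins_len = integer(0),
      insertion_seq = character(0), inverted = logical(0),
      ambiguous = logical(0), contig = character(0)))
  }
  for (i in seq_len(length(segs) - 1L)) {
    L <- segs[[i]]; R <- segs[[i + 1L]]
    o <- L$c_end - R$c_start + 1L
    type <- if (o >= mh_min) "microhomology"
            else if (o >= 0) "blunt"
            else "insertion"
    middle <- if (o < 0) substr(contig, L$c_end + 1L, R$c_start - 1L) else ""
    left <- if (L$strand == "+") list(pos = L$end, side = "upstream") else
      list(pos = L$start, side = "downstream")
    right <- if (R$strand == "+") list(pos = R$start, side = "downstream") else
      list(pos = R$end, side = "upstream")
    out <- rbind(out, data.frame(
      chrom_left = L$chrom, pos_left = left$pos, side_left = left$side,
      strand_left = L$strand,
      chrom_right = R$chrom, pos_right = right$pos, side_right = right$side,
      strand_right = R$strand,
      type = type,
      mh_len = if (type == "microhomology") o else 0L,
      ins_len = if (type == "insertion") -o else 0L,
      insertion_seq = middle,
      inverted = L$strand != R$strand,
      ambiguous = isTRUE(L$ambiguous) || isTRUE(R$ambiguous),
      contig = contig,
      stringsAsFactors = FALSE))
  }
  out
}

#' Split-align a contig against the reference
#'
#' Finds the longest exact match of the contig's prefix to the reference
#' (either strand) and likewise for its suffix, reporting both placements,
#' the contig overlap between them (negative overlap = gap), and any middle
#' bases claimed by neither anchor. Ambiguous equally long placements are
#' resolved toward \code{hint} (a nearby dosage breakpoint) when given,
#' otherwise the contig is flagged ambiguous.
#'
#' @param contig contig sequence.
#' @param genome named \code{DNAStringSet} reference.
#' @param min_anchor minimum anchor length in bp (default 30).
#' @param hint optional list(chrom, pos) used to break placement ties.
#' @param genome_alt optional second haplotype (see
#'   \code{\link{genome_index}}).
#' @param .idx optional \code{\link{genome_index}} for repeated calls.
#' @return list(prefix, suffix, overlap, middle, concordant, ambiguous), or
#'   \code{NULL} when either anchor is shorter than \code{min_anchor}.
#' @export
split_align <- function(contig, genome, min_anchor = 30, hint = NULL,
                        genome_alt = NULL, .idx = NULL) {
  if (nchar(contig) < 2 * min_anchor)
    stopf("contig shorter than 2 * min_anchor")
  idx <- if (is.null(.idx)) genome_index(genome, genome_alt) else .idx
  pre <- .pick_placement(.prefix_anchor(contig, idx, min_anchor), "prefix",
                         hint)
  # suffix anchor via the prefix of the reverse complement: a placement of
  # revcomp(contig)'s prefix at (chrom, s..e, strand) is a placement of the
  # contig's suffix at the same interval on the opposite strand
  sufrc <- .prefix_anchor(revcomp(contig), idx, min_anchor)
  if (!is.null(sufrc))
    sufrc <- lapply(sufrc, function(p) {
      p$strand <- if (p$strand == "+") "-" else "+"
      p
    })
  suf <- .pick_placement(sufrc, "suffix", hint)
  if (is.null(pre) || is.null(suf)) return(NULL)
  n <- nchar(contig)
  overlap <- pre$len + suf$len - n
  middle <- if (overlap < 0)
    substr(contig, pre$len + 1L, n - suf$len) else ""
  concordant <- pre$len == n ||
    (pre$chrom == suf$chrom && pre$strand == suf$strand &&
     overlap >= 0 &&
     ((pre$strand == "+" && suf$start - pre$start == n - suf$len) ||
      (pre$strand == "-" && pre$start - suf$start == n - pre$len)))
  list(prefix = pre, suffix = suf, overlap = overlap, middle = middle,
       concordant = concordant,
       ambiguous = isTRUE(pre$ambiguous) || isTRUE(suf$ambiguous))
}

#' Classify a split-aligned contig as a breakpoint junction
#'
#' Overlap >= 2 bp between the anchors is microhomology (the overlap length
#' is the microhomology tract); overlap of 0 or 1 bp with no gap is a blunt
#' fusion; a gap is an insertion whose middle bases are the inserted
#' sequence. The junction is inverted when the two anchors align to opposite
#' strands (head-to-head or tail-to-tail fusion).
#'
#' @param split result of \code{\link{split_align}}.
#' @param mh_min minimum overlap called microhomology (default 2).
#' @param contig optional contig sequence carried through to the output.
#' @return one-row Junction data.frame.
#' @export
classify_junction <- function(split, mh_min = 2, contig = NA_character_) {
  if (is.null(split)) stopf("split alignment failed; nothing to classify")
  pre <- split$prefix
  suf <- split$suffix
  o <- split$overlap
  type <- if (o >= mh_min) "microhomology"
          else if (o >= 0) "blunt"
          else "insertion"
  left <- if (pre$strand == "+")
    list(pos = pre$end, side = "upstream") else
    list(pos = pre$start, side = "downstream")
  right <- if (suf$strand == "+")
    list(pos = suf$start, side = "downstream") else
    list(pos = suf$end, side = "upstream")
  data.frame(
    chrom_left = pre$chrom, pos_left = left$pos, side_left = left$side,
    strand_left = pre$strand,
    chrom_right = suf$chrom, pos_right = right$pos, side_right = right$side,
    strand_right = suf$strand,
    type = type,
    mh_len = if (type == "microhomology") o else 0L,
    ins_len = if (type == "insertion") -o else 0L,
    insertion_seq = if (type == "insertion") split$middle else "",
    inverted = pre$strand != suf$strand,
    ambiguous = split$ambiguous,
    contig = contig,
    stringsAsFactors = FALSE)
}

#' Canonical orientation of a junction table
#'
#' A junction read from the reverse-complemented contig swaps its anchors
#' and flips both strands; canonicalisation orders the anchors (chromosome,
#' then position) so equivalent junctions compare equal.
#'
#' @param j junction data.frame (as from \code{\link{classify_junction}} or
#'   the simulator truth table).
#' @return the same table with anchors in canonical order.
#' @export
canonical_junctions <- function(j) {
  if (nrow(j) == 0) return(j)
  flip <- j$chrom_left > j$chrom_right |
    (j$chrom_left == j$chrom_right & j$pos_left > j$pos_right)
  sw <- function(a, b, f) list(ifelse(f, b, a), ifelse(f, a, b))
  flip_strand <- function(s) ifelse(s == "+", "-", "+")
  out <- j
  tmp <- sw(j$chrom_left, j$chrom_right, flip)
  out$chrom_left <- tmp[[1]]; out$chrom_right <- tmp[[2]]
  tmp <- sw(j$pos_left, j$pos_right, flip)
  out$pos_left <- tmp[[1]]; out$pos_right <- tmp[[2]]
  tmp <- sw(j$side_left, j$side_right, flip)
  out$side_left <- tmp[[1]]; out$side_right <- tmp[[2]]
  tmp <- sw(flip_strand(j$strand_left), flip_strand(j$strand_right), flip)
  out$strand_left <- ifelse(flip, tmp[[1]], j$strand_left)
  out$strand_right <- ifelse(flip, tmp[[2]], j$strand_right)
  if ("insertion_seq" %in% names(out))
    out$insertion_seq <- ifelse(flip & out$insertion_seq != "",
                                revcomp(out$insertion_seq),
                                out$insertion_seq)
  out
}

#' Match called junctions against a truth table
#'
#' Junctions match when their canonical anchors agree within \code{tol} bp.
#'
#' @param called,truth junction tables.
#' @param tol coordinate tolerance in bp.
#' @return data.frame with one row per truth junction: matched flag plus the
#'   called type/mh_len/ins_len for matched rows.
#' @export
match_junctions <- function(called, truth, tol = 1) {
  tr <- canonical_junctions(truth)
  ca <- canonical_junctions(called)
  ca_ins <- if ("ins_len" %in% names(ca)) ca$ins_len else
    nchar(ca$insertion_seq)
  out <- tr
  out$matched <- FALSE
  out$called_type <- NA_character_
  out$called_mh_len <- NA_integer_
  out$called_ins_len <- NA_integer_
  used <- logical(nrow(ca))
  for (i in seq_len(nrow(tr))) {
    hit <- which(!used &
                 ca$chrom_left == tr$chrom_left[i] &
                 ca$chrom_right == tr$chrom_right[i] &
                 abs(ca$pos_left - tr$pos_left[i]) <= tol &
                 abs(ca$pos_right - tr$pos_right[i]) <= tol)
    if (length(hit) == 0) next
    # truth junctions can sit within tol of one another: prefer the
    # candidate agreeing in type and signature, then the nearest one
    agree <- ca$type[hit] == tr$type[i] &
      ca$mh_len[hit] == tr$mh_len[i] &
      (tr$type[i] != "insertion" | ca_ins[hit] == tr$ins_len[i])
    dist <- abs(ca$pos_left[hit] - tr$pos_left[i]) +
      abs(ca$pos_right[hit] - tr$pos_right[i])
    h <- hit[order(!agree, dist)][1]
    used[h] <- TRUE
    out$matched[i] <- TRUE
    out$called_type[i] <- ca$type[h]
    out$called_mh_len[i] <- ca$mh_len[h]
    out$called_ins_len[i] <- ca_ins[h]
  }
  out
}

#' Summarise a junction set
#'
#' Counts junctions by type, reports the inversion fraction, histograms of
#' microhomology lengths and of insertion lengths in 25 bp bins, and (when
#' block sizes are supplied) a two-sided comparison of duplicated versus
#' triplicated block sizes.
#'
#' @param junctions junction table.
#' @param dup_sizes,trip_sizes optional numeric vectors of duplicated
#'   (state 3) and triplicated (state 4) block sizes in bp.
#' @return list(counts, n, inversion_fraction, mh_hist, ins_hist,
#'   block_test).
#' @export
summarize_junctions <- function(junctions, dup_sizes = NULL,
                                trip_sizes = NULL) {
  n <- nrow(junctions)
  counts <- table(factor(junctions$type,
                         levels = c("microhomology", "blunt", "insertion")))
  inv <- if (n > 0) mean(junctions$inverted) else NA_real_
  mh <- junctions$mh_len[junctions$type == "microhomology"]
  ins_len <- if ("ins_len" %in% names(junctions))
    junctions$ins_len[junctions$type == "insertion"] else
    nchar(junctions$insertion_seq[junctions$type == "insertion"])
  ins_hist <- if (length(ins_len))
    table(cut(ins_len, breaks = seq(0, 25 * ceiling(max(ins_len) / 25), 25)))
  else table(numeric(0))
  block_test <- NULL
  if (!is.null(dup_sizes) && !is.null(trip_sizes)) {
    if (length(dup_sizes) < 2 || length(trip_sizes) < 2)
      stopf("need >= 2 blocks per class for the size comparison")
    w <- stats::wilcox.test(dup_sizes, trip_sizes, exact = FALSE)
    tt <- stats::t.test(dup_sizes, trip_sizes)
    block_test <- list(p_wilcox = w$p.value, p_t = tt$p.value,
                       median_dup = stats::median(dup_sizes),
                       median_trip = stats::median(trip_sizes),
                       n_dup = length(dup_sizes),
                       n_trip = length(trip_sizes))
  }
  list(counts = counts, n = n, inversion_fraction = inv,
       mh_hist = table(mh), ins_hist = ins_hist, block_test = block_test)
}

#' Predict whether a junction creates a chimeric gene
#'
#' TRUE iff each anchor's retained side lies within a gene body and the two
#' genes read in the same direction across the junction after applying the
#' anchors' strand relation.
#'
#' @param junctions junction table.
#' @param genes \code{GRanges} of gene bodies with strand.
#' @return logical vector, one element per junction.
#' @export
predict_chimeric <- function(junctions, genes) {
  if (nrow(junctions) == 0) return(logical(0))
  gd <- as.data.frame(genes)
  gch <- as.character(gd$seqnames)
  gs <- gd$start
  ge <- gd$end
  gstr <- as.character(gd$strand)
  hit_genes <- function(ch, pos) which(gch == ch & gs <= pos & ge >= pos)
  vapply(seq_len(nrow(junctions)), function(i) {
    gl <- hit_genes(junctions$chrom_left[i], junctions$pos_left[i])
    gr <- hit_genes(junctions$chrom_right[i], junctions$pos_right[i])
    if (length(gl) == 0 || length(gr) == 0) return(FALSE)
    rel_l <- gstr[gl] == junctions$strand_left[i]
    rel_r <- gstr[gr] == junctions$strand_right[i]
    any(outer(rel_l, rel_r, "=="))
  }, TRUE)
}

#' Read a junction table TSV
#'
#' Reads a junction table in the truth-set schema (chrom_left, pos_left,
#' side_left, strand_left, chrom_right, pos_right, side_right, strand_right,
#' type, mh_len, ins_len, insertion_seq, inverted), e.g. a user-supplied
#' supplementary junction list.
#'
#' @param path TSV file.
#' @return junction data.frame.
#' @export
read_junction_table <- function(path) {
  j <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom_left", "pos_left", "chrom_right", "pos_right", "type",
            "inverted")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stopf("junction table %s lacks columns: %s", path,
          paste(miss, collapse = ", "))
  if (is.character(j$inverted))
    j$inverted <- toupper(j$inverted) %in% c("TRUE", "T", "YES", "1")
  j
}
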