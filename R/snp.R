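## Parent-diagnostic SNP discovery from hybrid and parental pileups,
## per-read parental assignment, 1 Mb parentage binning, and integration
## with copy-state segments.
##
## Thresholds follow the hybrid SNP-calling scheme: a position is diagnostic
## when the hybrid control shows two alleles at adequate depth, both parents
## are homozygous for different alleles, and both parental libraries cover
## the position.

#' Identify parent-diagnostic SNPs from three pileups
#'
#' A position is retained iff the hybrid pileup has depth >=
#' \code{min_hybrid_depth} with exactly two alleles above the noise floor,
#' each representing at least \code{min_allele_frac} of the calls; each
#' parent shows a single allele at >= \code{min_parent_hom} of its calls at
#' depth >= \code{min_depth_a} (parent A) / \code{min_depth_b} (parent B);
#' and the two parental alleles differ and match the hybrid's two alleles.
#'
#' @param hybrid,parent_a,parent_b pileups over the same reference
#'   (see \code{\link{build_pileup}}).
#' @param min_hybrid_depth minimum hybrid depth (default 25).
#' @param min_allele_frac minimum fraction for each hybrid allele (0.40).
#' @param min_parent_hom minimum parental major-allele fraction (0.97).
#' @param min_depth_a,min_depth_b minimum parental depths (6 and 1).
#' @param noise_frac alleles below this fraction of hybrid calls are treated
#'   as noise when counting alleles.
#' @return SnpTable: data.frame(chrom, pos, allele_a, allele_b), sorted.
#' @export
identify_snps <- function(hybrid, parent_a, parent_b,
                          min_hybrid_depth = 25, min_allele_frac = 0.40,
                          min_parent_hom = 0.97, min_depth_a = 6,
                          min_depth_b = 1, noise_frac = 0.05) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      allele_a = character(0), allele_b = character(0))
  if (nrow(hybrid) == 0) return(empty)
  bases <- c("A", "C", "G", "T")
  key <- function(p) paste(p$chrom, p$pos)
  ka <- match(key(hybrid), key(parent_a))
  kb <- match(key(hybrid), key(parent_b))
  H <- as.matrix(hybrid[, bases])
  dH <- rowSums(H)
  fH <- H / pmax(dH, 1)
  n_alleles <- rowSums(H > 0 & fH >= noise_frac)
  two_ok <- dH >= min_hybrid_depth & n_alleles == 2 &
    rowSums(fH >= min_allele_frac) == 2
  major <- function(p, idx) {
    M <- matrix(0, nrow(hybrid), 4, dimnames = list(NULL, bases))
    ok <- !is.na(idx)
    M[ok, ] <- as.matrix(p[idx[ok], bases])
    M
  }
  A <- major(parent_a, ka)
  B <- major(parent_b, kb)
  dA <- rowSums(A); dB <- rowSums(B)
  majA <- bases[max.col(A, ties.method = "first")]
  majB <- bases[max.col(B, ties.method = "first")]
  fA <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))] / pmax(dA, 1)
  fB <- B[cbind(seq_len(nrow(B)), max.col(B, ties.method = "first"))] / pmax(dB, 1)
  par_ok <- dA >= min_depth_a & dB >= min_depth_b &
    fA >= min_parent_hom & fB >= min_parent_hom & majA != majB
  # the two hybrid alleles must be exactly the two parental alleles
  alle_ok <- rep(FALSE, nrow(H))
  cand <- which(two_ok & par_ok)
  for (i in cand) {
    ai <- match(majA[i], bases); bi <- match(majB[i], bases)
    alle_ok[i] <- H[i, ai] > 0 && H[i, bi] > 0 &&
      fH[i, ai] >= min_allele_frac && fH[i, bi] >= min_allele_frac
  }
  keep <- two_ok & par_ok & alle_ok
  out <- data.frame(chrom = hybrid$chrom[keep], pos = hybrid$pos[keep],
                    allele_a = majA[keep], allele_b = majB[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Assign reads to parents at diagnostic SNPs
#'
#' Each unique alignment overlapping a SNP yields one call per overlapped
#' SNP: parent A if the read base matches the A allele, parent B for the B
#' allele, and \code{na} if it matches neither. A read whose bases match
#' different parents at different SNPs is conservatively reported \code{na}
#' at all its SNPs.
#'
#' @param alignments AlignmentSet (unique alignments used).
#' @param snps SnpTable.
#' @return calls: data.frame(id, mate, chrom, pos, call) with call in
#'   \code{"A"}, \code{"B"}, \code{"na"}.
#' @export
assign_reads <- function(alignments, snps) {
  if (nrow(snps) == 0) stopf("SNP table is empty")
  al <- alignments[alignments$unique, , drop = FALSE]
  res <- vector("list", 0)
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    a <- al[al$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(s$pos, s$pos),
                                IRanges::IRanges(a$start, a$start + a$width - 1L))
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    off <- s$pos[qi] - a$start[si] + 1L
    base <- substring(a$seq[si], off, off)
    call <- ifelse(base == s$allele_a[qi], "A",
                   ifelse(base == s$allele_b[qi], "B", "na"))
    res[[length(res) + 1L]] <- data.frame(
      id = a$id[si], mate = a$mate[si], chrom = ch, pos = s$pos[qi],
      call = call, stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(id = character(0), mate = integer(0),
                      chrom = character(0), pos = integer(0),
                      call = character(0)))
  calls <- do.call(rbind, res)
  # conflict rule: reads supporting both parents become na everywhere
  rk <- paste(calls$id, calls$mate)
  hasA <- unique(rk[calls$call == "A"])
  hasB <- unique(rk[calls$call == "B"])
  conflict <- rk %in% intersect(hasA, hasB)
  calls$call[conflict] <- "na"
  rownames(calls) <- NULL
  calls
}

#' Pool parental calls in consecutive non-overlapping bins
#'
#' @param calls call table from \code{\link{assign_reads}}.
#' @param seqlengths named chromosome lengths.
#' @param bin_size bin width in bp (1 Mb at genome scale).
#' @return ParentageBins: data.frame(chrom, bin, start, end, n_a, n_b, n_na,
#'   pct_a) tiling every chromosome; \code{pct_a} is the percentage of
#'   parent-A calls among assigned (non-na) calls, NA for empty bins.
#' @export
bin_parentage <- function(calls, seqlengths, bin_size = 1e6) {
  out <- lapply(names(seqlengths), function(ch) {
    len <- seqlengths[[ch]]
    n_bins <- as.integer(ceiling(len / bin_size))
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    b <- (cc$pos - 1L) %/% bin_size + 1L
    n_a <- tabulate(b[cc$call == "A"], nbins = n_bins)
    n_b <- tabulate(b[cc$call == "B"], nbins = n_bins)
    n_na <- tabulate(b[cc$call == "na"], nbins = n_bins)
    assigned <- n_a + n_b
    data.frame(chrom = ch, bin = seq_len(n_bins),
               start = (seq_len(n_bins) - 1L) * bin_size + 1L,
               end = pmin(seq_len(n_bins) * bin_size, len),
               n_a = n_a, n_b = n_b, n_na = n_na,
               pct_a = ifelse(assigned > 0, 100 * n_a / assigned, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parent-A allele fraction by copy state
#'
#' Groups parental calls by the copy state of the segment containing each
#' SNP and reports the parent-A (haploid-inducer) allele-call fraction per
#' state, with the mean and standard error across segments. In a diploid
#' hybrid carrying one extra parent-A-derived copy, state-3 regions are
#' expected near 2/3 parent-A calls and state-4 regions near 3/4; state-1
#' loss-of-heterozygosity regions approach 0.
#'
#' @param calls call table from \code{\link{assign_reads}}.
#' @param segments CopySegment table for the same sample.
#' @return data.frame(state, n_calls, pct_a, n_segments, seg_mean_pct_a,
#'   seg_se_pct_a).
#' @export
parent_fraction_by_state <- function(calls, segments) {
  cc <- calls[calls$call %in% c("A", "B"), , drop = FALSE]
  res <- vector("list", 0)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    c2 <- cc[cc$chrom == ch, , drop = FALSE]
    if (nrow(c2) == 0) next
    seg_idx <- findInterval(c2$pos, s$start)
    ok <- seg_idx >= 1 & c2$pos <= s$end[pmax(seg_idx, 1)]
    res[[length(res) + 1L]] <- data.frame(
      state = s$state[seg_idx[ok]],
      seg = paste0(ch, ":", seg_idx[ok]),
      a = c2$call[ok] == "A", stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(state = integer(0), n_calls = integer(0),
                      pct_a = numeric(0), n_segments = integer(0),
                      seg_mean_pct_a = numeric(0), seg_se_pct_a = numeric(0)))
  d <- do.call(rbind, res)
  per_seg <- stats::aggregate(a ~ state + seg, data = d, FUN = mean)
  out <- lapply(sort(unique(d$state)), function(st) {
    di <- d[d$state == st, ]
    ps <- per_seg$a[per_seg$state == st] * 100
    data.frame(state = st, n_calls = nrow(di),
               pct_a = 100 * mean(di$a),
               n_segments = length(ps),
               seg_mean_pct_a = mean(ps),
               seg_se_pct_a = if (length(ps) > 1) stats::sd(ps) / sqrt(length(ps)) else NA_real_)
  })
  do.call(rbind, out)
}
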