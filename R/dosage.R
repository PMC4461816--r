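## Binned relative dosage on a diploid-background-equals-2 scale, integer
## copy-state segmentation, and karyotype classification.
##
## Chromosomes are partitioned into consecutive non-overlapping bins and the
## percentage of mapped reads landing in each bin is recorded; relative
## coverage is the per-bin ratio of a sample's percentage to a reference
## (control sample or cohort mean), scaled so that the diploid background
## sits at 2. The anchoring at 2 is a convention: a haploid normalised
## against itself still reads 2, and the karyotype class label, not the
## scale, conveys ploidy.

#' Bin read starts and compute per-bin read percentages
#'
#' Each read is assigned to the bin containing its start coordinate; a read
#' starting at the last base of bin k counts in bin k. Percentages are
#' normalised by the total number of mapped reads.
#'
#' @param alignments AlignmentSet (unique alignments are counted).
#' @param seqlengths named chromosome lengths (see \code{\link{seqlens}}).
#' @param bin_size bin width in bp (>= 100); the genome-scale choices 100 kb,
#'   25 kb, 150 kb and 500 bp are all valid.
#' @return data.frame(chrom, bin, start, end, count, pct) tiling every
#'   chromosome; \code{pct} sums to 100 over all bins.
#' @export
bin_counts <- function(alignments, seqlengths, bin_size = 100000) {
  if (bin_size < 100) stopf("bin_size must be >= 100")
  al <- alignments[alignments$unique, , drop = FALSE]
  if (nrow(al) == 0) stopf("zero mapped reads")
  total <- nrow(al)
  out <- lapply(names(seqlengths), function(ch) {
    len <- seqlengths[[ch]]
    n_bins <- as.integer(ceiling(len / bin_size))
    starts <- (seq_len(n_bins) - 1L) * bin_size + 1L
    ends <- pmin(seq_len(n_bins) * bin_size, len)
    s <- al$start[al$chrom == ch]
    cnt <- tabulate((s - 1L) %/% bin_size + 1L, nbins = n_bins)
    data.frame(chrom = ch, bin = seq_len(n_bins), start = starts, end = ends,
               count = cnt, pct = 100 * cnt / total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean per-bin percentages across a cohort
#'
#' @param bin_list list of bin tables from \code{\link{bin_counts}} computed
#'   with identical binning.
#' @return bin table whose \code{pct} is the per-bin cohort mean.
#' @export
cohort_reference <- function(bin_list) {
  ref <- bin_list[[1]]
  m <- sapply(bin_list, function(b) {
    if (nrow(b) != nrow(ref)) stopf("cohort members have different binning")
    b$pct
  })
  ref$pct <- rowMeans(m)
  ref$count <- NA_integer_
  ref
}

#' Relative dosage profile scaled to a diploid background of 2
#'
#' Divides each sample bin percentage by the corresponding reference
#' percentage and multiplies by 2, so a bin at the diploid background reads
#' 2.0 and a triplicated bin reads 3.0. Bins where the reference percentage
#' is zero are masked (NA) rather than divided.
#'
#' @param sample_bins,reference_bins bin tables with identical binning
#'   (reference from a control individual or \code{\link{cohort_reference}}).
#' @return DosageProfile: the sample bin table with a \code{rel_cov} column.
#' @export
relative_dosage <- function(sample_bins, reference_bins) {
  if (nrow(sample_bins) != nrow(reference_bins) ||
      !all(sample_bins$chrom == reference_bins$chrom) ||
      !all(sample_bins$bin == reference_bins$bin))
    stopf("sample and reference use different binning")
  out <- sample_bins
  out$rel_cov <- ifelse(reference_bins$pct > 0,
                        2 * sample_bins$pct / reference_bins$pct, NA_real_)
  out
}

# absorb runs shorter than min_run into the flanking state whose mean
# relative coverage is closer
.merge_short_runs <- function(state, relcov, min_run) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0) break
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    i <- short[which.min(r$lengths[short])]
    idx <- starts[i]:ends[i]
    m <- mean(relcov[idx], na.rm = TRUE)
    left <- if (i > 1) r$values[i - 1] else NA
    right <- if (i < length(r$values)) r$values[i + 1] else NA
    pick <- if (is.na(left)) right
            else if (is.na(right)) left
            else if (abs(m - left) <= abs(m - right)) left else right
    state[idx] <- pick
  }
  state
}

#' Segment a dosage profile into integer copy states
#'
#' Median-smooths the relative coverage, rounds each bin to the nearest
#' integer state (clamped to 0..6) and merges runs shorter than
#' \code{min_run} into the flanking state with the closer mean. This
#' automates the by-eye block definition used for dosage plots.
#'
#' @param profile DosageProfile from \code{\link{relative_dosage}}.
#' @param min_run minimum run length in bins (>= 1).
#' @param smooth_window odd window for the running median.
#' @return CopySegment table: data.frame(chrom, start_bin, end_bin, start,
#'   end, n_bins, state, mean_rel) with adjacent segments differing in state.
#' @export
segment_profile <- function(profile, min_run = 3, smooth_window = 5) {
  if (min_run < 1) stopf("min_run must be >= 1")
  if (smooth_window %% 2 == 0) stopf("smooth_window must be odd")
  out <- lapply(unique(profile$chrom), function(ch) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    x <- p$rel_cov
    # masked bins inherit the nearest informative neighbour
    if (anyNA(x)) {
      ok <- which(!is.na(x))
      if (length(ok) == 0) return(NULL)
      x[is.na(x)] <- x[ok[pmax(1, findInterval(which(is.na(x)), ok))]]
    }
    sm <- if (length(x) >= smooth_window)
      stats::runmed(x, smooth_window, endrule = "median") else x
    state <- pmin(pmax(as.integer(round(sm)), 0L), 6L)
    state <- .merge_short_runs(state, x, min_run)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    data.frame(chrom = ch, start_bin = p$bin[starts], end_bin = p$bin[ends],
               start = p$start[starts], end = p$end[ends],
               n_bins = r$lengths, state = r$values,
               mean_rel = vapply(seq_along(starts), function(i)
                 mean(p$rel_cov[starts[i]:ends[i]], na.rm = TRUE), 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify each chromosome's karyotype from its copy segments
#'
#' euploid: a single segment at state 2. numerical: a single segment at a
#' state other than 2 (whole-chromosome gain or loss). shattered: at least
#' \code{shatter_min} copy-state transitions, or at least three distinct
#' states (the oscillating profile of a shattered chromosome). truncated:
#' the remaining few-breakpoint cases, one or two breaks separating the
#' background from a single altered state.
#'
#' @param segments CopySegment table from \code{\link{segment_profile}}.
#' @param shatter_min minimum transitions to call a chromosome shattered.
#' @return KaryotypeCall table: data.frame(chrom, class, n_segments,
#'   n_breakpoints, states).
#' @export
classify_karyotype <- function(segments, shatter_min = 5) {
  if (is.null(segments) || nrow(segments) == 0)
    stopf("empty segment list")
  out <- lapply(unique(segments$chrom), function(ch) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    n_seg <- nrow(s)
    n_states <- length(unique(s$state))
    trans <- n_seg - 1L
    class <- if (n_seg == 1L) {
      if (s$state == 2L) "euploid" else "numerical"
    } else if (trans >= shatter_min || n_states >= 3L) {
      "shattered"
    } else {
      "truncated"
    }
    data.frame(chrom = ch, class = class, n_segments = n_seg,
               n_breakpoints = trans,
               states = paste(sort(unique(s$state)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a dosage profile as TSV
#' @param profile DosageProfile.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write copy segments as BED with the state in the score column
#' @param segments CopySegment table.
#' @param path output file.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start0 = segments$start - 1L,
                    end = segments$end,
                    name = paste0("state", segments$state),
                    score = segments$state, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
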