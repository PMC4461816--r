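## Genomic-feature occupancy in windows centred on breakpoints, enrichment
## ratios against the remainder of the aneuploid chromosome, and empirical
## p-values from shuffled breakpoint locations.

#' Load feature annotations from GFF3/BED files
#'
#' Imports one file per feature class, converts to the internal 1-based
#' closed convention (handled by the importer) and merges overlapping
#' intervals within each class.
#'
#' @param paths named character vector of GFF3 or BED file paths; names are
#'   the feature class labels (gene, transposon, replication_origin, ...).
#' @return named list of reduced \code{GRanges}.
#' @export
load_features <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stopf("feature paths must be named by feature class")
  out <- lapply(paths, function(p) {
    gr <- tryCatch(rtracklayer::import(p),
                   error = function(e) stopf("failed to parse %s: %s", p,
                                             conditionMessage(e)))
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
  })
  names(out) <- names(paths)
  out
}

# feature intervals on one chromosome as an IRanges
.feature_ranges <- function(features, chrom) {
  if (methods::is(features, "GRanges")) {
    gd <- as.data.frame(features)
    gd <- gd[as.character(gd$seqnames) == chrom, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(gd$start, gd$end))
  } else if (methods::is(features, "IRanges")) {
    IRanges::reduce(features)
  } else {
    stopf("features must be GRanges or IRanges")
  }
}

#' Feature occupancy inside and outside breakpoint windows
#'
#' Windows of \code{window} bp are centred on each breakpoint, clipped to
#' the chromosome and unioned before summing, so clustered breakpoints are
#' not double-counted. Occupancy is the percentage of window bases covered
#' by the feature; \code{occ_elsewhere} is the same percentage over the rest
#' of the chromosome.
#'
#' @param breakpoints numeric vector of breakpoint positions (1-based).
#' @param features feature intervals (\code{GRanges} or \code{IRanges}).
#' @param window window size in bp (1000 and 10000 are the conventional
#'   choices).
#' @param chrom chromosome name (used to subset a \code{GRanges}).
#' @param chrom_len chromosome length in bp.
#' @return list(occ_in, occ_elsewhere, win_bp, else_bp, feat_in_bp,
#'   feat_else_bp).
#' @export
window_occupancy <- function(breakpoints, features, window, chrom,
                             chrom_len) {
  if (length(breakpoints) == 0) stopf("no breakpoints supplied")
  .occupancy(breakpoints, .feature_ranges(features, chrom), window,
             chrom_len)
}

# hot path shared with the permutation loop: features already reduced
.occupancy <- function(breakpoints, feat, window, chrom_len) {
  half <- window %/% 2
  win <- IRanges::reduce(IRanges::IRanges(
    pmax(1, breakpoints - half),
    pmin(chrom_len, breakpoints + (window - half) - 1)))
  win_bp <- sum(IRanges::width(win))
  feat_bp <- sum(IRanges::width(feat))
  feat_in <- sum(IRanges::width(IRanges::intersect(win, feat)))
  else_bp <- chrom_len - win_bp
  feat_else <- feat_bp - feat_in
  list(occ_in = 100 * feat_in / win_bp,
       occ_elsewhere = if (else_bp > 0) 100 * feat_else / else_bp else NA_real_,
       win_bp = win_bp, else_bp = else_bp,
       feat_in_bp = feat_in, feat_else_bp = feat_else)
}

#' Enrichment ratio of in-window versus elsewhere occupancy
#'
#' @param occ_in,occ_elsewhere occupancy percentages.
#' @return occ_in / occ_elsewhere; NA with a warning when the elsewhere
#'   occupancy is zero.
#' @export
enrichment_ratio <- function(occ_in, occ_elsewhere) {
  if (is.na(occ_elsewhere) || occ_elsewhere <= 0) {
    warning("elsewhere occupancy is zero; ratio undefined")
    return(NA_real_)
  }
  occ_in / occ_elsewhere
}

#' Permutation test for feature enrichment at breakpoints
#'
#' Shuffles breakpoint locations uniformly over the chromosome (preserving
#' their number) \code{n_shuffles} times and compares the shuffled
#' enrichment ratios with the observed one. Two one-sided empirical
#' p-values are reported with the add-one estimator
#' p = (1 + #\{shuffled >= observed\}) / (1 + n).
#'
#' @param breakpoints observed breakpoint positions.
#' @param features feature intervals.
#' @param window window size in bp.
#' @param chrom,chrom_len shuffle domain (the aneuploid chromosome).
#' @param n_shuffles number of shuffles (>= 100; 1000 conventionally).
#' @param seed integer seed; fixed seed gives identical p.
#' @param feature_class label carried into the result.
#' @param breakpoint_class label (e.g. "duplicated" or "triplicated").
#' @return one-row EnrichmentResult data.frame.
#' @export
permutation_p <- function(breakpoints, features, window, chrom, chrom_len,
                          n_shuffles = 1000, seed = NULL,
                          feature_class = "feature",
                          breakpoint_class = "all") {
  if (n_shuffles < 100) stopf("n_shuffles must be >= 100")
  feat <- .feature_ranges(features, chrom)
  obs <- .occupancy(breakpoints, feat, window, chrom_len)
  obs_ratio <- obs$occ_in / obs$occ_elsewhere
  nb <- length(breakpoints)
  with_seed(seed, {
    shuf <- vapply(seq_len(n_shuffles), function(i) {
      bp <- sample.int(chrom_len, nb, replace = TRUE)
      o <- .occupancy(bp, feat, window, chrom_len)
      o$occ_in / o$occ_elsewhere
    }, 0)
    ok <- !is.na(shuf)
    p_enrich <- (1 + sum(shuf[ok] >= obs_ratio)) / (1 + sum(ok))
    p_deplete <- (1 + sum(shuf[ok] <= obs_ratio)) / (1 + sum(ok))
    data.frame(feature = feature_class, breakpoint_class = breakpoint_class,
               window = window, occ_in = obs$occ_in,
               occ_elsewhere = obs$occ_elsewhere, ratio = obs_ratio,
               p_enrich = p_enrich, p_deplete = p_deplete,
               n_shuffles = n_shuffles,
               seed = if (is.null(seed)) NA_integer_ else seed,
               stringsAsFactors = FALSE)
  })
}
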