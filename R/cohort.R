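## Cohort-level tallies of karyotype outcomes and exact contingency
## statistics for cross-outcome tables.

#' Tally karyotype calls across a cohort
#'
#' Summarises per-sample aneuploidy: samples whose altered chromosomes all
#' belong to one class are counted under that class, samples mixing classes
#' under "combined", and fully euploid samples under "euploid". The
#' numerical class is further broken down by the number of whole-chromosome
#' gains or losses (single/double/triple/quadruple primary aneuploidy).
#'
#' @param karyotypes data.frame with columns \code{sample}, \code{chrom},
#'   \code{class} (one row per chromosome per sample, classes as produced by
#'   \code{\link{classify_karyotype}}).
#' @return list(by_sample, class_counts, numerical_multiplicity).
#' @export
tally_cohort <- function(karyotypes) {
  need <- c("sample", "chrom", "class")
  if (!all(need %in% names(karyotypes)))
    stopf("karyotypes must have columns %s", paste(need, collapse = ", "))
  samples <- unique(karyotypes$sample)
  by_sample <- do.call(rbind, lapply(samples, function(s) {
    k <- karyotypes[karyotypes$sample == s, , drop = FALSE]
    altered <- k$class[k$class != "euploid"]
    cls <- if (length(altered) == 0) "euploid"
           else if (length(unique(altered)) == 1) unique(altered)
           else "combined"
    data.frame(sample = s, class = cls,
               n_numerical = sum(k$class == "numerical"),
               n_truncated = sum(k$class == "truncated"),
               n_shattered = sum(k$class == "shattered"),
               stringsAsFactors = FALSE)
  }))
  cls_levels <- c("euploid", "numerical", "truncated", "shattered", "combined")
  cc <- table(factor(by_sample$class, levels = cls_levels))
  class_counts <- data.frame(class = names(cc), count = as.integer(cc),
                             pct = 100 * as.integer(cc) / nrow(by_sample))
  num <- by_sample$n_numerical[by_sample$n_numerical > 0]
  mult <- table(factor(pmin(num, 4), levels = 1:4,
                       labels = c("single", "double", "triple", "quadruple")))
  numerical_multiplicity <- data.frame(
    multiplicity = names(mult), count = as.integer(mult),
    pct = if (length(num)) 100 * as.integer(mult) / length(num) else
      rep(NA_real_, 4))
  list(by_sample = by_sample, class_counts = class_counts,
       numerical_multiplicity = numerical_multiplicity)
}

#' Exact test on a 2x2 contingency table
#'
#' Two-sided Fisher exact p-value with the sample odds ratio (Haldane 0.5
#' correction when a zero cell exists) and, alongside, the
#' continuity-corrected chi-square p-value for the same comparison of
#' proportions.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list(p, odds_ratio, chisq_p, table).
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  if (sum(tab) == 0) stopf("table has no observations")
  ft <- stats::fisher.test(tab)
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  chi <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value),
    error = function(e) NA_real_)
  list(p = ft$p.value, odds_ratio = unname(or), chisq_p = chi, table = tab)
}

#' Reconstruct integer counts from a printed total and percentages
#'
#' Published outcome tables often print a total with class percentages;
#' nearest-integer reconstruction recovers the underlying counts. The
#' result is flagged as reconstructed.
#'
#' @param total total number of individuals.
#' @param pcts named numeric vector of percentages.
#' @return named integer vector of counts with attribute
#'   \code{reconstructed = TRUE}.
#' @export
reconstruct_counts <- function(total, pcts) {
  counts <- round(total * pcts / 100)
  structure(stats::setNames(as.integer(counts), names(pcts)),
            reconstructed = TRUE)
}
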