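#' @importFrom Biostrings DNAStringSet DNAString reverseComplement PDict matchPDict
#'   matchPattern writeXStringSet width
#' @importFrom IRanges IRanges reduce gaps start end width findOverlaps coverage
#' @importFrom S4Vectors queryHits subjectHits elementNROWS
#' @importFrom stats rbinom rnorm runif median setNames wilcox.test t.test
#'   fisher.test chisq.test runmed ks.test
#' @importFrom utils read.delim write.table head tail
NULL

#' @importFrom data.table data.table rbindlist dcast as.data.table setorder
#' @importFrom methods is
NULL

.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Reverse-complement character sequences
#'
#' Vectorised reverse complement over plain character DNA strings.
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Chromosome lengths of a genome
#'
#' @param genome a named \code{DNAStringSet}.
#' @return named integer vector of sequence lengths.
#' @export
seqlens <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# First index at which two equal-length strings differ, 0 if identical.
first_mismatch <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  d <- which(ra != rb)
  if (length(d)) d[1] else 0L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
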