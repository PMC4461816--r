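# Shared fixtures. The expensive end-to-end run is built once per session
# and memoised; everything else is built fresh per test.

.fixture_env <- new.env(parent = emptyenv())

# deterministic toy genome from an explicit sequence
toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# random read-start simulation at a given copy-state profile: cheap stand-in
# for full read simulation when only dosage is under test.
# regions: data.frame(start, end, state); returns an AlignmentSet-like df.
simulate_starts <- function(chrom, regions, coverage = 50, read_len = 50,
                            seed = 1) {
  withr::with_seed(seed, {
    starts <- unlist(lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      len <- r$end - r$start + 1
      n <- stats::rpois(1, len * coverage * r$state / 2 / read_len)
      r$start + floor(stats::runif(n) * len)
    }))
    data.frame(id = paste0("r", seq_along(starts)), mate = 0L, chrom = chrom,
               start = as.integer(starts), strand = "+", width = read_len,
               seq = NA_character_, nhits = 1L, unique = TRUE,
               stringsAsFactors = FALSE)
  })
}

# small hybrid world reused by mapping/snp tests
small_world <- function(seed = 42, n_chrom = 2, chrom_len = 5e4,
                        snp_rate = 2e-3) {
  key <- paste0("world_", seed, "_", n_chrom, "_", chrom_len, "_", snp_rate)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_parental_genomes(n_chrom, chrom_len, snp_rate,
                                                 seed = seed)
  }
  .fixture_env[[key]]
}

# the full study-scale pipeline run (5 x 300 kb, 20 junctions, 50x paired):
# built once, shared by the acceptance tests
e2e_run <- function() {
  if (is.null(.fixture_env$e2e)) {
    .fixture_env$e2e <- run_pipeline(default_config(seed = 1), quiet = TRUE)
  }
  .fixture_env$e2e
}

# independent naive SNP filter used as the oracle for SNP discovery: applies
# the documented thresholds position by position, written without reference
# to identify_snps internals
naive_snp_filter <- function(planted, hybrid, parent_a, parent_b,
                             min_hybrid_depth = 25, min_allele_frac = 0.40,
                             min_parent_hom = 0.97, min_depth_a = 6,
                             min_depth_b = 1, noise_frac = 0.05) {
  bases <- c("A", "C", "G", "T")
  keep <- logical(nrow(planted))
  pk <- function(p) paste(p$chrom, p$pos)
  hk <- pk(hybrid); ak <- pk(parent_a); bk <- pk(parent_b)
  for (i in seq_len(nrow(planted))) {
    k <- paste(planted$chrom[i], planted$pos[i])
    hi <- match(k, hk); ai <- match(k, ak); bi <- match(k, bk)
    if (is.na(hi) || is.na(ai) || is.na(bi)) next
    h <- as.numeric(hybrid[hi, bases])
    dh <- sum(h)
    if (dh < min_hybrid_depth) next
    frac <- h / dh
    informative <- h > 0 & frac >= noise_frac
    if (sum(informative) != 2) next
    if (sum(frac >= min_allele_frac) != 2) next
    a <- as.numeric(parent_a[ai, bases])
    b <- as.numeric(parent_b[bi, bases])
    if (sum(a) < min_depth_a || sum(b) < min_depth_b) next
    if (max(a) / sum(a) < min_parent_hom) next
    if (max(b) / sum(b) < min_parent_hom) next
    maj_a <- bases[which.max(a)]
    maj_b <- bases[which.max(b)]
    if (maj_a == maj_b) next
    if (!setequal(bases[informative], c(maj_a, maj_b))) next
    if (maj_a != planted$allele_a[i] || maj_b != planted$allele_b[i]) next
    keep[i] <- TRUE
  }
  planted[keep, , drop = FALSE]
}

# brute-force exact-match scan of a read against a genome: the independent
# mapping oracle (no shared code with map_reads)
brute_scan <- function(genome, read) {
  hits <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
      p <- gregexpr(q, s, fixed = TRUE)[[1]]
      if (p[1] != -1)
        for (pos in p) hits[[length(hits) + 1L]] <-
          data.frame(chrom = ch, start = pos, strand = strand)
    }
  }
  if (length(hits) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  do.call(rbind, hits)
}

# brute-force two-sided Fisher p by enumerating all tables with the observed
# margins (counts <= 30)
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, 0)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
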