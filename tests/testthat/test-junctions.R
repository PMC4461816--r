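# a toy world with one planted rearranged chromosome used across the
# junction tests: blunt, microhomology-4 and 30 bp insertion junctions
junction_world <- function(seed = 51) {
  key <- paste0("jworld_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  p <- make_parental_genomes(1, 3e4, 1e-3, seed = seed)
  plan <- structure(list(
    blocks = data.frame(block = 1:4, start = c(1L, 8001L, 16001L, 23001L),
                        end = c(8000L, 16000L, 23000L, 30000L),
                        state = c(2L, 3L, 2L, 3L)),
    fragments = data.frame(frag = 1:4, block = c(1L, 3L, 2L, 4L),
                           start = c(1L, 16001L, 8001L, 23001L),
                           end = c(8000L, 23000L, 16000L, 30000L),
                           strand = c("+", "-", "+", "+")),
    junctions = data.frame(type = c("blunt", "microhomology", "insertion"),
                           mh_len = c(0L, 4L, 0L),
                           ins_len = c(0L, 0L, 30L)),
    chrom_len = 3e4L), class = "block_plan")
  sh <- build_shattered_chromosome(p, "chr1", plan, seed = seed + 1)
  .fixture_env[[key]] <- sh
  sh
}

test_that("breakpoints are emitted at copy-state transitions only", {
  seg_flat <- data.frame(chrom = "c", start_bin = 1, end_bin = 100,
                         start = 1, end = 50000, n_bins = 100, state = 2,
                         mean_rel = 2)
  expect_equal(nrow(detect_breakpoints(seg_flat)), 0)
  segs <- data.frame(chrom = "c", start_bin = c(1, 41, 81),
                     end_bin = c(40, 80, 120),
                     start = c(1, 20001, 40001), end = c(20000, 40000, 60000),
                     n_bins = 40, state = c(2, 3, 2), mean_rel = c(2, 3, 2))
  bp <- detect_breakpoints(segs)
  expect_equal(bp$pos, c(20000, 40000))
  expect_equal(bp$left_state, c(2, 3))
  expect_equal(bp$right_state, c(3, 2))
})

test_that("breakpoint read extraction pulls window reads plus their mates", {
  sh <- junction_world()
  nucleus <- list(list(genome = sh$parent_b, copies = 1L),
                  list(genome = sh$derived, copies = 1L))
  reads <- simulate_reads(nucleus, coverage = 30, read_len = 80,
                          paired = TRUE, insert_mean = 250, insert_sd = 20,
                          seed = 60)
  al <- map_reads_hybrid(sh$parent_a, sh$parent_b, reads)
  ext <- extract_breakpoint_reads(al, reads, "chr1", 8000, radius = 2000)
  # both mates of every extracted id are present
  tab <- table(ext$id)
  expect_true(all(tab == 2))
  # window size arithmetic: ~ 2 * radius * depth / read_len read starts,
  # plus out-of-window mates
  n_window <- sum(al$chrom == "chr1" & al$start >= 6000 & al$start <= 10000)
  expect_gte(nrow(ext), n_window)
  # unmapped junction-spanning mates ride along
  expect_true(any(!ext$mapped))
})

test_that("greedy assembly reconstructs a tiled region and respects the overlap floor", {
  sh <- junction_world()
  region <- substr(as.character(sh$parent_a[["chr1"]]), 10001, 10600)
  starts <- seq(1, 600 - 80 + 1, by = 20)
  reads <- data.frame(id = paste0("t", starts),
                      seq = substring(region, starts, starts + 79),
                      qual = strrep("I", 80), mate = 0L,
                      stringsAsFactors = FALSE)
  ctg <- assemble_local(reads, min_overlap = 31, min_reads = 3)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$contig == region ||
              ctg$contig == revcomp(region))
  expect_equal(ctg$support, length(starts))
  # reverse-complementing the read set yields the same contig up to strand
  reads_rc <- reads; reads_rc$seq <- revcomp(reads$seq)
  ctg2 <- assemble_local(reads_rc, min_overlap = 31, min_reads = 3)
  expect_equal(pmin(ctg$contig, revcomp(ctg$contig)),
               pmin(ctg2$contig, revcomp(ctg2$contig)))
  # two reads overlapping by min_overlap - 1 are not merged
  r2 <- data.frame(id = c("a", "b"),
                   seq = c(substr(region, 1, 80), substr(region, 51, 130)),
                   qual = strrep("I", 80), mate = 0L)
  expect_equal(nrow(assemble_local(r2, min_overlap = 31, min_reads = 1)), 0)
  # chained 31 bp overlaps merge (three reads clear the 2x read-length floor)
  r3 <- data.frame(id = c("a", "b", "c"),
                   seq = c(substr(region, 1, 80), substr(region, 50, 129),
                           substr(region, 99, 178)),
                   qual = strrep("I", 80), mate = 0L)
  ctg3 <- assemble_local(r3, min_overlap = 31, min_reads = 1)
  expect_equal(nrow(ctg3), 1)
  expect_equal(nchar(ctg3$contig), 178)
})

test_that("split alignment recovers planted junction signatures exactly", {
  sh <- junction_world()
  der <- as.character(sh$derived[[1]])
  jt <- sh$truth$junctions
  # contig spanning the blunt junction (derived coordinates around junction 1)
  for (j in 1:3) {
    pos <- jt$pos_derived[j]
    contig <- substr(der, pos - 200, pos + 200)
    sa <- split_align(contig, sh$parent_a, genome_alt = sh$parent_b)
    expect_false(sa$concordant)
    jc <- classify_junction(sa, contig = contig)
    expect_equal(jc$type, jt$type[j])
    expect_equal(jc$mh_len, jt$mh_len[j])
    if (jt$type[j] == "insertion") {
      expect_equal(jc$ins_len, jt$ins_len[j])
      expect_equal(jc$insertion_seq, jt$insertion_seq[j])
    }
    # anchors within 1 bp of truth after canonical ordering
    m <- match_junctions(jc, jt[j, , drop = FALSE])
    expect_true(m$matched)
  }
  # a concordant contig maps end to end
  plain <- substr(as.character(sh$parent_a[["chr1"]]), 2000, 2400)
  sa <- split_align(plain, sh$parent_a, genome_alt = sh$parent_b)
  expect_true(sa$concordant)
})

test_that("junction classification is invariant under reverse complement", {
  sh <- junction_world()
  der <- as.character(sh$derived[[1]])
  jt <- sh$truth$junctions
  for (j in 1:3) {
    pos <- jt$pos_derived[j]
    contig <- substr(der, pos - 150, pos + 150)
    j1 <- classify_junction(split_align(contig, sh$parent_a,
                                        genome_alt = sh$parent_b))
    j2 <- classify_junction(split_align(revcomp(contig), sh$parent_a,
                                        genome_alt = sh$parent_b))
    c1 <- canonical_junctions(j1)
    c2 <- canonical_junctions(j2)
    expect_equal(c1$type, c2$type)
    expect_equal(c1$mh_len, c2$mh_len)
    expect_equal(c1$pos_left, c2$pos_left)
    expect_equal(c1$pos_right, c2$pos_right)
    expect_equal(c1$inverted, c2$inverted)
  }
})

test_that("contig chaining decomposes a multi-junction contig", {
  sh <- junction_world()
  der <- as.character(sh$derived[[1]])
  jt <- sh$truth$junctions
  # one contig spanning junctions 2 and 3 (fragment 3 is 8 kb: use a wide span
  # around both junction coordinates)
  contig <- substr(der, jt$pos_derived[2] - 300, jt$pos_derived[3] + 300)
  segs <- chain_contig(contig, sh$parent_a, genome_alt = sh$parent_b)
  expect_equal(length(segs), 3)
  jx <- chain_junctions(segs, contig)
  expect_equal(nrow(jx), 2)
  m <- match_junctions(jx, jt[2:3, ])
  expect_true(all(m$matched))
  expect_equal(m$called_type, m$type)
  expect_equal(m$called_mh_len, m$mh_len)
})

test_that("junction summaries count types, inversions and compare block sizes", {
  jx <- data.frame(
    chrom_left = "c", pos_left = 1:20, side_left = "upstream",
    strand_left = "+",
    chrom_right = "c", pos_right = 101:120, side_right = "downstream",
    strand_right = rep(c("+", "-"), 10),
    type = rep(c("microhomology", "blunt", "insertion", "microhomology"), 5),
    mh_len = rep(c(5L, 0L, 0L, 9L), 5),
    ins_len = rep(c(0L, 0L, 40L, 0L), 5),
    insertion_seq = rep(c("", "", strrep("A", 40), ""), 5),
    inverted = rep(c(FALSE, TRUE), 10), stringsAsFactors = FALSE)
  s <- summarize_junctions(jx)
  expect_equal(unname(s$counts["microhomology"]), 10)
  expect_equal(unname(s$counts["blunt"]), 5)
  expect_equal(unname(s$counts["insertion"]), 5)
  expect_equal(s$inversion_fraction, 0.5)
  # all-forward joins give inversion fraction 0
  jf <- jx; jf$inverted <- FALSE
  expect_equal(summarize_junctions(jf)$inversion_fraction, 0)
  # duplicated blocks drawn 10x larger than triplicated: p < 0.01 at n = 23
  withr::with_seed(71, {
    dup <- rlnorm(23, log(2e5), 0.4)
    trip <- rlnorm(23, log(2e4), 0.4)
  })
  s2 <- summarize_junctions(jx, dup_sizes = dup, trip_sizes = trip)
  expect_lt(s2$block_test$p_wilcox, 0.01)
  expect_lt(s2$block_test$p_t, 0.01)
  expect_error(summarize_junctions(jx, dup_sizes = 1, trip_sizes = trip),
               ">= 2 blocks")
})

test_that("chimeric-gene prediction requires genic anchors and concordant orientation", {
  genes <- GenomicRanges::GRanges("c", IRanges::IRanges(
    start = c(100, 1000), end = c(500, 1500)), strand = c("+", "+"))
  mkj <- function(pl, pr, sl, sr) data.frame(
    chrom_left = "c", pos_left = pl, side_left = "upstream", strand_left = sl,
    chrom_right = "c", pos_right = pr, side_right = "downstream",
    strand_right = sr, type = "blunt", mh_len = 0L, ins_len = 0L,
    insertion_seq = "", inverted = sl != sr, stringsAsFactors = FALSE)
  # both anchors genic, forward join, genes on the same strand: chimeric
  expect_true(predict_chimeric(mkj(200, 1200, "+", "+"), genes))
  # one anchor intergenic: not chimeric
  expect_false(predict_chimeric(mkj(700, 1200, "+", "+"), genes))
  expect_false(predict_chimeric(mkj(200, 700, "+", "+"), genes))
  # inverted join between same-strand genes reads them in opposition
  expect_false(predict_chimeric(mkj(200, 1200, "+", "-"), genes))
  # but an inverted join onto an antisense gene is concordant again
  genes2 <- GenomicRanges::GRanges("c", IRanges::IRanges(
    start = c(100, 1000), end = c(500, 1500)), strand = c("+", "-"))
  expect_true(predict_chimeric(mkj(200, 1200, "+", "-"), genes2))
})

test_that("a purely diploid simulation yields no junction calls", {
  w <- small_world(seed = 81, n_chrom = 1, chrom_len = 4e4)
  reads <- simulate_reads(list(list(genome = w$parent_a, copies = 1L),
                               list(genome = w$parent_b, copies = 1L)),
                          coverage = 40, read_len = 80, paired = TRUE,
                          insert_mean = 250, insert_sd = 20, seed = 82)
  al <- map_reads_hybrid(w$parent_a, w$parent_b, reads)
  # scan a handful of arbitrary positions as if they were breakpoints
  idx <- genome_index(w$parent_a, w$parent_b)
  found <- 0
  for (pos in c(5000, 15000, 25000, 35000)) {
    ext <- extract_breakpoint_reads(al, reads, "chr1", pos, radius = 2000)
    seeds <- ext$seq[!ext$mapped]
    ctg <- assemble_local(ext, min_overlap = 31, min_reads = 2,
                          seeds = if (length(seeds)) seeds else NULL)
    for (k in seq_len(nrow(ctg))) {
      segs <- chain_contig(ctg$contig[k], w$parent_a, .idx = idx)
      found <- found + nrow(chain_junctions(segs, ctg$contig[k]))
    }
  }
  expect_equal(found, 0)
})

test_that("junction tables round-trip through the TSV reader", {
  sh <- junction_world()
  f <- tempfile(fileext = ".tsv")
  write.table(sh$truth$junctions, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_junction_table(f)
  expect_equal(back$pos_left, sh$truth$junctions$pos_left)
  expect_equal(back$type, sh$truth$junctions$type)
  expect_equal(back$inverted, sh$truth$junctions$inverted)
  unlink(f)
})
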