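test_that("parameter validation rejects degenerate rates and lengths", {
  expect_error(make_parental_genomes(snp_rate = 0), "snp_rate")
  expect_error(make_parental_genomes(snp_rate = 0.2), "snp_rate")
  expect_error(make_parental_genomes(chrom_len = 500), "chrom_len")
})

test_that("planted SNP count is binomial and fully recoverable by sequence comparison", {
  p <- make_parental_genomes(n_chrom = 2, chrom_len = 1e5, snp_rate = 1e-3,
                             seed = 7)
  # oracle: direct count of mismatched positions between the two sequences
  diff <- compare_genomes(p$parent_a, p$parent_b)
  expect_equal(nrow(diff), nrow(p$snps))
  expect_equal(diff$pos, p$snps$pos)
  expect_equal(diff$allele_a, p$snps$allele_a)
  expect_equal(diff$allele_b, p$snps$allele_b)
  # 3 sigma of Binomial(200000, 1e-3): mean 200, sd ~ 14.1
  expect_gt(nrow(diff), 200 - 3 * sqrt(200 * 0.999))
  expect_lt(nrow(diff), 200 + 3 * sqrt(200 * 0.999))
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_parental_genomes(2, 2e4, 1e-3, seed = 3)
  b <- make_parental_genomes(2, 2e4, 1e-3, seed = 3)
  expect_identical(as.character(a$parent_a), as.character(b$parent_a))
  expect_identical(a$snps, b$snps)
  r1 <- simulate_reads(list(list(genome = a$parent_a, copies = 2L)),
                       coverage = 5, read_len = 50, paired = FALSE, seed = 9)
  r2 <- simulate_reads(list(list(genome = a$parent_a, copies = 2L)),
                       coverage = 5, read_len = 50, paired = FALSE, seed = 9)
  expect_identical(r1, r2)
})

test_that("hand-specified block plans produce the expected derived lengths", {
  p <- make_parental_genomes(1, 1e4, 1e-3, seed = 11)
  mkplan <- function(junctions) {
    structure(list(
      blocks = data.frame(block = 1:2, start = c(1001L, 5001L),
                          end = c(2000L, 6200L), state = c(3L, 3L)),
      fragments = data.frame(frag = 1:2, block = 1:2,
                             start = c(1001L, 5001L), end = c(2000L, 6200L),
                             strand = c("+", "+")),
      junctions = junctions, chrom_len = 1e4L), class = "block_plan")
  }
  # blunt: lengths add
  sh <- build_shattered_chromosome(
    p, "chr1",
    mkplan(data.frame(type = "blunt", mh_len = 0L, ins_len = 0L)), seed = 1)
  expect_equal(Biostrings::width(sh$derived)[[1]], 1000 + 1200)
  # microhomology k = 4: overlap written once
  sh <- build_shattered_chromosome(
    p, "chr1",
    mkplan(data.frame(type = "microhomology", mh_len = 4L, ins_len = 0L)),
    seed = 1)
  expect_equal(Biostrings::width(sh$derived)[[1]], 1000 + 1200 - 4)
  # the acceptor flank was edited so the overlap is genuinely shared
  ref <- as.character(sh$parent_a[["chr1"]])
  expect_equal(substr(ref, 1997, 2000), substr(ref, 5001, 5004))
  # insertion: novel bases interposed
  sh <- build_shattered_chromosome(
    p, "chr1",
    mkplan(data.frame(type = "insertion", mh_len = 0L, ins_len = 30L)),
    seed = 1)
  expect_equal(Biostrings::width(sh$derived)[[1]], 1000 + 1200 + 30)
  expect_equal(nchar(sh$truth$junctions$insertion_seq), 30)
})

test_that("reverse-orientation fragments are recorded as inversion junctions", {
  p <- make_parental_genomes(1, 1e4, 1e-3, seed = 11)
  plan <- structure(list(
    blocks = data.frame(block = 1:2, start = c(1001L, 5001L),
                        end = c(2000L, 6200L), state = c(3L, 3L)),
    fragments = data.frame(frag = 1:2, block = 1:2,
                           start = c(1001L, 5001L), end = c(2000L, 6200L),
                           strand = c("+", "-")),
    junctions = data.frame(type = "blunt", mh_len = 0L, ins_len = 0L),
    chrom_len = 1e4L), class = "block_plan")
  sh <- build_shattered_chromosome(p, "chr1", plan, seed = 2)
  expect_true(sh$truth$junctions$inverted)
  expect_equal(sh$truth$junctions$strand_left, "+")
  expect_equal(sh$truth$junctions$strand_right, "-")
})

test_that("shattered construction is reproduced by an independent naive rebuild", {
  p <- make_parental_genomes(1, 5e4, 1e-3, seed = 13)
  plan <- random_block_plan(5e4, n_blocks = 6, n_fragments = 9,
                            min_block = 2000, seed = 21)
  sh <- build_shattered_chromosome(p, "chr1", plan, seed = 22)
  # oracle: naive string reconstruction from the truth set on the edited
  # reference, using none of the builder's helpers
  ref <- as.character(sh$parent_a[["chr1"]])
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fr <- sh$truth$fragments
  jc <- sh$truth$junctions
  fseq <- vapply(seq_len(nrow(fr)), function(i) {
    s <- substr(ref, fr$start[i], fr$end[i])
    if (fr$strand[i] == "-") rc(s) else s
  }, "")
  rebuilt <- fseq[1]
  for (j in seq_len(nrow(jc))) {
    nxt <- fseq[j + 1]
    rebuilt <- switch(
      jc$planted_type[j],
      microhomology = paste0(rebuilt,
                             substr(nxt, jc$planted_mh_len[j] + 1, nchar(nxt))),
      blunt = paste0(rebuilt, nxt),
      insertion = paste0(rebuilt, jc$insertion_seq[j], nxt))
  }
  expect_identical(rebuilt, as.character(sh$derived[[1]]))
})

test_that("expected copy states follow 1 + fragment coverage", {
  p <- make_parental_genomes(1, 5e4, 1e-3, seed = 13)
  plan <- random_block_plan(5e4, n_blocks = 6, min_block = 2000, seed = 33)
  sh <- build_shattered_chromosome(p, "chr1", plan, seed = 34)
  tcs <- truth_copy_states(sh$truth)
  expect_equal(tcs$start[1], 1)
  expect_equal(tcs$end[nrow(tcs)], 5e4)
  # block states and coverage-derived states agree where blocks are planted
  b <- sh$truth$blocks
  for (i in seq_len(nrow(b))) {
    mid <- (b$start[i] + b$end[i]) %/% 2
    row <- tcs[tcs$start <= mid & tcs$end >= mid, ]
    expect_equal(row$state, b$state[i])
  }
})

test_that("diploid-only nucleus at 50x gives per-base depth within 3 sigma of 50", {
  p <- make_parental_genomes(1, 3e4, 1e-3, seed = 17)
  rd <- simulate_reads(list(list(genome = p$parent_a["chr1"], copies = 2L)),
                       coverage = 50, read_len = 50, paired = FALSE,
                       seed = 21)
  # depth oracle from the read start positions encoded in the ids
  st <- as.integer(vapply(strsplit(rd$id, "_"), `[`, "", 3))
  for (base in c(5000, 15000, 25000)) {
    depth_at <- sum(st > base - 50 & st <= base)
    expect_gt(depth_at, 50 - 3 * sqrt(50))
    expect_lt(depth_at, 50 + 3 * sqrt(50))
  }
})

test_that("copy-3 truth blocks show 1.5x the diploid read density", {
  p <- make_parental_genomes(1, 4e4, 1e-3, seed = 23)
  # state-3 block: one copy on the intact homologue plus two derived
  # fragments; state-2 block: one plus one
  plan <- structure(list(
    blocks = data.frame(block = 1:2, start = c(1L, 20001L),
                        end = c(20000L, 40000L), state = c(2L, 3L)),
    fragments = data.frame(frag = 1:3, block = c(1L, 2L, 2L),
                           start = c(1L, 20001L, 20001L),
                           end = c(20000L, 40000L, 40000L),
                           strand = c("+", "+", "-")),
    junctions = data.frame(type = c("blunt", "blunt"), mh_len = 0L,
                           ins_len = 0L),
    chrom_len = 4e4L), class = "block_plan")
  sh <- build_shattered_chromosome(p, "chr1", plan, seed = 24)
  nucleus <- list(list(genome = sh$parent_b, copies = 1L),
                  list(genome = sh$derived, copies = 1L))
  rd <- simulate_reads(nucleus, coverage = 40, read_len = 50, paired = FALSE,
                       seed = 25)
  # density oracle from the start positions encoded in the read ids: the
  # parent-B homologue shares reference coordinates; the derived chromosome
  # is block1 (1..20000) then two copies of block2 (20001..60000)
  b_start <- as.integer(sub("^s1_chr1_(\\d+)_.*$", "\\1",
                            rd$id[grepl("^s1_", rd$id)]))
  d_start <- as.integer(sub("^s2_chr1_shattered_(\\d+)_.*$", "\\1",
                            rd$id[grepl("^s2_", rd$id)]))
  rate_b1 <- (sum(b_start <= 18000) + sum(d_start <= 18000)) / 18000
  rate_b2 <- (sum(b_start >= 22001 & b_start <= 38000) +
              sum(d_start >= 22001 & d_start <= 38000) +
              sum(d_start >= 42001 & d_start <= 58000)) / 16000
  expect_gt(rate_b2 / rate_b1, 1.5 * 0.9)
  expect_lt(rate_b2 / rate_b1, 1.5 * 1.1)
})

test_that("fastq round-trips and paired constraints are enforced", {
  p <- make_parental_genomes(1, 2e4, 1e-3, seed = 29)
  expect_error(simulate_reads(list(list(genome = p$parent_a, copies = 2L)),
                              coverage = 10, read_len = 100, paired = TRUE,
                              insert_mean = 150),
               "insert_mean")
  expect_error(simulate_reads(list(list(genome = p$parent_a, copies = 2L)),
                              coverage = 10, read_len = 30000),
               "read_len")
  rd <- simulate_reads(list(list(genome = p$parent_a, copies = 2L)),
                       coverage = 5, read_len = 60, paired = TRUE,
                       insert_mean = 200, insert_sd = 10, seed = 30)
  expect_true(all(rd$mate %in% 1:2))
  f <- tempfile(fileext = ".fastq")
  write_read_fastq(rd, f)
  back <- read_fastq(f)
  expect_equal(back$seq, rd$seq)
  expect_equal(back$mate, rd$mate)
  unlink(f)
})
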