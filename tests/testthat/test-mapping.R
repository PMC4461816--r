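test_that("read filtering drops Ns, trims low-quality tails, enforces min length", {
  reads <- data.frame(
    id = c("n", "clean", "tail"),
    seq = c("ACGNACGT", strrep("ACGT", 10),
            paste0(strrep("AC", 8), strrep("GT", 5))),   # 16 + 10 = 26 bp
    qual = c(strrep("I", 8), strrep("I", 40),
             paste0(strrep("I", 16), strrep("#", 10))),  # Q40 head, Q2 tail
    mate = 0L, stringsAsFactors = FALSE)
  out <- filter_reads(reads, qual_threshold = 20, min_len = 20)
  # N-containing read dropped; clean read untouched; trimmed read falls
  # below min length (26 - 10 = 16 < 20)
  expect_equal(out$id, "clean")
  expect_equal(out$seq, strrep("ACGT", 10))
  # with a laxer min length the trimmed read survives at its trimmed length
  out2 <- filter_reads(reads, qual_threshold = 20, min_len = 10)
  expect_equal(nchar(out2$seq[out2$id == "tail"]), 16)
})

test_that("exact mapper places unique reads and excludes multi-mappers", {
  g <- toy_genome(chr1 = paste0(
    "ACGTACGGTTCAGGCATTACGGATCCGGAAATTTCCCGGGAAACCCTTTG",
    "CATGCATGCGCGCGATATATCCGGTTAACCGGTTAACCAATTGGCCAATT"))
  # unique 20-mer at offset 11 (1-based)
  r_uniq <- substr(as.character(g[[1]]), 11, 30)
  al <- map_reads(g, data.frame(id = "u", seq = r_uniq, qual = "",
                                mate = 0L))
  expect_equal(al$start, 11)
  expect_equal(al$strand, "+")
  # reverse complement maps to the minus strand at the same interval
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r_uniq)))
  al2 <- map_reads(g, data.frame(id = "rc", seq = rc, qual = "", mate = 0L))
  expect_equal(al2$start, 11)
  expect_equal(al2$strand, "-")
  expect_equal(al2$seq, r_uniq)  # stored in reference orientation
  # a repeated sequence is excluded
  g2 <- toy_genome(chr1 = paste0(strrep("A", 30), "CCGGTTCAGGCATTACGGAT",
                                 strrep("T", 30), "CCGGTTCAGGCATTACGGAT",
                                 strrep("G", 30)))
  al3 <- map_reads(g2, data.frame(id = "m", seq = "CCGGTTCAGGCATTACGGAT",
                                  qual = "", mate = 0L))
  expect_equal(nrow(al3), 0)
  expect_error(map_reads(Biostrings::DNAStringSet(), al3), "empty genome")
})

test_that("mapper agrees with a brute-force scan on random genomes", {
  w <- small_world(seed = 5, n_chrom = 2, chrom_len = 2e4)
  g <- w$parent_a
  reads <- simulate_reads(list(list(genome = g, copies = 2L)), coverage = 1,
                          read_len = 40, paired = FALSE, seed = 6)
  reads <- reads[1:200, ]
  al <- map_reads(g, reads)
  for (i in seq_len(50)) {
    hits <- brute_scan(g, reads$seq[i])
    mine <- al[al$id == reads$id[i], ]
    if (nrow(hits) == 1) {
      expect_equal(nrow(mine), 1)
      expect_equal(mine$chrom, hits$chrom)
      expect_equal(mine$start, hits$start)
      expect_equal(mine$strand, hits$strand)
    } else {
      expect_equal(nrow(mine), 0)
    }
  }
})

test_that("hybrid mapping places reads carrying either parent's alleles", {
  w <- small_world(seed = 42)
  snp <- w$snps[5, ]
  chs <- as.character(w$parent_b[[snp$chrom]])
  read_b <- substr(chs, snp$pos - 20, snp$pos + 19)  # carries the B allele
  expect_equal(nrow(map_reads(w$parent_a,
                              data.frame(id = "b", seq = read_b, qual = "",
                                         mate = 0L))), 0)
  al <- map_reads_hybrid(w$parent_a, w$parent_b,
                         data.frame(id = "b", seq = read_b, qual = "",
                                    mate = 0L))
  expect_equal(nrow(al), 1)
  expect_equal(al$chrom, snp$chrom)
  expect_equal(al$start, snp$pos - 20)
})

test_that("SAM ingest honours coordinates, flags and the MAPQ floor", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0, strrep("A", 50), "*",
          sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, strrep("C", 50), "*",
          sep = "\t"),                               # unmapped: skipped
    paste("r3", 256, "chr1", 201, 60, "50M", "*", 0, 0, strrep("G", 50), "*",
          sep = "\t"),                               # secondary: skipped
    paste("r4", 16, "chr1", 301, 5, "30M2D18M", "*", 0, 0, strrep("T", 48),
          "*", sep = "\t"))                          # low MAPQ, reverse
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  al <- read_sam(f, mapq_floor = 20)
  expect_equal(nrow(al), 2)
  expect_equal(al$start[al$id == "r1"], 101)
  expect_true(al$unique[al$id == "r1"])
  r4 <- al[al$id == "r4", ]
  expect_equal(r4$strand, "-")
  expect_equal(r4$width, 50)  # 30M + 2D + 18M consume 50 reference bases
  expect_false(r4$unique)
  # malformed input is rejected with the offending line
  writeLines(c(sam, "broken\tline"), f)
  expect_error(read_sam(f), "line 7")
  writeLines(sam[3:6], f)
  expect_error(read_sam(f), "header")
  unlink(f)
})

test_that("SAM ingest agrees with Rsamtools on a small file", {
  skip_if_not_installed("Rsamtools")
  w <- small_world(seed = 8, n_chrom = 1, chrom_len = 12000)
  g <- w$parent_a
  reads <- simulate_reads(list(list(genome = g, copies = 2L)), coverage = 2,
                          read_len = 50, paired = FALSE, seed = 9)
  al <- map_reads(g, reads)
  sam <- c(sprintf("@HD\tVN:1.6\tSO:unsorted"),
           sprintf("@SQ\tSN:%s\tLN:%d", names(g), Biostrings::width(g)),
           sprintf("%s\t%d\t%s\t%d\t60\t50M\t*\t0\t0\t%s\t%s",
                   al$id, ifelse(al$strand == "-", 16L, 0L), al$chrom,
                   al$start, al$seq, strrep("I", 50)))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  mine <- read_sam(f)
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  ord_m <- order(mine$id)
  ord_s <- order(sb$qname)
  expect_equal(mine$id[ord_m], sb$qname[ord_s])
  expect_equal(mine$start[ord_m], sb$pos[ord_s])
  expect_equal(mine$strand[ord_m], as.character(sb$strand[ord_s]))
  unlink(f)
})

test_that("pileup counts are conserved and recover heterozygous ratios", {
  w <- small_world(seed = 42)
  reads <- simulate_reads(list(list(genome = w$parent_a, copies = 1L),
                               list(genome = w$parent_b, copies = 1L)),
                          coverage = 60, read_len = 50, paired = FALSE,
                          seed = 10)
  al <- map_reads_hybrid(w$parent_a, w$parent_b, reads)
  pos <- w$snps[1:25, c("chrom", "pos")]
  pu <- build_pileup(al, positions = pos, seqlengths = seqlens(w$parent_a))
  # conservation: allele counts equal the number of overlapping alignments
  for (i in seq_len(nrow(pu))) {
    a <- al[al$chrom == pu$chrom[i], ]
    n_over <- sum(a$start <= pu$pos[i] & a$start + a$width - 1 >= pu$pos[i])
    expect_equal(sum(pu[i, c("A", "C", "G", "T")]), n_over)
  }
  # heterozygous positions show both alleles near 50/50 (binomial at the
  # observed depth, 4 sigma guard)
  m <- match(paste(pu$chrom, pu$pos), paste(w$snps$chrom, w$snps$pos))
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  for (i in seq_len(nrow(pu))) {
    d <- sum(cnt[i, ])
    na <- cnt[i, w$snps$allele_a[m[i]]]
    expect_gt(na, d / 2 - 4 * sqrt(d) / 2)
    expect_lt(na, d / 2 + 4 * sqrt(d) / 2)
  }
  # empty alignment set gives an empty pileup
  expect_equal(nrow(build_pileup(al[0, ], positions = pos)), 0)
})
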