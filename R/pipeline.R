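## End-to-end orchestration: simulate -> map -> dosage -> SNP -> junctions ->
## enrichment, with one flat config carrying every analysis constant and all
## randomness funnelled through per-stage seeds derived from one run seed.

#' Default pipeline configuration
#'
#' Returns the flat configuration list used by \code{\link{run_pipeline}}.
#' Analysis constants carry their conventional values (hybrid SNP depth 25,
#' allele fraction 0.40, parental homozygosity 0.97, parental depths 6 and
#' 1, genome-scale dosage bins of 100 kb / 25 kb / 150 kb / 500 bp, 1 Mb
#' parentage bins, 2000 bp breakpoint read-extraction radius, microhomology
#' band 2-15 bp, enrichment windows 1000 and 10000 bp, 1000 shuffles).
#' Simulation-scale overrides (bin and parentage-bin sizes proportioned to
#' the 300 kb synthetic chromosomes) live under \code{sim}.
#'
#' @param seed run seed; every stochastic stage derives its own stream from
#'   it.
#' @return named list of class \code{shatterscan_config}.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    sim = list(
      n_chrom = 5L, chrom_len = 3e5, snp_rate = 1e-3,
      source_chrom = "chr3", n_blocks = 14L, n_fragments = 21L,
      state_probs = rep(0.25, 4), p_invert = 0.5,
      junction_mix = c(microhomology = 1, blunt = 1, insertion = 1) / 3,
      mh_range = c(2L, 15L), ins_range = c(1L, 125L), min_block = 5000L,
      coverage = 50, read_len = 100L, paired = TRUE,
      insert_mean = 400, insert_sd = 40, error_rate = 0,
      parent_coverage_a = 15, parent_coverage_b = 8,
      bin_size = 2000L, fine_bin = 500L, parentage_bin = 5e4,
      gene_fraction = 0.5, origin_fraction = 0.035
    ),
    dosage = list(bin_sizes = c(100000L, 25000L, 150000L, 500L),
                  min_run = 3L, smooth_window = 5L, shatter_min = 5L),
    snp = list(min_hybrid_depth = 25L, min_allele_frac = 0.40,
               min_parent_hom = 0.97, min_depth_a = 6L, min_depth_b = 1L,
               noise_frac = 0.05, parentage_bin = 1e6),
    junctions = list(radius = 2000L, min_overlap = 31L, min_reads = 2L,
                     min_anchor = 30L, mh_min = 2L),
    enrich = list(windows = c(1000L, 10000L), sim_window = 1000L,
                  shuffles = 1000L)
  ), class = "shatterscan_config")
}

#' Validate a pipeline configuration
#'
#' @param config configuration list.
#' @return the config, invisibly; errors on invalid settings.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed)) stopf("config must carry a seed")
  if (config$enrich$shuffles < 100)
    stopf("enrich$shuffles must be >= 100")
  if (config$sim$chrom_len < 10000) stopf("sim$chrom_len must be >= 10000")
  if (config$sim$snp_rate <= 0 || config$sim$snp_rate > 0.05)
    stopf("sim$snp_rate must be in (0, 0.05]")
  if (config$dosage$smooth_window %% 2 == 0)
    stopf("dosage$smooth_window must be odd")
  if (config$junctions$min_overlap < 15)
    stopf("junctions$min_overlap must be >= 15")
  invisible(config)
}

# uniformly placed synthetic feature annotation emulating a sparse or dense
# genomic feature class (genes at ~50% occupancy, origins at ~3.5%)
simulate_features <- function(chrom, chrom_len, fraction, mean_width,
                              seed = NULL) {
  with_seed(seed, {
    n <- max(1L, round(chrom_len * fraction / mean_width))
    starts <- sort(sample.int(chrom_len - mean_width, n))
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, width = mean_width),
      strand = sample(c("+", "-"), n, replace = TRUE))
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
  })
}

#' Run the full analysis pipeline on a simulated nucleus
#'
#' Simulates a Col/Ler-like hybrid carrying one shattered chromosome plus a
#' diploid control hybrid and the two parents; maps all reads; computes
#' dosage profiles, copy segments and karyotype calls; identifies
#' diagnostic SNPs from the control hybrid and assigns the aneuploid
#' sample's reads to parents; detects breakpoints on a fine-binned profile,
#' assembles and classifies junctions; and tests feature enrichment at
#' duplicated- and triplicated-block breakpoints against a permutation
#' null. Rerunning with the same config reproduces every output.
#'
#' @param config configuration from \code{\link{default_config}}.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV alongside the serialized config.
#' @param quiet suppress progress messages.
#' @return list with the truth set and every stage output.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_config(config)
  sc <- config$sim
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating parental genomes and shattered chromosome")
  parents <- make_parental_genomes(sc$n_chrom, sc$chrom_len, sc$snp_rate,
                                   seed = seed)
  plan <- random_block_plan(sc$chrom_len, n_blocks = sc$n_blocks,
                            n_fragments = sc$n_fragments,
                            state_probs = sc$state_probs,
                            junction_mix = sc$junction_mix,
                            p_invert = sc$p_invert, mh_range = sc$mh_range,
                            ins_range = sc$ins_range,
                            min_block = sc$min_block, seed = seed + 1L)
  sh <- build_shattered_chromosome(parents, sc$source_chrom, plan,
                                   seed = seed + 2L)
  genome_a <- sh$parent_a
  genome_b <- sh$parent_b

  say("simulating reads (aneuploid, control hybrid, parents)")
  aneuploid_nucleus <- list(
    list(genome = genome_a[setdiff(names(genome_a), sc$source_chrom)],
         copies = 1L),
    list(genome = genome_b, copies = 1L),
    list(genome = sh$derived, copies = 1L))
  control_nucleus <- list(list(genome = genome_a, copies = 1L),
                          list(genome = genome_b, copies = 1L))
  reads_an <- simulate_reads(aneuploid_nucleus, coverage = sc$coverage,
                             read_len = sc$read_len, paired = sc$paired,
                             insert_mean = sc$insert_mean,
                             insert_sd = sc$insert_sd,
                             error_rate = sc$error_rate, seed = seed + 3L)
  reads_ctrl <- simulate_reads(control_nucleus, coverage = sc$coverage,
                               read_len = sc$read_len, paired = sc$paired,
                               insert_mean = sc$insert_mean,
                               insert_sd = sc$insert_sd,
                               error_rate = sc$error_rate, seed = seed + 4L)
  reads_pa <- simulate_reads(list(list(genome = genome_a, copies = 2L)),
                             coverage = sc$parent_coverage_a,
                             read_len = sc$read_len, paired = FALSE,
                             error_rate = sc$error_rate, seed = seed + 5L)
  reads_pb <- simulate_reads(list(list(genome = genome_b, copies = 2L)),
                             coverage = sc$parent_coverage_b,
                             read_len = sc$read_len, paired = FALSE,
                             error_rate = sc$error_rate, seed = seed + 6L)

  say("mapping reads against both parental references")
  al_an <- map_reads_hybrid(genome_a, genome_b, reads_an)
  al_ctrl <- map_reads_hybrid(genome_a, genome_b, reads_ctrl)
  al_pa <- map_reads_hybrid(genome_a, genome_b, reads_pa)
  al_pb <- map_reads_hybrid(genome_a, genome_b, reads_pb)
  sl <- seqlens(genome_a)

  say("dosage profiling and karyotype classification")
  bins_an <- bin_counts(al_an, sl, sc$bin_size)
  bins_ctrl <- bin_counts(al_ctrl, sl, sc$bin_size)
  profile <- relative_dosage(bins_an, bins_ctrl)
  segments <- segment_profile(profile, min_run = config$dosage$min_run,
                              smooth_window = config$dosage$smooth_window)
  karyotype <- classify_karyotype(segments,
                                  shatter_min = config$dosage$shatter_min)

  say("SNP discovery and parental assignment")
  candidates <- compare_genomes(genome_a, genome_b)[, c("chrom", "pos")]
  pu_ctrl <- build_pileup(al_ctrl, positions = candidates, seqlengths = sl)
  pu_pa <- build_pileup(al_pa, positions = candidates, seqlengths = sl)
  pu_pb <- build_pileup(al_pb, positions = candidates, seqlengths = sl)
  snps <- identify_snps(pu_ctrl, pu_pa, pu_pb,
                        min_hybrid_depth = config$snp$min_hybrid_depth,
                        min_allele_frac = config$snp$min_allele_frac,
                        min_parent_hom = config$snp$min_parent_hom,
                        min_depth_a = config$snp$min_depth_a,
                        min_depth_b = config$snp$min_depth_b,
                        noise_frac = config$snp$noise_frac)
  calls <- assign_reads(al_an, snps)
  parentage <- bin_parentage(calls, sl, bin_size = sc$parentage_bin)
  state_fractions <- parent_fraction_by_state(calls, segments)

  say("breakpoint detection and junction assembly")
  fine_an <- bin_counts(al_an, sl, sc$fine_bin)
  fine_ctrl <- bin_counts(al_ctrl, sl, sc$fine_bin)
  fine_profile <- relative_dosage(fine_an, fine_ctrl)
  fine_segments <- segment_profile(fine_profile,
                                   min_run = config$dosage$min_run,
                                   smooth_window = config$dosage$smooth_window)
  breakpoints <- detect_breakpoints(fine_segments)
  # the outer edges of a restructured chromosome are breakpoint candidates
  # too: terminal fragments can join chromosome-end block edges
  noneu <- karyotype$chrom[karyotype$class != "euploid"]
  extra <- do.call(rbind, lapply(noneu, function(ch) {
    data.frame(chrom = ch, pos = c(1L, sl[[ch]]),
               left_state = NA_integer_, right_state = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  bp_all <- rbind(breakpoints, extra)
  idx <- genome_index(genome_a, genome_b)
  junctions <- NULL
  for (i in seq_len(nrow(bp_all))) {
    ext <- extract_breakpoint_reads(al_an, reads_an, bp_all$chrom[i],
                                    bp_all$pos[i],
                                    radius = config$junctions$radius)
    seeds <- ext$seq[!ext$mapped]
    if (length(seeds) == 0) next
    ctg <- assemble_local(ext, min_overlap = config$junctions$min_overlap,
                          min_reads = config$junctions$min_reads,
                          seeds = seeds)
    for (k in seq_len(nrow(ctg))) {
      segs <- chain_contig(ctg$contig[k], genome_a,
                           min_anchor = config$junctions$min_anchor,
                           hint = list(chrom = bp_all$chrom[i],
                                       pos = bp_all$pos[i]),
                           .idx = idx)
      j <- chain_junctions(segs, ctg$contig[k],
                           mh_min = config$junctions$mh_min)
      j <- j[!j$ambiguous, , drop = FALSE]
      if (nrow(j)) junctions <- rbind(junctions, j)
    }
  }
  if (!is.null(junctions)) {
    junctions <- canonical_junctions(junctions)
    key <- paste(junctions$chrom_left, junctions$pos_left,
                 junctions$chrom_right, junctions$pos_right, junctions$type,
                 junctions$mh_len, junctions$insertion_seq)
    junctions <- junctions[!duplicated(key), , drop = FALSE]
    rownames(junctions) <- NULL
  } else {
    junctions <- data.frame(
      chrom_left = character(0), pos_left = integer(0),
      side_left = character(0), strand_left = character(0),
      chrom_right = character(0), pos_right = integer(0),
      side_right = character(0), strand_right = character(0),
      type = character(0), mh_len = integer(0), ins_len = integer(0),
      insertion_seq = character(0), inverted = logical(0),
      ambiguous = logical(0), contig = character(0))
  }

  say("feature enrichment at breakpoints")
  src <- sc$source_chrom
  genes <- simulate_features(src, sc$chrom_len, sc$gene_fraction, 2000,
                             seed = seed + 7L)
  origins <- simulate_features(src, sc$chrom_len, sc$origin_fraction, 500,
                               seed = seed + 8L)
  bp_src <- breakpoints[breakpoints$chrom == src, , drop = FALSE]
  dup_bp <- bp_src$pos[bp_src$left_state == 3 | bp_src$right_state == 3]
  trip_bp <- bp_src$pos[bp_src$left_state == 4 | bp_src$right_state == 4]
  enr <- list()
  for (feat in c("gene", "replication_origin")) {
    fg <- if (feat == "gene") genes else origins
    for (cls in c("duplicated", "triplicated")) {
      bp <- if (cls == "duplicated") dup_bp else trip_bp
      if (length(bp) == 0) next
      enr[[length(enr) + 1L]] <- permutation_p(
        bp, fg, config$enrich$sim_window, src, sc$chrom_len,
        n_shuffles = config$enrich$shuffles, seed = seed + 9L,
        feature_class = feat, breakpoint_class = cls)
    }
  }
  enrichment <- if (length(enr)) do.call(rbind, enr) else
    data.frame(feature = character(0), breakpoint_class = character(0),
               window = integer(0), occ_in = numeric(0),
               occ_elsewhere = numeric(0), ratio = numeric(0),
               p_enrich = numeric(0), p_deplete = numeric(0),
               n_shuffles = integer(0), seed = integer(0))

  res <- list(config = config, truth = sh$truth, snps_truth = sh$snps,
              genome_a = genome_a, genome_b = genome_b, derived = sh$derived,
              reads = list(aneuploid = reads_an, control = reads_ctrl,
                           parent_a = reads_pa, parent_b = reads_pb),
              alignments = list(aneuploid = al_an, control = al_ctrl,
                                parent_a = al_pa, parent_b = al_pb),
              pileups = list(control = pu_ctrl, parent_a = pu_pa,
                             parent_b = pu_pb),
              profile = profile, segments = segments, karyotype = karyotype,
              snps = snps, calls = calls, parentage = parentage,
              state_fractions = state_fractions,
              fine_segments = fine_segments, breakpoints = breakpoints,
              junctions = junctions, features = list(gene = genes,
                                                     replication_origin = origins),
              enrichment = enrichment)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Write pipeline outputs to a run directory
#'
#' @param res result list from \code{\link{run_pipeline}}.
#' @param out_dir output directory (created).
#' @export
write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$profile, "dosage_profile.tsv")
  wt(res$segments, "segments.tsv")
  wt(res$karyotype, "karyotype.tsv")
  wt(res$snps, "snps.tsv")
  wt(res$parentage, "parentage_bins.tsv")
  wt(res$state_fractions, "parent_fraction_by_state.tsv")
  wt(res$breakpoints, "breakpoints.tsv")
  wt(res$junctions, "junctions.tsv")
  if (!is.null(res$enrichment)) wt(res$enrichment, "enrichment.tsv")
  cfg <- res$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
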