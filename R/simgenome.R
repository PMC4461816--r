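## Synthetic genomes, shattered chromosomes, reads and truth sets.
##
## The generator emulates a Col/Ler-like hybrid: two parental haplotypes
## differing only at planted SNPs, a diploid background, and one derived
## ("shattered") chromosome built from blocks of one parent at copy states
## 1-4, joined by junctions carrying microhomology, blunt fusions or short
## novel insertions, with roughly half of the fragments inverted.
## All coordinates are 1-based closed intervals (the IRanges convention).

#' Generate a pair of parental genomes differing at planted SNPs
#'
#' Builds a random genome for parent A (the haploid-inducer analogue) and a
#' second haplotype for parent B that differs from it only by single-base
#' substitutions at the returned SNP positions.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (all chromosomes equal; >= 10000).
#' @param snp_rate per-bp probability of a diagnostic SNP, in (0, 0.05].
#' @param seed integer seed; the call is deterministic given the seed.
#' @return list with elements \code{parent_a}, \code{parent_b} (named
#'   \code{DNAStringSet}s) and \code{snps}, a data.frame with columns
#'   \code{chrom}, \code{pos} (1-based), \code{allele_a}, \code{allele_b}.
#' @export
make_parental_genomes <- function(n_chrom = 5, chrom_len = 3e5,
                                  snp_rate = 1e-3, seed = NULL) {
  if (!is.numeric(snp_rate) || snp_rate <= 0 || snp_rate > 0.05)
    stopf("snp_rate must be in (0, 0.05], got %s", format(snp_rate))
  if (chrom_len < 10000)
    stopf("chrom_len must be >= 10000, got %d", chrom_len)
  if (n_chrom < 1) stopf("n_chrom must be >= 1")
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    seqs_a <- character(n_chrom)
    seqs_b <- character(n_chrom)
    snps <- vector("list", n_chrom)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_chrom)) {
      a <- sample(bases, chrom_len, replace = TRUE)
      n_snp <- stats::rbinom(1, chrom_len, snp_rate)
      pos <- sort(sample.int(chrom_len, n_snp))
      b <- a
      if (n_snp > 0) {
        ref <- a[pos]
        # substitute each SNP with one of the three alternative bases
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
        b[pos] <- alt
        snps[[i]] <- data.frame(chrom = chroms[i], pos = pos,
                                allele_a = ref, allele_b = unname(alt),
                                stringsAsFactors = FALSE)
      } else {
        snps[[i]] <- data.frame(chrom = character(0), pos = integer(0),
                                allele_a = character(0),
                                allele_b = character(0))
      }
      seqs_a[i] <- paste(a, collapse = "")
      seqs_b[i] <- paste(b, collapse = "")
    }
    parent_a <- Biostrings::DNAStringSet(stats::setNames(seqs_a, chroms))
    parent_b <- Biostrings::DNAStringSet(stats::setNames(seqs_b, chroms))
    list(parent_a = parent_a, parent_b = parent_b,
         snps = do.call(rbind, snps))
  })
}

#' Compare two parental genomes base by base
#'
#' Direct sequence comparison returning every position at which the two
#' haplotypes differ. Used as the pipeline's SNP candidate list and as the
#' independent check that no off-plan differences exist.
#'
#' @param parent_a,parent_b named \code{DNAStringSet}s with identical names
#'   and lengths.
#' @return data.frame(chrom, pos, allele_a, allele_b).
#' @export
compare_genomes <- function(parent_a, parent_b) {
  stopifnot(identical(names(parent_a), names(parent_b)))
  out <- lapply(names(parent_a), function(ch) {
    ra <- charToRaw(as.character(parent_a[[ch]]))
    rb <- charToRaw(as.character(parent_b[[ch]]))
    if (length(ra) != length(rb))
      stopf("chromosome %s differs in length between parents", ch)
    d <- which(ra != rb)
    data.frame(chrom = if (length(d)) ch else character(0), pos = d,
               allele_a = strsplit(rawToChar(ra[d]), "")[[1]],
               allele_b = strsplit(rawToChar(rb[d]), "")[[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Draw a random block plan for a shattered chromosome
#'
#' Partitions the source chromosome into \code{n_blocks} contiguous blocks,
#' assigns each an integer copy state in 1-4 (adjacent blocks always differ,
#' giving the oscillating profile characteristic of chromothripsis), then
#' lays out the derived chromosome as a shuffled sequence of fragments in
#' which a block of state s appears s - 1 times. Junction chemistry between
#' adjacent fragments is drawn from \code{junction_mix}.
#'
#' @param chrom_len length of the source chromosome.
#' @param n_blocks number of blocks to cut the chromosome into.
#' @param n_fragments optional exact number of fragments in the derived
#'   chromosome (= planted junctions + 1); states are resampled until the
#'   multiplicities sum to this value.
#' @param state_probs sampling weights for copy states 1:4.
#' @param junction_mix named weights for types
#'   \code{c(microhomology=, blunt=, insertion=)}.
#' @param p_invert probability a fragment is placed in reverse orientation.
#' @param mh_range,ins_range inclusive ranges for microhomology length and
#'   insertion length.
#' @param min_block minimum block width in bp.
#' @param seed integer seed.
#' @return an object of class \code{block_plan}: list with data.frames
#'   \code{blocks} (block, start, end, state), \code{fragments}
#'   (frag, block, start, end, strand) in derived order, and
#'   \code{junctions} (type, mh_len, ins_len) for each adjacent pair.
#' @export
random_block_plan <- function(chrom_len, n_blocks = 14, n_fragments = NULL,
                              state_probs = rep(0.25, 4),
                              junction_mix = c(microhomology = 1, blunt = 1,
                                               insertion = 1) / 3,
                              p_invert = 0.5, mh_range = c(2, 15),
                              ins_range = c(1, 125), min_block = 2000,
                              seed = NULL) {
  if (n_blocks < 2) stopf("n_blocks must be >= 2")
  chrom_len <- as.integer(chrom_len)
  if (n_blocks * min_block > chrom_len)
    stopf("chrom_len too small for %d blocks of >= %d bp", n_blocks, min_block)
  with_seed(seed, {
    for (try in 1:2000) {
      cuts <- sort(sample.int(chrom_len - 1, n_blocks - 1))
      if (all(diff(c(0, cuts, chrom_len)) >= min_block)) break
      if (try == 2000) stopf("could not place %d blocks of >= %d bp", n_blocks, min_block)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, chrom_len)
    # adjacent blocks must change state so every block edge is a dosage
    # transition; optionally hit an exact fragment count
    for (try in 1:5000) {
      states <- integer(n_blocks)
      states[1] <- sample(1:4, 1, prob = state_probs)
      for (i in 2:n_blocks) {
        allowed <- setdiff(1:4, states[i - 1])
        states[i] <- sample(allowed, 1, prob = state_probs[allowed])
      }
      nf <- sum(states - 1L)
      if (is.null(n_fragments) && nf >= 2) break
      if (!is.null(n_fragments) && nf == n_fragments) break
      if (try == 5000) stopf("could not satisfy fragment-count constraint")
    }
    blocks <- data.frame(block = seq_len(n_blocks), start = starts,
                         end = ends, state = states)
    fb0 <- rep(blocks$block, blocks$state - 1L)
    flips <- function(s) ifelse(s == "+", "-", "+")
    for (try in 1:2000) {
      frag_block <- fb0[sample(seq_along(fb0))]
      strand <- ifelse(stats::runif(length(frag_block)) < p_invert, "-", "+")
      # break colinear seams: a pair of consecutive fragments that are
      # reference-adjacent on the same strand would rebuild the reference
      # locally and leave no detectable junction; flip the right fragment
      for (i in seq_len(length(frag_block) - 1L)) {
        colinear <- strand[i] == strand[i + 1L] &&
          ((strand[i] == "+" && frag_block[i + 1L] == frag_block[i] + 1L) ||
           (strand[i] == "-" && frag_block[i + 1L] == frag_block[i] - 1L))
        if (colinear) strand[i + 1L] <- flips(strand[i + 1L])
      }
      # and reject layouts that repeat an adjacency (or its mirror image):
      # such junctions would share both reference anchors and could be
      # indistinguishable
      i <- seq_len(length(frag_block) - 1L)
      fwd <- paste(frag_block[i], strand[i], frag_block[i + 1L], strand[i + 1L])
      mir <- paste(frag_block[i + 1L], flips(strand[i + 1L]), frag_block[i],
                   flips(strand[i]))
      key <- pmin(fwd, mir)
      if (!anyDuplicated(key)) break
      if (try == 2000) stopf("could not lay out fragments without duplicate adjacencies")
    }
    fragments <- data.frame(
      frag = seq_along(frag_block),
      block = frag_block,
      start = blocks$start[frag_block],
      end = blocks$end[frag_block],
      strand = strand,
      stringsAsFactors = FALSE
    )
    nj <- nrow(fragments) - 1L
    types <- sample(names(junction_mix), nj, replace = TRUE,
                    prob = junction_mix)
    # fold-back adjacencies (same block, opposite strands) would need a
    # palindromic overlap; they are joined blunt or with an insertion
    foldback <- fragments$block[-nrow(fragments)] == fragments$block[-1] &
      fragments$strand[-nrow(fragments)] != fragments$strand[-1]
    for (j in which(foldback & types == "microhomology"))
      types[j] <- sample(c("blunt", "insertion"), 1)
    # at most one microhomology junction may claim a given (block, strand)
    # acceptor start: the acceptor flank is edited in reference space and two
    # different donors cannot both be matched there
    key <- paste(fragments$block[-1], fragments$strand[-1])
    seen <- character(0)
    for (j in which(types == "microhomology")) {
      if (key[j] %in% seen) types[j] <- sample(c("blunt", "insertion"), 1)
      else seen <- c(seen, key[j])
    }
    junctions <- data.frame(
      type = types,
      mh_len = ifelse(types == "microhomology",
                      sample(mh_range[1]:mh_range[2], nj, replace = TRUE), 0L),
      ins_len = ifelse(types == "insertion",
                       sample(ins_range[1]:ins_range[2], nj, replace = TRUE), 0L),
      stringsAsFactors = FALSE
    )
    structure(list(blocks = blocks, fragments = fragments,
                   junctions = junctions, chrom_len = chrom_len),
              class = "block_plan")
  })
}

# ---- derived-orientation accessors over a character-vector chromosome ----

frag_width <- function(f) f$end - f$start + 1L

# i-th base of fragment f read in derived orientation
derived_base <- function(refv, f, i) {
  if (f$strand == "+") refv[f$start + i - 1L] else comp_base(refv[f$end - i + 1L])
}

# i-th base counting from the derived end of fragment f
derived_base_from_end <- function(refv, f, i) {
  if (f$strand == "+") refv[f$end - i + 1L] else comp_base(refv[f$start + i - 1L])
}

# last k bases of f in derived orientation
derived_last_k <- function(refv, f, k) {
  vapply(k:1, function(i) derived_base_from_end(refv, f, i), "")
}

derived_first_k <- function(refv, f, k) {
  vapply(seq_len(k), function(i) derived_base(refv, f, i), "")
}

# reference positions storing the first k derived bases of f
first_k_positions <- function(f, k) {
  if (f$strand == "+") f$start + 0:(k - 1L) else f$end - 0:(k - 1L)
}

# write derived-orientation values into the first k bases of f
set_first_k <- function(refv, f, vals) {
  k <- length(vals)
  if (f$strand == "+") refv[f$start + 0:(k - 1L)] <- vals
  else refv[f$end - 0:(k - 1L)] <- comp_base(vals)
  refv
}

# reference position (and orientation) of the base just beyond f's derived end
pos_after <- function(f, len) {
  p <- if (f$strand == "+") f$end + 1L else f$start - 1L
  if (p < 1L || p > len) NA_integer_ else p
}
base_after <- function(refv, f) {
  p <- pos_after(f, length(refv))
  if (is.na(p)) return(NA_character_)
  if (f$strand == "+") refv[p] else comp_base(refv[p])
}
# reference position of the base just before f's derived start
pos_before <- function(f, len) {
  p <- if (f$strand == "+") f$start - 1L else f$end + 1L
  if (p < 1L || p > len) NA_integer_ else p
}
base_before <- function(refv, f) {
  p <- pos_before(f, length(refv))
  if (is.na(p)) return(NA_character_)
  if (f$strand == "+") refv[p] else comp_base(refv[p])
}

# set the reference base at ref position p so that its derived-orientation
# value (w.r.t. strand) avoids every base in `forbid`
edit_avoiding <- function(refv, p, strand, forbid) {
  choices <- setdiff(c("A", "C", "G", "T"),
                     if (strand == "+") forbid else comp_base(forbid))
  refv[p] <- if (length(choices)) sample(choices, 1) else refv[p]
  refv
}

#' Build a shattered chromosome from a block plan
#'
#' Concatenates the plan's oriented fragments into a derived chromosome.
#' Microhomology junctions share the terminal k bases of the left fragment
#' with the initial k bases of the right fragment (written once in the
#' derived sequence); where the reference flanks are incompatible the
#' acceptor fragment's first k bases are edited in the reference (identically
#' in both parents, so no off-plan SNPs arise) and the edit is recorded.
#' Single flanking bases are likewise edited where they would create
#' accidental homology extending a junction's signature, so that the realized
#' junction signature equals the planted one. Blunt junctions concatenate
#' directly; insertion junctions interpose a novel random sequence.
#'
#' @param parents list as returned by \code{\link{make_parental_genomes}}.
#' @param source_chrom name of the chromosome to shatter (parent A origin).
#' @param plan a \code{block_plan}; if \code{NULL} a random plan is drawn
#'   (extra arguments \code{...} are passed to \code{\link{random_block_plan}}).
#' @param seed integer seed for insertion sequences, flank edits and (if
#'   drawn here) the random plan.
#' @param ... passed to \code{\link{random_block_plan}} when plan is NULL.
#' @return list with \code{derived} (named \code{DNAStringSet} of one
#'   sequence), \code{truth} (blocks, fragments, junction table in reference
#'   and derived coordinates, reference edits, intended class), and the
#'   possibly edited \code{parent_a}, \code{parent_b}, \code{snps}.
#' @export
build_shattered_chromosome <- function(parents, source_chrom, plan = NULL,
                                       seed = NULL, ...) {
  stopifnot(source_chrom %in% names(parents$parent_a))
  with_seed(seed, {
    len <- Biostrings::width(parents$parent_a[source_chrom])
    if (is.null(plan)) plan <- random_block_plan(chrom_len = len, ...)
    fr <- plan$fragments
    jc <- plan$junctions
    if (nrow(fr) < 2) stopf("plan must contain at least two fragments")
    if (any(fr$start < 1 | fr$end > len | fr$start > fr$end))
      stopf("plan intervals fall outside %s", source_chrom)
    if (any(jc$type == "microhomology" &
            (jc$mh_len < 1 | jc$mh_len >= pmin(frag_width(fr[-1, ]),
                                               frag_width(fr[-nrow(fr), ])))))
      stopf("microhomology length must be shorter than both flanking fragments")

    refa <- strsplit(as.character(parents$parent_a[[source_chrom]]), "")[[1]]
    refb <- strsplit(as.character(parents$parent_b[[source_chrom]]), "")[[1]]
    edited <- integer(0)

    # positions pinned by microhomology acceptor windows: a no-extension edit
    # must not touch these
    pinned <- unlist(lapply(which(jc$type == "microhomology"), function(j) {
      first_k_positions(fr[j + 1L, ], jc$mh_len[j])
    }))

    apply_edit <- function(p, val) {
      if (refa[p] != val || refb[p] != val) edited <<- c(edited, p)
      refa[p] <<- val
      refb[p] <<- val
    }

    # fix-point resolution of microhomology planting and accidental-homology
    # suppression; edits propagate through shared reference regions
    for (iter in 1:30) {
      changed <- FALSE
      for (j in seq_len(nrow(jc))) {
        L <- fr[j, ]; R <- fr[j + 1L, ]
        k <- if (jc$type[j] == "microhomology") jc$mh_len[j] else 0L
        if (k > 0) {
          need <- derived_last_k(refa, L, k)
          cur <- derived_first_k(refa, R, k)
          if (!identical(cur, need)) {
            ps <- first_k_positions(R, k)
            vals <- if (R$strand == "+") need else comp_base(need)
            for (t in seq_len(k)) apply_edit(ps[t], vals[t])
            changed <- TRUE
          }
        }
        if (jc$type[j] %in% c("microhomology", "blunt")) {
          # forward: the derived base after the junction must not equal the
          # reference continuation of L, else the prefix anchor over-extends
          cont <- base_after(refa, L)
          nxt <- derived_base(refa, R, k + 1L)
          if (!is.na(cont) && cont == nxt) {
            p <- pos_after(L, len)
            if (!(p %in% pinned)) {
              refa_new <- edit_avoiding(refa, p, L$strand, nxt)
              apply_edit(p, refa_new[p])
            } else {
              # acceptor side pinned: edit the fragment-interior base instead
              p2 <- if (R$strand == "+") R$start + k else R$end - k
              if (!(p2 %in% pinned)) {
                refa_new <- edit_avoiding(refa, p2, R$strand, cont)
                apply_edit(p2, refa_new[p2])
              }
            }
            changed <- TRUE
          }
          # backward: the derived base before the junction must not equal the
          # reference continuation of R read leftwards
          cont2 <- base_before(refa, R)
          prv <- derived_base_from_end(refa, L, k + 1L)
          if (!is.na(cont2) && cont2 == prv) {
            p <- pos_before(R, len)
            if (!(p %in% pinned)) {
              refa_new <- edit_avoiding(refa, p, R$strand, prv)
              apply_edit(p, refa_new[p])
            } else {
              p2 <- if (L$strand == "+") L$end - k else L$start + k
              if (!(p2 %in% pinned)) {
                refa_new <- edit_avoiding(refa, p2, L$strand, cont2)
                apply_edit(p2, refa_new[p2])
              }
            }
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }

    # insertion sequences: endpoints must not extend a flank match
    ins_seqs <- character(nrow(jc))
    for (j in seq_len(nrow(jc))) {
      if (jc$type[j] != "insertion") next
      L <- fr[j, ]; R <- fr[j + 1L, ]
      s <- sample(c("A", "C", "G", "T"), jc$ins_len[j], replace = TRUE)
      cont <- base_after(refa, L)
      if (!is.na(cont) && s[1] == cont)
        s[1] <- sample(setdiff(c("A", "C", "G", "T"), cont), 1)
      cont2 <- base_before(refa, R)
      if (!is.na(cont2) && s[length(s)] == cont2)
        s[length(s)] <- sample(setdiff(c("A", "C", "G", "T"), cont2), 1)
      ins_seqs[j] <- paste(s, collapse = "")
    }

    # assemble the derived sequence
    ref_str <- paste(refa, collapse = "")
    frag_seq <- function(f) {
      s <- substr(ref_str, f$start, f$end)
      if (f$strand == "-") revcomp(s) else s
    }
    pieces <- character(0)
    pos_derived <- integer(nrow(jc))
    cur_len <- 0L
    for (i in seq_len(nrow(fr))) {
      fs <- frag_seq(fr[i, ])
      if (i == 1L) {
        pieces <- fs
        cur_len <- nchar(fs)
      } else {
        j <- i - 1L
        if (jc$type[j] == "microhomology") {
          pieces <- c(pieces, substr(fs, jc$mh_len[j] + 1L, nchar(fs)))
        } else if (jc$type[j] == "insertion") {
          pieces <- c(pieces, ins_seqs[j], fs)
        } else {
          pieces <- c(pieces, fs)
        }
        pos_derived[j] <- cur_len
        cur_len <- cur_len +
          switch(jc$type[j],
                 microhomology = nchar(fs) - jc$mh_len[j],
                 insertion = jc$ins_len[j] + nchar(fs),
                 blunt = nchar(fs))
      }
    }
    derived <- paste(pieces, collapse = "")

    # junction truth in reference coordinates
    anchor_left <- function(f) {
      if (f$strand == "+") list(pos = f$end, side = "upstream", strand = "+")
      else list(pos = f$start, side = "downstream", strand = "-")
    }
    anchor_right <- function(f) {
      if (f$strand == "+") list(pos = f$start, side = "downstream", strand = "+")
      else list(pos = f$end, side = "upstream", strand = "-")
    }
    jt <- do.call(rbind, lapply(seq_len(nrow(jc)), function(j) {
      al <- anchor_left(fr[j, ]); ar <- anchor_right(fr[j + 1L, ])
      data.frame(junction = j,
                 chrom_left = source_chrom, pos_left = al$pos,
                 side_left = al$side, strand_left = al$strand,
                 chrom_right = source_chrom, pos_right = ar$pos,
                 side_right = ar$side, strand_right = ar$strand,
                 type = jc$type[j], mh_len = jc$mh_len[j],
                 ins_len = jc$ins_len[j], insertion_seq = ins_seqs[j],
                 inverted = fr$strand[j] != fr$strand[j + 1L],
                 pos_derived = pos_derived[j],
                 stringsAsFactors = FALSE)
    }))

    # measure the realized junction signature on the final reference: flank
    # suppression makes it equal the planted one in all but rare pinned
    # conflicts, where an accidental 1-2 bp homology extension survives; the
    # truth table records what an ideal detector would report
    jt$planted_type <- jt$type
    jt$planted_mh_len <- jt$mh_len
    ref_after_t <- function(f, t) {
      p <- if (f$strand == "+") f$end + t else f$start - t
      if (p < 1L || p > len) return(NA_character_)
      if (f$strand == "+") refa[p] else comp_base(refa[p])
    }
    ref_before_t <- function(f, t) {
      p <- if (f$strand == "+") f$start - t else f$end + t
      if (p < 1L || p > len) return(NA_character_)
      if (f$strand == "+") refa[p] else comp_base(refa[p])
    }
    # walk the built sequence against the reference on both sides of each
    # junction point: the prefix-side match may extend past the nominal left
    # fragment end and the suffix-side match reaches left through any shared
    # bases, so the measured overlap is exactly what a split aligner sees
    for (j in seq_len(nrow(jc))) {
      if (jc$type[j] == "insertion") next  # endpoints resampled above: exact
      L <- fr[j, ]; R <- fr[j + 1L, ]
      k <- if (jc$type[j] == "microhomology") jc$mh_len[j] else 0L
      p <- pos_derived[j]
      dlen <- nchar(derived)
      f_ext <- 0L
      while (f_ext < 25L && p + f_ext + 1L <= dlen) {
        a <- ref_after_t(L, f_ext + 1L)
        if (is.na(a) || a != substr(derived, p + f_ext + 1L, p + f_ext + 1L))
          break
        f_ext <- f_ext + 1L
      }
      b_ext <- 0L
      while (b_ext < k + 25L && p - b_ext >= 1L) {
        ti <- k - b_ext  # R-index of the reference base compared next
        rb <- if (ti >= 1L) derived_base(refa, R, ti) else
          ref_before_t(R, 1L - ti)
        if (is.na(rb) || rb != substr(derived, p - b_ext, p - b_ext)) break
        b_ext <- b_ext + 1L
      }
      o <- f_ext + b_ext
      jt$type[j] <- if (o >= 2) "microhomology" else "blunt"
      jt$mh_len[j] <- if (o >= 2) o else 0L
      jt$pos_left[j] <- jt$pos_left[j] +
        if (fr$strand[j] == "+") f_ext else -f_ext
      shift_r <- k - b_ext
      jt$pos_right[j] <- jt$pos_right[j] +
        if (fr$strand[j + 1L] == "+") shift_r else -shift_r
    }
    jt$realized_exact <- jt$type == jt$planted_type &
      jt$mh_len == jt$planted_mh_len

    # drop planted SNPs destroyed by reference edits (both parents now equal)
    snps <- parents$snps
    if (length(edited)) {
      hit <- snps$chrom == source_chrom & snps$pos %in% edited
      snps <- snps[!hit, , drop = FALSE]
    }
    pa <- parents$parent_a
    pb <- parents$parent_b
    pa[[source_chrom]] <- Biostrings::DNAString(paste(refa, collapse = ""))
    pb[[source_chrom]] <- Biostrings::DNAString(paste(refb, collapse = ""))

    derived_name <- paste0(source_chrom, "_shattered")
    truth <- list(
      source_chrom = source_chrom,
      chrom_len = len,
      blocks = cbind(plan$blocks, parent = "A", chrom = source_chrom,
                     stringsAsFactors = FALSE),
      fragments = fr,
      junctions = jt,
      edits = sort(unique(edited)),
      class = "shattered",
      derived_name = derived_name
    )
    list(derived = Biostrings::DNAStringSet(stats::setNames(derived, derived_name)),
         truth = truth, parent_a = pa, parent_b = pb, snps = snps)
  })
}

#' Expected copy states along the source chromosome
#'
#' Copy state of a base = 1 (intact parent B homologue) + the number of
#' derived-chromosome fragments covering it. For plans in which a block of
#' state s contributes s - 1 fragments this reproduces the planted states.
#'
#' @param truth truth list from \code{\link{build_shattered_chromosome}}.
#' @return data.frame(start, end, state) tiling the source chromosome.
#' @export
truth_copy_states <- function(truth) {
  fr <- truth$fragments
  cov <- as.integer(IRanges::coverage(IRanges::IRanges(fr$start, fr$end),
                                      width = truth$chrom_len))
  r <- rle(1L + cov)
  ends <- cumsum(r$lengths)
  data.frame(start = c(1L, utils::head(ends, -1) + 1L), end = ends,
             state = r$values)
}

#' Simulate error-free or noisy short reads from a nucleus
#'
#' Draws uniform single-end or paired-end reads from a set of sequences with
#' integer copy counts. Expected depth at a base is proportional to its total
#' copy count; \code{coverage} anchors the depth of a copy-2 (diploid
#' background) base. Paired mates are emitted on opposite strands flanking a
#' normally distributed insert. Qualities are constant Q40.
#'
#' @param nucleus list of entries \code{list(genome = DNAStringSet, copies = n)}.
#' @param coverage expected depth of a copy-state-2 base (> 0).
#' @param read_len read length in bp.
#' @param paired emit read pairs.
#' @param insert_mean,insert_sd insert size distribution (paired only);
#'   \code{insert_mean} must exceed \code{2 * read_len}.
#' @param error_rate per-base uniform substitution probability.
#' @param seed integer seed; identical seeds give byte-identical reads.
#' @return a ReadSet: data.frame(id, seq, qual, mate) where mate is 0 for
#'   single-end reads and 1/2 for pairs sharing an id.
#' @export
simulate_reads <- function(nucleus, coverage = 50, read_len = 100,
                           paired = TRUE, insert_mean = 400, insert_sd = 40,
                           error_rate = 0, seed = NULL) {
  if (coverage <= 0) stopf("coverage must be > 0")
  if (paired && insert_mean <= 2 * read_len)
    stopf("insert_mean must exceed 2 * read_len for paired reads")
  minw <- min(unlist(lapply(nucleus, function(e) Biostrings::width(e$genome))))
  if (read_len > minw)
    stopf("read_len %d exceeds shortest sequence (%d bp)", read_len, minw)
  with_seed(seed, {
    out <- vector("list", 0)
    for (ei in seq_along(nucleus)) {
      entry <- nucleus[[ei]]
      g <- entry$genome
      copies <- entry$copies
      for (ch in names(g)) {
        L <- Biostrings::width(g[ch])
        chs <- as.character(g[[ch]])
        depth <- coverage / 2 * copies
        if (paired) {
          n <- round(depth * L / (2 * read_len))
          if (n < 1) next
          frag <- pmin(pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                            2L * read_len), L)
          start <- 1L + floor(stats::runif(n) * (L - frag + 1))
          r1 <- substring(chs, start, start + read_len - 1L)
          r2 <- revcomp(substring(chs, start + frag - read_len, start + frag - 1L))
          id <- sprintf("s%d_%s_%d_%d", ei, ch, start, seq_len(n))
          out[[length(out) + 1L]] <- data.frame(
            id = c(id, id), seq = c(r1, r2),
            qual = strrep("I", read_len),
            mate = rep(c(1L, 2L), each = n), stringsAsFactors = FALSE)
        } else {
          n <- round(depth * L / read_len)
          if (n < 1) next
          start <- 1L + floor(stats::runif(n) * (L - read_len + 1))
          r1 <- substring(chs, start, start + read_len - 1L)
          flip <- stats::runif(n) < 0.5
          r1[flip] <- revcomp(r1[flip])
          id <- sprintf("s%d_%s_%d_%d", ei, ch, start, seq_len(n))
          out[[length(out) + 1L]] <- data.frame(
            id = id, seq = r1, qual = strrep("I", read_len), mate = 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    reads <- do.call(rbind, out)
    if (is.null(reads))
      return(data.frame(id = character(0), seq = character(0),
                        qual = character(0), mate = integer(0)))
    rownames(reads) <- NULL
    if (error_rate > 0) {
      nerr <- stats::rbinom(nrow(reads), nchar(reads$seq), error_rate)
      for (i in which(nerr > 0)) {
        s <- strsplit(reads$seq[i], "")[[1]]
        p <- sample.int(length(s), nerr[i])
        s[p] <- vapply(s[p], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        reads$seq[i] <- paste(s, collapse = "")
      }
    }
    reads
  })
}

#' Write a genome as FASTA
#' @param genome named \code{DNAStringSet}.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a ReadSet as FASTQ
#' @param reads ReadSet data.frame (id, seq, qual, mate).
#' @param path output file (".gz" suffix gzips).
#' @export
write_read_fastq <- function(reads, path) {
  ids <- ifelse(reads$mate > 0, paste0(reads$id, "/", reads$mate), reads$id)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file into a ReadSet
#' @param path FASTQ file, optionally gzipped.
#' @return ReadSet data.frame(id, seq, qual, mate).
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) stopf("truncated FASTQ: %s", path)
  ids <- sub("^@", "", ln[seq(1, length(ln), 4)])
  ids <- sub("\\s.*$", "", ids)
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L, 0L))
  data.frame(id = sub("/[12]$", "", ids),
             seq = ln[seq(2, length(ln), 4)],
             qual = ln[seq(4, length(ln), 4)],
             mate = mate, stringsAsFactors = FALSE)
}

#' Write the truth set of a simulated shattered chromosome
#'
#' Emits blocks as BED (copy state in the score column), the junction table
#' and the SNP table as TSV.
#'
#' @param truth truth list from \code{\link{build_shattered_chromosome}}.
#' @param snps SNP table data.frame.
#' @param dir output directory (created if absent).
#' @export
write_truth <- function(truth, snps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- truth$blocks
  bed <- data.frame(chrom = b$chrom, start0 = b$start - 1L, end = b$end,
                    name = paste0("block", b$block), score = b$state,
                    strand = ".")
  utils::write.table(bed, file.path(dir, "blocks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(truth$junctions, file.path(dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
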