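# Truth-driven simulator: synthetic reference with embedded reference
# mobile-element decoys and a satellite region, planted non-reference
# insertions (TSD / target-site deletion, polyA tail, strand, zygosity,
# L1-style 5' truncation), and emission of the alignment signatures an
# aligner would produce (proper pairs, soft-clipped junction reads,
# multi-mapped or unmapped mates), written as a sorted indexed BAM.
#
# All randomness flows from the seed in the sim_config (R's Mersenne
# Twister); identical seeds give byte-identical FASTQ/SAM output.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic mobilome
#'
#' Four random consensus sequences standing in for the active human mobile
#' element families (Alu ~300 bp, L1 6 kb, SVA ~1.6 kb, HERV-K ~2.5 kb).
#' The sequences are synthetic: they carry no homology to the real RepBase
#' consensus library, but play the same role -- insertions are planted from
#' them and candidate reads are mapped back against them, so detection is
#' self-consistent. The default seed is fixed so the same library is shared
#' across simulations.
#'
#' @param seed RNG seed for the library
#' @param lengths named lengths per family
#' @return named character vector of sequences (names classify families)
#' @export
synthetic_mobilome <- function(seed = 4880L,
                               lengths = c(Alu = 300L, L1 = 6000L,
                                           SVA = 1600L, HERVK = 2500L)) {
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(withr_seed))
  out <- vapply(lengths, random_dna, character(1))
  names(out) <- paste0(c(Alu = "AluY", L1 = "L1HS", SVA = "SVA_E",
                         HERVK = "HERVK")[names(lengths)], "_synthetic")
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(saved) {
  if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
}

#' Simulation configuration
#'
#' @param genome_length reference length in bp
#' @param n_insertions number of planted non-reference insertions
#' @param coverage haploid sequence depth (X)
#' @param read_length read length in bp
#' @param insert_median,insert_sd fragment-size distribution (bp)
#' @param base_error_rate per-base substitution error rate
#' @param seed RNG seed (mandatory: full determinism)
#' @param mode "paired" or "single"
#' @param zygosity "hom", "het" or "mixed" (50/50 per insertion)
#' @param n_decoys reference mobile-element decoy copies embedded in the
#'   reference (recorded in the annotation BED)
#' @param chrom contig name
#' @param capture_targets optional data.table (chrom,start,end) of exome
#'   capture targets; when set, reads are sampled on-target only
#' @param family_probs insertion family mix over Alu/L1/SVA
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(genome_length = 2e6, n_insertions = 100L,
                       coverage = 10, read_length = 100L,
                       insert_median = 400L, insert_sd = 30,
                       base_error_rate = 0.001, seed,
                       mode = c("paired", "single"),
                       zygosity = c("hom", "het", "mixed"),
                       n_decoys = 20L, chrom = "sim1",
                       capture_targets = NULL,
                       family_probs = c(Alu = 0.854, L1 = 0.114, SVA = 0.032)) {
  if (missing(seed)) stop("sim_config: 'seed' is mandatory")
  mode <- match.arg(mode)
  zygosity <- match.arg(zygosity)
  stopifnot(coverage > 0, genome_length >= 5e4, read_length >= 30)
  structure(list(genome_length = as.integer(genome_length),
                 n_insertions = as.integer(n_insertions),
                 coverage = coverage, read_length = as.integer(read_length),
                 insert_median = as.integer(insert_median),
                 insert_sd = insert_sd, base_error_rate = base_error_rate,
                 seed = as.integer(seed), mode = mode, zygosity = zygosity,
                 n_decoys = as.integer(n_decoys), chrom = chrom,
                 capture_targets = capture_targets,
                 family_probs = family_probs),
            class = "sim_config")
}

#' Build a synthetic reference with embedded decoys and a satellite region
#'
#' A random sequence of the configured length with \code{n_decoys} slightly
#' diverged (2\%) copies of the mobilome consensus sequences embedded
#' (these are the "reference mobile elements" the 90 bp filter needs) and
#' one satellite-like tandem repeat interval.
#'
#' @param simcfg a \code{sim_config}
#' @param mobilome named character vector of family consensus sequences
#' @return list with \code{reference} (character), \code{ref_mei}
#'   (data.table chrom/start/end/family), \code{satellite} (data.table),
#'   \code{decoys} (placement detail for the emitter)
#' @export
make_reference <- function(simcfg, mobilome = synthetic_mobilome()) {
  set.seed(simcfg$seed)
  glen <- simcfg$genome_length
  genome <- random_dna(glen)
  fams <- vapply(names(mobilome), classify_family_header, character(1))

  # satellite: ~171 bp unit repeated ~30x, placed in the first tenth
  unit <- random_dna(171L)
  sat_seq <- strrep(unit, 30L)
  sat_start <- as.integer(glen * 0.05)
  substr(genome, sat_start + 1L, sat_start + nchar(sat_seq)) <- sat_seq
  satellite <- data.table::data.table(chrom = simcfg$chrom, start = sat_start,
                                      end = sat_start + nchar(sat_seq))

  # decoys: diverged consensus copies; with enough requested, one per family
  n_dec <- simcfg$n_decoys
  dec_fam_idx <- c(head(seq_along(mobilome), n_dec),
                   if (n_dec > length(mobilome))
                     sample(seq_along(mobilome), n_dec - length(mobilome),
                            replace = TRUE))
  occupied <- data.table::data.table(start = satellite$start - 1000L,
                                     end = satellite$end + 1000L)
  decoys <- list()
  for (i in seq_len(n_dec)) {
    cons <- mobilome[[dec_fam_idx[i]]]
    dlen <- nchar(cons)
    for (try in 1:200) {
      s <- sample.int(glen - dlen - 4000L, 1L) + 2000L
      if (!any(s < occupied$end + 1000L & s + dlen > occupied$start - 1000L)) break
      s <- NA_integer_
    }
    if (is.na(s)) stop("could not place decoy ", i, "; genome too small")
    copy <- mutate_seq(cons, 0.02)
    substr(genome, s + 1L, s + dlen) <- copy
    occupied <- rbind(occupied, data.table::data.table(start = s, end = s + dlen))
    decoys[[i]] <- data.table::data.table(
      chrom = simcfg$chrom, start = s, end = s + dlen,
      family = unname(fams[dec_fam_idx[i]]), cons_idx = dec_fam_idx[i])
  }
  decoys <- data.table::rbindlist(decoys)
  if (nrow(decoys) == 0L) {
    decoys <- data.table::data.table(chrom = character(0), start = integer(0),
                                     end = integer(0), family = character(0),
                                     cons_idx = integer(0))
  }
  data.table::setorder(decoys, start)
  ref_mei <- decoys[, c("chrom", "start", "end", "family")]
  list(reference = genome, ref_mei = ref_mei, satellite = satellite,
       decoys = decoys)
}

# substitute a fraction of bases (never to the same base)
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(bases, cur), 1L)
  }
  seq
}

draw_tsd <- function(n) {
  kind <- sample(c("dup", "del", "blunt"), n, replace = TRUE,
                 prob = c(0.93, 0.06, 0.01))
  sizes <- integer(n)
  dup_sizes <- 5:20
  dup_w <- stats::dnorm(dup_sizes, 13, 3)
  del_sizes <- 1:15
  del_w <- stats::dnorm(del_sizes, 7, 3)
  is_dup <- kind == "dup"; is_del <- kind == "del"
  sizes[is_dup] <- sample(dup_sizes, sum(is_dup), replace = TRUE, prob = dup_w)
  sizes[is_del] <- -sample(del_sizes, sum(is_del), replace = TRUE, prob = del_w)
  sizes
}

#' Plant insertions into the reference
#'
#' Draws insertion sites (>= 2 kb apart, >= 500 bp from decoys, away from
#' the satellite region and contig ends), families, strands, TSDs, polyA
#' tail lengths and L1 5' truncations, and assembles the donor haplotype:
#' at each site with TSD t > 0, \code{ref[0,L+t) + insert + ref[L,end)}
#' (the duplicated block flanks the insert); t < 0 deletes \code{|t|}
#' reference bases at the junction; t = 0 is blunt. The insert is the
#' (possibly truncated) family consensus with a polyA tail, reverse
#' complemented for minus-strand insertions.
#'
#' @param ref result of \code{\link{make_reference}}
#' @param mobilome named character vector of consensus sequences
#' @param simcfg a \code{sim_config}
#' @param tsd_bp optional integer vector recycled over insertions to force
#'   specific TSD sizes (testing hook)
#' @return list with \code{truth} (data.table), \code{donor} (haplotype
#'   string), \code{blocks} (donor block table for the emitter)
#' @export
plant_insertions <- function(ref, mobilome, simcfg, tsd_bp = NULL) {
  set.seed(simcfg$seed + 1L)
  glen <- simcfg$genome_length
  n <- simcfg$n_insertions
  fams <- vapply(names(mobilome), classify_family_header, character(1))
  forbidden <- rbind(
    data.table::data.table(start = ref$decoys$start - 500L,
                           end = ref$decoys$end + 500L),
    data.table::data.table(start = ref$satellite$start - 1000L,
                           end = ref$satellite$end + 1000L))
  sites <- integer(0)
  guard <- 0L
  while (length(sites) < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("cannot place ", n, " insertions ",
                               ">=2 kb apart in a ", glen, " bp genome")
    s <- sample.int(glen - 6000L, 1L) + 3000L
    if (any(abs(s - sites) < 2000L)) next
    if (any(s >= forbidden$start & s <= forbidden$end)) next
    sites <- c(sites, s)
  }
  sites <- sort(sites)
  fam_pick <- sample(names(simcfg$family_probs), n, replace = TRUE,
                     prob = simcfg$family_probs)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tsd <- if (is.null(tsd_bp)) draw_tsd(n) else rep_len(as.integer(tsd_bp), n)
  polyA_len <- sample(10:40, n, replace = TRUE)
  zyg <- switch(simcfg$zygosity,
                hom = rep("hom", n), het = rep("het", n),
                mixed = sample(c("hom", "het"), n, replace = TRUE))
  cons_by_fam <- setNames(as.character(mobilome), unname(fams))
  trunc <- integer(n)
  truth_rows <- list()
  pieces <- character(0)
  blocks <- list()
  dcur <- 0L; prev <- 0L
  for (i in seq_len(n)) {
    fam <- fam_pick[i]
    cons <- cons_by_fam[[fam]]
    if (fam == "L1" && runif(1) < 0.7) {
      trunc[i] <- sample.int(nchar(cons) - 1000L, 1L)
    }
    cons_t <- substr(cons, trunc[i] + 1L, nchar(cons))
    ins_fwd <- paste0(cons_t, strrep("A", polyA_len[i]))
    ins <- if (strand[i] == "+") ins_fwd else revcomp(ins_fwd)
    cons_lo <- if (strand[i] == "+") 0L else polyA_len[i]
    cons_hi <- cons_lo + nchar(cons_t)
    p_L <- sites[i]
    p_R <- p_L + tsd[i]
    bp_left <- min(p_L, p_R); bp_right <- max(p_L, p_R)
    ref_piece <- substr(ref$reference, prev + 1L, p_R)
    pieces <- c(pieces, ref_piece, ins)
    blocks[[length(blocks) + 1L]] <- data.table::data.table(
      dstart = dcur, dend = dcur + nchar(ref_piece), type = "ref",
      rstart = prev, ins_id = NA_integer_)
    dcur <- dcur + nchar(ref_piece)
    blocks[[length(blocks) + 1L]] <- data.table::data.table(
      dstart = dcur, dend = dcur + nchar(ins), type = "ins",
      rstart = NA_integer_, ins_id = i)
    dcur <- dcur + nchar(ins)
    prev <- p_L
    truth_rows[[i]] <- data.table::data.table(
      ins_id = i, chrom = simcfg$chrom, breakpoint = bp_left,
      bp_left = bp_left, bp_right = bp_right, tsd_bp = tsd[i],
      family = fam, strand = strand[i], zygosity = zyg[i],
      polyA_len = polyA_len[i], truncation_5p = trunc[i],
      ins_len = nchar(ins), cons_lo = cons_lo, cons_hi = cons_hi,
      cons_offset = trunc[i])
  }
  last <- substr(ref$reference, prev + 1L, glen)
  pieces <- c(pieces, last)
  blocks[[length(blocks) + 1L]] <- data.table::data.table(
    dstart = dcur, dend = dcur + nchar(last), type = "ref",
    rstart = prev, ins_id = NA_integer_)
  truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows) else
    data.table::data.table(
      ins_id = integer(0), chrom = character(0), breakpoint = integer(0),
      bp_left = integer(0), bp_right = integer(0), tsd_bp = integer(0),
      family = character(0), strand = character(0), zygosity = character(0),
      polyA_len = integer(0), truncation_5p = integer(0),
      ins_len = integer(0), cons_lo = integer(0), cons_hi = integer(0),
      cons_offset = integer(0))
  list(truth = truth,
       donor = paste(pieces, collapse = ""),
       blocks = data.table::rbindlist(blocks))
}

# inject substitution errors into a character vector of reads; returns the
# modified vector (vectorised draw, small scalar loop over error positions)
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  if (length(idx) == 0L) return(seqs)
  # flatten to (read, position) pairs; substituted base drawn uniformly
  # from the three alternatives via a fixed offset table
  ri <- rep(idx, nerr[idx])
  pos <- as.integer(ceiling(runif(length(ri)) * lens[ri]))
  shift <- sample.int(3L, length(ri), replace = TRUE)
  alt <- matrix(c("C", "G", "T",   # A ->
                  "A", "G", "T",   # C ->
                  "A", "C", "T",   # G ->
                  "A", "C", "G"),  # T ->
                nrow = 4L, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  cur <- substring(seqs[ri], pos, pos)
  new <- alt[cbind(match(cur, rownames(alt)), shift)]
  for (k in seq_along(ri)) {
    substr(seqs[ri[k]], pos[k], pos[k]) <- new[k]
  }
  seqs
}

# Classify reads given donor interval [a, b) (0-based) against the block
# table. Returns a data.table with SAM-ready fields (pos 1-based; pos = NA
# means unmapped). min_anchor: smallest reference-side segment an aligner
# could anchor (below it the read is unmapped or decoy-placed).
classify_sim_reads <- function(a, b, blocks, truth, decoys, min_anchor = 20L) {
  n <- length(a)
  bi1 <- findInterval(a, blocks$dstart)
  bi2 <- findInterval(b - 1L, blocks$dstart)
  pos <- rep(NA_integer_, n)     # 1-based SAM POS
  cigar <- rep("*", n)
  mapq <- rep(0L, n)
  rl <- b - a
  same <- bi1 == bi2
  t1 <- blocks$type[bi1]
  # fully inside one reference block
  full_ref <- same & t1 == "ref"
  pos[full_ref] <- blocks$rstart[bi1[full_ref]] +
    (a[full_ref] - blocks$dstart[bi1[full_ref]]) + 1L
  cigar[full_ref] <- paste0(rl[full_ref], "M")
  mapq[full_ref] <- 60L

  # fully inside an insert: decoy multi-map if the read sits in the
  # consensus part and the family has a reference copy, else unmapped
  full_ins <- same & t1 == "ins"
  if (any(full_ins)) {
    w <- which(full_ins)
    iid <- blocks$ins_id[bi1[w]]
    off <- a[w] - blocks$dstart[bi1[w]]
    tr <- truth[iid]
    in_cons <- off >= tr$cons_lo & (off + rl[w]) <= tr$cons_hi
    for (k in seq_along(w)) {
      if (!in_cons[k]) next
      d <- decoys[decoys$family == tr$family[k]]
      if (nrow(d) == 0L) next
      dlen <- d$end[1] - d$start[1]
      o <- min(max(off[k] - tr$cons_lo[k] + tr$cons_offset[k], 0L),
               dlen - rl[w[k]])
      if (o < 0L) next
      pos[w[k]] <- d$start[1] + o + 1L
      cigar[w[k]] <- paste0(rl[w[k]], "M")
      mapq[w[k]] <- 0L
    }
  }

  # junction-crossing reads (one junction; inserts are >> read length)
  cross <- bi2 == bi1 + 1L
  if (any(cross)) {
    w <- which(cross)
    left_len <- blocks$dend[bi1[w]] - a[w]
    right_len <- b[w] - blocks$dstart[bi2[w]]
    ref_to_ins <- blocks$type[bi1[w]] == "ref"
    # ref -> ins: anchor on the left, right soft clip at the 5' junction
    ok5 <- ref_to_ins & left_len >= min_anchor
    k <- w[ok5]
    pos[k] <- blocks$rstart[bi1[w][ok5]] + (a[k] - blocks$dstart[bi1[w][ok5]]) + 1L
    cigar[k] <- paste0(left_len[ok5], "M", right_len[ok5], "S")
    mapq[k] <- 60L
    # ins -> ref: anchor on the right, left soft clip at the 3' junction
    ok3 <- !ref_to_ins & right_len >= min_anchor
    k <- w[ok3]
    pos[k] <- blocks$rstart[bi2[w][ok3]] + 1L
    cigar[k] <- paste0(left_len[ok3], "S", right_len[ok3], "M")
    mapq[k] <- 60L
    # junction reads with too little reference anchor stay unmapped
  }
  data.table::data.table(pos = pos, cigar = cigar, mapq = mapq,
                         mapped = !is.na(pos))
}

sam_header <- function(chrom, chrom_len) {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len),
    "@PG\tID:meicall-sim\tPN:meicall-sim")
}

#' Emit truth-driven alignments as a sorted, indexed BAM
#'
#' Samples fragments (or single-end reads) uniformly from the donor
#' haplotype(s) at the configured coverage, injects base errors, derives
#' each read's alignment from the planted truth (proper pairs for fully
#' reference fragments, soft clips at junctions, decoy placement with MAPQ
#' 0 or unmapped for reads inside the insert), and writes a coordinate-
#' sorted indexed BAM. Heterozygous simulations draw half the fragments
#' from the reference haplotype.
#'
#' @param planted result of \code{\link{plant_insertions}}
#' @param ref result of \code{\link{make_reference}}
#' @param simcfg a \code{sim_config}
#' @param out_bam output BAM path (".bam")
#' @param fastq optional path prefix: writes \code{<prefix>_1.fq} /
#'   \code{_2.fq} (or \code{<prefix>.fq} single-end)
#' @return list with \code{bam}, read counts
#' @export
emit_alignments <- function(planted, ref, simcfg, out_bam, fastq = NULL) {
  set.seed(simcfg$seed + 2L)
  chrom <- simcfg$chrom
  rl <- simcfg$read_length
  glen <- simcfg$genome_length
  donor <- planted$donor
  blocks <- planted$blocks
  truth <- planted$truth
  ref_blocks <- data.table::data.table(dstart = 0L, dend = glen, type = "ref",
                                       rstart = 0L, ins_id = NA_integer_)
  haps <- list(list(seq = donor, blocks = blocks, len = nchar(donor)))
  het_any <- nrow(truth) > 0L && any(truth$zygosity == "het")
  if (het_any) {
    # one haplotype with all insertions minus the het ones would require a
    # third haplotype per combination; with sites >= 2 kb apart the local
    # evidence is what matters, so het insertions are emulated by drawing
    # half the fragments from the pure reference haplotype
    haps <- c(haps, list(list(seq = ref$reference, blocks = ref_blocks,
                              len = glen)))
  }
  sam_path <- paste0(out_bam, ".tmp.sam")
  writeLines(sam_header(chrom, glen), sam_path)
  qual_const <- strrep("I", rl)
  total_frags <- ceiling(glen * simcfg$coverage /
                           (if (simcfg$mode == "paired") 2L * rl else rl))
  fq1 <- NULL; fq2 <- NULL
  if (!is.null(fastq)) {
    if (simcfg$mode == "paired") {
      fq1 <- file(paste0(fastq, "_1.fq"), open = "wt")
      fq2 <- file(paste0(fastq, "_2.fq"), open = "wt")
    } else {
      fq1 <- file(paste0(fastq, ".fq"), open = "wt")
    }
  }
  n_emitted <- 0L; n_dropped_unplaced <- 0L
  chunk_size <- 200000L
  frag_id0 <- 0L
  targets <- simcfg$capture_targets
  remaining <- total_frags
  while (remaining > 0L) {
    m <- min(chunk_size, remaining)
    remaining <- remaining - m
    hap_idx <- if (het_any) sample(1:2, m, replace = TRUE) else rep(1L, m)
    out_chunk <- list()
    for (h in seq_along(haps)) {
      sel <- which(hap_idx == h)
      if (length(sel) == 0L) next
      hp <- haps[[h]]
      if (simcfg$mode == "paired") {
        flen <- pmax(as.integer(round(rnorm(length(sel), simcfg$insert_median,
                                            simcfg$insert_sd))), 2L * rl)
        if (is.null(targets)) {
          fstart <- sample.int(hp$len - max(flen) - 1L, length(sel),
                               replace = TRUE) - 1L
        } else {
          fstart <- sample_target_positions(targets, length(sel), flen, hp$len)
        }
        a1 <- fstart; b1 <- fstart + rl
        a2 <- fstart + flen - rl; b2 <- fstart + flen
        seq1 <- substring(hp$seq, a1 + 1L, b1)
        seq2 <- substring(hp$seq, a2 + 1L, b2)
        seq1 <- inject_errors(seq1, simcfg$base_error_rate)
        seq2 <- inject_errors(seq2, simcfg$base_error_rate)
        c1 <- classify_sim_reads(a1, b1, hp$blocks, truth, ref$decoys)
        c2 <- classify_sim_reads(a2, b2, hp$blocks, truth, ref$decoys)
        qn <- sprintf("sf%09d", frag_id0 + sel)
        both_unmapped <- !c1$mapped & !c2$mapped
        n_dropped_unplaced <- n_dropped_unplaced + sum(both_unmapped)
        keep <- !both_unmapped
        if (any(keep)) {
          out_chunk[[length(out_chunk) + 1L]] <-
            build_pair_records(qn[keep], seq1[keep], seq2[keep],
                               c1[keep], c2[keep], chrom, qual_const,
                               simcfg)
        }
        if (!is.null(fq1)) {
          writeLines(as.vector(rbind(paste0("@", qn, "/1"), seq1,
                                     "+", qual_const)), fq1)
          writeLines(as.vector(rbind(paste0("@", qn, "/2"),
                                     revcomp(seq2), "+", qual_const)), fq2)
        }
        n_emitted <- n_emitted + 2L * sum(keep)
      } else {
        if (is.null(targets)) {
          a <- sample.int(hp$len - rl - 1L, length(sel), replace = TRUE) - 1L
        } else {
          a <- sample_target_positions(targets, length(sel),
                                       rep(rl, length(sel)), hp$len)
        }
        b <- a + rl
        sq <- inject_errors(substring(hp$seq, a + 1L, b),
                            simcfg$base_error_rate)
        cl <- classify_sim_reads(a, b, hp$blocks, truth, ref$decoys)
        qn <- sprintf("sr%09d", frag_id0 + sel)
        strand_rev <- sample(c(FALSE, TRUE), length(sel), replace = TRUE)
        keep <- cl$mapped
        n_dropped_unplaced <- n_dropped_unplaced + sum(!keep)
        if (any(keep)) {
          flagv <- ifelse(strand_rev[keep], FLAG_REVERSE, 0L)
          out_chunk[[length(out_chunk) + 1L]] <- data.table::data.table(
            qname = qn[keep], flag = flagv, rname = chrom,
            pos = cl$pos[keep], mapq = cl$mapq[keep], cigar = cl$cigar[keep],
            rnext = "*", pnext = 0L, tlen = 0L, seq = sq[keep],
            qual = qual_const)
        }
        if (!is.null(fq1)) {
          out_sq <- ifelse(strand_rev, revcomp(sq), sq)
          writeLines(as.vector(rbind(paste0("@", qn), out_sq, "+",
                                     qual_const)), fq1)
        }
        n_emitted <- n_emitted + sum(keep)
      }
    }
    if (length(out_chunk)) {
      recs <- data.table::rbindlist(out_chunk)
      data.table::fwrite(recs, sam_path, sep = "\t", append = TRUE,
                         col.names = FALSE, quote = FALSE)
    }
    frag_id0 <- frag_id0 + m
  }
  if (!is.null(fq1)) close(fq1)
  if (!is.null(fq2)) close(fq2)
  tmp_bam <- Rsamtools::asBam(sam_path, sub("\\.bam$", ".unsorted", out_bam),
                              overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp_bam, sub("\\.bam$", "", out_bam))
  Rsamtools::indexBam(out_bam)
  unlink(c(sam_path, tmp_bam))
  list(bam = out_bam, n_reads = n_emitted,
       n_unplaced_dropped = n_dropped_unplaced)
}

sample_target_positions <- function(targets, n, flen, hap_len) {
  w <- targets$end - targets$start
  ti <- sample.int(nrow(targets), n, replace = TRUE, prob = w)
  off <- floor(runif(n) * w[ti])
  pmin(pmax(targets$start[ti] + as.integer(off), 0L), hap_len - flen - 1L)
}

build_pair_records <- function(qn, seq1, seq2, c1, c2, chrom, qual_const,
                               simcfg) {
  n <- length(qn)
  # read1 sequenced forward, read2 reverse; both SEQs stored donor-forward
  f1 <- rep(FLAG_PAIRED + FLAG_FIRST, n)
  f2 <- rep(FLAG_PAIRED + FLAG_SECOND + FLAG_REVERSE, n)
  f1 <- f1 + FLAG_MREVERSE
  m1 <- c1$mapped; m2 <- c2$mapped
  f1[!m1] <- f1[!m1] + FLAG_UNMAPPED
  f2[!m2] <- f2[!m2] + FLAG_UNMAPPED
  f1[!m2] <- f1[!m2] + FLAG_MUNMAPPED
  f2[!m1] <- f2[!m1] + FLAG_MUNMAPPED
  pos1 <- c1$pos; pos2 <- c2$pos
  pos1[!m1] <- pos2[!m1]   # unmapped read placed at its mate
  pos2[!m2] <- pos1[!m2]
  end1 <- c1$pos + cigar_ref_width(c1$cigar)
  end2 <- c2$pos + cigar_ref_width(c2$cigar)
  tlen1 <- integer(n); tlen2 <- integer(n)
  both <- m1 & m2
  lo <- pmin(pos1, pos2); hi <- pmax(end1, end2)
  span <- hi - lo
  tlen1[both] <- ifelse(pos1[both] <= pos2[both], span[both], -span[both])
  tlen2[both] <- -tlen1[both]
  # proper pair: both mapped, FR with forward upstream, ordinary span
  # (pairs bridging a whole insertion come out compressed and are not
  # flagged proper, matching aligner behaviour)
  max_span <- simcfg$insert_median + 4 * simcfg$insert_sd + 10
  min_span <- max(2L * nchar(seq1[1]), simcfg$insert_median - 4 * simcfg$insert_sd - 10)
  proper <- both & pos1 <= pos2 & span <= max_span & span >= min_span
  f1[proper] <- f1[proper] + FLAG_PROPER
  f2[proper] <- f2[proper] + FLAG_PROPER
  r1 <- data.table::data.table(qname = qn, flag = f1, rname = chrom,
                               pos = pos1, mapq = c1$mapq, cigar = c1$cigar,
                               rnext = "=", pnext = pos2, tlen = tlen1,
                               seq = seq1, qual = qual_const)
  r2 <- data.table::data.table(qname = qn, flag = f2, rname = chrom,
                               pos = pos2, mapq = c2$mapq, cigar = c2$cigar,
                               rnext = "=", pnext = pos1, tlen = tlen2,
                               seq = seq2, qual = qual_const)
  rbind(r1, r2)
}

#' Run a complete simulation and write all artifacts
#'
#' Generates the reference, plants insertions, emits the BAM, and writes
#' reference FASTA, mobilome FASTA, reference-ME BED, satellite BED and a
#' truth TSV into \code{out_dir}.
#'
#' @param simcfg a \code{sim_config}
#' @param out_dir output directory (created if needed)
#' @param mobilome named character vector (default: shared synthetic library)
#' @param fastq also write FASTQ files
#' @param tsd_bp optional forced TSD sizes (see \code{\link{plant_insertions}})
#' @return list of file paths plus \code{truth}
#' @export
simulate_dataset <- function(simcfg, out_dir, mobilome = synthetic_mobilome(),
                             fastq = FALSE, tsd_bp = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(simcfg, mobilome)
  planted <- plant_insertions(ref, mobilome, simcfg, tsd_bp = tsd_bp)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    mobilome = file.path(out_dir, "mobilome.fa"),
    ref_mei = file.path(out_dir, "reference_mei.bed"),
    satellite = file.path(out_dir, "satellite.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    bam = file.path(out_dir, "reads.bam"))
  refset <- Biostrings::DNAStringSet(setNames(ref$reference, simcfg$chrom))
  Biostrings::writeXStringSet(refset, paths$reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mobilome),
                              paths$mobilome)
  data.table::fwrite(ref$ref_mei, paths$ref_mei, sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(ref$satellite, paths$satellite, sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(planted$truth, paths$truth, sep = "\t")
  em <- emit_alignments(planted, ref, simcfg, paths$bam,
                        fastq = if (fastq) file.path(out_dir, "reads") else NULL)
  c(paths, list(truth_table = planted$truth, ref = ref,
                n_reads = em$n_reads))
}

#' Evaluate predictions against the planted truth
#'
#' A truth insertion is detected iff at least one prediction of the same
#' family lies within \code{window} bp of its breakpoint (edge distance
#' from the prediction window, 0 when overlapping). Each prediction is
#' credited to at most one truth record (the nearest). Sensitivity is
#' detected/total truth; PPV is matched predictions / total predictions
#' (NA with an empty call set).
#'
#' @param calls prediction \code{data.table} (the default, unflagged report)
#' @param truth truth \code{data.table} (needs chrom, breakpoint, family)
#' @param window matching window in bp (default 50)
#' @return list with \code{sensitivity}, \code{ppv}, \code{n_truth},
#'   \code{n_calls}, \code{matches} (per-prediction truth assignment)
#' @export
evaluate_calls <- function(calls, truth, window = 50L) {
  n_truth <- nrow(truth)
  n_calls <- if (is.null(calls)) 0L else nrow(calls)
  if (n_calls == 0L) {
    return(list(sensitivity = if (n_truth) 0 else NA_real_, ppv = NA_real_,
                n_truth = n_truth, n_calls = 0L,
                matches = integer(0)))
  }
  assigned <- rep(NA_integer_, n_calls)
  for (i in seq_len(n_calls)) {
    cand <- which(truth$chrom == calls$chrom[i] &
                    truth$family == calls$family[i])
    if (length(cand) == 0L) next
    d <- interval_gap(calls$window_start[i], calls$window_end[i],
                      truth$breakpoint[cand], truth$breakpoint[cand] + 1L)
    j <- which.min(d)
    if (d[j] <= window) assigned[i] <- cand[j]
  }
  detected <- length(unique(assigned[!is.na(assigned)]))
  list(sensitivity = if (n_truth) detected / n_truth else NA_real_,
       ppv = sum(!is.na(assigned)) / n_calls,
       n_truth = n_truth, n_calls = n_calls, matches = assigned)
}
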