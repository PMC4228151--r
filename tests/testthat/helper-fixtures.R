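# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# tiny deterministic mobilome for unit tests (fixed seed, independent of
# the package's synthetic_mobilome defaults)
tiny_mobilome <- function(seed = 42L, lengths = c(Alu = 300L, L1 = 800L,
                                                  SVA = 400L, HERVK = 350L)) {
  set.seed(seed)
  out <- vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(out) <- c("AluYa5", "L1HS", "SVA_E", "HERVK")[seq_along(lengths)]
  out
}

# mutate k positions of a sequence (always to a different base)
mutate_at <- function(seq, pos) {
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  seq
}

# write SAM records (data.frame with qname flag rname pos mapq cigar rnext
# pnext tlen seq qual) to a sorted indexed BAM; returns the BAM path
make_test_bam <- function(records, chrom = "chrT", chrom_len = 100000L,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  writeLines(hdr, sam)
  if (nrow(records)) {
    data.table::fwrite(records, sam, sep = "\t", append = TRUE,
                       col.names = FALSE, quote = FALSE)
  }
  tmp <- Rsamtools::asBam(sam, file.path(dir, "t.unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  out <- file.path(dir, "t.bam")
  Rsamtools::sortBam(tmp, file.path(dir, "t"))
  Rsamtools::indexBam(out)
  out
}

sam_rec <- function(qname = "r1", flag = 0L, rname = "chrT", pos = 1000L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = 0L,
                    tlen = 0L, seq = strrep("A", 100L),
                    qual = strrep("I", 100L)) {
  data.table::data.table(qname = qname, flag = flag, rname = rname,
                         pos = pos, mapq = mapq, cigar = cigar,
                         rnext = rnext, pnext = pnext, tlen = tlen,
                         seq = seq, qual = qual)
}

# a concordant FR pair: read1 at pos (fwd), read2 at pos+tlen-rl (rev)
sam_pair <- function(qname, pos, tlen = 400L, rl = 100L, chrom = "chrT",
                     seq1 = strrep("A", rl), seq2 = strrep("C", rl),
                     proper = TRUE, mapq = 60L) {
  extra <- if (proper) 2L else 0L
  p2 <- pos + tlen - rl
  rbind(
    sam_rec(qname, flag = 1L + extra + 32L + 64L, rname = chrom, pos = pos,
            mapq = mapq, cigar = paste0(rl, "M"), rnext = "=", pnext = p2,
            tlen = tlen, seq = seq1, qual = strrep("I", rl)),
    sam_rec(qname, flag = 1L + extra + 16L + 128L, rname = chrom, pos = p2,
            mapq = mapq, cigar = paste0(rl, "M"), rnext = "=", pnext = pos,
            tlen = -tlen, seq = seq2, qual = strrep("I", rl)))
}

# independent sliding-window Hamming oracle over a mobilome (plain integer
# comparison; both strands; N mismatches everything)
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_best_mismatches <- function(seq, mobilome_seqs) {
  q <- utf8ToInt(seq)
  n <- length(q)
  best <- Inf
  for (s in mobilome_seqs) {
    for (str in c(s, oracle_revcomp(s))) {
      v <- utf8ToInt(str)
      if (length(v) < n) next
      for (off in 1:(length(v) - n + 1L)) {
        mm <- sum(q != v[off:(off + n - 1L)])
        if (mm < best) best <- mm
      }
    }
  }
  best
}

# brute-force single-linkage clustering oracle: union-find over all pairs
# satisfying the predicate; returns a canonical partition signature
oracle_single_linkage <- function(starts, strand, tag, max_gap) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && strand[i] == strand[j] && tag[i] == tag[j] &&
        abs(starts[i] - starts[j]) <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# canonical signature of package clusters: sorted list of sorted member
# start vectors
cluster_signature <- function(clusters) {
  sig <- lapply(clusters, function(cl) sort(cl$anchors$start))
  sig[order(vapply(sig, function(x) paste(x, collapse = ","), character(1)))]
}

partition_signature <- function(partition, starts) {
  sig <- lapply(unname(partition), function(ix) sort(starts[ix]))
  sig[order(vapply(sig, function(x) paste(x, collapse = ","), character(1)))]
}

# minimal anchor table builder
anchor_dt <- function(start, strand = "+", tag = "Alu", chrom = "chr1",
                      evidence = "discordant", side = NA_character_,
                      clip_pos = NA_integer_, width = 100L,
                      origin = "discordant_mate",
                      qname = paste0("q", seq_along(start))) {
  data.table::data.table(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + width), strand = strand, evidence = evidence,
    side = side, tag = tag, clip_pos = as.integer(clip_pos),
    origin = origin, qname = qname, target_strand = NA_character_)
}

clip_anchor_dt <- function(clip_pos, side, tag, chrom = "chr1",
                           width = 65L,
                           qname = paste0("c", seq_along(clip_pos))) {
  # right-clipped reads (side 3prime) end at the clip; left-clipped start
  start <- ifelse(side == "3prime", clip_pos - width, clip_pos)
  anchor_dt(start = start, strand = "+", tag = tag, chrom = chrom,
            evidence = "clipped", side = side, clip_pos = clip_pos,
            width = width, origin = "clipped_tail", qname = qname)
}

make_cluster <- function(kind, start, end, tag = "Alu", chrom = "chr1",
                         clip_mode_pos = NA_integer_, support = 5L) {
  anchors <- anchor_dt(start = rep(start, support), tag = tag, chrom = chrom,
                       strand = if (kind %in% c("disc5", "clip5")) "+" else "-",
                       evidence = if (startsWith(kind, "disc")) "discordant" else "clipped",
                       side = if (kind == "clip5") "3prime"
                              else if (kind == "clip3") "5prime" else NA_character_,
                       clip_pos = rep(clip_mode_pos, support),
                       origin = if (startsWith(kind, "disc")) "discordant_mate" else "clipped_tail",
                       width = end - start)
  list(kind = kind, chrom = chrom, start = as.integer(start),
       end = as.integer(end), tag = tag, support = support,
       anchors = anchors, clip_mode_pos = as.integer(clip_mode_pos))
}

# one-row prediction builder for filter tests
pred_row <- function(chrom = "chr1", ws = 5000L, we = 5050L, bs = 5010L,
                     be = 5011L, family = "Alu", support = 10L,
                     support_clipped = 0L, has5 = TRUE, has3 = TRUE,
                     polyA_side = "none", tsd_bp = NA_integer_) {
  data.table::data.table(
    chrom = chrom, window_start = as.integer(ws), window_end = as.integer(we),
    breakpoint_start = as.integer(bs), breakpoint_end = as.integer(be),
    family = family, orientation = "unknown", tsd_bp = as.integer(tsd_bp),
    support = as.integer(support),
    support_disc_unique = as.integer(support - support_clipped),
    support_disc_multimapped = 0L,
    support_clipped = as.integer(support_clipped), support_unmapped = 0L,
    polyA_side = polyA_side, filters = "", gene_component = NA_character_,
    has5 = has5, has3 = has3)
}

new_event_for_test <- function(clusters, family = "Alu",
                               tsd_bp = NA_integer_) {
  list(clusters = clusters, family = family, tsd_bp = as.integer(tsd_bp))
}
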