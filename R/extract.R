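# BAM scanning: insert-size estimation, concordant/discordant pair
# classification, and harvesting of candidate reads (discordant mates,
# unmapped mates and soft-clipped tails) together with their anchors.
# Coordinates are 0-based half-open internally; conversion happens at the
# Rsamtools boundary.

FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_UNMAPPED <- 4L
FLAG_MUNMAPPED <- 8L; FLAG_REVERSE <- 16L; FLAG_MREVERSE <- 32L
FLAG_FIRST <- 64L; FLAG_SECOND <- 128L
FLAG_SECONDARY <- 256L; FLAG_QCFAIL <- 512L; FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Construct a minimal aligned-read record
#'
#' A lightweight list representation of one alignment used by the scalar
#' classification and clip-filter APIs (the BAM scanner works on vectorized
#' tables internally).
#'
#' @param name read name
#' @param chrom reference name (NA if unmapped)
#' @param start 0-based leftmost aligned position
#' @param strand "+" or "-"
#' @param left_clip,right_clip soft-clip lengths in bp
#' @param is_unique uniquely mapped per MAPQ evidence
#' @param is_unmapped read unmapped
#' @param mate_chrom,mate_start,mate_strand,mate_unmapped mate summary
#' @param seq read sequence (aligned orientation)
#' @param quals integer phred qualities (same length as seq)
#' @param template_len signed template length (TLEN)
#' @return a list of class \code{aligned_read}
#' @export
aligned_read <- function(name = "r", chrom = NA_character_, start = NA_integer_,
                         strand = "+", left_clip = 0L, right_clip = 0L,
                         is_unique = TRUE, is_unmapped = FALSE,
                         mate_chrom = NA_character_, mate_start = NA_integer_,
                         mate_strand = "+", mate_unmapped = FALSE,
                         seq = "", quals = integer(0),
                         template_len = 0L) {
  if (nzchar(seq) && length(quals) && length(quals) != nchar(seq)) {
    stop("quals length must equal seq length")
  }
  if (left_clip + right_clip > max(nchar(seq), left_clip + right_clip)) {
    stop("clips exceed read length")
  }
  structure(list(name = name, chrom = chrom, start = as.integer(start),
                 strand = strand, left_clip = as.integer(left_clip),
                 right_clip = as.integer(right_clip), is_unique = is_unique,
                 is_unmapped = is_unmapped, mate_chrom = mate_chrom,
                 mate_start = as.integer(mate_start),
                 mate_strand = mate_strand, mate_unmapped = mate_unmapped,
                 seq = seq, quals = quals,
                 template_len = as.integer(template_len)),
            class = "aligned_read")
}

# soft clip lengths from CIGAR strings (vectorized); hard clips (H) carry no
# sequence and are ignored here -- see extract_candidates
cigar_soft_clips <- function(cigar) {
  left <- rep(0L, length(cigar))
  right <- rep(0L, length(cigar))
  cigar[is.na(cigar)] <- ""
  ml <- regexpr("^(?:[0-9]+H)?([0-9]+)S", cigar, perl = TRUE)
  has_l <- ml > 0L
  if (any(has_l)) {
    lm <- regmatches(cigar, ml)
    left[has_l] <- as.integer(sub("S$", "", sub("^[0-9]+H", "", lm)))
  }
  mr <- regexpr("([0-9]+)S(?:[0-9]+H)?$", cigar, perl = TRUE)
  has_r <- mr > 0L
  if (any(has_r)) {
    rm_ <- regmatches(cigar, mr)
    right[has_r] <- as.integer(sub("S.*$", "", rm_))
  }
  list(left = left, right = right)
}

# reference span consumed by a CIGAR (M/D/N/=/X), vectorized
cigar_ref_width <- function(cigar) {
  out <- integer(length(cigar))
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (length(o) == 0L) { out[i] <- 0L; next }
    w <- as.integer(sub("[MIDNSHP=X]$", "", o))
    type <- sub("^[0-9]+", "", o)
    out[i] <- sum(w[type %in% c("M", "D", "N", "=", "X")])
  }
  out
}

#' Estimate the insert-size distribution from a BAM
#'
#' Samples absolute template lengths from the first \code{sample_size}
#' properly-paired alignments, trims values above the 99.5th percentile of
#' the sample (outlier robustness in the spirit of Picard's insert-size
#' metrics), and reports the median and standard deviation.
#'
#' @param bam path to a coordinate-sorted BAM
#' @param sample_size number of proper pairs to sample (default 10000)
#' @return list with \code{median}, \code{sd}, \code{n_sampled},
#'   \code{low_sample} (TRUE when fewer than 1000 pairs were available)
#' @export
estimate_insert_size <- function(bam, sample_size = 10000L) {
  bf <- Rsamtools::BamFile(bam, yieldSize = 200000L)
  open(bf)
  on.exit(close(bf))
  tlens <- integer(0)
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "isize"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  repeat {
    chunk <- Rsamtools::scanBam(bf, param = param)[[1]]
    if (length(chunk$flag) == 0L) break
    tlens <- c(tlens, abs(chunk$isize))
    if (length(tlens) >= sample_size) break
  }
  tlens <- head(tlens[!is.na(tlens) & tlens > 0L], sample_size)
  insert_size_stats(tlens)
}

#' Summarise sampled template lengths into insert-size statistics
#'
#' @param tlens integer vector of absolute template lengths
#' @return list with \code{median}, \code{sd}, \code{n_sampled}, \code{low_sample}
#' @export
insert_size_stats <- function(tlens) {
  if (length(tlens) == 0L) {
    stop("no properly-paired alignments found; cannot estimate insert size ",
         "(paired mode requires at least one proper pair)")
  }
  cut <- quantile(tlens, 0.995, names = FALSE, type = 7)
  kept <- tlens[tlens <= cut]
  list(median = median(kept), sd = if (length(kept) > 1L) sd(kept) else 0,
       n_sampled = length(tlens), low_sample = length(tlens) < 1000L)
}

#' Classify a read pair as concordant or one of four discordancy classes
#'
#' Discordancy classes are evaluated in a fixed order: one end unmapped,
#' then inter-chromosomal, then unexpected orientation (expected is
#' forward-reverse with the forward read upstream), then insert-size
#' discordance (absolute template length outside
#' median +/- \code{insert_size_sd_multiplier} * sd). Both-unmapped pairs
#' yield the distinct value \code{"skip"}.
#'
#' @param r1,r2 \code{\link{aligned_read}} mates
#' @param stats insert-size stats from \code{\link{estimate_insert_size}}
#' @param cfg a \code{caller_config}
#' @return one of \code{"concordant"}, \code{"disc_one_unmapped"},
#'   \code{"disc_interchrom"}, \code{"disc_orientation"},
#'   \code{"disc_insert_size"}, \code{"skip"}
#' @export
classify_pair <- function(r1, r2, stats, cfg = caller_config()) {
  if (r1$is_unmapped && r2$is_unmapped) return("skip")
  if (r1$is_unmapped || r2$is_unmapped) return("disc_one_unmapped")
  if (!identical(r1$chrom, r2$chrom)) return("disc_interchrom")
  if (r1$strand == r2$strand) return("disc_orientation")
  fwd <- if (r1$strand == "+") r1 else r2
  rev_ <- if (r1$strand == "+") r2 else r1
  if (fwd$start > rev_$start) return("disc_orientation")
  tlen <- abs(r1$template_len)
  lo <- stats$median - cfg$insert_size_sd_multiplier * stats$sd
  hi <- stats$median + cfg$insert_size_sd_multiplier * stats$sd
  if (tlen < lo || tlen > hi) return("disc_insert_size")
  "concordant"
}

# vectorized pair classification from single BAM records (mate information
# is taken from flags/mrnm/mpos, so no qname join is needed)
classify_records <- function(dt, stats, cfg) {
  unmapped <- has_flag(dt$flag, FLAG_UNMAPPED)
  munmapped <- has_flag(dt$flag, FLAG_MUNMAPPED)
  rev_ <- has_flag(dt$flag, FLAG_REVERSE)
  mrev <- has_flag(dt$flag, FLAG_MREVERSE)
  cls <- rep("concordant", nrow(dt))
  lo <- stats$median - cfg$insert_size_sd_multiplier * stats$sd
  hi <- stats$median + cfg$insert_size_sd_multiplier * stats$sd
  tl <- abs(dt$isize)
  bad_size <- !is.na(tl) & (tl < lo | tl > hi)
  cls[bad_size] <- "disc_insert_size"
  fwd_pos <- ifelse(rev_, dt$mpos, dt$pos)
  rev_pos <- ifelse(rev_, dt$pos, dt$mpos)
  bad_orient <- (rev_ == mrev) | (!is.na(fwd_pos) & !is.na(rev_pos) & fwd_pos > rev_pos)
  cls[bad_orient] <- "disc_orientation"
  interchrom <- !is.na(dt$mrnm) & !is.na(dt$rname) & dt$mrnm != dt$rname
  cls[interchrom] <- "disc_interchrom"
  cls[unmapped | munmapped] <- "disc_one_unmapped"
  cls[unmapped & munmapped] <- "skip"
  cls[!has_flag(dt$flag, FLAG_PAIRED)] <- "unpaired"
  cls
}

#' Decide whether a read's soft clip passes the clip filter
#'
#' A clip is accepted iff its length is at least \code{min_clip_length},
#' the mean phred quality of the clipped bases is at least
#' \code{min_clip_avg_quality}, and the opposite end is clipped by at most
#' \code{max_other_end_clip} bp. A read clipped beyond
#' \code{min_clip_length} at both ends is always rejected (the other-end
#' rule cannot hold).
#'
#' @param read an \code{\link{aligned_read}}
#' @param cfg a \code{caller_config}
#' @return list with \code{accept} (logical), \code{side} ("left"/"right" or
#'   NA) and \code{reason} (NA when accepted)
#' @export
clip_filter <- function(read, cfg = caller_config()) {
  if (read$is_unmapped) return(list(accept = FALSE, side = NA, reason = "unmapped"))
  for (side in c("right", "left")) {
    cl <- if (side == "right") read$right_clip else read$left_clip
    other <- if (side == "right") read$left_clip else read$right_clip
    if (cl < cfg$min_clip_length) next
    if (other > cfg$max_other_end_clip) {
      return(list(accept = FALSE, side = NA, reason = "other_end_clip"))
    }
    q <- if (side == "right") tail(read$quals, cl) else head(read$quals, cl)
    if (length(q) && mean(q) < cfg$min_clip_avg_quality) {
      return(list(accept = FALSE, side = NA, reason = "clip_quality"))
    }
    return(list(accept = TRUE, side = side, reason = NA_character_))
  }
  list(accept = FALSE, side = NA, reason = "clip_length")
}

# mean phred of the clipped bases, vectorized over quality strings
clip_mean_qual <- function(qual, cliplen, side) {
  n <- length(qual)
  out <- numeric(n)
  for (i in seq_len(n)) {
    q <- phred_from_qual(qual[i])
    cl <- cliplen[i]
    out[i] <- if (cl == 0L) NA_real_ else {
      if (side[i] == "right") mean(tail(q, cl)) else mean(head(q, cl))
    }
  }
  out
}

#' Extract candidate reads from a BAM
#'
#' Streams a coordinate-sorted, indexed BAM and emits one candidate per
#' piece of insertion evidence:
#' \itemize{
#'   \item discordant pairs with at least one uniquely mapped end: one
#'     candidate per unique anchor, carrying the mate's sequence (origin
#'     \code{discordant_mate}, \code{multimapped_mate} or
#'     \code{unmapped_mate} depending on the mate's mapping);
#'   \item uniquely mapped reads with a soft clip passing
#'     \code{\link{clip_filter}}: one candidate carrying the clipped tail
#'     (origin \code{clipped_tail}), with \code{side} \code{"3prime"} for a
#'     right clip and \code{"5prime"} for a left clip and \code{clip_pos}
#'     at the clip boundary.
#' }
#' In single-end mode only clipped candidates are emitted. Secondary,
#' supplementary and duplicate-flagged alignments are skipped. Hard-clipped
#' ends carry no sequence and are counted but never emitted.
#'
#' @param bam path to a coordinate-sorted indexed BAM
#' @param stats insert-size stats (\code{\link{estimate_insert_size}});
#'   may be NULL in single-end mode
#' @param cfg a \code{caller_config}
#' @param yield_size chunk size for streaming
#' @return \code{data.table} with columns qname, chrom, start, end, strand,
#'   evidence, side, origin, candidate_seq, clip_pos (0-based half-open)
#' @export
extract_candidates <- function(bam, stats = NULL, cfg = caller_config(),
                               yield_size = 500000L) {
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index not found for ", bam,
         " (expected ", bai, "); sort and index the BAM first, e.g. ",
         "Rsamtools::sortBam() + Rsamtools::indexBam()")
  }
  if (cfg$mode == "paired" && is.null(stats)) {
    stop("paired mode requires insert-size stats")
  }
  bf <- Rsamtools::BamFile(bam, yieldSize = yield_size)
  open(bf)
  on.exit(close(bf))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  clipped_parts <- list()
  disc_parts <- list()
  n_hardclip_skipped <- 0L
  ci <- 0L
  repeat {
    chunk <- Rsamtools::scanBam(bf, param = param)[[1]]
    n <- length(chunk$flag)
    if (n == 0L) break
    ci <- ci + 1L
    dt <- data.table::data.table(
      qname = chunk$qname, flag = chunk$flag,
      rname = as.character(chunk$rname), pos = chunk$pos,
      mapq = chunk$mapq, cigar = chunk$cigar,
      mrnm = as.character(chunk$mrnm), mpos = chunk$mpos,
      isize = chunk$isize)
    dt[is.na(cigar), cigar := ""]
    clips <- cigar_soft_clips(dt$cigar)
    dt[, `:=`(lclip = clips$left, rclip = clips$right)]
    unmapped <- has_flag(dt$flag, FLAG_UNMAPPED)
    unique_map <- !unmapped & !is.na(dt$mapq) & dt$mapq >= cfg$min_anchor_mapq
    n_hardclip_skipped <- n_hardclip_skipped +
      sum(grepl("H", dt$cigar[!unmapped], fixed = TRUE))

    # clipped-tail candidates
    maxclip <- pmax(dt$lclip, dt$rclip)
    cand_clip <- which(unique_map & maxclip >= cfg$min_clip_length)
    if (length(cand_clip)) {
      sub <- dt[cand_clip]
      seqs <- as.character(chunk$seq[cand_clip])
      quals <- as.character(chunk$qual[cand_clip])
      side <- ifelse(sub$rclip >= sub$lclip, "right", "left")
      cliplen <- ifelse(side == "right", sub$rclip, sub$lclip)
      other <- ifelse(side == "right", sub$lclip, sub$rclip)
      ok <- other <= cfg$max_other_end_clip
      mq <- clip_mean_qual(quals, cliplen, side)
      ok <- ok & !is.na(mq) & mq >= cfg$min_clip_avg_quality
      if (any(ok)) {
        sub <- sub[ok]; seqs <- seqs[ok]; side <- side[ok]
        cliplen <- cliplen[ok]
        refw <- cigar_ref_width(sub$cigar)
        a_start <- sub$pos - 1L              # 0-based aligned start
        a_end <- a_start + refw              # half-open aligned end
        tailseq <- ifelse(side == "right",
                          substring(seqs, nchar(seqs) - cliplen + 1L),
                          substring(seqs, 1L, cliplen))
        clipped_parts[[length(clipped_parts) + 1L]] <- data.table::data.table(
          qname = sub$qname, chrom = sub$rname, start = a_start, end = a_end,
          strand = ifelse(has_flag(sub$flag, FLAG_REVERSE), "-", "+"),
          evidence = "clipped",
          side = ifelse(side == "right", "3prime", "5prime"),
          origin = "clipped_tail", candidate_seq = tailseq,
          clip_pos = ifelse(side == "right", a_end, a_start))
      }
    }

    # discordant-pair candidates (paired mode only)
    if (cfg$mode == "paired") {
      cls <- classify_records(dt, stats, cfg)
      disc <- !cls %in% c("concordant", "skip", "unpaired")
      keep <- which(disc)
      if (length(keep)) {
        sub <- dt[keep]
        sub[, `:=`(seq = as.character(chunk$seq[keep]),
                   unique_map = unique_map[keep],
                   unmapped = unmapped[keep],
                   cls = cls[keep])]
        disc_parts[[length(disc_parts) + 1L]] <- sub
      }
    }
  }
  out <- list()
  if (length(clipped_parts)) out$clip <- data.table::rbindlist(clipped_parts)
  if (cfg$mode == "paired" && length(disc_parts)) {
    dd <- data.table::rbindlist(disc_parts)
    # join mates by qname + end-of-pair: anchor rows are uniquely mapped;
    # candidate_seq is the other end's sequence
    qname <- NULL; unique_map <- NULL; endno <- NULL; m_endno <- NULL
    dd[, endno := ifelse(has_flag(flag, FLAG_FIRST), 1L, 2L)]
    mates <- dd[, .(qname, m_endno = endno, mseq = seq,
                    m_unmapped = unmapped, m_unique = unique_map)]
    anchors <- dd[unique_map == TRUE]
    merged <- merge(anchors, mates, by = "qname", allow.cartesian = TRUE)
    merged <- merged[endno != m_endno]
    if (nrow(merged)) {
      merged[, origin := ifelse(m_unmapped, "unmapped_mate",
                         ifelse(m_unique, "discordant_mate",
                                "multimapped_mate"))]
      refw <- cigar_ref_width(merged$cigar)
      out$disc <- merged[, .(
        qname,
        chrom = rname, start = pos - 1L, end = pos - 1L + refw,
        strand = ifelse(has_flag(flag, FLAG_REVERSE), "-", "+"),
        evidence = "discordant", side = NA_character_,
        origin, candidate_seq = mseq, clip_pos = NA_integer_)]
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(
      qname = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), evidence = character(0),
      side = character(0), origin = character(0),
      candidate_seq = character(0), clip_pos = integer(0)))
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  # dedupe per (read name, side, origin)
  res <- unique(res, by = c("qname", "side", "origin", "chrom", "start"))
  res[nzchar(candidate_seq)]
}
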