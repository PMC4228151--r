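# Prediction assembly, filtering (flag-setting, order-independent),
# merging, orientation and gene-component annotation, and report output.

ORIGIN_LEVELS <- c("discordant_mate", "multimapped_mate", "clipped_tail",
                   "unmapped_mate")

prediction_columns <- c(
  "chrom", "window_start", "window_end", "breakpoint_start", "breakpoint_end",
  "family", "orientation", "tsd_bp", "support", "support_disc_unique",
  "support_disc_multimapped", "support_clipped", "support_unmapped",
  "polyA_side", "filters", "gene_component")

empty_predictions <- function() {
  data.table::data.table(
    chrom = character(0), window_start = integer(0), window_end = integer(0),
    breakpoint_start = integer(0), breakpoint_end = integer(0),
    family = character(0), orientation = character(0), tsd_bp = integer(0),
    support = integer(0), support_disc_unique = integer(0),
    support_disc_multimapped = integer(0), support_clipped = integer(0),
    support_unmapped = integer(0), polyA_side = character(0),
    filters = character(0), gene_component = character(0))
}

# polyA side of an event: clip3 cluster tagged polyA -> "3prime" (plus
# strand), clip5 cluster tagged polyT -> "5prime" (minus strand; the
# element's polyA reads as polyT on the reference forward strand)
event_polyA_side <- function(ev) {
  for (cl in ev$clusters) {
    if (cl$kind == "clip3" && cl$tag == "polyA") return("3prime")
    if (cl$kind == "clip5" && cl$tag == "polyT") return("5prime")
  }
  "none"
}

#' Build a prediction table from events
#'
#' Computes windows, breakpoints, per-origin support counts, TSD calls,
#' polyA side and orientation for a list of events.
#'
#' @param events event list from \code{\link{assemble_events}}
#' @param stats insert-size stats (NULL in single-end mode)
#' @param read_len representative read length
#' @param cfg a \code{caller_config}
#' @return prediction \code{data.table} (0-based half-open coordinates)
#' @export
events_to_predictions <- function(events, stats = NULL, read_len = 100L,
                                  cfg = caller_config()) {
  if (length(events) == 0L) return(empty_predictions())
  rows <- lapply(events, function(ev) {
    bp <- estimate_breakpoint(ev, stats, read_len, cfg)
    anchors <- data.table::rbindlist(lapply(ev$clusters, `[[`, "anchors"),
                                     fill = TRUE)
    anchors <- unique(anchors, by = c("qname", "side", "origin", "start"))
    oc <- table(factor(anchors$origin, levels = ORIGIN_LEVELS))
    pred <- data.table::data.table(
      chrom = ev$clusters[[1]]$chrom,
      window_start = as.integer(bp$window[1]),
      window_end = as.integer(bp$window[2]),
      breakpoint_start = as.integer(bp$bp_start),
      breakpoint_end = as.integer(bp$bp_end),
      family = ev$family,
      orientation = "unknown",
      tsd_bp = ev$tsd_bp,
      support = nrow(anchors),
      support_disc_unique = as.integer(oc[["discordant_mate"]]),
      support_disc_multimapped = as.integer(oc[["multimapped_mate"]]),
      support_clipped = as.integer(oc[["clipped_tail"]]),
      support_unmapped = as.integer(oc[["unmapped_mate"]]),
      polyA_side = event_polyA_side(ev),
      filters = "", gene_component = NA_character_)
    pred$orientation <- determine_orientation(pred)
    pred$has5 <- any(event_kinds(ev) %in% c("disc5", "clip5"))
    pred$has3 <- any(event_kinds(ev) %in% c("disc3", "clip3"))
    pred
  })
  data.table::rbindlist(rows)
}

add_flag <- function(filters, idx, flag) {
  cur <- filters[idx]
  filters[idx] <- ifelse(nzchar(cur), paste(cur, flag, sep = ","), flag)
  filters
}

#' Flag predictions with insufficient support
#'
#' Adds the \code{low_support} flag to predictions whose total support is
#' below \code{min_support} (default 5 reads). Flag-setting only: flagged
#' predictions are excluded from the default report but kept in the audit
#' output.
#'
#' @param preds prediction \code{data.table}
#' @param cfg a \code{caller_config}
#' @return predictions with updated \code{filters}
#' @export
filter_support <- function(preds, cfg = caller_config()) {
  if (nrow(preds) == 0L) return(preds)
  stopifnot(all(preds$support >= 1L))
  idx <- which(preds$support < cfg$min_support)
  preds$filters <- add_flag(preds$filters, idx, "low_support")
  preds
}

#' Load a reference mobile-element annotation BED
#'
#' BED4: chrom, start, end (0-based half-open), name = family label. Names
#' containing ALU/L1/SVA/HERV-K (case-insensitive) are mapped to the four
#' families; anything else becomes "Other".
#'
#' @param path BED file path
#' @return sorted \code{data.table} (chrom, start, end, family)
#' @export
load_reference_mei <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name")[1:4])
  fam <- vapply(bed$name, function(n) {
    tryCatch(classify_family_header(n), error = function(e) "Other")
  }, character(1))
  out <- data.table::data.table(chrom = bed$chrom, start = bed$start,
                                end = bed$end, family = fam)
  data.table::setorder(out, chrom, start)
  out
}

#' Flag predictions near reference mobile elements of the same family
#'
#' Adds the \code{reference_mei} flag when the prediction window lies
#' within \code{reference_mei_filter_window} bp (default 90, edge-to-edge;
#' 0 when overlapping) of an annotated reference element of the same
#' family.
#'
#' @param preds prediction \code{data.table}
#' @param ann annotation from \code{\link{load_reference_mei}}
#' @param cfg a \code{caller_config}
#' @return predictions with updated \code{filters}
#' @export
filter_reference_mei <- function(preds, ann, cfg = caller_config()) {
  if (nrow(preds) == 0L || is.null(ann) || nrow(ann) == 0L) return(preds)
  w <- cfg$reference_mei_filter_window
  hit <- vapply(seq_len(nrow(preds)), function(i) {
    a <- ann[chrom == preds$chrom[i] & family == preds$family[i]]
    if (nrow(a) == 0L) return(FALSE)
    any(interval_gap(preds$window_start[i], preds$window_end[i],
                     a$start, a$end) <= w)
  }, logical(1))
  preds$filters <- add_flag(preds$filters, which(hit), "reference_mei")
  preds
}

#' Flag predictions inside satellite DNA
#'
#' Adds the \code{satellite} flag when the prediction window overlaps a
#' satellite interval (half-open; adjacency is not overlap). With no
#' satellite annotation the predictions are returned unchanged.
#'
#' @param preds prediction \code{data.table}
#' @param satellite \code{data.table} with chrom, start, end (BED3), or NULL
#' @return predictions with updated \code{filters}
#' @export
filter_satellite <- function(preds, satellite = NULL) {
  if (nrow(preds) == 0L || is.null(satellite) || nrow(satellite) == 0L) {
    return(preds)
  }
  hit <- vapply(seq_len(nrow(preds)), function(i) {
    s <- satellite[chrom == preds$chrom[i]]
    if (nrow(s) == 0L) return(FALSE)
    any(interval_overlap(preds$window_start[i], preds$window_end[i],
                         s$start, s$end) > 0L)
  }, logical(1))
  preds$filters <- add_flag(preds$filters, which(hit), "satellite")
  preds
}

#' Flag single-sided predictions
#'
#' When \code{require_double_cluster} is TRUE (the whole-genome default),
#' predictions lacking evidence on the 5' or the 3' side of the insertion
#' (no cluster of any evidence type on that side) are flagged
#' \code{single_cluster}. The paired-end exome preset leaves this off so
#' insertions near capture-region borders survive.
#'
#' @param preds prediction \code{data.table} (with has5/has3 columns)
#' @param cfg a \code{caller_config}
#' @return predictions with updated \code{filters}
#' @export
filter_double_cluster <- function(preds, cfg = caller_config()) {
  if (nrow(preds) == 0L || !isTRUE(cfg$require_double_cluster)) return(preds)
  idx <- which(!(preds$has5 & preds$has3))
  preds$filters <- add_flag(preds$filters, idx, "single_cluster")
  preds
}

#' Merge nearby predictions of the same family
#'
#' Transitive closure over pairs of same-chromosome, same-family
#' predictions whose windows lie within \code{prediction_merge_window} bp
#' (default 50) of each other. Merged windows are unions, support is
#' summed, and the breakpoint is taken from the member with clipped
#' support, else from the member with the widest support. Idempotent.
#'
#' @param preds prediction \code{data.table}
#' @param cfg a \code{caller_config}
#' @return merged prediction \code{data.table}
#' @export
merge_predictions <- function(preds, cfg = caller_config()) {
  if (nrow(preds) <= 1L) return(preds)
  p <- data.table::copy(preds)
  data.table::setorder(p, chrom, family, window_start, window_end)
  key <- paste(p$chrom, p$family, sep = "\r")
  comp <- integer(nrow(p))
  cid <- 0L
  for (g in unique(key)) {
    idx <- which(key == g)
    # sorted by start within group: chain while gap <= window
    prev_end <- -Inf; gid <- 0L
    for (i in idx) {
      if (p$window_start[i] - prev_end > cfg$prediction_merge_window) {
        cid <- cid + 1L
      }
      comp[i] <- cid
      prev_end <- max(prev_end, p$window_end[i])
    }
  }
  merged <- lapply(split(seq_len(nrow(p)), comp), function(ix) {
    m <- p[ix]
    if (nrow(m) == 1L) return(m)
    best <- if (any(m$support_clipped > 0L)) {
      which.max(ifelse(m$support_clipped > 0L, m$support, -1L))
    } else which.max(m$support)
    out <- m[best]
    out$window_start <- min(m$window_start)
    out$window_end <- max(m$window_end)
    out$support <- sum(m$support)
    out$support_disc_unique <- sum(m$support_disc_unique)
    out$support_disc_multimapped <- sum(m$support_disc_multimapped)
    out$support_clipped <- sum(m$support_clipped)
    out$support_unmapped <- sum(m$support_unmapped)
    out$has5 <- any(m$has5); out$has3 <- any(m$has3)
    out
  })
  out <- data.table::rbindlist(merged)
  data.table::setorder(out, chrom, window_start)
  out
}

#' Insertion orientation from the polyA side
#'
#' A polyA tail detected on the 3' side means a plus-strand insertion; a
#' polyA tail on the 5' side (reading as polyT on the reference forward
#' strand) means minus strand; no homopolymer evidence leaves the
#' orientation unknown.
#'
#' @param pred one-row prediction (needs \code{polyA_side})
#' @return "+", "-" or "unknown"
#' @export
determine_orientation <- function(pred) {
  side <- pred$polyA_side
  if (identical(side, "3prime")) return("+")
  if (identical(side, "5prime")) return("-")
  "unknown"
}

#' Extract the 13 bp reference context around an insertion breakpoint
#'
#' For plus-strand insertions, 13 bp centred on the 3' clipped cluster's
#' clip position (6 bases left, the position, 6 right); for minus-strand
#' insertions, around the 5' clipped cluster's position. This is the
#' subsequence carrying the endonuclease TTTT/A[AT] motif. Positions closer
#' than 6 bp to a contig edge are N-padded.
#'
#' @param pred one-row prediction with clipped support and known orientation
#' @param reference a named character vector of contig sequences, or a
#'   \code{DNAStringSet}
#' @param clip3_pos,clip5_pos modal clip positions of the 3' and 5' clipped
#'   clusters (0-based); derived from the breakpoint interval when NULL
#'   (plus strand: breakpoint start; minus strand: breakpoint end boundary)
#' @return 13-character string, or NA when orientation is unknown or
#'   clipped support is absent
#' @export
breakpoint_context <- function(pred, reference, clip3_pos = NULL,
                               clip5_pos = NULL) {
  if (!pred$orientation %in% c("+", "-")) return(NA_character_)
  if (pred$support_clipped == 0L) return(NA_character_)
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  contig <- reference[[pred$chrom]]
  if (is.null(contig)) return(NA_character_)
  p <- if (pred$orientation == "+") {
    clip3_pos %||% pred$breakpoint_start
  } else {
    clip5_pos %||% (pred$breakpoint_end - 1L)
  }
  lo <- p - 6L; hi <- p + 6L  # 0-based inclusive positions lo..hi
  n <- nchar(contig)
  left_pad <- max(0L, -lo); right_pad <- max(0L, hi - (n - 1L))
  core <- substr(contig, max(lo, 0L) + 1L, min(hi, n - 1L) + 1L)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Load a refFlat-style gene model
#'
#' Tab-separated refFlat: geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds (0-based half-open,
#' exon lists comma-terminated). Transcripts with cdsStart == cdsEnd are
#' treated as non-coding.
#'
#' @param path refFlat file path
#' @return a \code{gene_model} list of interval tables
#' @export
load_gene_model <- function(path) {
  cols <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  g <- data.table::fread(path, header = FALSE, col.names = cols)
  exons <- list(); introns <- list(); utr5 <- list(); utr3 <- list()
  nc_exons <- list(); tx <- list()
  for (i in seq_len(nrow(g))) {
    es <- as.integer(strsplit(g$exonStarts[i], ",")[[1]])
    ee <- as.integer(strsplit(g$exonEnds[i], ",")[[1]])
    stopifnot(all(es >= g$txStart[i]), all(ee <= g$txEnd[i]))
    chrom <- g$chrom[i]; strand <- g$strand[i]
    coding <- g$cdsStart[i] < g$cdsEnd[i]
    tx[[i]] <- data.table::data.table(chrom = chrom, start = g$txStart[i],
                                      end = g$txEnd[i], strand = strand,
                                      gene = g$geneName[i])
    if (length(es) > 1L) {
      introns[[i]] <- data.table::data.table(chrom = chrom,
                                             start = ee[-length(ee)],
                                             end = es[-1L])
    }
    if (coding) {
      cs <- g$cdsStart[i]; ce <- g$cdsEnd[i]
      cds_e <- data.table::data.table(chrom = chrom,
                                      start = pmax(es, cs), end = pmin(ee, ce))
      exons[[i]] <- cds_e[start < end]
      left <- data.table::data.table(chrom = chrom, start = es,
                                     end = pmin(ee, cs))
      left <- left[start < end]
      right <- data.table::data.table(chrom = chrom, start = pmax(es, ce),
                                      end = ee)
      right <- right[start < end]
      if (strand == "+") {
        utr5[[i]] <- left; utr3[[i]] <- right
      } else {
        utr5[[i]] <- right; utr3[[i]] <- left
      }
    } else {
      nc_exons[[i]] <- data.table::data.table(chrom = chrom, start = es, end = ee)
    }
  }
  bind <- function(x) {
    if (length(x) == 0L) return(data.table::data.table(
      chrom = character(0), start = integer(0), end = integer(0)))
    data.table::rbindlist(x[!vapply(x, is.null, logical(1))])
  }
  structure(list(exons = bind(exons), nc_exons = bind(nc_exons),
                 utr5 = bind(utr5), utr3 = bind(utr3),
                 introns = bind(introns), transcripts = bind(tx)),
            class = "gene_model")
}

overlaps_any <- function(chrom, start, end, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(FALSE)
  t <- tab[tab$chrom == chrom]
  if (nrow(t) == 0L) return(FALSE)
  any(interval_overlap(start, end, t$start, t$end) > 0L)
}

#' Annotate a prediction with the highest-priority gene component
#'
#' One label per prediction, tested against the prediction window in the
#' priority order exonic/splice > non-coding exonic > UTR5 > UTR3 >
#' intronic > 1 kb upstream > 1 kb downstream > intergenic. Splice sites
#' (within 2 bp of an exon/intron boundary) share the top priority and are
#' reported as \code{splice}.
#'
#' @param pred one-row prediction
#' @param genes a \code{gene_model}
#' @return component label string
#' @export
annotate_gene_component <- function(pred, genes) {
  ch <- pred$chrom; s <- pred$window_start; e <- pred$window_end
  if (overlaps_any(ch, s, e, genes$exons)) return("exonic")
  # splice: window touches an intron border region (2 bp each side)
  introns <- genes$introns[genes$introns$chrom == ch]
  if (nrow(introns)) {
    edges <- c(introns$start, introns$end)
    if (any(interval_overlap(s, e, edges - 2L, edges + 2L) > 0L) &&
        overlaps_any(ch, s, e, introns)) {
      return("splice")
    }
  }
  if (overlaps_any(ch, s, e, genes$nc_exons)) return("ncRNA_exonic")
  if (overlaps_any(ch, s, e, genes$utr5)) return("UTR5")
  if (overlaps_any(ch, s, e, genes$utr3)) return("UTR3")
  if (overlaps_any(ch, s, e, genes$introns)) return("intronic")
  tx <- genes$transcripts[genes$transcripts$chrom == ch]
  if (nrow(tx)) {
    up <- ifelse(tx$strand == "+", tx$start - 1000L, tx$end)
    up_end <- ifelse(tx$strand == "+", tx$start, tx$end + 1000L)
    if (any(interval_overlap(s, e, up, up_end) > 0L)) return("upstream_1kb")
    dn <- ifelse(tx$strand == "+", tx$end, tx$start - 1000L)
    dn_end <- ifelse(tx$strand == "+", tx$end + 1000L, tx$start)
    if (any(interval_overlap(s, e, dn, dn_end) > 0L)) return("downstream_1kb")
  }
  "intergenic"
}

#' Write predictions to TSV (and optionally VCF)
#'
#' The TSV has the fixed column order documented in the package README
#' (0-based half-open coordinates). The optional VCF 4.2 uses symbolic
#' \code{<INS:ME:FAMILY>} ALT alleles with 1-based POS at the breakpoint
#' and CIPOS encoding the prediction window.
#'
#' @param preds prediction \code{data.table}
#' @param path output TSV path
#' @param format "tsv" or "vcf" (vcf writes both, the VCF beside the TSV)
#' @param reference_name label for the VCF header
#' @return \code{path}, invisibly
#' @export
write_predictions <- function(preds, path, format = c("tsv", "vcf"),
                              reference_name = "unknown") {
  format <- match.arg(format)
  out <- data.table::as.data.table(preds)
  for (col in prediction_columns) {
    if (!col %in% names(out)) out[, (col) := NA]
  }
  out <- out[, prediction_columns, with = FALSE]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  if (format == "vcf") {
    vcf_path <- sub("\\.tsv$", "", path)
    vcf_path <- paste0(vcf_path, ".vcf")
    write_predictions_vcf(preds, vcf_path, reference_name)
  }
  invisible(path)
}

write_predictions_vcf <- function(preds, path, reference_name = "unknown") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=meicall"),
    paste0("##reference=", reference_name),
    "##ALT=<ID=INS:ME:ALU,Description=\"Alu element insertion\">",
    "##ALT=<ID=INS:ME:L1,Description=\"L1 element insertion\">",
    "##ALT=<ID=INS:ME:SVA,Description=\"SVA element insertion\">",
    "##ALT=<ID=INS:ME:HERVK,Description=\"HERV-K element insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Window end (1-based)\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Window around POS\">",
    "##INFO=<ID=TSD,Number=1,Type=Integer,Description=\"Signed target site duplication length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(preds)) {
    pos1 <- preds$breakpoint_start + 1L  # VCF 1-based
    rows <- sprintf(
      "%s\t%d\t%s\t%s\t<INS:ME:%s>\t.\t%s\tSVTYPE=INS;END=%d;CIPOS=%d,%d;%sSUPPORT=%d",
      preds$chrom, pos1, paste0("mei_", seq_len(nrow(preds))), "N",
      toupper(preds$family),
      ifelse(nzchar(preds$filters), preds$filters, "PASS"),
      preds$window_end,
      preds$window_start - preds$breakpoint_start,
      preds$window_end - preds$breakpoint_start,
      ifelse(is.na(preds$tsd_bp), "", sprintf("TSD=%d;", preds$tsd_bp)),
      preds$support)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a prediction TSV written by \code{\link{write_predictions}}
#'
#' @param path TSV path
#' @return prediction \code{data.table}
#' @export
read_predictions <- function(path) {
  out <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("chrom", "family",
                                                           "orientation",
                                                           "polyA_side",
                                                           "filters",
                                                           "gene_component")))
  out[is.na(filters), filters := ""]
  out
}

#' Run the full insertion-calling pipeline on a BAM
#'
#' Orchestrates candidate extraction, mobilome tagging, clustering, event
#' assembly, prediction building, filtering and merging.
#'
#' @param bam coordinate-sorted indexed BAM path
#' @param mobilome mobilome FASTA path or \code{mobilome_db}
#' @param cfg a \code{caller_config}
#' @param ref_mei reference-ME BED path or table from
#'   \code{\link{load_reference_mei}} (optional)
#' @param satellite satellite BED3 path or table (optional)
#' @param genes refFlat path or \code{gene_model} (optional)
#' @param reference reference FASTA path or named sequences (optional;
#'   enables breakpoint context extraction)
#' @param verbose log per-stage counts to stderr
#' @return list with \code{predictions} (default report: unflagged, merged),
#'   \code{audit} (all predictions with filter flags), \code{stats},
#'   \code{counts} (per-stage counts)
#' @export
detect_meis <- function(bam, mobilome, cfg = caller_config(),
                        ref_mei = NULL, satellite = NULL, genes = NULL,
                        reference = NULL, verbose = FALSE) {
  db <- if (inherits(mobilome, "mobilome_db")) mobilome else build_mobilome(mobilome)
  counts <- list()
  stats <- NULL
  read_len <- 100L
  if (cfg$mode == "paired") {
    stats <- estimate_insert_size(bam)
    stage_log("insert-size", sprintf("median=%.0f sd=%.1f n=%d", stats$median,
                                     stats$sd, stats$n_sampled), verbose = verbose)
  }
  cands <- extract_candidates(bam, stats, cfg)
  if (nrow(cands)) {
    rl <- nchar(cands$candidate_seq[cands$origin != "clipped_tail"])
    if (length(rl)) read_len <- as.integer(stats::median(rl))
  }
  counts$candidates <- nrow(cands)
  stage_log("extract", counts$candidates, " candidate reads", verbose = verbose)
  anchors <- tag_anchors(cands, db, cfg)
  counts$anchors <- nrow(anchors)
  stage_log("mobilome", counts$anchors, " tagged anchors", verbose = verbose)
  if (cfg$mode == "single") anchors <- anchors[anchors$evidence == "clipped"]
  disc_cl <- list(); clip_cl <- list()
  for (ch in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == ch]
    disc_cl <- c(disc_cl, cluster_discordant(sub[sub$evidence == "discordant"], cfg))
    clip_cl <- c(clip_cl, cluster_clipped(sub[sub$evidence == "clipped"], cfg))
  }
  counts$clusters <- length(disc_cl) + length(clip_cl)
  stage_log("cluster", length(disc_cl), " discordant + ", length(clip_cl),
            " clipped clusters", verbose = verbose)
  events <- assemble_events(disc_cl, clip_cl, cfg)
  counts$events <- length(events)
  preds <- events_to_predictions(events, stats, read_len, cfg)
  preds <- filter_support(preds, cfg)
  if (!is.null(ref_mei)) {
    ann <- if (is.character(ref_mei)) load_reference_mei(ref_mei) else ref_mei
    preds <- filter_reference_mei(preds, ann, cfg)
  }
  if (!is.null(satellite)) {
    sat <- if (is.character(satellite)) {
      data.table::fread(satellite, header = FALSE,
                        col.names = c("chrom", "start", "end"))
    } else satellite
    preds <- filter_satellite(preds, sat)
  }
  preds <- filter_double_cluster(preds, cfg)
  audit <- data.table::copy(preds)
  pass <- preds[!nzchar(preds$filters)]
  pass <- merge_predictions(pass, cfg)
  if (!is.null(genes)) {
    gm <- if (is.character(genes)) load_gene_model(genes) else genes
    if (nrow(pass)) {
      pass$gene_component <- vapply(seq_len(nrow(pass)), function(i)
        annotate_gene_component(pass[i], gm), character(1))
    }
  }
  if (nrow(pass)) data.table::setorder(pass, chrom, window_start)
  counts$predictions <- nrow(pass)
  stage_log("predict", counts$predictions, " predictions pass (",
            nrow(audit) - sum(!nzchar(audit$filters)), " flagged)",
            verbose = verbose)
  drop_cols <- intersect(c("has5", "has3"), names(pass))
  if (length(drop_cols)) pass[, (drop_cols) := NULL]
  list(predictions = pass, audit = audit, stats = stats, counts = counts,
       config = cfg)
}
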