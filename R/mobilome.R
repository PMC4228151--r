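# Mobilome handling: a small library of mobile-element family consensus
# sequences (Alu, L1, SVA, HERV-K) used as the mapping target for candidate
# reads, plus polyA/polyT tail detection and anchor tagging.

ME_FAMILIES <- c("Alu", "L1", "SVA", "HERVK")

.seed_k <- 11L

.submat_env <- new.env(parent = emptyenv())
.submat_cache <- function() {
  if (is.null(.submat_env$m)) {
    .submat_env$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 0, mismatch = -1, baseOnly = FALSE)
  }
  .submat_env$m
}

classify_family_header <- function(header) {
  pats <- c(Alu = "ALU", L1 = "\\bL1|^L1|L1HS|LINE1|L1[A-Z0-9]", SVA = "SVA",
            HERVK = "HERV[-_]?K")
  hit <- vapply(pats, function(p) grepl(p, toupper(header)), logical(1))
  # 'ALU' never collides; L1 pattern may fire inside e.g. 'SVA_L1' -- treat
  # multi-family headers as unclassifiable
  fams <- names(pats)[hit]
  if (length(fams) == 1L) return(fams)
  if (length(fams) == 0L) {
    stop("cannot assign a mobile element family to FASTA header '", header,
         "'; header must contain one of ALU / L1 / SVA / HERV-K")
  }
  stop("FASTA header '", header, "' matches multiple families: ",
       paste(fams, collapse = ", "))
}

#' Build a mobilome database
#'
#' Reads a FASTA of mobile element family consensus sequences and indexes it
#' for candidate-read mapping. Each header must identify one of the four
#' active families (contains ALU, L1, SVA or HERV-K, case-insensitive).
#' Both strands are indexed; duplicate sequences under different names are
#' kept, and hits on tied entries report the first in FASTA order.
#'
#' @param fasta path to a mobilome FASTA, or a named character vector of
#'   sequences (names are treated like FASTA headers)
#' @return a \code{mobilome_db} object
#' @export
build_mobilome <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) == 0L) stop("empty mobilome FASTA: ", fasta)
    seqv <- toupper(as.character(seqs))
    names(seqv) <- sub("\\s.*$", "", names(seqs))
  } else {
    seqv <- toupper(fasta)
    if (is.null(names(seqv)) || length(seqv) == 0L) {
      stop("mobilome sequences must be a non-empty named vector or FASTA path")
    }
  }
  if (any(grepl("[^ACGTN]", seqv))) stop("mobilome sequences must be ACGTN")
  fam <- vapply(names(seqv), classify_family_header, character(1))
  entries <- data.table::data.table(
    name = names(seqv), family = unname(fam), seq = unname(seqv),
    len = nchar(seqv)
  )
  # concatenated subject: per entry, plus strand then minus strand, padded by
  # runs of N longer than any query so windows never span two entries
  pad <- strrep("N", 200L)
  pieces <- character(2L * nrow(entries))
  meta <- vector("list", 2L * nrow(entries))
  for (i in seq_len(nrow(entries))) {
    pieces[2L * i - 1L] <- entries$seq[i]
    pieces[2L * i] <- revcomp(entries$seq[i])
    meta[[2L * i - 1L]] <- list(entry = i, strand = "+")
    meta[[2L * i]] <- list(entry = i, strand = "-")
  }
  lens <- nchar(pieces)
  starts <- cumsum(c(1L, head(lens + nchar(pad), -1L)))
  subject <- paste(pieces, collapse = pad)
  piece_dt <- data.table::data.table(
    piece = seq_along(pieces),
    entry = vapply(meta, `[[`, integer(1), "entry"),
    strand = vapply(meta, `[[`, character(1), "strand"),
    start = starts, end = starts + lens  # half-open, 1-based start
  )
  # seed index: k-mer -> subject positions (environment hash), plus a
  # short-kmer presence set used to certify "no qualifying hit" cheaply
  idx <- new.env(parent = emptyenv(), size = 4L * sum(lens))
  screen_k <- 8L
  screen <- new.env(parent = emptyenv(), size = 4L * sum(lens))
  for (j in seq_len(nrow(piece_dt))) {
    s <- pieces[j]
    n <- nchar(s)
    if (n < .seed_k) next
    kpos <- seq_len(n - .seed_k + 1L)
    kmers <- substring(s, kpos, kpos + .seed_k - 1L)
    abs_pos <- piece_dt$start[j] + kpos - 1L
    keep <- !grepl("N", kmers, fixed = TRUE)
    kmers <- kmers[keep]; abs_pos <- abs_pos[keep]
    for (t in seq_along(kmers)) {
      km <- kmers[t]
      idx[[km]] <- c(idx[[km]], abs_pos[t])
    }
    spos <- seq_len(n - screen_k + 1L)
    skmers <- unique(substring(s, spos, spos + screen_k - 1L))
    for (km in skmers[!grepl("N", skmers, fixed = TRUE)]) {
      assign(km, TRUE, envir = screen)
    }
  }
  # 6-mer position index: exact secondary stage. Any placement with
  # m <= floor(0.1 n) mismatches contains a clean 6-mer (n >= 7m + 6 for
  # all n >= 18), so checking only 6-mer seed diagonals finds the true
  # best qualifying placement without a blind exhaustive scan.
  k6 <- 6L
  idx6 <- new.env(parent = emptyenv(), size = 4096L)
  for (j in seq_len(nrow(piece_dt))) {
    s <- pieces[j]
    n <- nchar(s)
    if (n < k6) next
    kpos <- seq_len(n - k6 + 1L)
    kmers <- substring(s, kpos, kpos + k6 - 1L)
    abs_pos <- piece_dt$start[j] + kpos - 1L
    keep <- !grepl("N", kmers, fixed = TRUE)
    sp <- split(abs_pos[keep], kmers[keep])
    for (km in names(sp)) {
      idx6[[km]] <- c(idx6[[km]], sp[[km]])
    }
  }
  structure(list(entries = entries, subject = Biostrings::DNAString(subject),
                 subject_chr = subject, pieces = piece_dt,
                 piece_start = piece_dt$start, piece_end = piece_dt$end,
                 index = idx, k = .seed_k,
                 index6 = idx6, k6 = k6,
                 screen = screen, screen_k = screen_k),
            class = "mobilome_db")
}

#' @export
print.mobilome_db <- function(x, ...) {
  cat("mobilome_db:", nrow(x$entries), "entries,",
      length(unique(x$entries$family)), "families\n")
  print(x$entries[, c("name", "family", "len")])
  invisible(x)
}

# index of the piece containing subject position 'pos' (1-based)
.piece_idx <- function(db, pos) findInterval(pos, db$piece_start)

# certify that no placement can meet the mismatch budget: if the query
# shares no screen_k-mer with the subject, every placement's longest clean
# run is < screen_k, so the best mismatch count is at least
# ceil((n - screen_k + 1) / screen_k); when that exceeds the allowance the
# query cannot map. Saves an exhaustive scan for homopolymer tails and
# random sequence.
.screen_rules_out <- function(seq, db, allow) {
  n <- nchar(seq)
  k <- db$screen_k
  if (n < k) return(FALSE)
  if (ceiling((n - k + 1L) / k) <= allow) return(FALSE)
  off <- seq_len(n - k + 1L)
  kmers <- unique(substring(seq, off, off + k - 1L))
  for (km in kmers) {
    if (!is.null(db$screen[[km]])) return(FALSE)
  }
  TRUE
}

# Candidate diagonals for 'seq' from the seed index. Returns integer vector
# of subject start positions for a full-length ungapped placement of seq;
# with counts = TRUE, a list with per-diagonal supporting-seed counts.
.seed_diagonals <- function(seq, db, counts = FALSE) {
  n <- nchar(seq)
  k <- db$k
  if (n < k) return(if (counts) list(diags = integer(0), support = integer(0))
                    else integer(0))
  off <- seq_len(n - k + 1L)
  kmers <- substring(seq, off, off + k - 1L)
  keep <- !duplicated(kmers)
  kmers <- kmers[keep]; off <- off[keep]
  hits <- mget(kmers, envir = db$index, ifnotfound = list(NULL))
  diags <- integer(0)
  for (t in seq_along(hits)) {
    h <- hits[[t]]
    if (!is.null(h)) diags <- c(diags, h - off[t] + 1L)
  }
  diags <- diags[diags >= 1L]
  if (!counts) return(sort(unique(diags)))
  tb <- table(diags)
  list(diags = as.integer(names(tb)), support = as.integer(tb))
}

# Exhaustive ungapped scan: mismatch count of seq at every valid subject
# offset (C-level Hamming via neditStartingAt). Used as a fallback when
# seeding cannot certify the best hit.
.exhaustive_best <- function(seq, db) {
  n <- nchar(seq)
  ps <- db$piece_start; pe <- db$piece_end
  starts <- unlist(lapply(seq_along(ps), function(j) {
    if (pe[j] - ps[j] < n) return(integer(0))
    ps[j]:(pe[j] - n)
  }))
  if (length(starts) == 0L) return(NULL)
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(seq), db$subject,
                                    starting.at = starts, with.indels = FALSE)
  list(starts = starts, mm = mm)
}

# candidate diagonals from the 6-mer index, restricted to in-piece
# full-length placements
.diagonals6 <- function(seq, db) {
  n <- nchar(seq)
  k <- db$k6
  if (n < k) return(integer(0))
  off <- seq_len(n - k + 1L)
  kmers <- substring(seq, off, off + k - 1L)
  keep <- !duplicated(kmers)
  kmers <- kmers[keep]; off <- off[keep]
  hits <- mget(kmers, envir = db$index6, ifnotfound = list(NULL))
  diags <- integer(0)
  for (t in seq_along(hits)) {
    h <- hits[[t]]
    if (!is.null(h)) diags <- c(diags, h - off[t] + 1L)
  }
  diags <- unique(diags[diags >= 1L])
  if (length(diags)) {
    pi <- .piece_idx(db, diags)
    diags <- diags[diags >= db$piece_start[pi] & diags + n <= db$piece_end[pi]]
  }
  sort(diags)
}

# Best ungapped placement of seq against db, exact for any mismatch
# allowance 'allow' satisfying n >= 7*allow + 6. Three stages: 11-mer
# seeded diagonals (certified optimal by pigeonhole when the best is
# small), 6-mer seeded diagonals (complete for qualifying placements),
# and a blind exhaustive scan only when even 6-mers cannot certify.
.best_ungapped <- function(seq, db, allow) {
  n <- nchar(seq)
  pat <- Biostrings::DNAString(seq)
  diags <- .seed_diagonals(seq, db)
  if (length(diags)) {
    pi <- .piece_idx(db, diags)
    ok <- diags >= db$piece_start[pi] & diags + n <= db$piece_end[pi]
    diags <- diags[ok]
  }
  if (length(diags)) {
    mm <- Biostrings::neditStartingAt(pat, db$subject,
                                      starting.at = diags, with.indels = FALSE)
    # a placement with m mismatches contains a clean k-mer when
    # n >= (k+1)*m + k; then its diagonal is among the seeded candidates
    if (n >= (db$k + 1L) * min(mm) + db$k) return(list(starts = diags, mm = mm))
  }
  if (n >= (db$k6 + 1L) * allow + db$k6) {
    d6 <- .diagonals6(seq, db)
    if (length(d6) == 0L) return(NULL)
    mm <- Biostrings::neditStartingAt(pat, db$subject, starting.at = d6,
                                      with.indels = FALSE)
    return(list(starts = d6, mm = mm))
  }
  .exhaustive_best(seq, db)
}

# Banded gapped fallback (band 3) for reads whose best ungapped placement
# fails the mismatch budget, e.g. clipped tails spanning a small indel.
.gapped_rescue <- function(seq, db, max_frac) {
  n <- nchar(seq)
  sd_ <- .seed_diagonals(seq, db, counts = TRUE)
  if (length(sd_$diags) == 0L) return(NULL)
  band <- 3L
  # a placement worth a banded realignment has a long exact stretch, i.e.
  # several seeds within the band of one diagonal; chance 11-mer hits from
  # unrelated sequence have support 1 and are skipped
  supp <- vapply(seq_along(sd_$diags), function(i)
    sum(sd_$support[abs(sd_$diags - sd_$diags[i]) <= band]), integer(1))
  diags <- sd_$diags[supp >= 4L]
  if (length(diags) == 0L) return(NULL)
  if (length(diags) > 8L) diags <- diags[order(-supp[supp >= 4L])][1:8]
  best <- NULL
  submat <- .submat_cache()
  for (d in diags) {
    pi <- .piece_idx(db, d)
    lo <- max(db$piece_start[pi], d - band)
    hi <- min(db$piece_end[pi], d + n + band)
    if (hi - lo < n - band) next
    win <- substr(db$subject_chr, lo, hi - 1L)
    al <- Biostrings::pairwiseAlignment(
      pattern = seq, subject = win, type = "global-local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 1)
    edits <- -as.integer(Biostrings::score(al))
    if (edits / n <= max_frac && (is.null(best) || edits < best$mm)) {
      best <- list(pos = lo, mm = edits, piece_idx = pi)
    }
  }
  best
}

#' Map a sequence against the mobilome
#'
#' Finds the best placement of \code{seq} (either strand, ungapped with a
#' banded gapped fallback) in the mobilome. A hit is reported only when the
#' best mismatch fraction over the query length is at most
#' \code{cfg$mobilome_max_mismatch_frac} (default 10\%). Queries shorter
#' than 18 bp never map (below the length at which reads map uniquely to
#' the mobilome). When the best placements in two different families tie,
#' the hit is flagged \code{ambiguous_across_families}.
#'
#' @param seq nucleotide string
#' @param db a \code{mobilome_db}
#' @param cfg a \code{caller_config}
#' @param max_mismatches optional absolute mismatch allowance overriding the
#'   fractional threshold (used by the random-read mapping experiment)
#' @return \code{NULL} or a list with \code{family}, \code{mismatches},
#'   \code{mismatch_frac}, \code{ambiguous_across_families},
#'   \code{target_strand}, \code{entry_name}
#' @export
map_to_mobilome <- function(seq, db, cfg = caller_config(), max_mismatches = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 18L) return(NULL)
  allow <- if (is.null(max_mismatches)) {
    floor(cfg$mobilome_max_mismatch_frac * n + 1e-9)
  } else {
    as.integer(max_mismatches)
  }
  if (.screen_rules_out(seq, db, allow)) return(NULL)
  res <- .best_ungapped(seq, db, allow)
  hit <- NULL
  if (!is.null(res) && min(res$mm) <= allow) {
    b <- min(res$mm)
    pos <- res$starts[res$mm == b]
    pi <- .piece_idx(db, pos)
    hit <- list(mm = b, entries = db$pieces$entry[pi],
                strands = db$pieces$strand[pi])
  } else if (is.null(max_mismatches)) {
    g <- .gapped_rescue(seq, db, cfg$mobilome_max_mismatch_frac)
    if (!is.null(g) && g$mm <= allow) {
      hit <- list(mm = g$mm, entries = db$pieces$entry[g$piece_idx],
                  strands = db$pieces$strand[g$piece_idx])
    }
  }
  if (is.null(hit)) return(NULL)
  fams <- db$entries$family[hit$entries]
  ambiguous <- length(unique(fams)) > 1L
  # tie-break: first entry in FASTA order; '+' strand before '-'
  ord <- order(hit$entries, hit$strands)
  first <- ord[1L]
  list(family = fams[first],
       mismatches = hit$mm,
       mismatch_frac = hit$mm / n,
       ambiguous_across_families = ambiguous,
       target_strand = hit$strands[first],
       entry_name = db$entries$name[hit$entries[first]])
}

#' Detect a terminal polyA or polyT stretch
#'
#' Scans both ends of \code{seq} for a terminal window that is at least 90\%
#' A (or T) and strictly longer than \code{cfg$min_polyA_length} (default:
#' longer than 8 bp). PolyA is checked before polyT.
#'
#' @param seq nucleotide string
#' @param cfg a \code{caller_config}
#' @return \code{"polyA"}, \code{"polyT"} or \code{"none"}
#' @export
detect_polytail <- function(seq, cfg = caller_config()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  minlen <- cfg$min_polyA_length
  if (n <= minlen) return("none")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  end_run <- function(base) {
    isb <- chars == base
    # longest terminal window (either end) with >= 90% 'base'
    best <- 0L
    from_start <- cumsum(isb) / seq_len(n)
    w <- which(from_start >= 0.9)
    if (length(w)) best <- max(best, max(w))
    from_end <- cumsum(rev(isb)) / seq_len(n)
    w <- which(from_end >= 0.9)
    if (length(w)) best <- max(best, max(w))
    best
  }
  if (end_run("A") > minlen) return("polyA")
  if (end_run("T") > minlen) return("polyT")
  "none"
}

#' Tag candidate reads with mobile element family or homopolymer evidence
#'
#' Converts candidate reads (discordant mates, unmapped mates, clipped
#' tails) into anchors tagged with the family their candidate sequence maps
#' to, or a polyA/polyT label for clipped tails, or \code{unmapped} for
#' unmapped-mate candidates whose sequence maps nowhere. Discordant pairs
#' whose two sequences both map to the mobilome are excluded (both ends
#' inside reference mobile elements), as are hits that are ambiguous across
#' families.
#'
#' @param candidates a \code{data.table} of candidate reads as produced by
#'   \code{\link{extract_candidates}}
#' @param db a \code{mobilome_db}
#' @param cfg a \code{caller_config}
#' @return a \code{data.table} of anchors (chrom, start, end, strand,
#'   evidence, side, tag, clip_pos, origin, qname)
#' @export
tag_anchors <- function(candidates, db, cfg = caller_config()) {
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), evidence = character(0), side = character(0),
    tag = character(0), clip_pos = integer(0), origin = character(0),
    qname = character(0), target_strand = character(0))
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  cand <- data.table::copy(candidates)
  nseq <- nrow(cand)
  tag <- character(nseq); tstrand <- rep(NA_character_, nseq)
  ambiguous <- logical(nseq); fam_hit <- logical(nseq)
  for (i in seq_len(nseq)) {
    h <- map_to_mobilome(cand$candidate_seq[i], db, cfg)
    if (!is.null(h)) {
      fam_hit[i] <- TRUE
      ambiguous[i] <- h$ambiguous_across_families
      tag[i] <- h$family
      tstrand[i] <- h$target_strand
    } else if (cand$origin[i] %in% c("clipped_tail")) {
      tag[i] <- switch(detect_polytail(cand$candidate_seq[i], cfg),
                       polyA = "polyA", polyT = "polyT", "")
    } else if (cand$origin[i] == "unmapped_mate") {
      # polytail on an unmapped mate cannot side a breakpoint; keep the
      # anchor but count it as generic unmapped support
      tag[i] <- "unmapped"
    } else {
      tag[i] <- ""
    }
  }
  cand[, `:=`(tag = tag, target_strand = tstrand, ambiguous = ambiguous,
              fam_hit = fam_hit)]
  # both-ends-map-to-ME exclusion for discordant pairs where both ends were
  # uniquely mapped (both emitted as candidates, origin discordant_mate)
  qname <- NULL; origin <- NULL  # NSE shims
  both <- cand[origin == "discordant_mate" & fam_hit == TRUE,
               .N, by = qname][N >= 2L, qname]
  keep <- !(cand$qname %in% both & cand$origin == "discordant_mate")
  keep <- keep & !cand$ambiguous & nzchar(cand$tag)
  out <- cand[keep, .(chrom, start, end, strand, evidence, side, tag,
                      clip_pos, origin, qname, target_strand)]
  out
}
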