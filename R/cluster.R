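# Cluster formation and joining: 5'/3' discordant clusters, 5'/3' clipped
# clusters, cluster-to-event joining with TSD / target-site-deletion calls,
# and breakpoint / prediction-window estimation.
#
# Cluster kinds: disc5 (forward-strand discordant anchors, upstream of the
# insertion), disc3 (reverse-strand), clip5 (right-clipped reads, whose
# clip position marks the 5' junction), clip3 (left-clipped reads, 3'
# junction).

new_cluster <- function(kind, chrom, start, end, tag, anchors,
                        clip_mode_pos = NA_integer_) {
  list(kind = kind, chrom = chrom, start = as.integer(start),
       end = as.integer(end), tag = tag, support = nrow(anchors),
       anchors = anchors, clip_mode_pos = as.integer(clip_mode_pos))
}

#' Cluster discordant anchors
#'
#' Single-linkage chaining over anchors sorted by start position: anchors
#' on the same chromosome and strand supporting the same family are chained
#' while consecutive start-to-start gaps are at most
#' \code{neighborhood_distance}. Forward-strand anchors form 5' discordant
#' clusters (\code{disc5}), reverse-strand anchors 3' clusters
#' (\code{disc3}). Anchors tagged \code{unmapped} carry no family and are
#' attached afterwards to the nearest family cluster on the same strand
#' within the neighborhood distance (or dropped).
#'
#' @param anchors \code{data.table} of discordant-evidence anchors
#' @param cfg a \code{caller_config}
#' @return list of clusters
#' @export
cluster_discordant <- function(anchors, cfg = caller_config()) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  stopifnot(all(anchors$evidence == "discordant"))
  a <- data.table::as.data.table(anchors)
  fam <- a[tag %in% ME_FAMILIES]
  unm <- a[tag == "unmapped"]
  clusters <- list()
  if (nrow(fam)) {
    data.table::setorder(fam, chrom, strand, tag, start, end, qname)
    grp_key <- paste(fam$chrom, fam$strand, fam$tag, sep = "\r")
    for (g in unique(grp_key)) {
      sub <- fam[grp_key == g]
      gap <- c(0L, diff(sub$start))
      cid <- cumsum(gap > cfg$neighborhood_distance)
      for (id in unique(cid)) {
        m <- sub[cid == id]
        clusters[[length(clusters) + 1L]] <- new_cluster(
          kind = if (m$strand[1] == "+") "disc5" else "disc3",
          chrom = m$chrom[1], start = min(m$start), end = max(m$end),
          tag = m$tag[1], anchors = m)
      }
    }
  }
  # attach unmapped-tag anchors to the nearest compatible cluster
  if (nrow(unm) && length(clusters)) {
    for (i in seq_len(nrow(unm))) {
      best <- 0L; bestd <- Inf
      for (j in seq_along(clusters)) {
        cl <- clusters[[j]]
        if (cl$chrom != unm$chrom[i] ||
            cl$anchors$strand[1] != unm$strand[i]) next
        d <- interval_gap(cl$start, cl$end, unm$start[i], unm$end[i])
        if (d <= cfg$neighborhood_distance && d < bestd) {
          bestd <- d; best <- j
        }
      }
      if (best > 0L) {
        cl <- clusters[[best]]
        cl$anchors <- rbind(cl$anchors, unm[i])
        cl$support <- cl$support + 1L
        cl$start <- min(cl$start, unm$start[i])
        cl$end <- max(cl$end, unm$end[i])
        clusters[[best]] <- cl
      }
    }
  }
  clusters
}

#' Can a 5' and a 3' discordant cluster be joined?
#'
#' TRUE iff the clusters are on the same chromosome, support the same
#' family, their spans overlap by at most \code{max_cluster_overlap}
#' (default 50 bp, the TSD allowance) or are separated by at most
#' \code{max_cluster_join_distance} (default 600 bp), and the 5' cluster
#' does not lie downstream of the 3' cluster.
#'
#' @param c5 a \code{disc5} cluster
#' @param c3 a \code{disc3} cluster
#' @param cfg a \code{caller_config}
#' @return logical
#' @export
join_discordant <- function(c5, c3, cfg = caller_config()) {
  stopifnot(c5$kind == "disc5", c3$kind == "disc3")
  if (c5$chrom != c3$chrom || c5$tag != c3$tag) return(FALSE)
  ov <- interval_overlap(c5$start, c5$end, c3$start, c3$end)
  gap <- interval_gap(c5$start, c5$end, c3$start, c3$end)
  if (ov > cfg$max_cluster_overlap) return(FALSE)
  if (gap > cfg$max_cluster_join_distance) return(FALSE)
  # 5' support must lie upstream of (or overlap) the 3' support
  if (c5$start > c3$start && ov == 0L) return(FALSE)
  TRUE
}

# modal value; ties broken toward the smallest
modal_pos <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Cluster clipped anchors
#'
#' Groups anchors clipped on the same side and supporting the same family
#' or homopolymer, whose clip positions lie within
#' \code{clip_position_tolerance} bp of the group's modal clip position.
#' Grouping is iterative: the most frequent remaining clip position (ties
#' toward the smallest) seeds a cluster that absorbs all anchors within the
#' tolerance; this is order-independent. Right-clipped anchors form
#' \code{clip5} clusters, left-clipped anchors \code{clip3} clusters.
#'
#' @param anchors \code{data.table} of clipped-evidence anchors
#' @param cfg a \code{caller_config}
#' @return list of clusters with \code{clip_mode_pos} set
#' @export
cluster_clipped <- function(anchors, cfg = caller_config()) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  stopifnot(all(anchors$evidence == "clipped"))
  a <- data.table::as.data.table(anchors)
  data.table::setorder(a, chrom, side, tag, clip_pos, start, qname)
  clusters <- list()
  grp_key <- paste(a$chrom, a$side, a$tag, sep = "\r")
  for (g in unique(grp_key)) {
    sub <- a[grp_key == g]
    remaining <- rep(TRUE, nrow(sub))
    while (any(remaining)) {
      mode_p <- modal_pos(sub$clip_pos[remaining])
      take <- remaining & abs(sub$clip_pos - mode_p) <= cfg$clip_position_tolerance
      m <- sub[take]
      clusters[[length(clusters) + 1L]] <- new_cluster(
        kind = if (m$side[1] == "3prime") "clip5" else "clip3",
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        tag = m$tag[1], anchors = m, clip_mode_pos = mode_p)
      remaining <- remaining & !take
    }
  }
  clusters
}

clip_tags_compatible <- function(t5, t3) {
  poly <- c("polyA", "polyT")
  if (t5 %in% ME_FAMILIES && t3 %in% ME_FAMILIES) return(t5 == t3)
  # one homopolymer + one family is the canonical TPRT signature; two
  # homopolymers name no family and are handled by the caller
  (t5 %in% poly && t3 %in% ME_FAMILIES) || (t3 %in% poly && t5 %in% ME_FAMILIES)
}

#' Join a 5' clipped cluster with a 3' clipped cluster
#'
#' The clusters are joined when their tags are compatible (same family, or
#' one polyA/polyT and the other a family) and the clip positions satisfy
#' \code{R - L} between \code{-max_target_deletion_gap} (target site
#' deletion allowance, default 20 bp) and \code{+max_cluster_overlap} (TSD
#' allowance, default 50 bp), where R is the 5' (right-clip) modal position
#' and L the 3' (left-clip) modal position. The signed difference is the
#' TSD call: positive = duplication, negative = target site deletion, zero
#' = blunt insertion.
#'
#' @param c5 a \code{clip5} cluster
#' @param c3 a \code{clip3} cluster
#' @param cfg a \code{caller_config}
#' @return \code{NULL}, or a list with \code{tsd_bp}, \code{family} (NA if
#'   both clusters are homopolymer-tagged), \code{c5}, \code{c3}
#' @export
join_clipped <- function(c5, c3, cfg = caller_config()) {
  stopifnot(c5$kind == "clip5", c3$kind == "clip3")
  if (c5$chrom != c3$chrom) return(NULL)
  if (!clip_tags_compatible(c5$tag, c3$tag)) return(NULL)
  R <- c5$clip_mode_pos; L <- c3$clip_mode_pos
  d <- R - L
  if (d < -cfg$max_target_deletion_gap || d > cfg$max_cluster_overlap) {
    return(NULL)
  }
  fam <- if (c5$tag %in% ME_FAMILIES) c5$tag
         else if (c3$tag %in% ME_FAMILIES) c3$tag else NA_character_
  list(tsd_bp = d, family = fam, c5 = c5, c3 = c3)
}

# ---- event assembly -------------------------------------------------------

new_event <- function(clusters, family, tsd_bp = NA_integer_) {
  list(clusters = clusters, family = family, tsd_bp = as.integer(tsd_bp))
}

event_kinds <- function(ev) vapply(ev$clusters, `[[`, character(1), "kind")

event_cluster <- function(ev, kind) {
  k <- event_kinds(ev)
  i <- which(k == kind)
  if (length(i)) ev$clusters[[i[1]]] else NULL
}

# inner interval of the discordant part of an event: [disc5 inner border,
# disc3 inner border); inner border of disc5 = max anchor end, of disc3 =
# min anchor start
disc_inner_interval <- function(ev) {
  c5 <- event_cluster(ev, "disc5"); c3 <- event_cluster(ev, "disc3")
  if (!is.null(c5) && !is.null(c3)) {
    lo <- c5$end; hi <- c3$start
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }  # TSD overlap inversion
    c(lo, hi)
  } else if (!is.null(c5)) {
    c(c5$end, c5$end)
  } else if (!is.null(c3)) {
    c(c3$start, c3$start)
  } else NULL
}

# greedy nearest-first pairing of 5' and 3' clusters using a joinability
# predicate; each cluster used at most once; ties broken leftmost
pair_clusters <- function(fives, threes, dist_fun, join_fun) {
  pairs <- list()
  if (length(fives) == 0L || length(threes) == 0L) {
    return(list(pairs = pairs, used5 = logical(length(fives)),
                used3 = logical(length(threes))))
  }
  cand <- data.table::CJ(i = seq_along(fives), j = seq_along(threes))
  cand[, d := mapply(function(i, j) dist_fun(fives[[i]], threes[[j]]),
                     i, j)]
  cand[, ok := mapply(function(i, j) !is.null(join_fun(fives[[i]], threes[[j]])),
                      i, j)]
  cand <- cand[ok == TRUE]
  lpos <- vapply(fives, `[[`, integer(1), "start")
  cand[, tiepos := lpos[i]]
  data.table::setorder(cand, d, tiepos, i, j)
  used5 <- logical(length(fives)); used3 <- logical(length(threes))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used5[i] || used3[j]) next
    used5[i] <- TRUE; used3[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- list(i = i, j = j)
  }
  list(pairs = pairs, used5 = used5, used3 = used3)
}

#' Assemble insertion events from clusters
#'
#' Joins discordant 5'/3' clusters into double-cluster events (greedy,
#' nearest first), joins clipped 5'/3' clusters into clipped events with a
#' TSD call, then attaches clipped events (or lone clipped clusters) to
#' discordant events of a compatible family when the clip positions fall
#' inside or within \code{neighborhood_distance} of the discordant event's
#' inner interval (greedy nearest-first, each cluster used once, leftmost
#' tie-break). Remaining single clusters become single-cluster events.
#' Joined clipped events whose two sides are both homopolymer-tagged name
#' no family and are dropped.
#'
#' @param disc_clusters list of discordant clusters
#' @param clip_clusters list of clipped clusters
#' @param cfg a \code{caller_config}
#' @return list of events
#' @export
assemble_events <- function(disc_clusters, clip_clusters,
                            cfg = caller_config()) {
  d5 <- Filter(function(c) c$kind == "disc5", disc_clusters)
  d3 <- Filter(function(c) c$kind == "disc3", disc_clusters)
  djoin <- pair_clusters(
    d5, d3,
    dist_fun = function(a, b) interval_gap(a$start, a$end, b$start, b$end),
    join_fun = function(a, b) if (join_discordant(a, b, cfg)) TRUE else NULL)
  events <- list()
  for (p in djoin$pairs) {
    events[[length(events) + 1L]] <- new_event(
      list(d5[[p$i]], d3[[p$j]]), family = d5[[p$i]]$tag)
  }
  for (i in which(!djoin$used5)) {
    events[[length(events) + 1L]] <- new_event(list(d5[[i]]), d5[[i]]$tag)
  }
  for (j in which(!djoin$used3)) {
    events[[length(events) + 1L]] <- new_event(list(d3[[j]]), d3[[j]]$tag)
  }

  c5 <- Filter(function(c) c$kind == "clip5", clip_clusters)
  c3 <- Filter(function(c) c$kind == "clip3", clip_clusters)
  cjoin <- pair_clusters(
    c5, c3,
    dist_fun = function(a, b) abs(a$clip_mode_pos - b$clip_mode_pos),
    join_fun = function(a, b) join_clipped(a, b, cfg))
  clip_events <- list()
  for (p in cjoin$pairs) {
    jj <- join_clipped(c5[[p$i]], c3[[p$j]], cfg)
    clip_events[[length(clip_events) + 1L]] <- new_event(
      list(c5[[p$i]], c3[[p$j]]), family = jj$family, tsd_bp = jj$tsd_bp)
  }
  for (i in which(!cjoin$used5)) {
    clip_events[[length(clip_events) + 1L]] <- new_event(list(c5[[i]]), c5[[i]]$tag)
  }
  for (j in which(!cjoin$used3)) {
    clip_events[[length(clip_events) + 1L]] <- new_event(list(c3[[j]]), c3[[j]]$tag)
  }
  merge_clip_into_disc(events, clip_events, cfg)
}

clip_event_positions <- function(ev) {
  ks <- event_kinds(ev)
  pos <- vapply(ev$clusters[ks %in% c("clip5", "clip3")],
                `[[`, integer(1), "clip_mode_pos")
  pos
}

families_compatible <- function(clip_fam, disc_fam) {
  if (is.na(clip_fam) || clip_fam %in% c("polyA", "polyT")) return(TRUE)
  identical(clip_fam, disc_fam)
}

#' Attach clipped events to discordant events
#'
#' A clipped event (joined pair or lone clipped cluster) is attached to a
#' discordant event of a compatible family when its clip positions fall
#' inside, or within \code{neighborhood_distance} of, the discordant
#' event's inner interval. Attachment is greedy by inner-border distance
#' (nearest first, leftmost tie-break) and each clipped event is used at
#' most once. Unattached clipped events survive as standalone events when
#' they name a family; homopolymer-only leftovers are dropped.
#'
#' @param events list of discordant events
#' @param clipped_events list of clipped events
#' @param cfg a \code{caller_config}
#' @return unified event list
#' @export
merge_clip_into_disc <- function(events, clipped_events,
                                 cfg = caller_config()) {
  if (length(clipped_events) && length(events)) {
    cand <- list()
    for (ci in seq_along(clipped_events)) {
      cev <- clipped_events[[ci]]
      cpos <- clip_event_positions(cev)
      cchrom <- cev$clusters[[1]]$chrom
      cfam <- cev$family
      for (ei in seq_along(events)) {
        dev <- events[[ei]]
        if (dev$clusters[[1]]$chrom != cchrom) next
        if (!families_compatible(cfam, dev$family)) next
        inner <- disc_inner_interval(dev)
        d <- max(interval_gap(inner[1], inner[2], min(cpos), max(cpos) + 1L), 0L)
        if (d > cfg$neighborhood_distance) next
        cand[[length(cand) + 1L]] <- list(ci = ci, ei = ei, d = d,
                                          tie = inner[1])
      }
    }
    if (length(cand)) {
      dt <- data.table::rbindlist(cand)
      data.table::setorder(dt, d, tie, ei, ci)
      used_c <- logical(length(clipped_events))
      for (r in seq_len(nrow(dt))) {
        ci <- dt$ci[r]; ei <- dt$ei[r]
        if (used_c[ci]) next
        used_c[ci] <- TRUE
        ev <- events[[ei]]
        cev <- clipped_events[[ci]]
        ev$clusters <- c(ev$clusters, cev$clusters)
        if (is.na(ev$family) || !ev$family %in% ME_FAMILIES) {
          ev$family <- cev$family
        }
        if (!is.na(cev$tsd_bp)) ev$tsd_bp <- cev$tsd_bp
        events[[ei]] <- ev
      }
      clipped_events <- clipped_events[!used_c]
    }
  }
  keep_clip <- Filter(function(e) !is.na(e$family) && e$family %in% ME_FAMILIES,
                      clipped_events)
  c(events, keep_clip)
}

#' Estimate the breakpoint and prediction window of an event
#'
#' \itemize{
#'   \item Both clipped clusters present: breakpoint is the interval
#'     between the two modal clip positions (a point when equal); the
#'     prediction window equals the breakpoint interval.
#'   \item One clipped cluster: breakpoint at its modal clip position,
#'     window padded by \code{clip_position_tolerance} on each side.
#'   \item Double discordant only: window spans the inner borders of the
#'     5' and 3' clusters (their overlap when inverted by a TSD);
#'     breakpoint at the window midpoint.
#'   \item Single discordant cluster: the mate must lie within the maximal
#'     template span, so for a 5' cluster the window runs from the cluster
#'     end to cluster start + median + multiplier*sd - read length
#'     (mirrored for a 3' cluster), clamped to be non-empty.
#' }
#'
#' @param ev an event
#' @param stats insert-size stats (may be NULL for clipped-only events)
#' @param read_len representative read length in bp
#' @param cfg a \code{caller_config}
#' @return list with \code{bp_start}, \code{bp_end} (half-open; width 1 =
#'   point), \code{window} (integer start/end)
#' @export
estimate_breakpoint <- function(ev, stats = NULL, read_len = 100L,
                                cfg = caller_config()) {
  if (length(ev$clusters) == 0L) stop("event with zero clusters")
  c5 <- event_cluster(ev, "clip5"); c3 <- event_cluster(ev, "clip3")
  if (!is.null(c5) && !is.null(c3)) {
    R <- c5$clip_mode_pos; L <- c3$clip_mode_pos
    lo <- min(R, L); hi <- max(R, L)
    if (lo == hi) hi <- lo + 1L  # point breakpoint, half-open width 1
    return(list(bp_start = lo, bp_end = hi, window = c(lo, hi)))
  }
  if (!is.null(c5) || !is.null(c3)) {
    p <- if (!is.null(c5)) c5$clip_mode_pos else c3$clip_mode_pos
    return(list(bp_start = p, bp_end = p + 1L,
                window = c(p - cfg$clip_position_tolerance,
                           p + cfg$clip_position_tolerance + 1L)))
  }
  d5 <- event_cluster(ev, "disc5"); d3 <- event_cluster(ev, "disc3")
  if (!is.null(d5) && !is.null(d3)) {
    inner <- disc_inner_interval(ev)
    if (inner[2] <= inner[1]) inner[2] <- inner[1] + 1L
    mid <- as.integer(floor((inner[1] + inner[2]) / 2))
    return(list(bp_start = mid, bp_end = mid + 1L, window = inner))
  }
  if (is.null(stats)) stop("single discordant cluster needs insert-size stats")
  span <- as.integer(round(stats$median + cfg$insert_size_sd_multiplier * stats$sd))
  if (!is.null(d5)) {
    lo <- d5$end
    hi <- d5$start + span - read_len
    if (hi <= lo) hi <- lo + 1L
    mid <- as.integer(floor((lo + hi) / 2))
    return(list(bp_start = mid, bp_end = mid + 1L, window = c(lo, hi)))
  }
  hi <- d3$start
  lo <- d3$end - span + read_len
  if (lo >= hi) lo <- hi - 1L
  mid <- as.integer(floor((lo + hi) / 2))
  list(bp_start = mid, bp_end = mid + 1L, window = c(lo, hi))
}
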