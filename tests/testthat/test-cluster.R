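cfg <- caller_config("wgs-pe")

test_that("discordant clustering chains starts within the neighborhood", {
  cl <- cluster_discordant(anchor_dt(c(100L, 250L, 420L)), cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$kind, "disc5")
  expect_equal(cl[[1]]$support, 3L)
  expect_equal(cl[[1]]$start, 100L)
  expect_equal(cl[[1]]$end, 520L)

  cl <- cluster_discordant(anchor_dt(c(100L, 350L)), cfg)
  expect_length(cl, 2L)

  cl <- cluster_discordant(anchor_dt(700L, strand = "-"), cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$kind, "disc3")
  expect_equal(cl[[1]]$support, 1L)

  # strand and family partition the clustering
  mixed <- rbind(anchor_dt(c(100L, 150L), tag = "Alu"),
                 anchor_dt(c(120L, 170L), tag = "L1", qname = c("x1", "x2")),
                 anchor_dt(130L, strand = "-", qname = "y1"))
  expect_length(cluster_discordant(mixed, cfg), 3L)
})

test_that("unmapped-tag anchors attach to the nearest family cluster", {
  a <- rbind(anchor_dt(c(1000L, 1100L), tag = "Alu"),
             anchor_dt(1150L, tag = "unmapped", origin = "unmapped_mate",
                       qname = "u1"),
             anchor_dt(9000L, tag = "unmapped", origin = "unmapped_mate",
                       qname = "u2"))
  cl <- cluster_discordant(a, cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$support, 3L)   # u1 attached, u2 (far away) dropped
  expect_equal(cl[[1]]$tag, "Alu")
})

test_that("discordant cluster joining respects overlap and gap limits", {
  mk <- function(kind, s, e) make_cluster(kind, s, e)
  expect_true(join_discordant(mk("disc5", 1000L, 1400L),
                              mk("disc3", 1390L, 1800L), cfg))  # overlap 10
  expect_false(join_discordant(mk("disc5", 1000L, 1400L),
                               mk("disc3", 2100L, 2500L), cfg)) # gap 700
  expect_false(join_discordant(mk("disc5", 1000L, 1500L),
                               mk("disc3", 1430L, 1800L), cfg)) # overlap 70
  # boundaries: overlap exactly 50 ok, 51 not; gap exactly 600 ok, 601 not
  expect_true(join_discordant(mk("disc5", 1000L, 1450L),
                              mk("disc3", 1400L, 1800L), cfg))
  expect_false(join_discordant(mk("disc5", 1000L, 1451L),
                               mk("disc3", 1400L, 1800L), cfg))
  expect_true(join_discordant(mk("disc5", 1000L, 1400L),
                              mk("disc3", 2000L, 2400L), cfg))
  expect_false(join_discordant(mk("disc5", 1000L, 1400L),
                               mk("disc3", 2001L, 2400L), cfg))
  # family mismatch and inverted order never join
  expect_false(join_discordant(mk("disc5", 1000L, 1400L),
                               make_cluster("disc3", 1390L, 1800L, tag = "L1"),
                               cfg))
  expect_false(join_discordant(mk("disc5", 2000L, 2400L),
                               mk("disc3", 1000L, 1400L), cfg))
})

test_that("clipped clustering groups around the modal clip position", {
  a <- clip_anchor_dt(c(5000L, 5001L, 5000L), side = "3prime", tag = "Alu")
  cl <- cluster_clipped(a, cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$kind, "clip5")
  expect_equal(cl[[1]]$clip_mode_pos, 5000L)
  expect_equal(cl[[1]]$support, 3L)

  cl <- cluster_clipped(clip_anchor_dt(c(5000L, 5010L), "3prime", "Alu"), cfg)
  expect_length(cl, 2L)

  cl <- cluster_clipped(clip_anchor_dt(7000L, "5prime", "polyT"), cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$kind, "clip3")
  expect_equal(cl[[1]]$tag, "polyT")

  # modal tie broken toward the smallest position
  a <- clip_anchor_dt(c(6000L, 6000L, 6002L, 6002L), "3prime", "Alu")
  cl <- cluster_clipped(a, cfg)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$clip_mode_pos, 6000L)
})

test_that("clipped cluster joining calls TSDs and target site deletions", {
  mk <- function(kind, pos, tag) {
    make_cluster(kind, pos - 60L, pos + 60L, tag = tag, clip_mode_pos = pos)
  }
  j <- join_clipped(mk("clip5", 5013L, "Alu"), mk("clip3", 5000L, "polyA"), cfg)
  expect_equal(j$tsd_bp, 13L)
  expect_equal(j$family, "Alu")
  j <- join_clipped(mk("clip5", 5000L, "L1"), mk("clip3", 5007L, "L1"), cfg)
  expect_equal(j$tsd_bp, -7L)
  expect_null(join_clipped(mk("clip5", 5060L, "Alu"), mk("clip3", 5000L, "Alu"),
                           cfg))
  # exact boundaries: +50 / -20 join, +51 / -21 do not
  expect_equal(join_clipped(mk("clip5", 5050L, "Alu"),
                            mk("clip3", 5000L, "Alu"), cfg)$tsd_bp, 50L)
  expect_null(join_clipped(mk("clip5", 5051L, "Alu"),
                           mk("clip3", 5000L, "Alu"), cfg))
  expect_equal(join_clipped(mk("clip5", 5000L, "Alu"),
                            mk("clip3", 5020L, "Alu"), cfg)$tsd_bp, -20L)
  expect_null(join_clipped(mk("clip5", 5000L, "Alu"),
                           mk("clip3", 5021L, "Alu"), cfg))
  # incompatible tags
  expect_null(join_clipped(mk("clip5", 5000L, "Alu"),
                           mk("clip3", 5000L, "L1"), cfg))
  expect_equal(join_clipped(mk("clip5", 5000L, "polyT"),
                            mk("clip3", 5005L, "SVA"), cfg)$family, "SVA")
})

test_that("clipped events attach to the nearest discordant event", {
  d5 <- make_cluster("disc5", 4500L, 4900L)
  d3 <- make_cluster("disc3", 5100L, 5500L)
  ev_disc <- assemble_events(list(d5, d3), list(), cfg)
  expect_length(ev_disc, 1L)

  c5 <- make_cluster("clip5", 4950L, 5070L, clip_mode_pos = 5013L)
  c3 <- make_cluster("clip3", 4940L, 5060L, tag = "polyA",
                     clip_mode_pos = 5000L)
  ev <- assemble_events(list(d5, d3), list(c5, c3), cfg)
  expect_length(ev, 1L)
  bp <- estimate_breakpoint(ev[[1]], list(median = 400, sd = 30), 100L, cfg)
  expect_equal(bp$bp_start, 5000L)     # clipped borders adopted
  expect_equal(bp$bp_end, 5013L)
  expect_equal(ev[[1]]$tsd_bp, 13L)

  # a clipped event 10 kb away stays separate
  far5 <- make_cluster("clip5", 15000L, 15100L, clip_mode_pos = 15060L)
  far3 <- make_cluster("clip3", 15000L, 15100L, clip_mode_pos = 15055L)
  ev <- assemble_events(list(d5, d3), list(far5, far3), cfg)
  expect_length(ev, 2L)

  # tie between two equidistant discordant events: leftmost wins
  cfg_wide <- caller_config("wgs-pe", neighborhood_distance = 500L)
  dA5 <- make_cluster("disc5", 1000L, 1400L)
  dA3 <- make_cluster("disc3", 1500L, 1900L)   # inner interval [1400,1500)
  dB5 <- make_cluster("disc5", 1999L, 2399L)
  dB3 <- make_cluster("disc3", 2499L, 2899L)   # inner interval [2399,2499)
  mid5 <- make_cluster("clip5", 1900L, 2000L, clip_mode_pos = 1949L)
  mid3 <- make_cluster("clip3", 1900L, 2000L, tag = "polyA",
                       clip_mode_pos = 1949L)  # distance 449 to both events
  ev <- assemble_events(list(dA5, dA3, dB5, dB3), list(mid5, mid3), cfg_wide)
  with_clip <- which(vapply(ev, function(e)
    any(event_kinds(e) %in% c("clip5", "clip3")), logical(1)))
  expect_length(with_clip, 1L)
  expect_equal(ev[[with_clip]]$clusters[[1]]$start, 1000L)
})

test_that("breakpoint estimation covers all four evidence configurations", {
  st <- list(median = 400, sd = 30)
  # (a) both clipped clusters
  ev <- new_event_for_test(list(
    make_cluster("clip5", 4950L, 5070L, clip_mode_pos = 5013L),
    make_cluster("clip3", 4940L, 5060L, clip_mode_pos = 5000L)))
  bp <- estimate_breakpoint(ev, st, 100L, cfg)
  expect_equal(c(bp$bp_start, bp$bp_end), c(5000L, 5013L))
  expect_equal(bp$window, c(5000L, 5013L))
  # (b) one clipped cluster
  ev <- new_event_for_test(list(make_cluster("clip5", 4950L, 5070L,
                                             clip_mode_pos = 5013L)))
  bp <- estimate_breakpoint(ev, st, 100L, cfg)
  expect_equal(c(bp$bp_start, bp$bp_end), c(5013L, 5014L))
  expect_equal(bp$window, c(5010L, 5017L))
  # (c) double discordant: inner borders 4990 and 5020, midpoint 5005
  ev <- new_event_for_test(list(make_cluster("disc5", 4600L, 4990L),
                                make_cluster("disc3", 5020L, 5400L)))
  bp <- estimate_breakpoint(ev, st, 100L, cfg)
  expect_equal(bp$window, c(4990L, 5020L))
  expect_equal(bp$bp_start, 5005L)
  # (d) single 5' discordant cluster: [4400, 4000 + 520 - 100) = [4400, 4420)
  ev <- new_event_for_test(list(make_cluster("disc5", 4000L, 4400L)))
  bp <- estimate_breakpoint(ev, st, 100L, cfg)
  expect_equal(bp$window, c(4400L, 4420L))
  # mirrored single 3' cluster
  ev <- new_event_for_test(list(make_cluster("disc3", 4000L, 4400L)))
  bp <- estimate_breakpoint(ev, st, 100L, cfg)
  expect_equal(bp$window, c(4400L - 520L + 100L, 4000L))
  expect_error(estimate_breakpoint(list(clusters = list(), family = "Alu",
                                        tsd_bp = NA_integer_), st, 100L, cfg),
               "zero clusters")
})

test_that("clustering is order-independent and matches brute-force single linkage", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    starts <- sort(sample.int(3000L, n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tag <- sample(c("Alu", "L1"), n, replace = TRUE)
    a <- anchor_dt(starts, strand = strand, tag = tag)
    cl <- cluster_discordant(a, cfg)
    # shuffled input gives identical clusters
    perm <- sample.int(n)
    cl2 <- cluster_discordant(a[perm], cfg)
    expect_identical(cluster_signature(cl), cluster_signature(cl2))
    # brute-force union-find oracle over the same predicate
    oracle <- oracle_single_linkage(starts, strand, tag,
                                    cfg$neighborhood_distance)
    expect_identical(cluster_signature(cl),
                     partition_signature(oracle, starts))
  }
})

test_that("no event double-counts an anchor", {
  d5 <- make_cluster("disc5", 4500L, 4900L)
  d3 <- make_cluster("disc3", 5100L, 5500L)
  c5 <- make_cluster("clip5", 4950L, 5070L, clip_mode_pos = 5013L)
  c3 <- make_cluster("clip3", 4940L, 5060L, tag = "polyA",
                     clip_mode_pos = 5000L)
  ev <- assemble_events(list(d5, d3), list(c5, c3), cfg)
  preds <- events_to_predictions(ev, list(median = 400, sd = 30), 100L, cfg)
  expect_equal(preds$support,
               preds$support_disc_unique + preds$support_disc_multimapped +
                 preds$support_clipped + preds$support_unmapped)
})
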