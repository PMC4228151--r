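mob <- synthetic_mobilome()

test_that("reference construction is deterministic and records annotation", {
  sc <- sim_config(genome_length = 2e5, n_insertions = 5L, coverage = 5,
                   seed = 9L, n_decoys = 6L)
  r1 <- make_reference(sc, mob)
  r2 <- make_reference(sc, mob)
  expect_identical(r1$reference, r2$reference)
  expect_identical(r1$ref_mei, r2$ref_mei)
  expect_equal(nrow(r1$ref_mei), 6L)
  expect_true(all(r1$ref_mei$family %in% c("Alu", "L1", "SVA", "HERVK")))
  expect_equal(nchar(r1$reference), 200000L)
  expect_equal(nrow(r1$satellite), 1L)
  # embedded decoy really is a (diverged) copy of its consensus
  d <- r1$decoys[1]
  cons <- mob[[d$cons_idx]]
  embedded <- substr(r1$reference, d$start + 1L, d$end)
  mm <- sum(utf8ToInt(embedded) != utf8ToInt(cons))
  expect_lt(mm / nchar(cons), 0.05)
  expect_gt(mm, 0L)

  # zero decoys give an empty annotation
  r0 <- make_reference(sim_config(genome_length = 1e5, n_insertions = 2L,
                                  coverage = 5, seed = 9L, n_decoys = 0L), mob)
  expect_equal(nrow(r0$ref_mei), 0L)
})

test_that("planted insertions have the TPRT structure stated in truth", {
  sc <- sim_config(genome_length = 3e5, n_insertions = 8L, coverage = 5,
                   seed = 13L)
  ref <- make_reference(sc, mob)
  pl <- plant_insertions(ref, mob, sc)
  tr <- pl$truth
  expect_equal(nrow(tr), 8L)
  # donor length accounting: genome + inserts + signed TSDs
  expect_equal(nchar(pl$donor),
               sc$genome_length + sum(tr$ins_len) + sum(tr$tsd_bp))
  # insertion sites at least 2 kb apart
  expect_true(all(diff(sort(tr$breakpoint)) >= 2000L))

  blocks <- pl$blocks
  ins_blocks <- blocks[blocks$type == "ins"]
  for (i in seq_len(nrow(tr))) {
    b <- ins_blocks[ins_blocks$ins_id == i]
    ins_seq <- substr(pl$donor, b$dstart + 1L, b$dend)
    expect_equal(nchar(ins_seq), tr$ins_len[i])
    # polyA tail at the junction-side end, per strand
    if (tr$strand[i] == "+") {
      expect_equal(substr(ins_seq, nchar(ins_seq) - tr$polyA_len[i] + 1L,
                          nchar(ins_seq)),
                   strrep("A", tr$polyA_len[i]))
    } else {
      expect_equal(substr(ins_seq, 1L, tr$polyA_len[i]),
                   strrep("T", tr$polyA_len[i]))
    }
    # duplicated target site flanks the insert for TSD > 0
    t <- tr$tsd_bp[i]
    if (t > 0L) {
      left_dup <- substr(pl$donor, b$dstart - t + 1L, b$dstart)
      right_dup <- substr(pl$donor, b$dend + 1L, b$dend + t)
      expect_equal(left_dup, right_dup)
    }
    # reference bases around the junctions match the reference coordinates:
    # the 5' junction sits at p_R, the 3' junction resumes at p_L
    p_R <- if (t >= 0L) tr$bp_right[i] else tr$bp_left[i]
    p_L <- if (t >= 0L) tr$bp_left[i] else tr$bp_right[i]
    expect_equal(substr(pl$donor, b$dstart - 19L, b$dstart),
                 substr(ref$reference, p_R - 19L, p_R))
    expect_equal(substr(pl$donor, b$dend + 1L, b$dend + 20L),
                 substr(ref$reference, p_L + 1L, p_L + 20L))
  }
})

test_that("an insertion-free simulation emits only proper concordant pairs", {
  sc <- sim_config(genome_length = 1e5, n_insertions = 0L, coverage = 8,
                   seed = 3L, n_decoys = 0L)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(sc, d, mob)
  bam <- Rsamtools::scanBam(sim$bam,
                            param = Rsamtools::ScanBamParam(
                              what = c("flag", "cigar")))[[1]]
  expect_gt(length(bam$flag), 5000L)
  expect_false(any(bitwAnd(bam$flag, 4L) > 0L))        # nothing unmapped
  expect_false(any(grepl("S", bam$cigar)))             # no soft clips
  expect_gt(mean(bitwAnd(bam$flag, 2L) > 0L), 0.99)    # nearly all proper
})

test_that("junction reads are soft-clipped at the planted breakpoints", {
  sc <- sim_config(genome_length = 2e5, n_insertions = 4L, coverage = 30,
                   seed = 19L, base_error_rate = 0)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(sc, d, mob)
  bam <- Rsamtools::scanBam(sim$bam,
                            param = Rsamtools::ScanBamParam(
                              what = c("flag", "pos", "cigar")))[[1]]
  clips <- meicall:::cigar_soft_clips(bam$cigar)
  tr <- sim$truth_table
  for (i in seq_len(nrow(tr))) {
    t <- tr$tsd_bp[i]
    p_R <- if (t >= 0L) tr$bp_right[i] else tr$bp_left[i]  # 5' junction
    p_L <- if (t >= 0L) tr$bp_left[i] else tr$bp_right[i]  # 3' junction
    rc <- which(clips$right > 0L)
    ends <- bam$pos[rc] - 1L + meicall:::cigar_ref_width(bam$cigar[rc])
    expect_gte(sum(ends == p_R), 1L)
    lc <- which(clips$left > 0L)
    expect_gte(sum(bam$pos[lc] - 1L == p_L), 1L)
  }
  # expected clipped yield: coverage * usable positions / read length per
  # junction; realised count within a factor of three of expectation
  min_clip <- 35L; rl <- sc$read_length; anchor <- 20L
  exp_per_junction <- sc$coverage * (rl - min_clip - anchor + 1L) / rl
  n_clip <- sum(clips$left > 0L | clips$right > 0L)
  expect_gt(n_clip, nrow(tr) * 2L * exp_per_junction / 3)
  expect_lt(n_clip, nrow(tr) * 2L * exp_per_junction * 3)
})

test_that("identical seeds reproduce byte-identical FASTQ and BAM content", {
  sc <- sim_config(genome_length = 1e5, n_insertions = 3L, coverage = 6,
                   seed = 23L, n_decoys = 4L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(sc, d1, mob, fastq = TRUE)
  simulate_dataset(sc, d2, mob, fastq = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, "reads_1.fq"))),
                   unname(tools::md5sum(file.path(d2, "reads_1.fq"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "reads_2.fq"))),
                   unname(tools::md5sum(file.path(d2, "reads_2.fq"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.tsv"))),
                   unname(tools::md5sum(file.path(d2, "truth.tsv"))))
})

test_that("single-end / capture-target simulation samples on target", {
  targets <- data.table::data.table(chrom = "sim1",
                                    start = c(20000L, 60000L),
                                    end = c(25000L, 65000L))
  sc <- sim_config(genome_length = 1e5, n_insertions = 0L, coverage = 10,
                   seed = 29L, mode = "single", n_decoys = 0L,
                   capture_targets = targets)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(sc, d, mob)
  bam <- Rsamtools::scanBam(sim$bam,
                            param = Rsamtools::ScanBamParam(what = "pos"))[[1]]
  expect_true(all((bam$pos >= 20000L & bam$pos <= 25001L) |
                    (bam$pos >= 60000L & bam$pos <= 65001L)))
  expect_gt(length(bam$pos), 500L)
})

test_that("evaluation arithmetic, nearest-match crediting and empty calls", {
  truth <- data.table::data.table(chrom = "c", breakpoint = c(1000L, 5000L,
                                                              5030L),
                                  family = c("Alu", "Alu", "Alu"))
  calls <- rbind(pred_row(chrom = "c", ws = 990L, we = 1010L, bs = 995L,
                          be = 996L),
                 pred_row(chrom = "c", ws = 5020L, we = 5040L, bs = 5025L,
                          be = 5026L))
  ev <- evaluate_calls(calls, truth)
  # call 2 overlaps both truths at 5000 (gap 0? no: gap 0 only for 5030)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$ppv, 1)
  # the shared call is credited to the nearest truth only
  expect_equal(sort(ev$matches), c(1L, 3L))

  # family mismatch is not a detection
  truth_l1 <- data.table::data.table(chrom = "c", breakpoint = 1000L,
                                     family = "L1")
  expect_equal(evaluate_calls(calls[1], truth_l1)$sensitivity, 0)

  ev0 <- evaluate_calls(calls[0], truth)
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$ppv))

  # perfect sensitivity arithmetic
  t100 <- data.table::data.table(chrom = "c",
                                 breakpoint = seq(1000L, by = 3000L,
                                                  length.out = 10L),
                                 family = "Alu")
  c99 <- data.table::rbindlist(lapply(t100$breakpoint[1:9], function(b)
    pred_row(chrom = "c", ws = b - 5L, we = b + 5L, bs = b, be = b + 1L)))
  ev <- evaluate_calls(c99, t100)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$ppv, 1)
})
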