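cfg <- caller_config("wgs-pe")

test_that("support filter boundaries: 5 passes, 4 is flagged", {
  p <- rbind(pred_row(support = 5L), pred_row(ws = 9000L, we = 9050L,
                                              bs = 9010L, be = 9011L,
                                              support = 4L))
  p <- filter_support(p, cfg)
  expect_equal(p$filters, c("", "low_support"))
})

test_that("reference-ME filter: 90 bp flags, 91 bp passes, family must match", {
  ann <- data.table::data.table(chrom = "chr1",
                                start = c(5140L, 5141L, 5140L),
                                end = c(5440L, 5441L, 5440L),
                                family = c("Alu", "Alu", "L1"))
  # prediction window [5000, 5050): distances 90, 91, 90
  p1 <- filter_reference_mei(pred_row(), ann[1], cfg)
  expect_equal(p1$filters, "reference_mei")
  p2 <- filter_reference_mei(pred_row(), ann[2], cfg)
  expect_equal(p2$filters, "")
  p3 <- filter_reference_mei(pred_row(), ann[3], cfg)   # L1 annotation
  expect_equal(p3$filters, "")
  # overlapping same-family annotation: distance 0, flagged
  p4 <- filter_reference_mei(pred_row(),
                             data.table::data.table(chrom = "chr1",
                                                    start = 5020L, end = 5320L,
                                                    family = "Alu"), cfg)
  expect_equal(p4$filters, "reference_mei")
})

test_that("satellite filter flags overlap but not adjacency", {
  sat <- data.table::data.table(chrom = "chr1", start = 4000L, end = 5010L)
  expect_equal(filter_satellite(pred_row(), sat)$filters, "satellite")
  sat_adj <- data.table::data.table(chrom = "chr1", start = 4000L, end = 5000L)
  expect_equal(filter_satellite(pred_row(), sat_adj)$filters, "")
  expect_equal(filter_satellite(pred_row(), NULL)$filters, "")
})

test_that("double-cluster requirement is preset-dependent", {
  both <- pred_row()
  one_sided <- pred_row(has3 = FALSE)
  expect_equal(filter_double_cluster(rbind(both, one_sided), cfg)$filters,
               c("", "single_cluster"))
  wes <- caller_config("wes-pe")
  expect_equal(filter_double_cluster(rbind(both, one_sided), wes)$filters,
               c("", ""))
})

test_that("filters are flag-setting and order-independent", {
  ann <- data.table::data.table(chrom = "chr1", start = 5100L, end = 5400L,
                                family = "Alu")
  sat <- data.table::data.table(chrom = "chr1", start = 4990L, end = 5025L)
  p0 <- rbind(pred_row(support = 4L), pred_row(ws = 9000L, we = 9050L,
                                               bs = 9010L, be = 9011L))
  run <- function(order) {
    p <- data.table::copy(p0)
    for (f in order) {
      p <- switch(f,
                  s = filter_support(p, cfg),
                  r = filter_reference_mei(p, ann, cfg),
                  t = filter_satellite(p, sat),
                  d = filter_double_cluster(p, cfg))
    }
    lapply(strsplit(p$filters, ","), sort)
  }
  expect_identical(run(c("s", "r", "t", "d")), run(c("d", "t", "r", "s")))
  expect_identical(run(c("r", "s", "d", "t")), run(c("s", "r", "t", "d")))
})

test_that("prediction merging is family-scoped, transitive and idempotent", {
  mk <- function(ws, fam = "Alu", support = 10L) {
    pred_row(ws = ws, we = ws + 30L, bs = ws + 10L, be = ws + 11L,
             family = fam, support = support)
  }
  # two Alu predictions 40 bp apart merge
  m <- merge_predictions(rbind(mk(5000L), mk(5070L)), cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$window_start, 5000L)
  expect_equal(m$window_end, 5100L)
  expect_equal(m$support, 20L)
  # different families 10 bp apart do not merge
  m <- merge_predictions(rbind(mk(5000L), mk(5040L, fam = "L1")), cfg)
  expect_equal(nrow(m), 2L)
  # chain A-B 40 bp, B-C 40 bp: all merged by transitivity
  m <- merge_predictions(rbind(mk(5000L), mk(5070L), mk(5140L)), cfg)
  expect_equal(nrow(m), 1L)
  # idempotent
  m2 <- merge_predictions(m, cfg)
  expect_identical(m, m2)
  # breakpoint taken from the clipped-supported member
  a <- mk(5000L); a$support_clipped <- 0L
  b <- mk(5040L); b$support_clipped <- 4L
  b$breakpoint_start <- 5055L; b$breakpoint_end <- 5056L
  m <- merge_predictions(rbind(a, b), cfg)
  expect_equal(m$breakpoint_start, 5055L)
})

test_that("orientation follows the polyA side", {
  expect_equal(determine_orientation(pred_row(polyA_side = "3prime")), "+")
  expect_equal(determine_orientation(pred_row(polyA_side = "5prime")), "-")
  expect_equal(determine_orientation(pred_row(polyA_side = "none")), "unknown")
})

test_that("breakpoint context extracts 13 bp around the clip position", {
  ref <- c(chr1 = paste0(strrep("C", 50L),
                         paste(rep(c("A", "G", "T", "C"), 25L), collapse = ""),
                         strrep("G", 50L)))
  p <- pred_row(bs = 60L, be = 61L, support_clipped = 3L,
                polyA_side = "3prime")
  p$orientation <- "+"
  ctx <- breakpoint_context(p, ref)
  expect_equal(nchar(ctx), 13L)
  expect_equal(ctx, substr(ref[["chr1"]], 60L - 6L + 1L, 60L + 6L + 1L))
  # minus strand uses the 5' clip position (breakpoint_end boundary)
  m <- pred_row(bs = 60L, be = 73L, support_clipped = 3L,
                polyA_side = "5prime")
  m$orientation <- "-"
  expect_equal(breakpoint_context(m, ref),
               substr(ref[["chr1"]], 72L - 6L + 1L, 72L + 6L + 1L))
  # near-edge positions are N-padded and keep width 13
  e <- pred_row(bs = 2L, be = 3L, support_clipped = 3L, polyA_side = "3prime")
  e$orientation <- "+"
  ctx <- breakpoint_context(e, ref)
  expect_equal(nchar(ctx), 13L)
  expect_equal(substr(ctx, 1L, 4L), "NNNN")
  # unknown orientation or no clipped support yields NA
  expect_true(is.na(breakpoint_context(pred_row(support_clipped = 3L), ref)))
  u <- pred_row(support_clipped = 0L); u$orientation <- "+"
  expect_true(is.na(breakpoint_context(u, ref)))
})

test_that("gene component annotation uses the priority order", {
  # one coding gene (+): tx 1000-9000, CDS 2000-8000, three exons
  refflat <- paste(
    c("GENE1", "NM_1", "chr1", "+", 1000L, 9000L, 2000L, 8000L, 3L,
      "1000,3000,7000,", "2500,3500,8000,"),
    collapse = "\t")
  ncrna <- paste(
    c("NCG", "NR_1", "chr1", "+", 20000L, 21000L, 20000L, 20000L, 1L,
      "20000,", "21000,"),
    collapse = "\t")
  f <- withr::local_tempfile(fileext = ".refflat")
  writeLines(c(refflat, ncrna), f)
  gm <- load_gene_model(f)
  lab <- function(ws, we) {
    annotate_gene_component(pred_row(ws = ws, we = we, bs = ws, be = ws + 1L),
                            gm)
  }
  expect_equal(lab(3100L, 3600L), "exonic")    # exon beats intron overlap
  expect_equal(lab(5000L, 5040L), "intronic")  # wholly intronic
  expect_equal(lab(1200L, 1400L), "UTR5")      # pre-CDS exon part
  expect_equal(lab(20100L, 20200L), "ncRNA_exonic")
  expect_equal(lab(500L, 540L), "upstream_1kb")
  expect_equal(lab(9200L, 9240L), "downstream_1kb")
  expect_equal(lab(50000L, 50040L), "intergenic")
})

test_that("prediction TSV round-trips and header-only output works", {
  d <- withr::local_tempdir()
  p <- rbind(pred_row(), pred_row(ws = 9000L, we = 9050L, bs = 9010L,
                                  be = 9011L, family = "L1",
                                  tsd_bp = 13L))
  p$gene_component <- c("intronic", NA_character_)
  path <- file.path(d, "preds.tsv")
  write_predictions(p, path)
  back <- read_predictions(path)
  core <- setdiff(meicall:::prediction_columns, character(0))
  expect_equal(as.data.frame(back[, core, with = FALSE]),
               as.data.frame(p[, core, with = FALSE]))

  write_predictions(meicall:::empty_predictions(), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^chrom\twindow_start")

  # VCF output is syntactically parseable by Rsamtools-free means
  write_predictions(p, path, format = "vcf")
  vcf <- readLines(file.path(d, "preds.vcf"))
  expect_true(any(grepl("^##fileformat=VCFv4.2", vcf)))
  body <- vcf[!startsWith(vcf, "#")]
  expect_length(body, 2L)
  expect_match(body[2], "<INS:ME:L1>")
  expect_match(body[2], "TSD=13")
})
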