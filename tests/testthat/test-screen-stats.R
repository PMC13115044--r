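# Hand-written eight-barcode fixture: equal recognized totals of 1000 in
# every sample, so relative-abundance ratios reduce to count ratios and the
# expected values below can be verified by hand (offset 0.001 throughout).
fixture_matrix <- function() {
  counts <- list(
    CK1 = c(B1 = 100L, B2 = 50L, B3 = 49L, B4 = 100L, B5 = 100L,
            B6 = 200L, B7 = 100L, B8 = 100L),
    CK2 = c(B1 = 100L, B2 = 50L, B3 = 49L, B4 = 100L, B5 = 100L,
            B6 = 20L, B7 = 100L, B8 = 100L),
    S10 = c(B1 = 100L, B2 = 50L, B3 = 49L, B4 = 0L, B5 = 400L,
            B6 = 200L, B7 = 25L, B8 = 30L),
    S10R = c(B1 = 100L, B2 = 50L, B3 = 49L, B4 = 10L, B5 = 300L,
             B6 = 150L, B7 = 40L, B8 = 50L))
  pad <- function(v) c(v, FILL = 1000L - sum(v))  # pad totals to 1000
  build_count_matrix(lapply(counts, pad))
}

test_that("CK1 filter keeps exactly the >= 50 barcodes", {
  cm <- fixture_matrix()
  kept <- filter_min_ck1(cm, screen_config())
  expect_setequal(kept, c("B1", "B2", "B4", "B5", "B6", "B7", "B8", "FILL"))
  expect_false("B3" %in% kept)           # 49 is below the boundary
  expect_true("B2" %in% kept)            # 50 is on the boundary: kept
  expect_equal(unname(attr(kept, "report")), c(8L, 1L))
  # min 1 retains everything with at least one CK1 read
  expect_length(filter_min_ck1(cm, screen_config(min_ck1_count = 1)), 9L)
  expect_error(filter_min_ck1(build_count_matrix(list(S10 = c(A = 1L)))),
               "CK1")
})

test_that("ratios, hits and groups match independent hand arithmetic", {
  cm <- fixture_matrix()
  cfg <- screen_config()
  rec <- assign_group(call_hits(compute_ratios(
    cm, setdiff(filter_min_ck1(cm, cfg), "FILL"), cfg), cfg), cfg)
  rec <- rec[order(rec$barcode), ]
  get <- function(b, col) rec[rec$barcode == b, col]

  # hand-computed rr values (equal totals of 1000 per sample)
  expect_equal(get("B1", "rr"), 1, tolerance = 1e-12)
  expect_equal(get("B2", "rr"), 1, tolerance = 1e-12)
  expect_equal(get("B4", "rr"), 0.001 / 1.001, tolerance = 1e-12)
  expect_equal(get("B5", "rr"), 4.001 / 1.001, tolerance = 1e-12)
  expect_equal(get("B6", "rr"), 1.001 / 0.101, tolerance = 1e-12)
  expect_equal(get("B7", "rr"), 0.251 / 1.001, tolerance = 1e-12)
  expect_equal(get("B8", "rr"), 0.301 / 1.001, tolerance = 1e-12)

  expect_identical(get("B1", "direction"), "none")
  expect_identical(get("B4", "direction"), "depleted")   # S10 = 0 barcode
  expect_identical(get("B5", "direction"), "enriched")
  expect_identical(get("B6", "direction"), "enriched")
  expect_identical(get("B7", "direction"), "depleted")
  expect_identical(get("B8", "direction"), "none")       # 0.3007 > 0.3

  expect_identical(get("B4", "group"), "group2")
  expect_identical(get("B5", "group"), "none")   # enriched but normal r_ctrl
  expect_identical(get("B6", "group"), "group1") # log2(0.101) < -1, enriched
  expect_identical(get("B7", "group"), "group2")
  expect_identical(get("B1", "group"), "none")
})

test_that("boundary rr values are not hits (strict inequalities)", {
  rec <- data.frame(barcode = c("a", "b", "c", "d"),
                    rr = c(3, 0.3, 3 + 1e-9, 0.3 - 1e-9),
                    r_ctrl = 1, stringsAsFactors = FALSE)
  out <- call_hits(rec, screen_config())
  expect_identical(out$direction, c("none", "none", "enriched", "depleted"))
  # spec'd group examples
  g <- assign_group(call_hits(data.frame(
    barcode = c("x", "y"), rr = c(5, 0.1), r_ctrl = c(0.2, 1.0),
    stringsAsFactors = FALSE), screen_config()), screen_config())
  expect_identical(g$group, c("group1", "group2"))
})

test_that("degenerate and malformed inputs are rejected with clear errors", {
  cm <- build_count_matrix(list(CK1 = c(A = 100L), CK2 = c(A = 100L)))
  expect_error(compute_ratios(cm), "S10")
  cm0 <- build_count_matrix(list(CK1 = c(A = 100L), CK2 = c(A = 100L),
                                 S10 = c(B = 1L)))
  attr(cm0, "totals")["S10"] <- 0
  cm0["B", "S10"] <- 0L
  expect_error(compute_ratios(cm0), "zero recognized")
  empty <- build_count_matrix(list(CK1 = integer(0)))
  expect_length(filter_min_ck1(empty), 0L)
})

test_that("rr is invariant to per-sample depth rescaling", {
  cm <- fixture_matrix()
  cfg <- screen_config()
  rec1 <- compute_ratios(cm, rownames(cm), cfg)
  scaled <- unclass(cm)
  scaled[, "S10"] <- scaled[, "S10"] * 7L
  scaled[, "CK1"] <- scaled[, "CK1"] * 3L
  cm2 <- structure(scaled, totals = colSums(scaled),
                   class = class(cm))
  rec2 <- compute_ratios(cm2, rownames(cm2), cfg)
  expect_equal(rec1$rr, rec2$rr, tolerance = 1e-12)
  expect_equal(rec1$r_ctrl, rec2$r_ctrl, tolerance = 1e-12)
  h1 <- assign_group(call_hits(rec1, cfg), cfg)
  h2 <- assign_group(call_hits(rec2, cfg), cfg)
  expect_identical(h1$direction, h2$direction)
  expect_identical(h1$group, h2$group)
})

test_that("hit counts are monotone in the thresholds", {
  cm <- fixture_matrix()
  rec <- compute_ratios(cm, rownames(cm), screen_config())
  n_enr <- vapply(c(1.5, 2, 3, 5, 10), function(u) {
    sum(call_hits(rec, screen_config(up_threshold = u))$direction ==
          "enriched")
  }, integer(1))
  expect_true(all(diff(n_enr) <= 0))
  n_dep <- vapply(c(0.9, 0.5, 0.3, 0.1, 0.01), function(d) {
    sum(call_hits(rec, screen_config(down_threshold = d))$direction ==
          "depleted")
  }, integer(1))
  expect_true(all(diff(n_dep) <= 0))
})

test_that("gene aggregation groups hit barcodes and flags ties", {
  records <- data.frame(
    barcode = c("b1", "b2", "b3", "b4", "b5"),
    rr = c(0.1, 0.1, 5, 0.2, 1),
    r_ctrl = c(1, 1, 0.2, 1, 1),
    hit = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = c("depleted", "depleted", "enriched", "depleted", "none"),
    group = c("group2", "group2", "group1", "group2", "none"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    barcode = c("b1", "b2", "b3", "b4", "b5"),
    chrom = "chr1", pos = 1:5, strand = "+",
    category = c("exon", "intron", "exon", "intergenic", "exon"),
    gene_id = c("gA", "gA", "gB", NA, "gC"),
    distance_to_tss = NA_integer_, stringsAsFactors = FALSE)
  out <- aggregate_by_gene(records, ann, early_cold_list = c("gA", "gZ"))
  expect_equal(nrow(out), 2L)            # b4 intergenic, b5 not a hit
  gA <- out[out$gene_id == "gA", ]
  expect_equal(gA$n_barcodes, 2L)
  expect_equal(gA$dominant_group, "group2")
  expect_true(gA$in_early_cold_list)
  s <- attr(out, "summary")
  expect_equal(s$n_hit_barcodes, 4L)
  expect_equal(s$n_mapped_hit_barcodes, 3L)
  expect_equal(s$n_candidate_genes, 2L)
  expect_equal(s$n_early_cold_overlap, 1L)
  # group1/group2 tie goes to group2 with a flag
  rec2 <- records[records$barcode %in% c("b1", "b3"), ]
  ann2 <- ann[ann$barcode %in% c("b1", "b3"), ]
  ann2$gene_id <- "gT"
  out2 <- aggregate_by_gene(rec2, ann2)
  expect_equal(out2$dominant_group, "group2")
  expect_true(out2$group_tie)
  # empty early list
  out3 <- aggregate_by_gene(records, ann)
  expect_false(any(out3$in_early_cold_list))
})

test_that("scatter table mirrors the ratio table row for row", {
  cm <- fixture_matrix()
  cfg <- screen_config()
  kept <- filter_min_ck1(cm, cfg)
  rec <- assign_group(call_hits(compute_ratios(cm, kept, cfg), cfg), cfg)
  st <- scatter_table(rec, highlight = "B6")
  expect_equal(nrow(st), length(kept))
  expect_equal(st$x, rec$log2_r_ctrl)
  expect_equal(st$y, rec$log2_r_cold)
  expect_true(st$highlight[st$barcode == "B6"])
  # rr = 1 barcodes with equal ratios sit on the diagonal
  diag_rows <- st$barcode %in% c("B1", "B2")
  expect_equal(st$x[diag_rows], st$y[diag_rows], tolerance = 1e-12)
  # zero S10 count maps to y = log2(offset) under equal totals
  expect_equal(st$y[st$barcode == "B4"], log2(0.001), tolerance = 1e-12)
})

test_that("screen_counts reports a complete summary", {
  cm <- fixture_matrix()
  res <- screen_counts(cm)
  expect_equal(res$summary$n_barcodes, 9L)
  expect_equal(res$summary$n_retained, 8L)
  expect_equal(res$summary$n_hits, 4L)
  expect_equal(res$summary$n_group1, 1L)
  expect_equal(res$summary$n_group2, 2L)
  expect_true(res$summary$parameters$offset_inside_rr)
})
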