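test_that("k-mer index enumerates both strands exactly", {
  # hand-enumerable toy genome; k just below the minimum is rejected
  expect_error(build_kmer_index(c(chr1 = "ACGTACGT"), k = 4), ">= 11")
  g <- c(chr1 = "ACGTACGTACGTACG")
  idx <- build_kmer_index(g, k = 11)
  expect_equal(nrow(idx), 2 * (15 - 11 + 1))
  fwd <- idx[idx$strand == "+", ]
  expect_setequal(fwd$pos, 1:5)
  expect_true(all(vapply(seq_len(nrow(fwd)), function(i) {
    substr(g[[1]], fwd$pos[i], fwd$pos[i] + 10) == fwd$kmer[i]
  }, logical(1))))
})

test_that("every indexed occurrence re-reads correctly from the genome", {
  g <- random_genome(10000, seed = 2)
  k <- 15
  idx <- build_kmer_index(g, k = k)
  expect_equal(nrow(idx), 2 * (10000 - k + 1))
  set.seed(3)
  probe <- idx[sample(nrow(idx), 500), ]
  for (i in seq_len(nrow(probe))) {
    if (probe$strand[i] == "+") {
      ref <- substr(g[[probe$chrom[i]]], probe$pos[i], probe$pos[i] + k - 1)
    } else {
      ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(g[[probe$chrom[i]]], probe$pos[i] - k + 1, probe$pos[i]))))
    }
    expect_identical(probe$kmer[i], ref)
  }
})

test_that("short chromosomes and ambiguous bases are tolerated", {
  expect_warning(idx <- build_kmer_index(c(chr1 = strrep("ACGT", 10),
                                           tiny = "ACGT"), k = 12),
                 "shorter than k")
  expect_true(all(idx$chrom == "chr1"))
  expect_message(idx2 <- build_kmer_index(c(chr1 = paste0(strrep("A", 20),
                                                          "N",
                                                          strrep("C", 20))),
                                          k = 12), "skipped")
  expect_false(any(grepl("N", idx2$kmer)))
})

test_that("verbatim and reverse-complement flanks map to the same locus", {
  g <- random_genome(20000, seed = 4)
  idx <- build_kmer_index(g, k = 21)
  p <- 5001L
  flank <- substr(g[[1]], p, p + 59)
  top <- map_flank(flank, idx, g)
  expect_equal(top$chrom[1], "chr1")
  expect_equal(top$pos[1], p)
  expect_equal(top$strand[1], "+")
  expect_equal(top$mismatches[1], 0L)
  # strand round-trip: the reverse complement maps to the window's other end
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(flank)))
  top_rc <- map_flank(rc, idx, g)
  expect_equal(top_rc$strand[1], "-")
  expect_equal(top_rc$pos[1], p + 59L)
  # random flank: unmapped
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  expect_equal(nrow(map_flank(junk, idx, g)), 0L)
})

test_that("seed-and-extend equals the full-scan Hamming aligner", {
  g <- random_genome(20000, seed = 6)
  # a 15 bp seed guarantees at least two intact seed k-mers for any two
  # substitutions in a 60 bp flank, so seeding can never miss the true locus
  idx <- build_kmer_index(g, k = 15)
  params <- map_params(k = 15)
  set.seed(7)
  n_flanks <- 500
  L <- 60
  agree <- 0L
  comparable <- 0L
  for (i in seq_len(n_flanks)) {
    p <- sample.int(20000 - L + 1, 1)
    fl <- substr(g[[1]], p, p + L - 1)
    st <- sample(c("+", "-"), 1)
    if (st == "-") {
      fl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fl)))
    }
    n_mm <- sample(0:2, 1)
    if (n_mm > 0) fl <- mutate_bases(fl, n_mm, seed = i)
    oracle <- bruteforce_best_locus(fl, g, max_mm = 2L)
    if (is.null(oracle)) next   # tied or unlocatable best: out of contract
    comparable <- comparable + 1L
    got <- map_flank(fl, idx, g, params)
    agree <- agree +
      (nrow(got) > 0 && got$chrom[1] == oracle$chrom &&
         got$pos[1] == oracle$pos && got$strand[1] == oracle$strand)
  }
  expect_gt(comparable, 450)
  expect_equal(agree, comparable)
})

test_that("pair association extracts barcodes and strips cassette remnants", {
  spec <- cassette_spec(barcode_len = 12L)
  bcs <- c("ACGTACGTACGT", "TTTTCCCCAAAA")
  r1 <- paste0(spec$upstream_anchor, bcs, spec$downstream_anchor)
  flank <- c("ACCATGGACCATGGTT", "GGTTACGGTTACGGTA")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "R1.fastq"); f2 <- file.path(d, "R2.fastq")
  # second pair's genomic mate still carries the cassette remnant
  write_fastq(c("p1", "p2", "p3"), c(r1, strrep("G", 50)), f1)
  write_fastq(c("p1", "p2", "p3"),
              c(flank[1], paste0(spec$downstream_anchor, flank[2]),
                "ACGTACGTACGTACGT"), f2)
  rec <- associate_pairs(f1, f2, spec, "CK1")
  expect_equal(rec$barcode, bcs)
  expect_equal(rec$flank, flank)
  expect_equal(sum(attr(rec, "dropped")), 1)
  # mate-count mismatch
  f3 <- file.path(d, "R3.fastq")
  write_fastq("p1", r1[1], f3)
  expect_error(associate_pairs(f1, f3, spec), "mate-count mismatch")
})

test_that("insertion calling applies modal-locus, support and tie rules", {
  g <- random_genome(20000, seed = 8)
  idx <- build_kmer_index(g, k = 21)
  fA <- substr(g[[1]], 2001, 2060)
  fB <- substr(g[[1]], 9001, 9060)
  # 10 concordant records -> unique with support 10
  rec <- data.frame(barcode = "b1", flank = rep(fA, 10),
                    stringsAsFactors = FALSE)
  call <- call_insertions(rec, idx, g)
  expect_equal(call$status, "unique")
  expect_equal(call$support, 10L)
  expect_equal(call$pos, 2001L)
  # 5 vs 5 records at two loci -> ambiguous
  rec <- data.frame(barcode = "b1", flank = c(rep(fA, 5), rep(fB, 5)),
                    stringsAsFactors = FALSE)
  call <- call_insertions(rec, idx, g, map_params(min_agree_frac = 0.8))
  expect_equal(call$status, "ambiguous")
  # 8 vs 2 passes min_agree_frac = 0.8; 7 vs 3 does not
  rec <- data.frame(barcode = "b1", flank = c(rep(fA, 8), rep(fB, 2)),
                    stringsAsFactors = FALSE)
  expect_equal(call_insertions(rec, idx, g)$status, "unique")
  rec <- data.frame(barcode = "b1", flank = c(rep(fA, 7), rep(fB, 3)),
                    stringsAsFactors = FALSE)
  expect_equal(call_insertions(rec, idx, g)$status, "conflicting")
  # single unmappable record -> unmapped
  rec <- data.frame(barcode = "b1", flank = strrep("ACGT", 15),
                    stringsAsFactors = FALSE)
  expect_equal(call_insertions(rec, idx, g)$status, "unmapped")
})

test_that("raising min_support never increases unique calls", {
  cfg <- sim_config(seed = 23, n_chrom = 1, chrom_len = 60000, n_genes = 10,
                    n_mutants = 40, depth_per_sample = 2000,
                    leap_depth = 400, subst_error_rate = 0.002)
  sim <- simulate_screen(cfg, withr::local_tempdir())
  idx <- build_kmer_index(sim$genome, 21)
  rec <- associate_pairs(sim$reads$leap_fastq$CK1[["R1"]],
                         sim$reads$leap_fastq$CK1[["R2"]],
                         cfg$cassette, "CK1")
  n_unique <- vapply(c(1L, 2L, 5L, 10L), function(ms) {
    calls <- call_insertions(rec, idx, sim$genome,
                             map_params(min_support = ms))
    sum(calls$status == "unique")
  }, integer(1))
  expect_true(all(diff(n_unique) <= 0))
})

test_that("noiseless simulation recovers every supported truth locus", {
  cfg <- sim_config(seed = 29, n_chrom = 2, chrom_len = 50000, n_genes = 12,
                    n_mutants = 60, depth_per_sample = 2000,
                    leap_depth = 2000, subst_error_rate = 0)
  sim <- simulate_screen(cfg, withr::local_tempdir())
  idx <- build_kmer_index(sim$genome, 21)
  rec <- rbind(
    associate_pairs(sim$reads$leap_fastq$CK1[["R1"]],
                    sim$reads$leap_fastq$CK1[["R2"]], cfg$cassette, "CK1"),
    associate_pairs(sim$reads$leap_fastq$S10R[["R1"]],
                    sim$reads$leap_fastq$S10R[["R2"]], cfg$cassette, "S10R"))
  calls <- call_insertions(rec, idx, sim$genome)
  truth <- sim$truth
  pair_support <- table(rec$barcode)
  for (i in seq_len(nrow(truth))) {
    b <- truth$barcode[i]
    n_pairs <- if (b %in% names(pair_support)) pair_support[[b]] else 0L
    if (n_pairs < 2L || truth$flank_truncated[i]) next
    call <- calls[calls$barcode == b, ]
    expect_equal(call$status, "unique", label = b)
    expect_equal(call$chrom, truth$chrom[i])
    expect_equal(call$pos, truth$pos[i])
    expect_equal(call$strand, truth$strand[i])
  }
})

test_that("BED export converts coordinates to 0-based half-open", {
  ins <- data.frame(barcode = c("b1", "b2"), chrom = c("chr1", "chr2"),
                    pos = c(100L, 7L), strand = c("+", "-"),
                    support = c(4L, 2L), n_mapped = c(4L, 2L),
                    status = c("unique", "conflicting"),
                    stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_insertions_bed(ins, tmp)
  lines <- readLines(tmp)
  expect_true(startsWith(lines[1], "#"))
  expect_equal(lines[2], "chr1\t99\t100\tb1\t4\t+")
  expect_length(lines, 2)  # non-unique calls excluded
})
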