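SAMPLES <- c("CK1", "CK2", "S10", "S10R")

#' Generate a synthetic reference genome and gene models
#'
#' Chromosomes are uniform-random A/C/G/T strings; genes are placed without
#' overlap (at least 1 bp apart) and each carries a 5' UTR, two to four exons
#' separated by introns, and a 3' UTR, with random strand. The layout is
#' deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences) and `models` (a [gene_model_set()]).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed_offset(config$seed, 1L, {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    genome <- vapply(chroms, function(ch) {
      paste(sample(DNA_BASES, config$chrom_len, replace = TRUE), collapse = "")
    }, character(1))
    per_chrom <- genes_per_chrom(config$n_genes, config$n_chrom)
    genes <- list(); feats <- list()
    gene_no <- 0L
    for (ci in seq_len(config$n_chrom)) {
      n_i <- per_chrom[ci]
      if (n_i == 0L) next
      lens <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]),
                     n_i, replace = TRUE)
      slack <- config$chrom_len - sum(lens) - (n_i - 1L)
      if (slack < 0L) {
        stop("cannot place genes on ", chroms[ci],
             ": total gene length exceeds chromosome length", call. = FALSE)
      }
      offs <- sort(sample.int(slack + 1L, n_i, replace = TRUE) - 1L)
      starts <- offs + cumsum(c(0L, lens[-n_i] + 1L)) + 1L
      strands <- sample(c("+", "-"), n_i, replace = TRUE)
      for (j in seq_len(n_i)) {
        gene_no <- gene_no + 1L
        gid <- sprintf("gene%03d", gene_no)
        st <- gene_structure(lens[j], strands[j])
        genes[[gene_no]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], strand = strands[j],
          start = starts[j], end = starts[j] + lens[j] - 1L,
          tss = if (strands[j] == "+") starts[j] else starts[j] + lens[j] - 1L,
          stringsAsFactors = FALSE)
        keep <- st$type != "intron"
        feats[[gene_no]] <- data.frame(
          gene_id = gid, type = st$type[keep],
          start = starts[j] + st$off_start[keep],
          end = starts[j] + st$off_end[keep],
          stringsAsFactors = FALSE)
      }
    }
    models <- gene_model_set(do.call(rbind, genes), do.call(rbind, feats))
    list(genome = genome, models = models)
  })
}

# Segment a gene of `len` bases into 5'UTR / exons / introns / 3'UTR, in
# transcript order, then project onto genomic (left-to-right) offsets.
# Minimum part sizes keep every category reachable.
gene_structure <- function(len, strand) {
  u5 <- sample(100:300, 1L)
  u3 <- sample(150:400, 1L)
  body <- len - u5 - u3
  n_ex <- sample(2:4, 1L)
  parts <- 2L * n_ex - 1L            # exons alternating with introns
  min_part <- 50L
  rest <- body - min_part * parts
  stopifnot(rest >= 0L)
  cuts <- sort(sample.int(rest + 1L, parts - 1L, replace = TRUE) - 1L)
  sizes <- min_part + diff(c(0L, cuts, rest))
  types <- c("five_prime_UTR",
             rep(c("exon", "intron"), length.out = parts),
             "three_prime_UTR")
  sizes <- c(u5, sizes, u3)
  if (strand == "-") { types <- rev(types); sizes <- rev(sizes) }
  off_end <- cumsum(sizes) - 1L
  off_start <- off_end - sizes + 1L
  data.frame(type = types, off_start = off_start, off_end = off_end,
             stringsAsFactors = FALSE)
}

#' Generate a barcoded mutant library with ground truth
#'
#' Places `n_mutants` cassette insertions uniformly over the genome, assigns
#' unique random barcodes and a fitness class to each mutant (class counts are
#' rounded deterministically from the configured fractions), draws per-mutant
#' fitnesses from the configured ranges, and records for every mutant: the
#' annotation category of its insertion point (computed by the same classifier
#' used downstream, so truth and pipeline can never disagree by construction),
#' the affected gene, and the screen outcome expected in the absence of
#' sampling noise (computed from closed-form abundances under the default
#' screen thresholds, or `screen_config` if supplied).
#'
#' @param config A [sim_config()].
#' @param genome Named character vector of chromosome sequences.
#' @param models A [gene_model_set()].
#' @param screen_cfg A [screen_config()] used for the expected noiseless
#'   classification.
#' @return A data.frame of class `sim_truth`, one row per mutant.
#' @export
generate_library <- function(config, genome, models,
                             screen_cfg = screen_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (4^config$barcode_len < config$n_mutants) {
    stop("barcode space exhausted: 4^barcode_len < n_mutants", call. = FALSE)
  }
  with_seed_offset(config$seed, 2L, {
    n <- config$n_mutants
    chrom_lens <- nchar(genome)
    chrom <- sample(names(genome), n, replace = TRUE,
                    prob = chrom_lens / sum(chrom_lens))
    pos <- vapply(chrom, function(ch) sample.int(chrom_lens[[ch]], 1L),
                  integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    barcode <- random_barcodes(n, config$barcode_len)

    n_cs <- round(config$frac_cold_sensitive * n)
    n_con <- round(config$frac_constitutive * n)
    class <- rep("neutral", n)
    picks <- sample.int(n, n_cs + n_con)
    class[picks[seq_len(n_cs)]] <- "cold_sensitive"
    if (n_con > 0L) class[picks[n_cs + seq_len(n_con)]] <- "constitutive"

    f_ctrl <- numeric(n); f_cold <- numeric(n)
    for (cls in unique(class)) {
      idx <- which(class == cls)
      rg <- config$fitness_ranges[[cls]]
      f_ctrl[idx] <- runif(length(idx), rg$ctrl[1], rg$ctrl[2])
      f_cold[idx] <- runif(length(idx), rg$cold[1], rg$cold[2])
    }

    ann <- classify_insertions(chrom, pos, models)
    flank_truncated <- ifelse(
      strand == "+",
      pos + config$flank_len - 1L > chrom_lens[chrom],
      pos - config$flank_len + 1L < 1L)

    truth <- data.frame(
      mutant_id = sprintf("mut%04d", seq_len(n)),
      barcode = barcode, chrom = chrom, pos = as.integer(pos),
      strand = strand, class = class,
      f_ctrl = f_ctrl, f_cold = f_cold,
      true_category = ann$category,
      affected_gene = ann$gene_id,
      flank_truncated = flank_truncated,
      stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    truth$expected_group <- expected_groups(truth, config, screen_cfg)
    class(truth) <- c("sim_truth", "data.frame")
    truth
  })
}

random_barcodes <- function(n, len) {
  draw <- function(m) {
    mat <- matrix(sample(DNA_BASES, m * len, replace = TRUE), nrow = m)
    do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

# Noiseless screen outcome implied by the fitness model: abundance ratios in
# closed form, then the same hit/group rule the screen applies.
expected_groups <- function(truth, config, screen_cfg) {
  ab <- evolve_abundances(truth, config)
  r_ctrl <- ab[, "CK2"] / ab[, "CK1"]
  r_cold <- ab[, "S10"] / ab[, "CK1"]
  off <- screen_cfg$offset
  rr <- (r_cold + off) / (r_ctrl + off)
  dir <- hit_direction(rr, screen_cfg)
  classify_group(dir, r_ctrl, screen_cfg)
}

#' Evolve mutant abundances across the screen arms
#'
#' The initial pool (CK1) is uniform. Over `g` population doublings a mutant
#' with relative fitness `f` multiplies by `2^(f * g)`; abundances are then
#' renormalised. CK2 applies (`f_ctrl`, `g_ctrl`) to CK1; S10 applies
#' (`f_cold`, `g_cold`) to CK1; S10R applies (`f_ctrl`, `g_rec`) to S10 (the
#' recovery culture grows out of the cold-stressed pool, not the initial one).
#'
#' @param truth A `sim_truth` table from [generate_library()].
#' @param config A [sim_config()].
#' @return Numeric matrix, mutants x samples (CK1, CK2, S10, S10R), each
#'   column summing to 1.
#' @export
evolve_abundances <- function(truth, config) {
  if (any(truth$f_ctrl < 0 | truth$f_cold < 0)) {
    stop("fitness must be non-negative", call. = FALSE)
  }
  n <- nrow(truth)
  ck1 <- rep(1 / n, n)
  grow <- function(a, f, g) {
    w <- a * 2^(f * g)
    w / sum(w)
  }
  ck2 <- grow(ck1, truth$f_ctrl, config$g_ctrl)
  s10 <- grow(ck1, truth$f_cold, config$g_cold)
  s10r <- grow(s10, truth$f_ctrl, config$g_rec)
  ab <- cbind(CK1 = ck1, CK2 = ck2, S10 = s10, S10R = s10r)
  rownames(ab) <- truth$barcode
  ab
}

#' Draw per-mutant read counts at a given depth
#'
#' A single multinomial draw per sample; this is exactly the draw
#' [emit_reads()] turns into reads, so count-level and read-level simulations
#' agree.
#'
#' @param abundances Matrix from [evolve_abundances()] (or any column subset).
#' @param depth Reads per sample.
#' @return Integer matrix of counts, same shape as `abundances`.
#' @export
sample_counts <- function(abundances, depth) {
  out <- apply(abundances, 2, function(p) rmultinom(1L, depth, p)[, 1L])
  rownames(out) <- rownames(abundances)
  out
}

# Apply per-base substitution errors at `rate` to a character vector of reads.
add_subst_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs)
  ne <- rbinom(length(seqs), L, rate)
  idx <- which(ne > 0L)
  for (j in idx) {
    ch <- strsplit(seqs[j], "", fixed = TRUE)[[1L]]
    p <- sample.int(L[j], ne[j])
    for (k in p) ch[k] <- sample(setdiff(DNA_BASES, ch[k]), 1L)
    seqs[j] <- paste(ch, collapse = "")
  }
  seqs
}

# Genomic flank carried by the genomic mate: flank_len bases starting at the
# insertion coordinate, read away from the cassette junction; on the minus
# strand the flank is the reverse complement of the bases ending at `pos`.
# Flanks running off a chromosome end are truncated.
truth_flanks <- function(truth, genome, flank_len) {
  lens <- nchar(genome)
  vapply(seq_len(nrow(truth)), function(i) {
    ch <- truth$chrom[i]; p <- truth$pos[i]
    if (truth$strand[i] == "+") {
      substr(genome[[ch]], p, min(p + flank_len - 1L, lens[[ch]]))
    } else {
      revcomp(substr(genome[[ch]], max(p - flank_len + 1L, 1L), p))
    }
  }, character(1))
}

#' Emit sequencing reads for a simulated screen
#'
#' Barcode-PCR reads (`anchor + barcode + anchor`) are drawn multinomially
#' from each sample's abundances at `depth_per_sample`. Flanking-sequence
#' libraries for CK1 and S10R are emitted as read pairs: the cassette mate
#' carries the barcode in the same architecture, the genomic mate carries
#' `flank_len` bases of genomic flank starting at the insertion coordinate
#' (strand-aware, truncated at chromosome ends). Per-base substitution noise
#' is applied at `subst_error_rate`. Deterministic given the config seed.
#'
#' @param truth A `sim_truth` table.
#' @param abundances Matrix from [evolve_abundances()].
#' @param config A [sim_config()].
#' @param genome Named character vector of chromosome sequences.
#' @param outdir Directory for FASTQ output (created if needed).
#' @return Invisibly, a list with `barcode_fastq` (named paths),
#'   `leap_fastq` (per-sample R1/R2 paths), `sampled_counts` (the internal
#'   multinomial draw, mutants x samples) and `leap_counts`.
#' @export
emit_reads <- function(truth, abundances, config, genome, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cas <- config$cassette
  with_seed_offset(config$seed, 3L, {
    cassette_read <- paste0(cas$upstream_anchor, truth$barcode,
                            cas$downstream_anchor)
    sampled <- sample_counts(abundances, config$depth_per_sample)
    barcode_fastq <- character(0)
    for (s in colnames(abundances)) {
      idx <- rep(seq_len(nrow(truth)), sampled[, s])
      reads <- add_subst_errors(cassette_read[idx], config$subst_error_rate)
      path <- file.path(outdir, paste0(s, ".fastq"))
      write_fastq(sprintf("%s_%07d", s, seq_along(reads)), reads, path)
      barcode_fastq[s] <- path
    }

    flanks <- truth_flanks(truth, genome, config$flank_len)
    leap_samples <- intersect(c("CK1", "S10R"), colnames(abundances))
    leap_counts <- if (length(leap_samples) > 0L) {
      sample_counts(abundances[, leap_samples, drop = FALSE],
                    config$leap_depth)
    } else {
      NULL
    }
    leap_fastq <- list()
    for (s in leap_samples) {
      idx <- rep(seq_len(nrow(truth)), leap_counts[, s])
      r1 <- add_subst_errors(cassette_read[idx], config$subst_error_rate)
      r2 <- add_subst_errors(flanks[idx], config$subst_error_rate)
      ids <- sprintf("%s_leap_%07d", s, seq_along(idx))
      p1 <- file.path(outdir, paste0(s, "_leap_R1.fastq"))
      p2 <- file.path(outdir, paste0(s, "_leap_R2.fastq"))
      write_fastq(ids, r1, p1)
      write_fastq(ids, r2, p2)
      leap_fastq[[s]] <- c(R1 = p1, R2 = p2)
    }
    invisible(list(barcode_fastq = barcode_fastq, leap_fastq = leap_fastq,
                   sampled_counts = sampled, leap_counts = leap_counts))
  })
}

#' Run the full synthetic screen generator
#'
#' Generates the reference, library, abundances and reads, and writes
#' everything under `outdir`: `genome.fasta`, `genes.gff3`, `truth.tsv`,
#' `config.yaml`, `early_cold_genes.txt` (a random `early_cold_frac` subset of
#' gene IDs standing in for an early cold-induced gene list), per-sample
#' barcode FASTQs and paired flanking-read FASTQs under `fastq/`, and the
#' internal multinomial draw `sampled_counts.tsv`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with `genome`, `models`, `truth`, `abundances`,
#'   `reads` (see [emit_reads()]) and `paths`.
#' @export
simulate_screen <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(config)
  truth <- generate_library(config, ref$genome, ref$models)
  ab <- evolve_abundances(truth, config)
  reads <- emit_reads(truth, ab, config, ref$genome, file.path(outdir, "fastq"))

  fasta <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), fasta)
  gff3 <- file.path(outdir, "genes.gff3")
  write_gff3(ref$models, gff3)
  truth_path <- file.path(outdir, "truth.tsv")
  write_tsv(truth, truth_path)
  cfg_path <- file.path(outdir, "config.yaml")
  write_sim_config(config, cfg_path)

  early_path <- file.path(outdir, "early_cold_genes.txt")
  early <- with_seed_offset(config$seed, 4L, {
    ids <- ref$models$genes$gene_id
    sort(sample(ids, round(config$early_cold_frac * length(ids))))
  })
  writeLines(early, early_path)

  sc <- data.frame(barcode = truth$barcode, reads$sampled_counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sc_path <- file.path(outdir, "sampled_counts.tsv")
  write_tsv(sc, sc_path)

  invisible(list(
    genome = ref$genome, models = ref$models, truth = truth,
    abundances = ab, reads = reads,
    paths = list(fasta = fasta, gff3 = gff3, truth = truth_path,
                 config = cfg_path, early_cold = early_path,
                 sampled_counts = sc_path,
                 barcode_fastq = reads$barcode_fastq,
                 leap_fastq = reads$leap_fastq)))
}
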