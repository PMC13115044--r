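#' Build a k-mer index of a genome
#'
#' Indexes every k-mer of every chromosome on both strands. For a forward
#' occurrence the stored position is the genomic coordinate of the k-mer's
#' first base; for a reverse-strand occurrence it is the genomic coordinate
#' that the k-mer's first base occupies when read 5'->3' on the minus strand
#' (i.e. the rightmost genomic base of the window). k-mers containing
#' non-A/C/G/T bases are skipped and tallied.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param k k-mer size (>= 11).
#' @return An object of class `kmer_index`: a keyed data.table with columns
#'   `kmer`, `chrom`, `pos`, `strand`, and attributes `k` and `chrom_lens`.
#' @export
build_kmer_index <- function(genome, k = 21L) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11", call. = FALSE)
  genome <- as_genome_chr(genome)
  skipped <- 0L
  parts <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < k) {
      warning("chromosome ", ch, " shorter than k; no k-mers indexed")
      next
    }
    n_pos <- L - k + 1L
    fwd <- substring(s, seq_len(n_pos), seq_len(n_pos) + k - 1L)
    rc <- revcomp(s)
    rev <- substring(rc, seq_len(n_pos), seq_len(n_pos) + k - 1L)
    # rc position i covers genome [L-i-k+2, L-i+1]; its first base in read
    # orientation sits at genome coordinate L-i+1 on the minus strand
    part <- data.table::data.table(
      kmer = c(fwd, rev),
      chrom = ch,
      pos = c(seq_len(n_pos), L - seq_len(n_pos) + 1L),
      strand = rep(c("+", "-"), each = n_pos))
    bad <- grepl("[^ACGT]", part$kmer)
    skipped <- skipped + sum(bad)
    parts[[ch]] <- part[!bad]
  }
  idx <- data.table::rbindlist(parts)
  if (skipped > 0L) {
    message(skipped, " k-mer(s) containing non-ACGT bases skipped")
  }
  data.table::setkey(idx, kmer)
  structure(idx, k = k, chrom_lens = nchar(genome), class = c("kmer_index",
                                                              class(idx)))
}

as_genome_chr <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome),
                       sub("\\s.*$", "", names(genome)))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

#' Default mapping parameters
#'
#' @param k Seed k-mer size.
#' @param min_seed_hits Minimum seeds agreeing on one (chrom, strand,
#'   diagonal) before ungapped verification.
#' @param max_mismatch_frac Maximum mismatch fraction for a reported locus.
#' @param min_support Minimum read pairs agreeing on a locus for a unique
#'   insertion call.
#' @param min_agree_frac Minimum fraction of a barcode's mapped pairs that
#'   must agree on the modal locus.
#' @param pos_slop Positional slack (bp) when clustering per-barcode loci.
#' @return Named list of parameters.
#' @export
map_params <- function(k = 21L, min_seed_hits = 2L, max_mismatch_frac = 0.1,
                       min_support = 2L, min_agree_frac = 0.8, pos_slop = 3L) {
  list(k = as.integer(k), min_seed_hits = as.integer(min_seed_hits),
       max_mismatch_frac = max_mismatch_frac,
       min_support = as.integer(min_support),
       min_agree_frac = min_agree_frac, pos_slop = as.integer(pos_slop))
}

#' Map flanking sequences to candidate genomic loci
#'
#' Seed-and-extend: every k-mer of a flank votes for a (chromosome, strand,
#' start) diagonal via the index; diagonals gathering at least `min_seed_hits`
#' votes are verified by ungapped comparison of the full flank against the
#' genome. Loci within `max_mismatch_frac` are returned ranked by score
#' (matches minus mismatches, ties by chromosome then position). The reported
#' position is the genomic coordinate aligned to the flank's first base --
#' the first genomic base adjacent to the cassette junction.
#'
#' @param flanks Character vector of flank sequences.
#' @param index A [build_kmer_index()] result.
#' @param genome The genome the index was built from (any form accepted by
#'   [build_kmer_index()]).
#' @param params A [map_params()] list.
#' @return A data.table with columns `flank_id`, `chrom`, `pos`, `strand`,
#'   `score`, `mismatches`, `votes`, ranked within each `flank_id`. Flanks
#'   with no reported locus are absent (unmapped).
#' @export
map_flanks <- function(flanks, index, genome, params = map_params()) {
  stopifnot(inherits(index, "kmer_index"))
  genome <- as_genome_chr(genome)
  k <- attr(index, "k")
  n <- length(flanks)
  empty <- data.table::data.table(
    flank_id = integer(0), chrom = character(0), pos = integer(0),
    strand = character(0), score = integer(0), mismatches = integer(0),
    votes = integer(0))
  if (n == 0L) return(empty)
  flen <- nchar(flanks)
  usable <- which(flen >= k)
  if (length(usable) == 0L) return(empty)

  seed_tabs <- lapply(usable, function(i) {
    n_off <- flen[i] - k + 1L
    data.table::data.table(
      flank_id = i, off = seq_len(n_off),
      kmer = substring(flanks[i], seq_len(n_off), seq_len(n_off) + k - 1L))
  })
  seeds <- data.table::rbindlist(seed_tabs)
  hits <- index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits[, start := data.table::fifelse(strand == "+", pos - off + 1L,
                                      pos + off - 1L)]
  cand <- hits[, .(votes = .N), by = .(flank_id, chrom, strand, start)]
  cand <- cand[votes >= params$min_seed_hits]
  if (nrow(cand) == 0L) return(empty)

  chrom_lens <- attr(index, "chrom_lens")
  fl <- flen[cand$flank_id]
  in_bounds <- data.table::fifelse(
    cand$strand == "+",
    cand$start >= 1L & cand$start + fl - 1L <= chrom_lens[cand$chrom],
    cand$start - fl + 1L >= 1L & cand$start <= chrom_lens[cand$chrom])
  cand <- cand[in_bounds]
  if (nrow(cand) == 0L) return(empty)

  ref <- character(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    L <- flen[cand$flank_id[r]]
    ref[r] <- if (cand$strand[r] == "+") {
      substr(genome[[cand$chrom[r]]], cand$start[r], cand$start[r] + L - 1L)
    } else {
      substr(genome[[cand$chrom[r]]], cand$start[r] - L + 1L, cand$start[r])
    }
  }
  minus <- cand$strand == "-"
  if (any(minus)) ref[minus] <- revcomp(ref[minus])
  mism <- vapply(seq_len(nrow(cand)), function(r) {
    hamming(flanks[cand$flank_id[r]], ref[r])
  }, integer(1))
  cand[, mismatches := mism]
  cand[, score := flen[flank_id] - 2L * mismatches]
  cand <- cand[mismatches <= params$max_mismatch_frac * flen[flank_id]]
  data.table::setnames(cand, "start", "pos")
  data.table::setorder(cand, flank_id, -score, chrom, pos, strand)
  cand[, .(flank_id, chrom, pos, strand, score, mismatches, votes)]
}

#' Map a single flank
#'
#' @inheritParams map_flanks
#' @param flank A single flank sequence.
#' @return data.frame of candidate loci ranked by score (may have zero rows:
#'   unmapped).
#' @export
map_flank <- function(flank, index, genome, params = map_params()) {
  res <- map_flanks(flank, index, genome, params)
  as.data.frame(res[, -"flank_id"])
}

#' Pair barcode reads with genomic flanks
#'
#' Walks two FASTQs in lockstep, extracts the barcode from the cassette mate
#' via [extract_barcodes()], and takes the flank from the genomic mate after
#' stripping any detectable cassette remnant (a leading downstream-anchor
#' match within the anchor mismatch tolerance). Pairs whose barcode cannot be
#' extracted are dropped and tallied.
#'
#' @param fastq_barcode,fastq_flank Paths to the cassette-mate and
#'   genomic-mate FASTQ files (same read order and length).
#' @param spec A [cassette_spec()].
#' @param source_sample Label recorded with each record.
#' @return data.frame with columns `barcode`, `flank`, `source_sample`, plus
#'   a `dropped` attribute tallying failed pairs by reason.
#' @export
associate_pairs <- function(fastq_barcode, fastq_flank, spec,
                            source_sample = NA_character_) {
  fq1 <- read_fastq(fastq_barcode)
  fq2 <- read_fastq(fastq_flank)
  if (length(fq1$seq) != length(fq2$seq)) {
    stop(sprintf("mate-count mismatch: %d reads in %s vs %d in %s",
                 length(fq1$seq), fastq_barcode, length(fq2$seq),
                 fastq_flank), call. = FALSE)
  }
  res <- extract_barcodes(fq1$seq, spec)
  keep <- res$reason == "ok"
  dropped <- table(res$reason[!keep])
  flank <- fq2$seq[keep]
  # strip a cassette remnant: downstream anchor leading the genomic mate
  pre <- substr(flank, 1L, nchar(spec$downstream_anchor))
  full <- nchar(pre) == nchar(spec$downstream_anchor)
  is_rem <- full & (pre == spec$downstream_anchor)
  if (spec$max_anchor_mismatches > 0L) {
    chk <- which(full & !is_rem)
    if (length(chk) > 0L) {
      is_rem[chk] <- vapply(pre[chk], function(s) {
        hamming(s, spec$downstream_anchor) <= spec$max_anchor_mismatches
      }, logical(1), USE.NAMES = FALSE)
    }
  }
  flank[is_rem] <- substr(flank[is_rem], nchar(spec$downstream_anchor) + 1L,
                          nchar(flank[is_rem]))
  out <- data.frame(barcode = res$barcode[keep], flank = flank,
                    source_sample = source_sample, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Call one insertion locus per barcode
#'
#' Each record's flank is mapped (distinct flank sequences are mapped once);
#' a record contributes its unique best locus, records whose best score is
#' tied across loci are counted as mapped but support no locus. Per barcode,
#' loci within `pos_slop` bp on the same chromosome and strand are clustered;
#' the modal cluster wins if it is strictly larger than any other
#' (`ambiguous` on ties), reaches `min_support` records and holds at least
#' `min_agree_frac` of the barcode's mapped records (`conflicting`
#' otherwise). Barcodes with no mapped record are `unmapped`.
#'
#' @param records data.frame from [associate_pairs()] (columns `barcode`,
#'   `flank`), possibly concatenated across samples.
#' @param index A [build_kmer_index()] result.
#' @param genome Genome accepted by [build_kmer_index()].
#' @param params A [map_params()] list.
#' @return data.frame with one row per barcode: `barcode`, `chrom`, `pos`,
#'   `strand`, `support`, `n_mapped`, `status`
#'   (`unique`/`ambiguous`/`conflicting`/`unmapped`).
#' @export
call_insertions <- function(records, index, genome, params = map_params()) {
  stopifnot(all(c("barcode", "flank") %in% names(records)))
  uniq <- unique(records$flank)
  mapped <- map_flanks(uniq, index, genome, params)
  # best locus per flank; drop it if the top score is shared by several loci
  best <- if (nrow(mapped) > 0L) {
    mapped[, {
      top <- score == max(score)
      if (sum(top) == 1L) .SD[top] else .SD[0L]
    }, by = flank_id]
  } else {
    mapped
  }
  tied <- setdiff(mapped$flank_id, best$flank_id)

  flank_of <- match(records$flank, uniq)
  rec <- data.table::data.table(barcode = records$barcode,
                                flank_id = flank_of)
  rec_best <- merge(rec, best, by = "flank_id", all.x = FALSE)
  rec[, is_mapped := flank_id %in% c(best$flank_id, tied)]
  n_mapped_tab <- rec[, .(n_mapped = sum(is_mapped)), by = barcode]
  n_mapped_of <- setNames(n_mapped_tab$n_mapped, n_mapped_tab$barcode)
  all_barcodes <- sort(unique(records$barcode))
  loci_of <- split(seq_len(nrow(rec_best)), rec_best$barcode)

  out <- lapply(all_barcodes, function(b) {
    n_mapped <- unname(n_mapped_of[[b]])
    idx <- loci_of[[b]]
    loci <- if (is.null(idx)) rec_best[0L] else rec_best[idx]
    base <- data.frame(barcode = b, chrom = NA_character_, pos = NA_integer_,
                       strand = NA_character_, support = 0L,
                       n_mapped = n_mapped, status = "unmapped",
                       stringsAsFactors = FALSE)
    if (n_mapped == 0L) return(base)
    if (nrow(loci) == 0L) {            # mapped but every record tied
      base$status <- "ambiguous"
      return(base)
    }
    cl <- cluster_loci(loci$chrom, loci$pos, loci$strand, params$pos_slop)
    sizes <- tabulate(cl)
    top <- which(sizes == max(sizes))
    if (length(top) > 1L) {
      base$status <- "ambiguous"
      return(base)
    }
    members <- which(cl == top)
    support <- length(members)
    if (support < params$min_support ||
        support < params$min_agree_frac * n_mapped) {
      base$status <- "conflicting"
      return(base)
    }
    pos_tab <- table(loci$pos[members])
    modal_pos <- as.integer(names(pos_tab)[which.max(pos_tab)])
    base$chrom <- loci$chrom[members[1L]]
    base$pos <- modal_pos
    base$strand <- loci$strand[members[1L]]
    base$support <- support
    base$status <- "unique"
    base
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Assign loci to clusters: same chrom and strand, consecutive positions no
# more than `slop` apart.
cluster_loci <- function(chrom, pos, strand, slop) {
  key <- paste(chrom, strand)
  ord <- order(key, pos)
  cl <- integer(length(pos))
  cur <- 0L
  last_key <- NULL
  last_pos <- NULL
  for (i in ord) {
    if (is.null(last_key) || key[i] != last_key || pos[i] - last_pos > slop) {
      cur <- cur + 1L
    }
    cl[i] <- cur
    last_key <- key[i]
    last_pos <- pos[i]
  }
  cl
}

#' Write insertion calls as TSV or BED6
#'
#' The TSV keeps 1-based insertion coordinates. The BED6 writer converts to
#' 0-based half-open single-base intervals (documented in a header comment)
#' and includes only `unique` calls.
#'
#' @param insertions data.frame from [call_insertions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_insertions <- function(insertions, path) {
  write_tsv(insertions, path)
}

#' @rdname write_insertions
#' @export
write_insertions_bed <- function(insertions, path) {
  u <- insertions[insertions$status == "unique", , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste("# BED6: 0-based half-open; insertion base",
                   "[pos-1, pos) from the 1-based call"), con)
  if (nrow(u) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", u$chrom, u$pos - 1L, u$pos,
                       u$barcode, u$support, u$strand), con)
  }
  invisible(path)
}
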