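# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the annotation oracle is a naive per-gene interval scan,
# the alignment oracle is a full-scan Hamming search via Biostrings.

# Naive scan over every gene's every interval; mirrors the documented
# annotation rule directly.
annotate_oracle <- function(chrom, pos, models, w = 1000L) {
  g <- models$genes
  f <- models$features
  genic <- which(g$chrom == chrom & g$start <= pos & pos <= g$end)
  if (length(genic) > 0L) {
    d <- abs(pos - g$tss[genic])
    gi <- genic[order(d, g$gene_id[genic])][1L]
    ff <- f[f$gene_id == g$gene_id[gi], ]
    inft <- ff$start <= pos & pos <= ff$end
    cat <- if (any(inft)) ff$type[which(inft)[1L]] else "intron"
    return(list(category = cat, gene_id = g$gene_id[gi]))
  }
  dist <- ifelse(g$strand == "+", g$tss - pos, pos - g$tss)
  prom <- which(g$chrom == chrom & dist >= 1L & dist <= w)
  if (length(prom) > 0L) {
    gi <- prom[order(dist[prom], g$gene_id[prom])][1L]
    return(list(category = "potential_promoter", gene_id = g$gene_id[gi],
                distance = dist[gi]))
  }
  list(category = "intergenic", gene_id = NA_character_)
}

# Full-scan Hamming aligner over both strands (Biostrings matchPattern does
# the exhaustive scan). Returns the best locus in the package's coordinate
# convention (position of the flank's first base) or NULL if the best score
# is tied or nothing is found within max_mm.
bruteforce_best_locus <- function(flank, genome, max_mm = 2L) {
  L <- nchar(flank)
  hits <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    fwd <- Biostrings::matchPattern(flank, subj, max.mismatch = max_mm)
    for (s in Biostrings::start(fwd)) {
      mm <- sum(charToRaw(flank) !=
                  charToRaw(substr(genome[[ch]], s, s + L - 1L)))
      hits[[length(hits) + 1L]] <- list(chrom = ch, pos = s, strand = "+",
                                        mm = mm)
    }
    rcp <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(flank)))
    rev <- Biostrings::matchPattern(rcp, subj, max.mismatch = max_mm)
    for (s in Biostrings::start(rev)) {
      mm <- sum(charToRaw(rcp) !=
                  charToRaw(substr(genome[[ch]], s, s + L - 1L)))
      # flank's first base sits at the window's right edge on minus strand
      hits[[length(hits) + 1L]] <- list(chrom = ch, pos = s + L - 1L,
                                        strand = "-", mm = mm)
    }
  }
  if (length(hits) == 0L) return(NULL)
  mms <- vapply(hits, `[[`, integer(1), "mm")
  best <- which(mms == min(mms))
  if (length(best) > 1L) return(NULL)
  hits[[best]]
}

# Tiny hand-laid gene model set used by several annotation tests:
# plus-strand gene at [2000, 4000] (TSS 2000) and minus-strand gene at
# [6000, 8000] (TSS 8000) on chr1.
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(2000L, 6000L), end = c(4000L, 8000L),
    tss = c(2000L, 8000L),
    stringsAsFactors = FALSE)
  feats <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA",
                "gB", "gB", "gB", "gB"),
    type = c("five_prime_UTR", "exon", "exon", "three_prime_UTR",
             "three_prime_UTR", "exon", "exon", "five_prime_UTR"),
    start = c(2000L, 2101L, 3501L, 3901L,
              6000L, 6101L, 7501L, 7901L),
    end = c(2100L, 2500L, 3900L, 4000L,
            6100L, 6500L, 7900L, 8000L),
    stringsAsFactors = FALSE)
  gene_model_set(genes, feats)
}

# Random genome helper for mapping tests.
random_genome <- function(lens, seed) {
  set.seed(seed)
  setNames(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)), paste0("chr", seq_along(lens)))
}

mutate_bases <- function(seq, n, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample.int(length(ch), n)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
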