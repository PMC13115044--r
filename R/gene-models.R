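#' Strand-aware gene models for insertion annotation
#'
#' A `gene_model_set` holds one representative transcript per gene: the
#' transcript span, its ordered exon intervals and (possibly empty) 5'/3' UTR
#' intervals, and the strand-aware transcription start site (TSS). All
#' coordinates are 1-based inclusive. Introns are not stored; they are the
#' gaps between consecutive stored features inside the span (see
#' [gene_introns()]).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` (+/-),
#'   `start`, `end`, `tss`.
#' @param features data.frame with columns `gene_id`,
#'   `type` (one of `five_prime_UTR`, `exon`, `three_prime_UTR`), `start`,
#'   `end`.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, features) {
  need_g <- c("gene_id", "chrom", "strand", "start", "end", "tss")
  need_f <- c("gene_id", "type", "start", "end")
  stopifnot(all(need_g %in% names(genes)), all(need_f %in% names(features)))
  genes <- genes[order(genes$gene_id), need_g, drop = FALSE]
  features <- features[order(features$gene_id, features$start), need_f,
                       drop = FALSE]
  rownames(genes) <- NULL
  rownames(features) <- NULL
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$tss <- as.integer(genes$tss)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  bad_tss <- ifelse(genes$strand == "+", genes$tss != genes$start,
                    genes$tss != genes$end)
  if (any(bad_tss)) {
    stop("TSS must equal span start on + and span end on - strand",
         call. = FALSE)
  }
  sp <- genes[match(features$gene_id, genes$gene_id), ]
  if (any(features$start < sp$start | features$end > sp$end)) {
    stop("feature interval outside its transcript span", call. = FALSE)
  }
  if (!all(features$type %in% c("five_prime_UTR", "exon", "three_prime_UTR"))) {
    stop("unknown feature type", call. = FALSE)
  }
  structure(list(genes = genes, features = features),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes on %d chromosome(s), %d features\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              nrow(x$features)))
  invisible(x)
}

#' Derive intron intervals from a gene model set
#'
#' Introns are the positions inside a transcript span not covered by any
#' stored exon or UTR interval.
#'
#' @param models A [gene_model_set()].
#' @return data.frame with columns `gene_id`, `start`, `end`.
#' @export
gene_introns <- function(models) {
  out <- vector("list", nrow(models$genes))
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    f <- models$features[models$features$gene_id == g$gene_id, ]
    f <- f[order(f$start), ]
    if (nrow(f) == 0L) next
    gaps_start <- f$end[-nrow(f)] + 1L
    gaps_end <- f$start[-1L] - 1L
    keep <- gaps_start <= gaps_end
    # also uncovered span ends (possible for UTR-less loaded models)
    lead_s <- g$start; lead_e <- f$start[1L] - 1L
    tail_s <- f$end[nrow(f)] + 1L; tail_e <- g$end
    st <- c(if (lead_s <= lead_e) lead_s, gaps_start[keep],
            if (tail_s <= tail_e) tail_s)
    en <- c(if (lead_s <= lead_e) lead_e, gaps_end[keep],
            if (tail_s <= tail_e) tail_e)
    if (length(st) > 0L) {
      out[[i]] <- data.frame(gene_id = g$gene_id, start = st, end = en,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0))
  }
  rownames(res) <- NULL
  res
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and UTR features (1-based inclusive coordinates,
#' one `<gene_id>.t1` transcript per gene). Exon features cover only the
#' non-UTR exonic intervals, mirroring the in-memory representation.
#'
#' @param models A [gene_model_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  f <- models$features
  tx_id <- paste0(g$gene_id, ".t1")
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_)
  gr_mrna <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "mRNA", ID = tx_id, Parent = g$gene_id)
  gi <- match(f$gene_id, g$gene_id)
  gr_feat <- GenomicRanges::GRanges(
    g$chrom[gi], IRanges::IRanges(f$start, f$end), strand = g$strand[gi],
    type = f$type, ID = NA_character_, Parent = tx_id[gi])
  gr <- c(gr_gene, gr_mrna, gr_feat)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 match(gr$type, c("gene", "mRNA", "five_prime_UTR", "exon",
                                  "three_prime_UTR")))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load gene models from a GFF3 file
#'
#' Keeps one representative transcript per gene (the longest mRNA; ties broken
#' by lexicographically smallest mRNA ID). Exon and UTR children of the
#' representative transcript become the stored feature intervals; introns are
#' derived as the gaps between them. Genes without UTR features simply never
#' yield UTR annotation calls (a message reports how many).
#'
#' @param path GFF3 path (1-based inclusive, gene/mRNA/exon hierarchy; UTR
#'   features optional).
#' @return A [gene_model_set()].
#' @export
load_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }, character(1))
  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  genes_gr <- gr[is_gene]
  mrna_gr <- gr[is_mrna]
  if (length(genes_gr) == 0L) stop("no gene features in ", path, call. = FALSE)
  mrna_parent <- parent_of[is_mrna]
  # representative transcript: longest, tie -> smallest ID
  m_ord <- order(mrna_parent, -GenomicRanges::width(mrna_gr),
                 as.character(mrna_gr$ID))
  keep <- m_ord[!duplicated(mrna_parent[m_ord])]
  rep_mrna <- mrna_gr[keep]
  rep_parent <- mrna_parent[keep]
  rep_id <- as.character(rep_mrna$ID)

  g_id <- as.character(genes_gr$ID)
  gi <- match(g_id, rep_parent)
  # genes without mRNA children fall back to the gene record as the span
  span_start <- ifelse(is.na(gi), GenomicRanges::start(genes_gr),
                       GenomicRanges::start(rep_mrna)[gi])
  span_end <- ifelse(is.na(gi), GenomicRanges::end(genes_gr),
                     GenomicRanges::end(rep_mrna)[gi])
  strand <- as.character(GenomicRanges::strand(genes_gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene without explicit strand in ", path, call. = FALSE)
  }
  genes <- data.frame(
    gene_id = g_id,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    strand = strand,
    start = as.integer(span_start),
    end = as.integer(span_end),
    tss = as.integer(ifelse(strand == "+", span_start, span_end)),
    stringsAsFactors = FALSE
  )

  is_feat <- type %in% c("exon", "five_prime_UTR", "three_prime_UTR")
  feat_gr <- gr[is_feat]
  feat_parent <- parent_of[is_feat]
  sel <- feat_parent %in% rep_id
  feat_gr <- feat_gr[sel]
  feat_parent <- feat_parent[sel]
  feat_gene <- rep_parent[match(feat_parent, rep_id)]
  features <- data.frame(
    gene_id = feat_gene,
    type = as.character(feat_gr$type),
    start = as.integer(GenomicRanges::start(feat_gr)),
    end = as.integer(GenomicRanges::end(feat_gr)),
    stringsAsFactors = FALSE
  )
  sp <- genes[match(features$gene_id, genes$gene_id), ]
  bad <- which(features$start < sp$start | features$end > sp$end)
  if (length(bad) > 0L) {
    stop(sprintf("feature outside its mRNA span: %s %s [%d,%d]",
                 features$gene_id[bad[1]], features$type[bad[1]],
                 features$start[bad[1]], features$end[bad[1]]),
         call. = FALSE)
  }
  no_utr <- setdiff(genes$gene_id,
                    features$gene_id[features$type != "exon"])
  if (length(no_utr) > 0L) {
    message(length(no_utr),
            " gene(s) without UTR features: UTR categories unreachable there")
  }
  gene_model_set(genes, features)
}
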