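ANNOT_CATEGORIES <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR",
                      "potential_promoter", "intergenic")

#' Classify insertion positions against gene models
#'
#' Implements the location-based annotation rule: a position inside a
#' transcript span is labelled with the matching sub-feature (5' UTR, exon or
#' 3' UTR, otherwise intron); a position outside every span but within
#' `promoter_window` bases upstream of a transcription start site
#' (strand-aware: `[TSS-w, TSS-1]` on plus, `[TSS+1, TSS+w]` on minus, with
#' the boundary inclusive at exactly `w`) is a potential promoter of the
#' nearest-TSS gene; everything else is intergenic. Overlaps resolve by
#' priority genic sub-feature > potential promoter > intergenic; among
#' overlapping genes the one with the nearest TSS wins, ties going to the
#' lexicographically smallest gene ID. Insertion strand is ignored: only the
#' position is annotated.
#'
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @param models A [gene_model_set()].
#' @param promoter_window Promoter window size in bp upstream of the TSS
#'   (default 1000).
#' @param unknown_chrom How to treat positions on chromosomes absent from the
#'   models: `"intergenic"` (default, with a warning) or `"error"`.
#' @return data.frame with columns `category`, `gene_id` (NA iff intergenic)
#'   and `distance_to_tss` (signed bp; filled for promoter calls).
#' @examples
#' genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     start = 2000L, end = 4000L, tss = 2000L)
#' feats <- data.frame(gene_id = "g1",
#'                     type = c("exon", "exon"),
#'                     start = c(2000L, 3501L), end = c(2500L, 4000L))
#' m <- gene_model_set(genes, feats)
#' classify_insertions("chr1", c(3000L, 1500L, 999L), m)
#' @export
classify_insertions <- function(chrom, pos, models, promoter_window = 1000L,
                                unknown_chrom = c("intergenic", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  stopifnot(length(chrom) == length(pos))
  n <- length(pos)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  out <- data.frame(category = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    distance_to_tss = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  known <- chrom %in% models$genes$chrom
  if (any(!known)) {
    if (unknown_chrom == "error") {
      stop("chromosome(s) absent from gene models: ",
           paste(unique(chrom[!known]), collapse = ", "), call. = FALSE)
    }
    warning("chromosome(s) absent from gene models treated as intergenic: ",
            paste(unique(chrom[!known]), collapse = ", "))
  }

  g <- models$genes
  lv <- sort(unique(c(chrom, g$chrom)))
  q <- GenomicRanges::GRanges(factor(chrom, lv), IRanges::IRanges(pos, pos))
  span <- GenomicRanges::GRanges(factor(g$chrom, lv),
                                 IRanges::IRanges(g$start, g$end))
  ov <- GenomicRanges::findOverlaps(q, span, ignore.strand = TRUE)
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    dtss <- abs(pos[qh] - g$tss[sh])
    ord <- order(qh, dtss, g$gene_id[sh])
    pick <- ord[!duplicated(qh[ord])]
    for (j in pick) {
      i <- qh[j]
      gi <- sh[j]
      out$gene_id[i] <- g$gene_id[gi]
      out$category[i] <- subfeature_category(pos[i], g$gene_id[gi], models)
      out$distance_to_tss[i] <- signed_tss_distance(pos[i], gi, g)
    }
  }

  # promoter windows, only where no genic call was made
  w <- as.integer(promoter_window)
  prom_start <- ifelse(g$strand == "+", pmax(g$tss - w, 1L), g$tss + 1L)
  prom_end <- ifelse(g$strand == "+", g$tss - 1L, g$tss + w)
  valid <- prom_start <= prom_end
  promr <- GenomicRanges::GRanges(factor(g$chrom[valid], lv),
                                  IRanges::IRanges(prom_start[valid],
                                                   prom_end[valid]))
  pidx <- which(valid)
  ovp <- GenomicRanges::findOverlaps(q, promr, ignore.strand = TRUE)
  if (length(ovp) > 0L) {
    qh <- S4Vectors::queryHits(ovp)
    sh <- pidx[S4Vectors::subjectHits(ovp)]
    open <- out$category[qh] == "intergenic"
    qh <- qh[open]; sh <- sh[open]
    if (length(qh) > 0L) {
      dtss <- abs(pos[qh] - g$tss[sh])
      ord <- order(qh, dtss, g$gene_id[sh])
      pick <- ord[!duplicated(qh[ord])]
      for (j in pick) {
        i <- qh[j]
        gi <- sh[j]
        out$category[i] <- "potential_promoter"
        out$gene_id[i] <- g$gene_id[gi]
        out$distance_to_tss[i] <- signed_tss_distance(pos[i], gi, g)
      }
    }
  }
  out
}

# Category of a position known to lie inside `gene_id`'s span.
subfeature_category <- function(p, gene_id, models) {
  f <- models$features[models$features$gene_id == gene_id, ]
  hit <- f$start <= p & p <= f$end
  if (any(hit)) f$type[which(hit)[1L]] else "intron"
}

# Signed distance to the TSS in the gene's reading direction: positive
# upstream of the TSS, negative downstream/inside.
signed_tss_distance <- function(p, gi, genes) {
  if (genes$strand[gi] == "+") genes$tss[gi] - p else p - genes$tss[gi]
}

#' Classify a single insertion
#'
#' Scalar wrapper around [classify_insertions()].
#'
#' @inheritParams classify_insertions
#' @param chrom,pos Single chromosome name and position.
#' @return A one-row data.frame (see [classify_insertions()]).
#' @export
classify_insertion <- function(chrom, pos, models, promoter_window = 1000L,
                               unknown_chrom = c("intergenic", "error")) {
  classify_insertions(chrom, pos, models, promoter_window, unknown_chrom)
}

#' Annotate mapped insertions
#'
#' Annotates every insertion with `status == "unique"`; other statuses are
#' excluded from gene assignment (they would produce unreliable candidate
#' genes) and reported in the tally attribute.
#'
#' @param insertions data.frame from [call_insertions()].
#' @param models A [gene_model_set()].
#' @param promoter_window Promoter window in bp.
#' @return data.frame with columns `barcode`, `chrom`, `pos`, `strand`,
#'   `category`, `gene_id`, `distance_to_tss`; attributes `tallies` (category
#'   counts) and `genes` (distinct gene IDs over non-intergenic calls).
#' @export
annotate_all <- function(insertions, models, promoter_window = 1000L) {
  u <- insertions[insertions$status == "unique", , drop = FALSE]
  ann <- classify_insertions(u$chrom, u$pos, models, promoter_window)
  out <- data.frame(barcode = u$barcode, chrom = u$chrom, pos = u$pos,
                    strand = u$strand, category = ann$category,
                    gene_id = ann$gene_id,
                    distance_to_tss = ann$distance_to_tss,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  tallies <- setNames(integer(length(ANNOT_CATEGORIES)), ANNOT_CATEGORIES)
  tab <- table(out$category)
  tallies[names(tab)] <- as.integer(tab)
  attr(out, "tallies") <- tallies
  attr(out, "genes") <- sort(unique(out$gene_id[!is.na(out$gene_id) &
                                                  out$category != "intergenic"]))
  out
}

#' Tally candidate genes by a user-supplied functional category table
#'
#' Joins candidate genes against a two-column gene -> functional-category
#' table and counts genes per category; genes absent from the table are
#' counted as `unannotated`.
#'
#' @param gene_ids Character vector of candidate gene IDs.
#' @param annotation data.frame with columns `gene_id` and `category`.
#' @return data.frame of `category`, `n_genes`.
#' @export
tally_gene_categories <- function(gene_ids, annotation) {
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  cat <- annotation$category[match(gene_ids, annotation$gene_id)]
  cat[is.na(cat)] <- "unannotated"
  tab <- table(cat)
  data.frame(category = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}
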