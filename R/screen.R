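#' Screening thresholds and conventions
#'
#' Parameters of the depletion/enrichment screen: the minimum CK1 read count
#' a barcode needs to enter the analysis, the strict ratio-of-ratios hit
#' thresholds, the offset added to abundance ratios, and the log2 CK2/CK1 cut
#' separating the two hit groups. Defaults follow the published screen
#' conventions: barcodes with at least 50 CK1 reads are kept, a barcode is a
#' hit when (S10/CK1)/(CK2/CK1) is strictly greater than 3 or strictly less
#' than 0.3, and 0.001 is added to ratio values before log2 transformation.
#' The same offset is also applied inside the ratio of ratios (numerator and
#' denominator) so that zero-count barcodes remain classifiable; this is an
#' extension of the plotting convention and is recorded in run metadata.
#'
#' @param min_ck1_count Minimum CK1 read count (default 50).
#' @param up_threshold,down_threshold Strict hit thresholds on the ratio of
#'   ratios (defaults 3 and 0.3).
#' @param offset Offset added to abundance ratios (default 0.001).
#' @param group_split_log2 log2(CK2/CK1 + offset) cut: enriched hits below it
#'   are group 1 (constitutive growth defect, relatively rescued in cold),
#'   depleted hits at or above it are group 2 (normal growth at room
#'   temperature, impaired specifically in cold). Default -1.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(min_ck1_count = 50L, up_threshold = 3,
                          down_threshold = 0.3, offset = 0.001,
                          group_split_log2 = -1) {
  if (!(down_threshold < 1 && 1 < up_threshold)) {
    stop("need down_threshold < 1 < up_threshold", call. = FALSE)
  }
  if (offset <= 0) stop("offset must be > 0", call. = FALSE)
  min_ck1_count <- as.integer(min_ck1_count)
  if (is.na(min_ck1_count) || min_ck1_count < 1L) {
    stop("min_ck1_count must be >= 1", call. = FALSE)
  }
  structure(list(min_ck1_count = min_ck1_count,
                 up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 offset = offset,
                 group_split_log2 = group_split_log2),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(paste0("screen_config: CK1 >= %d; hit if rr > %g or rr < %g ",
                     "(offset %g); group split log2 = %g\n"),
              x$min_ck1_count, x$up_threshold, x$down_threshold, x$offset,
              x$group_split_log2))
  invisible(x)
}

# Shared hit/group rules -- the single source of truth used both by the
# screen and by the simulator's expected noiseless classification.
hit_direction <- function(rr, config) {
  ifelse(rr > config$up_threshold, "enriched",
         ifelse(rr < config$down_threshold, "depleted", "none"))
}

classify_group <- function(direction, r_ctrl, config) {
  l2 <- log2(r_ctrl + config$offset)
  ifelse(direction == "enriched" & l2 < config$group_split_log2, "group1",
         ifelse(direction == "depleted" & l2 >= config$group_split_log2,
                "group2", "none"))
}

#' Filter barcodes on the CK1 read count
#'
#' Retains exactly the barcodes whose CK1 count is at least
#' `min_ck1_count`.
#'
#' @param matrix A `count_matrix` with a CK1 column.
#' @param config A [screen_config()].
#' @return Character vector of retained barcodes, with a `report` attribute
#'   giving retained/dropped tallies.
#' @export
filter_min_ck1 <- function(matrix, config = screen_config()) {
  if (!"CK1" %in% colnames(matrix)) {
    stop("count matrix has no CK1 column", call. = FALSE)
  }
  keep <- matrix[, "CK1"] >= config$min_ck1_count
  retained <- as.character(rownames(matrix)[keep])
  attr(retained, "report") <- c(retained = sum(keep), dropped = sum(!keep))
  retained
}

#' Compute abundance ratios per barcode
#'
#' Relative abundance is count divided by the sample's recognized-read total
#' (the `totals` attribute of the matrix). Ratios to CK1 are formed for CK2
#' (`r_ctrl`), S10 (`r_cold`) and, when present, S10R (`r_rec`); the
#' screening statistic is `rr = (r_cold + offset) / (r_ctrl + offset)`.
#'
#' @param matrix A `count_matrix` with CK1, CK2 and S10 columns (S10R
#'   optional).
#' @param retained Barcodes to keep (from [filter_min_ck1()]); defaults to
#'   all.
#' @param config A [screen_config()].
#' @return data.frame of screen records: counts, relative abundances,
#'   ratios, `rr` and log2 columns.
#' @export
compute_ratios <- function(matrix, retained = rownames(matrix),
                           config = screen_config()) {
  need <- c("CK1", "CK2", "S10")
  miss <- setdiff(need, colnames(matrix))
  if (length(miss) > 0L) {
    stop("count matrix lacks sample column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  totals <- attr(matrix, "totals")
  if (is.null(totals)) totals <- colSums(matrix)
  if (any(totals[need] == 0)) {
    stop("sample(s) with zero recognized reads: ",
         paste(need[totals[need] == 0], collapse = ", "), call. = FALSE)
  }
  stopifnot(all(retained %in% rownames(matrix)))
  m <- matrix[retained, , drop = FALSE]
  off <- config$offset
  rel <- sweep(m, 2L, totals[colnames(m)], "/")
  r_ctrl <- rel[, "CK2"] / rel[, "CK1"]
  r_cold <- rel[, "S10"] / rel[, "CK1"]
  has_rec <- "S10R" %in% colnames(m) && totals[["S10R"]] > 0
  r_rec <- if (has_rec) rel[, "S10R"] / rel[, "CK1"] else NA_real_
  rr <- (r_cold + off) / (r_ctrl + off)
  out <- data.frame(
    barcode = rownames(m),
    ck1 = m[, "CK1"], ck2 = m[, "CK2"], s10 = m[, "S10"],
    s10r = if ("S10R" %in% colnames(m)) m[, "S10R"] else NA_integer_,
    rel_ck1 = rel[, "CK1"], rel_ck2 = rel[, "CK2"], rel_s10 = rel[, "S10"],
    r_ctrl = r_ctrl, r_cold = r_cold, r_rec = r_rec,
    rr = rr,
    log2_r_ctrl = log2(r_ctrl + off),
    log2_r_cold = log2(r_cold + off),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call enrichment/depletion hits
#'
#' Strict thresholds, as printed: `rr > up_threshold` is an enriched hit,
#' `rr < down_threshold` a depleted hit; values exactly on a threshold are
#' not hits.
#'
#' @param records data.frame from [compute_ratios()].
#' @param config A [screen_config()].
#' @return `records` with `hit` (logical) and `direction`
#'   (`enriched`/`depleted`/`none`) columns.
#' @export
call_hits <- function(records, config = screen_config()) {
  records$direction <- hit_direction(records$rr, config)
  records$hit <- records$direction != "none"
  records
}

#' Assign hit barcodes to the two mutant groups
#'
#' Group 1: enriched hits whose control ratio is low
#' (`log2(r_ctrl + offset) < group_split_log2`) -- mutants with a
#' constitutive growth defect that is relatively alleviated in cold. Group
#' 2: depleted hits with a normal control ratio -- mutants that grow
#' normally at room temperature but are impaired specifically under cold.
#' Hits matching neither pattern keep group `none`.
#'
#' @param records Hit-called records from [call_hits()].
#' @param config A [screen_config()].
#' @return `records` with a `group` column (`group1`/`group2`/`none`).
#' @export
assign_group <- function(records, config = screen_config()) {
  records$group <- classify_group(records$direction, records$r_ctrl, config)
  records
}

#' Aggregate hit barcodes into gene-level candidates
#'
#' Hit barcodes with a unique, non-intergenic insertion annotation are
#' grouped by gene. Each gene call records its supporting barcodes, the
#' insertion categories involved, the per-group composition and the dominant
#' group (majority over supporting hit barcodes; ties involving group 2 go to
#' group 2 and are flagged), and membership in an optional early
#' cold-induced gene list (exact ID match).
#'
#' @param records Hit- and group-called screen records.
#' @param annotations Annotated insertions from [annotate_all()].
#' @param early_cold_list Optional character vector of early cold-induced
#'   gene IDs.
#' @return data.frame of gene calls with a `summary` attribute (hit counts,
#'   mapped hit counts, candidate genes, overlap size).
#' @export
aggregate_by_gene <- function(records, annotations, early_cold_list = NULL) {
  hits <- records[records$hit, , drop = FALSE]
  ann <- annotations[!is.na(annotations$gene_id) &
                       annotations$category != "intergenic", , drop = FALSE]
  merged <- merge(hits, ann[, c("barcode", "category", "gene_id")],
                  by = "barcode")
  genes <- sort(unique(merged$gene_id))
  rows <- lapply(genes, function(g) {
    sub <- merged[merged$gene_id == g, , drop = FALSE]
    tab <- c(group1 = sum(sub$group == "group1"),
             group2 = sum(sub$group == "group2"),
             none = sum(sub$group == "none"))
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1L
    dominant <- if (tie && "group2" %in% top) "group2" else top[1L]
    data.frame(
      gene_id = g,
      n_barcodes = nrow(sub),
      barcodes = paste(sort(sub$barcode), collapse = ","),
      n_group1 = tab[["group1"]], n_group2 = tab[["group2"]],
      n_ungrouped = tab[["none"]],
      dominant_group = dominant,
      group_tie = tie,
      categories = paste(sort(unique(sub$category)), collapse = ","),
      in_early_cold_list = g %in% early_cold_list,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    gene_id = character(0), n_barcodes = integer(0), barcodes = character(0),
    n_group1 = integer(0), n_group2 = integer(0), n_ungrouped = integer(0),
    dominant_group = character(0), group_tie = logical(0),
    categories = character(0), in_early_cold_list = logical(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_hit_barcodes = sum(records$hit),
    n_mapped_hit_barcodes = length(unique(merged$barcode)),
    n_candidate_genes = length(genes),
    n_early_cold_overlap = sum(out$in_early_cold_list))
  out
}

#' Scatter-plot table of control vs cold log2 ratios
#'
#' One row per retained barcode with the offset log2 ratios used for
#' plotting, plus hit/direction/group flags and an optional highlight set.
#'
#' @param records Screen records (ratios computed; hit/group columns used if
#'   present).
#' @param highlight Optional character vector of barcodes to flag.
#' @return data.frame with columns `barcode`, `x` (log2 CK2/CK1 + offset),
#'   `y` (log2 S10/CK1 + offset), `hit`, `direction`, `group`, `highlight`.
#' @export
scatter_table <- function(records, highlight = NULL) {
  data.frame(
    barcode = records$barcode,
    x = records$log2_r_ctrl,
    y = records$log2_r_cold,
    hit = if ("hit" %in% names(records)) records$hit else NA,
    direction = if ("direction" %in% names(records)) records$direction
                else NA_character_,
    group = if ("group" %in% names(records)) records$group
            else NA_character_,
    highlight = records$barcode %in% highlight,
    stringsAsFactors = FALSE)
}

#' Run the complete screen on a count matrix
#'
#' Applies the CK1 filter, computes ratios, calls hits and groups, and (when
#' annotations are supplied) aggregates candidates by gene.
#'
#' @param matrix A `count_matrix`.
#' @param config A [screen_config()].
#' @param annotations Optional annotated insertions from [annotate_all()].
#' @param early_cold_list Optional character vector of gene IDs.
#' @return List with `records`, `genes` (NULL without annotations) and
#'   `summary` (named list of tallies and the parameters used, including the
#'   offset-inside-rr convention flag).
#' @export
screen_counts <- function(matrix, config = screen_config(),
                          annotations = NULL, early_cold_list = NULL) {
  retained <- filter_min_ck1(matrix, config)
  rec <- compute_ratios(matrix, retained, config)
  rec <- call_hits(rec, config)
  rec <- assign_group(rec, config)
  genes <- NULL
  gene_summary <- list(n_mapped_hit_barcodes = NA_integer_,
                       n_candidate_genes = NA_integer_,
                       n_early_cold_overlap = NA_integer_)
  if (!is.null(annotations)) {
    genes <- aggregate_by_gene(rec, annotations, early_cold_list)
    gs <- attr(genes, "summary")
    gene_summary <- gs[c("n_mapped_hit_barcodes", "n_candidate_genes",
                         "n_early_cold_overlap")]
  }
  summary <- c(
    list(n_barcodes = nrow(matrix),
         n_retained = length(retained),
         n_hits = sum(rec$hit),
         n_enriched = sum(rec$direction == "enriched"),
         n_depleted = sum(rec$direction == "depleted"),
         n_group1 = sum(rec$group == "group1"),
         n_group2 = sum(rec$group == "group2"),
         n_hits_ungrouped = sum(rec$hit & rec$group == "none")),
    gene_summary,
    list(parameters = c(unclass(config),
                        list(offset_inside_rr = TRUE,
                             normalization = "recognized_read_totals"))))
  list(records = rec, genes = genes, summary = summary)
}
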