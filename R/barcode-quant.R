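#' Extract cassette barcodes from reads
#'
#' Locates the upstream anchor in each read (best-scoring occurrence,
#' leftmost on ties, allowing up to `max_anchor_mismatches` substitutions) and
#' returns the `barcode_len` bases that follow. A call is rejected when the
#' anchor is absent (`anchor_missing`), when the barcode window runs off the
#' read or the read is empty (`truncated`), when the barcode contains a
#' non-A/C/G/T base (`ambiguous_base`), or when the read is long enough to
#' contain the downstream anchor but that anchor does not match within
#' tolerance (`anchor_missing`). Quality strings are ignored: the fixed
#' architecture (two anchors plus fixed barcode length) already constrains
#' calls.
#'
#' @param reads Character vector of read sequences.
#' @param spec A [cassette_spec()].
#' @return data.frame with columns `barcode` (NA on no-call) and `reason`
#'   (`ok`, `anchor_missing`, `ambiguous_base`, `truncated`).
#' @examples
#' spec <- cassette_spec()
#' read <- paste0(spec$upstream_anchor, strrep("ACGT", 5), "AC",
#'                spec$downstream_anchor)
#' extract_barcodes(read, spec)
#' @export
extract_barcodes <- function(reads, spec) {
  stopifnot(inherits(spec, "cassette_spec"))
  n <- length(reads)
  reason <- rep("anchor_missing", n)
  barcode <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(barcode = barcode, reason = character(0),
                      stringsAsFactors = FALSE))
  }
  up <- spec$upstream_anchor
  down <- spec$downstream_anchor
  alen <- nchar(up)
  dlen <- nchar(down)
  blen <- spec$barcode_len
  len <- nchar(reads)

  reason[len == 0L] <- "truncated"

  # anchor location: exact-match fast path, Hamming scan for the rest
  pos <- rep(NA_integer_, n)
  hit <- regexpr(up, reads, fixed = TRUE)
  pos[hit > 0L] <- hit[hit > 0L]
  if (spec$max_anchor_mismatches > 0L) {
    todo <- which(is.na(pos) & len >= alen)
    for (i in todo) {
      pos[i] <- scan_anchor(reads[i], up, spec$max_anchor_mismatches)
    }
  }

  found <- which(!is.na(pos))
  bstart <- pos[found] + alen
  bend <- bstart + blen - 1L
  trunc <- bend > len[found]
  reason[found[trunc]] <- "truncated"
  ok <- found[!trunc]
  bc <- substr(reads[ok], bstart[!trunc], bend[!trunc])
  ambig <- grepl("[^ACGT]", bc)
  reason[ok[ambig]] <- "ambiguous_base"
  ok <- ok[!ambig]
  bc <- bc[!ambig]

  # downstream anchor check, only where the read is long enough to hold it
  dstart <- pos[ok] + alen + blen
  dend <- dstart + dlen - 1L
  checkable <- dend <= len[ok]
  sub <- substr(reads[ok[checkable]], dstart[checkable], dend[checkable])
  pass <- sub == down
  if (any(!pass) && spec$max_anchor_mismatches > 0L) {
    mm_idx <- which(!pass)
    pass[mm_idx] <- vapply(sub[mm_idx], function(s) {
      hamming(s, down) <= spec$max_anchor_mismatches
    }, logical(1), USE.NAMES = FALSE)
  }
  fail_dn <- ok[checkable][!pass]
  reason[fail_dn] <- "anchor_missing"
  keep <- setdiff(ok, fail_dn)
  barcode[keep] <- bc[match(keep, ok)]
  reason[keep] <- "ok"
  data.frame(barcode = barcode, reason = reason, stringsAsFactors = FALSE)
}

# Best-scoring (fewest mismatches) leftmost anchor offset, or NA if no offset
# reaches max_mm; ties go to the smaller offset.
scan_anchor <- function(read, anchor, max_mm) {
  ra <- charToRaw(read)
  aa <- charToRaw(anchor)
  A <- length(aa)
  L <- length(ra)
  if (L < A) return(NA_integer_)
  best <- A + 1L
  best_pos <- NA_integer_
  for (o in 0:(L - A)) {
    mm <- sum(ra[(o + 1L):(o + A)] != aa)
    if (mm < best) {
      best <- mm
      best_pos <- o + 1L
      if (best == 0L) break
    }
  }
  if (best <= max_mm) best_pos else NA_integer_
}

#' Extract a single barcode
#'
#' Scalar convenience wrapper around [extract_barcodes()].
#'
#' @inheritParams extract_barcodes
#' @param read A single read sequence.
#' @return A list with `barcode` (NA on no-call) and `reason`.
#' @export
extract_barcode <- function(read, spec) {
  res <- extract_barcodes(read, spec)
  list(barcode = res$barcode[1L], reason = res$reason[1L])
}

#' Count barcodes in one sample's FASTQ
#'
#' @param fastq_path Path to a (possibly gzipped) barcode-PCR FASTQ.
#' @param spec A [cassette_spec()].
#' @param sample_label Sample name (e.g. "CK1").
#' @return An object of class `barcode_counts`: list with `sample`, `counts`
#'   (named integer vector, lexicographic barcode order) and `report`
#'   (`total`, `recognized` and a no-call tally by reason;
#'   recognized + no-calls always equals total).
#' @export
count_sample <- function(fastq_path, spec, sample_label) {
  fq <- read_fastq(fastq_path)
  res <- extract_barcodes(fq$seq, spec)
  calls <- res$barcode[res$reason == "ok"]
  if (length(calls) > 0L) {
    counts <- table(calls)
    counts <- setNames(as.integer(counts), names(counts))
    counts <- counts[order(names(counts))]
  } else {
    counts <- setNames(integer(0), character(0))
  }
  nocall <- c(anchor_missing = sum(res$reason == "anchor_missing"),
              ambiguous_base = sum(res$reason == "ambiguous_base"),
              truncated = sum(res$reason == "truncated"))
  structure(
    list(sample = sample_label,
         counts = counts,
         report = list(total = length(fq$seq),
                       recognized = length(calls),
                       no_call = nocall)),
    class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf("barcode_counts [%s]: %d reads, %d recognized, %d barcodes\n",
              x$sample, x$report$total, x$report$recognized,
              length(x$counts)))
  invisible(x)
}

#' Build a barcode x sample count matrix
#'
#' Rows are the union of barcodes across samples in lexicographic order;
#' missing (barcode, sample) pairs are zero. Per-sample recognized-read
#' totals (the column sums) are kept as the `totals` attribute and are the
#' denominators of all relative abundances downstream.
#'
#' @param sample_counts List of [count_sample()] results (or named integer
#'   vectors, in which case names of the list are the sample labels).
#' @return Integer matrix of class `count_matrix` with attributes `totals`
#'   and `reports`.
#' @export
build_count_matrix <- function(sample_counts) {
  if (length(sample_counts) == 0L) stop("need at least one sample", call. = FALSE)
  labels <- vapply(seq_along(sample_counts), function(i) {
    x <- sample_counts[[i]]
    if (inherits(x, "barcode_counts")) x$sample else names(sample_counts)[i]
  }, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate sample labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  vecs <- lapply(sample_counts, function(x) {
    if (inherits(x, "barcode_counts")) x$counts else x
  })
  barcodes <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0L, nrow = length(barcodes), ncol = length(labels),
              dimnames = list(barcodes, labels))
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    m[names(v), i] <- as.integer(v)
  }
  reports <- lapply(sample_counts, function(x) {
    if (inherits(x, "barcode_counts")) x$report else NULL
  })
  names(reports) <- labels
  structure(m, totals = colSums(m), reports = reports,
            class = c("count_matrix", class(m)))
}

#' Optional directional collapse of sequencing-error barcodes
#'
#' Merges a barcode into a Hamming-distance-1 neighbour whose total count is
#' at least `ratio` times larger (the directional rule commonly used for
#' error-correcting amplicon barcodes). Off by default in the pipeline: the
#' screen statistic does not require it, and an aggressive collapse can merge
#' genuinely distinct mutants.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param ratio Minimum count ratio parent/child for a merge (default 10).
#' @return A `count_matrix` with merged rows.
#' @export
collapse_barcodes <- function(matrix, ratio = 10) {
  totals_row <- rowSums(matrix)
  ord <- order(-totals_row, rownames(matrix))
  bcs <- rownames(matrix)[ord]
  parent <- setNames(bcs, bcs)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (b in bcs) {
    # probe all Hamming-1 neighbours of b among already-accepted parents
    ch <- strsplit(b, "", fixed = TRUE)[[1L]]
    merged <- FALSE
    for (p in seq_along(ch)) {
      for (base in setdiff(DNA_BASES, ch[p])) {
        nb <- ch; nb[p] <- base
        nbs <- paste(nb, collapse = "")
        if (!is.null(seen[[nbs]]) &&
            totals_row[nbs] >= ratio * totals_row[b]) {
          parent[b] <- parent[nbs]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) seen[[b]] <- TRUE
  }
  grp <- parent[rownames(matrix)]
  agg <- rowsum(matrix + 0L, group = grp)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  storage.mode(agg) <- "integer"
  structure(agg, totals = colSums(agg), reports = attr(matrix, "reports"),
            class = c("count_matrix", class(agg)))
}

#' Write / read a count matrix as TSV
#'
#' First column `barcode`, one integer column per sample. Totals are the
#' column sums and are recomputed on read.
#'
#' @param matrix A `count_matrix`.
#' @param path File path.
#' @return `write_count_matrix` returns the path invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(matrix, path) {
  df <- data.frame(barcode = rownames(matrix), matrix + 0L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  structure(m, totals = colSums(m), reports = NULL,
            class = c("count_matrix", class(m)))
}

#' Write per-sample extraction reports as TSV
#'
#' @param matrix A `count_matrix` built by [build_count_matrix()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_extraction_report <- function(matrix, path) {
  reports <- attr(matrix, "reports")
  rows <- lapply(names(reports), function(s) {
    r <- reports[[s]]
    if (is.null(r)) return(NULL)
    data.frame(sample = s, total = r$total, recognized = r$recognized,
               anchor_missing = r$no_call[["anchor_missing"]],
               ambiguous_base = r$no_call[["ambiguous_base"]],
               truncated = r$no_call[["truncated"]],
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
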