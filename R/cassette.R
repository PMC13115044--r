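#' Cassette architecture for barcode extraction
#'
#' Describes the fixed read architecture of barcode-PCR amplicons: an upstream
#' anchor (cassette sequence immediately 5' of the barcode), a fixed-length
#' barcode, and a downstream anchor. The anchors are properties of the
#' transformation cassette used to build the mutant library and are fully
#' configurable; the defaults are arbitrary synthetic sequences used by the
#' simulator.
#'
#' @param upstream_anchor,downstream_anchor Anchor sequences flanking the
#'   barcode within a read (each at least 8 bases).
#' @param barcode_len Barcode length in bases (>= 8).
#' @param max_anchor_mismatches Maximum substitutions tolerated when locating
#'   an anchor (default 1).
#' @return An object of class `cassette_spec`.
#' @examples
#' spec <- cassette_spec()
#' spec$barcode_len
#' @export
cassette_spec <- function(upstream_anchor = "GTCGACGGTACCGAGCTC",
                          downstream_anchor = "GGATCCACTAGTTCTAGA",
                          barcode_len = 22L,
                          max_anchor_mismatches = 1L) {
  upstream_anchor <- toupper(upstream_anchor)
  downstream_anchor <- toupper(downstream_anchor)
  if (nchar(upstream_anchor) < 8L || nchar(downstream_anchor) < 8L) {
    stop("anchors must be at least 8 bases long", call. = FALSE)
  }
  if (grepl("[^ACGT]", upstream_anchor) || grepl("[^ACGT]", downstream_anchor)) {
    stop("anchors must contain only A/C/G/T", call. = FALSE)
  }
  barcode_len <- as.integer(barcode_len)
  if (is.na(barcode_len) || barcode_len < 8L) {
    stop("barcode_len must be an integer >= 8", call. = FALSE)
  }
  max_anchor_mismatches <- as.integer(max_anchor_mismatches)
  if (is.na(max_anchor_mismatches) || max_anchor_mismatches < 0L) {
    stop("max_anchor_mismatches must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(upstream_anchor = upstream_anchor,
         downstream_anchor = downstream_anchor,
         barcode_len = barcode_len,
         max_anchor_mismatches = max_anchor_mismatches),
    class = "cassette_spec"
  )
}

#' @export
print.cassette_spec <- function(x, ...) {
  cat("cassette_spec:",
      sprintf("%s-[%dbp barcode]-%s (<=%d anchor mismatches)\n",
              x$upstream_anchor, x$barcode_len, x$downstream_anchor,
              x$max_anchor_mismatches))
  invisible(x)
}
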