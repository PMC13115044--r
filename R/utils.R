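#' @importFrom stats rbinom rmultinom runif setNames median
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom methods is
#' @importFrom data.table := .N .SD data.table rbindlist setkey setnames
#'   setorder fifelse
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences (A/C/G/T, possibly N).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a deterministic RNG stream derived from `seed + offset`,
# restoring the caller's RNG state afterwards. Keeps every operation
# independently reproducible from a config seed.
with_seed_offset <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) + as.integer(offset))
  force(code)
}

# Hamming distance between two equal-length strings (byte comparison).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

#' Read a FASTQ file
#'
#' Reads a (possibly gzip-compressed) 4-line FASTQ file and validates record
#' structure; malformed records are reported by record index.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A list with character vectors `id`, `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d", path,
                 length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(id = character(0), seq = character(0), qual = character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ '%s': record %d", path, bad[1L]), call. = FALSE)
  }
  list(id = sub("^@", "", hdr), seq = seq, qual = qual)
}

#' Write a FASTQ file
#'
#' @param id,seq Character vectors of read identifiers and sequences.
#' @param path Output path.
#' @param qual Optional quality strings; defaults to constant Phred+33 'I'
#'   (Q40) of the appropriate length.
#' @return The path, invisibly.
#' @export
write_fastq <- function(id, seq, path, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (is.null(qual)) {
    qual <- vapply(nchar(seq), function(L) strrep("I", L), character(1))
  }
  rec <- as.vector(rbind(paste0("@", id), seq, "+", qual))
  writeLines(rec, path)
  invisible(path)
}

# Stable integer formatting for TSV outputs.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA", ...)
}
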