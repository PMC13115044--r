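#' Configuration of a synthetic pooled screen
#'
#' Defines every parameter of the synthetic screen: reference genome geometry,
#' mutant library size, fitness classes, the population doublings separating
#' the four screen samples (initial pool CK1, room-temperature control CK2,
#' cold-stressed S10, post-cold recovery S10R), sequencing depths and the
#' per-base substitution error rate. Fitness is relative: 1 is neutral growth,
#' values below 1 slow a mutant down by `2^(f * g)` over `g` population
#' doublings.
#'
#' The defaults describe the study conditions the package is validated under:
#' a compact two-chromosome genome dense in gene models, a 500-mutant library
#' with 5% cold-sensitive mutants (near-neutral at room temperature, fitness
#' 0.05-0.30 in cold), 5% constitutively slow mutants (the mirror image), four
#' control doublings, six cold doublings, and 2e5 barcode reads per sample.
#'
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bases (same for every chromosome).
#' @param n_genes Number of gene models to place, spread across chromosomes.
#' @param n_mutants Number of barcoded mutants in the pool.
#' @param barcode_len Barcode length in bases (>= 8).
#' @param frac_cold_sensitive,frac_constitutive Fractions of the library in
#'   each non-neutral fitness class; must sum to at most 1.
#' @param fitness_ranges Named list with elements `neutral`, `cold_sensitive`
#'   and `constitutive`, each a list with `ctrl` and `cold` length-2 ranges
#'   from which per-mutant fitnesses are drawn uniformly.
#' @param g_ctrl,g_cold,g_rec Population doublings for CK1->CK2, CK1->S10 and
#'   S10->S10R respectively.
#' @param depth_per_sample Barcode-PCR reads per sample.
#' @param leap_depth Read pairs per flanking-sequence library (CK1 and S10R).
#' @param flank_len Bases of genomic flank carried by the genomic mate.
#' @param subst_error_rate Per-base substitution probability applied to reads.
#' @param gene_len_range Length-2 range of gene-model lengths in bases.
#' @param early_cold_frac Fraction of genes marked as early cold-induced when
#'   the simulator emits a reference gene list.
#' @param cassette A [cassette_spec()] describing read architecture.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_mutants = 50, depth_per_sample = 1000)
#' cfg$g_cold
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 150000L,
                       n_genes = 40L,
                       n_mutants = 500L,
                       barcode_len = 22L,
                       frac_cold_sensitive = 0.05,
                       frac_constitutive = 0.05,
                       fitness_ranges = default_fitness_ranges(),
                       g_ctrl = 4,
                       g_cold = 6,
                       g_rec = 4,
                       depth_per_sample = 200000L,
                       leap_depth = 20000L,
                       flank_len = 60L,
                       subst_error_rate = 0.001,
                       gene_len_range = c(1200L, 2800L),
                       early_cold_frac = 0.2,
                       cassette = cassette_spec(barcode_len = barcode_len)) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
    n_mutants = as.integer(n_mutants), barcode_len = as.integer(barcode_len),
    frac_cold_sensitive = frac_cold_sensitive,
    frac_constitutive = frac_constitutive,
    fitness_ranges = fitness_ranges,
    g_ctrl = g_ctrl, g_cold = g_cold, g_rec = g_rec,
    depth_per_sample = as.integer(depth_per_sample),
    leap_depth = as.integer(leap_depth),
    flank_len = as.integer(flank_len),
    subst_error_rate = subst_error_rate,
    gene_len_range = as.integer(gene_len_range),
    early_cold_frac = early_cold_frac,
    cassette = cassette
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default fitness ranges for the three mutant classes
#'
#' Cold-sensitive mutants are near-neutral at room temperature and severely
#' impaired in cold; constitutive mutants are the mirror image (slow at room
#' temperature, near-neutral in cold), modelling mutants whose relative
#' abundance rises under cold because the rest of the pool outgrows them only
#' at room temperature.
#'
#' @return Named list of per-class `ctrl`/`cold` fitness ranges.
#' @export
default_fitness_ranges <- function() {
  list(
    neutral        = list(ctrl = c(1, 1),       cold = c(1, 1)),
    cold_sensitive = list(ctrl = c(0.95, 1.05), cold = c(0.05, 0.3)),
    constitutive   = list(ctrl = c(0.05, 0.3),  cold = c(0.95, 1.05))
  )
}

validate_sim_config <- function(cfg) {
  ok_frac <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!ok_frac(cfg$frac_cold_sensitive) || !ok_frac(cfg$frac_constitutive)) {
    stop("class fractions must be single numbers in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_cold_sensitive + cfg$frac_constitutive > 1 + 1e-12) {
    stop("frac_cold_sensitive + frac_constitutive must not exceed 1",
         call. = FALSE)
  }
  if (cfg$barcode_len < 8L) stop("barcode_len must be >= 8", call. = FALSE)
  if (cfg$depth_per_sample < 1L) stop("depth_per_sample must be >= 1", call. = FALSE)
  if (cfg$leap_depth < 1L) stop("leap_depth must be >= 1", call. = FALSE)
  if (cfg$n_chrom < 1L || cfg$chrom_len < 1000L) {
    stop("need n_chrom >= 1 and chrom_len >= 1000", call. = FALSE)
  }
  if (cfg$flank_len < 20L) stop("flank_len must be >= 20", call. = FALSE)
  if (cfg$subst_error_rate < 0 || cfg$subst_error_rate >= 1) {
    stop("subst_error_rate must be in [0, 1)", call. = FALSE)
  }
  if (length(cfg$gene_len_range) != 2L || cfg$gene_len_range[1] > cfg$gene_len_range[2]) {
    stop("gene_len_range must be an increasing length-2 range", call. = FALSE)
  }
  if (cfg$gene_len_range[1] < 1000L) {
    stop("gene_len_range minimum must be >= 1000 to fit UTRs and >= 2 exons",
         call. = FALSE)
  }
  for (cls in c("neutral", "cold_sensitive", "constitutive")) {
    rg <- cfg$fitness_ranges[[cls]]
    if (is.null(rg$ctrl) || is.null(rg$cold)) {
      stop("fitness_ranges$", cls, " must have 'ctrl' and 'cold' ranges",
           call. = FALSE)
    }
    if (any(unlist(rg) < 0)) {
      stop("fitness values must be non-negative (class ", cls, ")",
           call. = FALSE)
    }
  }
  # Packing feasibility: the most loaded chromosome must hold its genes with
  # at least a 1 bp gap between consecutive genes.
  per_chrom <- genes_per_chrom(cfg$n_genes, cfg$n_chrom)
  need <- max(per_chrom) * cfg$gene_len_range[2] + max(max(per_chrom) - 1L, 0L)
  if (need > cfg$chrom_len) {
    stop(sprintf(paste0("cannot place %d genes of up to %d bp on a %d bp ",
                        "chromosome: reduce n_genes or gene_len_range, or ",
                        "increase chrom_len"),
                 max(per_chrom), cfg$gene_len_range[2], cfg$chrom_len),
         call. = FALSE)
  }
  if (cfg$barcode_len * log(4) < log(cfg$n_mutants)) {
    stop("barcode space exhausted: 4^barcode_len < n_mutants", call. = FALSE)
  }
  invisible(cfg)
}

genes_per_chrom <- function(n_genes, n_chrom) {
  base <- n_genes %/% n_chrom
  extra <- n_genes %% n_chrom
  as.integer(base + (seq_len(n_chrom) <= extra))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d chrom x %d bp, %d genes, %d mutants ",
                     "(%.0f%% cold-sensitive, %.0f%% constitutive)\n",
                     "  doublings ctrl/cold/rec = %g/%g/%g; depth %d; ",
                     "leap depth %d; error %g; seed %d\n"),
              x$n_chrom, x$chrom_len, x$n_genes, x$n_mutants,
              100 * x$frac_cold_sensitive, 100 * x$frac_constitutive,
              x$g_ctrl, x$g_cold, x$g_rec, x$depth_per_sample,
              x$leap_depth, x$subst_error_rate, x$seed))
  invisible(x)
}

#' Write / read a simulation config as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config` returns the path invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$cassette <- unclass(x$cassette)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  cas <- do.call(cassette_spec, x$cassette)
  x$cassette <- NULL
  x$fitness_ranges <- lapply(x$fitness_ranges, function(r) {
    list(ctrl = as.numeric(r$ctrl), cold = as.numeric(r$cold))
  })
  do.call(sim_config, c(x, list(cassette = cas)))
}
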