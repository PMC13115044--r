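PIPELINE_STAGES <- c("simulate", "count", "map", "annotate", "screen")

#' Default pipeline configuration
#'
#' Nested per-stage configuration for [run_pipeline()]: `sim` holds
#' [sim_config()] arguments, `cassette` holds [cassette_spec()] arguments,
#' `map` holds [map_params()] arguments, `annotate` the promoter window and
#' `screen` the [screen_config()] arguments. `early_cold_list` may name a
#' gene-list file; the synthetic run writes one itself.
#'
#' @param seed Integer seed propagated to the simulator.
#' @return Nested named list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),
    cassette = list(),
    map = list(),
    annotate = list(promoter_window = 1000L),
    screen = list(),
    early_cold_list = NULL
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config Nested list as from [default_pipeline_config()].
#' @return `read_pipeline_config` returns the config list merged over
#'   defaults; `write_pipeline_config` returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = user$seed %||% 1L)
  for (k in names(user)) base[[k]] <- modify_defaults(base[[k]], user[[k]])
  base
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modify_defaults <- function(base, user) {
  if (!is.list(user) || !is.list(base)) return(user)
  for (k in names(user)) base[[k]] <- modify_defaults(base[[k]], user[[k]])
  base
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the screen pipeline end to end
#'
#' Runs the requested stages in dependency order against `outdir`:
#' \describe{
#'   \item{simulate}{generate reference, library, truth and FASTQ reads}
#'   \item{count}{extract barcodes from each sample FASTQ and build the
#'     count matrix (`counts.tsv`, `extraction_report.tsv`)}
#'   \item{map}{index the genome and call one insertion locus per barcode
#'     from the paired flanking reads (`insertions.tsv`)}
#'   \item{annotate}{classify unique insertions against the gene models
#'     (`annotations.tsv`)}
#'   \item{screen}{CK1 filter, ratios, hits, groups, gene aggregation
#'     (`screen.tsv`, `gene_calls.tsv`, `scatter.tsv`, `summary.json`)}
#' }
#' Every stage reads only files, so downstream stages can be re-run in
#' isolation and reproduce their outputs exactly. A run manifest
#' (`manifest.json`) is written last with the full parameter snapshot, input
#' file digests, per-stage tallies, package version and seed.
#'
#' @param config A nested config list ([default_pipeline_config()]) or a
#'   path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run (default all, in order).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir, stages = PIPELINE_STAGES) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cas <- do.call(cassette_spec, config$cassette %||% list())
  sim_args <- config$sim %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  sim_args$cassette <- cas
  scfg <- do.call(sim_config, sim_args)
  mpar <- do.call(map_params, config$map %||% list())
  sccfg <- do.call(screen_config, config$screen %||% list())
  tallies <- list()

  path <- function(...) file.path(outdir, ...)
  need <- function(p, stage) {
    if (!file.exists(p)) {
      stop(sprintf("[%s] required input missing: %s", stage, p),
           call. = FALSE)
    }
    p
  }

  if ("simulate" %in% stages) {
    stage_log("simulate", "generating synthetic screen (seed ", scfg$seed, ")")
    sim <- simulate_screen(scfg, outdir)
    tallies$simulate <- list(n_mutants = nrow(sim$truth),
                             n_genes = nrow(sim$models$genes),
                             reads_per_sample = scfg$depth_per_sample)
    stage_log("simulate", nrow(sim$truth), " mutants, ",
              nrow(sim$models$genes), " genes")
  }

  if ("count" %in% stages) {
    fq <- setNames(path("fastq", paste0(SAMPLES, ".fastq")), SAMPLES)
    present <- SAMPLES[file.exists(fq)]
    need(fq[["CK1"]], "count")
    counts <- lapply(present, function(s) {
      stage_log("count", "counting ", s)
      count_sample(fq[[s]], cas, s)
    })
    cm <- build_count_matrix(counts)
    write_count_matrix(cm, path("counts.tsv"))
    write_extraction_report(cm, path("extraction_report.tsv"))
    tallies$count <- list(n_barcodes = nrow(cm),
                          recognized = as.list(attr(cm, "totals")))
    stage_log("count", nrow(cm), " distinct barcodes across ",
              length(present), " samples")
  }

  if ("map" %in% stages) {
    fasta <- need(path("genome.fasta"), "map")
    genome <- as_genome_chr(fasta)
    stage_log("map", "indexing genome (k = ", mpar$k, ")")
    idx <- build_kmer_index(genome, mpar$k)
    recs <- list()
    for (s in c("CK1", "S10R")) {
      r1 <- path("fastq", paste0(s, "_leap_R1.fastq"))
      r2 <- path("fastq", paste0(s, "_leap_R2.fastq"))
      if (!file.exists(r1)) next
      need(r2, "map")
      stage_log("map", "pairing ", s)
      recs[[s]] <- associate_pairs(r1, r2, cas, s)
    }
    if (length(recs) == 0L) {
      stop("[map] no flanking-read FASTQ pairs found under ",
           path("fastq"), call. = FALSE)
    }
    rec <- do.call(rbind, recs)
    stage_log("map", "calling insertions from ", nrow(rec), " pairs")
    ins <- call_insertions(rec, idx, genome, mpar)
    write_insertions(ins, path("insertions.tsv"))
    write_insertions_bed(ins, path("insertions.bed"))
    tallies$map <- list(n_pairs = nrow(rec),
                        status = as.list(table(ins$status)))
    stage_log("map", sum(ins$status == "unique"), "/", nrow(ins),
              " barcodes uniquely mapped")
  }

  if ("annotate" %in% stages) {
    models <- load_gff3(need(path("genes.gff3"), "annotate"))
    ins <- read_tsv(need(path("insertions.tsv"), "annotate"))
    ann <- annotate_all(ins, models,
                        config$annotate$promoter_window %||% 1000L)
    write_tsv(ann, path("annotations.tsv"))
    tallies$annotate <- list(tallies = as.list(attr(ann, "tallies")),
                             n_genes = length(attr(ann, "genes")))
    stage_log("annotate", nrow(ann), " unique insertions annotated, ",
              length(attr(ann, "genes")), " genes touched")
  }

  if ("screen" %in% stages) {
    cm <- read_count_matrix(need(path("counts.tsv"), "screen"))
    if (!"CK1" %in% colnames(cm)) {
      stop("[screen] count matrix has no CK1 column", call. = FALSE)
    }
    ann <- if (file.exists(path("annotations.tsv"))) {
      read_tsv(path("annotations.tsv"))
    } else {
      NULL
    }
    early <- NULL
    early_path <- config$early_cold_list %||% path("early_cold_genes.txt")
    if (file.exists(early_path)) early <- readLines(early_path)
    res <- screen_counts(cm, sccfg, annotations = ann,
                         early_cold_list = early)
    write_tsv(res$records, path("screen.tsv"))
    if (!is.null(res$genes)) write_tsv(res$genes, path("gene_calls.tsv"))
    write_tsv(scatter_table(res$records), path("scatter.tsv"))
    jsonlite::write_json(res$summary, path("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tallies$screen <- res$summary[c("n_retained", "n_hits", "n_group1",
                                    "n_group2", "n_candidate_genes",
                                    "n_early_cold_overlap")]
    stage_log("screen", res$summary$n_retained, " retained, ",
              res$summary$n_hits, " hits")
  }

  manifest <- list(
    package = "coldscreen",
    version = as.character(packageVersion("coldscreen")),
    seed = scfg$seed,
    stages_run = stages,
    parameters = list(
      sim = serializable_config(scfg),
      map = mpar,
      annotate = list(promoter_window =
                        config$annotate$promoter_window %||% 1000L),
      screen = unclass(sccfg)),
    tallies = tallies,
    input_digests = file_digests(outdir)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

serializable_config <- function(cfg) {
  x <- unclass(cfg)
  x$cassette <- unclass(x$cassette)
  x
}

file_digests <- function(outdir) {
  files <- c("genome.fasta", "genes.gff3", "counts.tsv", "insertions.tsv",
             "annotations.tsv", "truth.tsv")
  files <- files[file.exists(file.path(outdir, files))]
  setNames(as.list(unname(tools::md5sum(file.path(outdir, files)))), files)
}
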