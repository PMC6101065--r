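#' Pipeline configuration
#'
#' Aggregates the per-stage parameters. All randomness in the pipeline (the
#' polishing position draws) flows from the single \code{seed}.
#'
#' @param k counting word length (default 30).
#' @param canonical canonical k-mer counting (default \code{TRUE}).
#' @param base_freq per-copy k-mer depth; \code{NULL} (default) estimates it
#'   from the k-mer frequency histogram (\code{\link{estimate_base_freq}}).
#' @param high_multiplier,mid_multiplier tier cutoffs as multiples of
#'   \code{base_freq} (defaults 10 and 3; see
#'   \code{\link{selection_params}}).
#' @param recruit run the recruitment stage (default \code{TRUE}); disabling
#'   both \code{recruit} and \code{polish} reduces the pipeline to the
#'   frequent-k-mer-only baseline.
#' @param min_score,seed_len,recruit_rounds recruitment controls (defaults
#'   \code{k - 5}, 12, 1; see \code{\link{recruitment_params}}).
#' @param polish run the polishing stage (default \code{TRUE}).
#' @param h,n_trials,edit_dist,n_partitions polishing controls (see
#'   \code{\link{polish_params}}).
#' @param assembly_k de Bruijn word length (default \code{k - 5}).
#' @param min_overlap,max_overlap_mismatch,min_output_len contig merging
#'   controls (defaults 10, 1, \code{2 * k}; see \code{\link{merge_params}}).
#' @param sim_threshold clustering similarity threshold (default 0.85).
#' @param seed master RNG seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(k = 30, canonical = TRUE, base_freq = NULL,
                            high_multiplier = 10, mid_multiplier = 3,
                            recruit = TRUE, min_score = k - 5, seed_len = 12,
                            recruit_rounds = 1, polish = TRUE,
                            h = min(15, k), n_trials = NULL, edit_dist = 1,
                            n_partitions = 1, assembly_k = k - 5,
                            min_overlap = 10, max_overlap_mismatch = 1,
                            min_output_len = 2 * k, sim_threshold = 0.85,
                            seed = 1) {
  stopifnot_scalar(k, "k", min = 2, integer = TRUE)
  stopifnot_scalar(assembly_k, "assembly_k", min = 2, max = k - 1,
                   integer = TRUE)
  cfg <- list(
    k = as.integer(k), canonical = isTRUE(canonical), base_freq = base_freq,
    high_multiplier = high_multiplier, mid_multiplier = mid_multiplier,
    recruit = isTRUE(recruit),
    recruitment = recruitment_params(k, min_score, seed_len, recruit_rounds),
    polish = isTRUE(polish),
    polish_params = polish_params(k, h, n_trials, edit_dist, seed,
                                  n_partitions),
    assembly_k = as.integer(assembly_k),
    merge = merge_params(min_overlap, max_overlap_mismatch, TRUE,
                         min_output_len),
    cluster = cluster_params(sim_threshold),
    seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_files <- list(
  simulate = c(genome = "00_genome.fa", truth = "00_truth.fa",
               truth_bed = "00_truth.bed", reads = "00_reads.fq"),
  count = c(kmers = "01_kmers.tsv"),
  classify = c(high = "02_high.tsv", intermediate = "02_intermediate.tsv",
               selection = "02_selection.json"),
  recruit = c(merged = "03_merged.tsv"),
  polish = c(polished = "04_polished.tsv"),
  assemble = c(contigs = "05_contigs.fa"),
  merge = c(repeats = "06_repeats.fa"),
  cluster = c(clusters = "07_clusters.tsv",
              representatives = "07_representatives.fa"),
  evaluate = c(metrics = "08_metrics.json"))

stage_log <- function(workdir, stage, n_in, n_out, t0) {
  line <- sprintf("[%s] stage=%s in=%d out=%d elapsed=%.2fs",
                  format(Sys.time(), "%H:%M:%S"), stage, n_in, n_out,
                  as.numeric(proc.time()[["elapsed"]]) - t0)
  message(line)
  invisible(line)
}

wd_path <- function(workdir, stage, what) {
  file.path(workdir, stage_files[[stage]][[what]])
}

need_file <- function(workdir, stage, what) {
  p <- wd_path(workdir, stage, what)
  if (!file.exists(p))
    stop("missing prerequisite file for stage: ", p, call. = FALSE)
  p
}

#' Run one pipeline stage against a working directory
#'
#' Each stage reads its prerequisites from \code{workdir} (as written by
#' earlier stages) and writes its own stage-stamped outputs there, so a run
#' can be resumed or partially re-executed; a resumed run produces the same
#' artifacts as a single invocation.
#'
#' @param stage one of \code{"simulate"}, \code{"count"}, \code{"classify"},
#'   \code{"recruit"}, \code{"polish"}, \code{"assemble"}, \code{"merge"},
#'   \code{"cluster"}, \code{"evaluate"}.
#' @param workdir working directory for intermediate artifacts.
#' @param config a \code{\link{pipeline_config}}.
#' @param reads read sequences or FASTA/FASTQ path(s) (stage "count").
#' @param library reference repeat library (stage "evaluate"): named
#'   character vector or FASTA path.
#' @param sim for stage "simulate": a list with \code{bg_len}, \code{specs}
#'   (repeat_sim_spec list) and \code{read_spec} (\code{\link{read_sim_spec}}).
#' @return The stage's primary result object, invisibly for writing stages.
#' @export
run_stage <- function(stage, workdir, config = pipeline_config(),
                      reads = NULL, library = NULL, sim = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!stage %in% names(stage_files)) stop("unknown stage: ", stage)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()[["elapsed"]])
  switch(stage,
    simulate = {
      if (is.null(sim)) stop("stage simulate needs `sim`")
      g <- simulate_genome(sim$bg_len, sim$specs, seed = config$seed)
      rd <- simulate_reads(g, sim$read_spec)
      write_fasta(c(genome = g$genome), wd_path(workdir, stage, "genome"))
      write_fasta(g$consensus, wd_path(workdir, stage, "truth"))
      utils::write.table(g$copies, wd_path(workdir, stage, "truth_bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_fastq(rd, wd_path(workdir, stage, "reads"))
      stage_log(workdir, stage, length(sim$specs), length(rd), t0)
      invisible(g)
    },
    count = {
      if (is.null(reads))
        reads <- need_file(workdir, "simulate", "reads")
      kt <- count_kmers(reads, config$k, config$canonical)
      write_kmer_table(kt, wd_path(workdir, stage, "kmers"))
      stage_log(workdir, stage, NA_integer_, length(kt), t0)
      invisible(kt)
    },
    classify = {
      kt <- read_kmer_table(need_file(workdir, "count", "kmers"),
                            config$canonical)
      bf <- config$base_freq
      if (is.null(bf)) bf <- estimate_base_freq(frequency_histogram(kt))
      sel <- selection_params(bf, config$high_multiplier,
                              config$mid_multiplier)
      tiers <- classify_kmers(kt, sel)
      write_kmer_table(tiers$high, wd_path(workdir, stage, "high"))
      write_kmer_table(tiers$intermediate,
                       wd_path(workdir, stage, "intermediate"))
      jsonlite::write_json(list(base_freq = bf,
                                high_multiplier = config$high_multiplier,
                                mid_multiplier = config$mid_multiplier),
                           wd_path(workdir, stage, "selection"),
                           auto_unbox = TRUE, digits = NA)
      stage_log(workdir, stage, length(kt),
                length(tiers$high) + length(tiers$intermediate), t0)
      invisible(tiers)
    },
    recruit = {
      high <- read_kmer_table(need_file(workdir, "classify", "high"),
                              config$canonical)
      if (config$recruit) {
        inter <- read_kmer_table(
          need_file(workdir, "classify", "intermediate"), config$canonical)
        merged <- iterative_recruit(inter, high, config$recruitment)
      } else merged <- high
      write_kmer_table(merged, wd_path(workdir, stage, "merged"))
      stage_log(workdir, stage, length(high), length(merged), t0)
      invisible(merged)
    },
    polish = {
      merged <- read_kmer_table(need_file(workdir, "recruit", "merged"),
                                config$canonical)
      polished <- if (config$polish)
        polish_kmers(merged, config$polish_params) else merged
      write_kmer_table(polished, wd_path(workdir, stage, "polished"))
      stage_log(workdir, stage, length(merged), length(polished), t0)
      invisible(polished)
    },
    assemble = {
      polished <- read_kmer_table(need_file(workdir, "polish", "polished"),
                                  config$canonical)
      contigs <- assemble_contigs(polished, config$assembly_k)
      write_fasta(contigs, wd_path(workdir, stage, "contigs"))
      stage_log(workdir, stage, length(polished), nrow(contigs), t0)
      invisible(contigs)
    },
    merge = {
      contigs <- read_contig_fasta(need_file(workdir, "assemble", "contigs"))
      reps <- merge_contigs(contigs, config$merge)
      write_fasta(reps, wd_path(workdir, stage, "repeats"))
      stage_log(workdir, stage, nrow(contigs), nrow(reps), t0)
      invisible(reps)
    },
    cluster = {
      reps <- read_contig_fasta(need_file(workdir, "merge", "repeats"))
      if (nrow(reps) == 0) {
        cl <- data.frame(repeat_id = character(0), cluster_id = integer(0),
                         is_representative = logical(0))
      } else cl <- cluster_repeats(reps, config$cluster)
      utils::write.table(cl, wd_path(workdir, stage, "clusters"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      keep <- reps[reps$id %in% cl$repeat_id[cl$is_representative], ,
                   drop = FALSE]
      write_fasta(keep, wd_path(workdir, stage, "representatives"))
      stage_log(workdir, stage, nrow(reps),
                length(unique(cl$cluster_id)), t0)
      invisible(cl)
    },
    evaluate = {
      if (is.null(library))
        library <- need_file(workdir, "simulate", "truth")
      reps <- read_contig_fasta(need_file(workdir, "merge", "repeats"))
      if (nrow(reps) == 0) {
        lib <- as_named_seqs(library)
        metrics <- structure(list(N = 0L, N_h = 0L, N_0 = 0L, C_avg = 0,
                                  C_m = 0, per_entry = NULL),
                             class = "library_metrics")
      } else metrics <- compute_metrics(reps, library)
      jsonlite::write_json(metrics[c("N", "N_h", "N_0", "C_avg", "C_m")],
                           wd_path(workdir, stage, "metrics"),
                           auto_unbox = TRUE, digits = NA)
      stage_log(workdir, stage, nrow(reps), metrics$N_0, t0)
      invisible(metrics)
    })
}

#' Run the full repeat-construction pipeline
#'
#' Executes count, classify, recruit, polish, assemble, merge and cluster in
#' order (recruit and polish become pass-throughs when disabled in the
#' config), writing every intermediate artifact to \code{workdir} with
#' stage-stamped names plus a JSON run manifest recording the configuration,
#' seed and per-stage record counts. Identical inputs, config and seed give
#' bit-identical artifacts.
#'
#' @param reads read sequences (character vector) or FASTA/FASTQ path(s).
#' @param config a \code{\link{pipeline_config}}.
#' @param workdir directory for intermediate and final artifacts.
#' @param library optional reference repeat library (named character vector
#'   or FASTA path); when supplied, an evaluate stage computes
#'   \code{\link{compute_metrics}} against it.
#' @return A list of class \code{repcon_run} with elements \code{repeats}
#'   (merged consensus repeats, a \code{contig_set}), \code{contigs},
#'   \code{clusters}, \code{metrics} (when a library was given),
#'   \code{manifest}, \code{workdir}.
#' @export
run_pipeline <- function(reads, config = pipeline_config(), workdir,
                         library = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  run1 <- function(stage, ...) {
    res <- tryCatch(run_stage(stage, workdir, config, ...),
                    error = function(e)
                      stop("stage ", stage, " failed: ", conditionMessage(e),
                           call. = FALSE))
    counts[[stage]] <<- if (is.data.frame(res)) nrow(res) else
      if (inherits(res, "library_metrics")) res$N_0 else length(res)
    res
  }
  run1("count", reads = reads)
  run1("classify")
  run1("recruit")
  run1("polish")
  contigs <- run1("assemble")
  reps <- run1("merge")
  clusters <- run1("cluster")
  metrics <- if (!is.null(library)) run1("evaluate", library = library)
    else NULL
  manifest <- list(
    config = unclass(config)[setdiff(names(config),
                                     c("recruitment", "polish_params",
                                       "merge", "cluster"))],
    params = list(recruitment = unclass(config$recruitment),
                  polish = unclass(config$polish_params),
                  merge = unclass(config$merge),
                  cluster = unclass(config$cluster)),
    seed = config$seed,
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(workdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(repeats = reps, contigs = contigs, clusters = clusters,
                 metrics = metrics, manifest = manifest, workdir = workdir),
            class = "repcon_run")
}

#' @export
print.repcon_run <- function(x, ...) {
  cat("repcon pipeline run\n")
  cat(sprintf("  workdir: %s\n", x$workdir))
  cat(sprintf("  consensus repeats: %d (longest %d bp)\n", nrow(x$repeats),
              if (nrow(x$repeats)) max(nchar(x$repeats$sequence)) else 0L))
  cat(sprintf("  clusters: %d\n",
              if (nrow(x$repeats)) length(unique(x$clusters$cluster_id))
              else 0L))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
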