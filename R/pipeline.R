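#' Configuration for the end-to-end synthetic pipeline
#'
#' @param sim A [sim_config()] describing the simulated assay.
#' @param emit_reads Whether to emit and re-extract raw reads (exercises
#'   the FASTQ path); when `FALSE` the simulated count table feeds the
#'   error-correction stage directly.
#' @param exclusions Optional timepoint exclusion table for
#'   [exclude_timepoints()].
#' @param gc_min Minimum sliding-window GC count for [gc_filter()].
#' @param chimera_ratio Dominance ratio for [remove_chimeras()].
#' @param min_reads,min_neutral Fitness-inference thresholds, see
#'   [estimate_fitness()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            emit_reads = FALSE,
                            exclusions = NULL,
                            gc_min = 4L,
                            chimera_ratio = 100,
                            min_reads = 10,
                            min_neutral = 3) {
  structure(
    list(sim = sim, emit_reads = emit_reads, exclusions = exclusions,
         gc_min = gc_min, chimera_ratio = chimera_ratio,
         min_reads = min_reads, min_neutral = min_neutral),
    class = "pipeline_config"
  )
}

read_stage_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  path
}

stage_current <- function(files, manifest) {
  if (is.null(manifest)) return(FALSE)
  all(vapply(files, function(f) {
    file.exists(f) &&
      identical(unname(tools::md5sum(f)),
                manifest$checksums[[basename(f)]] %||% "")
  }, logical(1)))
}

#' Run the simulate-correct-filter-fitness pipeline
#'
#' Orchestrates the stages end to end on synthetic data: simulation of
#' ground-truth lineage trajectories, optional read emission and
#' re-extraction, deletion-neighborhood error correction and centroid
#' construction (with lane merging and chimera removal), GC/timepoint
#' filters, and neutral-scaled fitness inference. Every stage writes a
#' TSV artifact; a JSON manifest records the configuration, seeds, file
#' checksums, and truth-recovery metrics. Re-running against an intact
#' output directory skips completed stages unless `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param force Re-run all stages even when outputs are current.
#' @return Invisibly, a list with the stage artifact paths, the fitness
#'   fit, the recovery metrics, and the manifest path.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    NULL
  }
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    lineages = file.path(out_dir, "lineages.tsv"),
    centroids = file.path(out_dir, "centroids.tsv"),
    filtered = file.path(out_dir, "filtered.tsv"),
    fitness = file.path(out_dir, "fitness.tsv")
  )
  ran <- character(0)

  # -- simulate ------------------------------------------------------------
  if (force || !stage_current(c(paths$counts, paths$lineages), manifest)) {
    sim <- simulate_pool(config$sim)
    write_stage_tsv(sim$counts, paths$counts)
    write_stage_tsv(sim$lineages, paths$lineages)
    ran <- c(ran, "simulate")
  }
  counts <- read_stage_tsv(paths$counts)
  lineages <- read_stage_tsv(paths$lineages)

  # -- extract (optional read round trip) ----------------------------------
  if (config$emit_reads) {
    if (force || !stage_current(file.path(out_dir, "extracted_counts.tsv"),
                                manifest) || "simulate" %in% ran) {
      set.seed(config$sim$seed + 1L)
      fq <- emit_reads(counts, config$sim, file.path(out_dir, "reads"))
      obs <- purrr::map2(fq$r1, fq$r2, function(f1, f2) {
        reads <- read_fastq_pair(f1, f2)
        extract_barcodes(reads, index_table = fq$index_table)
      })
      extracted <- purrr::map2_dfr(obs, fq$lanes, function(o, lane) {
        dplyr::mutate(count_barcodes(o), lane = lane)
      }) |>
        tidyr::separate_wider_regex(
          "library", c("R", replicate = "\\d+", "_T", timepoint = "\\d+")
        ) |>
        dplyr::mutate(replicate = as.integer(.data$replicate),
                      timepoint = as.integer(.data$timepoint))
      write_stage_tsv(extracted, file.path(out_dir, "extracted_counts.tsv"))
      ran <- c(ran, "extract")
    }
    raw <- read_stage_tsv(file.path(out_dir, "extracted_counts.tsv"))
    paths$extracted <- file.path(out_dir, "extracted_counts.tsv")
  } else {
    raw <- dplyr::select(counts, "replicate", "timepoint", "lane",
                         "env_bc", "lineage_bc", "count")
  }

  # -- error correction ----------------------------------------------------
  if (force || !stage_current(paths$centroids, manifest) ||
      length(ran) > 0L) {
    env_counts <- raw |>
      dplyr::group_by(sequence = .data$env_bc) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    lin_counts <- raw |>
      dplyr::group_by(sequence = .data$lineage_bc) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    env_map <- cluster_barcodes(env_counts)
    lin_map <- cluster_barcodes(lin_counts)
    centroids <- build_centroids(raw, env_map, lin_map)
    centroids <- merge_lanes(centroids)
    centroids <- remove_chimeras(centroids, ratio = config$chimera_ratio)
    write_stage_tsv(centroids, paths$centroids)
    ran <- c(ran, "correct")
  }
  centroids <- read_stage_tsv(paths$centroids)

  # -- filters -------------------------------------------------------------
  if (force || !stage_current(paths$filtered, manifest) ||
      length(ran) > 0L) {
    filtered <- gc_filter(centroids, min_gc = config$gc_min) |>
      dplyr::filter(!.data$gc_excluded) |>
      dplyr::select(-"gc_excluded") |>
      exclude_timepoints(config$exclusions)
    write_stage_tsv(filtered, paths$filtered)
    ran <- c(ran, "filter")
  }
  filtered <- read_stage_tsv(paths$filtered)

  # -- fitness -------------------------------------------------------------
  dg <- config$sim$generations_per_transfer *
    config$sim$transfers_per_timepoint
  fit_input <- filtered |>
    dplyr::inner_join(
      dplyr::select(lineages, "lineage", "env_bc", "lineage_bc"),
      by = c("env_bc", "lineage_bc")
    ) |>
    dplyr::mutate(generation = (.data$timepoint - 1) * dg)
  neutral_ids <- lineages$lineage[lineages$neutral]
  fit <- estimate_fitness(fit_input, neutral_ids,
                          min_reads = config$min_reads,
                          min_neutral = config$min_neutral)
  write_stage_tsv(tidy(fit), paths$fitness)
  recovery <- recovery_stats(fit, lineages)

  files <- unlist(paths)
  manifest_out <- list(
    package = as.character(utils::packageVersion("pleiofit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$sim$seed,
    params = list(
      n_lineages = config$sim$n_lineages,
      n_neutral = config$sim$n_neutral,
      n_timepoints = config$sim$n_timepoints,
      read_depth = config$sim$read_depth,
      gc_min = config$gc_min,
      chimera_ratio = config$chimera_ratio,
      min_reads = config$min_reads
    ),
    stages_run = as.list(ran),
    recovery = as.list(recovery),
    checksums = as.list(tools::md5sum(files[file.exists(files)]) |>
                          setNames(basename(files[file.exists(files)])))
  )
  jsonlite::write_json(manifest_out, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = paths, fit = fit, recovery = recovery,
                 manifest = manifest_path, stages_run = ran))
}
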