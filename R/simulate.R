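#' Configuration for a simulated pooled fitness assay
#'
#' Builds the parameter set for [simulate_pool()]. The defaults emulate a
#' desk-scale bulk fitness assay (BFA): barcoded lineages compete under
#' serial batch transfer (8 generations per transfer), an unadapted
#' ancestor is spiked in at a 9:1 ratio and serves as the putatively
#' neutral class, each transfer passes through a multinomial bottleneck,
#' and amplicon sequencing samples reads multinomially at a fixed depth.
#'
#' @param n_lineages Total number of barcoded lineages, including the
#'   neutral class.
#' @param n_neutral Number of putatively neutral (ancestor) lineages;
#'   their selection coefficient is 0 by construction.
#' @param fitness Distribution of per-generation selection coefficients
#'   for the adapted lineages: `list(dist = "uniform", min =, max =)`,
#'   `list(dist = "normal", mean =, sd =)`, or
#'   `list(dist = "fixed", s = <numeric>)` (recycled).
#' @param generations_per_transfer Generations elapsed per serial
#'   transfer (growth dilution cycle).
#' @param transfers_per_timepoint Number of transfers between sequenced
#'   timepoints; the generation gap between timepoints is
#'   `generations_per_transfer * transfers_per_timepoint`.
#' @param n_timepoints Number of sequenced timepoints (>= 2).
#' @param n_replicates Number of independent assay replicates.
#' @param bottleneck_size Cells sampled at each transfer (multinomial);
#'   `Inf` disables bottleneck drift.
#' @param read_depth Reads sampled per timepoint library (multinomial).
#' @param base_error_rate Per-base substitution error probability applied
#'   when emitting reads.
#' @param chimera_rate Probability that a read pair is chimeric, i.e. its
#'   environment barcode is re-paired with another molecule's.
#' @param umi_duplication_rate Probability that a molecule yields a
#'   duplicate read pair reusing the same UMI and sequence.
#' @param gc_bias_strength Strength (>= 0) of the GC-content read-depth
#'   bias; 0 disables it. See [apply_gc_bias()].
#' @param spike_ratio Ancestor:pool mixing ratio (9 means 9:1); the
#'   neutral class collectively holds `spike_ratio / (spike_ratio + 1)`
#'   of the initial population.
#' @param barcode_length Length of the lineage and environment barcodes;
#'   must lie in 24--28 so that barcodes survive the extraction regex.
#' @param environments Labels of the evolution (home) environments over
#'   which adapted lineages are distributed round-robin. Neutral lineages
#'   are labelled `"ancestor"`.
#' @param n_lanes Number of sequencing lanes the reads are split over.
#' @param seed Integer seed; all randomness in [simulate_pool()] derives
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_lineages = 20, n_neutral = 5, n_timepoints = 3,
#'                   read_depth = 1e4, seed = 1)
#' sim <- simulate_pool(cfg)
#' head(sim$counts)
sim_config <- function(n_lineages = 100,
                       n_neutral = 20,
                       fitness = list(dist = "uniform", min = -0.2, max = 0.3),
                       generations_per_transfer = 8L,
                       transfers_per_timepoint = 1L,
                       n_timepoints = 5L,
                       n_replicates = 2L,
                       bottleneck_size = 1e5,
                       read_depth = 1e6,
                       base_error_rate = 0,
                       chimera_rate = 0,
                       umi_duplication_rate = 0,
                       gc_bias_strength = 0,
                       spike_ratio = 9,
                       barcode_length = 26L,
                       environments = c("E1", "E2", "E3"),
                       n_lanes = 1L,
                       seed = 1L) {
  cfg <- list(
    n_lineages = as.integer(n_lineages),
    n_neutral = as.integer(n_neutral),
    fitness = fitness,
    generations_per_transfer = as.integer(generations_per_transfer),
    transfers_per_timepoint = as.integer(transfers_per_timepoint),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    bottleneck_size = bottleneck_size,
    read_depth = as.integer(read_depth),
    base_error_rate = base_error_rate,
    chimera_rate = chimera_rate,
    umi_duplication_rate = umi_duplication_rate,
    gc_bias_strength = gc_bias_strength,
    spike_ratio = spike_ratio,
    barcode_length = as.integer(barcode_length),
    environments = environments,
    n_lanes = as.integer(n_lanes),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(cfg$base_error_rate, cfg$chimera_rate, cfg$umi_duplication_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("error, chimera and duplication rates must be probabilities in [0, 1]")
  }
  if (cfg$n_neutral > cfg$n_lineages) {
    stop("n_neutral must not exceed n_lineages")
  }
  if (cfg$generations_per_transfer < 1L) {
    stop("generations_per_transfer must be >= 1")
  }
  if (!(cfg$barcode_length %in% 24:28)) {
    stop("barcode_length must lie in [24, 28] to survive the extraction regex")
  }
  if (cfg$gc_bias_strength < 0) stop("gc_bias_strength must be >= 0")
  if (cfg$spike_ratio < 0) stop("spike_ratio must be >= 0")
  if (cfg$n_lanes < 1L) stop("n_lanes must be >= 1")
  invisible(cfg)
}

draw_fitness <- function(fitness, n) {
  if (n == 0L) return(numeric(0))
  switch(fitness$dist,
    uniform = runif(n, fitness$min, fitness$max),
    normal = stats::rnorm(n, fitness$mean, fitness$sd),
    fixed = rep_len(fitness$s, n),
    stop("unknown fitness distribution: ", fitness$dist)
  )
}

#' Simulate lineage trajectories and barcode count tables
#'
#' Realizes exponential lineage dynamics under serial transfer: over a gap
#' of `dg` generations the expected frequency update is
#' `f_i' = f_i exp(s_i dg) / sum_j f_j exp(s_j dg)` (so adding a constant
#' to every `s` leaves trajectories unchanged), followed by a multinomial
#' bottleneck of `bottleneck_size` cells at each transfer and multinomial
#' read sampling of `read_depth` reads at each sequenced timepoint.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `bfa_sim` with elements
#'   \describe{
#'     \item{lineages}{tibble of ground truth: lineage id, home
#'       environment, barcodes, true `s`, neutral flag.}
#'     \item{counts}{tibble of read counts per
#'       (replicate, timepoint, lane, lineage).}
#'     \item{frequencies}{realized (post-bottleneck, pre-sequencing)
#'       frequencies per replicate and timepoint.}
#'     \item{expected_frequencies}{deterministic noise-free frequency
#'       trajectories.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_pool <- function(config) {
  validate_sim_config(config)
  if (config$n_timepoints < 2L) stop("n_timepoints must be at least 2")
  set.seed(config$seed)

  n <- config$n_lineages
  n_neu <- config$n_neutral
  n_adapt <- n - n_neu

  s <- c(draw_fitness(config$fitness, n_adapt), rep(0, n_neu))
  neutral <- c(rep(FALSE, n_adapt), rep(TRUE, n_neu))
  environment <- c(rep_len(config$environments, length.out = max(n_adapt, 0L))[seq_len(n_adapt)],
                   rep("ancestor", n_neu))

  envs <- unique(environment)
  env_bcs <- setNames(random_barcodes(length(envs), config$barcode_length), envs)
  lineage_bcs <- random_barcodes(n, config$barcode_length)

  lineages <- tibble::tibble(
    lineage = sprintf("L%04d", seq_len(n)),
    environment = environment,
    env_bc = unname(env_bcs[environment]),
    lineage_bc = lineage_bcs,
    s = s,
    neutral = neutral
  )

  # initial pool: ancestor spike-in vs adapted pool
  if (n_neu > 0L && n_adapt > 0L && config$spike_ratio > 0) {
    w_neutral <- config$spike_ratio / (config$spike_ratio + 1)
    f0 <- c(rep((1 - w_neutral) / n_adapt, n_adapt),
            rep(w_neutral / n_neu, n_neu))
  } else {
    f0 <- rep(1 / n, n)
  }

  dg <- config$generations_per_transfer * config$transfers_per_timepoint
  gens <- (seq_len(config$n_timepoints) - 1L) * dg

  # deterministic expected trajectory (no bottleneck, no sequencing noise)
  expected <- purrr::map(gens, function(g) {
    w <- f0 * exp(s * g)
    w / sum(w)
  })
  expected_frequencies <- tibble::tibble(
    lineage = rep(lineages$lineage, times = config$n_timepoints),
    timepoint = rep(seq_len(config$n_timepoints), each = n),
    generation = rep(gens, each = n),
    freq = unlist(expected)
  )

  gc_w <- if (config$gc_bias_strength > 0) {
    gc_bias_weight(gc_fraction(paste0(lineages$env_bc, lineages$lineage_bc)),
                   config$gc_bias_strength)
  } else {
    rep(1, n)
  }

  freq_rows <- list()
  count_rows <- list()
  for (r in seq_len(config$n_replicates)) {
    f <- f0
    for (t in seq_len(config$n_timepoints)) {
      if (t > 1L) {
        for (k in seq_len(config$transfers_per_timepoint)) {
          w <- f * exp(s * config$generations_per_transfer)
          f <- w / sum(w)
          if (is.finite(config$bottleneck_size)) {
            cells <- as.vector(rmultinom(1, config$bottleneck_size, f))
            f <- cells / sum(cells)
          }
        }
      }
      freq_rows[[length(freq_rows) + 1L]] <- tibble::tibble(
        replicate = r, timepoint = t, generation = gens[t],
        lineage = lineages$lineage, freq = f
      )
      p <- f * gc_w
      reads <- as.vector(rmultinom(1, config$read_depth, p / sum(p)))
      if (config$n_lanes > 1L) {
        lane_mat <- vapply(reads, function(k) {
          as.vector(rmultinom(1, k, rep(1 / config$n_lanes, config$n_lanes)))
        }, integer(config$n_lanes))
        for (lane in seq_len(config$n_lanes)) {
          count_rows[[length(count_rows) + 1L]] <- tibble::tibble(
            replicate = r, timepoint = t, generation = gens[t], lane = lane,
            lineage = lineages$lineage, count = lane_mat[lane, ]
          )
        }
      } else {
        count_rows[[length(count_rows) + 1L]] <- tibble::tibble(
          replicate = r, timepoint = t, generation = gens[t], lane = 1L,
          lineage = lineages$lineage, count = reads
        )
      }
    }
  }

  counts <- dplyr::bind_rows(count_rows) |>
    dplyr::left_join(
      dplyr::select(lineages, "lineage", "environment", "env_bc", "lineage_bc"),
      by = "lineage"
    ) |>
    dplyr::select("replicate", "timepoint", "generation", "lane", "lineage",
                  "environment", "env_bc", "lineage_bc", "count")

  structure(
    list(
      lineages = lineages,
      counts = counts,
      frequencies = dplyr::bind_rows(freq_rows),
      expected_frequencies = expected_frequencies,
      config = config
    ),
    class = "bfa_sim"
  )
}

#' @export
print.bfa_sim <- function(x, ...) {
  cat("Simulated bulk fitness assay\n")
  cat(sprintf("  %d lineages (%d neutral), %d timepoints, %d replicate(s)\n",
              x$config$n_lineages, x$config$n_neutral,
              x$config$n_timepoints, x$config$n_replicates))
  cat(sprintf("  read depth %d, bottleneck %s\n",
              x$config$read_depth, format(x$config$bottleneck_size)))
  invisible(x)
}

# Monotone GC weight: exp(strength * (gc - 0.5)); strength 0 gives 1.
gc_bias_weight <- function(gc, strength) {
  exp(strength * (gc - 0.5))
}

#' Distort a count table by GC-content read-depth bias
#'
#' Multiplies expected read counts by a monotone function of the GC
#' fraction of the full barcode (environment + lineage), then rescales so
#' that each library (replicate x timepoint x lane) keeps its original
#' total read count. Strength 0 is the identity. Counts in the returned
#' table are expected values and may be non-integer.
#'
#' @param counts Tibble with `env_bc`, `lineage_bc`, `count` and library
#'   key columns `replicate`, `timepoint`, `lane` (missing key columns are
#'   treated as a single library).
#' @param strength Bias strength, >= 0.
#' @return The count table with distorted `count`.
#' @export
apply_gc_bias <- function(counts, strength) {
  if (strength < 0) stop("strength must be >= 0")
  if (strength == 0) return(counts)
  keys <- intersect(c("replicate", "timepoint", "lane"), names(counts))
  counts |>
    dplyr::mutate(
      .w = gc_bias_weight(gc_fraction(paste0(.data$env_bc, .data$lineage_bc)),
                          strength)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      count = .data$count * .data$.w /
        sum(.data$count * .data$.w) * sum(.data$count)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".w")
}
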