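# Internal: per-(lineage, replicate, pair) log-frequency slopes.
# `counts` must have lineage, replicate, timepoint, generation, count.
# Library totals are the column sums of the analyzed set at each
# (replicate, timepoint); frequencies are count / total, so estimates are
# invariant to rescaling all counts at a timepoint.
slope_table <- function(counts, min_reads = 10) {
  if ("lane" %in% names(counts)) {
    counts <- counts |>
      dplyr::group_by(.data$lineage, .data$replicate, .data$timepoint,
                      .data$generation) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  counts <- counts |>
    dplyr::group_by(.data$replicate) |>
    tidyr::complete(.data$lineage,
                    tidyr::nesting(!!rlang::sym("timepoint"),
                                   !!rlang::sym("generation")),
                    fill = list(count = 0L)) |>
    dplyr::ungroup()
  counts |>
    dplyr::group_by(.data$replicate, .data$timepoint, .data$generation) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::group_by(.data$lineage, .data$replicate) |>
    dplyr::arrange(.data$generation, .by_group = TRUE) |>
    dplyr::mutate(
      pair = dplyr::row_number(),
      .f = .data$count / .data$.total,
      .f_next = dplyr::lead(.data$.f),
      .count_next = dplyr::lead(.data$count),
      .dg = dplyr::lead(.data$generation) - .data$generation,
      slope = (log(.data$.f_next) - log(.data$.f)) / .data$.dg,
      valid = .data$count >= min_reads & .data$.count_next >= min_reads
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$.dg)) |>
    dplyr::select("lineage", "replicate", "pair", "generation",
                  "slope", "valid")
}

#' Log-frequency slopes at consecutive valid timepoint pairs
#'
#' For one lineage trajectory, computes the slope of the natural log of
#' frequency between each pair of consecutive timepoints, divided by the
#' generations elapsed. A pair contributes only when the lineage has at
#' least `min_reads` reads at both of its timepoints; a timepoint below
#' the threshold invalidates both pairs touching it. Fewer than two
#' valid consecutive timepoints yield an empty result (the lineage's
#' fitness is missing, not zero).
#'
#' @param trajectory Tibble with `timepoint`, `generation` (strictly
#'   increasing), `count`, and `total` (library reads at that timepoint).
#' @param min_reads Read-support threshold for a valid timepoint.
#' @return Tibble with `pair` (index of the leading timepoint) and
#'   `slope` (per generation).
#' @export
#' @examples
#' traj <- tibble::tibble(timepoint = 1:2, generation = c(0, 8),
#'                        count = c(100, 200), total = c(1e5, 1e5))
#' pair_slopes(traj)  # slope = log(2) / 8
pair_slopes <- function(trajectory, min_reads = 10) {
  stopifnot(all(c("timepoint", "generation", "count", "total") %in%
                  names(trajectory)))
  trajectory <- dplyr::arrange(trajectory, .data$generation)
  if (any(diff(trajectory$generation) <= 0)) {
    stop("generation stamps must be strictly increasing")
  }
  f <- trajectory$count / trajectory$total
  n <- nrow(trajectory)
  if (n < 2L) {
    return(tibble::tibble(pair = integer(0), slope = numeric(0)))
  }
  k <- seq_len(n - 1L)
  valid <- trajectory$count[k] >= min_reads &
    trajectory$count[k + 1L] >= min_reads
  slope <- (log(f[k + 1L]) - log(f[k])) /
    (trajectory$generation[k + 1L] - trajectory$generation[k])
  tibble::tibble(pair = k[valid], slope = slope[valid])
}

#' Neutral reference slopes per timepoint pair
#'
#' Computes, for every consecutive timepoint pair in each replicate, the
#' median log-frequency slope of the putatively neutral lineages valid
#' at that pair (at least `min_reads` reads at both timepoints). When
#' fewer than `min_lineages` neutral lineages are valid, the counts of
#' the two lowest-total-count neutral lineages are merged (summed) and
#' the check repeats; a pair that still cannot field `min_lineages`
#' valid lineages after merging is marked unusable and excluded from
#' fitness estimation assay-wide.
#'
#' @param counts Count tibble with `lineage`, `replicate`, `timepoint`,
#'   `generation`, `count` (and optionally `lane`, summed over).
#' @param neutral Character vector of neutral lineage ids (non-empty).
#' @param min_reads Valid-timepoint read threshold (default 10).
#' @param min_lineages Minimum valid neutral lineages per pair
#'   (default 3).
#' @return Tibble with `replicate`, `pair`, `reference` (median neutral
#'   slope per generation), `n_valid`, `n_merges`, `usable`.
#' @export
neutral_reference <- function(counts, neutral, min_reads = 10,
                              min_lineages = 3) {
  if (length(neutral) == 0L) stop("neutral lineage set must be non-empty")
  if ("lane" %in% names(counts)) {
    counts <- counts |>
      dplyr::group_by(.data$lineage, .data$replicate, .data$timepoint,
                      .data$generation) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  totals <- counts |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(.total = sum(.data$count), .groups = "drop")

  out <- list()
  for (r in sort(unique(counts$replicate))) {
    sub <- dplyr::filter(counts, .data$replicate == r,
                         .data$lineage %in% neutral)
    grid <- sub |>
      dplyr::distinct(.data$timepoint, .data$generation) |>
      dplyr::arrange(.data$generation)
    mat0 <- sub |>
      dplyr::select("lineage", "timepoint", "count") |>
      tidyr::pivot_wider(names_from = "timepoint", values_from = "count",
                         values_fill = 0L)
    mat0 <- as.matrix(mat0[, as.character(grid$timepoint), drop = FALSE])
    lib <- totals$.total[match(paste(r, grid$timepoint),
                               paste(totals$replicate, totals$timepoint))]
    for (k in seq_len(nrow(grid) - 1L)) {
      mat <- mat0
      n_merges <- 0L
      repeat {
        valid <- mat[, k] >= min_reads & mat[, k + 1L] >= min_reads
        if (sum(valid) >= min_lineages) break
        if (nrow(mat) <= min_lineages) break
        tot <- rowSums(mat)
        lo <- order(tot)[1:2]
        merged <- colSums(mat[lo, , drop = FALSE])
        mat <- rbind(mat[-lo, , drop = FALSE], merged)
        n_merges <- n_merges + 1L
      }
      valid <- mat[, k] >= min_reads & mat[, k + 1L] >= min_reads
      usable <- sum(valid) >= min_lineages
      ref <- if (usable) {
        f1 <- mat[valid, k] / lib[k]
        f2 <- mat[valid, k + 1L] / lib[k + 1L]
        dg <- grid$generation[k + 1L] - grid$generation[k]
        median((log(f2) - log(f1)) / dg)
      } else {
        NA_real_
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        replicate = r, pair = k, reference = ref,
        n_valid = sum(valid), n_merges = n_merges, usable = usable
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Neutral-scaled fitness for a single trajectory
#'
#' Scales each valid pair slope by subtracting the neutral reference for
#' that pair, then summarizes: the estimate is the mean of the scaled
#' slopes and its standard error the sample standard deviation divided
#' by the square root of the number of pairs (missing when fewer than
#' two pairs contribute).
#'
#' @param trajectory As in [pair_slopes()].
#' @param reference Tibble with `pair`, `reference`, and optionally
#'   `usable` (unusable pairs are skipped), e.g. one replicate of
#'   [neutral_reference()].
#' @param min_reads Valid-timepoint read threshold.
#' @return One-row tibble: `s_hat`, `se`, `n_pairs`.
#' @export
scaled_fitness <- function(trajectory, reference, min_reads = 10) {
  sl <- pair_slopes(trajectory, min_reads = min_reads)
  if ("usable" %in% names(reference)) {
    reference <- dplyr::filter(reference, .data$usable)
  }
  sl <- dplyr::inner_join(sl, reference[, c("pair", "reference")],
                          by = "pair")
  scaled <- sl$slope - sl$reference
  summarize_scaled(scaled)
}

summarize_scaled <- function(scaled) {
  n <- length(scaled)
  tibble::tibble(
    s_hat = if (n > 0L) mean(scaled) else NA_real_,
    se = if (n >= 2L) sd(scaled) / sqrt(n) else NA_real_,
    n_pairs = n
  )
}

#' Combine per-replicate fitness estimates
#'
#' Averages replicate estimates by inverse-variance weighting:
#' `s = sum(s_r / se_r^2) / sum(1 / se_r^2)` with combined standard
#' error `sqrt(1 / sum(1 / se_r^2))`. Replicates with a missing standard
#' error (single-pair estimates) are excluded from the weighting; when
#' every replicate lacks a standard error the unweighted mean is
#' returned with a missing `se` and `method = "unweighted"`.
#'
#' @param estimates Tibble with `lineage`, `replicate`, `s_hat`, `se`.
#' @return Tibble with one row per lineage: `s_hat`, `se`,
#'   `n_replicates`, `method`.
#' @export
combine_replicates <- function(estimates) {
  estimates |>
    dplyr::filter(!is.na(.data$s_hat)) |>
    dplyr::group_by(.data$lineage) |>
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$se)
      if (any(ok & d$se == 0)) {
        # exact (noise-free) replicates carry infinite weight
        zero <- ok & d$se == 0
        tibble::tibble(
          s_hat = mean(d$s_hat[zero]),
          se = 0,
          n_replicates = sum(zero),
          method = "inverse_variance"
        )
      } else if (any(ok)) {
        w <- 1 / d$se[ok]^2
        tibble::tibble(
          s_hat = sum(d$s_hat[ok] * w) / sum(w),
          se = sqrt(1 / sum(w)),
          n_replicates = sum(ok),
          method = "inverse_variance"
        )
      } else {
        tibble::tibble(
          s_hat = mean(d$s_hat),
          se = NA_real_,
          n_replicates = nrow(d),
          method = "unweighted"
        )
      }
    }) |>
    dplyr::ungroup()
}

#' Estimate neutral-scaled selection coefficients from count trajectories
#'
#' The main fitness-inference entry point. For each lineage and
#' replicate, log-frequency slopes at consecutive valid timepoint pairs
#' are scaled by the per-pair median slope of the neutral class and
#' averaged; replicates are then combined by inverse-variance weighting.
#' All fitnesses are per generation.
#'
#' @param counts Count tibble with `lineage`, `replicate`, `timepoint`,
#'   `generation`, `count` (a `lane` column, if present, is summed over).
#'   Counts should already be restricted to the analyzed barcode set
#'   (after GC/chimera/lane filters and timepoint exclusions).
#' @param neutral Character vector of putatively neutral lineage ids.
#' @param min_reads Valid-timepoint read threshold (default 10).
#' @param min_neutral Minimum valid neutral lineages per pair
#'   (default 3).
#' @return An object of class `bfa_fit` with elements
#'   `replicate_estimates`, `combined`, `reference`, and `params`.
#'   Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
estimate_fitness <- function(counts, neutral, min_reads = 10,
                             min_neutral = 3) {
  reference <- neutral_reference(counts, neutral, min_reads = min_reads,
                                 min_lineages = min_neutral)
  slopes <- slope_table(counts, min_reads = min_reads)
  usable_ref <- dplyr::filter(reference, .data$usable)
  scaled <- slopes |>
    dplyr::filter(.data$valid) |>
    dplyr::inner_join(usable_ref[, c("replicate", "pair", "reference")],
                      by = c("replicate", "pair")) |>
    dplyr::mutate(scaled = .data$slope - .data$reference)
  per_rep <- scaled |>
    dplyr::group_by(.data$lineage, .data$replicate) |>
    dplyr::summarise(
      s_hat = mean(.data$scaled),
      se = ifelse(dplyr::n() >= 2L, sd(.data$scaled) / sqrt(dplyr::n()),
                  NA_real_),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  combined <- combine_replicates(per_rep) |>
    dplyr::mutate(neutral = .data$lineage %in% .env$neutral)

  structure(
    list(
      replicate_estimates = per_rep,
      combined = combined,
      reference = reference,
      params = list(min_reads = min_reads, min_neutral = min_neutral,
                    neutral = neutral)
    ),
    class = "bfa_fit"
  )
}

#' @export
print.bfa_fit <- function(x, ...) {
  cat("Neutral-scaled fitness estimates (per generation)\n")
  cat(sprintf("  %d lineages, %d replicate(s), %d usable timepoint pairs\n",
              nrow(x$combined),
              length(unique(x$replicate_estimates$replicate)),
              sum(x$reference$usable)))
  print(utils::head(x$combined))
  invisible(x)
}

#' Tidy a fitness fit into one row per lineage
#'
#' @param x A `bfa_fit` from [estimate_fitness()].
#' @param ... Unused.
#' @return The combined estimate tibble (`lineage`, `s_hat`, `se`,
#'   `n_replicates`, `method`, `neutral`).
#' @export
tidy.bfa_fit <- function(x, ...) {
  x$combined
}

#' One-row summary of a fitness fit
#'
#' @inheritParams tidy.bfa_fit
#' @return Tibble with lineage/replicate/pair tallies and the median
#'   absolute neutral deviation.
#' @export
glance.bfa_fit <- function(x, ...) {
  tibble::tibble(
    n_lineages = nrow(x$combined),
    n_replicates = length(unique(x$replicate_estimates$replicate)),
    n_usable_pairs = sum(x$reference$usable),
    median_se = median(x$combined$se, na.rm = TRUE),
    neutral_mad = median(abs(x$combined$s_hat[x$combined$neutral]),
                         na.rm = TRUE)
  )
}

#' Replicate-concordance plot for a fitness fit
#'
#' Scatterplot of the per-replicate fitness estimates of the first two
#' replicates (or a histogram of combined estimates when only one
#' replicate is present).
#'
#' @param object A `bfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfa_fit <- function(object, ...) {
  reps <- sort(unique(object$replicate_estimates$replicate))
  if (length(reps) >= 2L) {
    wide <- object$replicate_estimates |>
      dplyr::filter(.data$replicate %in% reps[1:2]) |>
      dplyr::select("lineage", "replicate", "s_hat") |>
      tidyr::pivot_wider(names_from = "replicate", values_from = "s_hat",
                         names_prefix = "rep_")
    ggplot2::ggplot(wide, ggplot2::aes(
      x = .data[[paste0("rep_", reps[1])]],
      y = .data[[paste0("rep_", reps[2])]]
    )) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(
        x = sprintf("fitness, replicate %s", reps[1]),
        y = sprintf("fitness, replicate %s", reps[2]),
        title = "Replicate concordance of fitness estimates"
      )
  } else {
    ggplot2::ggplot(object$combined, ggplot2::aes(x = .data$s_hat)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "fitness (per generation)", y = "lineages")
  }
}

#' Compare estimated fitness with simulation ground truth
#'
#' @param fit A `bfa_fit`.
#' @param truth Tibble with `lineage` and true `s` (e.g. the `lineages`
#'   element of a [simulate_pool()] result).
#' @return One-row tibble: `n`, `rmse`, `spearman`,
#'   `replicate_pearson` (Pearson correlation of the first two
#'   replicates' estimates, `NA` with one replicate).
#' @export
recovery_stats <- function(fit, truth) {
  d <- dplyr::inner_join(tidy(fit), truth[, c("lineage", "s")],
                         by = "lineage") |>
    dplyr::filter(!is.na(.data$s_hat))
  reps <- sort(unique(fit$replicate_estimates$replicate))
  rep_cor <- NA_real_
  if (length(reps) >= 2L) {
    wide <- fit$replicate_estimates |>
      dplyr::filter(.data$replicate %in% reps[1:2]) |>
      dplyr::select("lineage", "replicate", "s_hat") |>
      tidyr::pivot_wider(names_from = "replicate", values_from = "s_hat")
    wide <- wide[stats::complete.cases(wide), ]
    rep_cor <- cor(wide[[2]], wide[[3]])
  }
  tibble::tibble(
    n = nrow(d),
    rmse = sqrt(mean((d$s_hat - d$s)^2)),
    spearman = cor(d$s_hat, d$s, method = "spearman"),
    replicate_pearson = rep_cor
  )
}
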