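#' Classify a fitness effect against measurement noise
#'
#' A fitness estimate is called beneficial when it exceeds `k` standard
#' errors above zero, deleterious when below `-k` standard errors, and
#' neutral otherwise (no detectable effect within the bounds of
#' measurement noise). Missing estimates or standard errors give
#' `"missing"`. The classification is antisymmetric: negating `s_hat`
#' swaps beneficial and deleterious.
#'
#' @param s_hat Numeric vector of fitness estimates (per generation).
#' @param se Standard errors.
#' @param k Noise multiplier (default 2, roughly two-sided 95%).
#' @param cutoffs Optional fixed-cutoff mode: a length-2 numeric
#'   `c(deleterious_below, beneficial_above)`; when supplied, the
#'   standard errors are ignored and estimates are classified against
#'   these absolute fitness bounds instead of the noise envelope.
#' @return Character vector in
#'   `c("beneficial", "neutral", "deleterious", "missing")`.
#' @export
#' @examples
#' classify_effect(c(0.10, 0.01, -0.10), c(0.01, 0.02, 0.01))
#' classify_effect(c(0.25, 0.1, -0.02), cutoffs = c(-0.018, 0.2))
classify_effect <- function(s_hat, se = NULL, k = 2, cutoffs = NULL) {
  if (!is.null(cutoffs)) {
    stopifnot(length(cutoffs) == 2L, cutoffs[1] <= cutoffs[2])
    return(dplyr::case_when(
      is.na(s_hat) ~ "missing",
      s_hat > cutoffs[2] ~ "beneficial",
      s_hat < cutoffs[1] ~ "deleterious",
      TRUE ~ "neutral"
    ))
  }
  if (is.null(se)) stop("se is required unless fixed cutoffs are given")
  dplyr::case_when(
    is.na(s_hat) | is.na(se) ~ "missing",
    s_hat > k * se ~ "beneficial",
    s_hat < -k * se ~ "deleterious",
    TRUE ~ "neutral"
  )
}

#' Classify a lineage-by-environment fitness profile table
#'
#' @param profiles Tibble with `lineage`, `environment`, `s_hat`, `se`
#'   and a `home` column (the lineage's home environment) or a separate
#'   `home_map` tibble (`lineage`, `home`).
#' @param home_map Optional tibble mapping `lineage` to `home`.
#' @param k Noise multiplier for [classify_effect()].
#' @return `profiles` with `effect` and `is_home` columns added.
#' @export
classify_profiles <- function(profiles, home_map = NULL, k = 2) {
  if (!is.null(home_map)) {
    profiles <- dplyr::left_join(profiles, home_map[, c("lineage", "home")],
                                 by = "lineage")
  }
  if (!"home" %in% names(profiles)) {
    stop("profiles need a `home` column or a home_map")
  }
  profiles |>
    dplyr::mutate(
      effect = classify_effect(.data$s_hat, .data$se, k = k),
      is_home = .data$environment == .data$home
    )
}

#' Pleiotropy and cost-free-adaptation calls per lineage
#'
#' Pleiotropy is present when a lineage is non-neutral (beneficial or
#' deleterious) in at least one non-home environment; it is missing when
#' no non-home environment was measured. Adaptation is cost-free when
#' the lineage is beneficial at home and no measured non-home
#' environment is deleterious (each non-home effect near neutral or a
#' small benefit).
#'
#' @param profiles Classified profile tibble from [classify_profiles()].
#' @return Tibble with one row per lineage: `home`, `pleiotropic`,
#'   `cost_free`, `n_non_home_measured`.
#' @export
pleiotropy_summary <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$lineage, .data$home) |>
    dplyr::summarise(
      n_non_home_measured = sum(!.data$is_home & .data$effect != "missing"),
      pleiotropic = ifelse(
        .data$n_non_home_measured == 0L, NA,
        any(!.data$is_home &
              .data$effect %in% c("beneficial", "deleterious"))
      ),
      cost_free = ifelse(
        .data$n_non_home_measured == 0L, NA,
        any(.data$is_home & .data$effect == "beneficial") &
          !any(!.data$is_home & .data$effect == "deleterious")
      ),
      .groups = "drop"
    )
}

#' Per-lineage pleiotropy indicator
#'
#' @param profile Classified profile tibble (one lineage) from
#'   [classify_profiles()].
#' @return `TRUE`/`FALSE`, or `NA` when no non-home environment was
#'   measured.
#' @export
pleiotropy_present <- function(profile) {
  non_home <- profile[!profile$is_home & profile$effect != "missing", ]
  if (nrow(non_home) == 0L) return(NA)
  any(non_home$effect %in% c("beneficial", "deleterious"))
}

#' Per-lineage cost-free adaptation indicator
#'
#' @inheritParams pleiotropy_present
#' @return `TRUE` iff the lineage is beneficial at home and no measured
#'   non-home environment is deleterious; `NA` when no non-home
#'   environment was measured.
#' @export
cost_free <- function(profile) {
  non_home <- profile[!profile$is_home & profile$effect != "missing", ]
  if (nrow(non_home) == 0L) return(NA)
  home <- profile[profile$is_home, ]
  any(home$effect == "beneficial") && !any(non_home$effect == "deleterious")
}

# Pairwise Euclidean distances over shared measured environments; NA for
# pairs sharing fewer than `min_shared` environments. The distances do not
# depend on gene labels, so permutations reuse this matrix.
profile_distances <- function(mat, min_shared = 3L) {
  n <- nrow(mat)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      shared <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (sum(shared) < min_shared) next
      d[i, j] <- d[j, i] <- sqrt(sum((mat[i, shared] - mat[j, shared])^2))
    }
  }
  d
}

# Mean within-gene minus mean between-gene pairwise distance.
profile_distance_stat <- function(dmat, genes) {
  same <- outer(genes, genes, "==")
  ut <- upper.tri(dmat)
  within <- dmat[ut & same]
  between <- dmat[ut & !same]
  within <- within[!is.na(within)]
  between <- between[!is.na(between)]
  if (length(within) == 0L || length(between) == 0L) return(NA_real_)
  mean(within) - mean(between)
}

#' Permutation test for within-gene similarity of pleiotropic profiles
#'
#' Tests whether mutations in the same gene (arising in the same home
#' environment) have more similar pleiotropic profiles than mutations in
#' different genes. The statistic is the mean within-gene pairwise
#' distance minus the mean between-gene pairwise distance (Euclidean
#' over shared measured environments; pairs sharing fewer than
#' `min_shared` environments are skipped); similarity within genes makes
#' it negative. The null distribution permutes gene labels across
#' profiles; the one-sided p-value uses the add-one correction
#' `p = (1 + #(null <= observed)) / (n_permutations + 1)` and therefore
#' lies in (0, 1].
#'
#' @param profiles Tibble with `lineage`, `gene`, `environment`,
#'   `s_hat` (missing environments may be absent or `NA`).
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param min_shared Minimum shared measured environments per pair.
#' @return One-row tibble: `statistic`, `p_value`, `n_profiles`,
#'   `n_genes`, `n_permutations`. All-`NA` when fewer than two genes
#'   have two or more profiles.
#' @export
profile_similarity_test <- function(profiles, n_permutations = 10000,
                                    seed = 1L, min_shared = 3L) {
  wide <- profiles |>
    dplyr::select("lineage", "gene", "environment", "s_hat") |>
    tidyr::pivot_wider(names_from = "environment", values_from = "s_hat")
  genes <- wide$gene
  mat <- as.matrix(wide[, setdiff(names(wide), c("lineage", "gene"))])
  multi <- names(which(table(genes) >= 2L))
  if (length(multi) < 2L) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_profiles = nrow(mat),
                          n_genes = length(unique(genes)),
                          n_permutations = n_permutations))
  }
  dmat <- profile_distances(mat, min_shared)
  obs <- profile_distance_stat(dmat, genes)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    profile_distance_stat(dmat, sample(genes))
  }, numeric(1))
  p <- (1 + sum(null <= obs, na.rm = TRUE)) / (n_permutations + 1)
  tibble::tibble(statistic = obs, p_value = p, n_profiles = nrow(mat),
                 n_genes = length(unique(genes)),
                 n_permutations = n_permutations)
}

#' Collapse repeated identical mutations to their median profile
#'
#' Lineages carrying the same mutation are collapsed to a single profile
#' holding the median fitness per environment (display aggregation for
#' profile heatmaps).
#'
#' @param profiles Tibble with `mutation`, `environment`, `s_hat` (and
#'   any grouping columns such as `gene`, `home`).
#' @return Tibble with one row per (mutation, environment) and median
#'   `s_hat`; `n_lineages` gives the number collapsed.
#' @export
collapse_mutation_profiles <- function(profiles) {
  keys <- intersect(c("gene", "home", "mutation", "environment"),
                    names(profiles))
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_lineages = dplyr::n(),
      s_hat = median(.data$s_hat, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Heatmap of pleiotropic fitness profiles
#'
#' @param profiles Tibble with `lineage`, `environment`, `s_hat`.
#' @return A ggplot tile plot (lineages x environments, fill = fitness).
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$environment, y = .data$lineage, fill = .data$s_hat
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "assay environment", y = "lineage",
                  fill = "fitness\n(per gen)") +
    ggplot2::theme_minimal()
}
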