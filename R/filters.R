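#' Minimum GC count over a sliding window
#'
#' Slides a window of `window_length` bases across the sequence and
#' returns the minimum number of G/C bases observed in any window. When
#' the sequence is shorter than the window, the whole sequence is the
#' single window. The value is invariant under reverse complement.
#'
#' @param sequence Character vector of sequences.
#' @param window_length Window size in bases (default 26).
#' @return Integer vector of minimum window GC counts.
#' @export
#' @examples
#' min_gc_window(strrep("A", 26))  # 0
#' min_gc_window(strrep("G", 26))  # 26
min_gc_window <- function(sequence, window_length = 26L) {
  vapply(sequence, function(x) {
    if (is.na(x) || nchar(x) == 0L) stop("sequence must be non-empty")
    is_gc <- strsplit(x, "", fixed = TRUE)[[1]] %in% c("G", "C", "g", "c")
    n <- length(is_gc)
    if (n <= window_length) return(sum(is_gc))
    cs <- cumsum(is_gc)
    windows <- cs[window_length:n] - c(0L, cs[seq_len(n - window_length)])
    min(windows)
  }, integer(1), USE.NAMES = FALSE)
}

#' GC-content barcode exclusion filter
#'
#' Excludes barcodes whose frequency measurements are unreliable due to
#' GC-dependent amplification bias: a lineage is excluded when the
#' minimum GC count of a 26 bp sliding window across its barcode region
#' (environment barcode + lineage barcode concatenated) is less than
#' `min_gc`; a minimum of exactly `min_gc` is kept.
#'
#' @param records Tibble with `env_bc` and `lineage_bc` columns.
#' @param min_gc Minimum tolerated window GC count (default 4).
#' @param window_length Sliding window size (default 26).
#' @return `records` with a logical `gc_excluded` column added.
#' @export
gc_filter <- function(records, min_gc = 4L, window_length = 26L) {
  region <- paste0(records$env_bc, records$lineage_bc)
  dplyr::mutate(records,
                gc_excluded = min_gc_window(region, window_length) < min_gc)
}

#' Remove manually excluded timepoints from a count table
#'
#' Timepoints with pronounced GC-content bias (or library
#' cross-contamination) are excluded from fitness estimation via an
#' explicit configuration listing (environment/assay, replicate,
#' timepoint) triples. An empty configuration is the identity.
#'
#' @param counts Count tibble with `replicate` and `timepoint` columns.
#' @param exclusion_config Tibble (or list coercible to one) with columns
#'   among `assay`, `environment`, `replicate`, `timepoint`; each row
#'   removes the matching timepoint. Columns absent from `counts` are
#'   rejected.
#' @return The filtered count table.
#' @export
exclude_timepoints <- function(counts, exclusion_config) {
  if (is.null(exclusion_config) || NROW(exclusion_config) == 0L) {
    return(counts)
  }
  exclusion_config <- tibble::as_tibble(exclusion_config)
  unknown <- setdiff(names(exclusion_config), names(counts))
  if (length(unknown) > 0L) {
    stop("unknown keys in exclusion config: ", paste(unknown, collapse = ", "))
  }
  dplyr::anti_join(counts, exclusion_config, by = names(exclusion_config))
}

#' Assign barcodes to their home environment from sub-pool sequencing
#'
#' A barcode is assigned to an evolution environment iff it has at least
#' `min_reads` reads in total across the sub-pool libraries and strictly
#' more than `min_fraction` of those reads come from a single sub-pool.
#' Otherwise it is left `NA` (unassigned).
#'
#' @param subpool_counts Tibble with columns `lineage_bc` (optionally
#'   also `env_bc`), `subpool` (environment label of the sub-pool
#'   library), and `reads`.
#' @param min_reads Minimum total read support (default 3).
#' @param min_fraction Fraction of reads that must come from the top
#'   sub-pool, exceeded strictly (default 0.95).
#' @return Tibble with one row per barcode: key columns,
#'   `home_environment` (`NA` when unassigned), `total_reads`,
#'   `top_fraction`.
#' @export
assign_home_environment <- function(subpool_counts, min_reads = 3,
                                    min_fraction = 0.95) {
  keys <- intersect(c("env_bc", "lineage_bc"), names(subpool_counts))
  if (length(keys) == 0L) stop("subpool_counts needs a barcode key column")
  subpool_counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      total_reads = sum(.data$reads),
      top_fraction = max(tapply(.data$reads, .data$subpool, sum)) /
        sum(.data$reads),
      .top = names(which.max(tapply(.data$reads, .data$subpool, sum))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      home_environment = ifelse(
        .data$total_reads >= min_reads & .data$top_fraction > min_fraction,
        .data$.top, NA_character_
      )
    ) |>
    dplyr::select(dplyr::all_of(keys), "home_environment", "total_reads",
                  "top_fraction")
}
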