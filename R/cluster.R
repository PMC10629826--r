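#' Levenshtein (edit) distance
#'
#' Standard dynamic-programming edit distance with unit costs for
#' substitutions, insertions, and deletions. Symmetric, zero iff the
#' strings are equal, and satisfies the triangle inequality.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("ACGT", "AGT")
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  lv_pairs_cpp(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Single-base deletion set of a sequence
#'
#' Returns the sequence itself together with every string obtained by
#' deleting one base, duplicates collapsed. Self-inclusion makes the
#' overlap test detect single insertions and deletions as well as
#' substitutions: two barcodes share a deletion-set element iff they are
#' separated by about one edit.
#'
#' @param sequence A non-empty character scalar.
#' @return Character vector of deletion variants (including the input).
#' @export
#' @examples
#' deletion_set("ACGT")
deletion_set <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  n <- nchar(sequence)
  dels <- vapply(seq_len(n), function(p) {
    paste0(substr(sequence, 1L, p - 1L), substr(sequence, p + 1L, n))
  }, character(1))
  unique(c(sequence, dels))
}

# Deletion keys for many sequences at once: tibble(id, key). Sequences are
# grouped by length so the substring arithmetic stays vectorized.
deletion_keys <- function(sequences) {
  ids <- seq_along(sequences)
  lens <- nchar(sequences)
  out <- vector("list", length(unique(lens)) )
  k <- 0L
  for (len in sort(unique(lens))) {
    sel <- which(lens == len)
    x <- sequences[sel]
    keys <- c(x, unlist(lapply(seq_len(len), function(p) {
      paste0(substr(x, 1L, p - 1L), substr(x, p + 1L, len))
    })))
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      id = rep.int(sel, len + 1L),
      key = keys
    )
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# Candidate near-pairs: unique id pairs (i < j) whose deletion sets overlap.
candidate_pairs <- function(keys) {
  keys <- keys[keys$key %in% keys$key[duplicated(keys$key)], ]
  if (nrow(keys) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  groups <- split(keys$id, keys$key)
  pairs <- lapply(groups, function(g) {
    g <- unique(g)
    if (length(g) < 2L) return(NULL)
    t(utils::combn(sort(g), 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(pairs)
}

#' Group barcodes into deletion neighborhoods
#'
#' Builds the graph whose vertices are observed barcodes, with an edge
#' whenever two barcodes' single-base deletion sets overlap, and returns
#' its connected components ("deletion neighborhoods"). Every barcode
#' belongs to exactly one neighborhood; barcodes separated by one edit
#' (substitution, insertion, or deletion) always share a neighborhood.
#'
#' @param barcodes Tibble with columns `sequence`, `count`.
#' @return The input with a `neighborhood` integer column; the candidate
#'   near-pair index matrix is attached as attribute `"pairs"`.
#' @export
build_neighborhoods <- function(barcodes) {
  stopifnot(all(c("sequence", "count") %in% names(barcodes)))
  n <- nrow(barcodes)
  keys <- deletion_keys(barcodes$sequence)
  pairs <- candidate_pairs(keys)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs) > 0L) {
    g <- igraph::add_edges(g, t(pairs))
  }
  membership <- igraph::components(g)$membership
  out <- dplyr::mutate(barcodes, neighborhood = as.integer(membership))
  attr(out, "pairs") <- pairs
  out
}

# Deterministic processing order: descending count, lexicographic tie-break.
peak_order <- function(sequence, count) {
  order(-count, sequence)
}

#' Call peak barcodes within a deletion neighborhood
#'
#' Processes the neighborhood's barcodes in descending total count
#' (lexicographic tie-break) and accepts a barcode as a peak iff it
#' (1) contains no uncalled base `N`, (2) has no single-edit neighbor
#' with more total counts, (3) has more than 10 total counts, and
#' (4) is more than `max_edit` edits away from every already accepted
#' peak with more total counts.
#'
#' @param neighborhood Tibble with `sequence`, `count` for one
#'   neighborhood.
#' @param pairs Optional two-column matrix of candidate near-pair row
#'   indices (as produced by [build_neighborhoods()]); computed by
#'   all-pairs comparison when missing.
#' @param min_count Count that a peak must strictly exceed (default 10).
#' @param max_edit Edit radius used in criterion 4 and for error
#'   correction (default 3).
#' @return Character vector of peak sequences.
#' @export
call_peaks <- function(neighborhood, pairs = NULL, min_count = 10,
                       max_edit = 3) {
  seqs <- neighborhood$sequence
  cnts <- neighborhood$count
  m <- length(seqs)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
    colnames(pairs) <- NULL
  }
  # exact single-edit adjacency, verified on candidate pairs only
  adj <- vector("list", m)
  if (nrow(pairs) > 0L) {
    d <- lv_pairs_capped_cpp(seqs[pairs[, 1L]], seqs[pairs[, 2L]], 1L)
    one <- which(d == 1L)
    for (k in one) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  peaks <- integer(0)
  for (i in peak_order(seqs, cnts)) {
    if (has_n[i]) next
    if (cnts[i] <= min_count) next
    nb <- adj[[i]]
    if (length(nb) > 0L && any(cnts[nb] > cnts[i])) next
    if (length(peaks) > 0L) {
      bigger <- peaks[cnts[peaks] > cnts[i]]
      if (length(bigger) > 0L) {
        d <- lv_pairs_capped_cpp(rep(seqs[i], length(bigger)), seqs[bigger],
                                 max_edit)
        if (any(d <= max_edit)) next
      }
    }
    peaks <- c(peaks, i)
  }
  seqs[peaks]
}

#' Error-correct the non-peak barcodes of a neighborhood
#'
#' Each non-peak barcode corrects to a peak at Levenshtein distance at
#' most `max_edit`; when several peaks qualify it corrects to the one
#' with the higher total count (lexicographic tie-break). Non-peaks with
#' no peak within reach are discarded (`NA`). Peaks map to themselves.
#'
#' @param neighborhood Tibble with `sequence`, `count`.
#' @param peaks Character vector of peak sequences; computed with
#'   [call_peaks()] when missing.
#' @param max_edit Maximum correctable edit distance (default 3).
#' @inheritParams call_peaks
#' @return Tibble `sequence`, `count`, `corrected_to` (`NA` = discarded).
#' @export
correct_errors <- function(neighborhood, peaks = NULL, pairs = NULL,
                           min_count = 10, max_edit = 3) {
  if (is.null(peaks)) {
    peaks <- call_peaks(neighborhood, pairs = pairs, min_count = min_count,
                        max_edit = max_edit)
  }
  seqs <- neighborhood$sequence
  corrected <- rep(NA_character_, length(seqs))
  is_peak <- seqs %in% peaks
  corrected[is_peak] <- seqs[is_peak]
  non <- which(!is_peak)
  if (length(non) > 0L && length(peaks) > 0L) {
    pk_counts <- neighborhood$count[match(peaks, seqs)]
    ord <- order(-pk_counts, peaks)  # preference order among peaks
    dmat <- lv_cross_capped_cpp(seqs[non], peaks, max_edit)
    for (k in seq_along(non)) {
      ok <- ord[dmat[k, ord] <= max_edit]
      if (length(ok) > 0L) corrected[non[k]] <- peaks[ok[1L]]
    }
  }
  tibble::tibble(sequence = seqs, count = neighborhood$count,
                 corrected_to = corrected)
}

#' Cluster and error-correct a barcode count table
#'
#' End-to-end deletion-neighborhood error correction: neighborhoods are
#' built from overlapping single-base deletion sets, peaks are called
#' within each neighborhood, and every non-peak barcode is corrected to
#' a peak within `max_edit` edits or discarded. Environment and lineage
#' barcodes should be clustered separately.
#'
#' @param counts Tibble with columns `sequence` and `count` (total reads
#'   per distinct barcode sequence).
#' @inheritParams call_peaks
#' @return Tibble with `sequence`, `count`, `neighborhood`, `is_peak`,
#'   `corrected_to` (`NA` for discarded barcodes).
#' @export
cluster_barcodes <- function(counts, min_count = 10, max_edit = 3) {
  stopifnot(all(c("sequence", "count") %in% names(counts)))
  if (anyDuplicated(counts$sequence)) {
    counts <- counts |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  nb <- build_neighborhoods(counts)
  pairs <- attr(nb, "pairs")
  memb <- nb$neighborhood

  corrected <- rep(NA_character_, nrow(nb))
  is_peak <- rep(FALSE, nrow(nb))

  # singleton fast path
  sizes <- tabulate(memb)
  singleton <- sizes[memb] == 1L
  ok <- singleton & nb$count > min_count &
    !grepl("N", nb$sequence, fixed = TRUE)
  is_peak[ok] <- TRUE
  corrected[ok] <- nb$sequence[ok]

  multi <- which(!singleton)
  if (length(multi) > 0L) {
    pair_comp <- memb[pairs[, 1L]]
    pairs_by_comp <- split(seq_len(nrow(pairs)), pair_comp)
    for (comp in unique(memb[multi])) {
      rows <- which(memb == comp)
      sub <- nb[rows, c("sequence", "count")]
      local_pairs <- pairs[pairs_by_comp[[as.character(comp)]], , drop = FALSE]
      local_pairs <- cbind(match(local_pairs[, 1L], rows),
                           match(local_pairs[, 2L], rows))
      pk <- call_peaks(sub, pairs = local_pairs, min_count = min_count,
                       max_edit = max_edit)
      cor <- correct_errors(sub, peaks = pk, min_count = min_count,
                            max_edit = max_edit)
      corrected[rows] <- cor$corrected_to
      is_peak[rows] <- sub$sequence %in% pk
    }
  }

  dplyr::mutate(nb, is_peak = is_peak, corrected_to = corrected)
}

#' Aggregate corrected barcode pairs into centroids
#'
#' Applies independently derived correction maps for the environment and
#' lineage barcode classes to an observed count table, adds the counts of
#' error barcodes to their peaks, and drops corrected combinations whose
#' total count is 10 or fewer. Reads are conserved exactly: input total =
#' centroid total + discarded total.
#'
#' @param counts Tibble with `env_bc`, `lineage_bc`, `count` and any
#'   sample key columns (e.g. `library`, `replicate`, `timepoint`,
#'   `lane`), one row per observed combination per sample.
#' @param env_map,lineage_map Correction maps: tibbles with `sequence`,
#'   `corrected_to` from [cluster_barcodes()].
#' @param min_total Total count a centroid must strictly exceed
#'   (default 10).
#' @return Tibble of centroids with corrected `env_bc`, `lineage_bc`,
#'   sample keys, and summed `count`; attribute `"discarded"` holds the
#'   read-conservation tallies (`total_in`, `unassigned`, `low_count`,
#'   `kept`).
#' @export
build_centroids <- function(counts, env_map, lineage_map, min_total = 10) {
  keys <- setdiff(names(counts), c("env_bc", "lineage_bc", "count"))
  total_in <- sum(counts$count)

  env_lookup <- setNames(env_map$corrected_to, env_map$sequence)
  lin_lookup <- setNames(lineage_map$corrected_to, lineage_map$sequence)
  corr <- counts |>
    dplyr::mutate(
      env_bc = unname(env_lookup[.data$env_bc]),
      lineage_bc = unname(lin_lookup[.data$lineage_bc])
    )
  unassigned <- sum(corr$count[is.na(corr$env_bc) | is.na(corr$lineage_bc)])
  corr <- dplyr::filter(corr, !is.na(.data$env_bc), !is.na(.data$lineage_bc))

  agg <- corr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("env_bc", "lineage_bc",
                                                  keys)))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  totals <- agg |>
    dplyr::group_by(.data$env_bc, .data$lineage_bc) |>
    dplyr::summarise(.total = sum(.data$count), .groups = "drop")
  agg <- dplyr::left_join(agg, totals, by = c("env_bc", "lineage_bc"))
  low <- sum(agg$count[agg$.total <= min_total])
  out <- agg |>
    dplyr::filter(.data$.total > min_total) |>
    dplyr::select(-".total")

  attr(out, "discarded") <- list(
    total_in = total_in,
    unassigned = unassigned,
    low_count = low,
    kept = sum(out$count)
  )
  out
}

#' Intersect centroid tables across sequencing lanes
#'
#' Keeps only full barcodes (environment + lineage combination) observed
#' in every lane and sums their counts over lanes within the remaining
#' sample keys.
#'
#' @param centroids Centroid tibble containing a `lane` column.
#' @return Centroid tibble without the `lane` column.
#' @export
merge_lanes <- function(centroids) {
  if (!"lane" %in% names(centroids)) return(centroids)
  lanes <- unique(centroids$lane)
  keep <- centroids |>
    dplyr::distinct(.data$env_bc, .data$lineage_bc, .data$lane) |>
    dplyr::count(.data$env_bc, .data$lineage_bc) |>
    dplyr::filter(.data$n == length(lanes)) |>
    dplyr::select(-"n")
  keys <- setdiff(names(centroids), c("lane", "count"))
  centroids |>
    dplyr::inner_join(keep, by = c("env_bc", "lineage_bc")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Remove chimeric barcode combinations
#'
#' A centroid is removed when another centroid shares its lineage
#' (diverse) barcode under a different environment barcode and has at
#' least `ratio` times more total reads: such minor combinations arise
#' from PCR/sequencing chimeras that re-pair barcodes.
#'
#' @param centroids Centroid tibble.
#' @param ratio Read-count dominance ratio (default 100).
#' @return Filtered centroid tibble; removed combinations are attached
#'   as attribute `"chimeras"`.
#' @export
remove_chimeras <- function(centroids, ratio = 100) {
  totals <- centroids |>
    dplyr::group_by(.data$env_bc, .data$lineage_bc) |>
    dplyr::summarise(.total = sum(.data$count), .groups = "drop")
  flagged <- totals |>
    dplyr::group_by(.data$lineage_bc) |>
    dplyr::mutate(.max_other = {
      n <- dplyr::n()
      if (n > 1L) {
        vapply(seq_len(n), function(i) max(.data$.total[-i]), numeric(1))
      } else {
        rep(-Inf, n)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.max_other >= ratio * .data$.total)
  out <- dplyr::anti_join(centroids, flagged,
                          by = c("env_bc", "lineage_bc"))
  attr(out, "chimeras") <- dplyr::select(flagged, "env_bc", "lineage_bc",
                                         total = ".total")
  out
}
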