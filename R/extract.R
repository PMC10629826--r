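# Fuzzy-flank barcode extraction pattern. Group 2 captures the barcode
# (24-28 non-digit characters); the flank alternations each tolerate a
# single substitution (and, on the right, a single deletion).
BARCODE_PATTERN <- paste0(
  "\\D*?",
  "(GTACC|GGACC|GGTCC|G.TACC|GG.ACC|GGT.CC|GGTA.C|GGTAC.)",
  "(\\D{24,28})",
  "(.TAACT|A.AACT|AT.ACT|ATA.CT|ATAA.T|ATAAC|AAACT|ATACT|ATAAT)",
  "\\D*"
)

#' The barcode extraction regular expression
#'
#' Returns the pattern used by [extract_barcode()]: a lazily anchored
#' prefix, a left-flank alternation tolerating one substitution of
#' `GGTACC`, a 24--28 base barcode capture, and a right-flank alternation
#' tolerating one substitution or deletion of `ATAACT`.
#'
#' @return A character scalar (PCRE syntax).
#' @export
barcode_regex <- function() BARCODE_PATTERN

#' Extract a barcode from read sequence
#'
#' Searches each sequence for the fuzzy-flank pattern and returns the
#' barcode capture (group 2) of the leftmost match, or `NA` when the
#' pattern does not match. Extraction is position-shift invariant:
#' non-matching bases before the left flank do not change the capture.
#'
#' @param x Character vector of read sequences (the portion after the
#'   UMI and any inline index).
#' @return Character vector of barcodes (`NA` for non-matching reads).
#' @export
#' @examples
#' extract_barcode(paste0("TTTTTTTTTTGGTACC", strrep("A", 26),
#'                        "ATAACTTTTTTTTTTT"))
extract_barcode <- function(x) {
  extract_barcode_match(x)$barcode
}

# Barcode plus its span (1-based positions within x) for quality filtering.
extract_barcode_match <- function(x) {
  m <- regexec(BARCODE_PATTERN, x, perl = TRUE)
  starts <- vapply(m, function(mi) {
    if (mi[1] == -1L) NA_integer_ else mi[3]
  }, integer(1))
  lens <- vapply(m, function(mi) {
    if (mi[1] == -1L) NA_integer_ else attr(mi, "match.length")[3]
  }, integer(1))
  bc <- ifelse(is.na(starts), NA_character_,
               substr(x, starts, starts + lens - 1L))
  tibble::tibble(barcode = bc, start = starts, end = starts + lens - 1L)
}

#' Assign reads to libraries from inline indices
#'
#' Divides reads into libraries based on the inline index found
#' immediately after the UMI on read 1. Reads whose index matches no
#' table entry are assigned to the `"unassigned"` sink; with an empty
#' index table all reads fall into a single default library.
#'
#' @param reads Tibble with at least `seq1` (see [read_fastq_pair()]).
#' @param index_table Tibble with columns `index`, `library`. Duplicate
#'   index sequences are rejected.
#' @param umi_length UMI length on each mate (default 8).
#' @return `reads` with a `library` column added.
#' @export
demultiplex <- function(reads, index_table, umi_length = UMI_LENGTH) {
  if (is.null(index_table) || nrow(index_table) == 0L ||
      all(index_table$index == "")) {
    reads$library <- if (!is.null(index_table) && nrow(index_table) == 1L) {
      index_table$library
    } else {
      "library1"
    }
    return(reads)
  }
  if (anyDuplicated(index_table$index)) {
    stop("ambiguous index table: duplicate index sequences")
  }
  ilen <- unique(nchar(index_table$index))
  if (length(ilen) != 1L) {
    stop("all inline indices must have the same length")
  }
  obs <- substr(reads$seq1, umi_length + 1L, umi_length + ilen)
  map <- setNames(index_table$library, index_table$index)
  lab <- unname(map[obs])
  reads$library <- ifelse(is.na(lab), "unassigned", lab)
  reads
}

#' Mean-quality filter over the barcode regions
#'
#' Keeps a read pair iff the arithmetic mean Phred score over the
#' extracted barcode regions (both mates pooled) is at least
#' `min_quality`; a mean exactly at the threshold is kept.
#'
#' @param qual1,qual2 Quality strings of the regions that were searched
#'   (`qual2` optional).
#' @param span1,span2 Two-column matrices (start, end) of the barcode
#'   span within each searched region, as from the extraction step.
#' @param min_quality Minimum mean Phred score (default 30).
#' @param phred_offset ASCII offset of the encoding (default 33).
#' @return Logical vector: `TRUE` to keep.
#' @export
quality_filter <- function(qual1, span1, qual2 = NULL, span2 = NULL,
                           min_quality = 30, phred_offset = 33) {
  sum1 <- phred_region_stats(qual1, span1, phred_offset)
  if (!is.null(qual2)) {
    sum2 <- phred_region_stats(qual2, span2, phred_offset)
    mean_q <- (sum1$sum + sum2$sum) / (sum1$n + sum2$n)
  } else {
    mean_q <- sum1$sum / sum1$n
  }
  !is.na(mean_q) & mean_q >= min_quality
}

phred_region_stats <- function(qual, span, phred_offset) {
  region <- substr(qual, span[, 1L], span[, 2L])
  sums <- vapply(region, function(q) {
    if (is.na(q) || nchar(q) == 0L) return(NA_real_)
    sum(utf8ToInt(q)) - phred_offset * nchar(q)
  }, numeric(1), USE.NAMES = FALSE)
  list(sum = sums, n = nchar(region))
}

#' Drop duplicate-UMI observations within each library
#'
#' Within each library, at most one observation per UMI is retained (the
#' first in input order). The same UMI in different libraries is kept.
#' The operation never increases counts and is idempotent.
#'
#' @param observations Tibble with columns `library`, `umi`.
#' @return The deduplicated tibble.
#' @export
dedup_umis <- function(observations) {
  dplyr::distinct(observations, .data$library, .data$umi, .keep_all = TRUE)
}

#' Extract UMI-deduplicated barcode observations from read pairs
#'
#' Runs the full read-level pipeline: UMI construction (first 8 bases of
#' read 1 plus first 8 bases of read 2), inline-index demultiplexing,
#' fuzzy-flank barcode extraction on both mates, the mean-Q30 barcode
#' quality filter, and per-library UMI deduplication. By default read 1
#' carries the lineage (diverse) barcode and read 2 the environment
#' barcode; set `lineage_on = "read2"` to swap.
#'
#' @param reads Tibble from [read_fastq_pair()].
#' @param index_table Optional index table for [demultiplex()].
#' @param lineage_on Which mate carries the lineage barcode.
#' @param umi_length UMI length per mate.
#' @param min_quality Mean Phred threshold for the barcode regions.
#' @param phred_offset Quality encoding offset.
#' @param dedup Whether to apply UMI deduplication.
#' @return Tibble with `library`, `umi`, `env_bc`, `lineage_bc`; a QC
#'   list (`reads_in`, `no_match`, `quality_failed`, `duplicate_umis`,
#'   `kept`) is attached as attribute `"qc"`.
#' @export
extract_barcodes <- function(reads, index_table = NULL,
                             lineage_on = c("read1", "read2"),
                             umi_length = UMI_LENGTH, min_quality = 30,
                             phred_offset = 33, dedup = TRUE) {
  lineage_on <- match.arg(lineage_on)
  n_in <- nrow(reads)
  reads <- demultiplex(reads, index_table, umi_length = umi_length)

  ilen <- if (is.null(index_table) || nrow(index_table) == 0L) 0L else
    max(nchar(index_table$index))
  umi <- paste0(substr(reads$seq1, 1L, umi_length),
                substr(reads$seq2, 1L, umi_length))
  region1 <- substr(reads$seq1, umi_length + ilen + 1L, nchar(reads$seq1))
  rqual1 <- substr(reads$qual1, umi_length + ilen + 1L, nchar(reads$qual1))
  region2 <- substr(reads$seq2, umi_length + 1L, nchar(reads$seq2))
  rqual2 <- substr(reads$qual2, umi_length + 1L, nchar(reads$qual2))

  m1 <- extract_barcode_match(region1)
  m2 <- extract_barcode_match(region2)
  matched <- !is.na(m1$barcode) & !is.na(m2$barcode)

  keep_q <- quality_filter(rqual1, cbind(m1$start, m1$end),
                           rqual2, cbind(m2$start, m2$end),
                           min_quality = min_quality,
                           phred_offset = phred_offset)
  keep <- matched & !is.na(keep_q) & keep_q

  obs <- tibble::tibble(
    library = reads$library[keep],
    umi = umi[keep],
    env_bc = if (lineage_on == "read1") m2$barcode[keep] else m1$barcode[keep],
    lineage_bc = if (lineage_on == "read1") m1$barcode[keep] else
      m2$barcode[keep]
  )
  n_before_dedup <- nrow(obs)
  if (dedup) obs <- dedup_umis(obs)

  attr(obs, "qc") <- list(
    reads_in = n_in,
    no_match = sum(!matched),
    quality_failed = sum(matched & !(keep_q %in% TRUE)),
    duplicate_umis = n_before_dedup - nrow(obs),
    kept = nrow(obs)
  )
  obs
}

#' Count barcode observations per library
#'
#' @param observations Tibble from [extract_barcodes()].
#' @return Tibble of `library`, `env_bc`, `lineage_bc`, `count`.
#' @export
count_barcodes <- function(observations) {
  observations |>
    dplyr::count(.data$library, .data$env_bc, .data$lineage_bc,
                 name = "count") |>
    dplyr::arrange(.data$library, dplyr::desc(.data$count))
}
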