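# Fixed amplicon context emitted around each barcode. The left/right flanks
# are the sequences targeted by the extraction regex; the pads are construct
# context chosen free of flank-like motifs so an error-free read always
# matches at the true barcode.
LEFT_FLANK <- "GGTACC"
RIGHT_FLANK <- "ATAACT"
PAD_LEFT <- "CTCACTATCA"
PAD_RIGHT <- "CATCATCTCA"
UMI_LENGTH <- 8L

random_seq <- function(n, length) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
  apply(mat, 1, paste0, collapse = "")
}

# Apply iid per-base substitution errors to a character vector of sequences.
# Only sequences drawn to carry at least one error are touched.
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  hit <- which(n_err > 0L)
  if (length(hit) == 0L) return(seqs)
  seqs[hit] <- vapply(hit, function(i) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    paste0(chars, collapse = "")
  }, character(1))
  seqs
}

#' Emit paired-end amplicon reads from a simulated count table
#'
#' Expands a barcode count table into paired FASTQ files mimicking the
#' double-barcode amplicon design: read 1 carries an 8-base UMI, an
#' optional inline library index, and the lineage barcode between the
#' flanks `GGTACC`/`ATAACT` with 10 construct bases on either side;
#' read 2 carries an 8-base UMI and the environment barcode in the same
#' layout. Per-base substitution errors are applied once per molecule at
#' `config$base_error_rate`; with probability `config$chimera_rate` a
#' molecule's environment barcode is re-paired with that of another
#' sampled molecule; with probability `config$umi_duplication_rate` a
#' molecule emits a duplicate read pair reusing its UMI and post-error
#' sequence. All bases are written at Q40, Phred+33.
#'
#' @param counts Count tibble as produced by [simulate_pool()] (columns
#'   `replicate`, `timepoint`, `lane`, `env_bc`, `lineage_bc`, `count`).
#' @param config The [sim_config()] used to simulate the counts.
#' @param dir Output directory for the FASTQ files (one pair per lane).
#' @param index_table Optional tibble with columns `library`, `index`
#'   giving the inline index (placed after the UMI on read 1) for each
#'   `R<replicate>_T<timepoint>` library. Auto-generated when more than
#'   one library is present and no table is supplied.
#' @param seed Optional integer seed for read-level randomness.
#' @return A list with the FASTQ paths (`r1`, `r2`, per lane), the
#'   `index_table` used, and `n_pairs`, the number of read pairs written.
#' @export
emit_reads <- function(counts, config, dir, index_table = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  counts <- dplyr::filter(counts, .data$count > 0)
  lib <- sprintf("R%d_T%d", counts$replicate, counts$timepoint)
  libs <- sort(unique(lib))

  if (is.null(index_table)) {
    if (length(libs) > 1L) {
      index_table <- tibble::tibble(
        library = libs,
        index = random_barcodes(length(libs), 6L)
      )
    } else {
      index_table <- tibble::tibble(library = libs, index = "")
    }
  }
  idx <- setNames(index_table$index, index_table$library)

  # expand to molecules
  rows <- rep.int(seq_len(nrow(counts)), counts$count)
  mol <- counts[rows, c("env_bc", "lineage_bc", "lane")]
  mol$library <- lib[rows]
  n <- nrow(mol)

  # chimeras: re-pair the environment barcode with another molecule's
  if (config$chimera_rate > 0 && n > 1L) {
    is_chim <- rbinom(n, 1L, config$chimera_rate) == 1L
    if (any(is_chim)) {
      donor <- sample.int(n, sum(is_chim), replace = TRUE)
      mol$env_bc[is_chim] <- mol$env_bc[donor]
    }
  }

  umi1 <- random_seq(n, UMI_LENGTH)
  umi2 <- random_seq(n, UMI_LENGTH)
  seq1 <- paste0(umi1, idx[mol$library], PAD_LEFT, LEFT_FLANK,
                 mol$lineage_bc, RIGHT_FLANK, PAD_RIGHT)
  seq2 <- paste0(umi2, PAD_LEFT, LEFT_FLANK, mol$env_bc, RIGHT_FLANK,
                 PAD_RIGHT)
  seq1 <- mutate_bases(seq1, config$base_error_rate)
  seq2 <- mutate_bases(seq2, config$base_error_rate)

  # UMI duplicates: exact copies of the post-error molecule
  if (config$umi_duplication_rate > 0) {
    dup <- which(rbinom(n, 1L, config$umi_duplication_rate) == 1L)
    if (length(dup) > 0L) {
      seq1 <- c(seq1, seq1[dup])
      seq2 <- c(seq2, seq2[dup])
      mol <- dplyr::bind_rows(mol, mol[dup, ])
    }
  }

  ids <- sprintf("read_%07d", seq_len(length(seq1)))
  out_r1 <- character(0)
  out_r2 <- character(0)
  lanes <- sort(unique(mol$lane))
  for (lane in lanes) {
    sel <- which(mol$lane == lane)
    suffix <- if (length(lanes) > 1L) sprintf("_L%d", lane) else ""
    f1 <- file.path(dir, sprintf("reads%s_R1.fastq", suffix))
    f2 <- file.path(dir, sprintf("reads%s_R2.fastq", suffix))
    write_fastq(f1, ids[sel], seq1[sel])
    write_fastq(f2, ids[sel], seq2[sel])
    out_r1 <- c(out_r1, f1)
    out_r2 <- c(out_r2, f2)
  }

  list(r1 = out_r1, r2 = out_r2, lanes = lanes, index_table = index_table,
       n_pairs = length(seq1))
}

write_fastq <- function(path, ids, seqs) {
  qual <- strrep("I", nchar(seqs))
  rec <- character(4L * length(ids))
  rec[seq(1L, length(rec), by = 4L)] <- paste0("@", ids)
  rec[seq(2L, length(rec), by = 4L)] <- seqs
  rec[seq(3L, length(rec), by = 4L)] <- "+"
  rec[seq(4L, length(rec), by = 4L)] <- qual
  writeLines(rec, path)
  invisible(path)
}

#' Read a pair of FASTQ files into a tibble
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files (optionally
#'   gzipped).
#' @return Tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(s1) != length(s2)) {
    stop("mate files differ in read count")
  }
  tibble::tibble(
    id = names(s1),
    seq1 = as.character(s1),
    qual1 = as.character(S4Vectors::mcols(s1)$qualities),
    seq2 = as.character(s2),
    qual2 = as.character(S4Vectors::mcols(s2)$qualities)
  )
}
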