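# Shared helpers for building small in-code fixtures and independent
# oracles. Nothing here touches the implementation paths it checks.

# A minimal read pair whose mate 1 carries `lineage_bc` and mate 2
# `env_bc`, in the emitted amplicon layout (UMI + optional index + pads).
make_read_pair <- function(lineage_bc, env_bc, umi1 = strrep("A", 8),
                           umi2 = strrep("C", 8), index = "", q = "I") {
  seq1 <- paste0(umi1, index, "CTCACTATCA", "GGTACC", lineage_bc,
                 "ATAACT", "CATCATCTCA")
  seq2 <- paste0(umi2, "CTCACTATCA", "GGTACC", env_bc, "ATAACT",
                 "CATCATCTCA")
  tibble::tibble(
    id = "r1",
    seq1 = seq1, qual1 = strrep(q, nchar(seq1)),
    seq2 = seq2, qual2 = strrep(q, nchar(seq2))
  )
}

# Independent neighborhood oracle: all-pairs deletion-set intersection,
# connected components by label propagation (no hashing, no igraph).
naive_neighborhoods <- function(sequences) {
  n <- length(sequences)
  sets <- lapply(sequences, pleiofit::deletion_set)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (comp[i] != comp[j] &&
            length(intersect(sets[[i]], sets[[j]])) > 0L) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Normalize a membership vector so two partitions can be compared.
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# Random DNA sequences (test-local generator, independent of the
# package's barcode machinery).
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = "")
  }, character(1))
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
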