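test_that("deletion sets include self and collapse duplicates", {
  expect_setequal(deletion_set("ACGT"),
                  c("ACGT", "CGT", "AGT", "ACT", "ACG"))
  expect_setequal(deletion_set("AAA"), c("AAA", "AA"))
  set.seed(4)
  bc <- rand_dna(1, 26)
  expect_lte(length(deletion_set(bc)), 27L)
  expect_error(deletion_set(""), "non-empty")
})

test_that("levenshtein distance matches the independent DP oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "AGT"), 1L)
  expect_equal(levenshtein("", "ACGT"), 4L)
  set.seed(7)
  a <- rand_dna(200, 26)
  b <- c(rand_dna(100, 26), rand_dna(50, 25), rand_dna(50, 27))
  ours <- levenshtein(a, b)
  oracle <- mapply(function(x, y) drop(utils::adist(x, y)), a, b)
  expect_equal(ours, unname(oracle))
  # symmetry and triangle inequality on a few triples
  c3 <- rand_dna(50, 26)
  expect_equal(levenshtein(a[1:50], c3), levenshtein(c3, a[1:50]))
  expect_true(all(levenshtein(a[1:50], b[1:50]) <=
                    levenshtein(a[1:50], c3) + levenshtein(c3, b[1:50])))
})

test_that("neighborhoods are connected components of deletion-set overlap", {
  set.seed(8)
  distant <- rand_dna(12, 26)  # random 26-mers are pairwise far apart
  tbl <- tibble::tibble(sequence = distant, count = 100)
  nb <- build_neighborhoods(tbl)
  expect_equal(length(unique(nb$neighborhood)), 12L)

  # a substitution variant joins its source
  v <- paste0(ifelse(substr(distant[1], 1, 1) == "A", "C", "A"),
              substr(distant[1], 2, 26))
  tbl2 <- tibble::tibble(sequence = c(distant[1], v), count = c(100, 5))
  nb2 <- build_neighborhoods(tbl2)
  expect_equal(nb2$neighborhood[1], nb2$neighborhood[2])

  # transitive connection: d(X,Y) = 1, d(Y,Z) = 1, d(X,Z) = 2
  x <- strrep("ACGT", 6)  # 24-mer within barcode bounds
  y <- sub("^A", "T", x)
  z <- sub("G", "C", y)
  expect_equal(levenshtein(x, z), 2L)
  nb3 <- build_neighborhoods(tibble::tibble(sequence = c(x, y, z),
                                            count = c(9, 5, 2)))
  expect_equal(length(unique(nb3$neighborhood)), 1L)
  expect_equal(canonical_partition(nb3$neighborhood),
               canonical_partition(naive_neighborhoods(c(x, y, z))))
})

test_that("hashed neighborhoods equal the naive all-pairs construction", {
  set.seed(9)
  centers <- rand_dna(20, 26)
  variants <- unlist(lapply(centers, function(b) {
    vapply(1:9, function(i) {
      p <- sample(26, 1)
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, p, p)), 1)
      b
    }, character(1))
  }))
  seqs <- unique(c(centers, variants))
  nb <- build_neighborhoods(tibble::tibble(sequence = seqs, count = 10))
  expect_equal(canonical_partition(nb$neighborhood),
               canonical_partition(naive_neighborhoods(seqs)))
})

test_that("peak criteria boundaries follow the counting rules", {
  # single barcode: peak needs strictly more than 10 counts and no N
  expect_equal(call_peaks(tibble::tibble(sequence = "ACGTACGT", count = 11)),
               "ACGTACGT")
  expect_equal(call_peaks(tibble::tibble(sequence = "ACGTACGT", count = 10)),
               character(0))
  expect_equal(call_peaks(tibble::tibble(sequence = "ACGTNCGT", count = 50)),
               character(0))
  # a single-edit neighbor with more counts blocks the smaller barcode
  a <- strrep("AC", 13)
  b <- sub("^A", "G", a)
  nb <- tibble::tibble(sequence = c(a, b), count = c(100, 50))
  expect_equal(call_peaks(nb), a)
  # equal-count single-edit neighbors: neither blocks the other
  nb_eq <- tibble::tibble(sequence = c(a, b), count = c(50, 50))
  expect_setequal(call_peaks(nb_eq), c(a, b))
})

test_that("error correction respects the 3-edit radius and count ties", {
  peak <- strrep("ACGT", 6)
  sub1 <- function(x, i, to) {
    substr(x, i, i) <- to
    x
  }
  at3 <- sub1(sub1(sub1(peak, 1, "T"), 5, "G"), 9, "T")
  at4 <- sub1(at3, 13, "G")
  expect_equal(levenshtein(peak, at3), 3L)
  expect_equal(levenshtein(peak, at4), 4L)
  nb <- tibble::tibble(sequence = c(peak, at3, at4),
                       count = c(100, 5, 4))
  out <- correct_errors(nb, peaks = peak)
  expect_equal(out$corrected_to[out$sequence == at3], peak)
  expect_true(is.na(out$corrected_to[out$sequence == at4]))

  # within reach of two peaks: corrects to the higher-count peak
  p1 <- strrep("A", 26)
  p2 <- sub1(sub1(p1, 3, "G"), 7, "G")           # d(p1, p2) = 2
  mid <- sub1(p1, 3, "G")                        # d = 1 to both
  nb2 <- tibble::tibble(sequence = c(p1, p2, mid),
                        count = c(200, 90, 5))
  out2 <- correct_errors(nb2, peaks = c(p1, p2))
  expect_equal(out2$corrected_to[out2$sequence == mid], p1)
  # every peak maps to itself
  expect_equal(out2$corrected_to[out2$sequence %in% c(p1, p2)], c(p1, p2))
})

test_that("correction is idempotent on corrected output", {
  set.seed(10)
  true_bc <- rand_dna(10, 26)
  errs <- vapply(true_bc, function(b) {
    p <- sample(26, 1)
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(b, p, p)), 1)
    b
  }, character(1), USE.NAMES = FALSE)
  tbl <- tibble::tibble(sequence = c(true_bc, errs),
                        count = c(rep(500, 10), rep(3, 10)))
  res <- cluster_barcodes(tbl)
  expect_true(all(res$corrected_to[match(errs, res$sequence)] == true_bc))
  # every correction target is a peak
  expect_true(all(stats::na.omit(res$corrected_to) %in%
                    res$sequence[res$is_peak]))
  # rerun on the corrected totals: nothing changes
  corrected <- res |>
    dplyr::filter(!is.na(corrected_to)) |>
    dplyr::count(sequence = corrected_to, wt = count, name = "count")
  res2 <- cluster_barcodes(corrected)
  expect_true(all(res2$is_peak))
  expect_equal(res2$corrected_to, res2$sequence)
})

test_that("centroid construction conserves reads and applies thresholds", {
  env <- strrep("A", 26)
  lin1 <- strrep("C", 26)
  lin2 <- strrep("G", 26)
  lin1_err <- sub("^C", "T", lin1)
  id_map <- function(seqs) tibble::tibble(sequence = seqs,
                                          corrected_to = seqs)
  env_map <- id_map(env)
  lin_map <- tibble::tibble(
    sequence = c(lin1, lin2, lin1_err),
    corrected_to = c(lin1, lin2, lin1)
  )
  counts <- tibble::tibble(
    library = "s1",
    env_bc = env,
    lineage_bc = c(lin1, lin2, lin1_err),
    count = c(8, 10, 3)
  )
  out <- build_centroids(counts, env_map, lin_map)
  # lin1 centroid: 8 + 3 error reads = 11 > 10 kept; lin2 at 10 dropped
  expect_equal(nrow(out), 1L)
  expect_equal(out$lineage_bc, lin1)
  expect_equal(out$count, 11)
  disc <- attr(out, "discarded")
  expect_equal(disc$total_in, disc$kept + disc$unassigned + disc$low_count)
  expect_equal(disc$low_count, 10)
})

test_that("lane merging keeps only barcodes present in every lane", {
  cent <- tibble::tibble(
    env_bc = "E", lineage_bc = c("a", "a", "a", "b", "b", "c"),
    lane = c(1L, 2L, 3L, 1L, 2L, 2L),
    count = c(10, 20, 30, 5, 5, 7)
  )
  out <- merge_lanes(cent)
  expect_equal(out$lineage_bc, "a")
  expect_equal(out$count, 60)
  one_lane <- dplyr::filter(cent, lane == 2L)
  out1 <- merge_lanes(one_lane)
  expect_setequal(out1$lineage_bc, c("a", "b", "c"))
})

test_that("chimera removal uses the 100x dominance rule", {
  cent <- tibble::tibble(
    env_bc = c("E1", "E2", "E1", "E3", "E4"),
    lineage_bc = c("D1", "D1", "D2", "D2", "D3"),
    count = c(50000, 400, 50000, 600, 12)
  )
  out <- remove_chimeras(cent)
  expect_false(any(out$env_bc == "E2" & out$lineage_bc == "D1"))  # 125x
  expect_true(any(out$env_bc == "E3" & out$lineage_bc == "D2"))   # 83x
  expect_true(any(out$lineage_bc == "D3"))                        # unique
})
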