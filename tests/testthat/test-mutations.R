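test_that("mutation strings classify by the table dialect", {
  out <- classify_mutation(c("P261L", "Q107*", "I416_fs", "646403A>C",
                             "S753SVYRSFAHYS", "+/C862Y", "E701*_fs",
                             "131054G>GT", "M1T"))
  expect_equal(out$class,
               c("missense", "nonsense", "coding_indel", "noncoding",
                 "coding_indel", "missense", "coding_indel", "noncoding",
                 "missense"))
  expect_equal(out$heterozygous,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                 FALSE))
  expect_equal(out$mutation[6], "C862Y")  # prefix stripped
  expect_error(classify_mutation("what-is-this"), "unclassifiable")
})

test_that("the packaged spectrum matches the curated totals", {
  fx <- adaptive_mutation_fixture()
  spec <- tabulate_spectrum(fx)
  expected <- tibble::tribble(
    ~environment, ~ploidy, ~gene, ~total,
    "CLM", "2N", "PDR1", 15L, "CLM", "2N", "PDR3", 5L,
    "CLM", "1N", "PDR1", 29L, "CLM", "1N", "PDR3", 7L,
    "FLC4", "2N", "CYC8", 2L, "FLC4", "2N", "HAP1", 1L,
    "FLC4", "2N", "PDR1", 1L, "FLC4", "2N", "SSO2", 2L,
    "FLC4", "2N", "TUP1", 3L, "FLC4", "2N", "VPS35", 2L,
    "FLC4", "2N", "YHK8", 2L,
    "FLC4", "1N", "CSG2", 3L, "FLC4", "1N", "CYC8", 4L,
    "FLC4", "1N", "HAP1", 2L, "FLC4", "1N", "PDR1", 2L,
    "FLC4", "1N", "PDR3", 2L, "FLC4", "1N", "PDR5", 4L,
    "FLC4", "1N", "ROX1", 3L, "FLC4", "1N", "SKN7", 4L,
    "FLC4", "1N", "SUR1", 11L, "FLC4", "1N", "SXM1", 3L,
    "FLC4", "1N", "TUP1", 1L, "FLC4", "1N", "UPC2", 3L,
    "GlyEtOH", "2N", "HAP1", 3L, "GlyEtOH", "2N", "HEM2", 2L,
    "GlyEtOH", "2N", "HEM3", 7L, "GlyEtOH", "2N", "IRA1", 1L,
    "GlyEtOH", "2N", "IRA2", 1L, "GlyEtOH", "2N", "NDI1", 2L,
    "GlyEtOH", "2N", "WHI2", 4L,
    "GlyEtOH", "1N", "GPB2", 2L, "GlyEtOH", "1N", "IRA1", 19L,
    "GlyEtOH", "1N", "IRA2", 9L, "GlyEtOH", "1N", "SSK2", 2L,
    "GlyEtOH", "1N", "WHI2", 1L, "GlyEtOH", "1N", "YTA6", 2L
  )
  expect_equal(nrow(spec), nrow(expected))
  merged <- dplyr::left_join(expected, spec,
                             by = c("environment", "ploidy", "gene"))
  expect_equal(merged$total.y, merged$total.x)
  # class counts always sum to the row total
  expect_equal(spec$missense + spec$nonsense + spec$coding_indel +
                 spec$noncoding, spec$total)
  # empty input gives an empty table
  expect_equal(nrow(tabulate_spectrum(fx[0, ])), 0L)
})

test_that("ploidy overlap partitions adaptive genes per environment", {
  ov <- ploidy_overlap(tabulate_spectrum(adaptive_mutation_fixture()))
  clm <- dplyr::filter(ov, environment == "CLM")
  expect_setequal(clm$gene[clm$category == "shared"], c("PDR1", "PDR3"))
  expect_equal(sum(clm$category != "shared"), 0L)
  gly <- dplyr::filter(ov, environment == "GlyEtOH")
  expect_setequal(gly$gene[gly$category == "shared"],
                  c("IRA1", "IRA2", "WHI2"))
  expect_setequal(gly$gene[gly$category == "diploid_only"],
                  c("HAP1", "HEM2", "HEM3", "NDI1"))
  expect_setequal(gly$gene[gly$category == "haploid_only"],
                  c("GPB2", "SSK2", "YTA6"))
  # single-ploidy input: everything exclusive to that ploidy
  hap <- ploidy_overlap(tibble::tibble(environment = "X", ploidy = "1N",
                                       gene = c("G1", "G2")))
  expect_true(all(hap$category == "haploid_only"))
})

make_variants <- function() {
  # 20 clones from one evolution condition, each with a private variant,
  # then targeted rows exercising the individual filters.
  v <- tibble::tibble(
    clone = sprintf("c%02d", 1:20),
    condition = "CLM_1N",
    ploidy = "1N",
    chrom = "chr4",
    pos = 1000L + 1:20,
    ref = "A", alt = "T",
    gene = sprintf("GENE%02d", 1:20),
    effect = "missense",
    zygosity = "hom",
    quality = 500,
    mean_coverage = 50,
    ref_depth = 10,
    alt_depth = 10
  )
  v$chrom[1] <- "chrM"; v$gene[1] <- "COX1"
  v$gene[2] <- "FLO1"
  # same variant shared by clones 3..7: 5/20 = 25% of the condition
  v$chrom[3:7] <- "chr7"; v$pos[3:7] <- 400L; v$gene[3:7] <- "BCKG"
  v$quality[8] <- 100
  v$mean_coverage[9] <- 8
  v$zygosity[10] <- "het"; v$ref_depth[10] <- 30; v$alt_depth[10] <- 9
  v
}

test_that("variant filters drop and flag by the documented thresholds", {
  v <- make_variants()
  out <- filter_variants(v)
  row <- function(cl) out[out$clone == cl, ]
  # a private variant in 1/20 clones (5% <= 12%) passes all filters
  expect_true(row("c11")$kept)
  expect_equal(row("c01")$reason, "mitochondrial")
  expect_equal(row("c02")$reason, "flo_gene")
  # chr7:400 A>T present in 5 of 20 clones = 25% > 12%: background
  expect_equal(unique(out$reason[out$pos == 400]), "background")
  # quality 100 < 150 dropped, unless whitelisted
  expect_equal(row("c08")$reason, "low_quality")
  out_keep <- filter_variants(v, overrides = list(keep = "chr4:1008:A:T"))
  expect_true(out_keep$kept[out_keep$clone == "c08"])
  # haploid clone with mean coverage 8 < 10 dropped
  expect_equal(row("c09")$reason, "low_coverage_clone")
  # het with ref:alt = 30:9 (3.33 > 3) is flagged but kept
  expect_true(row("c10")$kept)
  expect_true(row("c10")$contamination_suspect)
  # het at exactly 3:1 is not flagged
  v31 <- v; v31$zygosity[11] <- "het"
  v31$ref_depth[11] <- 30; v31$alt_depth[11] <- 10
  out31 <- filter_variants(v31)
  expect_false(out31$contamination_suspect[out31$clone == "c11"])
  # explicit drop override wins
  out_drop <- filter_variants(v, overrides = list(drop = "chr4:1011:A:T"))
  expect_false(out_drop$kept[out_drop$clone == "c11"])
  expect_error(filter_variants(v, overrides = list(banana = "x")),
               "unknown override keys")
})

test_that("variant filtering is order independent", {
  v <- make_variants()
  out1 <- filter_variants(v)
  set.seed(20)
  shuffled <- v[sample(nrow(v)), ]
  out2 <- filter_variants(shuffled)
  key <- function(d) paste(d$clone, d$chrom, d$pos)
  expect_equal(out2$kept[match(key(out1), key(out2))], out1$kept)
  expect_equal(out2$reason[match(key(out1), key(out2))], out1$reason)
})

test_that("adaptive genes require recurrence, benefit, and coding hits", {
  variants <- tibble::tibble(
    clone = c("a", "b", "c", "d", "e", "f", "g", "h"),
    condition = "FLC4_1N",
    gene = c("GOOD", "GOOD", "ONEHIT", "BAD", "BAD", "PROM", "PROM",
             "ALLOWED"),
    mutation = c("A1T", "G2C", "C3G", "T4A", "T5G", "100A>T", "200G>C",
                 "A6V"),
    effect = c("missense", "missense", "missense", "missense", "missense",
               "noncoding", "noncoding", "missense")
  )
  fitness <- tibble::tibble(
    lineage = letters[1:8],
    s_hat = c(0.1, 0.15, 0.2, -0.05, -0.06, 0.2, 0.3, 0.5)
  )
  res <- identify_adaptive_genes(variants, fitness,
                                 allowlist = "ALLOWED")
  g <- res$genes
  expect_true(g$adaptive[g$gene == "GOOD"])
  expect_false(g$adaptive[g$gene == "ONEHIT"])   # one lineage only
  expect_false(g$adaptive[g$gene == "BAD"])      # median fitness < 0
  expect_false(g$adaptive[g$gene == "PROM"])     # non-coding only
  expect_true(g$adaptive[g$gene == "ALLOWED"])   # curated allowlist
  expect_true(all(res$candidates$gene %in% c("GOOD", "ALLOWED")))
  # carriers without fitness defer the gene with a warning
  expect_warning(
    identify_adaptive_genes(variants,
                            tibble::tibble(lineage = "zz", s_hat = 1)),
    "deferred"
  )
})

test_that("clone barcode matching needs 2 reads and 3x dominance", {
  known <- c(strrep("A", 26), strrep("C", 26))
  sub1 <- function(x, i, to) {
    substr(x, i, i) <- to
    x
  }
  mk <- function(clone, bcs, reads) {
    tibble::tibble(clone = clone, barcode = bcs, reads = reads)
  }
  # 6 vs 2 reads: assigned (3x exactly)
  out <- match_clone_barcodes(mk("cl1", known, c(6, 2)), known)
  expect_equal(out$barcode, known[1])
  # 5 vs 2: 2.5x < 3x, unassigned
  out <- match_clone_barcodes(mk("cl2", known, c(5, 2)), known)
  expect_true(is.na(out$barcode))
  # single read: unassigned
  out <- match_clone_barcodes(mk("cl3", known[1], 1), known)
  expect_true(is.na(out$barcode))
  # single-error extracted barcodes correct to the known barcode
  err <- sub1(known[1], 4, "G")
  out <- match_clone_barcodes(mk("cl4", c(known[1], err), c(2, 1)), known)
  expect_equal(out$barcode, known[1])
  expect_equal(out$reads, 3)
})
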