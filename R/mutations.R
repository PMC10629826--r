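MUTATION_CLASSES <- c("missense", "nonsense", "coding_indel", "noncoding")

#' Classify mutation strings
#'
#' Parses the compact mutation dialect used in adaptive-mutation tables:
#' `X123Y` is missense, `X123*` nonsense, anything ending in `_fs` a
#' frameshift (coding in/del), `pos REF>ALT` (e.g. `646403A>C`)
#' non-coding, multi-residue strings (e.g. `ILV1729I`) in-frame coding
#' in/dels, and a `+/` prefix marks a heterozygous call in diploids.
#'
#' @param mutation Character vector of mutation strings.
#' @return Tibble with `mutation` (prefix stripped), `heterozygous`, and
#'   `class` (one of `missense`, `nonsense`, `coding_indel`,
#'   `noncoding`). Unclassifiable strings raise an error naming the
#'   offender.
#' @export
#' @examples
#' classify_mutation(c("P261L", "Q107*", "I416_fs", "646403A>C"))
classify_mutation <- function(mutation) {
  het <- stringr::str_starts(mutation, stringr::fixed("+/"))
  body <- stringr::str_remove(mutation, "^\\+/")
  cls <- dplyr::case_when(
    stringr::str_detect(body, "^\\d+[ACGTacgt]+>[ACGTacgt]+$") ~ "noncoding",
    stringr::str_detect(body, "_fs$") ~ "coding_indel",
    stringr::str_detect(body, "\\*$") ~ "nonsense",
    stringr::str_detect(body, "^[A-Z]\\d+[A-Z]$") ~ "missense",
    stringr::str_detect(body, "^[A-Z]+\\d+[A-Z]+$") ~ "coding_indel",
    TRUE ~ NA_character_
  )
  if (anyNA(cls)) {
    stop("unclassifiable mutation string(s): ",
         paste(unique(body[is.na(cls)]), collapse = ", "))
  }
  tibble::tibble(mutation = body, heterozygous = het, class = cls)
}

#' Packaged table of curated adaptive mutations
#'
#' Loads the packaged transcription of the curated adaptive-mutation
#' lists from the three focal evolution conditions (clotrimazole `CLM`,
#' fluconazole `FLC4`, glycerol/ethanol `GlyEtOH`), for haploid (`1N`)
#' and diploid (`2N`) populations. One row per unique mutation within a
#' (home environment, ploidy, gene) cell; heterozygous diploid calls
#' keep their `+/` prefix in `mutation`.
#'
#' @return Tibble with columns `environment`, `ploidy`, `gene`,
#'   `mutation`, `class`.
#' @export
adaptive_mutation_fixture <- function() {
  path <- system.file("extdata", "adaptive_mutations.tsv",
                      package = "pleiofit", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccccc")
}

#' Tabulate a mutational spectrum
#'
#' Counts distinct mutation strings per (environment, ploidy, gene)
#' cell, broken down by mutation class. Class counts sum to the cell
#' total by construction.
#'
#' @param entries Tibble with `environment`, `ploidy`, `gene`,
#'   `mutation`, and optionally `class`; when `class` is absent it is
#'   derived with [classify_mutation()].
#' @return Tibble with one row per cell: `environment`, `ploidy`,
#'   `gene`, `total`, `missense`, `nonsense`, `coding_indel`,
#'   `noncoding`.
#' @export
tabulate_spectrum <- function(entries) {
  if (nrow(entries) == 0L) {
    return(tibble::tibble(
      environment = character(0), ploidy = character(0), gene = character(0),
      total = integer(0), missense = integer(0), nonsense = integer(0),
      coding_indel = integer(0), noncoding = integer(0)
    ))
  }
  if (!"class" %in% names(entries)) {
    entries$class <- classify_mutation(entries$mutation)$class
  }
  bad <- setdiff(unique(entries$class), MUTATION_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown mutation class(es): ", paste(bad, collapse = ", "))
  }
  entries |>
    dplyr::group_by(.data$environment, .data$ploidy, .data$gene) |>
    dplyr::summarise(
      total = dplyr::n_distinct(.data$mutation),
      missense = dplyr::n_distinct(.data$mutation[.data$class == "missense"]),
      nonsense = dplyr::n_distinct(.data$mutation[.data$class == "nonsense"]),
      coding_indel = dplyr::n_distinct(
        .data$mutation[.data$class == "coding_indel"]),
      noncoding = dplyr::n_distinct(
        .data$mutation[.data$class == "noncoding"]),
      .groups = "drop"
    )
}

#' Partition adaptive genes by ploidy of origin
#'
#' For each environment, classifies every mutated gene as haploid-only,
#' diploid-only, or shared, according to the ploidies in which it
#' acquired mutations.
#'
#' @param spectrum Output of [tabulate_spectrum()] (or any tibble with
#'   `environment`, `ploidy`, `gene`).
#' @return Tibble with `environment`, `gene`, `in_haploid`,
#'   `in_diploid`, `category` (`"shared"`, `"haploid_only"`,
#'   `"diploid_only"`).
#' @export
ploidy_overlap <- function(spectrum) {
  spectrum |>
    dplyr::distinct(.data$environment, .data$gene, .data$ploidy) |>
    dplyr::group_by(.data$environment, .data$gene) |>
    dplyr::summarise(
      in_haploid = any(.data$ploidy == "1N"),
      in_diploid = any(.data$ploidy == "2N"),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$in_haploid & .data$in_diploid ~ "shared",
      .data$in_haploid ~ "haploid_only",
      TRUE ~ "diploid_only"
    ))
}

MITO_NAMES <- c("chrM", "chrMT", "M", "MT", "Mito", "mito", "chrmt")

#' Filter externally called variants
#'
#' Applies the standard downstream filters to a variant table produced
#' by external callers: mitochondrial variants and variants in `FLO1` /
#' `FLO9` (poor alignment) are dropped; clones below the ploidy-specific
#' mean-coverage floor are dropped entirely; variants present in more
#' than `background_threshold` of the clones from the same evolutionary
#' condition are dropped as background; variants below the quality floor
#' are dropped unless whitelisted. Heterozygous variants with a ref:alt
#' depth ratio above `ratio_flag` are flagged (not dropped) as suspected
#' low-frequency contamination. Manual curation is represented by
#' explicit override lists. The result is independent of row order.
#'
#' @param variants Tibble with columns `clone`, `condition`, `ploidy`
#'   (`"1N"`/`"2N"`), `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`,
#'   `zygosity` (`"het"`/`"hom"`), `quality`, `mean_coverage`,
#'   `ref_depth`, `alt_depth`.
#' @param background_threshold Fraction of same-condition clones above
#'   which a variant is background (strictly greater; default 0.12).
#' @param quality_min Minimum variant quality score (default 150).
#' @param cov_min Named vector of mean-coverage floors per ploidy
#'   (default `c("1N" = 10, "2N" = 15)`).
#' @param ratio_flag Ref:alt ratio above which a heterozygous variant is
#'   flagged as suspected contamination (default 3).
#' @param overrides List with optional elements `keep` and `drop`:
#'   character vectors of variant keys (`"chrom:pos:ref:alt"`). `keep`
#'   rescues variants from the quality filter; `drop` removes variants
#'   unconditionally. Any other element name is rejected.
#' @return The input tibble with added columns `kept` (logical),
#'   `reason` (`NA` for kept rows), and `contamination_suspect`.
#' @export
filter_variants <- function(variants,
                            background_threshold = 0.12,
                            quality_min = 150,
                            cov_min = c("1N" = 10, "2N" = 15),
                            ratio_flag = 3,
                            overrides = list()) {
  unknown <- setdiff(names(overrides), c("keep", "drop"))
  if (length(unknown) > 0L) {
    stop("unknown override keys: ", paste(unknown, collapse = ", "))
  }
  keep_keys <- overrides$keep %||% character(0)
  drop_keys <- overrides$drop %||% character(0)

  v <- variants |>
    dplyr::mutate(.key = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                               sep = ":"))
  clones_per_cond <- v |>
    dplyr::distinct(.data$condition, .data$clone) |>
    dplyr::count(.data$condition, name = ".n_clones")
  carrier <- v |>
    dplyr::distinct(.data$condition, .data$.key, .data$clone) |>
    dplyr::count(.data$condition, .data$.key, name = ".n_carriers")

  v <- v |>
    dplyr::left_join(clones_per_cond, by = "condition") |>
    dplyr::left_join(carrier, by = c("condition", ".key")) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$.key %in% drop_keys ~ "override_drop",
        .data$chrom %in% MITO_NAMES ~ "mitochondrial",
        .data$gene %in% c("FLO1", "FLO9") ~ "flo_gene",
        .data$mean_coverage < cov_min[.data$ploidy] ~ "low_coverage_clone",
        .data$.n_carriers / .data$.n_clones > background_threshold ~
          "background",
        .data$quality < quality_min & !(.data$.key %in% keep_keys) ~
          "low_quality",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$reason),
      contamination_suspect = .data$kept & .data$zygosity == "het" &
        .data$ref_depth > ratio_flag * .data$alt_depth
    ) |>
    dplyr::select(-".key", -".n_clones", -".n_carriers")
  v
}

#' Identify adaptive gene targets
#'
#' For each evolution condition, a gene is called adaptive when it
#' acquired distinct mutations in more than one barcode lineage, the
#' median home-environment fitness of the lineages carrying mutations in
#' it is greater than 0, and at least one of its mutations is coding;
#' `allowlist` admits additional genes curated for pathway-level
#' interactions. Genes whose carriers all lack a fitness estimate are
#' deferred with a warning.
#'
#' @param variants Kept variant tibble with `clone`, `condition`,
#'   `gene`, `mutation`, `effect` (`"noncoding"` marks non-coding).
#' @param fitness Tibble with `lineage` (matching `clone`) and `s_hat`,
#'   the home-environment fitness.
#' @param allowlist Character vector of genes admitted by curation.
#' @return List with `genes` (per condition x gene: tallies, median
#'   carrier fitness, `adaptive`, `reason`) and `candidates`
#'   (per-lineage candidate mutations in adaptive genes).
#' @export
identify_adaptive_genes <- function(variants, fitness,
                                    allowlist = character(0)) {
  g <- variants |>
    dplyr::left_join(fitness[, c("lineage", "s_hat")],
                     by = c(clone = "lineage")) |>
    dplyr::group_by(.data$condition, .data$gene) |>
    dplyr::summarise(
      n_lineages = dplyr::n_distinct(.data$clone),
      n_mutations = dplyr::n_distinct(.data$mutation),
      any_coding = any(.data$effect != "noncoding"),
      n_fitness = sum(!is.na(.data$s_hat)),
      median_home_fitness = median(.data$s_hat, na.rm = TRUE),
      .groups = "drop"
    )
  deferred <- g$n_fitness == 0L
  if (any(deferred)) {
    warning("no carrier fitness for gene(s): ",
            paste(g$gene[deferred], collapse = ", "),
            "; deferred from adaptive calls")
  }
  g <- g |>
    dplyr::mutate(
      adaptive = !deferred & .data$n_lineages > 1L & .data$n_mutations > 1L &
        .data$median_home_fitness > 0 & .data$any_coding |
        .data$gene %in% allowlist,
      reason = dplyr::case_when(
        .data$gene %in% allowlist ~ "allowlist",
        deferred ~ "no_fitness",
        .data$n_lineages <= 1L | .data$n_mutations <= 1L ~ "single_lineage",
        !(.data$median_home_fitness > 0) ~ "non_beneficial",
        !.data$any_coding ~ "noncoding_only",
        TRUE ~ "recurrent_beneficial_coding"
      )
    )
  adaptive_genes <- g[g$adaptive, c("condition", "gene")]
  candidates <- dplyr::inner_join(variants, adaptive_genes,
                                  by = c("condition", "gene"))
  list(genes = g, candidates = candidates)
}

#' Match whole-genome-sequencing barcode reads to known barcodes
#'
#' Error-corrects each barcode extracted from a clone's whole-genome
#' reads to a known assay barcode when the two share any single-base
#' deletion (one sequencing error), then assigns a known barcode to a
#' clone iff its top barcode has at least `min_reads` supporting reads
#' and at least `ratio` times more reads than the runner-up.
#'
#' @param barcode_reads Tibble with `clone`, `barcode`, `reads`
#'   (optionally a `locus` column distinguishing the environment and
#'   lineage barcode loci).
#' @param known_barcodes Character vector of true assay barcodes.
#' @param min_reads Minimum supporting reads (default 2).
#' @param ratio Required dominance over the runner-up (default 3).
#' @return Tibble with one row per clone (x locus): `barcode` (`NA`
#'   when unassigned), `reads`, `runner_up_reads`.
#' @export
match_clone_barcodes <- function(barcode_reads, known_barcodes,
                                 min_reads = 2, ratio = 3) {
  keys_known <- deletion_keys(known_barcodes)
  keys_obs <- deletion_keys(unique(barcode_reads$barcode))
  obs_seqs <- unique(barcode_reads$barcode)
  hits <- dplyr::inner_join(keys_obs, keys_known, by = "key",
                            suffix = c("_obs", "_known")) |>
    dplyr::distinct(.data$id_obs, .data$id_known) |>
    dplyr::mutate(
      obs = obs_seqs[.data$id_obs],
      known = known_barcodes[.data$id_known],
      dist = levenshtein(.data$obs, .data$known)
    ) |>
    dplyr::group_by(.data$obs) |>
    dplyr::arrange(.data$dist, .data$known, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  map <- setNames(hits$known, hits$obs)

  keys <- intersect(c("clone", "locus"), names(barcode_reads))
  per_known <- barcode_reads |>
    dplyr::mutate(known = unname(map[.data$barcode])) |>
    dplyr::filter(!is.na(.data$known)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$known) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")

  per_known |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(dplyr::desc(.data$reads), .data$known,
                   .by_group = TRUE) |>
    dplyr::summarise(
      barcode = ifelse(
        .data$reads[1L] >= min_reads &
          (dplyr::n() == 1L || .data$reads[1L] >= ratio * .data$reads[2L]),
        .data$known[1L], NA_character_
      ),
      reads = .data$reads[1L],
      runner_up_reads = ifelse(dplyr::n() > 1L, .data$reads[2L], 0),
      .groups = "drop"
    )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
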