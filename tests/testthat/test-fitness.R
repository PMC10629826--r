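test_that("pair slopes follow the log-frequency closed form", {
  traj <- tibble::tibble(timepoint = 1:2, generation = c(0, 8),
                         count = c(100, 200), total = c(1e5, 1e5))
  sl <- pair_slopes(traj)
  expect_equal(sl$slope, log(2) / 8)
  # constant frequency: slope 0
  traj0 <- tibble::tibble(timepoint = 1:3, generation = c(0, 8, 16),
                          count = c(500, 500, 500), total = 1e5)
  expect_equal(pair_slopes(traj0)$slope, c(0, 0))
  # a timepoint with 9 reads invalidates both pairs touching it
  traj9 <- tibble::tibble(timepoint = 1:3, generation = c(0, 8, 16),
                          count = c(100, 9, 100), total = 1e5)
  expect_equal(nrow(pair_slopes(traj9)), 0L)
  # frequencies, not raw counts: doubling the library total halves f
  traj_tot <- tibble::tibble(timepoint = 1:2, generation = c(0, 8),
                             count = c(100, 100), total = c(1e5, 2e5))
  expect_equal(pair_slopes(traj_tot)$slope, log(0.5) / 8)
  expect_error(
    pair_slopes(tibble::tibble(timepoint = 1:2, generation = c(8, 8),
                               count = 1:2, total = 10)),
    "strictly increasing"
  )
})

test_that("neutral reference is the per-pair median and merges sparse sets", {
  mk_counts <- function(counts_mat, lineages) {
    tidyr::expand_grid(lineage = lineages, timepoint = 1:ncol(counts_mat)) |>
      dplyr::mutate(
        replicate = 1L,
        generation = (timepoint - 1) * 8,
        count = as.vector(t(counts_mat))
      )
  }
  # 10 neutral lineages, all valid: median of 10 slopes, no merging
  set.seed(16)
  m <- matrix(sample(200:400, 20), nrow = 10, ncol = 2)
  counts <- mk_counts(m, sprintf("n%02d", 1:10))
  ref <- neutral_reference(counts, sprintf("n%02d", 1:10))
  expect_equal(ref$n_merges, 0L)
  expect_true(ref$usable)
  tot1 <- sum(m[, 1]); tot2 <- sum(m[, 2])
  slopes <- (log(m[, 2] / tot2) - log(m[, 1] / tot1)) / 8
  expect_equal(ref$reference, median(slopes))

  # neutral lineages with 5 reads each: merging restores >= 3 valid
  m5 <- matrix(5, nrow = 8, ncol = 2)
  big <- matrix(c(2000, 2000), nrow = 1)
  counts5 <- dplyr::bind_rows(
    mk_counts(m5, sprintf("n%02d", 1:8)),
    mk_counts(big, "adapted")
  )
  ref5 <- neutral_reference(counts5, sprintf("n%02d", 1:8))
  expect_true(ref5$usable)
  expect_gt(ref5$n_merges, 0L)
  expect_equal(ref5$reference, 0)  # all-equal counts: slope exactly 0

  # symmetric neutral slopes: reference is 0
  msym <- rbind(c(100, 200), c(100, 100), c(200, 100))
  countsym <- mk_counts(msym, c("a", "b", "c"))
  refsym <- neutral_reference(countsym, c("a", "b", "c"))
  expect_equal(refsym$reference, 0)

  expect_error(neutral_reference(counts, character(0)), "non-empty")
})

test_that("scaled fitness is the mean of scaled slopes with its SE", {
  # counts engineered to give slopes 0.1, 0.12, 0.08 against reference 0
  slopes <- c(0.1, 0.12, 0.08)
  f <- cumprod(c(1e-3, exp(slopes * 8)))
  traj <- tibble::tibble(timepoint = 1:4, generation = (0:3) * 8,
                         count = f * 1e6, total = 1e6)
  ref <- tibble::tibble(pair = 1:3, reference = 0, usable = TRUE)
  est <- scaled_fitness(traj, ref)
  expect_equal(est$s_hat, 0.1, tolerance = 1e-12)
  expect_equal(est$se, 0.02 / sqrt(3), tolerance = 1e-9)
  expect_equal(est$n_pairs, 3L)
  # no usable pairs: missing estimate
  ref_un <- tibble::tibble(pair = 1:3, reference = 0, usable = FALSE)
  est_un <- scaled_fitness(traj, ref_un)
  expect_true(is.na(est_un$s_hat))
  expect_equal(est_un$n_pairs, 0L)
})

test_that("replicate combination is inverse-variance weighted", {
  est <- tibble::tibble(lineage = "L1", replicate = 1:2,
                        s_hat = c(0.1, 0.2), se = c(0.01, 0.02))
  out <- combine_replicates(est)
  expect_equal(out$s_hat, 0.12)
  expect_equal(out$se, sqrt(1 / (1 / 0.01^2 + 1 / 0.02^2)))
  expect_equal(out$method, "inverse_variance")
  # single replicate: identity
  out1 <- combine_replicates(est[1, ])
  expect_equal(out1$s_hat, 0.1)
  expect_equal(out1$se, 0.01)
  # equal standard errors: simple mean
  est_eq <- tibble::tibble(lineage = "L1", replicate = 1:3,
                           s_hat = c(0.1, 0.2, 0.3), se = 0.05)
  expect_equal(combine_replicates(est_eq)$s_hat, 0.2)
  # all standard errors missing: unweighted mean, flagged
  est_na <- tibble::tibble(lineage = "L1", replicate = 1:2,
                           s_hat = c(0.1, 0.3), se = NA_real_)
  out_na <- combine_replicates(est_na)
  expect_equal(out_na$s_hat, 0.2)
  expect_true(is.na(out_na$se))
  expect_equal(out_na$method, "unweighted")
  # combined se never exceeds the smallest replicate se, and shrinks
  # monotonically as replicates accumulate
  est3 <- tibble::tibble(lineage = "L1", replicate = 1:3,
                         s_hat = c(0.1, 0.12, 0.09),
                         se = c(0.02, 0.01, 0.03))
  se12 <- combine_replicates(est3[1:2, ])$se
  se123 <- combine_replicates(est3)$se
  expect_lt(se123, se12)
  expect_lte(se123, min(est3$se))
})

test_that("estimates are invariant to rescaling counts at a timepoint", {
  cfg <- sim_config(n_lineages = 15, n_neutral = 5, n_timepoints = 4,
                    read_depth = 1e5, bottleneck_size = Inf, seed = 17)
  sim <- simulate_pool(cfg)
  neutral <- sim$lineages$lineage[sim$lineages$neutral]
  fit1 <- estimate_fitness(sim$counts, neutral)
  scaled_counts <- sim$counts |>
    dplyr::mutate(count = ifelse(timepoint == 2, count * 5, count))
  fit2 <- estimate_fitness(scaled_counts, neutral)
  expect_equal(tidy(fit1)$s_hat, tidy(fit2)$s_hat, tolerance = 1e-12)
  expect_equal(tidy(fit1)$se, tidy(fit2)$se, tolerance = 1e-12)
})

test_that("scaling centers the neutral class at zero by construction", {
  cfg <- sim_config(n_lineages = 20, n_neutral = 9, n_timepoints = 3,
                    read_depth = 1e5, seed = 18)
  sim <- simulate_pool(cfg)
  neutral <- sim$lineages$lineage[sim$lineages$neutral]
  ref <- neutral_reference(sim$counts, neutral)
  slopes <- pleiofit:::slope_table(sim$counts)
  scaled <- slopes |>
    dplyr::filter(valid, lineage %in% neutral) |>
    dplyr::inner_join(ref, by = c("replicate", "pair"))
  meds <- scaled |>
    dplyr::group_by(replicate, pair) |>
    dplyr::summarise(m = median(slope - reference), .groups = "drop")
  expect_true(all(abs(meds$m) < 1e-14))
})

test_that("noise-free simulated fitness is recovered exactly", {
  s_true <- c(0.1, 0.05, -0.05, 0, 0, 0)
  cfg <- sim_config(n_lineages = 6, n_neutral = 3,
                    fitness = list(dist = "fixed",
                                   s = s_true[1:3]),
                    n_timepoints = 4, read_depth = 1e6,
                    bottleneck_size = Inf, n_replicates = 1, seed = 19)
  sim <- simulate_pool(cfg)
  # replace sampled counts with exact expected counts (noise off limit)
  exact <- sim$expected_frequencies |>
    dplyr::mutate(replicate = 1L, lane = 1L, count = freq * 1e6)
  neutral <- sim$lineages$lineage[sim$lineages$neutral]
  fit <- estimate_fitness(exact, neutral)
  got <- tidy(fit)
  expect_equal(got$s_hat[match(sim$lineages$lineage, got$lineage)],
               s_true, tolerance = 1e-10)
})
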