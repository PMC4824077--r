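# count tables, TMM, noise cut-off, loci, concordance, depth rule

test_that("count table frequencies are conservative and match ground truth", {
  calls <- tibble::tibble(
    read_id = sprintf("r%d", 1:4), sample_id = "s1", status = "aligned",
    tss_rel = c(31L, 31L, 31L, 32L))
  tab <- count_tss(calls)
  f <- tss_frequencies(tab)
  expect_equal(f$frequency, c(75, 25))
  expect_equal(sum(f$frequency), 100)

  m <- toy_model()
  lib <- simulate_race_library(m, clean_sim_config(m, depth = 1500L, seed = 51L))
  tab2 <- count_tss(call_tss(tag_reads(lib, m), m))
  truth <- attr(lib, "true_counts")
  got <- tss_frequencies(tab2)
  got <- dplyr::filter(got, .data$count > 0)
  j <- dplyr::full_join(got, truth,
                        by = c("tss_rel", "sample_id"),
                        suffix = c("", ".true"))
  expect_true(all(j$count == j$count.true))
  # per-sample frequencies always total 100%
  sums <- tapply(tss_frequencies(tab2)$frequency,
                 tss_frequencies(tab2)$sample_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("TMM factors match the edgeR reference implementation to 1e-8", {
  counts <- withr::with_seed(52, {
    matrix(stats::rpois(800, lambda = rep(c(5, 50, 200, 20), each = 200)),
           ncol = 4, dimnames = list(NULL, paste0("s", 1:4)))
  })
  counts[sample(length(counts), 60)] <- 0L
  tab <- counts_table(counts, positions = 1:200)
  tab <- tmm_normalize(tab)
  mine <- attr(tab, "tmm_factors")
  ref <- edgeR::calcNormFactors(counts_matrix <- as.matrix(
    tibble::as_tibble(tab)[paste0("s", 1:4)]), method = "TMM")
  expect_lt(max(abs(mine - ref)), 1e-8)
})

test_that("TMM is 1 for identical columns and invariant to pure depth changes", {
  base <- withr::with_seed(53, stats::rpois(100, 40) + 1L)
  same <- counts_table(cbind(s1 = base, s2 = base, s3 = base))
  expect_true(all(abs(attr(tmm_normalize(same), "tmm_factors") - 1) < 1e-12))

  scaled <- counts_table(cbind(s1 = base, s2 = base * 7L))
  expect_true(all(abs(attr(tmm_normalize(scaled), "tmm_factors") - 1) < 1e-12))

  # multiplying any sample's counts by a constant leaves factors unchanged
  # (exactly so for the unweighted trimmed mean; the precision weights'
  # reference term makes the weighted default invariant only to ~0.5%)
  mixed <- withr::with_seed(54, matrix(stats::rpois(300, 30) + 1L, ncol = 3,
                                       dimnames = list(NULL, paste0("s", 1:3))))
  f1 <- attr(tmm_normalize(counts_table(mixed)), "tmm_factors")
  mixed2 <- mixed; mixed2[, 2] <- mixed2[, 2] * 5L
  f2 <- attr(tmm_normalize(counts_table(mixed2)), "tmm_factors")
  expect_lt(max(abs(f1 - f2)), 5e-3)
  expect_lt(max(abs(f1 - f2)) / max(abs(f1)), 5e-3)

  sparse <- counts_table(cbind(s1 = c(rep(0L, 95), rep(10L, 5)),
                               s2 = c(rep(10L, 5), rep(0L, 95))))
  expect_error(tmm_normalize(sparse), "factor")
})

test_that("the noise cut-off removes sub-threshold TSSs with >= retention", {
  # 100000 reads per sample: 0.05% = 50 reads, 0.1% = 100 reads
  counts <- cbind(s1 = c(50L, 100L, 500L, 99350L),
                  s2 = c(50L, 100L, 700L, 99150L))
  tab <- counts_table(counts, positions = c(10L, 20L, 30L, 40L))
  v <- apply_cutoff(tab, cutoff_pct = 0.1)
  vw <- tidyr::pivot_wider(dplyr::select(v, "tss_rel", "sample_id", "valid"),
                           names_from = "sample_id", values_from = "valid")
  expect_identical(vw$s1, c(FALSE, TRUE, TRUE, TRUE))  # 0.05% out, 0.1% in
  expect_setequal(attr(v, "valid_positions"), c(20L, 30L, 40L))
  # removed mass + valid mass = 100% per sample
  tot <- dplyr::summarise(dplyr::group_by(v, .data$sample_id),
                          valid_mass = sum(.data$frequency[.data$valid]))
  expect_true(all(abs(tot$valid_mass +
                        attr(v, "noise_fraction")[tot$sample_id] - 100) < 1e-9))

  # raising the cut-off never increases the valid count
  cuts <- c(0.01, 0.05, 0.1, 0.5, 1, 5)
  nvalid <- vapply(cuts, function(ct) {
    length(attr(apply_cutoff(tab, ct), "valid_positions"))
  }, integer(1))
  expect_true(all(diff(nvalid) <= 0))
  expect_error(apply_cutoff(tab, 0), "cutoff")
})

test_that("all_replicates mode excludes TSSs failing the cut-off in any replicate", {
  # one TSS ranging 0.02-0.14% across replicates of one condition
  counts <- cbind(r1 = c(20L, 99980L), r2 = c(140L, 99860L))
  tab <- counts_table(counts, positions = c(35L, 100L))
  groups <- c(r1 = "ADRB2R", r2 = "ADRB2R")
  per_sample <- apply_cutoff(tab, 0.1, mode = "per_sample")
  expect_true(35L %in% attr(per_sample, "valid_positions"))
  strict <- apply_cutoff(tab, 0.1, mode = "all_replicates", groups = groups)
  expect_false(35L %in% attr(strict, "valid_positions"))
  expect_true(100L %in% attr(strict, "valid_positions"))
})

test_that("a constructed two-phase survivors curve recovers its breakpoint", {
  grid <- 10^seq(-3, 1, length.out = 25)
  # target survivors: steep noise phase to 10^-1 %, shallow phase beyond
  y <- c(84 - 6 * (0:12), 12 - (1:12))
  lib_target <- 1e6
  counts <- integer(0)
  for (k in 1:24) {
    n_k <- y[k] - y[k + 1]
    counts <- c(counts, rep(ceiling(grid[k] * 1e4), n_k))
  }
  counts <- c(counts, as.integer(lib_target - sum(counts)))  # dominant sink
  tab <- counts_table(cbind(s1 = counts), positions = seq_along(counts))
  est <- estimate_cutoff(tab, grid)
  expect_identical(est$curve$survivors, as.integer(y + 1))
  expect_lt(abs(log10(est$breakpoint) - (-1)), (4 / 24) + 1e-9)

  flat <- counts_table(cbind(s1 = rep(25000L, 4)), positions = 1:4)
  expect_error(estimate_cutoff(flat, grid), "degenerate")
})

test_that("true signal plus low-level noise yields a cut-off between them", {
  withr::with_seed(55, {
    noise <- sample(5:200, 300, replace = TRUE)     # <= 0.02% of 1e6
    true_tss <- c(300000, 200000, 100000, 50000, 5000)  # >= 0.5%
    filler <- 1e6 - sum(noise) - sum(true_tss)
    counts <- c(true_tss, noise, filler)
  })
  tab <- counts_table(cbind(s1 = as.integer(counts)),
                      positions = seq_along(counts))
  est <- estimate_cutoff(tab)
  expect_gt(est$breakpoint, 0.02)
  expect_lt(est$breakpoint, 0.5)
})

test_that("adjacent TSSs chain into loci exactly as configured", {
  one <- call_loci(c(31L, 32L, 33L, 34L), max_gap = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_members, 4L)
  expect_identical(one$span, 4L)

  two <- call_loci(c(-3209:-3201, -3174:-3166), max_gap = 5)
  expect_identical(nrow(two), 2L)
  expect_identical(two$start_rel, c(-3209L, -3174L))

  expect_identical(nrow(call_loci(integer())), 0L)

  # -1 and +1 are adjacent under the skip-zero convention
  straddle <- call_loci(c(-2L, -1L, 1L, 2L), max_gap = 1)
  expect_identical(nrow(straddle), 1L)
  expect_identical(straddle$span, 4L)
})

test_that("locus partition invariants hold on random position sets", {
  withr::with_seed(56, {
    for (i in 1:60) {
      pos <- sort(sample(setdiff(-300:300, 0), sample(5:80, 1)))
      gap <- sample(1:6, 1)
      loci <- call_loci(pos, max_gap = gap)
      members <- unlist(loci$members)
      expect_setequal(members, pos)               # union recovers the input
      expect_identical(anyDuplicated(members), 0L)  # each position once
      lin <- function(p) ifelse(p > 0, p - 1L, p)
      if (nrow(loci) > 1) {
        gaps_between <- lin(loci$start_rel[-1]) - lin(loci$end_rel[-nrow(loci)])
        expect_true(all(gaps_between > gap))
      }
      within_ok <- vapply(loci$members, function(mm) {
        length(mm) == 1 || all(diff(lin(mm)) <= gap)
      }, logical(1))
      expect_true(all(within_ok))
    }
  })
})

test_that("loci take exon-aware names when a model is supplied", {
  m <- toy_model()
  pos <- c(toy_rel(m, 100L), toy_rel(m, 101L), toy_rel(m, 240L),
           toy_rel(m, 600L))
  loci <- call_loci(pos, max_gap = 1, model = m)
  expect_identical(anyDuplicated(loci$locus_id), 0L)
  expect_true(all(grepl("^[FB][0-9]+$", loci$locus_id)))
})

test_that("replicate concordance reports shared sets and read mass", {
  counts <- cbind(a = c(40000L, 30000L, 30000L),
                  b = c(41000L, 29000L, 30000L))
  tab <- counts_table(counts, positions = c(1L, 2L, 3L))
  cc <- replicate_concordance(apply_cutoff(tab, 0.1))
  expect_setequal(cc$shared, c(1L, 2L, 3L))
  expect_true(all(abs(cc$shared_mass - 100) < 1e-9))
  expect_true(all(cc$unique_counts == 0))

  disjoint <- cbind(a = c(99900L, 100L, 0L, 0L),
                    b = c(0L, 0L, 100L, 99900L))
  tab2 <- counts_table(disjoint, positions = 1:4)
  cc2 <- replicate_concordance(apply_cutoff(tab2, 0.1))
  expect_length(cc2$shared, 0)
  expect_error(replicate_concordance(apply_cutoff(tab2, 0.1), samples = "a"),
               "2 replicates")
})

test_that("the depth rule is 50 reads per nt of variable region", {
  expect_identical(depth_check(150000, 3000)$status, "pass")
  expect_identical(depth_check(149999, 3000)$status, "warn")
  expect_identical(depth_check(149999, 3000)$deficit, 1)
  expect_identical(depth_check(5000, 100)$status, "pass")
  expect_error(depth_check(100, 0), "positive")
})
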