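# empirical-noise differential TSS testing and discriminatory selection

# multinomial replicate tables: probs_list is condition -> probability vector
# over `positions`; returns a TMM-normalised table plus the groups vector
sim_cond_tables <- function(probs_list, reps = 2L, depth = 1e5, seed = 1L,
                            positions = NULL) {
  npos <- length(probs_list[[1]])
  positions <- positions %||% seq_len(npos)
  cols <- list()
  groups <- character()
  withr::with_seed(seed, {
    for (cn in names(probs_list)) {
      for (r in seq_len(reps)) {
        id <- paste0(cn, r)
        cols[[id]] <- as.integer(stats::rmultinom(1, depth, probs_list[[cn]]))
        groups[id] <- cn
      }
    }
  })
  tab <- counts_table(do.call(cbind, cols), positions = positions)
  list(table = tmm_normalize(tab), groups = groups)
}

test_that("the empirical null records one (|M|, D) pair per position and pair", {
  probs <- rep(1 / 40, 40)
  d <- sim_cond_tables(list(A = probs, B = probs), reps = 3L, seed = 61L)
  null <- build_null(d$table, d$groups)
  # 3 replicates per condition -> 3 pairs each, x 40 positions
  expect_identical(nrow(null), 40L * 6L)
  expect_true(all(null$abs_m >= 0) && all(null$d >= 0))

  # identical replicates concentrate the null at (0, 0)
  base <- as.integer(stats::rmultinom(1, 1e4, probs))
  tab <- tmm_normalize(counts_table(cbind(A1 = base, A2 = base)))
  null0 <- build_null(tab, c(A1 = "A", A2 = "A"))
  expect_true(all(null0$abs_m == 0) && all(null0$d == 0))

  expect_error(build_null(tab, c(A1 = "A", A2 = "B")), "replicates")
})

test_that("identical conditions yield no significant TSSs", {
  base <- withr::with_seed(62, as.integer(stats::rmultinom(1, 5e4, rep(1 / 30, 30))))
  noise <- withr::with_seed(63, {
    replicate(4, pmax(0L, base + as.integer(round(stats::rnorm(30, 0, 3)))))
  })
  colnames(noise) <- c("A1", "A2", "B1", "B2")
  tab <- tmm_normalize(counts_table(noise))
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  null <- build_null(tab, groups)
  res <- test_pairwise(tab, groups, null, c("A", "B"))
  expect_identical(sum(res$significant), 0L)
})

test_that("a planted 30% vs 1% spike is detected", {
  npos <- 60
  pa <- c(0.30, rep(0.70 / (npos - 1), npos - 1))
  pb <- c(0.01, rep(0.99 / (npos - 1), npos - 1))
  d <- sim_cond_tables(list(A = pa, B = pb), reps = 2L, depth = 1e5, seed = 64L)
  null <- build_null(d$table, d$groups)
  res <- test_pairwise(d$table, d$groups, null, c("A", "B"))
  spike <- dplyr::filter(res, .data$tss_rel == 1L)
  expect_true(spike$significant)
  expect_lte(spike$p_adj, 0.05)
  # independent check that the spike is a genuine proportion difference
  ct <- counts_matrix <- as.matrix(tibble::as_tibble(d$table)[c("A1", "B1")])
  pt <- stats::prop.test(ct[1, ], colSums(ct))
  expect_lt(pt$p.value, 1e-10)
})

test_that("the contrast is symmetric up to the sign of M", {
  npos <- 50
  pa <- withr::with_seed(65, {p <- stats::rgamma(npos, 1); p / sum(p)})
  pb <- withr::with_seed(66, {p <- stats::rgamma(npos, 1); p / sum(p)})
  d <- sim_cond_tables(list(A = pa, B = pb), reps = 2L, seed = 67L)
  null <- build_null(d$table, d$groups)
  ab <- test_pairwise(d$table, d$groups, null, c("A", "B"))
  ba <- test_pairwise(d$table, d$groups, null, c("B", "A"))
  expect_identical(ab$tss_rel, ba$tss_rel)
  expect_equal(ab$m, -ba$m)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_identical(ab$significant, ba$significant)
  # BH never decreases p, and the significant set respects the raw level
  expect_true(all(ab$p_adj >= ab$p_raw))
  expect_true(all(ab$p_raw[ab$significant] <= 0.05))
})

test_that("the joint exceedance probability is monotone in |M| and D", {
  null <- structure(tibble::tibble(abs_m = abs(stats::rnorm(500)),
                                   d = abs(stats::rnorm(500))),
                    class = c("tss_null", "tbl_df", "tbl", "data.frame"),
                    pseudo_freq = 0.05)
  p_of <- function(m, d) mean(null$abs_m >= m & null$d >= d)
  withr::with_seed(68, {
    for (i in 1:50) {
      m1 <- stats::runif(1, 0, 2); d1 <- stats::runif(1, 0, 2)
      expect_gte(p_of(m1, d1), p_of(m1 + stats::runif(1), d1 + stats::runif(1)))
    }
  })
})

test_that("false positive rate stays near the nominal level on null data", {
  npos <- 500
  probs <- withr::with_seed(69, {p <- stats::rgamma(npos, 2); p / sum(p)})
  rates <- vapply(1:30, function(i) {
    d <- sim_cond_tables(list(A = probs, B = probs), reps = 2L, depth = 2e4,
                         seed = 700L + i)
    null <- build_null(d$table, d$groups)
    res <- test_pairwise(d$table, d$groups, null, c("A", "B"))
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(rates), 0.06)
})

test_that("positions absent from both tested conditions are skipped", {
  counts <- cbind(A1 = c(100L, 900L, 0L), A2 = c(110L, 890L, 0L),
                  B1 = c(90L, 910L, 0L), B2 = c(95L, 905L, 0L),
                  C1 = c(80L, 820L, 100L), C2 = c(85L, 815L, 100L))
  tab <- tmm_normalize(counts_table(counts, positions = c(1L, 2L, 3L)),
                       min_common = 2L)
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")
  null <- build_null(tab, groups)
  res <- test_pairwise(tab, groups, null, c("A", "B"))
  expect_identical(attr(res, "skipped"), 3L)
  expect_false(3L %in% res$tss_rel)
})

test_that("planted condition-specific TSSs dominate the discriminatory set", {
  npos <- 60
  conds <- paste0("c", 1:4)
  base <- rep(1e-4, npos)
  probs_list <- lapply(seq_along(conds), function(ci) {
    p <- base
    p[(ci - 1) * 2 + 1:2] <- 0.05  # two TSSs specific to this condition
    p / sum(p)
  })
  names(probs_list) <- conds
  d <- sim_cond_tables(probs_list, reps = 2L, depth = 1e5, seed = 71L)
  null <- build_null(d$table, d$groups)
  pairs <- utils::combn(conds, 2)
  results <- lapply(seq_len(ncol(pairs)), function(j) {
    test_pairwise(d$table, d$groups, null, pairs[, j])
  })
  disc <- select_discriminatory(results, d$table, d$groups, k = 30)
  expect_lte(nrow(disc$positions), 30L)
  expect_true(all(1:8 %in% disc$positions$tss_rel))

  # samples split by condition at the 2-cluster cut
  two <- sim_cond_tables(list(A = probs_list[[1]], B = probs_list[[2]]),
                         reps = 3L, depth = 1e5, seed = 72L)
  null2 <- build_null(two$table, two$groups)
  res2 <- test_pairwise(two$table, two$groups, null2, c("A", "B"))
  disc2 <- select_discriminatory(res2, two$table, two$groups)
  cut <- stats::cutree(disc2$sample_clust, 2)
  expect_identical(length(unique(cut[paste0("A", 1:3)])), 1L)
  expect_identical(length(unique(cut[paste0("B", 1:3)])), 1L)
  expect_false(cut[["A1"]] == cut[["B1"]])

  # an empty result set is valid
  d0 <- sim_cond_tables(list(A = rep(1 / 20, 20), B = rep(1 / 20, 20)),
                        reps = 2L, depth = 1e4, seed = 73L)
  null0 <- build_null(d0$table, d0$groups)
  res0 <- test_pairwise(d0$table, d0$groups, null0, c("A", "B"))
  if (sum(res0$significant) == 0) {
    disc0 <- select_discriminatory(res0, d0$table, d0$groups)
    expect_identical(nrow(disc0$positions), 0L)
  }
})

test_that("newick export writes parseable trees", {
  two <- sim_cond_tables(list(A = c(0.5, rep(0.5 / 19, 19)),
                              B = c(0.01, rep(0.99 / 19, 19))),
                         reps = 2L, depth = 1e5, seed = 74L)
  null <- build_null(two$table, two$groups)
  res <- test_pairwise(two$table, two$groups, null, c("A", "B"))
  disc <- select_discriminatory(res, two$table, two$groups)
  tf <- withr::local_tempfile(fileext = ".nwk")
  sf <- withr::local_tempfile(fileext = ".nwk")
  export_newick(disc, tf, sf)
  if (!is.null(disc$tss_clust)) {
    tree <- ape::read.tree(tf)
    expect_identical(sort(tree$tip.label),
                     sort(as.character(rownames(disc$matrix))))
  }
  tree_s <- ape::read.tree(sf)
  expect_setequal(tree_s$tip.label, colnames(disc$matrix))
})
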