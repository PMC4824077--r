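# spliced TSS alignment: exact examples, oracle equivalence, error profiling

read_tbl <- function(seqs, sample = "s1") {
  tibble::tibble(read_id = sprintf("m%04d", seq_along(seqs)),
                 sample_id = sample, sequence = seqs)
}

test_that("error-free contiguous and spliced reads are placed exactly", {
  m <- toy_model()
  lay <- splice_layouts(m)
  p <- 600L
  contig <- substr(m$ref, p, p + 99L)
  donor_idx <- gf_index(m, m$donor_sites[["F"]])
  acc_idx <- gf_index(m, m$acceptor_sites[["ex2"]])
  q <- 300L
  spliced <- paste0(substr(m$ref, q, donor_idx),
                    substr(m$ref, acc_idx, acc_idx + 60L))

  calls <- align_reads(read_tbl(c(contig, spliced)), m)
  expect_identical(calls$status, c("aligned", "aligned"))
  expect_identical(calls$tss_rel, c(toy_rel(m, p), toy_rel(m, q)))
  expect_identical(calls$edits, c(0L, 0L))
  expect_identical(calls$donor, c(NA, "F"))
  expect_identical(calls$acceptor, c(NA, "ex2"))

  # brute-force search confirms the spliced placement is unique
  o <- oracle_align(spliced, lay)
  expect_identical(o$status, "aligned")
  expect_identical(o$tss_idx, q)
  expect_identical(o$layout, 2L)

  # a read unrelated to the reference cannot be placed
  junk <- align_reads(read_tbl(random_dna(100, 999)), m)
  expect_identical(junk$status, "too_many_edits")
})

test_that("TSS calls are robust to leading non-reference insertions", {
  m <- toy_model()
  p <- 450L
  base <- substr(m$ref, p, p + 119L)
  pre1 <- paste0(ifelse(substr(m$ref, p - 1L, p - 1L) == "A", "C", "A"), base)
  pre2 <- paste0("NN", base)  # N never matches the reference
  pre2 <- gsub("N", ifelse(substr(m$ref, p - 1L, p - 1L) == "G", "T", "G"), pre2)
  calls <- align_reads(read_tbl(c(base, pre1, pre2)), m)
  expect_true(all(calls$status == "aligned"))
  expect_true(all(calls$tss_rel == toy_rel(m, p)))
})

test_that("vectorized oracle DP agrees with adist enumeration on tiny cases", {
  withr::with_seed(31, {
    for (i in 1:20) {
      ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
      read <- mutate_read(substr(ref, sample(20, 1), sample(25:55, 1)),
                          sample(0:3, 1), seed = i)
      expect_identical(as.numeric(oracle_start_dists(read, ref)),
                       dumb_start_dists(read, ref))
    }
  })
})

test_that("seeded aligner matches the brute-force oracle on random reads", {
  m <- toy_model()
  lay <- splice_layouts(m)
  n_cases <- 150L
  cases <- withr::with_seed(32, {
    lapply(seq_len(n_cases), function(i) {
      kind <- sample(c("contig", "spliced", "decoy"), 1,
                     prob = c(0.45, 0.45, 0.1))
      len <- sample(40:150, 1)
      if (kind == "decoy") {
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
      } else {
        li <- if (kind == "contig") 1L else sample(2:length(lay), 1)
        s <- sample(nchar(lay[[li]]$seq) - len, 1)
        clean <- substr(lay[[li]]$seq, s, s + len - 1L)
        mutate_read(clean, sample(0:floor(0.08 * len), 1), seed = 1000L + i)
      }
    })
  })
  calls <- align_reads(read_tbl(unlist(cases)), m)
  for (i in seq_len(n_cases)) {
    o <- oracle_align(cases[[i]], lay)
    expect_identical(calls$status[i], o$status)
    if (o$status == "aligned") {
      expect_identical(calls$edits[i], as.integer(o$edits))
      expect_identical(calls$tss_genomic[i],
                       racetss:::gf_genomic(m, o$tss_idx))
      expect_identical(calls$donor[i], lay[[o$layout]]$donor)
      expect_identical(calls$acceptor[i], lay[[o$layout]]$acceptor)
    }
  }
})

test_that("zero-error libraries map completely and reproduce ground truth", {
  m <- toy_model()
  cfg <- clean_sim_config(m, depth = 1500L, seed = 33L)
  lib <- simulate_race_library(m, cfg)
  tagged <- tag_reads(lib, m)
  calls <- call_tss(tagged, m)
  summ <- attr(calls, "mapping_summary")
  expect_true(all(summ$mapped_fraction == 1))
  truth <- attr(lib, "truth")
  j <- dplyr::inner_join(calls, truth, by = "read_id",
                         suffix = c("", ".truth"))
  expect_identical(nrow(j), nrow(calls))
  expect_identical(j$tss_rel, j$tss_rel.truth)
  # spliced calls only ever use annotated sites, and match the truth when
  # the fragment crosses the junction
  crossed <- !is.na(j$donor)
  expect_true(all(j$donor[crossed] == j$donor.truth[crossed]))
  expect_true(all(j$donor[crossed] %in% names(m$donor_sites)))
  expect_true(all(j$acceptor[crossed] %in% names(m$acceptor_sites)))
  # calls are sorted by read id
  expect_false(is.unsorted(calls$read_id))
})

test_that("decoy reads lower the mapped fraction accordingly", {
  m <- toy_model()
  cfg <- clean_sim_config(m, depth = 900L, seed = 34L)
  lib <- simulate_race_library(m, cfg)
  tagged <- tag_reads(lib, m)
  n_dec <- round(nrow(tagged) / 9)
  decoys <- tibble::tibble(
    read_id = sprintf("dec%04d", seq_len(n_dec)),
    sample_id = "s1",
    sequence = vapply(seq_len(n_dec), function(i) random_dna(120, 5000L + i),
                      character(1)),
    quality = strrep("I", 120))
  mixed <- dplyr::bind_rows(tibble::as_tibble(tagged), decoys)
  calls <- call_tss(mixed, m)
  summ <- attr(calls, "mapping_summary")
  frac <- sum(summ$mapped) / sum(summ$attempted)
  expect_lt(abs(frac - 0.9), 0.02)

  empty <- call_tss(tagged[0, ], m)
  expect_identical(nrow(empty), 0L)
})

test_that("error profiling recovers injected rates and flags TSS regions", {
  m <- toy_model()
  clean <- simulate_race_library(m, clean_sim_config(m, depth = 800L, seed = 35L))
  calls0 <- call_tss(tag_reads(clean, m), m)
  prof0 <- profile_errors(calls0, m)
  expect_identical(prof0$rates$substitution_rate, 0)
  expect_identical(prof0$rates$insertion_rate, 0)
  expect_identical(prof0$rates$deletion_rate, 0)
  expect_true(all(prof0$tss$tss_region_clean))

  cfg <- toy_sim_config(m, depth = 3000L, seed = 36L, capped_fraction = 1,
                        label_retention = 1, insertion_rate = 0.05,
                        homopolymer_indel_multiplier = 1)
  lib <- simulate_race_library(m, cfg)
  calls <- call_tss(tag_reads(lib, m), m)
  prof <- profile_errors(calls, m)
  # inserted bases inflate read length slightly; allow for that plus noise
  expect_lt(abs(prof$rates$insertion_rate - 0.05 / 1.05), 0.003)
})

test_that("homopolymer length is reported at each TSS", {
  expect_identical(racetss:::homopolymer_at("GGCAAGT", 4L), 2L)
  expect_identical(racetss:::homopolymer_at("GGCAAGT", 1L), 2L)
  expect_identical(racetss:::homopolymer_at("GGCAAGT", 3L), 1L)
  # a TSS at the first A of ...C A A G... sits in a 2-nt homopolymer
  ref <- paste0(random_dna(200, 40L), "CAAG", random_dna(200, 41L))
  m <- toy_model(len = 404L, reference = ref, donor_f = 50L, donor_b = 60L,
                 acceptor = 150L, anchor = 400L)
  calls <- tibble::tibble(read_id = "x", sample_id = "s1", status = "aligned",
                          tss_rel = toy_rel(m, 202L), tss_clean = TRUE,
                          n_mismatch = 0L, n_insertion = 0L, n_deletion = 0L,
                          read_len = 100L)
  prof <- profile_errors(calls, m)
  expect_identical(prof$tss$homopolymer_len, 2L)
})
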