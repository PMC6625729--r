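small_spec <- function(seed = 5, ...) {
  simulation_spec(n_secretome = 12, n_non_secretome = 12,
                  cds_len_range = c(120L, 250L), seed = seed, ...)
}

test_that("generation is deterministic under the seed, down to the files", {
  s1 <- generate_transcriptome(small_spec())
  s2 <- generate_transcriptome(small_spec())
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_transcriptome(s1, d1)
  write_transcriptome(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- generate_transcriptome(small_spec(seed = 6))
  expect_false(identical(
    vapply(s1$transcripts, `[[`, character(1), "cds"),
    vapply(s3$transcripts, `[[`, character(1), "cds")))
})

test_that("the scanner recovers every planted motif exactly", {
  sim <- generate_transcriptome(small_spec(seed = 7))
  cfg <- scan_config(min_triplets = 2, phases = 0:2)
  hits <- scan_transcriptome(sim$transcripts, cfg)
  tm <- sim$planted_motifs
  expect_gt(nrow(tm), 0)
  for (i in seq_len(nrow(tm))) {
    match_i <- hits$gene_id == tm$gene_id[i] & hits$region == tm$region[i] &
      hits$phase == tm$phase[i] & hits$start_nt == tm$start_nt[i] &
      hits$n_triplets == tm$n_triplets[i]
    expect_true(any(match_i),
                info = sprintf("planted motif %d not recovered", i))
  }
})

test_that("planting probabilities 1 and 0 give fractions 1 and 0", {
  spec <- simulation_spec(
    n_secretome = 10, n_non_secretome = 10, cds_len_range = c(150L, 200L),
    planted_motif = list(region = "CDS", phase = 2,
                         len_range_secretome = c(12, 14),
                         len_range_non = c(5, 6),
                         prob_secretome = 1, prob_non = 0),
    planted_tmd = NULL, seed = 8)
  sim <- generate_transcriptome(spec)
  sec <- Filter(function(t) t$is_secretome, sim$transcripts)
  non <- Filter(function(t) !t$is_secretome, sim$transcripts)
  cfg <- scan_config(min_triplets = 12, phases = 2, regions = "CDS")
  expect_equal(fraction_with_motif(sec, cfg)$fraction, 1)
  # negatives carry no planted signal; 12-triplet chance runs are essentially
  # impossible at this length
  expect_equal(fraction_with_motif(non, cfg)$fraction, 0)
})

test_that("UTR planting places recoverable runs at the recorded offsets", {
  spec <- simulation_spec(
    n_secretome = 8, n_non_secretome = 0,
    utr3_len_range = c(120L, 200L),
    planted_motif = list(region = "3UTR", phase = 1,
                         len_range_secretome = c(10, 12),
                         len_range_non = c(5, 6),
                         prob_secretome = 1, prob_non = 0),
    planted_tmd = NULL, seed = 9)
  sim <- generate_transcriptome(spec)
  hits <- scan_transcriptome(sim$transcripts,
                             scan_config(min_triplets = 10, regions = "3UTR"))
  tm <- sim$planted_motifs
  expect_identical(nrow(tm), 8L)
  for (i in seq_len(nrow(tm))) {
    expect_true(any(hits$gene_id == tm$gene_id[i] &
                      hits$phase == tm$phase[i] &
                      hits$start_nt == tm$start_nt[i] &
                      hits$n_triplets == tm$n_triplets[i]))
  }
})

test_that("planted TMDs create NYN runs that excision removes", {
  tr <- transcript("g", cds = paste(c("ATG", rep("GAA", 58), "TAA"),
                                    collapse = ""))
  set.seed(10)
  planted <- plant_tmd(tr, 25, start_res = 20)
  expect_identical(planted$interval, c(20L, 44L))
  expect_gte(max_run_length(planted$transcript$cds, 1), 25L)
  after <- rescan_after_excision(planted$transcript, "TMD",
                                 scan_config(min_triplets = 25, phases = 1))
  expect_identical(nrow(after), 0L)
  # zero-length TMD is the identity
  none <- plant_tmd(tr, 0)
  expect_identical(none$transcript, tr)
  expect_error(plant_tmd(tr, 100), "insufficient")
})

test_that("TMD planting drives NYN enrichment, motif planting drives NNY", {
  base <- list(n_secretome = 25L, n_non_secretome = 25L,
               cds_len_range = c(200L, 400L))
  cfg_nyn <- scan_config(min_triplets = 15, phases = 1, regions = "CDS")
  cfg_nny <- scan_config(min_triplets = 10, phases = 2, regions = "CDS")
  frac <- function(trs, cfg) fraction_with_motif(trs, cfg)$fraction
  sec_of <- function(sim) Filter(function(t) t$is_secretome, sim$transcripts)

  tmd_only <- generate_transcriptome(simulation_spec(
    n_secretome = base$n_secretome, n_non_secretome = base$n_non_secretome,
    cds_len_range = base$cds_len_range, planted_motif = NULL,
    planted_tmd = list(len_range = c(20L, 25L), prob_secretome = 1,
                       prob_non = 0), seed = 11))
  expect_gt(frac(sec_of(tmd_only), cfg_nyn), 0.9)
  expect_lt(frac(sec_of(tmd_only), cfg_nny), 0.3)

  motif_only <- generate_transcriptome(simulation_spec(
    n_secretome = base$n_secretome, n_non_secretome = base$n_non_secretome,
    cds_len_range = base$cds_len_range,
    planted_motif = list(region = "CDS", phase = 2,
                         len_range_secretome = c(10, 14),
                         len_range_non = c(5, 9),
                         prob_secretome = 1, prob_non = 0),
    planted_tmd = NULL, seed = 12))
  expect_gt(frac(sec_of(motif_only), cfg_nny), 0.9)
  expect_lt(frac(sec_of(motif_only), cfg_nyn), 0.3)
})

test_that("null transcriptomes decouple labels from sequence", {
  spec <- simulation_spec(n_secretome = 60, n_non_secretome = 60,
                          cds_len_range = c(150L, 300L), seed = 13)
  nul <- null_transcriptome(spec)
  labels <- vapply(nul$transcripts, function(t) t$is_secretome, logical(1))
  expect_identical(sum(labels), 60L)  # label counts preserved by permutation
  counts <- vapply(nul$transcripts, secrete_count, integer(1),
                   cfg = scan_config(min_triplets = 5, phases = 2,
                                     regions = "CDS"))
  r <- roc_auc(labels, counts)
  expect_lt(abs(r$auc - 0.5), 0.15)
})

test_that("written transcriptomes read back into identical analyses", {
  sim <- generate_transcriptome(small_spec(seed = 14))
  d <- withr::local_tempdir()
  write_transcriptome(sim, d)
  back <- read_transcriptome(d)
  expect_identical(length(back$transcripts), length(sim$transcripts))
  expect_identical(back$excluded, character(0))
  cfg <- scan_config()
  expect_identical(scan_transcriptome(back$transcripts, cfg),
                   scan_transcriptome(sim$transcripts, cfg))
  # annotations survive the round trip
  ids <- names(sim$transcripts)
  for (id in ids[c(1, length(ids))]) {
    expect_identical(back$transcripts[[id]]$is_secretome,
                     sim$transcripts[[id]]$is_secretome)
    expect_identical(back$transcripts[[id]]$tmd_intervals,
                     sim$transcripts[[id]]$tmd_intervals)
    expect_identical(back$transcripts[[id]]$sscr_len,
                     sim$transcripts[[id]]$sscr_len)
  }
})
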