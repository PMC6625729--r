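test_that("chi-squared enrichment matches the closed form and is symmetric", {
  flat <- chi2_enrichment(c(50, 50), c(50, 50))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)

  # closed-form oracle: sum((O - E)^2 / E) with E from the marginals
  closed_form <- function(a, b) {
    tab <- rbind(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  enr <- chi2_enrichment(c(90, 10), c(50, 50))
  expect_equal(enr$chi2, closed_form(c(90, 10), c(50, 50)), tolerance = 1e-12)
  expect_equal(enr$chi2, 800 / 21, tolerance = 1e-12)
  expect_equal(enr$fraction_a, 0.9)

  swapped <- chi2_enrichment(c(50, 50), c(90, 10))
  expect_equal(swapped$chi2, enr$chi2, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    a <- sample(1:200, 2)
    b <- sample(1:200, 2)
    expect_equal(chi2_enrichment(a, b)$chi2, closed_form(a, b),
                 tolerance = 1e-10)
  }
  expect_error(chi2_enrichment(c(0, 0), c(5, 5)), "marginal")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # step-up by hand: q_i = min over j >= i of p_j * n / j
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  byhand <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))
  expect_equal(bh_fdr(sort(p)), byhand)
})

test_that("AUC equals the pairwise Mann-Whitney enumeration", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(10, 9, 2, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(3, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(3, 1, 2, 0))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(1, 2)), "both classes")
  set.seed(32)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- sample(0:5, n, TRUE)
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(33)
  for (i in 1:20) {
    labels <- sample(c(TRUE, FALSE), 30, TRUE, prob = c(.4, .6))
    if (all(labels) || !any(labels)) next
    r <- roc_auc(labels, rnorm(30))
    p <- r$points
    expect_equal(unlist(p[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(p[nrow(p), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
    # trapezoid area equals the rank-based AUC
    trap <- sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-nrow(p)]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("length correlation recovers perfect and inverse proportionality", {
  # n_runs separated 6-triplet runs padded with purine codons to total_codons
  mk <- function(id, n_runs, total_codons) {
    blocks <- rep(c(strrep("TTC", 6), strrep("AGA", 2)), n_runs)
    pad <- total_codons - 8 * n_runs
    transcript(id, cds = paste(c(blocks, strrep("AGA", pad)), collapse = ""))
  }
  cfg <- scan_config(min_triplets = 5, phases = 2)
  prop <- lapply(1:4, function(i) mk(sprintf("p%d", i), i, 100 * i))
  expect_equal(length_correlation(prop, cfg)$r, 1, tolerance = 1e-12)
  anti <- lapply(1:4, function(i) mk(sprintf("a%d", i), 5 - i, 100 * i))
  expect_equal(length_correlation(anti, cfg)$r, -1, tolerance = 1e-12)
  expect_error(
    length_correlation(lapply(1:3, function(i)
      transcript(sprintf("c%d", i), cds = strrep("AAA", 10))),
      scan_config()),
    "constant")
})

test_that("codon shuffling preserves the codon multiset and is uniform", {
  expect_identical(shuffle_codons("ATG"), "ATG")
  set.seed(34)
  for (i in 1:20) {
    cds <- random_cds(30)
    sh <- shuffle_codons(cds)
    split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_identical(sort(split3(sh)), sort(split3(cds)))
  }
  # all 6 orderings of 3 distinct codons appear with frequency 1/6 +- 3 sigma
  n <- 6000
  got <- table(replicate(n, shuffle_codons("AAACCCGGG")))
  expect_identical(length(got), 6L)
  p <- 1 / 6
  band <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(got / n - p) < band + 1e-9))
})

test_that("permutation Z is degenerate for uniform-codon genes and large for planted runs", {
  tr <- transcript("mono", cds = strrep("GCT", 40))
  res <- permutation_z(tr, scan_config(phases = 2), n_shuffles = 50, seed = 1)
  expect_true(res$degenerate)
  expect_identical(res$z, 0)

  set.seed(35)
  cds <- paste(c("ATG", sample(c("GCA", "AGA", "GGA"), 60, TRUE),
                 rep("TTC", 15), sample(c("GCA", "AGA"), 20, TRUE), "TAA"),
               collapse = "")
  tr2 <- transcript("planted", cds = cds)
  res2 <- permutation_z(tr2, scan_config(phases = 2), n_shuffles = 300,
                        seed = 2)
  expect_gt(res2$z, 1.96)
  expect_identical(res2$observed, 15L)

  # reproducible and order-independent: same seed, same gene -> same rows
  res2b <- permutation_z(tr2, scan_config(phases = 2), n_shuffles = 300,
                         seed = 2)
  expect_identical(res2, res2b)
})

test_that("secrete_count permutation statistic counts threshold runs", {
  cds <- paste(c(rep("TTC", 12), rep("AGA", 5), rep("TTC", 11), rep("AGA", 4)),
               collapse = "")
  tr <- transcript("two", cds = cds)
  res <- permutation_z(tr, scan_config(min_triplets = 10, phases = 2),
                       statistic = "secrete_count", n_shuffles = 100, seed = 3)
  expect_identical(res$observed, 2L)
})

test_that("significant_fraction handles degenerate exclusion and hand counts", {
  pr <- data.frame(z = c(0, 3, 2.5, 1, 0), degenerate = c(TRUE, rep(FALSE, 4)))
  expect_equal(significant_fraction(pr), 2 / 4)
  expect_equal(significant_fraction(pr, include_degenerate = TRUE), 2 / 5)
  pr0 <- data.frame(z = rep(0, 4), degenerate = rep(FALSE, 4))
  expect_equal(significant_fraction(pr0), 0)
  pr3 <- data.frame(z = rep(3, 4), degenerate = rep(FALSE, 4))
  expect_equal(significant_fraction(pr3), 1)
})

test_that("ECDF comparison: identical, disjoint, and shifted samples", {
  same <- ecdf_compare(1:20, 1:20)
  expect_equal(same$ks_stat, 0)
  expect_true(all(diff(same$ecdf_with) >= 0))
  expect_equal(range(same$ecdf_with), c(0.05, 1))

  disjoint <- ecdf_compare(1:10, 101:110)
  expect_equal(disjoint$ks_stat, 1)

  set.seed(36)
  shifted <- ecdf_compare(rnorm(150, 1), rnorm(150, 0))
  expect_lt(shifted$ks_p, 0.01)
})

test_that("region distribution normalizes by mean region length", {
  trs <- list(
    transcript("a", cds = strrep("TTC", 40), utr5 = strrep("C", 12),
               utr3 = strrep("C", 12)),
    transcript("b", cds = strrep("AAA", 40), utr5 = strrep("A", 12)))
  hits <- scan_transcriptome(trs, scan_config(min_triplets = 4))
  rd <- region_distribution(hits, trs)
  expect_identical(rd$region, c("5UTR", "CDS", "3UTR"))
  expect_equal(rd$mean_length, c(12, 120, 12))  # absent UTRs excluded
  expect_equal(rd$density, rd$count / rd$mean_length)
  # all-CDS hits leave UTR counts at zero
  cds_only <- scan_transcriptome(trs, scan_config(min_triplets = 4,
                                                  regions = "CDS"))
  rd0 <- region_distribution(cds_only, trs)
  expect_equal(rd0$count[c(1, 3)], c(0, 0))
  rd_empty <- region_distribution(cds_only[0, ], trs)
  expect_equal(rd_empty$count, c(0, 0, 0))
})

test_that("positional histogram conserves mass and localizes 5' motifs", {
  trs <- list(transcript("a", cds = strrep("TTC", 20), utr5 = strrep("A", 30)))
  hits <- scan_transcriptome(trs, scan_config(min_triplets = 5))
  ph <- positional_distribution(hits, trs, n_bins = 5)
  expect_identical(sum(ph$count), nrow(hits))
  # the CDS run starts at transcript position 30/90 -> second bin of five
  expect_identical(ph$count[2], nrow(hits))
  expect_error(positional_distribution(hits, trs, 1), "n_bins")
})

test_that("UTR pyrimidine comparison excludes exactly the motif-bearing genes", {
  set.seed(38)
  mk <- function(id, sec, utr3) transcript(id, cds = strrep("GCA", 30),
                                           utr3 = utr3, is_secretome = sec)
  trs <- list(
    mk("s1", TRUE, strrep("C", 40)),          # carries a UTR motif
    mk("s2", TRUE, random_dna(40)),
    mk("s3", TRUE, random_dna(40)),
    mk("n1", FALSE, random_dna(40)),
    mk("n2", FALSE, random_dna(40)))
  cfg <- scan_config(min_triplets = 10)
  with_all <- utr_y_content_comparison(trs, exclude_secrete_utrs = FALSE,
                                       cfg = cfg)
  excl <- utr_y_content_comparison(trs, exclude_secrete_utrs = TRUE, cfg = cfg)
  row3 <- function(df) df[df$utr == "3UTR", ]
  expect_identical(row3(with_all)$n_secretome, 3L)
  expect_identical(row3(excl)$n_secretome, 2L)
  expect_identical(row3(excl)$n_excluded, 1L)
  # planted poly-C UTRs in the secretome group separate the means
  expect_gt(row3(with_all)$mean_secretome, row3(with_all)$mean_non_secretome)
})

test_that("threshold sweep flags the separating threshold on planted data", {
  set.seed(37)
  mk_gene <- function(id, runlen, sec) {
    body <- sample(c("GCA", "AGA", "GGA", "AAA"), 80, TRUE)
    at <- 30
    body[at:(at + runlen - 1)] <- "TTC"
    body[c(at - 1, at + runlen)] <- "AGA"
    transcript(id, cds = paste(c("ATG", body, "TAA"), collapse = ""),
               is_secretome = sec)
  }
  pos <- lapply(1:40, function(i) mk_gene(paste0("p", i), sample(10:14, 1), TRUE))
  neg <- lapply(1:40, function(i) mk_gene(paste0("n", i), sample(5:9, 1), FALSE))
  trs <- c(pos, neg)
  labels <- c(rep(TRUE, 40), rep(FALSE, 40))
  sw <- threshold_sweep(trs, labels, cfg = scan_config(phases = 2))
  expect_identical(attr(sw, "best_threshold"), 10L)
  expect_identical(sw$threshold, c(5L, 7L, 10L, 12L, 15L))
  expect_true(all(diff(sw$fraction_pos) <= 0))
})

test_that("fractions recover planted truth and error on empty sets", {
  sim <- generate_transcriptome(simulation_spec(
    n_secretome = 15, n_non_secretome = 15,
    planted_motif = list(region = "CDS", phase = 2,
                         len_range_secretome = c(12, 12),
                         len_range_non = c(5, 5),
                         prob_secretome = 1, prob_non = 0),
    planted_tmd = NULL, seed = 9))
  sec <- Filter(function(t) t$is_secretome, sim$transcripts)
  non <- Filter(function(t) !t$is_secretome, sim$transcripts)
  cfg <- scan_config(min_triplets = 12, phases = 2)
  expect_equal(fraction_with_motif(sec, cfg)$fraction, 1)
  expect_error(fraction_with_motif(list(), cfg), "empty")
})

test_that("gene group fractions split by label", {
  trs <- list(
    transcript("a", cds = strrep("TTC", 15), groups = "cell_wall",
               is_secretome = TRUE),
    transcript("b", cds = strrep("AAA", 15), groups = "mito"),
    transcript("c", cds = strrep("TTC", 15), groups = c("cell_wall", "SS"),
               is_secretome = TRUE))
  gf <- gene_group_fractions(trs, scan_config(min_triplets = 10, phases = 2))
  cw <- gf[gf$group == "cell_wall", ]
  expect_identical(cw$n, 2L)
  expect_equal(cw$fraction, 1)
  expect_equal(gf[gf$group == "mito", "fraction"], 0)
})
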