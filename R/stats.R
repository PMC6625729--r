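#' Fraction of genes carrying at least one motif
#'
#' @param transcripts Non-empty list of [transcript()] objects.
#' @param cfg A [scan_config()].
#' @return List with `fraction`, `n_with`, `n_total`.
#' @export
fraction_with_motif <- function(transcripts, cfg = scan_config()) {
  if (length(transcripts) == 0L) stop("empty gene set")
  counts <- vapply(transcripts, secrete_count, integer(1L), cfg = cfg)
  list(fraction = mean(counts >= 1L), n_with = sum(counts >= 1L),
       n_total = length(counts))
}

#' Chi-squared enrichment between two gene sets
#'
#' Pearson chi-squared test (df = 1, two-sided, no continuity correction) on
#' the 2x2 table of motif-positive/-negative counts in two gene sets.
#'
#' @param setA_counts,setB_counts Integer vectors `c(with_motif,
#'   without_motif)` for each set.
#' @return List of class `"enrichment_result"`: `table` (2x2 matrix),
#'   `fraction_a`, `fraction_b`, `chi2`, `p_value`, and `q_value` (NA until
#'   filled by [bh_fdr()] bookkeeping).
#' @examples
#' chi2_enrichment(c(90, 10), c(50, 50))
#' @export
chi2_enrichment <- function(setA_counts, setB_counts) {
  stopifnot(length(setA_counts) == 2L, length(setB_counts) == 2L,
            all(c(setA_counts, setB_counts) >= 0))
  tab <- rbind(A = setA_counts, B = setB_counts)
  colnames(tab) <- c("with", "without")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: zero marginal in the 2x2 table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 fraction_a = tab[1L, 1L] / sum(tab[1L, ]),
                 fraction_b = tab[2L, 1L] / sum(tab[2L, ]),
                 chi2 = unname(ht$statistic),
                 p_value = ht$p.value,
                 q_value = NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> %.3f vs %.3f with motif | chi2 = %.4g, p = %.3g\n",
              x$fraction_a, x$fraction_b, x$chi2, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' ROC curve and AUC for a binary gene classification
#'
#' The AUC is the normalized Mann-Whitney U with tie correction (average
#' ranks), equal to the trapezoidal area under the empirical ROC curve. The
#' default score in threshold analyses is the per-gene motif count at the
#' evaluated threshold; binary presence is obtained by passing
#' `as.integer(counts >= 1)`.
#'
#' @param labels Logical (or 0/1) vector; TRUE marks the positive class.
#'   Both classes must be present.
#' @param scores Numeric score per gene; higher predicts positive.
#' @param score_label Free-text description of the score, stored in the
#'   result.
#' @return List of class `"roc_result"`: `points` (data.frame of `fpr`,
#'   `tpr`, monotone from (0,0) to (1,1)), `auc`, `score_label`.
#' @examples
#' roc_auc(c(TRUE, TRUE, FALSE, FALSE), c(3, 1, 2, 0))$auc  # 0.75
#' @export
roc_auc <- function(labels, scores, score_label = "motif count") {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), !anyNA(labels), !anyNA(scores))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  cut <- cumsum(rle(s)$lengths)  # last index of each distinct score
  points <- data.frame(fpr = c(0, fp[cut] / n0), tpr = c(0, tp[cut] / n1))
  structure(list(points = points, auc = auc, score_label = score_label),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc> AUC = %.4f (score: %s, %d points)\n",
              x$auc, x$score_label, nrow(x$points)))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `"roc_result"` from [roc_auc()].
#' @param ... Passed to [plot()].
#' @method plot roc_result
#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

# motif counts per gene for a vector of thresholds, from one scan at the
# smallest threshold (a maximal run of length L qualifies at every t <= L)
.counts_by_threshold <- function(transcripts, thresholds, cfg) {
  base_cfg <- cfg
  base_cfg$min_triplets <- max(2L, min(thresholds))
  lens <- lapply(transcripts, function(t) {
    scan_transcript(t, base_cfg)$n_triplets
  })
  vapply(thresholds, function(th) {
    vapply(lens, function(x) sum(x >= th), integer(1L))
  }, integer(length(transcripts)))
}

#' Sweep motif-length thresholds and compare their classification power
#'
#' For each threshold, computes the ROC AUC of the per-gene motif count
#' against the labels, the motif-positive fraction in each class, and the
#' chi-squared enrichment p-value, and identifies the argmax-AUC threshold.
#'
#' @param transcripts List of [transcript()] objects.
#' @param labels Logical vector, TRUE for the positive (secretome) class.
#' @param thresholds Integer vector of at least 2 thresholds.
#' @param cfg A [scan_config()]; its `min_triplets` is overridden per
#'   threshold.
#' @return data.frame with columns `threshold`, `auc`, `fraction_pos`,
#'   `fraction_neg`, `chi2_p`; attribute `best_threshold` holds the
#'   argmax-AUC threshold (smallest in case of an exact tie).
#' @export
threshold_sweep <- function(transcripts, labels,
                            thresholds = c(5L, 7L, 10L, 12L, 15L),
                            cfg = scan_config()) {
  thresholds <- sort(unique(as.integer(thresholds)))
  stopifnot(length(thresholds) >= 2L, length(transcripts) == length(labels))
  labels <- as.logical(labels)
  cmat <- .counts_by_threshold(transcripts, thresholds, cfg)
  rows <- lapply(seq_along(thresholds), function(i) {
    counts <- cmat[, i]
    pos <- counts[labels] >= 1L
    neg <- counts[!labels] >= 1L
    enr <- tryCatch(
      chi2_enrichment(c(sum(pos), sum(!pos)), c(sum(neg), sum(!neg))),
      error = function(e) list(p_value = NA_real_))
    data.frame(threshold = thresholds[i],
               auc = roc_auc(labels, counts)$auc,
               fraction_pos = mean(pos), fraction_neg = mean(neg),
               chi2_p = enr$p_value)
  })
  res <- do.call(rbind, rows)
  attr(res, "best_threshold") <- res$threshold[which.max(res$auc)]
  res
}

#' Correlation between motif count and CDS length
#'
#' @param transcripts List of at least 3 [transcript()] objects.
#' @param cfg A [scan_config()].
#' @return List with `r` (Pearson), `counts`, `lengths`.
#' @export
length_correlation <- function(transcripts, cfg = scan_config()) {
  stopifnot(length(transcripts) >= 3L)
  counts <- vapply(transcripts, secrete_count, integer(1L), cfg = cfg)
  lengths <- vapply(transcripts, function(t) nchar(t$cds), integer(1L))
  if (stats::sd(counts) == 0 || stats::sd(lengths) == 0) {
    stop("correlation undefined for a constant vector")
  }
  list(r = stats::cor(counts, lengths), counts = counts, lengths = lengths)
}

#' Shuffle the codon order of a CDS
#'
#' Uniform random permutation of the codon list; the codon multiset (hence
#' codon usage and GC content) is preserved. Uses the current R random
#' number generator state; seed with [set.seed()] or let [permutation_z()]
#' manage per-gene streams.
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @return Shuffled DNA string.
#' @export
shuffle_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) %% 3L == 0L)
  n <- nchar(cds) %/% 3L
  if (n <= 1L) return(cds)
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(codons[sample.int(n)], collapse = "")
}

# deterministic per-gene seed in [0, 2^31 - 2], order-independent
.gene_seed <- function(seed, gene_id) {
  h <- sum(utf8ToInt(gene_id) * seq_len(nchar(gene_id))) %% 1000003
  as.integer((as.double(seed) * 1000003 + h) %% 2147483647)
}

#' Codon-shuffle permutation Z-score for one transcript
#'
#' Evaluates whether the motif signal of a CDS exceeds what its codon
#' composition alone produces. The codon order is shuffled `n_shuffles`
#' times; the statistic (longest run length in triplets by default, or the
#' motif count at the configured threshold) is computed on the real CDS and
#' on every shuffle, and `Z = (observed - mean) / sd` over the shuffles.
#' When all shuffles give the same value (sd = 0), Z is reported as 0 with
#' the `degenerate` flag set.
#'
#' Each gene draws from its own random stream derived from `(seed,
#' gene_id)`, so results do not depend on processing order.
#'
#' @param t A [transcript()].
#' @param cfg A [scan_config()]; phases taken from `cfg$phases`, class from
#'   `cfg$nt_class`, and for the `"secrete_count"` statistic the threshold
#'   from `cfg$min_triplets`. Only the CDS is permuted.
#' @param statistic `"max_run_length"` (default) or `"secrete_count"`.
#' @param n_shuffles Number of shuffles (>= 2), 1000 by default.
#' @param seed Integer base seed.
#' @return data.frame, one row per phase: `gene_id`, `phase`, `statistic`,
#'   `observed`, `mean`, `sd`, `z`, `degenerate`, `n_shuffles`, `seed`.
#' @export
permutation_z <- function(t, cfg = scan_config(),
                          statistic = c("max_run_length", "secrete_count"),
                          n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(t, "transcript"), n_shuffles >= 2L)
  statistic <- match.arg(statistic)
  phases <- cfg$phases
  cls <- .NT_CLASSES[[cfg$nt_class]]
  n_cod <- nchar(t$cds) %/% 3L
  codons <- substring(t$cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  # per-codon class membership at each intra-codon offset; a codon-order
  # shuffle permutes these rows, so no string work is needed per replicate
  okmat <- vapply(1:3, function(p) substr(codons, p, p) %in% cls,
                  logical(n_cod))
  stat_of <- function(ok) {
    r <- rle(ok)
    lens <- r$lengths[r$values]
    if (statistic == "max_run_length") {
      if (length(lens) == 0L) 0L else max(lens)
    } else {
      sum(lens >= cfg$min_triplets)
    }
  }
  observed <- vapply(phases, function(p) stat_of(okmat[, p + 1L]), integer(1L))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(.gene_seed(seed, t$gene_id))
  sims <- matrix(0L, nrow = n_shuffles, ncol = length(phases))
  for (i in seq_len(n_shuffles)) {
    perm <- sample.int(n_cod)
    for (j in seq_along(phases)) {
      sims[i, j] <- stat_of(okmat[perm, phases[j] + 1L])
    }
  }
  mu <- colMeans(sims)
  sdv <- apply(sims, 2L, stats::sd)
  degenerate <- sdv == 0
  z <- ifelse(degenerate, 0, (observed - mu) / sdv)
  data.frame(gene_id = t$gene_id, phase = phases, statistic = statistic,
             observed = observed, mean = mu, sd = sdv, z = z,
             degenerate = degenerate, n_shuffles = as.integer(n_shuffles),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

#' Permutation Z-scores for a list of transcripts
#'
#' @inheritParams permutation_z
#' @param transcripts List of [transcript()] objects.
#' @return Row-bound data.frame of per-gene, per-phase results.
#' @export
permutation_z_table <- function(transcripts, cfg = scan_config(),
                                statistic = c("max_run_length", "secrete_count"),
                                n_shuffles = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  res <- lapply(transcripts, permutation_z, cfg = cfg, statistic = statistic,
                n_shuffles = n_shuffles, seed = seed)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of genes with a significant permutation Z-score
#'
#' Share of genes with `Z >= cutoff` among non-degenerate genes (degenerate
#' genes, whose shuffles all gave the same statistic, are excluded from the
#' denominator unless `include_degenerate = TRUE`).
#'
#' @param perm_results data.frame from [permutation_z_table()] (filter to one
#'   phase first if phases should be assessed separately).
#' @param cutoff Z cutoff, 1.96 by default.
#' @param include_degenerate Keep degenerate genes in the denominator.
#' @return Numeric fraction (NaN when the denominator is empty).
#' @export
significant_fraction <- function(perm_results, cutoff = 1.96,
                                 include_degenerate = FALSE) {
  stopifnot(nrow(perm_results) > 0L)
  keep <- if (include_degenerate) rep(TRUE, nrow(perm_results))
          else !perm_results$degenerate
  mean(perm_results$z[keep] >= cutoff)
}

#' Compare value distributions between motif-bearing and motif-lacking genes
#'
#' Empirical CDFs of an external per-gene value (e.g. an ER-enrichment
#' log-ratio) for genes with and without the motif, evaluated on the union
#' grid, with the two-sample Kolmogorov-Smirnov statistic as the numeric
#' summary.
#'
#' @param values_with_motif,values_without Non-empty numeric vectors.
#' @return List with `grid`, `ecdf_with`, `ecdf_without` (step-function
#'   values on the grid), `ks_stat`, `ks_p`.
#' @export
ecdf_compare <- function(values_with_motif, values_without) {
  stopifnot(length(values_with_motif) > 0L, length(values_without) > 0L)
  grid <- sort(unique(c(values_with_motif, values_without)))
  ks <- suppressWarnings(stats::ks.test(values_with_motif, values_without))
  list(grid = grid,
       ecdf_with = stats::ecdf(values_with_motif)(grid),
       ecdf_without = stats::ecdf(values_without)(grid),
       ks_stat = unname(ks$statistic),
       ks_p = ks$p.value)
}

#' Motif counts per region, raw and normalized by mean region length
#'
#' The density divides the raw count by the mean length of the region over
#' the gene set; genes lacking a UTR are absent from that UTR's mean.
#'
#' @param hits Motif-hit data.frame from a scan with the regions of interest
#'   enabled.
#' @param transcripts The scanned transcripts (for region lengths).
#' @return data.frame with columns `region`, `count`, `mean_length`,
#'   `density` over 5UTR, CDS, 3UTR.
#' @export
region_distribution <- function(hits, transcripts) {
  regions <- c("5UTR", "CDS", "3UTR")
  lens <- list(
    `5UTR` = vapply(transcripts, function(t) nchar(t$utr5), integer(1L)),
    CDS = vapply(transcripts, function(t) nchar(t$cds), integer(1L)),
    `3UTR` = vapply(transcripts, function(t) nchar(t$utr3), integer(1L)))
  rows <- lapply(regions, function(rg) {
    lv <- lens[[rg]][lens[[rg]] > 0L]
    ml <- if (length(lv) > 0L) mean(lv) else NA_real_
    cnt <- sum(hits$region == rg)
    data.frame(region = rg, count = cnt, mean_length = ml,
               density = if (is.na(ml)) NA_real_ else cnt / ml)
  })
  do.call(rbind, rows)
}

#' Histogram of motif positions along the normalized gene length
#'
#' Motif starts are mapped to transcript coordinates (5'UTR, then CDS, then
#' 3'UTR) and divided by the total transcript length, giving relative
#' positions in \[0, 1); the bin counts sum to the number of hits.
#'
#' @param hits Motif-hit data.frame.
#' @param transcripts The scanned transcripts.
#' @param n_bins Number of equal-width bins (>= 2).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
positional_distribution <- function(hits, transcripts, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  ids <- vapply(transcripts, function(t) t$gene_id, character(1L))
  u5 <- stats::setNames(vapply(transcripts, function(t) nchar(t$utr5), integer(1L)), ids)
  cd <- stats::setNames(vapply(transcripts, function(t) nchar(t$cds), integer(1L)), ids)
  u3 <- stats::setNames(vapply(transcripts, function(t) nchar(t$utr3), integer(1L)), ids)
  total <- u5 + cd + u3
  offset <- ifelse(hits$region == "5UTR", 0L,
            ifelse(hits$region == "CDS", u5[hits$gene_id],
            ifelse(hits$region == "3UTR", u5[hits$gene_id] + cd[hits$gene_id],
                   0L)))
  relpos <- (offset + hits$start_nt) / total[hits$gene_id]
  relpos <- pmin(pmax(relpos, 0), 1 - 1e-12)
  bins <- findInterval(relpos, seq(0, 1, length.out = n_bins + 1L),
                       rightmost.closed = TRUE)
  counts <- tabulate(bins, nbins = n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
             count = counts)
}

#' Compare UTR pyrimidine content between secretome and non-secretome genes
#'
#' Mean Y content of each UTR per group with an unpaired two-sided t-test.
#' With `exclude_secrete_utrs = TRUE`, genes carrying at least one motif in
#' a given UTR are dropped from that UTR's comparison (testing whether the
#' enrichment persists beyond the motifs themselves). Genes lacking a UTR
#' are absent from that UTR's comparison; a group with no remaining genes
#' yields NA for its mean and for the p-value.
#'
#' @param transcripts List of [transcript()] objects with secretome flags.
#' @param exclude_secrete_utrs Drop motif-bearing UTRs before comparing.
#' @param cfg A [scan_config()] defining the motif for the exclusion.
#' @return data.frame, one row per UTR: `utr`, `mean_secretome`,
#'   `mean_non_secretome`, `n_secretome`, `n_non_secretome`, `p_value`,
#'   `n_excluded`.
#' @export
utr_y_content_comparison <- function(transcripts, exclude_secrete_utrs = FALSE,
                                     cfg = scan_config()) {
  stopifnot(length(transcripts) > 0L)
  rows <- lapply(c("5UTR", "3UTR"), function(rg) {
    field <- if (rg == "5UTR") "utr5" else "utr3"
    seqs <- vapply(transcripts, function(t) t[[field]], character(1L))
    sec <- vapply(transcripts, function(t) t$is_secretome, logical(1L))
    keep <- nzchar(seqs)
    excluded <- 0L
    if (exclude_secrete_utrs) {
      ucfg <- cfg
      ucfg$regions <- rg
      has_motif <- vapply(transcripts, function(t) {
        nzchar(t[[field]]) && secrete_count(t, ucfg) >= 1L
      }, logical(1L))
      excluded <- sum(keep & has_motif)
      keep <- keep & !has_motif
    }
    y <- vapply(seqs[keep], pyrimidine_content, numeric(1L), USE.NAMES = FALSE)
    g <- sec[keep]
    p <- if (sum(g) > 1L && sum(!g) > 1L) {
      stats::t.test(y[g], y[!g])$p.value
    } else NA_real_
    data.frame(utr = rg,
               mean_secretome = if (any(g)) mean(y[g]) else NA_real_,
               mean_non_secretome = if (any(!g)) mean(y[!g]) else NA_real_,
               n_secretome = sum(g), n_non_secretome = sum(!g),
               p_value = p, n_excluded = excluded)
  })
  do.call(rbind, rows)
}

#' Motif-positive fraction per gene group
#'
#' Splits genes by their group labels (e.g. cell wall, TA, mito, SS, TMD)
#' and reports the motif-positive fraction in each, mirroring per-category
#' abundance summaries.
#'
#' @param transcripts List of [transcript()] objects.
#' @param cfg A [scan_config()].
#' @param groups Character vector of group labels to summarize; defaults to
#'   all labels present.
#' @return data.frame with `group`, `n`, `n_with`, `fraction`.
#' @export
gene_group_fractions <- function(transcripts, cfg = scan_config(),
                                 groups = NULL) {
  all_groups <- unique(unlist(lapply(transcripts, function(t) t$groups)))
  if (is.null(groups)) groups <- sort(all_groups)
  counts <- vapply(transcripts, secrete_count, integer(1L), cfg = cfg)
  rows <- lapply(groups, function(g) {
    sel <- vapply(transcripts, function(t) g %in% t$groups, logical(1L))
    data.frame(group = g, n = sum(sel), n_with = sum(counts[sel] >= 1L),
               fraction = if (any(sel)) mean(counts[sel] >= 1L) else NA_real_)
  })
  do.call(rbind, rows)
}
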