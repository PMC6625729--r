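# Independent oracles and random-sequence helpers shared across tests.
# Oracles deliberately avoid the code paths of the implementation they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons, include_stop = TRUE) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  body <- sample(sense, n_codons - 1L - as.integer(include_stop), replace = TRUE)
  paste(c("ATG", body, if (include_stop) "TAA"), collapse = "")
}

# Exhaustive-window oracle: tests every (start, length) window of checked
# positions directly with all(); reports maximal qualifying windows.
oracle_find_runs <- function(seq, phase, nt_class = "Y", min_triplets = 10L) {
  cls <- switch(nt_class, Y = c("C", "T"), R = c("A", "G"), K = c("T", "G"),
                M = c("C", "A"), S = c("G", "C"), W = c("A", "T"))
  n <- nchar(seq)
  res <- data.frame(start_nt = integer(), n_triplets = integer())
  if (n < phase + 1L) return(res)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  checked <- seq.int(phase + 1L, n, by = 3L)
  y <- chars[checked] %in% cls
  K <- length(y)
  for (i in seq_len(K)) {
    if (K - i + 1L < min_triplets) next
    for (L in min_triplets:(K - i + 1L)) {
      window_ok <- all(y[i:(i + L - 1L)])
      if (!window_ok) break               # longer windows from i also fail
      left_max <- i == 1L || !y[i - 1L]
      right_max <- i + L - 1L == K || !y[i + L]
      if (left_max && right_max) {
        res <- rbind(res, data.frame(start_nt = (i - 1L) * 3L,
                                     n_triplets = L))
      }
    }
  }
  res[order(res$start_nt), , drop = FALSE]
}

# Regex-engine oracle: maximal runs of the class indicator found by gregexpr,
# an implementation route that shares nothing with rle-based scanning.
regex_find_runs <- function(seq, phase, nt_class = "Y", min_triplets = 10L) {
  cls <- switch(nt_class, Y = c("C", "T"), R = c("A", "G"), K = c("T", "G"),
                M = c("C", "A"), S = c("G", "C"), W = c("A", "T"))
  n <- nchar(seq)
  res <- data.frame(start_nt = integer(), n_triplets = integer())
  if (n < phase + 1L) return(res)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ind <- paste(ifelse(chars[seq.int(phase + 1L, n, by = 3L)] %in% cls,
                      "1", "0"), collapse = "")
  m <- gregexpr(sprintf("1{%d,}", min_triplets), ind)[[1L]]
  if (m[1L] == -1L) return(res)
  data.frame(start_nt = (as.integer(m) - 1L) * 3L,
             n_triplets = as.integer(attr(m, "match.length")))
}

# Pairwise Mann-Whitney AUC: enumerate every positive-negative pair.
oracle_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# RRY score by explicit per-offset, per-position loop.
oracle_rry <- function(motif_seq) {
  chars <- strsplit(motif_seq, "", fixed = TRUE)[[1L]]
  best <- 0
  for (off in 0:2) {
    hits <- 0
    for (i in seq_along(chars)) {
      slot <- (i - 1 + off) %% 3          # 0,1 -> R; 2 -> Y
      match <- if (slot == 2) chars[i] %in% c("C", "T")
               else chars[i] %in% c("A", "G")
      hits <- hits + match
    }
    best <- max(best, hits / length(chars))
  }
  best
}

# Complement without Biostrings (for the complementarity property).
complement_dna <- function(seq) chartr("ACGT", "TGCA", seq)

as_run_df <- function(df) {
  rownames(df) <- NULL
  df[, c("start_nt", "n_triplets"), drop = FALSE]
}
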