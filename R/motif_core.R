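#' Find maximal triplet-periodic runs of a nucleotide class
#'
#' Scans `seq` for uninterrupted runs of triplets whose base at offset `phase`
#' (0-based within the triplet) belongs to `nt_class`. A run is maximal: the
#' checked positions immediately before and after it are either out of bounds
#' or not in the class. `N` at a checked position breaks a run.
#'
#' Coordinates are 0-based within `seq`: `start_nt` is the start of the first
#' triplet of the run, so its first checked base sits at `start_nt + phase`.
#' The `sequence` column spans complete triplets from the run start and is
#' truncated at the end of `seq` if fewer than 3 nt remain after the last
#' checked base.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param phase Triplet offset of the checked base, 0, 1 or 2.
#' @param nt_class Checked nucleotide class (see [scan_config()]).
#' @param min_triplets Minimum run length in triplets (>= 1).
#' @return data.frame with columns `start_nt`, `n_triplets`, `sequence`,
#'   ordered left to right.
#' @examples
#' find_runs(strrep("T", 30), phase = 0, min_triplets = 10)
#' find_runs(strrep("GCT", 12), phase = 2, min_triplets = 10)
#' @export
find_runs <- function(seq, phase, nt_class = "Y", min_triplets = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  phase <- as.integer(phase)
  stopifnot(phase %in% 0:2)
  min_triplets <- as.integer(min_triplets)
  stopifnot(min_triplets >= 1L)
  nt_class <- match.arg(nt_class, names(.NT_CLASSES))
  empty <- data.frame(start_nt = integer(), n_triplets = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < phase + 1L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  checked <- seq.int(phase + 1L, n, by = 3L)
  ok <- chars[checked] %in% .NT_CLASSES[[nt_class]]
  r <- rle(ok)
  keep <- r$values & r$lengths >= min_triplets
  if (!any(keep)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ks <- starts[keep]
  kl <- r$lengths[keep]
  start_nt <- (ks - 1L) * 3L
  data.frame(start_nt = start_nt,
             n_triplets = kl,
             sequence = substring(seq, start_nt + 1L,
                                  pmin(start_nt + 3L * kl, n)),
             stringsAsFactors = FALSE)
}

#' Longest maximal run length, in triplets
#'
#' The permutation statistic of choice: the length (number of triplets) of the
#' longest uninterrupted run of the checked class at the given phase, 0 when
#' no checked position qualifies.
#'
#' @inheritParams find_runs
#' @return Integer scalar.
#' @export
max_run_length <- function(seq, phase, nt_class = "Y") {
  runs <- find_runs(seq, phase, nt_class, min_triplets = 1L)
  if (nrow(runs) == 0L) 0L else max(runs$n_triplets)
}

# does a CDS run overlap any TMD interval? Checked codons of a run are the
# consecutive codons start_nt/3 + 1 .. start_nt/3 + n_triplets (1-based).
.run_overlaps_tmd <- function(start_nt, n_triplets, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(start_nt)))
  c1 <- start_nt %/% 3L + 1L
  c2 <- c1 + n_triplets - 1L
  vapply(seq_along(c1), function(i) {
    any(intervals[, 1L] <= c2[i] & intervals[, 2L] >= c1[i])
  }, logical(1L))
}

#' Scan a transcript for SECReTE-type motifs
#'
#' Applies [find_runs()] to the requested regions of a transcript. CDS phases
#' are anchored to the reading frame (phase 2 = NNY, the third codon
#' position); each UTR is scanned independently at the configured offsets
#' from its own 5' end; `"FULL"` concatenates 5'UTR + CDS + 3'UTR with
#' offsets anchored at the transcript 5' end. Runs never cross region
#' boundaries except in `"FULL"` mode. Empty regions silently yield no hits.
#'
#' @param t A [transcript()].
#' @param cfg A [scan_config()].
#' @return data.frame of motif hits with columns `gene_id`, `region`, `phase`,
#'   `start_nt` (0-based within region), `n_triplets`, `sequence`,
#'   `rry_score` and `overlaps_tmd` (TRUE when any checked base of a CDS run
#'   falls in a codon covered by a TMD interval).
#' @examples
#' tr <- transcript("g1", cds = strrep("GCT", 12))
#' scan_transcript(tr, scan_config(phases = 2))
#' @export
scan_transcript <- function(t, cfg = scan_config()) {
  stopifnot(inherits(t, "transcript"), inherits(cfg, "scan_config"))
  out <- list()
  for (region in cfg$regions) {
    seq <- switch(region,
                  CDS = t$cds, `5UTR` = t$utr5, `3UTR` = t$utr3,
                  FULL = paste0(t$utr5, t$cds, t$utr3))
    if (!nzchar(seq)) next
    for (phase in cfg$phases) {
      runs <- find_runs(seq, phase, cfg$nt_class, cfg$min_triplets)
      if (nrow(runs) == 0L) next
      if (region == "CDS") {
        otmd <- .run_overlaps_tmd(runs$start_nt, runs$n_triplets,
                                  t$tmd_intervals)
      } else if (region == "FULL" && nrow(t$tmd_intervals) > 0L) {
        # map to CDS frame only when the run start aligns with the CDS
        off <- nchar(t$utr5)
        inside <- runs$start_nt >= off & (runs$start_nt - off) %% 3L == 0L
        otmd <- rep(FALSE, nrow(runs))
        if (any(inside)) {
          otmd[inside] <- .run_overlaps_tmd(runs$start_nt[inside] - off,
                                            runs$n_triplets[inside],
                                            t$tmd_intervals)
        }
      } else {
        otmd <- rep(FALSE, nrow(runs))
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = t$gene_id, region = region, phase = phase,
        start_nt = runs$start_nt, n_triplets = runs$n_triplets,
        sequence = runs$sequence,
        rry_score = vapply(runs$sequence, rry_score, numeric(1L),
                           USE.NAMES = FALSE),
        overlaps_tmd = otmd, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  res <- do.call(rbind, out)
  res[order(res$region, res$start_nt, res$phase), , drop = FALSE]
}

#' Scan a list of transcripts
#'
#' @param transcripts List of [transcript()] objects.
#' @param cfg A [scan_config()].
#' @return Combined motif-hit data.frame (see [scan_transcript()]).
#' @export
scan_transcriptome <- function(transcripts, cfg = scan_config()) {
  hits <- lapply(transcripts, scan_transcript, cfg = cfg)
  hits <- hits[vapply(hits, nrow, integer(1L)) > 0L]
  if (length(hits) == 0L) return(.empty_hits())
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

#' SECReTE count of a transcript
#'
#' Number of maximal qualifying runs across the configured regions and
#' phases. A gene may carry several motifs, each potentially in a different
#' frame; each maximal run counts once.
#'
#' @inheritParams scan_transcript
#' @return Integer scalar.
#' @export
secrete_count <- function(t, cfg = scan_config()) {
  nrow(scan_transcript(t, cfg))
}

#' RRY purity score of a motif sequence
#'
#' Distinguishes motifs that follow a purine-purine-pyrimidine (RRY) repeat
#' from motifs that are merely pyrimidine-rich (poly-Y also satisfies NNY).
#' Each nucleotide scores 1 when it matches the cyclic R,R,Y template and 0
#' otherwise; the score is the mean over the motif, maximized over the three
#' template offsets. Poly-pyrimidine sequences score exactly 1/3; perfect RRY
#' repeats score 1.
#'
#' @param motif_seq Non-empty DNA string.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' rry_score(strrep("AGT", 10))  # 1
#' rry_score(strrep("TTT", 10))  # 1/3
#' @export
rry_score <- function(motif_seq) {
  stopifnot(is.character(motif_seq), length(motif_seq) == 1L)
  if (!nzchar(motif_seq)) stop("motif_seq must be non-empty")
  chars <- strsplit(motif_seq, "", fixed = TRUE)[[1L]]
  is_r <- chars %in% c("A", "G")
  is_y <- chars %in% c("C", "T")
  tmpl <- c("R", "R", "Y")
  best <- 0
  for (off in 0:2) {
    letters <- tmpl[((seq_along(chars) - 1L + off) %% 3L) + 1L]
    best <- max(best, mean(ifelse(letters == "Y", is_y, is_r)))
  }
  best
}

#' Pyrimidine content of a sequence
#'
#' Fraction of C and T bases; N counts in the denominator only.
#'
#' @param seq Non-empty DNA string.
#' @return Numeric scalar in \[0, 1\].
#' @export
pyrimidine_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("seq must be non-empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(chars %in% c("C", "T"))
}
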