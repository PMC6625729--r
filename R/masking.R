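#' Excise protein-coordinate intervals from a CDS
#'
#' Removes the codons covered by any of the given 1-based inclusive residue
#' intervals and concatenates the flanks in order. Overlapping or touching
#' intervals are merged. Excision operates on whole codons, matching
#' residue-level TMD and signal-peptide definitions; concatenation may create
#' new runs spanning the junction, which downstream scans report as-is.
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param intervals Two-column matrix or list of `c(start, end)` residue
#'   intervals; NULL or empty for identity.
#' @return The excised DNA string; its length equals
#'   `nchar(cds) - 3 * (number of covered residues)`.
#' @examples
#' excise_protein_intervals(paste(rep("GCT", 5), collapse = ""), rbind(c(2, 3)))
#' @export
excise_protein_intervals <- function(cds, intervals) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) %% 3L == 0L)
  intervals <- .as_interval_matrix(intervals)
  n_res <- nchar(cds) %/% 3L
  if (nrow(intervals) == 0L) return(cds)
  if (any(intervals[, 1L] > intervals[, 2L])) stop("interval start > end")
  if (any(intervals[, 1L] < 1L) || any(intervals[, 2L] > n_res)) {
    stop(sprintf("interval outside protein length %d", n_res))
  }
  drop <- logical(n_res)
  for (i in seq_len(nrow(intervals))) {
    drop[intervals[i, 1L]:intervals[i, 2L]] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0L) return("")
  codons <- substring(cds, 3L * keep - 2L, 3L * keep)
  paste(codons, collapse = "")
}

#' Remove the signal-sequence coding region from a CDS
#'
#' Drops the first `sscr_len` codons (the region encoding the signal
#' peptide).
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param sscr_len Number of signal-peptide residues, `0 <= sscr_len <=`
#'   protein length.
#' @return The truncated DNA string.
#' @export
remove_sscr <- function(cds, sscr_len) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) %% 3L == 0L)
  sscr_len <- as.integer(sscr_len)
  n_res <- nchar(cds) %/% 3L
  stopifnot(sscr_len >= 0L, sscr_len <= n_res)
  if (sscr_len == 0L) return(cds)
  substring(cds, 3L * sscr_len + 1L)
}

#' Rescan a transcript after TMD and/or signal-sequence excision
#'
#' Builds the excised CDS (TMD intervals, the first `sscr_len` codons, or
#' both, merged) and scans it. Hit coordinates are reported in
#' excised-sequence space; the returned table carries an `excision_mode`
#' column. Only the CDS region is scanned; TMD intervals are not meaningful
#' on the excised sequence, so `overlaps_tmd` is FALSE throughout.
#'
#' @param t A [transcript()] carrying the annotations the mode requires.
#' @param mode One of `"TMD"`, `"SSCR"`, `"both"`.
#' @param cfg A [scan_config()].
#' @return Motif-hit data.frame with an extra `excision_mode` column.
#' @export
rescan_after_excision <- function(t, mode = c("TMD", "SSCR", "both"),
                                  cfg = scan_config()) {
  stopifnot(inherits(t, "transcript"))
  mode <- match.arg(mode)
  intervals <- .as_interval_matrix(NULL)
  if (mode %in% c("TMD", "both")) intervals <- t$tmd_intervals
  if (mode %in% c("SSCR", "both") && t$sscr_len > 0L) {
    intervals <- rbind(intervals, c(1L, t$sscr_len))
  }
  excised <- excise_protein_intervals(t$cds, intervals)
  hits <- if (nzchar(excised)) {
    tt <- transcript(t$gene_id, cds = excised,
                     is_secretome = t$is_secretome, groups = t$groups)
    cfg$regions <- "CDS"
    scan_transcript(tt, cfg)
  } else {
    .empty_hits()
  }
  hits$excision_mode <- rep(mode, nrow(hits))
  hits
}
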