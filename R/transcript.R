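#' @title Nucleotide classes used for triplet scanning
#' @description Two-letter IUPAC nucleotide classes available as the checked
#'   base of a triplet run. `Y` (pyrimidine) is the class defining SECReTE.
#' @format A named list of character vectors.
#' @keywords internal
.NT_CLASSES <- list(
  Y = c("C", "T"),
  R = c("A", "G"),
  K = c("T", "G"),
  M = c("C", "A"),
  S = c("G", "C"),
  W = c("A", "T")
)

.REGIONS <- c("5UTR", "CDS", "3UTR", "FULL")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases, maps U to T, and collapses any IUPAC ambiguity code other than
#' A/C/G/T to N. Characters outside the IUPAC nucleotide alphabet raise an
#' error.
#'
#' @param seq Character scalar.
#' @param id Record identifier used in error messages.
#' @return Normalized character scalar over A/C/G/T/N.
#' @export
normalize_sequence <- function(seq, id = "<sequence>") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", s)
  if (nzchar(bad)) {
    stop(sprintf("record '%s' contains non-IUPAC character(s): %s",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = " ")))
  }
  # ambiguity codes other than N are not informative for class scanning
  gsub("[RYSWKMBDHV]", "N", s)
}

#' Construct a Transcript record
#'
#' A Transcript bundles the sequences and annotations of one gene: the coding
#' sequence (start codon through stop codon), optional 5' and 3' UTRs, the
#' secretome flag, free-form group labels (e.g. `"cell_wall"`, `"TA"`,
#' `"mito"`, `"SS"`, `"TMD"`, `"SS&TMD"`), transmembrane-domain intervals in
#' 1-based inclusive protein coordinates, and the signal-peptide length in
#' residues.
#'
#' @param gene_id Character scalar identifier.
#' @param cds Coding sequence (length must be a multiple of 3).
#' @param utr5,utr3 Untranslated region sequences; may be empty strings.
#' @param is_secretome Logical flag.
#' @param groups Character vector of group labels.
#' @param tmd_intervals Two-column matrix (start, end) of 1-based inclusive
#'   residue intervals, or NULL for none.
#' @param sscr_len Integer signal-peptide length in residues (0 if none).
#' @return An object of class `"transcript"`.
#' @examples
#' tr <- transcript("g1", cds = strrep("GCT", 12))
#' nchar(tr$cds)
#' @export
transcript <- function(gene_id, cds, utr5 = "", utr3 = "",
                       is_secretome = FALSE, groups = character(),
                       tmd_intervals = NULL, sscr_len = 0L) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  cds <- normalize_sequence(cds, gene_id)
  utr5 <- normalize_sequence(utr5, gene_id)
  utr3 <- normalize_sequence(utr3, gene_id)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("gene '%s': CDS length %d is not a multiple of 3",
                 gene_id, nchar(cds)))
  }
  n_res <- nchar(cds) %/% 3L
  tmd_intervals <- .as_interval_matrix(tmd_intervals)
  if (nrow(tmd_intervals) > 0L) {
    if (any(tmd_intervals[, 1L] > tmd_intervals[, 2L])) {
      stop(sprintf("gene '%s': TMD interval start > end", gene_id))
    }
    if (any(tmd_intervals[, 1L] < 1L) || any(tmd_intervals[, 2L] > n_res)) {
      stop(sprintf("gene '%s': TMD interval outside protein length %d",
                   gene_id, n_res))
    }
  }
  sscr_len <- as.integer(sscr_len)
  if (is.na(sscr_len) || sscr_len < 0L || sscr_len > n_res) {
    stop(sprintf("gene '%s': sscr_len must lie in [0, %d]", gene_id, n_res))
  }
  structure(
    list(gene_id = gene_id, cds = cds, utr5 = utr5, utr3 = utr3,
         is_secretome = isTRUE(as.logical(is_secretome)),
         groups = as.character(groups),
         tmd_intervals = tmd_intervals, sscr_len = sscr_len),
    class = "transcript"
  )
}

.as_interval_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.vector(x) && length(x) == 2L) x <- matrix(x, ncol = 2L)
  stopifnot(is.matrix(x), ncol(x) == 2L)
  storage.mode(x) <- "integer"
  colnames(x) <- c("start", "end")
  x
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> CDS %d nt | 5'UTR %d nt | 3'UTR %d nt | %s\n",
              x$gene_id, nchar(x$cds), nchar(x$utr5), nchar(x$utr3),
              if (x$is_secretome) "secretome" else "non-secretome"))
  if (nrow(x$tmd_intervals) > 0L) {
    cat("  TMDs:", paste(sprintf("%d-%d", x$tmd_intervals[, 1L],
                                 x$tmd_intervals[, 2L]), collapse = "; "), "\n")
  }
  if (x$sscr_len > 0L) cat("  signal peptide:", x$sscr_len, "residues\n")
  invisible(x)
}

#' Scanning configuration
#'
#' Bundles the parameters of a triplet-run scan: the minimum run length in
#' triplets (the SECReTE threshold; 10 defines SECReTE10), the checked
#' nucleotide class, the transcript regions to scan and the triplet phases.
#' For the CDS, phases are anchored to the reading frame: phase 0 checks the
#' first codon position (YNN), phase 1 the second (NYN) and phase 2 the third
#' (NNY). UTRs are scanned at the same offsets from their own 5' end.
#'
#' @param min_triplets Integer >= 2; minimum number of consecutive qualifying
#'   triplets for a run to be reported.
#' @param nt_class One of `"Y"`, `"R"`, `"K"`, `"M"`, `"S"`, `"W"`.
#' @param regions Subset of `c("5UTR", "CDS", "3UTR", "FULL")`. `"FULL"`
#'   concatenates 5'UTR + CDS + 3'UTR and anchors offsets at the transcript
#'   5' end (for whole-gene profiles).
#' @param phases Subset of `0:2`.
#' @return An object of class `"scan_config"`.
#' @examples
#' scan_config()                      # SECReTE10, NNY/NYN/YNN, all regions
#' scan_config(min_triplets = 15, phases = 2)
#' @export
scan_config <- function(min_triplets = 10L, nt_class = "Y",
                        regions = c("CDS", "5UTR", "3UTR"), phases = 0:2) {
  min_triplets <- as.integer(min_triplets)
  if (is.na(min_triplets) || min_triplets < 2L) {
    stop("min_triplets must be an integer >= 2")
  }
  nt_class <- match.arg(nt_class, names(.NT_CLASSES))
  regions <- unique(match.arg(regions, .REGIONS, several.ok = TRUE))
  phases <- sort(unique(as.integer(phases)))
  if (length(phases) == 0L || !all(phases %in% 0:2)) {
    stop("phases must be a non-empty subset of 0:2")
  }
  structure(list(min_triplets = min_triplets, nt_class = nt_class,
                 regions = regions, phases = phases),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> threshold %d triplets | class %s={%s} | regions %s | phases %s\n",
              x$min_triplets, x$nt_class,
              paste(.NT_CLASSES[[x$nt_class]], collapse = ","),
              paste(x$regions, collapse = ","),
              paste(x$phases, collapse = ",")))
  invisible(x)
}

# empty motif-hit table with the canonical column set
.empty_hits <- function() {
  data.frame(gene_id = character(), region = character(),
             phase = integer(), start_nt = integer(),
             n_triplets = integer(), sequence = character(),
             rry_score = numeric(), overlaps_tmd = logical(),
             stringsAsFactors = FALSE)
}
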