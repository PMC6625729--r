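.split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.check_cds <- function(cds, code) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3L != 0L) stop("CDS length is not a multiple of 3")
  codons <- .split_codons(cds)
  if (length(codons) == 0L) return(codons)
  aa <- code[codons]
  if (anyNA(aa)) {
    stop(sprintf("CDS contains non-code codon(s): %s",
                 paste(unique(codons[is.na(aa)]), collapse = ", ")))
  }
  if (any(aa[-length(aa)] == "*")) stop("CDS contains an internal stop codon")
  codons
}

#' Translate a CDS to protein
#'
#' @param cds Coding sequence (length a multiple of 3, no internal stops).
#' @param code Genetic code, a named character vector mapping DNA codons to
#'   single-letter amino acids (`"*"` for stop); defaults to the standard
#'   code.
#' @return Amino-acid string (stop rendered as `*`).
#' @export
translate_cds <- function(cds, code = Biostrings::GENETIC_CODE) {
  codons <- .check_cds(cds, code)
  paste(code[codons], collapse = "")
}

.recode <- function(cds, direction, code) {
  codons <- .check_cds(cds, code)
  sub_map <- if (direction == "plus") c(A = "T", G = "C") else c(T = "A", C = "G")
  third <- substr(codons, 3L, 3L)
  editable <- third %in% names(sub_map)
  cand <- codons
  substr(cand[editable], 3L, 3L) <- sub_map[third[editable]]
  synonymous <- editable & code[cand] == code[codons]
  recoded <- ifelse(synonymous, cand, codons)
  structure(list(original = cds,
                 recoded = paste(recoded, collapse = ""),
                 direction = direction,
                 n_substitutions = sum(synonymous),
                 n_blocked = sum(editable & !synonymous)),
            class = "recode_result")
}

#' Synonymous (+)SECReTE recoding of a CDS
#'
#' Substitutes A with T and G with C at the third codon position wherever
#' the substitution is synonymous under the genetic code, enriching the NNY
#' signal along the gene without changing the encoded protein.
#' Non-synonymous candidates are skipped silently and counted in
#' `n_blocked`; stop codons are left untouched by the synonymy rule itself.
#'
#' @inheritParams translate_cds
#' @return List of class `"recode_result"`: `original`, `recoded`,
#'   `direction`, `n_substitutions`, `n_blocked`.
#' @examples
#' plus_secrete("GCA")$recoded  # "GCT"
#' plus_secrete("ATG")$recoded  # unchanged, no synonymous pyrimidine-ending Met codon
#' @export
plus_secrete <- function(cds, code = Biostrings::GENETIC_CODE) {
  .recode(cds, "plus", code)
}

#' Synonymous (-)SECReTE recoding of a CDS
#'
#' Mirror of [plus_secrete()]: T to A and C to G at third codon positions,
#' synonymous substitutions only, reducing the NNY signal. Motifs whose
#' pyrimidines cannot be removed synonymously survive.
#'
#' @inheritParams translate_cds
#' @return A `"recode_result"` (see [plus_secrete()]).
#' @export
minus_secrete <- function(cds, code = Biostrings::GENETIC_CODE) {
  .recode(cds, "minus", code)
}

#' Unconditional UTR recoding
#'
#' Outside coding regions no synonymy constraint applies, so every A (plus
#' direction) is replaced by T and every G by C, or the reverse for minus,
#' at all positions.
#'
#' @param seq UTR sequence.
#' @param direction `"plus"` or `"minus"`.
#' @return Recoded string.
#' @export
recode_utr <- function(seq, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  if (direction == "plus") chartr("AG", "TC", seq) else chartr("TC", "AG", seq)
}

#' Codon usage table with relative adaptiveness
#'
#' Stores codon frequencies and derives the relative adaptiveness
#' `w(codon) = freq / max(freq among synonyms)` used by [cai()]. Every sense
#' codon of the genetic code must be present with non-negative frequency and
#' every amino acid must have at least one codon of positive frequency.
#'
#' @param freq Named numeric vector of codon frequencies (any scale).
#' @param code Genetic code (see [translate_cds()]).
#' @return List of class `"codon_usage_table"` with `freq`, `w`, `code`.
#' @export
codon_usage_table <- function(freq, code = Biostrings::GENETIC_CODE) {
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, names(freq))
  if (length(missing) > 0L) {
    stop(sprintf("usage table lacks sense codon(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (any(freq < 0)) stop("frequencies must be non-negative")
  w <- stats::setNames(numeric(length(sense)), sense)
  for (aa in unique(code[sense])) {
    syn <- sense[code[sense] == aa]
    m <- max(freq[syn])
    if (m <= 0) stop(sprintf("amino acid %s has no codon with positive frequency", aa))
    w[syn] <- freq[syn] / m
  }
  structure(list(freq = freq[sense], w = w, code = code),
            class = "codon_usage_table")
}

#' Read a codon usage table from TSV
#'
#' Two columns: `codon`, `frequency` (header required; RNA codons accepted).
#'
#' @param path Path to the TSV file.
#' @inheritParams codon_usage_table
#' @return A [codon_usage_table()].
#' @export
read_codon_usage <- function(path, code = Biostrings::GENETIC_CODE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  stopifnot(all(c("codon", "frequency") %in% names(df)))
  freq <- stats::setNames(as.numeric(df$frequency),
                          chartr("Uu", "Tt", toupper(df$codon)))
  codon_usage_table(freq, code)
}

#' Flat codon usage (uniform over sense codons)
#'
#' Background usage in which every sense codon is equally likely; all
#' relative adaptiveness values are 1, so CAI is 1 for any CDS.
#'
#' @inheritParams codon_usage_table
#' @return A [codon_usage_table()].
#' @export
flat_codon_usage <- function(code = Biostrings::GENETIC_CODE) {
  sense <- names(code)[code != "*"]
  codon_usage_table(stats::setNames(rep(1, length(sense)), sense), code)
}

#' Codon adaptation index of a CDS
#'
#' Geometric mean of the relative adaptiveness `w` over the codons of the
#' CDS, excluding stop codons and amino acids with a single codon (Met,
#' Trp under the standard code), following the usual convention.
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param usage A [codon_usage_table()].
#' @return Numeric CAI in (0, 1].
#' @export
cai <- function(cds, usage) {
  stopifnot(inherits(usage, "codon_usage_table"))
  code <- usage$code
  codons <- .split_codons(cds)
  if (length(codons) == 0L) stop("empty CDS")
  aa <- code[codons]
  if (anyNA(aa)) {
    stop(sprintf("codon(s) absent from the genetic code: %s",
                 paste(unique(codons[is.na(aa)]), collapse = ", ")))
  }
  sense <- names(code)[code != "*"]
  n_syn <- table(code[sense])
  informative <- aa != "*" & n_syn[aa] > 1L
  codons <- codons[informative]
  if (length(codons) == 0L) stop("no informative codons for CAI")
  if (!all(codons %in% names(usage$w))) {
    stop("codon absent from the usage table")
  }
  exp(mean(log(usage$w[codons])))
}

#' Per-triplet NNY profile of a CDS
#'
#' For whole-gene motif profiles: a logical vector marking, for each codon,
#' whether its base at the given phase belongs to the class.
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param phase Intra-codon offset 0, 1 or 2 (2 = third position, NNY).
#' @param nt_class Checked class.
#' @return Logical vector of length `nchar(cds) / 3`.
#' @export
triplet_profile <- function(cds, phase = 2L, nt_class = "Y") {
  stopifnot(nchar(cds) %% 3L == 0L, phase %in% 0:2)
  codons <- .split_codons(cds)
  substr(codons, phase + 1L, phase + 1L) %in% .NT_CLASSES[[nt_class]]
}

#' Full recoding report for a transcript CDS
#'
#' Applies (+) or (-) SECReTE recoding and reports the NNY motif counts at
#' the configured threshold and at threshold 1 (the per-triplet run profile)
#' before and after, the CAI before and after, and the translated protein
#' (unchanged by construction).
#'
#' @param t A [transcript()] or a CDS string.
#' @param direction `"plus"` or `"minus"`.
#' @param cfg A [scan_config()] (class and threshold for the motif counts;
#'   counts are computed on the CDS at the configured phases).
#' @param usage A [codon_usage_table()] for CAI; NULL skips CAI.
#' @return List of class `"recode_report"` extending the `"recode_result"`
#'   fields with `count_before`, `count_after`, `count1_before`,
#'   `count1_after`, `cai_before`, `cai_after`, `protein`.
#' @export
recode_report <- function(t, direction = c("plus", "minus"),
                          cfg = scan_config(), usage = NULL) {
  direction <- match.arg(direction)
  cds <- if (inherits(t, "transcript")) t$cds else t
  rr <- .recode(cds, direction, if (is.null(usage)) Biostrings::GENETIC_CODE
                                else usage$code)
  count_at <- function(s, m) {
    sum(vapply(cfg$phases, function(p) {
      nrow(find_runs(s, p, cfg$nt_class, m))
    }, integer(1L)))
  }
  rr$count_before <- count_at(cds, cfg$min_triplets)
  rr$count_after <- count_at(rr$recoded, cfg$min_triplets)
  rr$count1_before <- count_at(cds, 1L)
  rr$count1_after <- count_at(rr$recoded, 1L)
  rr$cai_before <- if (is.null(usage)) NA_real_ else cai(cds, usage)
  rr$cai_after <- if (is.null(usage)) NA_real_ else cai(rr$recoded, usage)
  rr$protein <- translate_cds(rr$recoded,
                              if (is.null(usage)) Biostrings::GENETIC_CODE
                              else usage$code)
  class(rr) <- c("recode_report", "recode_result")
  rr
}

#' @export
print.recode_result <- function(x, ...) {
  cat(sprintf("<recode %s> %d substitution(s), %d blocked by synonymy, %d nt\n",
              x$direction, x$n_substitutions, x$n_blocked, nchar(x$original)))
  if (!is.null(x$count_before)) {
    cat(sprintf("  motif count %d -> %d (threshold run); %d -> %d (all runs)\n",
                x$count_before, x$count_after, x$count1_before, x$count1_after))
  }
  if (!is.null(x$cai_before) && !is.na(x$cai_before)) {
    cat(sprintf("  CAI %.4f -> %.4f\n", x$cai_before, x$cai_after))
  }
  invisible(x)
}
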