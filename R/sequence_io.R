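#' Read a FASTA file into a named vector of DNA strings
#'
#' Sequences are uppercased, RNA `U` is mapped to `T` and ambiguity codes
#' other than N are collapsed to N. Duplicate record ids and non-IUPAC
#' characters are hard errors. Record ids are the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return Named character vector, one DNA string per record; empty sequences
#'   allowed.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  vapply(ids, function(id) normalize_sequence(seqs[[id]], id), character(1L))
}

#' Write a named vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

.parse_intervals <- function(s, line = NA_integer_) {
  if (is.na(s) || !nzchar(s)) {
    return(.as_interval_matrix(NULL))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(vapply(m, length, integer(1L)) != 3L)) {
    stop(sprintf("line %s: malformed interval string '%s' (expected 's-e;s-e')",
                 line, s))
  }
  iv <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2L)))
  if (any(iv[, 1L] > iv[, 2L])) {
    stop(sprintf("line %s: interval start > end in '%s'", line, s))
  }
  .as_interval_matrix(iv)
}

#' Read a gene-annotation table
#'
#' Tab-separated with a header. Required columns: `gene_id`, `is_secretome`.
#' Optional: `groups` (comma-separated labels), `tmd_intervals`
#' (`"s1-e1;s2-e2"`, 1-based inclusive protein coordinates) and `sscr_len`
#' (signal-peptide residues). Unknown columns trigger a warning and are
#' ignored; malformed intervals are errors reporting the offending line.
#'
#' @param path Path to the TSV file.
#' @return Named list of annotation records (fields `is_secretome`, `groups`,
#'   `tmd_intervals`, `sscr_len`), keyed by gene id.
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  required <- c("gene_id", "is_secretome")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("annotation table lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  known <- c(required, "groups", "tmd_intervals", "sscr_len")
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring unknown annotation column(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  ann <- vector("list", nrow(df))
  names(ann) <- df$gene_id
  for (i in seq_len(nrow(df))) {
    ann[[i]] <- list(
      is_secretome = df$is_secretome[i] %in% c("1", "TRUE", "True", "true"),
      groups = if ("groups" %in% names(df) && nzchar(df$groups[i])) {
        trimws(strsplit(df$groups[i], ",", fixed = TRUE)[[1L]])
      } else character(),
      tmd_intervals = if ("tmd_intervals" %in% names(df)) {
        .parse_intervals(df$tmd_intervals[i], line = i + 1L)
      } else .as_interval_matrix(NULL),
      sscr_len = if ("sscr_len" %in% names(df) && nzchar(df$sscr_len[i])) {
        as.integer(df$sscr_len[i])
      } else 0L
    )
  }
  ann
}

#' Assemble Transcript records from sequence maps and annotations
#'
#' Every annotated gene must have a CDS; UTR maps may lack genes (missing
#' UTRs become empty strings). Genes whose CDS length is not a multiple of 3
#' are excluded (per-codon-position analysis is undefined for them) and
#' reported in the `excluded` field.
#'
#' @param cds_map,utr5_map,utr3_map Named character vectors as returned by
#'   [read_fasta()]; UTR maps may be NULL.
#' @param annotations Named list from [read_annotations()], or NULL to treat
#'   every CDS record as an unannotated non-secretome gene.
#' @return List with `transcripts` (list of [transcript()]) and `excluded`
#'   (character vector of excluded gene ids). The number of transcripts plus
#'   exclusions equals the number of annotated genes.
#' @export
assemble_transcripts <- function(cds_map, utr5_map = NULL, utr3_map = NULL,
                                 annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- stats::setNames(
      rep(list(list(is_secretome = FALSE, groups = character(),
                    tmd_intervals = .as_interval_matrix(NULL),
                    sscr_len = 0L)), length(cds_map)),
      names(cds_map))
  }
  ids <- names(annotations)
  no_cds <- setdiff(ids, names(cds_map))
  if (length(no_cds) > 0L) {
    stop(sprintf("annotated gene(s) missing from the CDS map: %s",
                 paste(no_cds, collapse = ", ")))
  }
  transcripts <- list()
  excluded <- character()
  for (id in ids) {
    cds <- cds_map[[id]]
    if (nchar(cds) %% 3L != 0L) {
      excluded <- c(excluded, id)
      next
    }
    a <- annotations[[id]]
    transcripts[[id]] <- transcript(
      id, cds = cds,
      utr5 = if (!is.null(utr5_map) && id %in% names(utr5_map)) utr5_map[[id]] else "",
      utr3 = if (!is.null(utr3_map) && id %in% names(utr3_map)) utr3_map[[id]] else "",
      is_secretome = a$is_secretome, groups = a$groups,
      tmd_intervals = a$tmd_intervals, sscr_len = a$sscr_len)
  }
  if (length(excluded) > 0L) {
    message(sprintf("excluded %d gene(s) with CDS length not divisible by 3: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  list(transcripts = transcripts, excluded = excluded)
}

#' Write a motif-hit table to TSV
#'
#' Rows are ordered by (gene_id, region, start, phase). Coordinates are
#' emitted 1-based inclusive (`start` column; internal representation is
#' 0-based), as stated in the file header. `rry_score` is written with full
#' double precision so a read back reproduces the hits exactly.
#'
#' @param hits Motif-hit data.frame (see [scan_transcript()]).
#' @param path Output path.
#' @param provenance Optional extra header comment lines (without `#`).
#' @return Invisibly, `path`.
#' @export
write_motif_table <- function(hits, path, provenance = character()) {
  cols <- names(.empty_hits())
  stopifnot(all(cols %in% names(hits)))
  hits <- hits[order(hits$gene_id, hits$region, hits$start_nt, hits$phase),
               cols, drop = FALSE]
  out <- data.frame(gene_id = hits$gene_id, region = hits$region,
                    phase = hits$phase, start = hits$start_nt + 1L,
                    n_triplets = hits$n_triplets, sequence = hits$sequence,
                    rry_score = sprintf("%.17g", hits$rry_score),
                    overlaps_tmd = as.integer(hits$overlaps_tmd),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# secretescan %s motif table",
                       as.character(utils::packageVersion("secretescan"))),
               "# coordinates: start is 1-based inclusive within the region",
               if (length(provenance) > 0L) paste("#", provenance)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif-hit table written by [write_motif_table()]
#'
#' @param path Path to the TSV file.
#' @return Motif-hit data.frame with the internal 0-based `start_nt` column.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c(gene_id = "character",
                                         region = "character",
                                         phase = "integer", start = "integer",
                                         n_triplets = "integer",
                                         sequence = "character",
                                         rry_score = "numeric",
                                         overlaps_tmd = "integer"))
  data.frame(gene_id = df$gene_id, region = df$region, phase = df$phase,
             start_nt = df$start - 1L, n_triplets = df$n_triplets,
             sequence = df$sequence, rry_score = df$rry_score,
             overlaps_tmd = as.logical(df$overlaps_tmd),
             stringsAsFactors = FALSE)
}

#' Read transcript regions from a transcript FASTA plus GFF3 annotations
#'
#' Optional alternative to separate per-region FASTA files. Features of type
#' `CDS`, `five_prime_UTR` and `three_prime_UTR` are interpreted in
#' transcript-space coordinates on the FASTA records named by `seqnames`;
#' the gene id is taken from the feature `Parent` attribute when present,
#' otherwise `ID`, otherwise the sequence name. Multi-part CDS features are
#' concatenated in coordinate order. Requires the rtracklayer package.
#'
#' @param fasta_path Transcript FASTA.
#' @param gff_path GFF3 file.
#' @return List of maps `cds`, `utr5`, `utr3` suitable for
#'   [assemble_transcripts()].
#' @export
read_transcripts_gff3 <- function(fasta_path, gff_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_transcripts_gff3 requires the rtracklayer package")
  }
  seqs <- read_fasta(fasta_path)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gff$type)
  keep <- type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  gff <- gff[keep]
  type <- type[keep]
  ids <- vapply(seq_along(gff), function(i) {
    p <- gff$Parent[[i]]
    if (length(p) > 0L) return(as.character(p[[1L]]))
    if (!is.null(gff$ID) && !is.na(gff$ID[i])) return(gff$ID[i])
    as.character(GenomicRanges::seqnames(gff)[i])
  }, character(1L))
  maps <- list(cds = character(), utr5 = character(), utr3 = character())
  slot <- c(CDS = "cds", five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  for (id in unique(ids)) {
    sel <- which(ids == id)
    for (ty in unique(type[sel])) {
      fsel <- sel[type[sel] == ty]
      fsel <- fsel[order(GenomicRanges::start(gff)[fsel])]
      seqname <- as.character(GenomicRanges::seqnames(gff)[fsel[1L]])
      if (!seqname %in% names(seqs)) {
        stop(sprintf("GFF3 feature references missing FASTA record '%s'", seqname))
      }
      pieces <- substring(seqs[[seqname]],
                          GenomicRanges::start(gff)[fsel],
                          GenomicRanges::end(gff)[fsel])
      maps[[slot[[ty]]]][id] <- paste(pieces, collapse = "")
    }
  }
  maps
}
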