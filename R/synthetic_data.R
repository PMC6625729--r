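# codon pools derived from a genetic code: for each intra-codon position,
# which amino acids have a synonym carrying Y (or R) at that position
.codon_pools <- function(code = Biostrings::GENETIC_CODE) {
  sense <- names(code)[code != "*"]
  pools <- list()
  for (p in 1:3) {
    base <- substr(sense, p, p)
    y_codons <- sense[base %in% c("C", "T")]
    r_codons <- sense[base %in% c("A", "G")]
    pools[[p]] <- list(
      y_codons = y_codons, r_codons = r_codons,
      aa_with_y = unique(code[y_codons]),
      aa_with_r = unique(code[r_codons]))
  }
  pools
}

# replace window codons so the base at `phase` is in Y, flanks in R.
# For phase 2 the edits are synonymous (the window is first resampled from
# amino acids that admit a Y-ending codon); for phases 0/1 codons are drawn
# directly from the Y-at-position pool (synonymy is not generally attainable
# there).
.force_window <- function(codons, wstart, wlen, phase, code, pools) {
  p <- phase + 1L
  pool <- pools[[p]]
  idx <- wstart:(wstart + wlen - 1L)
  if (phase == 2L) {
    for (i in idx) {
      aa <- code[codons[i]]
      if (!aa %in% pool$aa_with_y) {
        aa <- sample(pool$aa_with_y, 1L)
      }
      syn_y <- pool$y_codons[code[pool$y_codons] == aa]
      codons[i] <- sample(syn_y, 1L)[[1L]]
    }
  } else {
    codons[idx] <- sample(pool$y_codons, wlen, replace = TRUE)
  }
  for (i in c(wstart - 1L, wstart + wlen)) {
    if (i < 1L || i > length(codons)) next
    aa <- code[codons[i]]
    if (phase == 2L && aa %in% pool$aa_with_r) {
      syn_r <- pool$r_codons[code[pool$r_codons] == aa]
      codons[i] <- sample(syn_r, 1L)[[1L]]
    } else {
      codons[i] <- sample(pool$r_codons, 1L)[[1L]]
    }
  }
  codons
}

#' Specification for a synthetic labeled transcriptome
#'
#' Defines the gene counts, sequence-length ranges, background codon usage,
#' planted-motif scheme and planted-TMD scheme of a simulation. Defaults
#' describe a desk-scale secretome contrast: 400 secretome and 400
#' non-secretome genes, CDSs of 200-600 codons drawn from a uniform
#' sense-codon background, yeast-like UTR lengths, NNY (phase 2) motifs of
#' 10-14 triplets planted in 85% of secretome genes, decoy runs of 5-9
#' triplets in 25% of non-secretome genes, and hydrophobic TMD-like
#' stretches of 18-28 residues in half of the secretome and a fifth of the
#' non-secretome.
#'
#' @param n_secretome,n_non_secretome Gene counts per class.
#' @param cds_len_range Integer range of CDS lengths in codons (including
#'   start and stop).
#' @param utr5_len_range,utr3_len_range Integer UTR length ranges in nt
#'   (0 allowed).
#' @param usage A [codon_usage_table()] for the CDS background, or NULL for
#'   uniform sense-codon usage.
#' @param planted_motif List with fields `region` ("CDS", "5UTR" or
#'   "3UTR"), `phase` (0:2), `len_range_secretome`, `len_range_non`
#'   (triplet-count ranges), `prob_secretome`, `prob_non` (per-gene planting
#'   probabilities). NULL plants nothing.
#' @param planted_tmd List with fields `len_range` (residues),
#'   `prob_secretome`, `prob_non`. NULL plants nothing.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_secretome = 400L, n_non_secretome = 400L,
                            cds_len_range = c(200L, 600L),
                            utr5_len_range = c(20L, 150L),
                            utr3_len_range = c(50L, 300L),
                            usage = NULL,
                            planted_motif = list(
                              region = "CDS", phase = 2L,
                              len_range_secretome = c(10L, 14L),
                              len_range_non = c(5L, 9L),
                              prob_secretome = 0.85, prob_non = 0.25),
                            planted_tmd = list(
                              len_range = c(18L, 28L),
                              prob_secretome = 0.5, prob_non = 0.2),
                            seed = 1L) {
  stopifnot(n_secretome >= 0L, n_non_secretome >= 0L,
            cds_len_range[1L] >= 10L, cds_len_range[1L] <= cds_len_range[2L],
            all(utr5_len_range >= 0L), all(utr3_len_range >= 0L))
  if (!is.null(planted_motif)) {
    stopifnot(planted_motif$region %in% c("CDS", "5UTR", "3UTR"),
              planted_motif$phase %in% 0:2,
              planted_motif$prob_secretome >= 0, planted_motif$prob_secretome <= 1,
              planted_motif$prob_non >= 0, planted_motif$prob_non <= 1)
  }
  if (!is.null(planted_tmd)) {
    stopifnot(planted_tmd$prob_secretome >= 0, planted_tmd$prob_secretome <= 1,
              planted_tmd$prob_non >= 0, planted_tmd$prob_non <= 1)
  }
  if (!is.null(usage)) stopifnot(inherits(usage, "codon_usage_table"))
  structure(list(n_secretome = as.integer(n_secretome),
                 n_non_secretome = as.integer(n_non_secretome),
                 cds_len_range = as.integer(cds_len_range),
                 utr5_len_range = as.integer(utr5_len_range),
                 utr3_len_range = as.integer(utr3_len_range),
                 usage = usage, planted_motif = planted_motif,
                 planted_tmd = planted_tmd, seed = as.integer(seed)),
            class = "simulation_spec")
}

# hydrophobic codon pool: Leu/Ile/Val/Phe codons, all with T at position 2
.HYDROPHOBIC_CODONS <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG",
                         "ATT", "ATC", "ATA",
                         "GTT", "GTC", "GTA", "GTG",
                         "TTT", "TTC")

.sample_range <- function(range) {
  if (range[1L] == range[2L]) range[1L] else
    sample(seq.int(range[1L], range[2L]), 1L)
}

.random_utr <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plant an NNY-type run of exactly `len` triplets in a UTR string at a
# multiple-of-3 start, with purines at the breaking checked positions
.plant_utr_run <- function(utr, len, phase) {
  n <- nchar(utr)
  need <- 3L * len + phase + 1L  # through the last checked base
  if (n < need + 6L) stop("planting impossible: UTR shorter than the motif")
  max_start <- ((n - need) %/% 3L) * 3L
  s <- 3L * sample.int(max_start %/% 3L + 1L, 1L) - 3L  # 0-based, incl. 0
  chars <- strsplit(utr, "", fixed = TRUE)[[1L]]
  checked <- s + phase + 3L * (0:(len - 1L)) + 1L       # 1-based
  chars[checked] <- sample(c("C", "T"), len, replace = TRUE)
  for (b in c(s + phase - 3L + 1L, s + phase + 3L * len + 1L)) {
    if (b >= 1L && b <= n) chars[b] <- sample(c("A", "G"), 1L)
  }
  list(utr = paste(chars, collapse = ""), start_nt = s)
}

.synth_gene <- function(gene_id, is_secretome, spec, pools, code, sense,
                        sense_prob) {
  n_cod <- .sample_range(spec$cds_len_range)
  codons <- c("ATG",
              sample(sense, n_cod - 2L, replace = TRUE, prob = sense_prob),
              sample(c("TAA", "TAG", "TGA"), 1L))
  # no internal stops in the background draw
  internal <- which(code[codons[2:(n_cod - 1L)]] == "*") + 1L
  while (length(internal) > 0L) {
    codons[internal] <- sample(sense[code[sense] != "*"], length(internal),
                               replace = TRUE)
    internal <- which(code[codons[2:(n_cod - 1L)]] == "*") + 1L
  }
  utr5 <- .random_utr(.sample_range(spec$utr5_len_range))
  utr3 <- .random_utr(.sample_range(spec$utr3_len_range))
  tmd_iv <- .as_interval_matrix(NULL)
  truth_motif <- NULL
  truth_tmd <- NULL

  pm <- spec$planted_motif
  pt <- spec$planted_tmd
  plant_m <- !is.null(pm) &&
    stats::runif(1L) < (if (is_secretome) pm$prob_secretome else pm$prob_non)
  plant_t <- !is.null(pt) &&
    stats::runif(1L) < (if (is_secretome) pt$prob_secretome else pt$prob_non)

  if (plant_t) {
    tlen <- .sample_range(pt$len_range)
    lo <- 3L
    hi <- n_cod %/% 2L - tlen
    if (hi < lo) stop("planting impossible: CDS too short for the TMD")
    tstart <- sample(seq.int(lo, hi), 1L)
    codons[tstart:(tstart + tlen - 1L)] <-
      sample(.HYDROPHOBIC_CODONS, tlen, replace = TRUE)
    # purine at position 2 on both flanks keeps the NYN run maximal
    for (i in c(tstart - 1L, tstart + tlen)) {
      codons[i] <- sample(pools[[2L]]$r_codons, 1L)
    }
    tmd_iv <- .as_interval_matrix(c(tstart, tstart + tlen - 1L))
    truth_tmd <- data.frame(gene_id = gene_id, start_res = tstart,
                            end_res = tstart + tlen - 1L, len = tlen)
  }

  if (plant_m) {
    lr <- if (is_secretome) pm$len_range_secretome else pm$len_range_non
    mlen <- .sample_range(lr)
    if (pm$region == "CDS") {
      lo <- n_cod %/% 2L + 2L
      hi <- n_cod - 1L - mlen - 1L
      if (hi < lo) stop("planting impossible: CDS too short for the motif")
      wstart <- sample(seq.int(lo, hi), 1L)
      codons <- .force_window(codons, wstart, mlen, pm$phase, code, pools)
      truth_motif <- data.frame(gene_id = gene_id, region = "CDS",
                                phase = pm$phase,
                                start_nt = 3L * (wstart - 1L),
                                n_triplets = mlen)
    } else {
      field <- if (pm$region == "5UTR") "utr5" else "utr3"
      utr <- if (field == "utr5") utr5 else utr3
      planted <- .plant_utr_run(utr, mlen, pm$phase)
      if (field == "utr5") utr5 <- planted$utr else utr3 <- planted$utr
      truth_motif <- data.frame(gene_id = gene_id, region = pm$region,
                                phase = pm$phase, start_nt = planted$start_nt,
                                n_triplets = mlen)
    }
  }

  sscr <- 0L
  groups <- character()
  if (is_secretome) {
    has_ss <- stats::runif(1L) < 0.7
    if (has_ss) sscr <- .sample_range(c(15L, 25L))
    has_tmd <- nrow(tmd_iv) > 0L
    groups <- if (has_ss && has_tmd) "SS&TMD" else if (has_tmd) "TMD"
              else if (has_ss) "SS" else "sec_other"
    if (stats::runif(1L) < 0.10) groups <- c(groups, "cell_wall")
    if (stats::runif(1L) < 0.05) groups <- c(groups, "TA")
  } else {
    groups <- if (stats::runif(1L) < 0.15) "mito" else "cytonuclear"
  }

  list(transcript = transcript(gene_id, cds = paste(codons, collapse = ""),
                               utr5 = utr5, utr3 = utr3,
                               is_secretome = is_secretome, groups = groups,
                               tmd_intervals = tmd_iv, sscr_len = sscr),
       truth_motif = truth_motif, truth_tmd = truth_tmd)
}

#' Generate a labeled synthetic transcriptome with planted structure
#'
#' CDSs are random codon sequences drawn from the background usage (ATG
#' start, single terminal stop, no internal stops); UTRs are uniform-random
#' nucleotide strings. Motifs are planted by synonymous third-position
#' forcing inside CDSs (direct class-constrained codon draws for phases 0/1)
#' or by substring substitution in UTRs, with purine-class breaks at both
#' ends so each planted run is maximal at exactly its recorded length.
#' TMD-like stretches are hydrophobic-codon substitutions with recorded
#' residue intervals. Deterministic under the spec seed; each gene has its
#' own derived random stream, so output is independent of generation order.
#'
#' @param spec A [simulation_spec()].
#' @return List with `transcripts` (named list of [transcript()]),
#'   `planted_motifs` (data.frame: gene_id, region, phase, start_nt 0-based,
#'   n_triplets) and `planted_tmds` (data.frame: gene_id, start_res,
#'   end_res, len).
#' @export
generate_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  code <- if (is.null(spec$usage)) Biostrings::GENETIC_CODE else spec$usage$code
  pools <- .codon_pools(code)
  sense <- names(code)[code != "*"]
  sense_prob <- if (is.null(spec$usage)) NULL else {
    f <- spec$usage$freq[sense]
    f / sum(f)
  }
  ids <- c(sprintf("SECG%04d", seq_len(spec$n_secretome)),
           sprintf("NONG%04d", seq_len(spec$n_non_secretome)))
  labels <- rep(c(TRUE, FALSE), c(spec$n_secretome, spec$n_non_secretome))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(.gene_seed(spec$seed, ids[i]))
    out[[i]] <- .synth_gene(ids[i], labels[i], spec, pools, code, sense,
                            sense_prob)
  }
  transcripts <- lapply(out, `[[`, "transcript")
  names(transcripts) <- ids
  motifs <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(out, `[[`, "truth_motif")))
  tmds <- do.call(rbind, Filter(Negate(is.null),
                                lapply(out, `[[`, "truth_tmd")))
  if (is.null(motifs)) {
    motifs <- data.frame(gene_id = character(), region = character(),
                         phase = integer(), start_nt = integer(),
                         n_triplets = integer())
  }
  if (is.null(tmds)) {
    tmds <- data.frame(gene_id = character(), start_res = integer(),
                       end_res = integer(), len = integer())
  }
  list(transcripts = transcripts, planted_motifs = motifs,
       planted_tmds = tmds)
}

#' Plant a hydrophobic TMD-like codon stretch into a transcript
#'
#' Substitutes `tmd_len` consecutive codons with draws from a hydrophobic
#' pool (Leu/Ile/Val/Phe codons, all with a pyrimidine at the second
#' position, so the stretch carries an NYN run of at least its length) and
#' records the protein-coordinate interval. A zero-length TMD is the
#' identity.
#'
#' @param t A [transcript()].
#' @param tmd_len Stretch length in residues.
#' @param start_res 1-based residue start, or NULL to centre the stretch.
#' @return List with `transcript` (modified, interval appended to
#'   `tmd_intervals`) and `interval` (`c(start, end)`).
#' @export
plant_tmd <- function(t, tmd_len, start_res = NULL) {
  stopifnot(inherits(t, "transcript"), tmd_len >= 0L)
  if (tmd_len == 0L) {
    return(list(transcript = t, interval = NULL))
  }
  tmd_len <- as.integer(tmd_len)
  n_cod <- nchar(t$cds) %/% 3L
  if (is.null(start_res)) start_res <- max(2L, (n_cod - tmd_len) %/% 2L)
  start_res <- as.integer(start_res)
  if (start_res < 2L || start_res + tmd_len > n_cod) {
    stop("insufficient CDS length for the requested TMD stretch")
  }
  codons <- .split_codons(t$cds)
  codons[start_res:(start_res + tmd_len - 1L)] <-
    sample(.HYDROPHOBIC_CODONS, tmd_len, replace = TRUE)
  iv <- c(start_res, start_res + tmd_len - 1L)
  t2 <- transcript(t$gene_id, cds = paste(codons, collapse = ""),
                   utr5 = t$utr5, utr3 = t$utr3,
                   is_secretome = t$is_secretome, groups = t$groups,
                   tmd_intervals = rbind(t$tmd_intervals, iv),
                   sscr_len = t$sscr_len)
  list(transcript = t2, interval = iv)
}

#' Generate a null transcriptome: labels independent of sequence
#'
#' Generates a transcriptome from the spec and then randomly permutes the
#' secretome labels across genes (group labels are cleared, as they would
#' no longer be consistent), so any label-sequence association is broken.
#' Used for calibrating AUC, chi-squared and permutation analyses.
#'
#' @param spec A [simulation_spec()].
#' @return Same structure as [generate_transcriptome()].
#' @export
null_transcriptome <- function(spec) {
  sim <- generate_transcriptome(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(.gene_seed(spec$seed, "label-permutation"))
  labels <- vapply(sim$transcripts, function(t) t$is_secretome, logical(1L))
  perm <- sample(labels)
  sim$transcripts <- lapply(seq_along(sim$transcripts), function(i) {
    t <- sim$transcripts[[i]]
    t$is_secretome <- perm[i]
    t$groups <- character()
    t
  })
  names(sim$transcripts) <- vapply(sim$transcripts, function(t) t$gene_id,
                                   character(1L))
  sim
}

#' Write a synthetic transcriptome in the formats the readers accept
#'
#' Emits `cds.fa`, `utr5.fa`, `utr3.fa`, `annotations.tsv`,
#' `planted_motifs.tsv` and `planted_tmds.tsv` under `dir`. Identical specs
#' (including seed) produce byte-identical files.
#'
#' @param sim Result of [generate_transcriptome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_transcriptome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$transcripts
  get_map <- function(field) {
    v <- vapply(tr, `[[`, character(1L), field)
    v[nzchar(v)]
  }
  write_fasta(vapply(tr, `[[`, character(1L), "cds"),
              file.path(dir, "cds.fa"))
  write_fasta(get_map("utr5"), file.path(dir, "utr5.fa"))
  write_fasta(get_map("utr3"), file.path(dir, "utr3.fa"))
  ann <- data.frame(
    gene_id = vapply(tr, `[[`, character(1L), "gene_id"),
    is_secretome = as.integer(vapply(tr, `[[`, logical(1L), "is_secretome")),
    groups = vapply(tr, function(t) paste(t$groups, collapse = ","),
                    character(1L)),
    tmd_intervals = vapply(tr, function(t) {
      if (nrow(t$tmd_intervals) == 0L) "" else
        paste(sprintf("%d-%d", t$tmd_intervals[, 1L], t$tmd_intervals[, 2L]),
              collapse = ";")
    }, character(1L)),
    sscr_len = vapply(tr, `[[`, integer(1L), "sscr_len"))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$planted_motifs, file.path(dir, "planted_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$planted_tmds, file.path(dir, "planted_tmds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a transcriptome directory written by [write_transcriptome()]
#'
#' @param dir Directory containing `cds.fa`, optional UTR FASTAs and
#'   `annotations.tsv`.
#' @return List as returned by [assemble_transcripts()].
#' @export
read_transcriptome <- function(dir) {
  read_opt <- function(f) if (file.exists(f)) read_fasta(f) else NULL
  ann_path <- file.path(dir, "annotations.tsv")
  assemble_transcripts(
    cds_map = read_fasta(file.path(dir, "cds.fa")),
    utr5_map = read_opt(file.path(dir, "utr5.fa")),
    utr3_map = read_opt(file.path(dir, "utr3.fa")),
    annotations = if (file.exists(ann_path)) read_annotations(ann_path) else NULL)
}
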