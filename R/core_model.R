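#' @importFrom data.table data.table as.data.table setDT setkey := .N .SD copy fread fwrite rbindlist setnames setorder setattr
#' @importFrom stats pf ptukey phyper p.adjust t.test aov TukeyHSD rnorm rpois rnbinom rlnorm runif sd setNames approx pt qt median quantile rbinom
#' @importFrom utils head tail
NULL

# internal canonical codon tables ------------------------------------------

BASES <- c("A", "C", "G", "T")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- sort(setdiff(ALL_CODONS, STOP_CODONS))

# ribosome site labels spanning -3..+3 codons around the P-site (P = 0, A = +1)
SITE_LABELS <- c("-2", "-1", "E", "P", "A", "3", "4")
SITE_OFFSETS <- setNames(-3:3, SITE_LABELS)

#' Standard genetic-code codon groups
#'
#' Convenience accessors for the 61 sense codons and the codon families of
#' the branched-chain amino acids, used throughout the stalling analyses.
#'
#' @param amino_acid One of `"Val"`, `"Ile"`, `"Leu"`.
#' @return Character vector of codons (DNA alphabet).
#' @export
codon_family <- function(amino_acid = c("Val", "Ile", "Leu")) {
  amino_acid <- match.arg(amino_acid)
  switch(amino_acid,
    Val = c("GTT", "GTC", "GTA", "GTG"),
    Ile = c("ATT", "ATC", "ATA"),
    Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"))
}

#' @rdname codon_family
#' @export
sense_codons <- function() SENSE_CODONS

# TranscriptModel ------------------------------------------------------------

new_transcript_model <- function(transcript_id, gene_id, cds_nt) {
  codons <- substring(cds_nt, seq(1, nchar(cds_nt), 3), seq(3, nchar(cds_nt), 3))
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    cds_nt = cds_nt,
    codons = codons,
    n_codons = length(codons)
  ), class = "transcript_model")
}

#' Build a transcriptome container from CDS sequences
#'
#' A transcriptome is a named list of transcript models, one canonical CDS
#' per transcript. Sequences are canonicalised to uppercase DNA (U mapped to
#' T); records whose length is not a positive multiple of 3 or that contain
#' characters outside A/C/G/T(/U) are dropped with a warning.
#'
#' @param seqs Named character vector of CDS nucleotide sequences.
#' @param gene_ids Optional character vector of gene identifiers parallel to
#'   `seqs`; defaults to the sequence names (one canonical transcript per gene).
#' @return An object of class `transcriptome`: named list of transcript
#'   models with fields `transcript_id`, `gene_id`, `cds_nt`, `codons`,
#'   `n_codons`.
#' @export
transcriptome <- function(seqs, gene_ids = NULL) {
  if (length(seqs) == 0L) stop("no CDS records supplied")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all CDS records must be named")
  if (anyDuplicated(ids)) stop("duplicate transcript identifiers in CDS input")
  if (is.null(gene_ids)) gene_ids <- ids
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  keep <- rep(TRUE, length(seqs))
  bad_len <- nchar(seqs) == 0L | nchar(seqs) %% 3L != 0L
  bad_chr <- grepl("[^ACGT]", seqs)
  if (any(bad_len))
    warning(sprintf("skipping %d CDS record(s) with length not a multiple of 3: %s",
                    sum(bad_len), paste(head(ids[bad_len], 5), collapse = ", ")))
  if (any(bad_chr & !bad_len))
    warning(sprintf("skipping %d CDS record(s) with non-ACGTU characters: %s",
                    sum(bad_chr & !bad_len), paste(head(ids[bad_chr & !bad_len], 5), collapse = ", ")))
  keep <- !(bad_len | bad_chr)
  if (!any(keep)) stop("no valid CDS records after filtering")
  out <- mapply(new_transcript_model, ids[keep], gene_ids[keep], seqs[keep],
                SIMPLIFY = FALSE)
  names(out) <- ids[keep]
  class(out) <- "transcriptome"
  out
}

#' @export
print.transcriptome <- function(x, ...) {
  nc <- vapply(x, `[[`, integer(1), "n_codons")
  cat(sprintf("transcriptome: %d transcripts, %d-%d codons (median %d)\n",
              length(x), min(nc), max(nc), as.integer(stats::median(nc))))
  invisible(x)
}

#' Number of codons per transcript
#' @param tx A `transcriptome`.
#' @return Named integer vector.
#' @export
n_codons <- function(tx) vapply(tx, `[[`, integer(1), "n_codons")

#' Read coding sequences from a FASTA file
#'
#' Reads CDS records with [Biostrings::readBStringSet()], keeps the first
#' whitespace-delimited token of each header as the transcript identifier
#' (a `gene=` tag in the header, if present, supplies the gene identifier),
#' and applies the validation and U-to-T canonicalisation of
#' [transcriptome()].
#'
#' @param path Path to a FASTA file.
#' @return A `transcriptome`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  gene_ids <- ifelse(grepl("gene=", headers),
                     sub(".*gene=([^ \t]+).*", "\\1", headers), ids)
  seqs <- setNames(as.character(ss), ids)
  transcriptome(seqs, gene_ids)
}

#' Write a transcriptome to FASTA
#' @param tx A `transcriptome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(tx, path) {
  seqs <- vapply(tx, `[[`, character(1), "cds_nt")
  genes <- vapply(tx, `[[`, character(1), "gene_id")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- ifelse(genes == names(seqs), names(seqs),
                      paste0(names(seqs), " gene=", genes))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# SampleMeta / PositionalCounts ---------------------------------------------

#' Construct sample metadata
#'
#' @param sample_id Unique sample identifiers.
#' @param condition Condition label per sample (e.g. Ctrl, Leu, Ile, Val,
#'   Double, Triple).
#' @param replicate Replicate index per sample.
#' @param library_size Optional total assigned footprint count per sample;
#'   computed from the counts table when absent.
#' @return A `data.table` with one row per sample.
#' @export
sample_meta <- function(sample_id, condition, replicate, library_size = NA_real_) {
  sm <- data.table(sample_id = as.character(sample_id),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   library_size = as.numeric(library_size))
  if (anyDuplicated(sm$sample_id)) stop("duplicate sample_id in sample metadata")
  if (anyDuplicated(sm[, c("condition", "replicate")]))
    stop("(condition, replicate) pairs must be unique")
  if (any(!is.na(sm$library_size) & sm$library_size < 0))
    stop("library_size must be non-negative")
  sm
}

new_positional_counts <- function(counts, samples) {
  counts <- as.data.table(counts)
  setkey(counts, transcript_id, codon_position, sample_id)
  structure(list(counts = counts, samples = samples),
            class = "positional_counts")
}

#' @export
print.positional_counts <- function(x, ...) {
  cat(sprintf("positional_counts: %d rows, %d transcripts, %d samples%s\n",
              nrow(x$counts), length(unique(x$counts$transcript_id)),
              nrow(x$samples),
              if ("norm_rpm" %in% names(x$counts)) " (RPM/Norm_RPM layers present)" else ""))
  invisible(x)
}

#' Assemble positional footprint counts
#'
#' Core container for P-site-assigned codon-resolution footprint counts in
#' long format. Duplicate (transcript, position, sample) rows are summed
#' with a warning; missing library sizes are filled with per-sample count
#' totals.
#'
#' @param counts A data frame with columns `transcript_id`,
#'   `codon_position` (0-based), `sample_id`, `count`.
#' @param samples Sample metadata from [sample_meta()]; built from the
#'   counts table when `NULL`.
#' @param tx Optional `transcriptome` used to validate positions.
#' @return A `positional_counts` object.
#' @export
positional_counts <- function(counts, samples = NULL, tx = NULL) {
  counts <- as.data.table(counts)
  required <- c("transcript_id", "codon_position", "sample_id", "count")
  if (!all(required %in% names(counts)))
    stop("counts must have columns: ", paste(required, collapse = ", "))
  counts <- counts[, required, with = FALSE]
  counts[, transcript_id := as.character(transcript_id)]
  counts[, sample_id := as.character(sample_id)]
  counts[, codon_position := as.integer(codon_position)]
  counts[, count := as.numeric(count)]
  bad <- which(counts$count < 0 | counts$codon_position < 0 | !is.finite(counts$count))
  if (length(bad))
    stop(sprintf("invalid count/position at row %d (transcript %s, position %d, count %g)",
                 bad[1], counts$transcript_id[bad[1]],
                 counts$codon_position[bad[1]], counts$count[bad[1]]))
  if (!is.null(tx)) {
    nc <- n_codons(tx)
    unknown <- setdiff(unique(counts$transcript_id), names(nc))
    if (length(unknown))
      stop("counts reference transcripts absent from the transcriptome: ",
           paste(head(unknown, 5), collapse = ", "))
    over <- counts[codon_position >= nc[transcript_id]]
    if (nrow(over))
      stop(sprintf("position %d out of range for transcript %s (n_codons %d)",
                   over$codon_position[1], over$transcript_id[1],
                   nc[over$transcript_id[1]]))
  }
  ndup <- nrow(counts) - nrow(unique(counts[, c("transcript_id", "codon_position", "sample_id")]))
  if (ndup > 0) {
    warning(sprintf("summing %d duplicate (transcript, position, sample) count row(s)", ndup))
    counts <- counts[, .(count = sum(count)),
                     by = c("transcript_id", "codon_position", "sample_id")]
  }
  totals <- counts[, .(total = sum(count)), by = "sample_id"]
  if (is.null(samples)) {
    samples <- sample_meta(totals$sample_id, condition = totals$sample_id,
                           replicate = 1L, library_size = totals$total)
    samples$replicate <- seq_len(nrow(samples))
  } else {
    samples <- copy(as.data.table(samples))
    missing_s <- setdiff(unique(counts$sample_id), samples$sample_id)
    if (length(missing_s))
      stop("counts contain samples absent from metadata: ",
           paste(missing_s, collapse = ", "))
    samples[totals, library_size := ifelse(is.na(library_size), i.total, library_size),
            on = "sample_id"]
    samples[is.na(library_size), library_size := 0]
  }
  new_positional_counts(counts, samples)
}

#' Read a long-format positional count table
#'
#' @param path TSV with header `transcript_id`, `codon_position`,
#'   `sample_id`, `count` (positions 0-based).
#' @inheritParams positional_counts
#' @return A `positional_counts` object.
#' @export
read_position_counts <- function(path, samples = NULL, tx = NULL) {
  if (!file.exists(path)) stop("cannot read count table: ", path)
  counts <- fread(path, sep = "\t")
  positional_counts(counts, samples = samples, tx = tx)
}

#' Write a positional count table (round-trip safe)
#' @param pc A `positional_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_position_counts <- function(pc, path) {
  fwrite(pc$counts[, c("transcript_id", "codon_position", "sample_id", "count")],
         path, sep = "\t")
  invisible(path)
}

# BED output ------------------------------------------------------------------

#' Write called stall sites as BED6 in transcript coordinates
#'
#' Each codon becomes a 3-nt half-open interval on its transcript:
#' `start = 3 * codon_position`, `end = start + 3`. The BED name is the
#' condition and the score is `min(1000, round(-10 * log10(p)))` (capped at
#' 1000 when p = 0).
#'
#' @param sites A data frame of stall sites with columns `transcript_id`,
#'   `codon_position`, `condition`, `p`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stall_sites_bed <- function(sites, path) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- ifelse(sites$p <= 0, 1000, pmin(1000, round(-10 * log10(sites$p))))
  bed <- data.table(chrom = sites$transcript_id,
                    start = 3L * as.integer(sites$codon_position),
                    end = 3L * as.integer(sites$codon_position) + 3L,
                    name = sites$condition,
                    score = as.integer(score),
                    strand = "+")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# AnalysisConfig --------------------------------------------------------------

#' Analysis configuration with field-standard defaults
#'
#' Thresholds default to the values used throughout the stalling analyses:
#' transcripts need a cross-sample mean total count of at least 50 and at
#' least 30% positional coverage; metagene profiles trim 15 nt from each
#' CDS end; ramp regions span 20% of the CDS; polarised transcripts require
#' delta-polarity below -0.15 at p < 0.05; stall peaks require
#' log2FC(RPM) > 2, log2FC(Norm_RPM) > 2, fold over the gene mean > 1 and
#' p < 0.05; protein calls use adjusted p < 0.01 and |log2FC| > 0.26.
#'
#' @param ... Named overrides of any default listed in `default_config()`.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- default_config()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(all(vapply(cfg[setdiff(names(cfg), "seed")], function(v) all(is.finite(v)), logical(1))))
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @export
default_config <- function() {
  list(
    min_mean_total = 50,
    min_coverage_fraction = 0.30,
    edge_exclusion_nt = 15,
    region_fraction = 0.20,
    delta_polarity_cut = -0.15,
    polarity_alpha = 0.05,
    peak_log2fc_rpm = 2,
    peak_log2fc_norm = 2,
    peak_fc_gene_mean = 1,
    peak_p = 0.05,
    protein_p = 0.01,
    protein_log2fc = 0.26,
    pseudocount_rpm = 0.1,
    window_halfwidth_nt = 50,
    metagene_bins = 100,
    stall_metagene_bins = 50,
    min_reads_per_gene = 10,
    seed = 1L
  )
}

#' Load an analysis configuration from a JSON file
#'
#' Unset keys take the defaults of [default_config()]; unknown keys are a
#' fatal error. The fully resolved configuration is echoed via `message()`.
#'
#' @param path Path to a JSON object of key-value overrides.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  cfg <- do.call(analysis_config, as.list(raw))
  message("resolved config: ",
          paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = ", "))
  cfg
}
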