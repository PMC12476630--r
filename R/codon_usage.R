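# Genome-wide codon count table and positional codon bias along the CDS.

#' Gene-level codon count and fraction table
#'
#' Per-isoform triplet counts (terminal stop codon excluded, start codon
#' retained) are averaged within each gene — counts are averaged, then
#' normalised, which differs from averaging fractions when isoforms have
#' different lengths — and converted to per-gene fractions over the 61
#' sense codons.
#'
#' @param tx A `transcriptome`; the `gene_id` field maps isoforms to genes.
#' @return List with `counts` (gene x codon mean counts), `fractions`
#'   (gene x codon fractions summing to 1 per gene) and
#'   `mean_frequency_pct` (per-codon transcriptome mean frequency, %).
#' @export
build_codon_table <- function(tx) {
  if (!length(tx)) stop("empty transcriptome")
  iso_counts <- t(vapply(tx, function(t) {
    cods <- t$codons
    if (length(cods) && cods[length(cods)] %in% STOP_CODONS)
      cods <- cods[-length(cods)]
    cods <- cods[cods %in% SENSE_CODONS]
    tabulate(match(cods, SENSE_CODONS), length(SENSE_CODONS))
  }, numeric(length(SENSE_CODONS))))
  colnames(iso_counts) <- SENSE_CODONS
  genes <- vapply(tx, `[[`, character(1), "gene_id")
  gc <- rowsum(iso_counts, genes) / as.vector(table(genes)[sort(unique(genes))])
  fr <- gc / rowSums(gc)
  list(counts = gc, fractions = fr,
       mean_frequency_pct = colMeans(fr) * 100)
}

#' Positional codon bias along the CDS
#'
#' Bins every codon position by percent rank along its CDS and reports the
#' per-bin frequency of each codon, plus the ratio of each codon's
#' frequency in the first `region_fraction` of the CDS to its frequency in
#' the remainder, with a bootstrap confidence interval over genes.
#'
#' @param tx A `transcriptome`.
#' @param n_bins Number of relative-position bins (default 20).
#' @param region_fraction Early-region fraction for the ratio (default 0.20).
#' @param n_boot Bootstrap resamples over genes (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return List with `by_bin` (data.table: codon, bin, frequency; per-bin
#'   frequencies sum to 1) and `early_ratio` (data.table: codon, freq_early,
#'   freq_rest, ratio, ci_lo, ci_hi).
#' @export
positional_codon_bias <- function(tx, n_bins = 20L, region_fraction = 0.20,
                                  n_boot = 200L, conf = 0.95, seed = 1L) {
  if (!length(tx)) stop("empty transcriptome")
  ids <- names(tx)
  per_gene <- lapply(tx, function(t) {
    cods <- t$codons
    if (length(cods) && cods[length(cods)] %in% STOP_CODONS)
      cods <- cods[-length(cods)]
    L <- length(cods)
    sense <- cods %in% SENSE_CODONS
    pos <- which(sense)
    ci <- match(cods[sense], SENSE_CODONS)
    bin <- pmin(n_bins, ceiling(pos / L * n_bins))
    early <- pos <= max(1L, floor(region_fraction * L))
    list(ci = ci, bin = bin, early = early, L = L)
  })
  nco <- length(SENSE_CODONS)
  bin_counts <- matrix(0, nrow = nco, ncol = n_bins,
                       dimnames = list(SENSE_CODONS, seq_len(n_bins)))
  early_mat <- matrix(0, nrow = length(ids), ncol = nco)  # per-gene early counts
  rest_mat <- matrix(0, nrow = length(ids), ncol = nco)
  early_tot <- numeric(length(ids)); rest_tot <- numeric(length(ids))
  for (g in seq_along(per_gene)) {
    pg <- per_gene[[g]]
    for (j in seq_along(pg$ci))
      bin_counts[pg$ci[j], pg$bin[j]] <- bin_counts[pg$ci[j], pg$bin[j]] + 1
    te <- tabulate(pg$ci[pg$early], nco)
    tr <- tabulate(pg$ci[!pg$early], nco)
    early_mat[g, ] <- te; rest_mat[g, ] <- tr
    early_tot[g] <- sum(te); rest_tot[g] <- sum(tr)
  }
  freq_bin <- sweep(bin_counts, 2, pmax(1, colSums(bin_counts)), "/")
  by_bin <- data.table(codon = rep(SENSE_CODONS, n_bins),
                       bin = rep(seq_len(n_bins), each = nco),
                       frequency = as.vector(freq_bin))
  ratio_from <- function(idx) {
    fe <- colSums(early_mat[idx, , drop = FALSE]) / max(1, sum(early_tot[idx]))
    fr <- colSums(rest_mat[idx, , drop = FALSE]) / max(1, sum(rest_tot[idx]))
    ifelse(fr > 0, fe / fr, NA_real_)
  }
  obs_fe <- colSums(early_mat) / max(1, sum(early_tot))
  obs_fr <- colSums(rest_mat) / max(1, sum(rest_tot))
  obs <- ifelse(obs_fr > 0, obs_fe / obs_fr, NA_real_)
  set.seed(seed)
  boots <- replicate(n_boot, ratio_from(sample.int(length(ids), replace = TRUE)))
  qs <- apply(boots, 1, quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  early_ratio <- data.table(codon = SENSE_CODONS, freq_early = obs_fe,
                            freq_rest = obs_fr, ratio = obs,
                            ci_lo = qs[1, ], ci_hi = qs[2, ])
  list(by_bin = by_bin, early_ratio = early_ratio)
}
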