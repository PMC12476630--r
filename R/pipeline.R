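# One-config end-to-end pipeline over synthetic data: simulate -> filter ->
# dwell times -> positional metrics -> stall calling -> context ->
# stall-proteome enrichment. Every stage writes a TSV under the output
# directory; outputs are deterministic for a fixed seed.

#' Run the full synthetic-data analysis pipeline
#'
#' @param outdir Output directory (created if needed).
#' @param sim Named overrides for [sim_config()].
#' @param analysis Named overrides for [analysis_config()].
#' @param seed Overall seed; overrides `sim$seed` when given.
#' @param dwell_max_iter Cap on dwell-fit cycles (default 100).
#' @return Named character vector of written files, invisibly.
#' @export
run_pipeline <- function(outdir, sim = list(), analysis = list(), seed = NULL,
                         dwell_max_iter = 100L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, sim)
  if (!is.null(seed)) scfg$seed <- as.integer(seed)
  acfg <- do.call(analysis_config, analysis)
  files <- c()
  put <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  mt <- make_transcriptome(scfg)
  tx <- mt$tx
  put("transcriptome.fa", function(p) write_cds_fasta(tx, p))

  sim_out <- simulate_footprints(tx, scfg)
  pc <- sim_out$counts
  put("counts.tsv", function(p) write_position_counts(pc, p))
  if (!is.null(sim_out$truth$stalls))
    put("truth_stalls.tsv", function(p) fwrite(sim_out$truth$stalls, p, sep = "\t"))

  retained <- filter_transcripts(pc, tx, acfg$min_mean_total, acfg$min_coverage_fraction)
  put("retained_transcripts.tsv", function(p)
    fwrite(data.table(transcript_id = retained), p, sep = "\t"))
  pcn <- normalize_counts(subset_transcripts(pc, retained))

  dt <- estimate_dwell_times(pcn, tx, min_reads_per_gene = acfg$min_reads_per_gene,
                             max_iter = dwell_max_iter)
  put("dwell_times.tsv", function(p) fwrite(dwell_time_long(dt), p, sep = "\t"))
  wd <- summarize_window_dt(dt)
  put("dwell_window_mean.tsv", function(p) fwrite(wd, p, sep = "\t"))
  if (length(unique(pc$samples$condition)) >= 2L) {
    stats <- dt_anova_tukey(wd, pc$samples, control = scfg$conditions[1])
    put("dwell_stats.tsv", function(p) fwrite(stats, p, sep = "\t"))
  }

  mg <- metagene_profile(pcn, tx, exclude_nt = acfg$edge_exclusion_nt,
                         n_bins = acfg$metagene_bins)
  put("metagene.tsv", function(p) fwrite(mg, p, sep = "\t"))
  ri <- ramp_index(pcn, tx, region_fraction = acfg$region_fraction,
                   control = scfg$conditions[1])
  put("ramp_index.tsv", function(p) fwrite(ri$transcripts, p, sep = "\t"))
  put("ramp_summary.tsv", function(p) fwrite(ri$summary, p, sep = "\t"))
  pol <- polarity_score(pcn, tx)
  put("polarity.tsv", function(p) fwrite(pol, p, sep = "\t"))
  dpol <- delta_polarity_test(pol, pc$samples, control = scfg$conditions[1],
                              cut = acfg$delta_polarity_cut,
                              alpha = acfg$polarity_alpha)
  put("delta_polarity.tsv", function(p) fwrite(dpol, p, sep = "\t"))

  conds <- setdiff(scfg$conditions, scfg$conditions[1])
  all_sites <- list()
  for (cd in conds) {
    calls <- call_stall_sites(pcn, cd, control = scfg$conditions[1], cfg = acfg)
    sites <- calls[passes == TRUE]
    all_sites[[cd]] <- sites
    put(sprintf("stall_calls_%s.tsv", cd), function(p) fwrite(calls, p, sep = "\t"))
    put(sprintf("stall_sites_%s.bed", cd), function(p) write_stall_sites_bed(sites, p))
    ctx <- stall_codon_context(sites, tx, codon_family("Val"),
                               halfwidth_nt = acfg$window_halfwidth_nt)
    put(sprintf("stall_context_%s.tsv", cd), function(p)
      fwrite(ctx$profile, p, sep = "\t"))
    smg <- stall_site_metagene(sites, tx, n_bins = acfg$stall_metagene_bins)
    put(sprintf("stall_metagene_%s.tsv", cd), function(p) fwrite(smg, p, sep = "\t"))
  }

  # stall-proteome enrichment against a matched synthetic proteome: proteins
  # of multi-stall transcripts get short half-lives under full block
  if (length(all_sites)) {
    sites1 <- all_sites[[1]]
    site_counts <- table(sites1$transcript_id)
    universe <- retained
    prot_seed <- scfg$seed + 1000L
    prot <- simulate_proteome(length(universe), s = ifelse(universe %in% names(site_counts), 0, 1),
                              seed = prot_seed)
    prot$proteins[, transcript_id := universe]
    cls <- classify_proteins(prot$proteins, acfg$protein_p, acfg$protein_log2fc)
    down <- cls[class == "down", transcript_id]
    enr <- stall_proteome_enrichment(setNames(as.integer(site_counts), names(site_counts)),
                                     down, universe)
    put("stall_proteome_enrichment.tsv", function(p) fwrite(enr, p, sep = "\t"))
  }
  invisible(unlist(files))
}
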