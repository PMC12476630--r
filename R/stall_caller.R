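# Stall-site peak calling versus control, plus codon-context, overlap,
# positional-distribution, first-site-distance, and stall-proteome
# enrichment analyses. "Position" is a 0-based codon position throughout.

#' Call per-position ribosome stalling sites versus control
#'
#' For every transcript position, the replicate-mean RPM and Norm_RPM of
#' the condition are compared against the control (log2 fold changes with
#' pseudocounts: a fixed RPM pseudocount from the config and, on the
#' Norm_RPM scale, half the smallest nonzero Norm_RPM of the transcript);
#' the position is also tested for exceeding the transcript's mean
#' positional RPM in the condition (`fc_gene_mean`), and a Welch t-test is
#' run on log(Norm_RPM + pseudocount) across replicates. A site passes when
#' log2FC(RPM) > 2, log2FC(Norm_RPM) > 2, fc_gene_mean > 1 and p < 0.05
#' (config thresholds).
#'
#' @param pc A normalised `positional_counts` restricted to retained
#'   transcripts (see [filter_transcripts()]).
#' @param condition,control Condition labels.
#' @param cfg An [analysis_config()].
#' @return data.table of all tested positions: transcript_id,
#'   codon_position, condition, log2fc_rpm, log2fc_norm, fc_gene_mean, p,
#'   passes. Use `x[passes == TRUE]` for the called sites.
#' @export
call_stall_sites <- function(pc, condition, control = "Ctrl",
                             cfg = analysis_config()) {
  cts <- pc$counts
  if (!"norm_rpm" %in% names(cts)) stop("run normalize_counts() first")
  cond_of <- setNames(pc$samples$condition, pc$samples$sample_id)
  sids_c <- pc$samples$sample_id[pc$samples$condition == condition]
  sids_k <- pc$samples$sample_id[pc$samples$condition == control]
  if (length(sids_c) < 2L || length(sids_k) < 2L)
    stop("at least 2 replicates per group are required")
  sub <- cts[sample_id %in% c(sids_c, sids_k)]
  sub[, grp := ifelse(sample_id %in% sids_c, "cond", "ctrl")]
  nzmin <- sub[norm_rpm > 0, .(ps_norm = min(norm_rpm) / 2), by = "transcript_id"]
  # dense per-position stats including absent (zero) replicates
  nC <- length(sids_c); nK <- length(sids_k)
  st <- sub[, .(
    sum_rpm = sum(rpm), sum_norm = sum(norm_rpm),
    sum_lr = 0, n_obs = .N,
    sumsq_norm = sum(norm_rpm^2)
  ), by = c("transcript_id", "codon_position", "grp")]
  wide <- data.table::dcast(st, transcript_id + codon_position ~ grp,
                            value.var = c("sum_rpm", "sum_norm", "sumsq_norm", "n_obs"),
                            fill = 0)
  for (col in c("sum_rpm_cond", "sum_rpm_ctrl", "sum_norm_cond", "sum_norm_ctrl",
                "sumsq_norm_cond", "sumsq_norm_ctrl", "n_obs_cond", "n_obs_ctrl"))
    if (!col %in% names(wide)) wide[, (col) := 0]
  wide <- wide[nzmin, on = "transcript_id", nomatch = NULL]
  wide[, mean_rpm_cond := sum_rpm_cond / nC]
  wide[, mean_rpm_ctrl := sum_rpm_ctrl / nK]
  wide[, mean_norm_cond := sum_norm_cond / nC]
  wide[, mean_norm_ctrl := sum_norm_ctrl / nK]
  ps_rpm <- cfg$pseudocount_rpm
  wide[, log2fc_rpm := log2((mean_rpm_cond + ps_rpm) / (mean_rpm_ctrl + ps_rpm))]
  wide[, log2fc_norm := log2((mean_norm_cond + ps_norm) / (mean_norm_ctrl + ps_norm))]
  gene_mean <- wide[, .(gm = mean(mean_rpm_cond)), by = "transcript_id"]
  wide <- wide[gene_mean, on = "transcript_id"]
  wide[, fc_gene_mean := ifelse(gm > 0, mean_rpm_cond / gm, 0)]
  # Welch t on log(norm_rpm + pseudocount); zeros enter as log(pseudocount).
  # Moments of the log values are derived per group from sparse sums of
  # log-transformed replicate values, so rebuild them exactly:
  subp <- sub[nzmin, on = "transcript_id", nomatch = NULL]
  subp[, lval := log(norm_rpm + ps_norm)]
  lg <- subp[, .(sl = sum(lval), slsq = sum(lval^2), n = .N),
             by = c("transcript_id", "codon_position", "grp")]
  lw <- data.table::dcast(lg, transcript_id + codon_position ~ grp,
                          value.var = c("sl", "slsq", "n"), fill = 0)
  for (col in c("sl_cond", "sl_ctrl", "slsq_cond", "slsq_ctrl", "n_cond", "n_ctrl"))
    if (!col %in% names(lw)) lw[, (col) := 0]
  wide <- wide[lw, on = c("transcript_id", "codon_position")]
  lp <- log(wide$ps_norm)  # value of an absent (zero) replicate
  m1 <- (wide$sl_cond + (nC - wide$n_cond) * lp) / nC
  q1 <- (wide$slsq_cond + (nC - wide$n_cond) * lp^2) / nC
  s1 <- sqrt(pmax(0, (q1 - m1^2) * nC / (nC - 1)))
  m2 <- (wide$sl_ctrl + (nK - wide$n_ctrl) * lp) / nK
  q2 <- (wide$slsq_ctrl + (nK - wide$n_ctrl) * lp^2) / nK
  s2 <- sqrt(pmax(0, (q2 - m2^2) * nK / (nK - 1)))
  wide[, p := welch_p(m1, s1, rep(nC, .N), m2, s2, rep(nK, .N))]
  wide[, condition := condition]
  wide[, passes := log2fc_rpm > cfg$peak_log2fc_rpm &
         log2fc_norm > cfg$peak_log2fc_norm &
         fc_gene_mean > cfg$peak_fc_gene_mean &
         p < cfg$peak_p]
  out <- wide[, .(transcript_id, codon_position, condition,
                  log2fc_rpm, log2fc_norm, fc_gene_mean, p, passes)]
  setorder(out, transcript_id, codon_position)
  out[]
}

#' Codon context around called stall sites
#'
#' Extracts the codon window around each stall site (offset 0 = the called
#' position, A-site convention; windows truncated at CDS edges, no padding)
#' and counts occurrences of each queried codon per offset, plus the
#' proportion of windows containing at least one queried codon.
#'
#' @param sites data.table of called sites (transcript_id, codon_position).
#' @param tx The matching `transcriptome`.
#' @param codons Codons of interest (e.g. `codon_family("Val")`).
#' @param halfwidth_nt Window half-width in nucleotides (default 50).
#' @return List with `profile` (data.table: offset, codon, count),
#'   `proportion_containing` and `n_windows`.
#' @export
stall_codon_context <- function(sites, tx, codons, halfwidth_nt = 50) {
  sites <- as.data.table(sites)
  w <- floor(halfwidth_nt / 3)
  if (nrow(sites) == 0L)
    return(list(profile = data.table(offset = integer(0), codon = character(0),
                                     count = integer(0)),
                proportion_containing = NA_real_, n_windows = 0L))
  nc <- n_codons(tx)
  counts <- matrix(0L, nrow = 2 * w + 1, ncol = length(codons),
                   dimnames = list(as.character(-w:w), codons))
  contains <- logical(nrow(sites))
  for (r in seq_len(nrow(sites))) {
    id <- sites$transcript_id[r]
    j <- sites$codon_position[r] + 1L  # 1-based
    cods <- tx[[id]]$codons
    off <- max(1L, j - w):min(nc[id], j + w) - j
    hit <- cods[j + off]
    for (cd in codons) {
      sel <- which(hit == cd)
      if (length(sel)) counts[as.character(off[sel]), cd] <-
          counts[as.character(off[sel]), cd] + 1L
    }
    contains[r] <- any(hit %in% codons)
  }
  prof <- data.table(offset = rep(-w:w, length(codons)),
                     codon = rep(codons, each = 2 * w + 1),
                     count = as.vector(counts))
  list(profile = prof, proportion_containing = mean(contains),
       n_windows = nrow(sites))
}

#' Overlap of two stall-site sets with a hypergeometric test
#'
#' Upper-tail hypergeometric p-value for observing at least `|A intersect
#' B|` shared elements when `|A|` and `|B|` are drawn from a universe of
#' `universe_size` tested positions (or transcripts).
#'
#' @param a,b Character vectors of keys (e.g. "transcript:position" or
#'   transcript ids).
#' @param universe_size Total number of tested elements.
#' @return List: overlap, n_a, n_b, universe, p.
#' @export
stall_overlap <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (length(a) > universe_size || length(b) > universe_size)
    stop("set size exceeds the universe")
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = k, n_a = length(a), n_b = length(b),
       universe = universe_size, p = p)
}

#' Distribution of stall sites over relative CDS position
#'
#' @param sites data.table of called sites (transcript_id, codon_position,
#'   optionally condition).
#' @param tx The matching `transcriptome`.
#' @param n_bins Number of relative-position bins (default 50).
#' @return data.table: condition, bin, count, density (densities sum to 1
#'   per condition).
#' @export
stall_site_metagene <- function(sites, tx, n_bins = 50L) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L)
    return(data.table(condition = character(0), bin = integer(0),
                      count = integer(0), density = numeric(0)))
  if (!"condition" %in% names(sites)) sites[, condition := "all"]
  nc <- n_codons(tx)
  sites[, rel := (codon_position + 0.5) / nc[transcript_id]]
  sites[, bin := pmin(n_bins, ceiling(rel * n_bins))]
  out <- sites[, .(count = .N), by = c("condition", "bin")]
  out[, density := count / sum(count), by = "condition"]
  setorder(out, condition, bin)
  out[]
}

#' Signed distance between first stall sites of two conditions
#'
#' For transcripts with at least one site in each condition, the distance
#' (codons) between the most 5' site of `sites_a` and the most 5' site of
#' `sites_b`: `first(a) - first(b)`, so positive values mean the first site
#' of `sites_b` lies upstream.
#'
#' @param sites_a,sites_b data.tables of called sites.
#' @return data.table: transcript_id, first_a, first_b, distance.
#' @export
first_site_distance <- function(sites_a, sites_b) {
  fa <- as.data.table(sites_a)[, .(first_a = min(codon_position)), by = "transcript_id"]
  fb <- as.data.table(sites_b)[, .(first_b = min(codon_position)), by = "transcript_id"]
  out <- fa[fb, on = "transcript_id", nomatch = NULL]
  out[, distance := first_a - first_b]
  out[]
}

#' Enrichment of downregulated proteins among stall-harbouring transcripts
#'
#' For each stratum k = 0..K, counts the downregulated proteins whose
#' transcript carries at least k stall sites and reports an upper-tail
#' hypergeometric p for the overlap between the downregulated set and the
#' >=k-site transcripts within the tested universe. The k = 0 stratum is
#' the full downregulated set by construction (p = 1).
#'
#' @param site_counts Named integer vector: stall sites per transcript
#'   (transcripts absent are treated as 0).
#' @param down_set Character vector of transcripts whose protein is
#'   downregulated.
#' @param universe Character vector of all quantified-and-tested
#'   transcripts.
#' @param k_max Largest stratum (default 5).
#' @return data.table: k, n_with_k_sites, overlap, p, neg_log10_p,
#'   reference_line (the -log10 0.05 threshold).
#' @export
stall_proteome_enrichment <- function(site_counts, down_set, universe, k_max = 5L) {
  if (!length(universe)) stop("empty universe")
  down_set <- intersect(unique(down_set), universe)
  full <- setNames(rep(0L, length(universe)), universe)
  common <- intersect(names(site_counts), universe)
  full[common] <- as.integer(site_counts[common])
  N <- length(universe)
  rbindlist(lapply(0:k_max, function(k) {
    with_k <- names(full)[full >= k]
    ov <- length(intersect(with_k, down_set))
    p <- if (k == 0) 1 else phyper(ov - 1, length(with_k), N - length(with_k),
                                   length(down_set), lower.tail = FALSE)
    data.table(k = k, n_with_k_sites = length(with_k), overlap = ov,
               p = p, neg_log10_p = -log10(p),
               reference_line = -log10(0.05))
  }))
}
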