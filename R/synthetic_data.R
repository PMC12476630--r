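# Synthetic footprint data with planted ground truth.
#
# The generator mirrors the multiplicative 7-site dwell model used by the
# estimator: the expected count at codon i of gene g is
#   mu(g,i,s) = alpha_g * prod_{o=-3..+3} delta_o(codon at i+o) * A(g,i)
# where A(g,i) = beta^(# planted stalls strictly upstream of i) models
# downstream flux attenuation after elongation bottlenecks. Out-of-range
# offsets and stop codons contribute factor 1.

#' Simulation configuration
#'
#' Defaults describe the stated world the analyses are validated against:
#' 500 genes of 200-400 codons, log-normal per-gene expression, multiplicative
#' dwell factors with geometric mean 1 per site (log-sd 0.3 at the decoding
#' center E/P/A, 0.1 at the flanking sites), Poisson counting noise,
#' triplicate libraries of 5e6 assigned footprints, and a starvation
#' condition ("Val") multiplying the A-site dwell of all four valine codons
#' by 4.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 500L,
    length_range = c(200L, 400L),
    codon_weights = NULL,            # default: uniform over 61 sense codons
    positional_enrichment = NULL,    # named codon -> factor over first region_fraction
    region_fraction = 0.2,
    alpha_meanlog = 0,
    alpha_sdlog = 1,
    dwell_log_sd_center = 0.3,       # natural-log sd of log delta at E/P/A
    dwell_log_sd_flank = 0.1,        # ... at offsets -3,-2,+2,+3
    conditions = c("Ctrl", "Val"),
    condition_effects = list(Val = list(codons = c("GTT", "GTC", "GTA", "GTG"),
                                        fold = 4)),
    stall_frac = 0,                  # fraction of eligible positions spiked per condition
    stall_fold = 8,
    stall_region = c(0, 1),          # CDS fraction interval where stalls may be planted
    stall_sites = NULL,              # or explicit data.table(transcript_id, codon_position, condition, fold)
    attenuation_beta = 1,
    noise = "poisson",               # "poisson", "nb", or "none"
    nb_dispersion = 0.05,
    n_replicates = 3L,
    library_size = 5e6,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (cfg$attenuation_beta <= 0 || cfg$attenuation_beta > 1)
    stop("attenuation_beta must lie in (0, 1]")
  structure(cfg, class = "sim_config")
}

#' Draw a random dwell-factor truth table
#'
#' Per-site log dwell factors for the 61 sense codons, drawn i.i.d. normal
#' and centred so the geometric mean over sense codons is exactly 1 at every
#' offset (the identifiability constraint shared with the estimator).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A 7 x 61 numeric matrix of natural-log dwell factors with
#'   rownames the site labels (-2, -1, E, P, A, 3, 4) and colnames the sense
#'   codons.
#' @export
random_dwell_table <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  sds <- ifelse(abs(SITE_OFFSETS) <= 1, cfg$dwell_log_sd_center, cfg$dwell_log_sd_flank)
  m <- matrix(rnorm(7L * length(SENSE_CODONS), sd = rep(sds, length(SENSE_CODONS))),
              nrow = 7L, dimnames = list(SITE_LABELS, SENSE_CODONS))
  m - rowMeans(m)
}

#' Generate a synthetic transcriptome with optional positional codon bias
#'
#' Codons are drawn per position from global weights over the 61 sense
#' codons; inside the first `region_fraction` of each CDS the weights of
#' codons named in `positional_enrichment` are multiplied by their factor
#' and renormalised. Every CDS starts with ATG and ends with a stop codon.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with elements `tx` (a `transcriptome`) and `truth`
#'   (the realised configuration: weights, enrichment, region).
#' @export
make_transcriptome <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  w <- cfg$codon_weights
  if (is.null(w)) w <- setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (is.null(names(w)) || !all(names(w) %in% SENSE_CODONS))
    stop("codon_weights must be named with sense codons")
  base_w <- setNames(rep(0, length(SENSE_CODONS)), SENSE_CODONS)
  base_w[names(w)] <- w
  enr_w <- base_w
  if (!is.null(cfg$positional_enrichment)) {
    pe <- cfg$positional_enrichment
    if (is.null(names(pe)) || !all(names(pe) %in% SENSE_CODONS))
      stop("positional_enrichment must be named with sense codons")
    enr_w[names(pe)] <- enr_w[names(pe)] * pe
  }
  if (!all(is.finite(base_w)) || sum(base_w) <= 0 ||
      !all(is.finite(enr_w)) || sum(enr_w) <= 0)
    stop("codon weight distribution is not normalizable")
  lens <- if (cfg$length_range[1] == cfg$length_range[2]) {
    rep(cfg$length_range[1], cfg$n_genes)
  } else {
    sample(cfg$length_range[1]:cfg$length_range[2], cfg$n_genes, replace = TRUE)
  }
  seqs <- character(cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    L <- lens[g]
    if (L < 3L) stop("transcripts must have at least 3 codons")
    n_enr <- max(0L, floor(cfg$region_fraction * L) - 1L)  # positions 2..floor(rf*L)
    n_body <- L - 2L
    body <- c(
      if (n_enr > 0) sample(SENSE_CODONS, min(n_enr, n_body), replace = TRUE, prob = enr_w),
      if (n_body - n_enr > 0) sample(SENSE_CODONS, n_body - min(n_enr, n_body),
                                     replace = TRUE, prob = base_w)
    )
    stop_codon <- sample(STOP_CODONS, 1L)
    seqs[g] <- paste0(c("ATG", body, stop_codon), collapse = "")
  }
  ids <- sprintf("tx%04d", seq_len(cfg$n_genes))
  names(seqs) <- ids
  list(tx = transcriptome(seqs, gene_ids = sub("^tx", "g", ids)),
       truth = list(codon_weights = base_w, enriched_weights = enr_w,
                    region_fraction = cfg$region_fraction))
}

# flat position table used by both the simulator and the estimator -----------
position_table <- function(tx) {
  nc <- n_codons(tx)
  keep <- nc >= 7L
  if (!all(keep))
    warning(sprintf("skipping %d transcript(s) shorter than 7 codons", sum(!keep)))
  tx <- tx[keep]
  nc <- nc[keep]
  ids <- rep(names(tx), nc)
  pos <- unlist(lapply(nc, seq_len), use.names = FALSE)  # 1-based
  codons <- unlist(lapply(tx, `[[`, "codons"), use.names = FALSE)
  cidx <- match(codons, ALL_CODONS)
  offs <- unname(SITE_OFFSETS)
  start <- c(0L, cumsum(nc))[seq_along(nc)]           # offset of each transcript block
  tx_of <- rep(seq_along(nc), nc)
  M <- matrix(NA_integer_, nrow = length(pos), ncol = 7L)
  for (k in seq_len(7L)) {
    j <- pos + offs[k]
    ok <- j >= 1L & j <= nc[tx_of]
    M[ok, k] <- cidx[start[tx_of[ok]] + j[ok]]
  }
  list(transcript_id = ids, gene_id = rep(vapply(tx, `[[`, character(1), "gene_id"), nc),
       pos = pos, codon = codons, window = M, n = length(pos),
       tx_index = tx_of, n_codons_of = nc[tx_of])
}

# log dwell lookup over a window matrix: ld is length-64 vector indexed by
# ALL_CODONS (stops 0); NA window entries (out of range) contribute 0.
window_log_sum <- function(M, ld_by_offset) {
  s <- numeric(nrow(M))
  for (k in seq_len(ncol(M))) {
    v <- ld_by_offset[[k]][M[, k]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s
}

expand_ld <- function(log_delta) {
  # 7 x 61 matrix -> list of 7 length-64 vectors over ALL_CODONS (stops = 0)
  lapply(seq_len(7L), function(k) {
    v <- setNames(rep(0, length(ALL_CODONS)), ALL_CODONS)
    v[colnames(log_delta)] <- log_delta[k, ]
    unname(v)
  })
}

#' Simulate ribosome footprint counts with planted dwell effects and stalls
#'
#' Expected counts follow the multiplicative 7-site window model (see
#' module header); condition effects multiply the A-site dwell of the named
#' codons; planted stall positions multiply the local expectation by
#' `stall_fold` and attenuate all strictly downstream positions by
#' `attenuation_beta` each. Libraries are scaled to `library_size` before
#' noise is drawn.
#'
#' @param tx A `transcriptome`.
#' @param cfg A [sim_config()].
#' @param log_delta Optional 7 x 61 truth table (default
#'   [random_dwell_table()] under `cfg`).
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with `counts` (a `positional_counts` with sample
#'   metadata) and `truth` (log_delta, per-condition log_delta including
#'   A-site effects, per-gene alpha, planted stall table, beta, and the
#'   noiseless expected counts matrix `mu`).
#' @export
simulate_footprints <- function(tx, cfg = sim_config(), log_delta = NULL,
                                seed = cfg$seed) {
  set.seed(seed)
  if (is.null(log_delta)) log_delta <- random_dwell_table(cfg, seed = seed)
  pt <- position_table(tx)
  genes <- unique(pt$gene_id)
  alpha <- setNames(rlnorm(length(genes), cfg$alpha_meanlog, cfg$alpha_sdlog), genes)
  log_alpha_pos <- log(alpha)[pt$gene_id]

  conditions <- cfg$conditions
  # per-condition log delta (A-site fold on affected codons)
  ld_cond <- setNames(vector("list", length(conditions)), conditions)
  for (cd in conditions) {
    ld <- log_delta
    eff <- cfg$condition_effects[[cd]]
    if (!is.null(eff)) ld["A", eff$codons] <- ld["A", eff$codons] + log(eff$fold)
    ld_cond[[cd]] <- ld
  }

  # planted stall positions
  stalls <- cfg$stall_sites
  if (is.null(stalls) && cfg$stall_frac > 0) {
    non_ctrl <- setdiff(conditions, conditions[1])
    eligible <- which(pt$pos / pt$n_codons_of >= cfg$stall_region[1] &
                      pt$pos / pt$n_codons_of <= cfg$stall_region[2] &
                      pt$pos > 3 & pt$pos < pt$n_codons_of - 3)
    stalls <- rbindlist(lapply(non_ctrl, function(cd) {
      pick <- sample(eligible, max(1L, round(cfg$stall_frac * length(eligible))))
      data.table(transcript_id = pt$transcript_id[pick],
                 codon_position = pt$pos[pick] - 1L,   # report 0-based
                 condition = cd, fold = cfg$stall_fold)
    }))
  }
  if (!is.null(stalls)) {
    stalls <- as.data.table(stalls)
    if (!"fold" %in% names(stalls)) stalls[, fold := cfg$stall_fold]
  }

  pos_key <- paste(pt$transcript_id, pt$pos - 1L)
  sample_rows <- list()
  meta_rows <- list()
  mu_store <- list()
  for (cd in conditions) {
    ldc <- expand_ld(ld_cond[[cd]])
    log_mu <- log_alpha_pos + window_log_sum(pt$window, ldc)
    if (!is.null(stalls) && nrow(stalls[condition == cd])) {
      st <- stalls[condition == cd]
      hit <- match(paste(st$transcript_id, st$codon_position), pos_key)
      if (anyNA(hit)) stop("planted stall position outside its transcript")
      log_mu[hit] <- log_mu[hit] + log(st$fold)
      if (cfg$attenuation_beta < 1) {
        # attenuate strictly downstream of each planted stall
        att <- numeric(pt$n)
        for (r in seq_along(hit)) {
          i <- hit[r]
          block <- which(pt$tx_index == pt$tx_index[i] & pt$pos > pt$pos[i])
          att[block] <- att[block] + log(cfg$attenuation_beta)
        }
        log_mu <- log_mu + att
      }
    }
    mu <- exp(log_mu)
    mu <- mu / sum(mu) * cfg$library_size
    mu_store[[cd]] <- mu
    for (r in seq_len(cfg$n_replicates)) {
      sid <- sprintf("%s_rep%d", cd, r)
      y <- switch(cfg$noise,
        poisson = rpois(pt$n, mu),
        nb = rnbinom(pt$n, mu = mu, size = 1 / cfg$nb_dispersion),
        none = mu,
        stop("unknown noise law: ", cfg$noise))
      keep <- y > 0
      sample_rows[[sid]] <- data.table(transcript_id = pt$transcript_id[keep],
                                       codon_position = pt$pos[keep] - 1L,
                                       sample_id = sid, count = y[keep])
      meta_rows[[sid]] <- data.table(sample_id = sid, condition = cd,
                                     replicate = r, library_size = NA_real_)
    }
  }
  counts <- rbindlist(sample_rows)
  samples <- sample_meta(rbindlist(meta_rows)$sample_id,
                         rbindlist(meta_rows)$condition,
                         rbindlist(meta_rows)$replicate)
  pc <- positional_counts(counts, samples = samples, tx = tx)
  list(counts = pc,
       truth = list(log_delta = log_delta, log_delta_condition = ld_cond,
                    alpha = alpha, stalls = stalls,
                    beta = cfg$attenuation_beta,
                    mu = mu_store,
                    positions = data.table(transcript_id = pt$transcript_id,
                                           codon_position = pt$pos - 1L,
                                           gene_id = pt$gene_id,
                                           codon = pt$codon)))
}

#' Simulate proteome log2 fold changes under first-order turnover
#'
#' Half-lives are drawn log-normally (median ~ 30 h), each protein is
#' assigned a kinetic scenario (elapsed time `t`, synthesis retention `s`),
#' and replicate log2FC values are the closed-form prediction of
#' [predict_log2fc()] plus Gaussian noise.
#'
#' @param n Number of proteins.
#' @param t Hours since starvation onset (default 6).
#' @param s Synthesis-retention fraction in `[0,1]`, scalar or length-`n`.
#' @param half_life Optional length-`n` half-lives in hours; drawn
#'   log-normally when `NULL`.
#' @param noise_sd Gaussian sd of replicate log2FC noise.
#' @param n_replicates Replicates per protein.
#' @param seed Integer seed.
#' @return A list with `proteins` (data.table: protein_id, half_life, s,
#'   true_log2fc, log2fc, p, p_adj) and `replicates` (long table of
#'   replicate-level log2FC).
#' @export
simulate_proteome <- function(n, t = 6, s = 0, half_life = NULL,
                              noise_sd = 0.1, n_replicates = 3L, seed = 1L) {
  set.seed(seed)
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  if (is.null(half_life)) half_life <- rlnorm(n, log(30), 0.8)
  if (any(half_life <= 0)) stop("half-lives must be positive")
  s <- rep_len(s, n)
  true_fc <- predict_log2fc(t = t, t_half = half_life, s = s)
  reps <- data.table(protein_id = rep(sprintf("p%05d", seq_len(n)), each = n_replicates),
                     replicate = rep(seq_len(n_replicates), n),
                     log2fc = rep(true_fc, each = n_replicates) +
                       rnorm(n * n_replicates, sd = noise_sd))
  agg <- reps[, .(log2fc = mean(log2fc),
                  p = if (noise_sd > 0 && .N >= 2) t.test(log2fc)$p.value else as.numeric(all(log2fc == 0))),
              by = "protein_id"]
  agg[, p_adj := p.adjust(p, "BH")]
  proteins <- data.table(protein_id = sprintf("p%05d", seq_len(n)),
                         half_life = half_life, s = s, true_log2fc = true_fc)
  proteins <- proteins[agg, on = "protein_id"]
  list(proteins = proteins, replicates = reps)
}

#' Simulate spike-normalised tRNA charging qPCR Ct values
#'
#' Under the periodate-oxidation charging assay, uncharged tRNAs are lost
#' before RT-qPCR, so the target Ct rises by -log2(charged fraction)
#' relative to a fully charged pool: Ct(target) = ct_ref -
#' log2(charged_fraction) + noise, with a constant E. coli spike-in Ct per
#' sample.
#'
#' @param charged_fraction Named vector, per isoacceptor, of charged
#'   fraction in the starved condition (control condition is fully charged).
#' @param n_replicates Replicates per condition.
#' @param noise_sd Gaussian Ct noise sd.
#' @param ct_ref Target Ct at full charging.
#' @param spike_ct Spike-in Ct.
#' @param seed Integer seed.
#' @return data.table: sample_id, condition, isoacceptor, ct_target,
#'   ct_spike.
#' @export
simulate_charging_cts <- function(charged_fraction, n_replicates = 3L,
                                  noise_sd = 0, ct_ref = 22, spike_ct = 16,
                                  seed = 1L) {
  set.seed(seed)
  if (any(charged_fraction <= 0 | charged_fraction > 1))
    stop("charged fractions must lie in (0, 1]")
  iso <- names(charged_fraction)
  if (is.null(iso)) stop("charged_fraction must be named by isoacceptor")
  grid <- data.table(expand.grid(isoacceptor = iso,
                                 condition = c("Ctrl", "Starved"),
                                 replicate = seq_len(n_replicates),
                                 stringsAsFactors = FALSE))
  frac <- ifelse(grid$condition == "Ctrl", 1, charged_fraction[grid$isoacceptor])
  grid[, sample_id := sprintf("%s_rep%d", condition, replicate)]
  grid[, ct_target := ct_ref - log2(frac) + rnorm(.N, sd = noise_sd)]
  grid[, ct_spike := spike_ct + rnorm(.N, sd = noise_sd)]
  grid[, c("sample_id", "condition", "isoacceptor", "ct_target", "ct_spike")]
}
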