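# Positional ribosome-density metrics: library normalisation, transcript
# filtering, metagene profiles, 5'/3' ramp indices, polarity scores and
# codon-context density enrichment. All metrics operate on Norm_RPM (or raw
# per-transcript density fractions) and are therefore invariant to
# library-size rescaling.

# Welch t-test vectorised over rows; degenerate variance handled explicitly
welch_p <- function(m1, s1, n1, m2, s2, n2) {
  v <- s1^2 / n1 + s2^2 / n2
  d <- m1 - m2
  p <- rep(NA_real_, length(d))
  zero <- v == 0
  p[zero & d == 0] <- 1
  p[zero & d != 0] <- 0
  ok <- !zero & is.finite(v)
  tt <- d[ok] / sqrt(v[ok])
  df <- v[ok]^2 / ((s1[ok]^2 / n1[ok])^2 / (n1[ok] - 1) + (s2[ok]^2 / n2[ok])^2 / (n2[ok] - 1))
  p[ok] <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p
}

#' Add RPM and Norm_RPM layers to positional counts
#'
#' RPM is `count * 1e6 / library_size`; Norm_RPM divides each positional RPM
#' by the transcript's total RPM in that sample (so retained positions of a
#' transcript sum to 1 per sample). Transcripts with zero total density in a
#' sample have no Norm_RPM entries for that sample.
#'
#' @param pc A `positional_counts` object.
#' @return The object with `rpm` and `norm_rpm` columns added.
#' @export
normalize_counts <- function(pc) {
  if (any(pc$samples$library_size <= 0))
    stop("zero library size for sample(s): ",
         paste(pc$samples$sample_id[pc$samples$library_size <= 0], collapse = ", "))
  cts <- copy(pc$counts)
  lib <- setNames(pc$samples$library_size, pc$samples$sample_id)
  cts[, rpm := count * 1e6 / lib[sample_id]]
  cts[, norm_rpm := rpm / sum(rpm), by = c("transcript_id", "sample_id")]
  new_positional_counts(cts, pc$samples)
}

#' Filter transcripts on total counts and positional coverage
#'
#' Retains transcripts whose cross-sample mean total count is at least
#' `min_mean_total` and whose cross-sample mean fraction of positions with
#' nonzero counts is at least `min_coverage`.
#'
#' @param pc A `positional_counts` object.
#' @param tx The matching `transcriptome` (for transcript lengths).
#' @param min_mean_total Mean-total-count threshold (default 50).
#' @param min_coverage Mean coverage-fraction threshold (default 0.30).
#' @return Character vector of retained transcript ids.
#' @export
filter_transcripts <- function(pc, tx, min_mean_total = 50, min_coverage = 0.30) {
  nc <- n_codons(tx)
  ns <- nrow(pc$samples)
  per <- pc$counts[, .(total = sum(count), covered = sum(count > 0)),
                   by = c("transcript_id", "sample_id")]
  agg <- per[, .(mean_total = sum(total) / ns,
                 mean_cov = sum(covered) / ns), by = "transcript_id"]
  agg[, mean_cov := mean_cov / nc[transcript_id]]
  keep <- agg[mean_total >= min_mean_total & mean_cov >= min_coverage, transcript_id]
  if (length(keep) == 0L)
    stop(sprintf(paste0("no transcripts pass filtering (best mean total %.1f, ",
                        "best mean coverage %.2f)"),
                 max(agg$mean_total), max(agg$mean_cov)))
  keep
}

#' Restrict a positional_counts object to a transcript set
#' @param pc A `positional_counts` object.
#' @param transcripts Character vector of transcript ids.
#' @return A `positional_counts` with only those transcripts.
#' @export
subset_transcripts <- function(pc, transcripts) {
  new_positional_counts(pc$counts[transcript_id %in% transcripts], pc$samples)
}

#' Metagene profile of relative ribosome density along the CDS
#'
#' Per transcript and sample, the first and last `exclude_nt` nucleotides
#' (5 codons each for the default 15 nt) are dropped, the remaining density
#' is renormalised and scaled by the number of retained positions (so a
#' uniform transcript sits at 1 everywhere), positions are binned by percent
#' rank, and bin means are averaged across transcripts and replicates per
#' condition.
#'
#' @param pc A normalised `positional_counts` (see [normalize_counts()]).
#' @param tx The matching `transcriptome`.
#' @param exclude_nt Nucleotides trimmed from each CDS end (default 15).
#' @param n_bins Number of percent-rank bins (default 100).
#' @return data.table: condition, bin, mean_density, sem.
#' @export
metagene_profile <- function(pc, tx, exclude_nt = 15, n_bins = 100L) {
  ex <- as.integer(ceiling(exclude_nt / 3))
  nc <- n_codons(tx)
  ids <- intersect(unique(pc$counts$transcript_id), names(nc))
  lens <- nc[ids] - 2L * ex
  short <- lens < 1L
  if (any(short)) {
    warning(sprintf("skipping %d transcript(s) too short for %d-nt edge exclusion",
                    sum(short), exclude_nt))
    ids <- ids[!short]
    lens <- lens[!short]
  }
  if (!length(ids)) stop("no transcripts long enough for the metagene profile")
  cts <- pc$counts[transcript_id %in% ids]
  cts <- cts[, .(transcript_id, codon_position, sample_id, count)]
  cts[, rank := codon_position + 1L - ex]
  cts <- cts[rank >= 1L & rank <= lens[transcript_id]]
  cts[, d := count / sum(count), by = c("transcript_id", "sample_id")]
  Lp <- lens[cts$transcript_id]
  cts[, bin := pmin(n_bins, ceiling(rank / Lp * n_bins))]
  cts[, r := d * lens[transcript_id]]  # relative density, uniform => 1
  sums <- cts[, .(sum_r = sum(r)), by = c("transcript_id", "sample_id", "bin")]
  # slots per (transcript, bin) from arithmetic on ranks
  slot_list <- lapply(ids, function(id) {
    b <- pmin(n_bins, ceiling(seq_len(lens[id]) / lens[id] * n_bins))
    data.table(transcript_id = id, bin = seq_len(n_bins),
               n_slots = tabulate(b, n_bins))
  })
  slots <- rbindlist(slot_list)[n_slots > 0]
  # full grid: transcripts x samples x (bins with slots)
  full <- rbindlist(lapply(pc$samples$sample_id, function(sid) {
    s <- copy(slots)
    s[, sample_id := sid]
    s
  }))
  full[sums, sum_r := i.sum_r, on = c("transcript_id", "sample_id", "bin")]
  full[is.na(sum_r), sum_r := 0]
  full[, bin_mean := sum_r / n_slots]
  cond <- setNames(pc$samples$condition, pc$samples$sample_id)
  full[, condition := cond[sample_id]]
  full[, .(mean_density = mean(bin_mean),
           sem = sd(bin_mean) / sqrt(.N)), by = c("condition", "bin")][order(condition, bin)]
}

#' 5'/3' ramp indices of ribosome density
#'
#' Per transcript and sample, sums of Norm_RPM over the first and last
#' `region_fraction` of codon positions, and the log2 ratio of each sum to
#' the transcript's mean control sum. Condition-level summaries use Welch
#' t-tests versus control with Bonferroni correction across conditions.
#'
#' @param pc A normalised `positional_counts`.
#' @param tx The matching `transcriptome`.
#' @param region_fraction Fraction of CDS per region (default 0.20).
#' @param control Control condition label.
#' @return List with `transcripts` (per transcript x sample sums and log2
#'   ratios) and `summary` (per condition x region mean, sem, p, p_bonf).
#' @export
ramp_index <- function(pc, tx, region_fraction = 0.20, control = "Ctrl") {
  if (!control %in% pc$samples$condition) stop("control condition not present: ", control)
  nc <- n_codons(tx)
  cts <- pc$counts
  if (!"norm_rpm" %in% names(cts)) stop("run normalize_counts() first")
  n5 <- floor(region_fraction * nc)
  cts <- cts[transcript_id %in% names(nc)]
  reg <- cts[, {
    L <- nc[.BY$transcript_id]; k <- n5[.BY$transcript_id]
    .(sum5 = sum(norm_rpm[codon_position < k]),
      sum3 = sum(norm_rpm[codon_position >= L - k]))
  }, by = c("transcript_id", "sample_id")]
  # complete missing (transcript, sample) slots as zero density
  grid <- data.table(expand.grid(transcript_id = unique(reg$transcript_id),
                                 sample_id = pc$samples$sample_id,
                                 stringsAsFactors = FALSE))
  reg <- reg[grid, on = c("transcript_id", "sample_id")]
  reg[is.na(sum5), sum5 := 0]
  reg[is.na(sum3), sum3 := 0]
  cond <- setNames(pc$samples$condition, pc$samples$sample_id)
  reg[, condition := cond[sample_id]]
  ctrl_mean <- reg[condition == control,
                   .(ctrl5 = mean(sum5), ctrl3 = mean(sum3)), by = "transcript_id"]
  reg <- reg[ctrl_mean, on = "transcript_id"]
  reg <- reg[ctrl5 > 0 & ctrl3 > 0]
  reg[, log2_ratio_5 := log2(sum5 / ctrl5)]
  reg[, log2_ratio_3 := log2(sum3 / ctrl3)]
  reg <- reg[is.finite(log2_ratio_5) & is.finite(log2_ratio_3)]
  long <- data.table::melt(reg, id.vars = c("transcript_id", "condition"),
                           measure.vars = c("log2_ratio_5", "log2_ratio_3"),
                           variable.name = "region", value.name = "log2_ratio")
  long[, region := ifelse(region == "log2_ratio_5", "5prime", "3prime")]
  conds <- setdiff(unique(long$condition), control)
  summ <- rbindlist(lapply(conds, function(cd) {
    rbindlist(lapply(c("5prime", "3prime"), function(rg) {
      a <- long[condition == cd & region == rg, log2_ratio]
      b <- long[condition == control & region == rg, log2_ratio]
      p <- welch_p(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
      data.table(condition = cd, region = rg, mean_log2_ratio = mean(a),
                 sem = sd(a) / sqrt(length(a)), p = p)
    }))
  }))
  if (nrow(summ)) summ[, p_bonf := pmin(1, p * length(conds))]
  list(transcripts = reg[, c("transcript_id", "sample_id", "condition",
                             "sum5", "sum3", "log2_ratio_5", "log2_ratio_3")],
       summary = summ)
}

#' Polarity score of ribosome density along a CDS
#'
#' For 1-based position i of a transcript of L codons with density fraction
#' d_i, the polarity is sum(d_i * w_i) with w_i = (2i - (L+1)) / (L-1):
#' -1 when all density sits on the first codon, +1 on the last, 0 for a
#' uniform profile. Computed at codon resolution over the full CDS from raw
#' counts (library-size invariant).
#'
#' @param pc A `positional_counts` object.
#' @param tx The matching `transcriptome`.
#' @return data.table: transcript_id, sample_id, polarity (transcripts with
#'   zero density in a sample are absent).
#' @export
polarity_score <- function(pc, tx) {
  nc <- n_codons(tx)
  cts <- pc$counts[transcript_id %in% names(nc)]
  cts[, {
    L <- nc[.BY$transcript_id]
    w <- (2 * (codon_position + 1) - (L + 1)) / (L - 1)
    .(polarity = sum(count * w) / sum(count))
  }, by = c("transcript_id", "sample_id")]
}

#' Delta-polarity test against control
#'
#' Welch t-test on replicate-level polarity scores, condition versus
#' control, per transcript. Transcripts with `delta_polarity < cut` and
#' `p < alpha` carry `significant = TRUE` (5'-shifted ribosome occupancy).
#'
#' @param pol Output of [polarity_score()].
#' @param samples Sample metadata (sample_id, condition).
#' @param control Control condition label.
#' @param cut Delta-polarity threshold (default -0.15).
#' @param alpha Significance threshold (default 0.05).
#' @return data.table: transcript_id, condition, polarity_control,
#'   polarity_condition, delta_polarity, p, significant.
#' @export
delta_polarity_test <- function(pol, samples, control = "Ctrl",
                                cut = -0.15, alpha = 0.05) {
  samples <- as.data.table(samples)
  cond <- setNames(samples$condition, samples$sample_id)
  pol <- as.data.table(pol)
  pol[, condition := cond[sample_id]]
  nrep <- samples[, .N, by = "condition"]
  if (any(nrep$N < 2L)) stop("at least 2 replicates per condition are required")
  st <- pol[, .(m = mean(polarity), s = sd(polarity), n = .N),
            by = c("transcript_id", "condition")]
  ctrl <- st[condition == control]
  res <- st[condition != control][ctrl, on = "transcript_id",
                                  nomatch = NULL]
  res <- res[n >= 2L & i.n >= 2L]
  res[, p := welch_p(m, s, n, i.m, i.s, i.n)]
  res[, delta_polarity := m - i.m]
  out <- res[, .(transcript_id, condition,
                 polarity_control = i.m, polarity_condition = m,
                 delta_polarity, p)]
  out[, significant := delta_polarity < cut & p < alpha]
  out[]
}

#' Relative ribosome density around occurrences of a codon
#'
#' For every occurrence of `codon` (with a full window inside the CDS) the
#' replicate-mean Norm_RPM of the condition is divided by the control
#' baseline at each codon offset in `-floor(halfwidth_nt/3) ..
#' +floor(halfwidth_nt/3)`; a transcript-specific pseudocount (half the
#' smallest nonzero Norm_RPM) guards empty positions. The mean relative
#' density over occurrences is reported as log2.
#'
#' @param pc A normalised `positional_counts`.
#' @param tx The matching `transcriptome`.
#' @param codon Codon of interest (DNA alphabet).
#' @param condition,control Condition labels.
#' @param halfwidth_nt Window half-width in nucleotides (default 50; the
#'   wider 100-nt window is a choice of this parameter).
#' @return data.table: offset (codons), mean_log2_relative, n_occurrences.
#'   Empty (with a warning) when the codon does not occur.
#' @export
codon_window_enrichment <- function(pc, tx, codon, condition, control = "Ctrl",
                                    halfwidth_nt = 50) {
  w <- floor(halfwidth_nt / 3)
  nc <- n_codons(tx)
  ids <- intersect(unique(pc$counts$transcript_id), names(nc))
  cond_of <- setNames(pc$samples$condition, pc$samples$sample_id)
  cts <- pc$counts[transcript_id %in% ids]
  if (!"norm_rpm" %in% names(cts)) stop("run normalize_counts() first")
  # replicate-mean norm_rpm per position per group
  nrep_cond <- sum(cond_of == condition)
  nrep_ctrl <- sum(cond_of == control)
  mm <- cts[cond_of[sample_id] %in% c(condition, control),
            .(s = sum(norm_rpm)), by = .(transcript_id, codon_position,
                                         grp = cond_of[sample_id])]
  mm[, mean_norm := s / ifelse(grp == condition, nrep_cond, nrep_ctrl)]
  prof <- matrix(0, nrow = 0, ncol = 2 * w + 1)
  occ_total <- 0L
  acc <- numeric(2 * w + 1)
  for (id in ids) {
    codons <- tx[[id]]$codons
    occ <- which(codons == codon)
    occ <- occ[occ - w >= 1 & occ + w <= nc[id]]
    if (!length(occ)) next
    L <- nc[id]
    vc <- numeric(L); vk <- numeric(L)
    sub <- mm[transcript_id == id]
    vc[sub[grp == condition, codon_position] + 1L] <- sub[grp == condition, mean_norm]
    vk[sub[grp == control, codon_position] + 1L] <- sub[grp == control, mean_norm]
    nz <- c(vc[vc > 0], vk[vk > 0])
    ps <- if (length(nz)) min(nz) / 2 else 1e-6
    for (j in occ) {
      idx <- (j - w):(j + w)
      acc <- acc + (vc[idx] + ps) / (vk[idx] + ps)
      occ_total <- occ_total + 1L
    }
  }
  if (occ_total == 0L) {
    warning("codon ", codon, " has no windowed occurrences in the retained transcripts")
    return(data.table(offset = integer(0), mean_log2_relative = numeric(0),
                      n_occurrences = integer(0)))
  }
  data.table(offset = -w:w,
             mean_log2_relative = log2(acc / occ_total),
             n_occurrences = occ_total)
}

#' Codon-frequency shift in the early CDS of selected transcripts
#'
#' Per-transcript codon fractions over the first `region_fraction` of the
#' CDS are compared between a selected set (e.g. 5'-polarised transcripts)
#' and a background set: per codon, log2 of the ratio of mean fractions and
#' a Welch t-test with Benjamini-Hochberg adjustment across codons.
#'
#' @param tx A `transcriptome`.
#' @param selected,background Character vectors of transcript ids.
#' @param region_fraction Fraction of the CDS forming the early region.
#' @return data.table: codon, mean_selected, mean_background, log2fc, p,
#'   p_adj.
#' @export
region_codon_frequency_shift <- function(tx, selected, background,
                                         region_fraction = 0.20) {
  if (!length(selected) || !length(background))
    stop("both transcript sets must be non-empty")
  frac_mat <- function(ids) {
    t(vapply(ids, function(id) {
      cods <- tx[[id]]$codons
      k <- max(1L, floor(region_fraction * length(cods)))
      cods <- cods[seq_len(k)]
      cods <- cods[cods %in% SENSE_CODONS]
      tabulate(match(cods, SENSE_CODONS), length(SENSE_CODONS)) / max(1L, length(cods))
    }, numeric(length(SENSE_CODONS))))
  }
  A <- frac_mat(selected)
  B <- frac_mat(background)
  mA <- colMeans(A); mB <- colMeans(B)
  p <- welch_p(mA, apply(A, 2, sd), rep(nrow(A), ncol(A)),
               mB, apply(B, 2, sd), rep(nrow(B), ncol(B)))
  # single-member sets have no variance estimate
  if (nrow(A) < 2L || nrow(B) < 2L) p[] <- NA_real_
  out <- data.table(codon = SENSE_CODONS,
                    mean_selected = mA, mean_background = mB,
                    log2fc = ifelse(mB > 0, log2(mA / mB), NA_real_),
                    p = p)
  out[, p_adj := p.adjust(p, "BH")]
  out[]
}
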