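# Per-codon ribosome dwell-time inference.
#
# Model, per sample: E[count(g,i)] = exp(log alpha_g + sum_o log delta_o(c_{i+o})),
# o = -3..+3 (site labels -2,-1,E,P,A,3,4 with P = 0). Fitted by Poisson
# maximum likelihood with cyclic block updates, each of which is an exact
# block maximiser (codons at a fixed offset, like genes, partition the
# positions), so the likelihood is non-decreasing by construction.
# Identifiability: log delta has zero mean over the 61 sense codons at every
# offset; the shift is absorbed into the gene levels. Stop codons are fixed
# at delta = 1 and positions without a complete 7-sense-codon window are
# excluded from the fit.

#' Estimate per-codon, per-site dwell factors from positional counts
#'
#' @param pc A `positional_counts` object.
#' @param tx The matching `transcriptome`.
#' @param min_reads_per_gene Genes with fewer total reads in a sample are
#'   excluded from that sample's fit (default 10).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-8); use 0 to always run `max_iter` cycles.
#' @param max_iter Maximum update cycles (default 200).
#' @param samples Optional subset of sample ids to fit (default all).
#' @return A `dwell_time_table`: list with `log_delta` (per sample, a
#'   7 x 61 matrix of natural-log dwell factors, rows -2,-1,E,P,A,3,4),
#'   `gene_levels` (per sample, named log alpha), `converged`,
#'   `loglik` (per-cycle traces) and the sample metadata.
#' @export
estimate_dwell_times <- function(pc, tx, min_reads_per_gene = 10,
                                 tol = 1e-8, max_iter = 200L, samples = NULL) {
  pt <- position_table(tx)
  # fit positions: complete window of sense codons only
  sense_idx <- match(SENSE_CODONS, ALL_CODONS)
  ok <- rowSums(is.na(pt$window)) == 0L
  for (k in seq_len(7L)) ok <- ok & (pt$window[, k] %in% sense_idx)
  fit_key <- paste(pt$transcript_id[ok], pt$pos[ok] - 1L)
  W <- matrix(match(ALL_CODONS[pt$window[ok, ]], SENSE_CODONS), ncol = 7L)
  gene_of <- pt$gene_id[ok]
  if (is.null(samples)) samples <- pc$samples$sample_id
  cts <- pc$counts[sample_id %in% samples]
  cts_key <- paste(cts$transcript_id, cts$codon_position)

  out <- list(log_delta = list(), gene_levels = list(),
              converged = logical(0), loglik = list(),
              samples = pc$samples[pc$samples$sample_id %in% samples])
  for (sid in samples) {
    rows <- which(cts$sample_id == sid)
    y <- numeric(length(fit_key))
    m <- match(cts_key[rows], fit_key)
    hit <- !is.na(m)
    y[m[hit]] <- cts$count[rows][hit]
    gt <- rowsum(y, gene_of)
    keep_genes <- rownames(gt)[gt[, 1] >= min_reads_per_gene]
    use <- gene_of %in% keep_genes
    if (length(keep_genes) < 2L)
      stop("fewer than 2 genes pass the read filter for sample ", sid)
    fit <- fit_dwell_sample(y[use], W[use, , drop = FALSE], gene_of[use],
                            tol = tol, max_iter = max_iter)
    out$log_delta[[sid]] <- fit$log_delta
    out$gene_levels[[sid]] <- fit$log_alpha
    out$converged[sid] <- fit$converged
    out$loglik[[sid]] <- fit$loglik
    if (!fit$converged)
      warning("dwell-time fit did not converge for sample ", sid)
  }
  structure(out, class = "dwell_time_table")
}

fit_dwell_sample <- function(y, W, gene_of, tol, max_iter) {
  genes <- sort(unique(gene_of))
  g <- match(gene_of, genes)
  ng <- length(genes)
  npos <- length(y)
  total_g <- rowsum(y, g)[, 1]
  ld <- matrix(0, nrow = 7L, ncol = length(SENSE_CODONS),
               dimnames = list(SITE_LABELS, SENSE_CODONS))
  # constant numerators: reads by (offset, codon)
  numer <- lapply(seq_len(7L), function(k) {
    v <- numeric(length(SENSE_CODONS))
    rs <- rowsum(y, W[, k])
    v[as.integer(rownames(rs))] <- rs[, 1]
    v
  })
  log_alpha <- log(pmax(total_g, 0.5) / tabulate(g, ng))
  mu <- exp(log_alpha[g])  # delta all 1 at start
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_len(7L)) {
      fk <- W[, k]
      mu_div <- mu * exp(-ld[k, fk])
      den <- numeric(length(SENSE_CODONS))
      rs <- rowsum(mu_div, fk)
      den[as.integer(rownames(rs))] <- rs[, 1]
      upd <- numer[[k]] > 0 & den > 0
      new_ld <- ld[k, ]
      new_ld[upd] <- log(numer[[k]][upd] / den[upd])
      ld[k, ] <- new_ld
      mu <- mu_div * exp(new_ld[fk])
    }
    # exact gene-level update
    exp_g <- rowsum(mu, g)[, 1]
    fac <- ifelse(exp_g > 0, total_g / exp_g, 1)
    fac[fac <= 0] <- 1e-12
    log_alpha <- log_alpha + log(fac)
    mu <- mu * fac[g]
    # identifiability: centre log delta per site, absorb into gene levels
    mk <- rowMeans(ld)
    ld <- ld - mk
    log_alpha <- log_alpha + sum(mk)
    ll <- sum(y * log(pmax(mu, 1e-300)) - mu)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (tol == 0) converged <- TRUE
  list(log_delta = ld, log_alpha = setNames(log_alpha, genes),
       converged = converged, loglik = ll_trace)
}

#' @export
print.dwell_time_table <- function(x, ...) {
  cat(sprintf("dwell_time_table: %d sample(s), %d sense codons x 7 sites%s\n",
              length(x$log_delta), length(SENSE_CODONS),
              if (all(x$converged)) "" else " (NOT all converged)"))
  invisible(x)
}

#' Tidy export of a dwell-time table
#' @param dt A `dwell_time_table`.
#' @return data.table: sample_id, site, codon, log2_dt.
#' @export
dwell_time_long <- function(dt) {
  rbindlist(lapply(names(dt$log_delta), function(sid) {
    m <- dt$log_delta[[sid]]
    data.table(sample_id = sid,
               site = rep(rownames(m), ncol(m)),
               codon = rep(colnames(m), each = nrow(m)),
               log2_dt = as.vector(m) / log(2))
  }))
}

#' Window-mean dwell time per codon
#'
#' Arithmetic mean of log dwell over the seven ribosomal sites spanning
#' +-3 codons around the P-site, reported on the log2 scale.
#'
#' @param dt A `dwell_time_table` (or a single 7 x 61 matrix).
#' @return data.table: sample_id, codon, log2_dt.
#' @export
summarize_window_dt <- function(dt) {
  mats <- if (inherits(dt, "dwell_time_table")) dt$log_delta else list(sample = dt)
  rbindlist(lapply(names(mats), function(sid) {
    m <- mats[[sid]]
    if (!all(SITE_LABELS %in% rownames(m)))
      stop("dwell table is missing ribosomal site(s): ",
           paste(setdiff(SITE_LABELS, rownames(m)), collapse = ", "))
    data.table(sample_id = sid, codon = colnames(m),
               log2_dt = colMeans(m[SITE_LABELS, , drop = FALSE]) / log(2))
  }))
}

#' Per-codon ANOVA with Tukey HSD contrasts against control
#'
#' One-way fixed-effects ANOVA on replicate window-mean dwell times per
#' codon, followed by Tukey honest-significant-difference contrasts of each
#' condition against the control, computed from the studentized-range
#' distribution (Tukey-Kramer for unbalanced designs). Vectorised over
#' codons.
#'
#' @param window_dt data.table from [summarize_window_dt()] (columns
#'   sample_id, codon, log2_dt).
#' @param samples Sample metadata mapping sample_id to condition.
#' @param control Control condition label (default "Ctrl").
#' @param alpha Flagging threshold on the Tukey-adjusted p (default 0.01).
#' @return data.table: codon, condition, mean_control, mean_condition,
#'   delta_dt, anova_F, anova_p, tukey_p, flagged.
#' @export
dt_anova_tukey <- function(window_dt, samples, control = "Ctrl", alpha = 0.01) {
  samples <- as.data.table(samples)
  wd <- as.data.table(window_dt)[samples[, c("sample_id", "condition")], on = "sample_id"]
  conds <- unique(wd$condition)
  if (!control %in% conds) stop("control condition not present: ", control)
  if (length(conds) < 2L) stop("at least 2 conditions are required for ANOVA")
  X <- data.table::dcast(wd, codon ~ sample_id, value.var = "log2_dt")
  codons <- X$codon
  M <- as.matrix(X[, -1])
  cond_of <- samples$condition[match(colnames(M), samples$sample_id)]
  if (min(table(cond_of)) < 2L) stop("at least 2 replicates per condition are required")
  k <- length(conds)
  nj <- table(cond_of)[conds]
  N <- ncol(M)
  # group means per codon
  Gm <- matrix(0, nrow = nrow(M), ncol = length(conds),
               dimnames = list(NULL, conds))
  for (cd in conds) Gm[, cd] <- rowMeans(M[, cond_of == cd, drop = FALSE])
  grand <- rowMeans(M)
  ssb <- as.vector((Gm - grand)^2 %*% as.numeric(nj))
  resid <- M - Gm[, match(cond_of, conds), drop = FALSE]
  ssw <- rowSums(resid^2)
  df1 <- k - 1L
  df2 <- N - k
  mse <- ssw / df2
  Fst <- (ssb / df1) / mse
  anova_p <- pf(Fst, df1, df2, lower.tail = FALSE)
  degen <- mse <= 0 | !is.finite(Fst)
  if (any(degen)) {
    warning(sprintf("%d codon(s) with zero within-group variance; p set to 1", sum(degen)))
    anova_p[degen] <- 1
  }
  out <- rbindlist(lapply(setdiff(conds, control), function(cd) {
    se <- sqrt(mse / 2 * (1 / nj[[cd]] + 1 / nj[[control]]))
    q <- abs(Gm[, cd] - Gm[, control]) / se
    tp <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    tp[degen] <- 1
    data.table(codon = codons, condition = cd,
               mean_control = Gm[, control], mean_condition = Gm[, cd],
               delta_dt = Gm[, cd] - Gm[, control],
               anova_F = Fst, anova_p = anova_p, tukey_p = tp,
               flagged = tp < alpha)
  }))
  out
}

#' Relationship between dwell time and codon usage frequency
#'
#' @param dt_per_codon Named numeric vector of per-codon dwell times
#'   (log2 scale), e.g. one condition's window means.
#' @param freq Named numeric vector of codon frequencies (percent).
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `slope`, `intercept`, and the merged table. Correlations
#'   are `NA` when either variable is constant (slope 0 in that case).
#' @export
dt_frequency_relation <- function(dt_per_codon, freq) {
  common <- intersect(names(dt_per_codon), names(freq))
  if (length(common) < 3L) stop("need at least 3 codons shared between DT and frequency tables")
  x <- as.numeric(freq[common])
  y <- as.numeric(dt_per_codon[common])
  tab <- data.table(codon = common, frequency = x, log2_dt = y)
  if (sd(y) == 0 || sd(x) == 0) {
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                slope = 0, intercept = mean(y), table = tab))
  }
  ct_p <- stats::cor.test(x, y, method = "pearson")
  ct_s <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(pearson_r = unname(ct_p$estimate), pearson_p = ct_p$p.value,
       spearman_rho = unname(ct_s$estimate), spearman_p = ct_s$p.value,
       slope = fit$coefficients[2], intercept = fit$coefficients[1],
       table = tab)
}
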