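# First-order protein-turnover kinetics under reduced synthesis.
#
# Before starvation the protein is at steady state P0 = sigma / k with
# k = ln(2) / t_half. At t = 0 synthesis drops to s * sigma with k
# unchanged, so P(t)/P0 = s + (1 - s) * 2^(-t / t_half): the abundance
# relaxes from 1 toward the new steady state s with the protein's own
# half-life. The two guide scenarios are a total synthesis block (s = 0)
# and a 50% block (s = 0.5).

#' Predicted protein log2 fold change under reduced synthesis
#'
#' @param t Hours since starvation onset.
#' @param t_half Protein half-life in hours (> 0).
#' @param s Synthesis-retention fraction in `[0,1]` (0 = total block).
#' @return log2(P(t) / P(0)) = log2(s + (1 - s) * 2^(-t / t_half)).
#'   Vectorised over all arguments.
#' @export
predict_log2fc <- function(t, t_half, s) {
  if (any(t_half <= 0)) stop("t_half must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  log2(s + (1 - s) * 2^(-t / t_half))
}

#' Classify proteins by adjusted p-value and fold-change thresholds
#'
#' Strict inequalities: down requires `p_adj < p_cut` and
#' `log2fc < -fc_cut`; up requires `p_adj < p_cut` and `log2fc > fc_cut`;
#' everything else (including records with missing p, warned about) is
#' unchanged.
#'
#' @param records data.frame with columns `protein_id`, `log2fc`, `p_adj`.
#' @param p_cut Adjusted-p threshold (default 0.01).
#' @param fc_cut Absolute log2FC threshold (default 0.26).
#' @return The table with a `class` column plus a `counts` attribute
#'   (table of class labels).
#' @export
classify_proteins <- function(records, p_cut = 0.01, fc_cut = 0.26) {
  rec <- as.data.table(records)
  if (anyNA(rec$p_adj)) {
    warning(sprintf("%d protein(s) with missing adjusted p labelled unchanged",
                    sum(is.na(rec$p_adj))))
  }
  rec[, class := "unchanged"]
  rec[!is.na(p_adj) & p_adj < p_cut & log2fc < -fc_cut, class := "down"]
  rec[!is.na(p_adj) & p_adj < p_cut & log2fc > fc_cut, class := "up"]
  counts <- table(factor(rec$class, levels = c("up", "down", "unchanged")))
  setattr(rec, "counts", counts)
  rec[]
}

#' Compare half-life distributions across protein classes
#'
#' One-way ANOVA followed by Tukey HSD on (by default log-transformed)
#' half-lives of the up / down / unchanged classes. Classes with fewer
#' than 2 members are dropped with a warning.
#'
#' @param records Classified protein table with `half_life` and `class`.
#' @param log_scale Log-transform half-lives first (default TRUE; protein
#'   half-lives are heavily right-skewed).
#' @return List: `anova_F`, `anova_p`, `tukey` (data.table: contrast,
#'   diff, p_adj), `n_per_class`.
#' @export
halflife_group_comparison <- function(records, log_scale = TRUE) {
  rec <- as.data.table(records)[!is.na(half_life) & half_life > 0]
  tab <- table(rec$class)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping class(es) with < 2 members: ", paste(small, collapse = ", "))
    rec <- rec[!class %in% small]
  }
  if (length(unique(rec$class)) < 2L)
    stop("at least 2 non-empty classes are required")
  y <- if (log_scale) log(rec$half_life) else rec$half_life
  fit <- aov(y ~ cls, data = data.frame(y = y, cls = factor(rec$class)))
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$cls
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       tukey = data.table(contrast = rownames(tk),
                          diff = tk[, "diff"], p_adj = tk[, "p adj"]),
       n_per_class = table(rec$class))
}

#' Theoretical log2FC curves versus half-life, with observed values
#'
#' @param records Protein table with `half_life` and `log2fc`.
#' @param s_values Synthesis-retention scenarios (default c(0, 0.5)).
#' @param t Hours since starvation onset (default 6).
#' @param grid_points Number of half-life grid points (default 200).
#' @return List: `curves` (data.table: half_life, s, predicted_log2fc on a
#'   log-spaced grid) and `observed` (the input with its own predictions
#'   added per scenario).
#' @export
expected_vs_observed_curve <- function(records, s_values = c(0, 0.5), t = 6,
                                       grid_points = 200L) {
  rec <- as.data.table(records)[!is.na(half_life) & half_life > 0]
  hl_grid <- exp(seq(log(max(min(rec$half_life), 0.1)),
                     log(max(rec$half_life)), length.out = grid_points))
  curves <- rbindlist(lapply(s_values, function(s)
    data.table(half_life = hl_grid, s = s,
               predicted_log2fc = predict_log2fc(t, hl_grid, s))))
  obs <- copy(rec)
  for (s in s_values)
    obs[, (sprintf("pred_s%g", s)) := predict_log2fc(t, half_life, s)]
  list(curves = curves, observed = obs)
}
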