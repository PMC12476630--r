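# ribostall

Codon-resolution analysis of ribosome stalling from ribosome-profiling
footprint data, built for studies of translation elongation under
amino-acid limitation (e.g. branched-chain amino-acid starvation, where
uncharged tRNAs make ribosomes dwell on specific codons).

The package takes P-site-assigned, codon-resolution footprint count tables
plus CDS sequences and provides, as testable R functions:

- **Dwell-time inference.** Per sample, footprint counts are modelled as
  `E[count(g,i)] = exp(log α_g + Σ_o log δ_o(c_{i+o}))` over the seven
  ribosomal sites `o ∈ {−3..+3}` around the P-site (labels −2, −1, E, P, A,
  3, 4; A-site = +1). The multiplicative dwell factors δ are fitted by
  Poisson maximum likelihood with cyclic closed-form block updates under a
  zero-mean identifiability constraint on log δ per site over the 61 sense
  codons. Window-mean dwell times per codon are compared across conditions
  by one-way ANOVA with Tukey-HSD contrasts against control.
- **Positional metrics.** Library normalisation (RPM, Norm_RPM), transcript
  filtering (mean total ≥ 50, positional coverage ≥ 30%), metagene
  profiles (15-nt edge exclusion), 5′/3′ ramp indices over the outer 20% of
  the CDS, and the polarity score
  `π = Σ_i d_i·w_i, w_i = (2i − (L+1))/(L−1) ∈ [−1, 1]`,
  with Welch tests for Δπ < −0.15 at p < 0.05.
- **Stall-site peak calling.** Per position versus control:
  log2FC(RPM) > 2 ∧ log2FC(Norm_RPM) > 2 ∧ FC over the gene mean > 1 ∧
  p < 0.05 (Welch t-test across replicates), plus codon-context profiles,
  hypergeometric overlap tests, stall-site metagenes, first-site distances
  and stall–proteome enrichment strata.
- **Codon usage.** Gene-level codon count/fraction tables (isoform counts
  averaged, stop codon excluded) and positional codon bias along the CDS
  with bootstrap confidence intervals.
- **Protein turnover kinetics.** First-order decay from steady state with
  synthesis scaled by `s`: abundance ratio `s + (1−s)·2^(−t/t½)`, giving
  the expected proteome log2FC per half-life; classification at adjusted
  p < 0.01 and |log2FC| > 0.26; half-life comparisons across classes.
- **Assay analytics.** Polysome-profile smoothing/baselining/anchor
  alignment/AUC normalisation and P/M ratios; spike-normalised tRNA
  charging (2^(−ΔΔCt)) and ΔΔCt qPCR fold changes.
- **Synthetic data with planted truth.** A generator that mirrors the
  dwell model exactly (so noiseless recovery is an identity test):
  log-normal gene expression, per-site dwell tables, condition-specific
  A-site effects, planted stall spikes with downstream flux attenuation
  β per stall, Poisson/negative-binomial noise, and matching proteome /
  charging-assay simulators.

## Worked example

Simulate a valine-starvation experiment (200 genes, triplicates, Poisson
noise, a 4× A-site dwell increase on all four Val codons plus 8× stall
spikes at 0.5% of positions), then recover everything:

```r
library(ribostall)

cfg <- sim_config(n_genes = 200L, length_range = c(150L, 250L),
                  conditions = c("Ctrl", "Val"), n_replicates = 3L,
                  noise = "poisson", library_size = 2e6,
                  stall_frac = 0.005, stall_fold = 8, seed = 42L)
mt  <- make_transcriptome(cfg)
sim <- simulate_footprints(mt$tx, cfg)

keep <- filter_transcripts(sim$counts, mt$tx)
pc   <- normalize_counts(subset_transcripts(sim$counts, keep))

dt    <- estimate_dwell_times(pc, mt$tx)
stats <- dt_anova_tukey(summarize_window_dt(dt), pc$samples, control = "Ctrl")
stats[codon %in% codon_family("Val")]
#>     codon condition delta_dt  tukey_p flagged
#>  1:   GTA       Val    0.305 9.37e-14    TRUE
#>  2:   GTC       Val    0.256 9.37e-14    TRUE
#>  3:   GTG       Val    0.270 9.37e-14    TRUE
#>  4:   GTT       Val    0.262 9.39e-14    TRUE
```

`delta_dt` is the log2 window-mean dwell shift versus control: the planted
4× A-site increase spreads over the 7-site window as
log2(4)/7 ≈ 0.286, and only the four valine codons are flagged with an
upregulated dwell time (all other codons shift slightly negative from the
zero-mean constraint).

```r
calls <- call_stall_sites(pc, "Val", "Ctrl")
sites <- calls[passes == TRUE]
#> stall sites called: 289 across 154 transcripts (planted spikes: 193; recall 0.974)
```

The 101 calls beyond the planted spikes all carry a valine codon in the
ribosomal A-site — the dwell-driven stalls the condition itself creates —
and the codon-context profile peaks at A-site offset +1 (107 Val codons,
vs 15–23 at neighbouring offsets), with 92% of stall windows containing a
Val codon:

```r
ctx <- stall_codon_context(sites, mt$tx, codon_family("Val"))
ctx$proportion_containing
#> [1] 0.92
```

The kinetic model gives the expected proteome change for a 6-h starvation
of a protein with a 6-h half-life under a 50% synthesis block:

```r
predict_log2fc(t = 6, t_half = 6, s = 0.5)
#> [1] -0.4150375
```

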