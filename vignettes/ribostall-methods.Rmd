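---
title: "Models and methods behind ribostall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribostall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters with
their defaults and units, what the synthetic-data generator does and does
not emulate, the numerical choices, and the design decisions taken where
the methodology left genuine freedom. It states no empirical result that
the test suite does not itself compute.

## 1. The dwell-time model

Ribosome-profiling footprint density at a codon is inversely proportional
to the local elongation rate, so positional counts carry information about
how long the ribosome dwells with each codon at each of its sites. We
model, per sample,

$$\mathbb{E}[\,y_{g,i}\,] \;=\; \exp\Big(\log\alpha_g \;+\;
\sum_{o=-3}^{+3} \log\delta_o\big(c_{g,i+o}\big)\Big),$$

where $y_{g,i}$ is the count at codon position $i$ of gene $g$, $\alpha_g$
is a free per-gene level (expression × average density), and
$\delta_o(c)$ is the multiplicative dwell factor of codon $c$ at window
offset $o$. The seven offsets carry the ribosomal site labels −2, −1, E,
P, A, 3, 4 with the P-site at offset 0 and the decoding A-site at +1; the
window spans ±3 codons because starvation-induced dwell changes are
empirically smeared beyond the A-site.

**Assumptions.** Counts are Poisson given the rate (no overdispersion term
in the fit); site effects multiply independently (log-linear, no
codon-pair interactions); one canonical transcript per gene; no 5′/3′
ramp covariates. The model is a deliberate simplification of full
GLM-based dwell-time pipelines: it keeps exactly the quantity downstream
analyses consume (a per-site, per-codon dwell table) while remaining small
enough to admit an exact generative oracle.

**Fitting.** Genes with fewer than `min_reads_per_gene = 10` reads in a
sample are dropped from that sample's fit, as are positions whose 7-codon
window is incomplete or touches a stop codon (stop codons are fixed at
δ = 1; the terminal stop is never an interior codon of the window set).
The likelihood is maximised by cyclic block updates. Codons at a fixed
offset partition the positions, as do genes, so both block updates have
closed forms and are exact block maximisers:

* for each offset $o$ and codon $c$:
  $\delta_o(c) \leftarrow \sum y / \sum \hat\mu^{(-o,c)}$, the ratio of
  observed to expected-with-$\delta_o(c)=1$ counts;
* for each gene: $\alpha_g \leftarrow$ observed total / expected total.

The likelihood is therefore non-decreasing by construction (asserted per
cycle in the tests). Iteration stops when the relative log-likelihood
change falls below `tol = 1e-8` or after `max_iter = 200` cycles;
non-convergence returns a flagged result with a warning rather than an
error. For the noiseless identity check the acceptance test passes
`tol = 0, max_iter = 500` — at the default tolerance the fit is
statistically converged but can stop a little short of the 1e-6 parameter
accuracy the identity oracle demands; this is a solver setting, not a
threshold change.

**Identifiability.** The model is invariant to multiplying all
$\delta_o(\cdot)$ at one offset by a constant and dividing the gene levels
accordingly. We impose mean-zero $\log\delta$ per offset over the 61 sense
codons, re-centring at every cycle with the shift absorbed into
$\log\alpha$. A consequence worth knowing: a planted $4\times$ A-site
increase on the four valine codons is recovered as
$\log_2 4\cdot(1 - 4/61) \approx 1.87$ on those codons and $-4\log_2 4/61$
on every other codon. The window-mean (log2, averaged over the seven
sites) correspondingly shifts by $\log_2 4 / 7 \approx 0.29$ relative to
control.

**Condition comparison.** Window-mean dwell times per codon and replicate
enter a one-way fixed-effects ANOVA with Tukey-HSD contrasts of each
condition against control, computed directly from the studentized-range
distribution (Tukey–Kramer standard errors for unbalanced designs) and
vectorised across codons; codons are flagged at Tukey-adjusted p < 0.01.
With exactly two groups the Tukey p equals the pooled-variance two-sample
p (an identity the tests verify against `aov`/`TukeyHSD` and directly
against the q-distribution), which is also why the type-I calibration
test uses two groups: with more, Tukey controls the family-wise rate and
the flagged fraction would sit conservatively below the nominal level.

## 2. Positional metrics

All metrics are computed on per-transcript density fractions (Norm_RPM or
raw count fractions) and are invariant to library-size rescaling.

* **Filtering:** keep transcripts with cross-sample mean total count ≥ 50
  and mean fraction of covered (nonzero) positions ≥ 0.30.
* **Metagene profile:** trim 15 nt (5 codons) from each CDS end to avoid
  start/stop-codon peaks, renormalise, scale by the number of retained
  positions (uniform density ⇒ exactly 1), bin by percent rank into 100
  bins, and average bins across transcripts and replicates. Transcripts
  shorter than the two trims are skipped with a warning. Transcripts
  shorter than the bin count cannot populate every bin; such bins are
  simply absent rather than zero-filled.
* **Ramp indices:** sums of Norm_RPM over the first and last
  `region_fraction = 0.20` of codon positions (`floor(0.2·L)` codons per
  region, disjoint for L ≥ 10), log2-referenced to the transcript's mean
  control sum, summarised per condition with Welch t-tests and Bonferroni
  correction across conditions.
* **Polarity:** $\pi = \sum_i d_i w_i$ with $w_i = (2i-(L+1))/(L-1)$ over
  the **full** CDS at codon resolution — the edge trim is documented for
  the metagene but not for the polarity score, and we follow that reading;
  both resolution and trimming would be one-line changes. $\pi \in
  [-1,1]$, is exactly 0 for uniform density, and negates under profile
  reversal. Δπ versus control is tested per transcript with Welch t-tests
  on replicate scores; transcripts with Δπ < −0.15 and p < 0.05 are the
  5′-shifted set.
* **Codon-window enrichment:** around each occurrence of a codon of
  interest (full window inside the CDS; half-width 50 nt by default, the
  ±100 nt variant is the same parameter), the replicate-mean Norm_RPM of
  the condition is divided by the control baseline per offset and the mean
  ratio reported as log2.

**Welch everywhere.** Every "unpaired t-test" in the package is Welch's
unequal-variance test — the default unpaired test of the R environment the
original analyses were run in — applied uniformly. Degenerate cases are
explicit: zero variance with equal means gives p = 1, with unequal means
p = 0.

**Pseudocounts.** log2 fold changes of densities guard zeros with half
the smallest nonzero Norm_RPM of the transcript (scale-free, adapts to
coverage); RPM-scale fold changes use a fixed `pseudocount_rpm = 0.1`
from the configuration. The choice is visible in results only at
near-zero-density positions, which the fold-change thresholds exclude
anyway.

## 3. Stall-site calling

A position is a called stalling site when all four criteria hold versus
control: log2FC of mean RPM > 2, log2FC of mean Norm_RPM > 2, mean RPM
above the transcript's positional mean in the condition
(`fc_gene_mean > 1`), and Welch p < 0.05 on log(Norm_RPM + pseudocount)
across replicates. Choices the methodology left open, fixed here and
exposed in the configuration:

* "position" is a codon position (the counts are codon-resolution);
* `fc_gene_mean` is the replicate-mean RPM at the position over the mean
  positional RPM of the transcript in the same condition;
* the replicate test runs on the Norm_RPM scale (log-transformed, with the
  transcript pseudocount);
* raw p < 0.05 per position, no multiplicity correction — the criterion
  conjunction with two 4-fold thresholds is the real specificity guard
  (the null-simulation tests observe zero false calls at realistic
  coverage).

Context profiles place offset 0 at the called codon itself (the A-site
naming convention); windows are truncated at CDS edges without padding.
Overlap significance between two site (or transcript) sets uses the
upper-tail hypergeometric at k−1 against the universe of tested elements
(the universe — all retained vs all expressed transcripts — is an explicit
argument since the published choice is not stated). Enrichment of
downregulated proteins among transcripts with ≥ k stall sites reports
−log10 hypergeometric p per stratum, with the k = 0 stratum fixed at the
total downregulated count by construction.

## 4. Protein-turnover kinetics

"Standard degradation kinetics" is read as first-order decay from
pre-starvation steady state with unchanged degradation rate
$k = \ln 2 / t_{1/2}$ and synthesis scaled to $s\sigma$ at $t = 0$:

$$\frac{P(t)}{P(0)} = s + (1-s)\,2^{-t/t_{1/2}},$$

the unique one-compartment model consistent with the two guide scenarios
(total block $s=0$ and half block $s=0.5$). The closed form is verified
against RK4 integration of $dP/dt = s\sigma - kP$ to < 1e−9 across a
parameter grid. Whether starvation also modifies degradation is not
modelled ($k$ fixed — the minimal reading); the invariant
$\log_2\mathrm{FC} \in [-t/t_{1/2},\, 0]$ follows. Classification uses
strict inequalities (adjusted p < 0.01, |log2FC| > 0.26), so a protein at
exactly −0.26 is unchanged. Half-life group comparisons (ANOVA + Tukey)
run on log half-lives by default because half-life distributions are
heavily right-skewed; a raw-scale switch exists.

## 5. Assay analytics

Polysome traces are smoothed with a centred 5-point moving average (width
unspecified in the field's descriptions; edges truncated), baselined to
min = 0, aligned by piecewise-linear interpolation that maps each manual
anchor exactly onto its reference (terminal segments extrapolate with the
outer slopes), and normalised to unit trapezoidal AUC. Monosome/polysome
windows are explicit inputs (how they were chosen after alignment is not
stated in the source methodology); the P/M ratio is their AUC ratio,
optionally normalised to a control ratio.

tRNA charging: the periodate-oxidation assay destroys uncharged tRNA, so
the RT-qPCR Ct of a target rises by −log2(charged fraction). Per sample,
ΔCt references the E. coli spike-in; per isoacceptor, ΔΔCt references the
mean control ΔCt and relative charging is 2^(−ΔΔCt), tested on the log
scale against 0. IUPAC-ambiguous isoacceptor labels are single measurement
units. The ΔΔCt pipeline is invariant to adding a constant to all Cts of a
sample — the property the spike normalisation exists to provide.
Gene-expression ΔΔCt works identically with a housekeeping gene in place
of the spike.

## 6. The synthetic world

The generator mirrors the dwell model exactly — expected counts are
$\alpha_g \prod_o \delta_o(c_{i+o})$ times a planted-stall factor and a
bottleneck attenuation $\beta^{\#\{\text{stalls strictly upstream}\}}$ —
so that noiseless recovery by the estimator is an identity, not an
approximation. Stated defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| genes × length | 500 × 200–400 codons | desk-scale; matches the recovery oracle's 500 × 300 case |
| expression α | log-normal, sdlog 1 | typical mRNA-abundance spread |
| dwell log-sd | 0.3 at E/P/A, 0.1 flanking | dwell variation concentrated at the decoding centre |
| condition effect | 4× A-site on GTT/GTC/GTA/GTG ("Val") | strong valine-codon stalling under valine starvation |
| noise | Poisson (NB optional, dispersion 0.05) | counting noise; NB for overdispersed libraries |
| libraries | 3 replicates × 5e6 | triplicate design at realistic depth |
| stall spikes | fold 8, fraction 0 by default | planted positional peaks for caller recovery |
| attenuation β | 1 (off) | downstream flux loss per stall when enabled |

The "replicate CV 10%" of the stall-caller recovery world is realised by
Poisson noise at per-position mean ~100 (CV = 1/√100), i.e. by the
generator's own noise law. The attenuation world for the polarity
criterion is β = 0.8 with five stalls planted inside the first 20% of
each CDS; the closed-form expectation of the polarity under a
piecewise-uniform density with downstream factor $\beta^5 \approx 0.33$
is ≈ −0.23, comfortably past the −0.15 threshold — computed before
implementation, not tuned after.

**What the generator does not emulate** — and hence what a green test
does not establish: nucleotide-level footprint-length distributions and
P-site-assignment error; ribosome traffic/queuing (attenuation is a step
function per planted stall, not a TASEP); UTRs, uORFs and start/stop
peaks; codon-pair or structure-dependent pausing; isoform mixtures
(isoform handling exists only in the codon-usage table); batch effects
and library-prep biases. Recovery results certify the estimators against
their own generative assumptions, not against every failure mode of real
libraries.

## 7. Numerical and format conventions

* Internal coordinates are 0-based half-open; codon positions in all
  outputs are 0-based; BED output converts to nucleotide intervals
  (start = 3·codon, width 3) with score min(1000, round(−10·log10 p)).
* Duplicate count rows are summed on ingestion (with a warning); RNA
  alphabets are mapped U→T; CDS records failing the triplet or alphabet
  check are skipped, and an input with zero valid records is fatal.
* Configuration files are JSON key–value overrides of the documented
  defaults; unknown keys are fatal (typo protection), and the resolved
  configuration is echoed to the log.
* All generators take explicit integer seeds and are byte-reproducible;
  the end-to-end pipeline writes TSVs whose bytes are identical across
  runs with the same seed.
* Isoform codon tables average counts, then normalise (averaging
  fractions would weight isoforms unequally; the counts-averaging reading
  is documented in the function help).

## 8. Known limitations

The dwell model omits the positional ramp covariates and
footprint-length stratification of full pipelines, so absolute dwell
levels near CDS ends are less trustworthy than interior contrasts. The
stall caller tests positions independently; runs of adjacent slow codons
are reported as multiple sites. The hypergeometric enrichment treats
transcripts as exchangeable, ignoring expression-dependent detection. The
kinetic model assumes unchanged degradation; a starvation-induced decay
change would be absorbed into apparent synthesis retention. Polarity and
ramp indices summarise a whole transcript in one number and cannot
localise multi-modal redistribution — that is what the peak caller is
for.
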