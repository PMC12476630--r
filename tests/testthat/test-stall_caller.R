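sim_spikes <- function(n_genes = 40L, len = 150L, stall_frac = 0.01,
                       stall_fold = 8, seed = 1L, library_size = NULL) {
  if (is.null(library_size)) library_size <- n_genes * len * 100  # ~Poisson CV 10%
  cfg <- sim_config(n_genes = n_genes, length_range = c(len, len),
                    conditions = c("Ctrl", "Val"), condition_effects = list(),
                    stall_frac = stall_frac, stall_fold = stall_fold,
                    n_replicates = 3L, noise = "poisson",
                    library_size = library_size, seed = seed)
  mt <- make_transcriptome(cfg)
  sim <- simulate_footprints(mt$tx, cfg)
  keep <- filter_transcripts(sim$counts, mt$tx)
  list(tx = mt$tx, pc = normalize_counts(subset_transcripts(sim$counts, keep)),
       truth = sim$truth)
}

test_that("identical groups yield no stall calls", {
  s <- sim_spikes(n_genes = 10L, stall_frac = 0, seed = 2L)
  # duplicate the control as a fake condition: both groups identical
  cts <- s$pc$counts[, c("transcript_id", "codon_position", "sample_id", "count")]
  ctrl_ids <- s$pc$samples[condition == "Ctrl", sample_id]
  dup <- cts[sample_id %in% ctrl_ids]
  dup[, sample_id := sub("Ctrl", "Fake", sample_id)]
  sm <- rbind(s$pc$samples[condition == "Ctrl"],
              sample_meta(sub("Ctrl", "Fake", ctrl_ids), "Fake", 1:3))
  pc <- normalize_counts(positional_counts(rbind(cts[sample_id %in% ctrl_ids], dup),
                                           samples = sm))
  calls <- call_stall_sites(pc, "Fake", "Ctrl")
  expect_equal(sum(calls$passes), 0L)
  expect_true(all(calls$log2fc_rpm == 0))
})

test_that("planted 8x spikes are called; sub-threshold spikes are not", {
  s <- sim_spikes(seed = 3L)
  calls <- call_stall_sites(s$pc, "Val", "Ctrl")
  sites <- calls[passes == TRUE]
  truth_keys <- s$truth$stalls[, paste(transcript_id, codon_position)]
  called_keys <- sites[, paste(transcript_id, codon_position)]
  recall <- mean(truth_keys %in% called_keys)
  precision <- mean(called_keys %in% truth_keys)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # every emitted site satisfies the full conjunction
  expect_true(all(sites$log2fc_rpm > 2 & sites$log2fc_norm > 2 &
                  sites$fc_gene_mean > 1 & sites$p < 0.05))
  # 2.5x spikes (log2FC ~ 1.32 < 2) are never called regardless of p
  s2 <- sim_spikes(stall_fold = 2.5, seed = 4L)
  calls2 <- call_stall_sites(s2$pc, "Val", "Ctrl")
  truth2 <- s2$truth$stalls[, paste(transcript_id, codon_position)]
  expect_equal(sum(calls2[paste(transcript_id, codon_position) %in% truth2, passes]), 0L)
})

test_that("calling is invariant to library-size rescaling of one sample", {
  s <- sim_spikes(n_genes = 15L, seed = 5L)
  calls1 <- call_stall_sites(s$pc, "Val", "Ctrl")
  cts <- s$pc$counts[, c("transcript_id", "codon_position", "sample_id", "count")]
  cts[sample_id == "Val_rep1", count := count * 5]
  sm <- copy(s$pc$samples)[, library_size := ifelse(sample_id == "Val_rep1",
                                                    library_size * 5, library_size)]
  pc2 <- normalize_counts(positional_counts(cts, samples = sm))
  calls2 <- call_stall_sites(pc2, "Val", "Ctrl")
  expect_equal(calls2$passes, calls1$passes)
  expect_equal(calls2$log2fc_rpm, calls1$log2fc_rpm, tolerance = 1e-12)
})

test_that("codon context counts queried codons around planted sites", {
  body <- rep("GCC", 96)
  body[c(20, 40, 60)] <- "GTT"
  body[21] <- "ATT"   # Ile codon one downstream of the first site
  tx <- toy_tx(list(body))
  sites <- data.table(transcript_id = "tx1", codon_position = c(20L, 40L, 60L))
  ctx <- stall_codon_context(sites, tx, codon_family("Val"), halfwidth_nt = 50)
  expect_equal(ctx$profile[offset == 0 & codon == "GTT", count], 3L)
  expect_equal(ctx$proportion_containing, 1)
  expect_equal(ctx$n_windows, 3L)
  ile <- stall_codon_context(sites, tx, codon_family("Ile"))
  expect_equal(ile$profile[offset == 1 & codon == "ATT", count], 1L)
  # absent codons give proportion 0
  none <- stall_codon_context(sites, tx, "TGG")
  expect_equal(none$proportion_containing, 0)
  # window crossing the CDS start is truncated, not padded
  early <- stall_codon_context(data.table(transcript_id = "tx1", codon_position = 2L),
                               tx, "ATG")
  expect_equal(early$profile[offset == -2 & codon == "ATG", count], 1L)
  expect_equal(sum(early$profile[offset < -2, count]), 0L)
  # empty input -> empty profile
  empty <- stall_codon_context(sites[0], tx, "GTT")
  expect_equal(empty$n_windows, 0L)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # worked example: N=10, |A|=5, |B|=4, k=4 -> 5/210
  r <- stall_overlap(letters[1:5], letters[2:5], 10)
  expect_equal(r$overlap, 4L)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  # k = 0 and forced-overlap edge cases
  expect_equal(stall_overlap(letters[1:3], letters[4:6], 10)$p, 1)
  expect_equal(stall_overlap(letters[1:10], letters[1:4], 10)$p, 1)
  expect_error(stall_overlap(letters[1:5], letters[1:2], 3), "exceeds")
  # full enumeration oracle for all N <= 12
  for (N in c(5, 8, 12)) {
    for (K in 0:N) for (n in 0:N) {
      ks <- max(0, K + n - N):min(K, n)
      for (k in ks) {
        impl <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        expect_lt(abs(impl - enum_hyper_upper(N, K, n, k)), 1e-12)
      }
    }
  }
})

test_that("stall-site metagene and first-site distances behave as specified", {
  tx <- toy_tx(list(rep("GCC", 98), rep("GCA", 98)))
  sites <- data.table(transcript_id = "tx1", codon_position = 0L, condition = "Val")
  mg <- stall_site_metagene(sites, tx, n_bins = 50L)
  expect_equal(mg$bin, 1L)
  expect_equal(mg$density, 1)
  expect_equal(nrow(stall_site_metagene(sites[0], tx)), 0L)
  # uniform sites -> roughly flat histogram
  set.seed(6)
  usites <- data.table(transcript_id = "tx2",
                       codon_position = sample(0:99, 5000, replace = TRUE),
                       condition = "Val")
  mgu <- stall_site_metagene(usites, tx, n_bins = 10L)
  expect_gt(suppressWarnings(chisq.test(mgu$count)$p.value), 0.001)

  a <- data.table(transcript_id = c("tx1", "tx1", "tx2"), codon_position = c(50L, 70L, 5L))
  b <- data.table(transcript_id = c("tx1", "tx3"), codon_position = c(10L, 2L))
  d <- first_site_distance(a, b)
  expect_equal(d$transcript_id, "tx1")  # tx2/tx3 lack sites in the other set
  expect_equal(d$distance, 40L)
  expect_equal(first_site_distance(a, a)$distance, c(0L, 0L))
})

test_that("stall-proteome enrichment strata and nulls are correct", {
  universe <- sprintf("t%03d", 1:200)
  set.seed(7)
  site_counts <- setNames(rpois(80, 2), universe[1:80])
  down_random <- sample(universe, 30)
  enr <- stall_proteome_enrichment(site_counts, down_random, universe, k_max = 3L)
  expect_equal(enr[k == 0, overlap], 30L)   # k = 0 stratum is the full down set
  expect_equal(enr[k == 0, p], 1)
  # planted enrichment: down proteins drawn from multi-stall transcripts
  multi <- names(site_counts)[site_counts >= 3]
  enr2 <- stall_proteome_enrichment(site_counts, multi, universe, k_max = 3L)
  expect_lt(enr2[k == 3, p], 1e-6)
  expect_true(all(diff(enr2[k > 0, neg_log10_p]) >= 0))  # stronger with k
  expect_error(stall_proteome_enrichment(site_counts, multi, character(0)), "empty universe")
})

test_that("null simulations keep the false-call rate at zero", {
  fp <- vapply(1:5, function(sd) {
    s <- sim_spikes(n_genes = 10L, len = 100L, stall_frac = 0, seed = 100L + sd)
    sum(call_stall_sites(s$pc, "Val", "Ctrl")$passes)
  }, integer(1))
  expect_true(all(fp == 0L))
})
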