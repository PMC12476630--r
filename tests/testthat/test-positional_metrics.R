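test_that("normalisation produces RPM and Norm_RPM with the stated identities", {
  m <- matrix(c(2, 3, 5, 4, 6, 10), ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  pc <- normalize_counts(counts_from_matrix(m))
  expect_equal(pc$counts[sample_id == "s1", norm_rpm], c(0.2, 0.3, 0.5))
  # doubling a sample's counts leaves Norm_RPM unchanged (s2 = 2 * s1)
  expect_equal(pc$counts[sample_id == "s2", norm_rpm],
               pc$counts[sample_id == "s1", norm_rpm])
  # zero library size is fatal
  sm <- sample_meta("s1", "Ctrl", 1, 0)
  cts <- data.table(transcript_id = "tx1", codon_position = 0L,
                    sample_id = "s1", count = 0)
  pc0 <- positional_counts(cts, samples = sm)
  pc0$samples$library_size <- 0
  expect_error(normalize_counts(pc0), "zero library size")
})

test_that("transcript filtering applies both thresholds at their boundaries", {
  tx <- toy_tx(list(rep("GCC", 18), rep("GCC", 18), rep("GCC", 18)))
  mk <- function(id, total, frac_covered) {
    ncov <- round(frac_covered * 20)
    data.table(transcript_id = id, codon_position = seq_len(ncov) - 1L,
               sample_id = "s1", count = total / ncov)
  }
  cts <- rbindlist(list(mk("tx1", 49.9, 1),        # mean total below 50
                        mk("tx2", 100, 0.25),      # coverage below 30%
                        mk("tx3", 100, 0.35)))
  pc <- positional_counts(cts, tx = tx)
  expect_equal(filter_transcripts(pc, tx), "tx3")
  # all-zero transcript excluded by both rules; empty result fatal
  expect_error(filter_transcripts(subset_transcripts(pc, "tx1"), tx), "no transcripts pass")
})

test_that("metagene profile is exactly flat for uniform density", {
  tx <- toy_tx(list(rep("GCC", 198), rep("GCA", 158)))
  cts <- rbindlist(lapply(names(tx), function(id)
    data.table(transcript_id = id, codon_position = 0:(n_codons(tx)[id] - 1L),
               sample_id = "s1", count = 3)))
  pc <- normalize_counts(positional_counts(cts, tx = tx))
  prof <- metagene_profile(pc, tx, exclude_nt = 15, n_bins = 100L)
  expect_equal(nrow(prof), 100L)
  expect_lt(max(abs(prof$mean_density - 1)), 1e-12)
  # transcripts shorter than the trimmed window are skipped
  tx6 <- toy_tx(list(rep("GCC", 4), rep("GCC", 98)))
  cts6 <- rbindlist(lapply(names(tx6), function(id)
    data.table(transcript_id = id, codon_position = 0:(n_codons(tx6)[id] - 1L),
               sample_id = "s1", count = 1)))
  pc6 <- normalize_counts(positional_counts(cts6, tx = tx6))
  expect_warning(metagene_profile(pc6, tx6), "too short")
})

test_that("ramp index reproduces the hand-derived worked example", {
  tx <- toy_tx(list(rep("GCC", 98)))   # 100 codons
  ctrl <- rep(1, 100)
  cond <- c(rep(2, 20), rep(1, 80))
  m <- cbind(Ctrl_rep1 = ctrl, Ctrl_rep2 = ctrl, Val_rep1 = cond, Val_rep2 = cond)
  sm <- sample_meta(colnames(m), c("Ctrl", "Ctrl", "Val", "Val"), c(1, 2, 1, 2))
  pc <- normalize_counts(counts_from_matrix(m, samples = sm))
  ri <- ramp_index(pc, tx, region_fraction = 0.20, control = "Ctrl")
  r5 <- ri$transcripts[condition == "Val", log2_ratio_5][1]
  r3 <- ri$transcripts[condition == "Val", log2_ratio_3][1]
  expect_equal(round(r5, 3), 0.737)
  expect_equal(round(r3, 3), -0.263)
  # identical condition and control -> all ratios zero
  ri0 <- ramp_index(normalize_counts(counts_from_matrix(
    cbind(Ctrl_rep1 = ctrl, Ctrl_rep2 = ctrl, Val_rep1 = ctrl, Val_rep2 = ctrl),
    samples = sm)), tx, control = "Ctrl")
  expect_lt(max(abs(ri0$transcripts$log2_ratio_5)), 1e-12)
  # region_fraction 0.5 partitions the CDS; mirror profile gives swapped sums
  rihalf <- ramp_index(pc, tx, region_fraction = 0.5, control = "Ctrl")
  row <- rihalf$transcripts[condition == "Val"][1]
  expect_equal(row$sum5 + row$sum3, 1)
})

test_that("polarity score matches its closed forms and symmetries", {
  tx <- toy_tx(list(rep("GCC", 8)))    # L = 10
  first <- c(1, rep(0, 9))
  unif <- rep(1, 10)
  m <- cbind(a = first, b = unif)
  sm <- sample_meta(c("a", "b"), c("A", "B"), c(1, 1))
  pc <- counts_from_matrix(m, samples = sm)
  pol <- polarity_score(pc, tx)
  expect_equal(pol[sample_id == "a", polarity], -1)
  expect_equal(pol[sample_id == "b", polarity], 0)
  # L = 4: densities (0.75, 0, 0, 0.25) -> -0.5
  tx4 <- toy_tx(list(rep("GCC", 2)))
  pc4 <- counts_from_matrix(cbind(s1 = c(0.75, 0, 0, 0.25)),
                            samples = sample_meta("s1", "A", 1))
  expect_equal(polarity_score(pc4, tx4)$polarity, -0.5)
  # antisymmetry under reversal, boundedness (random densities)
  set.seed(44)
  for (i in 1:20) {
    d <- runif(10)
    p1 <- polarity_score(counts_from_matrix(cbind(s1 = d),
                                            samples = sample_meta("s1", "A", 1)), tx)
    p2 <- polarity_score(counts_from_matrix(cbind(s1 = rev(d)),
                                            samples = sample_meta("s1", "A", 1)), tx)
    expect_equal(p1$polarity, -p2$polarity, tolerance = 1e-12)
    expect_lte(abs(p1$polarity), 1)
  }
})

test_that("delta-polarity test applies the threshold conjunction", {
  mk_pol <- function(ctrl, cond) {
    rbindlist(list(
      data.table(transcript_id = "tx1", sample_id = sprintf("Ctrl_rep%d", 1:3),
                 polarity = ctrl),
      data.table(transcript_id = "tx1", sample_id = sprintf("Val_rep%d", 1:3),
                 polarity = cond)))
  }
  sm <- sample_meta(c(sprintf("Ctrl_rep%d", 1:3), sprintf("Val_rep%d", 1:3)),
                    rep(c("Ctrl", "Val"), each = 3), rep(1:3, 2))
  set.seed(45)
  # planted delta = -0.3, replicate sd 0.02 -> selected
  r1 <- delta_polarity_test(mk_pol(rnorm(3, 0, 0.02), rnorm(3, -0.3, 0.02)), sm)
  expect_true(r1$significant)
  # delta = -0.10: beyond alpha but above the cut -> never selected
  r2 <- delta_polarity_test(mk_pol(rnorm(3, 0, 0.001), rnorm(3, -0.1, 0.001)), sm)
  expect_false(r2$significant)
  expect_lt(r2$p, 0.05)   # significant p alone is not enough
  # identical replicates -> nothing selected
  r3 <- delta_polarity_test(mk_pol(c(0.1, 0.12, 0.11), c(0.1, 0.12, 0.11)), sm)
  expect_false(r3$significant)
  sm1 <- sample_meta(c("Ctrl_rep1", "Val_rep1"), c("Ctrl", "Val"), c(1, 1))
  expect_error(delta_polarity_test(mk_pol(0, 0)[sample_id %in% sm1$sample_id],
                                   sm1), "2 replicates")
})

test_that("codon-window enrichment is null for identical groups", {
  cfg <- sim_config(n_genes = 10L, length_range = c(120L, 120L),
                    conditions = "Ctrl", condition_effects = list(),
                    n_replicates = 2L, noise = "poisson", library_size = 2e5,
                    seed = 46L)
  mt <- make_transcriptome(cfg)
  sim <- simulate_footprints(mt$tx, cfg)
  pc <- normalize_counts(sim$counts)
  # compare the condition against itself
  prof <- codon_window_enrichment(pc, mt$tx, "GTT", condition = "Ctrl",
                                  control = "Ctrl")
  expect_lt(max(abs(prof$mean_log2_relative)), 1e-12)
  expect_equal(nrow(prof), 2 * 16 + 1)
  expect_warning(codon_window_enrichment(pc, mt$tx, "NNN", "Ctrl", "Ctrl"),
                 "no windowed occurrences")
})

test_that("planted density increase shows up at the queried codon offset", {
  # one transcript, 4x density exactly at GTT positions in the condition
  body <- rep("GCC", 118); body[c(30, 60, 90)] <- "GTT"
  tx <- toy_tx(list(body))
  base <- rep(10, 120)
  cond <- base; cond[c(30, 60, 90) + 1] <- 40
  m <- cbind(Ctrl_rep1 = base, Ctrl_rep2 = base, Val_rep1 = cond, Val_rep2 = cond)
  sm <- sample_meta(colnames(m), c("Ctrl", "Ctrl", "Val", "Val"), c(1, 2, 1, 2))
  pc <- normalize_counts(counts_from_matrix(m, samples = sm))
  prof <- codon_window_enrichment(pc, tx, "GTT", "Val", "Ctrl")
  at0 <- prof[offset == 0, mean_log2_relative]
  shoulder <- prof[abs(offset) > 2, mean_log2_relative]
  # closed form: condition total 1290 vs control 1200; transcript pseudocount
  # is half the smallest nonzero Norm_RPM (10/1290 here); the whole profile
  # carries the renormalisation constant log2(1200/1290)
  ps <- (10 / 1290) / 2
  exp0 <- log2((40 / 1290 + ps) / (10 / 1200 + ps))
  exps <- log2((10 / 1290 + ps) / (10 / 1200 + ps))
  expect_equal(at0, exp0, tolerance = 1e-6)
  expect_lt(max(abs(shoulder - exps)), 1e-6)
})

test_that("region codon-frequency shift recovers a constructed enrichment", {
  set.seed(47)
  mk_body <- function(p_gtt) {
    vapply(seq_len(118), function(i) {
      if (i <= 24 && runif(1) < p_gtt) "GTT" else sample(setdiff(sense_codons(), "GTT"), 1)
    }, "")
  }
  bg_tx <- toy_tx(replicate(40, mk_body(0.15), simplify = FALSE))
  sel_bodies <- replicate(40, mk_body(0.30), simplify = FALSE)
  all_tx <- toy_tx(c(lapply(names(bg_tx), function(id) bg_tx[[id]]$codons[2:119]),
                     sel_bodies))
  sel_ids <- names(all_tx)[41:80]
  bg_ids <- names(all_tx)[1:40]
  res <- region_codon_frequency_shift(all_tx, sel_ids, bg_ids)
  expect_equal(res[codon == "GTT", log2fc], 1, tolerance = 0.35)
  expect_lt(res[codon == "GTT", p_adj], 0.05)
  # identical singleton sets: log2fc 0, p missing
  res1 <- region_codon_frequency_shift(all_tx, bg_ids[1], bg_ids[1])
  expect_equal(res1[codon == "GTT", log2fc], 0)
  expect_true(is.na(res1[codon == "GTT", p]))
  expect_error(region_codon_frequency_shift(all_tx, character(0), bg_ids),
               "non-empty")
})
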