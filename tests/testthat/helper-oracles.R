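# Shared fixtures and independent oracles, built in code at test time.

library(data.table)

# upper-tail hypergeometric P(X >= k) by direct enumeration (oracle for
# stall_overlap; independent of stats::phyper)
enum_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# fixed-step RK4 integration of dP/dt = s*sigma - k*P from steady state
# P(0) = sigma/k (oracle for predict_log2fc)
rk4_log2fc <- function(t, t_half, s, n_steps = 20000L) {
  k <- log(2) / t_half
  sigma <- 1
  P <- sigma / k
  h <- t / n_steps
  f <- function(P) s * sigma - k * P
  for (i in seq_len(n_steps)) {
    k1 <- f(P); k2 <- f(P + h / 2 * k1); k3 <- f(P + h / 2 * k2); k4 <- f(P + h * k3)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  log2(P / (sigma / k))
}

# tiny deterministic transcriptome: bodies chosen so every codon window is
# well-defined; ids tx1..txN
toy_tx <- function(bodies) {
  seqs <- vapply(bodies, function(b) paste0(c("ATG", b, "TAA"), collapse = ""), "")
  names(seqs) <- sprintf("tx%d", seq_along(bodies))
  transcriptome(seqs)
}

# dense counts table for one or more samples from a matrix [position x sample]
counts_from_matrix <- function(m, transcript_id = "tx1", samples = NULL) {
  dt <- rbindlist(lapply(seq_len(ncol(m)), function(j)
    data.table(transcript_id = transcript_id,
               codon_position = seq_len(nrow(m)) - 1L,
               sample_id = colnames(m)[j], count = m[, j])))
  positional_counts(dt[count > 0 | TRUE], samples = samples)
}
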