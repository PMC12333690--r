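# Shared fixtures built in code.

# the canonical two-exon toy used in coordinate hand-walks
two_exon_model <- function(strand = "+", cds = NULL) {
  transcript_model("tx1", "g1", "chr1", strand,
                   rbind(c(100, 200), c(300, 400)), cds_span = cds)
}

# random multi-exon model for property tests
random_model <- function(id = "txr", coding = TRUE) {
  n_ex <- sample(1:8, 1)
  widths <- sample(30:300, n_ex, replace = TRUE)
  gaps <- sample(50:500, n_ex, replace = TRUE)
  starts <- 1000 + cumsum(gaps) + cumsum(c(0, widths[-n_ex]))
  exons <- cbind(starts, starts + widths)
  L <- sum(widths)
  cds <- NULL
  if (coding && L >= 30) {
    s <- sample.int(max(1, floor(L / 3)), 1)
    e <- s + sample.int(L - s - 1, 1)
    cds <- c(s, e)
  }
  transcript_model(id, "gr", "chrX", sample(c("+", "-"), 1), exons, cds_span = cds)
}

# a small catalog built from hand-authored calls via the real consensus path
toy_catalog <- function(calls_df, models) {
  suppressMessages(build_consensus(calls_df, models))
}

# hand-authored call rows with sensible defaults
call_row <- function(sample_id, region, transcript_id, tx_pos, prob_mod,
                     mod_ratio, n_reads = 50, kmer = "GGACT") {
  data.frame(sample_id = sample_id, region = region,
             transcript_id = transcript_id, tx_pos = tx_pos,
             n_reads = n_reads, prob_mod = prob_mod, kmer = kmer,
             mod_ratio = mod_ratio, stringsAsFactors = FALSE)
}

# a small but complete simulated experiment reused across files
small_sim <- function(seed = 5, ...) {
  run_simulation(sim_config(seed = seed, n_genes = 30, ...))
}
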