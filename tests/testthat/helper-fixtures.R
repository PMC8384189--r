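# Small configurations reused across tests. Kept deliberately tiny so the
# whole suite stays fast; anything statistical that needs size builds its
# own config.

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_genes_exp = 30L, n_genes_spike = 10L,
                   chrom_sizes = c(chrI = 200000L),
                   spike_chrom_sizes = c(spike_I = 80000L),
                   n_fragments = 2000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# a hand-rolled de_result table for gene-set tests
toy_de <- function(gene_id, log2fc, padj) {
  df <- data.frame(gene_id = gene_id, baseMean = 100, log2fc = log2fc,
                   se = 0.1, stat = log2fc / 0.1,
                   pvalue = padj, padj = padj, status = "tested",
                   stringsAsFactors = FALSE)
  class(df) <- c("de_result", "data.frame")
  df
}

# brute-force per-bp window sum oracle: value of the covering bin / bin
# size, summed over every bp of the (clipped) window
brute_force_window <- function(track, chrom, start, end) {
  v <- track$bins[[chrom]]
  L <- track$chrom_sizes[[chrom]]
  b <- track$bin_size
  bp <- seq.int(max(0, start), min(end, L) - 1L)
  if (!length(bp)) return(0)
  sum(v[bp %/% b + 1L] / b)
}
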