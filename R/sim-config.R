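#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_annotation()], [simulate_counts()] and [simulate_fragments()].
#' The defaults describe a desk-scale stand-in for a yeast nascent-RNA /
#' ChEC-seq experiment: a few hundred experimental genes on two chromosomes,
#' a spike-in genome on separate chromosomes (distinguished by chromosome
#' name prefix), negative-binomial counts with per-sample depth factors, and
#' cleavage fragments with a bimodal length distribution whose short mode
#' sits at or below 80 bp.
#'
#' @param seed Integer master seed. All randomness in the generators is
#'   derived from it through named child streams (see [child_seed()]), so
#'   adding a sample or a factor does not perturb previously generated data.
#' @param n_genes_exp,n_genes_spike Number of experimental and spike-in genes.
#' @param chrom_sizes Named integer vector of experimental chromosome sizes
#'   (bp).
#' @param spike_chrom_sizes Named integer vector of spike-in chromosome
#'   sizes; names must carry `spike_prefix`.
#' @param spike_prefix Chromosome-name prefix identifying the spike-in
#'   genome. Organism assignment of genes and fragments is by chromosome
#'   name, never by alignment.
#' @param conditions Character vector of exactly two condition labels
#'   (reference first).
#' @param replicates_per_condition Replicates per condition.
#' @param base_abundance Optional per-gene positive expected counts
#'   \eqn{q_i} (experimental then spike-in genes). Drawn log-normally
#'   (meanlog `log(100)`, sdlog 1) when `NULL`.
#' @param true_log2fc Optional per-gene true log2 fold changes for the
#'   experimental genes. When `NULL`, a fraction `frac_de` of experimental
#'   genes receives `lfc_magnitude`, negative for CR-class genes and
#'   positive for TFIID-class genes (the down-in-CR / up-in-TFIID pattern
#'   characteristic of Mediator tail disruption). Spike-in genes always have
#'   log2 fold change 0.
#' @param frac_de Fraction of experimental genes with a true effect.
#' @param lfc_magnitude Absolute true log2 fold change of affected genes.
#' @param dispersion Per-gene NB dispersion \eqn{\alpha_i} (recycled), with
#'   variance \eqn{\mu + \alpha \mu^2}.
#' @param depth_factors Optional per-sample depth factors \eqn{d_j}
#'   (length `conditions * replicates`); log-normal (sdlog 0.3) when `NULL`.
#' @param spikein_fraction Fraction of cleavage fragments assigned to the
#'   spike-in genome. The default 0.2 emulates a 1:4 spike-in to
#'   experimental mixing ratio.
#' @param class_fractions Named numeric vector with elements `CR`, `TFIID`
#'   and `unannotated` summing to 1; gene-class label proportions.
#' @param tata_prob Named numeric vector giving the probability of a TATA
#'   box per class.
#' @param gene_length_range Min/max simulated gene length (bp).
#' @param flank Minimum intergenic flank (bp) kept free on both sides of
#'   every gene.
#' @param uas_offset,uas_width Geometry of the upstream activating sequence
#'   (UAS) window where a bound factor cleaves: the window spans
#'   `[TSS - uas_offset - uas_width, TSS - uas_offset)` on the plus strand
#'   (mirrored on minus).
#' @param tes_background_boost Multiplier for free-MNase background density
#'   inside the nucleosome-depleted TES regions.
#' @param uas_signal_weight Probability that a `bound_factor` (or
#'   `tbp_like`) experimental-genome fragment comes from the targeted
#'   signal component rather than uniform background.
#' @param tbp_offset Fixed promoter offset (bp, relative to TSS, negative =
#'   upstream) at which `tbp_like` fragments centre.
#' @param tbp_jitter Standard deviation (bp) of the Gaussian jitter around
#'   `tbp_offset`.
#' @param fraglen_mix Data frame with columns `component`, `weight`, `mean`,
#'   `sd`, `min`, `max` describing the fragment-length mixture. One
#'   component must have `max <= 80` (the protected-footprint mode).
#' @param n_fragments Fragments generated per sample by
#'   [simulate_fragments()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_exp = 200L,
                       n_genes_spike = 50L,
                       chrom_sizes = c(chrI = 500000L, chrII = 500000L),
                       spike_chrom_sizes = c(spike_I = 200000L),
                       spike_prefix = "spike_",
                       conditions = c("ctrl", "depleted"),
                       replicates_per_condition = 3L,
                       base_abundance = NULL,
                       true_log2fc = NULL,
                       frac_de = 0.1,
                       lfc_magnitude = 1,
                       dispersion = 0.05,
                       depth_factors = NULL,
                       spikein_fraction = 0.2,
                       class_fractions = c(CR = 0.2, TFIID = 0.65,
                                           unannotated = 0.15),
                       tata_prob = c(CR = 0.8, TFIID = 0.1,
                                     unannotated = 0.3),
                       gene_length_range = c(500L, 2500L),
                       flank = 1000L,
                       uas_offset = 100L,
                       uas_width = 200L,
                       tes_background_boost = 2,
                       uas_signal_weight = 0.6,
                       tbp_offset = -60L,
                       tbp_jitter = 10,
                       fraglen_mix = default_fraglen_mix(),
                       n_fragments = 50000L) {
  # tolerate list-valued fields (e.g. a config read back from YAML)
  chrom_sizes <- unlist(chrom_sizes)
  spike_chrom_sizes <- unlist(spike_chrom_sizes)
  conditions <- unlist(conditions)
  if (is.list(base_abundance)) base_abundance <- unlist(base_abundance)
  if (is.list(true_log2fc)) true_log2fc <- unlist(true_log2fc)
  if (is.list(dispersion)) dispersion <- unlist(dispersion)
  if (is.list(depth_factors)) depth_factors <- unlist(depth_factors)
  if (is.list(fraglen_mix) && !is.data.frame(fraglen_mix))
    fraglen_mix <- as.data.frame(lapply(fraglen_mix, unlist),
                                 stringsAsFactors = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    n_genes_exp = as.integer(n_genes_exp),
    n_genes_spike = as.integer(n_genes_spike),
    chrom_sizes = chrom_sizes,
    spike_chrom_sizes = spike_chrom_sizes,
    spike_prefix = spike_prefix,
    conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    base_abundance = base_abundance,
    true_log2fc = true_log2fc,
    frac_de = frac_de,
    lfc_magnitude = lfc_magnitude,
    dispersion = dispersion,
    depth_factors = depth_factors,
    spikein_fraction = spikein_fraction,
    class_fractions = class_fractions,
    tata_prob = tata_prob,
    gene_length_range = as.integer(gene_length_range),
    flank = as.integer(flank),
    uas_offset = as.integer(uas_offset),
    uas_width = as.integer(uas_width),
    tes_background_boost = tes_background_boost,
    uas_signal_weight = uas_signal_weight,
    tbp_offset = as.integer(tbp_offset),
    tbp_jitter = tbp_jitter,
    fraglen_mix = fraglen_mix,
    n_fragments = as.integer(n_fragments)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default fragment-length mixture
#'
#' Two truncated-normal components: a short protected-footprint mode capped
#' at 80 bp and a longer nucleosome-scale mode.
#'
#' @return Data frame with columns `component`, `weight`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
default_fraglen_mix <- function() {
  data.frame(
    component = c("short", "long"),
    weight = c(0.3, 0.7),
    mean = c(60, 150),
    sd = c(10, 25),
    min = c(25, 81),
    max = c(80, 250),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$n_genes_exp < 0L || cfg$n_genes_spike < 0L)
    stop("gene counts must be non-negative")
  if (length(cfg$conditions) != 2L)
    stop("exactly two condition labels are required")
  if (any(cfg$chrom_sizes <= 0L) || any(cfg$spike_chrom_sizes <= 0L))
    stop("chromosome sizes must be positive")
  if (!all(startsWith(names(cfg$spike_chrom_sizes), cfg$spike_prefix)))
    stop("spike-in chromosome names must carry the spike prefix")
  if (any(startsWith(names(cfg$chrom_sizes), cfg$spike_prefix)))
    stop("experimental chromosome names must not carry the spike prefix")
  if (cfg$spikein_fraction < 0 || cfg$spikein_fraction > 1)
    stop("spikein_fraction must lie in [0, 1]")
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (!is.null(cfg$base_abundance) && any(cfg$base_abundance <= 0))
    stop("base_abundance must be positive")
  if (any(cfg$dispersion < 0))
    stop("dispersion must be non-negative")
  if (!is.null(cfg$depth_factors) && any(cfg$depth_factors <= 0))
    stop("depth_factors must be positive")
  fm <- cfg$fraglen_mix
  need <- c("component", "weight", "mean", "sd", "min", "max")
  if (!all(need %in% names(fm)))
    stop("fraglen_mix must have columns ", paste(need, collapse = ", "))
  if (any(fm$weight < 0) || sum(fm$weight) <= 0)
    stop("fraglen_mix weights must be non-negative and not all zero")
  if (!any(fm$max <= 80))
    stop("fraglen_mix must contain a component with max <= 80 bp")
  invisible(cfg)
}

#' Derive a deterministic child seed from a master seed and a stream name
#'
#' Every random stream in the generators (one per sample, per factor, ...)
#' is seeded independently so that regenerating one stream, or appending new
#' ones, never changes the others. The mapping hashes the stream name and
#' folds in the master seed; the result always fits a 32-bit signed integer.
#'
#' @param seed Integer master seed.
#' @param stream Character stream identifier, e.g. `"counts/ctrl_1"`.
#' @return A positive integer seed.
#' @export
child_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147483647
  out <- (h + (as.double(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer(out) + 1L
}

#' All sample identifiers implied by a configuration
#'
#' @param cfg A `sim_config`.
#' @return Character vector `<condition>_<replicate>` in condition-major
#'   order.
#' @export
sample_ids <- function(cfg) {
  as.vector(t(outer(cfg$conditions, seq_len(cfg$replicates_per_condition),
                    paste, sep = "_")))
}

#' Condition label of each sample
#'
#' @param cfg A `sim_config`.
#' @return Character vector parallel to [sample_ids()].
#' @export
sample_conditions <- function(cfg) {
  rep(cfg$conditions, each = cfg$replicates_per_condition)
}
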