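#' Simulate cleavage fragments for one ChEC-seq style sample
#'
#' Generates exactly `config$n_fragments` paired-end fragment spans for one
#' of three factor archetypes:
#'
#' * `bound_factor` — a UAS-bound factor: with probability
#'   `uas_signal_weight` a fragment midpoint falls uniformly inside the
#'   strand-aware UAS window of a random target gene, otherwise uniformly
#'   on the experimental genome (free-MNase-like background).
#' * `free_mnase` — background only, with density boosted by
#'   `tes_background_boost` inside the nucleosome-depleted TES regions
#'   (500 bp centred on each TES).
#' * `tbp_like` — a TATA-binding-protein-like footprint: signal fragments
#'   are short (drawn from the <= 80 bp mixture component only) and centre
#'   at `tbp_offset` bp from the TSS (strand-aware, Gaussian jitter
#'   `tbp_jitter`), atop uniform background.
#'
#' A fraction `spikein_fraction` of fragments (Bernoulli per fragment) is
#' placed uniformly on the spike-in chromosomes regardless of factor.
#' Fragment lengths come from `config$fraglen_mix`; fragments protruding
#' past a chromosome end are clipped and counted in the `n_clipped`
#' attribute. Fragment midpoints are integers with the convention
#' `midpoint = start + length %/% 2`; a signal fragment's midpoint equals
#' its drawn position exactly, so window-membership checks are exact.
#'
#' @param annotation A `gene_annotation`.
#' @param config A [sim_config()].
#' @param factor One of `"bound_factor"`, `"free_mnase"`, `"tbp_like"`.
#' @param sample_id Sample label stored with the fragments (also names the
#'   random stream, so each sample is independently reproducible).
#' @param target_genes Optional character vector of gene ids receiving
#'   signal (defaults to all experimental genes).
#' @return A `fragment_set`: data frame with columns `chrom`, `start`,
#'   `end`, `length`, `sample_id`, `organism`, plus attributes `n_clipped`
#'   and `factor`.
#' @export
simulate_fragments <- function(annotation, config,
                               factor = c("bound_factor", "free_mnase",
                                          "tbp_like"),
                               sample_id = factor,
                               target_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  factor <- match.arg(factor)
  n <- config$n_fragments
  set.seed(child_seed(config$seed,
                      paste0("fragments/", factor, "/", sample_id)))

  exp_ann <- annotation[annotation$organism == "experimental", , drop = FALSE]
  if (is.null(target_genes)) target_genes <- exp_ann$gene_id
  targets <- exp_ann[exp_ann$gene_id %in% target_genes, , drop = FALSE]

  is_spike <- stats::runif(n) < config$spikein_fraction

  # lengths: tbp_like signal fragments use only the short (<= 80 bp) mode
  len_all <- draw_fraglen(n, config$fraglen_mix)
  is_signal <- !is_spike &
    stats::runif(n) < switch(factor,
                             bound_factor = config$uas_signal_weight,
                             free_mnase = 0,
                             tbp_like = config$uas_signal_weight)
  if (factor == "tbp_like" && any(is_signal)) {
    short <- config$fraglen_mix[config$fraglen_mix$max <= 80, , drop = FALSE]
    len_all[is_signal] <- draw_fraglen(sum(is_signal), short)
  }

  chrom <- character(n)
  mid <- numeric(n)

  if (any(is_spike)) {
    pos <- sample_uniform_genome(sum(is_spike), config$spike_chrom_sizes)
    chrom[is_spike] <- pos$chrom
    mid[is_spike] <- pos$pos
  }

  bg <- !is_spike & !is_signal
  if (any(bg)) {
    if (factor == "free_mnase" && config$tes_background_boost != 1 &&
        nrow(targets)) {
      pos <- sample_background_tes_boost(sum(bg), exp_ann, config)
    } else {
      pos <- sample_uniform_genome(sum(bg), config$chrom_sizes)
    }
    chrom[bg] <- pos$chrom
    mid[bg] <- pos$pos
  }

  if (any(is_signal)) {
    if (nrow(targets) == 0L)
      stop("no target genes available for factor signal")
    gi <- sample.int(nrow(targets), sum(is_signal), replace = TRUE)
    if (factor == "bound_factor") {
      win <- uas_window(targets, config)
      mid[is_signal] <- win$start[gi] +
        floor(stats::runif(sum(is_signal)) * (win$end[gi] - win$start[gi]))
    } else { # tbp_like
      sgn <- ifelse(targets$strand == "+", 1, -1)
      mid[is_signal] <- targets$tss[gi] + sgn[gi] * config$tbp_offset +
        stats::rnorm(sum(is_signal), 0, config$tbp_jitter)
    }
    chrom[is_signal] <- targets$chrom[gi]
  }

  # integer midpoint convention: midpoint of a fragment = start + len %/% 2,
  # so a signal fragment's midpoint equals its drawn (integer) position
  mid <- round(mid)
  start <- as.integer(mid - len_all %/% 2L)
  end <- start + len_all
  sizes <- c(config$chrom_sizes, config$spike_chrom_sizes)
  lim <- sizes[chrom]
  clipped <- start < 0L | end > lim
  start <- pmax(start, 0L)
  end <- as.integer(pmin(end, lim))
  bad <- end <= start # fully off-chromosome windows collapse; keep 1 bp
  if (any(bad)) {
    start[bad] <- pmax(0L, pmin(start[bad], lim[bad] - 1L))
    end[bad] <- start[bad] + 1L
  }

  frags <- data.frame(chrom = chrom, start = start, end = end,
                      length = end - start,
                      sample_id = sample_id,
                      organism = ifelse(
                        startsWith(chrom, config$spike_prefix),
                        "spikein", "experimental"),
                      stringsAsFactors = FALSE)
  class(frags) <- c("fragment_set", "data.frame")
  attr(frags, "n_clipped") <- sum(clipped)
  attr(frags, "factor") <- factor
  if (sum(clipped))
    message(sum(clipped), " fragment(s) clipped at chromosome edges")
  frags
}

draw_fraglen <- function(n, mix) {
  if (n == 0L) return(integer(0))
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  len <- round(stats::rnorm(n, mix$mean[comp], mix$sd[comp]))
  as.integer(pmin(pmax(len, mix$min[comp]), mix$max[comp]))
}

sample_uniform_genome <- function(n, chrom_sizes) {
  ci <- sample.int(length(chrom_sizes), n, replace = TRUE,
                   prob = chrom_sizes)
  list(chrom = names(chrom_sizes)[ci],
       pos = stats::runif(n) * chrom_sizes[ci])
}

# Uniform background with extra mass in TES regions: choose the boosted TES
# compartment with probability proportional to its excess length, else fall
# back to the uniform genome.
sample_background_tes_boost <- function(n, exp_ann, config) {
  tes <- tesr_window(exp_ann, 500L)
  tes_len <- sum(tes$end - tes$start)
  genome_len <- sum(config$chrom_sizes)
  extra <- tes_len * (config$tes_background_boost - 1)
  p_extra <- extra / (genome_len + extra)
  in_tes <- stats::runif(n) < p_extra
  chrom <- character(n)
  pos <- numeric(n)
  if (any(in_tes)) {
    wi <- sample.int(nrow(tes), sum(in_tes), replace = TRUE,
                     prob = tes$end - tes$start)
    chrom[in_tes] <- tes$chrom[wi]
    pos[in_tes] <- tes$start[wi] +
      stats::runif(sum(in_tes)) * (tes$end[wi] - tes$start[wi])
  }
  if (any(!in_tes)) {
    u <- sample_uniform_genome(sum(!in_tes), config$chrom_sizes)
    chrom[!in_tes] <- u$chrom
    pos[!in_tes] <- u$pos
  }
  list(chrom = chrom, pos = pos)
}
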