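#' Simulate a gene annotation with experimental and spike-in genes
#'
#' Places non-overlapping genes on the configured chromosomes, keeping at
#' least `cfg$flank` bp free on both sides of every gene so that upstream
#' (UAS) and TES windows of neighbouring genes never collide. Genes are
#' distributed across chromosomes proportionally to chromosome size;
#' strands are random. Experimental genes receive coactivator-class labels
#' (`CR`, `TFIID`, `unannotated`) and TATA flags with the configured
#' probabilities; spike-in genes live on the spike chromosomes, are tagged
#' `organism = "spikein"` and always carry a true log2 fold change of 0.
#'
#' All coordinates are 0-based half-open. The transcription start site
#' (TSS) is `start` on the plus strand and `end - 1` on the minus strand;
#' the transcription end site (TES) is the opposite extremity.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `tes`, `organism`, `class`,
#'   `tata`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  exp_ann <- place_genes(
    n = config$n_genes_exp,
    chrom_sizes = config$chrom_sizes,
    id_prefix = "gene",
    config = config,
    stream = "annotation/experimental"
  )
  spike_ann <- place_genes(
    n = config$n_genes_spike,
    chrom_sizes = config$spike_chrom_sizes,
    id_prefix = "spike",
    config = config,
    stream = "annotation/spikein"
  )
  if (nrow(exp_ann)) {
    exp_ann$organism <- "experimental"
    set.seed(child_seed(config$seed, "annotation/labels"))
    cls <- sample(names(config$class_fractions), nrow(exp_ann),
                  replace = TRUE, prob = config$class_fractions)
    exp_ann$class <- cls
    exp_ann$tata <- stats::runif(nrow(exp_ann)) < config$tata_prob[cls]
  } else {
    exp_ann$organism <- character(0)
    exp_ann$class <- character(0)
    exp_ann$tata <- logical(0)
  }
  if (nrow(spike_ann)) {
    spike_ann$organism <- "spikein"
    spike_ann$class <- "unannotated"
    spike_ann$tata <- FALSE
  } else {
    spike_ann$organism <- character(0)
    spike_ann$class <- character(0)
    spike_ann$tata <- logical(0)
  }
  ann <- rbind(exp_ann, spike_ann)
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# Sequentially pack genes on each chromosome with >= flank bp gaps, sharing
# leftover space randomly among the gaps.
place_genes <- function(n, chrom_sizes, id_prefix, config, stream) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0),
                      tes = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  set.seed(child_seed(config$seed, stream))
  # proportional allocation, largest-remainder rounding
  share <- chrom_sizes / sum(chrom_sizes)
  alloc <- floor(share * n)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(share * n - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  out <- vector("list", length(chrom_sizes))
  for (k in seq_along(chrom_sizes)) {
    nk <- alloc[k]
    if (nk == 0L) next
    L <- chrom_sizes[k]
    lens <- as.integer(round(stats::runif(
      nk, config$gene_length_range[1], config$gene_length_range[2])))
    required <- sum(lens) + (nk + 1L) * config$flank
    if (required > L)
      stop("cannot place ", nk, " genes on chromosome '",
           names(chrom_sizes)[k], "' (", L, " bp, ", required,
           " bp required)")
    slack <- L - required
    # split the slack into nk + 1 random extra gap lengths
    cuts <- sort(stats::runif(nk))
    extra <- diff(c(0, cuts, 1)) * slack
    gaps <- config$flank + extra # nk + 1 gaps; the last trails the genes
    starts <- as.integer(floor(cumsum(gaps[seq_len(nk)]) +
                                 cumsum(c(0, lens[-nk]))))
    ends <- starts + lens
    strand <- sample(c("+", "-"), nk, replace = TRUE)
    out[[k]] <- data.frame(
      chrom = names(chrom_sizes)[k], start = starts, end = ends,
      strand = strand, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  ann$gene_id <- sprintf("%s_%04d", id_prefix, seq_len(nrow(ann)))
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann$tes <- ifelse(ann$strand == "+", ann$end - 1L, ann$start)
  ann[, c("gene_id", "chrom", "start", "end", "strand", "tss", "tes")]
}

#' Strand-aware upstream window of a gene
#'
#' The window covering `len` bp immediately upstream of the TSS:
#' `[tss - len, tss)` on the plus strand and `[tss + 1, tss + 1 + len)` on
#' the minus strand (0-based half-open).
#'
#' @param annotation A `gene_annotation` (or any data frame with `tss` and
#'   `strand`).
#' @param len Window length in bp.
#' @return Data frame with columns `chrom`, `start`, `end` parallel to the
#'   annotation rows (not clipped to chromosome bounds).
#' @export
upstream_window <- function(annotation, len = 500L) {
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - len, annotation$tss + 1L)
  data.frame(chrom = annotation$chrom,
             start = as.integer(start),
             end = as.integer(start + len),
             stringsAsFactors = FALSE)
}

#' TES-region window of a gene
#'
#' The window of `len` bp centred on the TES: `[tes - len/2, tes + len/2)`
#' for plus-strand genes and its strand mirror
#' `[tes - len/2 + 1, tes + len/2 + 1)` for minus-strand genes, so that a
#' minus-strand gene mirrored from a plus-strand gene has the exactly
#' mirrored window.
#'
#' @inheritParams upstream_window
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
tesr_window <- function(annotation, len = 500L) {
  half <- as.integer(len %/% 2)
  shift <- ifelse(annotation$strand == "-", 1L, 0L)
  data.frame(chrom = annotation$chrom,
             start = as.integer(annotation$tes - half + shift),
             end = as.integer(annotation$tes - half + len + shift),
             stringsAsFactors = FALSE)
}

#' UAS window of a gene under a simulation configuration
#'
#' @param annotation A `gene_annotation`.
#' @param config A [sim_config()]; `uas_offset`/`uas_width` set the
#'   geometry.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
uas_window <- function(annotation, config) {
  plus <- annotation$strand == "+"
  start <- ifelse(plus,
                  annotation$tss - config$uas_offset - config$uas_width,
                  annotation$tss + 1L + config$uas_offset)
  data.frame(chrom = annotation$chrom,
             start = as.integer(start),
             end = as.integer(start + config$uas_width),
             stringsAsFactors = FALSE)
}
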