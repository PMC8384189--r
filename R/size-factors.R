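#' Median-of-ratios size factors from spike-in genes
#'
#' Estimates per-sample library size factors from spike-in counts alone,
#' using the median-of-ratios estimator: for each spike-in gene \eqn{i}
#' with an all-positive count row, compute its geometric mean
#' \eqn{g_i = (\prod_j k_{ij})^{1/m}} across the \eqn{m} samples; the size
#' factor of sample \eqn{j} is the median over usable genes of
#' \eqn{k_{ij} / g_i}. Because spike-in material is added at a fixed ratio
#' to every culture, these factors estimate relative library depth free of
#' any genome-wide transcriptional shift in the experimental genome, and
#' can be transferred to the experimental genes of the same samples.
#'
#' Genes containing a zero in any sample have no positive geometric mean
#' and are excluded (no pseudocount). Size factors are reported as raw
#' medians, without rescaling to unit geometric mean; all downstream
#' statistics are invariant to a common rescaling.
#'
#' @param counts Integer matrix of spike-in gene counts (genes x samples),
#'   or a `count_matrix` (its `organism` tag selects the spike-in rows).
#' @return A `size_factors` object: list with `sf` (named positive reals)
#'   and `n_genes_used`.
#' @export
size_factors_median_of_ratios <- function(counts) {
  k <- spike_counts(counts)
  if (nrow(k) < 1L)
    stop("no spike-in gene with positive geometric mean")
  usable <- rowSums(k <= 0) == 0L
  if (!any(usable))
    stop("no spike-in gene with positive geometric mean")
  k <- k[usable, , drop = FALSE]
  g <- exp(rowMeans(log(k)))
  ratios <- k / g
  sf <- apply(ratios, 2, stats::median)
  structure(list(sf = sf, n_genes_used = sum(usable)),
            class = "size_factors")
}

spike_counts <- function(counts) {
  if (inherits(counts, "count_matrix")) {
    org <- counts$organism[rownames(counts$counts)]
    counts$counts[org == "spikein", , drop = FALSE]
  } else {
    as.matrix(counts)
  }
}

#' Apply size factors to a count matrix
#'
#' Divides every column by its size factor: `entry_ij = k_ij / sf_j`.
#'
#' @param counts Matrix (genes x samples) or `count_matrix`.
#' @param sf A `size_factors` object or named numeric vector; names must
#'   cover the sample columns.
#' @param drop_spike Drop spike-in rows from the result (only for
#'   `count_matrix` input).
#' @return Numeric matrix of normalized counts.
#' @export
apply_size_factors <- function(counts, sf, drop_spike = FALSE) {
  if (inherits(sf, "size_factors")) sf <- sf$sf
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  missing <- setdiff(colnames(m), names(sf))
  if (length(missing))
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  if (drop_spike && inherits(counts, "count_matrix")) {
    org <- counts$organism[rownames(norm)]
    norm <- norm[org != "spikein", , drop = FALSE]
  }
  norm
}

#' ChEC spike-in scale factors from fragment counts
#'
#' For coverage tracks, between-sample scaling uses the reciprocal of each
#' sample's spike-in fragment count: `scale_j = C / n_spike_j`, with the
#' constant `C` fixed so that the mean scale across samples is 1. A sample
#' that received proportionally more spike-in fragments (i.e. fewer
#' experimental cleavages per spike-in unit) is scaled down.
#'
#' @param fragments A list of `fragment_set` objects (one per sample), or
#'   a named numeric vector of spike-in fragment counts.
#' @return Named numeric vector of scale factors with mean 1.
#' @export
chec_scale_factors <- function(fragments) {
  if (is.list(fragments) && !is.data.frame(fragments)) {
    n_spike <- vapply(fragments, function(fr)
      sum(fr$organism == "spikein"), numeric(1))
    nm <- names(fragments)
    if (is.null(nm))
      nm <- vapply(fragments, function(fr)
        as.character(fr$sample_id[1]), character(1))
    names(n_spike) <- nm
  } else {
    n_spike <- fragments
  }
  zero <- n_spike <= 0
  if (any(zero))
    stop("no spike-in fragments in sample(s): ",
         paste(names(n_spike)[zero], collapse = ", "))
  inv <- 1 / n_spike
  inv / mean(inv)
}
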