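#' Binned fragment coverage track
#'
#' Each fragment contributes 1 unit of coverage over its full span (cut-end
#' pileup, where only the two 1-bp fragment ends contribute, is available
#' via `use = "cut-ends"`). Per-base coverage is averaged within
#' consecutive bins of `bin_size` bp tiling each chromosome from 0, then
#' normalized:
#'
#' * `"per-million"` / `"CPM"` — multiplied by `1e6 / n_fragments`, so the
#'   track is invariant to uniform duplication of the library;
#' * `"spike-scaled"` — multiplied by the supplied per-sample spike-in
#'   `scale` (see [chec_scale_factors()]);
#' * `"raw"` — no scaling.
#'
#' @param fragments A `fragment_set` (data frame with `chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param chrom_sizes Named chromosome sizes in bp.
#' @param bin_size Bin width in bp (default 10).
#' @param normalization One of `"per-million"`, `"CPM"`, `"spike-scaled"`,
#'   `"raw"`.
#' @param scale Spike-in scale factor (required for `"spike-scaled"`).
#' @param use `"span"` (default) or `"cut-ends"`.
#' @return A `signal_track`: list with `bins` (named list of per-chrom bin
#'   value vectors), `bin_size`, `chrom_sizes`, `normalization`, and an
#'   `n_clipped` attribute counting fragments truncated at chromosome
#'   bounds.
#' @export
fragment_coverage <- function(fragments, chrom_sizes, bin_size = 10L,
                              normalization = c("per-million", "CPM",
                                                "spike-scaled", "raw"),
                              scale = NULL,
                              use = c("span", "cut-ends")) {
  normalization <- match.arg(normalization)
  use <- match.arg(use)
  bin_size <- as.integer(bin_size)
  n_frag <- nrow(fragments)

  if (use == "cut-ends" && n_frag) {
    fragments <- data.frame(
      chrom = rep(fragments$chrom, 2L),
      start = c(fragments$start, fragments$end - 1L),
      end = c(fragments$start + 1L, fragments$end),
      stringsAsFactors = FALSE)
  }

  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("fragments on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))

  n_clipped <- 0L
  bins <- lapply(names(chrom_sizes), function(chrom) {
    L <- as.integer(chrom_sizes[[chrom]])
    nb <- as.integer(ceiling(L / bin_size))
    sub <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (!nrow(sub)) return(numeric(nb))
    s <- pmax(sub$start, 0L)
    e <- pmin(sub$end, L)
    clip <- sum(sub$start < 0L | sub$end > L)
    if (clip) {
      n_clipped <<- n_clipped + clip
      keep <- e > s
      s <- s[keep]; e <- e[keep]
    }
    cov <- IRanges::coverage(IRanges::IRanges(start = s + 1L, end = e),
                             width = L)
    starts <- seq.int(1L, L, by = bin_size)
    ends <- pmin(starts + bin_size - 1L, L)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov, start = starts,
                                                 end = ends)))
  })
  names(bins) <- names(chrom_sizes)
  if (n_clipped)
    warning(n_clipped, " fragment(s) clipped at chromosome bounds")

  factor <- switch(normalization,
                   "per-million" = , "CPM" = {
                     if (n_frag == 0) {
                       warning("empty fragment set; normalization skipped")
                       1
                     } else 1e6 / n_frag
                   },
                   "spike-scaled" = {
                     if (is.null(scale))
                       stop("spike-scaled normalization requires 'scale'")
                     scale
                   },
                   "raw" = 1)
  if (factor != 1) bins <- lapply(bins, `*`, factor)

  structure(list(bins = bins, bin_size = bin_size,
                 chrom_sizes = chrom_sizes,
                 normalization = normalization),
            class = "signal_track", n_clipped = n_clipped)
}

#' Signal in a genomic window
#'
#' Sums the bin values overlapping a 0-based half-open window, weighting
#' partial bins by their overlap fraction; equivalently, the per-bp sum of
#' `bin_value / bin_size` over the window. Windows extending past the
#' chromosome are clipped.
#'
#' @param track A `signal_track`.
#' @param chrom Chromosome name.
#' @param start,end Window (0-based half-open).
#' @return A single numeric value.
#' @export
window_signal <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$bins))
    stop("unknown chromosome: ", chrom)
  v <- track$bins[[chrom]]
  L <- track$chrom_sizes[[chrom]]
  b <- track$bin_size
  start <- max(0, start)
  end <- min(end, L)
  if (end <= start) return(0)
  first <- start %/% b
  last <- (end - 1L) %/% b
  idx <- (first:last) + 1L
  bin_start <- (first:last) * b
  bin_end <- pmin(bin_start + b, L)
  ov <- pmin(end, bin_end) - pmax(start, bin_start)
  sum(v[idx] * ov / b)
}

#' Per-gene upstream / TES-region enrichment scores
#'
#' For each gene, sums the track signal in the strand-aware upstream
#' window (`upstream_len` bp immediately 5' of the TSS) and in the
#' TES-region window (`tesr_len` bp centred on the TES), and forms
#' `log2((upstream + pc) / (tesr + pc))`. The TES region of a gene is
#' nucleosome-depleted but not factor-bound, so this ratio is a
#' within-sample specificity score that is robust to between-sample
#' differences in overall cleavage activity.
#'
#' @param track A `signal_track`.
#' @param annotation A `gene_annotation` (all rows are scored).
#' @param upstream_len,tesr_len Window lengths in bp (default 500 each).
#' @param pseudocount Added to both window sums before the ratio (default
#'   1 normalized unit) so zero-signal windows stay finite.
#' @return An `enrichment_scores` data frame: `gene_id`,
#'   `upstream_signal`, `tesr_signal`, `log2_ratio`, `clipped` (TRUE when
#'   either window was truncated at a chromosome edge).
#' @export
upstream_tesr_scores <- function(track, annotation, upstream_len = 500L,
                                 tesr_len = 500L, pseudocount = 1) {
  up <- upstream_window(annotation, upstream_len)
  te <- tesr_window(annotation, tesr_len)
  n <- nrow(annotation)
  up_sig <- numeric(n)
  te_sig <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    L <- track$chrom_sizes[[annotation$chrom[i]]]
    up_sig[i] <- window_signal(track, up$chrom[i], up$start[i], up$end[i])
    te_sig[i] <- window_signal(track, te$chrom[i], te$start[i], te$end[i])
    clipped[i] <- up$start[i] < 0 || up$end[i] > L ||
      te$start[i] < 0 || te$end[i] > L
  }
  res <- data.frame(gene_id = annotation$gene_id,
                    upstream_signal = up_sig,
                    tesr_signal = te_sig,
                    log2_ratio = log2((up_sig + pseudocount) /
                                        (te_sig + pseudocount)),
                    clipped = clipped,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_scores", "data.frame")
  res
}

#' Wilcoxon rank-sum comparison of score groups
#'
#' Two-sided Mann-Whitney test between two groups of per-gene scores. The
#' exact distribution is used when both groups have at most `exact_max`
#' values and there are no ties; otherwise the normal approximation with
#' tie correction.
#'
#' @param scores_A,scores_B Numeric vectors (each length >= 2).
#' @param exact_max Largest group size for the exact test (default 8).
#' @return List with `statistic` (Mann-Whitney U of group A) and
#'   `p_value`.
#' @export
compare_groups <- function(scores_A, scores_B, exact_max = 8L) {
  if (length(scores_A) < 2L || length(scores_B) < 2L)
    stop("each group needs at least 2 values")
  ties <- anyDuplicated(c(scores_A, scores_B)) > 0
  exact <- length(scores_A) <= exact_max && length(scores_B) <= exact_max &&
    !ties
  ht <- stats::wilcox.test(scores_A, scores_B, exact = exact,
                           correct = !exact)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pairwise rank-sum comparisons with Holm correction
#'
#' All pairwise two-sided Mann-Whitney tests between more than two groups,
#' with Holm adjustment across the pairs.
#'
#' @param values Numeric vector of scores.
#' @param group Group label per value.
#' @param exact_max Passed to [compare_groups()].
#' @return Data frame `group_1`, `group_2`, `p_value`, `p_holm`.
#' @export
compare_groups_pairwise <- function(values, group, exact_max = 8L) {
  g <- unique(as.character(group))
  pairs <- utils::combn(g, 2)
  p <- apply(pairs, 2, function(pr)
    compare_groups(values[group == pr[1]], values[group == pr[2]],
                   exact_max)$p_value)
  data.frame(group_1 = pairs[1, ], group_2 = pairs[2, ],
             p_value = p, p_holm = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}
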