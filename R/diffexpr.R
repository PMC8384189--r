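#' Method-of-moments dispersion estimates
#'
#' Estimates the per-gene negative-binomial dispersion \eqn{\alpha_i}
#' (variance \eqn{\mu + \alpha \mu^2}) from size-factor-normalized counts.
#' Within each condition, the moment estimator is
#' \eqn{\hat\alpha = (s^2 - \bar{w} m) / m^2} with \eqn{m} the group mean,
#' \eqn{s^2} the group sample variance and
#' \eqn{\bar{w} = \mathrm{mean}(1/sf_j)} the mean reciprocal size factor of
#' the group — the \eqn{\bar{w}} term is the Poisson (shot-noise)
#' contribution on the normalized scale, and makes the estimator exactly
#' invariant to a common rescaling of all size factors. Per-condition
#' estimates are floored at `alpha_floor` and averaged across conditions.
#'
#' With few replicates the per-gene moment estimate is extremely noisy;
#' chance underestimates of the variance would otherwise inflate Wald
#' statistics and break false-discovery control. When `pool_floor = TRUE`
#' (the default) each gene's dispersion is therefore additionally floored
#' at a genome-wide pooled dispersion (the 5% trimmed mean of the per-gene
#' estimates), a deliberately conservative guard that borrows strength
#' across genes without per-gene shrinkage toward a fitted trend.
#'
#' @param counts Integer matrix (genes x samples) or `count_matrix`.
#' @param sf A `size_factors` object or named numeric vector.
#' @param condition Named (by sample) or positional condition labels; taken
#'   from the `count_matrix` when omitted.
#' @param alpha_floor Minimum dispersion.
#' @param pool_floor Apply the genome-wide pooled floor (see Details).
#' @return Named numeric vector of dispersions; genes with zero counts in
#'   every sample are `NA` (flagged `low_count` downstream).
#' @export
estimate_dispersion <- function(counts, sf, condition = NULL,
                                alpha_floor = 1e-8, pool_floor = TRUE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (is.null(condition) && inherits(counts, "count_matrix"))
    condition <- counts$condition[colnames(m)]
  stopifnot(!is.null(condition), length(condition) == ncol(m))
  if (inherits(sf, "size_factors")) sf <- sf$sf
  sf <- sf[colnames(m)]
  norm <- sweep(m, 2, sf, "/")
  conds <- unique(condition)
  per_cond_fun <- function(cc) {
    sel <- condition == cc
    if (sum(sel) < 2L)
      stop("condition '", cc, "' has fewer than 2 replicates")
    x <- norm[, sel, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- apply(x, 1, stats::var)
    w <- mean(1 / sf[sel])
    pmax((s2 - w * mu) / mu^2, alpha_floor)
  }
  per_cond <- matrix(unlist(lapply(conds, per_cond_fun)), nrow = nrow(m))
  alpha <- rowMeans(per_cond)
  all_zero <- rowSums(m) == 0L
  alpha[all_zero] <- NA_real_
  if (pool_floor && any(!is.na(alpha))) {
    pooled <- mean(alpha, trim = 0.05, na.rm = TRUE)
    alpha <- pmax(alpha, pooled)
  }
  names(alpha) <- rownames(m)
  alpha
}

#' Two-group negative-binomial Wald test with fixed size factors
#'
#' Tests each gene for differential abundance between two conditions, with
#' size factors estimated externally (here: from spike-in genes) and held
#' fixed. For group means of normalized counts \eqn{\mu_A, \mu_B}, each
#' offset by a small pseudocount, the effect is
#' \eqn{\widehat{lfc} = \log_2(\mu_B / \mu_A)} and its squared standard
#' error follows from the delta method:
#' \deqn{se^2 = \frac{1}{\ln^2 2}\left(\frac{v_A}{n_A \mu_A^2} +
#'   \frac{v_B}{n_B \mu_B^2}\right),}
#' where \eqn{v} is the within-group variance of normalized counts, floored
#' at the NB moment value \eqn{\bar{w}\mu + \alpha\mu^2}
#' (\eqn{\bar{w} = \mathrm{mean}(1/sf)} in the group). The Wald statistic
#' \eqn{z = \widehat{lfc}/se} is referred to a standard normal, two-sided;
#' p-values are Benjamini-Hochberg adjusted across tested genes.
#'
#' The pseudocount is 0.5 on the scale of one size-factor unit
#' (`0.5 * mean(1/sf)`), which keeps fold changes finite at zero counts
#' while preserving exact invariance of `log2fc` and `p` under a common
#' rescaling of all size factors.
#'
#' This is a deliberately transparent simplification of a full NB GLM: no
#' per-gene dispersion shrinkage toward a trend, no fold-change shrinkage,
#' no independent filtering. Genes with zero counts in both groups are
#' flagged `low_count`, receive no p-value and are excluded from the BH
#' denominator.
#'
#' @param counts Integer matrix (genes x samples) or `count_matrix`.
#' @param sf A `size_factors` object or named numeric vector.
#' @param condition Condition labels per sample (taken from the
#'   `count_matrix` when omitted).
#' @param contrast Character vector `c(A, B)`; the reported fold change is
#'   B over A.
#' @param alpha Optional per-gene dispersions; estimated via
#'   [estimate_dispersion()] on the contrast samples when `NULL`.
#' @param pseudocount Pseudocount (in size-factor units) added to each
#'   group mean.
#' @return A `de_result` data frame: `gene_id`, `baseMean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj`, `status` (`tested` or `low_count`).
#' @export
wald_test_two_group <- function(counts, sf, condition = NULL,
                                contrast, alpha = NULL,
                                pseudocount = 0.5) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (is.null(condition) && inherits(counts, "count_matrix"))
    condition <- counts$condition[colnames(m)]
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% condition))
    stop("contrast condition(s) absent from data: ",
         paste(setdiff(contrast, condition), collapse = ", "))
  if (inherits(sf, "size_factors")) sf <- sf$sf
  sf <- sf[colnames(m)]
  keep <- condition %in% contrast
  m <- m[, keep, drop = FALSE]
  condition <- condition[keep]
  sf <- sf[keep]
  if (is.null(alpha))
    alpha <- estimate_dispersion(m, sf, condition)
  if (!is.null(names(alpha)) && !is.null(rownames(m)))
    alpha <- alpha[rownames(m)]

  norm <- sweep(m, 2, sf, "/")
  selA <- condition == contrast[1]
  selB <- condition == contrast[2]
  if (sum(selA) < 2L || sum(selB) < 2L)
    stop("both contrast conditions need >= 2 replicates")
  xa <- norm[, selA, drop = FALSE]
  xb <- norm[, selB, drop = FALSE]
  nA <- ncol(xa); nB <- ncol(xb)
  muA <- rowMeans(xa); muB <- rowMeans(xb)
  wA <- mean(1 / sf[selA]); wB <- mean(1 / sf[selB])
  vA <- pmax(apply(xa, 1, stats::var), wA * muA + alpha * muA^2,
             na.rm = TRUE)
  vB <- pmax(apply(xb, 1, stats::var), wB * muB + alpha * muB^2,
             na.rm = TRUE)
  pc <- pseudocount * mean(1 / sf)
  lfc <- log2((muB + pc) / (muA + pc))
  se <- sqrt((vA / (nA * (muA + pc)^2) + vB / (nB * (muB + pc)^2))) /
    log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))

  low <- rowSums(m[, selA, drop = FALSE]) == 0L &
    rowSums(m[, selB, drop = FALSE]) == 0L
  status <- ifelse(low, "low_count", "tested")
  p[low] <- NA_real_
  stat[low] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!low] <- stats::p.adjust(p[!low], method = "BH")

  res <- data.frame(gene_id = rownames(m),
                    baseMean = rowMeans(norm),
                    log2fc = lfc, se = se, stat = stat,
                    pvalue = p, padj = padj, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- contrast
  res
}

#' Write / read a differential-expression result table
#'
#' @param de A `de_result`.
#' @param path TSV path.
#' @return Invisibly `de` (writer); a `de_result` (reader).
#' @export
write_de_result <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(de)
}

#' @rdname write_de_result
#' @export
read_de_result <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("de_result", "data.frame")
  df
}
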