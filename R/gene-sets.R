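#' Round half-up to a fixed number of decimals
#'
#' Percentages are reported rounded half-up to one decimal (the convention
#' used when quoting shared / class fractions), rather than R's default
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Significantly up- and downregulated gene sets
#'
#' @param de A `de_result`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with character vectors `up` (`padj < alpha`, `log2fc > 0`)
#'   and `down` (`padj < alpha`, `log2fc < 0`).
#' @export
significant_sets <- function(de, alpha = 0.05) {
  sig <- !is.na(de$padj) & de$padj < alpha
  list(up = de$gene_id[sig & de$log2fc > 0],
       down = de$gene_id[sig & de$log2fc < 0])
}

#' Concordantly regulated genes across two contrasts
#'
#' Builds the union of genes significant in either contrast, then retains
#' only those whose fold change has the same (nonzero) sign in both
#' contrasts — direction, not dual significance, is the filter. Genes
#' significant in one result but absent from the other, and genes with a
#' zero fold change in either contrast (sign undefined), are dropped and
#' counted. The four bookkeeping categories always satisfy
#' `concordant_down + concordant_up + discordant + single_result =
#' union_significant`.
#'
#' @param de1,de2 `de_result` tables (a shared gene universe is taken as
#'   the intersection of their gene ids).
#' @param alpha Adjusted-p threshold applied to both contrasts.
#' @return A `regulated_sets` list: `union_significant`,
#'   `concordant_down`, `concordant_up`, `discordant_dropped`,
#'   `single_result_dropped` (character vectors), `table` (per-union-gene
#'   lfc/padj from both contrasts) and `counts` (named integer summary).
#' @export
concordant_union <- function(de1, de2, alpha = 0.05) {
  s1 <- significant_sets(de1, alpha)
  s2 <- significant_sets(de2, alpha)
  union_sig <- union(unlist(s1), unlist(s2))

  shared <- intersect(de1$gene_id, de2$gene_id)
  single <- setdiff(union_sig, shared)
  both <- intersect(union_sig, shared)

  l1 <- stats::setNames(de1$log2fc, de1$gene_id)[both]
  l2 <- stats::setNames(de2$log2fc, de2$gene_id)[both]
  p1 <- stats::setNames(de1$padj, de1$gene_id)[both]
  p2 <- stats::setNames(de2$padj, de2$gene_id)[both]

  same_dir <- sign(l1) == sign(l2) & sign(l1) != 0
  same_dir[is.na(same_dir)] <- FALSE
  down <- both[same_dir & l1 < 0]
  up <- both[same_dir & l1 > 0]
  discordant <- both[!same_dir]

  out <- list(
    union_significant = union_sig,
    concordant_down = down,
    concordant_up = up,
    discordant_dropped = discordant,
    single_result_dropped = single,
    table = data.frame(gene_id = both, lfc_1 = unname(l1),
                       lfc_2 = unname(l2), padj_1 = unname(p1),
                       padj_2 = unname(p2), stringsAsFactors = FALSE),
    counts = c(union_significant = length(union_sig),
               concordant_down = length(down),
               concordant_up = length(up),
               concordant_total = length(down) + length(up),
               discordant_dropped = length(discordant),
               single_result_dropped = length(single))
  )
  class(out) <- "regulated_sets"
  out
}

#' Venn overlap counts and shared fractions of two gene sets
#'
#' @param setA,setB Character vectors of gene ids.
#' @return List with `n_A`, `n_B`, `n_shared`, and `pct_of_A` / `pct_of_B`
#'   (shared fraction as a percentage, one decimal, half-up; `NA` for an
#'   empty set).
#' @export
venn_overlap <- function(setA, setB) {
  shared <- length(intersect(setA, setB))
  nA <- length(unique(setA))
  nB <- length(unique(setB))
  list(n_A = nA, n_B = nB, n_shared = shared,
       pct_of_A = if (nA == 0) NA_real_ else
         round_half_up(100 * shared / nA, 1),
       pct_of_B = if (nB == 0) NA_real_ else
         round_half_up(100 * shared / nB, 1))
}

#' Coactivator-class composition of a gene set
#'
#' Counts members per class and reports percentages over the annotated
#' (CR + TFIID) members only; unannotated genes are counted but excluded
#' from the denominator.
#'
#' @param gene_set Character vector of gene ids.
#' @param labels Named character vector (gene id -> class, one of `CR`,
#'   `TFIID`, `unannotated`), or a `gene_annotation`.
#' @return List with `n_total`, `n_annotated`, per-class counts `n_CR`,
#'   `n_TFIID`, `n_unannotated`, and percentages `pct_CR`, `pct_TFIID`
#'   (one decimal, half-up; `NA` when no member is annotated).
#' @export
class_fractions <- function(gene_set, labels) {
  if (inherits(labels, "gene_annotation"))
    labels <- stats::setNames(labels$class, labels$gene_id)
  cls <- labels[gene_set]
  cls[is.na(cls)] <- "unannotated"
  n_cr <- sum(cls == "CR")
  n_tf <- sum(cls == "TFIID")
  n_un <- sum(cls == "unannotated")
  n_ann <- n_cr + n_tf
  list(n_total = length(gene_set), n_annotated = n_ann,
       n_CR = n_cr, n_TFIID = n_tf, n_unannotated = n_un,
       pct_CR = if (n_ann == 0) NA_real_ else
         round_half_up(100 * n_cr / n_ann, 1),
       pct_TFIID = if (n_ann == 0) NA_real_ else
         round_half_up(100 * n_tf / n_ann, 1))
}

#' Fraction of a gene set changing by less than a fold threshold
#'
#' @param gene_set Character vector of gene ids.
#' @param lfc Named numeric vector of log2 fold changes covering the set.
#' @param fold_threshold Linear fold-change threshold (default 2); a gene
#'   counts when `2^|lfc| < fold_threshold` (strict).
#' @return List with `n`, `n_below` and `pct_below` (one decimal, half-up;
#'   `NA` for an empty set).
#' @export
magnitude_fraction <- function(gene_set, lfc, fold_threshold = 2) {
  v <- lfc[gene_set]
  if (anyNA(v))
    stop("log2 fold change missing for gene(s): ",
         paste(utils::head(gene_set[is.na(v)], 5), collapse = ", "))
  n <- length(v)
  below <- sum(2^abs(v) < fold_threshold)
  list(n = n, n_below = below,
       pct_below = if (n == 0) NA_real_ else
         round_half_up(100 * below / n, 1))
}
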