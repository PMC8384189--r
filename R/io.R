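#' @name io
#' @title Plain-text readers and writers
#'
#' @description
#' All on-disk formats are plain text. Interval files (BED6, 3-column
#' fragment BED, BEDPE, bedGraph) use 0-based half-open coordinates — the
#' same convention the package uses internally, so no shifting occurs at
#' the boundary. Tables (counts, labels, size factors, ground truth) are
#' tab-separated with a header.
NULL

#' Write / read a gene annotation as BED6 plus a label sidecar
#'
#' The BED6 file carries `chrom, start, end, gene_id, score(0), strand`;
#' the sidecar TSV carries `gene_id, organism, class, tata`.
#'
#' @param annotation A `gene_annotation`.
#' @param bed_path,labels_path Output paths.
#' @return Invisibly, the annotation (writer) or the reconstructed
#'   `gene_annotation` (reader).
#' @export
write_annotation <- function(annotation, bed_path, labels_path) {
  bed <- data.frame(annotation$chrom, annotation$start, annotation$end,
                    annotation$gene_id, rep(0L, nrow(annotation)),
                    annotation$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    annotation[, c("gene_id", "organism", "class", "tata")],
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotation)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(bed_path, labels_path) {
  bed <- utils::read.table(bed_path, sep = "\t",
                           col.names = c("chrom", "start", "end",
                                         "gene_id", "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer",
                                          "character"))
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  ann <- merge(bed[, c("gene_id", "chrom", "start", "end", "strand")],
               lab, by = "gene_id", sort = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann$tes <- ifelse(ann$strand == "+", ann$end - 1L, ann$start)
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand", "tss",
                 "tes", "organism", "class", "tata")]
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write / read a count matrix TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns. The sample
#' metadata (condition per sample) and gene organism tags travel in a
#' companion file when written via [write_count_matrix()].
#'
#' @param cm A `count_matrix`.
#' @param path Counts TSV path.
#' @param meta_path Optional sample-metadata TSV path
#'   (`sample_id, condition`).
#' @return Invisibly `cm` (writer); a `count_matrix` (reader; `organism`
#'   is reconstructed from gene id prefixes when no annotation is given).
#' @export
write_count_matrix <- function(cm, path, meta_path = NULL) {
  df <- data.frame(gene_id = cm$gene_id, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(
      data.frame(sample_id = cm$sample_id,
                 condition = unname(cm$condition[cm$sample_id])),
      meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cm)
}

#' @rdname write_count_matrix
#' @param organism Optional named character vector (per gene id); when
#'   `NULL` the reader tags genes on spike chromosomes by the
#'   `spike_prefix` of their gene id.
#' @param spike_prefix Prefix identifying spike-in gene ids.
#' @export
read_count_matrix <- function(path, meta_path = NULL, organism = NULL,
                              spike_prefix = "spike") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  cond <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    cond <- stats::setNames(meta$condition, meta$sample_id)[colnames(counts)]
  }
  if (is.null(organism))
    organism <- stats::setNames(
      ifelse(startsWith(df$gene_id, spike_prefix), "spikein",
             "experimental"),
      df$gene_id)
  structure(list(counts = counts, gene_id = df$gene_id,
                 sample_id = colnames(counts), condition = cond,
                 organism = organism, params = NULL),
            class = "count_matrix")
}

#' Write / read fragment spans
#'
#' Fragments are stored as 3-column BED (`chrom, start, end`; 0-based
#' half-open). [write_fragments_bedpe()] writes the same spans in minimal
#' BEDPE form, modelling each fragment as its two 1-bp outermost cut
#' positions.
#'
#' @param frags A `fragment_set`.
#' @param path Output path.
#' @return Invisibly `frags` (writers); a `fragment_set` (reader).
#' @export
write_fragments_bed <- function(frags, path) {
  utils::write.table(frags[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(frags)
}

#' @rdname write_fragments_bed
#' @export
write_fragments_bedpe <- function(frags, path) {
  bedpe <- data.frame(frags$chrom, frags$start, frags$start + 1L,
                      frags$chrom, frags$end - 1L, frags$end,
                      ".", 0L, "+", "-")
  utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(frags)
}

#' @rdname write_fragments_bed
#' @param sample_id Sample label to attach.
#' @param spike_prefix Chromosome prefix identifying spike-in fragments.
#' @export
read_fragments_bed <- function(path, sample_id = NA_character_,
                               spike_prefix = "spike_") {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer",
                                         "integer"))
  df$length <- df$end - df$start
  df$sample_id <- sample_id
  df$organism <- ifelse(startsWith(df$chrom, spike_prefix), "spikein",
                        "experimental")
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Write / read per-sample size factors
#'
#' @param sf A `size_factors` object from
#'   [size_factors_median_of_ratios()].
#' @param path TSV path (`sample_id, sf, n_genes_used`).
#' @return Invisibly `sf` (writer); a `size_factors` list (reader).
#' @export
write_size_factors <- function(sf, path) {
  utils::write.table(
    data.frame(sample_id = names(sf$sf), sf = unname(sf$sf),
               n_genes_used = sf$n_genes_used),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sf)
}

#' @rdname write_size_factors
#' @export
read_size_factors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(sf = stats::setNames(df$sf, df$sample_id),
                 n_genes_used = df$n_genes_used[1]),
            class = "size_factors")
}

#' Write / read a binned signal track as bedGraph
#'
#' Consecutive equal-valued bins are merged into single bedGraph intervals;
#' zero-valued intervals are omitted, as is conventional.
#'
#' @param track A `signal_track` from [fragment_coverage()].
#' @param path bedGraph path.
#' @return Invisibly `track` (writer). The reader returns a
#'   `signal_track`; it requires the original `chrom_sizes` and `bin_size`
#'   and the on-disk intervals must align to the bin grid.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$bins)) {
    v <- track$bins[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- c(0L, end_bin[-length(end_bin)])
    keep <- r$values != 0
    if (!any(keep)) next
    starts <- start_bin[keep] * track$bin_size
    ends <- pmin(end_bin[keep] * track$bin_size,
                 track$chrom_sizes[[chrom]])
    df <- data.frame(chrom, starts, ends,
                     format(r$values[keep], digits = 10,
                            scientific = FALSE, trim = TRUE))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(track)
}

#' @rdname write_bedgraph
#' @param chrom_sizes Named chromosome sizes (bp).
#' @param bin_size Bin width used when the track was written.
#' @param normalization Normalization tag to record on the track.
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 10L,
                          normalization = "per-million") {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  bins <- lapply(names(chrom_sizes), function(chrom) {
    nb <- as.integer(ceiling(chrom_sizes[[chrom]] / bin_size))
    v <- numeric(nb)
    sub <- df[df$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      b0 <- sub$start[k] %/% bin_size
      b1 <- (sub$end[k] - 1L) %/% bin_size
      v[(b0 + 1L):(b1 + 1L)] <- sub$value[k]
    }
    v
  })
  names(bins) <- names(chrom_sizes)
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, normalization = normalization),
            class = "signal_track")
}

#' Write ground-truth tables for a simulated dataset
#'
#' Emits the true per-gene log2 fold changes and dispersions, the true
#' per-sample depth factors, and the UAS window coordinates, so that every
#' downstream estimate can be checked against truth.
#'
#' @param annotation A `gene_annotation`.
#' @param params A [sim_params()] list.
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_ground_truth <- function(annotation, params, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "true_gene_params.tsv")
  utils::write.table(
    data.frame(gene_id = annotation$gene_id,
               true_log2fc = unname(params$true_log2fc[annotation$gene_id]),
               dispersion = unname(params$dispersion[annotation$gene_id]),
               base_abundance =
                 unname(params$base_abundance[annotation$gene_id])),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "true_depth_factors.tsv")
  utils::write.table(
    data.frame(sample_id = names(params$depth_factors),
               depth_factor = unname(params$depth_factors)),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "uas_windows.tsv")
  uw <- uas_window(annotation[annotation$organism == "experimental", ,
                              drop = FALSE], config)
  utils::write.table(
    cbind(gene_id = annotation$gene_id[annotation$organism ==
                                         "experimental"], uw),
    p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
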