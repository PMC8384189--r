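#' Default pipeline configuration
#'
#' A desk-scale end-to-end run: one simulated annotation shared by two
#' "strains" (the second with attenuated true effects, emulating an acute
#' depletion alongside a chronic deletion), spike-in normalized
#' differential transcription per strain, cross-strain concordant sets
#' with class composition, ChEC-style enrichment scoring of a bound factor
#' against free MNase, and a short-fragment TSS profile.
#'
#' @param seed Master seed.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_genes_exp = 200L, n_genes_spike = 50L,
                    n_fragments = 20000L),
    strains = list(deletion = 1.0, depletion = 0.6),
    contrast = c("ctrl", "depleted"),
    alpha = 0.05,
    chec = list(bin_size = 10L, upstream_len = 500L, tesr_len = 500L,
                pseudocount = 1),
    profile = list(max_len = 80L, flank = 1000L, bin = 10L)
  )
}

validate_pipeline_config <- function(config) {
  required <- c("seed", "simulate", "strains", "contrast", "alpha",
                "chec", "profile")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("malformed pipeline config; missing key(s): ",
         paste(missing, collapse = ", "))
  if (length(config$contrast) != 2L)
    stop("malformed pipeline config; 'contrast' must name two conditions")
  if (length(config$strains) < 2L)
    stop("malformed pipeline config; at least two 'strains' are required")
  invisible(config)
}

#' Run the full simulate / normalize / test / score pipeline
#'
#' Executes every stage in dependency order, writes all intermediate and
#' final tables as plain text under `outdir`, and records a run manifest
#' (config hash, seed, per-stage output files with MD5 digests, package
#' version) as `manifest.json`. Re-running with an identical configuration
#' and seed reproduces identical digests.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file holding one.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("medtail_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  config$contrast <- unlist(config$contrast)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t_start <- Sys.time()
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("medtail")),
                   stages = list())
  log_stage <- function(name, t0, files) {
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    manifest$stages[[name]] <<- list(
      files = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))))
  }

  ## simulate --------------------------------------------------------------
  t0 <- Sys.time()
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  ann <- simulate_annotation(cfg)
  params <- sim_params(ann, cfg)
  write_annotation(ann, file.path(outdir, "annotation.bed"),
                   file.path(outdir, "gene_labels.tsv"))
  write_ground_truth(ann, params, cfg, outdir)

  strains <- names(config$strains)
  counts_paths <- character(0)
  cms <- list()
  for (s in strains) {
    p <- params
    p$true_log2fc <- p$true_log2fc * config$strains[[s]]
    scfg <- cfg
    scfg$seed <- child_seed(cfg$seed, paste0("strain/", s))
    cms[[s]] <- simulate_counts(ann, scfg, params = p)
    cp <- file.path(outdir, paste0("counts_", s, ".tsv"))
    write_count_matrix(cms[[s]], cp,
                       file.path(outdir, paste0("samples_", s, ".tsv")))
    counts_paths <- c(counts_paths, cp)
  }
  frags <- list()
  for (f in c("bound_factor", "free_mnase", "tbp_like")) {
    frags[[f]] <- simulate_fragments(ann, cfg, factor = f, sample_id = f)
    write_fragments_bed(frags[[f]],
                        file.path(outdir, paste0("fragments_", f, ".bed")))
  }
  log_stage("simulate", t0,
            c(file.path(outdir, c("annotation.bed", "gene_labels.tsv",
                                  "true_gene_params.tsv",
                                  "true_depth_factors.tsv",
                                  "uas_windows.tsv")),
              counts_paths,
              file.path(outdir, paste0("fragments_",
                                       c("bound_factor", "free_mnase",
                                         "tbp_like"), ".bed"))))

  ## normalize -------------------------------------------------------------
  t0 <- Sys.time()
  sfs <- list()
  sf_paths <- character(0)
  for (s in strains) {
    sfs[[s]] <- size_factors_median_of_ratios(cms[[s]])
    sp <- file.path(outdir, paste0("size_factors_", s, ".tsv"))
    write_size_factors(sfs[[s]], sp)
    sf_paths <- c(sf_paths, sp)
  }
  log_stage("normalize", t0, sf_paths)

  ## detest ----------------------------------------------------------------
  t0 <- Sys.time()
  des <- list()
  de_paths <- character(0)
  for (s in strains) {
    exp_rows <- cms[[s]]$organism[cms[[s]]$gene_id] == "experimental"
    sub <- cms[[s]]$counts[exp_rows, , drop = FALSE]
    des[[s]] <- wald_test_two_group(sub, sfs[[s]],
                                    condition = cms[[s]]$condition,
                                    contrast = config$contrast)
    dp <- file.path(outdir, paste0("de_", s, ".tsv"))
    write_de_result(des[[s]], dp)
    de_paths <- c(de_paths, dp)
  }
  log_stage("detest", t0, de_paths)

  ## genesets --------------------------------------------------------------
  t0 <- Sys.time()
  rs <- concordant_union(des[[1]], des[[2]], alpha = config$alpha)
  labels <- stats::setNames(ann$class, ann$gene_id)
  summary <- c(as.list(rs$counts),
               list(pct_CR_down =
                      class_fractions(rs$concordant_down, labels)$pct_CR,
                    pct_TFIID_up =
                      class_fractions(rs$concordant_up, labels)$pct_TFIID))
  gs_path <- file.path(outdir, "gene_sets_summary.tsv")
  utils::write.table(
    data.frame(metric = names(summary),
               value = unlist(lapply(summary, function(x)
                 if (is.null(x) || is.na(x)) NA else x))),
    gs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  set_paths <- c(file.path(outdir, "concordant_down.txt"),
                 file.path(outdir, "concordant_up.txt"))
  writeLines(rs$concordant_down, set_paths[1])
  writeLines(rs$concordant_up, set_paths[2])
  log_stage("genesets", t0, c(gs_path, set_paths))

  ## chec-score ------------------------------------------------------------
  t0 <- Sys.time()
  chrom_sizes <- c(cfg$chrom_sizes, cfg$spike_chrom_sizes)
  exp_ann <- ann[ann$organism == "experimental", , drop = FALSE]
  score_paths <- character(0)
  scores <- list()
  for (f in c("bound_factor", "free_mnase")) {
    tr <- fragment_coverage(frags[[f]], chrom_sizes,
                            bin_size = config$chec$bin_size,
                            normalization = "per-million")
    write_bedgraph(tr, file.path(outdir, paste0("track_", f, ".bedgraph")))
    scores[[f]] <- upstream_tesr_scores(
      tr, exp_ann, upstream_len = config$chec$upstream_len,
      tesr_len = config$chec$tesr_len,
      pseudocount = config$chec$pseudocount)
    sp <- file.path(outdir, paste0("scores_", f, ".tsv"))
    utils::write.table(scores[[f]], sp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    score_paths <- c(score_paths,
                     file.path(outdir, paste0("track_", f, ".bedgraph")),
                     sp)
  }
  cmp <- compare_groups(scores$bound_factor$log2_ratio,
                        scores$free_mnase$log2_ratio)
  cmp_path <- file.path(outdir, "group_comparison.tsv")
  utils::write.table(
    data.frame(comparison = "bound_factor_vs_free_mnase",
               statistic = cmp$statistic, p_value = cmp$p_value),
    cmp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("chec-score", t0, c(score_paths, cmp_path))

  ## tbp-profile -----------------------------------------------------------
  t0 <- Sys.time()
  prof <- size_filtered_profile(frags$tbp_like, exp_ann, chrom_sizes,
                                max_len = config$profile$max_len,
                                flank = config$profile$flank,
                                bin = config$profile$bin)
  prof_path <- file.path(outdir, "tbp_profile.tsv")
  write_profile(prof, prof_path)
  log_stage("tbp-profile", t0, prof_path)

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  message(sprintf("pipeline complete in %.1fs: %s",
                  as.numeric(Sys.time() - t_start, units = "secs"),
                  outdir))
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
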