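#' Expand per-gene and per-sample ground-truth parameters
#'
#' Resolves the count-model parameters implied by a configuration: base
#' abundances \eqn{q_i}, true log2 fold changes, dispersions and per-sample
#' depth factors. Values supplied in the configuration are used as given
#' (recycled where scalar); missing ones are drawn from dedicated child
#' seed streams so they are reproducible and independent of any other
#' stream. Spike-in genes always get a log2 fold change of exactly 0.
#'
#' @param annotation A `gene_annotation` from [simulate_annotation()].
#' @param config A [sim_config()].
#' @return List with elements `base_abundance`, `true_log2fc`, `dispersion`
#'   (named per gene) and `depth_factors` (named per sample).
#' @export
sim_params <- function(annotation, config) {
  ng <- nrow(annotation)
  ids <- annotation$gene_id
  exp_idx <- annotation$organism == "experimental"

  if (is.null(config$base_abundance)) {
    set.seed(child_seed(config$seed, "params/abundance"))
    q <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
  } else {
    q <- rep_len(config$base_abundance, ng)
  }

  if (is.null(config$true_log2fc)) {
    set.seed(child_seed(config$seed, "params/lfc"))
    lfc <- numeric(ng)
    hit <- exp_idx & stats::runif(ng) < config$frac_de
    sign <- ifelse(annotation$class == "CR", -1,
                   ifelse(annotation$class == "TFIID", 1,
                          sample(c(-1, 1), ng, replace = TRUE)))
    lfc[hit] <- config$lfc_magnitude * sign[hit]
  } else {
    lfc <- numeric(ng)
    lfc[exp_idx] <- rep_len(config$true_log2fc, sum(exp_idx))
  }
  lfc[!exp_idx] <- 0

  alpha <- rep_len(config$dispersion, ng)

  n_samples <- length(config$conditions) * config$replicates_per_condition
  sids <- sample_ids(config)
  if (is.null(config$depth_factors)) {
    # one stream per sample: adding a sample never shifts existing depths
    d <- vapply(sids, function(s) {
      set.seed(child_seed(config$seed, paste0("params/depth/", s)))
      stats::rlnorm(1, meanlog = 0, sdlog = 0.3)
    }, numeric(1))
  } else {
    d <- rep_len(config$depth_factors, n_samples)
  }

  names(q) <- names(lfc) <- names(alpha) <- ids
  names(d) <- sample_ids(config)
  list(base_abundance = q, true_log2fc = lfc, dispersion = alpha,
       depth_factors = d)
}

#' Simulate a negative-binomial count matrix with a spike-in genome
#'
#' Draws counts \eqn{k_{ij} \sim NB(\mu_{ij}, \alpha_i)} with
#' \eqn{\mu_{ij} = d_j \, q_i \, 2^{lfc_i x_j}}, where \eqn{x_j} is 1 for
#' samples of the second condition and 0 otherwise, and the variance is
#' \eqn{\mu + \alpha \mu^2}. Spike-in genes have \eqn{lfc_i = 0}, so their
#' expected counts depend on the sample only through the depth factor
#' \eqn{d_j} — the property spike-in normalization relies on. A dispersion
#' of 0 yields Poisson draws.
#'
#' Each sample is drawn from its own child seed stream
#' (`"counts/<sample_id>"`), so appending samples never changes existing
#' columns.
#'
#' @param annotation A `gene_annotation`.
#' @param config A [sim_config()].
#' @param params Optional pre-computed [sim_params()] (resolved from
#'   `config` when `NULL`).
#' @return A `count_matrix`: list with `counts` (integer matrix, genes x
#'   samples), `gene_id`, `sample_id`, `condition`, `organism`, and the
#'   ground-truth `params`.
#' @export
simulate_counts <- function(annotation, config, params = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(params)) params <- sim_params(annotation, config)
  ng <- nrow(annotation)
  miss <- setdiff(annotation$gene_id, names(params$base_abundance))
  if (length(miss))
    stop("missing count-model parameters for genes: ",
         paste(utils::head(miss, 5), collapse = ", "))
  sid <- sample_ids(config)
  cond <- sample_conditions(config)
  x <- as.integer(cond == config$conditions[2])
  counts <- matrix(0L, nrow = ng, ncol = length(sid),
                   dimnames = list(annotation$gene_id, sid))
  q <- params$base_abundance[annotation$gene_id]
  lfc <- params$true_log2fc[annotation$gene_id]
  alpha <- params$dispersion[annotation$gene_id]
  d <- params$depth_factors[sid]
  for (j in seq_along(sid)) {
    set.seed(child_seed(config$seed, paste0("counts/", sid[j])))
    mu <- d[j] * q * 2^(lfc * x[j])
    pois <- alpha < 1e-12
    kj <- integer(ng)
    if (any(pois)) kj[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) kj[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                                size = 1 / alpha[!pois])
    counts[, j] <- kj
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 gene_id = annotation$gene_id,
                 sample_id = sid,
                 condition = stats::setNames(cond, sid),
                 organism = stats::setNames(annotation$organism,
                                            annotation$gene_id),
                 params = params),
            class = "count_matrix")
}
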