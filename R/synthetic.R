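#' Configuration for the synthetic multi-omics generator
#'
#' Defines the generative model used by [simulate_multiomics()]. Each gene
#' may carry a transcription-level effect `x_g` (shared by all RNA layers
#' and, attenuated, by the proteome) and/or a polysome-specific translation
#' effect `t_g` (visible only in the synaptic polysome layer and the
#' proteome). A small random subset of genes is flagged as scaffold
#' interactors and receives an additive protein-level recruitment shift,
#' modelling abundance gained by physical interaction with an overexpressed
#' scaffold rather than by synthesis. All effects are on the log2
#' fold-change scale (TG relative to WT).
#'
#' @param n_genes Number of genes (>= 10). Default 5000, a realistic size
#'   for a quantified synaptosomal proteome/transcriptome intersection.
#' @param frac_transcriptional Fraction of genes with a transcription-level
#'   effect, in `[0, 1]`.
#' @param frac_translational Fraction of genes with a polysome-specific
#'   translation effect, in `[0, 1]`.
#' @param translational_up_bias Probability that a translational effect is
#'   positive. Default 0.9: local translation mostly adds protein, which is
#'   what makes the up-regulated half of the proteome the concordant half.
#' @param sigma_transcription,sigma_translation Standard deviations (log2
#'   units) of the latent effect magnitudes.
#' @param alpha_translation Weight of the translation effect on the
#'   polysome layer and the proteome.
#' @param beta_transcription Weight of the transcription effect on the
#'   proteome. Kept below 1 by default: a snapshot proteome dilutes
#'   transcriptional input through degradation and turnover.
#' @param frac_interactome Fraction of genes flagged as scaffold
#'   interactors (exactly `round(frac_interactome * n_genes)` genes).
#' @param recruit_effect Additive log2 shift on the protein fold change of
#'   interactome members (scaffolding recruitment).
#' @param noise_sd_per_layer Named numeric vector of Gaussian measurement
#'   noise SDs (log2 units), one per layer in [omics_layers()].
#' @param n_replicates Replicates per genotype for count simulation
#'   (>= 2). Default 3, i.e. three WT/TG pairs.
#' @param baseline_mean Negative-binomial baseline mean count (> 0).
#' @param dispersion Negative-binomial size parameter (> 0); the count
#'   variance is `mu + mu^2 / dispersion`, so large values approach the
#'   Poisson limit.
#' @param seed Master integer seed; all randomness is derived from it via
#'   deterministic per-stage sub-streams.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [simulate_multiomics()], [simulate_counts()]
#' @export
synthetic_config <- function(n_genes = 5000,
                             frac_transcriptional = 0.2,
                             frac_translational = 0.15,
                             translational_up_bias = 0.9,
                             sigma_transcription = 0.5,
                             sigma_translation = 1.0,
                             alpha_translation = 1.0,
                             beta_transcription = 0.5,
                             frac_interactome = 0.05,
                             recruit_effect = 0.5,
                             noise_sd_per_layer = c(whole_tissue = 0.3,
                                                    syn_input = 0.3,
                                                    syn_polysome = 0.3,
                                                    proteome = 0.3),
                             n_replicates = 3,
                             baseline_mean = 100,
                             dispersion = 10,
                             seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || is.na(n_genes) ||
      n_genes < 10 || n_genes != round(n_genes)) {
    abort_config("`n_genes` must be a single integer >= 10.")
  }
  check_fraction(frac_transcriptional, "frac_transcriptional")
  check_fraction(frac_translational, "frac_translational")
  check_fraction(translational_up_bias, "translational_up_bias")
  check_fraction(frac_interactome, "frac_interactome")
  check_nonneg(sigma_transcription, "sigma_transcription")
  check_nonneg(sigma_translation, "sigma_translation")
  if (!is.numeric(alpha_translation) || length(alpha_translation) != 1 ||
      is.na(alpha_translation)) {
    abort_config("`alpha_translation` must be a single number.")
  }
  if (!is.numeric(beta_transcription) || length(beta_transcription) != 1 ||
      is.na(beta_transcription)) {
    abort_config("`beta_transcription` must be a single number.")
  }
  if (!is.numeric(recruit_effect) || length(recruit_effect) != 1 ||
      is.na(recruit_effect)) {
    abort_config("`recruit_effect` must be a single number.")
  }
  if (!is.numeric(noise_sd_per_layer) ||
      !all(omics_layers() %in% names(noise_sd_per_layer))) {
    abort_config(paste0(
      "`noise_sd_per_layer` must be a named numeric vector covering layers: ",
      paste(omics_layers(), collapse = ", "), "."
    ))
  }
  if (any(is.na(noise_sd_per_layer)) || any(noise_sd_per_layer < 0)) {
    abort_config("`noise_sd_per_layer` entries must be nonnegative.")
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 2 ||
      n_replicates != round(n_replicates)) {
    abort_config("`n_replicates` must be a single integer >= 2.")
  }
  check_positive(baseline_mean, "baseline_mean")
  check_positive(dispersion, "dispersion")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    abort_config("`seed` must be a single integer.")
  }

  structure(
    list(
      n_genes = as.integer(n_genes),
      frac_transcriptional = frac_transcriptional,
      frac_translational = frac_translational,
      translational_up_bias = translational_up_bias,
      sigma_transcription = sigma_transcription,
      sigma_translation = sigma_translation,
      alpha_translation = alpha_translation,
      beta_transcription = beta_transcription,
      frac_interactome = frac_interactome,
      recruit_effect = recruit_effect,
      noise_sd_per_layer = noise_sd_per_layer[omics_layers()],
      n_replicates = as.integer(n_replicates),
      baseline_mean = baseline_mean,
      dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Simulate a ground-truth-bearing multi-omics dataset
#'
#' Draws per-gene latent transcription effects `x_g` and translation
#' effects `t_g`, flags a scaffold-interactome subset, and composes the
#' four observed fold-change layers as
#' \describe{
#'   \item{whole_tissue}{`x_g + noise`}
#'   \item{syn_input}{`x_g + noise`}
#'   \item{syn_polysome}{`x_g + alpha_translation * t_g + noise`}
#'   \item{proteome}{`beta_transcription * x_g + alpha_translation * t_g +
#'     recruit_effect * interactome + noise`}
#' }
#' The translation channel is therefore visible only where polysome
#' engagement and protein abundance are measured, which is the structure
#' the concordance sweep is designed to detect.
#'
#' @param config A [synthetic_config()].
#' @param counts If `TRUE`, also simulate replicate negative-binomial count
#'   matrices for the three transcriptome layers via [simulate_counts()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `config`, `ground_truth` (tibble `id`, `x_g`, `t_g`, `interactome`),
#'   `fold_changes` (named list of [fold_change_table()] objects, one per
#'   layer) and `counts` (named list of count tibbles, or empty).
#' @examples
#' ds <- simulate_multiomics(synthetic_config(n_genes = 200, seed = 7))
#' head(ds$fold_changes$proteome)
#' @export
simulate_multiomics <- function(config, counts = FALSE) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must be created by `synthetic_config()`.")
  }
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))

  set.seed(substream_seed(config$seed, "latent"))
  has_x <- stats::runif(n) < config$frac_transcriptional
  x_g <- ifelse(has_x, stats::rnorm(n, 0, config$sigma_transcription), 0)
  has_t <- stats::runif(n) < config$frac_translational
  t_mag <- abs(stats::rnorm(n, 0, config$sigma_translation))
  t_sign <- ifelse(stats::runif(n) < config$translational_up_bias, 1, -1)
  t_g <- ifelse(has_t, t_sign * t_mag, 0)

  n_inter <- round(config$frac_interactome * n)
  interactome <- rep(FALSE, n)
  if (n_inter > 0) {
    interactome[sample.int(n, n_inter)] <- TRUE
  }

  expected <- list(
    whole_tissue = x_g,
    syn_input = x_g,
    syn_polysome = x_g + config$alpha_translation * t_g,
    proteome = config$beta_transcription * x_g +
      config$alpha_translation * t_g +
      config$recruit_effect * as.numeric(interactome)
  )

  fold_changes <- lapply(omics_layers(), function(layer) {
    set.seed(substream_seed(config$seed, paste0("noise_", layer)))
    noise <- stats::rnorm(n, 0, config$noise_sd_per_layer[[layer]])
    fold_change_table(ids, expected[[layer]] + noise, layer = layer)
  })
  names(fold_changes) <- omics_layers()

  dataset <- structure(
    list(
      config = config,
      ground_truth = tibble::tibble(
        id = ids, x_g = x_g, t_g = t_g, interactome = interactome
      ),
      fold_changes = fold_changes,
      counts = list()
    ),
    class = "synthetic_dataset"
  )

  if (isTRUE(counts)) {
    dataset$counts <- lapply(transcriptome_layers(), function(layer) {
      simulate_counts(config, dataset$fold_changes[[layer]], layer)
    })
    names(dataset$counts) <- transcriptome_layers()
  }
  dataset
}

#' Simulate replicate negative-binomial counts for one layer
#'
#' Per gene, a lognormal baseline size `s_g` sets the WT mean
#' `baseline_mean * s_g`; the TG mean is the WT mean times `2^log2fc`.
#' Counts are drawn from a negative binomial with size `dispersion`
#' (variance `mu + mu^2 / dispersion`), `n_replicates` columns per
#' genotype, with columns named `<genotype>_<layer>_<replicate>`.
#'
#' @param config A [synthetic_config()].
#' @param fold_changes A [fold_change_table()] covering all genes to
#'   simulate.
#' @param layer Layer name used in column labels and the sub-stream seed.
#' @return A tibble with an `id` column followed by
#'   `2 * n_replicates` integer count columns.
#' @export
simulate_counts <- function(config, fold_changes, layer) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must be created by `synthetic_config()`.")
  }
  check_positive(config$baseline_mean, "baseline_mean")
  check_positive(config$dispersion, "dispersion")
  fold_changes <- as_fold_change_table(fold_changes, layer = layer)
  if (nrow(fold_changes) == 0) {
    abort_input("`fold_changes` must cover at least one gene.")
  }
  n <- nrow(fold_changes)
  k <- config$n_replicates

  set.seed(substream_seed(config$seed, paste0("counts_", layer)))
  s_g <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
  wt_mu <- config$baseline_mean * s_g
  tg_mu <- wt_mu * 2^fold_changes$log2fc

  draw <- function(mu) {
    matrix(
      stats::rnbinom(n * k, mu = rep(mu, k), size = config$dispersion),
      nrow = n, ncol = k
    )
  }
  mat <- cbind(draw(wt_mu), draw(tg_mu))
  colnames(mat) <- c(
    sprintf("WT_%s_%d", layer, seq_len(k)),
    sprintf("TG_%s_%d", layer, seq_len(k))
  )
  dplyr::bind_cols(
    tibble::tibble(id = fold_changes$id),
    tibble::as_tibble(mat)
  )
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Writes one TSV fold-change table per layer (`fc_<layer>.tsv`, header
#' `id` / `log2fc`), optional TSV count matrices
#' (`counts_<layer>.tsv`), the ground truth (`ground_truth.tsv`) and the
#' interactome membership list (`interactome.txt`, one identifier per
#' line).
#'
#' @param dataset A `synthetic_dataset` from [simulate_multiomics()].
#' @param dir Output directory (created if missing).
#' @return A tibble manifest with columns `file` and `rows`.
#' @export
write_fixtures <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset")) {
    abort_input("`dataset` must be a `synthetic_dataset`.")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) {
    abort_input(sprintf("cannot create output directory '%s'.", dir))
  }

  manifest <- list()
  add <- function(manifest, file, rows) {
    c(manifest, list(tibble::tibble(file = file, rows = rows)))
  }

  for (layer in names(dataset$fold_changes)) {
    file <- sprintf("fc_%s.tsv", layer)
    write_fold_changes(dataset$fold_changes[[layer]], file.path(dir, file))
    manifest <- add(manifest, file, nrow(dataset$fold_changes[[layer]]))
  }
  for (layer in names(dataset$counts)) {
    file <- sprintf("counts_%s.tsv", layer)
    readr::write_tsv(dataset$counts[[layer]], file.path(dir, file))
    manifest <- add(manifest, file, nrow(dataset$counts[[layer]]))
  }
  readr::write_tsv(dataset$ground_truth, file.path(dir, "ground_truth.tsv"))
  manifest <- add(manifest, "ground_truth.tsv", nrow(dataset$ground_truth))

  inter_ids <- dataset$ground_truth$id[dataset$ground_truth$interactome]
  writeLines(inter_ids, file.path(dir, "interactome.txt"))
  manifest <- add(manifest, "interactome.txt", length(inter_ids))

  dplyr::bind_rows(manifest)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d genes, %d layers, %d interactome members, seed %d\n",
    x$config$n_genes, length(x$fold_changes),
    sum(x$ground_truth$interactome), x$config$seed
  ))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  flat <- x
  flat$noise_sd_per_layer <- paste(
    sprintf("%s=%g", names(x$noise_sd_per_layer), x$noise_sd_per_layer),
    collapse = ", "
  )
  for (nm in names(flat)) cat(sprintf("  %s: %s\n", nm, format(flat[[nm]])))
  invisible(x)
}
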