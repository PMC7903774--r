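# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: textbook sum formulas and exhaustive
# enumeration.

pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))
}

# P(X >= shared) by enumerating every draw of size_a from a labelled
# universe; feasible for universe <= 15.
hyper_tail_oracle <- function(size_a, size_b, shared, universe) {
  successes <- seq_len(size_b)
  draws <- utils::combn(universe, size_a)
  hits <- apply(draws, 2, function(d) sum(d %in% successes))
  mean(hits >= shared)
}

# Study-condition presets shared by property tests.
translation_dominant_config <- function(seed) {
  synthetic_config(
    n_genes = 5000,
    frac_translational = 0.3,
    translational_up_bias = 1,
    beta_transcription = 0.3,
    noise_sd_per_layer = c(whole_tissue = 0.2, syn_input = 0.2,
                           syn_polysome = 0.2, proteome = 0.2),
    seed = seed
  )
}

null_effect_config <- function(seed, n_genes = 1000) {
  synthetic_config(
    n_genes = n_genes,
    frac_transcriptional = 0,
    frac_translational = 0,
    frac_interactome = 0,
    recruit_effect = 0,
    seed = seed
  )
}

matched_profiles <- function(dataset, ...) {
  match_layers(
    dataset$fold_changes$proteome,
    dataset$fold_changes[transcriptome_layers()],
    ...
  )$profiles
}
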