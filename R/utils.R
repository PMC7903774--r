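#' Omics layers recognised by the pipeline
#'
#' The four abundance layers measured in the striatal study design: the
#' synaptosomal proteome (the ranking standard) and three transcriptome
#' layers — whole tissue RNA, whole synaptosomal ("input") RNA, and the
#' synaptic polysome-enriched fraction, which proxies actively translated
#' mRNA.
#'
#' @return Character vector of layer names.
#' @export
omics_layers <- function() {
  c("whole_tissue", "syn_input", "syn_polysome", "proteome")
}

#' @rdname omics_layers
#' @export
transcriptome_layers <- function() {
  setdiff(omics_layers(), "proteome")
}

#' Normalize gene/protein identifiers
#'
#' Canonical form used for all joins between layers and lists: whitespace
#' trimmed and case folded to lower case. Gene symbols are treated as
#' case-insensitive; accession-to-symbol mapping is assumed done upstream
#' (see [match_layers()] for the optional remap hook).
#'
#' @param raw Character vector of raw identifiers.
#' @return Character vector of normalized identifiers, same length.
#' @examples
#' normalize_identifier(c("Shank3 ", "RPLP1"))
#' @export
normalize_identifier <- function(raw) {
  if (!is.character(raw) || length(raw) == 0) {
    abort_input("`raw` must be a nonempty character vector of identifiers.")
  }
  out <- tolower(trimws(raw))
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    abort_input(sprintf(
      "empty or missing identifier at position(s) %s.",
      paste(utils::head(which(bad), 5L), collapse = ", ")
    ))
  }
  out
}

# Deterministic per-stage sub-stream seed derived from the master seed, so
# that e.g. count simulation for one layer does not perturb the latent draws.
substream_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 100003L
  as.integer((as.numeric(seed) %% 20000L) * 100003L + h)
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "syncordance_config_error")
}

abort_input <- function(msg) {
  rlang::abort(msg, class = "syncordance_input_error")
}

abort_param <- function(msg) {
  rlang::abort(msg, class = "syncordance_param_error")
}

abort_data <- function(msg) {
  rlang::abort(msg, class = "syncordance_data_error")
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort_config(sprintf("`%s` must be a single number in [0, 1].", name))
  }
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort_config(sprintf("`%s` must be a single nonnegative number.", name))
  }
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort_config(sprintf("`%s` must be a single positive number.", name))
  }
}
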