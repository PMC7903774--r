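#' Fold-change table for one omics layer
#'
#' A tibble with columns `id` (normalized identifier) and `log2fc`
#' (log2 fold change, TG relative to WT), carrying the layer name as an
#' attribute. Identifiers must be unique after normalization and all
#' values finite.
#'
#' @param id Character vector of identifiers (normalized internally).
#' @param log2fc Numeric vector of log2 fold changes, same length.
#' @param layer Layer name (free text; the four study layers are listed in
#'   [omics_layers()]).
#' @return A tibble of class `fold_change_table`.
#' @export
fold_change_table <- function(id, log2fc, layer) {
  id <- normalize_identifier(id)
  if (!is.numeric(log2fc) || length(log2fc) != length(id)) {
    abort_input("`log2fc` must be numeric and the same length as `id`.")
  }
  if (any(!is.finite(log2fc))) {
    abort_input(sprintf(
      "non-finite fold change for identifier(s): %s.",
      paste(utils::head(id[!is.finite(log2fc)], 5L), collapse = ", ")
    ))
  }
  if (anyDuplicated(id)) {
    abort_input(sprintf(
      "duplicate identifier(s) after normalization: %s.",
      paste(utils::head(unique(id[duplicated(id)]), 5L), collapse = ", ")
    ))
  }
  out <- tibble::tibble(id = id, log2fc = as.numeric(log2fc))
  attr(out, "layer") <- layer
  class(out) <- c("fold_change_table", class(out))
  out
}

as_fold_change_table <- function(x, layer = NULL) {
  if (inherits(x, "fold_change_table")) {
    if (!is.null(layer)) attr(x, "layer") <- layer
    return(x)
  }
  if (is.data.frame(x) && all(c("id", "log2fc") %in% names(x))) {
    return(fold_change_table(x$id, x$log2fc,
                             layer = layer %||% attr(x, "layer") %||% "unknown"))
  }
  abort_input("expected a fold_change_table or a data frame with `id` and `log2fc`.")
}

#' Layer name of a fold-change table
#' @param x A [fold_change_table()].
#' @return The layer name attribute.
#' @export
fc_layer <- function(x) attr(x, "layer")

#' Read / write fold-change tables
#'
#' TSV with header `id<TAB>log2fc`, one row per identifier.
#'
#' @param path File path.
#' @param layer Layer name to attach on read.
#' @return `read_fold_changes()` returns a [fold_change_table()];
#'   `write_fold_changes()` returns the input invisibly.
#' @export
read_fold_changes <- function(path, layer) {
  if (!file.exists(path)) {
    abort_input(sprintf("fold-change table '%s' does not exist.", path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), log2fc = readr::col_double()
  ))
  if (!all(c("id", "log2fc") %in% names(df))) {
    abort_input(sprintf("'%s' must have columns `id` and `log2fc`.", path))
  }
  fold_change_table(df$id, df$log2fc, layer = layer)
}

#' @rdname read_fold_changes
#' @param x A [fold_change_table()].
#' @export
write_fold_changes <- function(x, path) {
  x <- as_fold_change_table(x)
  readr::write_tsv(tibble::tibble(id = x$id, log2fc = x$log2fc), path)
  invisible(x)
}

#' Compute log2 fold changes from a replicate count matrix
#'
#' Per gene, `log2((mean normalized TG + pseudocount) /
#' (mean normalized WT + pseudocount))`. With
#' `normalization = "library_size"` each sample column is first rescaled so
#' its total equals the mean library size across samples.
#'
#' @param counts A data frame with an `id` column and one numeric column
#'   per sample (e.g. from [simulate_counts()]).
#' @param genotypes Character vector of genotype labels (`"WT"`/`"TG"`),
#'   one per sample column. If `NULL`, inferred from the text before the
#'   first underscore of each sample column name.
#' @param pseudocount Nonnegative value added to both genotype means
#'   before the ratio; default 1 stabilises genes with zero counts.
#' @param normalization `"library_size"` (default) or `"none"`.
#' @param layer Layer name for the returned table; if `NULL`, inferred
#'   from the sample column names when they follow
#'   `<genotype>_<layer>_<replicate>`.
#' @return A [fold_change_table()].
#' @examples
#' counts <- tibble::tibble(id = "shank3", WT_x_1 = 10, WT_x_2 = 10,
#'                          TG_x_1 = 20, TG_x_2 = 20)
#' compute_log2fc(counts, pseudocount = 0)
#' @export
compute_log2fc <- function(counts, genotypes = NULL, pseudocount = 1,
                           normalization = c("library_size", "none"),
                           layer = NULL) {
  normalization <- match.arg(normalization)
  if (!is.data.frame(counts) || !"id" %in% names(counts)) {
    abort_input("`counts` must be a data frame with an `id` column.")
  }
  sample_cols <- setdiff(names(counts), "id")
  if (length(sample_cols) == 0) {
    abort_input("`counts` has no sample columns.")
  }
  mat <- as.matrix(counts[sample_cols])
  if (!is.numeric(mat) || any(is.na(mat))) {
    abort_input("count columns must be numeric with no missing values.")
  }
  if (any(mat < 0)) {
    abort_input("negative counts are not allowed.")
  }
  check_nonneg(pseudocount, "pseudocount")

  if (is.null(genotypes)) {
    genotypes <- toupper(sub("_.*$", "", sample_cols))
  }
  if (length(genotypes) != length(sample_cols) ||
      !all(genotypes %in% c("WT", "TG"))) {
    abort_input("`genotypes` must label every sample column as 'WT' or 'TG'.")
  }
  if (!any(genotypes == "WT") || !any(genotypes == "TG")) {
    abort_input("need at least one replicate per genotype (WT and TG).")
  }
  if (is.null(layer)) {
    tokens <- sub("^[^_]+_", "", sample_cols)
    tokens <- sub("_[^_]*$", "", tokens)
    layer <- if (length(unique(tokens)) == 1 && nzchar(tokens[1])) {
      tokens[1]
    } else {
      "counts"
    }
  }

  if (normalization == "library_size") {
    lib <- colSums(mat)
    if (any(lib == 0)) {
      abort_input("a sample column has zero total counts; cannot library-size normalize.")
    }
    mat <- sweep(mat, 2, mean(lib) / lib, `*`)
  }
  wt_mean <- rowMeans(mat[, genotypes == "WT", drop = FALSE])
  tg_mean <- rowMeans(mat[, genotypes == "TG", drop = FALSE])
  fc <- log2((tg_mean + pseudocount) / (wt_mean + pseudocount))
  if (any(!is.finite(fc))) {
    abort_data(paste0(
      "non-finite fold change (zero mean with pseudocount 0?) for: ",
      paste(utils::head(counts$id[!is.finite(fc)], 5L), collapse = ", "), "."
    ))
  }
  fold_change_table(counts$id, fc, layer = layer)
}

resolve_duplicates <- function(tbl, policy) {
  dup_ids <- unique(tbl$id[duplicated(tbl$id)])
  if (length(dup_ids) == 0) {
    return(tbl)
  }
  if (policy == "error") {
    abort_data(sprintf(
      "duplicate identifiers in layer '%s': %s.",
      attr(tbl, "layer") %||% "?", paste(utils::head(dup_ids, 10L), collapse = ", ")
    ))
  }
  # max_abs keeps the strongest signal; ties broken by first occurrence.
  tbl$.ord <- seq_len(nrow(tbl))
  out <- tbl |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      log2fc = if (policy == "mean") {
        mean(.data$log2fc)
      } else {
        .data$log2fc[order(-abs(.data$log2fc), .data$.ord)][1]
      },
      .groups = "drop"
    )
  out
}

#' Join transcriptome layers onto the proteome standard
#'
#' Builds one matched profile per proteome identifier ("using proteomic
#' change as a standard"): transcript fold changes are joined by
#' normalized identifier, left absent (`NA`) where a layer lacks the gene,
#' and never imputed. Duplicate identifiers within a layer are resolved by
#' `duplicate_policy` before joining.
#'
#' @param proteome A [fold_change_table()] for the proteome layer.
#' @param transcriptomes A list of [fold_change_table()]s, named by layer
#'   (or carrying layer attributes).
#' @param duplicate_policy `"max_abs"` (keep the entry with the largest
#'   absolute fold change; default), `"mean"`, or `"error"`.
#' @param remap Optional data frame `raw_id`, `gene_symbol` applied to all
#'   tables before normalization, for upstream accession-to-symbol fixes.
#' @return A list with `profiles` — a tibble with columns `id`,
#'   `protein_log2fc`, then `<layer>_log2fc` per transcriptome layer — and
#'   `report`, a tibble of matched/unmatched counts per layer.
#' @export
match_layers <- function(proteome, transcriptomes = list(),
                         duplicate_policy = c("max_abs", "mean", "error"),
                         remap = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  proteome <- apply_remap(proteome, remap)
  if (!is.data.frame(proteome) || nrow(proteome) == 0) {
    abort_input("`proteome` table is empty.")
  }
  proteome <- tibble::tibble(
    id = normalize_identifier(proteome$id),
    log2fc = proteome$log2fc
  )
  attr(proteome, "layer") <- "proteome"
  proteome <- resolve_duplicates(proteome, duplicate_policy)
  if (length(transcriptomes) > 0 && is.null(names(transcriptomes))) {
    names(transcriptomes) <- vapply(
      transcriptomes, function(t) attr(t, "layer") %||% NA_character_, ""
    )
  }
  if (anyDuplicated(names(transcriptomes))) {
    abort_input("transcriptome layer names must be distinct.")
  }

  profiles <- tibble::tibble(
    id = proteome$id,
    protein_log2fc = proteome$log2fc
  )
  report <- list()
  for (layer in names(transcriptomes)) {
    tbl <- apply_remap(transcriptomes[[layer]], remap)
    tbl <- tibble::tibble(
      id = normalize_identifier(tbl$id),
      log2fc = tbl$log2fc
    )
    attr(tbl, "layer") <- layer
    tbl <- resolve_duplicates(tbl, duplicate_policy)
    col <- paste0(layer, "_log2fc")
    profiles[[col]] <- tbl$log2fc[match(profiles$id, tbl$id)]
    report[[layer]] <- tibble::tibble(
      layer = layer,
      matched = sum(!is.na(profiles[[col]])),
      unmatched = sum(is.na(profiles[[col]]))
    )
  }
  list(profiles = profiles, report = dplyr::bind_rows(report))
}

apply_remap <- function(tbl, remap) {
  if (is.null(remap)) {
    return(tbl)
  }
  if (!is.data.frame(remap) || !all(c("raw_id", "gene_symbol") %in% names(remap))) {
    abort_input("`remap` must be a data frame with columns `raw_id` and `gene_symbol`.")
  }
  key <- normalize_identifier(remap$raw_id)
  ids <- normalize_identifier(tbl$id)
  hit <- match(ids, key)
  ids[!is.na(hit)] <- normalize_identifier(remap$gene_symbol)[hit[!is.na(hit)]]
  out <- tibble::tibble(id = ids, log2fc = tbl$log2fc)
  attr(out, "layer") <- attr(tbl, "layer")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
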