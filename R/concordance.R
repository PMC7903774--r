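#' Balanced top-N selection by protein fold change
#'
#' Selects the `n/2` most up-regulated and `n/2` most down-regulated
#' identifiers by protein log2 fold change — the balanced ranked subsets
#' the correlation sweep walks through (e.g. top 700 = 350 up / 350 down).
#' Boundary ties are broken by lexical identifier order, so the selection
#' is invariant to input row order. If fewer than `n/2` genes of a sign
#' exist, all of that sign are taken and the shortfall recorded.
#'
#' @param profiles A profiles tibble from [match_layers()] (needs columns
#'   `id` and `protein_log2fc`).
#' @param n Even positive subset size.
#' @return An object of class `ranked_subset`: list with `n_requested`,
#'   `up_ids`, `down_ids` (ordered by decreasing absolute protein fold
#'   change) and `shortfall_up` / `shortfall_down` counts.
#' @export
select_top_balanced <- function(profiles, n) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort_input("`profiles` must be a nonempty data frame.")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0 ||
      n != round(n) || n %% 2 != 0) {
    abort_param("`n` must be a single positive even integer.")
  }
  half <- n / 2
  fc <- profiles$protein_log2fc
  id <- profiles$id

  up_pool <- which(fc > 0)
  up_ord <- up_pool[order(-fc[up_pool], id[up_pool])]
  up_ids <- id[utils::head(up_ord, half)]

  down_pool <- which(fc < 0)
  down_ord <- down_pool[order(fc[down_pool], id[down_pool])]
  down_ids <- id[utils::head(down_ord, half)]

  structure(
    list(
      n_requested = as.integer(n),
      up_ids = up_ids,
      down_ids = down_ids,
      shortfall_up = as.integer(half - length(up_ids)),
      shortfall_down = as.integer(half - length(down_ids))
    ),
    class = "ranked_subset"
  )
}

#' Pairwise-complete correlation with explicit degeneracy reporting
#'
#' Standard product-moment (Pearson) or rank (Spearman) correlation over
#' pairwise-complete observations. Rather than silently returning `NaN`,
#' degenerate inputs are flagged: fewer than 3 complete pairs
#' (`"too_few_pairs"`) or zero variance in either vector
#' (`"zero_variance"`), with `r = NA`.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` in either
#'   are dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `n_pairs` and `status` (`"ok"` or a
#'   degeneracy code).
#' @examples
#' correlate_pairs(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
correlate_pairs <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    abort_param("`x` and `y` must have equal length.")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n_pairs <- length(x)
  if (n_pairs < 3) {
    return(list(r = NA_real_, n_pairs = n_pairs, status = "too_few_pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n_pairs = n_pairs, status = "zero_variance"))
  }
  r <- stats::cor(x, y, method = method)
  list(r = r, n_pairs = n_pairs, status = "ok")
}

#' Ranked-subset correlation sweep across transcriptome layers
#'
#' For each subset size `n` in `n_grid` (balanced `n/2` up / `n/2` down by
#' protein fold change) and each transcriptome layer, correlates protein
#' vs transcript log2 fold changes over the subset's pairwise-complete
#' pairs. Degenerate cells are reported (status column), never abort the
#' sweep. `n_pairs` makes shrinking effective sample sizes visible.
#'
#' @param profiles A profiles tibble from [match_layers()].
#' @param n_grid Descending vector of even subset sizes; default
#'   `seq(700, 100, by = -100)`, the endpoints of the study's sweep with a
#'   step of 100.
#' @param layers Transcriptome layers to sweep; default: every
#'   `<layer>_log2fc` column present in `profiles`.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @return A tibble `layer`, `n`, `n_pairs`, `method`, `r`, `status`,
#'   ordered by layer then descending `n`.
#' @export
sweep_concordance <- function(profiles, n_grid = seq(700, 100, by = -100),
                              layers = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  layers <- resolve_layers(profiles, layers)
  if (length(n_grid) == 0 || is.unsorted(rev(n_grid), strictly = FALSE)) {
    abort_param("`n_grid` must be a nonempty descending vector of subset sizes.")
  }

  rows <- list()
  for (layer in layers) {
    col <- layer_column(profiles, layer)
    for (n in n_grid) {
      subset <- select_top_balanced(profiles, n)
      ids <- c(subset$up_ids, subset$down_ids)
      sel <- profiles[match(ids, profiles$id), ]
      res <- correlate_pairs(sel$protein_log2fc, sel[[col]], method = method)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = layer, n = as.integer(n), n_pairs = res$n_pairs,
        method = method, r = res$r, status = res$status
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Directional top-N concordance (up vs down)
#'
#' Separately correlates the top `n_per_direction` up-regulated proteins
#' (largest positive protein fold change) and the top `n_per_direction`
#' down-regulated proteins (most negative) against each transcriptome
#' layer — the decomposition that shows which direction of the proteomic
#' change carries the polysome concordance. Subsets exhaust the available
#' genes of a sign when `n_per_direction` exceeds them; `n_pairs` reports
#' what was actually used.
#'
#' @inheritParams sweep_concordance
#' @param n_per_direction Number of proteins per direction (>= 3);
#'   default 50.
#' @return A tibble `layer`, `direction`, `n`, `n_pairs`, `method`, `r`,
#'   `status`.
#' @export
directional_concordance <- function(profiles, n_per_direction = 50,
                                    layers = NULL,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  layers <- resolve_layers(profiles, layers)
  if (!is.numeric(n_per_direction) || length(n_per_direction) != 1 ||
      is.na(n_per_direction) || n_per_direction < 3 ||
      n_per_direction != round(n_per_direction)) {
    abort_param("`n_per_direction` must be a single integer >= 3.")
  }
  subset <- select_top_balanced(profiles, 2 * n_per_direction)
  sets <- list(up = subset$up_ids, down = subset$down_ids)

  rows <- list()
  for (layer in layers) {
    col <- layer_column(profiles, layer)
    for (direction in names(sets)) {
      sel <- profiles[match(sets[[direction]], profiles$id), ]
      res <- correlate_pairs(sel$protein_log2fc, sel[[col]], method = method)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = layer, direction = direction,
        n = as.integer(n_per_direction), n_pairs = res$n_pairs,
        method = method, r = res$r, status = res$status
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Permute one layer's values across identifiers
#'
#' Breaks the gene-wise link between the proteome and one transcriptome
#' layer while preserving that layer's marginal distribution — the
#' permutation null for sweep correlations. Because subset sizes are
#' chosen by ranking, nominal correlation p-values would be invalid; this
#' utility is the calibrated alternative.
#'
#' @param profiles A profiles tibble from [match_layers()].
#' @param layer Transcriptome layer to permute.
#' @param seed Integer seed for the permutation.
#' @return The profiles tibble with that layer's column permuted.
#' @export
shuffle_layer <- function(profiles, layer, seed = 1) {
  col <- layer_column(profiles, layer)
  set.seed(as.integer(seed))
  profiles[[col]] <- sample(profiles[[col]])
  profiles
}

resolve_layers <- function(profiles, layers) {
  if (!is.data.frame(profiles) ||
      !all(c("id", "protein_log2fc") %in% names(profiles))) {
    abort_input("`profiles` must have columns `id` and `protein_log2fc`.")
  }
  if (is.null(layers)) {
    layers <- sub("_log2fc$", "",
                  grep("_log2fc$", setdiff(names(profiles), "protein_log2fc"),
                       value = TRUE))
  }
  if (length(layers) == 0) {
    abort_input("no transcriptome layers found in `profiles`.")
  }
  layers
}

layer_column <- function(profiles, layer) {
  if (identical(layer, "proteome")) {
    return("protein_log2fc")
  }
  col <- if (layer %in% names(profiles)) layer else paste0(layer, "_log2fc")
  if (!col %in% names(profiles)) {
    abort_input(sprintf("layer '%s' not present in `profiles`.", layer))
  }
  col
}

#' @export
print.ranked_subset <- function(x, ...) {
  cat(sprintf(
    "<ranked_subset> n = %d: %d up (shortfall %d), %d down (shortfall %d)\n",
    x$n_requested, length(x$up_ids), x$shortfall_up,
    length(x$down_ids), x$shortfall_down
  ))
  invisible(x)
}
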