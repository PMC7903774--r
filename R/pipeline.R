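#' End-to-end pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs for one reproducible run,
#' in either of two modes: `"synthetic"` (generate a ground-truth-bearing
#' dataset) or `"user"` (ingest fold-change TSVs).
#'
#' @param mode `"synthetic"` or `"user"`.
#' @param synthetic A [synthetic_config()]; required in synthetic mode.
#' @param proteome_path Path to the proteome fold-change TSV (user mode).
#' @param transcriptome_paths Named character vector/list of fold-change
#'   TSV paths, names taken as layer names (user mode; at least one).
#' @param interactome_path Optional path to a plain-text interactome list;
#'   in synthetic mode the generator's own interactome members are used
#'   when this is `NULL`.
#' @param n_max,n_min,n_step Sweep grid: even subset sizes from `n_max`
#'   down to `n_min` in steps of `n_step`.
#' @param directional_n Subset size per direction for the up/down
#'   decomposition.
#' @param overlap_n_up Number of top up-regulated proteins intersected
#'   with the interactome list (default 63, a typical size for a
#'   differential proteome hit list).
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param duplicate_policy Passed to [match_layers()].
#' @param pseudocount Passed to [compute_log2fc()] when counts are
#'   quantified.
#' @param seed Integer seed echoed into the manifest (and used as the
#'   synthetic config's seed if one is not supplied explicitly).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "user"),
                            synthetic = NULL,
                            proteome_path = NULL,
                            transcriptome_paths = NULL,
                            interactome_path = NULL,
                            n_max = 700, n_min = 100, n_step = 100,
                            directional_n = 50,
                            overlap_n_up = 63,
                            method = c("pearson", "spearman"),
                            duplicate_policy = c("max_abs", "mean", "error"),
                            pseudocount = 1,
                            seed = 1) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  duplicate_policy <- match.arg(duplicate_policy)
  if (mode == "synthetic") {
    if (is.null(synthetic)) {
      synthetic <- synthetic_config(seed = seed)
    }
    if (!inherits(synthetic, "synthetic_config")) {
      abort_config("synthetic mode requires `synthetic` from `synthetic_config()`.")
    }
  } else {
    if (is.null(proteome_path)) {
      abort_config("user mode requires `proteome_path`.")
    }
    if (is.null(transcriptome_paths) || length(transcriptome_paths) < 1 ||
        is.null(names(transcriptome_paths)) ||
        any(!nzchar(names(transcriptome_paths)))) {
      abort_config("user mode requires >= 1 named entry in `transcriptome_paths`.")
    }
  }
  for (v in list(n_max = n_max, n_min = n_min, n_step = n_step)) {
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v)) {
      abort_config("sweep grid parameters must be positive integers.")
    }
  }
  if (n_min > n_max) {
    abort_config("`n_min` must not exceed `n_max`.")
  }
  structure(
    list(
      mode = mode, synthetic = synthetic,
      proteome_path = proteome_path,
      transcriptome_paths = transcriptome_paths,
      interactome_path = interactome_path,
      n_max = as.integer(n_max), n_min = as.integer(n_min),
      n_step = as.integer(n_step),
      directional_n = as.integer(directional_n),
      overlap_n_up = as.integer(overlap_n_up),
      method = method, duplicate_policy = duplicate_policy,
      pseudocount = pseudocount, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full concordance pipeline
#'
#' Executes simulate/ingest, layer matching, the ranked-subset correlation
#' sweep, the directional decomposition, and (when an interactome list is
#' available) the overlap statistics; writes every table as TSV plus a
#' JSON run manifest into `outdir`. Identical config and seed produce
#' byte-identical bundles. Each stage failure aborts with a message naming
#' the stage.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; default `run_<mode>_seed<seed>` under
#'   the working directory.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `profiles`, `report`, `sweep`,
#'   `directional`, `overlap` (or `NULL`), `manifest` and `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must be created by `pipeline_config()`.")
  }
  outdir <- outdir %||% sprintf("run_%s_seed%d", config$mode, config$seed)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    abort_input(sprintf("cannot create output directory '%s'.", outdir))
  }
  log_lines <- character()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "syncordance_stage_error", parent = e
      )
    })
  }

  interactome_ids <- NULL
  if (config$mode == "synthetic") {
    dataset <- stage("simulate", simulate_multiomics(config$synthetic))
    say("simulate", sprintf("%d genes across %d layers (seed %d)",
                            config$synthetic$n_genes,
                            length(dataset$fold_changes),
                            config$synthetic$seed))
    proteome <- dataset$fold_changes$proteome
    transcriptomes <- dataset$fold_changes[transcriptome_layers()]
    interactome_ids <-
      dataset$ground_truth$id[dataset$ground_truth$interactome]
    for (layer in names(dataset$fold_changes)) {
      write_fold_changes(dataset$fold_changes[[layer]],
                         file.path(outdir, sprintf("fc_%s.tsv", layer)))
    }
  } else {
    proteome <- stage("ingest",
                      read_fold_changes(config$proteome_path, "proteome"))
    transcriptomes <- stage("ingest", {
      out <- lapply(names(config$transcriptome_paths), function(layer) {
        read_fold_changes(config$transcriptome_paths[[layer]], layer)
      })
      names(out) <- names(config$transcriptome_paths)
      out
    })
    say("ingest", sprintf("proteome %d rows; %d transcriptome layer(s)",
                          nrow(proteome), length(transcriptomes)))
  }
  if (!is.null(config$interactome_path)) {
    interactome_ids <- stage("ingest", read_gene_list(config$interactome_path))
  }

  matched <- stage("match", match_layers(
    proteome, transcriptomes, duplicate_policy = config$duplicate_policy
  ))
  for (i in seq_len(nrow(matched$report))) {
    say("match", sprintf("%s: matched %d, unmatched %d",
                         matched$report$layer[i], matched$report$matched[i],
                         matched$report$unmatched[i]))
  }
  readr::write_tsv(matched$profiles, file.path(outdir, "matched.tsv"))
  readr::write_tsv(matched$report, file.path(outdir, "match_report.tsv"))

  n_grid <- seq(config$n_max, config$n_min, by = -config$n_step)
  sweep <- stage("sweep", sweep_concordance(
    matched$profiles, n_grid = n_grid, method = config$method
  ))
  say("sweep", sprintf("%d cells (%d sizes x %d layers)", nrow(sweep),
                       length(n_grid), length(unique(sweep$layer))))
  readr::write_tsv(sweep, file.path(outdir, "sweep.tsv"))

  directional <- stage("directional", directional_concordance(
    matched$profiles, n_per_direction = config$directional_n,
    method = config$method
  ))
  say("directional", sprintf("%d cells at n = %d per direction",
                             nrow(directional), config$directional_n))
  readr::write_tsv(directional, file.path(outdir, "directional.tsv"))

  overlap <- NULL
  if (!is.null(interactome_ids) && length(interactome_ids) > 0) {
    overlap <- stage("overlap", {
      top_up <- select_top_balanced(matched$profiles,
                                    2 * config$overlap_n_up)$up_ids
      overlap_stats(top_up, interactome_ids)
    })
    say("overlap", sprintf(
      "%d of %d top up-regulated proteins in interactome (%.1f%%)",
      overlap$shared, overlap$size_a, overlap$percent_of_a
    ))
    readr::write_tsv(
      tibble::tibble(
        size_a = overlap$size_a, size_b = overlap$size_b,
        shared = overlap$shared, percent_of_a = overlap$percent_of_a,
        shared_ids = paste(overlap$shared_ids, collapse = ";")
      ),
      file.path(outdir, "overlap.tsv")
    )
  }

  manifest <- list(
    package = "syncordance",
    version = as.character(utils::packageVersion("syncordance")),
    seed = config$seed,
    config = serialize_config(config),
    files = sort(setdiff(list.files(outdir), c("manifest.json", "run.log")))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(list(
    profiles = matched$profiles, report = matched$report, sweep = sweep,
    directional = directional, overlap = overlap, manifest = manifest,
    outdir = outdir
  ))
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    syn <- unclass(out$synthetic)
    syn$noise_sd_per_layer <- as.list(syn$noise_sd_per_layer)
    out$synthetic <- syn
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Validate pipeline input files without modifying them
#'
#' Checks each path for existence, expected header, numeric parsability of
#' the fold-change column, and duplicate identifiers. Count matrices
#' (header starting with `id` and more than two columns) are checked for
#' numeric, nonnegative cells.
#'
#' @param paths Character vector of TSV/list file paths.
#' @return A tibble of issues with columns `file`, `line`, `severity`
#'   (`"error"`/`"warning"`) and `message`; zero rows when all inputs are
#'   clean.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  push <- function(file, line, severity, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      file = file, line = line, severity = severity, message = message
    )
  }
  for (path in paths) {
    if (!file.exists(path)) {
      push(path, NA_integer_, "error", "file does not exist")
      next
    }
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0) {
      push(path, NA_integer_, "error", "file is empty")
      next
    }
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (identical(header[1], "id") && length(header) >= 2) {
      ids <- character()
      for (i in seq_along(lines)[-1]) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(fields) != length(header)) {
          push(path, i, "error",
               sprintf("expected %d fields, found %d", length(header),
                       length(fields)))
          next
        }
        vals <- suppressWarnings(as.numeric(fields[-1]))
        if (any(is.na(vals))) {
          push(path, i, "error",
               sprintf("non-numeric value '%s'",
                       fields[-1][which(is.na(vals))[1]]))
        }
        ids <- c(ids, tolower(trimws(fields[1])))
      }
      dup <- unique(ids[duplicated(ids)])
      for (d in dup) {
        push(path, NA_integer_, "warning",
             sprintf("duplicated identifier '%s'", d))
      }
    } else {
      # plain identifier list: flag blank interior lines only
      blank <- which(!nzchar(trimws(lines)))
      for (b in setdiff(blank, length(lines))) {
        push(path, b, "warning", "blank line in identifier list")
      }
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(file = character(), line = integer(),
                   severity = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
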