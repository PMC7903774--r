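#' Overlap statistics between two identifier lists
#'
#' Exact set intersection of two normalized identifier lists, with the
#' headline percentage expressed relative to the first list (`list_a`),
#' e.g. the fraction of an up-regulated proteome explained by membership
#' in a scaffold interactome. Duplicates within a list are collapsed with
#' a warning. The shared count is symmetric in the two lists;
#' `percent_of_a` is not, and the printed report names its denominator.
#'
#' @param list_a,list_b Nonempty character vectors of identifiers
#'   (normalized internally via [normalize_identifier()]).
#' @return An object of class `overlap_result`: list with `size_a`,
#'   `size_b`, `shared`, `percent_of_a` (full precision; the print method
#'   rounds to one decimal) and `shared_ids`.
#' @examples
#' res <- overlap_stats(c("Shank3", "Rplp1", "Drd1"), c("shank3", "homer1"))
#' res$shared
#' @export
overlap_stats <- function(list_a, list_b) {
  a <- collapse_duplicates(normalize_identifier(list_a), "list_a")
  b <- collapse_duplicates(normalize_identifier(list_b), "list_b")
  shared_ids <- sort(intersect(a, b))
  structure(
    list(
      size_a = length(a),
      size_b = length(b),
      shared = length(shared_ids),
      percent_of_a = 100 * length(shared_ids) / length(a),
      shared_ids = shared_ids
    ),
    class = "overlap_result"
  )
}

collapse_duplicates <- function(ids, label) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    rlang::warn(sprintf(
      "%s: collapsed %d duplicate identifier(s): %s.",
      label, length(dup), paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  unique(ids)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> shared %d of %d (list_a denominator) = %.1f%%; list_b size %d\n",
    x$shared, x$size_a, x$percent_of_a, x$size_b
  ))
  invisible(x)
}

#' Tag ribosomal-protein identifiers by symbol prefix
#'
#' Flags identifiers matching ribosomal-protein gene nomenclature:
#' cytosolic large/small subunit (`Rpl*`, `Rps*`, including the acidic
#' stalk `Rplp*`) and, by default, mitochondrial (`Mrpl*`, `Mrps*`).
#' The prefix set is configurable because conventions differ on whether
#' mitochondrial RPs count.
#'
#' @param ids Character vector of identifiers (normalized internally).
#' @param prefixes Character vector of case-insensitive symbol prefixes.
#' @return A list with `ids` (matching identifiers, input order) and
#'   `count`.
#' @examples
#' tag_ribosomal(c("Rplp1", "Rpl36a", "Shank3"))
#' @export
tag_ribosomal <- function(ids, prefixes = c("rpl", "rps", "mrpl", "mrps")) {
  ids <- normalize_identifier(ids)
  pattern <- paste0("^(", paste(tolower(prefixes), collapse = "|"), ")")
  hits <- ids[grepl(pattern, ids)]
  list(ids = hits, count = length(hits))
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `shared` common members when
#' `size_a` identifiers are drawn without replacement from a universe of
#' `universe` genes of which `size_b` are in the reference list. A
#' calibrated null for list overlaps; the universe must be supplied by
#' the user since no canonical default exists.
#'
#' @param size_a,size_b Sizes of the two lists.
#' @param shared Observed overlap count.
#' @param universe Total number of genes both lists are drawn from.
#' @return `P(X >= shared)` as a single number.
#' @export
hypergeometric_overlap_p <- function(size_a, size_b, shared, universe) {
  for (v in list(size_a = size_a, size_b = size_b, shared = shared,
                 universe = universe)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 ||
        v != round(v)) {
      abort_param("all counts must be single nonnegative integers.")
    }
  }
  if (shared > min(size_a, size_b) || max(size_a, size_b) > universe) {
    abort_param("inconsistent counts: need shared <= min(size_a, size_b) <= universe.")
  }
  stats::phyper(shared - 1, size_b, universe - size_b, size_a,
                lower.tail = FALSE)
}

#' Read / write plain-text identifier lists
#'
#' One identifier per line; blank lines ignored on read.
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector of normalized
#'   identifiers; `write_gene_list()` returns `ids` invisibly.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("gene list '%s' does not exist.", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_input(sprintf("gene list '%s' is empty.", path))
  }
  normalize_identifier(lines)
}

#' @rdname read_gene_list
#' @param ids Character vector of identifiers.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(normalize_identifier(ids), path)
  invisible(ids)
}
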