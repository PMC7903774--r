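test_that("identifier normalization trims, case-folds and rejects empties", {
  expect_identical(normalize_identifier("Shank3 "), "shank3")
  expect_identical(normalize_identifier("SHANK3"), normalize_identifier("Shank3"))
  expect_identical(normalize_identifier("Rplp1"), "rplp1")
  expect_error(normalize_identifier("   "), class = "syncordance_input_error")
  expect_error(normalize_identifier(character()), class = "syncordance_input_error")
})

test_that("fold-change tables enforce uniqueness and finiteness", {
  tbl <- fold_change_table(c("A", "b"), c(1, -2), layer = "proteome")
  expect_identical(tbl$id, c("a", "b"))
  expect_identical(fc_layer(tbl), "proteome")
  expect_error(fold_change_table(c("a", "A"), c(1, 2), "proteome"),
               class = "syncordance_input_error")
  expect_error(fold_change_table("a", NaN, "proteome"),
               class = "syncordance_input_error")
})

test_that("log2 fold change from counts matches hand-computed cases", {
  counts <- tibble::tibble(
    id = "g1",
    WT_x_1 = 10, WT_x_2 = 10, WT_x_3 = 10,
    TG_x_1 = 20, TG_x_2 = 20, TG_x_3 = 20
  )
  # equal library sizes within genotype; exact doubling
  fc <- compute_log2fc(counts, pseudocount = 0, normalization = "none")
  expect_equal(fc$log2fc, 1.0)
  expect_identical(fc_layer(fc), "x")

  same <- tibble::tibble(id = c("g1", "g2"),
                         WT_x_1 = c(5, 7), TG_x_1 = c(5, 7))
  expect_equal(compute_log2fc(same, pseudocount = 0,
                              normalization = "none")$log2fc, c(0, 0))

  zero_wt <- tibble::tibble(id = "g1", WT_x_1 = 0, TG_x_1 = 3)
  expect_equal(
    compute_log2fc(zero_wt, pseudocount = 1, normalization = "none")$log2fc,
    log2(4 / 1)
  )
})

test_that("library-size normalization equalizes depth before averaging", {
  # TG column sequenced twice as deep; gene truly unchanged
  counts <- tibble::tibble(id = c("g1", "g2"),
                           WT_x_1 = c(10, 90), TG_x_1 = c(20, 180))
  fc <- compute_log2fc(counts, pseudocount = 0, normalization = "library_size")
  expect_equal(fc$log2fc, c(0, 0))
  raw <- compute_log2fc(counts, pseudocount = 0, normalization = "none")
  expect_equal(raw$log2fc, c(1, 1))
})

test_that("fold changes are antisymmetric under genotype swap", {
  cfg <- synthetic_config(n_genes = 30, seed = 8)
  fc_true <- fold_change_table(sprintf("g%05d", 1:30),
                               stats::rnorm(30, 0, 0.5), layer = "syn_input")
  counts <- simulate_counts(cfg, fc_true, "syn_input")
  fwd <- compute_log2fc(counts, pseudocount = 0)
  swapped <- counts
  names(swapped) <- sub("^WT_", "XX_", names(swapped))
  names(swapped) <- sub("^TG_", "WT_", names(swapped))
  names(swapped) <- sub("^XX_", "TG_", names(swapped))
  rev <- compute_log2fc(swapped, pseudocount = 0)
  expect_equal(rev$log2fc, -fwd$log2fc)
})

test_that("quantification recovers generating fold changes at high replication", {
  cfg <- synthetic_config(n_genes = 20, n_replicates = 200, seed = 17)
  true_fc <- seq(-1.5, 1.5, length.out = 20)
  fc_tbl <- fold_change_table(sprintf("g%05d", 1:20), true_fc, layer = "syn_input")
  counts <- simulate_counts(cfg, fc_tbl, "syn_input")
  est <- compute_log2fc(counts, pseudocount = 0, normalization = "none")
  mat <- as.matrix(counts[-1])
  wt <- mat[, grepl("^WT_", colnames(mat))]
  tg <- mat[, grepl("^TG_", colnames(mat))]
  # delta-method SE of the log2 mean ratio
  se <- sqrt(
    apply(tg, 1, var) / (200 * rowMeans(tg)^2) +
      apply(wt, 1, var) / (200 * rowMeans(wt)^2)
  ) / log(2)
  expect_true(all(abs(est$log2fc - true_fc) < 3 * se))
})

test_that("invalid count input is rejected", {
  counts <- tibble::tibble(id = "g1", WT_x_1 = -1, TG_x_1 = 2)
  expect_error(compute_log2fc(counts), class = "syncordance_input_error")
  only_wt <- tibble::tibble(id = "g1", WT_x_1 = 1, WT_x_2 = 2)
  expect_error(compute_log2fc(only_wt), class = "syncordance_input_error")
})

test_that("layer matching joins on the proteome standard", {
  proteome <- fold_change_table(c("shank3", "drd1"), c(2, 1), "proteome")
  rna <- fold_change_table("shank3", 0.5, "syn_polysome")
  res <- match_layers(proteome, list(syn_polysome = rna))
  expect_identical(res$profiles$id, c("shank3", "drd1"))
  expect_equal(res$profiles$syn_polysome_log2fc, c(0.5, NA))
  expect_equal(res$report$matched, 1L)
  expect_equal(res$report$unmatched, 1L)

  # empty transcriptome list: protein values only
  alone <- match_layers(proteome, list())
  expect_identical(names(alone$profiles), c("id", "protein_log2fc"))
})

test_that("duplicate transcript entries are resolved per policy", {
  proteome <- fold_change_table("rplp1", 1, "proteome")
  dup <- tibble::tibble(id = c("rplp1", "Rplp1"), log2fc = c(0.2, -0.6))
  attr(dup, "layer") <- "syn_input"

  maxabs <- match_layers(proteome, list(syn_input = dup),
                         duplicate_policy = "max_abs")
  expect_equal(maxabs$profiles$syn_input_log2fc, -0.6)

  avg <- match_layers(proteome, list(syn_input = dup),
                      duplicate_policy = "mean")
  expect_equal(avg$profiles$syn_input_log2fc, mean(c(0.2, -0.6)))

  expect_error(
    match_layers(proteome, list(syn_input = dup), duplicate_policy = "error"),
    "rplp1", class = "syncordance_data_error"
  )

  # |fc| tie: first occurrence wins, regardless of sign
  tie <- tibble::tibble(id = c("rplp1", "rplp1"), log2fc = c(0.4, -0.4))
  tied <- match_layers(proteome, list(syn_input = tie))
  expect_equal(tied$profiles$syn_input_log2fc, 0.4)
})

test_that("matching never drops or invents proteome identifiers", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(5:60, 1)
    proteome <- fold_change_table(paste0("p", seq_len(n)),
                                  rnorm(n), "proteome")
    keep <- sample(n, sample.int(n, 1))
    rna <- fold_change_table(paste0("p", keep), rnorm(length(keep)),
                             "syn_input")
    res <- match_layers(proteome, list(syn_input = rna))
    expect_identical(res$profiles$id, proteome$id)
    expect_identical(res$report$matched + res$report$unmatched, n)
  }
})

test_that("an optional remap table redirects identifiers before the join", {
  proteome <- tibble::tibble(id = c("P99999", "drd1"), log2fc = c(2, 1))
  rna <- fold_change_table("shank3", 0.5, "syn_input")
  remap <- tibble::tibble(raw_id = "P99999", gene_symbol = "Shank3")
  res <- match_layers(proteome, list(syn_input = rna), remap = remap)
  expect_identical(res$profiles$id[1], "shank3")
  expect_equal(res$profiles$syn_input_log2fc, c(0.5, NA))
})
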