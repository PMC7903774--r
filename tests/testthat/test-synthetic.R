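test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_genes = 5), class = "syncordance_config_error")
  expect_error(synthetic_config(frac_translational = 1.2), "frac_translational",
               class = "syncordance_config_error")
  expect_error(synthetic_config(sigma_translation = -1), "sigma_translation",
               class = "syncordance_config_error")
  expect_error(synthetic_config(n_replicates = 1), "n_replicates",
               class = "syncordance_config_error")
  expect_error(synthetic_config(baseline_mean = 0), "baseline_mean",
               class = "syncordance_config_error")
  expect_error(synthetic_config(dispersion = 0), "dispersion",
               class = "syncordance_config_error")
  expect_error(
    synthetic_config(noise_sd_per_layer = c(proteome = 0.1)),
    "noise_sd_per_layer", class = "syncordance_config_error"
  )
})

test_that("identical config and seed give identical datasets; seeds differ", {
  cfg <- synthetic_config(n_genes = 300, seed = 11)
  a <- simulate_multiomics(cfg, counts = TRUE)
  b <- simulate_multiomics(cfg, counts = TRUE)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$fold_changes, b$fold_changes)
  expect_identical(a$counts, b$counts)
  c <- simulate_multiomics(synthetic_config(n_genes = 300, seed = 12))
  expect_false(identical(a$fold_changes$proteome$log2fc,
                         c$fold_changes$proteome$log2fc))
})

test_that("all layers cover the same identifier set", {
  ds <- simulate_multiomics(synthetic_config(n_genes = 120, seed = 2))
  ids <- ds$ground_truth$id
  for (layer in names(ds$fold_changes)) {
    expect_identical(ds$fold_changes[[layer]]$id, ids)
  }
})

test_that("zero effects and zero noise give exactly zero fold changes off the interactome", {
  cfg <- synthetic_config(
    n_genes = 100, sigma_transcription = 0, sigma_translation = 0,
    noise_sd_per_layer = c(whole_tissue = 0, syn_input = 0,
                           syn_polysome = 0, proteome = 0),
    seed = 5
  )
  ds <- simulate_multiomics(cfg)
  non_inter <- !ds$ground_truth$interactome
  for (layer in names(ds$fold_changes)) {
    expect_equal(ds$fold_changes[[layer]]$log2fc[non_inter],
                 rep(0, sum(non_inter)))
  }
  # interactome members still carry the recruitment shift on the proteome
  expect_equal(
    ds$fold_changes$proteome$log2fc[!non_inter],
    rep(cfg$recruit_effect, sum(!non_inter))
  )
})

test_that("interactome membership count is exactly round(frac * n_genes)", {
  for (frac in c(0, 0.05, 0.131)) {
    ds <- simulate_multiomics(
      synthetic_config(n_genes = 700, frac_interactome = frac, seed = 3)
    )
    expect_identical(sum(ds$ground_truth$interactome), as.integer(round(frac * 700)))
  }
})

test_that("without a translational channel the polysome layer is no more protein-concordant than input", {
  diffs <- vapply(1:20, function(seed) {
    ds <- simulate_multiomics(synthetic_config(
      n_genes = 2000, alpha_translation = 0, recruit_effect = 0, seed = seed
    ))
    fc <- ds$fold_changes
    cor(fc$proteome$log2fc, fc$syn_polysome$log2fc) -
      cor(fc$proteome$log2fc, fc$syn_input$log2fc)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("count simulation matches its negative-binomial moments", {
  cfg <- synthetic_config(n_genes = 40, n_replicates = 200, seed = 9)
  # one null gene, one exact doubling
  fc <- fold_change_table(
    sprintf("g%05d", 1:40), rep(c(0, 1), each = 20), layer = "syn_input"
  )
  counts <- simulate_counts(cfg, fc, "syn_input")
  mat <- as.matrix(counts[-1])
  wt <- mat[, grepl("^WT_", colnames(mat))]
  tg <- mat[, grepl("^TG_", colnames(mat))]
  expect_identical(ncol(wt), 200L)

  # fold change 0: WT and TG means agree within 3 SE
  for (g in 1:20) {
    se <- sqrt(var(wt[g, ]) / 200 + var(tg[g, ]) / 200)
    expect_lt(abs(mean(tg[g, ]) - mean(wt[g, ])), 3 * se)
  }
  # fold change 1: TG/WT mean ratio approximately 2
  ratios <- rowMeans(tg[21:40, ]) / rowMeans(wt[21:40, ])
  expect_lt(abs(mean(ratios) - 2), 0.1)

  # overdispersion: variance/mean well above 1 at moderate dispersion
  vm <- apply(wt, 1, var) / rowMeans(wt)
  expect_gt(mean(vm), 2)
})

test_that("large dispersion approaches the Poisson variance/mean limit", {
  cfg <- synthetic_config(n_genes = 50, n_replicates = 200,
                          dispersion = 1e9, seed = 13)
  fc <- fold_change_table(sprintf("g%05d", 1:50), rep(0, 50), layer = "syn_input")
  counts <- simulate_counts(cfg, fc, "syn_input")
  wt <- as.matrix(counts[grepl("^WT_", names(counts))])
  vm <- apply(wt, 1, var) / rowMeans(wt)
  expect_lt(abs(mean(vm) - 1), 0.1)
})

test_that("count columns encode genotype, layer and replicate", {
  cfg <- synthetic_config(n_genes = 10, n_replicates = 3, seed = 1)
  fc <- fold_change_table(sprintf("g%05d", 1:10), rep(0, 10), layer = "syn_polysome")
  counts <- simulate_counts(cfg, fc, "syn_polysome")
  expect_identical(
    names(counts),
    c("id", sprintf("WT_syn_polysome_%d", 1:3), sprintf("TG_syn_polysome_%d", 1:3))
  )
})

test_that("fixtures round-trip through TSV and the manifest matches", {
  dir <- withr::local_tempdir()
  ds <- simulate_multiomics(synthetic_config(n_genes = 700, seed = 4),
                            counts = TRUE)
  manifest <- write_fixtures(ds, dir)
  expect_setequal(
    manifest$file,
    c(sprintf("fc_%s.tsv", omics_layers()),
      sprintf("counts_%s.tsv", transcriptome_layers()),
      "ground_truth.tsv", "interactome.txt")
  )
  back <- read_fold_changes(file.path(dir, "fc_proteome.tsv"), "proteome")
  expect_equal(back$id, ds$fold_changes$proteome$id)
  expect_equal(back$log2fc, ds$fold_changes$proteome$log2fc)

  inter <- readLines(file.path(dir, "interactome.txt"))
  expect_identical(length(inter), as.integer(round(0.05 * 700)))
  expect_identical(manifest$rows[manifest$file == "interactome.txt"],
                   length(inter))

  # no counts -> no count files in the manifest
  ds2 <- simulate_multiomics(synthetic_config(n_genes = 20, seed = 4))
  dir2 <- withr::local_tempdir()
  manifest2 <- write_fixtures(ds2, dir2)
  expect_false(any(grepl("^counts_", manifest2$file)))
})

test_that("written fixtures are byte-identical across runs with the same seed", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 150, seed = 21)
  write_fixtures(simulate_multiomics(cfg, counts = TRUE), dir_a)
  write_fixtures(simulate_multiomics(cfg, counts = TRUE), dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
})
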