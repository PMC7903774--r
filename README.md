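# syncordance

Multi-omics fold-change concordance analysis for synaptosomal proteomes.

## The problem

When a synaptic scaffolding protein such as Shank3 is overexpressed, the
protein composition of the synaptosome changes. Two mechanisms can move a
protein's synaptic abundance: physical recruitment by the overexpressed
scaffold, and increased local synthesis from synaptically localized,
polysome-engaged mRNAs. `syncordance` implements the desk-side analysis
that separates these explanations using only fold-change tables:

1. **Overlap statistics** — how much of the up-regulated proteome is
   explained by membership in the scaffold's interactome? If only a small
   share (e.g. 8 of 63 proteins, 12.7%) physically interacts with the
   scaffold, recruitment cannot be the whole story.
2. **Ranked-subset correlation sweeps** — with the proteomic change as the
   standard, the per-gene protein log2 fold change (TG vs WT) is
   correlated with the transcript log2 fold change of three RNA layers:
   whole tissue, whole synaptosome ("input"), and the synaptic
   polysome-enriched fraction (a proxy for the actively translated
   mRNA pool). The correlation r(N) is computed on balanced top-N subsets
   (N/2 most up-regulated plus N/2 most down-regulated proteins) for N
   stepping from 700 down to 100. A layer whose concordance *grows* as the
   subset narrows to the strongest protein changes carries a genuine
   signal; local translation predicts this only for the polysome layer.
3. **Directional decomposition** — the top 50 up-regulated and top 50
   down-regulated proteins are correlated separately per layer. Local
   synthesis adds protein, so only the up-regulated half should gain
   polysome concordance.

Formally, for a balanced subset S_N ranked by protein log2 fold change
p_g, the sweep statistic per layer L is the Pearson (optionally Spearman)
correlation r_L(N) = cor({p_g}, {t_Lg}) over pairwise-complete pairs
g in S_N, and the overlap statistic for lists A (up-regulated proteome)
and B (interactome) is |A ∩ B| with the headline percentage
100·|A ∩ B|/|A|. An upper-tail hypergeometric probability for the overlap
is available when the user supplies a gene universe.

Because the subset sizes are chosen by ranking, no nominal correlation
p-values are reported; a permutation null (`shuffle_layer()`) is the
calibrated alternative.

The package also contains a first-class synthetic-data module: a
generative model with per-gene latent transcription effects, sign-biased
polysome-specific translation effects, a scaffold-interactome recruitment
channel, Gaussian measurement noise per layer, and negative-binomial
replicate count matrices (three WT/TG pairs by default). Every downstream
stage is validated against this ground truth.

## Worked example

```r
library(syncordance)

cfg <- pipeline_config("synthetic",
                       synthetic = synthetic_config(n_genes = 2000, seed = 1),
                       seed = 1)
res <- run_pipeline(cfg, outdir = "demo_run")
#> [simulate] 2000 genes across 4 layers (seed 1)
#> [match] whole_tissue: matched 2000, unmatched 0
#> ...
#> [sweep] 21 cells (7 sizes x 3 layers)
#> [directional] 6 cells at n = 50 per direction
#> [overlap] 8 of 63 top up-regulated proteins in interactome (12.7%)

tidyr::pivot_wider(res$sweep[, c("layer", "n", "r")],
                   names_from = layer, values_from = r)
#>       n whole_tissue syn_input syn_polysome
#>   <int>        <dbl>     <dbl>        <dbl>
#> 1   700        0.236     0.249        0.759
#> 2   600        0.256     0.253        0.781
#> 3   500        0.258     0.276        0.804
#> 4   400        0.279     0.307        0.827
#> 5   300        0.321     0.327        0.859
#> 6   200        0.366     0.353        0.887
#> 7   100        0.447     0.403        0.917

res$directional[res$directional$layer == "syn_polysome",
                c("direction", "n_pairs", "r")]
#>   direction n_pairs     r
#> 1 up             50 0.764
#> 2 down           50 0.468
```

Reading the numbers: only the polysome layer's correlation is high and
rises monotonically (0.76 → 0.92) as the subset narrows from the top 700
to the top 100 proteins — the signature of a translational contribution —
while the whole-tissue and input layers stay near the transcription-only
baseline. In the directional split, the up-regulated half carries most of
the polysome concordance (0.76 vs 0.47), as expected if local synthesis
adds protein. The run directory contains every table as TSV plus
`manifest.json`; rerunning with the same config and seed reproduces the
bundle byte for byte.

For the overlap worked example, the package ships deterministic
*synthetic stand-in* lists (the study's real lists are not publicly
deposited) that reproduce the published list structure:

```r
refs <- synthetic_reference_lists()
overlap_stats(refs$upregulated, refs$interactome)
#> <overlap_result> shared 8 of 63 (list_a denominator) = 12.7%; list_b size 793
tag_ribosomal(refs$upregulated)$count
#> [1] 6
```

User data enter through `pipeline_config("user", ...)` with fold-change
TSVs (`id<TAB>log2fc`) per layer, or from replicate count matrices via
`compute_log2fc()`. `validate_inputs()` checks files before a run, and
`inst/scripts/concord.R` wraps the pipeline for shell use.

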