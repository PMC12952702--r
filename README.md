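# idrscope

Intrinsically disordered regions (IDRs) dominate the proteins of the human
spliceosome: they interlace protein and RNA components across the splicing
cycle, are dense in regulatory post-translational modifications (PTMs), and
harbour cancer-associated variants. `idrscope` is an R package that turns
per-residue disorder evidence into a complete, reproducible analysis of a
(spliceosomal or other) proteome:

* **Region calling** — threshold/merge/minimum-length segmentation of
  per-residue disorder scores into ordered and disordered regions, with
  per-complex and per-class disorder summaries (per-protein vs per-residue
  means, box-plot five-number statistics, Tukey outliers).
* **IDR typing** — classification of long (≥ 25 residue) IDRs by
  compositional bias — RS-like, poly-P/Q, G-rich (Gly runs, RGG, [RSY]GG,
  R[AGT][AGTFIVR]), charged, noncharged (≥ 3-fold over vertebrate
  background) — and annotation of SS-IDRs, disordered regions carrying
  α-helical or β-strand elements.
* **PTM statistics** — residue-level 2×2 partition of PTM-bearing sites by
  region kind with a Fisher exact enrichment test (statistic: sample odds
  ratio *ad/bc*), paired Wilcoxon comparison of per-protein PTM densities,
  and annotation-level per-type in-IDR ratios and percentage distributions.
* **Mutation analysis** — mapping of cancer-associated variants onto typed
  regions, per-family and per-tumor-type summaries, and a within-protein
  permutation test for mutations flanking PTM sites (|Δposition| ≤ 5).
* **Evolutionary (DOT) analysis** — disorder calls mapped onto ortholog
  alignment columns; disorder-to-order transitions scored as binary-state
  Fitch parsimony changes per column (`changes per node` = Σ changes /
  (edges × scored columns)); Mann–Whitney comparison of SS-IDR columns vs
  other disordered columns; per-clade net gain of disorder via DELTRAN
  ancestral-state resolution.
* **Synthetic benchmark generator** — fully seeded simulation of proteomes
  with planted disordered segments, CB motifs, SS elements, PTMs at a
  controlled disordered/ordered odds ratio, PTM-flanking mutations and
  ortholog families evolved under per-edge gain/loss rates, with complete
  ground-truth bookkeeping.

## Worked example

```r
library(idrscope)

cfg <- sim_config(n_proteins = 40, n_families = 2, n_taxa = 8, seed = 42)
sim <- simulate_proteins(cfg)
pm  <- simulate_ptms_and_mutations(cfg, sim)

regions <- call_regions_all(sim$profiles)           # threshold 0.5
typed   <- type_regions(sim$proteins, regions, sim$ss)

summarize_group(sim$proteins, typed, by = "class")[1:4, c(1:4, 7)]
#>           group n_proteins per_protein_mean per_residue_mean median
#> 1      EJC/mRNP          5            43.18            43.24  46.08
#> 2         hnRNP          2            60.20            60.14  60.20
#> 3           LSM          8            46.91            48.33  45.15
#> 4 Prp19 complex          3            47.78            50.98  46.69
```

`per_protein_mean` averages each protein's disorder percentage (every
protein counts equally); `per_residue_mean` pools residues, so long
proteins weigh more.  PTM enrichment on the same dataset:

```r
part <- partition_ptms(pm$ptms, typed, protein_lengths(sim$proteins))
part$pooled
#>    a    b    c    d
#>  260 7882   76 8375
fisher_enrichment(part)
#> Fisher exact test (two_sided), sample odds ratio
#>   statistic = 3.63503   p = 8.346e-27   n = 16593
```

260 of the 8142 disordered residues carry a PTM versus 76 of 8451 ordered
residues — an odds ratio of 3.6, consistent with the simulated
disordered/ordered PTM odds ratio of 3.  The typing stage recovers every
planted compositionally biased segment in this run:

```r
subtype_recovery(sim$truth$regions, typed, protein_lengths(sim$proteins))
#>      subtype n_truth n_called precision recall
#> 1      CB_RS     400      400         1      1
#> 2      CB_PQ     400      400         1      1
#> 3       CB_G     400      400         1      1
#> 4 CB_CHARGED     400      400         1      1
```

And the DOT stage on a simulated ortholog family (per-edge gain/loss
probability 0.05) yields a changes-per-node rate of about 0.045:

```r
fams <- simulate_families(cfg, sim)
fam  <- fams$families[[1]]
cm   <- build_character_matrix(fam, fams$ortholog_regions)
ds   <- dot_summary(cm, fam$tree,
                    typed[typed$protein_id == fam$reference_id, ],
                    ss_idr_site_set(typed[typed$protein_id == fam$reference_id, ],
                                    cm, fam$reference_id))
ds$changes_per_node
#> [1] 0.0453
```

The whole chain — including mutation reports and run manifest — can be run
in one step with `run_all(pipeline_config(...))` on any dataset written by
`simulate_dataset()` or assembled from real score/site tables (see the
vignette for file formats).

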