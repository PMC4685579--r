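# hydraplast

Transcriptomic cross-analysis of epithelial plasticity in *Hydra* after
ablation of the interstitial stem-cell lineage.

## The problem

*Hydra*'s nervous system (neurons, nematocytes) and gland cells derive from
interstitial stem cells (i-cells). The two epitheliomuscular lineages —
ectodermal and endodermal — survive when the interstitial lineage is
eliminated by hydroxyurea (HU), heat shock (HS, in a thermosensitive strain)
or colchicine (Col), and the animals remain developmentally competent. Which
genes do the surviving epithelial cells up-regulate to compensate for the
loss of neurogenesis? Answering that requires crossing three bulk RNA-seq
designs:

1. **spatial** — five regions along the apico-basal axis (head H, upper body
   column R1, central body column R3 and R4, foot F; there is no R2 slice),
   three biological replicates each;
2. **treatment** — body-column samples from starved controls (3/4/6/10 d) and
   the HU (days 0/1/3/7 post-treatment), HS (day 7) and Col (day 10) arms,
   3–4 replicates, 37 samples in total;
3. **cell type** — FACS-sorted ectodermal, endodermal and i-cell fractions
   (4 replicates each) plus unsorted body column (2 samples).

`hydraplast` re-implements the full analysis as a tested R package, and ships
synthetic-data generators for all three designs with per-gene ground truth so
every stage has a parameter-recovery test surface.

## The statistics at the core

* **Normalization**: median-of-ratios size factors
  `s_j = median_g( K_gj / (prod_j K_gj)^(1/m) )` over zero-free reference
  genes, rescaled to geometric mean 1; variants for ablation designs (stable
  reference refit) and compositionally disjoint FACS fractions (within-group
  fit).
* **Differential expression**: per-gene NB model on normalized counts,
  method-of-moments dispersion shrunk onto an `a0 + a1/mu` trend, Wald
  statistic `log2FC / SE` against a normal reference, Benjamini–Hochberg FDR.
* **Selection rules** (the study's stated criteria): up-regulated =
  fold ≥ 2 with FDR ≤ 0.1; "collapsed" = retention ≤ 0.10 (>90% reduction);
  **i-cell-loss** signature = collapsed in all three arms; **gland**
  signature = collapsed after Col but stable-or-elevated (fold ≥ 0.8) in HU
  and HS; **plasticity candidate** = supported ≥2-fold up-regulation in at
  least 2 of the 3 arms.
* **Axial patterns**: a deterministic rule cascade on the max-normalized
  5-region profile — foot-restricted, apical, basal, bipolar, graded (both
  directions, via isotonic-regression fit), apolar, ubiquitous, ambiguous.
* **Ternary composition**: per-gene geometric-mean shares across the three
  sorted fractions (simplex coordinates), plus a contamination index of each
  fraction against unsorted tissue.
* **Morphometrics**: the RFamide basal index (RF⁺ peduncle length /
  peduncle diameter) with a two-sided Welch t-test and a two-sided
  variance-ratio F-test.

## Worked example

Simulate the three designs under the default "stated world" (1000 genes, 25
planted epithelial plasticity genes, 9 gland-signature genes, 200
interstitial-lineage genes, NB dispersion 0.1) and run the whole
cross-analysis:

```r
library(hydraplast)
pl <- run_pipeline()

table(pl$signatures$label)
#>           down_other      gland_signature           icell_lost
#>                    8                    8                  192
#> plasticity_candidate         unresponsive             up_other
#>                   27                  757                    8

pl$venn_up$cells
#>   HU_only   HS_only  Col_only     HU_HS    HU_Col    HS_Col HU_HS_Col
#>         2         2         4         1         0         1        25

head(pl$cross$candidates[, c("gene_id","max_fold","contexts_up","celltype","pattern")], 5)
#>   gene_id max_fold contexts_up        celltype                pattern
#> 1   g0017 6.542877   HU,HS,Col            endo graded_apical_to_basal
#> 2   g0012 6.205524   HU,HS,Col            endo             ubiquitous
#> 3   g0022 6.189222   HU,HS,Col both_epithelial                 apical
#> 4   g0004 6.078977   HU,HS,Col            ecto             ubiquitous
#> 5   g0014 6.069251   HU,HS,Col            endo             ubiquitous

pl$contamination$per_set
#>           set   n median_ratio
#> 1 gland_truth 200    0.1022488
```

Reading the output: 192 of the 200 planted interstitial-lineage genes are
called `icell_lost` (>90% down in all three arms); 25 of the 27
`plasticity_candidate` calls are the 25 planted plasticity genes, and after
the cell-type join the final epithelial candidate table holds them sorted by
maximal fold. The triple-intersection Venn cell (25) is the planted candidate
set. The endo-fraction contamination index over the gland gene set estimates
0.102 against a configured truth of 0.08 — within the ±30% recovery band the
estimator is tested to.

## Command line

```sh
inst/cli/hydraplast simulate  --seed 1 --out-dir out/
inst/cli/hydraplast signatures --counts out/counts_treatment.tsv \
    --sheet out/sheet_treatment.tsv --out-dir out/
inst/cli/hydraplast run-all --seed 1 --out-dir out/
```

Subcommands: `simulate`, `normalize`, `de`, `spatial`, `celltype`,
`signatures`, `morpho`, `run-all`; global flags `--config`, `--seed`,
`--out-dir`, `--log-level`, plus per-threshold overrides (`--up-fold`,
`--fdr-alpha`, ...). All outputs are byte-deterministic under a fixed seed.

## Documentation

The methods vignette (`vignettes/plasticity-pipeline.Rmd`) documents the
models, every tunable threshold with its default and rationale, what the
synthetic generators do and do not emulate, and known limitations.
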