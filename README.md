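# coldsplice

Quantification toolkit for cold-repressed poison-exon (PE) splicing and
the assays that establish its regulation.

Poison exons carry in-frame premature termination codons: when included,
the transcript is routed to nonsense-mediated decay (NMD), so PE inclusion
tunes gene output post-transcriptionally. In the cold-shock gene RBM3,
moderate hypothermia (32 °C) represses PE inclusion — percent spliced in
(PSI) drops roughly tenfold — and splicing factors such as HNRNPH1 drive
the switch through G-rich (G-quadruplex-forming) elements near the exon.
`coldsplice` is for RNA biologists and analysts who need the bespoke
quantifications around such a finding as reusable, tested components.

## What it computes

| Assay | Functions | Statistic |
|---|---|---|
| Junction-read PSI | `extract_junction_counts()`, `junction_psi()` | Ψ = (I/ℓ_inc) / (I/ℓ_inc + S/ℓ_skip), effective lengths ℓ_inc = 2ℓ, ℓ_skip = ℓ |
| Gel PSI | `gel_psi()` | Σ(I_inc/L_inc) / (Σ(I_inc/L_inc) + I_skip/L_skip) — length-normalized, mass-proportional staining |
| qPCR PE inclusion | `relative_expression()`, `pe_inclusion_ratio()` | 2^(Ct_ref − Ct) ratios, PE over constitutive amplicons (geometric-mean mode default) |
| RIP enrichment | `rip_fold_change()` | IP change normalized by input change and pulldown efficiency |
| CRISPR screen | `count_guides()`, `gene_score()` | exact 20-mer match counting; z vs non-targeting null, permutation p, BH q |
| Image quantification | `quantify_cell()` | per-unit-area soma/nucleus/cytoplasm means after Otsu segmentation |
| iCLIP / G4 | `normalize_track()`, `smooth_track()`, `scan_g4()` | crosslinks per million, window-5 rolling mean, QGRS-style G4 motifs |
| Group comparison | `delta_psi()` | ΔΨ with label-permutation p-value |

Every stage has a seeded synthetic-data generator (`sim_junction_reads()`,
`sim_gel()`, `sim_ct_table()`, `sim_screen_fastq()`, `sim_cell_image()`)
emitting standard formats (SAM with N-CIGAR junctions, FASTQ, CSV, TIFF,
bedGraph), so parameter recovery — not downloads — is the test surface.

## Worked example

Simulate the paired warm/cold design (synthesis-level PE inclusion 0.023
at 37 °C vs 0.002 at 32 °C, NMD blocked) and recover it with all three PSI
estimators:

```r
library(coldsplice)
demo <- demo_cold_induction(seed = 1)
aggregate(psi_hat ~ temperature + method, demo$psi, mean)
#>   temperature   method psi_hat
#> 1         32C      gel 0.00183
#> 2         37C      gel 0.02266
#> 3         32C junction 0.00201
#> 4         37C junction 0.02285
#> 5         32C     qpcr 0.00202
#> 6         37C     qpcr 0.02311
demo$delta$effect       # cooling effect on junction PSI (32C − 37C)
#> [1] -0.02083814
demo$nmd
#> $apparent_nmd_active   0.00466   # PE fraction visible with NMD degrading
#> $apparent_nmd_blocked  0.0229    # ...and with NMD blocked (SMG1i analogue)
#> $expected_nmd_active   0.00469   # closed form p*nu/(p*nu + 1 - p)
```

All three estimators agree with the configured truth, cooling shows a
negative ΔΨ in every replicate, and blocking NMD raises the apparent PE
fraction — active decay hides most PE-included molecules.

Individual estimators work on plain inputs:

```r
gel_psi(gel_lane("L1", intensity = c(100, 200), length_bp = c(300, 250),
                 isoform_label = c("inclusion", "skip")))
#> <psi_value[gel]> 0.2941

junction_psi(junction_counts(I_up = 10, I_down = 10, S = 10))
#> <psi_value[junction]> 0.5

scan_g4("GGGTTAGGGTTAGGGTTAGGG")
#>   start end tract_length tract_starts loops score
#> 1     0  21            3    0,6,12,18 3,3,3    49
```

See `vignettes/coldsplice-methods.Rmd` for the models, parameter
defaults, numerical choices and limitations.

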