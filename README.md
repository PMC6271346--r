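# plfatax

PLFA chemotaxonomy for aquatic food-web studies: estimate how much of the
biomass at the base of a pond food web is heterotrophic (bacteria, fungi)
versus autotrophic (green algae, cyanobacteria, diatoms) from phospholipid
fatty acid (PLFA) compositions, and trace the transfer of group-specific
fatty acids into zooplankton lipid fractions.

The package is written for microbial ecologists working with FAME/PLFA
tables from gas chromatography: isolate profiles, seston compositions per
pond, and consumer compositions per lipid fraction (neutral,
acetone-mobile, free fatty acid, phospholipid).

## What it computes

**Unmixing model.** Each seston sample's PLFA composition (as proportions of
total measured FA) is modelled as a convex mixture of taxon signatures:

    s_i ≈ a_i' F(R),   a_i ≥ 0,  Σ_k a_ik = 1

where `R` is a taxa × FA *ratio matrix* (each taxon's FA amounts referenced
to 16:0 = 1) and `F(R)` its row-normalization. Abundances `a_i` are
estimated per sample by simplex-constrained non-negative least squares.
Because published ratio matrices are only approximate for local communities,
the engine then adjusts `R` itself by projected steepest descent, each
nonzero element confined to ±50% of its input value (`[0.5 r0, 1.5 r0]`),
with the 16:0 reference frozen at 1 and structural zeros never touched —
the CHEMTAX family of algorithms. Two standard stabilization protocols are
provided: successive runs (each run restarts from the previous optimized
matrix) and randomized starts (many perturbed inputs, best fraction
averaged and refit).

**Marker sums and retention.** Group contributions are also quantified
directly from marker fatty acids (fungi: 16:1ω5; bacteria: 15:0,
iso/anteiso, hydroxy and cyclopropyl FAs, 18:1ω8; autotrophs: C16 and C18
PUFA), and selective retention of essential ω3 PUFAs is measured as the
consumer:seston ratio of the EPA+DHA share.

**Supporting modules.** A fatty-acid nomenclature parser (ω/w spellings,
iso/anteiso and mid-chain methyl branches, hydroxy and cyclopropyl acids,
double-zero saturates), ratio-matrix construction from isolate libraries
with the standard low-abundance and single-taxon filters, profile-similarity
identification of isolates, PCA variable screening (chains < 14 carbons,
Kaiser–Meyer–Olkin adequacy > 0.5, communality > 0.5), Spearman rank
correlation, and a synthetic-data generator for closed-loop validation.

A taxa × PLFA ratio matrix for 9 taxon groups of Mediterranean temporary
ponds (3 fungal phyla, 3 bacterial phyla, 3 algal groups) ships as a
packaged fixture (`inst/extdata/table3_input.csv`), together with its
published bounded-optimization output and the marker scheme.

## Worked example

```r
library(plfatax)

R0 <- read_ratio_matrix(system.file("extdata", "table3_input.csv",
                                    package = "plfatax"))

# four synthetic pond samples in which heterotrophs hold 90% of biomass
g <- gen_pond_samples(preset_scenario("heterotroph_dominated",
                                      n_samples = 4, seed = 1, cv = 0.10))
res <- chemtax_fit(g$samples, R0)
round(res$abundances, 3)
#>           Ascomycetes Zygomycetes Basidiomycetes Actinobacteria Firmicutes
#> sample_01       0.076       0.110          0.254          0.155      0.157
#> sample_02       0.327       0.000          0.092          0.164      0.070
#> sample_03       0.051       0.229          0.150          0.200      0.206
#> sample_04       0.289       0.398          0.004          0.139      0.085
#>           Proteobacteria Green algae Cyanobacteria Diatoms
#> sample_01          0.153       0.018         0.005   0.072
#> sample_02          0.209       0.043         0.047   0.047
#> sample_03          0.090       0.000         0.023   0.051
#> sample_04          0.000       0.008         0.005   0.071
```

Each row is a sample's estimated biomass fractions (rows sum to 1); the fit
residual here is RMSE 2.2e-4. Summing the six heterotroph columns gives
0.905, 0.862, 0.926 and 0.915 — recovering the 0.90 heterotroph share the
generator used, within the 10% compositional noise.

The `analysis/` directory holds four numbered drivers that run the complete
study on synthetic data and write their tables under `results/`:
`01_build_ratio_matrix.R` (isolate library → ratio matrix → identification),
`02_unmix_ponds.R` (abundance estimation per community regime, bound
compliance, protocol comparison), `03_trophic_transfer.R` (marker transfer
into consumer lipid fractions, EPA/DHA retention), `04_ordination.R`
(screening, PCA, rank correlations). `run_pipeline()` chains the same steps
from one YAML config and writes a run manifest.

## Limitations

Field PLFA data from the original pond survey are not deposited anywhere,
so all end-to-end numbers here are computed on synthetic communities whose
regimes (heterotroph-dominated, green-algae-dominated, mixed cyanobacteria)
mirror the field observations qualitatively. The bounded factorization has
the usual rotational ambiguity of mixture models: abundances are recovered
well, individual ratio elements only partially. See the methods vignette
(`vignettes/plfa-chemotaxonomy.Rmd`) for the model, parameter choices and
numerical details.
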