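# dietbarcode

Stomach-content DNA-metabarcoding diet analysis for R.

When the diet of a fish (or any predator) is characterized by sequencing the
prey DNA in its stomach, the data arrive as an OTU-by-sample table of read
counts plus a taxonomy, sample metadata, and optionally a phylogeny over the
OTUs. `dietbarcode` takes the analysis from that point: it quantifies what
each population or season eats, how diverse and how overlapping those diets
are, whether diet composition differs between groups, and which
environmental variables drive the differences. It is aimed at trophic
ecologists comparing diets across sites, habitats or seasons — for example
invasive-fish surveys where trophic plasticity is the question — and it
ships a Dirichlet-multinomial simulator so every stage can be exercised and
tested without sequencing data.

## What it computes

**Diet composition.** For prey taxon *i* in a group of *T* stomachs with
food, the frequency of occurrence is `FO_i = 100 · N_i / T` (stomachs
containing the taxon), and the relative read abundance is the per-stomach
read proportion averaged over stomachs,
`RRA_i = (100 / N) Σ_j S_ij / Σ_i S_ij` — a proxy for relative biomass.
Phyla aggregate into five food categories (phytoplankton, protozoa,
zooplankton, zoobenthos, detritus); the FO–RRA plane classifies taxa as
generalist (high FO, low RRA), specialist (low FO, high RRA), dominant or
rare prey.

**Trophic diversity and niche.** Per stomach: Shannon–Wiener
`H′ = −Σ p_i ln p_i`, Pielou evenness `J = H′ / ln S`, and Levins niche
breadth `B = 1 / Σ p_i²`. Between diets *x* and *y*: Schoener overlap
`α = 1 − ½ Σ |P_xi − P_yi|`, with α > 0.6 conventionally read as
biologically significant overlap.

**Community structure.** Bray–Curtis and weighted UniFrac distances, NMDS
(Kruskal stress-1), one-factor and pairwise PERMANOVA (999 permutations by
default), Kruskal–Wallis tests with compact letter displays, an LDA
effect-size (LEfSe-style) biomarker screen, and rarefaction/accumulation
curves.

**Environmental drivers.** Iterative VIF screening (threshold 10),
Spearman correlation matrices, standardized multiple regression, binomial
and gamma GLMs for size/group effects, Hellinger transformation with the
DCA gradient-length rule for choosing linear (RDA) vs unimodal (CCA)
ordination, RDA with Monte-Carlo permutation tests (5000) and envfit
vectors, and Mantel tests (10,000 permutations) against haversine
geographic distance.

## Worked example

The package ships two published-style diet tables as fixtures: phylum-level
FO/RRA for five populations from two habitat types (`table1`) and for four
seasons in one reservoir (`table2`). `profile_mode()` runs the diet-metric
stages directly on such a table:

```r
library(dietbarcode)
pm <- profile_mode(paper_fixture("table1"))

round(pm$category_means, 2)
#> phytoplankton      protozoa   zooplankton    zoobenthos      detritus         other
#>         52.84          8.78         12.95          3.12         13.48          8.81

round(pm$overlap$alpha, 2)
#>        DJ  NDJ  QDH SKSK   XJ
#> DJ   1.00 0.35 0.49 0.11 0.57
#> NDJ  0.35 1.00 0.37 0.11 0.37
#> QDH  0.49 0.37 1.00 0.33 0.58
#> SKSK 0.11 0.11 0.33 1.00 0.25
#> XJ   0.57 0.37 0.58 0.25 1.00
```

Across the five populations the mean diet is dominated by phytoplankton
(52.84% of reads), and every pairwise Schoener overlap stays below the 0.6
significance threshold (range 0.11–0.58): the populations eat substantially
different diets. The strategy table tells the same story taxon by taxon —
e.g. for SKSK, Chlorophyta is `generalist` (FO 100, RRA 2.74: eaten by
everyone, but never much) while Bacillariophyta is `dominant` (FO 100,
RRA 63.16).

The full pipeline runs from raw counts (here simulated) and writes a TSV
bundle plus a JSON manifest:

```r
res <- run_pipeline(list(
  synthetic = list(scenario = "populations"),
  seed = 11, out_dir = "out"
))
```

A thin CLI over the same functions is in
`inst/scripts/dietbarcode.R` (`run --config run.json`,
`profile --input table.tsv --out dir`).

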