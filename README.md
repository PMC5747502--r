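# crossferome

Comparative analysis of type I interferon (IFN) responses across vertebrate
species.

Stimulating cells with type I IFN up-regulates hundreds of
interferon-stimulated genes (ISGs) — the *interferome* — the front line of
antiviral immunity. When the same experiment is run in many species on one
platform, the shared and private parts of that response become measurable:
a conserved "core" of ISGs up-regulated by every species, mammal-only
additions, lineage- and species-specific responders, and the evolutionary
signatures (gene-family expansion, elevated dN/dS) that virus–host conflict
leaves on antiviral genes. `crossferome` implements that comparative
workflow end to end for researchers in innate immunity and molecular
evolution, together with a ground-truthed simulator used to calibrate every
statistical component.

## The model in brief

Per species, genes are tested for differential expression between IFN and
mock libraries; a gene is an **ISG** when its Benjamini–Hochberg FDR < 0.05
with log2FC > 0 (an **IRG** when log2FC < 0). Calls are projected onto
orthologous gene clusters (paralogs averaged over the up-regulated copies),
each orthogroup is binned by the number of species carrying a call, and

* **core^vert** = orthogroups that are ISGs in *all* species (top bin),
* **core^mamm** = additionally those ISGs in every mammal but not the
  outgroup.

Comparative statistics include Jaccard similarity of per-species ISG/IRG
repertoires, PCA of one-to-one shared ISG responses, resampling enrichment
of an antiviral gene panel (empirical `p = (r+1)/(B+1)` against B = 100
draws of 40 ISGs), expansion ratios (`multiple/single` copy families)
against 500 resampled backgrounds, a permutation trend test of expansion
versus species-count bin, Wilcoxon/Kruskal–Wallis contrasts of dN/dS and of
basal expression, an induction-by-copy-class ANOVA, and median
normalisation of genome-screen hit counts.

The package ships a transcribed catalogue of the 90 published core ISGs
(62 core^vert + 28 mammal-only; `read_core_table()`), and
`simulation_config()` / `simulate_interferome()` generate full synthetic
datasets (counts, orthology map, dN/dS, hit counts) with known truth.

## Worked example

```r
library(crossferome)

res <- run_pipeline(simulation_config(seed = 1), "interferome_out")
make_report(res)
```

```
== comparative interferome report ==

core (all species)       : 60
additional mammal core   : 28

per-species calls:
  chicken    ISG  103  IRG   57
  cow        ISG  174  IRG   80
  ...
  sheep      ISG  177  IRG   89

statistics (seed 1):
  antiviral enrichment    : 10/10 species with p < 0.05 (min p 0.009901)
  expansion enrichment    : 4/10 species with p < 0.05
  bin-expansion trend     : slope 0.0706, p 0.04598
  dN/dS ISG vs non-ISG    : Wilcoxon p 1.22e-184, Kruskal-Wallis p 1.22e-184
  basal FPKM contrast     : Kruskal-Wallis p 2.4e-56
  induction ~ copy class  : F 0.088, p 0.767
```

Reading this: the simulation plants 62 all-species core ISGs; the pipeline
recovers 60 of them at this seed (and 28/28 mammal-only additions) with no
false core calls. The antiviral panel is significantly more induced than
random ISG draws in every species (the smallest attainable p at B = 100 is
1/101 ≈ 0.0099), widely shared ISGs are more likely to carry paralogs
(positive trend), ISGs show elevated dN/dS, and the two bat species show
the planted elevation of basal interferome expression. The
induction-by-copy-class ANOVA is null here because the generator plants no
copy-class effect.

The packaged core catalogue reproduces the published table structure:

```r
core_table_counts(read_core_table())
#> # A tibble: 1 × 5
#>   n_total n_core_vert n_core_mamm_extra n_core_vert_antigen_presentation n_core_vert_antiviral
#> 1      90          62                28                                9                    14
```

Each result type has `tidy()`/`glance()` and `autoplot()` methods, e.g.
`autoplot(res$stats$similarity_up)` for the species-similarity heatmap. A
thin command-line front end is installed at `inst/cli/crossferome.R`
(`simulate`, `run`, `report` subcommands).

## Method details

See the methods vignette,
`vignettes/cross-species-interferome.Rmd`, for the response definition, the
differential-expression stand-in and its normalisation, paralog-merging
rules, the design of every comparative statistic, what the simulator does
and does not emulate, and known limitations.
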