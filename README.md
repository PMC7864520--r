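# saaquant

Quantification of seeded serum amyloid A (SAA) aggregation from
fluorescence micrographs, with a sequence-homology toolkit relating
species-level seeding activity to SAA sequence features.

## The problem

AA amyloidosis develops when SAA, an acute-phase protein, aggregates into
cross-β fibrils that deposit in organs. Amyloid-enhancing factor (AEF) —
fibril-containing tissue extract — acts as a *seed*: added to soluble SAA
it shortens the onset of aggregation dramatically, and AEFs from different
donor species seed with different efficiency. Experiments of this kind
image fluorophore-labelled SAA in microplates over about a week and need
three quantitative readouts:

1. **How much aggregate is in a frame?** The per-pixel brightness
   standard deviation of the raw image (the *SD statistic*): background
   frames sit at the camera noise SD, while fluorophore concentrated into
   aggregates widens the brightness histogram.
2. **How fast, and how dose-dependent?** Boltzmann sigmoid fits of SD
   versus time (half-time `t50`, lag `t50 − 2/slope`) and a rising
   four-parameter logistic on endpoint SD versus AEF fraction
   (`half_max_fraction`, the EC50 idea transposed to a promoting factor):

   `y(t) = baseline + (plateau − baseline) / (1 + exp(−slope·(t − t50)))`

   `y(x) = bottom + (top − bottom) / (1 + (half_max/x)^hill)`

3. **What do the aggregates look like?** Dotted (isolated blurred
   puncta) versus mesh (one connected filament network) classification
   from connected components and skeleton density, plus z-stack thickness
   maps.

The homology side reproduces the comparative-sequence analysis: affine-gap
global alignment (Gotoh), progressive multiple alignment, percent identity
and minimum-pairwise-identity "overall homology", per-column conservation
classes, UPGMA trees, monophyly checks, and a **discriminative-site scan**
that finds alignment columns whose physicochemical class (by default the
charge partition acidic/basic/neutral) cleanly separates a high-activity
from a low-activity species group — the pattern behind residues such as a
basic lysine in weak seeders versus neutral residues in strong seeders.

A synthetic-data module (seeded nucleation–elongation ODE
`dF/dt = (k_n + k_e·F)(T − F)`, a virtual fluorescence microscope in two
morphologies, and a tree-structured sequence-family simulator with planted
discriminative sites) provides ground truth for every stage, so the whole
pipeline is testable end to end without any external data.

## Worked example

```r
library(saaquant)
library(dplyr)

# one synthetic frame at half conversion, and its SD readout
img <- render_micrograph(0.5, imaging_params(rng_seed = 7))
sd_statistic(img)
#> [1] 9.593232

# a full assay: 5 species x 5 AEF fractions x 8 times x 3 replicates
assay <- generate_assay(panel = default_panel(), rng_seed = 1)
ep <- quantify_images(assay) |> filter(time_h == 168, aef_fraction == 1.0)
rank_activity(ep)
#> # A tibble: 5 × 5
#>   species mean_sd     n  rank tied
#>   <chr>     <dbl> <int> <int> <lgl>
#> 1 mouse     44.0      3     1 FALSE
#> 2 cat       11.1      3     2 FALSE
#> 3 camel      8.39     3     3 FALSE
#> 4 cattle     8.31     3     4 FALSE
#> 5 goat       8.00     3     5 FALSE

quantify_images(assay) |>
  filter(species == "cat", aef_fraction == 1.0) |>
  summarize_timecourse() |>
  fit_sigmoid()
#> Boltzmann sigmoid fit
#>   baseline 4.82, plateau 10.47
#>   t50 31.21 h, slope 0.07296 /h, lag 3.795 h
#>   RSS 1.284 on 8 points

# sequence family with planted discriminative sites at columns 48 and 125
fam <- simulate_sequence_family(sequence_sim_params(rng_seed = 1))
aln <- progressive_msa(fam$sequences)
overall_homology(aln)
#> # A tibble: 1 × 4
#>   min_identity mean_identity conserved_column_fraction n_sequences
#>          <dbl>         <dbl>                     <dbl>       <int>
#> 1         71.5          80.2                     0.592           6

discriminative_site_scan(aln, c("mouse", "cat"), c("camel", "cattle", "goat"))
```

The ranking mirrors the biology the generator encodes: the two
high-seeding species occupy the top two positions, with a wide gap to the
camel/cattle/goat group. The site scan always recovers the planted columns
48 (neutral vs basic) and 125 (acidic vs neutral); at realistic sequence
divergence it also reports a few clade-specific substitutions that are
statistically indistinguishable from planted sites — see the methods
vignette (`vignettes/saaquant-methods.Rmd`) on phylogenetic confounding.

Disk-level runs go through the pipeline verbs under one seeded config:

```r
cfg <- default_config(outdir = "run1", seed = 1)
run_all(cfg)   # simulate -> quantify -> homology -> report
```

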