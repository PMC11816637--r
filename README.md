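# dipoleratio

Compartment-resolved ratiometric quantification of the membrane dipole
potential in living cells.

## What it does, and for whom

The dipole potential — the large positive electric potential inside the
membrane–water interface generated by ordered lipid and water dipoles —
shapes the conformational landscape of membrane proteins, yet it is
almost always measured only in the plasma membrane. The dye F66, a
dipole-potential-sensitive 3-hydroxyflavone, makes an organelle-resolved
measurement possible: its excited state splits by intramolecular proton
transfer into a normal (N\*) and a tautomer (T\*) species, and the ratio
of its two emission bands,

$$R = \frac{T - \bar b_T}{N - \bar b_N},$$

computed per pixel after background subtraction, rises monotonically with
the dipole potential. Staining cells long enough for the dye to reach all
internal membranes, adding a brief surface stain for the plasma membrane,
and co-labeling one organelle class (LysoTracker, Golgi-RFP, ER-GFP,
MitoTracker) yields dual-band confocal images from which this package
computes, per individual cell:

* a seeded-watershed segmentation into plasma-membrane and interior
  pixels on the F66 intensity relief,
* intracellular-membrane masks (F66 intensity above 4× the cell-free
  background mean) and organelle masks (marker intensity above a
  maximum-entropy/Kapur threshold),
* median T\*/N\* ratios with quartiles per compartment, and the organelle
  median normalized to the plasma-membrane median of the same cell,
* group statistics: Welch's t-test (plasma membrane vs organelle) and
  one-way ANOVA with Tukey's HSD (between organelles, on normalized
  ratios).

It is aimed at membrane-biophysics and cell-biology labs running
emission-ratiometric probes on standard confocal setups. A synthetic
image generator with ground truth (packaged with per-cell-line ratio
distributions for SKBR-3, HeLa and SH-SY5Y cells) makes every stage
testable by parameter recovery, with no microscope data required.

## Worked example

```r
library(dipoleratio)

ds  <- generate_experiment("skbr3", "lysosome", 20, seed = 1,
                           params = synthetic_params(image_size = 160))
res <- analyze_dataset(ds)
head(res$measurements, 6)
#>   cell_id       compartment median_ratio    q1    q3 n_pixels normalized_ratio
#> 1       1                PM        3.304 3.094 3.552      142           1.0000
#> 2       1          lysosome        2.896 2.676 3.183      254           0.8768
#> 3       1 intracellular_all        2.878 2.528 3.207      544           0.8711
#> 4       2                PM        3.498 3.255 3.753      166           1.0000
#> 5       2          lysosome        2.805 2.564 3.083      366           0.8020
#> 6       2 intracellular_all        2.874 2.514 3.253      650           0.8216

go  <- analyze_dataset(generate_experiment("skbr3", "golgi", 20, seed = 2,
                                           params = synthetic_params(image_size = 160)))
cmp <- compare_compartments(list(lysosome = res$measurements,
                                 golgi    = go$measurements))
format_comparison(cmp)
#> lysosome: PM 3.487 +/- 0.240 (n=20) vs organelle 2.484 +/- 0.373 (n=20), Welch t=10.10 df=32.4 p=1.53e-11 ****
#> golgi: PM 3.533 +/- 0.357 (n=20) vs organelle 2.176 +/- 0.267 (n=20), Welch t=13.62 df=35.2 p=1.38e-15 ****
#> ANOVA (normalized ratios): F=6.83 p=0.0128 *
#>   Tukey golgi-lysosome: diff=-0.095 p=0.0128 *
```

Each row is one (cell, compartment) measurement: `median_ratio` is the
median background-subtracted T\*/N\* ratio over the compartment's valid
pixels (higher = larger dipole potential), `q1`/`q3` its quartiles,
`n_pixels` the valid pixel count, and `normalized_ratio` the compartment
median divided by the plasma-membrane median of that cell (1 for the
plasma membrane by definition). The comparison block shows the lysosomal
and Golgi dipole potential well below the plasma membrane, and the
normalized Golgi level below the lysosomal one — the inward-decreasing
gradient along the secretory/endocytic pathway.

Real images enter through `read_channel_stack()` (TIFF, explicit
channel-to-page map), `read_seed_set()` (JSON: per-cell interior seeds,
outside seed, cell-free background rectangle; 0-based row/col
coordinates, half-open rectangles), and `analyze()`. A thin command-line
wrapper with `analyze`, `simulate` and `compare` subcommands is installed
at `inst/cli/dipoleratio.R`.

See the vignette (`vignettes/dipole-potential-mapping.Rmd`) for the model
assumptions, parameter defaults, and what the synthetic data do and do
not emulate.

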