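# immunofishr

Quantitative image analysis for **immunoFISH** experiments — assays that
combine single-molecule RNA FISH (smFISH) with immunofluorescence so
that individual transcripts, nuclear architecture and protein levels can
be measured simultaneously in the same cells.

In a typical experiment, a HER2-amplified breast-cancer line is
hybridised with intron- and exon-targeting probe pools, counterstained
for DNA or lamin A/C, and immunostained for a protein of interest;
multi-channel 3D widefield stacks are then acquired in 0.2 μm optical
sections. `immunofishr` turns such stacks into per-cell biology:

* **Spot detection** — each transcript appears as a ~0.25 μm
  diffraction-limited particle. Channels are filtered with a
  scale-normalised 3D Mexican-hat (Laplacian-of-Gaussian) filter, local
  maxima become candidates, and an automatic threshold computed from the
  statistics of all candidate responses (a density-valley rule in log
  space; exact Otsu is available) separates particles from noise, with
  sub-voxel localisation and PSF-sized photometry.
* **Segmentation** — nuclei via smoothing → Otsu → 3D hole filling →
  distance-transform watershed; micronuclei by a volume-and-proximity
  rule; cell bodies by distance-limited Voronoi dilation (or seeded
  watershed on a membrane channel); per-cell mean protein intensities.
* **Spatial analysis** — compartment assignment (nucleus, micronucleus,
  cytoplasm), intron/exon colocalization that classifies unspliced
  pre-mRNA (nuclear by definition), transcription-focus detection by
  single-linkage clustering with intensity normalisation to transcript
  equivalents, and RNA-focus/DNA-locus colocalization across rounds.
* **Registration** — a second staining round (e.g. DNA FISH after RNA
  FISH) shrinks and deforms nuclei. Control points on the nuclear
  boundaries drive a global similarity transform plus per-nucleus
  polynomial displacement patches, leaving the cytoplasm untouched.
* **Quantification** — per-cell profiles, the population estimator
  (total spots ÷ nuclei), condition summaries with percent-of-reference,
  and cross-assay Pearson concordance.
* **Synthetic data** — a ground-truthed generator (geometry, transcript
  truth tables, Gaussian-PSF/Poisson rendering, knockdown and
  between-round distortion scenarios) so the entire pipeline is testable
  with no external data.

Tabular results are tibbles throughout and compose with dplyr/ggplot2;
images and label volumes are plain 3D arrays (z, y, x) with physical
voxel sizes in μm.

## A worked example

```r
library(immunofishr)
library(dplyr)

# simulate a steady-state field: 5 cells, ~100 transcripts per cell
sc  <- scenario_config("steady_state",
                       transcripts = list(pre_mrna_fraction = 0.1))
sim <- simulate_scenario(sc, seed = 42)
sim$image
#> <image_stack> 4 channel(s), 40 x 448 x 448 voxels (z y x)
#>   voxel size: 0.200 x 0.107 x 0.107 um
#>   channels: nuclear, exon, intron, protein

# detect exon-channel particles and assign them to compartments
spots <- detect_spots(sim$image, channel_name = "exon") |>
  mutate(channel = "exon") |>
  assign_compartments(sim$geometry)
count(spots, compartment)
#> # A tibble: 3 × 2
#>   compartment     n
#>   <chr>       <int>
#> 1 cytoplasm     374
#> 2 nucleus        77
#> 3 outside         1

# per-cell profiles and the population estimator
prof <- build_cell_profiles(spots, labels = sim$geometry)
prof |> select(cell_id, n_exon)
#> # A tibble: 5 × 2
#>   cell_id n_exon
#>     <int>  <int>
#> 1       1    113
#> 2       2    111
#> 3       3    127
#> 4       4     66
#> 5       5     34
attr(prof, "population_estimator")
#> exon
#> 90.4
```

452 detected particles against 453 ground-truth transcripts, with the
negative binomial cell-to-cell spread (34 to 127 per cell) recovered
cell by cell, is what "quantitative" means here: at this SNR and
density the detector counts transcripts to about a percent.

An end-to-end run (detection, segmentation, spatial analysis,
quantification, CSV/JSON outputs with full provenance) is one call:

```r
res <- run_pipeline(list(
  seed = 42,
  input = list(simulate = list(name = "steady_state")),
  channels = list(nuclear = "nuclear", exon = "exon", intron = "intron",
                  protein = "protein")
))
```

or from a shell, `inst/cli/immunofishr run --config pipeline.yaml`.
Real TIFF stacks enter through `read_image_stack()` (voxel size from the
metadata sidecar or given explicitly).

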