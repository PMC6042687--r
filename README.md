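# ctfish

Quantification of chromosome territories (CTs) in multi-channel 3D FISH
image stacks.

In interphase nuclei, each chromosome folds into a discrete territory.
Oligopaint FISH renders whole chromosomes or arms as separate fluorescent
domains, and the biology — territory compaction, inter-chromosomal
intermixing, somatic homolog pairing, radial positioning, intra-arm
folding, translocations — is read out as measurements on segmented voxel
masks. `ctfish` is the full measurement pipeline for such stacks, written
for researchers quantifying nuclear architecture in *Drosophila* (or any
system with paint-style FISH), plus a ground-truthed nucleus simulator for
validating every step.

## What it computes

For a nucleus mask `N` and per-channel territory masks:

- volume fraction `V_CT / V_N` and homolog pairing (a paint presenting a
  single FISH signal, after a 10% speck filter)
- pairwise overlap `O(A|B) = |A ∩ B| / |B|` (both directions), intermixing
  of each CT with the union of all others, and contact (overlap or
  26-adjacency) frequencies
- radial position via five equal-volume concentric shells (shell 1 =
  periphery, shell 5 = center), by exact equal-count ranking of the
  boundary-distance transform
- compacity (sphericity) `ψ = π^(1/3) (6V)^(2/3) / S` with a
  staircase-corrected voxel surface `S` (1 for a ball, ~0.806 for a cube)
- minimal edge-to-edge distances and, for three band probes (cen/mid/tel)
  on one arm, the 8-state open/closed fold configuration (closed ⇔ cen–tel
  contact)
- population summaries: median-overlap and contact/pairing heatmaps, shell
  profiles, Tukey box summaries, `R²`, Mann–Whitney and Fisher tests, and a
  translocation screen for persistently elevated overlap

Segmentation follows the classic two-threshold 3D hysteresis scheme (seeds
at `high` grow through voxels ≥ `low`), with automatic Otsu-based
thresholds, camera-offset subtraction and half-maximum refinement; the
nucleus comes from the DNA counterstain. 3D spot detection
(Laplacian-of-Gaussian) covers focus counting.

The simulator builds nuclei as ellipsoids containing bead-chain territories
folded by an anchored biased random walk with a tunable `confinement` dial
(a condensin-II-like compaction axis), homolog pairing, optional
translocations and sub-arm band probes, and renders them with PSF blur,
Poisson shot noise and camera read noise — with full ground truth for every
metric.

## Worked example

```r
library(ctfish)
p  <- sim_params(seed = 8)                    # default simulated world
tr <- simulate_cell(p)                        # geometry + ground truth
st <- render_microscopy(tr, cell_id = "demo") # noisy microscope stack
st
#> <ct_stack 'demo'> 64 x 128 x 128 voxels (z,y,x), 4 channel(s)
#>   spacing (z,y,x): 0.25 x 0.1 x 0.1 um
#>   channels: dna, chr2L, chr2R, chrX

cell <- segment_cell(st)                      # nucleus + territories
cell
#> <ct_cell 'demo'> nucleus 66506 voxels
#>   chr2L: 1 component(s)
#>   chr2R: 2 component(s)
#>   chrX: 1 component(s)

measure_cell(cell)[, c("nucleus_volume", "vol_chr2L", "volfrac_chr2L",
                       "paired_chr2L", "compacity_chr2L")]
#> # A tibble: 1 × 5
#>   nucleus_volume vol_chr2L volfrac_chr2L paired_chr2L compacity_chr2L
#>            <dbl>     <dbl>         <dbl> <lgl>                  <dbl>
#> 1           166.      6.02        0.0362 TRUE                   0.752
```

The nucleus measures 166 µm³; chromosome 2L occupies 6.0 µm³ (3.6% of the
nucleus), presents one FISH signal (its homologs are paired, matching the
simulation's ground truth), and has intermediate compacity 0.75 — a blobby
but not spherical territory. The measured 2L-on-2R overlap for this cell is
0.087 against a ground truth of 0.095, inside the pipeline's validated
±0.05 recovery band.

A whole population runs as one reproducible pipeline
(simulate → segment → measure → report):

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "ctfish")
res <- run_pipeline(cfg, "demo_out", seed = 1, n_cells = 20)
res$summary          # heatmaps; autoplot(res$summary) for the ggplot view
```

which writes per-cell OME-TIFF stacks, truth and label masks, `cells.csv`,
report CSVs (`overlap_heatmap.csv`, `contact_heatmap.csv`,
`shell_profiles.csv`, `config_frequencies.csv`, `translocation_screen.csv`,
`summary.json`) and a `manifest.json` with the seed, parameters and
excluded cells. The same stages are available from a shell via
`inst/cli/ctfish.R` (subcommands `simulate`, `segment`, `measure`,
`report`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the demonstration computation from scratch at the given seed — a
simulated, rendered, segmented and fully measured population, aggregated
into the population report — and writes the results JSON.

## Documentation

The methods vignette (`vignettes/territory-quantification.Rmd`) describes
the measurement model, the simulator's assumptions and limits, every
tunable parameter with its default and rationale, and the package's
numerical choices.
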