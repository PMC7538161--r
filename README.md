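# oligostate

Oligomeric-state composition of fluorescently tagged protein assemblies
from single-molecule TIRF intensities.

## The problem

CaMKII-alpha holoenzymes are dodecamers (two stacked hexameric hub rings).
Activation destabilizes the holoenzyme, releasing dimers and intermediate
oligomers. In a single-molecule pull-down assay, each surface-captured
complex appears as one fluorescent spot whose integrated intensity reports
how many mEGFP-tagged subunits it carries — but two optical facts blur
that readout: the intensity of a single emitting GFP on an EMCCD camera is
log-normally distributed, and a substantial fraction of GFP (~30%) is
dark. This package turns spot-intensity histograms into oligomeric
composition estimates while accounting for both, and provides the
surrounding image pipeline, a truth-labelled synthetic-data generator, and
structural geometry metrics for the hub ring. It is written for
single-molecule microscopists and structural biochemists analyzing
stoichiometry data of oligomeric complexes.

## The model

A bright fluorophore's intensity is log-normal,

    p(x; mu, sigma) = 1/(x sigma sqrt(2 pi)) exp(-(ln x - mu)^2 / (2 sigma^2)),

and each fluorophore is dark with probability nu. The discretized monomer
distribution carries the dark fraction as a point mass nu at zero
intensity; the intensity distribution of an n-mer is the n-fold
self-convolution of that pmf, equivalently a Binomial(n, 1 - nu) mixture
over bright counts. The analysis (i) fits the low-intensity peak to a
monomer + dimer mixture for (mu, sigma); (ii) estimates nu by
auto-convolving the monomer distribution 12 times and centering the
predicted dodecamer peak on the observed high-intensity peak; (iii) fits
the observed density to the monomer/dimer/dodecamer mixture; and (iv)
quantifies intermediate and aggregate species from the positive fit
residual. Details and design rationale are in
`vignettes/oligomer-composition.Rmd`.

## Worked example

Simulate the default holoenzyme scenario (25% monomer, 10% dimer, 5%
hexamer, 60% dodecamer; mu = ln 500, sigma = 0.35, dark fraction 0.3;
20,000 molecules) and recover its composition:

```r
library(oligostate)
tab <- simulate_spot_table(holoenzyme_scenario(seed = 1))
rep <- fit_oligomer_composition(tab$intensity[tab$detected])
print(rep)
#> oligomeric composition report
#> monomer intensity model: mu = 6.2529 (median 519.5 ADU), sigma = 0.3549, dark fraction nu = 0.330
#>   dark fraction used: 0.330
#>   species: smaller 30.6%, intermediate 0.6%, dodecamer 68.8%, aggregate 0.0%
```

Reading the output: the fitted single-fluorophore parameters (true values
ln 500 = 6.215 and 0.35) and the dark-fraction estimate 0.33 (true 0.30)
come from the low peak and the dodecamer-peak alignment; the species
percentages refer to detected spots, for which the ground truth here is
29.0% smaller and 65.5% dodecamer — hexamers overlap the dodecamer peak's
lower flank, so part of that 5.5% is absorbed into the dodecamer category
(see the vignette's limitations section).

## Analysis workflow

The `analysis/` scripts are thin narrative drivers over the package and
write their tables to `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | paired unactivated/activated spot tables |
| `02_fit_composition.R` | composition fits; smaller-species fold change (~2x) |
| `03_image_pipeline.R` | synthetic TIRF stacks -> detection -> intensities -> fit |
| `04_bleach_steps.R` | photobleaching-step classification of 1/2/12-mer traces |
| `05_hub_geometry.R` | ring adjacency, inter-helix angle series, displacement field |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_data.R`.

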