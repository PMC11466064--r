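# spincolocal

Quantification toolkit for studies of inhibitory synapses and GABA-A
receptor pharmacology in the spinal dorsal horn. It implements, as tested
reusable R functions, the four analysis stages such studies chain together:

1. **Object-based synaptic-puncta colocalization** on multichannel
   immunofluorescence images: per-channel thresholding (Otsu by default),
   8-connected particle labeling, an equivalent-diameter size filter that
   retains objects between 0.2 and 3 µm, morphological enlargement of every
   punctum by 0.1 µm, and a strict >50% area-overlap rule for declaring a
   reference punctum colocalized with the other channel. Cluster densities
   (puncta/µm², centroid-in-ROI rule) are stratified by region of interest
   (e.g. superficial vs deep dorsal horn), and group differences are
   summarized as percent reduction with an unpaired t test.
2. **RNAscope-style cell calling**: nuclei are segmented from the nuclear
   stain, each nucleus is expanded by 2 µm, and a cell is positive for a
   marker when ≥ 3 transcript dots fall inside the expanded area; marker
   coexpression fractions are tabulated per region.
3. **Hill concentration-response fitting**: nonlinear least squares of
   *R* = *E*max·*c*ⁿ / (*c*ⁿ + EC₅₀ⁿ) (baseline optionally fixed to 0, EC₅₀
   parameterized on the log₁₀ scale), with EC-fraction concentrations from
   the closed form EC_f = EC₅₀·(f/(1−f))^(1/n).
4. **Percent maximal possible effect** for withdrawal-threshold time
   series: %MPE(t) = 100·(E(t) − E_predrug)/(E_preCCI − E_predrug), its
   peak-window mean (0.5 and 1 h by default), and group comparisons.

A seeded synthetic-data generator produces ground-truth-carrying puncta
fields, FISH fields, dose-response tables and behavioral cohorts, so every
stage is validated by simulation recovery and by brute-force oracles.

## Worked example

Simulate a two-channel field in which half of the receptor-subunit puncta
are truly colocalized with scaffold puncta, then run the full detection and
colocalization chain:

```r
library(spincolocal)

params <- punctaSimParams(trueColocFraction = 0.5, seed = 7)
sim <- simulatePunctaField(params)
sim$field
#> ImageField 'sim_puncta_seed7': 533 x 533 px (80.0 x 80.0 um), 0.15 um/px
#> channels: geph, a2

a2   <- filterBySize(detectPuncta(sim$field, "a2"))
geph <- filterBySize(detectPuncta(sim$field, "geph"))
a2
#> PunctaSet: 792 puncta, channel 'a2', field 'sim_puncta_seed7'
#>   threshold: otsu (0.427)
#>   size filter: [0.2, 3] um
#>   diameter (um): median 0.794, range [0.339, 1.88]

colocalize(a2, geph, roi = fullFieldROI(sim$field))
#> ColocalizationResult: a2 vs geph (field 'sim_puncta_seed7')
#>   dilation 0.1 um, overlap > 0.5
#>   422 / 792 reference puncta colocalized (fraction 0.533)
#>   ROI 'full_field': colocalized density 0.06602 /um^2 (reference 0.1239)
```

The recovered colocalized fraction (0.533) matches the generating truth
(0.500 in this field) to within chance overlap. Downstream, group means of
such densities feed the percent-reduction statistic:

```r
percentReduction(0.23, 0.005)   # control vs knockout mean density, /um^2
#> [1] 97.8
```

and a noisy potentiation curve simulated at EC₅₀ = 0.15 µM, Emax = 162.7%
is refitted to within its standard errors:

```r
fitPotentiation(simulateDoseResponse(0.15, 1.2, 162.7,
                10^seq(-3, 1.5, length.out = 9),
                noiseSd = 8, replicates = 5, seed = 7))
#> HillFit (baseline fixed to 0)
#>   ec50     0.1369  (SE 0.00994)
#>   hill     1.15127  (SE 0.0816)
#>   emax     161.943  (SE 2.5)
#>   converged, RSS 2990, n = 45
```

`runPipeline()` chains simulate → detect → filter → colocalize on one
seeded field and writes all artifacts (TIFF + sidecar, CSVs, result JSON)
plus a checksummed manifest to an output directory.

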