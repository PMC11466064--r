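---
title: "Methods: puncta colocalization, cell calling, Hill fitting and %MPE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puncta colocalization, cell calling, Hill fitting and %MPE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `spincolocal`, in the order the analysis chain runs. It also states
what the synthetic-data generators emulate, and what passing the package's
simulation-recovery tests does and does not establish about real tissue
data.

## Puncta detection and size filtering

An `ImageField` holds named per-channel intensity matrices with a physical
pixel size in µm. Pixel size is mandatory metadata at analysis time and is
never defaulted or guessed, because every downstream threshold (size
bounds, dilation, expansion) is expressed in physical units; only the
simulator carries a default (0.15 µm/px, typical sampling for a 40×
oil-immersion confocal setup).

Detection thresholds one channel and labels connected components:

* **Threshold method** (`detectPuncta`, default `"otsu"`): per-image Otsu
  on a 256-level histogram spanning the channel's intensity range, making
  detection invariant to constant intensity offsets on noise-free data.
  `"triangle"` (histogram-geometry threshold, better for very sparse
  foreground) and `"fixed"` (a user value, for batches acquired under
  constant imaging parameters) are also available. The choice of per-image
  versus per-batch thresholding is deliberately exposed as configuration
  rather than hard-coded, since either is defensible when acquisition
  parameters are held constant. A constant channel cannot support a
  data-driven threshold; it yields an empty set flagged
  `"constant_image"`, not an error.
* **Connectivity**: 8-connected, the particle-analysis convention. The
  underlying 4-connected labeling comes from EBImage; diagonally adjacent
  components are then merged by union-find. Correctness is tested against
  a brute-force breadth-first-search oracle on random masks.
* **Size filter** (`filterBySize`): equivalent circular diameter
  \(d = 2\sqrt{A/\pi}\) from the pixel area; the retention interval is the
  inclusive \([0.2, 3]\) µm (exclusion strictly below 0.2 and strictly
  above 3 µm, ties kept). Area-derived diameter is used because the
  procedure defines no shape measure. The filter is idempotent and
  monotone in its bounds.
* **Coordinates**: pixel indices are 0-based with origin at the top-left;
  a pixel's physical position is its index times the pixel size. Cluster
  density counts puncta by *centroid*-in-ROI, which assigns each punctum
  to exactly one region and so avoids double counting across the
  superficial/deep dorsal horn boundary.

## Object-based colocalization

Both channels are first dilated by a disk of radius 0.1 µm (`dilatePuncta`)
— the standard enlargement that prevents edge exclusion of abutting
objects. Three conventions are fixed and documented rather than guessed:

* A dilation radius that is positive but below one pixel rounds up to one
  pixel, so a nonzero dilation always has an effect.
* Both channels are dilated, since the procedure enlarges "individual
  puncta detected" without restriction to one channel.
* A reference punctum is colocalized when the fraction of its own
  (dilated) pixels covered by the **union** of other-channel (dilated)
  puncta **strictly exceeds** 0.5. Overlap is measured relative to the
  reference punctum's area; a punctum straddling two partners sums its
  covered pixels but is counted once. Measuring relative to the smaller of
  the two partners would be an alternative reading; it is intentionally
  *not* implemented silently — only the reference-area convention is
  offered, and both directions are available by swapping the arguments
  (the operation is genuinely asymmetric, and a constructed asymmetric
  case is pinned against a per-pixel oracle in the tests).

The reference channel is conventionally the receptor-subunit channel and
the other channel the scaffold (gephyrin), matching the direction in which
colocalized cluster densities are reported.

Group summaries use `percentReduction` — \(100(\bar x_{ctl} -
\bar x_{test})/\bar x_{ctl}\), rounded to one decimal, negative values
reporting increases — and `compareGroups` (means, SEMs, pooled-variance
unpaired two-sided t test; a zero-variance equal-means comparison yields a
flagged undefined p rather than an error). `adjustBonferroni` multiplies p
by the declared number of tests, capped at 1.

## RNAscope cell calling

`segmentNuclei` thresholds the nuclear channel and labels components,
dropping those below 10 µm² as debris. No watershed splitting is applied:
touching nuclei merge, which is documented behavior, and the simulator
keeps nuclei disjoint. `expandNucleus` dilates the nuclear pixel set by a
2 µm disk ("2 µm larger than the nucleus" read as a 2 µm dilation radius
of the nuclear boundary, the natural morphological reading). Marker dots
are detected with `detectPuncta` **without** the 0.2–3 µm size filter:
transcript dots are small, and the size cutoff belongs to the
immunohistochemical cluster procedure only. A cell is positive for a
marker when ≥ 3 dots fall inside its expanded area (`callPositive`).

A dot inside two cells' overlapping expanded areas is assigned to the cell
with the nearer nucleus centroid; an exact tie goes to the lower cell id.
The original counting rule does not address contested dots, so the
tie-break is fixed here and tested. Per-fluorophore background staining is
handled only through the ≥ 3-dot rule, as in the original procedure — no
background subtraction is added. `coexpressionFractions` computes, per
region, the fraction of conditioning-marker-positive cells that are also
target-positive, with per-section mean and SD when section ids are
present; a zero denominator is flagged undefined.

## Hill concentration-response fitting

The model is \(R = b + E_{max}\, c^{n_H}/(c^{n_H} + EC_{50}^{n_H})\), with
the baseline \(b\) fixed to 0 by default — the convention for normalized
agonist currents and for percent-potentiation curves
(`fitPotentiation`). Percent potentiation itself is defined as
\(100\,(I_{mod} - I_{ctrl})/I_{ctrl}\) at a low (EC₅) agonist
concentration; the plotted quantity is conventional but its formula is
rarely written out, so it is fixed here as `percentPotentiation`.

Numerical choices:

* EC₅₀ is parameterized as \(10^\ell\) to keep it positive; optimization
  is Levenberg–Marquardt (`minpack.lm::nls.lm`) with convergence tolerance
  1e-10 on the relative SSE change and at most 500 iterations. A parameter
  tolerance is deliberately not used: on exact-fit (noise-free) data it
  can report a spuriously singular gradient.
* Initializer: EC₅₀ at the concentration whose response is nearest half
  the maximal observed response, \(n_H = 1\), \(E_{max}\) at the maximal
  observed response (baseline at the minimum when free). Tests verify
  recovery from any initializer within 10× of truth, and that the final
  SSE never exceeds the initializer's.
* Standard errors come from the Gauss–Newton approximation
  \((J^\top J)^{-1}\hat\sigma^2\) at the solution, with the EC₅₀ SE mapped
  from the log scale by the delta method.
* Replicates are pooled without per-cell weighting, matching pooled
  presentation of 6–11 cells per curve.
* Degenerate inputs error early (fewer than 3 distinct concentrations,
  all-equal responses — which also covers all-zero potentiation);
  non-convergence returns a flagged `HillFit` with diagnostics rather
  than an error.

`ecFraction` uses the closed form \(EC_f = EC_{50}(f/(1-f))^{1/n_H}\),
verified in tests against numeric root finding to 1e-9; EC₅ (f = 0.05) is
the conventional virtually nondesensitizing agonist concentration.

## Percent maximal possible effect

\(\%MPE(t) = 100\,(E(t) - E_{predrug})/(E_{preCCI} - E_{predrug})\). The
source formula is printed without the ×100 factor (and with an unbalanced
parenthesis); the conventional percent form is implemented, consistent
with the %MPE axis labeling. The ratio is computed before scaling so the
0% and 100% identities hold exactly in floating point. Values are **not**
clipped to [0, 100]: overshoot and worsening are meaningful and clipping
would bias means. The windowed summary averages the 0.5 h and 1 h time
points per animal and then averages animals — the statistically standard
reading of a windowed effect summary, flagged here as an assumption since
averaging group means first would be the alternative. Equal pre-injury and
pre-drug baselines leave nothing to reverse and raise an error.

## What the simulators emulate — and what they do not

`simulatePunctaField` places Poisson numbers of objects (density × area)
uniformly over the field; a chosen fraction of second-channel objects is
placed concentric with a first-channel object, *sharing its nominal
diameter*, because a truly colocalized pair represents one synaptic
structure imaged in two channels. Spots are isotropic 2D Gaussians with
FWHM equal to the nominal diameter (diffraction-limited puncta, and the
definition that makes "diameter" well defined for ground truth) on a
constant background with additive Gaussian noise — the simplest model
that exercises thresholding. Defaults: 80 × 80 µm field, 0.15 µm pixels,
0.15 puncta/µm² per channel (the scale of measured cluster densities,
kept below the generator's guard that rejects configurations whose
expected within-channel object overlap exceeds 20%), diameters
N(0.6, 0.1) µm so ≥ 99% of truth survives the size filter. Images are
generated and analyzed in 2D; thin confocal stacks are represented as a
single plane, since the source procedure's projection handling is not
stated. One integer seed drives deterministic per-channel sub-streams;
identical parameters and seed give bit-identical output.

`simulateFishField` places disjoint disk nuclei (rejection sampling with a
2.5 µm margin; infeasible packings are rejected up front using the ~55%
jamming coverage of random sequential placement), draws per-cell marker
positivity from Bernoulli expression probabilities, and gives positive
cells Poisson(15) dots placed inside the expanded nuclear area, plus a
uniform per-fluorophore background dot rate (default 0.004/µm², keeping
the expected background per expanded area below one dot — mirroring the
fluorophore-dependent background levels that the ≥ 3-dot rule is meant to
absorb). Default cells are split into superficial/deep regions by field
half.

`simulateBehaviorCohort` gives each animal a pre-injury baseline (default
5.5 g, a typical electronic von Frey withdrawal threshold), a post-injury
threshold reduced by the injury drop fraction (default 0.6), and
post-drug thresholds whose expected %MPE equals the set drug effect at
the peak window (≤ 1 h) with exponential decay (time constant 1.5 h)
afterwards.

Not emulated: 3D point-spread functions, optical aberrations, channel
bleed-through, tissue autofluorescence texture, probe chemistry, and
kinetics of current desensitization. Passing the recovery tests therefore
shows the *procedures* are implemented correctly and are statistically
well behaved under controlled truth — it does not certify performance on
real tissue, where background structure and optical effects add error
modes the simulator does not produce.

## Validation problem sizes and known limitations

The test suite validates: oracle equivalence of colocalization on 100
random 128 × 128 px two-channel fields (exact, punctum for punctum);
recovery of true colocalized fractions {0, 0.25, 0.5, 0.75, 1} within
0.05, pooling four noise-free 60 × 60 µm fields per level at 0.05
puncta/µm² — dilute enough that chance overlap stays well inside the
tolerance; density recovery at 0.2/µm² within three Poisson standard
errors; FISH positivity sensitivity and specificity ≥ 0.95 on simulated
fields of 40 cells; Hill recovery to 1e-6 relative error noise-free and
median relative EC₅₀ error < 0.15 under 5% noise with 8 concentrations ×
5 replicates over 100 seeds; and the exact %MPE identities over 1000
randomized baselines.

Known limitations, all inherent to the faithful re-implementation rather
than incidental:

* **No spot splitting.** Overlapping puncta merge into one labeled object
  (the source procedure describes no watershed), so object counts bias
  low as density grows — at 0.4/µm² with 0.25 µm spots the undercount
  reaches several percent. Density recovery is therefore validated at
  0.2/µm², and the simulator refuses configurations whose expected
  within-channel overlap exceeds 20%.
* **Chance colocalization.** With both channels at appreciable density,
  some reference puncta exceed 50% coverage by accident; at the dilute
  test conditions this contributes ≲ 0.02 to recovered fractions, but it
  grows with density and dilation, as it does in the real assay.
* **Per-image Otsu** can shift with field content; batch-constant
  acquisition is better served by a fixed threshold, which is why the
  method is configurable.
* The deep-dorsal-horn scaffold–α2 colocalization comparison in the
  source data prints a reduction (92.3%) inconsistent with its own group
  densities (0.175 vs 0.003/µm² implies ≈ 98.3%); that value is excluded
  from the package's worked-example checks, which use the four cluster
  densities and the scaffold–α3 colocalization pair that do verify.
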