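---
title: "Label-free nucleolus quantification: models, parameters and design choices"
author: "nucleoDHM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free nucleolus quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoDHM)
```

# The problem

The nucleolus — the largest nuclear biomolecular condensate and the site of
ribosome biogenesis — is a sensitive morphological biomarker: its number per
nucleus, its area, and its material state change under drug treatment,
ribosomal-protein depletion, viral infection and ageing. Digital holographic
microscopy (DHM) images it without any staining: each phase-image pixel is
proportional to the optical path length (OPL), the physical thickness of the
specimen times its refractive-index contrast. nucleoDHM implements the
computational side of a correlative DHM–fluorescence workflow:

1. **Fluorescence-guided segmentation.** Nuclei from DAPI, nucleoli from a
   GFP-tagged nucleolar marker (e.g. fibrillarin), producing per-cell counts,
   areas and area ratios.
2. **Optical-thickness index.** Phase → OPL conversion and a
   background-subtracted disc statistic that tracks the nucleolar material
   state (e.g. opto-gelation).
3. **Label-free segmentation harness.** A compact U-net trained on phase
   images with the fluorescence masks as labels, with Dice loss, Adam,
   seed-ensemble voting and k-fold cross-validation.
4. **Synthetic correlative triplets** with analytic ground truth, so every
   stage is testable without microscope data.

# Fluorescence segmentation

## Nuclei (DAPI)

Each DAPI image is normalized to $[0,1]$ by its own maximum and smoothed with
a Gaussian of $\sigma = 3$ px. Because background and nucleoplasm form two
histogram modes, the threshold is placed at the lowest histogram bin strictly
between the two dominant modes (256 equal-width bins on $[0,1]$). The
binarized image is closed with a disc of radius 3 (filling small holes and
smoothing contours), components smaller than 2000 px are discarded, and the
mask is dilated by a disc of radius 2.

Numerical choices worth stating:

* *Mode finding.* The two dominant modes are the two highest histogram local
  maxima that are separated by a genuine dip (a bin strictly lower than both).
  Without that separation requirement, two noisy bins on the flank of a single
  mode can masquerade as "two modes".
* *Ties in the valley.* A wide empty valley ties many bins at zero; the middle
  bin of the minimal run is used, which is both deterministic and centred.
* *Fallback.* If two modes exist but no interior minimum separates them the
  method falls back to Otsu's threshold with a warning. A unimodal (e.g.
  constant) image raises an error rather than returning an empty mask — a
  blank field is an acquisition problem, not an empty result.

## Nucleoli (GFP)

GFP images are divided by the dataset-wide maximum and then standardized
image-wise using the mean and standard deviation of the pixels inside the
nuclei. The standardized image is mapped onto reference nucleus statistics
(mean 0.12, sd 0.08 by default, configurable). This choice deserves a note:
standardization to literally zero mean and unit variance would be
incompatible with the sub-unity threshold ladder that follows, so the
package maps nucleus statistics to a reference point at which the tuned
thresholds are meaningful. The reference values are a documented
interpretation; both are exposed in `segParams()`.

Seed detection runs an increasing threshold ladder $t_0 = 0.083$ to
$t_N = 0.3$ in steps of $0.025$ (the last step is clamped so the ladder ends
exactly at 0.3, which a pure arithmetic sequence from 0.083 would miss). At
each threshold the superlevel set is cleaned by an opening (disc radius 2)
then a closing (disc radius 3), and a region genealogy is maintained:

* a region at threshold $t_{i+1}$ is always a subset of a region at $t_i$;
* a region may split into subregions as the threshold rises;
* a region never disappears — if its superlevel set empties, its last
  nonempty version is retained.

The genealogy is enforced by construction: the processed mask at $t_{i+1}$ is
intersected with each current region, and its connected components within
that region become the children. When the ladder ends, the seed of each final
subregion is its intensity maximum $I_{\mathrm{seed}}$ (ties broken by the
lexicographically smallest (row, col), for determinism).

Two region-growing passes expand each seed to the connected superlevel set
containing it (8-connectivity), then fill enclosed holes:

* **counting** stop: $\max(\alpha I_{\mathrm{seed}}, \tau)$ with
  $\alpha = 0.85$, $\tau = 0.15$ — regions hug bright cores so neighbouring
  nucleoli stay separate;
* **area** stop: the constant $\tau$ — regions extend to faint shoulders for
  honest area estimates.

Growing is implemented as a superlevel-set flood fill, which is equivalent to
iterative pixel accretion with an intensity floor but needs no tie-breaking:
membership is threshold-based, not order-based.

Before growing, every seed passes a mitosis screen: grown with the permissive
stop $\tau_{\mathrm{mitosis}} = 0.11$, a seed is discarded iff the region has
area $> 1000$ px **and** maximum intensity $< 0.25$ — the signature of a
mitotic cell, whose nucleolar marker is dispersed (dim but extended). A
discarded seed contributes to neither mask.

Both masks are finally multiplied element-wise by the nucleus mask: only
structures inside a nucleus count as nucleoli.

## Cluster and border filters

Isolated nuclei are convex; overlapping nuclei of clustered cells are not.
For each nucleus region the solidity (area / convex-hull area, hull
rasterized at pixel centres with inclusive boundary) is computed; regions
with solidity below 0.95, and regions touching any image edge, are removed
together with their nucleoli. The filter is idempotent. Degenerate
(collinear) pixel sets fall back to hull area = pixel count so solidity never
exceeds 1.

# Clinical features

Per nucleus: nucleolus count (counting-mask regions assigned through their
seed pixel), individual and total nucleolar areas (area-mask pixel counts
$\times$ pixel size$^2$), and the nucleolar-to-nuclear area ratio. The pixel
size is camera pixel $\times$ binning / (objective $\times$ lens $\times$
C-mount) — 0.151 µm/pixel for the default configuration. Cells with zero
detected nucleoli stay in the table (and in the count mean) but are excluded
from the mean nucleolar area, which is undefined for them; by default the
mean nucleolar area averages per nucleolus rather than per cell (whether the
field's reported figure averages one way or the other is not fixed, so it is
an option).

# Optical thickness

Phase (radians) converts to OPL (nm) as
$\mathrm{OPL} = \varphi \, \lambda / 2\pi$; the default wavelength is 550 nm
(transmitted light through a 550/49 nm bandpass). The nucleolar
optical-thickness index is the mean OPL over a disc of **12 pixels** centred
on the nucleolus minus the mean OPL over an equal disc in a background
region. "Disc of 12 pixels" is read as a disc of *area* 12 pixels — the 12
pixels nearest the centre, ties broken by (row, col) — not a radius. The
nucleolus centre defaults to the brightest phase pixel of the nucleolar
region.

Two background conventions exist and the package implements both:
`"nucleoplasm"` (default) places the reference disc inside the same nucleus,
outside all nucleolar regions, nearest to the nucleolus — matching the
"adjacent nucleoplasm" usage in dose–response comparisons; `"extranuclear"`
places it outside the nucleus. The default is a documented choice between
two published wordings, not a resolution of them. A cytoplasmic variant
samples a 12-pixel disc at approximately 5 µm from the nucleus boundary
(converted to pixels via the calibrated pixel size) against a cell-free
reference disc.

The index is linear in the phase, invariant to global phase offsets, and
antisymmetric under swapping the two discs — all tested properties. On
synthetic gelation phantoms whose plateau contrast is raised by factors 1.09
and 1.32 over a fixed nucleoplasm, the recovered per-condition percent
changes are 9% and 32% in closed form.

# The U-net harness

The label-free path trains 2-D U-nets to predict the fluorescence-derived
masks directly from phase images. Phase frames are cubic-spline upsampled to
the fluorescence resolution, cropped top-left so each dimension divides
$2^{\mathrm{depth}}$, and normalized by their maximum. Training uses Dice
loss with an additive smoothing constant of 1 in numerator and denominator,
Adam at a fixed learning rate of $10^{-4}$, batch size 1, and a per-epoch
image order shuffled by the seeded RNG so a fixed seed reproduces the
weights bit-exactly. For nucleoli, six models trained from distinct seeded
initializations vote: a pixel is foreground when at least two models mark it
(probability > 0.5); the nucleolus mask is then multiplied element-wise by
the nucleus prediction. Threefold cross-validation partitions the dataset
with the seeded RNG so every image is tested exactly once.

The architecture is scalable (depth and base channel width are
configuration); the package's test profile is depth 3 with base width 4 on
128 × 128 synthetic frames — small enough to train an entire six-model
ensemble on one CPU core in about ten minutes while still overfitting its
training set to ensemble Dice ≥ 0.9, which is the property the harness
tests assert. The full-resolution profile (1408 × 1920, depth 5) is a
configuration preset, not a test target. Convolutions, pooling and
upsampling (with their backward passes) are implemented in compiled code;
gradients are verified against finite differences in the tests.

# The synthetic generator

`randomScene()` + `generateTriplet()` emulate correlative triplets:

* **DAPI**: background 0.08; elliptical nuclei (semi-axes 38–55 px at the
  default 512 × 512 frame) at levels 0.65–0.85 with a quadratic radial
  falloff to 70% at the rim. The falloff matters: it spreads each nucleus's
  intensities into one broad continuous histogram mode. Flat-intensity
  ellipses would produce one narrow spike per nucleus, and the inter-mode
  valley search could land between two nucleus levels — a failure of the
  synthetic data, not of the method. A perinucleolar chromatin ring can be
  enabled via the scene background (off by default to keep the histogram
  cleanly bimodal).
* **GFP**: nucleoplasm 0.05; each nucleolus a raised-cosine bump (plateau to
  $0.9R$, cosine shoulder to $1.1R$, half-maximum radius exactly $R$) peaking
  at 0.5–0.9. The graded shoulder is what makes the counting and area
  stopping criteria produce visibly different regions. The ground-truth
  nucleolus mask is the support of the bump ($r < 1.1R$).
* **Phase**: nucleoplasm plateau 0.4 rad, hard nucleolar plateaus 0.8–1.2
  rad, rendered analytically at 1/4 of the fluorescence resolution (pixel
  centres of the coarse grid mapped into fluorescence coordinates), so
  plateau pixels carry the plateau value exactly and downstream OPL indices
  have closed-form expectations.
* **Mitotic cells**: DAPI-bright discs with dim extended GFP (level 0.2,
  radius 26–34 px) — exactly the phenotype the mitosis screen removes.
* **Clusters and borders**: overlapping nucleus pairs at centre distance
  1.75 × radius (union solidity ≈ 0.92, safely below the 0.95 cut while
  still forming one connected region) and nuclei truncated by the frame.
* **Noise**: additive Gaussian per channel, fluorescence clamped at zero.
  One seeded RNG; the same seed gives bit-identical scenes and renders.

What the generator does *not* emulate: optical blur and shot noise,
intensity vignetting, chromatic misalignment between channels, nucleolar
substructure (fibrillar centres), out-of-focus light and phase-unwrapping
artefacts. Passing tests therefore demonstrate algorithmic correctness at
the stated conditions, not segmentation accuracy on real microscope data —
the reported reference values (≈2.4 nucleoli/cell, ≈23 µm², ratio ≈0.14 for
HeLa) are context, not a claim this package reproduces from synthetic
scenes.

## Study conditions used by the tests

The end-to-end recovery checks run 20 seeded scenes of ~5 cells with
well-separated nucleoli (half-maximum radius 5–10 px, shoulders at least
6 px apart, standardized peaks ≥ 0.37): per-cell counts match ground truth
for ≥ 95% of cells noise-free and ≥ 85% at noise sd 0.02, and area-mask
pixels stay within 15% of the ground-truth supports. The DL harness trains
on 20 one-nucleus 128 × 128 frames with 2–4 nucleoli each. These sizes keep
the full suite within desk scale; they are the package's chosen test
profile, stated here so results are interpretable.

# Known limitations

* Segmentation is strictly 2-D; no watershed separation of touching
  nucleoli — the genealogy split plus the counting stop is the only
  separation mechanism, as designed.
* The GFP standardization scale is an interpretation (see above); changing
  the reference statistics rescales all thresholds' meaning.
* The thickness index is a *relative* OPL contrast; it does not decompose
  into physical height and refractive index, which a single phase image
  cannot identify.
* The raw phase import supports the declared binary dialect (little-endian
  float32, row-major, shape from a sidecar/arguments); other exports need
  those arguments changed, not new code.
* The U-net harness is desk-scale by default; it demonstrates the training
  machinery (loss, optimizer, ensembling, cross-validation), not
  state-of-the-art segmentation accuracy.
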