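---
title: "Quantifying fine-scale axon-terminal topography with the Topographic Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fine-scale axon-terminal topography with the Topographic Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoquant)
```

## The measurement problem

Neighbouring neurons of the same class often tile a shared target neuropil
along an anatomical axis at a scale of only a few micrometers. The motivating
system is the larval *Drosophila* nociceptive circuit: the three class IV
dendritic arborization neurons of each hemisegment (dorsal, middle and
ventral — D, M, V) send axons into one compact neuropil in the ventral nerve
cord, where their presynaptic terminals occupy stereotyped dorsal, middle and
ventral sub-domains. Such fine-scale maps cannot be read off landmarks; they
need a per-animal, per-neuron summary statistic that is invariant to the
neuropil's absolute position and size.

## The model: per-voxel Topographic Index

Given a 3D two-channel stack — one channel labelling a single neuron's axon
terminal (the *clone*), one labelling the whole neuropil (the *reference*) —
both channels are thresholded into voxel masks. The reference mask defines a
dorsal boundary $D$ (the dorsal-most reference voxel's coordinate along the
designated dorsal–ventral axis) and a ventral boundary $V$ (the
ventral-most). For each clone voxel $i$ *inside* the reference mask, with
coordinate $y_i$ along that axis,

$$ d_i = \max(y_i - D,\, 0), \qquad v_i = \max(V - y_i,\, 0), \qquad
   \mathrm{TI}_i = \frac{d_i}{d_i + v_i} \in [0, 1], $$

and the clone-level index is the unweighted mean
$\mathrm{TI} = \tfrac1n \sum_i \mathrm{TI}_i$. TI = 0 means the terminal sits
at the dorsal extreme of the neuropil, TI = 1 at the ventral extreme; a
terminal spread around the middle scores near 0.5. Because the statistic is a
ratio of distances along one axis, it is invariant to joint translation of
clone and reference, to in-plane position, and (for a grid-aligned axis) to
the voxel spacing; flipping the dorsal–ventral axis maps TI to $1 -
\mathrm{TI}$. These invariances are enforced as property tests.

Assumptions worth stating explicitly:

* **Distances are axis-parallel**, not 3D Euclidean distances to the mask
  surface: the boundaries are defined by the dorsal-most / ventral-most
  reference signal along the dorsal–ventral axis, so $d_i + v_i$ is constant
  within a global-boundary analysis and TI is the voxel's fractional depth.
* **Voxels are weighted uniformly** — the average runs over voxels, not
  intensity. A brighter voxel does not count more.
* **One clone per stack.** Instance segmentation is out of scope; the
  labelling techniques this supports (MARCM, FLP-out) produce single-clone
  stacks.

## Pipeline stages and their tunable parameters

`clone_ti_from_stack()` composes the stages; each setting is recorded in the
result's provenance.

| parameter | default | meaning / rationale |
|---|---|---|
| `threshold_method` | `"otsu"` | How "signal-positive" voxels are defined. The original workflow does not state its rule, so the default is the standard parameter-free two-class cut; `fixed` and `fraction_of_max` support reproducibility studies. |
| `boundary_mode` | `"global"` | The boundary definition anchors to the dorsal-most / ventral-most reference signal of the whole neuropil, which is what the verbal definition says; `per_column` (independent extents per anterior–posterior × depth column) is provided because schematic drawings of the method are ambiguous on this point. Both are reported in provenance. |
| `spacing_um` | z 0.3, y 0.15, x 0.15 µm | Physical voxel pitch. 0.3 µm is the stated acquisition z-step; 0.15 µm is a typical confocal lateral pixel size at 60×/NA 1.4. For a grid-aligned axis the spacing cancels out of TI. |
| `background` | 0 | Optional constant background subtraction standing in for deconvolution, which is proprietary and out of scope. Off by default: thresholding is what defines the masks. |
| `crop` | off | Cropping to the reference bounding box never changes TI (tested); it only bounds memory. |

Degenerate inputs are errors, not NaNs: an empty mask after thresholding, a
clone that does not intersect the neuropil, and a zero-thickness neuropil all
abort with a stage-tagged message. Clone voxels outside the neuropil are
counted (`n_voxels_excluded`) and ignored; voxels beyond a boundary — which
can only arise from independent thresholding or per-column boundaries — are
clipped to TI 0 or 1 rather than silently dropped.

## Statistics

Group comparisons follow the field's convention: one-way ANOVA for
three-group designs with post hoc Fisher's LSD, and two-sample t tests for
two-group designs. These are computed from first principles:
$F = \mathrm{MS}_{\mathrm{between}} / \mathrm{MS}_{\mathrm{within}}$ with
$df_1 = k-1$, $df_2 = N-k$; the LSD statistic for groups $a, b$ is

$$ t = \frac{\bar x_a - \bar x_b}{\sqrt{\mathrm{MSE}\,(1/n_a + 1/n_b)}},
   \quad df = df_2, $$

two-sided, unadjusted (that is what LSD means; with exactly two groups it
*is* the pooled t test, asserted exactly in tests). Tail probabilities come
from R's `pf`/`pt`; the test suite checks `f_sf` against the closed form
$(1 + 2F/df_2)^{-df_2/2}$ for $df_1 = 2$ at $10^{-10}$, and the whole ANOVA
against `stats::aov` — independent routes, so a regression in either layer is
caught. Formatted output renders p values below $10^{-4}$ as `p < 0.0001`,
matching the reporting convention; machine outputs keep full precision. A
simulation test confirms the type-I error at $\alpha = 0.05$ over 2000 null
replicates lies inside the exact binomial 99% band.

## What the synthetic generator emulates — and what it does not

`generate_stack()` builds the *stated world* the tests live in:

* a **box neuropil** (ellipsoid optional) spanning 40 voxels (6 µm) along
  the dorsal–ventral axis — the geometry is a design choice, since only the
  dorsal–ventral extent enters the statistic;
* a **clone blob**: the 150 voxels nearest (physical distance; a
  Gaussian-profile sphere thresholded to a voxel count) to a center placed at
  fraction $q$ of the dorsal→ventral span. Real terminals are arbor-shaped,
  but TI is shape-agnostic — only the voxel depth distribution matters;
* **optics and detection**: isotropic Gaussian blur of σ = 0.3 µm (≈ 2
  lateral voxels), Poisson shot noise at unit gain, Gaussian read noise
  (sd 3) over a background of 10 with signal amplitudes 100–120, i.e. an SNR
  of about 8 — a conservative stand-in for a well-exposed confocal stack.
  Intensities are quantized to non-negative integers as a detector would;
* **determinism**: everything is a pure function of the spec and its seed;
  ground-truth masks are stored before blur and noise and never touched by
  them.

Scenario simulations add per-clone biological variability as Gaussian jitter
of $q$ (sd 0.06, truncated to [0.02, 0.98]) around group centers 0.20 / 0.55
/ 0.80 — the middle group's center matches the observed "overall TI close to
0.55" for M terminals, and the jitter magnitude yields group spreads
comparable to published error bars. The `M_ventralized` scenario moves the M
center onto V, emulating perturbations (e.g. loss of postsynaptic BMP
signalling) that abolish the M–V separation.

A green recovery test therefore establishes that segmentation + boundary
extraction + TI averaging recover a known fractional position within 0.05
under realistic blur and noise. It does *not* establish robustness to what
the generator omits: arbor-shaped terminals, spatially varying background,
anisotropic point-spread functions, chromatic offsets between channels, or
imperfect reorientation of the nerve cord. Those require real stacks.

## Numerical and design choices

* **Coordinates**: voxel indices are 0-based at voxel centers; distances are
  index × spacing. No sub-voxel interpolation is applied at boundaries — the
  original method does not state any, and the discretization error (half a
  voxel over a 40-voxel span, ≈ 0.0125 in TI) is well inside the recovery
  tolerance.
* **Otsu on continuous data** uses 256 histogram bins over the data range;
  the exhaustive all-cut-points search is kept in the test suite as the
  oracle.
* **Ties** in blob construction are broken by stable ordering, keeping the
  generator bit-reproducible.
* **TIFF I/O** is a minimal in-package baseline codec (uncompressed,
  little-endian, one grayscale page per slice per channel) because no TIFF
  package is available in the supported dependency set; it was
  cross-validated against an independent Python reader/writer during
  development. Axis roles and channel names travel in a JSON sidecar, since
  baseline TIFF has no standard slot for them.
* **Scenario discrimination testing** is stochastic by construction: under
  the ventralized null the M-vs-V p value is uniform, so a single fixed-seed
  experiment fails ~5% of the time no matter the implementation. The
  acceptance protocol therefore runs three independent experiments per
  scenario and requires control significance in 3/3 and ventralized
  non-significance in at least 2/3 (a-priori failure probability < 1%).

## Limitations

* The anterior–posterior extent of terminals is not quantified; the index is
  one-dimensional by design.
* ROIs for intensity ratios are inputs (drawn on the nuclear or membrane
  marker channel); there is no nucleus auto-detection and no overlap
  exclusion for adjacent cells.
* No bleed-through or chromatic correction; the supported experimental
  designs handle this by fluorophore choice and identical acquisition
  settings.
* Thresholding is global per channel; intensity gradients with depth would
  bias masks and are not modelled or corrected.
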