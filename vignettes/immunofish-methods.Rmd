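---
title: "Models and methods behind immunofishr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind immunofishr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunofishr)
```

immunofishr analyses combined single-molecule RNA FISH and
immunofluorescence (immunoFISH) experiments: multi-channel 3D widefield
stacks in which individual transcripts appear as diffraction-limited
particles, nuclei are delineated by a DNA stain or lamin immunostain, and
protein levels are read out as immunofluorescence intensity. This
vignette explains the models the package implements, the defaults it
chooses where the underlying experimental literature is silent, and what
its synthetic-data validation can and cannot establish about real data.

## The measurement model

### Spots

A transcript hybridised by a pool of fluorescent oligo probes is a point
emitter. The microscope's point-spread function (PSF) is approximated as
an anisotropic Gaussian: the in-plane sigma default 0.106 μm corresponds
to a 0.25 μm full width at half maximum, the apparent size of a
diffraction-limited particle at a 60x/1.42 NA acquisition
(sigma = FWHM / 2.355), and the axial sigma default 0.30 μm reflects
widefield axial elongation. A spot of integrated brightness $A$ at
position $\mu$ contributes

$$ I(v) = A \; \frac{g(v - \mu)}{\sum_{v'} g(v' - \mu)} $$

to voxel $v$, where $g$ is the Gaussian sampled at voxel centres; the
local normalisation makes the noise-free voxel sum exactly $A$, so
photometric linearity in amplitude and in transcript multiplicity is
exact by construction. Shot noise is Poisson on signal plus uniform
background, with additive Gaussian read noise; an optional smoothed
random field emulates the low-frequency autofluorescence of FFPE tissue.

### Detection

Detection follows the classic scale-space recipe:

1. **Mexican-hat filtering.** The channel is convolved with a negated,
   scale-normalised Laplacian of Gaussian whose per-axis scales in voxel
   units derive from the physical expected FWHM, so voxel anisotropy is
   handled without resampling. The second-derivative kernels are
   recentred to sum exactly to zero: a constant image maps to exactly
   zero and the response is exactly linear,
   `filter(aI + b) = a filter(I)`. Convolution uses replicate padding;
   zero padding would manufacture spurious rim maxima against the
   uniform camera background.
2. **Candidates.** All strict 26-neighbourhood local maxima with
   positive response, greedily pruned so that no candidate lies within
   `min_separation` (default 0.3 μm, about one particle diameter) of a
   stronger one; ties break by response and then voxel order, making the
   candidate set deterministic.
3. **Automatic threshold.** The threshold is computed from the
   statistics of all candidate responses in log space, which makes the
   retained set invariant under intensity rescaling. Plain two-class
   Otsu is exposed (`auto_threshold(..., method = "otsu")`, implemented
   as the exact exhaustive between-class-variance search) but is *not*
   the default: in a realistic field the noise maxima outnumber true
   spots by two to three orders of magnitude, and the single Otsu split
   then falls inside the noise mode — we measured F1 = 0.01 under
   exactly the conditions the package is validated at. The default
   `method = "valley"` instead cuts at the deepest density valley of the
   log-response distribution, restricted to cuts that keep the noise
   bulk (at least 40% of candidates) below and a non-trivial class
   above. On clean bimodal input it retains the same set as Otsu; under
   heavy imbalance it finds the near-empty gap between the noise and
   signal modes. A deterministic `threshold_multiplier` plays the role
   of the manual threshold refinement an interactive analyst would
   perform; reproducibility is preferred over eyeballing. If the
   threshold fails to separate anything (it would retain more than a
   fifth of tens of thousands of maxima), the channel is declared
   signal-free rather than flooding downstream stages with noise.
4. **Localisation and photometry.** Sub-voxel centres come from
   separable three-point quadratic interpolation of the response peak,
   clipped to half a voxel; integrated raw intensity is summed over a
   PSF-sized box after subtracting the box-shell background estimate.

Coordinates follow the voxel-centre convention throughout: the centre of
0-based voxel $i$ is at $(i + 0.5) \times$ voxel size, axis order
(z, y, x).

### Segmentation

The nuclear channel is smoothed (default 0.5 μm), thresholded by global
histogram Otsu, hole-filled in 3D, split by marker-controlled watershed
on the smoothed Euclidean distance transform (seeds are distance maxima
at least `split_min_distance_um` apart), and cleaned of components below
a volume floor. All 3D primitives — exact anisotropic Euclidean
distance/feature transforms, connected components, and Meyer-flooding
watershed — are small compiled routines, since the installed image
toolkits provide them in 2D only. The pipeline is fully deterministic;
interactive correction is replaced by explicit parameters, and external
curated masks can be substituted anywhere a label volume is accepted.

Micronuclei are separated from nuclei by a pure rule: working down from
the largest component, a component is a micronucleus when its volume is
strictly below `max_fraction` (default 10%) of the median volume of the
main nuclei accreted so far *and* its boundary lies within
`max_distance_um` (default 5 μm) of a main nucleus, which becomes its
parent. Both thresholds are operational defaults — the experimental
literature shows micronuclei but does not quantify them — and are
exposed in the configuration.

Cell bodies default to distance-limited Voronoi dilation of the nuclei
(default reach 5 μm). A seeded watershed on an intensity channel is
available for membrane-marking stains, but a protein channel whose
intensity tracks expression is deliberately *not* used by default: dim
cells would lose their cytoplasm to the threshold. Whether per-cell
protein intensity should be whole-cell or membrane-restricted is not
settled; the package measures the whole-cell mean.

### Spatial analysis

Spots inherit the compartment of their containing voxel (micronucleus
over nucleus over cytoplasm, `outside` otherwise). Intron- and
exon-channel detections are paired by greedy one-to-one matching in
order of ascending distance with a 0.3 μm cutoff — about one particle
diameter; the literature gives no number, so it is a config value. An
intron spot with an exon partner is an unspliced pre-mRNA; intron-only
spots are flagged for QC, since intronic signal without its exon partner
indicates a detection or registration problem. Transcription foci are
single-linkage clusters of nuclear spots at 0.3 μm whose summed
intensity reaches at least two transcript equivalents, the unit being
the median integrated intensity of cytoplasmic singles; lone bright
spots qualify. The minimum of two equivalents is an operational
definition of "focus", not an empirical constant.

### Registration of staining rounds

Sequential rounds (RNA FISH, then harsher DNA FISH) shrink and deform
nuclei. Registration is purely geometric, from the nuclear masks:

1. nuclei are matched across rounds by mutual nearest centroids (gated
   at 10 μm);
2. per nucleus and z-plane, the boundary is traced, ordered by angle
   about the plane centroid (nuclei are star-convex to an excellent
   approximation), resampled to equal arc length with a deterministic
   max-x anchor, and aligned across rounds by the exhaustive cyclic
   shift minimising the normalised sum of squares, refined to
   sub-step resolution;
3. a global similarity transform is fitted by least squares over all
   pairs, and per-nucleus residual displacements are interpolated by
   least-squares polynomial patches (in-plane, total degree growing
   from quadratic to quintic with the number of boundary samples, with
   a mild ridge on the nonlinear terms), tapered to zero with a cosine
   profile over a 1 μm margin outside the nucleus so that cytoplasmic
   voxels and spots are returned bit-identical;
4. correspondences are refined by two rounds of point-to-curve
   projection (ICP): the normal coordinate of each correspondence comes
   from the data and the tangential coordinate from the smooth field.

The last point addresses the aperture problem of boundary matching:
tangential motion of a smooth closed contour is nearly unobservable, so
arc-length pairings carry tangential error of the order of the
deformation amplitude while their normal component is accurate to a few
hundredths of a micrometre. The patch fit therefore weights the normal
projection of every correspondence at 1 and the tangential projection at
0.1. A related, documented limitation: a small *global rotation* between
rounds is aliased with cyclic re-parameterisation of the contours and is
only partially attributed to the global similarity term (the residual
patches absorb the rest, so warped boundaries still coincide); rotation
recovery is exact only for the scale-plus-translation case, which is the
physically relevant one for shrinkage.

Forward (spot) and inverse (image) fields are fitted separately from the
swapped correspondences; images are resampled by inverse mapping with
in-plane Catmull-Rom and axial linear interpolation. Whether the
original software fitted one warp per field or per nucleus is ambiguous;
per-nucleus correction is implemented, which the per-nucleus support
structure makes explicit.

### Quantification

Per-cell profiles tabulate counts by channel and compartment, pre-mRNA
calls, focus statistics and mean protein intensities. The population
mean transcripts per cell is also computed as total spot count divided
by the number of nuclei — the field's estimator — and equals the mean of
per-cell counts exactly when no spot falls outside a cell. Cells
touching the field border are flagged and excluded from population
summaries by default to avoid truncation bias (togglable). Condition
summaries report means, medians, cell-to-cell CV and percent-of-
reference; cross-assay concordance uses Pearson correlation with a
two-sided t-distribution p-value via `stats::cor.test`, with no
multiple-testing correction since single correlations are reported.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline is validated.

* **Geometry.** Nuclei are randomly oriented oblate ellipsoids with
  in-plane semi-axes 5.5–7.0 μm and axial semi-axes 2.5–3.2 μm —
  an 11–14 μm diameter typical of cultured breast-cancer lines — with
  low-order radial "wrinkles" (modes 2–3, ~4% amplitude) of the kind
  lamin staining reveals. Micronuclei are spheres of 1–8% of the parent
  volume placed 1–5 μm outside the parent boundary. Cells are
  distance-limited Voronoi dilations (5 μm). Voxels default to
  0.2 × 0.107 × 0.107 μm, emulating 0.2 μm optical sections at
  60x/1.42 NA.
* **Counts.** Per-cell totals are negative binomial with configurable
  dispersion (default 5), capturing cell-to-cell heterogeneity; the
  literature describes that heterogeneity qualitatively but supplies no
  dispersion, so the default is an exposed placeholder. Mature mRNA is
  placed uniformly within compartments, with 10% of the mature pool
  still nuclear (en route to export); unspliced pre-mRNA (3% at steady
  state) is confined to nuclei and micronuclei and appears in both the
  intron and exon channels at the same coordinate. With those two
  defaults a complete cytoplasmic knockdown retains ≈ 1/8 of the
  transcripts, all nuclear — the behaviour the assay demonstrates with
  siRNA. Transcription foci place multi-transcript spots (Poisson mean
  8, floor 2) at genomic loci, of which a configurable fraction
  (default 0.8) is transcriptionally active; foci-per-cell counts are
  likewise exposed placeholders.
* **Second round.** Between-round distortion is an in-plane contraction
  of each nucleus about its centroid (default factor 0.9) plus a
  sinusoidal displacement field with per-nucleus random phases,
  amplitude 0.4 μm and wavelength 25 μm — about two nuclear diameters,
  the scale of a bulk shrinkage gradient; "slight" shrinkage does not
  oscillate within a single nucleus, and a field that did would also
  contradict the premise that a per-nucleus polynomial patch can
  represent it. The displacement tapers to zero over a 1 μm margin, so
  everything outside the nuclei is bit-identical between rounds, and the
  exact forward field is returned for validation. The distortion is
  deliberately in-plane: the per-plane contour correspondence (and the
  2D-per-plane warp it supports) assumes z-planes map to themselves.
* **Time courses** are expressed purely as per-condition scalings of
  the generator means (e.g. 100% / 65% / 86%); no kinetic model is
  implemented because none is fitted in this kind of analysis.

Seeded determinism is a contract: identical configurations and seeds
give bit-identical geometries, truth tables and rendered stacks.

## What the validation shows — and does not

The validation suite (`validate_*` functions, also driven by
`scripts/acceptance.R`) measures, at desk scale on one CPU:

* detection F1 on 200 spots at peak SNR 5 in a 64 × 256 × 256 field
  (≈ 0.02 spots/μm³);
* per-cell and population count recovery over 40 cells at mean 100
  (10 fields of 4 cells — a single field of realistic cells at this
  voxel size cannot hold 40 of them);
* exact compartment fidelity on noise-free truth;
* the knockdown contrast (cytoplasmic detections in the treated
  condition versus control, nuclear counts preserved);
* registration recovery under shrink 0.9 + 0.4 μm deformation: boundary
  residuals before/after, re-colocalization of generator RNA-focus/
  DNA-locus pairs at 0.5 μm with and without warping, and cytoplasm
  bit-identity. One caveat is structural: under these pinned distortion
  magnitudes the per-locus displacement has median ≈ 0.5 μm — exactly
  the colocalization cutoff — so the *unregistered* matched fraction
  fluctuates around 50% across seeds and is not a reliable contrast,
  while the registered recovery is at or near 100% with residuals
  around a quarter voxel;
* brute-force oracle equivalences for the filter, threshold,
  suppression, matching and correlation primitives;
* correlation of detected against true totals across 7 simulated lines
  spanning 50-fold expression.

Passing these establishes internal correctness: the pipeline recovers
what the forward model put in. It does not establish performance on real
micrographs, whose PSFs are not Gaussian, whose backgrounds are
structured (autofluorescent granules, probe aggregates), whose nuclei
are not star-convex ellipsoids, and whose true counts are unknown. The
published headline numbers for this assay (≈ 1300 transcripts per cell
in an amplified line; cross-assay correlations of 0.8–0.99) came from
the authors' own microscopy, which is not publicly deposited, and are
therefore not reproducible targets here.

## Numerical choices and degenerate inputs

* Otsu (exact, exhaustive) resolves ties toward the lowest cut; an
  all-equal response vector returns that value so everything is
  retained.
* Quadratic sub-voxel interpolation is clipped to ±0.5 voxel and falls
  back to the voxel centre at flat or edge peaks.
* The watershed resolves priority ties by insertion order, making
  splits deterministic; any foreground component without a distance
  seed receives one at its distance maximum.
* Polynomial patches are fitted in coordinates normalised per nucleus;
  rank-deficient designs drop to lower order, and collinear
  correspondences are an error.
* Warp application skips resampling entirely when the displacement is
  numerically zero, so identity warps are bit-exact.
* Sizes used in the shipped validation (fields of 4–5 cells,
  ≤ 64 × 448 × 448 voxels) were chosen so the full suite runs in a few
  minutes on one core; all are parameters, and nothing in the method
  depends on them.
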