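---
title: "Quantifying collective endothelial cell behavior: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective endothelial cell behavior: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecpolarity)
```

# Overview

`ecpolarity` implements the quantitative toolbox used to measure collective
cell behavior in endothelial monolayers (scratch-wound assays) and at
vascular sprouting fronts (retina whole mounts): axial front–rear polarity
and its population-level polarity index, object-based junction
co-localization, acceptor-photobleaching FRET efficiency and biosensor
activation-peak counting, AFM cell–cell detachment analysis, and the
spatial correlation length of monolayer velocity fields. A synthetic-data
module generates every input with known ground truth, which is how the test
suite exercises each stage end to end.

This vignette records the models, the parameters that matter, and the design
decisions taken where the underlying procedures left choices open.

# Axial polarity and the polarity index

The polarity axis of a cell is the vector from the nucleus centroid to the
Golgi centroid; its angle $\alpha$ is measured against the inward normal of
the nearest free-edge segment, so $\alpha = 0^\circ$ points into the wound
(or ahead of the sprouting front). Angles are degrees in $(-180, 180]$ in
all I/O; radians are internal.

For $N$ cells, the polarity index is the length of the mean resultant
vector,

$$
\mathrm{PI} \;=\; \sqrt{\Big(\tfrac1N\sum_i \cos\alpha_i\Big)^2 +
                        \Big(\tfrac1N\sum_i \sin\alpha_i\Big)^2},
$$

which is 1 when all cells share one direction and tends to 0 for angles
uniform on the circle. For a finite uniform sample the expected PI is
$\approx \sqrt{\pi}/(2\sqrt{N})$, i.e. about 0.003 at $N = 10^5$ — the
baseline against which "random" must be judged. For von Mises-distributed
angles with concentration $\kappa$, the large-sample PI converges to the
Bessel ratio $I_1(\kappa)/I_0(\kappa)$; the tests use an independent
numerical-integration oracle for this value.

**Nucleus–Golgi assignment.** When the two organelle channels are segmented
independently, centroids are paired by *globally* minimizing the total
Euclidean distance over all one-to-one assignments (Hungarian solution via
`clue::solve_LSAP`), not greedily: greedy pairing is provably beaten on
simple configurations, and the tests compare against an exhaustive search
for up to 7 cells. Pairs farther apart than `max_distance_um` (default
30 µm, roughly two cell radii) are dissolved afterwards; the published
procedure is silent on this guard, but without it a missing Golgi silently
steals its neighbour's.

**Distance binning.** The PI-vs-distance profile uses half-open bins
$[k\,w, (k+1)\,w)$ of width $w = 50$ µm starting at the edge, so every cell
belongs to exactly one bin and a cell exactly on a boundary goes to the
farther bin.

**Leader/follower rows.** Row 1 comprises the cells whose neighbourhood
region touches the free edge, determined by nearest-cell ownership of
densely sampled edge points (Voronoi ownership without constructing the
diagram); subsequent rows are peeled over a Gabriel-filtered Delaunay
adjacency of the nucleus centroids. The Gabriel filter (no third cell
inside the circle having the edge as diameter) removes convex-hull
shortcuts that would let peeling skip a row at image borders, and keeps a
confluent sheet connected because the Gabriel graph contains the Euclidean
minimum spanning tree. Adjacency edges longer than 3 times the median
adjacency edge are pruned, so genuinely separate cell clusters disconnect
(and are then seeded from their most edge-proximal cell, with a warning).
The follower set defaults to rows 2–5; rows 2–4 are available via
`follower_set(rows = 2:4)` since both definitions are in circulation, and
results should state which was used.

**Uncoordination threshold.** Even a fully randomized monolayer shows
PI > 0 near the wound because the free interface geometrically biases
polarity. The threshold separating coordinated from uncoordinated behavior
is therefore derived empirically from a junction-disrupted reference
condition: pool the per-bin PIs across that condition's images, exclude the
first (leader) bin, and take mean + 1 sample SD. Applied to the published
reference summary (per-bin PI $0.10 \pm 0.04$ in α-catenin-depleted
monolayers), the rule gives 0.14. Pooling across images was chosen as the
default because the derivation is phrased across the monolayer; a
per-image mode (threshold per image, then averaged) is provided as a flag.
Whether population PIs should pool cells or average per-image PIs is
likewise left to the caller: `polarity_index` on concatenated records pools
cells, applying it per image and summarizing gives the other convention.

**Circular statistics.** `rayleigh_test` provides the standard Rayleigh
test of circular uniformity ($Z = N\,\mathrm{PI}^2$, Greenwood–Durand
p-value approximation); which specific circular test accompanied the
original angular histograms is not documented, so the package exposes the
conventional default rather than guessing further.

# Object-based co-localization

Both channels are segmented into binary masks (global Otsu threshold by
default, objects under 9 px removed) and the overlap percentage is
$100\,|A \cap B| / |D|$. The denominator mask $D$ defaults to the *query*
channel — "vinculin/VE-cadherin co-localization" reads as the fraction of
the vinculin mask overlapping VE-cadherin — with `reference` and
symmetric `union` modes exposed, because the original convention is not
stated; outputs record the mode used. The same operation serves PLA
quantification (PLA-dot mask as query against the junction mask) and
calcium-switch time courses, where identical segmentation settings are
enforced across the series and missing timepoints are flagged, never
interpolated. Intensity-correlation coefficients (Manders, Pearson) are
deliberately out of scope: the implemented readout is the pixel-overlap
object method.

# FRET analyses

**Acceptor photobleaching.** Donor images are Gaussian-filtered
(SD 0.75 px) and the efficiency is
$EF = (I_{\mathrm{post}} - I_{\mathrm{pre}})/I_{\mathrm{post}}$ over the
ROI means. Negative EF (donor loss) is returned but flagged rather than
clipped.

**Biosensor activation peaks.** Traces are differentiated by first
difference at the frame spacing (1 s default); local maxima of the
differential are candidate activations; a candidate survives only if the
underlying intensity at the post-rise frame exceeds the background level;
surviving maxima within 3 frames of each other merge into one event. Three
decisions deserve note:

* *"Above background"* is made explicit as intensity
  $> \mu_{bg} + z\,\sigma_{bg}$ of the paired no-activation trace. The
  default is $z = 2$. With Gaussian noise, a $2\sigma$ cutoff admits
  roughly 2% of frames as chance candidates, which is acceptable for
  flagging activity but inflates *counts* on long traces; the analysis
  scripts and the recovery tests therefore count events at $z = 3$, and
  callers comparing event counts between conditions should do the same.
  At a signal-to-noise ratio of 5 the $z = 3$ detector recovers simulated
  event counts within ±1 in ≥ 90% of runs.
* *Merging is transitive*: maxima $m_1, m_2$ with $|m_1 - m_2| \le 3$
  join, and chains extend ($\{5, 7, 9\}$ is one event). The pairwise
  phrasing of the rule admits an anchored-window reading; chaining is the
  only order-independent closure, and generator and detector share the one
  implementation (`merge_peak_frames`), so ground truth and detection can
  never diverge on the rule itself.
* Photobleaching detrending of time-lapse traces is available as an
  optional moving-average flag only; no correction is applied by default.

# AFM detachment analysis

Force–distance curves carry an approach and a retract segment. Each is
baseline-corrected by the mean force over its far-separation 10%, and the
detachment work is the area enclosed between the corrected traces,
integrated by the trapezoid rule and converted at 1 pN µm = $10^{-3}$ fJ.
The default integrates the approach–retract hysteresis (the area a
force–distance plot visually encloses); a retract-only mode (retract
against its own baseline) is a flag, since the published caption does not
distinguish the two — for a flat approach they agree. With additive noise
the rectified integrand acquires a small positive bias
($\sigma/\sqrt{2\pi}$ per unit separation, ≈ 0.01 fJ at 3 pN noise over a
10 µm range); noiseless curves integrate exactly, which the tests verify to
$10^{-6}$ relative error against analytic triangular wells. The maximum
detachment force is the deepest baseline-corrected retract excursion, and
the cadherin-dependent fraction counts events *strictly* above 150 pN, the
threshold calibrated on VE-cadherin-knockdown histograms. Instrument-native
binary formats and contact-mechanics fitting are out of scope; curves enter
as CSV tables.

# Velocity correlation length

The spatial autocorrelation
$C(r) = \langle u'(x)\,u'(x+r)\rangle / \langle u'^2 \rangle$ is computed
from the mean-subtracted x-component (the wound-closure direction) of a
gridded velocity field, with zero-padded FFTs so no periodic wrap-around
enters, then binned radially at the grid spacing. The correlation length
$\lambda$ comes from least-squares fitting $C(r) = e^{-r/\lambda}$ over the
contiguous run of lags with $C > 0.05$ (at least 4 bins); the amplitude is
fixed at 1 because $C(0) = 1$ by construction, with a two-parameter
$A e^{-r/\lambda}$ fit behind a flag. An isotropic mode (averaging x and y
components) exists but is off by default. On a single 256×256 field at
10 µm spacing with a synthesized 100 µm correlation length, the estimate is
unbiased with a spread of roughly ±8% across realizations; averaging
correlation curves over replicate fields before fitting (as one would over
replicate movies) tightens this, and both average-then-fit and
fit-then-average are possible since curves and fits are separate objects.

`block_piv` provides minimal cross-correlation PIV (64 px windows, 50%
overlap, parabolic subpixel peak) for frame pairs; it is a faithful
stand-in for dedicated PIV software, not a reimplementation of multi-pass
deformation algorithms, and flags featureless or peak-less windows invalid.

# The synthetic-data generators

The generators emulate the *statistical structure* of each assay, not its
biology — no signaling, junction mechanics or force propagation is
simulated:

* `gen_monolayer` places nuclei on a jittered lattice beside a straight
  wound edge (or an arc front), samples polarity angles from a von Mises
  distribution whose concentration $\kappa(d)$ depends on distance to the
  edge, and puts each Golgi exactly `golgi_offset_um` (default 5 µm) from
  its nucleus along the sampled axis. Sampling uses the Best–Fisher
  rejection method with $\kappa = 0$ handled exactly as uniform.
  Two profile presets define the simulated study conditions:
  `kappa_coordinated()` ($\kappa = 2$, mean-resultant length ≈ 0.70, out to
  300 µm) for a coordinated monolayer, and `kappa_floor()` for an
  uncoordinated one retaining only the geometric interface bias — a leader
  band at $\kappa = 0.8$ (PI ≈ 0.37) and a floor of $\kappa = 0.2$
  (PI ≈ 0.10) to 300 µm. The floor magnitude is a free parameter nowhere
  quantified in the literature; 0.2 was fixed so the floor's mean-resultant
  length matches the ≈ 0.1 residual per-bin PI reported for
  junction-disrupted monolayers, and the leader band so the first-row PI
  lands near the ≈ 0.36 reported for their leader cells. Default problem
  sizes mirror a realistic experiment: 4 images per condition, ~600 cells
  per 600 × 400 µm field. At these sizes the derived threshold is ≈ 0.15–0.2
  and the coordinated/uncoordinated profile structure reproduces cleanly;
  note that because the threshold is mean + 1 SD of bins drawn from the
  reference condition itself, roughly one random replicate in seven shows a
  single reference bin grazing the threshold — a property of the rule, not
  of the implementation.
* `gen_coloc_pair` builds non-overlapping discs and copies a prescribed
  fraction of channel A's spots into channel B, so the achieved overlap is
  exact up to spot-count rounding and recorded.
* `gen_photobleach_pair` constructs constant donor pairs satisfying
  $(I_{post} - I_{pre})/I_{post} = EF$ exactly before noise.
* `gen_activation_trace` adds impulse peaks on a flat background and
  records the ground-truth event count *after* the same 3-frame merge rule
  the detector uses.
* `gen_force_curve` builds a soft contact rise plus a triangular retract
  adhesion well whose enclosed area ($\tfrac12\,\mathrm{depth}\times
  \mathrm{width}$) and depth are the recorded work and maximum force; well
  vertices are included in the sample grid so noiseless trapezoid
  integration is exact. Contact metadata defaults (300 pN, 5 s) follow the
  standard cell–cell adhesion protocol.
* `gen_velocity_field` synthesizes Gaussian random fields spectrally with
  $S(k) \propto (1 + (kL)^2)^{-3/2}$, the 2-D spectral density whose
  covariance is $e^{-r/L}$.

All generators are deterministic for a fixed seed. What passing tests on
these inputs shows is that each computation does what it claims on data
with known structure; they do not certify segmentation quality on real
stainings, PIV on real textures, or any biological conclusion.

# Degenerate inputs and numerical choices

* Zero-length polarity vectors are flagged `NA`, never silently dropped at
  record construction; profile code drops flagged records explicitly.
* Constant images are degenerate for Otsu thresholding and return an empty
  mask with a warning; empty denominator masks are errors.
* Zero-variance velocity fields make correlation undefined: error, not
  `NaN`. Zero-donor pixels are excluded from ratio maps, not infinities.
* The one-parameter exponential fit minimizes SSE by golden-section search
  (`optimize`, tolerance $\sqrt{\epsilon}$), exact to ~$10^{-8}$ relative
  on noiseless data; the two-parameter fit uses the exact log-linear
  solution polished by Nelder–Mead, avoiding the zero-residual failure
  mode of `nls` on clean data.
* Assignment ties are resolved by the deterministic order of the LSAP
  solver; rerunning any stage with the same config and seed is
  byte-identical, and every output embeds its config snapshot and package
  version.

# Known limitations

* Segmentation is thresholding + labeling only; there is a documented
  escape hatch to externally produced centroid tables or masks, and no
  learned segmentation is attempted.
* Junction-morphology classes (linear/serrated/reticular) and stress-fiber
  connections are consumed as manual annotations and tallied
  (length-weighted for perimeter shares; segment-counted shares would
  require the original annotation protocol, which is not specified).
* The published population PIs and AFM work values derive from raw images
  and force curves that are not deposited; the package reproduces the
  *rules* (threshold derivation, formulas, counting conventions) and
  validates them on synthetic ground truth instead of claiming those
  numbers.
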