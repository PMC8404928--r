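---
title: "Spline-encoded medial descriptors: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spline-encoded medial descriptors: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmd)
```

## The model

`sdmd` represents an 8-bit image as a stack of *threshold sets*
$T_i = \{x : I(x) \ge i\}$. Each selected set is simplified (small islands
and holes below a fraction $\varepsilon$ of $|T_i|$ are removed), its
medial axis transform (MAT) is computed — the skeleton $S_{T_i}$ together
with the distance transform $DT_{T_i}$, so that
$T_i \approx \bigcup_{x \in S_{T_i}} B(x, DT(x))$ — and the skeleton is
pruned by *saliency* $\sigma = \rho / DT$, where $\rho$ is the length of
image boundary (in boundary pixels) that collapses onto the skeletal
point. Each remaining skeletal branch, viewed as a 3-D curve
$(x, y, DT)$, is fitted by a clamped uniform B-spline with the fewest
control points that keep the maximal 3-D deviation under
$\tau = \gamma \cdot \mathrm{diag}$. The file stores, per layer, only the
intensity, a polarity flag, and the spline degrees and control points.

Decoding rasterizes every spline with de Casteljau's algorithm at any
requested scale, stamps a disc of radius $r$ at every sample, composites
the layers in increasing intensity and optionally blends consecutive
layers with distance-transform weights. Because only control points are
stored, decoding at $s\times$ the original resolution costs no extra
storage (super-resolution decode).

Two encoder choices make the representation cheap in practice:

* **Adaptive polarity** — for each layer both $T_i^{\uparrow}$ and the
  complementary lower set are encoded and the one with fewer control
  points is kept (a flag records the choice). Thin dark structures
  (cartoon outlines, grid lines) are dramatically cheaper as lower sets.
* **Per-channel parameters** — colour images are encoded in YCbCr
  (full-range BT.601) and the chroma channels use
  $(\mathrm{round}(n_1 L),\; \min(1, n_2\varepsilon),\; n_3\sigma,\;
  n_4\gamma)$ with defaults $n_1 = 0.5, n_2 = 5, n_3 = 2, n_4 = 1$,
  exploiting the eye's lower chromatic acuity.

## Parameters

| parameter | default | meaning | effect of increasing |
|---|---|---|---|
| `L` | 18 | number of threshold layers (1–256) | quality ↑, compression ↓ |
| `eps` | 0.01 | island/hole fraction of $|T_i|$ | compression ↑, small detail lost |
| `sigma_thr` | 1.0 | saliency pruning threshold (boundary px per radius px) | smoother isophotes, compression ↑ |
| `gamma` | 0.002 | spline tolerance as a fraction of the image diagonal | compression ↑, geometric error ↑ |

The working ranges are $L \in [10, 20]$, $\sigma \in [0.6, 1.4]$,
$\gamma = 0.002$, $\varepsilon = 0.01$. $\gamma$ is deliberately relative
to the diagonal: re-encoding the same scene at twice the resolution then
uses twice the absolute tolerance, which is what keeps the control-point
count resolution-invariant.

With a salient-region map (`salient_map()`), the island rule uses
`eps_salient` for components mostly inside the map and `eps_background`
elsewhere, so important small detail survives while the background is
cleaned aggressively.

## Numerical and algorithmic choices

**Distance transform.** Exact Euclidean (Felzenszwalb–Huttenlocher lower
envelopes), distance measured to the nearest *background pixel centre*.
Reconstruction stamps *open* discs ($\lVert p - c\rVert < r$): with this
convention the pair is self-consistent — the nearest background pixel, at
distance exactly $DT$, is never painted foreground.

**Skeleton detection.** Every boundary contour (outer contours of
8-connected components, inner contours around 4-connected holes) is
parameterized by arc length with a Moore trace; the trace terminates on
the first repeated walk state, whose period is the contour length. Each
foreground pixel knows its nearest contour point (exact feature
transform). A pixel is skeletal when the feature points in its
8-neighbourhood are separated by at least $2\sqrt 2$ (the largest
spurious jump along straight or staircase boundaries, so sub-pixel detail
cannot register) *and* at least $DT$ — a 60° feature-angle criterion
that rejects shallow digitization corners. The candidate set is thinned
to one-pixel width by Guo–Hall passes, which preserve 8-connectivity,
and then *coverage-completed*: any foreground pixel left outside the
open-disc union is itself the centre of an inscribed disc, and the
deepest such pixels are added (in decreasing $DT$ order) until the disc
union reproduces the layer exactly. The unregularized MAT therefore
reconstructs its layer with zero symmetric difference by construction;
saliency pruning and the fragment filter below are what introduce loss.
$\rho$ is the shorter circular arc between the two feature parameters
(summed contour lengths when they lie on different contours); since the
straddle line of a medial branch lies between pixels, each pixel that
survives thinning inherits the collapsed arc of its thinning-removed
straddle partners.

A consequence worth knowing: on a *digital* disc the flats of the
digitized circle are genuine micro-corners with $\sigma \approx 1{-}1.4$,
by the same arithmetic that gives $\sigma = 2$ along a square's
diagonals. At `sigma_thr = 1` a digital disc therefore keeps a few short
interior stubs besides its centre; they are harmless for reconstruction
(their discs lie inside the shape) and disappear at `sigma_thr = 1.5`.

**Island filtering at the MAT level.** Skeletal fragments shorter than 4
samples whose disc union cannot cover $\varepsilon |T_i|$ pixels are
dropped before fitting. They encode edge raggedness of iso-contours on
smooth gradients — boundary detail of exactly the scale the
$\varepsilon$ island rule already declares negligible — and would
otherwise dominate the byte budget on smooth imagery.

**Polarity pairing.** A flip layer at intensity $i$ encodes
$\{I \le i-1\}$, so its decode-time complement is exactly
$\{I \ge i\}$. Pairing at $i$ itself would mispaint every flat region
sitting exactly at a selected intensity — the common case for graphics
and cartoon content, where the histogram-based layer selection picks the
region values themselves.

**Layer selection.** `histogram` (default) greedily adds the intensity
that most reduces $\sum_x |I(x) - q(x)|$, $q$ quantizing down to the
nearest selected layer, and stops early once the remaining error is below
half an intensity level per pixel: beyond that point layers encode
rounding noise. `uniform` spaces intensities evenly over the channel
range. Both always include the channel minimum, whose upper set spans the
frame and costs two bytes (a `full` marker).

**Border Y-structures.** Shapes cut by the frame produce spurious
Y-shaped junctions. The encoder extends the canvas with an outward
semi-disc over every border run (radius half the run length, capped at
twice the run's local thickness — an uncapped semi-disc over a
frame-spanning run would dwarf the shape and pull its medial axis out of
the frame), skeletonizes the extended shape, and clips the MAT back to
the frame. At decode time, spline ends lying exactly on the frame ring
are prolonged linearly — direction and radius slope taken from the end
control legs, so the extension is independent of the rendering scale —
for as long as the extrapolation keeps leaving the frame, stopping when
the extrapolated disc is tangent to it (the 45°-plane rule). This covers
the acute corners where shapes meet the border.

**Spline fitting.** Chord-length parameterization in $(x, y, r)$;
endpoints clamped to the first and last samples; interior control points
solved by least squares (QR). The search accepts the first fit with
$\le \tau$ error over increasing control-point counts (degrees 1–3 per
count, capped at 64 control points); failing that, the branch splits at
its worst sample and both halves recurse. Branches of up to 3 samples
are stored as polylines. Fitted control points are clamped to the
container's representable ranges (radii in $[0, \mathrm{diag}]$).

**Rasterization.** Splines are converted to Bézier segments by knot
insertion and evaluated by de Casteljau with adaptive parameter
refinement until consecutive rounded samples are 8-connected. Discs are
stamped at the sub-pixel sample positions; the integer chain is the
operation's contract. For a decode at scale $s$, coordinates map through
$x \mapsto s\,x + (s-1)/2$ — the affine map that preserves pixel-centre
alignment, so a scale-2 decode box-downsamples onto the scale-1 decode.

**Inter-layer interpolation.** A pixel in layer $i$ but not in layer
$i+1$ receives $v_i + (v_{i+1} - v_i)\, d_i / (d_i + d_{i+1})$, with
$d_i$ its distance to layer $i$'s boundary and $d_{i+1}$ its distance to
layer $i+1$; the symmetric weights make the blend continuous at both
boundaries. A layer that covers the whole frame has no boundary to blend
from, so its band keeps $v_i$ — without this exemption, flat dark
regions of binary images would be blended wholesale toward the next
intensity.

**Container.** Little-endian; magic `SDMD`, version, `u16` sizes, a
colormode byte, then per channel varint-counted layers of
`{intensity, flags, splines}`; spline coordinates are 16-bit fixed point
over $[-w, 2w] \times [-h, 2h]$ (decode-time extensions may leave the
frame) and radii over $[0, \mathrm{diag}]$. Knots are clamped uniform and
never stored. Quantization error is at most $3w/65535$ px in position —
invisible at any realistic size.

## What the synthetic fixtures emulate

`make_fixture()` generates the image families this codec targets —
large shapes over smooth or flat backgrounds: an Archimedean spiral
crossing the frame border (border-Y-structure stress), cushion treemaps
(smooth per-cell luminance gradients with sharp cell boundaries),
anti-aliased discs over a linear gradient, flat colour bands spanning the
frame, cartoon-like blobs with thin dark outlines (the lower-polarity
mechanism), and glyph-like strokes. All geometry is relative to the image
side and the random draws are size-independent, so the same seed
re-renders the same scene at any resolution.

What they do *not* emulate: sensor noise, texture, and high
spatial-frequency detail (fur, foliage). On such content medial
descriptors are known to compress and reconstruct poorly, and passing
results on these fixtures say nothing about it. SSIM is computed on the
luma plane (11×11 Gaussian window, sd 1.5, $K_1 = 0.01$, $K_2 = 0.03$).

On these fixtures at 512², the presets reach SSIM ≥ 0.85 with
compression ratios from ~48 (treemap, the densest scene) to several
hundred (spiral, cartoon); the test suite and `scripts/acceptance.R`
recompute these numbers. Binary line art is the hardest class for the
*cross-scale* comparison: a scale-2 decode box-downsampled is
anti-aliased while the scale-1 decode is binary, so the mean absolute
difference concentrates along the (long) edge perimeter.

## Problem sizes used by the tests

Unit tests run on shapes up to 64² and fixtures at 96–256²; the
end-to-end quality floor, the feature ablations and the
resolution-invariance check run at 512–1024², and the super-resolution
check decodes a 500² encoding at 3000². These sizes exercise every code
path at the study conditions while keeping a full suite run in minutes on
one CPU core.

## Known limitations

* Thin structures (≲ 3 px) have no stable medial representation at a
  given polarity; the adaptive polarity usually, but not always, finds
  the thick side. Content thin in *both* polarities (hairlines over
  textured ground) degrades.
* The saliency score is scale-invariant by design, so it cannot
  distinguish a small genuine corner from edge raggedness; the MAT-level
  island rule covers the difference only down to scale
  $\varepsilon |T_i|$.
* Sharp wedges with opening angles below 90° are rounded off by the
  feature-angle detector.
* No entropy coding: the container stores control points plainly, so
  byte sizes are ~6 bytes per control point plus small headers.
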