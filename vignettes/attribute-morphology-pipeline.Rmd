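---
title: "A max-tree pipeline for vegetation segmentation and crop/weed classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A max-tree pipeline for vegetation segmentation and crop/weed classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegmorph)
```

## The problem

Vision systems for precision agriculture must first separate vegetation
from soil and then decide, per plant region, whether it is a value crop or
a weed. The common approach thresholds a vegetation index image globally
(Otsu, RATS), which fails under uneven lighting, textured soil, or low
vegetation content, and then needs connected-component labelling plus
noise post-processing before a region classifier can run.

`vegmorph` implements an alternative built entirely on connected attribute
morphology. A single hierarchical image representation — the max-tree —
carries the whole pipeline: marker selection, region segmentation, shape
description and classification all read off the same structure, every
decision is local, and the segmentation emits labelled regions directly.

## The max-tree

An 8-bit image $f$ is decomposed into its upper level sets
$L_k = \{f \ge k\}$, $k = 0..255$. The connected components of the $L_k$
(peak components) are nested for decreasing $k$; storing each distinct
component once — at the highest level at which it occurs — and linking it
to the smallest strictly-containing component yields the canonical
max-tree. Leaves are the regional maxima; the root is the whole image.
Walking a branch from a leaf to the root enumerates exactly the regions
obtained by thresholding around that maximum with a decreasing threshold.

`max_tree()` builds the structure by union-find over value-sorted pixels
(ties broken by pixel index, so the tree is deterministic), in compiled
code. The dual `min_tree()` is the max-tree of $255 - f$ with levels
mapped back. Connectivity is 4 by default and configurable to 8; the
contract is the canonical structure, not the construction algorithm, and
the test suite checks the tree against brute-force level-set enumeration.

During construction, node attributes are propagated from the leaves to
the root so that each pixel is touched once: area, raw coordinate sums up
to second order (from which central moments follow), grey extrema, and
the convex hull. Hulls are propagated as point sets: a node's hull is the
hull of its children's hull vertices plus the four corners of its own
proper pixels. Using pixel corners (not centres) gives a one-pixel-wide
region a nonzero hull area and makes solidity of a single pixel exactly 1.

## Marker selection by extinction values

Images of real fields carry enormous numbers of regional maxima (noise,
soil texture, registration artefacts). Markers are filtered by
**grey-range extinction values**: for each maximum, the largest
grey-range filter size it survives, equal to the contrast between the
maximum and the level at which its component merges with a component
containing a more dominant maximum. The globally dominant maximum
receives the full image range. Dominance ties between equal-valued maxima
resolve to the leaf containing the smallest column-major pixel index —
an arbitrary but deterministic rule.

Maxima with extinction below 10 grey levels (on the 1–255 scale) are
discarded; the value 10 keeps anything that rises at least 10 levels over
its merging background, which on NDVI imagery separates vegetation from
sensor noise. The comparison is inclusive (a maximum at exactly 10
survives): the discard rule is stated for strictly smaller values.

## Stability-based region selection

For every marker, the branch to the root is scanned. The component at
threshold $k$ on a branch is stable while the plant region stays isolated
and grows abruptly when it merges into the background. The growth factor
over a span of $\Delta$ grey levels is

$$G(R_k) = \frac{A(R') - A(R_k)}{A(R_k)},$$

where $R'$ is the branch component $\Delta$ levels darker. Because the
canonical tree skips levels at which nothing changes, $R'$ is taken as
the candidate with the largest level $\le k - \Delta$ — the component
*strictly below* the span. The alternative reading (smallest level
$\ge k-\Delta$) would return the same stable component for any
well-contrasted object whose branch jumps directly to the background,
so no growth spike would ever be observed; the convention implemented is
the one under which merge detection works. When the span runs past the
root, the root's area is used.

The raw argmax of $G$ favours tiny regions (adding a few pixels to a
small region multiplies its area), so the choice is adjusted towards
slightly larger, repeated regions. With $B$ the current best candidate:

1. examine candidates $R$ with $G_{\min} < G(R) < G(B)$ in descending
   growth order (ties by descending level);
2. take the first with $A(R) > K \cdot A(B)$;
3. count the consecutive following candidates $R'$ with
   $(1 - e_A) A(R) \le A(R') \le (1 + e_A) A(R)$;
4. if at least $l$ such regions exist, set $B \leftarrow R$ and restart
   from step 1; otherwise stop.

Both inequalities in step 1 are strict, matching the step's formal
statement rather than the looser prose around it, and a successful
step 4 restarts the scan from the top with the new $B$; since each
adjustment multiplies $A(B)$ by more than $K \ge 1$, the loop terminates.
A branch whose maximal growth does not exceed $G_{\min}$ contributes no
region.

Accepted regions smaller than the area threshold $T$ are discarded
regardless of growth — this replaces the noise post-processing step that
global thresholding requires. Exact duplicates are recognised by
canonical node identity (two selections are the same region if and only
if they resolve to the same tree node); nested non-identical regions are
kept deliberately, since inner regions can capture single plants inside
larger overlapping-vegetation regions.

### Parameters

| parameter | meaning | default | unit |
|---|---|---|---|
| `delta` | growth span | 30 | grey levels |
| `g_min` | minimal allowed growth | 10 | ratio |
| `k_factor` | size factor for adjustment | 15 | ratio |
| `e_area` | area similarity tolerance | 0.15 | fraction |
| `l_similar` | required run of similar regions | 6 | count |
| `t_area` | minimal region area | 0 (off) | pixels |
| `min_extinction` | marker contrast cutoff | 10 | grey levels |

The first five defaults are the empirically determined field-imagery
values; `t_area` has no canonical value (it depends on ground resolution
and the smallest plant worth detecting) and therefore defaults to
disabled — the examples and tests use 50 px. `delta` is the one parameter
worth tuning per dataset; segmentation quality should be (and, on the
synthetic fields, is) flat across a wide band of values, which
`segment_tree()` makes cheap to verify since the tree and the extinction
values are reused across the sweep.

## Region features

Five descriptors per region, all computable incrementally:

* **solidity** — area over convex-hull area (hull over pixel corners);
* **eccentricity** — of the equivalent ellipse:
  $\sqrt{1 - \lambda_2/\lambda_1}$ from the eigenvalues of the
  second-order central moment matrix divided by area; defined as 0 for a
  single pixel ($\lambda_1 = 0$);
* **circularity** — moment-based and perimeter-free,
  $A^2 / \bigl(2\pi(\mu_{20} + \mu_{02} + A/6)\bigr)$;
* **non-compactness** — Hu's first moment invariant with the discrete
  correction, $2\pi\bigl((\mu_{20}+\mu_{02})/A^2 + 1/(6A)\bigr)$;
* **grey range** — $f_{\max} - f_{\min}$ inside the region, the only
  grey-dependent feature.

Perimeter-based circularity is deliberately avoided: the perimeter is
neither increasing nor incrementally computable on nested regions. The
$A/6$ terms are the per-pixel discrete correction (the second moment of a
unit square about its centre is $1/12$ per axis), chosen so an ideal disk
scores exactly 1 in both circularity and non-compactness; under this
construction the two are exact reciprocals, which the tests assert
identically. Moments use pixel-centre coordinates; the discrete
correction lives in the feature formulas, not in the stored sums.

Feature vectors are min–max normalized to $[0,1]$ per feature across the
dataset. In cross-validation the statistics come from the training folds
only and test values are clipped to $[0,1]$; a constant feature maps to
0.5. Min–max (rather than standardisation) keeps the inputs of the
margin-based classifier bounded.

## Crop/weed classification with rejection

Classification is a two-class support-vector machine over the five
features, selected over a fixed kernel grid — linear with
$C \in \{1,10,100,1000\}$, radial basis with the same costs crossed with
$\gamma \in \{10^{-3}, 10^{-4}\}$, polynomial with degree $\in \{2,3,4\}$
(cost 1, as no cost is specified for that kernel) — by F1 on a stratified
70/30 train/validation split.

Evaluation is image-level $k$-fold ($k = 10$): images, not regions, are
partitioned, so no region of a test image influences training,
normalization, or model selection. Mixed regions (containing both crop
and weed) are duplicated into one crop-labelled and one weed-labelled
training copy, and the minority class is oversampled with replacement to
exact balance. (The duplication direction — oversampling the smaller
class — is the only reading of the balancing step that actually achieves
balance.) At test time a mixed region is accepted as correct under either
decision, since resolving it is a pixel-level problem outside this
package's scope; a strict scoring mode is available.

Probabilities satisfy $p_{\text{crop}} = 1 - p_{\text{weed}}$ and come
from a Platt sigmoid fitted by logistic regression on the training
decision values of the selected SVM. Fitting the calibration explicitly
keeps the whole procedure deterministic under a seed and pins the
probability contract independently of the SVM backend. A region is
**rejected** when the winning probability falls below the confidence
$c \in [0.5, 1]$; at $c = 0.5$ nothing is rejected, and raising $c$
trades recall for precision, which `pr_over_confidence()` sweeps into an
interpolated precision–recall curve. No single operating $c$ is
canonical; the curve is the result.

## Baselines and evaluation

`otsu_threshold()` maximises the between-class variance over the image
histogram, scoring only occupied grey levels (thresholds inside histogram
gaps produce identical splits) and resolving ties to the lowest
threshold. `rats_threshold()` implements the gradient-weighted mean
intensity with a Sobel magnitude ($\sqrt{g_x^2+g_y^2}$, replicate
borders) and weight cutoff $\eta\lambda$; a content-free image leaves all
weights zero and raises the method's characteristic
"threshold not well-defined" error rather than returning a number.
Masks are compared by pixel counts: $p = TP/(TP+FP)$, $r = TP/(TP+FN)$,
$F_1 = 2pr/(p+r)$, with $p := 0$ for an empty prediction so $F_1$ stays
defined. Interpolated precision at recall $r$ is the maximum precision at
any recall $\ge r$ (the closure of the strict inequality, so the curve is
defined at its own support points).

## The synthetic field generator

No public imagery ships with the package; `generate_field()` produces the
test bed. It emulates the statistical structure the method relies on:

* **soil** — a base level plus smoothed uniform texture (box-blurred)
  plus an optional linear illumination gradient; soil maxima have small
  extinction values and must be rejected by the marker filter;
* **speckle** — sparse single-pixel bright outliers (default amplitude
  12 grey levels, just above the extinction cutoff) standing in for the
  sensor-noise and registration maxima that motivate marker filtering;
  their branches resolve to sub-`t_area` selections and vanish from the
  output when the size criterion is on;
* **plants** — crops as compact rosettes (a core disk with 5–7
  overlapping elliptical leaves), weeds as thin high-aspect blades;
  rendered flat at `soil_level + contrast` with a one-pixel edge ramp at
  a quarter of the contrast, emulating the fading, imprecise plant
  borders of real imagery. The two shape families give the classes
  strongly separated eccentricity distributions, which is what makes the
  shape-only classifier recoverable;
* **mixed regions** — with `overlap_prob`, a weed is planted across an
  existing crop, and the merged connected component is labelled `mixed`;
* **low-vegetation variant** — `generate_lowveg()` caps the foreground
  at 0.5% and defaults to four small plants under a 40-level illumination
  gradient: the regime where any single global threshold must either
  flood bright-side soil or miss dark-side plants, while the local method
  is unaffected.

Everything is reproducible bit-for-bit from the spec seed. What the
generator does **not** emulate: textured plant interiors (real leaves
have internal NDVI structure; synthetic cores are flat, so each plant is
one clean regional maximum), heavy-tailed soil reflectance, registration
parallax, and plant-shape diversity beyond the two families. Passing the
synthetic recovery tests therefore demonstrates the machinery — marker
selection, stability segmentation, feature separation — under controlled
conditions, not performance on any real dataset.

## Numerical choices

* NDVI values at `NIR + VIS = 0` are defined as 0 (signal-free pixels
  behave like dark background); the index is quantized to 8 bits by
  linear mapping of $[-1,1]$ with round-half-up, since the grey-level
  machinery (extinction values on the 1–255 range) presumes 8-bit input.
  How to map the index onto grey levels is genuinely open; linear is the
  assumption-free choice, and a loaded single-channel image is trusted to
  be already quantized.
* All tie-breaks are deterministic: pixel-index order in tree
  construction, smallest-pixel dominance in extinction, higher level for
  equal growth (the more contrasted core), descending level within equal
  growth in the adjustment scan, lowest threshold in Otsu, first grid row
  for equal validation F1.
* Degenerate inputs fail loudly: empty images, constant images for Otsu,
  gradient-free images for RATS, a class left empty after mixed
  duplication, fewer images than folds.

## Problem sizes

The test suite validates the tree, attributes, extinction values and
area opening against brute-force level-set oracles on tens of random
12–16 px images at 6–8 grey levels — small enough that exhaustive
enumeration is exact and fast, large enough to exercise merging, plateaus
and nesting. The recovery studies use ten 512×512 fields (about 2.6 M
pixels total), ten low-vegetation fields of the same size, an eight-point
$\Delta$ sweep reusing each field's tree, and a 20-image classification
set of 256×256 fields yielding roughly 110 labelled regions. The full
suite runs in about a minute and a half on one core.

## Known limitations

* Near-duplicate nested regions are returned by design; only exact
  (same-node) duplicates are removed. On real data a large fraction of
  output regions can be near-duplicates of each other.
* Each marker's branch is examined independently; shared ancestors are
  re-scanned, so degenerate trees have quadratic worst-case cost (not
  observed in practice, where region selection is a small fraction of
  runtime).
* The mixed class is detected but not resolved; pixel-level
  classification inside mixed regions is out of scope.
* The segmentation works on bright-on-dark structure (max-tree). Dark
  vegetation on bright soil would need the dual pipeline on the
  min-tree, which the data structure supports but the pipeline does not
  orchestrate.
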