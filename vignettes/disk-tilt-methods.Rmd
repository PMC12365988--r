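---
title: "Measuring flower-head inclination from segmentation masks"
author: "DiskTilt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flower-head inclination from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiskTilt)
```

## The measurement problem

The tilt angle of a sunflower flower head (capitulum) — the angle between
the head's plane and its supporting stem — is a phenotypic trait that
matters for light interception, seed filling and the pose planning of
harvesting robots. DiskTilt measures it without contact, from the two
per-class instance-segmentation masks (head, stem) that an upstream
segmentation model produces for a field photograph. The package takes
masks as input; it contains no segmentation model and trains nothing.

The geometric model is:

1. The head boundary is an ellipse. Its outer contour pixels are fitted
   with the general conic $Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0$ by
   minimizing the algebraic residual
   $\sum_i (Ax_i^2 + Bx_iy_i + Cy_i^2 + Dx_i + Ey_i + F)^2$
   subject to the ellipse discriminant constraint $4AC - B^2 > 0$. The
   *major axis* of the fitted ellipse is the head's orientation
   reference: direction $\vec v = (\cos\theta, \sin\theta)$, slope
   $k_l = \tan\theta$, endpoints offset $a/2$ from the center.
2. The stem centerline — the per-scanline midpoints of the stem mask —
   follows a cubic polynomial
   $f(t) = a_0 + a_1 t + a_2 t^2 + a_3 t^3$,
   fitted by ordinary least squares.
3. The stem meets the head where the polynomial crosses the ellipse
   (the root of the substituted system nearest the stem's head end), and
   the stem's local direction there is the tangent slope
   $k_s = f'(t) = a_1 + 2a_2 t + 3a_3 t^2$.
4. The tilt angle combines the two slopes. Two conventions are provided:
   the acute form
   $\theta = \arctan\left|\frac{k_l - k_s}{1 + k_l k_s}\right| \in [0^\circ, 90^\circ]$,
   and an oriented form
   $\theta = \arccos(\hat v \cdot \hat d) \in [0^\circ, 180^\circ)$
   with $\hat v$ the major axis oriented toward increasing $x$ and
   $\hat d$ the stem tangent oriented from the stem interior toward the
   intersection point.

### Why two angle conventions

The acute slope formula cannot exceed 90°, yet field heads are routinely
recorded at obtuse inclinations (a head leaning *with* its stem vs.
*against* it are different poses, e.g. 74° vs. 106°). The oriented
convention distinguishes these supplementary configurations and is the
package default; the acute form is retained as a selectable mode, and
`min(θ, 180° − θ)` of the oriented value always equals it (this identity
is asserted over random direction pairs in the test suite).

The oriented convention is tied to the image frame through the
"major axis toward $+x$" rule, because an ellipse's axis has no
intrinsic orientation. Consequently it is invariant under image
rotations only while the major axis stays off vertical; a rotation that
pushes the axis through vertical flips the reference and maps
$\theta \mapsto 180^\circ - \theta$. The acute convention is invariant
under all rotations. The tests assert exactly these two statements.

## Numerical design

**Conic fit.** Unconstrained minimization of the algebraic residual has
the trivial zero solution, so the fit solves the direct ellipse-specific
least-squares problem under the normalization $4AC - B^2 = 1$ (the
scatter-matrix block decomposition with a $3\times3$ eigenproblem). This
always returns an ellipse — a hyperbola or parabola is impossible by
construction — and is deterministic. Input points are centered at their
mean before fitting and the conic is translated back, purely for
conditioning. Any fixed normalization scale would serve the downstream
geometry; $4AC - B^2 = 1$ is the conventional choice.

**Standard form.** The center solves $2Ah + Bk + D = 0$,
$Bh + 2Ck + E = 0$; axis lengths come from the eigenvalues of the
quadratic part. The rotation uses
$\theta = \tfrac12\,\mathrm{atan2}(B, A - C)$, which is ambiguous by
90°; the quadrant is fixed by checking which eigenvalue the direction
belongs to, so $\theta$ always points along the *major* axis,
normalized to $(-90^\circ, 90^\circ]$. A circle has no defined rotation
and gets $\theta = 0$ by convention. Axis lengths are stored as full
lengths ($a$, $b$), with the semi-axes $a/2$, $b/2$ used wherever the
implicit equation is evaluated; the axis endpoints sit at $a/2$ from
the center.

**Stem fit and frames.** A photographed stem is near-vertical, which
makes $y = f(x)$ ill-posed. The centerline therefore records a scan
frame — the image coordinate with the larger bounding-box extent of the
stem mask — and the polynomial is fitted in that frame ($x = f(y)$ for
y-major). Slopes are mapped back to the image $dy/dx$ frame only at
tangent evaluation ($1/f'$, with a vertical flag when
$|f'| < 10^{-12}$). The independent coordinate is internally centered
and scaled to $[-1, 1]$ for the least-squares solve and the
coefficients are expanded back; this is invisible externally.

**Polynomial order.** The pipeline fixes order 3: stems bend smoothly
and a cubic captures the main trend, while order 4 adds flexibility with
little residual gain and more risk of oscillation between plants.
`compareOrders()` operationalizes "lower order unless it clearly pays"
with a 5% relative-residual stopping rule (`tolRel = 0.05`): the order
stops increasing when the next order improves the residual sum of
squares by less than 5%. It is a diagnostic, not part of the pipeline.

**Intersection.** Substituting the stem polynomial into the implicit
ellipse equation gives a univariate polynomial (degree ≤ 6 for a
cubic); its roots are the eigenvalues of the companion matrix, with
roots accepted as real when $|\mathrm{Im}| \le 10^{-8}(1 +
|\mathrm{Re}|)$. The parameter is centered and scaled to $[-1, 1]$
before building the companion matrix — in raw pixel coordinates the
degree-6 coefficients span ~15 orders of magnitude and the eigenvalues
lose several digits. Among real roots within the fitting domain
extended by 25% per side, the one nearest the stem's head end (the
centerline endpoint closest to the ellipse center) is selected: the
measurement wants the crossing where the stem *enters* the head, and
segmentation masks often stop a little short of the ellipse, so bounded
extrapolation bridges the gap without runaway cubic behavior. If no
admissible real root exists (disjoint masks) the curve point of minimum
distance to the ellipse boundary is returned, flagged
`closest_approach_fallback`. Tangent evaluation uses a tighter 10%
margin and clamps into it. Exact roots are verified on-curve to
$10^{-6}$ in normalized ellipse coordinates.

**Clipped-scanline trim.** Scanline midpoints are only unbiased where
the full band width is present. Two situations clip a run: scanlines
abutting the head (the stem mask ends at the head boundary, cutting the
run diagonally) and the two ends of a strongly slanted band. Both bias
the midpoints by several pixels exactly where the tangent is evaluated;
on synthetic scenes this alone moved the noiseless 200-scene RMSE from
about 0.55° (with occasional multi-degree outliers on near-45° stems)
to about 0.2°. `measureTilt()` therefore drops centerline points whose
run is shorter than 0.75 of the median run, or whose distance to the
fitted ellipse boundary (first-order approximation
$|Q|/\|\nabla Q\|$ on the implicit form) is below one stem width
(`headClearFactor`, default 1; set 0 to disable). The trim never leaves
fewer points than the fit needs. No other smoothing or outlier
rejection is applied to contours or centerlines — the fit uses all
boundary points as-is.

**Error codes.** Degenerate inputs raise conditions with stable codes
(`EMPTY_HEAD`, `EMPTY_STEM`, `CENTERLINE_TOO_SHORT`, `TOO_FEW_POINTS`,
`DEGENERATE_POINTS`, `IMAGINARY_ELLIPSE`, ...), so batch callers can
tell failure modes apart.

## The synthetic scene generator

No public image set with ground-truth inclinations exists, so the
package ships a generator whose scenes have *exactly* known angles: a
filled ellipse (the head) with a constant-width band (the stem)
attached to its boundary, rasterized at 512×512 by default.

Construction works backwards from the angle: the target angle is drawn
uniformly from the requested range (default [70°, 120°], the span
reported for field-grown heads), the ellipse rotation is drawn in
(−55°, 55°), and the stem tangent at the attachment point is then
*placed* at the target angle from the major axis. The attachment point
is the boundary point whose outward direction continues the stem, and a
cubic with mild random curvature ($|a_2| \le 2\times10^{-4}$,
$|a_3| \le 6\times10^{-7}$ in centered coordinates) extends it downward
(y-major frame — stems grow down from the head in image coordinates,
which exercises the frame-swap path; the acute equivalent is stored
alongside). Geometry that would leave the image is rejected and
redrawn *without* redrawing the angle, so the angle distribution stays
exactly uniform (the test suite checks a KS statistic < 0.05 at
n = 2000). Ellipse full major axes span 130–210 px, axis ratios
0.55–0.85, band widths 10–16 px — proportions matching a mature head
and stem filling a reasonable fraction of a 512 px frame.

The band is rendered per scanline with half-width scaled by
$\sqrt{1 + f'^2}$, so its perpendicular width is near-constant *and*
scanline midpoints fall exactly on the generating curve. Stem pixels
inside the head are removed, as in per-class instance masks.

Boundary jitter emulates segmentation raggedness: each pixel at
chessboard distance $d$ from the mask boundary flips with probability
$0.5\,e^{-d/j}$ under the scene's seed. This is a deliberately simple,
seedable noise model; it is not claimed to match the error statistics
of any particular segmentation network. Real masks additionally show
structured errors — occlusion by leaves, merged instances, systematic
boundary offsets — that the generator does not emulate, so passing the
synthetic accuracy checks demonstrates the correctness and noise
tolerance of the *geometry*, not field-level accuracy of a full
system.

The augmentation utility reproduces the training-time image
perturbations with their original default ranges — brightness ±50%,
rotation ±90° (exact at multiples of 90° on square grids, which the
tests exploit as an oracle), additive Gaussian noise with σ up to 20%
of full scale — and `splitDataset()`/`splitShares()` reproduce the
8:1:1 split bookkeeping. Share percentages are *truncated* to two
decimals, since that is the only convention consistent with the
published accounting (220/1163 reported as 18.91%).

## What the checks compute

The testthat suite and `scripts/acceptance.R` recompute, from scratch:

* full-pipeline RMSE against generator truth on 200 noiseless scenes
  and 200 scenes with 1.5 px jitter (budgets 1° and 3°);
* ellipse round-trip recovery on 500 random ellipses (budget $10^{-6}$
  relative) with the discriminant constraint verified on every fit;
* companion-matrix intersections against a $10^5$-point sign-change
  oracle (budget 0.5 px);
* oriented/acute convention consistency on 1000 direction pairs
  (budget $10^{-9}$ degrees);
* the hand-derivable metrics example (MAE 1/3, RMSE $1/\sqrt3$,
  R² 0.5), the RMSE ≥ MAE ordering on random data, and the
  ten-plant reference table;
* the dataset-split shares (67.41 / 7.91 / 18.91).

Problem sizes (200/500/100/1000 repetitions, 512² rasters) are the
package's chosen working points: large enough for stable estimates,
small enough that the whole suite runs in a few minutes on one CPU.

## Known limitations

* Purely 2-D: projection foreshortening is not modeled; a head tilted
  toward the camera reads differently than one tilted across it.
* One head, one stem per measurement; `pairInstances()` associates
  instances greedily by centroid-to-stem-end distance but no branch or
  junction topology is analyzed.
* The oriented convention's image-frame dependence (above).
* The centerline is scanline midpoints, not a morphological skeleton;
  for smooth unbranched stems the two nearly coincide, and midpoints
  are cheaper and deterministic, but strongly recurved stems (slope
  beyond ~±2 from the scan axis over a long arc) would need the
  skeleton.
* The error statistics of real segmentation masks are not emulated
  beyond boundary jitter; accuracy numbers on synthetic scenes bound
  the geometric error only.
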