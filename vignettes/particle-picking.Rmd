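---
title: "Probability-ratio template matching for cryo-EM particle selection"
author: "cryopick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-ratio template matching for cryo-EM particle selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopick)
```

## The generative model

A cryo-EM micrograph is modelled as locally normalised white Gaussian
noise plus a small number of particle projections:

$$X(\vec r) = \mu(\vec r) + \sigma(\vec r)\,N(\vec r)
  + \sum_{i=1}^{N} A_{k_i\phi_i}(\vec r - \vec t_i),$$

where $N(\vec r)$ is unit white noise, $\mu$ and $\sigma$ are smooth
position-dependent normalisation fields (ice thickness, exposure and other
uncontrolled factors vary across a micrograph), and each particle $i$ is a
copy of one of $K$ reference images ("templates", in practice 2D class
averages) at position $\vec t_i$, rotated in-plane by $\phi_i$.  Because
the model's noise is Gaussian, the natural similarity between micrograph
and template is Gaussian too — and unlike a plain cross-correlation
coefficient it is *not* invariant to intensity scale, so the fields
$\mu, \sigma$ must be estimated everywhere.

## Local normalisation by masked FFT correlation

A circular mask of radius $R$ splits a particle box into the particle area
$M_i$ (inside) and background area $M_o$ (outside).  For every candidate
box position $\vec t$, the mean and standard deviation of the pixels under
$M_o$,

$$\mu(\vec t) = \frac{1}{|M_o|}\sum_{\vec q\in M_o} X(\vec q + \vec t),
\qquad
\sigma^2(\vec t) = \frac{1}{|M_o|}\sum_{\vec q\in M_o} X^2(\vec q+\vec t)
 - \mu^2(\vec t),$$

are obtained for all $\vec t$ simultaneously from two FFT
cross-correlations of $X$ and $X^2$ with the binary mask
(`localBackgroundStats()`).  The same background normalisation is applied
to every extracted particle (`normalizeParticle()`), which forces its
$M_o$ pixels to mean 0 / sd 1 by construction.

Numerical choices here:

* round-off can leave slightly negative variances; they are clamped to
  zero before the square root;
* positions whose $\sigma$ does not strictly exceed a degeneracy floor of
  $10^{-6}\times$ the global micrograph sd are flagged invalid and can
  never produce picks — the similarity below divides by $\sigma$, and a
  perfectly flat region carries no evidence either way;
* the FFT implies circular (wrap-around) boundaries; rather than treating
  edges specially, any candidate whose box would cross the true
  micrograph edge is excluded at peak selection.  Rectangular micrographs
  are first padded to a square with Gaussian noise matching the global
  mean/sd, from a seeded generator (`padToSquare()`, default seed 0), so
  runs are reproducible.

## The similarity metric

With unit-variance normalised noise, the probability of observing the
micrograph given a particle $A_{k\phi}$ at $\vec t$, relative to the
probability of observing pure noise there, reduces to the log ratio

$$\log R_{\phi,k}(\vec t) =
  \frac{1}{\sigma(\vec t)}\sum_{\vec q} X(\vec q+\vec t)A_{k\phi}(\vec q)
  - \frac{\mu(\vec t)}{\sigma(\vec t)}\sum_{\vec q} A_{k\phi}(\vec q)
  - \frac{1}{2}\sum_{\vec q} A^2_{k\phi}(\vec q),$$

whose only position-dependent term is a single FFT cross-correlation.
The template sums are cached once per (template, rotation).  $R > 1$
means "more likely a particle than solvent".  To give thresholds a
predictable range the ratio is rescaled by its expectation under the
model,

$$E\langle R_k\rangle = \exp\!\Big(\frac{1}{2|M_i|}\sum_{\vec q}
A_k^2\Big),
\qquad
S_{\phi,k}(\vec t) = \frac{R_{\phi,k}(\vec t) - 1}{E\langle R_k\rangle - 1}.$$

Useful thresholds then typically lie in $(0, 1]$; the default is 0.3.
Two implementation notes:

* $\sum A^2/2$ can exceed 700 for strong templates, overflowing
  `exp()`.  All maps are therefore computed and stored in the log-ratio
  ("exponent") domain, and $S$ is formed as
  `expm1(logR) / expm1(logE)` only where needed.  In clean synthetic
  data $S$ at a true match can exceed 1 by a large factor — the
  normaliser divides by $|M_i|$ inside the exponent while a perfect
  match's log ratio grows with $\sum A^2/2$ itself; on real data, with
  imperfect templates and coloured noise, values stay below 1.
* $E\langle R_k\rangle$ is a per-template constant (computed from the
  unrotated prepared reference), so within one template $S$ is a fixed
  increasing transform of the log ratio.  Maxima and argmaxima over
  rotations can therefore be taken in the overflow-safe exponent domain
  and give exactly the maxima of $S$.
* $\mu$ and $\sigma$ are evaluated once per candidate position (constant
  across the box), which is what lets them be pulled out of the template
  sums above.

## Template preparation

Users supply CTF-*corrected* references (class averages).  For each
micrograph the picker internally modulates them by that micrograph's CTF,
so picking is fully CTF-corrected.  The CTF is the standard astigmatic
weak-phase model with CTFFIND-style parameters (defocus U/V in Å,
astigmatism angle, kV, Cs in mm, amplitude contrast $Q$, optional phase
shift): $\mathrm{CTF}(f,\alpha) = -[\sqrt{1-Q^2}\sin\chi + Q\cos\chi]$
with the usual defocus + spherical-aberration phase $\chi$.  The sign
follows the protein-is-dark convention; `invertContrast = TRUE` flips a
dark-particle micrograph on load.  The signed CTF is applied (not its
absolute value).  No envelope/B-factor is applied.  On the self-conjugate
Nyquist row/column of an even box an astigmatic CTF evaluates differently
for the two coincident azimuths; the transfer function is Hermitian-
symmetrised there so the filtered image is exactly real.

The preparation pipeline per template is: strict low-pass filter → CTF
multiplication → mask to $M_i$ → rotate (bilinear, about the box centre
$((b{-}1)/2, (b{-}1)/2)$) for every sampled angle with re-masking → final
strict low-pass.  The angular grid covers $[0,360)$ at a user sampling
(default 5°, i.e. $\Phi = 72$).

Two constraints compete in this pipeline and cannot both hold exactly:
a template supported strictly inside $M_i$ and a template with exactly
zero Fourier power beyond the cutoff (band-limited functions cannot have
compact support).  Because the low-pass exists to bound template bias —
no information beyond the cutoff may be imprinted on the picks — the
band limit is enforced *last* and holds exactly; the region outside
$M_i$ is then small but nonzero (a few percent of the template peak for
smooth references; up to ~15 % once strong CTF oscillations delocalise
the signal).  All cached sums run over the full box, so the FFT
correlation algebra above remains exact and self-consistent regardless.
In-plane rotation preserves $\sum A^2$ within ~2 % for smooth references
and within ~5 % after CTF modulation; the per-rotation cached sums are
always the exact sums of the images actually used.

The default cutoff of 20 Å is deliberately conservative: template bias
("Einstein-from-noise") is real and reproducible — see the template-bias
test below.

## Peak search, pruning, FOM maps

Candidate positions are strict 4-neighbour local maxima of the
best-over-rotations map that exceed the threshold (strict `>`).  They are
pruned by a minimum inter-particle distance (default two-thirds of the
particle diameter; useful values are 60–90 % of it): peaks closer than
the minimum distance are clustered by transitive closure, and within each
cluster the best remaining peak is kept and its too-close neighbours
discarded, recursively — so several peaks per cluster may survive, all
pairwise separated, and the global maximum always survives.  Equal peaks
are ordered by (row, column) for determinism.  Per-template survivors are
then combined across templates and pruned once more on their $S$ values.

The per-template best-over-rotations maps are the FOM (figure-of-merit)
maps.  They are kept in the exponent domain and quantised to single
precision *at construction*, because they are cached to disk as MRC
(mode 2, float32) files with a STAR sidecar: this way re-reading them and
re-picking at a new threshold/distance — a seconds-long operation that
makes threshold tuning cheap — reproduces in-memory picking
bit-identically.  Peak search operates on these per-template best maps;
since $S$ is monotone in the exponent within a template, searching the
best map is equivalent to searching every rotation's map and keeping the
best survivor.

## Sorting by difference-image Z-scores

For every picked particle the prepared template in its recorded
orientation is subtracted from the extracted, normalised particle image.
If the pick is a true particle the residual is background noise; junk
(ice, aggregates, carbon edges) leaves structure.  Five statistics of the
residual within $M_i$ summarise this: mean, population sd, skewness,
excess kurtosis (both defined as 0 for a zero-sd residual, and the excess
convention makes the pure-noise expectation 0), and the sd between the
sds of the four box quadrants (split at the box centre, each intersected
with $M_i$).  Each feature is converted to an absolute Z-score across the
particle set — absolute, because both tails of signed features like
skewness indicate non-noise residuals — and particles are ranked by their
average Z-score, worst first.  Inspecting only the top of the ranking is
an efficient way to discard false positives.  Sorting can be re-run at
any later processing stage by supplying an updated template assignment.

## The synthetic benchmark

`simulateMicrograph()` draws micrographs from the generative model
itself: constant or smooth-gradient $\mu$/$\sigma$ fields (emulating
ice-thickness and dose variation), unit white noise, and rotated,
optionally CTF-convolved template stamps at rejection-sampled positions
with a minimum pairwise separation.  The SNR is defined as the mean
squared in-$M_i$ signal over the local noise variance, because
per-micrograph SNR has no universal definition.  Optional artifact blobs
(soft discs of 6–8$\sigma$ amplitude, random sign, with heavy internal
texture) emulate the high-contrast junk the sorter is meant to catch.
Everything is reproducible from one integer seed.

What the simulator does *not* emulate: coloured (non-white) noise,
structured backgrounds (carbon edges, crystalline ice), particle overlap
and aggregation, beam-induced motion, radiation damage, and templates
that differ systematically from the planted particles.  Passing tests
therefore demonstrate the algorithm's correctness under its own model
assumptions, not its performance on real micrographs; on real data the
similarity values are far smaller and threshold choice matters much more.

The documented study conditions used by the test-suite and the
acceptance script: 512×512 px micrographs at 3 Å/px; two analytic
templates in 40-px boxes — a soft disc (top-view-like, radius 9.8 px) and
a rounded rod (side-view-like, 25.2×9.8 px, breaking rotational symmetry
modulo 180°) — mask radius 14 px (84 Å particle diameter); SNR 2; 20
planted particles; threshold 0.25; minimum distance 56 Å (= 2/3 of the
diameter); match radius a quarter of the diameter.  Picking templates are
scaled to the planted particle contrast ($\sqrt{\mathrm{SNR}}$), as class
averages of normalised particles would be.  These sizes keep the whole
suite within a couple of minutes on one CPU while leaving every quantity
(e.g. $\sum A^2/2 \approx 600$) inside double range.  The sorting
benchmark plants 200 particles plus 10 artifacts in 1024×1024 px; the
template-bias run picks a particle-free micrograph at threshold 0.1 with
a weak-contrast (0.05-amplitude) reference — the regime of real data,
where faint templates make many noise peaks cross a low threshold — and
compares the unaligned pick average against the reference and against an
equally sized random-position control.

## Coordinate and file conventions

Pixel coordinates are 0-based, (x = column, y = row), origin at the
top-left pixel centre; a pick denotes the particle *centre* (for an even
box this is a half-integer position).  Template indices are 0-based.
MRC2014 mode 2 (float32, little-endian) is used for images, stacks and
FOM maps; a write-then-read cycle quantises doubles once and is exact
thereafter.  STAR files use a single loop per data block with
conventional cryo-EM column names; reals are written with 17 significant
digits so doubles survive the text round trip exactly.  A supplied pixel
size always overrides the MRC header, which is frequently wrong in
practice.

## Known limitations

* Similarity values near high-variance regions (carbon, dust) can be
  inflated because the noise-only probability in the denominator drops;
  no suppression beyond the $\sigma$ floor is attempted, matching the
  observation that such false positives are better removed by sorting
  and classification.
* In extreme synthetic regimes ($\sum A^2 \gtrsim 1400$) $S$ itself can
  overflow double precision even though all internal computations are
  log-domain; the study conditions avoid this, and real-data values are
  orders of magnitude smaller.
* Bilinear rotation is interpolation-exact only at multiples of 90°; for
  smooth low-passed references the round-trip error stays below ~5 % of
  the template peak.
* Micrograph binning, helical picking, per-particle CTF refinement and
  GPU acceleration are out of scope.
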