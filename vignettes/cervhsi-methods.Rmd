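---
title: "Methods: consensus, registration, tissue indices and paired inference in cervhsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus, registration, tissue indices and paired inference in cervhsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervhsi)
```

`cervhsi` analyses hyperspectral reflectance cubes of the cervix for tissue
changes associated with cervical intraepithelial neoplasia (CIN). This
vignette documents the statistical and numerical machinery: what each stage
assumes, which parameters matter, how the synthetic phantom is built, and
where the design was genuinely open.

## The analysis model

A subject contributes a hypercube $R(x, y, \lambda) \in [0,1]$ on a regular
wavelength grid (default 500–995 nm in 5 nm steps, 100 bands), several
examiners' binary annotations drawn on a higher-resolution colposcope image
(classes *major*, *minor*, *healthy*), and $\ge 4$ landmark pairs relating
the two frames.

**Registration.** The colposcope$\to$HSI map is modeled as a homography
$[x', y', 1]^\top \sim H [x, y, 1]^\top$, adequate because the
externalized cervix is imaged near-frontally and is approximately planar at
the working distance. $H$ is estimated by Hartley-normalized DLT (translate
centroids to the origin, scale mean distance to $\sqrt 2$, solve the
$2n \times 9$ system by SVD), followed by BFGS refinement of the 8 free
parameters of the back-projection error
$\sum_i (x_i' - \hat x_i)^2 + (y_i' - \hat y_i)^2$. On noise-free
correspondences the estimate is exact (tests require $10^{-6}$ elementwise
agreement with the generating transform); with noise it is the plain
least-squares minimizer — no robust loss, because landmark sets are small
and hand-curated, and the published workflow rejected none. Degeneracy
(three collinear points among four, or an (almost) collinear full set,
detected both geometrically and as a vanishing gap between DLT singular
values) is an error, not a warning.

**Annotation transfer.** Binary masks are warped by inverse
nearest-neighbor mapping: a destination pixel is set iff its center, mapped
through $H^{-1}$, rounds to a set source pixel. Masks therefore stay
strictly binary; no interpolation threshold is introduced. Pixel
coordinates are 0-based with $x$ = column, $y$ = row and centers at integer
coordinates — an arbitrary but load-bearing convention that the tests pin
down.

**Consensus.** With $n$ examiners, the consensus map is the per-pixel
fraction of examiners marking that pixel (a normalized 2-D histogram of the
annotations). The CIN reference mask keeps pixels with consensus
$\ge \tau$; the comparison is *inclusive* because the source protocol
describes 50 % both as "exceeded" and as "at least half", and the latter
appears twice — with 5 examiners, 3/5 passes $\tau = 0.5$. Healthy
annotations are pooled as a plain union with no threshold (examiners mark
only a representative healthy patch, so absence of a mark is not
disagreement), minus any CIN pixel so the classes are disjoint. Examiner
agreement is summarized by pairwise intersection-over-union; a pair with an
empty union is *undefined* and excluded from cross-subject averages rather
than scored 0, since 0 would conflate "both empty" with "disjoint". An
examiner who marked no lesion still counts in the consensus denominator
(an empty mask is an opinion), but produces undefined IoU entries.

**Tissue indices.** Each index compares mean absorbance
$A = -\log_{10}\max(R, 10^{-4})$ inside two wavelength windows:
$\mathrm{raw} = \bar A_{\text{num}} - \bar A_{\text{den}}$ (difference
mode; a quotient mode exists), mapped linearly onto $[0,1]$ by configured
`scale = c(raw_min, raw_max)` and clipped. The floor $10^{-4}$ bounds
absorbance at 4 and is inert at tissue-realistic reflectance. Defaults
(nm): TWI 955–980 vs 880–900, THI 530–590 vs 785–825, StO2 570–590 vs
740–780, NIR 655–735 vs 825–925; scales TWI/NIR $(-0.5, 0.5)$, THI/StO2
$(-0.5, 1.5)$. The vendor's exact proprietary formulas are not published;
these windows follow the cited system description and live entirely in
configuration, so **only signs and orderings of lesion-vs-healthy
differences are interpretable, never absolute values**. Difference-mode
indices are invariant to uniform multiplicative illumination change, which
adds a constant to all absorbances.

**Paired inference.** Per subject and index, the lesion and healthy region
means form one pair; differences are oriented CIN $-$ healthy. The Wilcoxon
signed-rank test uses midranks, drops zero differences before ranking
(Wilcoxon's original policy, matching the common scientific-stack default;
a Pratt switch exists), and reports $W = \min(W^+, W^-)$. For $n \le 25$
nonzero differences the two-sided $p$ is exact: the null distribution of
$W^+$ over all $2^n$ sign assignments is enumerated by shift-convolution on
doubled midranks — identical to literal enumeration, polynomial time, and
well-defined under ties (a constant paired shift, maximally tied, still
yields $p = 2/2^n$). Beyond that, the normal approximation with tie
correction and a 0.5 continuity correction is used. The effect estimate is
the Hodges–Lehmann pseudo-median (median of all $n(n+1)/2$ Walsh averages,
self-pairs included) with a seeded percentile bootstrap CI (default
$B = 10^4$, level 0.95; percentile rather than BCa as the minimal reading
of "nonparametric bootstrap"). The standardized effect size is
$r = |Z|/\sqrt n$ with $Z$ the tie-corrected deviate, reported in every
mode. Raw two-sided $p$-values are reported without multiplicity
adjustment, matching the reporting convention of the analysis this package
operationalizes.

## The phantom generator

Because no clinical cubes are distributable, the package ships a seeded
phantom that states its world explicitly:

* **Scene**: a "cervix" disc (default radius 0.38 × image side, i.e.
  ~32 mm at 0.45 mm/px for a 96 px frame) on a dark background, with one
  *major* and one *minor* lesion polygon placed inside the disc.
* **Optics**: single-layer Beer–Lambert,
  $R = R_{\text{base}}(\lambda) \exp(-\sum_i c_i(x,y)\,\varepsilon_i(\lambda))$
  plus i.i.d. Gaussian sensor noise (sd 0.01 reflectance units), clipped to
  $[0,1]$. $R_{\text{base}}$ rises gently from 0.5 to 0.6 across the grid.
  No scattering, no acetowhitening kinetics, no spectral camera response:
  the simplest forward model that makes band-ratio indices respond with the
  correct *sign*.
* **Chromophores**: Gaussian-peak absorption templates — oxyhemoglobin
  doublet at 542/577 nm (width 12 nm), deoxyhemoglobin at 555 (15) and
  760 (30) nm, water at 970 (35) nm. Baseline concentrations 0.30 / 0.20 /
  0.40 (arbitrary units); lesions multiply hemoglobin by 2.0 (major) or
  1.5 (minor) and water by 1.8 / 1.4. These place signal exactly in the
  windows the indices read, emulating the elevated vascularization and
  water content of dysplastic tissue without claiming physical accuracy.
* **Examiners**: each simulated examiner redraws every lesion boundary with
  smooth radial jitter (a 4-harmonic random Fourier series with marginal sd
  `boundary_jitter_sd`, default 3 px — contiguous over/under-segmentation,
  not salt-and-pepper), adds a personal uniform dilation/erosion bias
  (±4 px) and misses a region entirely with probability 0.05; the healthy
  reference is the examiner's own jittered view of the disc minus their
  lesion marks. At zero noise every examiner reproduces the truth exactly.
  The published record quantifies disagreement only as mean IoU ≈ 0.5 for
  the union-of-CIN class; the jitter defaults were chosen once to land in
  that order of magnitude and are not revisited. They were not fitted to
  any distribution, because none is stated.
* **Second view**: a pseudo-RGB projection (bands nearest 620/540/500 nm)
  resampled through the inverse of a true homography (rotation ±0.12 rad,
  1/2 downscale, small translation, projective terms $\sim 5\times10^{-5}$)
  into a 2× frame, with landmark pairs exactly related by the true
  transform plus Gaussian destination-coordinate noise (default sd 0.5 px).
* **Seeding**: one root seed expands into per-component streams by a fixed
  affine congruential rule (`derive_subseed`), so cube noise, examiner
  jitter, landmark noise and bootstrap resampling never share a stream, and
  identical seeds give bit-identical output.

A green end-to-end test therefore establishes that the pipeline *recovers
injected chromophore contrasts through realistic geometric and annotation
noise* — it does not establish clinical sensitivity, absolute index
accuracy, or robustness to scattering, specular glints, and illumination
structure, none of which the phantom contains.

## Numerical choices

* Consensus thresholding subtracts $10^{-12}$ before comparing, so lattice
  values $k/n$ are kept at exactly $\tau = k/n$.
* Homography normalization fixes $h_{33} = 1$ unless $|h_{33}|$ is within
  $10^{-8}$ of zero relative to the Frobenius norm, in which case unit
  Frobenius normalization is used.
* The DLT refuses configurations whose 8th singular value falls below
  $10^{-10}$ of the largest (non-unique solution).
* Polygon rasterization uses the even-odd rule with pixel centers;
  degenerate (sub-pixel) polygons rasterize to empty masks.
* `zscore_spectrum` divides by the population (n) standard deviation by
  default — the convention is not stated in the source analysis — with a
  `sample` switch; tests cover both closed forms.
* Bootstrap quantiles use R's default type 7; with $B = 2000$ the
  difference between quantile types is far below Monte-Carlo noise.
* Subjects whose thresholded CIN mask (or residual healthy mask) is empty
  are flagged and excluded pairwise from the paired table, with their IDs
  recorded — exclusion-with-logging rather than imputation, since the
  reference analysis never faced this case.

## Open design points, resolved

* *Signed-rank vs rank-sum*: the source text names both; the paired design
  and the named software function imply signed-rank, which is implemented.
* *Grid endpoints*: "500–1000 nm in 5 nm steps" is inconsistent with "100
  bands"; 500–995 nm/100 bands is adopted. The ENVI reader accepts any
  uniform grid.
* *Band window restriction*: one passage mentions analysing 590–975 nm;
  whether outer bands were excluded is unstated. Full-grid analysis is the
  default; index windows are configurable, so any restriction is a config
  choice.
* *Healthy-region provenance*: whether healthy annotations were warped
  like CIN ones or drawn directly on HSI is not fully explicit; everything
  is warped through the same homography here.
* *Exact test under ties*: enumeration over sign assignments is
  well-defined with midranks, so exactness is kept for tied small samples
  rather than falling back to the approximation.

## Limitations

Absolute index values are package-defined, not device-comparable. The
phantom's noise model is Gaussian and spatially white; real cubes have
structured illumination, specular reflections and motion. The homography
assumes a planar cervix; strong protrusion would need a non-rigid model,
explicitly out of scope. Agreement statistics beyond IoU (kappa, STAPLE
fusion) and any CIN-grade classification are likewise out of scope.
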