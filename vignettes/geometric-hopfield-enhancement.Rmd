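---
title: "Geometrically regularized Hopfield networks for gray-scale image enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometrically regularized Hopfield networks for gray-scale image enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geohnn)
```

## The model

`geohnn` enhances 8-bit gray-scale images by posing enhancement as *Q-class
pixel labeling* solved by a Hopfield-type recurrent network whose coupling is
regulated by the local geometry of the image.

A classical Hopfield network over bipolar states
$\delta \in \{-1,+1\}^N$ has symmetric weights $\psi_{ij}$ (zero diagonal in
the binary version), biases $\wp_i$, net input
$\phi_i = \sum_j \psi_{ij}\delta_j + \wp_i$, threshold activation
$\delta_i \leftarrow \mathrm{sign}(\phi_i)$, and Lyapunov energy

$$E(\delta) = -\tfrac12 \sum_{i,j}\psi_{ij}\delta_i\delta_j -
  \sum_i \wp_i \delta_i .$$

Under asynchronous single-node updates each accepted flip strictly lowers
$E$, so the dynamics reach a fixed point in finitely many sweeps. We use the
standard negative-quadratic sign convention throughout; it is the only
convention under which the descent statement is true and testable, and both
the classical network and the labeling network below share it. When
$\phi_i = 0$ the node holds its current state, which keeps the energy trace
monotone (the threshold rule is otherwise undefined at zero).

For enhancement, every pixel $i$ of a patch carries a one-hot indicator
$\delta_{iq} \in \{0,1\}$, $\sum_q \delta_{iq} = 1$, over $Q$ prototype
intensities $I_1 < \dots < I_Q$. The labeling objective combines a
quantization term and a neighborhood term,

$$\Pi(\delta) = \sum_i \sum_q \lVert \xi_i - I_q\rVert^2 \,\delta_{iq}
 \;+\; s \sum_i \sum_{j \in \mu_i} \bar\kappa(i,j)\,[q_i = q_j],$$

over ordered neighbor pairs $\mu_i$ (4- or 8-neighborhood), where $\xi_i$ is
the pixel intensity and $\bar\kappa(i,j) = (\kappa_i + \kappa_j)/2$ is the
pairwise coupling. The network realization uses neighbor weights
$\psi_{ij} = 2\bar\kappa(i,j)$ and per-pixel, per-class biases
$\wp_q(i) = \frac1Q\sum_r d_r(i) - 8\kappa_i\,(Q - d_q(i))$ with
$d_q(i) = (\xi_i - I_q)^2$.

**Smoothness sign.** With $s = +1$ the neighborhood term *penalizes*
agreement, and a large $\kappa$ drives the labeling toward checkerboard
configurations — the opposite of the smooth, perceptually coherent output the
method aims for. The default is therefore the Potts convention $s = -1$
(`smoothness_sign = "potts"`), which rewards agreement; the
agreement-penalizing convention remains available as
`smoothness_sign = "paper"` and is exercised by the tests. Both signs admit
the same descent guarantee.

## Geometric regulation

The coupling field $\kappa$ is not uniform: it is modulated by the local
orientation structure so that strong oriented edges are coupled weakly (and
thus preserved) while flat regions are smoothed.

* `structure_orientation()` estimates the per-pixel dominant orientation
  $\hat\chi$ as the leading eigenvector of the window-averaged structure
  tensor (gradients by central differences; Sobel available). The
  orientation sign is fixed by requiring the first nonzero component to be
  nonnegative; all downstream quantities are sign-invariant.
* The directional gradient energy
  $\lvert \nabla^T\hat\chi \rvert^2 = \lvert\nabla\rvert^2 \cos^2
  \angle(\nabla, \hat\chi)$ is pooled over the same window
  (`windowed_directional_energy()`).
* `kappa_field()` sets $\kappa_i = \kappa_0 / (1 + e_i/\bar e)$, where $e_i$
  is the pooled energy and $\bar e$ its mean. The specific modulation is a
  design choice: it is bounded in $(0, \kappa_0]$, strictly decreasing in
  edge energy, and parameter-free beyond $\kappa_0$.

Updates are *sign-sequenced*: the alternating matrix of signs
$(-1)^{i+j}$ (`sign_matrix()`) splits the pixels into two checkerboard
parities, and each sweep updates all $+1$-parity pixels, then all
$-1$-parity pixels. In the 4-neighborhood, equal-parity pixels are mutually
uncoupled, so each half-sweep is an exact block coordinate-descent step and
can be computed vectorized; the 8-neighborhood falls back to strictly
sequential updates. Each pixel takes the class minimizing its local
objective, changing only on strict improvement (tolerance $10^{-12}$), so
$\Pi$ is non-increasing across sweeps and termination is guaranteed; the
fixed point cannot be improved by any single-pixel relabel.

The default class count comes from the Euler-characteristic branch formula
for a smooth quadric hypersurface, `class_count(n)` $= n+3$ for even $n$,
$n+2$ for odd $n$; the default hyperplane dimension 2 gives $Q = 5$. What
$n$ should denote for a 2-D image is genuinely open; we expose it as
`hyperplane_dim` (and `Q` directly) in the configuration.

## The enhancement pipeline

`enhance_image()` composes the stages as follows:

1. the image is mean/variance-normalized once (z-score, then affine rescale
   to $[0,1]$; the stored parameters make the map invertible to $10^{-9}$);
2. $Q$ prototypes are estimated *globally* — by default the equal-mass
   quantile midpoints $(2q-1)/2Q$ of the intensity distribution, which is
   deterministic; seeded k-means is available;
3. the image is partitioned into `patch_rows` × `patch_cols` patches
   (default 22 × 20 = 440, reflect padding), and orientation, $\kappa$ and
   the labeling network run independently per patch;
4. the converged labels are reassembled, and each class's occupied global
   intensity interval $[\mathrm{lo}_q, \mathrm{hi}_q]$ is stretched linearly
   onto the equal-width band $[(q-1)/Q,\ q/Q]$;
5. the stretched image is denormalized and blended with the input in the
   original intensity domain:
   $\mathrm{out} = \alpha\,\mathrm{stretched} + (1-\alpha)\,\mathrm{input}$,
   clipped to $[0,1]$.

An earlier design normalized, labeled, prototyped, stretched and
denormalized *each patch independently*. With 10 × 10 patches every patch
then re-anchors to its own mean/variance and its own band layout, which
introduces strong blocking artifacts at patch seams; on the synthetic
fixture these artifacts cost more reference fidelity (VIF) than the contrast
redistribution gains. Estimating the prototypes and the band stretch
globally while keeping the network optimization per patch removes the seams
and preserves the local character of the relaxation; this global/local split
is the design the package ships.

**Parameters.**

| key | default | meaning |
|---|---|---|
| `patch_rows`, `patch_cols` | 22, 20 | partition grid (440 patches) |
| `Q` / `hyperplane_dim` | 5 (from dim 2) | intensity classes |
| `kappa0` | 0.01 | global coupling ceiling |
| `alpha` | 0.7 | blend weight of the remap |
| `neighborhood` | 4 | pixel neighborhood |
| `window_*` | Gaussian 5 × 5, $\sigma=1$ | orientation window |
| `max_sweeps` | 100 | labeling sweep budget |
| `smoothness_sign` | `"potts"` | neighborhood term sign |

$\kappa_0$ is dimensionally a squared intensity (it competes with
$d_q(i) = (\xi_i - I_q)^2$). The default $0.01$ equals the squared quarter
band-width $(1/2Q)^2$ at $Q = 5$: misclassification costs near a band
boundary are then comparable to the cost of disagreeing with a neighbor, so
neither term dominates. $\alpha = 0.7$ keeps a 30% anchor to the input;
$\alpha = 0$ is bit-exactly the identity (the blend happens in the original
domain), which doubles as a pipeline integrity check.

`recompute_orientation = TRUE` re-estimates the orientation and coupling
fields from the prototype-rendered labeling between outer passes (up to 4),
for use when the initial gradients are unreliable; the default is a single
precomputation, which is faster and was never observed to change converged
labels on smooth phantoms.

## Bipolar codecs and MPF learning

Since Hopfield states are bipolar, 8-bit images enter the learning path as
bit planes: `bitplane_decompose()` produces eight $\{-1,+1\}$ planes (LSB
first; round-half-up quantization to 0..255), and the round trip through
`bitplane_recompose()` is the identity on all 256 values.

`onoff_encode()` maps normalized intensities to a ternary ON/no-firing/OFF
code by equal-width tertiles $[0,\frac13)$, $[\frac13,\frac23)$,
$[\frac23,1]$, emulating the ON/OFF response of retinal ganglion cells. The
32-node training vectors for learning are the codes of the first 32 pixels
of each partition patch, with no-firing states resolved to OFF so the
vectors are bipolar; with the default grid an image yields 440 vectors. How
a single 8-bit pixel should expand into a 32-bit abstract ON/OFF vector is
underdetermined, and this block-based construction is our documented
interpretation. Likewise, the learned 32-node network is *not* fed into the
enhancement network (whose weights and biases come from the closed forms
above); the learning path serves the classical storage/recall pipeline, and
the gap is deliberate.

Minimum probability flow estimates weights and biases without the partition
function by minimizing the flow from data states to their single-bit-flip
Hamming neighbors,

$$K(\theta) = \frac{1}{|D|}\sum_{x \in D}\sum_{i}
  \exp\!\big[(E_\theta(x) - E_\theta(x^{(i)}))/2\big]
  = \frac{1}{|D|}\sum_{x}\sum_i e^{-\delta_i \phi_i},$$

which depends on energy differences only. The gradient is analytic
(`mpf_gradient()`, checked against central finite differences at $10^{-6}$
relative), and `fit_mpf()` runs gradient descent with Armijo backtracking
(initial step 0.2, sup-norm gradient tolerance $10^{-5}$, 500 iterations),
so the objective trace is non-increasing by construction. `gibbs_sample()`
provides seeded single-site Gibbs draws from $P \propto e^{-E}$ for
consistency experiments; `make_ising_dataset()` plants a nearest-neighbor
ring for recovery scoring.

## Evaluation metrics

No canonical formulas exist for "the" five perceptual metrics, so the
package fixes and documents one variant of each; all parameters are exposed
so alternates can be compared.

* **Entropy**: Shannon entropy (bits) of the 256-bin histogram.
* **GLCM contrast / homogeneity**: Haralick statistics
  $\sum g(a,b)(a-b)^2$ and $\sum g(a,b)/(1+|a-b|)$ on the symmetrized
  co-occurrence table averaged over offsets
  $\{(0,1),(1,0),(1,1),(1,-1)\}$ at 256 native levels.
* **VIF**: pixel-domain, multi-scale (4 dyadic scales, Gaussian windows of
  size $2^{5-s}+1$, HVS noise variance $\sigma_n^2 = 2$ on the 0–255
  scale). Identical images score 1 to $10^{-6}$; a constant test image
  scores 0; values above 1 indicate amplified local gain.
* **WPSNR**: PSNR on the 0–255 scale with noise-visibility weights
  $w_i = 1/(1+\theta\sigma_i^2)$, $\theta = 1/\max\sigma_i^2$, local
  variance in a 5 × 5 box. A flat reference reduces it to plain PSNR;
  identical images return the 100 dB cap.
* **Aggregation**: population $\sigma$ (divisor $n$) by default, as a
  descriptive spread; sample $\sigma$ by flag.

## The synthetic fixtures

`make_phantom()` renders ellipses, rectangles and ramps over a smooth
background with seeded band-limited texture; `degrade_image()` applies
Gaussian blur, mid-anchored contrast compression, gamma and seeded additive
noise, skipping identity stages so the identity spec is the bit-exact
identity map. The frozen `standard_fixture()` (220 × 200 phantom, texture
seed 7; blur $\sigma = 1.5$, contrast scale 0.4, noise $\sigma = 0.01$, seed
11) emulates the salient features of low-quality clinical images — oriented
lesion edges, compressed dynamic range, mild noise — but not MRI physics,
modality-specific noise statistics, or anatomy. Passing the enhancement
audits on it shows the pipeline restores information content, texture
contrast and reference fidelity under those degradations; it does not show
clinical image quality.

## Numerical choices and degenerate inputs

* Quantization to 0..255 is round-half-up; histogram/GLCM binning uses the
  same rule.
* Reflect (mirror) padding everywhere, to avoid spurious edge gradients.
* Constant patches: normalization returns them unchanged with a degenerate
  flag; labeling short-circuits to the nearest prototype; a constant image
  is returned unenhanced.
* Prototypes are forced strictly increasing with an $\varepsilon = 10^{-6}$
  separation; patches with fewer distinct values than $Q$ are padded with
  interval midpoints and flagged.
* Label updates and threshold activations hold the current state on ties.
* VIF guards zero-variance windows with an $\varepsilon = 10^{-10}$ floor.

## Scales used by the shipped tests

The test suite audits the descent and oracle properties at 500 random
32-node networks, 100 exhaustively enumerated networks of up to 10 nodes,
200 corrupted-probe recall trials at 64 nodes, 200 seeded 3 × 3 labeling
patches with a single-relabel oracle, a 16-node planted ring with 5000
Gibbs samples, and the full 220 × 200 fixture; these sizes are the
package's choice of a thorough-but-quick audit and can be scaled up by
editing the loops.

## Known limitations

* 8-bit gray-scale only; no DICOM/NIfTI ingestion, no color.
* The labeling relaxation finds coordinate-wise local minima, not global
  optima; the checkerboard schedule makes it deterministic but order
  effects at exact ties remain.
* The learned MPF network and the enhancement network are not coupled.
* GLCM at 256 levels on small patches is sparse; metric comparisons across
  images of very different sizes should fix `levels` accordingly.
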