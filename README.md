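# geohnn

Gray-scale image enhancement with a geometrically regularized Hopfield
network, for researchers working with low-contrast 8-bit imagery (medical
scans, phantoms, micrographs) who want an energy-based, fully deterministic
enhancement pipeline together with the perceptual metrics to judge it.

## What it does

Enhancement is posed as **Q-class pixel labeling** solved by a Hopfield-type
recurrent network. Each pixel carries a one-hot indicator over Q prototype
intensities $I_1 < \dots < I_Q$, and the network minimizes

$$\Pi(\delta) = \sum_i \sum_q \lVert \xi_i - I_q \rVert^2\, \delta_{iq}
\; - \; \sum_i \sum_{j \in \mu_i} \bar\kappa(i,j)\, [q_i = q_j],$$

a quantization term plus a Potts-style neighborhood term whose coupling
$\bar\kappa$ is *regulated by image geometry*: a structure-tensor orientation
field and its directional gradient energy
$|\nabla^T\hat\chi|^2 = |\nabla|^2 \cos^2\angle(\nabla,\hat\chi)$ shrink the
coupling on strong oriented edges, so edges are preserved while flat regions
are smoothed. Updates run in checkerboard order derived from the sign matrix
$(-1)^{i+j}$, each sweep is an exact coordinate-descent step, and the
objective trace is provably non-increasing. Converged classes are remapped by
stretching each class's occupied intensity interval onto its equal-width band
$[(q-1)/Q,\, q/Q]$, then blended with the input.

The package also provides:

* the classical binary/continuous Hopfield baseline (Hebbian storage,
  asynchronous Lyapunov descent, recall),
* minimum-probability-flow (MPF) estimation of Hopfield weights/biases from
  bipolar data, with an analytic gradient and a seeded Gibbs sampler,
* bipolar bit-plane and ON/OFF ternary codecs for 8-bit images,
* the five-metric evaluation suite — entropy, VIF, WPSNR, GLCM contrast,
  GLCM homogeneity — with mean/σ aggregation,
* deterministic synthetic phantoms and degradations, so everything runs
  without external data,
* a CLI (`exec/geohnn`) with `enhance`, `evaluate`, `fixture` and
  `train-mpf` subcommands.

## Worked example

```r
library(geohnn)

fx  <- standard_fixture()                      # frozen phantom + degraded pair
res <- enhance_image(fx$degraded, mhnn_config())

rbind(degraded = evaluate_pair(fx$original, fx$degraded),
      enhanced = evaluate_pair(fx$original, res$image))
```

```
         entropy    vif   wpsnr contrast homogeneity
degraded  5.6548 0.2579 16.1092  18.6358      0.3482
enhanced  5.9714 0.2917 15.2610  40.6544      0.3582
```

Reading the rows: the degradation (blur σ = 1.5, contrast compressed to 40%,
noise σ = 0.01) leaves the image with low information content and texture
contrast. Enhancement raises entropy (5.65 → 5.97 bits: more usable intensity
levels), more than doubles GLCM contrast (18.6 → 40.7: stronger local texture
differences), and raises VIF against the *clean* original (0.258 → 0.292:
more of the original's information survives in the enhanced image).
Homogeneity rises slightly; WPSNR dips, the usual price of contrast
amplification under a squared-error metric. All 440 patch networks converged
(`res$diagnostics`).

From a shell the same run is:

```sh
Rscript exec/geohnn fixture /tmp/fx
Rscript exec/geohnn enhance /tmp/fx/degraded.png /tmp/out.png
Rscript exec/geohnn evaluate /tmp/report.csv --ref /tmp/fx/original.png --test /tmp/out.png
```

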