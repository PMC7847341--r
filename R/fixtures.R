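# Deterministic synthetic phantoms and degradations. These stand in for the
# clinical MRI/cancer images the enhancement pipeline targets: a smooth
# background, bright lesion-like structures with oriented edges, a ramp, and
# seeded band-limited texture. All generation is seeded and text-free so
# every test and the acceptance run are reproducible offline.

render_shape <- function(img, shape) {
  h <- nrow(img); w <- ncol(img)
  kind <- match.arg(shape$kind, c("ellipse", "rectangle", "ramp"))
  ctr <- shape$center; ax <- shape$axes
  if (ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > h ||
      ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > w) {
    stop("shape does not fit inside the canvas", call. = FALSE)
  }
  if (shape$intensity < 0 || shape$intensity > 1) {
    stop("shape intensity must be in [0, 1]", call. = FALSE)
  }
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (kind == "ellipse") {
    mask <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
    img[mask] <- shape$intensity
  } else if (kind == "rectangle") {
    mask <- abs(rr - ctr[1]) <= ax[1] & abs(cc - ctr[2]) <= ax[2]
    img[mask] <- shape$intensity
  } else {   # ramp: intensity rises linearly left to right across the extent
    mask <- abs(rr - ctr[1]) <= ax[1] & abs(cc - ctr[2]) <= ax[2]
    cmin <- ctr[2] - ax[2]; cmax <- ctr[2] + ax[2]
    frac <- (cc - cmin) / max(cmax - cmin, 1)
    img[mask] <- shape$intensity * frac[mask]
  }
  img
}

#' Render a medical-like phantom image
#'
#' Draws shapes over a constant background and adds seeded band-limited
#' texture (Gaussian noise smoothed with a Gaussian filter, rescaled to unit
#' standard deviation, scaled by `texture_amp`). Fully deterministic per
#' seed.
#'
#' @param height,width canvas size.
#' @param shapes list of shapes, each a list with `kind` (`"ellipse"`,
#'   `"rectangle"` or `"ramp"`), `center` (row, col), `axes` (semi-axes in
#'   rows, cols) and `intensity` in \[0, 1\]. Shapes must fit in the canvas.
#' @param background background intensity.
#' @param texture_amp texture standard deviation (0 disables texture).
#' @param seed texture RNG seed.
#' @return numeric matrix in \[0, 1\].
#' @export
make_phantom <- function(height = 220L, width = 200L, shapes = list(),
                         background = 0.2, texture_amp = 0.05, seed = 7L) {
  stopifnot(height >= 1L, width >= 1L,
            background >= 0, background <= 1, texture_amp >= 0)
  img <- matrix(background, height, width)
  for (shape in shapes) img <- render_shape(img, shape)
  if (texture_amp > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(height * width), height, width)
    noise <- gauss_blur(noise, 2)
    noise <- noise / stats::sd(as.vector(noise))
    img <- img + texture_amp * noise
  }
  clip01(img)
}

#' Degrade an image
#'
#' Applies, in order: Gaussian blur (`blur_sigma`), mid-anchored contrast
#' compression (`x -> 0.5 + contrast_scale * (x - 0.5)`), gamma correction,
#' seeded additive Gaussian noise, and clipping to \[0, 1\]. Stages at their
#' identity settings are skipped, so the identity spec is bit-exactly the
#' identity map.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param blur_sigma Gaussian blur sigma (>= 0).
#' @param contrast_scale contrast factor in (0, 1\].
#' @param gamma gamma exponent (> 0).
#' @param noise_sigma additive noise standard deviation (>= 0).
#' @param seed noise RNG seed.
#' @return degraded matrix in \[0, 1\].
#' @export
degrade_image <- function(img, blur_sigma = 0, contrast_scale = 1, gamma = 1,
                          noise_sigma = 0, seed = 1L) {
  assert_gray(img)
  stopifnot(blur_sigma >= 0, contrast_scale > 0, contrast_scale <= 1,
            gamma > 0, noise_sigma >= 0)
  out <- img
  if (blur_sigma > 0) out <- gauss_blur(out, blur_sigma)
  if (contrast_scale != 1) out <- 0.5 + contrast_scale * (out - 0.5)
  if (gamma != 1) out <- clip01(out)^gamma
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(out), sd = noise_sigma),
                        nrow(out), ncol(out))
  }
  if (blur_sigma > 0 || contrast_scale != 1 || gamma != 1 || noise_sigma > 0) {
    out <- clip01(out)
  }
  out
}

#' The standard brain-like fixture pair
#'
#' A fixed 220 x 200 phantom (large ellipse, two lesions, a ramp strip,
#' texture amplitude 0.05, seed 7) and its degraded counterpart (blur sigma
#' 1.5, contrast scale 0.4, noise sigma 0.01, seed 11). These settings are
#' frozen so that enhancement experiments and tests run on identical inputs.
#'
#' @return list with `original`, `degraded`, and `manifest` (the specs).
#' @export
standard_fixture <- function() {
  shapes <- list(
    list(kind = "ellipse", center = c(110, 100), axes = c(72, 62),
         intensity = 0.55),
    list(kind = "ellipse", center = c(80, 70), axes = c(14, 11),
         intensity = 0.9),
    list(kind = "ellipse", center = c(140, 130), axes = c(9, 15),
         intensity = 0.85),
    list(kind = "ramp", center = c(205, 100), axes = c(10, 90),
         intensity = 0.8)
  )
  phantom_spec <- list(height = 220L, width = 200L, shapes = shapes,
                       background = 0.2, texture_amp = 0.05, seed = 7L)
  degrade_spec <- list(blur_sigma = 1.5, contrast_scale = 0.4, gamma = 1,
                       noise_sigma = 0.01, seed = 11L)
  original <- do.call(make_phantom, phantom_spec)
  degraded <- do.call(degrade_image, c(list(img = original), degrade_spec))
  list(original = original, degraded = degraded,
       manifest = list(phantom = phantom_spec, degrade = degrade_spec))
}

#' Planted ring Ising dataset for parameter-recovery experiments
#'
#' Builds a nearest-neighbor ring coupling matrix (zero biases) and draws
#' Gibbs samples from it; the planted parameters are returned alongside the
#' samples so estimators can be scored against the truth.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param coupling ring coupling strength.
#' @param n_samples number of Gibbs samples.
#' @param seed RNG seed.
#' @param burn_in discarded initial sweeps (default 200).
#' @return list with `weights` (planted matrix), `biases` (zeros) and
#'   `samples`.
#' @export
make_ising_dataset <- function(n_nodes = 16L, coupling = 0.5,
                               n_samples = 5000L, seed = 1L,
                               burn_in = 200L) {
  stopifnot(n_nodes >= 2L)
  w <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes)) {
    j <- i %% n_nodes + 1L
    w[i, j] <- w[i, j] + coupling
    w[j, i] <- w[j, i] + coupling
  }
  diag(w) <- 0
  b <- rep(0, n_nodes)
  samples <- gibbs_sample(w, b, n_samples = n_samples, burn_in = burn_in,
                          seed = seed)
  list(weights = w, biases = b, samples = samples)
}
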