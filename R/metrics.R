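# Perceptual evaluation suite: Shannon entropy, GLCM contrast/homogeneity
# (Haralick), pixel-domain multi-scale visual information fidelity (VIF) and
# noise-visibility-weighted PSNR (WPSNR), plus mean/sigma aggregation over an
# image set.

quantize_levels <- function(img, levels) {
  v <- clip01(img)
  matrix(pmin(levels - 1L, floor(v * (levels - 1L) + 0.5)),
         nrow(img), ncol(img))
}

#' Shannon entropy of an image
#'
#' Entropy (base-2) of the intensity histogram; `0 log 0` is taken as 0.
#' Bounded by `log2(levels)` (8 bits for the default 256 levels); a constant
#' image has entropy 0 and an exactly uniform histogram attains the bound.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param levels number of histogram bins (default 256).
#' @return entropy in bits.
#' @export
img_entropy <- function(img, levels = 256L) {
  assert_gray(img)
  q <- quantize_levels(img, levels)
  p <- tabulate(as.integer(q) + 1L, nbins = levels) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized intensity pairs at the given pixel
#' offsets, optionally symmetrized, normalizes each offset's table to sum 1,
#' and averages the tables over offsets. Offsets larger than the image are
#' skipped with a warning.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param offsets list of `(row, col)` integer offsets; the default is the
#'   four standard directions (0,1), (1,0), (1,1), (1,-1).
#' @param levels number of gray levels (default 256).
#' @param symmetric count each pair in both orders (default TRUE).
#' @return `levels` x `levels` matrix summing to 1; entry `[a+1, b+1]` is the
#'   probability of level pair (a, b).
#' @export
glcm <- function(img, offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                     c(1L, -1L)),
                 levels = 256L, symmetric = TRUE) {
  assert_gray(img)
  stopifnot(levels >= 2L)
  q <- quantize_levels(img, levels)
  h <- nrow(q); w <- ncol(q)
  tabs <- list()
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rs <- max(1L, 1L - dr):min(h, h - dr)
    cs <- max(1L, 1L - dc):min(w, w - dc)
    if (length(rs) < 1L || length(cs) < 1L || rs[1] > rs[length(rs)] ||
        cs[1] > cs[length(cs)]) {
      warning(sprintf("offset (%d, %d) larger than image; skipped", dr, dc))
      next
    }
    a <- as.integer(q[rs, cs, drop = FALSE])
    b <- as.integer(q[rs + dr, cs + dc, drop = FALSE])
    tab <- tabulate(a * levels + b + 1L, nbins = levels * levels)
    if (symmetric) {
      tab <- tab + tabulate(b * levels + a + 1L, nbins = levels * levels)
    }
    tabs[[length(tabs) + 1L]] <- tab / sum(tab)
  }
  if (!length(tabs)) stop("no usable offsets", call. = FALSE)
  g <- Reduce(`+`, tabs) / length(tabs)
  matrix(g, levels, levels, byrow = TRUE)   # row index = first level a
}

#' GLCM contrast
#'
#' \eqn{\sum_{a,b} g(a,b) (a - b)^2}: the expected squared intensity
#' difference between neighboring pixels. Zero for a diagonal table.
#'
#' @param g normalized co-occurrence matrix from [glcm()].
#' @return nonnegative scalar.
#' @export
glcm_contrast <- function(g) {
  l <- nrow(g)
  d <- outer(0:(l - 1L), 0:(l - 1L), `-`)
  sum(g * d^2)
}

#' GLCM homogeneity
#'
#' \eqn{\sum_{a,b} g(a,b) / (1 + |a - b|)}: a likeness measure in (0, 1\],
#' equal to 1 for a diagonal table.
#'
#' @param g normalized co-occurrence matrix from [glcm()].
#' @return scalar in (0, 1\].
#' @export
glcm_homogeneity <- function(g) {
  l <- nrow(g)
  d <- outer(0:(l - 1L), 0:(l - 1L), `-`)
  sum(g / (1 + abs(d)))
}

#' Visual information fidelity (pixel domain, multi-scale)
#'
#' Per scale, Gaussian-window local statistics of the reference and test
#' images give the local gain `g = cov / (var_ref + eps)` and residual
#' variance; the VIF is the ratio of test-channel to reference-channel
#' information, \eqn{\sum_s \log_2(1 + g^2 \sigma^2_{ref} / (\sigma^2_v +
#' \sigma^2_n)) / \sum_s \log_2(1 + \sigma^2_{ref}/\sigma^2_n)}. Identical
#' images score 1; a constant test image scores 0; values above 1 indicate
#' amplified information in the test image.
#'
#' @param ref,test numeric matrices in \[0, 1\] of equal size, at least
#'   32 x 32.
#' @param n_scales number of dyadic scales (default 4).
#' @param sigma_nsq HVS noise variance on the 0-255 scale (default 2).
#' @return nonnegative scalar.
#' @export
vif <- function(ref, test, n_scales = 4L, sigma_nsq = 2) {
  assert_gray(ref, "ref"); assert_gray(test, "test")
  if (!all(dim(ref) == dim(test))) {
    stop("`ref` and `test` must have the same dimensions", call. = FALSE)
  }
  if (min(dim(ref)) < 32L) {
    stop("images must be at least 32 x 32", call. = FALSE)
  }
  r <- ref * 255; t <- test * 255
  eps <- 1e-10
  num <- 0; den <- 0
  for (s in seq_len(n_scales)) {
    n <- 2^(n_scales - s + 1) + 1
    win <- gauss_kernel(as.integer(n), n / 5)
    if (s > 1L) {
      r <- conv2_reflect(r, win)[seq(1, nrow(r), 2), seq(1, ncol(r), 2)]
      t <- conv2_reflect(t, win)[seq(1, nrow(t), 2), seq(1, ncol(t), 2)]
    }
    mu1 <- conv2_reflect(r, win); mu2 <- conv2_reflect(t, win)
    s1 <- pmax(conv2_reflect(r * r, win) - mu1^2, 0)
    s2 <- pmax(conv2_reflect(t * t, win) - mu2^2, 0)
    s12 <- conv2_reflect(r * t, win) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    lo1 <- s1 < eps
    g[lo1] <- 0; sv[lo1] <- s2[lo1]; s1[lo1] <- 0
    lo2 <- s2 < eps
    g[lo2] <- 0; sv[lo2] <- 0
    neg <- g < 0
    sv[neg] <- s2[neg]; g[neg] <- 0
    sv[sv < eps] <- eps
    num <- num + sum(log2(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log2(1 + s1 / sigma_nsq))
  }
  if (den <= 0) return(0)
  num / den
}

#' Weighted peak signal-to-noise ratio
#'
#' PSNR on the 0-255 scale with noise-visibility weights that de-emphasize
#' errors in high-activity regions of the reference:
#' \eqn{w_i = 1 / (1 + \theta \sigma^2_i)} with \eqn{\sigma^2_i} the local
#' variance in a 5 x 5 window and \eqn{\theta = 1 / \max_i \sigma^2_i}.
#' A variance-free (flat) reference gives uniform weights and plain PSNR;
#' identical images return `cap_db`.
#'
#' @param ref,test numeric matrices in \[0, 1\] of equal size.
#' @param cap_db value returned for a zero weighted error (default 100 dB).
#' @return WPSNR in dB (capped at `cap_db`).
#' @export
wpsnr <- function(ref, test, cap_db = 100) {
  assert_gray(ref, "ref"); assert_gray(test, "test")
  if (!all(dim(ref) == dim(test))) {
    stop("`ref` and `test` must have the same dimensions", call. = FALSE)
  }
  r <- ref * 255; t <- test * 255
  win <- box_kernel(min(5L, 2L * min((min(dim(r)) - 1L) %/% 2L, 2L) + 1L))
  m <- conv2_reflect(r, win)
  v <- pmax(conv2_reflect(r * r, win) - m^2, 0)
  mx <- max(v)
  w <- if (mx <= 0) matrix(1, nrow(r), ncol(r)) else 1 / (1 + v / mx)
  wmse <- sum(w * (r - t)^2) / sum(w)
  if (wmse <= 0) return(cap_db)
  min(cap_db, 10 * log10(255^2 / wmse))
}

#' Evaluate one (reference, test) image pair
#'
#' Entropy, GLCM contrast and homogeneity are computed on the test image;
#' VIF and WPSNR on the pair.
#'
#' @param ref,test numeric matrices in \[0, 1\] of equal size.
#' @param levels gray levels for entropy and GLCM (default 256).
#' @param n_scales,sigma_nsq VIF parameters.
#' @param cap_db WPSNR cap.
#' @return one-row data frame with columns `entropy`, `vif`, `wpsnr`,
#'   `contrast`, `homogeneity`.
#' @export
evaluate_pair <- function(ref, test, levels = 256L, n_scales = 4L,
                          sigma_nsq = 2, cap_db = 100) {
  g <- glcm(test, levels = levels)
  data.frame(entropy = img_entropy(test, levels),
             vif = vif(ref, test, n_scales, sigma_nsq),
             wpsnr = wpsnr(ref, test, cap_db),
             contrast = glcm_contrast(g),
             homogeneity = glcm_homogeneity(g))
}

#' Aggregate metric reports
#'
#' Per-metric mean and standard deviation over a set of reports. The default
#' is the population sigma (divisor n), as a descriptive spread; set
#' `sigma = "sample"` for the n-1 divisor.
#'
#' @param reports data frame of rows from [evaluate_pair()].
#' @param sigma `"population"` (default) or `"sample"`.
#' @return data frame with rows `mean` and `sd`.
#' @export
aggregate_reports <- function(reports, sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  if (!is.data.frame(reports) || nrow(reports) < 1L) {
    stop("`reports` must be a nonempty data frame", call. = FALSE)
  }
  num <- reports[vapply(reports, is.numeric, TRUE)]
  mu <- vapply(num, mean, 1)
  n <- nrow(num)
  sd_fun <- function(x) {
    if (n == 1L) return(0)
    s2 <- stats::var(x)
    if (sigma == "population") sqrt(s2 * (n - 1) / n) else sqrt(s2)
  }
  sg <- vapply(num, sd_fun, 1)
  out <- rbind(as.data.frame(as.list(mu)), as.data.frame(as.list(sg)))
  rownames(out) <- c("mean", "sd")
  out
}
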