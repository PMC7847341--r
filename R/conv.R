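# Small 2-D filtering utilities shared by the geometry, metric and fixture
# code. Kernels are dense matrices with odd dimensions; boundaries are handled
# by mirror (reflect) padding, which avoids spurious gradients at image edges.

# Mirror-pad a matrix. Reflection excludes the edge sample (the first padded
# row above row 1 is row 2); pads larger than dim-1 are clamped to the border.
pad_reflect <- function(x, top = 0L, bottom = 0L, left = 0L, right = 0L) {
  nr <- nrow(x); nc <- ncol(x)
  mirror <- function(n, pad_front, pad_back) {
    front <- if (pad_front > 0L) pmin(pmax(rev(seq_len(pad_front)) + 1L, 1L), n) else integer(0)
    back  <- if (pad_back  > 0L) pmin(pmax(n - seq_len(pad_back), 1L), n) else integer(0)
    c(front, seq_len(n), back)
  }
  x[mirror(nr, top, bottom), mirror(nc, left, right), drop = FALSE]
}

# 2-D correlation with reflect boundary; kernel dimensions must be odd.
conv2_reflect <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  xp <- pad_reflect(x, pr, pr, pc, pc)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * xp[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
    }
  }
  out
}

# Normalized isotropic Gaussian kernel of odd size.
gauss_kernel <- function(size, sigma) {
  stopifnot(size >= 1L, size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

box_kernel <- function(size) {
  stopifnot(size >= 1L, size %% 2L == 1L)
  matrix(1 / size^2, size, size)
}

# Gaussian blur with kernel size chosen from sigma (6 sigma support, odd).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(x)) - 1L) + 1L)
  if (size %% 2L == 0L) size <- size - 1L
  conv2_reflect(x, gauss_kernel(max(size, 1L), sigma))
}
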