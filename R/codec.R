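#' Bipolar bit-plane decomposition
#'
#' A Hopfield network is a bipolar system: its states are -1/+1. An 8-bit
#' image is therefore represented as a stack of 8 bipolar planes, one per bit
#' position; plane `k` (k = 0 is the least significant bit) holds +1 where bit
#' `k` of the quantized pixel value is set and -1 elsewhere.
#'
#' @param img numeric matrix in \[0, 1\]; values are clipped and quantized to
#'   0..255 with round-half-up before decomposition.
#' @return an object of class `bitplane_stack`: a list with `planes` (list of
#'   8 matrices with entries in \{-1, +1\}, index 1 = LSB), `height`, `width`.
#' @seealso [bitplane_recompose()]
#' @export
bitplane_decompose <- function(img) {
  q <- quantize8(img)
  qi <- matrix(as.integer(q), nrow(q), ncol(q))
  planes <- lapply(0:7, function(k) {
    p <- matrix(-1, nrow(qi), ncol(qi))
    p[bitwAnd(qi, bitwShiftL(1L, k)) > 0L] <- 1
    p
  })
  structure(list(planes = planes, height = nrow(qi), width = ncol(qi)),
            class = "bitplane_stack")
}

#' Recompose an image from bipolar bit planes
#'
#' Inverse of [bitplane_decompose()]: pixel value is the sum of `2^k` over
#' planes holding +1, rescaled to \[0, 1\]. The round trip
#' `bitplane_recompose(bitplane_decompose(x))` is the identity on 8-bit input.
#'
#' @param stack a `bitplane_stack`.
#' @return numeric matrix in \[0, 1\].
#' @export
bitplane_recompose <- function(stack) {
  if (!inherits(stack, "bitplane_stack") || length(stack$planes) != 8L) {
    stop("`stack` must be a bitplane_stack with 8 planes", call. = FALSE)
  }
  for (p in stack$planes) {
    if (!all(p == 1 | p == -1)) {
      stop("bit-plane entries must be exactly -1 or +1", call. = FALSE)
    }
  }
  val <- Reduce(`+`, Map(function(p, k) (p > 0) * 2^k, stack$planes, 0:7))
  val / 255
}

#' Partition an image into a grid of patches
#'
#' Reflect-pads the image so that its dimensions divide evenly, then tiles it
#' into `patch_rows` x `patch_cols` equally sized patches in row-major order.
#' The default 22 x 20 grid yields the 440-partition scheme used by the
#' enhancement pipeline.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param patch_rows,patch_cols number of patch rows / columns (>= 1).
#' @return an object of class `patch_grid`: list with the padded image
#'   (`padded`), patch size (`patch_h`, `patch_w`), pad amounts, original
#'   dimensions and a row-major list `patches` of `(rows, cols)` index ranges.
#' @export
partition_grid <- function(img, patch_rows = 22L, patch_cols = 20L) {
  assert_gray(img)
  patch_rows <- as.integer(patch_rows); patch_cols <- as.integer(patch_cols)
  if (patch_rows < 1L || patch_cols < 1L) {
    stop("`patch_rows` and `patch_cols` must be >= 1", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  if (patch_rows * patch_cols > h * w) {
    stop("patch count exceeds pixel count", call. = FALSE)
  }
  ph <- as.integer(ceiling(h / patch_rows))
  pw <- as.integer(ceiling(w / patch_cols))
  pad_bottom <- ph * patch_rows - h
  pad_right  <- pw * patch_cols - w
  padded <- pad_reflect(img, 0L, pad_bottom, 0L, pad_right)
  patches <- vector("list", patch_rows * patch_cols)
  idx <- 1L
  for (pr in seq_len(patch_rows)) {
    for (pc in seq_len(patch_cols)) {
      patches[[idx]] <- list(rows = ((pr - 1L) * ph + 1L):(pr * ph),
                             cols = ((pc - 1L) * pw + 1L):(pc * pw))
      idx <- idx + 1L
    }
  }
  structure(list(patch_rows = patch_rows, patch_cols = patch_cols,
                 patch_h = ph, patch_w = pw,
                 pad_bottom = pad_bottom, pad_right = pad_right,
                 height = h, width = w,
                 padded = padded, patches = patches, pad_mode = "reflect"),
            class = "patch_grid")
}

#' Extract one patch from a partition
#' @param grid a `patch_grid`.
#' @param i patch index (row-major, 1-based).
#' @return numeric matrix of size `patch_h` x `patch_w`.
#' @export
get_patch <- function(grid, i) {
  stopifnot(inherits(grid, "patch_grid"))
  p <- grid$patches[[i]]
  grid$padded[p$rows, p$cols, drop = FALSE]
}

#' Reassemble patches into an image
#'
#' Places the patches back at their grid positions and removes the reflect
#' padding. Reassembling untouched patches reproduces the input bit-exactly.
#'
#' @param grid a `patch_grid`.
#' @param patches list of matrices, one per grid cell, in row-major order.
#' @return numeric matrix with the original (unpadded) dimensions.
#' @export
assemble_patches <- function(grid, patches) {
  stopifnot(inherits(grid, "patch_grid"),
            length(patches) == length(grid$patches))
  out <- matrix(0, nrow(grid$padded), ncol(grid$padded))
  for (i in seq_along(patches)) {
    p <- grid$patches[[i]]
    stopifnot(nrow(patches[[i]]) == grid$patch_h,
              ncol(patches[[i]]) == grid$patch_w)
    out[p$rows, p$cols] <- patches[[i]]
  }
  out[seq_len(grid$height), seq_len(grid$width), drop = FALSE]
}

#' Normalize a patch to zero mean / unit variance, rescaled to \[0, 1\]
#'
#' Pixel values are z-scored (sample mean 0, sample variance 1) and then
#' affinely rescaled to \[0, 1\] so that downstream distance terms stay in a
#' bounded domain. The returned `norm` record stores everything needed to
#' invert the map with [denormalize_patch()]. A constant patch (zero
#' variance) is returned unchanged with `var = 0` and `degenerate = TRUE`.
#'
#' @param patch numeric matrix with at least 2 pixels.
#' @return list with `patch` (normalized matrix) and `norm` (list with `mean`,
#'   `var`, `zmin`, `zmax`, `degenerate`).
#' @export
normalize_patch <- function(patch) {
  if (!is.matrix(patch) || length(patch) < 2L) {
    stop("`patch` must be a matrix with at least 2 pixels", call. = FALSE)
  }
  m <- mean(patch)
  v <- stats::var(as.vector(patch))
  if (!is.finite(v) || v <= 1e-24) {
    return(list(patch = patch,
                norm = list(mean = m, var = 0, zmin = 0, zmax = 0,
                            degenerate = TRUE)))
  }
  z <- (patch - m) / sqrt(v)
  zmin <- min(z); zmax <- max(z)
  list(patch = (z - zmin) / (zmax - zmin),
       norm = list(mean = m, var = v, zmin = zmin, zmax = zmax,
                   degenerate = FALSE))
}

#' Invert [normalize_patch()]
#' @param patch normalized matrix (values in \[0, 1\]).
#' @param norm the `norm` record returned by [normalize_patch()].
#' @return matrix on the original intensity scale (not clipped).
#' @export
denormalize_patch <- function(patch, norm) {
  if (isTRUE(norm$degenerate)) return(patch)
  z <- patch * (norm$zmax - norm$zmin) + norm$zmin
  z * sqrt(norm$var) + norm$mean
}

#' ON/OFF ternary encoding of a patch
#'
#' Emulates the ON/OFF response of retinal ganglion cells: the intensity range
#' is split into three equal-width intervals \[0, 1/3), \[1/3, 2/3), \[2/3, 1\]
#' mapped to -1 (OFF), 0 (no firing) and +1 (ON). The encoding is monotone in
#' intensity.
#'
#' @param patch numeric matrix with values in \[0, 1\].
#' @return integer matrix with entries in \{-1, 0, +1\} and an attribute
#'   `thresholds = c(1/3, 2/3)`.
#' @export
onoff_encode <- function(patch) {
  assert_gray(patch, "patch")
  s <- matrix(0L, nrow(patch), ncol(patch))
  s[patch < 1 / 3] <- -1L
  s[patch >= 2 / 3] <- 1L
  attr(s, "thresholds") <- c(1 / 3, 2 / 3)
  s
}

#' Build 32-node bipolar training vectors from an image
#'
#' For each patch of the partition the normalized patch is ON/OFF ternary
#' encoded and the first 32 pixels (row-major) form one training vector for
#' the 32-node network learned by minimum probability flow. Zero (no-firing)
#' states are resolved to OFF (-1) so the vectors are bipolar.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param patch_rows,patch_cols partition grid (default 22 x 20 = 440 patches).
#' @param n_nodes training vector length (default 32); patches must contain at
#'   least this many pixels.
#' @return matrix with one bipolar \{-1, +1\} row per patch.
#' @export
onoff_training_vectors <- function(img, patch_rows = 22L, patch_cols = 20L,
                                   n_nodes = 32L) {
  grid <- partition_grid(img, patch_rows, patch_cols)
  if (grid$patch_h * grid$patch_w < n_nodes) {
    stop(sprintf("patches have %d pixels; need >= %d",
                 grid$patch_h * grid$patch_w, n_nodes), call. = FALSE)
  }
  vecs <- matrix(0, length(grid$patches), n_nodes)
  for (i in seq_along(grid$patches)) {
    np <- normalize_patch(get_patch(grid, i))
    code <- onoff_encode(clip01(np$patch))
    v <- as.integer(t(code))[seq_len(n_nodes)]  # row-major flatten
    v[v == 0L] <- -1L
    vecs[i, ] <- v
  }
  vecs
}
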