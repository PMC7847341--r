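#' Sign-sequencing matrix
#'
#' The alternating matrix of signs with entry \eqn{(-1)^{i+j}} (0-based), used
#' to sequence the labeling network's updates in checkerboard order: all
#' +1-parity cells are updated first, then all -1-parity cells. Adjacent
#' (4-neighborhood) entries always differ, so cells updated together are never
#' neighbors.
#'
#' @param rows,cols matrix dimensions (>= 1).
#' @return matrix with entries in \{+1, -1\}, entry (1,1) = +1.
#' @export
sign_matrix <- function(rows, cols) {
  stopifnot(rows >= 1L, cols >= 1L)
  outer(0:(rows - 1L), 0:(cols - 1L), function(i, j) 1 - 2 * ((i + j) %% 2))
}

#' Class count for a smooth quadric hypersurface
#'
#' Branch formula for the Euler characteristic of a smooth quadric in
#' projective (n+1)-space: n + 3 when n + 1 is odd, n + 2 when n + 1 is even.
#' It supplies the default number of intensity classes Q of the labeling
#' network (`n = 2` gives Q = 5).
#'
#' @param n hyperplane dimension parameter (>= 1); vectorized.
#' @return integer class count.
#' @export
class_count <- function(n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  as.integer(ifelse((n + 1) %% 2 == 1, n + 3, n + 2))
}

# Per-pixel image gradient (column = horizontal component, row = vertical),
# central differences with mirror boundary; Sobel available as an alternative.
image_gradient <- function(img, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  if (operator == "central") {
    xp <- pad_reflect(img, 1L, 1L, 1L, 1L)
    nr <- nrow(img); nc <- ncol(img)
    gx <- (xp[1L + seq_len(nr), 2L + seq_len(nc)] -
           xp[1L + seq_len(nr), seq_len(nc)]) / 2
    gy <- (xp[2L + seq_len(nr), 1L + seq_len(nc)] -
           xp[seq_len(nr), 1L + seq_len(nc)]) / 2
  } else {
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
    gx <- conv2_reflect(img, sx)
    gy <- conv2_reflect(img, t(sx))
  }
  list(gx = gx, gy = gy)
}

window_kernel <- function(window) {
  shape <- match.arg(window$shape, c("gaussian", "box"))
  size <- as.integer(window$size %||% 5L)
  if (size %% 2L == 0L) stop("window size must be odd", call. = FALSE)
  if (shape == "gaussian") {
    gauss_kernel(size, window$sigma %||% 1.0)
  } else {
    box_kernel(size)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local orientation by the structure tensor
#'
#' Estimates the per-pixel dominant orientation \eqn{\hat\chi} (the unit
#' eigenvector of the window-averaged structure tensor belonging to its
#' largest eigenvalue, i.e. the local gradient direction) and the windowed
#' directional gradient energy \eqn{\overline{|\nabla^T \hat\chi|^2}}. The
#' orientation sign is fixed by the convention that the first nonzero
#' component is >= 0; the directional energy is invariant to that choice.
#' A constant image yields \eqn{\hat\chi = (1, 0)} everywhere and zero energy.
#'
#' @param img numeric matrix in \[0, 1\], at least as large as the window.
#' @param window list with `shape` ("gaussian" or "box"), odd `size`, `sigma`.
#' @param operator gradient operator, `"central"` (default) or `"sobel"`.
#' @return object of class `orientation_field`: list with `chi_c`, `chi_r`
#'   (horizontal / vertical orientation components), `dir_energy` (windowed
#'   directional energy, >= 0), `window`, `operator`.
#' @export
structure_orientation <- function(img,
                                  window = list(shape = "gaussian", size = 5L,
                                                sigma = 1.0),
                                  operator = c("central", "sobel")) {
  assert_gray(img)
  operator <- match.arg(operator)
  size <- as.integer(window$size %||% 5L)
  if (min(dim(img)) < size) {
    stop("image must be at least as large as the window", call. = FALSE)
  }
  g <- image_gradient(img, operator)
  k <- window_kernel(window)
  jcc <- conv2_reflect(g$gx^2, k)
  jrr <- conv2_reflect(g$gy^2, k)
  jcr <- conv2_reflect(g$gx * g$gy, k)
  theta <- 0.5 * atan2(2 * jcr, jcc - jrr)
  cx <- cos(theta); cy <- sin(theta)
  flip <- (cx < 0) | (cx == 0 & cy < 0)
  cx[flip] <- -cx[flip]; cy[flip] <- -cy[flip]
  orient <- structure(list(chi_c = cx, chi_r = cy, dir_energy = NULL,
                           window = window, operator = operator),
                      class = "orientation_field")
  orient$dir_energy <- windowed_directional_energy(img, orient)
  orient
}

#' Directional gradient energy of a single gradient vector
#'
#' \eqn{|\nabla^T\hat\chi|^2 = |\nabla|^2 \cos^2 \angle(\nabla, \hat\chi)},
#' i.e. the squared projection of the gradient on the unit orientation.
#'
#' @param grad numeric 2-vector (horizontal, vertical gradient components).
#' @param chi_hat unit 2-vector; an error is raised if its norm deviates from
#'   1 by more than 1e-6.
#' @return nonnegative scalar; bounded by `sum(grad^2)` (Cauchy-Schwarz).
#' @export
directional_energy <- function(grad, chi_hat) {
  stopifnot(length(grad) == 2L, length(chi_hat) == 2L)
  if (abs(sqrt(sum(chi_hat^2)) - 1) > 1e-6) {
    stop("`chi_hat` must be a unit vector", call. = FALSE)
  }
  sum(grad * chi_hat)^2
}

#' Windowed directional gradient energy map
#'
#' Computes the pointwise directional energy \eqn{(\nabla \cdot \hat\chi)^2}
#' at every pixel and convolves it with the normalized orientation window
#' (whose size and shape set the neighborhood over which the energy is
#' pooled). A 1 x 1 box window returns the pointwise map exactly.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param orient an `orientation_field` computed on `img`.
#' @return nonnegative matrix of the same shape as `img`.
#' @export
windowed_directional_energy <- function(img, orient) {
  stopifnot(inherits(orient, "orientation_field"))
  g <- image_gradient(img, orient$operator)
  point <- (g$gx * orient$chi_c + g$gy * orient$chi_r)^2
  pmax(conv2_reflect(point, window_kernel(orient$window)), 0)
}

#' Spatially varying coupling field
#'
#' Modulates the global coupling `kappa0` by the local directional gradient
#' energy: \eqn{\kappa(i) = \kappa_0 / (1 + e_i / \bar e)} where \eqn{\bar e}
#' is the mean energy. Pixels on strong oriented edges receive weaker
#' neighborhood coupling, which preserves edges during labeling; a flat
#' energy map yields \eqn{\kappa \equiv \kappa_0}. \eqn{\kappa} is strictly
#' decreasing in the local energy and lies in \eqn{(0, \kappa_0]}.
#'
#' @param kappa0 global coupling (> 0).
#' @param dir_energy nonnegative matrix of windowed directional energies.
#' @return object of class `kappa_field`: list with `kappa0` and the
#'   per-pixel matrix `kappa`.
#' @export
kappa_field <- function(kappa0, dir_energy) {
  if (!(is.numeric(kappa0) && length(kappa0) == 1L && kappa0 > 0)) {
    stop("`kappa0` must be a positive scalar", call. = FALSE)
  }
  if (any(dir_energy < 0)) stop("`dir_energy` must be >= 0", call. = FALSE)
  m <- mean(dir_energy)
  kappa <- if (m <= 0) {
    matrix(kappa0, nrow(dir_energy), ncol(dir_energy))
  } else {
    kappa0 / (1 + dir_energy / m)
  }
  structure(list(kappa0 = kappa0, kappa = kappa), class = "kappa_field")
}
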