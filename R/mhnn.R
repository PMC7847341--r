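# Q-class pixel labeling by a geometrically regularized Hopfield-type
# network: a data term pulls each pixel toward one of Q prototype
# intensities, a kappa-weighted neighborhood term couples neighboring
# labels, and updates run in checkerboard (sign-sequenced) order.

neighbor_offsets <- function(neighborhood) {
  neighborhood <- as.character(neighborhood)
  switch(neighborhood,
    "4" = list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)),
    "8" = list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
               c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)),
    stop("`neighborhood` must be 4 or 8", call. = FALSE))
}

# Shift a matrix by (dr, dc); vacated cells get `fill`.
shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)   # destination rows
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Initialize class prototype intensities
#'
#' The `"quantile"` method (default, deterministic) places prototype `q` at
#' the mass midpoint of the q-th equal-mass intensity interval, i.e. the
#' (2q-1)/(2Q) quantile. The `"kmeans"` method runs seeded Lloyd iterations
#' and sorts the centers. If the patch has fewer distinct values than Q the
#' prototypes are padded with interval midpoints of \[0, 1\] and the result is
#' flagged `degenerate`. Prototypes are always strictly increasing (ties are
#' separated by a small epsilon).
#'
#' @param patch numeric matrix with values in \[0, 1\].
#' @param Q number of classes (>= 2).
#' @param method `"quantile"` or `"kmeans"`.
#' @param seed RNG seed for the kmeans initialization.
#' @return object of class `class_prototypes`: list with `Q`, sorted
#'   intensity vector `I`, and `degenerate` flag.
#' @export
init_prototypes <- function(patch, Q, method = c("quantile", "kmeans"),
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(Q >= 2L)
  v <- as.vector(patch)
  distinct <- sort(unique(v))
  degenerate <- length(distinct) < Q
  if (degenerate) {
    pads <- (2 * seq_len(Q) - 1) / (2 * Q)
    pads <- pads[vapply(pads, function(p) all(abs(p - distinct) > 1e-9), TRUE)]
    I <- sort(c(distinct, pads))[seq_len(Q)]
  } else if (method == "quantile") {
    I <- as.numeric(stats::quantile(v, probs = (2 * seq_len(Q) - 1) / (2 * Q),
                                    names = FALSE, type = 7))
  } else {
    set.seed(seed)
    I <- sort(as.numeric(stats::kmeans(v, centers = Q, nstart = 3)$centers))
  }
  eps <- 1e-6
  for (q in seq_len(Q)[-1]) {
    if (I[q] <= I[q - 1]) I[q] <- I[q - 1] + eps
  }
  structure(list(Q = as.integer(Q), I = I, degenerate = degenerate),
            class = "class_prototypes")
}

#' Build the labeling-network parameters for a patch
#'
#' Neighbor weights follow \eqn{\psi_{ij} = 2\kappa} for j in the pixel
#' neighborhood (zero otherwise, no self-connection); with the spatially
#' varying coupling field, the pairwise value \eqn{\bar\kappa(i,j) =
#' (\kappa_i + \kappa_j)/2} keeps the weights symmetric. Per-pixel,
#' per-class biases follow
#' \eqn{\wp_q(i) = \frac1Q \sum_r d_r(i) - 8\kappa_i (Q - d_q(i))} with
#' \eqn{d_q(i) = (\xi_i - I_q)^2} the squared distance to prototype q.
#'
#' @param patch numeric matrix in \[0, 1\].
#' @param prototypes a `class_prototypes`.
#' @param kappa a `kappa_field` defined on the patch (or a single number,
#'   taken as a uniform field).
#' @param neighborhood 4 (default) or 8.
#' @param smoothness_sign `"potts"` (default; neighbor agreement lowers the
#'   objective, producing smooth labelings) or `"paper"` (the
#'   agreement-penalizing convention with a positive neighborhood term).
#' @return object of class `mhnn_params`.
#' @export
build_network <- function(patch, prototypes, kappa, neighborhood = 4,
                          smoothness_sign = c("potts", "paper")) {
  assert_gray(patch, "patch")
  stopifnot(inherits(prototypes, "class_prototypes"))
  smoothness_sign <- match.arg(smoothness_sign)
  h <- nrow(patch); w <- ncol(patch)
  kap <- if (inherits(kappa, "kappa_field")) kappa$kappa else
    matrix(kappa, h, w)
  if (!all(dim(kap) == c(h, w))) {
    stop("`kappa` must be defined on the patch", call. = FALSE)
  }
  Q <- prototypes$Q
  D <- array(0, c(h, w, Q))
  for (q in seq_len(Q)) D[, , q] <- (patch - prototypes$I[q])^2
  biases <- array(0, c(h, w, Q))
  dbar <- apply(D, c(1, 2), mean)
  for (q in seq_len(Q)) biases[, , q] <- dbar - 8 * kap * (Q - D[, , q])
  structure(list(patch = patch, prototypes = prototypes, kappa = kap,
                 neighborhood = as.integer(as.character(neighborhood)),
                 offsets = neighbor_offsets(neighborhood),
                 sign = if (smoothness_sign == "potts") -1 else 1,
                 smoothness_sign = smoothness_sign,
                 D = D, biases = biases, Q = Q),
            class = "mhnn_params")
}

assert_labels <- function(labels, params) {
  if (!all(dim(labels) == dim(params$patch))) {
    stop("`labels` must match the patch dimensions", call. = FALSE)
  }
  if (!all(labels %in% seq_len(params$Q))) {
    stop("`labels` must be one-hot class assignments in 1..Q", call. = FALSE)
  }
  invisible(labels)
}

# Pairwise-mean kappa along one offset (matrix over destination pixels).
kbar_offset <- function(kap, off) {
  (kap + shift_mat(kap, off[1], off[2])) / 2
}

#' Labeling objective
#'
#' \eqn{\Pi = \sum_i \sum_q (\xi_i - I_q)^2 \delta_{iq} + s \sum_i
#' \sum_{j \in \mu_i} \bar\kappa(i,j)\, [q_i = q_j]} over ordered neighbor
#' pairs, where s = +1 for `smoothness_sign = "paper"` and s = -1 for
#' `"potts"`. With \eqn{\kappa = 0} the objective reduces to the per-pixel
#' quantization error, minimized by nearest-prototype assignment.
#'
#' @param labels integer matrix of class assignments (1..Q), one class per
#'   pixel (the one-hot state).
#' @param params an `mhnn_params`.
#' @return scalar objective value.
#' @export
mhnn_objective <- function(labels, params) {
  stopifnot(inherits(params, "mhnn_params"))
  assert_labels(labels, params)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels))
  data_term <- sum(params$D[idx])
  smooth <- 0
  for (off in params$offsets) {
    nb <- shift_mat(labels, off[1], off[2])
    agree <- !is.na(nb) & nb == labels
    kb <- kbar_offset(params$kappa, off)
    smooth <- smooth + sum(kb[agree])
  }
  data_term + params$sign * smooth
}

#' Unipolar step activation
#'
#' 1 when the net input is positive, 0 otherwise.
#'
#' @param phi net input (vectorized).
#' @return 0/1.
#' @export
step_activation_01 <- function(phi) {
  as.integer(phi > 0)
}

#' Network energy of a label state
#'
#' Hopfield-form energy \eqn{E = -\sum_i\sum_j \psi_{ij}\delta_i\delta_j -
#' \sum_i \wp_i \delta_i} evaluated per class channel on +/-1-recoded
#' indicators (0 recoded to -1), with \eqn{\psi_{ij} = 2\bar\kappa(i,j)} on
#' the neighborhood and the class-dependent biases of [build_network()].
#'
#' @param labels integer matrix of class assignments.
#' @param params an `mhnn_params`.
#' @return scalar energy.
#' @export
network_energy <- function(labels, params) {
  stopifnot(inherits(params, "mhnn_params"))
  assert_labels(labels, params)
  e <- 0
  for (q in seq_len(params$Q)) {
    d <- 2 * (labels == q) - 1
    for (off in params$offsets) {
      nb <- shift_mat(d, off[1], off[2])
      kb <- 2 * kbar_offset(params$kappa, off)
      valid <- !is.na(nb)
      e <- e - sum(kb[valid] * d[valid] * nb[valid])
    }
    e <- e - sum(params$biases[, , q] * d)
  }
  e
}

# Smoothness cost maps: for each class q, the kappa-weighted count of
# neighbors currently labeled q, at every pixel.
agreement_maps <- function(labels, params) {
  h <- nrow(labels); w <- ncol(labels)
  A <- array(0, c(h, w, params$Q))
  for (off in params$offsets) {
    nb <- shift_mat(labels, off[1], off[2])
    kb <- kbar_offset(params$kappa, off)
    valid <- !is.na(nb)
    for (q in seq_len(params$Q)) {
      m <- matrix(0, h, w)
      sel <- valid & nb == q
      m[sel] <- kb[sel]
      A[, , q] <- A[, , q] + m
    }
  }
  A
}

#' Run the sign-sequenced labeling network
#'
#' Initializes every pixel at its nearest prototype, then sweeps the patch in
#' checkerboard order (+1-parity cells of the sign matrix first, then
#' -1-parity cells), assigning each pixel the class that minimizes its local
#' objective given its neighbors' current labels. A label changes only when
#' it strictly lowers the objective, so the objective trace is non-increasing
#' and the dynamics terminate at a labeling that no single-pixel change can
#' improve. For the 4-neighborhood, cells of equal parity are uncoupled and
#' are updated as one vectorized block; the 8-neighborhood falls back to
#' strictly sequential updates within each parity.
#'
#' @param patch numeric matrix in \[0, 1\] (the patch `params` was built on).
#' @param params an `mhnn_params`.
#' @param max_sweeps maximum number of full sweeps (default 100).
#' @param seed unused by the deterministic schedule; kept for interface
#'   stability.
#' @return list with `labels` (integer matrix), `objective_trace` (value
#'   after initialization and after each sweep), `converged`, `sweeps`.
#' @export
run_sequenced <- function(patch, params, max_sweeps = 100L, seed = NULL) {
  stopifnot(inherits(params, "mhnn_params"), max_sweeps >= 1L)
  if (!isTRUE(all.equal(patch, params$patch))) {
    stop("`params` was not built on `patch`", call. = FALSE)
  }
  h <- nrow(patch); w <- ncol(patch); Q <- params$Q
  dmat <- matrix(params$D, h * w, Q)          # columns = classes
  labels <- matrix(max.col(-dmat, ties.method = "first"), h, w)
  parity <- sign_matrix(h, w)
  s <- params$sign
  trace <- mhnn_objective(labels, params)
  converged <- FALSE
  sweeps <- 0L
  tol <- 1e-12
  for (sw in seq_len(max_sweeps)) {
    changed <- FALSE
    for (par in c(1, -1)) {
      mask <- parity == par
      if (params$neighborhood == 4L) {
        A <- agreement_maps(labels, params)
        cost <- dmat + 2 * s * matrix(A, h * w, Q)
        cur <- cost[cbind(seq_len(h * w), as.vector(labels))]
        best <- max.col(-cost, ties.method = "first")
        bestval <- cost[cbind(seq_len(h * w), best)]
        take <- mask & matrix(bestval < cur - tol, h, w)
        if (any(take)) {
          labels[take] <- matrix(best, h, w)[take]
          changed <- TRUE
        }
      } else {
        for (i in which(mask)) {
          r <- (i - 1L) %% h + 1L
          cc <- (i - 1L) %/% h + 1L
          costs <- params$D[r, cc, ]
          for (off in params$offsets) {
            rr <- r + off[1]; ccn <- cc + off[2]
            if (rr < 1L || rr > h || ccn < 1L || ccn > w) next
            q <- labels[rr, ccn]
            costs[q] <- costs[q] +
              2 * s * (params$kappa[r, cc] + params$kappa[rr, ccn]) / 2
          }
          best <- which.min(costs)
          if (costs[best] < costs[labels[r, cc]] - tol) {
            labels[r, cc] <- best
            changed <- TRUE
          }
        }
      }
    }
    sweeps <- sw
    trace <- c(trace, mhnn_objective(labels, params))
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  list(labels = labels, objective_trace = trace, converged = converged,
       sweeps = sweeps)
}

#' Contrast remap of a converged labeling
#'
#' For each class q, the intensity interval its pixels occupy is linearly
#' stretched onto the q-th equal-width band \[(q-1)/Q, q/Q\]; a class
#' occupying a single value maps to the band center, and empty classes are
#' skipped. The result is blended with the input patch
#' (`alpha * stretched + (1 - alpha) * patch`) and clipped to \[0, 1\].
#'
#' @param patch numeric matrix in \[0, 1\].
#' @param labels converged class assignments on `patch`.
#' @param prototypes the `class_prototypes` used for labeling.
#' @param alpha blend weight in \[0, 1\]; 0 returns the input exactly.
#' @return numeric matrix in \[0, 1\].
#' @export
enhance_patch <- function(patch, labels, prototypes, alpha = 0.7) {
  assert_gray(patch, "patch")
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(patch)
  Q <- prototypes$Q
  stretched <- patch
  for (q in seq_len(Q)) {
    sel <- labels == q
    if (!any(sel)) next
    lo <- min(patch[sel]); hi <- max(patch[sel])
    lo_t <- (q - 1) / Q; hi_t <- q / Q
    stretched[sel] <- if (hi > lo) {
      lo_t + (patch[sel] - lo) / (hi - lo) * (hi_t - lo_t)
    } else {
      (lo_t + hi_t) / 2
    }
  }
  clip01(alpha * stretched + (1 - alpha) * patch)
}
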