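#' Enhancement pipeline configuration
#'
#' Collects and validates every tunable of the enhancement pipeline. Unknown
#' keys are rejected. `Q = NULL` derives the class count from
#' [class_count()]`(hyperplane_dim)` (the default `hyperplane_dim = 2` gives
#' Q = 5).
#'
#' @param patch_rows,patch_cols partition grid; the 22 x 20 default yields
#'   the 440-partition scheme.
#' @param neighborhood 4 (default) or 8.
#' @param kappa0 global neighborhood coupling (> 0); the default 0.01 is
#'   comparable to the squared quarter band-width (1/(2Q))^2 at the default
#'   Q = 5, balancing the data and smoothness terms.
#' @param hyperplane_dim dimension parameter feeding [class_count()].
#' @param Q explicit class count override (>= 2) or NULL.
#' @param alpha blend weight of the contrast remap in \[0, 1\]; default 0.7.
#' @param max_sweeps labeling sweep budget per patch.
#' @param seed RNG seed (kmeans prototypes; recorded in diagnostics).
#' @param smoothness_sign `"potts"` (default) or `"paper"`; see
#'   [build_network()].
#' @param recompute_orientation recompute the orientation and coupling fields
#'   from the prototype-rendered labeling between outer passes (default
#'   FALSE: one precomputation per patch).
#' @param proto_method prototype initialization, `"quantile"` or `"kmeans"`.
#' @param window_shape,window_size,window_sigma orientation window.
#' @return named list of class `mhnn_config`.
#' @export
mhnn_config <- function(patch_rows = 22L, patch_cols = 20L, neighborhood = 4L,
                        kappa0 = 0.01, hyperplane_dim = 2L, Q = NULL,
                        alpha = 0.7, max_sweeps = 100L, seed = 1L,
                        smoothness_sign = c("potts", "paper"),
                        recompute_orientation = FALSE,
                        proto_method = c("quantile", "kmeans"),
                        window_shape = c("gaussian", "box"),
                        window_size = 5L, window_sigma = 1.0) {
  smoothness_sign <- match.arg(smoothness_sign)
  proto_method <- match.arg(proto_method)
  window_shape <- match.arg(window_shape)
  stopifnot(patch_rows >= 1L, patch_cols >= 1L,
            neighborhood %in% c(4L, 8L),
            kappa0 > 0, hyperplane_dim >= 1L,
            alpha >= 0, alpha <= 1, max_sweeps >= 1L,
            window_size >= 1L, window_size %% 2L == 1L, window_sigma > 0)
  if (is.null(Q)) Q <- class_count(hyperplane_dim)
  stopifnot(Q >= 2L)
  structure(list(patch_rows = as.integer(patch_rows),
                 patch_cols = as.integer(patch_cols),
                 neighborhood = as.integer(neighborhood),
                 kappa0 = kappa0,
                 hyperplane_dim = as.integer(hyperplane_dim),
                 Q = as.integer(Q), alpha = alpha,
                 max_sweeps = as.integer(max_sweeps),
                 seed = as.integer(seed),
                 smoothness_sign = smoothness_sign,
                 recompute_orientation = isTRUE(recompute_orientation),
                 proto_method = proto_method,
                 window_shape = window_shape,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma),
            class = "mhnn_config")
}

#' Build a config from a named list, rejecting unknown keys
#' @param x named list (e.g. parsed from YAML).
#' @return validated `mhnn_config`.
#' @export
as_mhnn_config <- function(x) {
  if (inherits(x, "mhnn_config")) return(x)
  known <- names(formals(mhnn_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(mhnn_config, x)
}

# Odd window size that fits inside a patch.
fit_window_size <- function(size, dims) {
  s <- min(size, min(dims))
  if (s %% 2L == 0L) s <- s - 1L
  max(s, 1L)
}

label_one_patch <- function(x, protos, config) {
  if (length(unique(as.vector(x))) < 2L) {
    # flat patch: nearest-prototype label, no network needed
    dmat <- vapply(protos$I, function(I) (x[1] - I)^2, 1)
    return(list(labels = matrix(which.min(dmat), nrow(x), ncol(x)),
                diag = list(sweeps = 0L, pi_init = NA_real_,
                            pi_final = NA_real_, converged = TRUE,
                            degenerate = TRUE)))
  }
  window <- list(shape = config$window_shape,
                 size = fit_window_size(config$window_size, dim(x)),
                 sigma = config$window_sigma)
  run_pass <- function(img_for_geom) {
    orient <- structure_orientation(img_for_geom, window)
    kap <- kappa_field(config$kappa0, orient$dir_energy)
    params <- build_network(x, protos, kap, config$neighborhood,
                            config$smoothness_sign)
    list(params = params,
         res = run_sequenced(x, params, config$max_sweeps))
  }
  pass <- run_pass(x)
  if (config$recompute_orientation) {
    for (outer in 1:4) {
      rendered <- clip01(matrix(protos$I[pass$res$labels], nrow(x), ncol(x)))
      nxt <- run_pass(rendered)
      if (identical(nxt$res$labels, pass$res$labels)) {
        pass <- nxt
        break
      }
      pass <- nxt
    }
  }
  tr <- pass$res$objective_trace
  list(labels = pass$res$labels,
       diag = list(sweeps = pass$res$sweeps, pi_init = tr[1],
                   pi_final = tr[length(tr)],
                   converged = pass$res$converged, degenerate = FALSE))
}

#' Enhance a gray-scale image
#'
#' End-to-end pipeline. The image is mean/variance-normalized once and Q
#' prototype intensities are estimated globally, so the intensity remap is
#' spatially consistent; the geometry (orientation and coupling fields) and
#' the sign-sequenced labeling networks run per patch of the partition (the
#' default 22 x 20 grid gives the 440-partition scheme), which localizes the
#' optimization. The converged labels are reassembled and each class's
#' occupied global intensity interval is stretched onto its equal-width
#' band, the result is denormalized and blended with the original image in
#' the original intensity domain (`alpha` weight, so `alpha = 0` is
#' bit-exactly the identity). Deterministic for a given config.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param config an `mhnn_config` (or named list of its keys).
#' @return list with `image` (enhanced matrix, same dimensions as `img`) and
#'   `diagnostics` (one data-frame row per patch: `patch`, `sweeps`,
#'   `pi_init`, `pi_final`, `converged`, `degenerate`).
#' @export
enhance_image <- function(img, config = mhnn_config()) {
  assert_gray(img)
  config <- as_mhnn_config(config)
  nimg <- normalize_patch(img)
  x <- clip01(nimg$patch)
  if (nimg$norm$degenerate) {
    # constant image: nothing to enhance
    return(list(image = img,
                diagnostics = data.frame(patch = 1L, sweeps = 0L,
                                         pi_init = NA_real_,
                                         pi_final = NA_real_,
                                         converged = TRUE,
                                         degenerate = TRUE)))
  }
  protos <- init_prototypes(x, config$Q, method = config$proto_method,
                            seed = config$seed)
  grid <- partition_grid(x, config$patch_rows, config$patch_cols)
  n <- length(grid$patches)
  label_patches <- vector("list", n)
  diags <- vector("list", n)
  for (i in seq_len(n)) {
    r <- tryCatch(label_one_patch(get_patch(grid, i), protos, config),
                  error = function(e) {
                    stop(sprintf("patch %d (of %d): %s", i, n,
                                 conditionMessage(e)), call. = FALSE)
                  })
    label_patches[[i]] <- r$labels
    diags[[i]] <- c(list(patch = i), r$diag)
  }
  labels <- matrix(0L, nrow(grid$padded), ncol(grid$padded))
  for (i in seq_len(n)) {
    p <- grid$patches[[i]]
    labels[p$rows, p$cols] <- label_patches[[i]]
  }
  labels <- labels[seq_len(grid$height), seq_len(grid$width), drop = FALSE]
  enh <- enhance_patch(x, labels, protos, alpha = 1)
  out <- denormalize_patch(enh, nimg$norm)
  list(image = clip01(config$alpha * out + (1 - config$alpha) * img),
       diagnostics = do.call(rbind, lapply(diags, as.data.frame)))
}
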