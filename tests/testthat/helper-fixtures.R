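# Shared generators and brute-force oracles used across test files.

# Random symmetric zero-diagonal network with bipolar-friendly scaling.
rand_hopfield <- function(n, seed, bias_sd = 0) {
  set.seed(seed)
  w <- matrix(rnorm(n * n, sd = 1 / sqrt(n)), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  b <- if (bias_sd > 0) rnorm(n, sd = bias_sd) else rep(0, n)
  hopfield_net(w, b)
}

rand_bipolar <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(c(-1, 1), n, replace = TRUE)
}

# All 2^n bipolar states, one per row.
all_states <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(g) <- NULL
  g
}

# Brute-force GLCM by explicit pair loops (independent of the package path).
glcm_bruteforce <- function(q, offsets, levels, symmetric = TRUE) {
  h <- nrow(q); w <- ncol(q)
  tabs <- list()
  for (off in offsets) {
    tab <- matrix(0, levels, levels)
    for (r in seq_len(h)) {
      for (cc in seq_len(w)) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        a <- q[r, cc] + 1; b <- q[r2, c2] + 1
        tab[a, b] <- tab[a, b] + 1
        if (symmetric) tab[b, a] <- tab[b, a] + 1
      }
    }
    tabs[[length(tabs) + 1]] <- tab / sum(tab)
  }
  Reduce(`+`, tabs) / length(tabs)
}

# Nearest-prototype labeling (the kappa -> 0 reference).
nearest_proto_labels <- function(patch, protos) {
  d <- sapply(protos$I, function(I) (as.vector(patch) - I)^2)
  matrix(apply(d, 1, which.min), nrow(patch), ncol(patch))
}

tmp_png <- function(img) {
  f <- tempfile(fileext = ".png")
  write_gray(img, f)
  f
}
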