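test_that("prototype initialization places equal-mass midpoints and handles degeneracy", {
  set.seed(21)
  p <- matrix(runif(4000), 50, 80)   # near-uniform histogram
  pr <- init_prototypes(p, 2)
  expect_lt(max(abs(pr$I - c(0.25, 0.75))), 0.03)
  expect_false(pr$degenerate)

  const <- matrix(0.4, 4, 4)
  prc <- init_prototypes(const, 2)
  expect_true(prc$degenerate)
  expect_true(0.4 %in% prc$I)
  expect_length(prc$I, 2)

  for (Q in 2:5) {
    pq <- init_prototypes(matrix(rep(c(0.2, 0.5), 8), 4, 4), Q)
    expect_true(all(diff(pq$I) > 0))   # strictly increasing after padding
  }
  km <- init_prototypes(p, 3, method = "kmeans", seed = 2)
  expect_true(all(diff(km$I) > 0))
})

test_that("labeling objective evaluates data plus ordered-pair smoothness terms", {
  patch <- matrix(c(0.2, 0.8), 1, 2)
  pr <- init_prototypes(matrix(c(0.25, 0.75), 1, 2), 2)
  pr$I <- c(0.25, 0.75)
  pm <- build_network(patch, pr, 0.1, 4, smoothness_sign = "paper")
  expect_equal(mhnn_objective(matrix(c(1L, 2L), 1, 2), pm), 0.005)
  expect_equal(mhnn_objective(matrix(c(1L, 1L), 1, 2), pm), 0.505)

  # potts sign rewards agreement instead
  pm2 <- build_network(patch, pr, 0.1, 4, smoothness_sign = "potts")
  expect_equal(mhnn_objective(matrix(c(1L, 1L), 1, 2), pm2),
               0.0025 + 0.3025 - 0.2)

  # kappa = 0 reduces to quantization error, minimized by nearest prototype
  pm0 <- build_network(patch, pr, 0, 4)
  expect_equal(mhnn_objective(matrix(c(1L, 2L), 1, 2), pm0), 0.005)
  expect_error(mhnn_objective(matrix(c(1L, 3L), 1, 2), pm0), "1..Q")
})

test_that("network construction follows the 2-kappa weight and bias formulas", {
  pr <- init_prototypes(matrix(c(0.25, 0.75), 1, 2), 2)
  pr$I <- c(0.25, 0.75)
  pm <- build_network(matrix(0.5, 3, 3), pr, 0.1, 4)
  # uniform kappa: every neighbor pair weight 2*kappa (pairwise mean = kappa)
  off <- geohnn:::kbar_offset(pm$kappa, c(0, 1))
  expect_equal(2 * off[2, 2], 0.2)   # interior pair
  # bias: d1 = d2 = 0.0625 -> (1/Q) sum d - 8 kappa (Q - d_q) = -1.4875
  expect_equal(pm$biases[1, 1, 1], -1.4875)
  expect_equal(pm$biases[1, 1, 2], -1.4875)
  # kappa -> 0: bias tends to the mean quantization error for every class
  pm0 <- build_network(matrix(0.5, 3, 3), pr, 1e-15, 4)
  expect_equal(pm0$biases[1, 1, ], rep(0.0625, 2), tolerance = 1e-10)
})

test_that("unipolar step activation is 1 only for positive input", {
  expect_equal(step_activation_01(0.5), 1L)
  expect_equal(step_activation_01(0), 0L)
  expect_equal(step_activation_01(-3), 0L)
  expect_equal(step_activation_01(c(-1, 0, 2)), c(0L, 0L, 1L))
})

test_that("network energy decomposes over decoupled pixels and tracks descent", {
  pr <- init_prototypes(matrix(c(0.25, 0.75), 1, 2), 2)
  pr$I <- c(0.25, 0.75)
  # bias-free check: kappa-only coupling on an agreeing pair
  patch <- matrix(c(0.3, 0.3), 1, 2)
  pm <- build_network(patch, pr, 0.05, 4)
  pm$biases[] <- 0
  lab <- matrix(c(1L, 1L), 1, 2)
  # per class channel: both channels have |d|=1 products, psi = 2*kbar = 0.1
  expect_equal(network_energy(lab, pm), -2 * 2 * 0.1 * 1 * 1)

  set.seed(33)
  for (i in 1:20) {
    p <- matrix(runif(36), 6, 6)
    prq <- init_prototypes(p, 3)
    par <- build_network(p, prq, runif(1, 0.005, 0.05), 4)
    res <- run_sequenced(p, par)
    init <- nearest_proto_labels(p, prq)
    expect_lte(network_energy(res$labels, par),
               network_energy(init, par) + 1e-9)
  }
})

test_that("sequenced relaxation descends the objective to a single-flip optimum", {
  set.seed(17)
  # kappa = 0: one sweep, exact nearest-prototype labeling
  p <- matrix(runif(64), 8, 8)
  prot <- init_prototypes(p, 3)
  par0 <- build_network(p, prot, 0, 4)
  r0 <- run_sequenced(p, par0)
  expect_true(r0$converged)
  expect_identical(r0$labels, nearest_proto_labels(p, prot))

  # 2x2 patches, Q=2: converged labeling beats all 16 labelings reachable by
  # one-pixel changes (full enumeration oracle)
  for (i in 1:20) {
    p2 <- matrix(runif(4), 2, 2)
    pr2 <- init_prototypes(p2, 2)
    par2 <- build_network(p2, pr2, runif(1, 0.01, 0.3), 4)
    r2 <- run_sequenced(p2, par2)
    expect_true(all(diff(r2$objective_trace) <= 1e-12))
    pi_star <- mhnn_objective(r2$labels, par2)
    grid <- expand.grid(rep(list(1:2), 4))
    for (j in seq_len(nrow(grid))) {
      cand <- matrix(as.integer(unlist(grid[j, ])), 2, 2)
      if (sum(cand != r2$labels) == 1) {
        expect_gte(mhnn_objective(cand, par2), pi_star - 1e-9)
      }
    }
  }

  # a large potts coupling absorbs an isolated outlier into the majority class
  p3 <- matrix(0.2, 3, 3); p3[2, 2] <- 0.8
  pr3 <- init_prototypes(p3, 2)
  par3 <- build_network(p3, pr3, 0.5, 4, smoothness_sign = "potts")
  r3 <- run_sequenced(p3, par3)
  expect_true(all(r3$labels == r3$labels[1, 1]))

  # 8-neighborhood sequential path also descends
  par8 <- build_network(p, prot, 0.02, 8)
  r8 <- run_sequenced(p, par8)
  expect_true(all(diff(r8$objective_trace) <= 1e-12))
  expect_true(r8$converged)
})

test_that("patch enhancement stretches occupied class intervals onto bands", {
  pr <- init_prototypes(matrix(c(0.25, 0.75), 1, 2), 2)
  pr$I <- c(0.25, 0.75)
  patch <- matrix(c(0.4, 0.45, 0.55, 0.6), 1, 4)
  labels <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  out <- enhance_patch(patch, labels, pr, alpha = 1)
  expect_equal(as.vector(out), c(0, 0.5, 0.5, 1))

  expect_identical(enhance_patch(patch, labels, pr, alpha = 0), patch)

  set.seed(8)
  p <- matrix(runif(100), 10, 10)
  prq <- init_prototypes(p, 4)
  lab <- nearest_proto_labels(p, prq)
  for (a in c(0.3, 0.7, 1)) {
    e <- enhance_patch(p, lab, prq, a)
    expect_true(min(e) >= 0 && max(e) <= 1)
  }
})

test_that("image enhancement is deterministic, shape-preserving, identity at alpha 0", {
  set.seed(99)
  img <- matrix(runif(60 * 50), 60, 50)
  cfg <- mhnn_config(patch_rows = 6, patch_cols = 5)
  r1 <- enhance_image(img, cfg)
  r2 <- enhance_image(img, cfg)
  expect_identical(r1$image, r2$image)
  expect_equal(dim(r1$image), dim(img))
  expect_equal(nrow(r1$diagnostics), 30)
  expect_true(all(r1$diagnostics$converged))

  r0 <- enhance_image(img, mhnn_config(patch_rows = 6, patch_cols = 5,
                                       alpha = 0))
  expect_identical(r0$image, img)

  const <- matrix(0.5, 40, 40)
  rc <- enhance_image(const, mhnn_config(patch_rows = 4, patch_cols = 4))
  expect_identical(rc$image, const)
})

test_that("config validation rejects unknown keys and bad values", {
  expect_error(as_mhnn_config(list(kappa_zero = 1)), "unknown config key")
  expect_error(mhnn_config(alpha = 1.5))
  expect_error(mhnn_config(neighborhood = 6))
  expect_error(mhnn_config(window_size = 4))
  cfg <- as_mhnn_config(list(Q = 3, alpha = 0.5))
  expect_equal(cfg$Q, 3L)
  expect_equal(mhnn_config()$Q, 5L)   # class_count(2)
})
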