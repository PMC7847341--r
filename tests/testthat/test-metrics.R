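test_that("entropy hits its closed-form landmarks and permutation invariance", {
  expect_equal(img_entropy(matrix(0.5, 10, 10)), 0)
  uniform <- matrix((0:255) / 255, 16, 16)
  expect_identical(img_entropy(uniform), 8)
  two <- matrix(c(0, 1), 8, 8)
  expect_equal(img_entropy(two), 1)
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  perm <- matrix(sample(as.vector(img)), 10, 10)
  expect_equal(img_entropy(perm), img_entropy(img))
  expect_lte(img_entropy(img, levels = 64), log2(64))
})

test_that("GLCM counting matches the worked 2x2 examples", {
  img <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  g1 <- glcm(img, offsets = list(c(0L, 1L)), levels = 2)
  expect_equal(g1, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  g2 <- glcm(img, offsets = list(c(1L, 0L)), levels = 2)
  expect_equal(g2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  set.seed(3)
  big <- matrix(runif(400), 20, 20)
  g <- glcm(big, levels = 32)
  expect_equal(sum(g), 1)
  expect_warning(glcm(matrix(c(0, 1), 1, 2), offsets = list(c(5L, 0L),
                                                            c(0L, 1L)),
                      levels = 2), "skipped")
})

test_that("GLCM contrast and homogeneity agree with brute-force pair counting", {
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  # all two-level 2x2 images (16) and 3x3 images (512), exhaustive
  for (n in c(2L, 3L)) {
    combos <- as.matrix(expand.grid(rep(list(0:1), n * n)))
    for (i in seq_len(nrow(combos))) {
      q <- matrix(combos[i, ], n, n)
      g_pkg <- glcm(matrix(q, n, n), levels = 2)
      g_ref <- glcm_bruteforce(q, offs, 2)
      expect_equal(g_pkg, g_ref)
      d <- outer(0:1, 0:1, `-`)
      expect_equal(glcm_contrast(g_pkg), sum(g_ref * d^2))
      expect_equal(glcm_homogeneity(g_pkg), sum(g_ref / (1 + abs(d))))
    }
  }
})

test_that("contrast and homogeneity kernels hit their landmark values", {
  diag_tab <- diag(c(0.5, 0.3, 0.2))
  expect_equal(glcm_contrast(diag_tab), 0)
  expect_equal(glcm_homogeneity(diag_tab), 1)
  off_tab <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(glcm_contrast(off_tab), 1)
  expect_equal(glcm_homogeneity(off_tab), 0.5)
})

test_that("VIF scores identity at 1, constants at 0, and orders blur severity", {
  ph <- make_phantom(shapes = list(list(kind = "ellipse", center = c(110, 100),
                                        axes = c(50, 40), intensity = 0.8)),
                     texture_amp = 0.1, seed = 5)
  expect_equal(vif(ph, ph), 1, tolerance = 1e-6)
  expect_equal(vif(ph, matrix(0.5, nrow(ph), ncol(ph))), 0, tolerance = 1e-3)
  mild <- degrade_image(ph, blur_sigma = 0.8)
  strong <- degrade_image(ph, blur_sigma = 3)
  expect_gt(vif(ph, mild), vif(ph, strong))
  expect_error(vif(ph, ph[1:100, ]), "same dimensions")
  expect_error(vif(ph[1:20, 1:20], ph[1:20, 1:20]), "32")
})

test_that("WPSNR reduces to plain PSNR on flat references and caps at identity", {
  flat <- matrix(0.5, 64, 64)
  expect_equal(wpsnr(flat, flat), 100)
  e <- 10 / 255
  expect_equal(wpsnr(flat, flat + e), 10 * log10(255^2 / 10^2))
  # same error energy hurts less inside a high-variance region
  set.seed(6)
  ref <- matrix(0.5, 64, 64)
  ref[, 1:32] <- 0.2 + 0.6 * matrix(runif(64 * 32), 64, 32)  # textured half
  t_tex <- ref; t_tex[10:19, 10:19] <- ref[10:19, 10:19] + 0.1   # no clipping
  t_flat <- ref; t_flat[10:19, 45:54] <- ref[10:19, 45:54] + 0.1
  expect_equal(sum((ref - t_tex)^2), sum((ref - t_flat)^2))  # equal energy
  expect_gt(wpsnr(ref, t_tex), wpsnr(ref, t_flat))
})

test_that("pair evaluation and aggregation produce the five-metric report", {
  ph <- make_phantom(shapes = list(list(kind = "rectangle",
                                        center = c(110, 100),
                                        axes = c(40, 40), intensity = 0.9)),
                     texture_amp = 0.05, seed = 9)
  deg <- degrade_image(ph, blur_sigma = 1, contrast_scale = 0.6,
                       noise_sigma = 0.01, seed = 2)
  rep1 <- evaluate_pair(ph, ph)
  expect_equal(rep1$vif, 1, tolerance = 1e-6)
  expect_equal(rep1$wpsnr, 100)
  rep2 <- evaluate_pair(ph, deg)
  expect_true(all(is.finite(unlist(rep2))))

  agg1 <- aggregate_reports(rep2)
  expect_equal(unlist(agg1["mean", ]), unlist(rep2[1, ]),
               ignore_attr = TRUE)
  expect_true(all(agg1["sd", ] == 0))

  df <- data.frame(entropy = c(6, 8))
  expect_equal(aggregate_reports(df)["sd", "entropy"], 1)           # population
  expect_equal(aggregate_reports(df, "sample")["sd", "entropy"], sqrt(2))
  expect_equal(aggregate_reports(df)["mean", "entropy"], 7)
  expect_error(aggregate_reports(data.frame()), "nonempty")
})
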