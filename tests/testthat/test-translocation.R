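test_that("local contrast enhancement respects its range contract", {
  const <- matrix(100, 64, 64)
  out <- local_contrast_enhance(const)
  expect_true(all(out == out[1, 1]))
  expect_true(out[1, 1] >= 0 && out[1, 1] <= 1)

  set.seed(1)
  img <- matrix(runif(96 * 96, 0, 500), 96, 96)
  out <- local_contrast_enhance(img)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_error(local_contrast_enhance(matrix(c(1, NA, 3, 4), 2)),
               "non-finite")
})

test_that("enhancement preserves two-level ordering", {
  # checkerboard of two levels: every tile sees the same histogram, so the
  # tile mappings agree and ordering must survive globally
  img <- matrix(0.2, 64, 64)
  img[(row(img) + col(img)) %% 2 == 0] <- 0.8
  out <- local_contrast_enhance(img, tile = 16)
  expect_lt(max(out[img == 0.2]), min(out[img == 0.8]) + 1e-12)
})

test_that("gaussian smoothing matches the closed-form kernel", {
  const <- matrix(7, 32, 32)
  expect_equal(gaussian_smooth(const, 2), const, tolerance = 1e-12)

  # unit impulse reproduces the normalized separable kernel
  img <- matrix(0, 33, 33)
  img[17, 17] <- 1
  sigma <- 1.5
  out <- gaussian_smooth(img, sigma)
  rad <- ceiling(3 * sigma)
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  expected <- outer(k, k)
  got <- out[(17 - rad):(17 + rad), (17 - rad):(17 + rad)]
  expect_equal(got, expected, tolerance = 1e-12)

  set.seed(2)
  noisy <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  expect_lt(var(as.vector(gaussian_smooth(noisy, 2))),
            var(as.vector(noisy)))
})

test_that("isodata threshold finds the Ridler-Calvard fixed point", {
  x <- c(rep(0, 50), rep(100, 50))
  expect_equal(isodata_threshold(x), 50)
  expect_equal(isodata_threshold(c(0, 0, 0, 90, 100, 110)), 50)
  # affine equivariance: adding a constant shifts the threshold by it
  set.seed(3)
  img <- matrix(c(rnorm(200, 10, 2), rnorm(100, 60, 5)), 10)
  t0 <- isodata_threshold(img)
  expect_equal(isodata_threshold(img + 17), t0 + 17, tolerance = 1e-6)
  expect_error(isodata_threshold(matrix(5, 4, 4)), "constant")
})

test_that("conditional watershed labels and splits discs correctly", {
  empty <- conditional_watershed(matrix(FALSE, 32, 32))
  expect_true(all(empty == 0))

  one <- disc_mask(64, 64, cbind(32, 32), 10)
  expect_equal(max(conditional_watershed(one)), 1)

  two_far <- disc_mask(64, 64, rbind(c(20, 20), c(45, 45)), c(8, 8))
  expect_equal(max(conditional_watershed(two_far)), 2)

  # overlapping equal discs split along the perpendicular bisector
  two_touch <- disc_mask(64, 64, rbind(c(32, 24), c(32, 40)), c(10, 10))
  lab <- conditional_watershed(two_touch, min_area = 50, min_seed_sep = 5)
  expect_equal(max(lab), 2)
  cols <- col(lab)
  left_lab <- lab[32, 24]; right_lab <- lab[32, 40]
  expect_false(any(lab > 0 & cols < 31 & lab != left_lab))
  expect_false(any(lab > 0 & cols > 33 & lab != right_lab))

  # undersized components are discarded entirely
  lab2 <- conditional_watershed(two_touch, min_area = 1000)
  expect_equal(max(lab2), 0)
})

test_that("rejected splits keep a single label when the component is large enough", {
  two_touch <- disc_mask(64, 64, rbind(c(32, 26), c(32, 38)), c(10, 10))
  # fragments ~ 300 px each; min_area between fragment and component size
  lab <- conditional_watershed(two_touch, min_area = 350)
  expect_equal(max(lab), 1)
})

test_that("voronoi rings are annuli restricted to nearest-nucleus zones", {
  nuc <- matrix(0L, 48, 48)
  nuc[disc_mask(48, 48, cbind(24, 24), 8)] <- 1L
  w <- 5
  rings <- voronoi_rings(nuc, band_width = w)
  bv <- brute_voronoi(nuc)
  expected <- nuc == 0 & bv$dist <= w
  expect_identical(rings > 0, expected)
  expect_identical(attr(rings, "empty_rings"), integer(0))

  # two distant nuclei: rings disjoint, each inside its Voronoi zone
  nuc2 <- matrix(0L, 64, 64)
  nuc2[disc_mask(64, 64, cbind(20, 20), 7)] <- 1L
  nuc2[disc_mask(64, 64, cbind(45, 45), 7)] <- 2L
  r2 <- voronoi_rings(nuc2, band_width = w)
  bv2 <- brute_voronoi(nuc2)
  expect_true(all(r2[r2 > 0] == bv2$owner[r2 > 0]))
  expect_length(intersect(which(r2 == 1), which(r2 == 2)), 0)

  expect_error(voronoi_rings(nuc, band_width = 0), "band_width")
})

test_that("close rings never cross the equidistant line", {
  # two nuclei 2w apart: rings meet but every ring pixel stays nearest to
  # its own nucleus (pixel-exact, brute force)
  w <- 5
  nuc <- matrix(0L, 64, 64)
  nuc[disc_mask(64, 64, cbind(32, 22), 6)] <- 1L
  nuc[disc_mask(64, 64, cbind(32, 22 + 2 * w + 12), 6)] <- 2L
  rings <- voronoi_rings(nuc, band_width = w)
  bv <- brute_voronoi(nuc)
  px <- which(rings > 0)
  expect_true(all(rings[px] == bv$owner[px]))
  expect_true(all(bv$dist[px] <= w))
  expect_true(all(nuc[px] == 0))
})

test_that("measurement returns exact ratios on constructed images", {
  nuc <- matrix(0L, 48, 48)
  nuc[disc_mask(48, 48, cbind(24, 24), 8)] <- 1L
  rings <- voronoi_rings(nuc, band_width = 4)

  uniform <- matrix(50, 48, 48)
  rec <- measure_cells(uniform, nuc, rings)
  expect_equal(rec$nc_ratio, 1)

  v <- 120
  gr <- matrix(0, 48, 48)
  gr[nuc == 1] <- 2 * v
  gr[rings == 1] <- v
  rec2 <- measure_cells(gr, nuc, rings)
  expect_equal(rec2$nc_ratio, 2)

  # empty input is valid
  rec3 <- measure_cells(uniform, matrix(0L, 48, 48), matrix(0L, 48, 48))
  expect_equal(nrow(rec3), 0)
})

test_that("N/C ratio is invariant under scaling the GR channel", {
  cfg <- sim_config(seed = 9, n_cells = 6, noise_cv = 0.05,
                    touching_frac = 0, image_shape = c(128L, 128L))
  sim <- gen_translocation_image(cfg)
  q1 <- quantify_translocation(sim$nuclear, sim$gr)
  q2 <- quantify_translocation(sim$nuclear, sim$gr * 3.7)
  expect_equal(q1$records$nc_ratio, q2$records$nc_ratio, tolerance = 1e-12)
})

test_that("pipeline recovers the true ratio on a synthetic image", {
  cfg <- sim_config(seed = 7, n_cells = 20, nc_ratio_true = 3,
                    noise_cv = 0.05, touching_frac = 0)
  sim <- gen_translocation_image(cfg)
  q <- quantify_translocation(sim$nuclear, sim$gr)
  expect_gte(nrow(q$records), 15)
  expect_lt(abs(median(q$records$nc_ratio) - 3) / 3, 0.10)
})

test_that("median estimated ratio increases with the true ratio", {
  meds <- vapply(c(1, 2, 4), function(r) {
    cfg <- sim_config(seed = 21, n_cells = 10, nc_ratio_true = r,
                      noise_cv = 0.05, touching_frac = 0,
                      image_shape = c(192L, 192L))
    sim <- gen_translocation_image(cfg)
    median(quantify_translocation(sim$nuclear, sim$gr)$records$nc_ratio)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("treatment summaries and Welch tests behave", {
  rec <- data.frame(treatment = rep("a", 5), nc_ratio = rep(2, 5))
  s <- summarize_translocation(rec, control = "a")
  expect_equal(s$sd_ratio, 0)

  rec2 <- data.frame(treatment = rep(c("ctl", "trt"), each = 3),
                     nc_ratio = rep(c(1, 2, 3), 2))
  s2 <- summarize_translocation(rec2, control = "ctl")
  expect_equal(s2$p_value[s2$treatment == "trt"], 1)
  expect_equal(s2$t[s2$treatment == "trt"], 0)

  set.seed(4)
  rec3 <- data.frame(
    treatment = rep(c("ctl", "trt"), each = 50),
    nc_ratio = c(rnorm(50, 1, 0.1), rnorm(50, 2, 0.1))
  )
  s3 <- summarize_translocation(rec3, control = "ctl")
  expect_lt(s3$p_value[s3$treatment == "trt"], 0.01)
  expect_lt(s3$mean_ratio[s3$treatment == "ctl"],
            s3$mean_ratio[s3$treatment == "trt"])
})
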