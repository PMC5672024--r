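test_that("spot quantification subtracts and floors", {
  expect_equal(as.numeric(spot_quantify(500, 0)), 500)
  floored <- spot_quantify(100, 100)
  expect_equal(as.numeric(floored), 1)
  expect_equal(attr(floored, "n_floored"), 1L)

  tab <- gen_peptide_array(5, list(a = 1), base_intensity = 1000,
                           background = 100, n_replicates = 3,
                           noise_cv = 0.05, seed = 2)
  net <- spot_quantify(tab$spot_intensity, tab$local_background)
  expect_lt(abs(mean(net) - 1000) / 1000, 0.05)
})

test_that("modulation index is a log10 fold change and antisymmetric", {
  expect_equal(as.numeric(modulation_index(c(5, 5), c(5, 5))), 0)
  expect_equal(as.numeric(modulation_index(c(100, 100), c(10, 10))), 1)
  expect_equal(as.numeric(modulation_index(c(10, 10), c(100, 100))), -1)
  a <- c(40, 60); b <- c(9, 11)
  expect_equal(as.numeric(modulation_index(a, b)),
               -as.numeric(modulation_index(b, a)))
  # all-floored cells are flagged unreliable
  m <- modulation_index(c(1, 1), c(500, 500), floor_eps = 1)
  expect_true(attr(m, "unreliable"))
})

test_that("peptide t-test matches the pooled-variance hand computation", {
  r <- peptide_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$p, 2 * stats::pt(-sqrt(1.5), df = 4), tolerance = 1e-6)

  same <- peptide_ttest(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_warning(r0 <- peptide_ttest(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(r0$p, 0)
  expect_error(peptide_ttest(1, c(1, 2)), "replicates")
})

test_that("null p-values are uniform", {
  set.seed(10)
  ps <- vapply(1:4000, function(i) {
    peptide_ttest(rnorm(5, 100, 10), rnorm(5, 100, 10))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ward clustering handles the degenerate small cases", {
  two <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  hc <- ward_cluster(two)
  expect_equal(nrow(hc$merge), 1)
  expect_equal(hc$height, 5) # Euclidean distance of the only merge

  dup <- rbind(c(1, 2), c(5, 5), c(1, 2))
  hcd <- ward_cluster(dup)
  expect_equal(hcd$height[1], 0)
  expect_equal(sort(hclust_merge_sets(hcd)[[1]]), c(1, 3))

  expect_error(ward_cluster(rbind(c(1, NA), c(2, 3))), "NaN/NA")
})

test_that("ward clustering agrees with stats::hclust ward.D2", {
  set.seed(11)
  for (i in 1:30) {
    x <- matrix(rnorm(6 * 3), 6)
    mine <- ward_cluster(x)
    ref <- stats::hclust(stats::dist(x), method = "ward.D2")
    expect_equal(mine$height, ref$height)
    expect_identical(mine$merge, ref$merge)
  }
})

test_that("ward merge heights are non-decreasing", {
  set.seed(12)
  for (i in 1:20) {
    x <- matrix(rnorm(8 * 4), 8)
    hc <- ward_cluster(x)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("two compound groups with distinct effects are recovered by the 2-cut", {
  n_pep <- 8
  hits <- 0L
  for (s in 1:25) {
    eff_a <- rep(c(5, 1), length.out = n_pep)
    eff_b <- rep(c(1, 5), length.out = n_pep)
    tab <- gen_peptide_array(
      n_pep,
      list(a1 = eff_a, a2 = eff_a, b1 = eff_b, b2 = eff_b),
      base_intensity = 1000, background = 100, n_replicates = 3,
      noise_cv = 0.05, seed = s
    )
    prof <- mi_profile(tab)
    mi <- prof$mi[, c("a1", "a2", "b1", "b2")]
    hc <- ward_cluster(t(mi))
    grp <- stats::cutree(hc, k = 2)
    ok <- (grp["a1"] == grp["a2"]) && (grp["b1"] == grp["b2"]) &&
      (grp["a1"] != grp["b1"])
    hits <- hits + ok
  }
  expect_equal(hits, 25L)
})

test_that("compounds with identical effect vectors merge first", {
  tab <- gen_peptide_array(
    6, list(x = c(4, 1, 4, 1, 4, 1), y = c(4, 1, 4, 1, 4, 1),
            z = c(1, 1, 1, 1, 1, 1)),
    base_intensity = 1000, background = 0, n_replicates = 3,
    noise_cv = 0, seed = 1
  )
  prof <- suppressWarnings(mi_profile(tab))
  hc <- ward_cluster(t(prof$mi[, c("x", "y", "z")]))
  first <- hclust_merge_sets(hc)[[1]]
  expect_equal(first, c(1, 2)) # x and y
  expect_equal(hc$height[1], 0)
  # identical compounds end adjacent in the leaf order
  ord <- hc$order
  expect_equal(abs(which(ord == 1) - which(ord == 2)), 1)
})

test_that("mi_profile returns a zero solvent column and matching p matrix", {
  tab <- gen_peptide_array(5, list(cmp = 3), base_intensity = 1000,
                           background = 100, n_replicates = 3,
                           noise_cv = 0.05, seed = 4)
  prof <- mi_profile(tab)
  expect_true(all(prof$mi[, "DMSO"] == 0))
  expect_true(all(prof$p[, "DMSO"] == 1))
  expect_true(all(prof$mi[, "cmp"] > 0)) # 3-fold enhancement
  expect_true(all(prof$p[, "cmp"] < 0.05))
})

test_that("heatmap ordering permutes to leaf order and round-trips via CSV", {
  set.seed(13)
  mi <- matrix(rnorm(5 * 4), 5, 4,
               dimnames = list(paste0("p", 1:5), paste0("c", 1:4)))
  rc <- ward_cluster(mi)
  cc <- ward_cluster(t(mi))
  ord <- profile_heatmap(mi, rc, cc)
  expect_identical(ord, mi[rc$order, cc$order])
  # already-ordered input keeps the identity ordering
  rc2 <- ward_cluster(ord)
  ord2 <- profile_heatmap(ord, NULL, NULL)
  expect_identical(ord2, ord)

  csv <- tempfile(fileext = ".csv")
  profile_heatmap(mi, rc, cc, csv = csv)
  back <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(unname(back), unname(ord), tolerance = 1e-12)
  expect_identical(rownames(back), rownames(ord))
})
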