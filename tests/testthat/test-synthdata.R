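test_that("image generator handles the empty and noiseless identity cases", {
  cfg <- sim_config(seed = 1, n_cells = 0, noise_cv = 0)
  sim <- gen_translocation_image(cfg)
  expect_equal(length(sim$truth), 0)
  expect_equal(nrow(sim$truth_summary), 0)
  expect_true(all(sim$nuclear == cfg$background_level))
  expect_true(all(sim$gr == cfg$gr_background))

  cfg1 <- sim_config(seed = 2, n_cells = 8, nc_ratio_true = 1, noise_cv = 0,
                     touching_frac = 0)
  sim1 <- gen_translocation_image(cfg1)
  for (t in sim1$truth) {
    expect_identical(mean(sim1$gr[t$nucleus_idx]), mean(sim1$gr[t$cyto_idx]))
  }
})

test_that("truth-mask averaging recovers the requested N/C ratio", {
  cfg <- sim_config(seed = 7, n_cells = 20, nc_ratio_true = 3,
                    noise_cv = 0.05)
  sim <- gen_translocation_image(cfg)
  r <- vapply(sim$truth, function(t) {
    mean(sim$gr[t$nucleus_idx]) / mean(sim$gr[t$cyto_idx])
  }, numeric(1))
  expect_lt(abs(mean(r) - 3) / 3, 0.05)
})

test_that("generator output is deterministic per seed and non-negative", {
  cfg <- sim_config(seed = 11, n_cells = 10, noise_cv = 0.1)
  a <- gen_translocation_image(cfg)
  b <- gen_translocation_image(cfg)
  expect_identical(a$nuclear, b$nuclear)
  expect_identical(a$gr, b$gr)
  expect_identical(a$truth_summary, b$truth_summary)
  expect_gte(min(a$nuclear), 0)
  expect_gte(min(a$gr), 0)
})

test_that("per-cell truth masks are disjoint", {
  cfg <- sim_config(seed = 5, n_cells = 12, touching_frac = 0.5)
  sim <- gen_translocation_image(cfg)
  all_px <- unlist(lapply(sim$truth, function(t) c(t$nucleus_idx, t$cyto_idx)))
  expect_equal(anyDuplicated(all_px), 0)
  for (t in sim$truth) {
    expect_length(intersect(t$nucleus_idx, t$cyto_idx), 0)
  }
})

test_that("placement failure is signalled when cells cannot fit", {
  cfg <- sim_config(seed = 1, n_cells = 100, image_shape = c(64, 64),
                    nucleus_radius_range = c(8, 10), touching_frac = 0)
  expect_error(gen_translocation_image(cfg, max_tries = 50),
               "placement failed")
})

test_that("reporter wells reproduce group means exactly at zero noise", {
  g <- data.frame(label = c("solvent", "TNF"), mean_rlu = c(100, 10100),
                  n_replicates = c(3, 3))
  w <- gen_reporter_wells(g, noise_cv = 0, seed = 1)
  expect_equal(w$readout, rep(c(100, 10100), each = 3))
  ifr <- induction_factor(w[w$treatment == "TNF", ],
                          w[w$treatment == "solvent", ])
  expect_equal(ifr$induction_factor, 101)
  expect_error(
    gen_reporter_wells(data.frame(label = "x", mean_rlu = 0,
                                  n_replicates = 3), 0.1, 1),
    "positive"
  )
})

test_that("reporter noise realizes the requested coefficient of variation", {
  g <- data.frame(label = "a", mean_rlu = 100, n_replicates = 10000)
  w <- gen_reporter_wells(g, noise_cv = 0.05, seed = 42)
  cv <- sd(w$readout) / mean(w$readout)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("binding curve follows the four-parameter logistic", {
  conc <- 10^seq(-1, 3, length.out = 9)
  cur <- gen_binding_curve(ic50 = 10, hill = 1, top = 100, bottom = 0,
                           concentrations = conc, noise_cv = 0, seed = 1)
  # midpoint at c = ic50
  mid <- gen_binding_curve(10, 1, 100, 0, 10, 0, 1)
  expect_equal(mid$response, 50)
  # c -> 0 approaches top
  low <- gen_binding_curve(10, 1, 100, 0, 1e-9, 0, 1)
  expect_lt(abs(low$response - 100), 1e-6)
  # strictly decreasing on a grid for hill > 0
  expect_true(all(diff(cur$response) < 0))
  expect_error(gen_binding_curve(10, 1, 100, 0, numeric(0), 0, 1), "empty")
})

test_that("peptide array encodes fold changes over solvent", {
  tab <- gen_peptide_array(4, list(cmpA = 1), base_intensity = 1000,
                           background = 100, n_replicates = 3,
                           noise_cv = 0, seed = 1)
  prof <- mi_profile(tab, solvent = "DMSO")
  expect_true(all(prof$mi == 0))

  tab10 <- gen_peptide_array(4, list(cmpA = 10), base_intensity = 1000,
                             background = 0, n_replicates = 3,
                             noise_cv = 0, seed = 1)
  prof10 <- suppressWarnings(mi_profile(tab10, solvent = "DMSO"))
  expect_equal(unname(prof10$mi[, "cmpA"]), rep(1, 4))

  expect_warning(
    gen_peptide_array(2, list(a = 2), n_replicates = 1, noise_cv = 0,
                      seed = 1),
    "t-test"
  )
  expect_error(gen_peptide_array(2, list(a = -1), seed = 1), "positive")
})

test_that("synthetic proteins place K/R/C exactly where requested", {
  s <- gen_protein(7, cys_positions = 2, kr_positions = c(3, 4, 7),
                   seed = 1, kr_residues = c("K", "R", "K"))
  res <- strsplit(s, "")[[1]]
  expect_equal(res[2], "C")
  expect_equal(res[3], "K")
  expect_equal(res[4], "R")
  expect_equal(res[7], "K")
  expect_false(any(res[c(1, 5, 6)] %in% c("K", "R", "C")))

  # no K/R anywhere: digestion yields a single peptide
  s2 <- gen_protein(30, cys_positions = c(5, 10), seed = 2)
  expect_equal(nrow(digest(s2)), 1)

  expect_error(gen_protein(10, cys_positions = 3, kr_positions = 3),
               "conflicting")
})
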