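#' Simulation configuration for two-channel translocation images
#'
#' Bundles and validates the parameters of the synthetic fluorescence image
#' generator. Cells are drawn as disc nuclei with a concentric annular
#' cytoplasm, the simplest geometry for which the nuclear-to-cytoplasm (N/C)
#' intensity ratio has an exact analytic ground truth.
#'
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param n_cells number of cells to place (>= 0).
#' @param image_shape integer (rows, cols) of the image grid.
#' @param nucleus_radius_range (min, max) nuclear radius in pixels; each
#'   nucleus draws its radius uniformly from this range.
#' @param cyto_extent width of the cytoplasmic annulus in pixels.
#' @param background_level nuclear-channel background intensity (AU).
#' @param noise_cv coefficient of variation of the additive Gaussian pixel
#'   noise (sd = `noise_cv` x noiseless local mean); 0 disables noise.
#' @param nc_ratio_true true N/C ratio of the GR channel (dimensionless, > 0).
#' @param touching_frac fraction of cells placed as touching (overlapping)
#'   pairs, to exercise watershed splitting; 0 places all cells apart.
#' @param nuclear_level nuclear-channel intensity inside nuclei (AU).
#' @param gr_cyto_level GR-channel intensity in the cytoplasmic annulus (AU);
#'   the nuclear GR intensity is `nc_ratio_true * gr_cyto_level`.
#' @param gr_background GR-channel intensity outside cells (AU).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 20L,
                       image_shape = c(256L, 256L),
                       nucleus_radius_range = c(8, 12),
                       cyto_extent = 5,
                       background_level = 100,
                       noise_cv = 0.05,
                       nc_ratio_true = 3,
                       touching_frac = 0.2,
                       nuclear_level = 1000,
                       gr_cyto_level = 200,
                       gr_background = 20) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    length(n_cells) == 1L, n_cells >= 0,
    length(image_shape) == 2L, all(image_shape >= 16),
    length(nucleus_radius_range) == 2L,
    nucleus_radius_range[1] <= nucleus_radius_range[2],
    nucleus_radius_range[1] >= 1,
    cyto_extent >= 1,
    noise_cv >= 0,
    nc_ratio_true > 0,
    touching_frac >= 0, touching_frac <= 1,
    background_level >= 0, nuclear_level > 0,
    gr_cyto_level > 0, gr_background >= 0
  )
  # a cell (nucleus + annulus) must fit inside the image
  if (2 * (nucleus_radius_range[2] + cyto_extent) + 2 >= min(image_shape)) {
    stop("cell extent does not fit inside image_shape")
  }
  structure(
    list(
      seed = as.integer(seed), n_cells = as.integer(n_cells),
      image_shape = as.integer(image_shape),
      nucleus_radius_range = as.numeric(nucleus_radius_range),
      cyto_extent = as.numeric(cyto_extent),
      background_level = as.numeric(background_level),
      noise_cv = as.numeric(noise_cv),
      nc_ratio_true = as.numeric(nc_ratio_true),
      touching_frac = as.numeric(touching_frac),
      nuclear_level = as.numeric(nuclear_level),
      gr_cyto_level = as.numeric(gr_cyto_level),
      gr_background = as.numeric(gr_background)
    ),
    class = "sim_config"
  )
}

# lognormal draws with a given mean and coefficient of variation;
# cv = 0 degenerates to the mean exactly
rlnorm_cv <- function(n, mean, cv) {
  stopifnot(all(mean > 0), cv >= 0)
  if (cv == 0) return(rep_len(mean, n) * rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

# linear indices of a disc at (r0, c0) with radius rad, clipped to the grid
.disc_idx <- function(shape, r0, c0, rad) {
  rr <- max(1L, floor(r0 - rad)):min(shape[1], ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(shape[2], ceiling(c0 + rad))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= rad^2
  g <- g[keep, , drop = FALSE]
  (g$col - 1L) * shape[1] + g$row
}

#' Generate a synthetic two-channel GR translocation image
#'
#' Places disc nuclei (optionally including touching pairs) on a dark
#' background, paints a bright nuclear-stain channel and a GR channel whose
#' mean intensity inside each nucleus is, before noise, exactly
#' `nc_ratio_true` times its mean over the concentric cytoplasmic annulus.
#' Pixel noise is additive Gaussian with sd proportional to the local
#' noiseless mean; intensities are clamped at zero.
#'
#' @param config a [sim_config()].
#' @param max_tries placement retry budget per cell before failing.
#'
#' @return a list with elements
#'   * `nuclear`, `gr`: numeric intensity matrices (row, col),
#'   * `truth`: per-cell list of `cell_id`, `nucleus_idx`, `cyto_idx`
#'     (linear pixel indices), `true_nc_ratio`, `center`, `radius`,
#'   * `truth_summary`: data.frame with one row per cell.
#' @export
gen_translocation_image <- function(config, max_tries = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$image_shape
  withr::with_seed(config$seed, {
    n <- config$n_cells
    nuclear <- matrix(config$background_level, shape[1], shape[2])
    gr <- matrix(config$gr_background, shape[1], shape[2])
    truth <- list()
    if (n > 0) {
      margin <- config$nucleus_radius_range[2] + config$cyto_extent + 1
      n_pairs <- floor(n * config$touching_frac / 2)
      centers <- matrix(numeric(0), ncol = 2)
      radii <- numeric(0)

      place_one <- function(rad, partner = NULL) {
        for (i in seq_len(max_tries)) {
          if (is.null(partner)) {
            cand <- c(
              stats::runif(1, margin + 1, shape[1] - margin),
              stats::runif(1, margin + 1, shape[2] - margin)
            )
          } else {
            # overlapping neighbour: centers closer than the radius sum
            ang <- stats::runif(1, 0, 2 * pi)
            dist <- 0.8 * (rad + partner$rad)
            cand <- partner$center + dist * c(cos(ang), sin(ang))
            if (any(cand < margin + 1) || cand[1] > shape[1] - margin ||
                cand[2] > shape[2] - margin) next
          }
          ok <- TRUE
          if (nrow(centers) > 0) {
            d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
            # keep annuli of unrelated cells disjoint
            sep <- radii + rad + 2 * config$cyto_extent + 2
            if (!is.null(partner)) {
              # the partner is allowed (and required) to be close
              pid <- partner$index
              if (any(d[-pid] < sep[-pid])) ok <- FALSE
            } else if (any(d < sep)) ok <- FALSE
          }
          if (ok) return(cand)
        }
        stop("cell placement failed within the retry budget")
      }

      draw_radius <- function() {
        stats::runif(1, config$nucleus_radius_range[1],
                     config$nucleus_radius_range[2])
      }

      k <- 0L
      while (k < n) {
        rad <- draw_radius()
        if (k + 1 < n && (k / 2) < n_pairs) {
          # place a touching pair
          c1 <- place_one(rad)
          centers <- rbind(centers, c1); radii <- c(radii, rad)
          rad2 <- draw_radius()
          c2 <- place_one(rad2, partner = list(
            center = c1, rad = rad, index = nrow(centers)
          ))
          centers <- rbind(centers, c2); radii <- c(radii, rad2)
          k <- k + 2L
        } else {
          c1 <- place_one(rad)
          centers <- rbind(centers, c1); radii <- c(radii, rad)
          k <- k + 1L
        }
      }

      # rasterize; where nuclei of a touching pair overlap, the earlier cell
      # keeps the pixel so masks stay disjoint
      taken <- integer(length(nuclear)) # 0 = free, else owning cell
      for (i in seq_len(n)) {
        nuc <- .disc_idx(shape, centers[i, 1], centers[i, 2], radii[i])
        nuc <- nuc[taken[nuc] == 0L]
        taken[nuc] <- i
        truth[[i]] <- list(cell_id = i, nucleus_idx = nuc,
                           center = centers[i, ], radius = radii[i])
      }
      for (i in seq_len(n)) {
        out <- .disc_idx(shape, centers[i, 1], centers[i, 2],
                         radii[i] + config$cyto_extent)
        cyt <- setdiff(out, truth[[i]]$nucleus_idx)
        cyt <- cyt[taken[cyt] == 0L]
        taken[cyt] <- -i
        truth[[i]]$cyto_idx <- cyt
        truth[[i]]$true_nc_ratio <- config$nc_ratio_true
      }
      for (i in seq_len(n)) {
        nuclear[truth[[i]]$nucleus_idx] <- config$nuclear_level
        gr[truth[[i]]$cyto_idx] <- config$gr_cyto_level
        gr[truth[[i]]$nucleus_idx] <-
          config$nc_ratio_true * config$gr_cyto_level
      }
    }
    if (config$noise_cv > 0) {
      nuclear <- pmax(0, nuclear + stats::rnorm(length(nuclear),
                                                sd = config$noise_cv * nuclear))
      gr <- pmax(0, gr + stats::rnorm(length(gr),
                                      sd = config$noise_cv * gr))
      dim(nuclear) <- shape
      dim(gr) <- shape
    }
    truth_summary <- if (length(truth)) {
      data.frame(
        cell_id = vapply(truth, `[[`, integer(1), "cell_id"),
        center_row = vapply(truth, function(t) t$center[1], numeric(1)),
        center_col = vapply(truth, function(t) t$center[2], numeric(1)),
        radius = vapply(truth, `[[`, numeric(1), "radius"),
        n_nucleus_px = vapply(truth, function(t) length(t$nucleus_idx),
                              integer(1)),
        n_cyto_px = vapply(truth, function(t) length(t$cyto_idx), integer(1)),
        true_nc_ratio = vapply(truth, `[[`, numeric(1), "true_nc_ratio")
      )
    } else {
      data.frame(cell_id = integer(0), center_row = numeric(0),
                 center_col = numeric(0), radius = numeric(0),
                 n_nucleus_px = integer(0), n_cyto_px = integer(0),
                 true_nc_ratio = numeric(0))
    }
    list(nuclear = nuclear, gr = gr, truth = truth,
         truth_summary = truth_summary, config = config)
  })
}

#' Simulate reporter-assay luminescence wells
#'
#' Draws replicate relative-light-unit readouts per treatment group with
#' multiplicative lognormal noise of a given coefficient of variation,
#' emulating triplicate luciferase reporter wells.
#'
#' @param groups data.frame with columns `label`, `mean_rlu` (> 0) and
#'   `n_replicates` (>= 1); optionally `concentration`.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed integer seed.
#'
#' @return a well table: data.frame with columns `treatment`,
#'   `concentration`, `replicate`, `readout`.
#' @export
gen_reporter_wells <- function(groups, noise_cv, seed) {
  stopifnot(is.data.frame(groups),
            all(c("label", "mean_rlu", "n_replicates") %in% names(groups)))
  if (any(groups$mean_rlu <= 0)) stop("group means must be positive")
  if (any(groups$n_replicates < 1)) stop("n_replicates must be >= 1")
  conc <- if ("concentration" %in% names(groups)) groups$concentration else NA
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(groups)), function(i) {
      n <- groups$n_replicates[i]
      data.frame(
        treatment = groups$label[i],
        concentration = if (length(conc) > 1) conc[i] else conc,
        replicate = seq_len(n),
        readout = rlnorm_cv(n, groups$mean_rlu[i], noise_cv)
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate a competition-binding displacement curve
#'
#' Evaluates the four-parameter logistic
#' `bottom + (top - bottom) / (1 + (c / ic50)^hill)` at the given
#' concentrations and applies multiplicative lognormal noise, emulating a
#' radioligand displacement assay read in percent of specific binding.
#'
#' @param ic50 true half-maximal inhibitory concentration (> 0, same units
#'   as `concentrations`).
#' @param hill Hill slope (> 0 for a decreasing displacement curve).
#' @param top,bottom upper/lower plateaus in percent; `top > bottom`.
#' @param concentrations positive competitor concentrations.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#'
#' @return data.frame with columns `concentration`, `response` and
#'   `response_true` (noiseless).
#' @export
gen_binding_curve <- function(ic50, hill, top, bottom, concentrations,
                              noise_cv = 0, seed = 1L) {
  stopifnot(ic50 > 0, top > bottom)
  if (length(concentrations) == 0) stop("empty concentration list")
  stopifnot(all(concentrations > 0))
  mu <- bottom + (top - bottom) / (1 + (concentrations / ic50)^hill)
  withr::with_seed(seed, {
    resp <- if (noise_cv > 0) {
      # noise applied on a strictly positive scale, then shifted back, so
      # curves with bottom = 0 stay non-negative
      offset <- max(0, -min(mu)) + 1
      rlnorm_cv(length(mu), mu + offset, noise_cv) - offset
    } else {
      mu
    }
    data.frame(concentration = concentrations, response = resp,
               response_true = mu)
  })
}

#' Simulate a coregulator peptide-array intensity table
#'
#' Emulates a nuclear-receptor coregulator peptide array: each peptide spot
#' has a solvent-condition net intensity `base_intensity`, each compound
#' multiplies it by a peptide-specific fold change, and a constant local
#' background is added on top. Noise is multiplicative lognormal on the net
#' signal.
#'
#' @param n_peptides number of peptide motifs on the array.
#' @param effects named list, one element per compound, each a positive
#'   fold-change vector of length `n_peptides` (or length 1, recycled).
#' @param base_intensity solvent-condition net spot intensity (AU).
#' @param background constant local background (AU).
#' @param n_replicates replicate arrays per condition; values < 2 warn,
#'   since the downstream t-test is undefined.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed integer seed.
#' @param solvent_label label used for the solvent control rows.
#'
#' @return data.frame with columns `peptide_id`, `compound`, `replicate`,
#'   `spot_intensity`, `local_background`.
#' @export
gen_peptide_array <- function(n_peptides, effects, base_intensity = 1000,
                              background = 100, n_replicates = 3,
                              noise_cv = 0.05, seed = 1L,
                              solvent_label = "DMSO") {
  stopifnot(n_peptides >= 1, is.list(effects), length(effects) >= 1,
            !is.null(names(effects)), base_intensity > 0, background >= 0)
  effects <- lapply(effects, function(f) {
    f <- rep_len(f, n_peptides)
    if (any(f <= 0)) stop("fold changes must be positive")
    f
  })
  if (n_replicates < 2) {
    warning("n_replicates < 2: downstream t-test undefined")
  }
  conditions <- c(stats::setNames(list(rep(1, n_peptides)), solvent_label),
                  effects)
  peptide_ids <- sprintf("pep%03d", seq_len(n_peptides))
  withr::with_seed(seed, {
    out <- lapply(names(conditions), function(cmp) {
      fold <- conditions[[cmp]]
      mu <- fold * base_intensity
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        data.frame(
          peptide_id = peptide_ids, compound = cmp, replicate = r,
          spot_intensity = rlnorm_cv(n_peptides, mu, noise_cv) + background,
          local_background = background
        )
      }))
    })
    do.call(rbind, out)
  })
}

#' Construct a synthetic protein sequence with placed K/R/C residues
#'
#' Builds a random amino-acid sequence carrying cysteines exactly at
#' `cys_positions` and lysine/arginine exactly at `kr_positions`; all other
#' residues are drawn from the remaining 17-letter alphabet. Used as a
#' digestion fixture with fully known cleavage structure.
#'
#' @param length sequence length.
#' @param cys_positions 1-based positions that must be `C`.
#' @param kr_positions 1-based positions that must be `K` or `R` (chosen at
#'   random per position unless `kr_residues` is given).
#' @param seed integer seed.
#' @param kr_residues optional character vector, same length as
#'   `kr_positions`, fixing which of K/R goes at each position.
#'
#' @return a single character string.
#' @export
gen_protein <- function(length, cys_positions = integer(0),
                        kr_positions = integer(0), seed = 1L,
                        kr_residues = NULL) {
  stopifnot(length >= 1,
            all(cys_positions >= 1), all(cys_positions <= length),
            all(kr_positions >= 1), all(kr_positions <= length))
  if (length(intersect(cys_positions, kr_positions)) > 0) {
    stop("conflicting positions: a residue cannot be both C and K/R")
  }
  if (anyDuplicated(c(cys_positions, kr_positions))) {
    stop("duplicated positions")
  }
  if (!is.null(kr_residues)) {
    stopifnot(length(kr_residues) == length(kr_positions),
              all(kr_residues %in% c("K", "R")))
  }
  other <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   c("K", "R", "C"))
  withr::with_seed(seed, {
    res <- sample(other, length, replace = TRUE)
    res[cys_positions] <- "C"
    res[kr_positions] <- if (is.null(kr_residues)) {
      sample(c("K", "R"), length(kr_positions), replace = TRUE)
    } else {
      kr_residues
    }
    paste(res, collapse = "")
  })
}
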