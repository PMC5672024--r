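#' Tile-wise local contrast enhancement (CLAHE)
#'
#' Contrast-limited adaptive histogram equalization of a single channel,
#' used to flatten spatial illumination heterogeneity before nuclear
#' segmentation. The input is rescaled to `[0, 1]`, equalized tile-wise with
#' a clip limit, and the output is guaranteed to stay within `[0, 1]`.
#'
#' @param img numeric intensity matrix with finite, non-negative values.
#' @param tile approximate tile side in pixels (>= 8).
#' @param clip_limit CLAHE contrast ceiling (>= 1); higher values allow
#'   more contrast amplification.
#' @return numeric matrix in `[0, 1]`, same dimensions as `img`.
#' @export
local_contrast_enhance <- function(img, tile = 32, clip_limit = 2) {
  stopifnot(is.matrix(img), tile >= 8)
  if (!all(is.finite(img))) stop("non-finite pixels")
  rng <- range(img)
  if (diff(rng) == 0) {
    # constant image: map the value into [0,1] and return it unchanged
    v <- rng[1]
    if (v > 1) v <- 1
    if (v < 0) v <- 0
    return(matrix(v, nrow(img), ncol(img)))
  }
  x <- (img - rng[1]) / diff(rng)
  nx <- max(2L, round(ncol(x) / tile))
  ny <- max(2L, round(nrow(x) / tile))
  y <- EBImage::clahe(EBImage::Image(x), nx = nx, ny = ny,
                      limit = clip_limit)
  y <- EBImage::imageData(y)
  pmin(pmax(y, 0), 1)
}

# 1-D Gaussian convolution matrix with reflecting boundary, acting on
# vectors of length n
.gauss_convmat <- function(n, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (off in (-rad):rad) {
    j <- seq_len(n) + off
    # reflect (mirror without repeating the edge pixel, style "symmetric")
    j <- ifelse(j < 1, 1 - j, j)
    j <- ifelse(j > n, 2 * n + 1 - j, j)
    # fold indices that reflect past both ends (very large sigma)
    while (any(j < 1 | j > n)) {
      j <- ifelse(j < 1, 1 - j, j)
      j <- ifelse(j > n, 2 * n + 1 - j, j)
    }
    m[cbind(seq_len(n), j)] <- m[cbind(seq_len(n), j)] + k[off + rad + 1]
  }
  m
}

#' Gaussian smoothing with reflecting boundary
#'
#' Separable convolution with a normalized Gaussian kernel (radius 3 sigma),
#' reflecting the image at its borders. A constant image is returned
#' unchanged (kernel normalization).
#'
#' @param img numeric intensity matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return smoothed matrix, same dimensions.
#' @export
gaussian_smooth <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0, all(is.finite(img)))
  mr <- .gauss_convmat(nrow(img), sigma)
  mc <- .gauss_convmat(ncol(img), sigma)
  mr %*% img %*% t(mc)
}

#' Isodata (Ridler-Calvard) automatic threshold
#'
#' Iterates `t <- (mean(img[img <= t]) + mean(img[img > t])) / 2` from the
#' global mean until the update falls below `tol`, and returns the converged
#' threshold. The threshold is affine-equivariant: adding a constant to all
#' pixels shifts it by the same constant.
#'
#' @param img numeric matrix or vector with at least two distinct values.
#' @param tol convergence tolerance on the threshold update; defaults to
#'   1/65536 of the image's dynamic range so the same code serves both
#'   integer-scaled and unit-scaled images.
#' @param max_iter iteration cap.
#' @return the converged threshold (scalar).
#' @export
isodata_threshold <- function(img, tol = NULL, max_iter = 200L) {
  x <- as.numeric(img)
  if (!all(is.finite(x))) stop("non-finite pixels")
  rng <- range(x)
  if (diff(rng) == 0) stop("constant image has no isodata threshold")
  if (is.null(tol)) tol <- diff(rng) / 65536
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]
    hi <- x[x > t_cur]
    if (length(hi) == 0) break # t reached the maximum; previous t stands
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

# seed selection within one connected component: one candidate per basin
# of the tolerance-merged watershed of the distance transform (so shallow
# ridge maxima do not spawn seeds), placed at the basin's distance maximum
# (lowest linear index on ties), then greedily suppressed so surviving
# seeds are >= min_sep apart (deeper seed wins, lowest index on ties)
.select_seeds <- function(dist_map, basin_map, comp_idx, shape, min_sep) {
  basins <- setdiff(unique(basin_map[comp_idx]), 0)
  cand_idx <- vapply(basins, function(b) {
    bi <- comp_idx[basin_map[comp_idx] == b]
    bi[which.max(dist_map[bi])]
  }, numeric(1))
  d <- dist_map[cand_idx]
  ord <- order(-d, cand_idx)
  cand_idx <- cand_idx[ord]
  cand_r <- (cand_idx - 1) %% shape[1] + 1
  cand_c <- (cand_idx - 1) %/% shape[1] + 1
  keep <- integer(0)
  for (i in seq_along(cand_idx)) {
    if (length(keep) == 0) {
      keep <- i
    } else {
      dd <- sqrt((cand_r[keep] - cand_r[i])^2 + (cand_c[keep] - cand_c[i])^2)
      if (all(dd >= min_sep)) keep <- c(keep, i)
    }
  }
  cbind(row = cand_r[keep], col = cand_c[keep])
}

#' Conditional watershed labelling of a nuclear mask
#'
#' Labels connected components of a binary nuclear mask and splits touching
#' nuclei: within each component, seeds are placed at distance-transform
#' maxima at least `min_seed_sep` apart and pixels are assigned to the
#' nearest seed. The split is accepted only if every resulting fragment has
#' area at least `min_area` (the "conditional" rule); otherwise the
#' component keeps a single label. Components or fragments below `min_area`
#' are discarded.
#'
#' @param mask logical or 0/1 matrix (foreground = nuclei).
#' @param min_area minimum accepted object area in pixels.
#' @param min_seed_sep minimum seed separation in pixels.
#' @param seed_depth_tol minimum depth (in distance-transform units) a
#'   basin must have to contribute its own seed; shallower ridge maxima are
#'   absorbed into their deeper neighbour.
#' @return integer label matrix, 0 = background, labels 1..K consecutive.
#' @export
conditional_watershed <- function(mask, min_area = 50, min_seed_sep = 5,
                                  seed_depth_tol = 1) {
  stopifnot(is.matrix(mask))
  m <- (mask > 0) * 1
  shape <- dim(m)
  comps <- EBImage::bwlabel(m)
  comps <- EBImage::imageData(comps)
  out <- matrix(0L, shape[1], shape[2])
  next_lab <- 0L
  ncomp <- max(comps)
  if (ncomp == 0) return(out)
  dist_all <- EBImage::imageData(EBImage::distmap(m))
  basin_all <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(dist_all), tolerance = seed_depth_tol)
  )
  for (cid in seq_len(ncomp)) {
    idx <- which(comps == cid)
    if (length(idx) < min_area) next
    seeds <- .select_seeds(dist_all, basin_all, idx, shape, min_seed_sep)
    if (nrow(seeds) > 1) {
      rows <- (idx - 1L) %% shape[1] + 1L
      cols <- (idx - 1L) %/% shape[1] + 1L
      d2 <- sapply(seq_len(nrow(seeds)), function(s) {
        (rows - seeds[s, 1])^2 + (cols - seeds[s, 2])^2
      })
      assign <- max.col(-d2, ties.method = "first")
      areas <- tabulate(assign, nbins = nrow(seeds))
      if (all(areas >= min_area)) {
        for (s in seq_len(nrow(seeds))) {
          next_lab <- next_lab + 1L
          out[idx[assign == s]] <- next_lab
        }
        next
      }
    }
    next_lab <- next_lab + 1L
    out[idx] <- next_lab
  }
  out
}

#' Drop labelled objects touching the image border
#'
#' Border nuclei have asymmetrically truncated cytoplasmic rings and are
#' excluded from measurement by default. Remaining labels are renumbered
#' consecutively.
#'
#' @param labels integer label matrix.
#' @return relabelled matrix.
#' @export
exclude_border_labels <- function(labels) {
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- setdiff(border, 0L)
  labels[labels %in% border] <- 0L
  keep <- sort(setdiff(unique(as.vector(labels)), 0L))
  relab <- integer(max(c(0L, keep)) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  matrix(ifelse(labels > 0, relab[labels + 1L], 0L),
         nrow(labels), ncol(labels))
}

# distance from every pixel to the nearest pixel of each label;
# returns an (npix x K) matrix of Euclidean distances
.label_distances <- function(labels) {
  ks <- sort(setdiff(unique(as.vector(labels)), 0L))
  shape <- dim(labels)
  d <- matrix(Inf, length(labels), length(ks))
  for (j in seq_along(ks)) {
    inv <- matrix(1, shape[1], shape[2])
    inv[labels == ks[j]] <- 0
    # distmap gives, for non-zero pixels, the distance to the nearest zero
    d[, j] <- as.vector(EBImage::imageData(EBImage::distmap(inv)))
  }
  colnames(d) <- ks
  d
}

#' Voronoi-restrained cytoplasmic ring ROIs
#'
#' For each labelled nucleus, the cytoplasmic ring is the set of
#' non-nuclear pixels within Euclidean distance `band_width` of that
#' nucleus, restricted to the pixels whose nearest nucleus is that nucleus
#' (its Voronoi zone). Rings therefore never compete: no ring pixel is
#' strictly closer to another nucleus. Empty rings are flagged.
#'
#' @param nuclei integer nucleus label matrix.
#' @param band_width ring width in pixels (>= 1).
#' @return integer ring label matrix keyed to nucleus IDs, with attribute
#'   `empty_rings` (integer vector of nucleus IDs whose ring is empty).
#' @export
voronoi_rings <- function(nuclei, band_width = 5) {
  stopifnot(is.matrix(nuclei))
  if (band_width < 1) stop("band_width must be >= 1")
  ks <- sort(setdiff(unique(as.vector(nuclei)), 0L))
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (length(ks) == 0) {
    attr(out, "empty_rings") <- integer(0)
    return(out)
  }
  d <- .label_distances(nuclei)
  owner <- ks[max.col(-d, ties.method = "first")] # nearest nucleus, low ID wins ties
  mind <- d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
  ring <- nuclei == 0L & matrix(mind <= band_width, nrow(nuclei))
  out[ring] <- owner[as.vector(ring)]
  present <- ks %in% out
  attr(out, "empty_rings") <- ks[!present]
  out
}

#' Per-cell N/C ratio measurement
#'
#' Measures, for every labelled cell, the arithmetic mean of the raw GR
#' channel over the nuclear ROI and over the cytoplasmic ring, and their
#' ratio (the N/C ratio). Cells with an empty ring or non-positive
#' cytoplasmic mean are excluded, with reasons recorded in the
#' `excluded` attribute.
#'
#' @param gr raw (unenhanced) GR intensity matrix.
#' @param nuclei nucleus label matrix.
#' @param rings ring label matrix from [voronoi_rings()].
#' @return data.frame with columns `cell_id`, `nuc_mean`, `cyto_mean`,
#'   `nc_ratio`, `n_nuc_px`, `n_cyto_px`; attribute `excluded` is a
#'   data.frame of dropped cells and reasons.
#' @export
measure_cells <- function(gr, nuclei, rings) {
  stopifnot(is.matrix(gr), all(dim(gr) == dim(nuclei)),
            all(dim(gr) == dim(rings)))
  ks <- sort(setdiff(unique(as.vector(nuclei)), 0L))
  rec <- list()
  excl <- list()
  for (k in ks) {
    nuc <- gr[nuclei == k]
    cyt <- gr[rings == k]
    if (length(cyt) == 0) {
      excl[[length(excl) + 1L]] <- data.frame(cell_id = k,
                                              reason = "empty ring")
      next
    }
    cm <- mean(cyt)
    if (cm <= 0) {
      excl[[length(excl) + 1L]] <- data.frame(cell_id = k,
                                              reason = "non-positive cytoplasmic mean")
      next
    }
    rec[[length(rec) + 1L]] <- data.frame(
      cell_id = k, nuc_mean = mean(nuc), cyto_mean = cm,
      nc_ratio = mean(nuc) / cm,
      n_nuc_px = length(nuc), n_cyto_px = length(cyt)
    )
  }
  out <- if (length(rec)) do.call(rbind, rec) else {
    data.frame(cell_id = integer(0), nuc_mean = numeric(0),
               cyto_mean = numeric(0), nc_ratio = numeric(0),
               n_nuc_px = integer(0), n_cyto_px = integer(0))
  }
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else {
    data.frame(cell_id = integer(0), reason = character(0))
  }
  out
}

#' End-to-end per-cell translocation quantification
#'
#' Runs the full imaging pipeline on a two-channel image: the nuclear-stain
#' channel is contrast-enhanced, Gaussian-smoothed, isodata-thresholded and
#' split by conditional watershed; cytoplasmic rings are grown around each
#' nucleus under Voronoi restriction; and per-cell N/C ratios are measured
#' on the raw GR channel. Enhancement and smoothing affect segmentation
#' only, never the measured intensities.
#'
#' @param nuclear nuclear-stain channel matrix.
#' @param gr GR channel matrix (raw).
#' @param tile,clip_limit see [local_contrast_enhance()].
#' @param sigma Gaussian smoothing sd in pixels.
#' @param min_area,min_seed_sep see [conditional_watershed()].
#' @param band_width cytoplasmic ring width in pixels.
#' @param exclude_border drop nuclei touching the image border (default).
#' @return list with `records` (see [measure_cells()]), `nuclei` and
#'   `rings` label matrices, and the `threshold` used.
#' @export
quantify_translocation <- function(nuclear, gr, tile = 32, clip_limit = 2,
                                   sigma = 2, min_area = 50,
                                   min_seed_sep = 5, band_width = 5,
                                   exclude_border = TRUE) {
  enh <- local_contrast_enhance(nuclear, tile = tile,
                                clip_limit = clip_limit)
  sm <- gaussian_smooth(enh, sigma = sigma)
  thr <- isodata_threshold(sm)
  nuclei <- conditional_watershed(sm > thr, min_area = min_area,
                                  min_seed_sep = min_seed_sep)
  if (exclude_border) nuclei <- exclude_border_labels(nuclei)
  rings <- voronoi_rings(nuclei, band_width = band_width)
  records <- measure_cells(gr, nuclei, rings)
  list(records = records, nuclei = nuclei, rings = rings, threshold = thr)
}

#' Per-treatment translocation summary with Welch tests against control
#'
#' Summarizes per-cell N/C ratios by treatment (mean, SD, n) and tests each
#' treatment against the control group with a two-sided Welch t-test.
#'
#' @param records data.frame with columns `treatment` and `nc_ratio`.
#' @param control control treatment label.
#' @return data.frame with columns `treatment`, `n`, `mean_ratio`,
#'   `sd_ratio`, `t`, `p_value` (NA for the control row).
#' @export
summarize_translocation <- function(records, control) {
  stopifnot(all(c("treatment", "nc_ratio") %in% names(records)))
  groups <- split(records$nc_ratio, records$treatment)
  if (length(groups) < 1) stop("no groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (!control %in% names(groups)) stop("control group not present")
  ctrl <- groups[[control]]
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (g == control) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (stats::sd(x) == 0 && stats::sd(ctrl) == 0 &&
               mean(x) == mean(ctrl)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      ht <- stats::t.test(x, ctrl)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(treatment = g, n = length(x), mean_ratio = mean(x),
               sd_ratio = stats::sd(x), t = tt$statistic,
               p_value = tt$p.value)
  })
  do.call(rbind, out)
}
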