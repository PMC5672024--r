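#' Net spot intensity (signal minus background)
#'
#' Subtracts the local background from the raw spot intensity. Net values
#' at or below zero are floored at a small positive epsilon so downstream
#' log-ratios stay defined; the number of floored spots is recorded in the
#' `n_floored` attribute.
#'
#' @param spot_intensity raw spot intensities (AU).
#' @param local_background local background estimates (AU), recycled.
#' @param floor_eps positive flooring value (default 1 AU).
#' @return numeric vector of net intensities with attribute `n_floored`.
#' @export
spot_quantify <- function(spot_intensity, local_background, floor_eps = 1) {
  stopifnot(all(is.finite(spot_intensity)), all(is.finite(local_background)),
            floor_eps > 0)
  net <- spot_intensity - local_background
  floored <- net <= 0
  net[floored] <- floor_eps
  structure(net, n_floored = sum(floored))
}

#' Modulation index of a peptide-compound pair
#'
#' Log10 ratio of the mean net ligand intensity to the mean net solvent
#' intensity: MI = +1 means 10-fold enhanced coregulator binding, -1 means
#' 10-fold displacement, 0 no modulation. Replicates are aggregated by
#' mean before the ratio. A cell whose replicates were all floored on
#' either side is flagged unreliable.
#'
#' @param ligand_nets replicate net intensities with ligand.
#' @param solvent_nets replicate net intensities with solvent.
#' @param floor_eps the flooring epsilon used upstream.
#' @return MI (scalar) with logical attribute `unreliable`.
#' @export
modulation_index <- function(ligand_nets, solvent_nets, floor_eps = 1) {
  ml <- mean(ligand_nets)
  ms <- mean(solvent_nets)
  if (ml <= 0 || ms <= 0) stop("means must be positive after flooring")
  structure(log10(ml / ms),
            unreliable = all(ligand_nets <= floor_eps) ||
              all(solvent_nets <= floor_eps))
}

#' Student's t-test for a ligand effect on one peptide
#'
#' Two-sample pooled-variance (Student) t-test of ligand versus solvent
#' replicate net intensities, two-sided. Degenerate inputs with zero pooled
#' variance return p = 1 when the means agree, and p = 0 (flagged by a
#' warning) when they differ.
#'
#' @param ligand_nets replicate net intensities with ligand (n >= 2).
#' @param solvent_nets replicate net intensities with solvent (n >= 2).
#' @return list with `t` and `p`.
#' @export
peptide_ttest <- function(ligand_nets, solvent_nets) {
  if (length(ligand_nets) < 2 || length(solvent_nets) < 2) {
    stop("need at least 2 replicates per side")
  }
  pooled_ss <- sum((ligand_nets - mean(ligand_nets))^2) +
    sum((solvent_nets - mean(solvent_nets))^2)
  if (pooled_ss == 0) {
    if (mean(ligand_nets) == mean(solvent_nets)) {
      return(list(t = 0, p = 1))
    }
    warning("zero pooled variance with unequal means: p -> 0")
    return(list(t = sign(mean(ligand_nets) - mean(solvent_nets)) * Inf,
                p = 0))
  }
  ht <- stats::t.test(ligand_nets, solvent_nets, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Peptide x compound modulation-index profile
#'
#' Builds the full modulation-index matrix (peptides as rows, compounds as
#' columns) and the matching per-cell Student t-test p-values from a long
#' array table. The solvent column is identically 0 by construction.
#'
#' @param array_table data.frame with columns `peptide_id`, `compound`,
#'   `replicate`, `spot_intensity`, `local_background`.
#' @param solvent solvent (control) compound label.
#' @param floor_eps flooring epsilon for net intensities.
#' @return list with matrices `mi` and `p` (peptide x compound), and
#'   `unreliable` (logical matrix).
#' @export
mi_profile <- function(array_table, solvent = "DMSO", floor_eps = 1) {
  need <- c("peptide_id", "compound", "replicate", "spot_intensity",
            "local_background")
  stopifnot(all(need %in% names(array_table)))
  if (!solvent %in% array_table$compound) stop("solvent condition missing")
  array_table$net <- as.numeric(
    spot_quantify(array_table$spot_intensity, array_table$local_background,
                  floor_eps = floor_eps)
  )
  peps <- sort(unique(array_table$peptide_id))
  cmps <- unique(array_table$compound)
  cmps <- c(solvent, setdiff(cmps, solvent))
  mi <- matrix(NA_real_, length(peps), length(cmps),
               dimnames = list(peps, cmps))
  pv <- mi
  unrel <- matrix(FALSE, length(peps), length(cmps),
                  dimnames = list(peps, cmps))
  for (i in seq_along(peps)) {
    sol <- array_table$net[array_table$peptide_id == peps[i] &
                             array_table$compound == solvent]
    for (j in seq_along(cmps)) {
      lig <- array_table$net[array_table$peptide_id == peps[i] &
                               array_table$compound == cmps[j]]
      m <- modulation_index(lig, sol, floor_eps = floor_eps)
      mi[i, j] <- as.numeric(m)
      unrel[i, j] <- attr(m, "unreliable")
      pv[i, j] <- if (cmps[j] == solvent) 1 else {
        if (length(lig) >= 2 && length(sol) >= 2) {
          peptide_ttest(lig, sol)$p
        } else {
          NA_real_
        }
      }
    }
  }
  mi[, solvent] <- 0
  list(mi = mi, p = pv, unreliable = unrel)
}

#' Ward hierarchical clustering via the Lance-Williams recurrence
#'
#' Agglomerative clustering with Euclidean distances under Ward's
#' minimum-variance criterion: at each step the pair of clusters whose
#' merge least increases the total within-cluster sum of squares is joined,
#' with inter-cluster dissimilarities updated by the Lance-Williams
#' recurrence on squared distances (the "ward.D2" convention, heights on
#' the original distance scale). Ties are broken deterministically by the
#' lowest pair index.
#'
#' @param x numeric matrix; rows are the items to cluster (transpose first
#'   to cluster columns).
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
ward_cluster <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (any(!is.finite(x))) stop("NaN/NA entries not allowed")
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1L, n)
  id <- -seq_len(n)           # hclust convention: negatives are singletons
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        i <- act[ii]; j <- act[jj]
        if (d2[i, j] < best_d) {
          best_d <- d2[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    a <- id[i]; b <- id[j]
    # hclust row convention: singletons (negative) first, by ascending
    # absolute index; formed clusters ascending
    pair <- c(a, b)
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[step, ] <- pair
    height[step] <- sqrt(best_d)
    # Lance-Williams update (Ward, on squared distances)
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * best_d) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
  }
  order <- .leaf_order(merge)
  structure(
    list(merge = merge, height = height, order = order,
         labels = rownames(x), method = "ward.D2",
         dist.method = "euclidean",
         call = match.call()),
    class = "hclust"
  )
}

# depth-first leaf order from an hclust merge matrix
.leaf_order <- function(merge) {
  n <- nrow(merge) + 1
  collect <- function(node) {
    if (node < 0) return(-node)
    c(collect(merge[node, 1]), collect(merge[node, 2]))
  }
  collect(nrow(merge))
}

#' Cluster-ordered modulation-index matrix
#'
#' Permutes the rows and columns of a modulation-index matrix to the leaf
#' orders of its row and column dendrograms, optionally writes the ordered
#' matrix to CSV, and optionally draws a diverging heatmap centered at 0.
#'
#' @param mi peptide x compound MI matrix.
#' @param row_clust,col_clust `hclust` objects for rows and columns (e.g.
#'   from [ward_cluster()]); `NULL` keeps the original order.
#' @param csv optional path to write the ordered matrix as CSV.
#' @param draw draw a heatmap with pheatmap (if installed).
#' @return the ordered matrix (invisibly if `draw`).
#' @export
profile_heatmap <- function(mi, row_clust = NULL, col_clust = NULL,
                            csv = NULL, draw = FALSE) {
  stopifnot(is.matrix(mi))
  ro <- if (is.null(row_clust)) seq_len(nrow(mi)) else row_clust$order
  co <- if (is.null(col_clust)) seq_len(ncol(mi)) else col_clust$order
  ord <- mi[ro, co, drop = FALSE]
  if (!is.null(csv)) {
    utils::write.csv(ord, csv, row.names = TRUE)
  }
  if (draw && requireNamespace("pheatmap", quietly = TRUE)) {
    lim <- max(abs(ord))
    pheatmap::pheatmap(
      ord, cluster_rows = FALSE, cluster_cols = FALSE,
      breaks = seq(-lim, lim, length.out = 101),
      color = grDevices::colorRampPalette(c("blue", "white", "red"))(100)
    )
    return(invisible(ord))
  }
  ord
}
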