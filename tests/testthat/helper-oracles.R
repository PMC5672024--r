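# independent oracles and small fixture builders used across the suite

# binary disc mask on an nr x nc grid
disc_mask <- function(nr, nc, centers, radii) {
  m <- matrix(FALSE, nr, nc)
  rr <- row(m); cc <- col(m)
  for (i in seq_len(nrow(centers))) {
    m <- m | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2)
  }
  m
}

# brute-force nearest-nucleus owner and distance for every pixel:
# for each pixel, the minimum Euclidean distance to any pixel of each
# labelled nucleus, with the lowest label winning ties
brute_voronoi <- function(nuclei) {
  ks <- sort(setdiff(unique(as.vector(nuclei)), 0L))
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  pr <- as.vector(row(nuclei)); pc <- as.vector(col(nuclei))
  dmat <- sapply(ks, function(k) {
    idx <- which(nuclei == k)
    kr <- (idx - 1L) %% nr + 1L
    kc <- (idx - 1L) %/% nr + 1L
    apply(cbind(pr, pc), 1, function(p) {
      sqrt(min((kr - p[1])^2 + (kc - p[2])^2))
    })
  })
  owner <- ks[max.col(-dmat, ties.method = "first")]
  mind <- dmat[cbind(seq_len(nrow(dmat)), max.col(-dmat, ties.method = "first"))]
  list(owner = matrix(owner, nr, nc), dist = matrix(mind, nr, nc))
}

# exhaustive greedy Ward oracle: at every step recompute, for every pair
# of current clusters, the increase in total within-cluster sum of squares
# caused by merging them, and merge the minimizing pair; returns the
# sequence of merged leaf-index sets
greedy_ward_merges <- function(x) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    xs <- x[rows, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_d) { best_d <- delta; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# leaf-index sets in merge order from an hclust-style object
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# exhaustive digestion oracle: every (start, end) substring whose start is
# 1 or just after a cleavage site, whose end is a cleavage site or the
# C-terminus, and which contains at most max_missed internal sites
brute_digest_spans <- function(seq, sites, max_missed) {
  n <- nchar(seq)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- list()
  for (s in starts) {
    for (e in ends) {
      if (e < s) next
      internal <- sum(sites >= s & sites < e)
      if (internal <= max_missed) {
        out[[length(out) + 1L]] <- c(s, e, internal)
      }
    }
  }
  do.call(rbind, out)
}

# one-to-one matching of truth nuclei to segmented labels at an IoU cutoff
match_nuclei_iou <- function(truth, labels, cutoff = 0.5) {
  ks <- sort(setdiff(unique(as.vector(labels)), 0L))
  used <- logical(length(ks))
  matched <- 0L
  for (t in truth) {
    best_iou <- 0; best_k <- 0L
    for (i in seq_along(ks)) {
      if (used[i]) next
      lab_idx <- which(labels == ks[i])
      inter <- length(intersect(t$nucleus_idx, lab_idx))
      if (inter == 0) next
      iou <- inter / length(union(t$nucleus_idx, lab_idx))
      if (iou > best_iou) { best_iou <- iou; best_k <- i }
    }
    if (best_iou >= cutoff) { matched <- matched + 1L; used[best_k] <- TRUE }
  }
  matched
}
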