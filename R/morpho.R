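#' Split a dendritic tree into apical and basal compartments
#'
#' Dendrites are assigned automatically by where each stem originates
#' relative to the soma centroid: stems whose origin point lies above the
#' centroid (pia side, smaller depth) are apical, stems originating below
#' are basal. Every dendritic node belongs to exactly one of the two sets.
#'
#' @param tree a `morphology_tree`.
#' @return list with integer node-id vectors `apical` and `basal`.
#' @export
split_apical_basal <- function(tree) {
  nodes <- tree$nodes
  soma_ids <- nodes$id[nodes$type == 1]
  stems <- nodes[nodes$parent %in% soma_ids & nodes$type != 1, ]
  if (nrow(stems) == 0) stop("tree has no dendritic nodes")
  apical <- integer(0)
  basal <- integer(0)
  for (i in seq_len(nrow(stems))) {
    ids <- tree_descendants(nodes, stems$id[i])
    if (stems$y[i] < tree$soma[["depth"]]) {
      apical <- c(apical, ids)
    } else {
      basal <- c(basal, ids)
    }
  }
  list(apical = apical, basal = basal)
}

# segment table for a set of dendritic node ids: one row per edge
# (parent -> node), with 2D length (x, depth) and both endpoint depths.
dendrite_segments <- function(tree, ids = NULL) {
  nodes <- tree$nodes
  if (is.null(ids)) ids <- nodes$id[nodes$type != 1]
  dn <- nodes[nodes$id %in% ids, ]
  pidx <- match(dn$parent, nodes$id)
  keep <- !is.na(pidx)
  dn <- dn[keep, ]
  pn <- nodes[pidx[keep], ]
  data.frame(
    id = dn$id,
    length = sqrt((dn$x - pn$x)^2 + (dn$y - pn$y)^2),
    x0 = pn$x, x1 = dn$x, d0 = pn$y, d1 = dn$y
  )
}

# cable length of the portion of each segment lying at depth <= dmax
clipped_length <- function(segs, dmax) {
  lo <- pmin(segs$d0, segs$d1)
  hi <- pmax(segs$d0, segs$d1)
  frac <- ifelse(hi == lo, as.numeric(lo <= dmax),
                 pmax(0, pmin(hi, dmax) - lo) / (hi - lo))
  sum(segs$length * frac)
}

# number of branches: segments delimited by stem origin, bifurcation,
# terminal. Equals the number of edges leaving a junction (soma or a node
# with >= 2 children) within the given node set.
count_branches <- function(tree, ids) {
  nodes <- tree$nodes
  sub <- nodes[nodes$id %in% ids, ]
  if (nrow(sub) == 0) return(0L)
  n_children <- table(factor(sub$parent, levels = nodes$id))
  junctions <- nodes$id[nodes$type == 1 | n_children >= 2]
  sum(sub$parent %in% junctions)
}

#' Morphological features of a reconstruction
#'
#' Computes the superficial span and coverage density plus apical/basal
#' length and branch counts. `span_200` is the maximal lateral (x) extent
#' of dendrite within 200 um of the pia; `density_200` is the dendritic
#' cable length in that region divided by the `span_200 x 200 um`
#' rectangle. Lengths are 2D (slice-plane) sums of inter-node segment
#' lengths; all features are invariant under lateral translation and
#' reflection.
#'
#' @param tree a `morphology_tree`.
#' @param superficial_depth depth cut for span/density in um (default 200).
#' @return one-row data frame with `span_200`, `density_200`,
#'   `apical_length`, `basal_length`, `apical_branches`, `basal_branches`,
#'   `length_ratio`, `branch_ratio`, `soma_depth`.
#' @export
compute_features <- function(tree, superficial_depth = 200) {
  parts <- split_apical_basal(tree)
  seg_a <- dendrite_segments(tree, parts$apical)
  seg_b <- dendrite_segments(tree, parts$basal)
  segs <- rbind(seg_a, seg_b)

  nodes <- tree$nodes
  sup <- nodes[nodes$type != 1 & nodes$y <= superficial_depth, ]
  if (nrow(sup) == 0) {
    span <- 0
    dens <- 0
  } else {
    span <- max(sup$x) - min(sup$x)
    len_sup <- clipped_length(segs, superficial_depth)
    dens <- if (span > 0) len_sup / (span * superficial_depth) else 0
  }
  ap_len <- sum(seg_a$length)
  ba_len <- sum(seg_b$length)
  data.frame(
    span_200 = span, density_200 = dens,
    apical_length = ap_len, basal_length = ba_len,
    apical_branches = count_branches(tree, parts$apical),
    basal_branches = count_branches(tree, parts$basal),
    length_ratio = if (ba_len > 0) ap_len / ba_len else NA_real_,
    branch_ratio = {
      bb <- count_branches(tree, parts$basal)
      if (bb > 0) count_branches(tree, parts$apical) / bb else NA_real_
    },
    soma_depth = unname(tree$soma[["depth"]])
  )
}

#' Cluster neurons into BT and ST groups
#'
#' 2-means clustering on z-scored `(span_200, density_200)`; the cluster
#' with the larger mean `density_200` is labelled BT (broad-tufted), the
#' other ST (slender-tufted), so labels do not depend on the arbitrary
#' k-means cluster index. Per-cluster 95% confidence ellipses come from a
#' 2D Gaussian fit at the 0.95 chi-square quantile with 2 degrees of
#' freedom.
#'
#' @param features data frame with columns `span_200` and `density_200`
#'   (one row per neuron), e.g. rbind-ed [compute_features()] output.
#' @param seed seed for the k-means restarts (50 restarts).
#' @return list with `labels` (character, `"BT"`/`"ST"`), `centers`
#'   (matrix in original units) and `ellipses` (per-cluster list of
#'   `center`, `cov`, `radius2` and a 100-point `path` matrix).
#' @export
cluster_bt_st <- function(features, seed = 1L) {
  stopifnot(nrow(features) >= 4)
  xy <- as.matrix(features[, c("span_200", "density_200")])
  if (nrow(unique(xy)) < 2) stop("fewer than 2 distinct feature points")
  z <- scale(xy)
  z[, apply(xy, 2, sd) == 0] <- 0
  km <- with_seed(seed, kmeans(z, centers = 2, nstart = 50, iter.max = 100))
  dens_mean <- tapply(xy[, "density_200"], km$cluster, mean)
  bt_cluster <- as.integer(names(which.max(dens_mean)))
  labels <- ifelse(km$cluster == bt_cluster, "BT", "ST")
  centers <- rbind(
    BT = colMeans(xy[labels == "BT", , drop = FALSE]),
    ST = colMeans(xy[labels == "ST", , drop = FALSE])
  )
  ellipses <- lapply(c(BT = "BT", ST = "ST"), function(lb) {
    pts <- xy[labels == lb, , drop = FALSE]
    ctr <- colMeans(pts)
    cv <- if (nrow(pts) > 2) stats::cov(pts) else diag(1e-12, 2)
    r2 <- qchisq(0.95, df = 2)
    theta <- seq(0, 2 * pi, length.out = 100)
    ev <- eigen(cv, symmetric = TRUE)
    ax <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0) * r2))
    path <- t(ctr + ax %*% rbind(cos(theta), sin(theta)))
    colnames(path) <- colnames(xy)
    list(center = ctr, cov = cv, radius2 = r2, path = path)
  })
  list(labels = labels, centers = centers, ellipses = ellipses)
}

#' Laminar profile container
#'
#' @param bin_edges depth bin edges in um from the pia, increasing,
#'   contiguous.
#' @param values nonnegative per-bin values (fluorescence intensity or
#'   cable-length density, arbitrary units).
#' @return an object of class `laminar_profile`.
#' @export
laminar_profile <- function(bin_edges, values) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE),
            length(values) == length(bin_edges) - 1L,
            all(values >= 0))
  structure(list(bin_edges = as.numeric(bin_edges),
                 values = as.numeric(values)),
            class = "laminar_profile")
}

#' Depth profile of dendritic cable length
#'
#' Distributes each dendritic segment's length across depth bins in
#' proportion to its depth overlap, then normalizes the profile to unit
#' sum.
#'
#' @param tree a `morphology_tree`.
#' @param bin_edges depth bin edges (um from pia) covering the tree.
#' @return a [laminar_profile()].
#' @export
dendritic_density_profile <- function(tree, bin_edges) {
  segs <- dendrite_segments(tree)
  if (nrow(segs) == 0) stop("empty tree")
  nb <- length(bin_edges) - 1L
  vals <- numeric(nb)
  lo <- pmin(segs$d0, segs$d1)
  hi <- pmax(segs$d0, segs$d1)
  for (b in seq_len(nb)) {
    e0 <- bin_edges[b]
    e1 <- bin_edges[b + 1L]
    frac <- ifelse(
      hi == lo,
      as.numeric(lo >= e0 & lo < e1),
      pmax(0, pmin(hi, e1) - pmax(lo, e0)) / (hi - lo)
    )
    vals[b] <- sum(segs$length * frac)
  }
  tot <- sum(vals)
  if (tot == 0) stop("tree has no cable inside the bins")
  laminar_profile(bin_edges, vals / tot)
}

#' Axo-dendritic overlap score
#'
#' Both profiles are normalized to unit sum and the score is the dot
#' product over bins, an overlap measure in the spirit of Peters' rule:
#' 0 when the supports are disjoint, up to the maximum bin product for
#' coincident one-hot profiles. If the bin edges differ, the second profile
#' is resampled onto the first's bin centers by linear interpolation.
#'
#' @param dendrite_profile,axon_profile [laminar_profile()] objects.
#' @return scalar overlap.
#' @export
overlap_dot <- function(dendrite_profile, axon_profile) {
  p1 <- dendrite_profile
  p2 <- axon_profile
  if (!isTRUE(all.equal(p1$bin_edges, p2$bin_edges))) {
    centers1 <- (head(p1$bin_edges, -1) + tail(p1$bin_edges, -1)) / 2
    centers2 <- (head(p2$bin_edges, -1) + tail(p2$bin_edges, -1)) / 2
    if (length(centers2) < 2) stop("cannot resample a single-bin profile")
    v2 <- approx(centers2, p2$values, xout = centers1,
                 yleft = 0, yright = 0)$y
  } else {
    v2 <- p2$values
  }
  v1 <- p1$values / sum(p1$values)
  s2 <- sum(v2)
  if (s2 == 0) return(0)
  v2 <- v2 / s2
  sum(v1 * v2)
}

#' Read/write a laminar profile as 2-column delimited text
#'
#' Columns: depth bin center (um) and value; bin width inferred from the
#' center spacing.
#'
#' @param path file path.
#' @return a [laminar_profile()].
#' @export
read_laminar_profile <- function(path) {
  d <- read.table(path, header = TRUE, comment.char = "#")
  centers <- d[[1]]
  w <- diff(centers)
  stopifnot(length(w) >= 1, all(abs(w - w[1]) < 1e-8))
  edges <- c(centers - w[1] / 2, centers[length(centers)] + w[1] / 2)
  laminar_profile(edges, d[[2]])
}

#' @rdname read_laminar_profile
#' @param profile a [laminar_profile()].
#' @export
write_laminar_profile <- function(profile, path) {
  centers <- (head(profile$bin_edges, -1) + tail(profile$bin_edges, -1)) / 2
  write.table(data.frame(depth_bin_center = centers, value = profile$values),
              path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
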