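#' Parameters for the stochastic morphology generator
#'
#' Two parameter sets emulate the two layer-2/3 pyramidal classes: BT
#' (broad-tufted) trees have two oblique apical trunks and a wide, dense
#' superficial tuft with a modest basal arbor and superficial somata; ST
#' (slender-tufted) trees have a single narrow vertical trunk, a sparse
#' tuft and a disproportionate basal arbor, with deeper somata.
#'
#' @param bt,st named lists overriding individual class parameters (soma
#'   depth, trunk count/angle, tuft levels and branch lengths, basal stem
#'   counts and lengths, all in um or radians).
#' @return an object of class `morpho_sim_params`.
#' @export
morpho_sim_params <- function(bt = list(), st = list()) {
  base_bt <- list(
    soma_depth_mean = 180, soma_depth_sd = 15,
    trunk_angles = c(-0.45, 0.45), tuft_target_depth = c(50, 80),
    tuft_levels = 3, tuft_branch_len = c(120, 110, 90), tuft_spread = 0.9,
    basal_stems = 4, basal_stem_len = 60, basal_levels = 1,
    basal_child_len = 50, basal_spread = 0.9
  )
  base_st <- list(
    soma_depth_mean = 280, soma_depth_sd = 20,
    trunk_angles = 0, tuft_target_depth = c(60, 90),
    tuft_levels = 1, tuft_branch_len = 80, tuft_spread = 0.8,
    basal_stems = 7, basal_stem_len = 70, basal_levels = 2,
    basal_child_len = 55, basal_spread = 0.9
  )
  structure(list(BT = utils::modifyList(base_bt, bt),
                 ST = utils::modifyList(base_st, st)),
            class = "morpho_sim_params")
}

# incremental SWC node accumulator
new_tree_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$rows <- list()
  b$next_id <- 1L
  b
}

add_node <- function(b, type, x, d, radius, parent) {
  id <- b$next_id
  b$rows[[id]] <- data.frame(id = id, type = type, x = x, y = d, z = 0,
                             radius = radius, parent = parent)
  b$next_id <- id + 1L
  id
}

# Grow a wiggly branch from (x, d) under `parent_id`. Direction per step:
# dx = step*sin(angle), d_depth = -step*cos(angle), so angle 0 points at the
# pia and pi points down. Depth is kept >= 2 um by deflecting to horizontal.
grow_branch <- function(b, parent_id, x, d, angle, length, type,
                        step = 10, wiggle = 0.12, radius = 0.7) {
  n_steps <- max(1L, round(length / step))
  for (i in seq_len(n_steps)) {
    angle <- angle + rnorm(1, 0, wiggle)
    nx <- x + step * sin(angle)
    nd <- d - step * cos(angle)
    if (nd < 2) {
      nd <- 2
      angle <- sign(angle + 1e-9) * pi / 2
    }
    parent_id <- add_node(b, type, nx, nd, radius, parent_id)
    x <- nx
    d <- nd
  }
  list(tip = parent_id, x = x, d = d, angle = angle)
}

grow_tuft <- function(b, tip, level, branch_len, spread) {
  if (level == 0) return(invisible())
  len <- branch_len[min(length(branch_len), length(branch_len) - level + 1)]
  node <- b$rows[[tip]]
  for (s in c(-1, 1)) {
    ang <- s * runif(1, spread * 0.5, spread * 1.4)
    g <- grow_branch(b, tip, node$x, node$y, ang, len * runif(1, 0.85, 1.15),
                     type = 4)
    grow_tuft(b, g$tip, level - 1, branch_len, spread)
  }
}

grow_basal <- function(b, tip, level, child_len, spread) {
  if (level == 0) return(invisible())
  node <- b$rows[[tip]]
  for (s in c(-1, 1)) {
    ang <- pi + s * runif(1, 0.3, spread)
    g <- grow_branch(b, tip, node$x, node$y, ang,
                     child_len * runif(1, 0.85, 1.15), type = 3)
    grow_basal(b, g$tip, level - 1, child_len, spread)
  }
}

simulate_one_tree <- function(p) {
  b <- new_tree_builder()
  soma_d <- max(60, rnorm(1, p$soma_depth_mean, p$soma_depth_sd))
  soma <- add_node(b, 1, 0, soma_d, 8, -1)
  # apical: one or two trunks climbing toward the tuft target depth
  for (a in p$trunk_angles) {
    target <- runif(1, p$tuft_target_depth[1], p$tuft_target_depth[2])
    ang <- a + rnorm(1, 0, 0.05)
    len <- max(20, (soma_d - 10 - target) / max(cos(ang), 0.5))
    g <- grow_branch(b, soma, 0, soma_d - 10, ang, len, type = 4,
                     wiggle = 0.06)
    grow_tuft(b, g$tip, p$tuft_levels, p$tuft_branch_len, p$tuft_spread)
  }
  # basal arbor below the soma
  for (k in seq_len(p$basal_stems)) {
    ang <- pi + runif(1, -p$basal_spread, p$basal_spread)
    g <- grow_branch(b, soma, 0, soma_d + 10, ang,
                     p$basal_stem_len * runif(1, 0.85, 1.15), type = 3)
    grow_basal(b, g$tip, p$basal_levels, p$basal_child_len, p$basal_spread)
  }
  do.call(rbind, b$rows)
}

#' Simulate BT-like and ST-like dendritic reconstructions
#'
#' @param n_bt,n_st number of trees of each class.
#' @param params a [morpho_sim_params()].
#' @param seed integer seed; fixed seed gives identical SWC output.
#' @return list with `trees` (list of `morphology_tree`, labels set) and
#'   `truth` (data frame `id`, `label`, `soma_depth`).
#' @export
simulate_morphologies <- function(n_bt, n_st, params = morpho_sim_params(),
                                  seed = 1L) {
  stopifnot(inherits(params, "morpho_sim_params"), n_bt + n_st >= 1)
  labels <- c(rep("BT", n_bt), rep("ST", n_st))
  with_seed(seed, {
    trees <- lapply(seq_along(labels), function(i) {
      nodes <- simulate_one_tree(params[[labels[i]]])
      morphology_tree(nodes, label = labels[i])
    })
    truth <- data.frame(
      id = seq_along(labels), label = labels,
      soma_depth = vapply(trees, function(tr) tr$soma[["depth"]], 0)
    )
    list(trees = trees, truth = truth)
  })
}

#' Simulate laminar afferent-fluorescence profiles
#'
#' Depth templates for the four long-range afferent systems: POm
#' (higher-order thalamus) peaks in L1 with a second deep peak at L5a; VPM
#' (first-order thalamus) peaks at L4 depth; M1 and S2 corticocortical
#' projections peak superficially. A small multiplicative noise term makes
#' repeated draws distinct; profiles are nonnegative and normalized to
#' unit sum.
#'
#' @param afferent one of `"POm"`, `"VPM"`, `"M1"`, `"S2"`.
#' @param bin_edges depth bin edges in um from the pia, increasing.
#' @param seed integer seed.
#' @return a [laminar_profile()].
#' @export
simulate_laminar_profile <- function(afferent, bin_edges = seq(0, 800, 25),
                                     seed = 1L) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE), bin_edges[1] >= 0)
  centers <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  g <- function(mu, s) exp(-(centers - mu)^2 / (2 * s^2))
  template <- switch(
    afferent,
    POm = 1.0 * g(40, 45) + 0.6 * g(700, 60),
    VPM = 1.0 * g(420, 60) + 0.25 * g(80, 50),
    M1  = 1.0 * g(50, 50) + 0.25 * g(600, 100),
    S2  = 1.0 * g(60, 50) + 0.3 * g(350, 80),
    stop("unknown afferent label: ", afferent)
  )
  vals <- with_seed(seed, template * rlnorm(length(template), 0, 0.05))
  laminar_profile(bin_edges, vals / sum(vals))
}
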