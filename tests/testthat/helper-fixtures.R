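# Hand-built SWC node tables for analytic morphology checks.

# soma plus a single chain of dendritic nodes at the given depths;
# type inferred from the first node's position relative to the soma.
chain_tree <- function(soma_depth, node_depths, x = 0) {
  type <- if (node_depths[1] < soma_depth) 4 else 3
  n <- length(node_depths)
  nodes <- data.frame(
    id = seq_len(n + 1),
    type = c(1, rep(type, n)),
    x = c(x, rep(x, n)),
    y = c(soma_depth, node_depths),
    z = 0,
    radius = c(8, rep(0.5, n)),
    parent = c(-1, seq_len(n))
  )
  morphology_tree(nodes)
}

# one-hot laminar profile over unit bins
onehot_profile <- function(n_bins, hot, width = 50) {
  v <- numeric(n_bins)
  v[hot] <- 1
  laminar_profile(seq(0, n_bins * width, width), v)
}

# match detected events to ground-truth plateaus by interval overlap
match_events <- function(detected, truth) {
  if (nrow(detected) == 0 || nrow(truth) == 0) {
    return(list(tp = 0, matched_truth = 0,
                duration_errors = numeric(0)))
  }
  used <- rep(FALSE, nrow(truth))
  dur_err <- numeric(0)
  tp <- 0
  for (i in seq_len(nrow(detected))) {
    d0 <- detected$onset[i]
    d1 <- d0 + detected$duration[i]
    hit <- which(!used & truth$onset < d1 & (truth$onset + truth$duration) > d0)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      tp <- tp + 1
      dur_err <- c(dur_err, abs(detected$duration[i] - truth$duration[hit[1]]))
    }
  }
  list(tp = tp, matched_truth = sum(used), duration_errors = dur_err)
}
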