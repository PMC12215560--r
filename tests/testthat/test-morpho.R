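test_that("apical/basal split follows the soma-centroid origin rule", {
  # stem originating 1 um above the centroid is apical
  just_above <- chain_tree(100, c(99, 89, 79))
  parts <- split_apical_basal(just_above)
  expect_length(parts$apical, 3)
  expect_length(parts$basal, 0)

  # all stems below -> basal set is everything, apical empty
  below <- chain_tree(100, c(101, 111, 121))
  parts <- split_apical_basal(below)
  expect_length(parts$apical, 0)
  expect_length(parts$basal, 3)
})

test_that("split partitions the dendrites with no loss and no overlap", {
  sim <- simulate_morphologies(3, 3, seed = 13)
  for (tree in sim$trees) {
    parts <- split_apical_basal(tree)
    dend <- tree$nodes$id[tree$nodes$type != 1]
    expect_setequal(c(parts$apical, parts$basal), dend)
    expect_length(intersect(parts$apical, parts$basal), 0)
  }
})

test_that("features match analytic values on a straight cable", {
  # unbranched 100-um vertical apical cable from the pia down to the soma
  tree <- chain_tree(100, seq(90, 0, by = -10))
  f <- compute_features(tree)
  expect_equal(f$apical_length, 100)
  expect_equal(f$apical_branches, 1)
  expect_equal(f$basal_length, 0)
  expect_equal(f$soma_depth, 100)
  # vertical cable has zero lateral span, density falls back to 0
  expect_equal(f$span_200, 0)
  expect_equal(f$density_200, 0)
})

test_that("features are invariant under lateral translation and reflection", {
  sim <- simulate_morphologies(1, 1, seed = 17)
  for (tree in sim$trees) {
    f0 <- compute_features(tree)
    shifted <- tree
    shifted$nodes$x <- shifted$nodes$x + 137
    shifted$soma[["x"]] <- shifted$soma[["x"]] + 137
    expect_equal(compute_features(morphology_tree(shifted$nodes)), f0)
    mirrored <- tree
    mirrored$nodes$x <- -mirrored$nodes$x
    expect_equal(compute_features(morphology_tree(mirrored$nodes)), f0)
  }
})

test_that("BT population is denser superficially than ST", {
  sim <- simulate_morphologies(8, 8, seed = 19)
  feats <- do.call(rbind, lapply(sim$trees, compute_features))
  expect_gt(mean(feats$density_200[sim$truth$label == "BT"]),
            mean(feats$density_200[sim$truth$label == "ST"]))
})

test_that("two-means clustering recovers the two morphological classes", {
  sim <- simulate_morphologies(20, 20, seed = 23)
  feats <- do.call(rbind, lapply(sim$trees, compute_features))
  cl <- cluster_bt_st(feats, seed = 1)
  expect_gte(mean(cl$labels == sim$truth$label), 0.9)
  # labels are assigned by the density rule, not the k-means index
  expect_gt(mean(feats$density_200[cl$labels == "BT"]),
            mean(feats$density_200[cl$labels == "ST"]))
  expect_true(all(c("BT", "ST") %in% rownames(cl$centers)))
  expect_named(cl$ellipses, c("BT", "ST"))

  # duplicated identical points in two groups 10 SD apart: perfect recovery
  pts <- data.frame(span_200 = rep(c(100, 400), each = 10),
                    density_200 = rep(c(0.01, 0.03), each = 10))
  cl2 <- cluster_bt_st(pts, seed = 1)
  expect_identical(cl2$labels, rep(c("ST", "BT"), each = 10))
  expect_error(cluster_bt_st(data.frame(span_200 = rep(1, 5),
                                        density_200 = rep(2, 5))),
               "distinct")
})

test_that("dendritic density profile distributes cable length across bins", {
  tree <- chain_tree(110, seq(100, 0, by = -10))
  # drop the soma-to-stem segment contribution by starting the chain at the
  # soma depth: use a cable spanning exactly 0-100 um
  tree2 <- chain_tree(100, seq(90, 0, by = -10))
  prof <- dendritic_density_profile(tree2, seq(0, 300, 50))
  expect_equal(prof$values, c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(sum(prof$values), 1)

  sim <- simulate_morphologies(5, 5, seed = 29)
  edges <- seq(0, 800, 25)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  com <- vapply(sim$trees, function(tr) {
    sum(centers * dendritic_density_profile(tr, edges)$values)
  }, 0)
  expect_gt(mean(com[sim$truth$label == "ST"]),
            mean(com[sim$truth$label == "BT"]))
})

test_that("overlap score is a bounded symmetric dot product", {
  a <- onehot_profile(8, 1)
  b <- onehot_profile(8, 5)
  expect_equal(overlap_dot(a, b), 0)
  expect_equal(overlap_dot(a, a), 1)
  p <- laminar_profile(seq(0, 400, 50), c(1, 2, 3, 2, 1, 0, 0, 1))
  q <- laminar_profile(seq(0, 400, 50), c(0, 1, 1, 4, 2, 2, 0, 0))
  expect_equal(overlap_dot(p, q), overlap_dot(q, p))
  expect_gte(overlap_dot(p, q), 0)
  expect_lte(overlap_dot(p, q), 1)
  # resampling path: same shape on finer bins gives a similar score
  q_fine <- laminar_profile(seq(0, 400, 25),
                            rep(c(0, 1, 1, 4, 2, 2, 0, 0), each = 2))
  expect_lt(abs(overlap_dot(p, q_fine) - overlap_dot(p, q)), 0.02)
})

test_that("BT trees overlap POm more than ST trees do, and vice versa for VPM", {
  sim <- simulate_morphologies(6, 6, seed = 31)
  edges <- seq(0, 800, 25)
  pom <- simulate_laminar_profile("POm", edges, seed = 1)
  vpm <- simulate_laminar_profile("VPM", edges, seed = 1)
  dp <- lapply(sim$trees, dendritic_density_profile, bin_edges = edges)
  ov_pom <- vapply(dp, overlap_dot, 0, axon_profile = pom)
  ov_vpm <- vapply(dp, overlap_dot, 0, axon_profile = vpm)
  bt <- sim$truth$label == "BT"
  expect_gt(mean(ov_pom[bt]), mean(ov_pom[!bt]))
  expect_gt(mean(ov_vpm[!bt]), mean(ov_vpm[bt]))
})

test_that("SWC and laminar-profile files round-trip", {
  sim <- simulate_morphologies(1, 0, seed = 37)
  f <- tempfile(fileext = ".swc")
  write_swc(sim$trees[[1]], f)
  back <- read_swc(f)
  expect_equal(back$nodes$y, sim$trees[[1]]$nodes$y, tolerance = 1e-6)
  expect_equal(compute_features(back), compute_features(sim$trees[[1]]),
               tolerance = 1e-6)

  prof <- simulate_laminar_profile("M1", seq(0, 800, 25), seed = 3)
  fp <- tempfile(fileext = ".tsv")
  write_laminar_profile(prof, fp)
  back_p <- read_laminar_profile(fp)
  expect_equal(back_p$values, prof$values, tolerance = 1e-6)
  expect_equal(back_p$bin_edges, prof$bin_edges, tolerance = 1e-6)
})
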