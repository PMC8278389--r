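test_that("a cluster of identical frames has single-bin support per angle", {
  ang <- matrix(rep(c(0.3, -2.0), each = 20), 20, 2)
  traj <- dihedral_trajectory(ang)
  fp <- build_fingerprints(traj, rep(1L, 20), n_bins = 36)
  for (a in 1:2) {
    expect_equal(sum(fp$clusters[[1]]$support[, a]), 1L)
    expect_equal(sum(fp$clusters[[1]]$probs[, a]), 1)
  }
})

test_that("disjoint planted ranges give disjoint supports", {
  set.seed(41)
  a1 <- rvonmises(300, -2, 60); a2 <- rvonmises(300, 2, 60)
  traj <- dihedral_trajectory(matrix(c(a1, a2), ncol = 1))
  fp <- build_fingerprints(traj, rep(1:2, each = 300), n_bins = 36)
  s1 <- fp$clusters[[1]]$support[, 1]
  s2 <- fp$clusters[[2]]$support[, 1]
  expect_false(any(s1 & s2))
})

test_that("full fingerprint sets count clusters x angles distributions", {
  w <- synthetic_world()
  s <- sample_unbiased(w, 2400, seed = 42)
  fp <- build_fingerprints(s$traj, s$truth, n_bins = 36)
  expect_length(fp$clusters, 12L)
  expect_equal(sum(vapply(fp$clusters, function(cl) ncol(cl$probs),
                          integer(1))), 72L)
  expect_error(build_fingerprints(s$traj, rep(0L, 2400)), "empty cluster")
})

test_that("probabilities normalize per angle and support tracks them", {
  w <- tiny_world(K = 3, M = 2)
  s <- sample_unbiased(w, 500, seed = 43)
  fp <- build_fingerprints(s$traj, s$truth, n_bins = 24)
  for (cl in fp$clusters) {
    expect_equal(unname(colSums(cl$probs)), c(1, 1), tolerance = 1e-9)
    expect_identical(cl$support, cl$probs > 0)
  }
})

test_that("classification scores count in-support angles; full score assigns", {
  w <- tiny_world(K = 3, M = 2, kappa = 60)
  s <- sample_unbiased(w, 600, seed = 44)
  fp <- build_fingerprints(s$traj, s$truth, n_bins = 24)
  # a frame at a cluster mode matches with full score
  res <- classify_frame(w$modes[2, ], fp)
  expect_equal(res$label, 2L)
  expect_equal(unname(res$scores[2]), 2L)
  # one angle outside every support -> unclassified, score < N_CV
  probe <- w$modes[2, ]
  supports <- sapply(fp$clusters, function(cl) cl$support[, 1])
  empty_bin <- which(rowSums(supports) == 0)[1]
  probe[1] <- fp$bin_edges[empty_bin] + pi / 24 / 2
  res2 <- classify_frame(probe, fp)
  expect_equal(res2$label, 0L)
  expect_true(all(res2$scores < 2))
  expect_error(classify_frame(0.1, fp), "1 angles")
})

test_that("training frames all classify (self-consistency of supports)", {
  w <- tiny_world(K = 3, M = 2)
  s <- sample_unbiased(w, 900, seed = 45)
  fp <- build_fingerprints(s$traj, s$truth, n_bins = 24)
  cls <- classify_trajectory(s$traj, fp)
  expect_equal(cls$fraction_classified, 1)
  # every assigned frame carries a full score for its own label
  idx <- cbind(seq_along(cls$labels), cls$labels)
  expect_true(all(cls$scores[idx] == 2L))
})

test_that("overlap ties resolve to the cluster with higher probability mass", {
  # two clusters sharing the identical second angle; first angles disjoint
  # except a deliberate overlap bin where cluster 1 has far more mass
  n_bins <- 12
  h <- 2 * pi / n_bins
  bin_center <- function(k) -pi + (k - 0.5) * h
  a1 <- c(rep(bin_center(3), 90), rep(bin_center(4), 10))
  a2 <- c(rep(bin_center(4), 2), rep(bin_center(5), 98))
  traj <- dihedral_trajectory(cbind(c(a1, a2), rep(bin_center(8), 200)))
  fp <- build_fingerprints(traj, rep(1:2, each = 100), n_bins = n_bins)
  probe <- c(bin_center(4), bin_center(8))
  res <- classify_frame(probe, fp)                 # both reach full score
  expect_equal(res$label, 1L)                      # 0.10 > 0.02
  res_first <- classify_frame(probe, fp, tie_break = "first")
  expect_equal(res_first$label, 1L)
})

test_that("lowering support_min_count never lowers the classified fraction", {
  w <- tiny_world(K = 3, M = 2)
  s <- sample_unbiased(w, 500, seed = 46)
  s2 <- sample_unbiased(w, 500, seed = 47)
  fr <- vapply(c(5, 2, 1), function(mc) {
    fp <- build_fingerprints(s$traj, s$truth, n_bins = 24,
                             support_min_count = mc)
    classify_trajectory(s2$traj, fp)$fraction_classified
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("classification is invariant under rigid 2*pi shifts", {
  w <- tiny_world(K = 3, M = 2)
  s <- sample_unbiased(w, 400, seed = 48)
  fp <- build_fingerprints(s$traj, s$truth, n_bins = 24)
  s2 <- sample_unbiased(w, 200, seed = 49)
  shifted <- dihedral_trajectory(s2$traj$angles + 2 * pi)
  expect_identical(classify_trajectory(shifted, fp)$labels,
                   classify_trajectory(s2$traj, fp)$labels)
})

test_that("core-only fingerprints are narrower than core+halo", {
  w <- tiny_world(K = 2, M = 2, kappa = 10)
  s <- sample_unbiased(w, 600, seed = 50)
  D <- distance_matrix(s$traj, c(1, 1))
  model <- density_peaks(D, k = 2)
  fp_all <- build_fingerprints(s$traj, model$labels, n_bins = 24)
  fp_core <- build_fingerprints(s$traj, model$labels, n_bins = 24,
                                frames = "core", is_core = model$is_core)
  supp <- function(fp) sum(vapply(fp$clusters,
                                  function(cl) sum(cl$support), integer(1)))
  expect_lte(supp(fp_core), supp(fp_all))
  expect_error(build_fingerprints(s$traj, model$labels, frames = "core"),
               "is_core")
})
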