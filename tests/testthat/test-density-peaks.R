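# small helper: distance_matrix object from an explicit matrix
as_dm <- function(m) torsmap:::new_distance_matrix(as.matrix(m))

test_that("density counts neighbors with a strict cutoff", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  expect_equal(compute_density(as_dm(m), 1.5), c(2L, 2L, 2L))
  # cutoff below every distance: empty neighborhoods
  expect_equal(compute_density(as_dm(m), 0.5), c(0L, 0L, 0L))
  # pair exactly at the cutoff is NOT counted
  expect_equal(compute_density(as_dm(m), 1), c(0L, 0L, 0L))
  expect_error(compute_density(as_dm(m), 0), "positive")
})

test_that("delta: increasing densities along a line give next-point distances", {
  # points on a line at 0, 1, 3, 6 with rho strictly increasing
  pos <- c(0, 1, 3, 6)
  m <- abs(outer(pos, pos, "-"))
  rho <- c(1L, 2L, 3L, 4L)
  dl <- compute_delta(as_dm(m), rho)
  expect_equal(dl$delta[1:3], c(1, 2, 3))      # next denser point
  expect_equal(dl$nearest_higher[1:3], c(2L, 3L, 4L))
  expect_equal(dl$delta[4], 6)                 # global max: farthest point
  expect_true(is.na(dl$nearest_higher[4]))
})

test_that("density ties break by index: exactly one pseudo-maximum", {
  m <- matrix(2, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 1
  rho <- rep(0L, 4)
  dl <- compute_delta(as_dm(m), rho)
  expect_true(is.na(dl$nearest_higher[1]))     # lowest index wins
  expect_equal(sum(is.na(dl$nearest_higher)), 1L)
  expect_true(all(is.finite(dl$delta)))
  expect_equal(dl$delta[2], 1)                 # to point 1
})

test_that("density and delta match brute force on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    ang <- matrix(runif(50 * 3, -pi, pi), 50, 3)
    D <- distance_matrix(dihedral_trajectory(ang), runif(3, 0.5, 3))
    d_c <- stats::quantile(D$values[upper.tri(D$values)], runif(1, 0.02, 0.3))
    rho <- compute_density(D, d_c)
    expect_identical(rho, bf_density(D$values, d_c))
    dl <- compute_delta(D, rho)
    expect_equal(dl$delta, bf_delta(D$values, rho), tolerance = 0)
  }
})

test_that("cutoff tuning hits the neighbor-count window", {
  set.seed(32)
  ang <- matrix(runif(100 * 2, -pi, pi), 100, 2)
  D <- distance_matrix(dihedral_trajectory(ang), c(1, 1))
  d_c <- tune_cutoff(D, 0.02)
  expect_gte(mean(compute_density(D, d_c)), 1.5)
  expect_lte(mean(compute_density(D, d_c)), 2.5)
  # near-1 fraction: cutoff at or beyond the maximum distance
  d_all <- tune_cutoff(D, 0.995)
  expect_gte(d_all, max(D$values))
  # equidistant simplex: step function has no usable value at fraction 0.5
  m <- matrix(1, 12, 12); diag(m) <- 0
  expect_error(tune_cutoff(as_dm(m), 0.5), "tuning failed|degenerate")
})

test_that("center selection: thresholds, top-k, manual, and errors", {
  rho <- c(10L, 9L, 2L, 1L, 8L)
  delta <- c(5, 4, 0.1, 0.2, 3)
  expect_equal(select_centers(rho, delta, d_c = 1, rho_min = 5, delta_min = 2),
               c(1L, 2L, 5L))
  expect_equal(select_centers(rho, delta, d_c = 1, k = 1), 1L)
  expect_equal(select_centers(rho, delta, d_c = 1, mode = "manual",
                              centers = c(5, 1)), c(1L, 5L))
  expect_error(select_centers(rho, delta, d_c = 1, rho_min = 99,
                              delta_min = 99), "no cluster centers")
  expect_error(select_centers(rho, delta, d_c = 1, mode = "manual",
                              centers = integer(0)), "non-empty")
})

test_that("assignment descends the density gradient; halo by center cutoff", {
  # chain: dense center (1), then 2 and 3 strung outward; 3 is beyond d_c
  # from the center but chained through its denser neighbor 2
  pos <- c(0, 0.8, 1.6, 10, 10.8)
  m <- abs(outer(pos, pos, "-"))
  d_c <- 1
  rho <- c(5L, 3L, 2L, 4L, 1L)
  dl <- compute_delta(as_dm(m), rho)
  ah <- assign_and_halo(as_dm(m), rho, dl$nearest_higher,
                        centers = c(1L, 4L), d_c = d_c)
  expect_equal(ah$labels, c(1L, 1L, 1L, 2L, 2L))
  expect_true(ah$is_core[1])                   # a center is its own core
  expect_true(ah$is_core[2])
  expect_false(ah$is_core[3])                  # assigned but halo
  expect_true(all(ah$is_core[4:5]))
})

test_that("labels follow the nearest-denser descent and centers rank by rho", {
  set.seed(33)
  w <- tiny_world(K = 3, M = 2)
  s <- sample_unbiased(w, 600, seed = 33)
  D <- distance_matrix(s$traj, c(1, 1))
  model <- density_peaks(D, k = 3)
  expect_setequal(unique(model$labels), 1:3)
  # descent property: every non-center inherits its nearest_higher's label
  noncenter <- setdiff(seq_along(model$labels), model$centers)
  expect_equal(model$labels[noncenter],
               model$labels[model$nearest_higher[noncenter]])
  # centers labeled 1..K by decreasing density
  ctr <- model$centers[order(model$labels[model$centers])]
  expect_true(all(diff(model$rho[ctr]) <= 0))
  # planted partition recovered exactly
  expect_equal(adjusted_rand_index(model$labels, s$truth), 1)
})

test_that("frame permutation permutes the clustering consistently", {
  set.seed(34)
  w <- tiny_world(K = 2, M = 2)
  s <- sample_unbiased(w, 200, seed = 34)
  D1 <- distance_matrix(s$traj, c(1, 1))
  model1 <- density_peaks(D1, k = 2)
  perm <- sample(200)
  traj2 <- subset_frames(s$traj, perm)
  D2 <- distance_matrix(traj2, c(1, 1))
  model2 <- density_peaks(D2, k = 2)
  expect_identical(model2$rho, model1$rho[perm])
  expect_equal(adjusted_rand_index(model2$labels, model1$labels[perm]), 1)
})

test_that("border-density halo marks low-density boundary points", {
  set.seed(35)
  w <- tiny_world(K = 2, M = 2, kappa = 1.5)   # overlapping basins
  s <- sample_unbiased(w, 400, seed = 35)
  D <- distance_matrix(s$traj, c(1, 1))
  m1 <- density_peaks(D, k = 2, halo = "center-cutoff")
  m2 <- density_peaks(D, k = 2, halo = "border")
  expect_identical(m1$labels, m2$labels)     # halo rule changes cores only
  expect_true(any(!m2$is_core))
  expect_true(all(m2$is_core[m2$centers]))
})
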