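test_that("uniform circular samples give a flat profile", {
  set.seed(11)
  traj <- dihedral_trajectory(matrix(runif(1e6, -pi, pi), ncol = 1))
  p <- free_energy_profile(traj, 1, n_bins = 36)
  # sampling-noise bound on ln p: sd ~ sqrt(1/n_k), n_k ~ 27800
  expect_true(all(abs(p$free_energy) < 0.05))
  expect_identical(min(p$free_energy), 0)
})

test_that("symmetric two-mode mixture gives two near-equal minima", {
  set.seed(12)
  n <- 2e5
  x <- c(rvonmises(n / 2, -pi / 2, 8), rvonmises(n / 2, pi / 2, 8))
  traj <- dihedral_trajectory(matrix(x, ncol = 1))
  p <- free_energy_profile(traj, 1, n_bins = 36)
  expect_length(p$minima_idx, 2L)
  expect_lt(abs(diff(p$free_energy[p$minima_idx])), 0.1)
  # both crossings equivalent by symmetry; barrier approximates the
  # analytic -log density ratio between antimode and mode
  f_true <- -log(dvonmises(0, pi / 2, 8) + dvonmises(0, -pi / 2, 8)) +
    log(dvonmises(pi / 2, pi / 2, 8) + dvonmises(pi / 2, -pi / 2, 8))
  expect_equal(p$lowest_barrier, f_true, tolerance = 0.15)
})

test_that("weighted profiles: uniform weights match unweighted, and a
           known reweighting is honored", {
  set.seed(13)
  x <- rvonmises(5e3, 0.3, 2)
  traj <- dihedral_trajectory(matrix(x, ncol = 1))
  p0 <- free_energy_profile(traj, 1, n_bins = 24)
  p1 <- free_energy_profile(traj, 1, n_bins = 24,
                            frame_weights = rep(2.5, 5e3))
  expect_equal(p1$free_energy, p0$free_energy, tolerance = 1e-12)
  expect_error(free_energy_profile(traj, 1, frame_weights = rep(0, 5e3)),
               "not all zero")
  expect_error(free_energy_profile(traj, 1, n_bins = 4), "at least 8")
})

test_that("degenerate single-bin input warns and flags unimodal", {
  traj <- dihedral_trajectory(matrix(rep(0.7, 50), ncol = 1))
  expect_warning(p <- free_energy_profile(traj, 1, n_bins = 36),
                 "degenerate")
  expect_true(p$unimodal)
  expect_error(lowest_rotational_barrier(p), "unimodal")
})

test_that("directed barrier: worked example and symmetric double well", {
  # minima at F = {0, 1}, maxima at {6, 7}: cheapest crossing is from
  # the F=1 minimum over the F=6 maximum -> barrier 5
  f <- rep(6, 36)
  f[5] <- 0; f[23] <- 1           # minima
  f[14] <- 6; f[32] <- 7          # maxima (segments between are lower)
  f[6:13] <- 3; f[15:22] <- 3; f[24:31] <- 4; f[c(33:36, 1:4)] <- 4
  f[14] <- 6; f[32] <- 7
  fx <- profile_fixture(f)
  p <- free_energy_profile(fx$traj, 1, n_bins = fx$n_bins,
                           frame_weights = fx$weights, smooth_window = 1)
  expect_equal(p$lowest_barrier, 5, tolerance = 1e-9)

  # symmetric double well: both minima at 0, single barrier height B
  theta <- seq(-pi, pi, length.out = 73)[-1] - pi / 72
  f2 <- 3.5 * (1 - cos(2 * theta)) / 2
  fx2 <- profile_fixture(f2)
  p2 <- free_energy_profile(fx2$traj, 1, n_bins = 72,
                            frame_weights = fx2$weights, smooth_window = 1)
  # bin centers straddle the analytic extrema: agreement to the bin width
  expect_equal(p2$lowest_barrier, 3.5, tolerance = 0.02)
  expect_length(p2$minima_idx, 2L)
  expect_length(p2$maxima_idx, 2L)
})

test_that("barrier extraction matches brute-force enumeration on random
           periodic profiles", {
  set.seed(14)
  for (rep in 1:40) {
    f <- random_periodic_profile(n_bins = 48)
    fx <- profile_fixture(f)
    p <- free_energy_profile(fx$traj, 1, n_bins = 48,
                             frame_weights = fx$weights, smooth_window = 1,
                             min_barrier = 0)
    if (p$unimodal) {
      prv <- c(48, 1:47); nxt <- c(2:48, 1)
      expect_lt(sum(f < f[prv] & f < f[nxt]), 2)
    } else {
      expect_equal(p$lowest_barrier, bf_lowest_barrier(f), tolerance = 1e-9)
    }
  }
})

test_that("minima and maxima alternate on the periodic grid", {
  set.seed(15)
  for (rep in 1:10) {
    f <- random_periodic_profile(n_bins = 40)
    fx <- profile_fixture(f)
    p <- free_energy_profile(fx$traj, 1, n_bins = 40,
                             frame_weights = fx$weights, smooth_window = 1)
    k <- length(p$minima_idx)
    if (k < 2) next
    expect_length(p$maxima_idx, k)
    pos <- sort(c(p$minima_idx, p$maxima_idx))
    kinds <- ifelse(pos %in% p$minima_idx, "min", "max")
    expect_true(all(kinds != c(kinds[-1], kinds[1])))
  }
})

test_that("normalized weights reproduce the reference barrier table", {
  w <- compute_weights(c(tauA = 6, tauB = 1.5, tauC = 2,
                         tauD = 1.2, tauE = 2.5, tauF = 4))
  expect_equal(unname(w$rounded), c(5, 1.3, 1.7, 1, 2.1, 3.3))
  expect_equal(min(w$normalized), 1)
  expect_equal(unname(w$normalized[4]), 1)
})

test_that("weights are scale invariant and validate inputs", {
  b <- c(2.4, 1.2, 3.7)
  expect_equal(compute_weights(b * 7)$normalized, compute_weights(b)$normalized)
  expect_equal(unname(compute_weights(c(2.4, 1.2))$normalized), c(2, 1))
  expect_equal(unname(compute_weights(c(3, 3, 3))$rounded), c(1, 1, 1))
  expect_error(compute_weights(c(1, 0)), "positive")
  expect_error(compute_weights(c(1, -2)), "positive")
  # rounding is half away from zero: 1.25 -> 1.3, 2.0833 -> 2.1
  expect_equal(unname(compute_weights(c(1.5, 1.2))$rounded[1]), 1.3)
})

test_that("sub-kT dimples are merged by persistence pruning", {
  theta <- seq(-pi, pi, length.out = 37)[-1] - pi / 36
  f <- 3 * (1 - cos(2 * theta)) / 2          # double well, barrier 3
  f[22] <- f[22] - 0.55                      # shallow dimple on a slope
  fx <- profile_fixture(f)
  p <- free_energy_profile(fx$traj, 1, n_bins = 36,
                           frame_weights = fx$weights, smooth_window = 1)
  expect_length(p$minima_idx, 2L)            # dimple not a basin
  expect_equal(p$lowest_barrier, 3, tolerance = 0.05)
  p0 <- free_energy_profile(fx$traj, 1, n_bins = 36,
                            frame_weights = fx$weights, smooth_window = 1,
                            min_barrier = 0)
  expect_length(p0$minima_idx, 3L)           # raw minima retained
  expect_equal(p0$lowest_barrier, bf_lowest_barrier(f - min(f)),
               tolerance = 1e-9)
  expect_lt(p0$lowest_barrier, 1)
})
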