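kT300 <- 0.0083144621 * 300

test_that("bias reweighting: max-bias frame gets weight 1, kT drop gives 1/e", {
  b <- c(0, 5, 10, 10 - kT300)
  fw <- reweight(b, 300)
  expect_equal(max(fw$W), 1)
  expect_equal(fw$W[3], 1)
  expect_equal(fw$W[4], exp(-1))
  expect_equal(fw$W[1], exp(-10 / kT300))
  # unbiased limit: zero bias everywhere -> all weights 1
  expect_equal(reweight(rep(0, 5), 300)$W, rep(1, 5))
  expect_error(reweight(numeric(0)), "empty")
  expect_error(reweight(c(1, NA)), "finite")
  # optional well-tempered prefactor gamma/(gamma-1) sharpens weights
  fw2 <- reweight(b, 300, well_tempered_factor = 15 / 0.3)
  expect_lt(fw2$W[1], fw$W[1])
})

test_that("cluster populations: uniform weights, unclassified mass, errors", {
  lab <- c(1, 1, 2, 2, 0, 1)
  pops <- cluster_populations(lab)
  expect_equal(unname(pops$P), c(3, 2) / 6)
  expect_equal(pops$unclassified, 1 / 6)
  expect_equal(sum(pops$P) + pops$unclassified, 1)
  pops2 <- cluster_populations(c(1, 1, 2, 2))
  expect_equal(unname(pops2$P), c(0.5, 0.5))
  expect_equal(cluster_populations(rep(0, 4))$unclassified, 1)
  expect_error(cluster_populations(c(1, 2), weights = c(0, 0)),
               "not all zero")
})

test_that("free-energy differences follow -kT log(Pi/Pj)", {
  expect_equal(delta_g(0.3, 0.3), 0)
  expect_equal(delta_g(exp(1) * 0.1, 0.1, 300), -kT300)
  expect_equal(delta_g(exp(1) * 0.1, 0.1, 300), -2.4943, tolerance = 1e-4)
  # antisymmetry and additivity
  expect_equal(delta_g(0.2, 0.5), -delta_g(0.5, 0.2))
  expect_equal(delta_g(0.2, 0.7),
               delta_g(0.2, 0.4) + delta_g(0.4, 0.7))
  # zero probability: infinite difference, not an exception
  expect_equal(delta_g(0, 0.5), Inf)
  expect_equal(delta_g(0.5, 0), -Inf)
})

test_that("conditional energy averages: constants, reductions, recovery", {
  w <- tiny_world(K = 2, M = 2)
  s <- sample_unbiased(w, 400, seed = 61)
  traj <- s$traj
  traj$energy_solute <- rep(7.5, 400)
  traj$energy_solute_solvent <- rnorm(400, 2, 1)
  ce <- conditional_energy_average(traj, s$truth, cluster = 1,
                                   component = "solute")
  expect_equal(ce$mean, 7.5)
  expect_equal(ce$se, 0)
  # equal weights match the unweighted mean
  ce1 <- conditional_energy_average(traj, s$truth, weights = rep(2, 400),
                                    cluster = 2, component = "solute_solvent")
  expect_equal(ce1$mean, mean(traj$energy_solute_solvent[s$truth == 2]))
  expect_error(conditional_energy_average(traj, s$truth, cluster = 99),
               "empty")
  expect_error(conditional_energy_average(s$traj, s$truth, cluster = 1),
               "no solute energy column")
  # bootstrap SE is seeded and reproducible
  ce2 <- conditional_energy_average(traj, s$truth, cluster = 2,
                                    component = "solute_solvent", seed = 5)
  ce3 <- conditional_energy_average(traj, s$truth, cluster = 2,
                                    component = "solute_solvent", seed = 5)
  expect_identical(ce2$se, ce3$se)
})

test_that("planted cluster energy means are recovered within 2 SE", {
  w <- tiny_world(K = 2, M = 2)
  w$energy_solute <- c(0, 3); w$energy_cross <- c(0, 1)
  w$noise_solute <- 2; w$noise_cross <- 2
  s <- sample_unbiased(w, 2000, seed = 62)
  traj <- attach_energies(s$traj, s$truth, w, seed = 63)
  for (cl in 1:2) {
    ce <- conditional_energy_average(traj, s$truth, cluster = cl,
                                     component = "solute")
    expect_lt(abs(ce$mean - w$energy_solute[cl]), 2 * ce$se + 1e-9)
  }
})

test_that("decomposition identities: TdS = dG - dU, zero reference row", {
  w <- tiny_world(K = 3, M = 2)
  w$energy_solute <- c(0, 2, 4); w$energy_cross <- c(0, 0.5, 1)
  s <- sample_unbiased(w, 1500, seed = 64)
  traj <- attach_energies(s$traj, s$truth, w, seed = 65)
  rep1 <- thermo_report(traj, s$truth, reference = 2)
  tab <- rep1$table
  ref <- tab[tab$cluster == 2, ]
  expect_identical(c(ref$dG, ref$dU, ref$TdS), c(0, 0, 0))
  expect_equal(tab$TdS, tab$dG - tab$dU, tolerance = 1e-12)
  expect_equal(sum(tab$P) + rep1$unclassified, 1, tolerance = 1e-9)
  expect_error(thermo_report(traj, s$truth, reference = 9), "absent")
})

test_that("identical cluster energies put all of dG into the entropy term", {
  w <- tiny_world(K = 2, M = 2)
  w$energy_solute <- c(1, 1); w$energy_cross <- c(0.5, 0.5)
  w$noise_solute <- 0; w$noise_cross <- 0
  w$mixture_probs <- c(0.7, 0.3)
  s <- sample_unbiased(w, 2000, seed = 66)
  traj <- attach_energies(s$traj, s$truth, w, seed = 67)
  rep1 <- thermo_report(traj, s$truth, reference = 1)
  tab <- rep1$table
  expect_equal(tab$dU[tab$cluster == 2], 0, tolerance = 1e-9)
  expect_equal(tab$TdS[tab$cluster == 2], tab$dG[tab$cluster == 2],
               tolerance = 1e-9)
})

test_that("reweighting round trip recovers a planted biased distribution", {
  # two-state world; a +2 kT step bias on half the circle suppresses one
  # state, reweighting restores the planted populations
  modes <- matrix(c(-pi / 2, pi / 2), 2, 1)
  w <- synthetic_world(K = 2, modes = modes, kappa = 8,
                       mixture_probs = c(0.65, 0.35), barriers = 2)
  kT <- kB * 300
  w$bias_fn <- function(theta) ifelse(theta < 0, 2 * kT, 0)
  s <- sample_biased(w, 20000, seed = 68)
  # the bias visibly distorts raw populations
  raw <- mean(s$truth == 1)
  expect_lt(raw, 0.55)
  fw <- reweight(s$traj$bias, 300)
  pops <- cluster_populations(s$truth, fw)
  neff <- sum(fw$W)^2 / sum(fw$W^2)
  se <- sqrt(0.65 * 0.35 / neff)
  expect_lt(abs(pops$P[["C1"]] - 0.65), 3 * se)
})
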