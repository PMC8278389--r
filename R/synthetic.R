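#' Draw from a von Mises distribution
#'
#' Best-Fisher envelope-rejection sampler for the von Mises distribution,
#' the minimal unimodal periodic family used by the synthetic trajectory
#' generator. Concentration `kappa = 0` degenerates to the uniform
#' circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k) {
      u3 <- stats::runif(k)
      out[got + seq_len(k)] <- sign(u3 - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

#' von Mises density
#' @param x angles (radians).
#' @inheritParams rvonmises
#' @export
dvonmises <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0,
                                               expon.scaled = TRUE) *
                                exp(kappa))
}

#' Sum-of-Gaussian-hills bias over one torsion
#'
#' Returns a bias function emulating the final bias of a well-tempered
#' metadynamics run on a single torsion: a sum of periodic Gaussian hills
#' (each evaluated at the periodic distance from its center).
#'
#' @param centers hill centers (radians).
#' @param width Gaussian width (rad); 0.3 by default, a typical hill
#'   width for torsional collective variables.
#' @param height hill height in kJ/mol (use `2.5 * kB * temperature` for
#'   hills of 2.5 kT).
#' @return a vectorized function of one angle returning the bias (kJ/mol).
#' @export
gaussian_hills_bias <- function(centers, width = 0.3, height) {
  force(centers); force(width); force(height)
  function(theta) {
    v <- numeric(length(theta))
    for (c0 in centers) {
      d <- periodic_diff(theta, c0)
      v <- v + height * exp(-d^2 / (2 * width^2))
    }
    v
  }
}

#' Define a synthetic world of planted conformers
#'
#' Specifies a ground-truth generative model in M-dimensional torsional
#' space: K conformers, each a product of per-angle von Mises modes, with
#' mixture probabilities, per-conformer energy-component means, and an
#' optional bias potential over one designated torsion. Every sampler
#' drawing from a world is byte-reproducible under a fixed seed.
#'
#' The default world emulates a moderately flexible drug-like molecule:
#' six torsions, twelve conformers whose mode combinations sit on a
#' well-separated grid, four conformers carrying most of the mixture
#' mass, and per-torsion rotational barriers spanning 1.2-6 kT so the
#' barrier weights range from 1 to 5.
#'
#' @param K number of conformers.
#' @param modes K x M matrix of von Mises mean angles (radians).
#' @param kappa von Mises concentration, scalar or length-M vector.
#' @param mixture_probs K probabilities summing to 1.
#' @param angle_names M torsion labels.
#' @param barriers per-angle lowest rotational barriers (kT) used to form
#'   clustering weights for this world.
#' @param bias_angle index of the torsion the bias acts on.
#' @param bias_fn vectorized bias function of that torsion (kJ/mol), or
#'   `NULL`.
#' @param energy_solute,energy_cross length-K per-conformer mean solute
#'   and solute-solvent energies (kJ/mol).
#' @param noise_solute,noise_cross Gaussian noise s.d. of those
#'   components.
#' @param solvent_mean,noise_solvent common solvent-solvent energy mean
#'   and (large) noise s.d., exercising the cancellation of the
#'   solvent-solvent term between conformers.
#' @param temperature kelvin.
#' @return an object of class `synthetic_world`.
#' @export
synthetic_world <- function(K = 12,
                            modes = NULL,
                            kappa = 50,
                            mixture_probs = NULL,
                            angle_names = NULL,
                            barriers = c(6, 1.5, 2, 1.2, 2.5, 4),
                            bias_angle = 1L,
                            bias_fn = NULL,
                            energy_solute = NULL,
                            energy_cross = NULL,
                            noise_solute = 4,
                            noise_cross = 4,
                            solvent_mean = -10000,
                            noise_solvent = 400,
                            temperature = 300) {
  if (is.null(modes)) {
    if (K != 12)
      stop("the default mode grid defines 12 conformers; supply `modes` ",
           "for other K")
    grids <- list(tauA = c(-2 * pi / 3, 0, 2 * pi / 3),
                  tauB = c(-2.9, 0.3),
                  tauC = c(-1.0, 2.1),
                  tauD = c(-0.5, 2.6),
                  tauE = c(-pi / 2, pi / 2),
                  tauF = c(-2.6, 0.6))
    i <- seq_len(K) - 1L
    modes <- cbind(tauA = grids$tauA[i %% 3L + 1L],
                   tauB = grids$tauB[i %% 2L + 1L],
                   tauC = grids$tauC[(i %/% 2L) %% 2L + 1L],
                   tauD = grids$tauD[(i %/% 4L) %% 2L + 1L],
                   tauE = grids$tauE[(i %/% 3L) %% 2L + 1L],
                   tauF = grids$tauF[(i %/% 6L) %% 2L + 1L])
  }
  modes <- as.matrix(modes)
  M <- ncol(modes)
  if (nrow(modes) != K) stop("modes must have K rows")
  if (is.null(angle_names))
    angle_names <- colnames(modes) %||% paste0("tau", seq_len(M))
  if (is.null(mixture_probs)) {
    if (K == 12) {
      # four dominant conformers (crystal-like analogues), eight minor
      mixture_probs <- rep(0.05, 12)
      mixture_probs[c(2, 8, 10, 12)] <- 0.15
    } else mixture_probs <- rep(1 / K, K)
  }
  if (length(mixture_probs) != K || abs(sum(mixture_probs) - 1) > 1e-9)
    stop("mixture_probs must be K probabilities summing to 1")
  kappa <- rep_len(kappa, M)
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  if (length(barriers) != M) stop("barriers must have one entry per angle")
  if (is.null(energy_solute)) energy_solute <- seq(0, 3, length.out = K)
  if (is.null(energy_cross)) energy_cross <- seq(0, 1, length.out = K)
  if (length(energy_solute) != K || length(energy_cross) != K)
    stop("energy means must have length K")
  structure(list(K = K, M = M, modes = modes, kappa = kappa,
                 mixture_probs = mixture_probs, angle_names = angle_names,
                 barriers = barriers, bias_angle = as.integer(bias_angle),
                 bias_fn = bias_fn,
                 energy_solute = energy_solute, energy_cross = energy_cross,
                 noise_solute = noise_solute, noise_cross = noise_cross,
                 solvent_mean = solvent_mean, noise_solvent = noise_solvent,
                 temperature = temperature),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d conformers in %d torsions (%s)\n",
              x$K, x$M, paste(x$angle_names, collapse = ", ")))
  cat(sprintf("  kappa = %s; dominant mass on conformers %s\n",
              paste(format(x$kappa), collapse = "/"),
              paste(which(x$mixture_probs >= max(x$mixture_probs) - 1e-12),
                    collapse = ", ")))
  if (!is.null(x$bias_fn))
    cat("  bias potential on", x$angle_names[x$bias_angle], "\n")
  invisible(x)
}

# draw component indices and angle matrix for n frames
draw_mixture <- function(world, n) {
  comp <- sample.int(world$K, n, replace = TRUE, prob = world$mixture_probs)
  ang <- matrix(0, n, world$M)
  for (a in seq_len(world$M)) {
    for (c in seq_len(world$K)) {
      sel <- comp == c
      if (any(sel))
        ang[sel, a] <- rvonmises(sum(sel), world$modes[c, a], world$kappa[a])
    }
  }
  colnames(ang) <- world$angle_names
  list(comp = comp, ang = ang)
}

#' Sample an unbiased trajectory from a planted world
#'
#' Frames are drawn conformer-by-conformer from the mixture, then
#' per-angle from the conformer's von Mises modes. A fraction of frames
#' can be replaced by uniform draws over the torus — out-of-basin
#' "noise" frames (true label 0) emulating the unassignable configurations
#' of a real solution trajectory.
#'
#' @param world a [synthetic_world()].
#' @param n number of frames.
#' @param seed integer seed (fixed seed, identical output).
#' @param noise_fraction fraction of frames replaced by uniform noise.
#' @return list with `traj` (a [dihedral_trajectory()]) and `truth`
#'   (integer vector of planted labels, 0 for noise frames).
#' @export
sample_unbiased <- function(world, n, seed = 1L, noise_fraction = 0) {
  stopifnot(inherits(world, "synthetic_world"), n >= 1)
  with_seed(seed, {
    d <- draw_mixture(world, n)
    truth <- d$comp
    if (noise_fraction > 0) {
      nn <- round(noise_fraction * n)
      if (nn > 0) {
        idx <- sample.int(n, nn)
        d$ang[idx, ] <- matrix(stats::runif(nn * world$M, -pi, pi), nn)
        truth[idx] <- 0L
      }
    }
    list(traj = dihedral_trajectory(d$ang, angle_names = world$angle_names,
                                    time = seq_len(n) - 1),
         truth = truth)
  })
}

#' Sample a biased trajectory from a planted world
#'
#' Emulates sampling under a static bias potential \eqn{V} acting on the
#' designated torsion: the biased density is
#' \eqn{p_{biased}(\tau) \propto p(\tau)\, e^{-V(\tau_b)/k_B T}}
#' (the bias adds to the potential energy, depressing the probability of
#' the regions where hills were deposited), realized by exact rejection
#' from the unbiased mixture. The deposited bias at each accepted frame
#' is recorded in the trajectory's `bias` column so that [reweight()]
#' undoes it exactly.
#'
#' @inheritParams sample_unbiased
#' @return list with `traj` (bias column filled) and `truth`.
#' @export
sample_biased <- function(world, n, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"), n >= 1)
  if (is.null(world$bias_fn)) stop("world has no bias function")
  kT <- kB * world$temperature
  grid <- seq(-pi, pi, length.out = 2049)
  vg <- world$bias_fn(grid)
  if (any(!is.finite(vg))) stop("bias function is unbounded on [-pi, pi)")
  vmin <- min(vg)
  with_seed(seed, {
    ang <- matrix(0, n, world$M)
    comp <- integer(n)
    vkept <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- max(n - got, 256L)
      d <- draw_mixture(world, m)
      v <- world$bias_fn(d$ang[, world$bias_angle])
      acc <- stats::runif(m) < exp(-(v - vmin) / kT)
      k <- min(sum(acc), n - got)
      if (k > 0) {
        take <- which(acc)[seq_len(k)]
        ang[got + seq_len(k), ] <- d$ang[take, , drop = FALSE]
        comp[got + seq_len(k)] <- d$comp[take]
        vkept[got + seq_len(k)] <- v[take]
        got <- got + k
      }
    }
    colnames(ang) <- world$angle_names
    list(traj = dihedral_trajectory(ang, angle_names = world$angle_names,
                                    time = seq_len(n) - 1, bias = vkept),
         truth = comp)
  })
}

#' Attach per-frame energy components to a trajectory
#'
#' Adds solute, solvent and solute-solvent potential-energy columns drawn
#' from the world's per-conformer means plus Gaussian noise. The
#' solvent-solvent column has a single large common mean and large noise
#' for every conformer, so that the naive total-energy estimator of
#' conformer energy differences drowns in solvent fluctuations while the
#' solute + solute-solvent split does not.
#'
#' @param traj a [dihedral_trajectory()].
#' @param truth planted labels (0 allowed; noise frames draw from the
#'   across-conformer mean).
#' @param world a [synthetic_world()].
#' @param seed integer seed.
#' @return the trajectory with energy columns attached.
#' @export
attach_energies <- function(traj, truth, world, seed = 1L) {
  assert_trajectory(traj)
  n <- n_frames(traj)
  if (length(truth) != n) stop("truth labels length mismatch")
  with_seed(seed, {
    mu_s <- ifelse(truth > 0, world$energy_solute[pmax(truth, 1L)],
                   mean(world$energy_solute))
    mu_x <- ifelse(truth > 0, world$energy_cross[pmax(truth, 1L)],
                   mean(world$energy_cross))
    traj$energy_solute <- mu_s + stats::rnorm(n, 0, world$noise_solute)
    traj$energy_solute_solvent <- mu_x + stats::rnorm(n, 0, world$noise_cross)
    traj$energy_solvent <- world$solvent_mean +
      stats::rnorm(n, 0, world$noise_solvent)
    traj
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar between -1 and 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  nch2 <- ch2(length(a))
  expected <- sum_a * sum_b / nch2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
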