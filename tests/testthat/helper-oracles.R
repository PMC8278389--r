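# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct formulas) so they check the
# package implementations from a different direction.

# plain double-loop pairwise distance matrix
bf_distance_matrix <- function(angles, w, form = "euclidean") {
  n <- nrow(angles)
  D <- matrix(0, n, n)
  pd <- function(a, b) {
    d <- abs(a - b)
    if (d > pi) d <- 2 * pi - d
    d
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ds <- mapply(pd, angles[i, ], angles[j, ]) * w
    D[i, j] <- if (form == "euclidean") sqrt(sum(ds^2)) else sum(ds)
  }
  D
}

# brute-force density: strict inequality, self excluded
bf_density <- function(Dm, d_c) {
  n <- nrow(Dm)
  vapply(seq_len(n), function(i) sum(Dm[i, -i] < d_c), integer(1))
}

# brute-force delta with the index tie-break (lower index = denser)
bf_delta <- function(Dm, rho) {
  n <- nrow(Dm)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    higher <- which(rho > rho[i] | (rho == rho[i] & seq_len(n) < i))
    delta[i] <- if (length(higher)) min(Dm[i, higher]) else max(Dm[i, ])
  }
  delta
}

# brute-force lowest directed barrier on a finite periodic profile:
# enumerate every ordered pair of strict local minima and both circular
# directions; cost = max F on the open path - F(start)
bf_lowest_barrier <- function(f) {
  n <- length(f)
  prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n - 1) + 1, 1)
  minima <- which(f < f[prv] & f < f[nxt])
  stopifnot(length(minima) >= 2)
  path_max <- function(i, j) {       # open path i -> j going forward
    idx <- if (i < j) seq(i + 1, j - 1)
    else c(if (i < n) seq(i + 1, n) else integer(0), seq_len(j - 1))
    if (!length(idx)) -Inf else max(f[idx])
  }
  best <- Inf
  for (i in minima) for (j in minima) {
    if (i == j) next
    best <- min(best, path_max(i, j) - f[i], path_max(j, i) - f[i])
  }
  best
}

# a trajectory whose histogram reproduces an arbitrary periodic profile
# exactly: one frame per bin center, weighted by exp(-F)
profile_fixture <- function(f_values) {
  n_bins <- length(f_values)
  centers <- seq(-pi, pi, length.out = n_bins + 1)[-1] - pi / n_bins
  list(traj = dihedral_trajectory(matrix(centers, ncol = 1),
                                  angle_names = "tau1"),
       weights = exp(-(f_values - min(f_values))),
       n_bins = n_bins)
}

# random smooth periodic free-energy curve (finite, generic values)
random_periodic_profile <- function(n_bins, n_harmonics = 3) {
  theta <- seq(-pi, pi, length.out = n_bins + 1)[-1] - pi / n_bins
  f <- numeric(n_bins)
  for (k in seq_len(n_harmonics))
    f <- f + stats::rnorm(1, 0, 2 / k) * cos(k * theta + stats::runif(1, 0, 2 * pi))
  f - min(f)
}

# small well-separated planted world (K basins in M torsions)
tiny_world <- function(K = 3, M = 2, kappa = 40) {
  modes <- matrix(wrap_angle(seq(0, 2 * pi, length.out = K + 1)[seq_len(K)]),
                  K, M)
  modes[, seq_len(M) %% 2 == 0] <- wrap_angle(modes[, seq_len(M) %% 2 == 0] + 1)
  synthetic_world(K = K, modes = modes, kappa = kappa,
                  mixture_probs = rep(1 / K, K),
                  barriers = rep(2, M))
}
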