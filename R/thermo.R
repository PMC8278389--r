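#' Boltzmann constant in kJ/(mol K)
#' @export
kB <- 0.0083144621

#' Frame weights from the deposited bias potential
#'
#' Undoes a metadynamics bias: each frame receives the Boltzmann weight of
#' its total bias shifted by the maximum deposited bias,
#' \deqn{W_i = \exp[(V_i - \max_j V_j) / k_B T],}
#' so frames where the maximum bias was deposited (the deepest free-energy
#' region along the biased coordinate) carry weight exactly 1 and all
#' others correspondingly less. With `well_tempered_factor` set to the
#' bias factor \eqn{\gamma}, the standard final-bias estimator prefactor
#' \eqn{\gamma/(\gamma-1)} is applied to the bias before exponentiation.
#'
#' @param bias numeric vector of per-frame total bias (kJ/mol).
#' @param temperature kelvin.
#' @param well_tempered_factor optional bias factor gamma > 1; `NULL`
#'   (default) uses the plain max-shifted weight.
#' @return an object of class `frame_weights`: `W` in (0, 1] with
#'   `max(W) == 1`, and `kT`.
#' @export
reweight <- function(bias, temperature = 300, well_tempered_factor = NULL) {
  if (!length(bias)) stop("empty bias vector")
  if (any(!is.finite(bias))) stop("bias must be finite")
  if (!(temperature > 0)) stop("temperature must be positive")
  kT <- kB * temperature
  v <- as.numeric(bias)
  if (!is.null(well_tempered_factor)) {
    g <- well_tempered_factor
    if (!(g > 1)) stop("well_tempered_factor must exceed 1")
    v <- v * g / (g - 1)
  }
  structure(list(W = exp((v - max(v)) / kT), kT = kT,
                 temperature = temperature),
            class = "frame_weights")
}

# internal: accept frame_weights, numeric vector, or NULL (uniform)
resolve_frame_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  w <- if (inherits(weights, "frame_weights")) weights$W else as.numeric(weights)
  if (length(w) != n)
    stop("frame weights length does not match number of frames")
  if (any(w < 0) || all(w == 0)) stop("frame weights must be nonnegative, not all zero")
  w
}

#' Reweighted conformer populations
#'
#' Equilibrium probability of each conformer cluster from a classified
#' (possibly biased) trajectory: the bias-corrected weight of each
#' cluster's frames over the total weight. The unclassified mass is
#' reported separately; together with the cluster probabilities it sums
#' to 1.
#'
#' @param labels a `classified_trajectory` or integer label vector
#'   (0 = unclassified).
#' @param weights a [reweight()] result, numeric weights, or `NULL` for
#'   an unbiased trajectory.
#' @return list with `P` (named per-cluster probabilities) and
#'   `unclassified`.
#' @export
cluster_populations <- function(labels, weights = NULL) {
  if (inherits(labels, "classified_trajectory")) labels <- labels$labels
  labels <- as.integer(labels)
  w <- resolve_frame_weights(weights, length(labels))
  tot <- sum(w)
  if (!(tot > 0)) stop("total frame weight is zero")
  ids <- sort(unique(labels[labels > 0L]))
  P <- vapply(ids, function(c) sum(w[labels == c]) / tot, numeric(1))
  names(P) <- if (length(ids)) paste0("C", ids) else character(0)
  list(P = P, unclassified = sum(w[labels == 0L]) / tot)
}

#' Free-energy difference between two conformers
#'
#' \eqn{\Delta G_{i,j} = -k_B T \ln(P_i / P_j)} from equilibrium
#' probabilities. A zero probability yields an infinite difference
#' (with the appropriate sign) rather than an error.
#'
#' @param P_i,P_j probabilities.
#' @param temperature kelvin.
#' @return kJ/mol.
#' @export
delta_g <- function(P_i, P_j, temperature = 300) {
  if (P_i < 0 || P_j < 0) stop("probabilities must be nonnegative")
  -kB * temperature * (log(P_i) - log(P_j))
}

#' Weighted conditional mean of an energy component within a cluster
#'
#' The reweighted ensemble average of a potential-energy component over
#' the frames classified in one cluster — the mean of the reweighted
#' conditional energy density given the cluster — with a bootstrap
#' standard error over frames.
#'
#' @param traj a [dihedral_trajectory()] carrying the requested energy
#'   column.
#' @param labels classified labels (vector or `classified_trajectory`).
#' @param weights frame weights (see [cluster_populations()]).
#' @param cluster cluster id.
#' @param component `"solute"`, `"solute_solvent"`, `"solvent"`, or
#'   `"total"` (sum of all three).
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed integer seed for the bootstrap.
#' @return list with `mean` (kJ/mol), `se`, `n`.
#' @export
conditional_energy_average <- function(traj, labels, weights = NULL,
                                       cluster, component = "solute",
                                       n_boot = 200, seed = 1L) {
  assert_trajectory(traj)
  if (inherits(labels, "classified_trajectory")) labels <- labels$labels
  e <- energy_component(traj, component)
  sel <- which(labels == cluster)
  if (!length(sel)) stop("cluster ", cluster, " is empty")
  w <- resolve_frame_weights(weights, n_frames(traj))[sel]
  e <- e[sel]
  est <- sum(w * e) / sum(w)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(sel), replace = TRUE)
    sum(w[idx] * e[idx]) / sum(w[idx])
  }, numeric(1)))
  list(mean = est, se = stats::sd(boot), n = length(sel))
}

energy_component <- function(traj, component) {
  component <- match.arg(component,
                         c("solute", "solute_solvent", "solvent", "total"))
  get <- function(field, what) {
    v <- traj[[field]]
    if (is.null(v)) stop("trajectory has no ", what, " energy column")
    v
  }
  switch(component,
         solute = get("energy_solute", "solute"),
         solute_solvent = get("energy_solute_solvent", "solute-solvent"),
         solvent = get("energy_solvent", "solvent"),
         total = get("energy_solute", "solute") +
           get("energy_solvent", "solvent") +
           get("energy_solute_solvent", "solute-solvent"))
}

#' Free energy, potential energy and entropy of conformers
#'
#' Builds the complete thermodynamic report for a classified trajectory:
#' reweighted populations, \eqn{\Delta G} relative to a reference
#' conformer, the potential-energy difference from the solute plus
#' solute-solvent energy split,
#' \deqn{\Delta U_{i,ref} = \Delta\langle E\rangle^{solute} +
#'       \Delta\langle E\rangle^{solute-solvent},}
#' (the solvent-solvent term cancels between conformers since a
#' conformational change of the solute leaves it unchanged), and the
#' entropic contribution by difference, \eqn{T\Delta S = \Delta G -
#' \Delta H} with \eqn{\Delta H \simeq \Delta U} (no volume change).
#'
#' @param traj a [dihedral_trajectory()] with energy columns.
#' @param labels a `classified_trajectory` or label vector.
#' @param weights frame weights from [reweight()], or `NULL`.
#' @param reference reference cluster id.
#' @param temperature kelvin.
#' @param n_boot,seed bootstrap controls for the energy standard errors.
#' @return an object of class `thermo_report`: a data frame `table` with
#'   one row per cluster (`P`, `dG`, `dU`, `TdS`, `dU_se`) plus fields
#'   `reference`, `unclassified`, `temperature`.
#' @export
thermo_report <- function(traj, labels, weights = NULL, reference,
                          temperature = 300, n_boot = 200, seed = 1L) {
  assert_trajectory(traj)
  if (inherits(labels, "classified_trajectory")) labels <- labels$labels
  pops <- cluster_populations(labels, weights)
  ids <- as.integer(sub("^C", "", names(pops$P)))
  if (!reference %in% ids)
    stop("reference cluster ", reference, " is empty or absent")
  avg <- function(cid, comp, s)
    conditional_energy_average(traj, labels, weights, cid, comp,
                               n_boot = n_boot, seed = s)
  rows <- lapply(seq_along(ids), function(k) {
    cid <- ids[k]
    su <- avg(cid, "solute", seed + 2L * cid)
    sx <- avg(cid, "solute_solvent", seed + 2L * cid + 1L)
    data.frame(cluster = cid, P = unname(pops$P[k]),
               E_solute = su$mean, E_solute_se = su$se,
               E_cross = sx$mean, E_cross_se = sx$se,
               n = su$n)
  })
  tab <- do.call(rbind, rows)
  ref <- tab[tab$cluster == reference, ]
  tab$dG <- vapply(tab$P, delta_g, numeric(1), P_j = ref$P,
                   temperature = temperature)
  tab$dU <- (tab$E_solute - ref$E_solute) + (tab$E_cross - ref$E_cross)
  tab$dU_se <- ifelse(tab$cluster == reference, 0,
                      sqrt(tab$E_solute_se^2 + ref$E_solute_se^2 +
                           tab$E_cross_se^2 + ref$E_cross_se^2))
  tab$TdS <- tab$dG - tab$dU
  ref_row <- tab$cluster == reference
  tab$dG[ref_row] <- 0; tab$dU[ref_row] <- 0; tab$TdS[ref_row] <- 0
  structure(list(table = tab, reference = reference,
                 unclassified = pops$unclassified,
                 temperature = temperature),
            class = "thermo_report")
}

#' @export
print.thermo_report <- function(x, ...) {
  if (is.na(x$reference))
    cat(sprintf("Conformer populations (T = %g K)\n", x$temperature))
  else
    cat(sprintf("Conformer thermodynamics (T = %g K, reference C%d)\n",
                x$temperature, x$reference))
  keep <- intersect(c("cluster", "P", "dG", "dU", "dU_se", "TdS"),
                    names(x$table))
  out <- x$table[, keep, drop = FALSE]
  out[-1] <- lapply(out[-1], round, digits = 4)
  print(out, row.names = FALSE)
  cat(sprintf("Unclassified fraction: %.4f\n", x$unclassified))
  invisible(x)
}
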