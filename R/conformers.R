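#' Fit a conformational-macrostate model to a dihedral trajectory
#'
#' The package's main entry point, in the style of a classic model-fitting
#' function: takes a reference trajectory (typically gas phase, where all
#' basins are sampled), builds the barrier-weighted periodic distance
#' matrix, runs density-peaks clustering, and summarizes every cluster as
#' a torsional fingerprint. The returned object classifies new
#' trajectories via [predict.conformer_clust()].
#'
#' Weights can be supplied directly (e.g. from tabulated barriers via
#' [compute_weights()]); with `weights = NULL` they are derived from the
#' trajectory itself through per-torsion free-energy profiles and their
#' lowest rotational barriers.
#'
#' @param traj a [dihedral_trajectory()].
#' @param weights a `torsion_weights`, numeric vector, or `NULL` to
#'   estimate from per-torsion profiles.
#' @param neighbor_fraction target mean neighbor fraction for the density
#'   cutoff (default 0.02).
#' @param form distance form, `"euclidean"` (default) or `"manhattan"`.
#' @param use_rounded use one-decimal rounded weights (default).
#' @param mode,rho_min,delta_min,k,centers center selection, see
#'   [select_centers()].
#' @param halo core/halo convention, see [assign_and_halo()].
#' @param fingerprint_bins bins per angle for fingerprints (default 36).
#' @param support_min_count minimum bin count kept in fingerprint support.
#' @param fingerprint_frames `"all"` (core + halo, default) or `"core"`.
#' @param profile_bins bins for barrier profiles when weights are
#'   estimated.
#' @param keep_distance keep the N x N distance matrix in the fit object.
#' @return an object of class `conformer_clust` with components `weights`,
#'   `clustering` (a `cluster_model`), `fingerprints`, `labels`,
#'   `centers`, and the center frames' angles (`center_angles`).
#' @seealso [predict.conformer_clust()], [plot.conformer_clust()]
#' @export
conformer_clust <- function(traj, weights = NULL, neighbor_fraction = 0.02,
                            form = c("euclidean", "manhattan"),
                            use_rounded = TRUE,
                            mode = c("auto", "manual"), rho_min = NULL,
                            delta_min = NULL, k = NULL, centers = NULL,
                            halo = c("center-cutoff", "border"),
                            fingerprint_bins = 36, support_min_count = 1,
                            fingerprint_frames = c("all", "core"),
                            profile_bins = 72, keep_distance = FALSE) {
  assert_trajectory(traj)
  form <- match.arg(form)
  mode <- match.arg(mode)
  halo <- match.arg(halo)
  fingerprint_frames <- match.arg(fingerprint_frames)
  if (is.null(weights)) {
    barr <- vapply(traj$angle_names, function(a) {
      p <- free_energy_profile(traj, a, n_bins = profile_bins)
      if (p$unimodal)
        stop("cannot derive a weight for unimodal torsion '", a,
             "'; supply weights explicitly")
      p$lowest_barrier
    }, numeric(1))
    weights <- compute_weights(barr)
  } else if (!inherits(weights, "torsion_weights")) {
    weights <- compute_weights(weights)
  }
  D <- distance_matrix(traj, weights, form = form, use_rounded = use_rounded)
  cl <- density_peaks(D, neighbor_fraction = neighbor_fraction,
                      mode = mode, rho_min = rho_min, delta_min = delta_min,
                      k = k, centers = centers, halo = halo)
  fp <- build_fingerprints(traj, cl$labels, n_bins = fingerprint_bins,
                           support_min_count = support_min_count,
                           frames = fingerprint_frames,
                           is_core = cl$is_core)
  ctr_by_label <- cl$centers[order(cl$labels[cl$centers])]
  structure(list(weights = weights,
                 clustering = cl,
                 fingerprints = fp,
                 labels = cl$labels,
                 centers = cl$centers,
                 center_angles = traj$angles[ctr_by_label, , drop = FALSE],
                 angle_names = traj$angle_names,
                 n_frames = n_frames(traj),
                 form = form,
                 neighbor_fraction = neighbor_fraction,
                 distance = if (keep_distance) D else NULL,
                 call = match.call()),
            class = "conformer_clust")
}

#' @export
print.conformer_clust <- function(x, ...) {
  cat("Conformational macrostate model\n")
  cat(sprintf("  %d frames, %d torsions, %d conformers (d_c = %.4g)\n",
              x$n_frames, length(x$angle_names), length(x$centers),
              x$clustering$d_c))
  invisible(x)
}

#' @export
summary.conformer_clust <- function(object, ...) {
  cl <- object$clustering
  k <- length(cl$centers)
  lab <- factor(cl$labels, levels = seq_len(k))
  tab <- data.frame(cluster = seq_len(k),
                    center_frame = cl$centers[order(cl$labels[cl$centers])],
                    size = as.integer(table(lab)),
                    core = as.integer(tapply(cl$is_core, lab, sum)),
                    rho = cl$rho[cl$centers[order(cl$labels[cl$centers])]],
                    delta = cl$delta[cl$centers[order(cl$labels[cl$centers])]])
  structure(list(table = tab, d_c = cl$d_c,
                 weights = object$weights,
                 n_frames = object$n_frames), class = "summary.conformer_clust")
}

#' @export
print.summary.conformer_clust <- function(x, ...) {
  cat(sprintf("Conformer clusters (%d frames, d_c = %.4g):\n",
              x$n_frames, x$d_c))
  print(x$table, row.names = FALSE)
  cat("\nTorsion weights:\n")
  print(x$weights)
  invisible(x)
}

#' Representative conformer structures
#'
#' The cluster-center frames' torsional angles, one row per conformer.
#'
#' @param object a `conformer_clust` fit.
#' @param ... unused.
#' @export
coef.conformer_clust <- function(object, ...) object$center_angles

#' Classify new frames with a fitted conformer model
#'
#' Applies the fingerprint matcher: a frame is assigned to a conformer
#' only when every torsion falls in a nonzero-support bin of that
#' conformer's fingerprint.
#'
#' @param object a `conformer_clust` fit.
#' @param newdata a [dihedral_trajectory()]; defaults to refitting labels
#'   on the training trajectory's assignments.
#' @param tie_break see [classify_frame()].
#' @param ... unused.
#' @return a `classified_trajectory`.
#' @export
predict.conformer_clust <- function(object, newdata = NULL,
                                    tie_break = c("product", "first"), ...) {
  if (is.null(newdata))
    stop("supply `newdata` (a dihedral_trajectory) to classify")
  classify_trajectory(newdata, object$fingerprints,
                      tie_break = match.arg(tie_break))
}

#' Decision-graph plot of a conformer fit
#'
#' @param x a `conformer_clust` fit.
#' @param ... passed to the underlying plot.
#' @export
plot.conformer_clust <- function(x, ...) plot(x$clustering, ...)

#' @export
labels.conformer_clust <- function(object, ...) object$labels
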