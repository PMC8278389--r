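#' Tune the density cutoff to a target mean neighbor count
#'
#' Chooses the cutoff \eqn{d_c} so that the average number of neighbors
#' per point (strictly closer than \eqn{d_c}) matches a target fraction
#' of the data set — 2 percent by default, the standard operating point
#' of the density-peaks procedure — to within half a neighbor. Since the
#' mean neighbor count is \eqn{2P/N} with \eqn{P} the number of pairs
#' strictly below the cutoff, a deterministic bisection on the pooled
#' pairwise distance values converges onto a cutoff whose pair count lies
#' in the target window. Heavily tied distance multisets (e.g. all points
#' mutually equidistant) can make every window count unattainable, which
#' is reported as a tuning error.
#'
#' @param D a `distance_matrix`.
#' @param target_neighbor_fraction target mean neighbor count as a
#'   fraction of N, in (0, 1).
#' @return scalar `d_c`.
#' @export
tune_cutoff <- function(D, target_neighbor_fraction = 0.02) {
  if (!inherits(D, "distance_matrix")) stop("expected a 'distance_matrix'")
  f <- target_neighbor_fraction
  if (!(f > 0 && f < 1)) stop("target_neighbor_fraction must be in (0, 1)")
  n <- D$n_points
  npairs <- n * (n - 1) / 2
  # mean rho = 2P/n where P = number of pairs strictly below d_c
  target_mean <- f * n
  p0 <- target_mean * n / 2
  tol_pairs <- n / 4                   # |mean - target| <= 0.5 neighbor
  lo <- 0
  hi <- max(D$values) * (1 + 1e-9) + 1e-12
  if (min(p0 + tol_pairs, npairs) >= .cpp_count_below(D$values, hi) &&
      p0 - tol_pairs <= npairs && p0 + tol_pairs >= npairs) {
    return(hi)                          # target at or above all distances
  }
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    cnt <- .cpp_count_below(D$values, mid)
    if (cnt >= p0 - tol_pairs && cnt <= p0 + tol_pairs && mid > 0)
      return(mid)
    if (cnt < p0) lo <- mid else hi <- mid
  }
  stop("cutoff tuning failed: the pairwise distance distribution is too ",
       "degenerate to reach a mean neighbor count of ",
       format(target_mean), " +/- 0.5 (n = ", n, "); the distance ",
       "multiset has no usable value near the target")
}

#' Local density: neighbors within the cutoff
#'
#' \eqn{\rho_i} is the integer number of points strictly closer to point
#' \eqn{i} than the cutoff: \eqn{\rho_i = \sum_{j \ne i} \chi(d_{ij} -
#' d_c)} with \eqn{\chi(x) = 1} iff \eqn{x < 0}. A pair at exactly the
#' cutoff distance is not counted.
#'
#' @param D a `distance_matrix`.
#' @param d_c positive distance cutoff.
#' @return integer vector of densities.
#' @export
compute_density <- function(D, d_c) {
  if (!inherits(D, "distance_matrix")) stop("expected a 'distance_matrix'")
  if (!(d_c > 0)) stop("d_c must be positive")
  .cpp_density(D$values, d_c)
}

# precedence order used everywhere ties in rho occur: higher rho first,
# ties broken by lower frame index (which therefore counts as "denser")
density_order <- function(rho) order(-rho, seq_along(rho))

#' Distance to the nearest denser point
#'
#' \eqn{\delta_i} is the minimum distance from point \eqn{i} to any point
#' of higher density; the global density maximum instead receives the
#' maximum of its distances to all points, making it the unique top of the
#' decision graph. Density ties are broken by frame index (the lower index
#' counts as denser), so exactly one global maximum exists.
#'
#' @param D a `distance_matrix`.
#' @param rho integer densities from [compute_density()].
#' @return list with `delta` (numeric) and `nearest_higher` (integer,
#'   `NA` for the global density maximum).
#' @export
compute_delta <- function(D, rho) {
  if (!inherits(D, "distance_matrix")) stop("expected a 'distance_matrix'")
  if (length(rho) != D$n_points) stop("rho length does not match matrix")
  .cpp_delta(D$values, density_order(rho))
}

#' Select cluster centers from the decision graph
#'
#' Cluster centers are the decision-graph outliers: points that are both
#' locally dense (high \eqn{\rho}) and far from any denser point (high
#' \eqn{\delta}). Three selection modes are available:
#' \itemize{
#'   \item `auto` with thresholds: every point with `rho >= rho_min` and
#'     `delta >= delta_min`. Defaults: `rho_min` is half the mean density
#'     and `delta_min` twice the cutoff, a conservative reading of "dense
#'     and well separated" for data whose basins are wider than `d_c`.
#'   \item `auto` with `k`: the top `k` points by \eqn{\gamma = \rho\delta}.
#'   \item `manual`: an explicit index list, mirroring a visual pick from
#'     the decision graph.
#' }
#'
#' @param rho,delta decision-graph coordinates.
#' @param d_c the cutoff used to build `rho` (for the default `delta_min`).
#' @param mode `"auto"` or `"manual"`.
#' @param rho_min,delta_min auto-mode thresholds.
#' @param k optional number of centers (top-k by `rho * delta`).
#' @param centers manual-mode index vector.
#' @return integer vector of center indices, ordered by decreasing `rho`.
#' @export
select_centers <- function(rho, delta, d_c, mode = c("auto", "manual"),
                           rho_min = NULL, delta_min = NULL, k = NULL,
                           centers = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(centers) || !length(centers))
      stop("manual mode requires a non-empty center index list")
    centers <- as.integer(centers)
    if (any(centers < 1L | centers > length(rho)))
      stop("center index out of range")
    ordr <- density_order(rho)
    return(ordr[ordr %in% centers])
  }
  if (!is.null(k)) {
    gamma <- as.numeric(rho) * delta
    sel <- order(-gamma, seq_along(gamma))[seq_len(k)]
  } else {
    if (is.null(rho_min)) rho_min <- mean(rho) / 2
    if (is.null(delta_min)) delta_min <- 2 * d_c
    sel <- which(rho >= rho_min & delta >= delta_min)
  }
  if (!length(sel))
    stop("no cluster centers selected; lower rho_min/delta_min or ",
         "inspect the decision graph")
  ordr <- density_order(rho)
  ordr[ordr %in% sel]
}

#' Assign points to centers and split core from halo
#'
#' Non-center points are assigned in a single pass in order of decreasing
#' density, each inheriting the label of its nearest denser point. The
#' core of a cluster consists of the members lying strictly within the
#' cutoff `d_c` of their cluster center; the remaining members form the
#' halo, the noise fringe still affiliated with the cluster. The
#' alternative `halo = "border"` convention instead computes, per
#' cluster, a border density (the highest average density over pairs of
#' points from different clusters within `d_c` of each other) and marks
#' members below it as halo.
#'
#' @param D a `distance_matrix`.
#' @param rho densities.
#' @param nearest_higher from [compute_delta()].
#' @param centers center indices.
#' @param d_c distance cutoff.
#' @param halo `"center-cutoff"` (default) or `"border"`.
#' @return list with `labels` (integer, 1..K; centers labeled 1..K in
#'   order of decreasing density) and `is_core` (logical).
#' @export
assign_and_halo <- function(D, rho, nearest_higher, centers, d_c,
                            halo = c("center-cutoff", "border")) {
  halo <- match.arg(halo)
  if (!length(centers)) stop("centers must be non-empty")
  n <- length(rho)
  labels <- integer(n)
  # centers labeled 1..K in order of decreasing rho
  ctr_ord <- centers[order(-rho[centers], centers)]
  labels[ctr_ord] <- seq_along(ctr_ord)
  for (i in density_order(rho)) {
    if (labels[i] == 0L) labels[i] <- labels[nearest_higher[i]]
  }
  center_of <- integer(length(ctr_ord))
  center_of[labels[ctr_ord]] <- ctr_ord
  dvals <- D$values
  if (halo == "center-cutoff") {
    d_to_center <- dvals[cbind(seq_len(n), center_of[labels])]
    is_core <- d_to_center < d_c | seq_len(n) %in% ctr_ord
  } else {
    # original FSFDP border-density halo
    rho_b <- numeric(length(ctr_ord))
    for (i in seq_len(n)) {
      nb <- which(dvals[i, ] < d_c & labels != labels[i])
      if (length(nb)) {
        avg <- (rho[i] + rho[nb]) / 2
        rho_b[labels[i]] <- max(rho_b[labels[i]], max(avg))
      }
    }
    is_core <- rho >= rho_b[labels]
  }
  list(labels = labels, is_core = is_core)
}

#' Density-peaks clustering of a distance matrix
#'
#' Runs the full fast-search-and-find-of-density-peaks procedure: tunes
#' the cutoff to the target mean neighbor fraction, computes densities
#' and decision-graph distances, selects centers, assigns every point and
#' splits cores from halos.
#'
#' @param D a `distance_matrix`.
#' @param neighbor_fraction target mean neighbor count as a fraction of N
#'   (default 0.02); ignored when `d_c` is given.
#' @param d_c optional explicit cutoff.
#' @inheritParams select_centers
#' @inheritParams assign_and_halo
#' @return an object of class `cluster_model`: `rho`, `delta`,
#'   `nearest_higher`, `centers`, `labels`, `is_core`, `d_c`.
#' @export
density_peaks <- function(D, neighbor_fraction = 0.02, d_c = NULL,
                          mode = c("auto", "manual"), rho_min = NULL,
                          delta_min = NULL, k = NULL, centers = NULL,
                          halo = c("center-cutoff", "border")) {
  mode <- match.arg(mode)
  halo <- match.arg(halo)
  if (is.null(d_c)) d_c <- tune_cutoff(D, neighbor_fraction)
  rho <- compute_density(D, d_c)
  dl <- compute_delta(D, rho)
  ctrs <- select_centers(rho, dl$delta, d_c, mode = mode,
                         rho_min = rho_min, delta_min = delta_min,
                         k = k, centers = centers)
  ah <- assign_and_halo(D, rho, dl$nearest_higher, ctrs, d_c, halo = halo)
  structure(list(rho = rho, delta = dl$delta,
                 nearest_higher = dl$nearest_higher,
                 centers = ctrs, labels = ah$labels,
                 is_core = ah$is_core, d_c = d_c),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  k <- length(x$centers)
  cat(sprintf("Density-peaks clustering: %d points, %d clusters (d_c = %.4g)\n",
              length(x$rho), k, x$d_c))
  tab <- table(factor(x$labels, levels = seq_len(k)))
  core <- tapply(x$is_core, factor(x$labels, levels = seq_len(k)), sum)
  print(data.frame(cluster = seq_len(k), center = x$centers[order(x$labels[x$centers])],
                   size = as.integer(tab), core = as.integer(core)),
        row.names = FALSE)
  invisible(x)
}

#' Decision-graph table
#'
#' The per-point (rho, delta) pairs that make up the decision graph, for
#' export and inspection.
#'
#' @param model a `cluster_model`.
#' @return data frame with `point`, `rho`, `delta`, `is_center`.
#' @export
decision_graph <- function(model) {
  if (!inherits(model, "cluster_model")) stop("expected a 'cluster_model'")
  data.frame(point = seq_along(model$rho), rho = model$rho,
             delta = model$delta,
             is_center = seq_along(model$rho) %in% model$centers)
}

#' @export
plot.cluster_model <- function(x, ...) {
  graphics::plot(x$rho, x$delta, pch = 20, col = "grey40",
                 xlab = expression(rho ~ "(neighbors)"),
                 ylab = expression(delta),
                 main = "Decision graph", ...)
  graphics::points(x$rho[x$centers], x$delta[x$centers], pch = 1,
                   cex = 2, col = "red", lwd = 2)
  invisible(x)
}
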