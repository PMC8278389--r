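#' Periodic absolute difference between two angles
#'
#' The absolute difference on the circle: \eqn{d = |a - b|}, and when the
#' result exceeds \eqn{\pi} periodicity is accounted for by subtracting it
#' from \eqn{2\pi}. Always in \eqn{[0, \pi]}. Vectorized.
#'
#' @param a,b angles in radians.
#' @return nonnegative difference(s), at most `pi`.
#' @examples
#' periodic_diff(3.0, -3.0)  # 2*pi - 6
#' @export
periodic_diff <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("angles must be finite")
  d <- abs(a - b)
  d <- d %% (2 * pi)
  ifelse(d > pi, 2 * pi - d, d)
}

#' Barrier-weighted distance between two configurations
#'
#' Combines the per-torsion periodic differences \eqn{d_n} into one
#' configuration distance, each dimension scaled by its barrier weight
#' \eqn{w_n}:
#' \deqn{d_{ij} = \sqrt{\sum_{n=1}^{N_{CV}} (w_n d_n)^2}}
#' (the default Euclidean form, which preserves the metric property), or
#' \eqn{\sum_n w_n d_n} with `form = "manhattan"`.
#'
#' @param frame_i,frame_j numeric angle vectors of equal length (radians).
#' @param weights a [compute_weights()] result or positive numeric vector
#'   of per-torsion weights.
#' @param form `"euclidean"` (default) or `"manhattan"`.
#' @param use_rounded when `weights` is a `torsion_weights` object, use the
#'   one-decimal rounded weights (default) or the unrounded ratios.
#' @return scalar distance (weighted radians).
#' @export
config_distance <- function(frame_i, frame_j, weights,
                            form = c("euclidean", "manhattan"),
                            use_rounded = TRUE) {
  form <- match.arg(form)
  if (length(frame_i) != length(frame_j))
    stop(sprintf("dimension mismatch: frames of length %d and %d",
                 length(frame_i), length(frame_j)))
  w <- resolve_weights(weights, length(frame_i), use_rounded)
  d <- periodic_diff(frame_i, frame_j) * w
  if (form == "euclidean") sqrt(sum(d^2)) else sum(d)
}

# internal constructor
new_distance_matrix <- function(values, weight_vector_id = "") {
  structure(list(values = values, n_points = nrow(values),
                 weight_vector_id = weight_vector_id),
            class = "distance_matrix")
}

#' Pairwise distance matrix of a trajectory
#'
#' Computes all pairwise barrier-weighted periodic distances between
#' frames. The computation runs in row blocks in compiled code, so peak
#' working memory beyond the returned matrix is proportional to the block
#' size rather than to \eqn{N^2}.
#'
#' @inheritParams config_distance
#' @param traj a [dihedral_trajectory()] with at least 2 frames.
#' @param block_size rows per block for the blocked computation.
#' @return an object of class `distance_matrix` with fields `values`
#'   (N x N symmetric, zero diagonal), `n_points`, `weight_vector_id`.
#' @export
distance_matrix <- function(traj, weights,
                            form = c("euclidean", "manhattan"),
                            use_rounded = TRUE, block_size = 2048L) {
  assert_trajectory(traj)
  form <- match.arg(form)
  if (n_frames(traj) < 2L)
    stop("insufficient data: need at least 2 frames for a distance matrix")
  w <- resolve_weights(weights, n_torsions(traj), use_rounded)
  vals <- .cpp_distance_matrix(traj$angles, w,
                               if (form == "euclidean") 0L else 1L,
                               as.integer(block_size))
  id <- sprintf("%s[%s]", form,
                paste(format(w, trim = TRUE), collapse = ","))
  new_distance_matrix(vals, weight_vector_id = id)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d x %d (%s)\n", x$n_points, x$n_points,
              x$weight_vector_id))
  invisible(x)
}
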