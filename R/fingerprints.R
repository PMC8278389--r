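# shared periodic binning: bin index on [-pi, pi) with n_bins equal bins
angle_bin <- function(x, n_bins) {
  pmin(floor((wrap_angle(x) + pi) / (2 * pi) * n_bins) + 1L, n_bins)
}

new_fingerprint_set <- function(clusters, bin_edges, angle_names,
                                support_min_count = 1L) {
  structure(list(clusters = clusters, bin_edges = bin_edges,
                 angle_names = angle_names,
                 n_bins = length(bin_edges) - 1L,
                 support_min_count = as.integer(support_min_count)),
            class = "fingerprint_set")
}

#' Build per-cluster torsional fingerprints
#'
#' A fingerprint is, for each cluster, the normalized probability
#' distribution of every torsional angle over a shared periodic bin grid,
#' together with its nonzero-support mask. By default all frames assigned
#' to a cluster — core and halo alike — contribute; `frames = "core"`
#' restricts to core frames.
#'
#' Bins whose raw count falls below `support_min_count` are zeroed (and
#' the distribution renormalized) and excluded from the support; the
#' default of 1 keeps every populated bin, the literal nonzero-probability
#' rule.
#'
#' @param traj the [dihedral_trajectory()] that was clustered.
#' @param labels integer cluster labels (1..K) for every frame, e.g. from
#'   [density_peaks()].
#' @param n_bins bins per angle (default 36, i.e. 10 degrees — coarse
#'   enough that a few hundred reference frames populate a mode's full
#'   support, fine enough to separate modes).
#' @param support_min_count minimum raw count for a bin to stay in the
#'   support.
#' @param frames `"all"` (default) or `"core"`.
#' @param is_core logical vector, required for `frames = "core"`.
#' @return a `fingerprint_set`.
#' @export
build_fingerprints <- function(traj, labels, n_bins = 36,
                               support_min_count = 1, frames = c("all", "core"),
                               is_core = NULL) {
  assert_trajectory(traj)
  frames <- match.arg(frames)
  labels <- as.integer(labels)
  if (length(labels) != n_frames(traj))
    stop("labels length does not match number of frames")
  keep <- labels > 0L
  if (frames == "core") {
    if (is.null(is_core)) stop("frames = 'core' requires is_core")
    keep <- keep & is_core
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    stop("empty cluster set: no frames carry a positive cluster label")
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  bins <- apply(traj$angles, 2, angle_bin, n_bins = n_bins)
  clusters <- lapply(ids, function(cid) {
    sel <- which(keep & labels == cid)
    if (!length(sel))
      stop("empty cluster: no frames available for cluster ", cid)
    counts <- apply(bins[sel, , drop = FALSE], 2, function(b)
      tabulate(b, nbins = n_bins))
    counts[counts < support_min_count] <- 0L
    if (any(colSums(counts) == 0))
      stop("cluster ", cid, ": support_min_count wipes out an entire angle ",
           "distribution")
    probs <- sweep(counts, 2, colSums(counts), "/")
    colnames(probs) <- traj$angle_names
    list(cluster_id = cid, n_frames = length(sel),
         probs = probs, support = probs > 0)
  })
  new_fingerprint_set(clusters, edges, traj$angle_names,
                      support_min_count = support_min_count)
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("Fingerprint set: %d clusters x %d angles, %d bins\n",
              length(x$clusters), length(x$angle_names), x$n_bins))
  invisible(x)
}

#' Classify one frame against a fingerprint set
#'
#' For every cluster, each torsion whose instantaneous value falls in a
#' nonzero-support bin of that cluster's fingerprint contributes 1 to the
#' match score. A frame matches a cluster when its score reaches the
#' number of torsions; a frame matching no cluster is unclassified
#' (label 0). When several clusters reach a full score the tie is broken
#' by the largest product of per-angle bin probabilities
#' (`tie_break = "product"`, the default) or by the lowest cluster id
#' (`"first"`).
#'
#' @param frame numeric angle vector (radians).
#' @param fingerprints a `fingerprint_set`.
#' @param tie_break `"product"` or `"first"`.
#' @return list with `label` (0 = unclassified) and `scores`
#'   (per-cluster integer match scores).
#' @export
classify_frame <- function(frame, fingerprints,
                           tie_break = c("product", "first")) {
  res <- classify_matrix(matrix(frame, nrow = 1L), fingerprints,
                         match.arg(tie_break))
  list(label = res$labels[1], scores = res$scores[1, ])
}

# vectorized core shared by classify_frame / classify_trajectory
classify_matrix <- function(angles, fingerprints, tie_break) {
  if (ncol(angles) != length(fingerprints$angle_names))
    stop(sprintf("frame has %d angles but fingerprints describe %d",
                 ncol(angles), length(fingerprints$angle_names)))
  n <- nrow(angles)
  m <- ncol(angles)
  K <- length(fingerprints$clusters)
  bins <- matrix(angle_bin(angles, fingerprints$n_bins), nrow = n)
  scores <- matrix(0L, n, K)
  logp <- matrix(-Inf, n, K)
  for (c in seq_len(K)) {
    cl <- fingerprints$clusters[[c]]
    sc <- integer(n)
    lp <- numeric(n)
    for (a in seq_len(m)) {
      hit <- cl$support[bins[, a], a]
      sc <- sc + hit
      lp <- lp + ifelse(hit, log(cl$probs[bins[, a], a]), -Inf)
    }
    scores[, c] <- sc
    logp[, c] <- lp
  }
  full <- scores == m
  nfull <- rowSums(full)
  labels <- integer(n)
  one <- nfull == 1L
  labels[one] <- max.col(full[one, , drop = FALSE], ties.method = "first")
  multi <- which(nfull > 1L)
  if (length(multi)) {
    if (tie_break == "product") {
      lp2 <- logp[multi, , drop = FALSE]
      lp2[!full[multi, , drop = FALSE]] <- -Inf
      labels[multi] <- max.col(lp2, ties.method = "first")
    } else {
      labels[multi] <- max.col(full[multi, , drop = FALSE],
                               ties.method = "first")
    }
  }
  cluster_ids <- vapply(fingerprints$clusters, `[[`, integer(1), "cluster_id")
  mapped <- ifelse(labels > 0L, cluster_ids[pmax(labels, 1L)], 0L)
  colnames(scores) <- paste0("C", cluster_ids)
  list(labels = as.integer(mapped), scores = scores)
}

#' Classify every frame of a trajectory
#'
#' Vectorized application of [classify_frame()] over a trajectory.
#'
#' @param traj a [dihedral_trajectory()].
#' @param fingerprints a `fingerprint_set`.
#' @inheritParams classify_frame
#' @return an object of class `classified_trajectory` with `labels`
#'   (0 = unclassified), `scores` (N x K), and `fraction_classified`.
#' @export
classify_trajectory <- function(traj, fingerprints,
                                tie_break = c("product", "first")) {
  assert_trajectory(traj)
  res <- classify_matrix(traj$angles, fingerprints, match.arg(tie_break))
  structure(list(labels = res$labels, scores = res$scores,
                 fraction_classified = mean(res$labels != 0L)),
            class = "classified_trajectory")
}

#' @export
print.classified_trajectory <- function(x, ...) {
  cat(sprintf("Classified trajectory: %d frames, %.1f%% assigned\n",
              length(x$labels), 100 * x$fraction_classified))
  tab <- table(x$labels[x$labels != 0])
  if (length(tab)) print(tab)
  invisible(x)
}
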