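#' Wrap angles onto the canonical interval [-pi, pi)
#'
#' All torsional angles in the package live on the half-open interval
#' \eqn{[-\pi, \pi)}. A single convention avoids double counting of the
#' \eqn{\pm\pi} boundary when binning periodic histograms.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, every value in `[-pi, pi)`.
#' @examples
#' wrap_angle(3.5)        # -> 3.5 - 2*pi
#' wrap_angle(wrap_angle(3.5)) == wrap_angle(3.5)  # idempotent
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  # %% can return 2*pi for values a hair below the boundary; fold those back
  w[w >= pi] <- -pi
  w
}

#' Construct a dihedral-angle trajectory
#'
#' The central data container: an `N_frames x N_CV` matrix of torsional
#' angles (radians), with optional per-frame timestamps, total bias
#' potential (kJ/mol, e.g. the final well-tempered metadynamics bias
#' evaluated at each frame) and potential-energy components (kJ/mol) used
#' in the enthalpy/entropy decomposition.
#'
#' Angles are wrapped to `[-pi, pi)` on construction.
#'
#' @param angles numeric matrix, frames in rows, torsions in columns.
#' @param angle_names character vector of unique torsion labels; defaults
#'   to the matrix column names or `tau1..tauM`.
#' @param time optional numeric vector of frame times (ps).
#' @param bias optional numeric vector, per-frame total bias (kJ/mol).
#' @param energy_solute,energy_solvent,energy_solute_solvent optional
#'   numeric vectors of per-frame potential-energy components (kJ/mol).
#' @param degrees logical; if `TRUE`, `angles` are given in degrees and
#'   converted to radians immediately.
#' @return an object of class `dihedral_trajectory`.
#' @export
dihedral_trajectory <- function(angles, angle_names = NULL, time = NULL,
                                bias = NULL, energy_solute = NULL,
                                energy_solvent = NULL,
                                energy_solute_solvent = NULL,
                                degrees = FALSE) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  if (ncol(angles) < 1L)
    stop("trajectory needs at least one torsional angle (N_CV >= 1)")
  if (nrow(angles) < 1L)
    stop("empty trajectory: no frames")
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("non-finite angle values in trajectory")
  if (degrees) angles <- angles * pi / 180
  angles <- wrap_angle(angles)
  if (is.null(angle_names)) {
    angle_names <- colnames(angles)
    if (is.null(angle_names)) angle_names <- paste0("tau", seq_len(ncol(angles)))
  }
  angle_names <- as.character(angle_names)
  if (length(angle_names) != ncol(angles))
    stop("angle_names length does not match number of angle columns")
  if (anyDuplicated(angle_names))
    stop("angle_names must be unique")
  colnames(angles) <- angle_names
  n <- nrow(angles)
  chk <- function(v, what) {
    if (is.null(v)) return(NULL)
    v <- as.numeric(v)
    if (length(v) != n)
      stop(sprintf("%s has %d entries but trajectory has %d frames",
                   what, length(v), n))
    v
  }
  structure(
    list(angles = angles,
         angle_names = angle_names,
         time = chk(time, "time"),
         bias = chk(bias, "bias"),
         energy_solute = chk(energy_solute, "energy_solute"),
         energy_solvent = chk(energy_solvent, "energy_solvent"),
         energy_solute_solvent = chk(energy_solute_solvent,
                                     "energy_solute_solvent")),
    class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf("Dihedral trajectory: %d frames x %d torsions (%s)\n",
              nrow(x$angles), ncol(x$angles),
              paste(x$angle_names, collapse = ", ")))
  extras <- c("time", "bias", "energy_solute", "energy_solvent",
              "energy_solute_solvent")
  have <- extras[!vapply(x[extras], is.null, logical(1))]
  if (length(have)) cat("  with columns:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / torsions in a trajectory
#' @param traj a `dihedral_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$angles)

#' @rdname n_frames
#' @export
n_torsions <- function(traj) ncol(traj$angles)

# internal: stop unless x is a dihedral_trajectory
assert_trajectory <- function(x) {
  if (!inherits(x, "dihedral_trajectory"))
    stop("expected a 'dihedral_trajectory' object")
  invisible(x)
}

#' Subset frames of a trajectory
#'
#' Keeps all optional columns aligned with the retained frames.
#'
#' @param traj a `dihedral_trajectory`.
#' @param idx integer or logical frame index.
#' @param stride alternatively, keep every `stride`-th frame.
#' @return a `dihedral_trajectory` with the selected frames.
#' @export
subset_frames <- function(traj, idx = NULL, stride = NULL) {
  assert_trajectory(traj)
  if (is.null(idx)) {
    if (is.null(stride)) stop("give either idx or stride")
    idx <- seq(1L, n_frames(traj), by = as.integer(stride))
  }
  pick <- function(v) if (is.null(v)) NULL else v[idx]
  dihedral_trajectory(traj$angles[idx, , drop = FALSE],
                      angle_names = traj$angle_names,
                      time = pick(traj$time), bias = pick(traj$bias),
                      energy_solute = pick(traj$energy_solute),
                      energy_solvent = pick(traj$energy_solvent),
                      energy_solute_solvent = pick(traj$energy_solute_solvent))
}
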