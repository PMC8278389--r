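#' One-dimensional torsional free-energy profile
#'
#' Estimates \eqn{F(\theta) = -\ln p(\theta)} (in units of \eqn{k_B T})
#' from a (optionally weighted) periodic histogram of one torsional angle,
#' shifts the profile so its minimum is exactly zero, and locates minima
#' and maxima on the periodic grid. Empty bins receive an infinite
#' sentinel and are skipped by the barrier search.
#'
#' Extrema are located on a lightly smoothed profile (circular moving
#' average of the histogram, window `smooth_window` bins) to suppress
#' single-bin sampling noise; the reported `free_energy` vector itself is
#' unsmoothed.
#'
#' @param traj a [dihedral_trajectory()].
#' @param angle angle name or column index.
#' @param n_bins number of periodic bins over `[-pi, pi)` (default 72,
#'   i.e. 5 degree resolution); must be at least 8.
#' @param temperature simulation temperature in kelvin; only used when
#'   `units = "kJ/mol"`.
#' @param frame_weights optional nonnegative per-frame weights (e.g. from
#'   [reweight()]); uniform weights reproduce the unweighted profile.
#' @param smooth_window odd integer width (bins) of the circular moving
#'   average used for extrema detection; 1 disables smoothing.
#' @param min_barrier persistence threshold in \eqn{k_B T}: neighboring
#'   minima separated by a barrier below this are merged into the deeper
#'   one before the barrier search (default 1 — a sub-\eqn{k_B T}
#'   crossing is a conformational adjustment, not a transition, and
#'   under-sampled tail bins would otherwise masquerade as basins). Set
#'   to 0 to keep every raw local minimum.
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @return an object of class `torsion_profile` with fields
#'   `angle_name`, `bin_centers`, `free_energy`, `minima_idx`,
#'   `maxima_idx`, `lowest_barrier`, `unimodal`, `censored_barrier`.
#' @export
free_energy_profile <- function(traj, angle, n_bins = 72,
                                temperature = 300,
                                frame_weights = NULL,
                                smooth_window = 3, min_barrier = 1,
                                units = c("kT", "kJ/mol")) {
  assert_trajectory(traj)
  units <- match.arg(units)
  if (n_bins < 8) stop("n_bins must be at least 8")
  if (is.character(angle)) {
    if (!angle %in% traj$angle_names) stop("unknown angle: ", angle)
    aname <- angle
  } else aname <- traj$angle_names[angle]
  x <- traj$angles[, aname]
  n <- length(x)
  if (is.null(frame_weights)) frame_weights <- rep(1, n)
  if (length(frame_weights) != n)
    stop("frame_weights length does not match number of frames")
  if (any(frame_weights < 0) || all(frame_weights == 0))
    stop("frame_weights must be nonnegative and not all zero")

  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  centers <- edges[-1] - diff(edges) / 2
  bin <- pmin(floor((x + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  counts <- as.numeric(tapply(frame_weights, factor(bin, levels = seq_len(n_bins)),
                              sum, default = 0))
  p <- counts / sum(counts)
  f_raw <- ifelse(p > 0, -log(p), Inf)
  f <- f_raw - min(f_raw)

  # smoothed probabilities for extrema detection
  ps <- circular_ma(p, smooth_window)
  fs <- ifelse(ps > 0, -log(ps), Inf)
  fs <- fs - min(fs)

  ext <- periodic_extrema(fs)
  minima <- prune_minima(fs, ext$minima, min_barrier)
  unimodal <- length(minima) < 2L
  if (sum(p > 0) <= 1L) {
    warning("degenerate profile: all frames fall in a single bin")
    unimodal <- TRUE
    minima <- minima[seq_len(min(1L, length(minima)))]
  }
  barrier <- NA_real_
  censored <- FALSE
  maxima <- integer(0)
  if (!unimodal) {
    segs <- crossing_costs(fs, minima)
    maxima <- vapply(segs, `[[`, integer(1), "top_idx")
    b <- lowest_crossing(fs, minima, segs)
    barrier <- b$barrier
    censored <- b$censored
  } else if (length(ext$maxima)) {
    maxima <- ext$maxima[seq_len(min(length(minima), length(ext$maxima)))]
  }
  scale <- if (units == "kJ/mol") 0.0083144621 * temperature else 1
  structure(list(angle_name = aname,
                 bin_centers = centers,
                 free_energy = f * scale,
                 smoothed_free_energy = fs * scale,
                 minima_idx = minima,
                 maxima_idx = sort(maxima),
                 lowest_barrier = barrier * scale,
                 unimodal = unimodal,
                 censored_barrier = censored,
                 n_bins = n_bins, units = units,
                 temperature = temperature),
            class = "torsion_profile")
}

# circular moving average, window w (odd); w = 1 returns x unchanged
circular_ma <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) stop("smooth_window must be odd")
  k <- (w - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (s in seq_len(k)) {
    out <- out + x[((seq_len(n) - 1 + s) %% n) + 1] +
      x[((seq_len(n) - 1 - s) %% n) + 1]
  }
  out / w
}

# Local minima and maxima of a periodic sequence, plateau-aware.
# Runs of equal values are collapsed; a run is a minimum (maximum) when
# both neighboring distinct runs are higher (lower). Returns one
# representative index (middle of the run). Infinite values may form
# maxima runs; they never form minima for profiles (Inf = empty bin).
periodic_extrema <- function(f) {
  n <- length(f)
  if (n < 3L || length(unique(f)) == 1L)
    return(list(minima = integer(0), maxima = integer(0)))
  # run-length encode circularly
  r <- rle(f)
  vals <- r$values
  lens <- r$lengths
  if (length(vals) > 1L && vals[1] == vals[length(vals)]) {
    # merge wrap-around run
    lens[1] <- lens[1] + lens[length(vals)]
    start_offset <- r$lengths[length(vals)]
    vals <- vals[-length(vals)]
    lens <- lens[-length(lens)]
  } else start_offset <- 0L
  m <- length(vals)
  if (m == 1L) return(list(minima = integer(0), maxima = integer(0)))
  starts <- (cumsum(c(0, lens[-m])) - start_offset) %% n + 1L
  mids <- (starts - 1L + (lens - 1L) %/% 2L) %% n + 1L
  minima <- integer(0); maxima <- integer(0)
  for (i in seq_len(m)) {
    prev <- vals[if (i == 1L) m else i - 1L]
    nxt <- vals[if (i == m) 1L else i + 1L]
    if (vals[i] < prev && vals[i] < nxt) minima <- c(minima, mids[i])
    if (vals[i] > prev && vals[i] > nxt && is.finite(vals[i]))
      maxima <- c(maxima, mids[i])
    if (is.infinite(vals[i]) && vals[i] > 0) maxima <- c(maxima, mids[i])
  }
  list(minima = sort(minima), maxima = sort(maxima))
}

# Segment structure between adjacent cyclic minima. For each forward
# segment minima[a] -> minima[a+1] the top is the highest FINITE bin
# strictly between them (empty/infinite bins are skipped); a segment
# whose gap holds no finite bin at all is censored: the two basins are
# separated by entirely unsampled territory, and the top index falls on
# the first empty bin as a placeholder.
crossing_costs <- function(f, minima) {
  n <- length(f)
  k <- length(minima)
  lapply(seq_len(k), function(a) {
    b <- if (a == k) 1L else a + 1L
    i <- minima[a]; j <- minima[b]
    path <- if (i < j) (if (j - i > 1L) seq(i + 1L, j - 1L) else integer(0))
    else c(if (i < n) seq(i + 1L, n) else integer(0),
           if (j > 1L) seq_len(j - 1L) else integer(0))
    fin <- path[is.finite(f[path])]
    if (length(fin)) {
      top_idx <- fin[which.max(f[fin])]
      list(a = a, b = b, top = f[top_idx], top_idx = top_idx,
           censored = FALSE)
    } else {
      list(a = a, b = b, top = Inf,
           top_idx = if (length(path)) path[1] else i, censored = TRUE)
    }
  })
}

# Merge minima separated by sub-threshold barriers (persistence pruning):
# repeatedly find the cheapest directed crossing between adjacent minima
# and, while it costs less than the threshold, drop its departing (i.e.
# shallower) minimum. Censored crossings separate genuinely unconnected
# basins and are never pruned.
prune_minima <- function(f, minima, threshold) {
  while (length(minima) >= 2L) {
    segs <- crossing_costs(f, minima)
    best <- Inf; drop_pos <- NA_integer_
    for (s in segs) {
      if (s$censored) next
      for (pos in c(s$a, s$b)) {
        cost <- s$top - f[minima[pos]]
        if (cost < best) { best <- cost; drop_pos <- pos }
      }
    }
    if (!is.finite(best) || best >= threshold) break
    minima <- minima[-drop_pos]
  }
  minima
}

# Lowest directed barrier over the surviving minima. Finite crossings
# cost top - f(departing minimum); if only censored crossings exist the
# best available lower bound (global finite maximum as top) is reported
# with the censored flag.
lowest_crossing <- function(f, minima, segs) {
  best <- Inf
  for (s in segs) {
    if (s$censored) next
    best <- min(best, s$top - f[minima[s$a]], s$top - f[minima[s$b]])
  }
  if (is.finite(best)) return(list(barrier = best, censored = FALSE))
  global_cap <- max(f[is.finite(f)])
  best <- min(vapply(segs, function(s)
    global_cap - min(f[minima[s$a]], f[minima[s$b]]), numeric(1)))
  list(barrier = best, censored = TRUE)
}

#' Lowest rotational free-energy barrier of a torsion profile
#'
#' Enumerates all directed transitions between adjacent (cyclic) minima;
#' the cost of a transition is the intervening maximum minus the free
#' energy of the departing minimum. Returns the minimum such cost.
#'
#' @param profile a `torsion_profile`.
#' @return scalar barrier in the profile's units.
#' @export
lowest_rotational_barrier <- function(profile) {
  if (!inherits(profile, "torsion_profile"))
    stop("expected a 'torsion_profile'")
  if (profile$unimodal || length(profile$minima_idx) < 2L)
    stop("no barrier: profile of '", profile$angle_name, "' is unimodal")
  profile$lowest_barrier
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat(sprintf("Torsion profile '%s': %d bins, %d minima, %d maxima\n",
              x$angle_name, x$n_bins, length(x$minima_idx),
              length(x$maxima_idx)))
  if (!x$unimodal)
    cat(sprintf("  lowest rotational barrier: %.3f %s%s\n",
                x$lowest_barrier, x$units,
                if (x$censored_barrier) " (censored: unsampled gap)" else ""))
  else cat("  unimodal profile: no rotational barrier\n")
  invisible(x)
}

#' @export
plot.torsion_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  graphics::plot(x$bin_centers[ok], x$free_energy[ok], type = "l",
                 xlab = expression(theta ~ "(rad)"),
                 ylab = paste0("F (", x$units, ")"),
                 main = x$angle_name, ...)
  graphics::points(x$bin_centers[x$minima_idx],
                   x$free_energy[x$minima_idx], pch = 19, col = "blue")
  graphics::points(x$bin_centers[x$maxima_idx],
                   pmin(x$free_energy[x$maxima_idx],
                        max(x$free_energy[ok])), pch = 4, col = "red")
  invisible(x)
}

# round half away from zero at `digits` decimals (so 1.25 -> 1.3)
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Normalized clustering weights from rotational barriers
#'
#' Each torsion's weight is its lowest rotational barrier divided by the
#' smallest barrier among all torsions, so the easiest rotation carries
#' weight 1 and harder rotations count proportionally more in the
#' configuration distance. Weights are additionally rounded
#' half-away-from-zero to one decimal, the form in which they are
#' typically tabulated; the distance metric uses the rounded weights by
#' default (switchable, see [config_distance()]).
#'
#' @param barriers named or unnamed numeric vector of per-torsion lowest
#'   rotational barriers (any common energy unit); all must be positive.
#' @return an object of class `torsion_weights` with fields `raw`,
#'   `normalized`, `rounded`.
#' @examples
#' compute_weights(c(tauA = 6, tauB = 1.5, tauC = 2,
#'                   tauD = 1.2, tauE = 2.5, tauF = 4))$rounded
#' @export
compute_weights <- function(barriers) {
  barriers <- unlist(barriers)
  if (!is.numeric(barriers) || !length(barriers))
    stop("barriers must be a non-empty numeric vector")
  if (any(!is.finite(barriers)) || any(barriers <= 0))
    stop("all barriers must be positive and finite")
  normalized <- barriers / min(barriers)
  structure(list(raw = barriers,
                 normalized = normalized,
                 rounded = round_half_away(normalized, 1)),
            class = "torsion_weights")
}

#' @export
print.torsion_weights <- function(x, ...) {
  tab <- data.frame(barrier = x$raw, weight = x$rounded)
  if (!is.null(names(x$raw))) rownames(tab) <- names(x$raw)
  cat("Torsion clustering weights (barrier / lowest barrier):\n")
  print(tab)
  invisible(x)
}

# internal: accept a torsion_weights or plain numeric vector
resolve_weights <- function(weights, n_cv, use_rounded = TRUE) {
  w <- if (inherits(weights, "torsion_weights")) {
    if (use_rounded) weights$rounded else weights$normalized
  } else as.numeric(weights)
  if (length(w) != n_cv)
    stop(sprintf("weight vector has length %d but trajectory has %d torsions",
                 length(w), n_cv))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite")
  w
}
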