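#' Deterministic quasi-uniform sphere lattice
#'
#' Golden-angle (Fibonacci) lattice of `n` points on the unit sphere. Fully
#' deterministic, so surface areas are bit-reproducible.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (rolling-probe point sampling)
#'
#' Shrake-Rupley SASA: for each atom, points are placed on the sphere of
#' radius `r_i + probe` using a deterministic quasi-uniform lattice; a point
#' is accessible if it lies outside the expanded sphere `r_j + probe` of
#' every other atom. The per-atom area is `4*pi*(r_i+probe)^2` times the
#' accessible point fraction. Computed on heavy atoms by default, matching
#' the convention of standard accessibility programs.
#'
#' @param coords N x 3 frame coordinates (Angstrom) or a `serp_trajectory`
#'   (with `frame`).
#' @param topology a `serp_topology` supplying van der Waals radii.
#' @param probe probe radius (Angstrom, default 1.4, a water molecule).
#' @param n_points lattice points per atom (default 960).
#' @param heavy_only exclude hydrogens (default TRUE).
#' @param frame frame index when `coords` is a trajectory.
#' @return list of class `sasa_result`: `per_atom` (area per included atom,
#'   Angstrom^2, named by atom index), `per_residue` data frame, `total`,
#'   `probe`, `n_points`.
#' @export
shrake_rupley <- function(coords, topology = NULL, probe = 1.4,
                          n_points = 960, heavy_only = TRUE, frame = 1) {
  if (inherits(coords, "serp_trajectory")) {
    if (is.null(topology)) topology <- coords$topology
    coords <- frame_coords(coords, frame)
  }
  at <- topology$atoms
  idx <- if (heavy_only) which(!at$is_hydrogen) else seq_len(nrow(at))
  if (!length(idx)) stop("no atoms included")
  radii <- at$vdw_radius[idx]
  if (anyNA(radii) || any(radii <= 0)) stop("missing or non-positive vdw radius")
  xyz <- coords[idx, , drop = FALSE]
  rr <- radii + probe
  lattice <- fibonacci_sphere(n_points)
  n <- length(idx)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(lattice * rr[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    dc <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dc < rr[i] + rr & seq_len(n) != i)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- colSums((t(pts[acc, , drop = FALSE]) - xyz[j, ])^2)
      acc[acc] <- d2 > rr[j]^2
    }
    area[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_points
  }
  names(area) <- idx
  rkey <- paste(at$chain[idx], at$resid[idx], sep = ":")
  pr <- stats::aggregate(area, by = list(key = rkey), FUN = sum)
  first <- !duplicated(rkey)
  ord <- match(unique(rkey), pr$key)
  per_residue <- data.frame(
    chain = at$chain[idx][first], resid = at$resid[idx][first],
    resname = at$resname[idx][first], area = pr$x[ord],
    stringsAsFactors = FALSE
  )
  structure(list(per_atom = area, per_residue = per_residue,
                 total = sum(area), probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Trailing-window SASA of a trajectory
#'
#' Computes the total accessible area for every frame in the trailing time
#' window and returns its mean and standard deviation, the time-averaged
#' summary used for stationary structural comparisons.
#'
#' @param traj a `serp_trajectory`.
#' @param window trailing window in ns (default 20); must not exceed the
#'   series span.
#' @param ... arguments passed to [shrake_rupley()].
#' @return list with `mean`, `sd`, `totals` and `times` (window frames only).
#' @export
trajectory_sasa <- function(traj, window = 20, ...) {
  times <- traj$times
  keep <- .trailing_frames(times, window)
  totals <- vapply(keep, function(k)
    shrake_rupley(frame_coords(traj, k), traj$topology, ...)$total, numeric(1))
  list(mean = mean(totals),
       sd = if (length(totals) > 1) stats::sd(totals) else 0,
       totals = totals, times = times[keep])
}
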