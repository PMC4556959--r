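# All generators are deterministic under (spec, seed) and return their ground
# truth alongside the data, so downstream checks can be exact.

#' Specify a prescribed per-atom covariance structure
#'
#' Assembles a 3N x 3N positive-definite covariance from isotropic per-atom
#' marginals plus planted per-axis cross-correlations between chosen atom
#' pairs. Positive definiteness is verified at build time.
#'
#' @param n_atoms number of atoms.
#' @param sigma per-atom fluctuation standard deviation per axis (Angstrom);
#'   scalar or length `n_atoms`.
#' @param cross optional data frame with columns `i`, `j`, `rho`: per-axis
#'   correlation `rho` between like axes of atoms i and j.
#' @return object of class `cov_spec` with the assembled `Sigma`.
#' @export
covariance_spec <- function(n_atoms, sigma = 0.5, cross = NULL) {
  stopifnot(n_atoms >= 1)
  sigma <- rep_len(sigma, n_atoms)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  n3 <- 3 * n_atoms
  Sigma <- diag(rep(sigma^2, each = 3), n3)
  if (!is.null(cross)) {
    stopifnot(all(c("i", "j", "rho") %in% names(cross)))
    for (r in seq_len(nrow(cross))) {
      i <- cross$i[r]; j <- cross$j[r]; rho <- cross$rho[r]
      if (i == j || i < 1 || j < 1 || i > n_atoms || j > n_atoms)
        stop("invalid cross-correlation pair (", i, ", ", j, ")")
      v <- sigma[i] * sigma[j] * rho
      bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
      Sigma[cbind(bi, bj)] <- v
      Sigma[cbind(bj, bi)] <- v
    }
  }
  if (any(sigma > 0)) {
    ok <- tryCatch({ chol(Sigma[rep(sigma, each = 3) > 0,
                                 rep(sigma, each = 3) > 0, drop = FALSE]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("assembled covariance is not positive definite")
  }
  structure(list(n_atoms = n_atoms, sigma = sigma, cross = cross,
                 Sigma = Sigma), class = "cov_spec")
}

.generic_topology <- function(n_atoms, resname = "GLY", name = "CA",
                              element = "C") {
  atoms <- data.frame(
    name = rep_len(name, n_atoms), element = rep_len(element, n_atoms),
    resname = rep_len(resname, n_atoms), resid = seq_len(n_atoms),
    chain = "A", stringsAsFactors = FALSE
  )
  atoms
}

#' Sample a Gaussian coordinate ensemble with known covariance
#'
#' Frames are drawn i.i.d. from a multivariate normal around a mean
#' structure, giving an ensemble whose true fluctuation covariance is the
#' spec's matrix; the closed-form target for covariance/RMSF/LMI estimators.
#'
#' @param spec a `cov_spec`.
#' @param n_frames number of frames.
#' @param seed RNG seed (deterministic output).
#' @param mean_structure optional N x 3 mean coordinates; default places the
#'   atoms 10 Angstrom apart on a line.
#' @param dt frame spacing (ns).
#' @return list with `traj` (a `serp_trajectory` of pseudo C-alpha atoms) and
#'   `truth` (the 3N x 3N covariance).
#' @export
gen_gaussian_trajectory <- function(spec, n_frames, seed = 1,
                                    mean_structure = NULL, dt = 0.1) {
  stopifnot(inherits(spec, "cov_spec"), n_frames >= 1)
  n <- spec$n_atoms
  if (is.null(mean_structure))
    mean_structure <- cbind(10 * (seq_len(n) - 1), 0, 0)
  mean_structure <- as.matrix(mean_structure)
  stopifnot(nrow(mean_structure) == n, ncol(mean_structure) == 3)
  set.seed(seed)
  n3 <- 3 * n
  dev <- matrix(0, n_frames, n3)
  live <- rep(spec$sigma, each = 3) > 0
  if (any(live)) {
    ch <- chol(spec$Sigma[live, live, drop = FALSE])
    z <- matrix(stats::rnorm(n_frames * sum(live)), n_frames)
    dev[, live] <- z %*% ch
  }
  coords <- array(0, c(n_frames, n, 3))
  mu_flat <- as.numeric(t(mean_structure))  # atom-major x,y,z
  for (k in seq_len(n_frames))
    coords[k, , ] <- matrix(mu_flat + dev[k, ], ncol = 3, byrow = TRUE)
  top <- topology_from_atoms(.generic_topology(n), mean_structure)
  list(traj = new_trajectory(top, coords, times = (seq_len(n_frames) - 1) * dt),
       truth = spec$Sigma)
}

# deterministic choice of "contact on" frames: exact count, seeded order
.planted_frames <- function(n_frames, fraction, seed) {
  n_on <- ceiling(fraction * n_frames)
  if (n_on == 0) return(integer(0))
  set.seed(seed)
  sort(sample.int(n_frames, n_on))
}

#' Generate a planted-interaction geometry rig
#'
#' Builds a minimal two-residue system (a Glu-like acidic group facing an
#' Arg-like guanidinium for salt bridges, or a backbone N-H donor facing a
#' carbonyl O acceptor for hydrogen bonds) whose contact geometry satisfies
#' the detection criteria in exactly `ceiling(fraction * n_frames)` frames
#' (chosen deterministically from the seed) and violates the distance cutoff
#' by at least 0.5 Angstrom in all others. Occupancy checks on the output are
#' therefore exact equalities.
#'
#' @param kind `"saltbridge"` or `"hbond"`.
#' @param fraction target occupancy in `[0, 1]`.
#' @param n_frames number of frames.
#' @param target_distance contact distance (Angstrom, default 2.8); the
#'   donor-acceptor distance for H-bonds, oxygen-hydrogen for salt bridges.
#' @param target_angle H-bond D-H/D-A angle in contact frames (deg, default
#'   0); must be < 90.
#' @param d_cut cutoff the off frames must violate (default 3.0).
#' @param seed RNG seed for the frame schedule.
#' @param resid_a,resid_b residue numbers given to the two groups.
#' @return list with `traj` (annotated topology) and `truth` (planted pair,
#'   contact frames, exact occupancy).
#' @export
gen_interaction_rig <- function(kind = c("saltbridge", "hbond"),
                                fraction = 0.5, n_frames = 10,
                                target_distance = 2.8, target_angle = 0,
                                d_cut = 3.0, seed = 1,
                                resid_a = 289, resid_b = 362) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (target_distance <= 0) stop("target_distance must be positive")
  if (target_angle < 0 || target_angle >= 90)
    stop("target_angle must be in [0, 90) degrees")
  if (target_distance > d_cut)
    stop("target_distance exceeds the cutoff; contact frames impossible")

  if (kind == "saltbridge") {
    # GLU: CD with carboxylate OE1/OE2; ARG: NH1 with HH11 pointing at OE1
    atoms <- data.frame(
      name = c("CD", "OE1", "OE2", "NH1", "HH11", "NE", "HE"),
      element = c("C", "O", "O", "N", "H", "N", "H"),
      resname = c(rep("GLU", 3), rep("ARG", 4)),
      resid = c(rep(resid_a, 3), rep(resid_b, 4)),
      chain = "A", stringsAsFactors = FALSE
    )
    base <- function(gap) rbind(
      c(-1.25, 0, 0),            # CD
      c(0, 0, 0),                # OE1
      c(-1.85, 1.05, 0),         # OE2 (off-axis, stays > cutoff from H)
      c(gap + 1.0, 0, 0),        # NH1
      c(gap, 0, 0),              # HH11, points at OE1
      c(gap + 2.3, 0.4, 0),      # NE
      c(gap + 2.3, 1.4, 0)       # HE
    )
    on_coords <- base(target_distance)
    off_coords <- base(d_cut + 0.5 + 0.5)   # violates cutoff by >= 0.5 A
    pair_atoms <- c(2L, 5L)
  } else {
    # donor residue: backbone N-H; acceptor residue: carbonyl O
    atoms <- data.frame(
      name = c("N", "H", "CA", "O", "C"),
      element = c("N", "H", "C", "O", "C"),
      resname = "GLY",
      resid = c(rep(resid_a, 3), rep(resid_b, 2)),
      chain = "A", stringsAsFactors = FALSE
    )
    th <- target_angle * pi / 180
    place <- function(d) rbind(
      c(0, 0, 0),                          # N (donor)
      c(1.0, 0, 0),                        # H along +x
      c(-0.9, 1.1, 0),                     # CA
      d * c(cos(th), sin(th), 0),          # O at angle th from D->H
      d * c(cos(th), sin(th), 0) + c(0.6, 1.1, 0)  # C
    )
    on_coords <- place(target_distance)
    off_coords <- place(d_cut + 0.5 + 0.5)
    pair_atoms <- c(1L, 4L)
  }
  top <- topology_from_atoms(atoms, on_coords)
  top <- annotate_chemistry(top)
  frames_on <- .planted_frames(n_frames, fraction, seed)
  coords <- array(NA_real_, c(n_frames, nrow(atoms), 3))
  for (k in seq_len(n_frames))
    coords[k, , ] <- if (k %in% frames_on) on_coords else off_coords
  traj <- new_trajectory(top, coords, times = (seq_len(n_frames) - 1) * 0.1)
  truth <- list(
    kind = kind, pair_atoms = pair_atoms,
    resid_a = resid_a, resid_b = resid_b,
    frames_on = frames_on,
    occupancy = length(frames_on) / n_frames,
    target_distance = target_distance, target_angle = target_angle,
    seed = seed
  )
  list(traj = traj, truth = truth)
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

#' Generate a rigid-body tumbling trajectory
#'
#' Applies an independent random proper rotation and translation to a base
#' structure in every frame. Internal geometry is exact, so any residual
#' fluctuation after superposition is numerical error.
#'
#' @param base_coords N x 3 base structure (N >= 3).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param topology optional matching `serp_topology`; default pseudo
#'   C-alpha chain.
#' @param translation_scale uniform translation half-range (Angstrom).
#' @return a `serp_trajectory`.
#' @export
gen_rigid_tumble <- function(base_coords, n_frames, seed = 1, topology = NULL,
                             translation_scale = 10) {
  base_coords <- as.matrix(base_coords)
  if (nrow(base_coords) < 3) stop("need at least 3 atoms")
  set.seed(seed)
  n <- nrow(base_coords)
  coords <- array(NA_real_, c(n_frames, n, 3))
  for (k in seq_len(n_frames)) {
    rot <- .random_rotation()
    tr <- stats::runif(3, -translation_scale, translation_scale)
    coords[k, , ] <- sweep(base_coords %*% rot, 2, tr, `+`)
  }
  if (is.null(topology))
    topology <- topology_from_atoms(.generic_topology(n), base_coords)
  new_trajectory(topology, coords, times = (seq_len(n_frames) - 1) * 0.1)
}

#' Generate a noisy sigmoidal denaturation curve with known parameters
#'
#' Single or double Boltzmann transition plus additive Gaussian noise whose
#' standard deviation is a percentage of the curve's dynamic range (the sum
#' of absolute transition amplitudes).
#'
#' @param midpoints transition midpoints, within `x_range`.
#' @param widths transition widths (> 0), recycled.
#' @param amplitudes transition amplitudes, recycled.
#' @param baseline shared baseline.
#' @param noise_pct noise standard deviation as percent of dynamic range.
#' @param n_points number of x points.
#' @param x_range length-2 range of x.
#' @param seed RNG seed.
#' @return list with `curve` (a `serp_curve`) and `truth` (all parameters).
#' @export
gen_denaturation_curve <- function(midpoints, widths = 0.15, amplitudes = 1,
                                   baseline = 0, noise_pct = 1,
                                   n_points = 25, x_range = c(0, 5),
                                   seed = 1) {
  k <- length(midpoints)
  widths <- rep_len(widths, k)
  amplitudes <- rep_len(amplitudes, k)
  if (any(midpoints < x_range[1] | midpoints > x_range[2]))
    stop("midpoints must lie within x_range")
  if (any(widths <= 0)) stop("widths must be positive")
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  y0 <- .sigmoid_model(x, baseline, amplitudes, midpoints, widths)
  set.seed(seed)
  sd_noise <- noise_pct / 100 * sum(abs(amplitudes))
  y <- y0 + stats::rnorm(n_points, 0, sd_noise)
  list(curve = new_curve(x, y, kind = "denaturation"),
       truth = list(midpoints = sort(midpoints), widths = widths,
                    amplitudes = amplitudes, baseline = baseline,
                    noise_sd = sd_noise, seed = seed))
}

#' Generate a Gaussian emission band
#'
#' Unit-peak Gaussian spectrum for first-moment checks; warns when the grid
#' truncates the band (within 4 widths of the centre), since truncation
#' biases the moment towards the retained side.
#'
#' @param center band centre (nm).
#' @param width Gaussian sigma (nm).
#' @param grid wavelength grid; default symmetric over centre +/- 4 widths.
#' @return a `serp_curve`.
#' @export
gen_spectrum <- function(center, width,
                         grid = seq(center - 4 * width, center + 4 * width,
                                    length.out = 201)) {
  stopifnot(width > 0)
  if (min(grid) > center - 4 * width + 1e-9 ||
      max(grid) < center + 4 * width - 1e-9)
    warning("grid truncates the band; first moment will be biased")
  y <- exp(-(grid - center)^2 / (2 * width^2))
  new_curve(grid, y, kind = "spectrum")
}
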