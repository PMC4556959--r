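#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets. Reflections are excluded, so
#' the returned rotation always has determinant +1.
#'
#' @param mobile N x 3 matrix to be moved (Angstrom).
#' @param reference N x 3 target matrix.
#' @param weights optional non-negative weights of length N (e.g. masses).
#' @return list of class `kabsch_fit` with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom) and `coords` (the transformed mobile set).
#'   The transform maps a row vector x to `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("need matched N x 3 point sets with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative, length N, with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  cc <- crossprod(p * w, q)
  sv <- svd(cc)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2)
    stop("degenerate (collinear or coincident) point set")
  s <- sign(det(sv$u) * det(sv$v))
  if (s == 0) s <- 1
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  moved <- p %*% rot
  rmsd <- sqrt(sum(w * rowSums((moved - q)^2)))
  translation <- as.numeric(cr - cm %*% rot)
  out <- list(rotation = rot, translation = translation, rmsd = rmsd,
              coords = sweep(mobile %*% rot, 2, translation, `+`))
  class(out) <- "kabsch_fit"
  out
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> rmsd = %.4g A, det(R) = %.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Remove global translation and rotation from a trajectory
#'
#' Superposes every frame on a reference structure using the selected atoms,
#' applying each frame's rigid transform to all atoms. With
#' `reference = "iterated-mean"` the frames are first fitted to frame 1, then
#' repeatedly re-fitted to the running mean structure until the mean moves by
#' less than `tol` (maximum coordinate shift).
#'
#' @param traj a `serp_trajectory`.
#' @param reference `"iterated-mean"` (default) or `"first-frame"`.
#' @param selection atoms used to compute the fit (see [select_atoms()]);
#'   default `"all"`.
#' @param weights optional per-selected-atom weights.
#' @param tol mean-structure convergence threshold (Angstrom).
#' @param max_iter iteration cap for the mean-structure refinement.
#' @return The fitted `serp_trajectory`.
#' @export
fit_trajectory <- function(traj, reference = c("iterated-mean", "first-frame"),
                           selection = "all", weights = NULL,
                           tol = 1e-6, max_iter = 50) {
  reference <- match.arg(reference)
  sel <- select_atoms(traj, selection)
  if (!length(sel)) stop("empty selection")
  tt <- n_frames(traj)
  coords <- traj$coords

  fit_all <- function(coords, ref_sel) {
    for (k in seq_len(tt)) {
      fr <- matrix(coords[k, , ], ncol = 3)
      f <- kabsch_superpose(fr[sel, , drop = FALSE], ref_sel, weights)
      coords[k, , ] <- sweep(fr %*% f$rotation, 2, f$translation, `+`)
    }
    coords
  }
  mean_sel <- function(coords) {
    m <- matrix(0, length(sel), 3)
    for (k in seq_len(tt)) m <- m + matrix(coords[k, , ], ncol = 3)[sel, , drop = FALSE]
    m / tt
  }

  ref <- matrix(coords[1, , ], ncol = 3)[sel, , drop = FALSE]
  coords <- fit_all(coords, ref)
  if (reference == "iterated-mean" && tt > 1) {
    for (it in seq_len(max_iter)) {
      m <- mean_sel(coords)
      if (max(abs(m - ref)) < tol) break
      ref <- m
      coords <- fit_all(coords, ref)
    }
  }
  new_trajectory(traj$topology, coords, traj$times)
}

#' Per-frame RMSD against a reference frame
#'
#' Computes the root-mean-square deviation of each frame from a reference
#' frame over a selection, without re-fitting (run [fit_trajectory()] first to
#' remove global motion).
#'
#' @param traj a `serp_trajectory` (normally already fitted).
#' @param ref_frame index of the reference frame (default 1), or an N_sel x 3
#'   coordinate matrix.
#' @param selection atoms to include (default `"all"`).
#' @return data frame with `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, ref_frame = 1, selection = "all") {
  sel <- select_atoms(traj, selection)
  ref <- if (is.matrix(ref_frame)) ref_frame
         else frame_coords(traj, ref_frame)[sel, , drop = FALSE]
  if (nrow(ref) != length(sel)) stop("reference does not match selection size")
  tt <- n_frames(traj)
  out <- numeric(tt)
  for (k in seq_len(tt)) {
    fr <- frame_coords(traj, k)[sel, , drop = FALSE]
    out[k] <- sqrt(mean(rowSums((fr - ref)^2)))
  }
  data.frame(time = traj$times, rmsd = out)
}

#' Trailing-window time average of a series
#'
#' Arithmetic mean over the trailing time window, i.e. over frames with
#' `t > t_max - window` (so a window equal to the full span averages every
#' frame). Used to summarise structural series over the final stationary
#' stretch of a simulation.
#'
#' @param values numeric series.
#' @param times frame times (ns), strictly increasing, same length.
#' @param window trailing window width in ns (default 20).
#' @return scalar mean over the window.
#' @export
stationary_value <- function(values, times, window = 20) {
  stopifnot(length(values) == length(times), length(values) >= 1)
  mean(values[.trailing_frames(times, window)])
}

# frames in the trailing half-open window (t_max - window, t_max]; a window
# covering the full span (or more, up to tolerance) keeps every frame
.trailing_frames <- function(times, window) {
  span <- max(times) - min(times)
  if (window > span + 1e-9)
    stop("window (", window, " ns) exceeds series span (", span, " ns)")
  if (window >= span - 1e-9) return(seq_along(times))
  which(times > max(times) - window)
}

#' Per-residue root-mean-square fluctuations
#'
#' RMSF about the trajectory-mean position, `sqrt(<|r_i - <r_i>|^2>)`, with
#' time averages taken over all frames (population denominator, so that
#' `sum(rmsf^2)` equals the trace of the coordinate covariance matrix for the
#' same selection). Default selection is one C-alpha per residue; residues
#' lacking a C-alpha are skipped with a warning.
#'
#' @param traj a fitted `serp_trajectory` (global motion removed; this
#'   function does not fit).
#' @param selection `"calpha"` (default, one value per residue) or any
#'   [select_atoms()] selection (one value per selected atom).
#' @return data frame of class `fluctuation_profile` with `chain`, `resid`,
#'   `resname`, `atom` (index) and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2) stop("RMSF needs at least two frames")
  at <- traj$topology$atoms
  if (identical(selection, "calpha")) {
    sel <- which(at$name == "CA" & !at$is_hydrogen)
    res <- traj$topology$residues
    have <- paste(at$chain[sel], at$resid[sel])
    missing <- setdiff(paste(res$chain, res$resid), have)
    if (length(missing))
      warning(length(missing), " residue(s) lack a CA atom and were skipped")
    if (!length(sel)) stop("no C-alpha atoms in topology")
  } else {
    sel <- select_atoms(traj, selection)
  }
  x <- traj$coords[, sel, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  msf <- apply(dev2, 2, mean) * 3  # mean over frames and axes, times 3 axes
  out <- data.frame(chain = at$chain[sel], resid = at$resid[sel],
                    resname = at$resname[sel], atom = sel,
                    rmsf = sqrt(msf), stringsAsFactors = FALSE)
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' Radius of gyration series
#'
#' Per-frame `Rg = sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`, mass-weighted
#' by default, with an optional trailing-window stationary mean.
#'
#' @param traj a `serp_trajectory`.
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @param selection atoms to include (default `"all"`).
#' @param window optional trailing window (ns) for a stationary mean.
#' @return data frame with `time` and `rg` (Angstrom); when `window` is given
#'   the stationary mean is attached as attribute `"stationary"`.
#' @export
radius_of_gyration <- function(traj, mass_weighted = TRUE, selection = "all",
                               window = NULL) {
  sel <- select_atoms(traj, selection)
  m <- if (mass_weighted) traj$topology$atoms$mass[sel] else rep(1, length(sel))
  w <- m / sum(m)
  tt <- n_frames(traj)
  rg <- numeric(tt)
  for (k in seq_len(tt)) {
    fr <- frame_coords(traj, k)[sel, , drop = FALSE]
    com <- colSums(fr * w)
    rg[k] <- sqrt(sum(w * rowSums(sweep(fr, 2, com)^2)))
  }
  out <- data.frame(time = traj$times, rg = rg)
  if (!is.null(window))
    attr(out, "stationary") <- stationary_value(rg, traj$times, window)
  out
}
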