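#' Covariance matrix of coordinate fluctuations
#'
#' Builds the 3N x 3N covariance `C = <dr dr^T>` with
#' `dr_i = r_i - <r_i>`, averaging over frames (population denominator, the
#' time average). Global translation/rotation should already be removed with
#' [fit_trajectory()]; a reminder warning is controlled by `fitted`.
#'
#' @param traj a fitted `serp_trajectory`.
#' @param selection atoms to include (default `"calpha"`).
#' @param fitted set to TRUE to assert the trajectory was superposed (no
#'   warning); FALSE merely warns, it does not fit.
#' @return object of class `cov_matrix`: `matrix` (3N x 3N, Angstrom^2),
#'   `atoms` (indices), `resid`, `chain`, `n_frames`.
#' @export
covariance <- function(traj, selection = "calpha", fitted = TRUE) {
  sel <- select_atoms(traj, selection)
  tt <- n_frames(traj)
  if (tt < 2) stop("covariance needs at least two frames")
  if (!isTRUE(fitted))
    warning("trajectory not marked as fitted; global motion will inflate C")
  if (tt <= 3 * length(sel))
    warning("fewer frames (", tt, ") than degrees of freedom (",
            3 * length(sel), "); covariance will be rank-deficient")
  # T x 3N matrix, atom-major column blocks (x,y,z per atom)
  x <- traj$coords[, sel, , drop = FALSE]
  xm <- matrix(aperm(x, c(1, 3, 2)), nrow = tt)  # columns: atom1 x,y,z, atom2 ...
  xc <- sweep(xm, 2, colMeans(xm))
  cmat <- crossprod(xc) / tt
  at <- traj$topology$atoms
  structure(list(matrix = cmat, atoms = sel, resid = at$resid[sel],
                 chain = at$chain[sel], n_frames = tt),
            class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf("<cov_matrix> %d x %d (%d atoms, %d frames), trace %.4g A^2\n",
              nrow(x$matrix), ncol(x$matrix), length(x$atoms), x$n_frames,
              sum(diag(x$matrix))))
  invisible(x)
}

.logdet <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) stop("covariance block is not positive definite")
  as.numeric(d$modulus)
}

#' Linear mutual information between atom fluctuations
#'
#' Gaussian mutual information between the 3-D fluctuation vectors of every
#' atom pair, computed from covariance-matrix determinants:
#' `I_ij = (ln det C_i + ln det C_j - ln det C_ij) / 2`, with `C_i` the 3 x 3
#' marginal block and `C_ij` the 6 x 6 joint block. The generalized
#' correlation coefficient `gcc = sqrt(1 - exp(-2 I / 3))` rescales I to
#' `[0, 1]` for Pearson-like reporting. The diagonal is reported as `Inf`
#' (gcc 1).
#'
#' @param cov a `cov_matrix`.
#' @param eps ridge added to the matrix (Angstrom^2, default 1e-10) to keep
#'   marginal blocks nonsingular for near-static atoms.
#' @return object of class `correlation_result`: `lmi` (N x N, nats), `gcc`
#'   (N x N), `atoms`, `resid`, `chain`, `n_frames`.
#' @export
lmi <- function(cov, eps = 1e-10) {
  stopifnot(inherits(cov, "cov_matrix"))
  cm <- cov$matrix + diag(eps, nrow(cov$matrix))
  n <- length(cov$atoms)
  ld3 <- numeric(n)
  for (i in seq_len(n)) {
    bi <- (3 * i - 2):(3 * i)
    ld3[i] <- .logdet(cm[bi, bi])
  }
  imat <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      bi <- (3 * i - 2):(3 * i)
      for (j in (i + 1):n) {
        bj <- (3 * j - 2):(3 * j)
        bij <- c(bi, bj)
        v <- 0.5 * (ld3[i] + ld3[j] - .logdet(cm[bij, bij]))
        imat[i, j] <- imat[j, i] <- v
      }
    }
  }
  diag(imat) <- Inf
  gcc <- sqrt(pmax(1 - exp(-2 * imat / 3), 0))
  diag(gcc) <- 1
  structure(list(lmi = imat, gcc = gcc, atoms = cov$atoms,
                 resid = cov$resid, chain = cov$chain,
                 n_frames = cov$n_frames),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  off <- x$lmi[upper.tri(x$lmi)]
  cat(sprintf("<correlation_result> %d atoms; off-diagonal LMI max %.4g, median %.4g nats\n",
              length(x$atoms),
              if (length(off)) max(off) else NA, if (length(off)) stats::median(off) else NA))
  invisible(x)
}

#' Rank long-range correlated residue pairs
#'
#' Selects residue pairs whose spatial separation exceeds `d_min` (so they
#' cannot belong to the same local structural element) with a sequence
#' separation of at least `min_seq_sep`, and ranks them by linear mutual
#' information (descending; ties broken by residue index order).
#'
#' @param result a `correlation_result`.
#' @param structure a `serp_trajectory` (pair distances averaged over frames)
#'   or an N x 3 coordinate matrix for the result's atoms.
#' @param d_min distance filter in Angstrom (default 20, i.e. 2 nm).
#' @param top_k number of pairs to return (default 10; `Inf` for all).
#' @param min_seq_sep minimum |resid_i - resid_j| on the same chain
#'   (default 4); pairs on different chains always pass.
#' @param dist_stat `"mean"` (default), `"min"` or `"max"` over frames.
#' @return data frame with `resid_a`, `resid_b`, `chain_a`, `chain_b`,
#'   `lmi`, `gcc`, `distance`, ranked.
#' @export
long_range_pairs <- function(result, structure, d_min = 20, top_k = 10,
                             min_seq_sep = 4,
                             dist_stat = c("mean", "min", "max")) {
  dist_stat <- match.arg(dist_stat)
  stopifnot(inherits(result, "correlation_result"))
  n <- length(result$atoms)
  if (inherits(structure, "serp_trajectory")) {
    tt <- n_frames(structure)
    acc <- matrix(if (dist_stat == "min") Inf else if (dist_stat == "max") -Inf else 0, n, n)
    for (k in seq_len(tt)) {
      fr <- frame_coords(structure, k)[result$atoms, , drop = FALSE]
      d <- as.matrix(stats::dist(fr))
      acc <- switch(dist_stat, mean = acc + d / tt, min = pmin(acc, d),
                    max = pmax(acc, d))
    }
    dmat <- acc
  } else {
    xyz <- as.matrix(structure)
    if (nrow(xyz) != n) stop("structure does not match the result's atoms")
    dmat <- as.matrix(stats::dist(xyz))
  }
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  sep_ok <- result$chain[i] != result$chain[j] |
    abs(result$resid[i] - result$resid[j]) >= min_seq_sep
  keep <- dmat[pairs] > d_min & sep_ok
  i <- i[keep]; j <- j[keep]
  out <- data.frame(
    resid_a = result$resid[i], resid_b = result$resid[j],
    chain_a = result$chain[i], chain_b = result$chain[j],
    lmi = result$lmi[cbind(i, j)], gcc = result$gcc[cbind(i, j)],
    distance = dmat[cbind(i, j)], stringsAsFactors = FALSE
  )
  ord <- order(-out$lmi, out$resid_a, out$resid_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(top_k) && nrow(out) > top_k) out <- out[seq_len(top_k), , drop = FALSE]
  out
}
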