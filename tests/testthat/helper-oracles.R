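# Independent oracles, kept deliberately naive (plain double loops over the
# stated predicates) so they cannot share a defect with the implementation.

oracle_hbonds <- function(coords, top, d_cut = 3, ang_cut = 30) {
  don <- top$chem$donors
  acc <- top$chem$acceptors
  rkey <- paste(top$atoms$chain, top$atoms$resid)
  out <- NULL
  for (r in seq_len(nrow(don))) {
    d <- don$donor[r]; h <- don$hydrogen[r]
    for (a in acc) {
      if (a == d || rkey[a] == rkey[d]) next
      dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dda > d_cut) next
      v1 <- coords[h, ] - coords[d, ]
      v2 <- coords[a, ] - coords[d, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang <= ang_cut)
        out <- rbind(out, c(donor = d, hydrogen = h, acceptor = a))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor")))
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}

oracle_salt_bridges <- function(coords, top, d_cut = 3) {
  ox <- top$chem$acidic_oxygens
  bh <- top$chem$basic_hydrogens
  out <- NULL
  for (o in ox) for (h in bh) {
    d <- sqrt(sum((coords[o, ] - coords[h, ])^2))
    if (d <= d_cut) out <- rbind(out, c(oxygen = o, hydrogen = h))
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("oxygen", "hydrogen")))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# brute-force weighted-RMSD minimisation over rigid transforms: Euler-angle
# parameterisation, centroids aligned, many restarts through optim
oracle_min_rmsd <- function(mobile, reference, weights = NULL, n_starts = 24) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sum(w * rowSums((p %*% rotmat(ang) - q)^2))
  best <- Inf
  set.seed(99)
  starts <- rbind(matrix(0, 1, 3),
                  matrix(runif(3 * (n_starts - 1), -pi, pi), ncol = 3))
  for (s in seq_len(nrow(starts))) {
    o <- optim(starts[s, ], obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# trapezoid integral on a refined grid via linear interpolation
oracle_first_moment_fine <- function(x, y, factor = 10) {
  xf <- seq(min(x), max(x), length.out = factor * length(x))
  yf <- approx(x, y, xout = xf)$y
  pracma::trapz(xf, xf * yf) / pracma::trapz(xf, yf)
}

# accessible area of two equal spheres of radius R at centre distance d:
# each loses a cap of height h = R - d/2 (area 2*pi*R*h) when overlapping
oracle_two_sphere_area <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}
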