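#' Read a two-column curve file
#'
#' Reads whitespace- or comma-delimited `x y` text with `#` comments, the
#' interchange format for emission spectra, CD ramps, titrations and
#' densitometry traces.
#'
#' @param path file path.
#' @param kind optional tag (`"spectrum"`, `"thermal"`, `"chemical"`, ...).
#' @return list of class `serp_curve` with `x`, `y`, `kind`.
#' @export
read_curve <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  txt <- gsub(",", " ", txt)
  parts <- strsplit(trimws(txt), "[[:space:]]+")
  if (any(vapply(parts, length, 1L) < 2)) stop("curve lines need two columns")
  x <- as.numeric(vapply(parts, `[`, "", 1))
  y <- as.numeric(vapply(parts, `[`, "", 2))
  if (anyNA(x) || anyNA(y)) stop("non-numeric values in ", path)
  new_curve(x, y, kind)
}

#' Construct a curve object
#' @param x strictly increasing abscissa (nm, deg C, M, ...).
#' @param y signal values, same length.
#' @param kind optional tag.
#' @return list of class `serp_curve`.
#' @export
new_curve <- function(x, y, kind = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  structure(list(x = as.numeric(x), y = as.numeric(y), kind = kind),
            class = "serp_curve")
}

#' @export
print.serp_curve <- function(x, ...) {
  cat(sprintf("<serp_curve%s> %d points, x in [%g, %g]\n",
              if (is.null(x$kind)) "" else paste0(": ", x$kind),
              length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

.curve_xy <- function(curve, y = NULL) {
  if (inherits(curve, "serp_curve")) list(x = curve$x, y = curve$y)
  else list(x = as.numeric(curve), y = as.numeric(y))
}

#' First moment of a normalised emission spectrum
#'
#' Normalises the spectrum `L(lambda)` to unit area by the trapezoid rule and
#' returns the intensity-weighted mean wavelength
#' `lambda_1 = integral of lambda L(lambda) dlambda`. Red-shifts of this
#' moment track tryptophan solvent exposure during unfolding.
#'
#' @param curve a `serp_curve`, or numeric x values.
#' @param y signal values when `curve` is numeric.
#' @return the first moment, in the units of x (nm).
#' @export
first_moment <- function(curve, y = NULL) {
  c2 <- .curve_xy(curve, y)
  if (length(c2$x) < 3) stop("spectrum needs at least 3 points")
  if (any(c2$y < 0)) stop("spectrum must be non-negative")
  z <- pracma::trapz(c2$x, c2$y)
  if (z <= 0) stop("spectrum has zero integral; cannot normalise")
  pracma::trapz(c2$x, c2$x * c2$y) / z
}

#' Mean residue differential extinction coefficient
#'
#' Converts a CD signal in millidegrees to the per-residue differential
#' extinction coefficient:
#' `delta_eps = theta / (k * conc * pathlength * n_residues)` with
#' `k = 32980` (the standard mdeg to delta-epsilon conversion constant).
#'
#' @param theta CD signal (mdeg); may be a vector.
#' @param conc molar protein concentration (mol/L).
#' @param pathlength cuvette path (cm).
#' @param n_residues number of residues.
#' @param k conversion constant (default 32980).
#' @return delta-epsilon per residue (cm^-1 M^-1).
#' @export
mean_residue_delta_epsilon <- function(theta, conc, pathlength, n_residues,
                                       k = 32980) {
  if (conc <= 0 || pathlength <= 0 || n_residues <= 0 || k <= 0)
    stop("conc, pathlength, n_residues and k must be positive")
  theta / (k * conc * pathlength * n_residues)
}

# Boltzmann sigmoid sum: b0 + sum_k A_k / (1 + exp((m_k - x) / w_k))
.sigmoid_model <- function(x, b0, A, m, w) {
  y <- rep(b0, length(x))
  for (k in seq_along(m)) y <- y + A[k] / (1 + exp((m[k] - x) / w[k]))
  y
}

#' Evaluate the Boltzmann sigmoid model
#' @param x abscissa values.
#' @param baseline shared baseline b0.
#' @param amplitudes,midpoints,widths per-transition parameter vectors.
#' @return model values.
#' @export
sigmoid_sum <- function(x, baseline, amplitudes, midpoints, widths) {
  stopifnot(length(amplitudes) == length(midpoints),
            length(widths) == length(midpoints))
  .sigmoid_model(x, baseline, amplitudes, midpoints, widths)
}

.auto_init <- function(x, y, n_transitions) {
  dy <- diff(y) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  span <- diff(range(x))
  m1 <- xm[which.max(abs(dy))]
  if (n_transitions == 1) {
    m <- m1
  } else {
    far <- abs(xm - m1) > span / 5
    if (!any(far)) stop("cannot locate two distinct transitions for init")
    m2 <- xm[far][which.max(abs(dy[far]))]
    m <- sort(c(m1, m2))
  }
  amp_total <- y[length(y)] - y[1]
  list(b0 = y[1], A = rep(amp_total / n_transitions, n_transitions),
       m = m, w = rep(span / 15, n_transitions))
}

#' Fit one- or two-transition sigmoids to a denaturation curve
#'
#' Least-squares fit of the Boltzmann model
#' `y = b0 + sum_k A_k / (1 + exp((m_k - x)/w_k))` by Levenberg-Marquardt
#' (minpack.lm). Auto-initialisation places midpoints at the steepest points
#' of the numerical derivative. Transitions are returned sorted by midpoint.
#' A fit is flagged low-confidence when a transition amplitude is not
#' resolved above the residual noise or a midpoint standard error exceeds a
#' quarter of the x span (e.g. on a flat or purely drifting curve).
#'
#' @param curve a `serp_curve` or numeric x values.
#' @param y signal values when `curve` is numeric.
#' @param n_transitions 1 or 2.
#' @param init optional list with `b0`, `A`, `m`, `w` overriding auto-init.
#' @param max_iter maximum LM iterations.
#' @return object of class `sigmoid_fit`: `transitions` data frame
#'   (`midpoint`, `width`, `amplitude` and their standard errors),
#'   `baseline`, `rss`, `sigma`, `converged`, `low_confidence`, `fitted`.
#' @export
fit_denaturation <- function(curve, y = NULL, n_transitions = 1, init = NULL,
                             max_iter = 200) {
  c2 <- .curve_xy(curve, y)
  x <- c2$x; yv <- c2$y
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (!n_transitions %in% c(1, 2)) stop("n_transitions must be 1 or 2")
  n_min <- 4 * (2 * n_transitions) + 2
  if (length(x) < n_min)
    warning("few points (", length(x), ") for ", n_transitions,
            "-transition fit; ", n_min, " recommended")
  span <- diff(range(x))
  # candidate starts: user init, or the derivative-based auto-init at a few
  # width scales (the width is the least identifiable parameter and a poor
  # start can strand the optimiser in a collapsed-width local minimum);
  # lowest-RSS solution wins
  if (is.null(init)) {
    auto <- .auto_init(x, yv, n_transitions)
    cands <- lapply(c(30, 15, 8, 4), function(f) {
      a <- auto; a$w <- rep(span / f, n_transitions); a
    })
  } else {
    cands <- list(init)
  }
  lower <- c(-Inf, rep(-Inf, n_transitions), rep(min(x), n_transitions),
             rep(span * 1e-3, n_transitions))
  upper <- c(Inf, rep(Inf, n_transitions), rep(max(x), n_transitions),
             rep(span, n_transitions))
  resid_fn <- function(p) {
    A <- p[2:(1 + n_transitions)]
    m <- p[(2 + n_transitions):(1 + 2 * n_transitions)]
    w <- p[(2 + 2 * n_transitions):(1 + 3 * n_transitions)]
    yv - .sigmoid_model(x, p[1], A, m, w)
  }
  fit <- NULL
  err <- NULL
  for (cand in cands) {
    start <- c(b0 = cand$b0,
               setNames(cand$A, paste0("A", seq_len(n_transitions))),
               setNames(cand$m, paste0("m", seq_len(n_transitions))),
               setNames(cand$w, paste0("w", seq_len(n_transitions))))
    this <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) { err <<- conditionMessage(e); NULL }
    )
    if (!is.null(this) &&
        (is.null(fit) || sum(this$fvec^2) < sum(fit$fvec^2)))
      fit <- this
  }
  if (is.null(fit)) stop("sigmoid fit failed: ", err)
  p <- fit$par
  A <- p[2:(1 + n_transitions)]
  m <- p[(2 + n_transitions):(1 + 2 * n_transitions)]
  w <- p[(2 + 2 * n_transitions):(1 + 3 * n_transitions)]
  rss <- sum(fit$fvec^2)
  dof <- max(length(x) - length(p), 1)
  sigma <- sqrt(rss / dof)
  se <- tryCatch({
    covp <- sigma^2 * solve(fit$hessian / 2)
    sqrt(pmax(diag(covp), 0))
  }, error = function(e) rep(NA_real_, length(p)))
  names(se) <- names(p)
  ord <- order(m)
  tr <- data.frame(
    midpoint = unname(m[ord]), width = unname(w[ord]),
    amplitude = unname(A[ord]),
    se_midpoint = unname(se[paste0("m", seq_len(n_transitions))][ord]),
    se_width = unname(se[paste0("w", seq_len(n_transitions))][ord]),
    se_amplitude = unname(se[paste0("A", seq_len(n_transitions))][ord])
  )
  low_conf <- any(abs(tr$amplitude) < 3 * sigma) ||
    any(is.na(tr$se_midpoint)) ||
    any(tr$se_midpoint > span / 4, na.rm = TRUE)
  if (low_conf)
    warning("low-confidence fit: transition not resolved above noise")
  out <- list(
    transitions = tr, baseline = unname(p[1]), rss = rss, sigma = sigma,
    converged = fit$info %in% 1:4, low_confidence = low_conf,
    n_transitions = n_transitions,
    fitted = .sigmoid_model(x, p[1], A, m, w), x = x, y = yv
  )
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %d transition(s), RSS %.4g%s\n",
              x$n_transitions, x$rss,
              if (x$low_confidence) " [low confidence]" else ""))
  for (k in seq_len(nrow(x$transitions)))
    cat(sprintf("  midpoint %.4g +/- %.2g, width %.4g, amplitude %.4g\n",
                x$transitions$midpoint[k], x$transitions$se_midpoint[k],
                x$transitions$width[k], x$transitions$amplitude[k]))
  invisible(x)
}

#' Thermal transition midpoint from a CD ramp
#'
#' Fits a single Boltzmann sigmoid to a CD-signal-versus-temperature ramp
#' (e.g. the 216 nm signal over 20-90 deg C) and returns the midpoint
#' temperature T-half.
#'
#' @inheritParams fit_denaturation
#' @return the midpoint temperature (deg C), with the full `sigmoid_fit` as
#'   attribute `"fit"` and the low-confidence flag as attribute
#'   `"low_confidence"`.
#' @export
thermal_midpoint <- function(curve, y = NULL, init = NULL) {
  fit <- fit_denaturation(curve, y, n_transitions = 1, init = init)
  out <- fit$transitions$midpoint[1]
  attr(out, "fit") <- fit
  attr(out, "low_confidence") <- fit$low_confidence
  out
}

#' Normalise gel-lane band densities
#'
#' Divides each band density by the total density of its lane, so band
#' populations are comparable across lanes and time points. A display column
#' multiplies selected minor bands (e.g. dimer-pentamer oligomers) by
#' `scale_minor` for plotting; analysis values are never scaled.
#'
#' @param densities data frame with columns `lane`, `band`, `density`
#'   (non-negative).
#' @param scale_minor display scale factor for minor bands (default 5).
#' @param minor_bands character vector of band names to scale for display.
#' @return data frame with `lane`, `band`, `fraction` (sums to 1 per lane)
#'   and `display` (scaled fractions).
#' @export
lane_normalize <- function(densities, scale_minor = 5, minor_bands = NULL) {
  stopifnot(is.data.frame(densities),
            all(c("lane", "band", "density") %in% names(densities)))
  if (any(densities$density < 0)) stop("densities must be non-negative")
  totals <- tapply(densities$density, densities$lane, sum)
  if (any(totals <= 0))
    stop("lane(s) with zero total density: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  frac <- densities$density / totals[as.character(densities$lane)]
  disp <- frac
  if (!is.null(minor_bands)) {
    sc <- densities$band %in% minor_bands
    disp[sc] <- disp[sc] * scale_minor
  }
  out <- data.frame(lane = densities$lane, band = densities$band,
                    fraction = as.numeric(frac), display = as.numeric(disp),
                    stringsAsFactors = FALSE)
  out
}

#' Aggregate normalised lane fractions over replicates
#'
#' Computes mean and standard deviation of each band's fraction across
#' replicate lanes (e.g. triplicate experiments).
#'
#' @param normalized output of [lane_normalize()] on replicate lanes.
#' @return data frame with `band`, `mean`, `sd`, `n`.
#' @export
summarize_lanes <- function(normalized) {
  sp <- split(normalized$fraction, normalized$band)
  data.frame(
    band = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
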