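#' Compare two trajectory variants end-to-end
#'
#' Runs the full comparative workflow on two trajectories (e.g. wild type and
#' a point mutant): superposition, stationary RMSD / radius of gyration /
#' SASA, hydrogen-bond and salt-bridge occupancies with persistent-bond
#' counts and between-variant unique-bond differencing, per-residue RMSF with
#' a mapped difference profile, and long-range correlated-pair ranking from
#' linear mutual information. Residues are mapped between variants
#' positionally by (chain, residue number), so a mutated residue maps onto
#' its counterpart even though the residue name differs.
#'
#' @param traj_a,traj_b `serp_trajectory` objects with annotated topologies.
#' @param labels length-2 labels for the variants.
#' @param d_cut interaction distance cutoff (Angstrom, default 3).
#' @param ang_cut H-bond angle cutoff (deg, default 30).
#' @param occ_threshold persistence threshold (default 0.5).
#' @param probe,n_points SASA parameters.
#' @param window trailing time-average window (ns, default 20); capped at
#'   each trajectory's span with a warning.
#' @param d_min,top_k,min_seq_sep long-range correlated-pair parameters
#'   (defaults 20 Angstrom, 10 pairs, 4 residues).
#' @param fit_selection atoms used for superposition (default `"calpha"`).
#' @param run_sasa,run_lmi switch off the expensive stages if not needed.
#' @return list of class `comparison_report`; see Details for components.
#' @details The report holds one summary per variant (`variants`, each with
#'   `rmsd_stationary`, `rg_stationary`, `sasa_mean`, `sasa_sd`,
#'   `n_hbonds_persistent`, `n_saltbridges_persistent`, `rmsf`,
#'   `long_range_pairs`, occupancy tables), the differencing results
#'   (`hbond_diff`, `saltbridge_diff`), the mapped `delta_rmsf`
#'   (A minus B), and `parameters` echoing every setting.
#' @export
compare_variants <- function(traj_a, traj_b, labels = c("A", "B"),
                             d_cut = 3.0, ang_cut = 30, occ_threshold = 0.5,
                             probe = 1.4, n_points = 960, window = 20,
                             d_min = 20, top_k = 10, min_seq_sep = 4,
                             fit_selection = "calpha",
                             run_sasa = TRUE, run_lmi = TRUE) {
  stopifnot(inherits(traj_a, "serp_trajectory"),
            inherits(traj_b, "serp_trajectory"))
  params <- list(d_cut = d_cut, ang_cut = ang_cut,
                 occ_threshold = occ_threshold, probe = probe,
                 n_points = n_points, window = window, d_min = d_min,
                 top_k = top_k, min_seq_sep = min_seq_sep,
                 fit_selection = fit_selection)

  summarise <- function(traj, label) {
    use_proxy <- !any(traj$topology$atoms$is_hydrogen)
    if (use_proxy)
      warning("trajectory ", label, " has no hydrogens; interaction ",
              "detection falls back to heavy-atom proxy mode")
    span <- max(traj$times) - min(traj$times)
    win <- window
    if (win > span) {
      warning("window ", window, " ns exceeds span of ", label,
              " (", span, " ns); using full span")
      win <- span
    }
    sel <- tryCatch(select_atoms(traj, fit_selection), error = function(e) NULL)
    fitted <- if (is.null(sel)) traj else fit_trajectory(traj, selection = fit_selection)
    rmsd <- rmsd_series(fitted, selection = if (is.null(sel)) "all" else fit_selection)
    rg <- radius_of_gyration(traj)
    out <- list(
      label = label,
      rmsd_stationary = if (span > 0) stationary_value(rmsd$rmsd, rmsd$time, win)
                        else rmsd$rmsd[1],
      rg_stationary = if (span > 0) stationary_value(rg$rg, rg$time, win)
                      else rg$rg[1],
      rmsd_series = rmsd, rg_series = rg,
      rmsf = rmsf(fitted,
                  selection = if (any(traj$topology$atoms$name == "CA"))
                    "calpha" else "heavy"),
      hbond_occupancy = occupancy(traj, "hbond", d_cut = d_cut,
                                  ang_cut = ang_cut, proxy = use_proxy),
      saltbridge_occupancy = occupancy(traj, "saltbridge", d_cut = d_cut,
                                       proxy = use_proxy)
    )
    out$n_hbonds_persistent <-
      sum(out$hbond_occupancy$occupancy > occ_threshold)
    out$n_saltbridges_persistent <-
      sum(out$saltbridge_occupancy$occupancy > occ_threshold)
    if (run_sasa) {
      s <- trajectory_sasa(traj, window = if (span > 0) win else 0,
                           probe = probe, n_points = n_points)
      out$sasa_mean <- s$mean; out$sasa_sd <- s$sd
    }
    if (run_lmi && n_frames(traj) >= 2) {
      cv <- suppressWarnings(covariance(fitted))
      cr <- lmi(cv)
      out$long_range_pairs <- long_range_pairs(cr, fitted, d_min = d_min,
                                               top_k = top_k,
                                               min_seq_sep = min_seq_sep)
    }
    out
  }

  a <- summarise(traj_a, labels[1])
  b <- summarise(traj_b, labels[2])

  # positional residue mapping by (chain, resid)
  ka <- paste(a$rmsf$chain, a$rmsf$resid)
  kb <- paste(b$rmsf$chain, b$rmsf$resid)
  common <- intersect(ka, kb)
  unmapped <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmapped))
    warning("residues present in only one variant excluded from delta-RMSF: ",
            paste(unmapped, collapse = ", "))
  ia <- match(common, ka); ib <- match(common, kb)
  delta_rmsf <- data.frame(
    chain = a$rmsf$chain[ia], resid = a$rmsf$resid[ia],
    rmsf_a = a$rmsf$rmsf[ia], rmsf_b = b$rmsf$rmsf[ib],
    delta = a$rmsf$rmsf[ia] - b$rmsf$rmsf[ib],
    stringsAsFactors = FALSE
  )

  report <- list(
    variants = setNames(list(a, b), labels),
    hbond_diff = occupancy_diff(a$hbond_occupancy, b$hbond_occupancy,
                                threshold = occ_threshold),
    saltbridge_diff = occupancy_diff(a$saltbridge_occupancy,
                                     b$saltbridge_occupancy,
                                     threshold = occ_threshold),
    delta_rmsf = delta_rmsf,
    parameters = params,
    provenance = list(package_version = as.character(utils::packageVersion("serpdyn")),
                      date = format(Sys.time(), "%Y-%m-%d"))
  )
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (v in x$variants) {
    cat(sprintf("  %s: RMSD* %.3f A, Rg* %.3f A%s, HB>thr %d, SB>thr %d\n",
                v$label, v$rmsd_stationary, v$rg_stationary,
                if (!is.null(v$sasa_mean))
                  sprintf(", SASA* %.0f A^2", v$sasa_mean) else "",
                v$n_hbonds_persistent, v$n_saltbridges_persistent))
  }
  cat(sprintf("  unique persistent H-bonds: %d vs %d; salt bridges: %d vs %d\n",
              nrow(x$hbond_diff$unique_to_a), nrow(x$hbond_diff$unique_to_b),
              nrow(x$saltbridge_diff$unique_to_a),
              nrow(x$saltbridge_diff$unique_to_b)))
  cat("  (* trailing-window time averages)\n")
  invisible(x)
}

#' Track a candidate salt-bridge distance between two residues
#'
#' Convenience orchestration over [pair_distance_series()]: extracts the
#' charged-group distance series between two residues (acidic oxygens of one,
#' basic hydrogens of the other) and reports the fraction of frames with the
#' distance below a cutoff.
#'
#' @param traj a `serp_trajectory` with annotated topology.
#' @param resid_a,resid_b residue numbers of the two partners.
#' @param chain_a,chain_b chains (default `"A"`).
#' @param threshold contact threshold (Angstrom, default 3).
#' @param mode passed to [pair_distance_series()].
#' @return list with `series` (time, distance) and `fraction_below`.
#' @export
track_pair <- function(traj, resid_a, resid_b, chain_a = "A", chain_b = "A",
                       threshold = 3.0, mode = "saltbridge") {
  at <- traj$topology$atoms
  for (rr in list(c(chain_a, resid_a), c(chain_b, resid_b))) {
    if (!any(at$chain == rr[1] & at$resid == as.integer(rr[2])))
      stop("residue ", rr[2], " (chain ", rr[1], ") not found in topology")
  }
  series <- pair_distance_series(
    traj,
    list(chain = chain_a, resid = as.integer(resid_a)),
    list(chain = chain_b, resid = as.integer(resid_b)),
    mode = mode
  )
  list(series = series,
       fraction_below = mean(series$distance < threshold),
       threshold = threshold)
}
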