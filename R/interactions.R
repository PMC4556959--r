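# cross-set Euclidean distances between rows of a (na x 3) and b (nb x 3)
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.require_chem <- function(topology, need_h = TRUE, proxy = FALSE) {
  if (is.null(topology$chem))
    stop("topology is not annotated; run annotate_chemistry() first")
  if (need_h && !proxy && !any(topology$atoms$is_hydrogen))
    stop("topology has no hydrogens; explicit hydrogens are required ",
         "(enable heavy-atom proxy mode to override)")
}

#' Detect hydrogen bonds in one frame
#'
#' A donor/hydrogen/acceptor triple is a hydrogen bond when the donor-acceptor
#' heavy-atom distance is within `d_cut` and the angle between the D->H and
#' D->A vectors is within `ang_cut` (the convention of standard MD H-bond
#' tools; the supplement-style alternative, 180 minus the D-H-A angle, is
#' available via `angle_convention`). Intra-residue pairs are excluded.
#' Boundary-equal distances and angles count as bonded.
#'
#' @param coords N x 3 frame coordinates (Angstrom), or a `serp_trajectory`
#'   together with `frame`.
#' @param topology an annotated `serp_topology`.
#' @param d_cut donor-acceptor distance cutoff (Angstrom, default 3.0).
#' @param ang_cut angle cutoff in degrees (default 30).
#' @param angle_convention `"DH-DA"` (angle between D->H and D->A, default) or
#'   `"DHA-deviation"` (deviation of the D-H-A angle from 180 degrees).
#' @param frame frame index when `coords` is a trajectory.
#' @param proxy heavy-atom proxy mode for hydrogen-free topologies: the angle
#'   criterion is dropped and only the D-A distance is tested (documented
#'   deviation from the full geometric definition).
#' @return data frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices; `hydrogen` is `NA` in proxy mode), `d_da` and `angle`.
#' @export
detect_hbonds <- function(coords, topology = NULL, d_cut = 3.0, ang_cut = 30,
                          angle_convention = c("DH-DA", "DHA-deviation"),
                          frame = 1, proxy = FALSE) {
  angle_convention <- match.arg(angle_convention)
  if (inherits(coords, "serp_trajectory")) {
    if (is.null(topology)) topology <- coords$topology
    coords <- frame_coords(coords, frame)
  }
  .require_chem(topology, need_h = TRUE, proxy = proxy)
  at <- topology$atoms
  don <- topology$chem$donors
  acc <- topology$chem$acceptors
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), d_da = numeric(0),
                      angle = numeric(0))
  if (proxy && nrow(don) == 0) {
    # proxy: any N/O with at least one bound H unknown -> use all N/O as donors
    don <- data.frame(donor = acc, hydrogen = rep(NA_integer_, length(acc)))
  }
  if (!nrow(don) || !length(acc)) return(empty)
  dmat <- .cross_dist(coords[don$donor, , drop = FALSE],
                      coords[acc, , drop = FALSE])
  rkey <- paste(at$chain, at$resid, sep = ":")
  hits <- which(dmat <= d_cut, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  d_idx <- don$donor[hits[, 1]]
  h_idx <- don$hydrogen[hits[, 1]]
  a_idx <- acc[hits[, 2]]
  keep <- d_idx != a_idx & rkey[d_idx] != rkey[a_idx]
  d_idx <- d_idx[keep]; h_idx <- h_idx[keep]; a_idx <- a_idx[keep]
  dda <- dmat[hits][keep]
  if (!length(d_idx)) return(empty)
  if (proxy || all(is.na(h_idx))) {
    ang <- rep(NA_real_, length(d_idx))
    sel <- rep(TRUE, length(d_idx))
  } else {
    dh <- coords[h_idx, , drop = FALSE] - coords[d_idx, , drop = FALSE]
    da <- coords[a_idx, , drop = FALSE] - coords[d_idx, , drop = FALSE]
    if (angle_convention == "DH-DA") {
      cosang <- rowSums(dh * da) / (sqrt(rowSums(dh^2)) * sqrt(rowSums(da^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    } else {
      hd <- -dh
      ha <- coords[a_idx, , drop = FALSE] - coords[h_idx, , drop = FALSE]
      cosang <- rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
      ang <- 180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    sel <- ang <= ang_cut
  }
  data.frame(donor = d_idx[sel], hydrogen = h_idx[sel], acceptor = a_idx[sel],
             d_da = dda[sel], angle = ang[sel])
}

#' Detect salt-bridge contacts in one frame
#'
#' A contact is scored when an acidic-residue oxygen (Asp OD1/OD2, Glu
#' OE1/OE2, C-terminal carboxylate) lies within `d_cut` of a basic-residue
#' hydrogen (Arg, Lys, protonated His). Contacts are reported at atom level;
#' residue-level aggregation happens in [occupancy()].
#'
#' @inheritParams detect_hbonds
#' @param d_cut oxygen-hydrogen distance cutoff (Angstrom, default 3.0).
#' @param proxy heavy-atom proxy mode: basic nitrogens stand in for their
#'   hydrogens and the cutoff is extended by 1.0 Angstrom (one N-H bond
#'   length); a documented deviation for hydrogen-free inputs.
#' @return data frame with `oxygen`, `hydrogen` atom indices (the `hydrogen`
#'   column holds the nitrogen in proxy mode) and `distance`.
#' @export
detect_salt_bridges <- function(coords, topology = NULL, d_cut = 3.0,
                                frame = 1, proxy = FALSE) {
  if (inherits(coords, "serp_trajectory")) {
    if (is.null(topology)) topology <- coords$topology
    coords <- frame_coords(coords, frame)
  }
  .require_chem(topology, need_h = TRUE, proxy = proxy)
  at <- topology$atoms
  ox <- topology$chem$acidic_oxygens
  if (proxy) {
    bh <- integer(0)
    for (rn in names(.basic_nitrogen_names))
      bh <- c(bh, which(at$resname == rn & at$name %in% .basic_nitrogen_names[[rn]]))
    bh <- sort(unique(bh))
    d_cut <- d_cut + 1.0
  } else {
    bh <- topology$chem$basic_hydrogens
  }
  empty <- data.frame(oxygen = integer(0), hydrogen = integer(0),
                      distance = numeric(0))
  if (!length(ox) || !length(bh)) return(empty)
  dmat <- .cross_dist(coords[ox, , drop = FALSE], coords[bh, , drop = FALSE])
  hits <- which(dmat <= d_cut, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  data.frame(oxygen = ox[hits[, 1]], hydrogen = bh[hits[, 2]],
             distance = dmat[hits])
}

.pair_keys <- function(topology, i_idx, j_idx, level) {
  at <- topology$atoms
  if (level == "atom-pair") {
    paste(at$serial[i_idx], at$serial[j_idx], sep = "~")
  } else {
    paste(paste(at$chain[i_idx], at$resid[i_idx], at$resname[i_idx], sep = ":"),
          paste(at$chain[j_idx], at$resid[j_idx], at$resname[j_idx], sep = ":"),
          sep = "~")
  }
}

#' Interaction occupancy over a trajectory
#'
#' Runs a detector on every frame and reports, per interaction pair, the
#' fraction of frames in which it is present. At residue level a frame counts
#' once if any constituent atom pair is detected. Pairs never detected are
#' omitted (occupancy-0 rows are suppressed).
#'
#' @param traj a `serp_trajectory` with an annotated topology.
#' @param detector `"hbond"` or `"saltbridge"`.
#' @param level `"residue-pair"` (default) or `"atom-pair"`.
#' @param ... further arguments passed to the detector (`d_cut`, `ang_cut`,
#'   `proxy`, ...).
#' @return data frame of class `occupancy_table` with pair identity columns,
#'   `occupancy` and `n_frames`; attribute `"level"` records the level. For
#'   hydrogen bonds the pair is directional (donor residue first).
#' @export
occupancy <- function(traj, detector = c("hbond", "saltbridge"),
                      level = c("residue-pair", "atom-pair"), ...) {
  detector <- match.arg(detector)
  level <- match.arg(level)
  top <- traj$topology
  tt <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (k in seq_len(tt)) {
    fr <- frame_coords(traj, k)
    det <- if (detector == "hbond")
      detect_hbonds(fr, top, ...)
    else
      detect_salt_bridges(fr, top, ...)
    if (!nrow(det)) next
    i_idx <- det[[1]]
    j_idx <- if (detector == "hbond") det$acceptor else det$hydrogen
    keys_all <- .pair_keys(top, i_idx, j_idx, level)
    pos <- match(unique(keys_all), keys_all)
    for (w in pos) {
      key <- keys_all[w]
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      if (is.null(meta[[key]])) meta[[key]] <- c(i_idx[w], j_idx[w])
    }
  }
  keys <- ls(counts)
  at <- top$atoms
  if (!length(keys)) {
    out <- data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      occupancy = numeric(0), n_frames = integer(0))
  } else {
    ij <- t(vapply(keys, function(k) meta[[k]], numeric(2)))
    i_idx <- ij[, 1]; j_idx <- ij[, 2]
    out <- data.frame(
      chain_a = at$chain[i_idx], resid_a = at$resid[i_idx],
      resname_a = at$resname[i_idx], chain_b = at$chain[j_idx],
      resid_b = at$resid[j_idx], resname_b = at$resname[j_idx],
      occupancy = vapply(keys, function(k) counts[[k]], numeric(1)) / tt,
      n_frames = tt, stringsAsFactors = FALSE
    )
    if (level == "atom-pair") {
      out$atom_a <- at$name[i_idx]
      out$atom_b <- at$name[j_idx]
    }
    out$key <- keys
    out <- out[order(out$key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "level") <- level
  attr(out, "detector") <- detector
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Difference two occupancy tables at a persistence threshold
#'
#' Splits interaction pairs into those persistently present (occupancy
#' strictly above `threshold`) in only one variant, and those persistent in
#' both. A pair with occupancy exactly at the threshold is not counted as
#' persistent in either table.
#'
#' @param a,b `occupancy_table` objects at the same level.
#' @param threshold persistence threshold (default 0.5, i.e. "more than 50%
#'   occupancy").
#' @return list with `unique_to_a`, `unique_to_b` and `shared` data frames.
#' @export
occupancy_diff <- function(a, b, threshold = 0.5) {
  if (!identical(attr(a, "level"), attr(b, "level")))
    stop("occupancy tables are at different levels (",
         attr(a, "level"), " vs ", attr(b, "level"), ")")
  occ <- function(tab, keys) {
    v <- setNames(rep(0, length(keys)), keys)
    if (nrow(tab)) v[tab$key] <- tab$occupancy
    v
  }
  keys <- union(a$key, b$key)
  oa <- occ(a, keys); ob <- occ(b, keys)
  pick <- function(tab, other_tab, kk) {
    src <- rbind(
      if (nrow(tab)) tab[tab$key %in% kk, , drop = FALSE],
      if (nrow(other_tab)) other_tab[other_tab$key %in% setdiff(kk, tab$key), , drop = FALSE]
    )
    if (is.null(src)) src <- tab[0, , drop = FALSE]
    rownames(src) <- NULL
    src
  }
  ua <- keys[oa > threshold & ob <= threshold]
  ub <- keys[ob > threshold & oa <= threshold]
  sh <- keys[oa > threshold & ob > threshold]
  list(
    unique_to_a = pick(a, b, ua),
    unique_to_b = pick(b, a, ub),
    shared = pick(a, b, sh)
  )
}

#' Residue-pair distance time series
#'
#' Per frame, the minimum distance between two atom groups. With
#' `mode = "saltbridge"` the groups are restricted to the acidic oxygens of
#' one residue and the basic hydrogens of the other (swapping automatically
#' if given in the opposite order), which tracks the charged-group distance
#' of a candidate salt bridge. With `mode = "min"` the raw selections are
#' used.
#'
#' @param traj a `serp_trajectory` (annotated topology required for
#'   `mode = "saltbridge"`).
#' @param sel_a,sel_b selections for the two groups (see [select_atoms()]).
#' @param mode `"saltbridge"` (default) or `"min"`.
#' @return data frame with `time` (ns) and `distance` (Angstrom).
#' @export
pair_distance_series <- function(traj, sel_a, sel_b,
                                 mode = c("saltbridge", "min")) {
  mode <- match.arg(mode)
  top <- traj$topology
  ia <- select_atoms(top, sel_a)
  ib <- select_atoms(top, sel_b)
  if (identical(sort(ia), sort(ib)))
    stop("the two selections are identical; self-distance is ill-defined")
  if (mode == "saltbridge") {
    .require_chem(top)
    ox <- intersect(ia, top$chem$acidic_oxygens)
    bh <- intersect(ib, top$chem$basic_hydrogens)
    if (!length(ox) || !length(bh)) {
      ox <- intersect(ib, top$chem$acidic_oxygens)
      bh <- intersect(ia, top$chem$basic_hydrogens)
    }
    if (!length(ox) || !length(bh))
      stop("selections contain no acidic-oxygen / basic-hydrogen groups")
    ia <- ox; ib <- bh
  }
  tt <- n_frames(traj)
  d <- numeric(tt)
  for (k in seq_len(tt)) {
    fr <- frame_coords(traj, k)
    d[k] <- min(.cross_dist(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE]))
  }
  data.frame(time = traj$times, distance = d)
}
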