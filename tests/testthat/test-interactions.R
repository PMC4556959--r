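test_that("hydrogen-bond predicate: distance and angle boundaries", {
  # collinear N-H...O at 2.9 A is a bond with angle 0
  top <- hbond_geometry(2.9, 0)
  hb <- detect_hbonds(top$ref_coords, top)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$angle, 0, tolerance = 1e-8)
  expect_equal(hb$d_da, 2.9, tolerance = 1e-12)
  # 3.1 A collinear is excluded by the distance cutoff
  top2 <- hbond_geometry(3.1, 0)
  expect_equal(nrow(detect_hbonds(top2$ref_coords, top2)), 0)
  # boundary-equal distance counts as bonded
  top3 <- hbond_geometry(3.0, 0)
  expect_equal(nrow(detect_hbonds(top3$ref_coords, top3)), 1)
  # angle beyond 30 degrees is excluded even when close
  top4 <- hbond_geometry(2.8, 40)
  expect_equal(nrow(detect_hbonds(top4$ref_coords, top4)), 0)
  # unannotated topology errors
  raw <- topology_from_atoms(top$atoms, top$ref_coords)
  expect_error(detect_hbonds(raw$ref_coords, raw), "annotat")
})

test_that("H-bond detection equals the brute-force predicate oracle on a grid", {
  for (d in seq(2.5, 3.5, by = 0.25)) {
    for (ang in c(0, 10, 20, 29, 30, 31, 45)) {
      top <- hbond_geometry(d, ang)
      got <- detect_hbonds(top$ref_coords, top)
      want <- oracle_hbonds(top$ref_coords, top)
      expect_equal(nrow(got), nrow(want),
                   info = sprintf("d=%.2f ang=%d", d, ang))
      if (ang != 30)  # boundary angle checked only via oracle agreement:
        expect_equal(nrow(got), as.integer(d <= 3 && ang < 30))
    }
  }
})

test_that("salt-bridge detection: templates, protonation, oracle equality", {
  # Glu OE1 2.8 A from Arg HH11 -> one residue pair
  rig <- gen_interaction_rig("saltbridge", 1, 1, target_distance = 2.8, seed = 1)
  sb <- detect_salt_bridges(frame_coords(rig$traj, 1), rig$traj$topology)
  expect_equal(nrow(sb), 1)
  at <- rig$traj$topology$atoms
  expect_equal(at$resname[sb$oxygen], "GLU")
  expect_equal(at$resname[sb$hydrogen], "ARG")
  # neutral His contributes nothing; protonated does
  his <- data.frame(name = c("ND1", "HD1"), element = c("N", "H"),
                    resname = "HIS", resid = 10, chain = "A")
  glu <- data.frame(name = c("CD", "OE1"), element = c("C", "O"),
                    resname = "GLU", resid = 20, chain = "A")
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(4.9, 0, 0), c(3.65, 0, 0))
  atoms <- rbind(his, glu)
  top_n <- annotate_chemistry(topology_from_atoms(atoms, xyz))
  expect_equal(nrow(detect_salt_bridges(top_n$ref_coords, top_n)), 0)
  top_p <- annotate_chemistry(topology_from_atoms(atoms, xyz),
                              his_protonation = c("A:10" = "protonated"))
  expect_equal(nrow(detect_salt_bridges(top_p$ref_coords, top_p)), 1)
})

test_that("detectors match O(N^2) brute force exactly on randomized rigs", {
  for (s in 1:25) {
    top <- random_interaction_topology(n_groups = 12, seed = s)
    xyz <- top$ref_coords
    hb <- detect_hbonds(xyz, top)
    hb_o <- oracle_hbonds(xyz, top)
    expect_equal(nrow(hb), nrow(hb_o), info = paste("seed", s))
    if (nrow(hb)) {
      got <- hb[order(hb$donor, hb$acceptor), c("donor", "acceptor")]
      expect_equal(unname(as.matrix(got)),
                   unname(hb_o[, c("donor", "acceptor"), drop = FALSE]),
                   info = paste("seed", s))
    }
    sb <- detect_salt_bridges(xyz, top)
    sb_o <- oracle_salt_bridges(xyz, top)
    expect_equal(nrow(sb), nrow(sb_o), info = paste("seed", s))
    if (nrow(sb)) {
      got <- sb[order(sb$oxygen, sb$hydrogen), c("oxygen", "hydrogen")]
      expect_equal(unname(as.matrix(got)), unname(sb_o),
                   info = paste("seed", s))
    }
  }
})

test_that("detected sets are monotone in the distance cutoff", {
  for (s in 1:5) {
    top <- random_interaction_topology(n_groups = 12, seed = 100 + s)
    xyz <- top$ref_coords
    cuts <- c(2.5, 3.0, 3.5, 4.0)
    prev_h <- prev_s <- character(0)
    for (cc in cuts) {
      hb <- detect_hbonds(xyz, top, d_cut = cc)
      sb <- detect_salt_bridges(xyz, top, d_cut = cc)
      cur_h <- paste(hb$donor, hb$acceptor)
      cur_s <- paste(sb$oxygen, sb$hydrogen)
      expect_true(all(prev_h %in% cur_h))
      expect_true(all(prev_s %in% cur_s))
      prev_h <- cur_h; prev_s <- cur_s
    }
  }
})

test_that("occupancy counts frames exactly and suppresses empty pairs", {
  rig <- gen_interaction_rig("saltbridge", 0.6, 5, seed = 4)
  tab <- occupancy(rig$traj, "saltbridge")
  expect_equal(nrow(tab), 1)
  expect_identical(tab$occupancy, 0.6)
  # planted fraction 0.37 at T = 1000 is exact
  rig2 <- gen_interaction_rig("hbond", 0.37, 1000, seed = 6)
  tab2 <- occupancy(rig2$traj, "hbond")
  expect_identical(tab2$occupancy, 0.37)
  # zero fraction: pair absent
  rig0 <- gen_interaction_rig("saltbridge", 0, 5, seed = 4)
  expect_equal(nrow(occupancy(rig0$traj, "saltbridge")), 0)
  # atom-level table carries atom names
  tab3 <- occupancy(rig$traj, "saltbridge", level = "atom-pair")
  expect_true(all(c("atom_a", "atom_b") %in% names(tab3)))
  expect_identical(tab3$occupancy, 0.6)
})

test_that("occupancy is invariant under frame permutation and averages unions", {
  rig <- gen_interaction_rig("saltbridge", 0.4, 10, seed = 9)
  tr <- rig$traj
  perm <- sample(10)
  tr_p <- new_trajectory(tr$topology,
                         array(tr$coords[perm, , ], c(10, n_atoms(tr), 3)))
  expect_equal(occupancy(tr_p, "saltbridge")$occupancy,
               occupancy(tr, "saltbridge")$occupancy)
  # disjoint-window weighted average
  half1 <- new_trajectory(tr$topology, tr$coords[1:4, , , drop = FALSE])
  half2 <- new_trajectory(tr$topology, tr$coords[5:10, , , drop = FALSE])
  o1 <- occupancy(half1, "saltbridge")$occupancy
  o2 <- occupancy(half2, "saltbridge")$occupancy
  if (length(o1) == 0) o1 <- 0
  if (length(o2) == 0) o2 <- 0
  expect_equal((4 * o1 + 6 * o2) / 10, occupancy(tr, "saltbridge")$occupancy)
})

test_that("residue-level salt bridges imply at least one atom-level contact", {
  for (s in 1:5) {
    top <- random_interaction_topology(n_groups = 12, seed = 200 + s)
    coords <- array(top$ref_coords, c(1, nrow(top$atoms), 3))
    tr <- new_trajectory(top, coords)
    res_tab <- occupancy(tr, "saltbridge", level = "residue-pair")
    atom_tab <- occupancy(tr, "saltbridge", level = "atom-pair")
    expect_true(nrow(res_tab) <= nrow(atom_tab))
    if (nrow(res_tab)) expect_true(all(res_tab$occupancy > 0))
  }
})

test_that("occupancy differencing applies a strict threshold", {
  mk <- function(frac, seed = 31) {
    rig <- gen_interaction_rig("saltbridge", frac, 10, seed = seed)
    occupancy(rig$traj, "saltbridge")
  }
  a <- mk(0.8); b <- mk(0.2)
  d <- occupancy_diff(a, b)
  expect_equal(nrow(d$unique_to_a), 1)
  expect_equal(nrow(d$unique_to_b), 0)
  expect_equal(nrow(d$shared), 0)
  # identical tables: nothing unique
  d2 <- occupancy_diff(a, a)
  expect_equal(nrow(d2$unique_to_a), 0)
  expect_equal(nrow(d2$unique_to_b), 0)
  expect_equal(nrow(d2$shared), 1)
  # exactly 0.5 on both sides is in neither set (strict >)
  c5 <- mk(0.5)
  d3 <- occupancy_diff(c5, c5)
  expect_equal(nrow(d3$unique_to_a) + nrow(d3$unique_to_b) + nrow(d3$shared), 0)
  # level mismatch errors
  rig <- gen_interaction_rig("saltbridge", 0.8, 10, seed = 31)
  atom_tab <- occupancy(rig$traj, "saltbridge", level = "atom-pair")
  expect_error(occupancy_diff(a, atom_tab), "level")
})

test_that("pair distance series returns per-frame minima and errors on self", {
  rig <- gen_interaction_rig("saltbridge", 0.9, 10, target_distance = 2.7,
                             seed = 13)
  s <- pair_distance_series(rig$traj, list(resid = 289), list(resid = 362))
  expect_equal(nrow(s), 10)
  expect_equal(sort(unique(round(s$distance, 6))), c(2.7, 4.0))
  expect_equal(mean(s$distance < 3), 0.9)
  expect_error(pair_distance_series(rig$traj, list(resid = 289),
                                    list(resid = 289)),
               "identical")
})
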