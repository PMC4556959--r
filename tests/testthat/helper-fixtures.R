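# Text fixtures are built in code at test time.

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, chain, resid, x, y, z, 1, 0, toupper(element))
}

# one glycine: 4 heavy atoms + backbone amide H
write_gly_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "H",  "GLY", "A", 1, -0.950, 0.300, 0.000),
    pdb_atom_line(3, "CA", "GLY", "A", 1, 1.450, 0.200, 0.000, "C"),
    pdb_atom_line(4, "C",  "GLY", "A", 1, 2.200, -1.100, 0.000),
    pdb_atom_line(5, "O",  "GLY", "A", 1, 1.700, -2.200, 0.000),
    "END"
  )
  writeLines(lines, path)
  path
}

write_two_chain_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0, "C"),
    pdb_atom_line(3, "CA", "GLY", "B", 1, 0, 10, 0, "C"),
    pdb_atom_line(4, "CA", "SER", "B", 2, 3.8, 10, 0, "C"),
    "END"
  )
  writeLines(lines, path)
  path
}

# a rigged hydrogen-bond geometry: donor N-H at origin along +x, acceptor O
# at distance d from N, at `ang` degrees from the D->H direction
hbond_geometry <- function(d, ang) {
  th <- ang * pi / 180
  atoms <- data.frame(
    name = c("N", "H", "CA", "O"),
    element = c("N", "H", "C", "O"),
    resname = "GLY", resid = c(1, 1, 1, 2), chain = "A",
    stringsAsFactors = FALSE
  )
  coords <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(-0.9, 1.1, 0),
    d * c(cos(th), sin(th), 0)
  )
  annotate_chemistry(topology_from_atoms(atoms, coords))
}

# an arginine side-chain head with guanidinium hydrogens at covalent distance
arg_head_atoms <- function(resid = 362, origin = c(0, 0, 0)) {
  nm <- c("NE", "HE", "CZ", "NH1", "HH11", "HH12", "NH2", "HH21", "HH22")
  el <- c("N", "H", "C", "N", "H", "H", "N", "H", "H")
  xyz <- rbind(
    c(0, 0, 0), c(0, -1.0, 0),
    c(1.33, 0.6, 0),
    c(2.5, 0.0, 0), c(3.4, 0.4, 0), c(2.5, -1.0, 0),
    c(1.33, 2.0, 0), c(0.55, 2.6, 0), c(2.2, 2.5, 0)
  )
  list(atoms = data.frame(name = nm, element = el, resname = "ARG",
                          resid = resid, chain = "A",
                          stringsAsFactors = FALSE),
       coords = sweep(xyz, 2, origin, `+`))
}

# random annotated many-atom rig for detector-vs-oracle checks: a soup of
# donor (N-H), acceptor (O), acidic (GLU OE1) and basic (ARG NH1-HH11)
# groups at random positions with spacings spanning the cutoff region
random_interaction_topology <- function(n_groups = 15, seed = 1, box = NULL) {
  set.seed(seed)
  if (is.null(box)) box <- max(6, ceiling((n_groups * 30)^(1 / 3)))
  atoms <- NULL
  coords <- NULL
  rid <- 0
  for (g in seq_len(n_groups)) {
    rid <- rid + 1
    ctr <- runif(3, 0, box)
    # always include every group type at least once
    type <- if (g <= 4) c("don", "acc", "glu", "arg")[g]
            else sample(c("don", "acc", "glu", "arg"), 1)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    if (type == "don") {
      a <- data.frame(name = c("N", "H"), element = c("N", "H"),
                      resname = "GLY", resid = rid, chain = "A")
      x <- rbind(ctr, ctr + u)
    } else if (type == "acc") {
      a <- data.frame(name = "O", element = "O", resname = "GLY",
                      resid = rid, chain = "A")
      x <- rbind(ctr)
    } else if (type == "glu") {
      a <- data.frame(name = c("CD", "OE1"), element = c("C", "O"),
                      resname = "GLU", resid = rid, chain = "A")
      x <- rbind(ctr, ctr + 1.25 * u)
    } else {
      a <- data.frame(name = c("NH1", "HH11"), element = c("N", "H"),
                      resname = "ARG", resid = rid, chain = "A")
      x <- rbind(ctr, ctr + u)
    }
    atoms <- rbind(atoms, a)
    coords <- rbind(coords, x)
  }
  annotate_chemistry(topology_from_atoms(atoms, coords))
}
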