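#' @importFrom stats setNames
NULL

# Element-keyed van der Waals radii (Angstrom), after the Chothia-style table
# used by classic accessibility programs. Overridable in read_pdb_topology()
# and topology_from_atoms().
.default_vdw_radii <- c(
  C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00,
  P = 1.80, FE = 1.47, ZN = 1.39, MG = 1.18, CA = 1.74,
  K = 2.75, "NA" = 2.27, CL = 1.75
)

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  K = 39.098, "NA" = 22.990, CL = 35.45
)

.normalize_element <- function(el) {
  el <- toupper(trimws(el))
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

.lookup_element <- function(el, table, default) {
  key <- toupper(el)
  out <- unname(table[key])
  out[is.na(out)] <- default
  out
}

#' Build a topology from an atom table
#'
#' Constructs the internal topology object from a per-atom data frame and a
#' reference coordinate set. This is the programmatic entry point used by the
#' synthetic-data generators and by tests; PDB files go through
#' [read_pdb_topology()].
#'
#' @param atoms data frame with columns `name`, `element`, `resname`,
#'   `resid`, `chain`; optional `serial`, `mass`, `vdw_radius`.
#' @param coords numeric N x 3 matrix of reference coordinates (Angstrom),
#'   used for distance-based chemistry inference in [annotate_chemistry()].
#' @param radii named vector of element-keyed van der Waals radii overriding
#'   the built-in table.
#' @return An object of class `serp_topology`.
#' @export
topology_from_atoms <- function(atoms, coords, radii = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix matching the atom table")
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  atoms$element <- .normalize_element(atoms$element)
  atoms$is_hydrogen <- atoms$element == "H"
  rtab <- .default_vdw_radii
  if (!is.null(radii)) rtab[toupper(names(radii))] <- radii
  if (is.null(atoms$vdw_radius))
    atoms$vdw_radius <- .lookup_element(atoms$element, rtab, 1.80)
  if (is.null(atoms$mass))
    atoms$mass <- .lookup_element(atoms$element, .element_masses, 12.011)
  rkey <- paste(atoms$chain, atoms$resid, sep = "|")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[first], resid = atoms$resid[first],
    resname = atoms$resname[first], stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms, residues = residues,
         ref_coords = unname(coords), chem = NULL),
    class = "serp_topology"
  )
}

#' @export
print.serp_topology <- function(x, ...) {
  cat(sprintf("<serp_topology> %d atoms, %d residues, %d chains%s\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain)),
              if (is.null(x$chem)) "" else " (chemistry annotated)"))
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a `serp_topology` or `serp_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "serp_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Read a PDB file into a topology
#'
#' Parses ATOM/HETATM records (first MODEL if several) and annotates each atom
#' with element, mass and van der Waals radius. Elements are taken from the
#' element column when present and otherwise inferred from the atom-name
#' column.
#'
#' @param path path to a PDB file.
#' @param radii optional named element-keyed radius overrides (Angstrom).
#' @return A `serp_topology` with reference coordinates from the first model.
#' @export
read_pdb_topology <- function(path, radii = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path)
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep("", nrow(at))
  elesy <- trimws(elesy)
  need <- is.na(elesy) | elesy == ""
  if (any(need))
    elesy[need] <- suppressWarnings(bio3d::atom2ele(at$elety[need]))
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elesy,
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  topology_from_atoms(atoms, coords, radii = radii)
}

#' Construct a trajectory object
#'
#' @param topology a `serp_topology`.
#' @param coords numeric array of dimension T x N x 3 (frames, atoms, xyz),
#'   Angstrom.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @return An object of class `serp_trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "serp_topology"))
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3)
    stop("coords must be a T x N x 3 array")
  if (d[2] != nrow(topology$atoms))
    stop("coords atom dimension (", d[2], ") does not match topology (",
         nrow(topology$atoms), ")")
  if (d[1] < 1) stop("trajectory must contain at least one frame")
  if (is.null(times)) times <- seq_len(d[1]) - 1
  if (length(times) != d[1]) stop("times length must equal number of frames")
  if (d[1] > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, coords = unname(coords),
                 times = as.numeric(times)),
            class = "serp_trajectory")
}

#' @export
print.serp_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<serp_trajectory> %d frames x %d atoms, t = %.3f..%.3f ns\n",
              d[1], d[2], x$times[1], x$times[d[1]]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `serp_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of coordinates
#' @param traj a `serp_trajectory`.
#' @param i frame index.
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Read a coordinate trajectory
#'
#' Supported formats: multi-model PDB (MODEL/ENDMDL blocks) and the plain-text
#' `xyz-frames` format (repeated blocks of a line holding the atom count N
#' followed by N lines `name x y z`). Frame times are assigned as
#' `(frame - 1) * dt` since neither format carries physical time.
#'
#' @param path path to the trajectory file.
#' @param topology the matching `serp_topology`; every frame must contain its
#'   atoms in order.
#' @param format `"multi-model-pdb"` or `"xyz-frames"`.
#' @param dt frame spacing in ns (default 0.1).
#' @return A `serp_trajectory`.
#' @export
read_trajectory <- function(path, topology,
                            format = c("multi-model-pdb", "xyz-frames"),
                            dt = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  n <- nrow(topology$atoms)
  if (format == "multi-model-pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("failed to parse multi-model PDB '", path,
                               "': ", conditionMessage(e))
    )
    xyz <- pdb$xyz
    if (is.null(xyz) || length(xyz) == 0) stop("no frames in ", path)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    xyz <- unclass(xyz)
    if (ncol(xyz) != 3 * n)
      stop("frame shape mismatch: file frames have ", ncol(xyz) / 3,
           " atoms, topology has ", n)
    tt <- nrow(xyz)
    coords <- array(NA_real_, c(tt, n, 3))
    for (k in seq_len(tt))
      coords[k, , ] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    frames <- list()
    i <- 1L
    fr <- 0L
    while (i <= length(lines)) {
      fr <- fr + 1L
      cnt <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(cnt)) stop("frame ", fr, ": expected atom count, got '",
                           lines[i], "'")
      if (cnt != n || i + cnt > length(lines)) {
        avail <- min(cnt, length(lines) - i)
        stop("frame ", fr, ": expected ", n, " atoms, found ",
             if (cnt != n) cnt else avail)
      }
      block <- lines[(i + 1):(i + cnt)]
      parts <- strsplit(trimws(block), "[[:space:]]+")
      bad <- which(vapply(parts, length, 1L) < 4)
      if (length(bad)) stop("frame ", fr, ": malformed coordinate line ", bad[1])
      m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      if (anyNA(m)) stop("frame ", fr, ": non-numeric coordinates")
      frames[[fr]] <- m
      i <- i + cnt + 1L
    }
    if (fr == 0L) stop("no frames in ", path)
    coords <- array(NA_real_, c(fr, n, 3))
    for (k in seq_len(fr)) coords[k, , ] <- frames[[k]]
  }
  tt <- dim(coords)[1]
  new_trajectory(topology, coords, times = (seq_len(tt) - 1) * dt)
}

#' Write a trajectory to disk
#'
#' Writes either a multi-model PDB (coordinates at the standard 3-decimal PDB
#' precision) or the plain-text `xyz-frames` format read by
#' [read_trajectory()].
#'
#' @param traj a `serp_trajectory`.
#' @param path output path.
#' @param format `"multi-model-pdb"` or `"xyz-frames"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("multi-model-pdb", "xyz-frames")) {
  format <- match.arg(format)
  at <- traj$topology$atoms
  tt <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "multi-model-pdb") {
    nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
    for (k in seq_len(tt)) {
      xyz <- frame_coords(traj, k)
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        at$serial, nm, substr(at$resname, 1, 3), substr(at$chain, 1, 1),
        at$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(at$element)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (k in seq_len(tt)) {
      xyz <- frame_coords(traj, k)
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("%s %.3f %.3f %.3f", at$name,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

# residues treated as acidic / basic by the salt-bridge chemistry templates
.acidic_oxygen_names <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_nitrogen_names <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
  HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"),
  HSE = c("ND1", "NE2"), HSP = c("ND1", "NE2"), HIP = c("ND1", "NE2")
)
.his_names <- c("HIS", "HSD", "HSE", "HSP", "HIP")

#' Annotate donor/acceptor and salt-bridge chemistry
#'
#' Populates the topology with hydrogen-bond donors (heavy atom + covalently
#' bonded hydrogen, inferred by a distance criterion in the reference
#' coordinates), acceptors (N and O atoms), acidic oxygens (Asp OD1/OD2,
#' Glu OE1/OE2, C-terminal OXT and its carbonyl O) and basic hydrogens
#' (hydrogens bonded to Arg NE/NH1/NH2, Lys NZ, and protonated-His ND1/NE2).
#' Histidine contributes basic hydrogens only when marked protonated, either
#' by residue name (HSP/HIP) or through `his_protonation`.
#'
#' @param topology a `serp_topology` with reference coordinates.
#' @param his_protonation named character vector mapping histidine residues
#'   (names `"chain:resid"` or plain resid) to `"protonated"` or `"neutral"`.
#' @param dh_max maximum donor-hydrogen covalent distance (Angstrom,
#'   default 1.2) used to pair each hydrogen with its heavy atom.
#' @return The topology with a populated `chem` component. Idempotent.
#' @export
annotate_chemistry <- function(topology, his_protonation = NULL, dh_max = 1.2) {
  stopifnot(inherits(topology, "serp_topology"))
  at <- topology$atoms
  xyz <- topology$ref_coords
  n <- nrow(at)
  rkey <- paste(at$chain, at$resid, sep = ":")

  if (!is.null(his_protonation)) {
    keys <- names(his_protonation)
    if (is.null(keys)) stop("his_protonation must be a named vector")
    for (k in keys) {
      hit <- if (grepl(":", k)) rkey == k else as.character(at$resid) == k
      rn <- unique(at$resname[hit])
      if (!length(rn) || !any(rn %in% .his_names))
        stop("his_protonation entry '", k, "' does not name a His residue")
    }
  }
  is_protonated_his <- function(chain, resid, resname) {
    if (resname %in% c("HSP", "HIP")) return(TRUE)
    if (is.null(his_protonation)) return(FALSE)
    key1 <- paste(chain, resid, sep = ":")
    v <- his_protonation[key1]
    if (is.na(v)) v <- his_protonation[as.character(resid)]
    !is.na(v) && tolower(v) %in% c("protonated", "hsp", "hip", "true", "yes")
  }

  std <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","HSD","HSE",
           "HSP","HIP","ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
           "TYR","VAL")
  unk <- setdiff(unique(at$resname), std)
  if (length(unk))
    warning("non-standard residues skipped by chemistry templates: ",
            paste(unk, collapse = ", "))

  # donor pairs: each hydrogen bound to the nearest heavy atom within dh_max
  h_idx <- which(at$is_hydrogen)
  heavy_idx <- which(!at$is_hydrogen)
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(h_idx) && length(heavy_idx)) {
    for (h in h_idx) {
      d2 <- rowSums(sweep(xyz[heavy_idx, , drop = FALSE], 2, xyz[h, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= dh_max) {
        d <- heavy_idx[j]
        if (at$element[d] %in% c("N", "O", "S"))
          donors <- rbind(donors, data.frame(donor = d, hydrogen = h))
      }
    }
  }

  acceptors <- which(at$element %in% c("N", "O") & !at$is_hydrogen)

  acidic <- logical(n)
  for (rn in names(.acidic_oxygen_names))
    acidic <- acidic | (at$resname == rn & at$name %in% .acidic_oxygen_names[[rn]])
  acidic <- acidic | at$name == "OXT"
  has_oxt <- unique(rkey[at$name == "OXT"])
  acidic <- acidic | (at$name == "O" & rkey %in% has_oxt)
  acidic_oxygens <- which(acidic & at$element == "O")

  basic_h <- integer(0)
  if (nrow(donors)) {
    for (r in seq_len(nrow(donors))) {
      d <- donors$donor[r]
      rn <- at$resname[d]
      nm <- at$name[d]
      ok <- FALSE
      if (rn %in% names(.basic_nitrogen_names) && nm %in% .basic_nitrogen_names[[rn]]) {
        ok <- if (rn %in% .his_names)
          is_protonated_his(at$chain[d], at$resid[d], rn) else TRUE
      }
      if (ok) basic_h <- c(basic_h, donors$hydrogen[r])
    }
  }

  topology$chem <- list(
    donors = donors,
    acceptors = acceptors,
    acidic_oxygens = acidic_oxygens,
    basic_hydrogens = basic_h
  )
  topology
}

#' Select atom indices from a topology
#'
#' @param topology a `serp_topology` (or `serp_trajectory`).
#' @param selection `"all"`, `"heavy"`, `"calpha"`, `"backbone"`, an integer
#'   vector of atom indices, or a list with any of `chain`, `resid`,
#'   `resname`, `name`, `element` to intersect.
#' @return integer vector of atom indices (topology order preserved).
#' @export
select_atoms <- function(topology, selection = "all") {
  if (inherits(topology, "serp_trajectory")) topology <- topology$topology
  at <- topology$atoms
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (!length(idx) || any(idx < 1 | idx > nrow(at)))
      stop("atom index selection out of range")
    return(idx)
  }
  if (is.character(selection) && length(selection) == 1) {
    idx <- switch(selection,
      all = seq_len(nrow(at)),
      heavy = which(!at$is_hydrogen),
      calpha = which(at$name == "CA" & !at$is_hydrogen),
      backbone = which(at$name %in% c("N", "CA", "C", "O")),
      stop("unknown selection keyword: ", selection)
    )
    if (!length(idx)) stop("selection '", selection, "' matches no atoms")
    return(idx)
  }
  if (is.list(selection)) {
    keep <- rep(TRUE, nrow(at))
    if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
    if (!is.null(selection$resid)) keep <- keep & at$resid %in% selection$resid
    if (!is.null(selection$resname)) keep <- keep & at$resname %in% selection$resname
    if (!is.null(selection$name)) keep <- keep & at$name %in% selection$name
    if (!is.null(selection$element))
      keep <- keep & at$element %in% .normalize_element(selection$element)
    idx <- which(keep)
    if (!length(idx)) stop("selection matches no atoms")
    return(idx)
  }
  stop("unsupported selection")
}
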