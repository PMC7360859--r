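## Structures, trajectories and region selections.
##
## Coordinates are Angstrom everywhere; times are ns everywhere.

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)

mass_from_element <- function(element, atom_name) {
  el <- toupper(trimws(element))
  ## fallback: infer element from the first alphabetic character of the name
  miss <- is.na(el) | el == "" | !(el %in% names(ATOMIC_MASSES))
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", toupper(trimws(atom_name[miss])))
    el[miss] <- substr(guess, 1, 1)
  }
  m <- ATOMIC_MASSES[el]
  if (anyNA(m)) stop("cannot assign a mass for element(s): ",
                     paste(unique(el[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Construct a molecular structure
#'
#' A `structure3d` bundles per-atom annotation with one coordinate set.
#' All per-atom vectors must have equal length; author residue numbering
#' is kept verbatim (insertion codes are part of the residue key).
#'
#' @param atom_name character, PDB atom names (e.g. "CA").
#' @param resid integer, author residue numbers.
#' @param chain character, chain identifiers.
#' @param element character, element symbols ("" to infer from atom name).
#' @param xyz numeric n x 3 matrix of coordinates, Angstrom.
#' @param icode character, insertion codes (default "").
#' @param mass numeric, atomic masses in amu; inferred from `element` when NULL.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atom_name, resid, chain, element, xyz,
                        icode = rep("", length(atom_name)), mass = NULL) {
  n <- length(atom_name)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(resid) == n, length(chain) == n,
            length(element) == n, nrow(xyz) == n, length(icode) == n)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  if (is.null(mass)) mass <- mass_from_element(element, atom_name)
  if (any(mass <= 0)) stop("atomic masses must be positive")
  obj <- list(atom_name = as.character(atom_name),
              resid = as.integer(resid),
              icode = as.character(icode),
              chain = as.character(chain),
              element = as.character(element),
              mass = as.numeric(mass),
              xyz = xyz)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", length(x$atom_name), "atoms,",
      length(unique(paste(x$chain, x$resid, x$icode))), "residues, chains:",
      paste(unique(x$chain), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(s) length(s$atom_name)

#' Construct a trajectory
#'
#' An ordered set of coordinate frames over one topology.
#'
#' @param topology a `structure3d`.
#' @param coords numeric array n_atoms x 3 x n_frames (Angstrom) or a list of
#'   n x 3 matrices.
#' @param frame_interval time between saved frames, ns (> 0).
#' @return an object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, coords, frame_interval = 1) {
  stopifnot(inherits(topology, "structure3d"), frame_interval > 0)
  if (is.list(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(dim(coords), 1))
  if (dim(coords)[1] != n_atoms(topology))
    stop("frame atom count (", dim(coords)[1], ") does not match topology (",
         n_atoms(topology), ")")
  if (dim(coords)[3] < 1) stop("a trajectory needs at least one frame")
  obj <- list(topology = topology, coords = coords,
              frame_interval = as.numeric(frame_interval))
  class(obj) <- "trajectory3d"
  obj
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("trajectory3d:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, frame interval", x$frame_interval, "ns\n")
  invisible(x)
}

n_frames <- function(t) dim(t$coords)[3]

frame_coords <- function(t, i) t$coords[, , i, drop = TRUE]

#' Define a region of a receptor by chain and residue range
#'
#' CDR and variable-domain definitions are explicit author-numbering ranges
#' supplied by the user; no renumbering scheme (IMGT/Kabat) is applied.
#'
#' @param name region label; one of "CDR3_alpha", "CDR3_beta", "V_alpha",
#'   "V_beta", "CDR_loops_alpha", "CDR_loops_beta", "custom".
#' @param chain_id chain identifier in the topology.
#' @param residue_range inclusive integer pair `c(start, end)`.
#' @return an object of class `region_selection`.
#' @export
region_selection <- function(name, chain_id, residue_range) {
  valid <- c("CDR3_alpha", "CDR3_beta", "V_alpha", "V_beta",
             "CDR_loops_alpha", "CDR_loops_beta", "custom")
  if (!name %in% valid)
    stop("region name must be one of: ", paste(valid, collapse = ", "))
  residue_range <- as.integer(residue_range)
  stopifnot(length(residue_range) == 2)
  if (residue_range[1] > residue_range[2])
    stop("residue range start must be <= end")
  obj <- list(name = name, chain_id = as.character(chain_id),
              residue_range = residue_range)
  class(obj) <- "region_selection"
  obj
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Resolve a region selection to atom indices
#'
#' @param selection a `region_selection`.
#' @param topology a `structure3d`.
#' @param backbone_only restrict to backbone atoms N, CA, C, O.
#' @return sorted integer vector of atom indices; silently empty selections
#'   are forbidden (hard error).
#' @export
resolve_selection <- function(selection, topology, backbone_only = FALSE) {
  stopifnot(inherits(selection, "region_selection"),
            inherits(topology, "structure3d"))
  if (!selection$chain_id %in% topology$chain)
    stop("chain '", selection$chain_id, "' not present in topology")
  keep <- topology$chain == selection$chain_id &
    topology$resid >= selection$residue_range[1] &
    topology$resid <= selection$residue_range[2]
  if (backbone_only) keep <- keep & topology$atom_name %in% BACKBONE_NAMES
  idx <- sort(which(keep))
  if (length(idx) == 0)
    stop("selection '", selection$name, "' (chain ", selection$chain_id,
         ", residues ", selection$residue_range[1], "-",
         selection$residue_range[2], ") resolves to zero atoms")
  idx
}

## ---- PDB I/O (ATOM/MODEL/ENDMDL, fixed columns) -----------------------------

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  at <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(at) == 0) stop("no ATOM records in ", path)
  ln <- lines[at]
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("unparseable coordinate field in ", path, " at line ", at[bad[1]])
  altloc <- substr(ln, 17, 17)
  keep <- altloc %in% c(" ", "", "A", "1")  # first altloc kept
  list(atom_name = trimws(substr(ln, 13, 16))[keep],
       resid = as.integer(substr(ln, 23, 26))[keep],
       icode = trimws(substr(ln, 27, 27))[keep],
       chain = substr(ln, 22, 22)[keep],
       element = trimws(substr(ln, 77, 78))[keep],
       xyz = cbind(x, y, z)[keep, , drop = FALSE])
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM records; for multi-model files only the first
#' MODEL is returned (use [read_trajectory()] for the full ensemble).
#' Author residue numbering and insertion codes are preserved; the first
#' alternate location is kept.
#'
#' @param path PDB file path.
#' @return a `structure3d`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(ends)) lines <- lines[seq_len(ends[1])]
  p <- parse_pdb_atoms(lines, path)
  structure3d(p$atom_name, p$resid, p$chain, p$element, p$xyz, icode = p$icode)
}

format_pdb_frame <- function(s, xyz, model = NULL) {
  nm <- s$atom_name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), paste0(" ", formatC(nm, width = -3)))
  body <- sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  seq_along(nm) %% 100000, nm4, "ALA", s$chain, s$resid,
                  ifelse(s$icode == "", " ", s$icode),
                  xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                  toupper(substr(ifelse(s$element == "", substr(nm, 1, 1), s$element), 1, 2)))
  if (is.null(model)) body
  else c(sprintf("MODEL     %4d", model), body, "ENDMDL")
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param x a `structure3d` or `trajectory3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure3d")) {
    writeLines(c(format_pdb_frame(x, x$xyz), "END"), path)
  } else if (inherits(x, "trajectory3d")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n_frames(x)))
      writeLines(format_pdb_frame(x$topology, frame_coords(x, i), model = i), con)
    writeLines("END", con)
  } else stop("x must be a structure3d or trajectory3d")
  invisible(path)
}

## ---- trajectory container ---------------------------------------------------

#' Write a trajectory to the frame-major binary container
#'
#' Self-describing one-line ASCII header (magic, atom count, frame count,
#' frame interval in ns, float precision) followed by little-endian doubles,
#' frame-major.
#'
#' @param traj a `trajectory3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("TCRTRJ1 natoms=%d nframes=%d frame_interval=%.17g precision=float64\n",
                 dim(traj$coords)[1], n_frames(traj), traj$frame_interval)
  writeBin(charToRaw(hdr), con)
  for (i in seq_len(n_frames(traj)))
    writeBin(as.numeric(t(frame_coords(traj, i))), con, size = 8, endian = "little")
  invisible(path)
}

read_container <- function(path, topology) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "\n") break
    hdr <- c(hdr, ch)
  }
  hdr <- paste(hdr, collapse = "")
  if (!startsWith(hdr, "TCRTRJ1")) stop("not a trajectory container: ", path)
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([0-9.eE+-]+)"), hdr))[[1]]
    if (length(m) < 2) stop("malformed container header: missing ", key)
    as.numeric(m[2])
  }
  na <- as.integer(get_field("natoms"))
  nf <- as.integer(get_field("nframes"))
  fi <- get_field("frame_interval")
  if (na != n_atoms(topology))
    stop("container atom count (", na, ") does not match topology (",
         n_atoms(topology), ")")
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (i in seq_len(nf)) {
    v <- readBin(con, "numeric", n = 3 * na, size = 8, endian = "little")
    if (length(v) < 3 * na)
      stop("truncated trajectory container at frame ", i, " of ", nf)
    coords[, , i] <- matrix(v, ncol = 3, byrow = TRUE)
  }
  trajectory3d(topology, coords, frame_interval = fi)
}

read_multimodel_pdb <- function(path, topology, frame_interval) {
  lines <- readLines(path)
  starts <- which(substr(lines, 1, 5) == "MODEL")
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(starts) == 0) {  # single implicit model
    s <- read_pdb(path)
    return(trajectory3d(topology, s$xyz, frame_interval))
  }
  if (length(ends) < length(starts))
    stop("truncated multi-model PDB: model ", length(starts), " has no ENDMDL")
  frames <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    p <- parse_pdb_atoms(lines[starts[i]:ends[i]], path)
    if (nrow(p$xyz) != n_atoms(topology))
      stop("model ", i, " atom count (", nrow(p$xyz),
           ") does not match topology (", n_atoms(topology), ")")
    frames[[i]] <- p$xyz
  }
  trajectory3d(topology, frames, frame_interval)
}

#' Read a trajectory (binary container or multi-model PDB)
#'
#' Dispatches on content: files starting with the container magic are read
#' as the binary format (frame interval from the header); anything else is
#' parsed as multi-model PDB with `frame_interval` from the argument.
#'
#' @param path trajectory file.
#' @param topology a `structure3d` whose atom count every frame must match.
#' @param frame_interval ns between frames for PDB input (container input
#'   carries its own).
#' @return a `trajectory3d`.
#' @export
read_trajectory <- function(path, topology, frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", 7)
  if (identical(rawToChar(magic), "TCRTRJ1"))
    read_container(path, topology)
  else
    read_multimodel_pdb(path, topology, frame_interval)
}
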