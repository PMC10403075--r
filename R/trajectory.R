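## Trilayer frames and trajectories: typed-atom topology + coordinates (nm),
## with multi-model PDB import/export.

## canonical residue-name <-> code maps used in PDB files
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL",
          Nle = "NLE", Sar = "SAR", Aib = "AIB",
          R8 = "XR8", S5 = "XS5", B5 = "XB5", S8 = "XS8")
.aa3_rev <- structure(names(.aa3), names = unname(.aa3))

#' Default residue-name classification map
#'
#' Maps PDB residue names to molecule classes: `POP*` phospholipid,
#' `TRI`/`TRIO`/`TO` triolein, waters, common ion names, and the peptide
#' residue names (natural three-letter codes plus `NLE`, `SAR`, `AIB` and
#' the olefin-arm codes `XR8`/`XS5`/`XB5`/`XS8`).
#'
#' @return data.frame of `resid`, `class`.
#' @export
default_class_map <- function() {
  rbind(
    data.frame(resid = c("POP", "POPC", "DMPC", "DPPC"), class = "PL"),
    data.frame(resid = c("TRI", "TRIO", "TO", "TGL"), class = "TO"),
    data.frame(resid = c("HOH", "TIP", "TIP3", "WAT", "SOL"),
               class = "water"),
    data.frame(resid = c("SOD", "CLA", "NA", "CL", "POT", "K", "ION"),
               class = "ion"),
    data.frame(resid = unname(.aa3), class = "peptide")
  )
}

## shared topology constructor; fills role flags from atom/residue names
build_topology <- function(atom_name, resid, chain, resno,
                           class_map = default_class_map()) {
  n <- length(atom_name)
  cls <- class_map$class[match(resid, class_map$resid)]
  if (anyNA(cls))
    stop("unclassified residue name(s): ",
         paste(unique(resid[is.na(cls)]), collapse = ", "),
         "; extend the class map", call. = FALSE)
  molecule_id <- ifelse(cls == "peptide",
                        paste0("pep:", chain),
                        paste0(cls, ":", chain, ":", resno))
  top <- data.frame(
    id = seq_len(n),
    atom_name = atom_name,
    element = toupper(substr(gsub("[0-9]", "", atom_name), 1, 1)),
    molecule_class = cls,
    molecule_id = molecule_id,
    residue_index = ifelse(cls == "peptide", resno, NA_integer_),
    resid = resid,
    chain = chain,
    stringsAsFactors = FALSE)
  top$is_phosphorus <- cls == "PL" & atom_name == "P"
  top$is_c_alpha <- cls == "peptide" & atom_name == "CA"
  top$is_donor_heavy <- cls == "peptide" & atom_name == "N"
  top$is_donor_h <- cls == "peptide" & atom_name %in% c("H", "HN")
  top$is_acceptor <- cls == "TO" & grepl("^O[0-9]*$", atom_name)
  ## link each amide H to the N of its own residue
  top$donor_parent <- NA_integer_
  hs <- which(top$is_donor_h)
  if (length(hs)) {
    key <- paste(top$molecule_id, top$residue_index)
    nidx <- which(top$is_donor_heavy)
    top$donor_parent[hs] <- nidx[match(key[hs], key[nidx])]
  }
  top
}

validate_topology <- function(top) {
  pl <- top[top$molecule_class == "PL", ]
  if (nrow(pl)) {
    np <- tapply(pl$is_phosphorus, pl$molecule_id, sum)
    if (any(np != 1))
      stop("every phospholipid must carry exactly one phosphorus atom",
           call. = FALSE)
  }
  pep <- top[top$molecule_class == "peptide", ]
  if (nrow(pep)) {
    nca <- tapply(pep$is_c_alpha,
                  paste(pep$molecule_id, pep$residue_index), sum)
    if (any(nca != 1))
      stop("every peptide residue must carry exactly one c-alpha",
           call. = FALSE)
  }
  invisible(top)
}

#' Trilayer trajectory container
#'
#' A topology table of typed atoms plus an `n_atoms x 3 x n_frames`
#' coordinate array in nm and the periodic box lengths in nm.
#' `trilayer_frame()` is the single-frame case; [get_frame()] extracts one
#' frame from a trajectory.
#'
#' @param topology topology data.frame (see [read_trajectory()]).
#' @param coords coordinates in nm: `n x 3` matrix (frame) or
#'   `n x 3 x F` array (trajectory).
#' @param box periodic box lengths, nm triple.
#' @return a `TrilayerTrajectory` (or `TrilayerFrame`).
#' @export
trilayer_trajectory <- function(topology, coords, box) {
  validate_topology(topology)
  if (length(dim(coords)) == 2)
    coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(dim(coords)[1] == nrow(topology), dim(coords)[2] == 3,
            length(box) == 3)
  structure(list(topology = topology, coords = coords,
                 box = as.numeric(box)),
            class = "TrilayerTrajectory")
}

#' @rdname trilayer_trajectory
#' @export
trilayer_frame <- function(topology, coords, box) {
  validate_topology(topology)
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            nrow(coords) == nrow(topology))
  structure(list(topology = topology, coords = coords,
                 box = as.numeric(box)),
            class = "TrilayerFrame")
}

#' @rdname trilayer_trajectory
#' @param traj a `TrilayerTrajectory`.
#' @param frame frame index.
#' @export
get_frame <- function(traj, frame = 1) {
  stopifnot(inherits(traj, "TrilayerTrajectory"))
  trilayer_frame(traj$topology, traj$coords[, , frame], traj$box)
}

n_frames <- function(traj) {
  if (inherits(traj, "TrilayerFrame")) 1L else dim(traj$coords)[3]
}

as_traj <- function(x) {
  if (inherits(x, "TrilayerFrame"))
    trilayer_trajectory(x$topology, x$coords, x$box)
  else x
}

#' @export
print.TrilayerTrajectory <- function(x, ...) {
  cat("TrilayerTrajectory:", nrow(x$topology), "atoms,",
      dim(x$coords)[3], "frames, box",
      paste(round(x$box, 2), collapse = " x "), "nm\n")
  print(table(x$topology$molecule_class))
  invisible(x)
}

#' @export
print.TrilayerFrame <- function(x, ...) {
  cat("TrilayerFrame:", nrow(x$topology), "atoms, box",
      paste(round(x$box, 2), collapse = " x "), "nm\n")
  invisible(x)
}

#' Read a trilayer trajectory from multi-model PDB
#'
#' Parses a (possibly multi-model) PDB file via `bio3d`, converts
#' coordinates to nm, classifies molecules from residue names via the
#' class map, and tags atom roles: phosphorus (`P` of a phospholipid),
#' peptide c-alpha, backbone amide donors (`N`/`H`), and triolein ester
#' oxygens as hydrogen-bond acceptors. The periodic box is taken from the
#' `CRYST1` record.
#'
#' @param path PDB file path.
#' @param class_map residue-name classification map
#'   (default [default_class_map()]).
#' @return a `TrilayerTrajectory`.
#' @export
read_trajectory <- function(path, class_map = default_class_map()) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  top <- build_topology(trimws(a$elety), trimws(a$resid), trimws(a$chain),
                        a$resno, class_map)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(top)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  ## box from CRYST1 (bio3d does not retain it)
  box <- c(NA_real_, NA_real_, NA_real_)
  head_lines <- readLines(path, n = 50)
  cl <- grep("^CRYST1", head_lines, value = TRUE)
  if (length(cl)) {
    box <- c(as.numeric(substr(cl[1], 7, 15)),
             as.numeric(substr(cl[1], 16, 24)),
             as.numeric(substr(cl[1], 25, 33))) / 10
  }
  if (anyNA(box))
    stop("no CRYST1 record: periodic box is required", call. = FALSE)
  trilayer_trajectory(top, coords, box)
}

#' Write a trajectory to multi-model PDB
#'
#' Fixed-column PDB v3.3 layout; one `MODEL`/`ENDMDL` block per frame,
#' coordinates converted from nm to Angstrom, box as `CRYST1`.
#'
#' @param traj a `TrilayerTrajectory` or `TrilayerFrame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  traj <- as_traj(traj)
  top <- traj$topology
  nf <- n_frames(traj)
  namef <- ifelse(nchar(top$atom_name) < 4,
                  sprintf(" %-3s", top$atom_name),
                  top$atom_name)
  resno <- top$residue_index
  other <- top$molecule_class != "peptide"
  resno[other] <- as.integer(sub(".*:", "", top$molecule_id[other]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    traj$box[1] * 10, traj$box[2] * 10, traj$box[3] * 10, 90, 90, 90), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f] * 10
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      top$id %% 100000, namef, top$resid, top$chain, resno %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
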