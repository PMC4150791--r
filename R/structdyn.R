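# Trajectory post-processing: residue-to-DNA minimum-distance contacts
# (time-averaged), hydrogen-bond occupancy under geometric criteria, and
# Shrake-Rupley solvent-accessible surface area with burial fractions.

DNA_RESIDUE_NAMES <- c("DA", "DC", "DG", "DT")

# Bondi van der Waals radii (Angstrom) by element.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80,
                 S = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                 ZN = 1.39)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue in
# an extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column).
MAX_SASA_GXG <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
                  GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
                  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
                  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Construct a trajectory from atom metadata and per-frame coordinates
#'
#' @param atoms data.frame with columns `atom_id`, `element`, `resno`
#'   (residue index), `resid` (residue name), and optionally
#'   `chain_class` (`"protein"` or `"dna"`; derived from `resid` via the
#'   DNA residue-name whitelist DA/DC/DG/DT when absent) and `name`
#'   (atom name).
#' @param frames List of numeric matrices (n_atoms x 3), one per frame;
#'   constant atom roster across frames.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(atoms, frames) {
  need <- c("atom_id", "element", "resno", "resid")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!length(frames)) stop("need >= 1 frame", call. = FALSE)
  for (fr in frames) {
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != nrow(atoms))
      stop("each frame must be an n_atoms x 3 matrix", call. = FALSE)
    if (!all(is.finite(fr)))
      stop("coordinates must be finite", call. = FALSE)
  }
  if (is.null(atoms$chain_class))
    atoms$chain_class <- ifelse(atoms$resid %in% DNA_RESIDUE_NAMES,
                                "dna", "protein")
  structure(list(atoms = atoms, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,", nrow(x$atoms), "atoms (",
      sum(x$atoms$chain_class == "protein"), "protein /",
      sum(x$atoms$chain_class == "dna"), "DNA )\n")
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; atoms are classified as DNA
#' by the residue-name whitelist DA/DC/DG/DT, everything else as protein.
#' Elements are taken from the element column when present, else derived
#' from the atom name.
#'
#' @param path Path to a multi-model PDB file.
#' @return A [trajectory].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  element <- toupper(trimws(if (!is.null(at$elesy)) at$elesy else ""))
  no_elem <- is.na(element) | element == ""
  if (any(no_elem)) {
    guess <- toupper(substr(trimws(gsub("[0-9]", "", at$elety)), 1L, 1L))
    element[no_elem] <- guess[no_elem]
  }
  atoms <- data.frame(atom_id = at$eleno, name = trimws(at$elety),
                      element = element, resno = at$resno,
                      resid = trimws(at$resid))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  trajectory(atoms, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  name <- if (!is.null(at$name)) at$name else at$element
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$atom_id, substr(name, 1L, 4L), substr(at$resid, 1L, 3L),
      at$resno, xyz[, 1L], xyz[, 2L], xyz[, 3L], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

frame_matrix <- function(traj, frame) {
  if (frame < 1L || frame > length(traj$frames))
    stop("frame ", frame, " out of range", call. = FALSE)
  traj$frames[[frame]]
}

# All pairwise Euclidean distances between two coordinate sets.
cross_distances <- function(a, b) {
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

#' Minimum residue-to-DNA distance in one frame
#'
#' Minimum over all (residue atom, DNA atom) pairwise Euclidean distances.
#'
#' @param traj A [trajectory].
#' @param residue_index Protein residue number.
#' @param frame Frame index (default 1).
#' @return Distance in Angstrom.
#' @export
min_residue_dna_distance <- function(traj, residue_index, frame = 1L) {
  res_sel <- traj$atoms$resno == residue_index &
    traj$atoms$chain_class == "protein"
  dna_sel <- traj$atoms$chain_class == "dna"
  if (!any(res_sel))
    stop("no protein atoms for residue ", residue_index, call. = FALSE)
  if (!any(dna_sel)) stop("no DNA atoms in trajectory", call. = FALSE)
  xyz <- frame_matrix(traj, frame)
  min(cross_distances(xyz[res_sel, , drop = FALSE],
                      xyz[dna_sel, , drop = FALSE]))
}

#' Time-averaged residue-to-DNA contact distances
#'
#' Per residue, the arithmetic mean over frames of the per-frame minimum
#' distance to any DNA atom.  `frames` restricts the analysis window
#' (e.g. to the unconstrained tail of a simulation).
#'
#' @param traj A [trajectory].
#' @param residues Integer vector of protein residue numbers.
#' @param frames Frame indices to analyze (default all).
#' @return Object of class `contact_matrix`: data.frame `residue`,
#'   `mean_min_dist`, with the per-frame series in attribute `series`
#'   (matrix residues x frames).
#' @export
time_averaged_contacts <- function(traj, residues,
                                   frames = seq_along(traj$frames)) {
  if (!length(frames)) stop("empty frame selection", call. = FALSE)
  series <- matrix(NA_real_, nrow = length(residues),
                   ncol = length(frames),
                   dimnames = list(residues, frames))
  for (j in seq_along(frames))
    for (i in seq_along(residues))
      series[i, j] <- min_residue_dna_distance(traj, residues[i],
                                               frames[j])
  out <- data.frame(residue = residues, mean_min_dist = rowMeans(series))
  attr(out, "series") <- series
  class(out) <- c("contact_matrix", "data.frame")
  out
}

#' Hydrogen-bond geometric criteria
#'
#' @param max_distance Maximum donor-acceptor heavy-atom distance in
#'   Angstrom (closed interval; default 3.5).
#' @param min_angle Minimum donor-hydrogen-acceptor angle in degrees
#'   (default 140); only applied when hydrogen positions are supplied.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 140) {
  if (max_distance <= 0) stop("max_distance must be > 0", call. = FALSE)
  if (min_angle <= 0 || min_angle > 180)
    stop("min_angle must be in (0, 180]", call. = FALSE)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of analyzed frames in which at least one donor-acceptor pair
#' satisfies all geometric criteria: donor-acceptor distance within
#' `max_distance` (closed interval) and, when `hydrogens` maps donors to
#' their hydrogen atoms, donor-hydrogen-acceptor angle of at least
#' `min_angle`.  Without hydrogens (common for heavy-atom-only models) a
#' distance-only criterion applies, with a warning.
#'
#' @param traj A [trajectory].
#' @param donors,acceptors Atom ids (matching `atoms$atom_id`).
#' @param hydrogens Optional integer vector parallel to `donors` giving
#'   each donor's hydrogen atom id.
#' @param criteria A [hbond_criteria].
#' @param frames Frame indices to analyze (default all).
#' @return Occupancy fraction in `[0, 1]`.
#' @export
hbond_occupancy <- function(traj, donors, acceptors, hydrogens = NULL,
                            criteria = hbond_criteria(),
                            frames = seq_along(traj$frames)) {
  idx <- function(ids, what) {
    i <- match(ids, traj$atoms$atom_id)
    if (anyNA(i))
      stop("unknown ", what, " atom id(s): ",
           paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  di <- idx(donors, "donor"); ai <- idx(acceptors, "acceptor")
  hi <- if (!is.null(hydrogens)) {
    if (length(hydrogens) != length(donors))
      stop("hydrogens must parallel donors", call. = FALSE)
    idx(hydrogens, "hydrogen")
  } else {
    warning("no hydrogens supplied: distance-only hydrogen-bond criterion",
            call. = FALSE)
    NULL
  }
  if (!length(frames)) stop("empty frame selection", call. = FALSE)
  hit <- 0L
  for (f in frames) {
    xyz <- frame_matrix(traj, f)
    d <- cross_distances(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
    ok <- d <= criteria$max_distance
    if (!is.null(hi) && any(ok)) {
      pair <- which(ok, arr.ind = TRUE, useNames = FALSE)
      keep <- logical(nrow(pair))
      for (r in seq_len(nrow(pair))) {
        dh <- xyz[di[pair[r, 1L]], ] - xyz[hi[pair[r, 1L]], ]
        ah <- xyz[ai[pair[r, 2L]], ] - xyz[hi[pair[r, 1L]], ]
        cosang <- sum(dh * ah) / (sqrt(sum(dh^2)) * sqrt(sum(ah^2)))
        keep[r] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >=
          criteria$min_angle
      }
      ok <- any(keep)
    } else {
      ok <- any(ok)
    }
    hit <- hit + ok
  }
  hit / length(frames)
}

# Deterministic near-uniform points on the unit sphere (golden-spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of one frame (Shrake-Rupley)
#'
#' Per atom, the fraction of `n_points` quadrature points on the expanded
#' sphere of radius `r_vdw + probe_radius` that fall outside every
#' neighboring atom's expanded sphere, times the expanded sphere area;
#' per-residue SASA is the sum over the residue's atoms.
#'
#' @param traj A [trajectory] (or any object accepted by it).
#' @param frame Frame index.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Quadrature points per atom (default 960).
#' @param radii Named vector of van der Waals radii by element (default
#'   Bondi).
#' @return Named numeric vector: SASA per residue number (Angstrom^2),
#'   with per-atom values in attribute `atom_sasa`.
#' @export
sasa <- function(traj, frame = 1L, probe_radius = 1.4, n_points = 960L,
                 radii = BONDI_RADII) {
  at <- traj$atoms
  r <- radii[toupper(at$element)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(at$element[is.na(r)]), collapse = ", "),
         call. = FALSE)
  r <- unname(r) + probe_radius
  xyz <- frame_matrix(traj, frame)
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  atom_sasa <- numeric(n)
  d2 <- cross_distances(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < r[i] + r & seq_len(n) != i)
    sphere <- sweep(pts * r[i], 2L, xyz[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(sphere, 2L, xyz[j, ], "-")
        buried <- buried | rowSums(dj^2) < r[j]^2
        if (all(buried)) break
      }
      frac <- mean(!buried)
    } else frac <- 1
    atom_sasa[i] <- frac * 4 * pi * r[i]^2
  }
  out <- tapply(atom_sasa, at$resno, sum)
  res <- stats::setNames(as.numeric(out), names(out))
  attr(res, "atom_sasa") <- atom_sasa
  res
}

#' Fraction of a residue buried, averaged over a trajectory
#'
#' `1 - mean(SASA over frames) / reference_SASA`, clamped to `[0, 1]`.
#' The default reference is the residue type's theoretical maximum
#' exposure in an extended Gly-X-Gly tripeptide.
#'
#' @param traj A [trajectory].
#' @param residue_index Residue number.
#' @param reference Reference SASA in Angstrom^2: a single number, or
#'   `NULL` to look the residue type up in `reference_table`.
#' @param reference_table Named vector of per-residue-type maximum SASA
#'   (default [MAX_SASA_GXG], keyed by 3-letter residue name).
#' @param frames Frame indices to analyze (default all).
#' @param ... Passed to [sasa()].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_buried <- function(traj, residue_index, reference = NULL,
                            reference_table = MAX_SASA_GXG,
                            frames = seq_along(traj$frames), ...) {
  sel <- traj$atoms$resno == residue_index
  if (!any(sel)) stop("residue ", residue_index, " not found", call. = FALSE)
  if (is.null(reference)) {
    rtype <- unique(traj$atoms$resid[sel])[1L]
    reference <- reference_table[toupper(rtype)]
    if (is.na(reference))
      stop("residue type ", rtype, " missing from reference table",
           call. = FALSE)
  }
  if (reference <= 0) stop("reference SASA must be > 0", call. = FALSE)
  vals <- vapply(frames, function(f) {
    s <- sasa(traj, frame = f, ...)
    s[[as.character(residue_index)]]
  }, 0)
  min(max(1 - mean(vals) / reference, 0), 1)
}
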