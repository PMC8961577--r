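#' Atom-level topology of a bilayer system
#'
#' A topology annotates every atom with its species, molecule id, role tag,
#' element, mass and leaflet. Role tags resolve uniquely within a molecule
#' and are the only handle the analyses use to find atoms (phosphates,
#' C--H pairs, donors, acceptors, ...).
#'
#' @param species character vector, one species name per atom.
#' @param molid integer molecule id per atom.
#' @param role role tag per atom (NA for atoms not used by any analysis).
#' @param element chemical element per atom.
#' @param resname residue name per atom (defaults to species).
#' @param registry species registry (see \code{\link{default_species}}).
#' @return data.frame of class \code{md_topology} with columns
#'   \code{serial}, \code{species}, \code{resname}, \code{molid},
#'   \code{role}, \code{element}, \code{mass}, \code{leaflet}.
#' @export
md_topology <- function(species, molid, role, element,
                        resname = species, registry = default_species()) {
  n <- length(species)
  stopifnot(length(molid) == n, length(role) == n, length(element) == n)
  top <- data.frame(
    serial = seq_len(n), species = species, resname = resname,
    molid = as.integer(molid), role = role, element = element,
    mass = mass_of_element(element), leaflet = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  dup <- stats::aggregate(role ~ molid, data = top[!is.na(top$role), ],
                          FUN = function(r) anyDuplicated(r) > 0)
  if (nrow(dup) && any(dup$role))
    stop_ommtraj("role tags must resolve uniquely within a molecule",
                 class = "ommtraj_role_error")
  attr(top, "registry") <- registry
  class(top) <- c("md_topology", "data.frame")
  top
}

registry_of <- function(topology) {
  attr(topology, "registry") %||% default_species()
}

#' Trajectory container
#'
#' Ordered frames of an orthorhombic-box system: coordinates in nm, times
#' in ps. Times must be strictly increasing and the atom count constant.
#'
#' @param topology an \code{md_topology}.
#' @param coords numeric array n_atoms x 3 x n_frames (nm).
#' @param box n_frames x 3 matrix of box edges (nm), or length-3 vector
#'   recycled to all frames.
#' @param times frame times in ps.
#' @return object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, coords, box, times) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (!is.matrix(box)) box <- matrix(box, nf, 3, byrow = TRUE)
  if (length(times) != nf || nrow(box) != nf)
    stop_ommtraj("frames, times and boxes must agree in length",
                 class = "ommtraj_domain_error")
  if (dim(coords)[1] != nrow(topology))
    stop_ommtraj("atom count mismatch between topology (", nrow(topology),
                 ") and coordinates (", dim(coords)[1], ")",
                 class = "ommtraj_topology_mismatch")
  if (nf > 1 && any(diff(times) <= 0))
    stop_ommtraj("frame times must be strictly increasing",
                 class = "ommtraj_domain_error")
  if (any(box <= 0) || any(!is.finite(box)))
    stop_ommtraj("box components must be positive and finite",
                 class = "ommtraj_domain_error")
  if (any(!is.finite(coords)))
    stop_ommtraj("coordinates must be finite", class = "ommtraj_domain_error")
  structure(list(topology = topology, coords = coords, box = box,
                 times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$coords)[1], "atoms,", n_frames(x), "frames, ",
      sprintf("t = %g..%g ps\n", x$times[1], x$times[n_frames(x)]))
  cat("  box (frame 1):", paste(sprintf("%.3f", x$box[1, ]), collapse = " x "),
      "nm\n")
  cat("  species:", paste(unique(x$topology$species), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an \code{md_trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Number of molecules per species in a topology
#' @param topology an \code{md_topology}.
#' @return named integer vector.
#' @export
species_molecule_counts <- function(topology) {
  mol <- topology[!duplicated(topology$molid), ]
  table_to_named(table(mol$species))
}

table_to_named <- function(tb) stats::setNames(as.integer(tb), names(tb))

## atom indices of a role within each molecule of a species, in molid order
role_indices <- function(topology, species, role) {
  sel <- which(topology$species == species & topology$role %in% role)
  sel[order(topology$molid[sel])]
}

## phosphate atom index per lipid molecule (glycerol-linked for PIP2)
phosphate_indices <- function(topology) {
  reg <- registry_of(topology)
  lip <- topology$species %in% LIPID_SPECIES
  mols <- unique(topology$molid[lip])
  idx <- integer(length(mols))
  for (sp in unique(topology$species[lip])) {
    prole <- reg[[sp]]$phosphate_role
    if (is.null(prole))
      stop_ommtraj("species ", sp, " has no phosphate role",
                   class = "ommtraj_role_error")
    sel <- which(topology$species == sp & topology$role == prole)
    idx[match(topology$molid[sel], mols)] <- sel
  }
  if (any(idx == 0L))
    stop_ommtraj("some lipid molecules lack a phosphate-role atom",
                 class = "ommtraj_role_error")
  stats::setNames(idx, mols)
}

#' Assign bilayer leaflets from the first frame
#'
#' Each lipid is assigned to the upper or lower leaflet by the sign of its
#' phosphate z coordinate relative to the mean phosphate z in the first
#' frame; the assignment is kept fixed for all frames (lipid flip-flop is
#' assumed absent on the simulated timescales). Water and ions get leaflet
#' \code{"none"}.
#'
#' @param traj an \code{md_trajectory}.
#' @return the trajectory with \code{topology$leaflet} filled in.
#' @export
assign_leaflets <- function(traj) {
  top <- traj$topology
  pidx <- phosphate_indices(top)
  z <- traj$coords[pidx, 3, 1]
  mid <- mean(z)
  leaf <- ifelse(z > mid, "upper", "lower")
  if (length(unique(leaf)) < 2L)
    warning("degenerate leaflet assignment: all phosphates on one side ",
            "of the midplane")
  top$leaflet <- "none"
  top$leaflet[top$species %in% LIPID_SPECIES] <-
    leaf[match(top$molid[top$species %in% LIPID_SPECIES], names(pidx))]
  traj$topology <- top
  traj
}

## per-molecule center of mass for selected molecules, one frame
molecule_com <- function(coords, topology, molids, dims = 1:2) {
  sel <- topology$molid %in% molids
  m <- topology$mass[sel]
  g <- factor(topology$molid[sel], levels = molids)
  tot <- rowsum(m, g, reorder = FALSE)
  wx <- rowsum(m * coords[sel, dims, drop = FALSE], g, reorder = FALSE)
  wx / as.numeric(tot)
}
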