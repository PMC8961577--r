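## ---- species/role maps -----------------------------------------------------

#' Species/role map
#'
#' A species map translates residue names and atom names of a particular
#' force-field dialect into the package's species and role tags. It is a
#' two-level list: \code{residues} (residue name -> species name) and
#' \code{atoms} (species name -> list of atom name -> role). Maps are
#' usually loaded from YAML; \code{native_species_map()} is the identity
#' dialect used by the package's own writers, and a CHARMM36-flavored map
#' ships at \code{system.file("extdata", "charmm36_map.yaml",
#' package = "ommtraj")}.
#'
#' @param path YAML file with \code{residues} and \code{atoms} entries.
#' @return list with elements \code{residues} and \code{atoms}.
#' @export
read_species_map <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$residues) || is.null(m$atoms))
    stop_ommtraj("species map must have 'residues' and 'atoms' entries",
                 class = "ommtraj_parse_error")
  m
}

#' @rdname read_species_map
#' @param registry species registry whose role names the map should expose.
#' @export
native_species_map <- function(registry = default_species()) {
  atoms <- lapply(registry, function(sp)
    as.list(stats::setNames(names(sp$roles), names(sp$roles))))
  list(residues = as.list(stats::setNames(names(registry), names(registry))),
       atoms = atoms)
}

resolve_species_map <- function(species_map) {
  if (is.null(species_map)) return(native_species_map())
  if (is.character(species_map)) return(read_species_map(species_map))
  species_map
}

guess_element <- function(atomname, species) {
  if (species %in% c("NA", "CL")) return(species)
  first <- sub("^[0-9]*", "", atomname)
  el <- toupper(substr(first, 1, 1))
  if (!el %in% c("H", "C", "N", "O", "P", "S"))
    stop_ommtraj("cannot infer element for atom name '", atomname, "'",
                 class = "ommtraj_parse_error")
  el
}

## annotate a raw atom table (resid, resname, atomname) -> md_topology
build_topology <- function(atoms, species_map, registry = default_species()) {
  map <- resolve_species_map(species_map)
  sp <- unlist(map$residues[atoms$resname], use.names = FALSE)
  known <- atoms$resname %in% names(map$residues)
  if (!all(known))
    stop_ommtraj("unmapped residue name(s): ",
                 paste(unique(atoms$resname[!known]), collapse = ", "),
                 class = "ommtraj_unmapped_species")
  new_mol <- c(TRUE, atoms$resid[-1] != atoms$resid[-nrow(atoms)] |
                     atoms$resname[-1] != atoms$resname[-nrow(atoms)])
  molid <- cumsum(new_mol)
  role <- rep(NA_character_, nrow(atoms))
  element <- character(nrow(atoms))
  for (s in unique(sp)) {
    sel <- sp == s
    rmap <- map$atoms[[s]]
    role[sel] <- unlist(lapply(atoms$atomname[sel],
                               function(a) rmap[[a]] %||% NA_character_))
    reg_roles <- registry[[s]]$roles
    element[sel] <- ifelse(is.na(role[sel]),
                           vapply(atoms$atomname[sel], guess_element, "", s),
                           unname(reg_roles[role[sel]]))
  }
  if (anyNA(element))
    stop_ommtraj("role(s) missing from the species registry",
                 class = "ommtraj_role_error")
  md_topology(species = sp, molid = molid, role = role, element = element,
              resname = atoms$resname, registry = registry)
}

## ---- GRO -------------------------------------------------------------------

parse_gro_block <- function(lines, start) {
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms))
    stop_ommtraj("malformed GRO atom count at line ", start + 1L,
                 class = "ommtraj_parse_error")
  end <- start + 1L + natoms + 1L
  if (end > length(lines)) return(NULL)        # truncated block
  al <- lines[(start + 2L):(start + 1L + natoms)]
  if (any(nchar(al) < 44))
    stop_ommtraj("malformed GRO atom record near line ",
                 start + 1L + which(nchar(al) < 44)[1],
                 class = "ommtraj_parse_error")
  coords <- cbind(as.numeric(substr(al, 21, 28)),
                  as.numeric(substr(al, 29, 36)),
                  as.numeric(substr(al, 37, 44)))
  if (anyNA(coords))
    stop_ommtraj("malformed GRO coordinates near line ", start + 2L,
                 class = "ommtraj_parse_error")
  boxv <- as.numeric(strsplit(trimws(lines[end]), "\\s+")[[1]])
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-12))
    stop_ommtraj("triclinic boxes are not supported (off-diagonal GRO box ",
                 "components found)", class = "ommtraj_domain_error")
  tm <- regmatches(lines[start], regexpr("t=\\s*[-0-9.eE+]+", lines[start]))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(atoms = data.frame(
         resid = as.integer(substr(al, 1, 5)),
         resname = trimws(substr(al, 6, 10)),
         atomname = trimws(substr(al, 11, 15)),
         stringsAsFactors = FALSE),
       coords = coords, box = boxv[1:3], time = time, next_start = end + 1L)
}

read_gro_file <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  start <- 1L
  while (start <= length(lines) && nzchar(trimws(lines[start]))) {
    bl <- parse_gro_block(lines, start)
    if (is.null(bl)) {
      warning("truncated GRO frame discarded at line ", start)
      break
    }
    blocks[[length(blocks) + 1L]] <- bl
    start <- bl$next_start
  }
  if (!length(blocks))
    stop_ommtraj("no complete GRO frame in ", path,
                 class = "ommtraj_parse_error")
  blocks
}

#' Read a structure file
#'
#' Reads a GRO or PDB file (first frame only) and annotates every atom via
#' the species map. Coordinates are returned in nm (PDB Angstrom values are
#' converted); the box must be orthorhombic.
#'
#' @param path file path.
#' @param format "gro" or "pdb" (default: from the file extension).
#' @param species_map a species map list, a YAML path, or NULL for the
#'   native dialect (see \code{\link{read_species_map}}).
#' @return list with elements \code{topology} (\code{md_topology}) and
#'   \code{frame} (list with \code{time} ps, \code{box} nm, \code{coords}
#'   n x 3 nm).
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"),
                           species_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "gro") {
    bl <- read_gro_file(path)[[1L]]
    top <- build_topology(bl$atoms, species_map)
    frame <- list(time = if (is.na(bl$time)) 0 else bl$time,
                  box = bl$box, coords = bl$coords)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    cr <- grep("^CRYST1", readLines(path), value = TRUE)
    if (!length(cr))
      stop_ommtraj("PDB file lacks a CRYST1 box record",
                   class = "ommtraj_parse_error")
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    angles <- as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                           substr(cr[1], 48, 54)))
    if (anyNA(box))
      stop_ommtraj("malformed CRYST1 record", class = "ommtraj_parse_error")
    if (!anyNA(angles) && any(abs(angles - 90) > 1e-6))
      stop_ommtraj("triclinic boxes are not supported",
                   class = "ommtraj_domain_error")
    atoms <- data.frame(resid = at$resno, resname = trimws(at$resid),
                        atomname = trimws(at$elety), stringsAsFactors = FALSE)
    top <- build_topology(atoms, species_map)
    frame <- list(time = 0, box = box / 10,
                  coords = cbind(at$x, at$y, at$z) / 10)
  }
  list(topology = top, frame = frame)
}

#' Write a structure or trajectory as (multi-frame) GRO
#'
#' Writes coordinates in the native role dialect (residue names are species
#' names, atom names are role tags), one GRO block per frame with the frame
#' time in the title line.
#'
#' @param traj an \code{md_trajectory} (or the list returned by
#'   \code{read_structure}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gro <- function(traj, path) {
  if (!inherits(traj, "md_trajectory"))
    traj <- md_trajectory(traj$topology, traj$frame$coords,
                          traj$frame$box, traj$frame$time)
  top <- traj$topology
  atomname <- ifelse(is.na(top$role), top$element, top$role)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     top$molid %% 100000L, top$resname, atomname,
                     top$serial %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(sprintf("ommtraj frame t= %g", traj$times[f]),
                 sprintf("%5d", nrow(top)), lines,
                 sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                         traj$box[f, 2], traj$box[f, 3])), con)
  }
  invisible(path)
}

#' Read trajectory frames
#'
#' Reads frames from a multi-frame GRO file or a DCD file and attaches them
#' to an existing topology. XTC is not supported; convert to DCD or
#' multi-frame GRO first. Frames must match the topology's atom count.
#'
#' @param path trajectory file.
#' @param topology \code{md_topology} from \code{\link{read_structure}}.
#' @param format "gro", "dcd" or "xtc" ("auto" from the extension).
#' @param dt frame spacing in ps, used when the file stores no times
#'   (DCD, GRO without t= titles). Default 1 ps.
#' @return an \code{md_trajectory}.
#' @export
read_frames <- function(path, topology, format = c("auto", "gro", "dcd", "xtc"),
                        dt = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro", "dcd", "xtc")) ext else "gro"
  }
  if (format == "xtc")
    stop_ommtraj("XTC reading is not supported; convert the trajectory to ",
                 "DCD or multi-frame GRO (e.g. 'mdconvert' or ",
                 "'gmx trjconv')", class = "ommtraj_parse_error")
  if (format == "gro") {
    blocks <- read_gro_file(path)
    n <- vapply(blocks, function(b) nrow(b$atoms), 1L)
    if (any(n != nrow(topology)))
      stop_ommtraj("frame atom count (", n[which(n != nrow(topology))[1]],
                   ") does not match topology (", nrow(topology), ")",
                   class = "ommtraj_topology_mismatch")
    coords <- array(0, c(nrow(topology), 3, length(blocks)))
    for (f in seq_along(blocks)) coords[, , f] <- blocks[[f]]$coords
    times <- vapply(blocks, `[[`, 0, "time")
    if (anyNA(times)) times <- (seq_along(blocks) - 1) * dt
    box <- do.call(rbind, lapply(blocks, `[[`, "box"))
  } else {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    nf <- nrow(xyz)
    if (ncol(xyz) != 3L * nrow(topology))
      stop_ommtraj("DCD atom count (", ncol(xyz) / 3,
                   ") does not match topology (", nrow(topology), ")",
                   class = "ommtraj_topology_mismatch")
    coords <- array(0, c(nrow(topology), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    box <- if (!is.null(cell)) cell[, 1:3, drop = FALSE] / 10 else
      stop_ommtraj("DCD file lacks unit-cell records",
                   class = "ommtraj_parse_error")
    if (!is.null(cell) && any(abs(cell[, 4:6] - 90) > 1e-4))
      stop_ommtraj("triclinic boxes are not supported",
                   class = "ommtraj_domain_error")
    times <- (seq_len(nf) - 1) * dt
  }
  md_trajectory(topology, coords, box, times)
}
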