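#' Species registry for bilayer components
#'
#' The analyses operate on "role skeletons": every atom of a molecule carries
#' a role tag (phosphate \code{P}, headgroup nitrogen \code{N}, choline methyl
#' \code{ME1}..\code{ME3}, carbonyl oxygens \code{OC1}/\code{OC2}, sn-1 chain
#' carbons \code{C2}..\code{C16} with hydrogens \code{H<i>A}/\code{H<i>B},
#' and so on). A \code{species_info} record states, for one species, which
#' roles exist and what they are used for: hydrogen-bond donors and
#' acceptors, the headgroup vector used for rotational autocorrelation
#' (phosphate to nitrogen for POPC/POPE/POPS; inositol C2 to C5 for
#' PI(3,4)P2), choline methyls for charge pairs, carbonyl oxygens, and the
#' ordered sn-1 carbons for the deuterium order parameter.
#'
#' Formal charges are the physiological ones: POPC and POPE are zwitterionic
#' (0 e), POPS carries -1 e, PI(3,4)P2 with a protonated 4-phosphate carries
#' -4 e, and the monatomic ions +1/-1 e.
#'
#' @param name species name.
#' @param formal_charge integer formal charge in e.
#' @param donor_atoms list of c(heavy-atom role, attached-hydrogen role).
#' @param acceptor_atoms character vector of acceptor oxygen roles.
#' @param headgroup_vector length-2 character: tail and head role of the
#'   headgroup vector.
#' @param choline_methyls roles of the choline methyl carbons (POPC only).
#' @param carbonyl_oxygens roles of the ester carbonyl oxygens.
#' @param anionic_oxygens roles counted as negatively charged oxygens for
#'   choline charge pairs.
#' @param sn1_carbons named list: carbon role -> character vector of attached
#'   hydrogen roles, in chain order.
#' @param phosphate_role role of the (glycerol-linked) phosphate atom used
#'   for leaflet assignment and density-peak thickness.
#' @param roles named character vector mapping every role of the species to
#'   its chemical element.
#' @return an object of class \code{species_info}.
#' @export
species_info <- function(name, formal_charge, donor_atoms = list(),
                         acceptor_atoms = character(),
                         headgroup_vector = NULL, choline_methyls = character(),
                         carbonyl_oxygens = character(),
                         anionic_oxygens = character(),
                         sn1_carbons = list(), phosphate_role = NULL,
                         roles = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (formal_charge != round(formal_charge))
    stop_ommtraj("formal charge must be an integer number of e",
                 class = "ommtraj_domain_error")
  structure(list(
    name = name, formal_charge = as.integer(formal_charge),
    donor_atoms = donor_atoms, acceptor_atoms = acceptor_atoms,
    headgroup_vector = headgroup_vector, choline_methyls = choline_methyls,
    carbonyl_oxygens = carbonyl_oxygens, anionic_oxygens = anionic_oxygens,
    sn1_carbons = sn1_carbons, phosphate_role = phosphate_role,
    roles = roles
  ), class = "species_info")
}

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, NA. = 22.990, CL = 35.453)

mass_of_element <- function(el) {
  el[el == "NA"] <- "NA."
  m <- ATOMIC_MASSES[el]
  if (anyNA(m))
    stop_ommtraj("unknown element(s): ",
                 paste(unique(el[is.na(m)]), collapse = ", "),
                 class = "ommtraj_role_error")
  unname(m)
}

## sn-1 palmitoyl carbons 2..16, two hydrogens each
sn1_chain_roles <- function(n_carbons = 15L) {
  idx <- seq(2L, length.out = n_carbons)
  ch <- stats::setNames(
    lapply(idx, function(i) paste0("H", i, c("A", "B"))),
    paste0("C", idx))
  ch
}

lipid_core_roles <- function(sn1) {
  carbons <- names(sn1)
  hyd <- unlist(sn1, use.names = FALSE)
  c(P = "P", OP1 = "O", OP2 = "O", OP3 = "O", OC1 = "O", OC2 = "O",
    stats::setNames(rep("C", length(carbons)), carbons),
    stats::setNames(rep("H", length(hyd)), hyd))
}

#' Default species definitions
#'
#' Returns the registry of the seven species handled by the package:
#' POPC, POPE, POPS, PIP2 (PI(3,4)P2), WATER (3-point), NA and CL.
#'
#' @param n_sn1_carbons number of sn-1 chain carbons carrying order-parameter
#'   hydrogens (default 15, carbons 2--16 of a palmitoyl chain).
#' @return named list of \code{species_info} objects.
#' @export
default_species <- function(n_sn1_carbons = 15L) {
  sn1 <- sn1_chain_roles(n_sn1_carbons)
  core <- lipid_core_roles(sn1)
  list(
    POPC = species_info("POPC", 0L,
      donor_atoms = list(),
      acceptor_atoms = c("OP1", "OP2", "OP3", "OC1", "OC2"),
      headgroup_vector = c("P", "N"),
      choline_methyls = c("ME1", "ME2", "ME3"),
      carbonyl_oxygens = c("OC1", "OC2"),
      anionic_oxygens = c("OP1", "OP2", "OP3"),
      sn1_carbons = sn1, phosphate_role = "P",
      roles = c(core, N = "N", ME1 = "C", ME2 = "C", ME3 = "C")),
    POPE = species_info("POPE", 0L,
      donor_atoms = list(c("N", "HN1"), c("N", "HN2"), c("N", "HN3")),
      acceptor_atoms = c("OP1", "OP2", "OP3", "OC1", "OC2"),
      headgroup_vector = c("P", "N"),
      carbonyl_oxygens = c("OC1", "OC2"),
      anionic_oxygens = c("OP1", "OP2", "OP3"),
      sn1_carbons = sn1, phosphate_role = "P",
      roles = c(core, N = "N", HN1 = "H", HN2 = "H", HN3 = "H")),
    POPS = species_info("POPS", -1L,
      donor_atoms = list(c("N", "HN1"), c("N", "HN2"), c("N", "HN3")),
      acceptor_atoms = c("OP1", "OP2", "OP3", "OC1", "OC2", "OCA", "OCB"),
      headgroup_vector = c("P", "N"),
      carbonyl_oxygens = c("OC1", "OC2"),
      anionic_oxygens = c("OP1", "OP2", "OP3", "OCA", "OCB"),
      sn1_carbons = sn1, phosphate_role = "P",
      roles = c(core, N = "N", HN1 = "H", HN2 = "H", HN3 = "H",
                OCA = "O", OCB = "O")),
    PIP2 = species_info("PIP2", -4L,
      donor_atoms = list(c("O6I", "HO6")),
      acceptor_atoms = c("OP1", "OP2", "OP3", "OC1", "OC2",
                         "O3A", "O3B", "O4A", "O6I"),
      headgroup_vector = c("C2I", "C5I"),
      carbonyl_oxygens = c("OC1", "OC2"),
      anionic_oxygens = c("OP1", "OP2", "OP3", "O3A", "O3B", "O4A"),
      sn1_carbons = sn1, phosphate_role = "P",
      roles = c(core, C2I = "C", C5I = "C", O3A = "O", O3B = "O",
                O4A = "O", O6I = "O", HO6 = "H")),
    WATER = species_info("WATER", 0L,
      donor_atoms = list(c("OW", "HW1"), c("OW", "HW2")),
      acceptor_atoms = "OW",
      roles = c(OW = "O", HW1 = "H", HW2 = "H")),
    `NA` = species_info("NA", 1L, roles = stats::setNames("NA", "NA")),
    CL = species_info("CL", -1L, roles = stats::setNames("CL", "CL"))
  )
}

LIPID_SPECIES <- c("POPC", "POPE", "POPS", "PIP2")

is_lipid_species <- function(sp) sp %in% LIPID_SPECIES

#' Formal charges of the bilayer species
#'
#' @return named integer vector of formal charges in e.
#' @export
species_charges <- function() {
  c(POPC = 0L, POPE = 0L, POPS = -1L, PIP2 = -4L,
    WATER = 0L, `NA` = 1L, CL = -1L)
}
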