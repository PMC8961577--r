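## Water-membrane interface statistics: geometric hydrogen bonds, choline
## charge pairs, sodium-lipid contacts.

#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair is hydrogen bonded when the D-A minimum-image
#' distance is below \code{d_da_max} and the angle between the D-A vector
#' and the D-H covalent bond is below \code{angle_max}.
#'
#' @param d_da_max donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_max D-A versus D-H angle cutoff in degrees (default 35).
#' @return object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_da_max = 0.35, angle_max = 35) {
  if (d_da_max <= 0 || angle_max <= 0 || angle_max >= 90)
    stop_ommtraj("criteria out of range: need d_da_max > 0 and ",
                 "0 < angle_max < 90", class = "ommtraj_domain_error")
  structure(list(d_da_max = d_da_max, angle_max = angle_max),
            class = "hbond_criteria")
}

## donor table: one row per (heavy atom, hydrogen) pair
donor_table <- function(topology, species = NULL) {
  reg <- registry_of(topology)
  species <- species %||% names(reg)
  out <- list()
  for (s in intersect(species, unique(topology$species))) {
    heavy_roles <- unique(vapply(reg[[s]]$donor_atoms, `[`, "", 1L))
    covered <- integer()
    for (pair in reg[[s]]$donor_atoms) {
      dsel <- role_indices(topology, s, pair[1])
      hsel <- role_indices(topology, s, pair[2])
      ## pair heavy atoms with their hydrogens molecule by molecule;
      ## molecules may carry only a subset of the hydrogen roles
      keep <- topology$molid[dsel] %in% topology$molid[hsel]
      dsel <- dsel[keep]
      hsel <- hsel[match(topology$molid[dsel], topology$molid[hsel])]
      covered <- union(covered, topology$molid[dsel])
      if (!length(dsel)) next
      out[[length(out) + 1L]] <- data.frame(
        d = dsel, h = hsel, species = s, molid = topology$molid[dsel])
    }
    with_heavy <- unique(topology$molid[topology$species == s &
                                          topology$role %in% heavy_roles])
    orphans <- setdiff(with_heavy, covered)
    if (length(orphans))
      stop_ommtraj("donor heavy atom(s) of ", s, " without any attached ",
                   "hydrogen role (molecule ", orphans[1], ")",
                   class = "ommtraj_role_error")
  }
  if (!length(out))
    return(data.frame(d = integer(), h = integer(), species = character(),
                      molid = integer()))
  do.call(rbind, out)
}

acceptor_table <- function(topology, species = NULL) {
  reg <- registry_of(topology)
  species <- species %||% names(reg)
  out <- list()
  for (s in intersect(species, unique(topology$species))) {
    acc <- reg[[s]]$acceptor_atoms
    if (!length(acc)) next
    asel <- which(topology$species == s & topology$role %in% acc)
    if (!length(asel)) next
    out[[length(out) + 1L]] <- data.frame(
      a = asel, species = s, molid = topology$molid[asel])
  }
  if (!length(out))
    return(data.frame(a = integer(), species = character(),
                      molid = integer()))
  do.call(rbind, out)
}

#' Find hydrogen bonds in one frame
#'
#' All (donor, hydrogen, acceptor) triples satisfying the geometric
#' criteria under periodic boundary conditions. When several hydrogens of
#' the same donor heavy atom satisfy the angle criterion for one acceptor,
#' only the best (smallest-angle) hydrogen is kept, so a D-A pair
#' contributes at most one bond. Intramolecular pairs are excluded by
#' default. The neighbor search uses a cell list and returns exactly the
#' all-pairs result.
#'
#' @param traj an \code{md_trajectory}.
#' @param frame frame index (default 1).
#' @param criteria an \code{hbond_criteria}.
#' @param donor_species,acceptor_species restrict either side.
#' @param exclude_intramolecular drop same-molecule pairs (default TRUE).
#' @param method neighbor-search method, "cell" or "brute".
#' @return data.frame with columns \code{d}, \code{h}, \code{a} (atom
#'   indices), \code{d_molid}, \code{a_molid}, \code{d_species},
#'   \code{a_species}, \code{dist}, \code{angle}.
#' @export
find_hbonds <- function(traj, frame = 1L, criteria = hbond_criteria(),
                        donor_species = NULL, acceptor_species = NULL,
                        exclude_intramolecular = TRUE,
                        method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- traj$topology
  don <- donor_table(top, donor_species)
  acc <- acceptor_table(top, acceptor_species)
  empty <- data.frame(d = integer(), h = integer(), a = integer(),
                      d_molid = integer(), a_molid = integer(),
                      d_species = character(), a_species = character(),
                      dist = numeric(), angle = numeric())
  if (!nrow(don) || !nrow(acc)) return(empty)
  x <- traj$coords[, , frame]
  box <- traj$box[frame, ]
  ## candidate (D,H) x A pairs within the distance cutoff on D-A
  cand <- pairs_within(x[don$d, , drop = FALSE], x[acc$a, , drop = FALSE],
                       box, criteria$d_da_max, method = method)
  if (!nrow(cand)) return(empty)
  di <- don$d[cand$i]; ai <- acc$a[cand$j]
  keep <- !(exclude_intramolecular &
              don$molid[cand$i] == acc$molid[cand$j]) & di != ai
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  v_da <- minimum_image(x[acc$a[cand$j], , drop = FALSE] -
                          x[don$d[cand$i], , drop = FALSE], box)
  v_dh <- minimum_image(x[don$h[cand$i], , drop = FALSE] -
                          x[don$d[cand$i], , drop = FALSE], box)
  cosang <- rowSums(v_da * v_dh) /
    (sqrt(rowSums(v_da^2)) * sqrt(rowSums(v_dh^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- ang < criteria$angle_max
  cand <- cand[ok, , drop = FALSE]; ang <- ang[ok]
  if (!nrow(cand)) return(empty)
  res <- data.frame(d = don$d[cand$i], h = don$h[cand$i], a = acc$a[cand$j],
                    d_molid = don$molid[cand$i], a_molid = acc$molid[cand$j],
                    d_species = don$species[cand$i],
                    a_species = acc$species[cand$j],
                    dist = cand$d, angle = ang)
  ## best hydrogen per (D, A) pair
  key <- paste(res$d, res$a)
  res <- res[order(key, res$angle), ]
  res <- res[!duplicated(paste(res$d, res$a)), ]
  rownames(res) <- NULL
  res
}

analysis_frames <- function(traj, frames = NULL, skip_ns = 0, stride = 1L) {
  fr <- frames %||% frames_after_skip(traj, skip_ns)
  fr[seq(1L, length(fr), by = stride)]
}

#' Water molecules hydrogen bonded to each lipid species
#'
#' Lipid-water hydrogen bonds (either direction) per lipid molecule,
#' averaged over molecules of each species and over the analyzed frames.
#'
#' @param traj an \code{md_trajectory}.
#' @param criteria an \code{hbond_criteria}.
#' @param frames frame indices (default: all after \code{skip_ns}).
#' @param skip_ns equilibration skip in ns.
#' @param count "bonds" counts every H-bond (a water doubly bonded to one
#'   lipid counts 2); "waters" counts distinct water partners.
#' @return named numeric vector, mean count per lipid for each species.
#' @export
water_hbonds_per_lipid <- function(traj, criteria = hbond_criteria(),
                                   frames = NULL, skip_ns = 0,
                                   count = c("bonds", "waters")) {
  count <- match.arg(count)
  top <- traj$topology
  fr <- analysis_frames(traj, frames, skip_ns)
  nmol <- species_molecule_counts(top)
  lsp <- intersect(LIPID_SPECIES, names(nmol))
  acc <- stats::setNames(numeric(length(lsp)), lsp)
  if (!"WATER" %in% names(nmol)) return(acc / max(length(fr), 1))
  for (f in fr) {
    hb <- find_hbonds(traj, f, criteria)
    lw <- hb[(hb$d_species %in% lsp & hb$a_species == "WATER") |
               (hb$d_species == "WATER" & hb$a_species %in% lsp), ,
             drop = FALSE]
    if (!nrow(lw)) next
    lipid_mol <- ifelse(lw$d_species == "WATER", lw$a_molid, lw$d_molid)
    lipid_sp <- ifelse(lw$d_species == "WATER", lw$a_species, lw$d_species)
    water_mol <- ifelse(lw$d_species == "WATER", lw$d_molid, lw$a_molid)
    if (count == "waters") {
      k <- !duplicated(paste(lipid_mol, water_mol))
      lipid_sp <- lipid_sp[k]
    }
    tb <- table(lipid_sp)
    acc[names(tb)] <- acc[names(tb)] + as.numeric(tb)
  }
  acc / (nmol[lsp] * length(fr))
}

#' Lipid-lipid hydrogen-bond matrix
#'
#' For every donor-capable species, the mean number of hydrogen bonds its
#' molecules donate to each partner species (bonds attributed to the donor
#' molecule). A species with no donor hydrogens (POPC) is reported from
#' the acceptor side: bonds it accepts per molecule, by donor species.
#' The \code{All} column is the row sum.
#'
#' @inheritParams water_hbonds_per_lipid
#' @return matrix, rows = reference species, columns = partner species
#'   plus \code{All}.
#' @export
lipid_lipid_hbond_matrix <- function(traj, criteria = hbond_criteria(),
                                     frames = NULL, skip_ns = 0) {
  top <- traj$topology
  reg <- registry_of(top)
  fr <- analysis_frames(traj, frames, skip_ns)
  nmol <- species_molecule_counts(top)
  lsp <- intersect(LIPID_SPECIES, names(nmol))
  m <- matrix(0, length(lsp), length(lsp),
              dimnames = list(reference = lsp, partner = lsp))
  for (f in fr) {
    hb <- find_hbonds(traj, f, criteria, donor_species = lsp,
                      acceptor_species = lsp)
    if (!nrow(hb)) next
    tb <- table(factor(hb$d_species, lsp), factor(hb$a_species, lsp))
    m <- m + as.matrix(tb)
  }
  out <- m * 0
  for (s in lsp) {
    donor_capable <- length(reg[[s]]$donor_atoms) > 0
    out[s, ] <- if (donor_capable) m[s, ] else m[, s]
    out[s, ] <- out[s, ] / (nmol[[s]] * length(fr))
  }
  cbind(out, All = rowSums(out))
}

#' Expected hydrogen bonds under equal affinity
#'
#' Given the observed total number of hydrogen bonds formed per molecule
#' of a reference species, the expected count toward each partner if every
#' eligible partner were equally attractive - i.e. proportional to the
#' partner mole fractions alone.
#'
#' @param observed_all observed total bonds per reference molecule.
#' @param fractions named mole fractions of the eligible partner species
#'   (renormalized internally, so a donor-restricted subset can be
#'   passed as-is).
#' @param digits decimals for reporting (default 2; NULL for unrounded).
#' @return named numeric vector of expected counts, summing to
#'   \code{observed_all} before rounding.
#' @export
expected_hbonds <- function(observed_all, fractions, digits = 2) {
  if (observed_all < 0)
    stop_ommtraj("observed total must be non-negative",
                 class = "ommtraj_domain_error")
  e <- observed_all * fractions / sum(fractions)
  if (!is.null(digits)) e <- round_half_up(e, digits)
  e
}

#' Choline-oxygen charge pairs
#'
#' Pairs between the positively charged choline methyl carbons of POPC and
#' negatively charged lipid oxygens within the distance cutoff (minimum
#' image), excluding intramolecular pairs. Reported per POPC molecule and,
#' per partner species, also per partner molecule.
#'
#' @param traj an \code{md_trajectory}.
#' @param cutoff Me-O distance cutoff in nm (default 0.4).
#' @param include_carbonyls also count carbonyl oxygens as partners
#'   (default FALSE).
#' @param frames,skip_ns frame selection.
#' @param method neighbor-search method.
#' @return list with \code{per_popc} (named by partner species, plus
#'   \code{All}) and \code{per_partner} (pairs per partner molecule).
#' @export
charge_pairs <- function(traj, cutoff = 0.4, include_carbonyls = FALSE,
                         frames = NULL, skip_ns = 0,
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- traj$topology
  reg <- registry_of(top)
  fr <- analysis_frames(traj, frames, skip_ns)
  nmol <- species_molecule_counts(top)
  if (!"POPC" %in% names(nmol))
    return(list(per_popc = c(All = 0), per_partner = numeric()))
  me <- which(top$species == "POPC" & top$role %in% reg$POPC$choline_methyls)
  lsp <- intersect(LIPID_SPECIES, names(nmol))
  osel <- integer(); osp <- character()
  for (s in lsp) {
    oro <- reg[[s]]$anionic_oxygens
    if (include_carbonyls) oro <- union(oro, reg[[s]]$carbonyl_oxygens)
    w <- which(top$species == s & top$role %in% oro)
    osel <- c(osel, w); osp <- c(osp, rep(s, length(w)))
  }
  cnt <- stats::setNames(numeric(length(lsp)), lsp)
  for (f in fr) {
    p <- pairs_within(traj$coords[me, , f, drop = TRUE],
                      traj$coords[osel, , f, drop = TRUE],
                      traj$box[f, ], cutoff, method = method)
    if (!nrow(p)) next
    keep <- top$molid[me[p$i]] != top$molid[osel[p$j]]
    tb <- table(factor(osp[p$j[keep]], lsp))
    cnt <- cnt + as.numeric(tb)
  }
  cnt <- cnt / length(fr)
  list(per_popc = c(cnt / nmol[["POPC"]],
                    All = sum(cnt) / nmol[["POPC"]]),
       per_partner = cnt / nmol[lsp])
}

#' Sodium-lipid contacts
#'
#' A sodium ion is membrane bound when at least one lipid oxygen lies
#' within the cutoff (minimum-image distance). Reports the number of bound
#' Na+ per lipid, the multiplicity (mean number of lipid oxygens within
#' the cutoff per bound ion) and the same count restricted to carbonyl
#' oxygens, averaged over the analyzed frames.
#'
#' @param traj an \code{md_trajectory}.
#' @param cutoff Na-O distance cutoff in nm (default 0.325).
#' @param frames,skip_ns frame selection.
#' @param method neighbor-search method.
#' @return list with \code{bound_per_lipid}, \code{multiplicity},
#'   \code{carbonyl_bound_per_lipid}, \code{n_bound} (mean per frame).
#' @export
sodium_contacts <- function(traj, cutoff = 0.325, frames = NULL,
                            skip_ns = 0, method = c("cell", "brute")) {
  method <- match.arg(method)
  top <- traj$topology
  reg <- registry_of(top)
  fr <- analysis_frames(traj, frames, skip_ns)
  na_sel <- which(top$species == "NA")
  if (!length(na_sel))
    stop_ommtraj("no Na+ ions in the system",
                 class = "ommtraj_selection_error")
  lip_o <- which(top$species %in% LIPID_SPECIES & top$element == "O")
  carb <- unlist(lapply(intersect(LIPID_SPECIES, unique(top$species)),
                        function(s) which(top$species == s &
                          top$role %in% reg[[s]]$carbonyl_oxygens)))
  n_lip <- sum(!duplicated(top$molid) & top$species %in% LIPID_SPECIES)
  bound <- mult <- carb_bound <- nb <- 0
  frames_with_bound <- 0L
  for (f in fr) {
    p <- pairs_within(traj$coords[na_sel, , f, drop = TRUE],
                      traj$coords[lip_o, , f, drop = TRUE],
                      traj$box[f, ], cutoff, method = method)
    per_ion <- tabulate(p$i, nbins = length(na_sel))
    b <- per_ion > 0
    bound <- bound + sum(b)
    nb <- nb + sum(b)
    if (any(b)) {
      mult <- mult + mean(per_ion[b])
      frames_with_bound <- frames_with_bound + 1L
    }
    pc <- pairs_within(traj$coords[na_sel, , f, drop = TRUE],
                       traj$coords[carb, , f, drop = TRUE],
                       traj$box[f, ], cutoff, method = method)
    carb_bound <- carb_bound + sum(tabulate(pc$i,
                                            nbins = length(na_sel)) > 0)
  }
  nf <- length(fr)
  list(bound_per_lipid = bound / nf / n_lip,
       multiplicity = if (frames_with_bound) mult / frames_with_bound else 0,
       carbonyl_bound_per_lipid = carb_bound / nf / n_lip,
       n_bound = nb / nf)
}
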