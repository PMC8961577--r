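## Synthetic bilayer trajectories with known ground truth.
##
## Lipids are coarse role skeletons: one atom per role the analyses touch.
## The lateral, rotational, tail-orientation and transverse (z) degrees of
## freedom are generated independently, each from a closed-form model whose
## parameters are recorded as ground truth:
##   - lateral:  2D Brownian walks, per-step variance 2*D*dt per axis
##   - headgroup vectors: isotropic rotational diffusion on the sphere,
##     C1(tau) = exp(-2*Dr*tau)
##   - C-H tail vectors: fixed polar angle with cos^2(theta) = (2S+1)/3,
##     uniform azimuth, so the ensemble S_CD equals the target S
##   - phosphate z: Normal(+-d_PP/2, sigma_z^2) by leaflet
## Waters, Na+ and Cl- are placed at canonical contact geometries with
## generous clearances so that constructed hydrogen-bond, charge-pair and
## ion-contact counts are recovered exactly by the interface metrics on
## static snapshots (n_frames = 1, where lipids sit on their grid sites).

## Table-3-like lateral diffusion defaults per model, nm^2/ns
DIFFUSION_DEFAULTS <- rbind(
  `1` = c(POPC = 8.4, POPE = 8.6, POPS = NA,  PIP2 = 8.1),
  `2` = c(POPC = 6.3, POPE = 6.2, POPS = 3.5, PIP2 = 4.8),
  `3` = c(POPC = 7.2, POPE = 7.4, POPS = 6.3, PIP2 = 5.9),
  `4` = c(POPC = 6.1, POPE = 5.6, POPS = 2.9, PIP2 = 5.1),
  `5` = c(POPC = 8.4, POPE = 9.1, POPS = NA,  PIP2 = NA)) * 1e-3

## role offsets within a lipid skeleton, relative to the phosphate,
## (dx, dy, dz) with dz measured outward (multiplied by -1 in the lower
## leaflet). Chosen so that role-role distances respect the contact-metric
## cutoffs (see the methods vignette).
lipid_role_offsets <- function(species, n_sn1_carbons) {
  base <- list(P = c(0, 0, 0), OP1 = c(0, 0, 0.60),
               OP2 = c(0, 0.15, -0.05), OP3 = c(0, -0.15, -0.05),
               OC1 = c(0.25, 0, -0.35), OC2 = c(-0.25, 0, -0.35))
  idx <- seq(2L, length.out = n_sn1_carbons)
  for (i in idx)
    base[[paste0("C", i)]] <- c(0.05 * (-1)^i, 0, -(0.50 + 0.127 * (i - 2)))
  extra <- switch(species,
    POPS = list(OCA = c(0.10, -0.10, 0.25), OCB = c(-0.10, 0.10, 0.25)),
    PIP2 = list(C2I = c(0, 0, 0.30), O3A = c(0.10, 0.10, 0.40),
                O3B = c(-0.10, 0.10, 0.40), O4A = c(0.10, -0.10, 0.40),
                O6I = c(-0.10, -0.10, 0.40), HO6 = c(-0.10, -0.10, 0.50)),
    list())
  c(base, extra)
}

#' Specification of a synthetic bilayer trajectory
#'
#' Collects every parameter of the generator together with its validation.
#' The defaults emulate the four-component outer-mitochondrial-membrane
#' model with realistic composition (model 2): 784 lipids in a
#' 15.6 x 15.6 nm box, phosphate peak-to-peak thickness 4.13 nm, lateral
#' diffusion coefficients matching the reported per-species values, and
#' 150 mM-scale counter-ion numbers with full charge neutralization.
#'
#' @param model OMM model preset 1..5, sets composition and diffusion
#'   defaults.
#' @param n_lipids total lipid count (even; default 784).
#' @param counts optional integer count override per species.
#' @param box_xy lateral box edges (nm).
#' @param d_pp phosphate peak-to-peak distance (nm).
#' @param sigma_z transverse spread of the phosphate positions (nm).
#' @param diffusion named per-species lateral diffusion coefficients
#'   (nm^2/ns).
#' @param rot_diffusion named per-species rotational diffusion constants of
#'   the headgroup vector (rad^2/ns); the generated rotational
#'   autocorrelation decays as exp(-2 D_r tau).
#' @param scd_targets named list: species -> per-carbon target S_CD values
#'   (length \code{n_sn1_carbons}, each in [-0.5, 1]).
#' @param n_sn1_carbons number of sn-1 carbons carrying C-H pairs.
#' @param waters_per_lipid named integer counts of hydrogen-bonded waters
#'   constructed per lipid of each species.
#' @param na_bound_per_lipid target number of membrane-bound Na+ per lipid.
#' @param na_multiplicity integer 1..3, lipid oxygens coordinating each
#'   bound Na+ (drawn from carbonyl/phosphate oxygens).
#' @param chargepairs_per_popc 0 or 1 constructed choline--oxygen charge
#'   pair per POPC (static snapshots only).
#' @param n_salt_pairs bulk Na+/Cl- pairs beyond neutralization.
#' @param neutralize add counter-ions so lipids + Na+ - Cl- sum to zero.
#' @param with_solvent place waters and ions at all.
#' @param n_frames,dt number of frames and spacing (ps).
#' @param detail \code{"full"} role skeletons or \code{"minimal"} (one
#'   phosphate atom per lipid; for large-scale diffusion studies).
#' @param seed RNG seed; all generator streams derive from it.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(model = 2, n_lipids = 784L, counts = NULL,
                           box_xy = c(15.6, 15.6), d_pp = 4.13,
                           sigma_z = 0.15, diffusion = NULL,
                           rot_diffusion = c(POPC = 0.4, POPE = 0.3,
                                             POPS = 0.25, PIP2 = 0.15),
                           scd_targets = NULL, n_sn1_carbons = 15L,
                           waters_per_lipid = c(POPC = 7, POPE = 8,
                                                POPS = 13, PIP2 = 19),
                           na_bound_per_lipid = 0.29, na_multiplicity = 3L,
                           chargepairs_per_popc = 1L, n_salt_pairs = 110L,
                           neutralize = TRUE, with_solvent = TRUE,
                           n_frames = 100L, dt = 100,
                           detail = c("full", "minimal"), seed = 1L) {
  detail <- match.arg(detail)
  comp <- build_composition(omm_model_fractions(model), n_lipids,
                            counts = counts)
  if (is.null(diffusion)) {
    diffusion <- DIFFUSION_DEFAULTS[as.character(model), ]
    diffusion <- diffusion[names(comp$counts)[comp$counts > 0]]
  }
  if (anyNA(diffusion) || any(diffusion < 0))
    stop_ommtraj("diffusion coefficients must be non-negative",
                 class = "ommtraj_config_error")
  if (any(rot_diffusion < 0))
    stop_ommtraj("rotational diffusion constants must be non-negative",
                 class = "ommtraj_config_error")
  if (is.null(scd_targets)) {
    idx <- seq(2L, length.out = n_sn1_carbons)
    prof <- ifelse(idx <= 8, 0.22, pmax(0.22 - 0.015 * (idx - 8), 0.05))
    scd_targets <- lapply(stats::setNames(LIPID_SPECIES, LIPID_SPECIES),
                          function(s) prof)
  }
  for (s in names(scd_targets)) {
    if (any(scd_targets[[s]] < -0.5 | scd_targets[[s]] > 1))
      stop_ommtraj("S_CD targets must lie in [-0.5, 1]",
                   class = "ommtraj_domain_error")
  }
  dt_ns <- dt / 1000
  step <- sqrt(4 * max(diffusion, 0) * dt_ns)
  if (step >= min(box_xy) / 4)
    stop_ommtraj("per-step displacement scale sqrt(4 D dt) = ",
                 signif(step, 3), " nm exceeds a quarter of the box",
                 class = "ommtraj_config_error")
  if (sigma_z <= 0)
    stop_ommtraj("sigma_z must be positive", class = "ommtraj_config_error")
  if (!na_multiplicity %in% 1:3)
    stop_ommtraj("na_multiplicity must be 1, 2 or 3 (available oxygen ",
                 "sites: OC1, OC2, OP2)", class = "ommtraj_config_error")
  if (any(waters_per_lipid < 0) || any(waters_per_lipid > 24))
    stop_ommtraj("waters_per_lipid must be in 0..24",
                 class = "ommtraj_config_error")
  if (na_bound_per_lipid < 0 || na_bound_per_lipid > 1)
    stop_ommtraj("na_bound_per_lipid must be in [0, 1]",
                 class = "ommtraj_config_error")
  structure(list(
    model = model, composition = comp, box_xy = box_xy, d_pp = d_pp,
    sigma_z = sigma_z, diffusion = diffusion,
    rot_diffusion = rot_diffusion, scd_targets = scd_targets,
    n_sn1_carbons = as.integer(n_sn1_carbons),
    waters_per_lipid = waters_per_lipid,
    na_bound_per_lipid = na_bound_per_lipid,
    na_multiplicity = as.integer(na_multiplicity),
    chargepairs_per_popc = as.integer(chargepairs_per_popc),
    n_salt_pairs = as.integer(n_salt_pairs), neutralize = neutralize,
    with_solvent = with_solvent, n_frames = as.integer(n_frames), dt = dt,
    detail = detail, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Read a synthetic-bilayer specification from YAML
#'
#' @param path YAML file whose keys are \code{synthetic_spec} arguments.
#' @return a \code{synthetic_spec}.
#' @export
read_synthetic_spec <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("diffusion", "rot_diffusion", "waters_per_lipid", "counts"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$scd_targets)) args$scd_targets <-
    lapply(args$scd_targets, as.numeric)
  bad <- setdiff(names(args), names(formals(synthetic_spec)))
  if (length(bad))
    stop_ommtraj("invalid spec field(s): ", paste(bad, collapse = ", "),
                 class = "ommtraj_config_error")
  do.call(synthetic_spec, args)
}

## 2D Brownian walks: increments ~ N(0, 2 D dt) per axis.
## Returns unwrapped displacements from the origin, dims (n, 2, n_frames).
brownian_walk_2d <- function(n, n_frames, dt_ps, d_nm2_ns) {
  dt_ns <- dt_ps / 1000
  sd <- sqrt(2 * rep_len(d_nm2_ns, n) * dt_ns)
  walk <- array(0, c(n, 2, n_frames))
  if (n_frames > 1) {
    for (axis in 1:2) {
      inc <- matrix(stats::rnorm((n_frames - 1) * n, sd = sd),
                    nrow = n, ncol = n_frames - 1)
      for (f in 2:n_frames)
        walk[, axis, f] <- walk[, axis, f - 1] + inc[, f - 1]
    }
  }
  walk
}

## isotropic rotational diffusion of unit vectors, dims (n, 3, n_frames).
## Tangential-kick steps are subdivided so the per-substep angular variance
## stays small (the projected-kick scheme has O(variance) rate bias at
## large steps); 0.0025 rad^2 per tangent dimension keeps the bias under 1%.
rotational_walk <- function(init, n_frames, dt_ps, dr_rad2_ns) {
  n <- nrow(init)
  dt_ns <- dt_ps / 1000
  var_frame <- 2 * rep_len(dr_rad2_ns, n) * dt_ns
  nsub <- max(1L, ceiling(max(var_frame) / 0.0025))
  sd <- sqrt(var_frame / nsub)
  v <- array(0, c(n, 3, n_frames))
  v[, , 1] <- init
  cur <- init
  for (f in seq_len(n_frames - 1L)) {
    for (s in seq_len(nsub)) {
      g <- matrix(stats::rnorm(3L * n, sd = sd), n, 3)
      g <- g - cur * rowSums(g * cur)    # project onto tangent plane
      cur <- normalize_rows(cur + g)
    }
    v[, , f + 1L] <- cur
  }
  v
}

## unit vectors at fixed polar angle from z with cos^2 = (2S+1)/3,
## uniform azimuth and random hemisphere, so E[S_CD] = s exactly
scd_vectors <- function(s, n) {
  if (s < -0.5 || s > 1)
    stop_ommtraj("S_CD target outside [-0.5, 1]",
                 class = "ommtraj_domain_error")
  cth <- sqrt((2 * s + 1) / 3) * sample(c(-1, 1), n, replace = TRUE)
  sth <- sqrt(pmax(0, 1 - cth^2))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(sth * cos(phi), sth * sin(phi), cth)
}

## lipid bookkeeping table: species, leaflet, grid site
lipid_layout <- function(spec) {
  comp <- spec$composition
  rows <- list()
  for (leaf in c("upper", "lower")) {
    cnt <- comp$leaflet_counts[leaf, ]
    sp <- rep(names(cnt), cnt)
    n <- length(sp)
    k <- ceiling(sqrt(n))
    gx <- ((seq_len(n) - 1) %% k + 0.5) * spec$box_xy[1] / k
    gy <- ((seq_len(n) - 1) %/% k + 0.5) * spec$box_xy[2] / k
    sp <- sample(sp)                      # mix species over the grid
    rows[[leaf]] <- data.frame(species = sp, leaflet = leaf,
                               x = gx, y = gy, stringsAsFactors = FALSE)
  }
  out <- rbind(rows$upper, rows$lower)
  out$sgn <- ifelse(out$leaflet == "upper", 1, -1)
  out$lipid <- seq_len(nrow(out))
  out
}

#' Generate ground-truth lateral Brownian positions
#'
#' Independent 2D Brownian walks for every lipid of the spec, per-step
#' Gaussian increments with variance 2 D dt per axis. The unwrapped walk is
#' returned alongside box-wrapped positions so MSD analyses can be checked
#' against exact bookkeeping.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{layout} (lipid table), \code{unwrapped} and
#'   \code{wrapped} arrays (n_lipids x 2 x n_frames) and \code{times} (ps).
#' @export
generate_lateral_positions <- function(spec) {
  set.seed(spec$seed)
  layout <- lipid_layout(spec)
  d <- spec$diffusion[layout$species]
  d[is.na(d)] <- 0
  walk <- brownian_walk_2d(nrow(layout), spec$n_frames, spec$dt, d)
  unwrapped <- walk
  unwrapped[, 1, ] <- unwrapped[, 1, ] + layout$x
  unwrapped[, 2, ] <- unwrapped[, 2, ] + layout$y
  wrapped <- unwrapped
  for (axis in 1:2) {
    l <- spec$box_xy[axis]
    wrapped[, axis, ] <- wrapped[, axis, ] -
      l * floor(wrapped[, axis, ] / l)
  }
  list(layout = layout, unwrapped = unwrapped, wrapped = wrapped,
       times = (seq_len(spec$n_frames) - 1) * spec$dt)
}

#' Generate ground-truth headgroup unit vectors
#'
#' Isotropic rotational diffusion on the unit sphere via small tangential
#' Gaussian kicks (variance 2 D_r dt per tangent dimension, renormalized
#' each step), for which the first-rank autocorrelation is exactly
#' exp(-2 D_r tau). A deterministic planar-rotor mode (rotation about z at
#' fixed angular rate) is provided for analytic checks: C1(tau) =
#' cos(omega tau).
#'
#' @param spec a \code{synthetic_spec}.
#' @param mode "diffusion" (default) or "planar".
#' @param omega angular rate in rad/ns (planar mode).
#' @return list with \code{layout} and \code{vectors}
#'   (n_lipids x 3 x n_frames).
#' @export
generate_headgroup_vectors <- function(spec, mode = c("diffusion", "planar"),
                                       omega = 1) {
  mode <- match.arg(mode)
  set.seed(spec$seed + 1L)
  layout <- lipid_layout(spec)
  n <- nrow(layout)
  if (mode == "planar") {
    t_ns <- (seq_len(spec$n_frames) - 1) * spec$dt / 1000
    phi0 <- stats::runif(n, 0, 2 * pi)
    v <- array(0, c(n, 3, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      a <- phi0 + omega * t_ns[f]
      v[, , f] <- cbind(cos(a), sin(a), 0)
    }
    return(list(layout = layout, vectors = v))
  }
  dr <- spec$rot_diffusion[layout$species]
  dr[is.na(dr)] <- 0
  init <- cbind(0, 0, layout$sgn)
  list(layout = layout,
       vectors = rotational_walk(init, spec$n_frames, spec$dt, dr))
}

#' Generate ground-truth C-H tail orientations
#'
#' C-H unit vectors at the fixed polar angle reproducing each per-carbon
#' target S_CD in expectation.
#'
#' @param spec a \code{synthetic_spec}.
#' @param species lipid species name.
#' @param n_vectors vectors per carbon per frame (default: count of the
#'   species in the composition).
#' @return list of arrays, one per carbon (n_vectors x 3 x n_frames).
#' @export
generate_tail_orientations <- function(spec, species = "POPC",
                                       n_vectors = NULL) {
  set.seed(spec$seed + 2L)
  targets <- spec$scd_targets[[species]]
  n <- n_vectors %||% spec$composition$counts[[species]]
  lapply(stats::setNames(seq_along(targets),
                         paste0("C", seq_along(targets) + 1L)),
         function(ci) {
           v <- array(0, c(n, 3, spec$n_frames))
           for (f in seq_len(spec$n_frames))
             v[, , f] <- scd_vectors(targets[ci], n)
           v
         })
}

#' Generate ground-truth transverse (z) phosphate structure
#'
#' Phosphate z coordinates drawn from Normal(+-d_PP/2, sigma_z^2) by
#' leaflet; the remaining roles sit at fixed per-role offsets along z.
#'
#' @param spec a \code{synthetic_spec}.
#' @return the lipid layout with a \code{z_phosphate} column.
#' @export
generate_z_structure <- function(spec) {
  set.seed(spec$seed + 3L)
  layout <- lipid_layout(spec)
  layout$z_phosphate <- stats::rnorm(nrow(layout),
                                     mean = layout$sgn * spec$d_pp / 2,
                                     sd = spec$sigma_z)
  layout
}

## orientation frame helpers for constructed water geometry
water_cone_dirs <- function(w, sgn) {
  th <- 20 * pi / 180
  phi <- (seq_len(w) - 1) * 2 * pi / max(w, 1L)
  cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th) * sgn, w))
}

na_contact_dirs <- function(k, sgn) {
  th <- 35 * pi / 180
  phi <- (seq_len(k) - 1) * 2 * pi / 3
  cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th) * sgn, k))
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Assembles the full system: role-skeleton lipids on a per-leaflet grid,
#' lateral Brownian motion, rotational headgroup diffusion, per-carbon
#' C-H orientations at the target order parameters, Gaussian phosphate z
#' structure, and (optionally) hydrogen-bonded waters, membrane-bound Na+
#' with fixed coordination multiplicity, and bulk counter ions. All
#' constructed contact geometries are exact on static snapshots
#' (\code{n_frames = 1}); in dynamic mode lipids diffuse and the charge-pair
#' construction is disabled.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{trajectory} (\code{md_trajectory}, leaflets
#'   assigned) and \code{ground_truth} (parameters actually used, realized
#'   contact counts, per-lipid unwrapped phosphate walks, seed).
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  registry <- default_species(spec$n_sn1_carbons)
  layout <- lipid_layout(spec)
  n_lip <- nrow(layout)
  nf <- spec$n_frames
  comp <- spec$composition

  ## --- degrees of freedom ---------------------------------------------
  d <- spec$diffusion[layout$species]; d[is.na(d)] <- 0
  walk <- brownian_walk_2d(n_lip, nf, spec$dt, d)
  dr <- spec$rot_diffusion[layout$species]; dr[is.na(dr)] <- 0
  hg <- rotational_walk(cbind(0, 0, layout$sgn), nf, spec$dt, dr)
  ## transverse structure redrawn each frame (instantaneously decorrelated
  ## undulation), so density-profile sampling grows with frame count
  zpm <- matrix(stats::rnorm(n_lip * nf, layout$sgn * spec$d_pp / 2,
                             spec$sigma_z), n_lip, nf)

  static <- nf == 1L
  chargepairs <- if (static && spec$detail == "full")
    spec$chargepairs_per_popc else 0L

  ## --- contact bookkeeping --------------------------------------------
  n_bound <- if (spec$with_solvent && spec$detail == "full")
    round(spec$na_bound_per_lipid * n_lip) else 0L
  hosts <- if (n_bound > 0) sample(n_lip, n_bound) else integer()
  total_q <- total_lipid_charge(comp)
  n_na <- if (spec$with_solvent)
    spec$n_salt_pairs + if (spec$neutralize) max(0L, -total_q) else 0L
    else 0L
  n_cl <- if (spec$with_solvent) spec$n_salt_pairs else 0L
  if (n_bound > n_na)
    stop_ommtraj("requested bound Na+ (", n_bound, ") exceeds available ",
                 "Na+ (", n_na, ")", class = "ommtraj_config_error")

  pair_partner <- rep(NA_integer_, n_lip)
  if (chargepairs > 0) {
    eligible <- which(layout$species %in% c("POPC", "POPE") &
                      !(layout$lipid %in% hosts))
    for (i in which(layout$species == "POPC")) {
      cand <- eligible[eligible != i & layout$leaflet[eligible] ==
                         layout$leaflet[i]]
      if (!length(cand))
        stop_ommtraj("no eligible charge-pair partner for POPC lipid ", i,
                     class = "ommtraj_config_error")
      ## nearest grid neighbor among eligible lipids
      dx <- minimum_image(cbind(layout$x[cand] - layout$x[i],
                                layout$y[cand] - layout$y[i]), spec$box_xy)
      pair_partner[i] <- cand[which.min(rowSums(dx^2))]
    }
  }

  ## --- topology ---------------------------------------------------------
  skeleton <- if (spec$detail == "minimal") {
    stats::setNames(lapply(LIPID_SPECIES, function(s) c(P = "P")),
                    LIPID_SPECIES)
  } else {
    stats::setNames(lapply(LIPID_SPECIES, function(s)
      registry[[s]]$roles), LIPID_SPECIES)
  }
  at_species <- character(); at_role <- character()
  at_molid <- integer(); at_element <- character(); at_lipid <- integer()
  for (i in seq_len(n_lip)) {
    roles <- skeleton[[layout$species[i]]]
    at_species <- c(at_species, rep(layout$species[i], length(roles)))
    at_role <- c(at_role, names(roles))
    at_element <- c(at_element, unname(roles))
    at_molid <- c(at_molid, rep(i, length(roles)))
    at_lipid <- c(at_lipid, rep(i, length(roles)))
  }
  w_per <- if (spec$with_solvent && spec$detail == "full")
    round(spec$waters_per_lipid[layout$species]) else rep(0L, n_lip)
  w_per[is.na(w_per)] <- 0L
  n_w <- sum(w_per)
  next_mol <- n_lip
  if (n_w > 0) {
    at_species <- c(at_species, rep("WATER", 3L * n_w))
    at_role <- c(at_role, rep(c("OW", "HW1", "HW2"), n_w))
    at_element <- c(at_element, rep(c("O", "H", "H"), n_w))
    at_molid <- c(at_molid, rep(next_mol + seq_len(n_w), each = 3L))
    at_lipid <- c(at_lipid, rep(rep(seq_len(n_lip), w_per), each = 3L))
    next_mol <- next_mol + n_w
  }
  if (n_na > 0) {
    at_species <- c(at_species, rep("NA", n_na))
    at_role <- c(at_role, rep("NA", n_na))
    at_element <- c(at_element, rep("NA", n_na))
    at_molid <- c(at_molid, next_mol + seq_len(n_na))
    at_lipid <- c(at_lipid, c(hosts, rep(NA_integer_, n_na - n_bound)))
    next_mol <- next_mol + n_na
  }
  if (n_cl > 0) {
    at_species <- c(at_species, rep("CL", n_cl))
    at_role <- c(at_role, rep("CL", n_cl))
    at_element <- c(at_element, rep("CL", n_cl))
    at_molid <- c(at_molid, next_mol + seq_len(n_cl))
    at_lipid <- c(at_lipid, rep(NA_integer_, n_cl))
    next_mol <- next_mol + n_cl
  }
  top <- md_topology(at_species, at_molid, at_role, at_element,
                     registry = registry)
  n_atoms <- nrow(top)

  lz <- spec$d_pp + 4.5
  box <- c(spec$box_xy, lz)

  ## precompute per-atom skeleton offsets for lipid atoms
  lipid_atoms <- which(!is.na(at_lipid) & at_species %in% LIPID_SPECIES)
  off <- matrix(0, n_atoms, 3)
  for (s in LIPID_SPECIES) {
    offs <- lipid_role_offsets(s, spec$n_sn1_carbons)
    sel <- lipid_atoms[at_species[lipid_atoms] == s &
                         at_role[lipid_atoms] %in% names(offs)]
    if (!length(sel)) next
    om <- do.call(rbind, offs[at_role[sel]])
    om[, 3] <- om[, 3] * layout$sgn[at_lipid[sel]]
    off[sel, ] <- om
  }

  hyd_roles <- lapply(registry[LIPID_SPECIES], function(sp) sp$sn1_carbons)

  ## atom index bookkeeping, computed once and reused for every frame
  li <- at_lipid[lipid_atoms]
  full <- spec$detail == "full"
  head_idx <- list()
  if (full) {
    for (s in c("POPC", "POPE", "POPS")) {
      nsel <- which(at_species == s & at_role == "N")
      if (!length(nsel)) next
      sat <- switch(s,
        POPC = list(ME1 = c(0.10, 0, 0.02), ME2 = c(-0.07, 0.07, 0.02),
                    ME3 = c(-0.07, -0.07, 0.02)),
        list(HN2 = c(0.10, 0, 0), HN3 = c(0, 0.10, 0)))
      sat_idx <- lapply(names(sat), function(r) {
        rsel <- which(at_species == s & at_role == r)
        list(rows = rsel, map = match(at_lipid[rsel], at_lipid[nsel]),
             off = sat[[r]])
      })
      hn1 <- if (s != "POPC") which(at_species == s & at_role == "HN1")
      head_idx[[s]] <- list(nsel = nsel, li = at_lipid[nsel],
                            sat = sat_idx, hn1 = hn1)
    }
  }
  c5i_sel <- if (full) which(at_species == "PIP2" & at_role == "C5I")
  tail_idx <- list()
  if (full) {
    for (s in LIPID_SPECIES) {
      if (!any(layout$species == s)) next
      for (ci in seq_along(spec$scd_targets[[s]])) {
        crole <- paste0("C", ci + 1L)
        csel2 <- which(at_species == s & at_role == crole)
        for (hrole in hyd_roles[[s]][[crole]]) {
          hsel <- which(at_species == s & at_role == hrole)
          tail_idx[[length(tail_idx) + 1L]] <-
            list(h = hsel, c = csel2[match(at_lipid[hsel], at_lipid[csel2])],
                 s_target = spec$scd_targets[[s]][ci])
        }
      }
    }
  }
  paired <- which(!is.na(pair_partner))
  me1_paired <- integer()
  if (length(paired)) {
    me1_all <- which(at_species == "POPC" & at_role == "ME1")
    me1_paired <- me1_all[match(paired, at_lipid[me1_all])]
  }
  op1_sel <- if (full) which(at_role == "OP1" &
                               at_species %in% LIPID_SPECIES)
  ow_sel <- which(at_species == "WATER" & at_role == "OW")
  whost <- rep(seq_len(n_lip), w_per)       # host lipid of each water
  wdirs <- if (n_w > 0) do.call(rbind, lapply(seq_len(n_lip), function(i)
    if (w_per[i] > 0) water_cone_dirs(w_per[i], layout$sgn[i])))
  na_sel <- which(at_species == "NA")
  contact_roles <- c("OC1", "OC2", "OP2")[seq_len(spec$na_multiplicity)]
  na_contact_idx <- lapply(seq_len(n_bound), function(bi) {
    i <- hosts[bi]
    vapply(contact_roles, function(r)
      which(at_species == layout$species[i] & at_role == r &
              at_lipid == i), 1L)
  })
  free_na <- na_sel[seq_len(n_na) > n_bound]
  cl_sel <- which(at_species == "CL")
  ion_grid <- function(m, k) cbind(((seq_len(m) - 1) %% k + 0.5),
                                   ((seq_len(m) - 1) %/% k + 0.5))

  coords <- array(0, c(n_atoms, 3, nf))
  half_z <- lz / 2
  for (f in seq_len(nf)) {
    pxy <- cbind(layout$x + walk[, 1, f], layout$y + walk[, 2, f])
    zp <- zpm[, f]
    pos <- matrix(0, n_atoms, 3)
    ## skeleton atoms at fixed offsets from the phosphate
    pos[lipid_atoms, 1] <- pxy[li, 1] + off[lipid_atoms, 1]
    pos[lipid_atoms, 2] <- pxy[li, 2] + off[lipid_atoms, 2]
    pos[lipid_atoms, 3] <- zp[li] + off[lipid_atoms, 3]
    ## headgroup-vector head atoms ride the rotational walk
    nvec <- hg[, , f, drop = FALSE]; dim(nvec) <- c(n_lip, 3)
    for (s in names(head_idx)) {
      hi <- head_idx[[s]]
      npos <- cbind(pxy[hi$li, 1], pxy[hi$li, 2], zp[hi$li]) +
        0.35 * nvec[hi$li, , drop = FALSE]
      pos[hi$nsel, ] <- npos
      for (sa in hi$sat)
        pos[sa$rows, ] <- npos[sa$map, ] +
          matrix(sa$off, length(sa$rows), 3, byrow = TRUE)
      if (!is.null(hi$hn1))
        pos[hi$hn1, ] <- npos[match(at_lipid[hi$hn1], hi$li), ] +
          0.10 * nvec[at_lipid[hi$hn1], , drop = FALSE]
    }
    if (length(c5i_sel)) {
      li_s <- at_lipid[c5i_sel]
      pos[c5i_sel, ] <- cbind(pxy[li_s, 1], pxy[li_s, 2],
                              zp[li_s] + 0.30 * layout$sgn[li_s]) +
        0.29 * nvec[li_s, , drop = FALSE]
    }
    ## tail hydrogens at the target order parameters
    for (ti in tail_idx)
      pos[ti$h, ] <- pos[ti$c, ] + 0.109 * scd_vectors(ti$s_target,
                                                       length(ti$h))
    ## constructed charge pairs: POPC ME1 near its partner's OP3
    if (length(paired)) {
      p <- pair_partner[paired]
      pos[me1_paired, ] <- cbind(pxy[p, 1] - 0.28, pxy[p, 2] - 0.15,
                                 zp[p] + 0.21 * layout$sgn[p])
    }
    ## hydration waters on a cone above OP1
    if (n_w > 0) {
      op1 <- matrix(NA_real_, n_lip, 3)
      op1[at_lipid[op1_sel], ] <- pos[op1_sel, ]
      ow <- op1[whost, , drop = FALSE] + 0.28 * wdirs
      pos[ow_sel, ] <- ow
      pos[ow_sel + 1L, ] <- ow - 0.10 * wdirs
      pos[ow_sel + 2L, ] <- ow + cbind(0, 0, 0.10 * layout$sgn[whost])
    }
    ## bound Na+ below the carbonyl region; the coordinating oxygens are
    ## moved onto a 0.30-nm sphere around the ion
    for (bi in seq_len(n_bound)) {
      i <- hosts[bi]
      q <- c(pxy[i, 1], pxy[i, 2], zp[i] - 0.80 * layout$sgn[i])
      pos[na_sel[bi], ] <- q
      dirs <- na_contact_dirs(spec$na_multiplicity, layout$sgn[i])
      pos[na_contact_idx[[bi]], ] <-
        matrix(q, spec$na_multiplicity, 3, byrow = TRUE) + 0.30 * dirs
    }
    ## free ions in the bulk, on a lateral grid near the box faces
    if (length(free_na)) {
      g <- ion_grid(length(free_na), ceiling(sqrt(length(free_na))))
      pos[free_na, ] <- cbind(g[, 1] * box[1] / ceiling(sqrt(length(free_na))),
                              g[, 2] * box[2] / ceiling(sqrt(length(free_na))),
                              half_z - 0.3)
    }
    if (length(cl_sel)) {
      g <- ion_grid(length(cl_sel), ceiling(sqrt(length(cl_sel))))
      pos[cl_sel, ] <- cbind(g[, 1] * box[1] / ceiling(sqrt(length(cl_sel))),
                             g[, 2] * box[2] / ceiling(sqrt(length(cl_sel))),
                             -(half_z - 0.3))
    }
    ## shift z into [0, Lz) and wrap laterally
    pos[, 3] <- pos[, 3] + half_z
    pos <- wrap_coords(pos, box)
    coords[, , f] <- pos
  }

  traj <- md_trajectory(top, coords, box, (seq_len(nf) - 1) * spec$dt)
  traj <- assign_leaflets(traj)

  unwrapped <- walk
  unwrapped[, 1, ] <- unwrapped[, 1, ] + layout$x
  unwrapped[, 2, ] <- unwrapped[, 2, ] + layout$y

  gt <- structure(list(
    seed = spec$seed, model = spec$model, composition = comp,
    total_lipid_charge = total_q,
    diffusion = spec$diffusion, rot_diffusion = spec$rot_diffusion,
    raf_decay_rate = 2 * spec$rot_diffusion,
    scd_targets = spec$scd_targets, d_pp = spec$d_pp,
    sigma_z = spec$sigma_z,
    waters_per_lipid = if (n_w > 0) spec$waters_per_lipid else NULL,
    na_bound_per_lipid = n_bound / n_lip,
    na_multiplicity = if (n_bound > 0) spec$na_multiplicity else NA,
    na_carbonyl_bound_per_lipid = if (n_bound > 0) n_bound / n_lip else 0,
    chargepairs_per_popc = if (chargepairs > 0) 1 else 0,
    contacts_exact = static,
    n_na = n_na, n_cl = n_cl,
    lipid_species = layout$species, lipid_leaflet = layout$leaflet,
    unwrapped_xy = unwrapped
  ), class = "bilayer_ground_truth")
  list(trajectory = traj, ground_truth = gt)
}

#' Write a generated system to disk
#'
#' Writes the trajectory as multi-frame GRO and the ground truth (without
#' the per-frame walks) as JSON.
#'
#' @param spec a \code{synthetic_spec} (or YAML path).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the list of written paths.
#' @export
generate_bilayer_files <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- generate_bilayer(spec)
  gro <- file.path(out_dir, "trajectory.gro")
  write_gro(sys$trajectory, gro)
  gt <- sys$ground_truth
  gt$unwrapped_xy <- NULL
  gt$lipid_species <- NULL
  gt$lipid_leaflet <- NULL
  gt$composition <- list(n_total = gt$composition$n_total,
                         counts = as.list(gt$composition$counts))
  js <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(unclass(gt), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(trajectory = gro, ground_truth = js))
}
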