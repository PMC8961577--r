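## One-command analysis: configuration, orchestration, report output.

#' Analysis configuration
#'
#' Collects the inputs and every tunable of the analysis pipeline, with
#' the standard defaults: 20 ns equilibration skip, 0.02 nm density bins,
#' 0.35 nm / 35 degree hydrogen-bond criteria, 0.4 nm charge-pair cutoff,
#' 0.325 nm sodium-contact cutoff.
#'
#' @param structure structure file (GRO/PDB), or NULL when
#'   \code{synthetic} is given.
#' @param traj_file trajectory file (multi-frame GRO or DCD); optional.
#' @param species_map species map (list or YAML path); NULL = native.
#' @param synthetic a \code{synthetic_spec} (or YAML path) to generate
#'   instead of reading files.
#' @param metrics subset of \code{c("structure", "dynamics", "interface")}.
#' @param skip_ns equilibration skip in ns (default 20).
#' @param bin_width density-profile bin width in nm.
#' @param fit_window MSD fit window in ps (NULL = 10--50\% of max lag).
#' @param origin_stride time-origin stride for MSD/RAF.
#' @param hbond_d,hbond_angle hydrogen-bond criteria (nm, degrees).
#' @param chargepair_cutoff,na_cutoff contact cutoffs in nm.
#' @param interface_stride analyze every k-th frame for contact metrics.
#' @param dt frame spacing in ps for trajectory formats without times.
#' @param seed seed recorded in the metadata (the generator draws from its
#'   own spec seed).
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(structure = NULL, traj_file = NULL,
                            species_map = NULL, synthetic = NULL,
                            metrics = c("structure", "dynamics",
                                        "interface"),
                            skip_ns = 20, bin_width = 0.02,
                            fit_window = NULL, origin_stride = 1L,
                            hbond_d = 0.35, hbond_angle = 35,
                            chargepair_cutoff = 0.4, na_cutoff = 0.325,
                            interface_stride = 1L, dt = 1, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(structure) && is.null(synthetic))
    stop_ommtraj("either a structure file or a synthetic spec is required",
                 class = "ommtraj_config_error")
  for (v in c(bin_width, hbond_d, chargepair_cutoff, na_cutoff))
    if (v <= 0)
      stop_ommtraj("cutoffs and bin widths must be positive",
                   class = "ommtraj_config_error")
  structure(as.list(environment()), class = "analysis_config")
}

config_hash <- function(config) {
  relevant <- unclass(config)
  relevant$seed <- NULL                   # seed is logged separately
  hash_object(relevant)
}

#' Run the full bilayer analysis
#'
#' Loads (or generates) the trajectory, assigns leaflets, applies the
#' equilibration skip, and computes the requested metric groups:
#' \describe{
#'   \item{structure}{area per lipid, phosphate density profile and
#'     peak-to-peak thickness, total lipid charge, surface charge density,
#'     per-species S_CD profiles.}
#'   \item{dynamics}{per-species MSD curves and diffusion coefficients
#'     with half-interval errors, headgroup RAF curves.}
#'   \item{interface}{water hydrogen bonds per lipid, lipid-lipid
#'     hydrogen-bond matrix with equal-affinity expected values, choline
#'     charge pairs, sodium contacts.}
#' }
#'
#' @param config an \code{analysis_config}.
#' @return object of class \code{report_bundle}: named list of tables and
#'   curves plus \code{metadata} (frame range, seed, config hash, package
#'   version).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  gt <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    if (is.character(spec)) spec <- read_synthetic_spec(spec)
    sys <- generate_bilayer(spec)
    traj <- sys$trajectory
    gt <- sys$ground_truth
  } else {
    st <- read_structure(config$structure, species_map = config$species_map)
    traj <- if (is.null(config$traj_file))
      md_trajectory(st$topology, st$frame$coords, st$frame$box,
                    st$frame$time)
    else read_frames(config$traj_file, st$topology, dt = config$dt)
  }
  traj <- assign_leaflets(traj)
  total_ns <- (traj$times[n_frames(traj)] - traj$times[1]) / 1000
  if (n_frames(traj) > 1 && config$skip_ns >= total_ns)
    stop_ommtraj("equilibration skip (", config$skip_ns,
                 " ns) is not shorter than the trajectory (",
                 total_ns, " ns)", class = "ommtraj_config_error")
  skip <- if (n_frames(traj) > 1) config$skip_ns else 0
  keep <- frames_after_skip(traj, skip)

  top <- traj$topology
  nmol <- species_molecule_counts(top)
  lsp <- intersect(LIPID_SPECIES, names(nmol))
  bundle <- list()

  if ("structure" %in% config$metrics) {
    apl <- area_per_lipid(traj, skip_ns = skip)
    prof <- density_profile(traj, LIPID_SPECIES, role = "P",
                            bin_width = config$bin_width, skip_ns = skip)
    comp <- tryCatch(
      build_composition(counts = nmol[lsp], n_total = sum(nmol[lsp]),
                        fractions = NULL),
      error = function(e) NULL)
    bundle$structure <- list(
      apl = apl,
      thickness = bilayer_thickness(prof),
      phosphate_profile = prof,
      total_lipid_charge = if (!is.null(comp)) total_lipid_charge(comp),
      surface_charge_density = if (!is.null(comp))
        surface_charge_density(comp, apl$mean),
      scd = stats::setNames(lapply(lsp, function(s)
        order_parameter_scd(traj, s, skip_ns = skip)), lsp))
  }

  if ("dynamics" %in% config$metrics && n_frames(traj) > 3) {
    sub <- subset_frames(traj, keep)
    uw <- unwrap_lateral(sub)
    curves <- stats::setNames(lapply(lsp, function(s)
      msd(uw, s, origin_stride = config$origin_stride)), lsp)
    fits <- lapply(curves, function(cv)
      tryCatch(fit_diffusion(cv, config$fit_window),
               error = function(e) NULL))
    rafs <- stats::setNames(lapply(lsp, function(s)
      rotational_autocorrelation(sub, s,
                                 origin_stride = config$origin_stride)),
      lsp)
    dtab <- do.call(rbind, lapply(lsp, function(s) {
      ft <- fits[[s]]
      data.frame(species = s,
                 D_1e8cm2s = if (is.null(ft)) NA else ft$D_1e8cm2s,
                 error_1e8cm2s = if (is.null(ft)) NA else ft$error_1e8cm2s)
    }))
    bundle$dynamics <- list(msd = curves, diffusion = dtab, raf = rafs)
  }

  if ("interface" %in% config$metrics) {
    crit <- hbond_criteria(config$hbond_d, config$hbond_angle)
    ifr <- analysis_frames(traj, skip_ns = skip,
                           stride = config$interface_stride)
    hyd <- water_hbonds_per_lipid(traj, crit, frames = ifr)
    hbm <- lipid_lipid_hbond_matrix(traj, crit, frames = ifr)
    frac <- nmol[lsp] / sum(nmol[lsp])
    expected <- t(vapply(rownames(hbm), function(s) {
      elig <- lsp            # all lipids; donor-restricted for POPC row
      if (s == "POPC")
        elig <- lsp[vapply(lsp, function(p)
          length(registry_of(top)[[p]]$donor_atoms) > 0, TRUE)]
      e <- stats::setNames(rep(NA_real_, length(lsp)), lsp)
      e[elig] <- expected_hbonds(hbm[s, "All"], frac[elig])
      e
    }, stats::setNames(numeric(length(lsp)), lsp)))
    cp <- charge_pairs(traj, config$chargepair_cutoff, frames = ifr)
    ion <- if ("NA" %in% names(nmol))
      sodium_contacts(traj, config$na_cutoff, frames = ifr)
    bundle$interface <- list(water_hbonds = hyd, hbond_matrix = hbm,
                             expected_hbonds = expected,
                             charge_pairs = cp, sodium = ion)
  }

  bundle$ground_truth <- gt
  bundle$metadata <- list(
    package_version = as.character(utils::packageVersion("ommtraj")),
    config_hash = config_hash(config),
    seed = config$seed %||% (if (!is.null(gt)) gt$seed),
    frames_analyzed = range(keep),
    times_analyzed_ps = range(traj$times[keep]),
    n_frames_total = n_frames(traj),
    defaults = list(skip_ns = config$skip_ns,
                    hbond = list(d_da_max = config$hbond_d,
                                 angle_max = config$hbond_angle),
                    chargepair_cutoff = config$chargepair_cutoff,
                    na_cutoff = config$na_cutoff,
                    bin_width = config$bin_width))
  class(bundle) <- "report_bundle"
  bundle
}

## frame subset preserving classes
subset_frames <- function(traj, keep) {
  md_trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
                traj$box[keep, , drop = FALSE], traj$times[keep])
}

#' Write a report bundle to a directory
#'
#' TSV tables for the structure, diffusion, hydration, interaction and
#' ion statistics, TSV curves (density, S_CD, MSD, RAF) and a JSON
#' metadata file.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$structure)) {
    s <- bundle$structure
    w(data.frame(
      quantity = c("area_per_lipid_nm2", "apl_sd_nm2", "thickness_nm",
                   "total_lipid_charge_e", "surface_charge_density_e_nm2"),
      value = c(s$apl$mean, s$apl$sd, s$thickness,
                s$total_lipid_charge %||% NA,
                s$surface_charge_density %||% NA)), "structure.tsv")
    w(data.frame(z = s$phosphate_profile$z,
                 density = s$phosphate_profile$density),
      "phosphate_density.tsv")
    for (sp in names(s$scd))
      w(as.data.frame(s$scd[[sp]]), paste0("scd_", sp, ".tsv"))
  }
  if (!is.null(bundle$dynamics)) {
    w(bundle$dynamics$diffusion, "diffusion.tsv")
    for (sp in names(bundle$dynamics$msd))
      w(as.data.frame(bundle$dynamics$msd[[sp]]),
        paste0("msd_", sp, ".tsv"))
    for (sp in names(bundle$dynamics$raf))
      w(as.data.frame(bundle$dynamics$raf[[sp]]),
        paste0("raf_", sp, ".tsv"))
  }
  if (!is.null(bundle$interface)) {
    i <- bundle$interface
    w(data.frame(species = names(i$water_hbonds),
                 hbonds_per_lipid = as.numeric(i$water_hbonds)),
      "water_hbonds.tsv")
    w(cbind(data.frame(species = rownames(i$hbond_matrix)),
            as.data.frame(i$hbond_matrix)), "hbond_matrix.tsv")
    w(cbind(data.frame(species = rownames(i$expected_hbonds)),
            as.data.frame(i$expected_hbonds)), "expected_hbonds.tsv")
    w(data.frame(partner = names(i$charge_pairs$per_popc),
                 pairs_per_popc = as.numeric(i$charge_pairs$per_popc)),
      "charge_pairs.tsv")
    if (!is.null(i$sodium))
      w(data.frame(quantity = c("na_bound_per_lipid", "multiplicity",
                                "carbonyl_bound_per_lipid"),
                   value = c(i$sodium$bound_per_lipid,
                             i$sodium$multiplicity,
                             i$sodium$carbonyl_bound_per_lipid)),
        "sodium_contacts.tsv")
  }
  meta <- file.path(dir, "metadata.json")
  jsonlite::write_json(bundle$metadata, meta, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, meta))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("ommtraj report bundle\n")
  if (!is.null(x$structure))
    cat(sprintf("  APL %.4f nm^2, thickness %.3f nm\n",
                x$structure$apl$mean, x$structure$thickness))
  if (!is.null(x$dynamics)) {
    d <- x$dynamics$diffusion
    cat("  D (1e-8 cm^2/s):",
        paste(sprintf("%s %.1f", d$species, d$D_1e8cm2s), collapse = ", "),
        "\n")
  }
  if (!is.null(x$interface))
    cat("  water H-bonds/lipid:",
        paste(sprintf("%s %.2f", names(x$interface$water_hbonds),
                      x$interface$water_hbonds), collapse = ", "), "\n")
  cat("  frames", x$metadata$frames_analyzed[1], "to",
      x$metadata$frames_analyzed[2], "of", x$metadata$n_frames_total, "\n")
  invisible(x)
}
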