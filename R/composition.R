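#' Build an integer membrane composition from mole fractions
#'
#' Converts per-species mole fractions into integer lipid counts for a
#' bilayer of \code{n_total} lipids. Counts are the nearest integers to
#' \code{fraction * n_total}; any residual (the roundings need not sum to
#' \code{n_total}) is absorbed by the most abundant species. Per-leaflet
#' counts are half of each species count, with odd species counts alternated
#' between the two leaflets so that each leaflet holds exactly
#' \code{n_total / 2} lipids.
#'
#' @param fractions named numeric vector of mole fractions (names from
#'   POPC, POPE, POPS, PIP2); must sum to 1.
#' @param n_total even total number of lipids in the bilayer (default 784).
#' @param counts optional named integer vector overriding the rounded
#'   counts (must sum to \code{n_total}); fractions are then recomputed.
#' @return object of class \code{membrane_composition}: list with
#'   \code{n_total}, \code{fractions}, \code{counts}, and a 2-row
#'   \code{leaflet_counts} matrix (upper/lower).
#' @examples
#' comp <- build_composition(c(POPC = 0.59, POPE = 0.31, POPS = 0, PIP2 = 0.10))
#' comp$counts
#' total_lipid_charge(comp)
#' @export
build_composition <- function(fractions, n_total = 784L, counts = NULL) {
  if (n_total <= 0 || n_total %% 2 != 0)
    stop_ommtraj("n_total must be a positive even lipid count",
                 class = "ommtraj_domain_error")
  if (is.null(counts)) {
    if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
      stop_ommtraj("fractions must be named by species",
                   class = "ommtraj_domain_error")
    if (any(fractions < 0))
      stop_ommtraj("fractions must be non-negative",
                   class = "ommtraj_domain_error")
    if (abs(sum(fractions) - 1) > 1e-9)
      stop_ommtraj("fractions must sum to 1 (got ", sum(fractions), ")",
                   class = "ommtraj_domain_error")
    counts <- round(fractions * n_total)
    resid <- n_total - sum(counts)
    if (resid != 0) {
      largest <- which.max(counts)
      counts[largest] <- counts[largest] + resid
    }
  } else {
    if (sum(counts) != n_total)
      stop_ommtraj("count override must sum to n_total",
                   class = "ommtraj_domain_error")
    counts <- counts[order(match(names(counts), LIPID_SPECIES))]
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(counts < 0))
    stop_ommtraj("negative species count", class = "ommtraj_domain_error")

  upper <- counts %/% 2L
  odd <- which(counts %% 2L == 1L)
  ## odd counts come in pairs (total is even); alternate the spare lipid
  if (length(odd)) {
    add_upper <- odd[seq_along(odd) %% 2L == 1L]
    upper[add_upper] <- upper[add_upper] + 1L
  }
  lower <- counts - upper
  leaflet_counts <- rbind(upper = upper, lower = lower)

  structure(list(
    n_total = as.integer(n_total),
    fractions = counts / n_total,
    counts = counts,
    leaflet_counts = leaflet_counts
  ), class = "membrane_composition")
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("Membrane composition:", x$n_total, "lipids\n")
  print(data.frame(species = names(x$counts), count = as.integer(x$counts),
                   fraction = round(as.numeric(x$fractions), 4),
                   upper = as.integer(x$leaflet_counts["upper", ]),
                   lower = as.integer(x$leaflet_counts["lower", ])),
        row.names = FALSE)
  cat("Total lipid charge:", total_lipid_charge(x), "e\n")
  invisible(x)
}

#' Outer-mitochondrial-membrane model compositions
#'
#' Mole fractions of the five OMM bilayer models: varying POPS and
#' PI(3,4)P2 content on a POPC/POPE background.
#'
#' @param model integer 1..5.
#' @return named numeric vector of fractions (POPC, POPE, POPS, PIP2).
#' @export
omm_model_fractions <- function(model) {
  tab <- rbind(
    `1` = c(POPC = 0.59, POPE = 0.31, POPS = 0.00, PIP2 = 0.10),
    `2` = c(POPC = 0.57, POPE = 0.31, POPS = 0.02, PIP2 = 0.10),
    `3` = c(POPC = 0.50, POPE = 0.24, POPS = 0.20, PIP2 = 0.06),
    `4` = c(POPC = 0.43, POPE = 0.17, POPS = 0.39, PIP2 = 0.01),
    `5` = c(POPC = 0.57, POPE = 0.43, POPS = 0.00, PIP2 = 0.00))
  if (!model %in% 1:5)
    stop_ommtraj("model must be 1..5", class = "ommtraj_domain_error")
  tab[as.character(model), ]
}

#' Total formal charge of the lipids of a composition
#'
#' Sum over species of count times formal charge (POPC 0, POPE 0, POPS -1,
#' PI(3,4)P2 -4 e).
#'
#' @param comp a \code{membrane_composition}.
#' @return integer charge in e.
#' @export
total_lipid_charge <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  ch <- species_charges()[names(comp$counts)]
  if (anyNA(ch))
    stop_ommtraj("unknown species in composition",
                 class = "ommtraj_domain_error")
  as.integer(sum(comp$counts * ch))
}

#' Ideal-mixing estimate of the area per lipid
#'
#' Mole-fraction-weighted mean of single-component reference areas, the
#' standard ideal-mixing estimate used to sanity-check multi-component
#' bilayer areas (e.g. 0.57 x 0.643 + 0.43 x 0.566 = 0.610 nm^2 for a
#' POPC/POPE mixture).
#'
#' @param fractions named mole fractions over the referenced species,
#'   summing to 1.
#' @param reference_apls named reference areas per lipid in nm^2.
#' @return estimated area per lipid in nm^2.
#' @export
ideal_mixing_apl <- function(fractions, reference_apls) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_ommtraj("fractions must sum to 1 over the referenced species",
                 class = "ommtraj_domain_error")
  ref <- reference_apls[names(fractions)]
  if (anyNA(ref))
    stop_ommtraj("missing reference APL for: ",
                 paste(names(fractions)[is.na(ref)], collapse = ", "),
                 class = "ommtraj_domain_error")
  sum(fractions * ref)
}

#' Surface charge density of a bilayer
#'
#' Charge per unit membrane surface. With the default convention the total
#' lipid charge is divided by four times the leaflet area (two leaflets,
#' each with area \code{n_leaflet * apl}, and the charge split between the
#' two membrane surfaces): \code{Q / (4 * n_leaflet * apl)}. The
#' \code{"per-leaflet"} convention divides each leaflet's own charge by
#' twice the leaflet area, which is identical for symmetric leaflets.
#'
#' @param comp a \code{membrane_composition}.
#' @param apl area per lipid in nm^2.
#' @param convention \code{"total-over-4A"} (default) or
#'   \code{"per-leaflet"}.
#' @return surface charge density in e/nm^2.
#' @export
surface_charge_density <- function(comp, apl,
                                   convention = c("total-over-4A",
                                                  "per-leaflet")) {
  convention <- match.arg(convention)
  if (apl <= 0)
    stop_ommtraj("area per lipid must be positive",
                 class = "ommtraj_domain_error")
  q <- total_lipid_charge(comp)
  n_leaflet <- comp$n_total / 2
  area <- n_leaflet * apl
  switch(convention,
         "total-over-4A" = q / (4 * area),
         "per-leaflet" = (q / 2) / (2 * area))
}
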