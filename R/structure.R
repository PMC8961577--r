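## Structural observables: area per lipid, partial density profiles,
## phosphate peak-to-peak thickness, deuterium order parameter.

## frames at or after the equilibration skip (ps)
frames_after_skip <- function(traj, skip_ns = 0) {
  keep <- which(traj$times >= traj$times[1] + skip_ns * 1000)
  if (!length(keep))
    stop_ommtraj("equilibration skip (", skip_ns, " ns) leaves no frames",
                 class = "ommtraj_config_error")
  keep
}

#' Area per lipid
#'
#' Per frame, the lateral box area divided by the number of lipids per
#' leaflet; reported as the mean and standard deviation over analyzed
#' frames.
#'
#' @param traj an \code{md_trajectory} with leaflets assigned.
#' @param skip_ns equilibration skip in ns (default 0; trajectory times
#'   start at the first frame).
#' @return object of class \code{apl_result}: list with \code{mean},
#'   \code{sd}, \code{series} (per-frame nm^2), \code{n_leaflet}.
#' @export
area_per_lipid <- function(traj, skip_ns = 0) {
  top <- traj$topology
  if (all(is.na(top$leaflet))) traj <- assign_leaflets(traj)
  top <- traj$topology
  mols <- top[!duplicated(top$molid) & top$species %in% LIPID_SPECIES, ]
  n_up <- sum(mols$leaflet == "upper")
  n_lo <- sum(mols$leaflet == "lower")
  if (n_up != n_lo)
    stop_ommtraj("leaflets hold ", n_up, " and ", n_lo, " lipids; ",
                 "area per lipid needs equal leaflets - analyze each ",
                 "leaflet with an explicit per-leaflet normalization",
                 class = "ommtraj_domain_error")
  keep <- frames_after_skip(traj, skip_ns)
  series <- traj$box[keep, 1] * traj$box[keep, 2] / n_up
  structure(list(mean = mean(series),
                 sd = if (length(series) > 1) stats::sd(series) else 0,
                 series = series, n_leaflet = n_up),
            class = "apl_result")
}

#' @export
print.apl_result <- function(x, ...) {
  cat(sprintf("Area per lipid: %.4f +- %.4f nm^2 (%d lipids/leaflet, %d frames)\n",
              x$mean, x$sd, x$n_leaflet, length(x$series)))
  invisible(x)
}

#' Partial density profile along the bilayer normal
#'
#' Histogram of the z coordinates of the selected atoms, re-centered per
#' frame on the bilayer midplane (the mean phosphate z), averaged over
#' frames and normalized by bin volume. The integral of the count density
#' over the profile equals the mean number of selected atoms per frame.
#'
#' @param traj an \code{md_trajectory}.
#' @param selection logical or integer atom selection, or a species name.
#' @param bin_width bin width in nm (default 0.02).
#' @param role restrict a species selection to one role (e.g. "P").
#' @param skip_ns equilibration skip in ns.
#' @param mass if TRUE weight atoms by mass (kg/m^3-convertible), else
#'   count density in 1/nm^3.
#' @return object of class \code{density_profile}: data.frame-like list
#'   with \code{z} (bin centers, nm), \code{density}, \code{bin_width},
#'   \code{n_frames}.
#' @export
density_profile <- function(traj, selection, bin_width = 0.02, role = NULL,
                            skip_ns = 0, mass = FALSE) {
  if (bin_width <= 0)
    stop_ommtraj("bin width must be positive", class = "ommtraj_domain_error")
  top <- traj$topology
  if (is.character(selection)) {
    sel <- which(top$species %in% selection &
                   (if (is.null(role)) TRUE else top$role %in% role))
  } else if (is.logical(selection)) {
    sel <- which(selection)
  } else sel <- as.integer(selection)
  if (!length(sel))
    stop_ommtraj("empty selection", class = "ommtraj_empty_selection")
  keep <- frames_after_skip(traj, skip_ns)
  pidx <- phosphate_indices(top)
  zext <- max(traj$box[, 3])
  edges <- seq(-zext / 2 - bin_width, zext / 2 + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1L)
  w <- if (mass) top$mass[sel] else rep(1, length(sel))
  area <- 0
  for (f in keep) {
    mid <- mean(traj$coords[pidx, 3, f])
    z <- traj$coords[sel, 3, f] - mid
    z <- minimum_image(z, traj$box[f, 3])   # re-centered, wrapped to box
    bi <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- bi >= 1L & bi <= length(counts)
    cnt <- rowsum(w[ok], bi[ok])
    at <- as.integer(rownames(cnt))
    counts[at] <- counts[at] + cnt[, 1]
    area <- area + traj$box[f, 1] * traj$box[f, 2]
  }
  nf <- length(keep)
  dens <- counts / nf / ((area / nf) * bin_width)
  if (mass) dens <- dens * 1.66053906660  # u/nm^3 -> kg/m^3
  structure(list(z = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, bin_width = bin_width, n_frames = nf,
                 mean_area = area / nf, mass_weighted = mass),
            class = "density_profile")
}

## 3-point parabolic refinement of a peak position
parabolic_peak <- function(z, y, i) {
  if (i <= 1L || i >= length(y)) return(z[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(z[i])
  z[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * (z[2] - z[1])
}

#' Phosphate peak-to-peak bilayer thickness
#'
#' Distance between the phosphate-density maxima of the two leaflets,
#' each refined by 3-point parabolic interpolation around the maximal bin.
#'
#' @param profile a \code{density_profile} of the phosphate atoms (one
#'   peak per leaflet).
#' @return thickness in nm.
#' @export
bilayer_thickness <- function(profile) {
  z <- profile$z; y <- profile$density
  lo <- which(z < 0); hi <- which(z >= 0)
  if (!length(lo) || !length(hi) || all(y[lo] == 0) || all(y[hi] == 0))
    stop_ommtraj("density profile lacks a peak in one leaflet",
                 class = "ommtraj_degenerate_profile")
  i1 <- lo[which.max(y[lo])]; i2 <- hi[which.max(y[hi])]
  p1 <- parabolic_peak(z, y, i1); p2 <- parabolic_peak(z, y, i2)
  p2 - p1
}

#' Deuterium order parameter profile along the sn-1 chain
#'
#' For each chain carbon i, S_CD = <3/2 cos^2(theta_i) - 1/2> where theta_i
#' is the angle between the C-H bond and the bilayer normal (the z axis),
#' averaged over molecules, attached hydrogens and frames.
#'
#' @param traj an \code{md_trajectory}.
#' @param species lipid species.
#' @param chain chain selector (only "sn1" is defined).
#' @param skip_ns equilibration skip in ns.
#' @return object of class \code{scd_profile}: data.frame with columns
#'   \code{carbon} (chain index, first tail carbon = 2), \code{scd},
#'   \code{n_samples}.
#' @export
order_parameter_scd <- function(traj, species, chain = "sn1", skip_ns = 0) {
  stopifnot(chain == "sn1")
  top <- traj$topology
  reg <- registry_of(top)
  sn1 <- reg[[species]]$sn1_carbons
  if (is.null(sn1) || !length(sn1))
    stop_ommtraj("species ", species, " has no sn1 chain roles",
                 class = "ommtraj_role_error")
  keep <- frames_after_skip(traj, skip_ns)
  out <- data.frame(carbon = integer(), scd = numeric(),
                    n_samples = integer())
  for (ci in seq_along(sn1)) {
    crole <- names(sn1)[ci]
    csel <- role_indices(top, species, crole)
    if (!length(csel)) next
    acc <- 0; n <- 0L
    for (hrole in sn1[[ci]]) {
      hsel <- role_indices(top, species, hrole)
      if (length(hsel) != length(csel))
        stop_ommtraj("carbon ", crole, " lacks hydrogen role ", hrole,
                     class = "ommtraj_role_error")
      for (f in keep) {
        v <- matrix(traj$coords[hsel, , f] - traj$coords[csel, , f],
                    ncol = 3)
        c2 <- v[, 3]^2 / rowSums(v * v)
        acc <- acc + sum(1.5 * c2 - 0.5)
        n <- n + length(hsel)
      }
    }
    out <- rbind(out, data.frame(carbon = ci + 1L, scd = acc / n,
                                 n_samples = n))
  }
  class(out) <- c("scd_profile", "data.frame")
  attr(out, "species") <- species
  out
}

#' Plot an order-parameter profile
#'
#' Plots -S_CD against the carbon index, the customary axis convention for
#' acyl-chain order parameter figures.
#'
#' @param x an \code{scd_profile}.
#' @param ... passed to \code{plot}.
#' @export
plot.scd_profile <- function(x, ...) {
  plot(x$carbon, -x$scd, type = "b", xlab = "sn-1 carbon",
       ylab = expression(-S[CD]),
       main = attr(x, "species"), ...)
  invisible(x)
}
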