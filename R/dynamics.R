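## Translational and rotational dynamics: multi-origin MSD, diffusion
## fitting with the half-interval error estimate, headgroup rotational
## autocorrelation.

## center of mass with molecules made whole under PBC (reference = first
## atom of each molecule; valid while molecular extent < box/2)
molecule_com_pbc <- function(coords, topology, molids, box) {
  sel <- topology$molid %in% molids
  g <- factor(topology$molid[sel], levels = molids)
  ref_rows <- !duplicated(topology$molid[sel])
  ref <- coords[which(sel)[ref_rows], 1:2, drop = FALSE]
  rel <- coords[sel, 1:2, drop = FALSE] - ref[as.integer(g), , drop = FALSE]
  rel <- minimum_image(rel, box[1:2])
  m <- topology$mass[sel]
  com_rel <- rowsum(m * rel, g, reorder = FALSE) / as.numeric(rowsum(m, g,
                                                       reorder = FALSE))
  ref + com_rel
}

#' Unwrap lateral center-of-mass motion
#'
#' Computes the per-frame lateral (x, y) center of mass of each selected
#' molecule, takes frame-to-frame displacements by minimum image,
#' accumulates them into continuous paths, and (optionally) subtracts the
#' mean lateral drift of each leaflet at every step.
#'
#' @param traj an \code{md_trajectory} with leaflets assigned.
#' @param species lipid species to include (default: all lipids).
#' @param remove_drift subtract the per-leaflet mean displacement at each
#'   step (default TRUE).
#' @return list with \code{xy} (n_mol x n_frames x 2 unwrapped positions),
#'   \code{molids}, \code{species}, \code{leaflet}, \code{times}.
#' @export
unwrap_lateral <- function(traj, species = LIPID_SPECIES,
                           remove_drift = TRUE) {
  top <- traj$topology
  if (all(is.na(top$leaflet))) {
    traj <- assign_leaflets(traj)
    top <- traj$topology
  }
  mols <- top[!duplicated(top$molid) & top$species %in% species, ]
  molids <- mols$molid
  nf <- n_frames(traj)
  n <- length(molids)
  if (!n)
    stop_ommtraj("no molecules of species ",
                 paste(species, collapse = "/"),
                 class = "ommtraj_selection_error")
  xy <- array(0, c(n, nf, 2))
  prev <- molecule_com_pbc(traj$coords[, , 1], top, molids, traj$box[1, ])
  xy[, 1, ] <- prev
  if (nf > 1) {
    half <- outer(rep(1, n), traj$box[1, 1:2] / 2)
    for (f in 2:nf) {
      cur <- molecule_com_pbc(traj$coords[, , f], top, molids,
                              traj$box[f, ])
      step <- minimum_image(cur - prev, traj$box[f, 1:2])
      too_big <- abs(step) >= matrix(traj$box[f, 1:2] / 2, n, 2,
                                     byrow = TRUE) - 1e-12
      if (any(too_big))
        stop_ommtraj("unwrap failure at frame ", f, ": molecule ",
                     molids[which(rowSums(too_big) > 0)[1]],
                     " moved half a box in one step",
                     class = "ommtraj_unwrap_error")
      if (remove_drift) {
        for (leaf in unique(mols$leaflet)) {
          lsel <- mols$leaflet == leaf
          step[lsel, 1] <- step[lsel, 1] - mean(step[lsel, 1])
          step[lsel, 2] <- step[lsel, 2] - mean(step[lsel, 2])
        }
      }
      xy[, f, ] <- xy[, f - 1, ] + step
      prev <- cur
    }
  }
  list(xy = xy, molids = molids, species = mols$species,
       leaflet = mols$leaflet, times = traj$times)
}

## multi-origin MSD workhorse on an (n_mol, n_frames, 2) array
msd_multi_origin <- function(xy, lags, origin_stride = 1L) {
  nf <- dim(xy)[2]
  n <- dim(xy)[1]
  msd <- numeric(length(lags))
  nsamp <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    if (lag == 0) { msd[k] <- 0; nsamp[k] <- n * nf; next }
    origins <- seq(1L, nf - lag, by = origin_stride)
    d1 <- xy[, origins + lag, 1, drop = FALSE] -
      xy[, origins, 1, drop = FALSE]
    d2 <- xy[, origins + lag, 2, drop = FALSE] -
      xy[, origins, 2, drop = FALSE]
    msd[k] <- mean(d1 * d1 + d2 * d2)
    nsamp[k] <- n * length(origins)
  }
  list(msd = msd, n_samples = nsamp)
}

#' Lateral mean squared displacement
#'
#' MSD(tau) = <|r(t0) - r(t0 + tau)|^2> of the lateral center of mass,
#' averaged over all molecules of the species and over time origins spaced
#' by \code{origin_stride}. Lags run to half the trajectory length.
#'
#' @param traj an \code{md_trajectory}, or the list from
#'   \code{\link{unwrap_lateral}}.
#' @param species species to analyze.
#' @param origin_stride origin spacing in frames (default 1 = every frame).
#' @param max_lag largest lag in frames (default: half the trajectory).
#' @param remove_drift passed to \code{unwrap_lateral}.
#' @return object of class \code{msd_curve}: data.frame with \code{tau}
#'   (ps), \code{msd} (nm^2), \code{n_samples}.
#' @export
msd <- function(traj, species, origin_stride = 1L, max_lag = NULL,
                remove_drift = TRUE) {
  uw <- if (inherits(traj, "md_trajectory"))
    unwrap_lateral(traj, species = species, remove_drift = remove_drift)
  else traj
  sel <- uw$species %in% species
  if (!any(sel))
    stop_ommtraj("no molecules of species ", paste(species, collapse = "/"),
                 class = "ommtraj_selection_error")
  xy <- uw$xy[sel, , , drop = FALSE]
  nf <- dim(xy)[2]
  if (nf < 2)
    stop_ommtraj("MSD needs at least 2 frames",
                 class = "ommtraj_domain_error")
  max_lag <- max_lag %||% (nf %/% 2L)
  lags <- 0:max_lag
  res <- msd_multi_origin(xy, lags, origin_stride)
  dt <- uw$times[2] - uw$times[1]
  out <- data.frame(tau = lags * dt, msd = res$msd,
                    n_samples = res$n_samples)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a lateral diffusion coefficient to an MSD curve
#'
#' Unweighted least squares of MSD against lag time over the fit window
#' (free intercept); D = slope / (2 N_f) with N_f = 2 translational
#' degrees of freedom. The error estimate is the absolute difference of
#' the D values fitted over the first and second halves of the window.
#'
#' @param curve an \code{msd_curve}.
#' @param fit_window c(tau_min, tau_max) in ps; default the 10--50\% span
#'   of the available lags.
#' @return object of class \code{diffusion_estimate}: list with \code{D}
#'   (nm^2/ns), \code{D_1e8cm2s} (units of 1e-8 cm^2/s), \code{error}
#'   (same convention), \code{fit_window}.
#' @export
fit_diffusion <- function(curve, fit_window = NULL) {
  tmax <- max(curve$tau)
  fit_window <- fit_window %||% c(0.1 * tmax, 0.5 * tmax)
  sel <- which(curve$tau >= fit_window[1] & curve$tau <= fit_window[2] &
                 curve$tau > 0)
  if (length(sel) < 8)
    stop_ommtraj("fit window too narrow: ", length(sel),
                 " points (need >= 4 per half)", class = "ommtraj_fit_error")
  slope_of <- function(idx) {
    stats::coef(stats::lm(msd ~ tau, data = curve[idx, ]))[["tau"]]
  }
  ## slope in nm^2/ps -> D = slope/4 nm^2/ps = slope/4 * 1000 nm^2/ns
  d_full <- slope_of(sel) / 4 * 1000
  half <- length(sel) %/% 2L
  d1 <- slope_of(sel[seq_len(half)]) / 4 * 1000
  d2 <- slope_of(sel[(half + 1L):length(sel)]) / 4 * 1000
  structure(list(D = d_full, D_1e8cm2s = d_full * 1000,
                 error = abs(d1 - d2), error_1e8cm2s = abs(d1 - d2) * 1000,
                 fit_window = fit_window),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.3g nm^2/ns (%.2f +- %.2f x 1e-8 cm^2/s), window %g-%g ps\n",
              x$D, x$D_1e8cm2s, x$error_1e8cm2s,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

## headgroup unit vectors per molecule per frame, (n, n_frames, 3)
headgroup_vectors <- function(traj, species) {
  top <- traj$topology
  reg <- registry_of(top)
  hv <- reg[[species]]$headgroup_vector
  if (is.null(hv))
    stop_ommtraj("species ", species, " has no headgroup vector",
                 class = "ommtraj_role_error")
  tailsel <- role_indices(top, species, hv[1])
  headsel <- role_indices(top, species, hv[2])
  if (!length(tailsel))
    stop_ommtraj("no molecules of species ", species,
                 class = "ommtraj_selection_error")
  nf <- n_frames(traj)
  v <- array(0, c(length(tailsel), nf, 3))
  for (f in seq_len(nf)) {
    d <- minimum_image(matrix(traj$coords[headsel, , f] -
                                traj$coords[tailsel, , f], ncol = 3),
                       traj$box[f, ])
    v[, f, ] <- normalize_rows(d)
  }
  v
}

## multi-origin first-rank autocorrelation on an (n, n_frames, 3) array
c1_multi_origin <- function(v, lags, origin_stride = 1L) {
  nf <- dim(v)[2]
  c1 <- numeric(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    if (lag == 0) { c1[k] <- 1; next }
    origins <- seq(1L, nf - lag, by = origin_stride)
    dots <- v[, origins, 1, drop = FALSE] * v[, origins + lag, 1, drop = FALSE] +
      v[, origins, 2, drop = FALSE] * v[, origins + lag, 2, drop = FALSE] +
      v[, origins, 3, drop = FALSE] * v[, origins + lag, 3, drop = FALSE]
    c1[k] <- mean(dots)
  }
  c1
}

#' Rotational autocorrelation of the headgroup vector
#'
#' C1(tau) = <n(t0) . n(t0 + tau)> over molecules and time origins, with n
#' the unit headgroup vector (phosphate-to-nitrogen, or inositol C2-to-C5
#' for PIP2) - the first-Legendre (P1 = cos theta) rotational
#' autocorrelation function.
#'
#' @param traj an \code{md_trajectory}, or an (n, n_frames, 3) array of
#'   unit vectors with a \code{times} attribute.
#' @param species lipid species.
#' @param origin_stride origin spacing in frames.
#' @param max_lag largest lag in frames (default: half the trajectory).
#' @return object of class \code{raf_curve}: data.frame with \code{tau}
#'   (ps) and \code{c1}.
#' @export
rotational_autocorrelation <- function(traj, species = "POPE",
                                       origin_stride = 1L, max_lag = NULL) {
  if (inherits(traj, "md_trajectory")) {
    v <- headgroup_vectors(traj, species)
    times <- traj$times
  } else {
    v <- traj
    times <- attr(traj, "times")
  }
  nf <- dim(v)[2]
  max_lag <- max_lag %||% (nf %/% 2L)
  lags <- 0:max_lag
  dt <- if (nf > 1) times[2] - times[1] else 0
  out <- data.frame(tau = lags * dt,
                    c1 = c1_multi_origin(v, lags, origin_stride))
  class(out) <- c("raf_curve", "data.frame")
  out
}

#' Fit an exponential decay rate to a RAF curve
#'
#' Least-squares fit of log C1 against tau over the region where C1 stays
#' above a floor; for isotropic rotational diffusion the decay rate equals
#' 2 D_r.
#'
#' @param curve a \code{raf_curve}.
#' @param floor smallest C1 included in the fit (default 0.1).
#' @return decay rate in 1/ns.
#' @export
fit_raf_decay <- function(curve, floor = 0.1) {
  sel <- which(curve$c1 > floor & curve$tau > 0)
  if (length(sel) < 3)
    stop_ommtraj("too few points above the C1 floor",
                 class = "ommtraj_fit_error")
  gap <- which(diff(sel) > 1L)           # fit only the contiguous head
  if (length(gap)) sel <- sel[seq_len(gap[1])]
  if (length(sel) < 3)
    stop_ommtraj("too few contiguous points above the C1 floor",
                 class = "ommtraj_fit_error")
  fit <- stats::lm(log(c1) ~ tau, data = curve[sel, ])
  -stats::coef(fit)[["tau"]] * 1000      # 1/ps -> 1/ns
}

#' Headgroup tilt distribution
#'
#' Histogram of the angle between the headgroup vector and the outward
#' bilayer normal (+z for the upper leaflet, -z for the lower, so the two
#' leaflets are directly comparable).
#'
#' @param traj an \code{md_trajectory} with leaflets assigned.
#' @param species lipid species.
#' @param breaks histogram breaks in degrees (default every 2 degrees).
#' @return object of class \code{tilt_histogram}: data.frame with
#'   \code{angle} (bin centers, degrees) and \code{density} (1/degree).
#' @export
pn_tilt_distribution <- function(traj, species = "POPE",
                                 breaks = seq(0, 180, by = 2)) {
  if (all(is.na(traj$topology$leaflet))) traj <- assign_leaflets(traj)
  v <- headgroup_vectors(traj, species)
  top <- traj$topology
  mols <- top[!duplicated(top$molid) & top$species == species, ]
  sgn <- ifelse(mols$leaflet == "lower", -1, 1)
  cosang <- sweep(v[, , 3, drop = FALSE], 1, sgn, `*`)
  ang <- acos(pmin(1, pmax(-1, as.numeric(cosang)))) * 180 / pi
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  out <- data.frame(angle = h$mids, density = h$density)
  class(out) <- c("tilt_histogram", "data.frame")
  out
}
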