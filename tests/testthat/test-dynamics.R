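## a minimal P-only trajectory with prescribed per-frame xy paths
path_traj <- function(paths, box = c(10, 10, 8), dt = 100, z = NULL) {
  n <- dim(paths)[1]; nf <- dim(paths)[2]
  z <- z %||% rep(c(6, 2), length.out = n)
  top <- md_topology(rep("POPC", n), seq_len(n), rep("P", n), rep("P", n))
  coords <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    xy <- paths[, f, , drop = FALSE]
    dim(xy) <- c(n, 2)
    coords[, 1:2, f] <- xy - box[1:2][col(xy)] * floor(xy / box[1:2][col(xy)])
    coords[, 3, f] <- z
  }
  md_trajectory(top, coords, box, (seq_len(nf) - 1) * dt)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("whole-system drift unwraps to zero displacement", {
  n <- 8; nf <- 20
  paths <- array(0, c(n, nf, 2))
  base <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  for (f in seq_len(nf)) {
    paths[, f, 1] <- base[, 1] + 0.3 * (f - 1)
    paths[, f, 2] <- base[, 2] + 0.1 * (f - 1)
  }
  traj <- path_traj(paths)
  uw <- unwrap_lateral(traj, remove_drift = TRUE)
  expect_equal(uw$xy[, nf, ], uw$xy[, 1, ], tolerance = 1e-9)
  ## and MSD of a static-after-drift system is zero
  cv <- msd(uw, "POPC")
  expect_equal(max(abs(cv$msd)), 0, tolerance = 1e-18)
})

test_that("boundary-crossing walks unwrap to the stored generator path", {
  spec <- synthetic_spec(model = 5, n_lipids = 24, n_frames = 300, dt = 100,
                         diffusion = c(POPC = 8e-3, POPE = 8e-3),
                         detail = "minimal", with_solvent = FALSE,
                         box_xy = c(4, 4), seed = 19)
  sys <- generate_bilayer(spec)
  gt <- sys$ground_truth
  uw <- unwrap_lateral(sys$trajectory, remove_drift = FALSE)
  truth <- aperm(gt$unwrapped_xy, c(1, 3, 2))
  ## same paths up to the constant initial offset
  for (d in 1:2) {
    delta <- uw$xy[, , d] - truth[, , d]
    expect_lt(max(abs(sweep(delta, 1, delta[, 1]))), 1e-9)
  }
  ## wrapping did occur: some stored frame-to-frame jumps exceed half a box
  wrapped_x <- sys$trajectory$coords[, 1, ]
  expect_gt(sum(abs(diff(t(wrapped_x))) > 2), 0)
})

test_that("a single frame yields an empty displacement series", {
  paths <- array(runif(12), c(6, 1, 2))
  traj <- path_traj(paths)
  uw <- unwrap_lateral(traj)
  expect_equal(dim(uw$xy), c(6, 1, 2))
  expect_error(msd(uw, "POPC"), "2 frames")
})

test_that("half-box steps are reported as unwrap failures", {
  paths <- array(1, c(2, 3, 2))
  paths[2, , 1] <- c(2, 7, 7)     # a 5 nm step in a 10 nm box: ambiguous
  expect_error(unwrap_lateral(path_traj(paths, box = c(10, 10, 8))),
               class = "ommtraj_unwrap_error")
})

test_that("MSD closed forms: ballistic and static motion", {
  n <- 5; nf <- 30; v <- 0.004
  paths <- array(0, c(n, nf, 2))
  base <- cbind(seq_len(n), seq_len(n))
  for (f in seq_len(nf)) {
    paths[, f, 1] <- base[, 1] + v * (f - 1) * 100
    paths[, f, 2] <- base[, 2]
  }
  traj <- path_traj(paths)
  cv <- msd(traj, "POPC", remove_drift = FALSE)
  expect_equal(cv$msd, (v * cv$tau)^2, tolerance = 1e-9)
  cvs <- msd(path_traj(array(1, c(n, nf, 2))), "POPC", remove_drift = FALSE)
  expect_true(all(cvs$msd == 0))
})

test_that("vectorized multi-origin MSD equals the brute-force double loop", {
  set.seed(23)
  xy <- array(rnorm(10 * 50 * 2), c(10, 50, 2))
  res <- ommtraj:::msd_multi_origin(xy, lags = c(1, 5, 17, 25))
  for (k in seq_along(c(1, 5, 17, 25))) {
    lag <- c(1, 5, 17, 25)[k]
    expect_equal(res$msd[k], msd_oracle(xy, lag), tolerance = 1e-12)
  }
  ## origin stride subsamples origins
  res2 <- ommtraj:::msd_multi_origin(xy, lags = 5, origin_stride = 7L)
  origins <- seq(1, 45, by = 7)
  manual <- mean(sapply(origins, function(t0)
    mean(rowSums((xy[, t0 + 5, ] - xy[, t0, ])^2))))
  expect_equal(res2$msd, manual, tolerance = 1e-12)
})

test_that("diffusion fits recover exact linear MSD with zero error", {
  tau <- seq(0, 5000, by = 100)
  curve <- structure(data.frame(tau = tau, msd = 4 * 2e-3 * tau / 1000,
                                n_samples = 1),
                     class = c("msd_curve", "data.frame"))
  ft <- fit_diffusion(curve, fit_window = c(500, 4000))
  expect_equal(ft$D, 2e-3, tolerance = 1e-12)
  expect_equal(ft$error, 0, tolerance = 1e-12)
  ## a constant offset does not bias the slope (free intercept)
  curve$msd <- curve$msd + 0.37
  ft2 <- fit_diffusion(curve, fit_window = c(500, 4000))
  expect_equal(ft2$D, 2e-3, tolerance = 1e-12)
  expect_error(fit_diffusion(curve, fit_window = c(100, 400)),
               class = "ommtraj_fit_error")
})

test_that("rotational autocorrelation: frozen vectors and brute force", {
  v <- array(0, c(6, 40, 3))
  v[, , 3] <- 1
  attr(v, "times") <- (0:39) * 100
  raf <- rotational_autocorrelation(v)
  expect_true(all(raf$c1 == 1))
  ## brute-force equality on random unit vectors
  set.seed(29)
  w <- array(rnorm(8 * 30 * 3), c(8, 30, 3))
  for (f in 1:30) w[, f, ] <- w[, f, ] / sqrt(rowSums(w[, f, ]^2))
  attr(w, "times") <- (0:29) * 100
  raf2 <- rotational_autocorrelation(w, max_lag = 12)
  for (lag in c(1, 7, 12))
    expect_equal(raf2$c1[raf2$tau == lag * 100], c1_oracle(w, lag),
                 tolerance = 1e-12)
})

test_that("headgroup vectors come from the topology roles", {
  ## two POPE lipids with P->N along +z and +x
  traj <- make_frame_traj(
    species = rep("POPE", 4), molid = c(1, 1, 2, 2),
    roles = rep(c("P", "N"), 2), elements = rep(c("P", "N"), 2),
    coords = rbind(c(1, 1, 3), c(1, 1, 3.35),
                   c(3, 3, 3), c(3.35, 3, 3)),
    box = c(5, 5, 6), times = 0)
  v <- ommtraj:::headgroup_vectors(traj, "POPE")
  expect_equal(v[1, 1, ], c(0, 0, 1))
  expect_equal(v[2, 1, ], c(1, 0, 0))
  expect_error(ommtraj:::headgroup_vectors(traj, "WATER"),
               class = "ommtraj_role_error")
})

test_that("tilt histograms are leaflet-aware and solid-angle shaped", {
  ## all vectors along the outward normal in both leaflets -> all mass at 0
  coords <- rbind(c(1, 1, 6), c(1, 1, 6.35),    # upper: +z
                  c(3, 3, 2), c(3, 3, 1.65))    # lower: -z
  traj <- make_frame_traj(
    species = rep("POPE", 4), molid = c(1, 1, 2, 2),
    roles = rep(c("P", "N"), 2), elements = rep(c("P", "N"), 2),
    coords = coords, box = c(5, 5, 8), times = 0)
  h <- pn_tilt_distribution(traj, "POPE")
  expect_equal(sum(h$density[h$angle > 4]), 0)
  ## isotropic vectors follow sin(theta)
  set.seed(31)
  n <- 4000
  u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  p <- cbind(runif(n, 0, 20), runif(n, 0, 20), 10)
  coords <- matrix(0, 2 * n, 3)
  coords[seq(1, 2 * n, 2), ] <- p
  coords[seq(2, 2 * n, 2), ] <- p + 0.35 * u
  suppressWarnings(traj2 <- assign_leaflets(make_frame_traj(
    species = rep("POPE", 2 * n), molid = rep(seq_len(n), each = 2),
    roles = rep(c("P", "N"), n), elements = rep(c("P", "N"), n),
    coords = coords, box = c(20, 20, 20), times = 0)))
  h2 <- pn_tilt_distribution(traj2, "POPE", breaks = seq(0, 180, 10))
  expected <- sin(h2$angle * pi / 180)
  expected <- expected / sum(expected * 10)
  expect_lt(max(abs(h2$density - expected)), 0.002)
})
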