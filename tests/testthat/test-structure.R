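test_that("area per lipid is box area over lipids per leaflet", {
  xyz <- rbind(cbind(1:392, 1, 6), cbind(1:392, 1, 2))
  traj <- phosphate_traj(xyz, box = c(15.6, 15.6, 9),
                         times = c(0, 100, 200))
  apl <- area_per_lipid(traj)
  expect_equal(apl$mean, 15.6 * 15.6 / 392, tolerance = 1e-12)
  expect_equal(apl$sd, 0)
  ## box series with a known mean
  traj$box[, 1] <- c(15.5, 15.6, 15.7)
  apl2 <- area_per_lipid(traj)
  expect_equal(apl2$mean, mean(traj$box[, 1] * 15.6) / 392,
               tolerance = 1e-12)
  expect_true(apl2$mean >= min(apl2$series) && apl2$mean <= max(apl2$series))
})

test_that("unequal leaflets are rejected with guidance", {
  xyz <- rbind(cbind(1:3, 1, 6), cbind(1:5, 1, 2))
  traj <- phosphate_traj(xyz, box = c(5, 5, 9))
  expect_error(area_per_lipid(traj), "per-leaflet")
})

test_that("density profiles conserve counts and resolve delta peaks", {
  xyz <- rbind(cbind(1:10, 1, 6), cbind(1:10, 1, 2))   # peaks 4 nm apart
  traj <- phosphate_traj(xyz, box = c(10, 10, 10))
  prof <- density_profile(traj, "POPC", role = "P", bin_width = 0.02)
  integral <- sum(prof$density) * prof$bin_width * prof$mean_area
  expect_equal(integral, 20, tolerance = 1e-6)
  expect_equal(bilayer_thickness(prof), 4, tolerance = 1e-9)
  expect_error(density_profile(traj, "POPS"),
               class = "ommtraj_empty_selection")
  expect_error(density_profile(traj, "POPC", bin_width = 0), "positive")
})

test_that("a uniform slab yields a flat profile within counting noise", {
  set.seed(3)
  n <- 4000
  xyz <- cbind(runif(n, 0, 5), runif(n, 0, 5), runif(n, 0, 5))
  ## two phosphates define the midplane; the slab is the selection
  xyz <- rbind(cbind(2.5, 2.5, 3.5), cbind(2.5, 2.5, 1.5), xyz)
  traj <- phosphate_traj(xyz, box = c(5, 5, 5))
  prof <- density_profile(traj, selection = 2 + seq_len(n),
                          bin_width = 0.25)
  inside <- abs(prof$z) < 2                # away from the wrap edge
  d <- prof$density[inside]
  expect_lt(stats::sd(d) / mean(d), 0.2)   # Poisson noise at ~200/bin
})

test_that("thickness interpolates Gaussian peaks and ignores peak heights", {
  set.seed(5)
  n <- 6000
  z <- c(rnorm(n, 2.03, 0.15), rnorm(n / 2, -2.03, 0.15))  # asymmetric
  xyz <- cbind(runif(length(z), 0, 12), runif(length(z), 0, 12), z + 4)
  traj <- phosphate_traj(xyz, box = c(12, 12, 8))
  prof <- density_profile(traj, "POPC", role = "P", bin_width = 0.02)
  expect_lt(abs(bilayer_thickness(prof) - 4.06), 0.02)
  expect_error(bilayer_thickness(
    structure(list(z = seq(-1, 1, 0.02),
                   density = c(rep(0, 50), rep(1, 51)),
                   bin_width = 0.02), class = "density_profile")),
    class = "ommtraj_degenerate_profile")
})

test_that("S_CD hits its analytic limits", {
  r <- default_species(1)      # single-carbon chain, one labelled hydrogen
  r$POPC$sn1_carbons <- list(C2 = "H2A")
  along_z <- scd_limit_traj(c(0, 0, 0.109))
  in_plane <- scd_limit_traj(c(0.109, 0, 0))
  attr(along_z$topology, "registry") <- r
  attr(in_plane$topology, "registry") <- r
  expect_equal(order_parameter_scd(along_z, "POPC")$scd, 1)
  expect_equal(order_parameter_scd(in_plane, "POPC")$scd, -0.5)
})

test_that("isotropic C-H orientations give S_CD near zero", {
  set.seed(7)
  n <- 200; nfr <- 50
  r <- default_species(1)
  r$POPC$sn1_carbons <- list(C2 = "H2A")
  top <- md_topology(rep("POPC", 2 * n), rep(seq_len(n), each = 2),
                     rep(c("C2", "H2A"), n), rep(c("C", "H"), n),
                     registry = r)
  coords <- array(0, c(2 * n, 3, nfr))
  base <- cbind(runif(n, 0, 5), runif(n, 0, 5), 3)
  for (f in seq_len(nfr)) {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    coords[seq(1, 2 * n, 2), , f] <- base
    coords[seq(2, 2 * n, 2), , f] <- base + 0.109 * u
  }
  traj <- md_trajectory(top, coords, c(5, 5, 6), (0:(nfr - 1)) * 100)
  expect_lt(abs(order_parameter_scd(traj, "POPC")$scd), 0.01)
})

test_that("structural metrics are invariant to translation and z rotation", {
  spec <- synthetic_spec(model = 2, n_lipids = 60, n_frames = 5, seed = 17,
                         with_solvent = FALSE)
  sys <- generate_bilayer(spec)
  traj <- sys$trajectory
  scd0 <- order_parameter_scd(traj, "POPC")$scd
  apl0 <- area_per_lipid(traj)$mean
  lipids <- c("POPC", "POPE", "POPS", "PIP2")
  prof0 <- bilayer_thickness(density_profile(traj, lipids, role = "P"))
  ## rigid translation
  tr2 <- traj
  tr2$coords <- tr2$coords + 0.37
  expect_equal(order_parameter_scd(tr2, "POPC")$scd, scd0)
  expect_equal(area_per_lipid(tr2)$mean, apl0)
  expect_equal(bilayer_thickness(density_profile(tr2,
    c("POPC", "POPE", "POPS", "PIP2"), role = "P")), prof0,
    tolerance = 1e-9)
  ## rotation about z
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  tr3 <- traj
  for (f in 1:5) tr3$coords[, 1:2, f] <- tr3$coords[, 1:2, f] %*% t(R)
  expect_equal(order_parameter_scd(tr3, "POPC")$scd, scd0, tolerance = 1e-12)
})
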