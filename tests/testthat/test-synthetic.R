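test_that("the generator is deterministic under its seed", {
  spec <- synthetic_spec(model = 2, n_lipids = 40, n_frames = 5, seed = 9,
                         n_salt_pairs = 2, na_bound_per_lipid = 0.1)
  a <- generate_bilayer(spec)
  b <- generate_bilayer(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  spec2 <- spec; spec2$seed <- 10L
  c <- generate_bilayer(spec2)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
  ## seed change keeps the composition
  expect_identical(a$ground_truth$composition$counts,
                   c$ground_truth$composition$counts)
})

test_that("zero diffusion gives static lateral positions", {
  spec <- synthetic_spec(model = 5, n_lipids = 16, n_frames = 10, seed = 1,
                         diffusion = c(POPC = 0, POPE = 0),
                         detail = "minimal", with_solvent = FALSE)
  lat <- generate_lateral_positions(spec)
  expect_equal(lat$unwrapped[, , 10], lat$unwrapped[, , 1])
})

test_that("generated Brownian walks recover their diffusion coefficient", {
  spec <- synthetic_spec(model = 5, n_lipids = 392, n_frames = 400,
                         dt = 100, diffusion = c(POPC = 5e-3, POPE = 5e-3),
                         detail = "minimal", with_solvent = FALSE, seed = 21)
  lat <- generate_lateral_positions(spec)
  ## ensemble MSD at a quarter of the run against 4 D tau
  xy <- aperm(lat$unwrapped, c(1, 3, 2))
  for (lag in c(25, 50, 100)) {
    disp2 <- (xy[, 1 + lag, 1] - xy[, 1, 1])^2 +
      (xy[, 1 + lag, 2] - xy[, 1, 2])^2
    expected <- 4 * 5e-3 * lag * 0.1       # nm^2, tau in ns
    se <- stats::sd(disp2) / sqrt(length(disp2))
    expect_lt(abs(mean(disp2) - expected), 3 * se)
  }
})

test_that("rotational generator limits: frozen, planar, diffusive", {
  spec0 <- synthetic_spec(model = 5, n_lipids = 24, n_frames = 20, seed = 4,
                          rot_diffusion = c(POPC = 0, POPE = 0),
                          detail = "minimal", with_solvent = FALSE)
  hv <- generate_headgroup_vectors(spec0)
  expect_equal(hv$vectors[, , 20], hv$vectors[, , 1])
  ## planar rotor: C1(tau) = cos(omega tau)
  specp <- synthetic_spec(model = 5, n_lipids = 10, n_frames = 40, dt = 100,
                          detail = "minimal", with_solvent = FALSE, seed = 5)
  hvp <- generate_headgroup_vectors(specp, mode = "planar", omega = 2)
  v <- aperm(hvp$vectors, c(1, 3, 2))
  attr(v, "times") <- (0:39) * 100
  raf <- rotational_autocorrelation(v, max_lag = 20)
  expect_equal(raf$c1, cos(2 * raf$tau / 1000), tolerance = 1e-10)
})

test_that("spherical diffusion decays at 2 D_r within three standard errors", {
  spec <- synthetic_spec(model = 5, n_lipids = 300, n_frames = 60, dt = 100,
                         rot_diffusion = c(POPC = 0.5, POPE = 0.5),
                         detail = "minimal", with_solvent = FALSE, seed = 6)
  hv <- generate_headgroup_vectors(spec)
  v <- aperm(hv$vectors, c(1, 3, 2))
  ## C1 at selected lags <= 1/(2 Dr): mean dot from origin 1
  for (lag in c(5, 10)) {
    dots <- rowSums(v[, 1, ] * v[, 1 + lag, ])
    expected <- exp(-2 * 0.5 * lag * 0.1)
    se <- stats::sd(dots) / sqrt(length(dots))
    expect_lt(abs(mean(dots) - expected), 3 * se)
  }
})

test_that("tail orientations hit the order-parameter limits exactly", {
  expect_equal(ommtraj:::scd_vectors(1, 5)[, 3]^2, rep(1, 5))
  v <- ommtraj:::scd_vectors(-0.5, 5)
  expect_equal(v[, 3], rep(0, 5))
  expect_error(ommtraj:::scd_vectors(1.2, 5), class = "ommtraj_domain_error")
  ## Monte-Carlo convergence at the target
  set.seed(11)
  v <- ommtraj:::scd_vectors(0.2, 2e5)
  expect_lt(abs(mean(1.5 * v[, 3]^2 - 0.5) - 0.2), 0.01)
})

test_that("z structure recovers the prescribed peak separation", {
  spec <- synthetic_spec(model = 2, n_lipids = 200, seed = 13,
                         detail = "minimal", with_solvent = FALSE)
  zs <- generate_z_structure(spec)
  up <- zs$z_phosphate[zs$leaflet == "upper"]
  lo <- zs$z_phosphate[zs$leaflet == "lower"]
  expect_lt(abs(mean(up) - 4.13 / 2), 3 * 0.15 / sqrt(length(up)))
  expect_lt(abs(mean(lo) + 4.13 / 2), 3 * 0.15 / sqrt(length(lo)))
})

test_that("charge bookkeeping neutralizes exactly on request", {
  spec <- synthetic_spec(model = 2, n_lipids = 100, n_frames = 1, seed = 2,
                         n_salt_pairs = 7)
  sys <- generate_bilayer(spec)
  gt <- sys$ground_truth
  expect_equal(gt$total_lipid_charge + gt$n_na - gt$n_cl, 0)
})

test_that("spec validation catches configuration errors", {
  expect_error(synthetic_spec(model = 2, diffusion = c(POPC = -1)),
               class = "ommtraj_config_error")
  expect_error(synthetic_spec(model = 2, n_lipids = 100, dt = 1e9),
               class = "ommtraj_config_error")
  expect_error(synthetic_spec(model = 2, na_multiplicity = 5),
               class = "ommtraj_config_error")
  expect_error(synthetic_spec(model = 2,
                              scd_targets = list(POPC = c(2, 0.2))),
               class = "ommtraj_domain_error")
  expect_error(
    generate_bilayer(synthetic_spec(model = 2, n_lipids = 100, n_frames = 1,
                                    n_salt_pairs = 0, neutralize = FALSE,
                                    na_bound_per_lipid = 0.9)),
    class = "ommtraj_config_error")
})

test_that("YAML specs round trip through read_synthetic_spec", {
  spec <- read_synthetic_spec(system.file("extdata", "model2_spec.yaml",
                                          package = "ommtraj"))
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(spec$composition$n_total, 784L)
  expect_equal(spec$d_pp, 4.13)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model: 2", "bogus_field: 1"), f)
  expect_error(read_synthetic_spec(f), class = "ommtraj_config_error")
})

test_that("a generated system passes the core invariants and writes files", {
  spec <- synthetic_spec(model = 2, n_lipids = 60, n_frames = 3, seed = 8,
                         n_salt_pairs = 3, na_bound_per_lipid = 0.1)
  sys <- generate_bilayer(spec)
  traj <- sys$trajectory
  expect_true(all(is.finite(traj$coords)))
  expect_true(all(diff(traj$times) > 0))
  expect_true(all(traj$box > 0))
  ## every lipid molecule has every role of its species
  top <- traj$topology
  reg <- default_species()
  for (s in c("POPC", "POPE", "POPS", "PIP2")) {
    mols <- unique(top$molid[top$species == s])
    if (!length(mols)) next
    per_mol <- table(top$molid[top$species == s])
    expect_true(all(per_mol == length(reg[[s]]$roles)))
  }
  out <- withr::local_tempdir()
  paths <- generate_bilayer_files(spec, out)
  expect_true(file.exists(paths$trajectory))
  gt <- jsonlite::read_json(paths$ground_truth)
  expect_equal(gt$seed, 8L)
  st <- read_structure(paths$trajectory)
  expect_equal(nrow(st$topology), nrow(top))
})
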