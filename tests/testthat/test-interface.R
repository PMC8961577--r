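## one POPE donor (N-H) and one POPC acceptor oxygen at a chosen geometry
donor_acceptor_traj <- function(d_da = 0.30, angle_deg = 0, box = c(5, 5, 5)) {
  n <- c(1, 1, 1)
  th <- angle_deg * pi / 180
  h <- n + 0.10 * c(cos(th), sin(th), 0)
  a <- n + d_da * c(1, 0, 0)             # D-A along +x
  make_frame_traj(
    species = c("POPE", "POPE", "POPC"), molid = c(1, 1, 2),
    roles = c("N", "HN1", "OP1"), elements = c("N", "H", "O"),
    coords = rbind(n, h, a), box = box)
}

test_that("hydrogen-bond criteria: distance and angle boundaries", {
  expect_equal(nrow(find_hbonds(donor_acceptor_traj(0.30, 0))), 1L)
  expect_equal(nrow(find_hbonds(donor_acceptor_traj(0.36, 0))), 0L)
  expect_equal(nrow(find_hbonds(donor_acceptor_traj(0.30, 40))), 0L)
  expect_equal(nrow(find_hbonds(donor_acceptor_traj(0.30, 34.9))), 1L)
  hb <- find_hbonds(donor_acceptor_traj(0.30, 10))
  expect_equal(hb$angle, 10, tolerance = 1e-9)
  expect_equal(hb$dist, 0.30, tolerance = 1e-9)
})

test_that("pairs split across the periodic boundary are found", {
  tr <- make_frame_traj(
    species = c("POPE", "POPE", "POPC"), molid = c(1, 1, 2),
    roles = c("N", "HN1", "OP1"), elements = c("N", "H", "O"),
    coords = rbind(c(0.1, 2, 2), c(0.02, 2, 2), c(4.9, 2, 2)),
    box = c(5, 5, 5))
  hb <- find_hbonds(tr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dist, 0.2, tolerance = 1e-9)
})

test_that("neighbor-searched H-bonds equal the 27-image all-pairs oracle", {
  spec <- synthetic_spec(model = 2, n_lipids = 40, n_frames = 1, seed = 37,
                         n_salt_pairs = 5, na_bound_per_lipid = 0.2)
  sys <- generate_bilayer(spec)
  hb_cell <- find_hbonds(sys$trajectory, method = "cell")
  hb_brute <- find_hbonds(sys$trajectory, method = "brute")
  expect_equal(hb_cell, hb_brute)
  ## explicit 27-image enumeration on a smaller snapshot
  spec2 <- synthetic_spec(model = 2, n_lipids = 8, n_frames = 1, seed = 38,
                          waters_per_lipid = c(POPC = 2, POPE = 2,
                                               POPS = 2, PIP2 = 2),
                          n_salt_pairs = 2, na_bound_per_lipid = 0.25,
                          chargepairs_per_popc = 0)
  sys2 <- generate_bilayer(spec2)
  hb <- find_hbonds(sys2$trajectory)
  oracle <- hbond_oracle(sys2$trajectory)
  expect_equal(nrow(hb), nrow(oracle))
  expect_equal(sort(paste(hb$d, hb$a)), sort(paste(oracle$d, oracle$a)))
})

test_that("multiple in-range hydrogens yield a single best-H bond", {
  n <- c(1, 1, 1)
  tr <- make_frame_traj(
    species = c("POPE", "POPE", "POPE", "POPE", "POPC"),
    molid = c(1, 1, 1, 1, 2),
    roles = c("N", "HN1", "HN2", "HN3", "OP1"),
    elements = c("N", "H", "H", "H", "O"),
    coords = rbind(n, n + c(0.1, 0, 0), n + c(0.098, 0.02, 0),
                   n + c(0, 0, 0.1), n + c(0.3, 0, 0)),
    box = c(5, 5, 5))
  hb <- find_hbonds(tr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 0, tolerance = 1e-9)
})

test_that("water hydration counts recover the constructed geometry", {
  spec <- synthetic_spec(model = 2, n_lipids = 100, n_frames = 1, seed = 41,
                         waters_per_lipid = c(POPC = 3, POPE = 5, POPS = 2,
                                              PIP2 = 7),
                         n_salt_pairs = 0, na_bound_per_lipid = 0)
  sys <- generate_bilayer(spec)
  hyd <- water_hbonds_per_lipid(sys$trajectory, skip_ns = 0)
  expect_equal(hyd, c(POPC = 3, POPE = 5, POPS = 2, PIP2 = 7))
  ## each constructed water donates exactly one bond, so counting distinct
  ## waters gives the same result
  hydw <- water_hbonds_per_lipid(sys$trajectory, skip_ns = 0,
                                 count = "waters")
  expect_equal(hydw, hyd)
})

test_that("no waters or distant waters give zero hydration", {
  spec <- synthetic_spec(model = 5, n_lipids = 20, n_frames = 1, seed = 2,
                         with_solvent = FALSE)
  sys <- generate_bilayer(spec)
  hyd <- water_hbonds_per_lipid(sys$trajectory, skip_ns = 0)
  expect_true(all(hyd == 0))
  ## a lone water beyond the cutoff
  tr <- make_frame_traj(
    species = c("POPE", "POPE", "WATER", "WATER", "WATER"),
    molid = c(1, 1, 2, 2, 2),
    roles = c("N", "HN1", "OW", "HW1", "HW2"),
    elements = c("N", "H", "O", "H", "H"),
    coords = rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.4, 1, 1),
                   c(1.3, 1, 1), c(1.5, 1, 1)),
    box = c(5, 5, 5))
  expect_equal(unname(water_hbonds_per_lipid(tr, skip_ns = 0)["POPE"]), 0)
})

test_that("the lipid-lipid matrix attributes bonds to donors, All = row sum", {
  ## two POPE molecules donor->acceptor, plus far-apart spectators
  tr <- make_frame_traj(
    species = c("POPE", "POPE", "POPE", "POPE", "POPE", "POPE"),
    molid = c(1, 1, 2, 3, 3, 4),
    roles = c("N", "HN1", "OP1", "N", "HN1", "OP1"),
    elements = c("N", "H", "O", "N", "H", "O"),
    coords = rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.3, 1, 1),
                   c(3, 3, 3), c(3.1, 3, 3), c(4.4, 4.4, 4.4)),
    box = c(6, 6, 6))
  m <- lipid_lipid_hbond_matrix(tr, skip_ns = 0)
  expect_equal(m["POPE", "POPE"], 1 / 4)   # one bond over four POPE
  expect_equal(m["POPE", "All"], sum(m["POPE", colnames(m) != "All"]))
  ## all-far-apart systems give zeros
  spec <- synthetic_spec(model = 2, n_lipids = 60, n_frames = 1, seed = 3,
                         with_solvent = FALSE)
  m0 <- lipid_lipid_hbond_matrix(generate_bilayer(spec)$trajectory,
                                 skip_ns = 0)
  expect_true(all(m0 == 0))
})

test_that("expected H-bond counts follow mole fractions", {
  f2 <- c(POPC = 0.57, POPE = 0.31, POPS = 0.02, PIP2 = 0.10)
  e <- expected_hbonds(1.34, f2)
  expect_equal(unname(e), c(0.76, 0.42, 0.03, 0.13))
  expect_equal(unname(expected_hbonds(1.57,
    c(POPC = 0.50, POPE = 0.24, POPS = 0.20, PIP2 = 0.06))["POPE"]), 0.38)
  ## single-species membrane: expected equals the observed total
  expect_equal(unname(expected_hbonds(1.02, c(POPE = 1))), 1.02)
  ## donor-restricted normalization (POPC row of a 4-species mixture)
  e2 <- expected_hbonds(0.27, f2[c("POPE", "POPS", "PIP2")])
  expect_equal(unname(e2), c(0.19, 0.01, 0.06))
  ## unrounded values sum to the observed total
  expect_equal(sum(expected_hbonds(1.34, f2, digits = NULL)), 1.34)
})

test_that("charge pairs obey the Me-O cutoff and the brute-force oracle", {
  mk <- function(d) make_frame_traj(
    species = c("POPC", "POPS"), molid = c(1, 2),
    roles = c("ME1", "OCA"), elements = c("C", "O"),
    coords = rbind(c(1, 1, 1), c(1 + d, 1, 1)), box = c(5, 5, 5))
  expect_equal(unname(charge_pairs(mk(0.35), skip_ns = 0)$per_popc["All"]), 1)
  expect_equal(unname(charge_pairs(mk(0.45), skip_ns = 0)$per_popc["All"]), 0)
  ## replicated motif scales linearly and cell equals brute
  spec <- synthetic_spec(model = 2, n_lipids = 80, n_frames = 1, seed = 43,
                         n_salt_pairs = 0, na_bound_per_lipid = 0)
  sys <- generate_bilayer(spec)
  cp_cell <- charge_pairs(sys$trajectory, skip_ns = 0, method = "cell")
  cp_brute <- charge_pairs(sys$trajectory, skip_ns = 0, method = "brute")
  expect_equal(cp_cell, cp_brute)
  expect_equal(unname(cp_cell$per_popc[["All"]]), 1)
})

test_that("sodium contacts report binding, multiplicity and carbonyls", {
  ## one Na at 0.30 nm from three oxygens of one POPE
  base <- c(2, 2, 2)
  tr <- make_frame_traj(
    species = c("POPE", "POPE", "POPE", "POPE", "NA", "NA"),
    molid = c(1, 1, 1, 1, 2, 3),
    roles = c("P", "OP2", "OC1", "OC2", "NA", "NA"),
    elements = c("P", "O", "O", "O", "NA", "NA"),
    coords = rbind(base + c(0, 0, 0.5), base + c(0.3, 0, 0),
                   base + c(-0.3, 0, 0), base + c(0, 0.3, 0),
                   base, base + c(2, 2, 0)),
    box = c(6, 6, 6))
  ion <- sodium_contacts(tr, skip_ns = 0)
  expect_equal(ion$n_bound, 1)
  expect_equal(ion$multiplicity, 3)
  expect_equal(ion$bound_per_lipid, 1)        # one lipid in the system
  expect_equal(ion$carbonyl_bound_per_lipid, 1)
  ## beyond the cutoff: not bound
  tr2 <- make_frame_traj(
    species = c("POPE", "NA"), molid = c(1, 2),
    roles = c("OP2", "NA"), elements = c("O", "NA"),
    coords = rbind(c(1, 1, 1), c(1.34, 1, 1)), box = c(5, 5, 5))
  expect_equal(sodium_contacts(tr2, skip_ns = 0)$n_bound, 0)
})

test_that("generator ion-contact targets are recovered exactly", {
  spec <- synthetic_spec(model = 2, n_lipids = 80, n_frames = 1, seed = 47,
                         na_bound_per_lipid = 0.25, na_multiplicity = 3,
                         n_salt_pairs = 10)
  sys <- generate_bilayer(spec)
  ion <- sodium_contacts(sys$trajectory, skip_ns = 0)
  expect_equal(ion$bound_per_lipid, 0.25)
  expect_equal(ion$multiplicity, 3)
  ion_b <- sodium_contacts(sys$trajectory, skip_ns = 0, method = "brute")
  expect_equal(ion, ion_b)
})
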