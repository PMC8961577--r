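## Fixture builders and independent oracles used across the test files.

## minimal one-atom-per-lipid trajectory: phosphates at given coordinates
phosphate_traj <- function(xyz, box, times = 0, species = "POPC") {
  n <- nrow(xyz)
  top <- md_topology(species = rep_len(species, n), molid = seq_len(n),
                     role = rep("P", n), element = rep("P", n))
  nf <- length(times)
  coords <- array(rep(as.numeric(t(xyz)), nf), c(3, n, nf))
  coords <- aperm(coords, c(2, 1, 3))
  md_trajectory(top, coords, box, times)
}

## a tiny hand-built frame with arbitrary species/roles
make_frame_traj <- function(species, roles, elements, molid, coords, box,
                            times = 0) {
  top <- md_topology(species = species, molid = molid, role = roles,
                     element = elements)
  nf <- length(times)
  cc <- array(0, c(nrow(coords), 3, nf))
  for (f in seq_len(nf)) cc[, , f] <- coords
  md_trajectory(top, cc, box, times)
}

## two POPC lipids, one sn1 carbon with one labelled hydrogen each,
## C-H bond along a chosen offset
scd_limit_traj <- function(h_offset) {
  make_frame_traj(
    species = rep("POPC", 4), molid = c(1, 1, 2, 2),
    roles = rep(c("C2", "H2A"), 2), elements = rep(c("C", "H"), 2),
    coords = rbind(c(1, 1, 3), c(1, 1, 3) + h_offset,
                   c(2, 2, 3), c(2, 2, 3) + h_offset),
    box = c(5, 5, 6))
}

## brute-force minimum image: smallest displacement over all images within
## a given shift radius (27 images for r = 1, enough for in-box points;
## wider r covers displacements several boxes long)
min_image_27 <- function(v, box, r = 1L) {
  shifts <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  imgs <- sweep(shifts, 2, box, `*`) + matrix(v, nrow(shifts), 3,
                                              byrow = TRUE)
  unname(imgs[which.min(rowSums(imgs^2)), ])
}

## brute-force hydrogen-bond enumeration over 27 periodic images
hbond_oracle <- function(traj, frame = 1, d_max = 0.35, ang_max = 35,
                         exclude_intra = TRUE) {
  top <- traj$topology
  reg <- ommtraj::default_species()
  x <- traj$coords[, , frame]
  box <- traj$box[frame, ]
  res <- list()
  for (ds in unique(top$species)) {
    for (pair in reg[[ds]]$donor_atoms) {
      dsel <- which(top$species == ds & top$role == pair[1])
      hsel <- which(top$species == ds & top$role == pair[2])
      hsel <- hsel[match(top$molid[dsel], top$molid[hsel])]
      for (k in seq_along(dsel)) {
        for (as_ in unique(top$species)) {
          acc <- which(top$species == as_ &
                         top$role %in% reg[[as_]]$acceptor_atoms)
          for (a in acc) {
            if (a == dsel[k]) next
            if (exclude_intra && top$molid[a] == top$molid[dsel[k]]) next
            vda <- min_image_27(x[a, ] - x[dsel[k], ], box)
            if (sqrt(sum(vda^2)) >= d_max) next
            vdh <- min_image_27(x[hsel[k], ] - x[dsel[k], ], box)
            cosang <- sum(vda * vdh) / sqrt(sum(vda^2) * sum(vdh^2))
            ang <- acos(min(1, max(-1, cosang))) * 180 / pi
            if (ang < ang_max)
              res[[length(res) + 1L]] <- data.frame(
                d = dsel[k], h = hsel[k], a = a, angle = ang)
          }
        }
      }
    }
  }
  if (!length(res)) return(data.frame(d = integer(), h = integer(),
                                      a = integer(), angle = numeric()))
  out <- do.call(rbind, res)
  ## best hydrogen per (D, A) pair
  out <- out[order(out$d, out$a, out$angle), ]
  out[!duplicated(paste(out$d, out$a)), ]
}

## brute-force multi-origin MSD: explicit loops over molecules and origins
msd_oracle <- function(xy, lag) {
  nf <- dim(xy)[2]
  tot <- 0; n <- 0L
  for (m in seq_len(dim(xy)[1])) {
    for (t0 in seq_len(nf - lag)) {
      d <- xy[m, t0 + lag, ] - xy[m, t0, ]
      tot <- tot + sum(d^2)
      n <- n + 1L
    }
  }
  tot / n
}

## brute-force multi-origin C1
c1_oracle <- function(v, lag) {
  nf <- dim(v)[2]
  tot <- 0; n <- 0L
  for (m in seq_len(dim(v)[1])) {
    for (t0 in seq_len(nf - lag)) {
      tot <- tot + sum(v[m, t0, ] * v[m, t0 + lag, ])
      n <- n + 1L
    }
  }
  tot / n
}

## minimal CHARMM-style DCD writer (orthorhombic cell per frame), enough
## for bio3d::read.dcd; used to exercise the DCD reader path
write_minimal_dcd <- function(path, coords_nm, box_nm) {
  nf <- dim(coords_nm)[3]
  natom <- dim(coords_nm)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    tmp <- raw(0)
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf          # NSET
  icntrl[2] <- 1L          # ISTART
  icntrl[3] <- 1L          # NSAVC
  icntrl[11] <- 1L         # crystal cell present
  icntrl[20] <- 24L        # CHARMM version
  rec(function(c.) {
    writeChar("CORD", c., nchars = 4, eos = NULL)
    writeBin(icntrl, c., size = 4L)
  })
  rec(function(c.) {
    writeBin(1L, c., size = 4L)
    writeChar(sprintf("%-80s", "ommtraj test dcd"), c., nchars = 80,
              eos = NULL)
  })
  rec(function(c.) writeBin(natom, c., size = 4L))
  for (f in seq_len(nf)) {
    b <- box_nm * 10
    ## XTLABC order with cosines of the cell angles (orthorhombic: 0)
    rec(function(c.) writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])),
                              c., size = 8L))
    for (dim in 1:3)
      rec(function(c.) writeBin(as.double(coords_nm[, dim, f] * 10), c.,
                                size = 4L))
  }
  invisible(path)
}

## text of a 3-atom single-water GRO file (coordinates in nm)
water_gro_text <- function() {
  c("single water",
    "    3",
    "    1WATER   OW    1   1.000   1.000   1.000",
    "    1WATER  HW1    2   1.070   1.000   1.030",
    "    1WATER  HW2    3   0.930   1.000   1.030",
    "   3.00000   3.00000   3.00000")
}
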