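test_that("contact function hits its midpoint, tails, and symmetry exactly", {
  expect_identical(pair_contact(4), 0.5)
  expect_lt(pair_contact(100), 1e-100)
  expect_equal(pair_contact(0), 1 / (1 + exp(-20)), tolerance = 1e-15)
  for (delta in c(0.5, 1, 2))
    expect_equal(pair_contact(4 - delta) + pair_contact(4 + delta), 1,
                 tolerance = 1e-15)
  d <- seq(0, 12, by = 0.25)
  expect_true(all(diff(pair_contact(d)) < 0))
  expect_true(all(pair_contact(d) > 0 & pair_contact(d) < 1))
})

test_that("contact numbers average frames and match a nested-loop oracle", {
  # single frame, 1-atom residues at exactly 4 A
  one <- helix_trajectory(list(list(
    A = matrix(c(0, 0, 0), 1L), B = matrix(c(4, 0, 0), 1L))))
  expect_equal(contact_number(one, "A", "B"), 0.5, tolerance = 1e-15)

  # two frames: the result is the mean of the per-frame sums
  two <- helix_trajectory(list(
    list(A = matrix(c(0, 0, 0), 1L), B = matrix(c(3, 0, 0), 1L)),
    list(A = matrix(c(0, 0, 0), 1L), B = matrix(c(5, 0, 0), 1L))))
  expect_equal(contact_number(two, "A", "B"),
               (pair_contact(3) + pair_contact(5)) / 2, tolerance = 1e-15)

  # random 5-atom residues over 10 frames vs brute force
  traj <- random_trajectory(n_res = 2L, n_atoms = 5L, n_frames = 10L)
  oracle <- mean(vapply(traj$frames, function(f) {
    s <- 0
    for (k in seq_len(nrow(f$R1)))
      for (l in seq_len(nrow(f$R2)))
        s <- s + 1 / (1 + exp(5 * (sqrt(sum((f$R1[k, ] - f$R2[l, ])^2)) - 4)))
    s
  }, numeric(1)))
  expect_equal(contact_number(traj, "R1", "R2"), oracle, tolerance = 1e-12)
  # symmetry
  expect_equal(contact_number(traj, "R1", "R2"),
               contact_number(traj, "R2", "R1"), tolerance = 1e-15)
})

test_that("minimum-image distances apply only when a box is given", {
  frame <- list(A = matrix(c(0.5, 0, 0), 1L), B = matrix(c(9.5, 0, 0), 1L))
  no_box <- helix_trajectory(list(frame))
  boxed <- helix_trajectory(list(frame), box = c(10, 10, 10))
  expect_equal(contact_number(no_box, "A", "B"), pair_contact(9),
               tolerance = 1e-15)
  expect_equal(contact_number(boxed, "A", "B"), pair_contact(1),
               tolerance = 1e-15)
})

test_that("missing residues are reported with frame and residue", {
  traj <- random_trajectory()
  expect_error(contact_number(traj, "R1", "R9"), "R9")
})

test_that("coincident and far-apart limits of the contact sum", {
  far <- helix_trajectory(list(list(
    A = matrix(runif(9), 3L), B = matrix(runif(9) + 500, 3L))))
  expect_lt(contact_number(far, "A", "B"), 1e-100)
  same <- matrix(rep(c(1, 2, 3), each = 4), 4L)
  coin <- helix_trajectory(list(list(A = same, B = same)))
  expect_equal(contact_number(coin, "A", "B"),
               16 * (1 / (1 + exp(-20))), tolerance = 1e-6)
})

test_that("tilt recovers known rotations of an ideal helix within a degree", {
  h <- ideal_helix(30L)
  expect_lt(tilt_angle(h), 1)
  for (th in c(15, 30, 45)) {
    rot <- h %*% t(rotation_matrix(th, "x"))
    expect_equal(tilt_angle(rot), th, tolerance = 1)
  }
})

test_that("tilt is invariant to translation and axis reflection", {
  h <- ideal_helix(25L, axis = c(1, 0, 2))
  t0 <- tilt_angle(h)
  expect_equal(tilt_angle(sweep(h, 2L, c(10, -3, 7), `+`)), t0,
               tolerance = 1e-9)
  expect_equal(tilt_angle(-h), t0, tolerance = 1e-9)
  expect_true(t0 >= 0 && t0 <= 90)
})

test_that("tilt matches an independent eigen-decomposition oracle", {
  set.seed(55)
  for (rep in 1:10) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    cloud <- outer(rnorm(80, 0, 10), axis) +
      matrix(rnorm(240, 0, 0.8), 80L, 3L)
    # oracle: principal axis via SVD of the centered cloud
    ctr <- sweep(cloud, 2L, colMeans(cloud))
    v1 <- svd(ctr)$v[, 1L]
    want <- acos(min(1, abs(v1[3L]))) * 180 / pi
    expect_equal(tilt_angle(cloud), want, tolerance = 1e-9)
  }
})

test_that("a near-isotropic cloud warns that the axis is ill-defined", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_warning(tilt_angle(cube), "ill-defined")
})

test_that("tilt distributions honor stride and report per-frame angles", {
  mk <- function(th) list(H = ideal_helix(20L) %*% t(rotation_matrix(th, "x")))
  traj <- helix_trajectory(rep(list(mk(10), mk(40)), 6L))
  td <- tilt_distribution(traj)
  expect_length(td$angles, 12L)
  # a finite helix's principal axis deviates from the ideal axis by a
  # fraction of a degree (incomplete final turn), hence the 0.5-degree slack
  modes <- sort(unique(round(td$angles, 6)))
  expect_length(modes, 2L)
  expect_true(all(abs(modes - c(10, 40)) < 0.5))
  expect_identical(sum(td$histogram$count), 12L)
  counts <- td$histogram$count[td$histogram$count > 0]
  expect_identical(counts, c(6L, 6L))

  td2 <- tilt_distribution(traj, stride = 5L)
  expect_length(td2$angles, floor(12 / 5))
  td1 <- tilt_distribution(traj, stride = 1L)
  expect_identical(td1$angles, td$angles)

  same <- helix_trajectory(rep(list(mk(25)), 4L))
  a <- tilt_distribution(same)$angles
  expect_equal(sd(a), 0, tolerance = 1e-12)
})

test_that("XYZ frames round-trip through the plain-text reader", {
  traj <- random_trajectory(n_res = 2L, n_atoms = 3L, n_frames = 4L)
  coords <- withr::local_tempfile(fileext = ".dat")
  groups <- withr::local_tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(seq_along(traj$frames), function(fi) {
    m <- do.call(rbind, traj$frames[[fi]])
    data.frame(frame = fi, x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  write.table(format(rows, digits = 12), coords, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(c("residue\telement",
               paste(rep(c("R1", "R2"), each = 3L), "C", sep = "\t")),
             groups)
  back <- read_xyz_frames(coords, groups)
  expect_equal(contact_number(back, "R1", "R2"),
               contact_number(traj, "R1", "R2"), tolerance = 1e-9)

  # nm input is converted to Angstrom at the boundary
  nm <- read_xyz_frames(coords, groups, unit = "nm")
  expect_equal(max(nm$frames[[1L]]$R1), 10 * max(back$frames[[1L]]$R1),
               tolerance = 1e-9)

  # hydrogens are excluded from the grouping
  writeLines(c("residue\telement",
               paste(rep(c("R1", "R2"), each = 3L), c("C", "H", "C"),
                     sep = "\t")), groups)
  noH <- read_xyz_frames(coords, groups)
  expect_identical(nrow(noH$frames[[1L]]$R1), 2L)
})

test_that("multi-model PDB files load as trajectories", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(serial, name, res, resno, x, y, z, ele) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, resno, x, y, z, ele)
  }
  lines <- c("MODEL        1",
             atom_line(1, "CA", "LEU", 1, 0, 0, 0, "C"),
             atom_line(2, "CB", "LEU", 1, 1, 0, 0, "C"),
             atom_line(3, "CA", "VAL", 2, 4, 0, 0, "C"),
             "ENDMDL",
             "MODEL        2",
             atom_line(1, "CA", "LEU", 1, 0, 0, 0, "C"),
             atom_line(2, "CB", "LEU", 1, 1, 0, 0, "C"),
             atom_line(3, "CA", "VAL", 2, 6, 0, 0, "C"),
             "ENDMDL", "END")
  writeLines(lines, pdb)
  traj <- read_pdb_trajectory(pdb)
  expect_length(traj$frames, 2L)
  expect_identical(sort(names(traj$frames[[1L]])), c("LEU1", "VAL2"))
  expect_equal(contact_number(traj, "LEU1", "VAL2"),
               (pair_contact(3) + pair_contact(4) +
                  pair_contact(5) + pair_contact(6)) / 2, tolerance = 1e-9)
})
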