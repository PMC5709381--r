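test_that("internal container round trip is bitwise lossless", {
  set.seed(1)
  co <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  topo <- mc_topology(data.frame(
    species = rep(c("protein", "POPC"), c(3, 4)),
    molecule = c(1, 1, 1, 2:5), residue = c(1, 2, 3, 1, 1, 1, 1),
    role = rep(c("protein-bead", "headgroup"), c(3, 4)),
    leaflet = rep(c("unassigned", "inner"), c(3, 4))))
  traj <- mc_trajectory(co, c(10, 12, 8), dt = 2, topo)
  path <- withr::local_tempfile(fileext = ".mct")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(back$coords, traj$coords)
  expect_identical(back$box, traj$box)
  expect_identical(back$topology, traj$topology)
  expect_identical(back$dt, traj$dt)
})

test_that("GRO write/read recovers coordinates and box", {
  co <- array(c(1.234, 5.5, 9.999, 0.1, 2.2, 3.3, 4.4, 5.5, 6.6), c(1, 3, 3))
  traj <- mc_trajectory(co, c(10, 10, 10))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj, path)
  back <- read_trajectory(path)
  expect_equal(dim(back$coords), c(1, 3, 3))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(back$box[1, ], c(10, 10, 10))
})

test_that("frame-count mismatch and unsupported formats raise typed errors", {
  co <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  path <- withr::local_tempfile(fileext = ".mct")
  write_trajectory(mc_trajectory(co, c(5, 5, 5)), path)
  expect_error(read_trajectory(path, expect_frames = 3),
               class = "mc_structural_error")
  xtc <- withr::local_tempfile(fileext = ".xtc")
  writeLines("x", xtc)
  expect_error(read_trajectory(xtc), class = "mc_format_error")
  expect_error(read_trajectory("no/such/file.gro"), class = "mc_format_error")
})

test_that("triclinic GRO boxes are rejected as unsupported", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               "    1SOL    SOL    1   1.000   1.000   1.000",
               "  10.0 10.0 10.0 0.0 0.0 2.0 0.0 0.0 0.0"), path)
  expect_error(read_gro(path), class = "mc_format_error")
})

test_that("minimum-image displacement follows the nearest periodic image", {
  box <- c(10, 10, 10)
  d <- minimum_image_displacement(c(0.5, 0.5), c(9.5, 9.5), box,
                                  lateral_only = TRUE)
  expect_equal(unname(d), c(-1, -1))
  expect_equal(sqrt(sum(d^2)), sqrt(2))
  expect_equal(unname(minimum_image_displacement(c(1, 2, 3), c(1, 2, 3), box)),
               c(0, 0, 0))
  # random pairs against the brute-force 9-image oracle
  set.seed(7)
  for (i in 1:50) {
    a <- runif(3, 0, 10); b <- runif(3, 0, 10)
    d <- minimum_image_displacement(a, b, box, lateral_only = TRUE)
    expect_equal(sqrt(sum(d[1:2]^2)), brute_min_image(a, b, box),
                 tolerance = 1e-12)
    # components within (-L/2, L/2]; invariant under box translations
    expect_true(all(d[1:2] > -5 - 1e-12 & d[1:2] <= 5 + 1e-12))
    d2 <- minimum_image_displacement(a + c(30, -20, 0), b, box,
                                     lateral_only = TRUE)
    expect_equal(d2[1:2], d[1:2], tolerance = 1e-9)
  }
})

test_that("COM removal cancels drift, is idempotent, ignores static frames", {
  set.seed(2)
  nf <- 20; np <- 6
  steps <- array(rnorm(nf * np * 3, sd = 0.1), c(nf, np, 3))
  co <- apply(steps, c(2, 3), cumsum)
  drift <- matrix(seq_len(nf), nf, np)  # +1 nm/frame collective drift in x
  co[, , 1] <- co[, , 1] + drift
  traj <- mc_trajectory(co, c(50, 50, 50))
  fixed <- remove_com_motion(traj)
  for (k in 1:3) {
    cm <- rowMeans(fixed$coords[, , k])
    expect_equal(cm, rep(cm[1], nf), tolerance = 1e-10)
  }
  # selection-centroid MSD is zero at all lags
  cxy <- cbind(rowMeans(fixed$coords[, , 1]), rowMeans(fixed$coords[, , 2]))
  expect_equal(max(brute_msd_2d(cxy)), 0, tolerance = 1e-18)
  # idempotent
  again <- remove_com_motion(fixed)
  expect_equal(again$coords, fixed$coords, tolerance = 1e-12)
  # a single static reference particle leaves the trajectory unchanged
  co2 <- co; co2[, 1, ] <- 3
  traj2 <- mc_trajectory(co2, c(50, 50, 50))
  expect_equal(remove_com_motion(traj2, selection = 1)$coords, co2,
               tolerance = 1e-12)
  expect_error(remove_com_motion(traj, selection = integer(0)),
               class = "mc_argument_error")
})

test_that("unwrap reconstructs boundary crossings and inverts wrap", {
  # particle crossing +x boundary: 0.1 -> 9.9 is a -0.2 step
  co <- array(0, c(2, 1, 3))
  co[1, 1, ] <- c(0.1, 5, 5); co[2, 1, ] <- c(9.9, 5, 5)
  traj <- mc_trajectory(co, c(10, 10, 10), wrapped = TRUE)
  un <- unwrap(traj)
  expect_equal(un$coords[2, 1, 1] - un$coords[1, 1, 1], -0.2,
               tolerance = 1e-12)
  # already-continuous trajectory unchanged
  co2 <- array(seq(4, 5.9, length.out = 20), c(20, 1, 3))
  t2 <- mc_trajectory(co2, c(10, 10, 10), wrapped = TRUE)
  expect_equal(unwrap(t2)$coords, co2, tolerance = 1e-12)
  # 1000-step wrapped random walk: unwrap then wrap recovers the input
  set.seed(3)
  walk <- apply(array(rnorm(1001 * 4 * 3, sd = 0.8), c(1001, 4, 3)),
                c(2, 3), cumsum)
  wrapped <- wrap(mc_trajectory(walk, c(6, 6, 6)))
  round_trip <- wrap(unwrap(mc_trajectory(wrapped$coords, c(6, 6, 6),
                                          wrapped = TRUE)))
  expect_equal(round_trip$coords, wrapped$coords, tolerance = 1e-9)
  # a near-half-box step is ambiguous and warns with particle and frame
  co3 <- array(c(1, 4.02, 5, 5, 5, 5), c(2, 1, 3))
  expect_warning(unwrap(mc_trajectory(co3, c(6, 6, 6), wrapped = TRUE)),
                 class = "mc_unwrap_warning")
})

test_that("trajectory and topology invariants are enforced", {
  expect_error(mc_trajectory(array(0, c(2, 3, 2)), c(1, 1, 1)),
               class = "mc_structural_error")
  expect_error(mc_trajectory(array(0, c(2, 3, 3)), c(1, -1, 1)),
               class = "mc_argument_error")
  expect_error(mc_topology(data.frame(species = "a", residue = 0)),
               class = "mc_labelling_error")
  expect_error(mc_topology(data.frame(species = "a", role = "nonsense")),
               class = "mc_labelling_error")
})
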