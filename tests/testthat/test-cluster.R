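make_protein_traj <- function(beads_per_protein, positions, box,
                              residues = NULL) {
  # positions: list of matrices (beads x 2 or 3), one per protein
  n <- sum(vapply(positions, nrow, 0L))
  co <- array(0, c(1L, n, 3L))
  off <- 0L; mol <- integer(n); res <- integer(n)
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    idx <- off + seq_len(nrow(p))
    co[1, idx, 1] <- p[, 1]; co[1, idx, 2] <- p[, 2]
    co[1, idx, 3] <- if (ncol(p) >= 3) p[, 3] else box[3] / 2
    mol[idx] <- i
    res[idx] <- residues[[i]] %||% seq_len(nrow(p))
    off <- off + nrow(p)
  }
  topo <- mc_topology(data.frame(species = "protein", molecule = mol,
                                 residue = res, role = "protein-bead",
                                 leaflet = "unassigned"))
  mc_trajectory(co, box, dt = 1, topo, wrapped = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("protein centroids are minimum-image consistent", {
  box <- c(10, 10, 10)
  tr <- make_protein_traj(2, list(rbind(c(0, 0), c(2, 2))), box)
  ce <- protein_centroids(tr)
  expect_equal(c(ce$x[1, 1], ce$y[1, 1]), c(1, 1))
  # molecule straddling the boundary: centroid at 0 (mod box), not 5
  tr2 <- make_protein_traj(2, list(rbind(c(0.1, 5), c(9.9, 5))), box)
  ce2 <- protein_centroids(tr2)
  expect_equal(ce2$x[1, 1], 0, tolerance = 1e-9)
  # random 100-bead protein: equals brute-force mean after unwrapping
  set.seed(51)
  beads <- cbind(runif(100, -1.5, 1.5) + 9.8, runif(100, 3, 4))
  wrapped <- cbind(beads[, 1] %% 10, beads[, 2])
  tr3 <- make_protein_traj(100, list(wrapped), box)
  ce3 <- protein_centroids(tr3)
  expect_equal(ce3$x[1, 1], mean(beads[, 1]) %% 10, tolerance = 1e-9)
  expect_equal(ce3$y[1, 1], mean(beads[, 2]), tolerance = 1e-9)
  # missing residues are a labelling error naming the protein
  expect_error(protein_centroids(tr3, residue_range = 500:600),
               class = "mc_labelling_error")
})

test_that("contact graph edges follow the cutoff exactly", {
  box <- c(100, 100, 10)
  g1 <- build_contact_graph(rbind(c(10, 10), c(18.1, 10)), box, cutoff = 8.2)
  expect_equal(nrow(g1$edges), 1)
  g2 <- build_contact_graph(rbind(c(10, 10), c(18.3, 10)), box, cutoff = 8.2)
  expect_equal(nrow(g2$edges), 0)
  # exact boundary distance counts as a contact
  g3 <- build_contact_graph(rbind(c(10, 10), c(18.2, 10)), box, cutoff = 8.2)
  expect_equal(nrow(g3$edges), 1)
  # contact across the periodic boundary
  g4 <- build_contact_graph(rbind(c(1, 50), c(94, 50)), box, cutoff = 8.2)
  expect_equal(nrow(g4$edges), 1)
  # 50 random points: edge set equals the brute-force all-pairs check
  set.seed(52)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  g5 <- build_contact_graph(pts, box, cutoff = 12)
  brute <- which(outer(seq_len(50), seq_len(50), Vectorize(function(i, j)
    i < j && brute_min_image(pts[i, ], pts[j, ], box) <= 12)), arr.ind = TRUE)
  expect_equal(g5$edges[order(g5$edges[, 1], g5$edges[, 2]), , drop = FALSE],
               unname(brute[order(brute[, 1], brute[, 2]), , drop = FALSE]))
  expect_error(build_contact_graph(pts, c(10, 10, 10), cutoff = 8.2),
               class = "mc_argument_error")
})

test_that("connected components match a BFS oracle and partition the set", {
  # empty edge set: all singletons
  cf <- connected_clusters(structure(list(
    edges = matrix(integer(0), 0, 2), n = 9L, cutoff = 1), class = "contact_graph"))
  expect_equal(cf$sizes, rep(1L, 9))
  expect_equal(cf$degree, rep(0L, 9))
  # randomized graphs vs BFS
  set.seed(53)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    m <- sample(0:min(60, n * (n - 1) / 2), 1)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    edges <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    cf <- connected_clusters(structure(list(
      edges = unname(edges), n = n, cutoff = 1), class = "contact_graph"))
    expect_true(same_partition(cf$membership, bfs_components(n, edges)))
    expect_equal(sum(cf$sizes), n)  # partition property
  }
})

test_that("enlarging the cutoff never shrinks any cluster", {
  set.seed(54)
  pts <- cbind(runif(40, 0, 80), runif(40, 0, 80))
  box <- c(80, 80, 10)
  prev <- NULL
  for (cutoff in c(4, 8, 12, 16)) {
    cf <- connected_clusters(build_contact_graph(pts, box, cutoff = cutoff))
    if (!is.null(prev)) expect_true(all(cf$size_label >= prev))
    prev <- cf$size_label
  }
})

test_that("cluster series statistics use the documented averaging", {
  box <- c(100, 100, 10)
  # static singletons over 10 frames
  pts <- cbind(seq(5, 95, by = 30), 50)
  co <- array(0, c(10, nrow(pts), 3))
  for (f in 1:10) { co[f, , 1] <- pts[, 1]; co[f, , 2] <- pts[, 2] }
  topo <- mc_topology(data.frame(species = "protein",
                                 molecule = seq_len(nrow(pts)), residue = 1L,
                                 role = "protein-bead", leaflet = "unassigned"))
  tr <- mc_trajectory(co, box, 1, topo, wrapped = TRUE)
  cs <- cluster_size_series(tr, cutoff = 8.2)
  expect_true(all(cs$stats$mean_size == 1))
  # clusters {4, 3}: number-average 3.5, protein-weighted 25/7
  pts2 <- rbind(cbind(seq(0, 24, 8), 10), cbind(seq(50, 66, 8), 40))
  tr2 <- points_trajectory(pts2, box)
  s_num <- cluster_size_series(tr2, cutoff = 8.2)
  expect_equal(s_num$stats$mean_size, 3.5)
  expect_equal(s_num$stats$max_size, 4L)
  s_w <- cluster_size_series(tr2, cutoff = 8.2, mean_type = "weight")
  expect_equal(s_w$stats$mean_size, 25 / 7)
})

test_that("neighbor fractions and bootstrap errors behave as closed forms say", {
  # chain of 5: fractions 2/5 one-neighbour, 3/5 two-neighbour
  tr <- points_trajectory(cbind(seq(0, 32, 8), 50), c(100, 100, 10))
  cs <- cluster_size_series(tr, cutoff = 8.2)
  nf <- neighbor_fractions(cs, n_boot = 200, seed = 1)
  expect_equal(nf$fraction[nf$neighbors == "1"], 0.4)
  expect_equal(nf$fraction[nf$neighbors == "2"], 0.6)
  expect_equal(nf$fraction[nf$neighbors == ">2"], 0)
  # constant statistic: exactly zero bootstrap SE
  tr2 <- points_trajectory(cbind(seq(0, 72, 8), 50), c(100, 100, 10))
  cs2 <- cluster_size_series(tr2, cutoff = 8.2)
  # all 10 in one chain: degree-0 fraction is constantly 0
  nf2 <- neighbor_fractions(cs2, n_boot = 100, seed = 2)
  expect_equal(nf2$se_boot[nf2$neighbors == "0"], 0)
  # Bernoulli fixture: SE ~ sqrt(p(1-p)/n) within 20% at n = 100
  deg <- rep(c(1L, 2L), each = 50)
  fake <- structure(list(degree = matrix(deg, nrow = 1)), class = "cluster_series")
  nf3 <- neighbor_fractions(fake, n_boot = 2000, seed = 3)
  expect_lt(abs(nf3$se_boot[nf3$neighbors == "1"] - 0.05) / 0.05, 0.2)
  expect_error(neighbor_fractions(cs, n_boot = 1), class = "mc_argument_error")
})

test_that("pair displacement maps are inversion symmetric with unit maximum", {
  box <- c(100, 100, 10)
  tr <- make_protein_traj(1, list(rbind(c(20, 50)), rbind(c(25, 50))), box)
  ce <- protein_centroids(tr)
  pm <- pair_displacement_map(ce, bin_width = 1, max_range = 10)
  hits <- which(pm$counts > 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 2)
  expect_true(all(pm$counts[hits] == 1))
  # inversion symmetry
  expect_equal(pm$counts, pm$counts[nrow(pm$counts):1, ncol(pm$counts):1],
               tolerance = 1e-12)
  # isolated protein: empty map
  tr1 <- make_protein_traj(1, list(rbind(c(20, 50))), box)
  pm1 <- pair_displacement_map(protein_centroids(tr1), bin_width = 1)
  expect_true(all(pm1$counts == 0))
  # hexagonal packing: six first-shell maxima at the lattice spacing
  d <- 6
  hexpts <- rbind(c(0, 0), d * cbind(cos(seq(0, 5) * pi / 3),
                                     sin(seq(0, 5) * pi / 3))) + 50
  trh <- points_trajectory(hexpts, box)
  pmh <- pair_displacement_map(protein_centroids(trh), bin_width = 1,
                               max_range = 8)
  mid <- (pmh$breaks[-1] + pmh$breaks[-length(pmh$breaks)]) / 2
  peak_cells <- which(pmh$counts == 1, arr.ind = TRUE)
  radii <- sqrt(mid[peak_cells[, 1]]^2 + mid[peak_cells[, 2]]^2)
  expect_true(all(abs(radii - d) < 1.5))
  expect_error(pair_displacement_map(ce, bin_width = 0),
               class = "mc_argument_error")
})

test_that("residue contact frequencies follow the 0.7 nm centroid rule", {
  box <- c(50, 50, 10)
  # two single-residue proteins at centroid distance 0.69: one contact
  near <- make_protein_traj(1, list(rbind(c(10, 10)), rbind(c(10.69, 10))), box)
  m1 <- residue_contact_frequencies(near, partner = "protein")
  expect_equal(attr(m1, "total"), 2)  # both partners' residues counted
  far <- make_protein_traj(1, list(rbind(c(10, 10)), rbind(c(10.71, 10))), box)
  expect_equal(attr(residue_contact_frequencies(far, partner = "protein"),
                    "total"), 0)
  # single protein: empty map
  solo <- make_protein_traj(1, list(rbind(c(10, 10))), box)
  expect_equal(attr(residue_contact_frequencies(solo, partner = "protein"),
                    "total"), 0)
  # contrived fixture: residue 2 of every protein is the only contact,
  # over 10 frames; its frequency is 1
  mk <- function() {
    pos <- list(rbind(c(10, 10), c(12, 10)), rbind(c(12.5, 10), c(20, 18)))
    res <- list(1:2, 2:3)
    tr <- make_protein_traj(2, pos, box, residues = res)
    co <- array(tr$coords[rep(1, 10), , ], c(10, 4, 3))
    mc_trajectory(co, box, 1, tr$topology, wrapped = TRUE)
  }
  tr10 <- mk()
  m10 <- residue_contact_frequencies(tr10, partner = "protein")
  expect_equal(m10$frequency[m10$residue == 2], 1)
  expect_equal(sum(m10$frequency), 1)
  expect_equal(nrow(contact_hotspots(m10, percent = 50)), 1)
  # headgroup partner requires labelled headgroups
  expect_error(residue_contact_frequencies(tr10, partner = "lipid-headgroup"),
               class = "mc_labelling_error")
})
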