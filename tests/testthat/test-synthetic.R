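test_that("fGn sample autocovariance matches the closed form", {
  for (alpha in c(0.5, 0.7, 1.0, 1.5)) {
    set.seed(10 + round(10 * alpha))
    n <- 256; p <- 400
    x <- fgn(n, alpha, p)
    for (k in 0:5) {
      # per-series product moments are independent across series, so their
      # spread gives an honest standard error of the pooled mean
      per <- colMeans(x[1:(n - k), , drop = FALSE] *
                        x[(1 + k):n, , drop = FALSE])
      theo <- fgn_autocov(k, alpha)
      se <- sd(per) / sqrt(p)
      expect_lt(abs(mean(per) - theo), 3 * se)
    }
  }
})

test_that("fGn sample covariance matrix matches a Cholesky-construction oracle", {
  # independent exact sampler: L %*% z with L = chol(Gamma); compare the
  # circulant-embedding output's covariance against the same target matrix
  alpha <- 0.6; n <- 8
  Gamma <- outer(1:n, 1:n, function(i, j) fgn_autocov(i - j, alpha))
  set.seed(42)
  x <- fgn(n, alpha, 40000)
  emp <- tcrossprod(x) / ncol(x)
  expect_lt(max(abs(emp - Gamma)), 0.03)
  # oracle route agrees with the analytic target it was built from
  z <- matrix(rnorm(n * 40000), n)
  y <- t(chol(Gamma)) %*% z
  emp2 <- tcrossprod(y) / ncol(y)
  expect_lt(max(abs(emp2 - Gamma)), 0.03)
})

test_that("generated trajectories have the prescribed ensemble MSD", {
  preset <- mc_preset("test-normal", list(diffusion_spec("s", 1, 1, 500L)),
                      n_frames = 64L, box = c(100, 100, 10), seed = 5)
  traj <- generate_diffusive_trajectory(preset)
  co <- traj$unwrapped
  for (k in c(1, 2, 5, 10, 20)) {
    d2 <- (co[1 + k, , 1] - co[1, , 1])^2 + (co[1 + k, , 2] - co[1, , 2])^2
    target <- 4 * k
    se <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - target), 3 * se)
  }
})

test_that("ballistic limit alpha = 2 gives MSD proportional to lag squared", {
  preset <- mc_preset("ball", list(diffusion_spec("s", 1, 2, 200L)),
                      n_frames = 32L, box = c(100, 100, 10), seed = 6)
  co <- generate_diffusive_trajectory(preset)$unwrapped
  msd <- sapply(c(1, 2, 4, 8), function(k)
    mean((co[1 + k, , 1] - co[1, , 1])^2 + (co[1 + k, , 2] - co[1, , 2])^2))
  expect_equal(msd / msd[1], c(1, 4, 16, 64), tolerance = 1e-9)
})

test_that("fractional preset is exactly reproducible under its seed", {
  p <- mc_preset("rep", list(diffusion_spec("s", 1, 0.5, 20L)),
                 n_frames = 128L, seed = 9)
  a <- generate_diffusive_trajectory(p)
  b <- generate_diffusive_trajectory(p)
  expect_identical(a$coords, b$coords)
  c2 <- generate_diffusive_trajectory(p, seed = 10)
  expect_false(identical(a$coords, c2$coords))
})

test_that("preset registry carries the published parameterizations", {
  reg <- preset_registry()
  expect_true(all(c("PC-lipid", "PM_s-POPE", "noPIP2G_s-POPE", "PC-protein",
                    "PM_s-protein", "noChol_s-protein",
                    "crowded-protein-subdiffusive", "free-Brownian")
                  %in% names(reg)))
  pc <- preset_registry("PC-lipid")
  expect_equal(pc$species[[1]]$d_alpha, 37)
  expect_equal(pc$species[[1]]$alpha, 1)
  expect_equal(preset_registry("PM_s-protein")$species[[1]]$d_alpha, 0.4)
  expect_equal(preset_registry("crowded-protein-subdiffusive")$species[[1]]$alpha,
               0.5)
  expect_error(preset_registry("no-such-preset"), class = "mc_lookup_error")
})

test_that("crowded disks: bound pairs persist and adhesion drives clustering", {
  # two disks in contact with adhesion_prob = 1 never separate
  t2 <- generate_crowded_disks(2, box = c(30, 30, 10), disk_radius = 2,
                               step_D = 0.5, adhesion_range = 4.4,
                               adhesion_prob = 1, n_frames = 150, seed = 21)
  # force contact at start is not guaranteed by placement; use a crowded box
  # so the pair binds early, then check it never unbinds afterwards
  d <- sapply(seq_len(150), function(f) {
    dd <- minimum_image_displacement(t2$coords[f, 1, 1:2],
                                     t2$coords[f, 2, 1:2], c(30, 30),
                                     lateral_only = TRUE)
    sqrt(sum(dd^2))
  })
  first_bound <- which(d < 4.4)[1]
  if (!is.na(first_bound))
    expect_true(all(d[first_bound:150] < 4.4 + 1e-9))

  # free limit: no adhesion, tiny radius recovers Brownian statistics
  tf <- generate_crowded_disks(40, box = c(200, 200, 10), disk_radius = 0.05,
                               step_D = 1, adhesion_range = 0.2,
                               adhesion_prob = 0, n_frames = 400, seed = 22)
  m <- compute_msd(tf, discard_initial = 0)
  fit <- fit_anomalous(m, fit_min = 1, fit_max = 100)
  expect_lt(abs(fit$alpha - 1), 0.1)
  expect_lt(abs(fit$D_alpha - 1), 0.25)

  # mean cluster size is non-decreasing in adhesion probability
  mean_size <- sapply(c(0, 0.5, 0.95), function(ap) {
    sizes <- sapply(1:5, function(s) {
      tr <- generate_crowded_disks(60, box = c(60, 60, 10), disk_radius = 2,
                                   step_D = 0.5, adhesion_range = 4.4,
                                   adhesion_prob = ap, n_frames = 60,
                                   seed = 100 + s)
      cs <- cluster_size_series(tr, cutoff = 4.4, stride = 59)
      cs$stats$mean_size[nrow(cs$stats)]
    })
    mean(sizes)
  })
  expect_true(all(diff(mean_size) >= 0))
})

test_that("cluster-configuration fixtures have the stated properties", {
  # all singletons
  s1 <- sample_cluster_configuration(12, data.frame(size = 1, weight = 1),
                                     box = c(137, 137, 10), seed = 31)
  cf <- connected_clusters(build_contact_graph(
    protein_centroids(s1$trajectory), cutoff = 8.2))
  expect_equal(length(cf$sizes), 12)
  expect_true(all(cf$sizes == 1))
  # one chain of 5: degrees two 1s and three 2s at the growth spacing
  ch <- sample_cluster_configuration(5, data.frame(size = 5, weight = 1),
                                     spacing = 7, branch_prob = 0,
                                     box = c(137, 137, 10), seed = 32)
  cf2 <- connected_clusters(build_contact_graph(
    protein_centroids(ch$trajectory), cutoff = 7.05))
  expect_equal(sort(cf2$degree), c(1L, 1L, 2L, 2L, 2L))
  # mixed sizes: detected partition equals ground truth
  mx <- sample_cluster_configuration(40, data.frame(size = c(1, 4),
                                                    weight = c(.5, .5)),
                                     box = c(137, 137, 10), seed = 33)
  cf3 <- connected_clusters(build_contact_graph(
    protein_centroids(mx$trajectory), cutoff = 8.2))
  expect_true(same_partition(mx$labels, cf3$membership))
  expect_error(sample_cluster_configuration(
    5, data.frame(size = 5, weight = 2)), class = "mc_argument_error")
})

test_that("undulating-bilayer generator obeys its target spectrum", {
  # flat target: measured variance is only the per-particle noise
  flat <- generate_undulating_bilayer(amplitude = 0, L = 16, grid = 0.5,
                                      noise_sd = 0.1, n_frames = 1, seed = 41)
  z <- flat$trajectory$coords[1, , 3]
  labs <- flat$trajectory$topology$leaflet
  expect_lt(sd(z[labs == "inner"]), 0.15)
  # Parseval at the generator: field variance ~ sum of target spectrum.
  # A band-flat spectrum averages over ~10^3 modes, so the per-frame
  # variance concentrates tightly around the target sum.
  gb <- generate_undulating_bilayer(amplitude = 1e-3, exponent = 0, L = 16,
                                    grid = 0.5, n_frames = 8, noise_sd = 0,
                                    seed = 42)
  vars <- apply(gb$height_ground_truth, 1, function(h) var(as.vector(h)))
  expect_equal(mean(vars), sum(gb$target_spectrum$S), tolerance = 0.05)
  expect_error(generate_undulating_bilayer(amplitude = 1, grid = 0.3, L = 1),
               class = "mc_argument_error")
})
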