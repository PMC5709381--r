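#' Exact fractional Gaussian noise by circulant embedding
#'
#' Generates stationary Gaussian increment series whose autocovariance is
#' that of fractional Gaussian noise with anomalous exponent `alpha`
#' (Hurst index `alpha/2`):
#' `gamma(k) = 0.5 * (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)` for a unit
#' step variance. The Davies-Harte circulant embedding is exact (the target
#' covariance is reproduced to machine precision in distribution), at
#' `O(n log n)` cost per series. `alpha = 1` reduces to white noise and
#' `alpha = 2` to a frozen per-series constant (ballistic limit); both are
#' special-cased.
#'
#' @param n number of increments per series.
#' @param alpha anomalous exponent in (0, 2].
#' @param n_series number of independent series (columns).
#' @return an `n x n_series` matrix of unit-variance fGn increments.
#' @export
fgn <- function(n, alpha, n_series = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 2)
    mc_stop("'alpha' must lie in (0, 2]", "mc_argument_error")
  if (alpha == 1) return(matrix(stats::rnorm(n * n_series), n, n_series))
  if (alpha == 2) {
    v <- stats::rnorm(n_series)  # constant velocity per series
    return(matrix(v, n, n_series, byrow = TRUE))
  }
  m <- 2L * n
  g <- fgn_autocov(c(0:n, (n - 1):1), alpha)
  lambda <- Re(stats::fft(g))
  lambda <- pmax(lambda, 0)  # fGn embedding is nonneg definite; clip fp dust
  out <- matrix(0, n, n_series)
  # chunk the column dimension to bound the complex workspace
  chunk <- max(1L, min(n_series, as.integer(2^22 / m)))
  for (s in seq(1L, n_series, by = chunk)) {
    cols <- s:min(s + chunk - 1L, n_series)
    p <- length(cols)
    a <- matrix(0 + 0i, m, p)
    a[1L, ] <- sqrt(lambda[1L]) * stats::rnorm(p)
    a[n + 1L, ] <- sqrt(lambda[n + 1L]) * stats::rnorm(p)
    re <- matrix(stats::rnorm((n - 1L) * p), n - 1L, p)
    im <- matrix(stats::rnorm((n - 1L) * p), n - 1L, p)
    a[2:n, ] <- sqrt(lambda[2:n] / 2) * complex(real = re, imaginary = im)
    a[(n + 2L):m, ] <- Conj(a[n:2, , drop = FALSE])
    x <- Re(stats::mvfft(a)) / sqrt(m)
    out[, cols] <- x[1:n, , drop = FALSE]
  }
  out
}

#' Autocovariance of fractional Gaussian noise
#'
#' Closed form for unit step variance: `0.5 (|k+1|^a - 2|k|^a + |k-1|^a)`.
#'
#' @param k integer lag(s).
#' @param alpha anomalous exponent (`2H`).
#' @return autocovariance at each lag.
#' @export
fgn_autocov <- function(k, alpha) {
  0.5 * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

#' Diffusion species specification
#'
#' One species entry for the synthetic generator: `n_particles` independent
#' 2D walkers with ensemble mean squared displacement
#' `MSD(t) = 4 * d_alpha * t^alpha` (lateral 2D convention; `d_alpha` in
#' nm^2/ns^alpha on the same numeric scale as published diffusion tables).
#'
#' @param species species name.
#' @param d_alpha generalized diffusion coefficient (> 0).
#' @param alpha anomalous exponent in (0, 2]; 1 is normal diffusion.
#' @param n_particles number of walkers.
#' @return a `diffusion_spec` list.
#' @export
diffusion_spec <- function(species, d_alpha, alpha = 1, n_particles = 100L) {
  check_positive(d_alpha, "d_alpha")
  if (alpha <= 0 || alpha > 2)
    mc_stop("'alpha' must lie in (0, 2]", "mc_argument_error")
  check_positive(n_particles, "n_particles")
  structure(list(species = species, d_alpha = d_alpha, alpha = alpha,
                 n_particles = as.integer(n_particles)),
            class = "diffusion_spec")
}

#' Generate lateral diffusive trajectories with known ground truth
#'
#' For each species in the preset, draws 2D fractional (or normal) Brownian
#' trajectories whose ensemble MSD equals `4 d_alpha dt^alpha` in expectation
#' at every lag of the frame grid. Increments are exact fractional Gaussian
#' noise ([fgn()]); x and y are independent; z is fixed at mid-box.
#' Coordinates are wrapped into the box with the unwrapped copy retained, so
#' displacement-based analyses need no unwrap step.
#'
#' @param preset a `synthetic_preset` from [preset_registry()] /
#'   [mc_preset()], or a single [diffusion_spec()].
#' @param n_frames,dt,box,seed override the preset's values if given.
#' @return an [mc_trajectory()]; particle species in the topology follow the
#'   preset, molecules carrying `d_alpha`-bearing species named
#'   `"protein"`-like are flagged as proteins.
#' @export
generate_diffusive_trajectory <- function(preset, n_frames = NULL, dt = NULL,
                                          box = NULL, seed = NULL) {
  if (inherits(preset, "diffusion_spec"))
    preset <- mc_preset("adhoc", list(preset))
  stopifnot(inherits(preset, "synthetic_preset"))
  n_frames <- as.integer(n_frames %||% preset$n_frames)
  dt <- dt %||% preset$dt
  box <- box %||% preset$box
  seed <- seed %||% preset$seed
  if (!is.null(seed)) set.seed(seed)
  total <- sum(vapply(preset$species, `[[`, 1L, "n_particles"))
  co <- array(0, c(n_frames, total, 3L))
  species <- character(total); is_prot <- logical(total)
  off <- 0L
  for (sp in preset$species) {
    np <- sp$n_particles
    idx <- off + seq_len(np)
    sigma <- sqrt(2 * sp$d_alpha * dt^sp$alpha)  # per-dimension step scale
    x0 <- cbind(stats::runif(np, 0, box[1]), stats::runif(np, 0, box[2]))
    for (k in 1:2) {
      steps <- sigma * fgn(n_frames - 1L, sp$alpha, np)
      co[, idx, k] <- rbind(x0[, k],
                            matrix(x0[, k], n_frames - 1L, np, byrow = TRUE) +
                              apply(steps, 2L, cumsum))
    }
    co[, idx, 3L] <- box[3] / 2
    species[idx] <- sp$species
    is_prot[idx] <- grepl("protein", sp$species, ignore.case = TRUE)
    off <- off + np
  }
  topo <- mc_topology(data.frame(
    species = species, molecule = seq_len(total), residue = 1L,
    role = ifelse(is_prot, "protein-bead", "other"),
    leaflet = "unassigned"))
  traj <- mc_trajectory(co, box, dt, topo, wrapped = FALSE)
  wrap(traj)  # wrapped coords + unwrapped copy retained
}

#' Crowded adhesive-disk dynamics
#'
#' A Monte-Carlo stand-in for protein crowding: `n_disks` hard disks take
#' Gaussian lateral steps (target free diffusion coefficient `step_D`);
#' moves that would overlap another disk are rejected, and moves that would
#' break an existing contact (pair distance below `adhesion_range`) are
#' rejected with probability `adhesion_prob`. With `adhesion_prob = 0` and
#' vanishing radius this reduces to free Brownian motion; with
#' `adhesion_prob = 1` contacts are permanent and clusters only coalesce.
#' Not a physical force model: a generator of clustering phenomenology with
#' tunable stickiness.
#'
#' @param n_disks number of disks.
#' @param box length-3 box (nm); dynamics are lateral (x,y).
#' @param disk_radius hard-core radius (nm).
#' @param step_D free-step diffusion coefficient (nm^2/ns).
#' @param adhesion_range contact distance (nm); pairs closer than this are
#'   "bound".
#' @param adhesion_prob probability of rejecting a bond-breaking move.
#' @param n_frames,dt trajectory length and frame spacing (ns).
#' @param seed RNG seed.
#' @param max_placement_tries retries for non-overlapping initial placement.
#' @return an [mc_trajectory()] with one "protein-bead" particle per disk.
#' @export
generate_crowded_disks <- function(n_disks, box, disk_radius = 2,
                                   step_D = 1, adhesion_range = 4.4,
                                   adhesion_prob = 0.9, n_frames = 100L,
                                   dt = 1, seed = NULL,
                                   max_placement_tries = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  lx <- box[1]; ly <- box[2]
  packing <- n_disks * pi * disk_radius^2 / (lx * ly)
  if (packing >= 0.7)
    mc_stop(sprintf("packing fraction %.2f too high for placement", packing),
            "mc_placement_error")
  pos <- matrix(NA_real_, n_disks, 2)
  placed <- 0L
  for (try in seq_len(max_placement_tries)) {
    cand <- c(stats::runif(1, 0, lx), stats::runif(1, 0, ly))
    ok <- placed == 0L || {
      d <- minimum_image_displacement(
        pos[seq_len(placed), , drop = FALSE],
        matrix(cand, placed, 2, byrow = TRUE), box[1:2])
      d <- rbind(d)
      all(sqrt(d[, 1]^2 + d[, 2]^2) >= 2 * disk_radius)
    }
    if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
    if (placed == n_disks) break
  }
  if (placed < n_disks)
    mc_stop("could not place all disks without overlap", "mc_placement_error")

  sigma <- sqrt(2 * step_D * dt)
  co <- array(0, c(n_frames, n_disks, 3L))
  unw <- pos  # unwrapped accumulator
  wpos <- pos
  co[1, , 1:2] <- pos
  co[1, , 3] <- box[3] / 2
  lat <- box[1:2]
  pair_dist <- function(p, i, x) {
    dx <- x[1] - p[, 1]; dy <- x[2] - p[, 2]
    dx <- dx - lx * round(dx / lx); dy <- dy - ly * round(dy / ly)
    r <- sqrt(dx^2 + dy^2); r[i] <- Inf
    r
  }
  for (f in 2:n_frames) {
    for (i in seq_len(n_disks)) {
      step <- stats::rnorm(2, 0, sigma)
      old <- wpos[i, ]
      new <- old + step
      neww <- new - c(lx, ly) * floor(new / c(lx, ly))
      r_old <- pair_dist(wpos, i, old)
      r_new <- pair_dist(wpos, i, neww)
      if (any(r_new < 2 * disk_radius)) next  # hard-core rejection
      breaks <- any(r_old < adhesion_range & r_new >= adhesion_range)
      if (breaks && stats::runif(1) < adhesion_prob) next
      wpos[i, ] <- neww
      unw[i, ] <- unw[i, ] + step
    }
    co[f, , 1:2] <- wpos
    co[f, , 3] <- box[3] / 2
  }
  topo <- mc_topology(data.frame(
    species = "protein", molecule = seq_len(n_disks), residue = 1L,
    role = "protein-bead", leaflet = "unassigned"))
  traj <- mc_trajectory(co, box, dt, topo, wrapped = TRUE)
  traj$unwrapped <- unwrap(traj)$coords
  traj
}

#' Sample a single-frame cluster configuration with known partition
#'
#' Grows clusters as random trees on a spacing grid: sizes are drawn from
#' `size_distribution`, each new member attaches at distance `spacing` to a
#' uniformly chosen existing member with probability `branch_prob`
#' (branching) or to the last-placed member (chain). Clusters are laid out
#' with inter-cluster gaps greater than `2 * cutoff`, which makes the
#' generated partition the unique answer for any contact cutoff in
#' `[spacing, cutoff]`.
#'
#' @param n_proteins total number of proteins.
#' @param size_distribution data frame or list of `(size, weight)`; weights
#'   sum to 1.
#' @param spacing intra-cluster bond length (nm); must not exceed `cutoff`.
#' @param branch_prob probability of branching versus chaining.
#' @param box length-3 box (nm).
#' @param cutoff the downstream contact cutoff the layout must respect (nm).
#' @param seed RNG seed.
#' @return list with `trajectory` (single frame, one bead per protein) and
#'   `labels` (integer ground-truth cluster id per protein).
#' @export
sample_cluster_configuration <- function(n_proteins, size_distribution,
                                         spacing = 7, branch_prob = 0.3,
                                         box = c(137, 137, 10),
                                         cutoff = 8.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_df <- as.data.frame(size_distribution)
  names(sd_df) <- c("size", "weight")[seq_len(ncol(sd_df))]
  if (abs(sum(sd_df$weight) - 1) > 1e-8)
    mc_stop("size distribution weights must sum to 1", "mc_argument_error")
  if (spacing > cutoff)
    mc_stop("'spacing' must not exceed 'cutoff'", "mc_argument_error")
  sizes <- integer(0)
  while (sum(sizes) < n_proteins) {
    s <- sd_df$size[sample.int(nrow(sd_df), 1L, prob = sd_df$weight)]
    sizes <- c(sizes, min(s, n_proteins - sum(sizes)))
  }
  # grow each cluster as a tree around the origin
  grow <- function(sz) {
    p <- matrix(0, sz, 2)
    if (sz > 1) for (j in 2:sz) {
      for (attempt in 1:200) {
        parent <- if (stats::runif(1) < branch_prob)
          sample.int(j - 1L, 1L) else j - 1L
        th <- stats::runif(1, 0, 2 * pi)
        cand <- p[parent, ] + spacing * c(cos(th), sin(th))
        dd <- sqrt(colSums((t(p[seq_len(j - 1L), , drop = FALSE]) - cand)^2))
        # keep non-parent members at least `spacing` away so no extra bonds
        # shorter than spacing appear, but extra contacts within the cluster
        # are harmless for the partition
        if (all(dd >= 0.95 * spacing)) { p[j, ] <- cand; break }
        if (attempt == 200) p[j, ] <- cand
      }
    }
    p
  }
  shapes <- lapply(sizes, function(sz) {
    p <- grow(sz)
    sweep(p, 2L, colMeans(p))  # centre so the bounding radius is tight
  })
  # sequential placement; the inter-cluster gap (bead to bead, minimum
  # image) must exceed 2 * cutoff so the partition is unambiguous
  gap <- 2 * cutoff + 0.05
  placed <- vector("list", length(sizes))
  allx <- numeric(0); ally <- numeric(0)
  for (i in seq_along(sizes)) {
    ok <- FALSE
    for (attempt in 1:5000) {
      ctr <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
      px <- shapes[[i]][, 1] + ctr[1]; py <- shapes[[i]][, 2] + ctr[2]
      if (length(allx)) {
        dx <- outer(px, allx, `-`); dx <- dx - box[1] * round(dx / box[1])
        dy <- outer(py, ally, `-`); dy <- dy - box[2] * round(dy / box[2])
        if (min(dx^2 + dy^2) <= gap^2) next
      }
      placed[[i]] <- cbind(px, py); allx <- c(allx, px); ally <- c(ally, py)
      ok <- TRUE
      break
    }
    if (!ok)
      mc_stop("box too small to place clusters with the required gaps",
              "mc_placement_error")
  }
  pos <- do.call(rbind, placed)
  labels <- rep(seq_along(sizes), sizes)
  co <- array(0, c(1L, n_proteins, 3L))
  co[1, , 1] <- pos[, 1] %% box[1]
  co[1, , 2] <- pos[, 2] %% box[2]
  co[1, , 3] <- box[3] / 2
  topo <- mc_topology(data.frame(
    species = "protein", molecule = seq_len(n_proteins), residue = 1L,
    role = "protein-bead", leaflet = "unassigned"))
  list(trajectory = mc_trajectory(co, box, dt = 1, topo, wrapped = TRUE),
       labels = labels)
}

#' Undulating bilayer surfaces with a prescribed height spectrum
#'
#' Draws, per frame, independent Gaussian Fourier amplitudes with
#' `<|h_q|^2> = S(q) = A q^-p` on the discrete grid (q = 0 excluded,
#' optional q_min/q_max cutoffs), inverts the transform to a height field
#' h(x, y), and scatters phosphate beads uniformly in-plane with
#' `z = h(x, y) +/- leaflet_separation / 2 + noise`. The Fourier convention
#' matches [undulation_spectrum()] (forward transform divided by the number
#' of grid cells), so the realized spectrum is directly comparable with the
#' target.
#'
#' @param amplitude `A` in `S(q) = A q^-p` (nm^2 per mode).
#' @param exponent spectral exponent `p` (4 for tension-free bending modes).
#' @param L lateral box edge (nm); the grid is `L / grid` cells per axis.
#' @param grid grid spacing (nm); must divide `L`.
#' @param q_min,q_max optional band limits (nm^-1); modes outside are zeroed.
#' @param leaflet_separation inner/outer leaflet z offset (nm).
#' @param noise_sd per-particle z noise s.d. (nm).
#' @param n_phosphates_per_leaflet beads per leaflet per frame.
#' @param n_frames number of independent surface frames.
#' @param box_z box height (nm).
#' @param seed RNG seed.
#' @return list with `trajectory` (phosphate beads, leaflet-labelled),
#'   `target_spectrum` (data frame of mode `q` and target `S`), and
#'   `height_ground_truth` (n_frames x nx x ny array of the analytic field).
#' @export
generate_undulating_bilayer <- function(amplitude, exponent = 4, L = 128,
                                        grid = 0.5, q_min = NULL,
                                        q_max = NULL,
                                        leaflet_separation = 4,
                                        noise_sd = 0.3,
                                        n_phosphates_per_leaflet = 2 *
                                          as.integer(round(L / grid))^2,
                                        n_frames = 1L, box_z = 60,
                                        seed = NULL) {
  if (abs(L / grid - round(L / grid)) > 1e-9)
    mc_stop("'grid' must divide 'L'", "mc_argument_error")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(L / grid))
  qax <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / L
  qmag <- sqrt(outer(qax^2, qax^2, `+`))
  S <- matrix(0, n, n)
  nz <- qmag > 0
  S[nz] <- amplitude * qmag[nz]^(-exponent)
  if (!is.null(q_min)) S[qmag < q_min] <- 0
  if (!is.null(q_max)) S[qmag > q_max] <- 0
  if (any(!is.finite(S)))
    mc_stop("target spectrum is not finite on the q-grid",
            "mc_argument_error")
  npl <- as.integer(n_phosphates_per_leaflet)
  total <- 2L * npl
  co <- array(0, c(n_frames, total, 3L))
  hgt <- array(0, c(n_frames, n, n))
  z0 <- box_z / 2
  for (f in seq_len(n_frames)) {
    w <- matrix(stats::rnorm(n * n), n, n)
    W <- stats::fft(w) / n  # E|W|^2 = 1 per mode, Hermitian by construction
    h <- Re(stats::fft(W * sqrt(S), inverse = TRUE))
    hgt[f, , ] <- h
    for (leaf in 1:2) {
      idx <- (leaf - 1L) * npl + seq_len(npl)
      x <- stats::runif(npl, 0, L); y <- stats::runif(npl, 0, L)
      ci <- pmin(floor(x / grid) + 1L, n); cj <- pmin(floor(y / grid) + 1L, n)
      zoff <- if (leaf == 1L) -leaflet_separation / 2 else leaflet_separation / 2
      co[f, idx, 1] <- x
      co[f, idx, 2] <- y
      co[f, idx, 3] <- z0 + h[cbind(ci, cj)] + zoff +
        stats::rnorm(npl, 0, noise_sd)
    }
  }
  topo <- mc_topology(data.frame(
    species = "phosphate", molecule = seq_len(total), residue = 1L,
    role = "phosphate",
    leaflet = rep(c("inner", "outer"), each = npl)))
  traj <- mc_trajectory(co, c(L, L, box_z), dt = 1, topo, wrapped = FALSE)
  list(trajectory = traj,
       target_spectrum = data.frame(q = qmag[nz], S = S[nz]),
       height_ground_truth = hgt)
}
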