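# independent oracles used across test files; deliberately naive

# connected components by breadth-first search on an explicit edge list
bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# double-loop time-averaged MSD for one particle's 2D track
brute_msd_2d <- function(xy) {
  T <- nrow(xy)
  vapply(seq_len(T - 1L), function(k) {
    d <- xy[(1 + k):T, , drop = FALSE] - xy[1:(T - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
}

# brute-force lateral minimum-image distance via the 9 periodic images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) {
    d <- (b[1:2] + c(ix, iy) * box[1:2]) - a[1:2]
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# two partitions are equal up to label permutation
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# single-frame trajectory from a lateral point matrix, one bead per protein
points_trajectory <- function(pts, box, role = "protein-bead") {
  n <- nrow(pts)
  co <- array(0, c(1L, n, 3L))
  co[1, , 1] <- pts[, 1]; co[1, , 2] <- pts[, 2]
  co[1, , 3] <- if (ncol(pts) >= 3) pts[, 3] else box[3] / 2
  topo <- mc_topology(data.frame(
    species = "protein", molecule = seq_len(n), residue = 1L,
    role = role, leaflet = "unassigned"))
  mc_trajectory(co, box, dt = 1, topo, wrapped = TRUE)
}
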