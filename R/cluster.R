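#' Per-frame lateral centroids of protein domains
#'
#' Computes the (x, y) centroid of each protein over the beads of the given
#' residue range (by default all residues, i.e. whole-protein centroids; for
#' Kir-type channels the cytoplasmic-domain residues 1-45 and 141-377 are
#' the conventional choice). Centroids are minimum-image consistent within a
#' molecule: beads are unwrapped around the molecule's first bead before
#' averaging, so molecules straddling the periodic boundary are handled
#' correctly, and the centroid is re-wrapped into the box.
#'
#' @param traj an [mc_trajectory()] with proteins flagged in its topology.
#' @param residue_range integer residue ids to include; `NULL` for all.
#' @return a `protein_centroids` list: `x` and `y` are `n_frames x
#'   n_proteins` matrices, plus `box`, `dt` and `proteins` (molecule ids).
#' @export
protein_centroids <- function(traj, residue_range = NULL) {
  stopifnot(inherits(traj, "mc_trajectory"))
  top <- traj$topology
  prot <- attr(top, "proteins")
  if (length(prot) == 0L)
    mc_stop("topology flags no protein molecules", "mc_labelling_error")
  nf <- n_frames(traj)
  cx <- matrix(NA_real_, nf, length(prot))
  cy <- matrix(NA_real_, nf, length(prot))
  for (pi in seq_along(prot)) {
    idx <- which(top$molecule == prot[pi])
    if (!is.null(residue_range)) {
      have <- idx[top$residue[idx] %in% residue_range]
      if (length(have) == 0L)
        mc_stop(sprintf(
          "protein molecule %d has no beads in the requested residue range",
          prot[pi]), "mc_labelling_error")
      idx <- have
    }
    for (f in seq_len(nf)) {
      box <- traj$box[f, ]
      x <- traj$coords[f, idx, 1]; y <- traj$coords[f, idx, 2]
      # unwrap the molecule around its first bead (minimum image)
      x <- x[1] + (x - x[1]) - box[1] * round((x - x[1]) / box[1])
      y <- y[1] + (y - y[1]) - box[2] * round((y - y[1]) / box[2])
      cx[f, pi] <- mean(x) %% box[1]
      cy[f, pi] <- mean(y) %% box[2]
    }
  }
  structure(list(x = cx, y = cy, box = traj$box, dt = traj$dt,
                 proteins = prot),
            class = "protein_centroids")
}

#' Build the protein contact graph for one frame
#'
#' Proteins are "interacting" when their lateral minimum-image centroid
#' distance is at most `cutoff` (default 8.2 nm, the conventional
#' Kir2.2 cytoplasmic-domain contact distance); the boundary distance counts
#' as a contact. Distances are 2D (x, y): transmembrane proteins share the
#' bilayer plane, so z excursions from undulations must not affect contact
#' calls.
#'
#' @param centroids a `protein_centroids`, or an `n x 2` matrix of lateral
#'   positions for a single frame.
#' @param box length-2/3 box edges (nm); taken from `centroids` if absent.
#' @param cutoff contact distance (nm); must not exceed half the smallest
#'   lateral box edge.
#' @param frame frame index when `centroids` spans several frames.
#' @return a `contact_graph`: edge matrix (two columns of protein indices),
#'   `n`, `cutoff`.
#' @export
build_contact_graph <- function(centroids, box = NULL, cutoff = 8.2,
                                frame = 1L) {
  if (inherits(centroids, "protein_centroids")) {
    box <- centroids$box[frame, ]
    pts <- cbind(centroids$x[frame, ], centroids$y[frame, ])
  } else {
    pts <- as.matrix(centroids)[, 1:2, drop = FALSE]
    if (is.null(box)) mc_stop("'box' required with raw coordinates",
                              "mc_argument_error")
  }
  if (cutoff > min(box[1:2]) / 2)
    mc_stop("cutoff exceeds half the smallest lateral box edge; minimum image ambiguous",
            "mc_argument_error")
  if (any(!is.finite(pts)))
    mc_stop("centroids must be finite", "mc_argument_error")
  n <- nrow(pts)
  edges <- matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    dx <- outer(pts[, 1], pts[, 1], `-`)
    dy <- outer(pts[, 2], pts[, 2], `-`)
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    d <- sqrt(dx^2 + dy^2)
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    edges <- unname(hit)
  }
  structure(list(edges = edges, n = n, cutoff = cutoff),
            class = "contact_graph")
}

#' Connected clusters of a contact graph
#'
#' Clusters are the connected components of the contact graph. Returns the
#' per-protein cluster membership, cluster-size label and neighbour count
#' (graph degree) for one frame.
#'
#' @param graph a `contact_graph` from [build_contact_graph()].
#' @return a `cluster_frame`: `membership` (cluster id per protein),
#'   `sizes` (per cluster), `size_label` and `degree` (per protein).
#' @export
connected_clusters <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges) > 0L)
    g <- igraph::add_edges(g, t(graph$edges))
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  sizes <- as.integer(comp$csize)
  structure(list(
    membership = membership, sizes = sizes,
    size_label = sizes[membership],
    degree = as.integer(igraph::degree(g)),
    cutoff = graph$cutoff),
    class = "cluster_frame")
}

#' Cluster statistics over a trajectory
#'
#' Applies [build_contact_graph()] and [connected_clusters()] to every
#' `stride`-th frame, returning the per-protein cluster-size label matrix
#' (the raw material of cluster-evolution plots) together with per-frame
#' mean and maximum cluster size. "Mean cluster size" averages over
#' clusters, singletons included (`mean = "number"`); `mean = "weight"`
#' gives the protein-weighted average instead.
#'
#' @param traj an [mc_trajectory()], or a precomputed `protein_centroids`.
#' @param cutoff contact distance (nm).
#' @param stride analyse every `stride`-th frame.
#' @param residue_range residues defining the centroid, see
#'   [protein_centroids()].
#' @param mean_type `"number"` (average over clusters) or `"weight"`
#'   (average cluster size experienced by a protein).
#' @return a `cluster_series`: `frames`, `time` (ns), `mean_size`,
#'   `max_size`, `n_clusters` per analysed frame; `size_label` and `degree`
#'   matrices (frames x proteins); `frames_list` of `cluster_frame`s.
#' @export
cluster_size_series <- function(traj, cutoff = 8.2, stride = 1L,
                                residue_range = NULL,
                                mean_type = c("number", "weight")) {
  mean_type <- match.arg(mean_type)
  cent <- if (inherits(traj, "protein_centroids")) traj
          else protein_centroids(traj, residue_range)
  frames <- seq(1L, nrow(cent$x), by = stride)
  np <- ncol(cent$x)
  size_label <- matrix(NA_integer_, length(frames), np)
  degree <- matrix(NA_integer_, length(frames), np)
  stats_df <- data.frame(frame = frames, time = (frames - 1L) * cent$dt,
                         mean_size = NA_real_, max_size = NA_integer_,
                         n_clusters = NA_integer_)
  frames_list <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    cf <- connected_clusters(build_contact_graph(cent, cutoff = cutoff,
                                                 frame = frames[i]))
    frames_list[[i]] <- cf
    size_label[i, ] <- cf$size_label
    degree[i, ] <- cf$degree
    stats_df$mean_size[i] <- if (mean_type == "number") mean(cf$sizes)
                             else mean(cf$size_label)
    stats_df$max_size[i] <- max(cf$sizes)
    stats_df$n_clusters[i] <- length(cf$sizes)
  }
  structure(list(stats = stats_df, size_label = size_label, degree = degree,
                 frames_list = frames_list, cutoff = cutoff,
                 mean_type = mean_type),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<cluster_series> %d frames, %d proteins, cutoff %.2f nm\n",
    nrow(s), ncol(x$size_label), x$cutoff))
  cat(sprintf("  mean cluster size (%s-average): %.2f (final frame %.2f)\n",
              x$mean_type, mean(s$mean_size), s$mean_size[nrow(s)]))
  cat(sprintf("  max cluster size: %d\n", max(s$max_size)))
  invisible(x)
}

#' @export
plot.cluster_series <- function(x, ...) {
  s <- x$stats
  graphics::plot(s$time / 1000, s$mean_size, type = "l",
                 xlab = "time (us)", ylab = "mean cluster size", ...)
  invisible(x)
}

#' Neighbour-count fractions with bootstrap standard errors
#'
#' Fractions of proteins with exactly 1, exactly 2, or more than 2 protein
#' neighbours (contact-graph degree), pooled over the frames of a
#' [cluster_size_series()]; proteins with no neighbours are reported
#' separately. Standard errors are bootstrap estimates obtained by
#' resampling proteins with replacement (default 1000 iterations).
#'
#' @param series a `cluster_series`, or a `cluster_frame`.
#' @param n_boot bootstrap iterations (>= 2).
#' @param seed RNG seed for resampling.
#' @param frames which analysed frames to pool; default all.
#' @return data frame with rows `0`, `1`, `2`, `>2`: `fraction` and
#'   `se_boot`.
#' @export
neighbor_fractions <- function(series, n_boot = 1000L, seed = NULL,
                               frames = NULL) {
  if (n_boot < 2L)
    mc_stop("'n_boot' must be at least 2", "mc_argument_error")
  deg <- if (inherits(series, "cluster_frame")) {
    matrix(series$degree, nrow = 1L)
  } else {
    series$degree[frames %||% seq_len(nrow(series$degree)), , drop = FALSE]
  }
  np <- ncol(deg)
  if (!is.null(seed)) set.seed(seed)
  frac_of <- function(cols) {
    d <- deg[, cols, drop = FALSE]
    c(`0` = mean(d == 0L), `1` = mean(d == 1L),
      `2` = mean(d == 2L), `>2` = mean(d > 2L))
  }
  point <- frac_of(seq_len(np))
  boots <- vapply(seq_len(n_boot), function(b)
    frac_of(sample.int(np, np, replace = TRUE)), numeric(4))
  se <- apply(boots, 1L, stats::sd)
  data.frame(neighbors = names(point), fraction = unname(point),
             se_boot = unname(se))
}

#' 2D map of lateral protein-pair displacements
#'
#' Accumulates the minimum-image lateral displacement vectors between all
#' unordered protein pairs (both orientations, so the map is inversion
#' symmetric) over a frame window into a square 2D histogram, normalized to
#' a maximum of 1. The first-shell structure of this map distinguishes
#' linear from branched packing.
#'
#' @param centroids a `protein_centroids`.
#' @param bin_width histogram bin width (nm).
#' @param window integer frame range to accumulate; default all frames.
#' @param max_range half-width of the map (nm).
#' @return a `pair_displacement_map`: `counts` matrix (normalized), `breaks`
#'   bin edges (nm), `bin_width`, `window`.
#' @export
pair_displacement_map <- function(centroids, bin_width = 0.5, window = NULL,
                                  max_range = 15) {
  stopifnot(inherits(centroids, "protein_centroids"))
  if (bin_width <= 0)
    mc_stop("'bin_width' must be positive", "mc_argument_error")
  window <- window %||% seq_len(nrow(centroids$x))
  # odd bin count with centres at multiples of bin_width, so the histogram
  # is exactly inversion symmetric
  half <- ceiling(max_range / bin_width)
  nb <- 2L * half + 1L
  breaks <- seq(-(half + 0.5) * bin_width, (half + 0.5) * bin_width,
                by = bin_width)
  counts <- matrix(0, nb, nb)
  np <- ncol(centroids$x)
  if (np >= 2L) {
    up <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    for (f in window) {
      box <- centroids$box[f, ]
      dx <- centroids$x[f, up[, 2]] - centroids$x[f, up[, 1]]
      dy <- centroids$y[f, up[, 2]] - centroids$y[f, up[, 1]]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dx <- c(dx, -dx); dy <- c(dy, -dy)  # unordered pairs: both signs
      keep <- abs(dx) < max_range & abs(dy) < max_range
      if (!any(keep)) next
      ix <- round(dx[keep] / bin_width) + half + 1L
      iy <- round(dy[keep] / bin_width) + half + 1L
      tab <- unclass(table(factor(ix, levels = 1:nb),
                           factor(iy, levels = 1:nb)))
      dimnames(tab) <- NULL
      counts <- counts + tab
    }
  }
  if (max(counts) > 0) counts <- counts / max(counts)
  structure(list(counts = counts, breaks = breaks, bin_width = bin_width,
                 window = range(window)),
            class = "pair_displacement_map")
}

#' @export
plot.pair_displacement_map <- function(x, ...) {
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::image(mid, mid, x$counts, col = grDevices::gray(seq(1, 0, -0.01)),
                  xlab = "dx (nm)", ylab = "dy (nm)", asp = 1, ...)
  invisible(x)
}

#' Residue-level contact frequencies
#'
#' Counts contacts in which a residue's centroid lies within `cutoff`
#' (default 0.7 nm) of a partner centroid — either residues of *other*
#' proteins (`partner = "protein"`) or lipid headgroup beads
#' (`partner = "lipid-headgroup"`) — pooled over all protein copies (by
#' residue id) and all frames of the window. Frequencies are normalized by
#' the total interaction count, matching "fraction of total interactions"
#' reporting; `threshold` helps select residues above a given percentage.
#'
#' @param traj an [mc_trajectory()].
#' @param partner `"protein"` or `"lipid-headgroup"`.
#' @param cutoff contact distance (nm).
#' @param window frames to analyse; default all.
#' @return a `residue_contact_map`: data frame with `residue`, `count`,
#'   `frequency`; attribute `total` (total contacts counted).
#' @export
residue_contact_frequencies <- function(traj, partner = c("protein",
                                                          "lipid-headgroup"),
                                        cutoff = 0.7, window = NULL) {
  partner <- match.arg(partner)
  top <- traj$topology
  prot <- attr(top, "proteins")
  if (length(prot) == 0L)
    mc_stop("topology flags no protein molecules", "mc_labelling_error")
  window <- window %||% seq_len(n_frames(traj))
  # per-protein per-residue bead index lists
  pidx <- lapply(prot, function(m) which(top$molecule == m))
  resids <- sort(unique(unlist(lapply(pidx, function(i) top$residue[i]))))
  counts <- setNames(numeric(length(resids)), resids)
  head_idx <- which(top$role == "headgroup")
  if (partner == "lipid-headgroup" && length(head_idx) == 0L)
    mc_stop("no beads labelled 'headgroup' in the topology",
            "mc_labelling_error")
  for (f in window) {
    box <- traj$box[f, ]
    # residue centroids per protein (lateral + z, contacts are 3D at the
    # residue scale but minimum image applied laterally)
    cent <- lapply(pidx, function(idx) {
      sp <- split(idx, top$residue[idx])
      t(vapply(sp, function(ii) c(
        mean(traj$coords[f, ii, 1]), mean(traj$coords[f, ii, 2]),
        mean(traj$coords[f, ii, 3])), numeric(3)))
    })
    if (partner == "protein") {
      npr <- length(cent)
      if (npr < 2L) next
      for (a in seq_len(npr - 1L)) for (b in (a + 1L):npr) {
        ca <- cent[[a]]; cb <- cent[[b]]
        dx <- outer(ca[, 1], cb[, 1], `-`)
        dy <- outer(ca[, 2], cb[, 2], `-`)
        dz <- outer(ca[, 3], cb[, 3], `-`)
        dx <- dx - box[1] * round(dx / box[1])
        dy <- dy - box[2] * round(dy / box[2])
        hit <- which(sqrt(dx^2 + dy^2 + dz^2) <= cutoff, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        ra <- rownames(ca)[hit[, 1]]; rb <- rownames(cb)[hit[, 2]]
        for (r in c(ra, rb)) counts[r] <- counts[r] + 1
      }
    } else {
      hx <- traj$coords[f, head_idx, 1]
      hy <- traj$coords[f, head_idx, 2]
      hz <- traj$coords[f, head_idx, 3]
      for (a in seq_along(cent)) {
        ca <- cent[[a]]
        dx <- outer(ca[, 1], hx, `-`); dx <- dx - box[1] * round(dx / box[1])
        dy <- outer(ca[, 2], hy, `-`); dy <- dy - box[2] * round(dy / box[2])
        dz <- outer(ca[, 3], hz, `-`)
        nhit <- rowSums(sqrt(dx^2 + dy^2 + dz^2) <= cutoff)
        counts[rownames(ca)] <- counts[rownames(ca)] + nhit
      }
    }
  }
  total <- sum(counts)
  out <- data.frame(residue = as.integer(names(counts)),
                    count = unname(counts),
                    frequency = if (total > 0) unname(counts) / total
                                else 0 * unname(counts))
  attr(out, "total") <- total
  attr(out, "cutoff") <- cutoff
  attr(out, "partner") <- partner
  class(out) <- c("residue_contact_map", "data.frame")
  out
}

#' Residues above a contact-frequency threshold
#'
#' @param map a `residue_contact_map`.
#' @param percent threshold as a percentage of total interactions.
#' @return the subset of residues with `frequency >= percent / 100`.
#' @export
contact_hotspots <- function(map, percent = 0.7) {
  map[map$frequency >= percent / 100, , drop = FALSE]
}
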