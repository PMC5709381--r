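#' Lateral radial distribution function of lipids around proteins
#'
#' Computes the 2D (in-plane) radial distribution function
#' `g(r) = <area density of targets in the annulus [r, r + dr) around a
#' reference> / (N_target / A_box)`, averaged over references and frames,
#' with lateral minimum-image distances. The normalization is per leaflet:
#' target beads can be restricted to one leaflet so the two monolayers are
#' not conflated. By default the reference is the protein centroid
#' (consistent with the cluster analysis); `reference` can also be an
#' explicit coordinate matrix or particle selection, e.g. protein surface
#' beads.
#'
#' No excluded-area correction is applied for the protein footprint, so
#' `g(r)` is depleted below the protein radius by construction.
#'
#' @param traj an [mc_trajectory()].
#' @param reference `"centroid"` (per-protein lateral centroids), or integer
#'   particle indices whose positions are used as references.
#' @param target integer particle indices, or a species/role name; default
#'   all `headgroup` beads.
#' @param r_max largest distance (nm); at most half the smallest lateral box
#'   edge.
#' @param dr bin width (nm).
#' @param leaflet restrict targets to `"inner"`, `"outer"` or `"both"`.
#' @param window frames to average; default all.
#' @param residue_range residues for centroid references, see
#'   [protein_centroids()].
#' @return an `rdf_profile`: data frame with `r` (bin centre, nm), `g`, and
#'   `count` (raw pair counts per bin); attributes record the conventions.
#' @export
lateral_rdf <- function(traj, reference = "centroid", target = NULL,
                        r_max = 12, dr = 0.1,
                        leaflet = c("both", "inner", "outer"),
                        window = NULL, residue_range = NULL) {
  leaflet <- match.arg(leaflet)
  if (r_max > min(traj$box[, 1:2]) / 2)
    mc_stop("'r_max' exceeds half the smallest lateral box edge",
            "mc_argument_error")
  if (dr <= 0) mc_stop("'dr' must be positive", "mc_argument_error")
  window <- window %||% seq_len(n_frames(traj))
  tgt <- if (is.null(target)) which(traj$topology$role == "headgroup")
         else resolve_selection(traj, target)
  if (leaflet != "both")
    tgt <- tgt[traj$topology$leaflet[tgt] == leaflet]
  if (length(tgt) == 0L)
    mc_stop("target selection is empty", "mc_argument_error")
  cent <- NULL
  if (identical(reference, "centroid"))
    cent <- protein_centroids(traj, residue_range)
  nb <- ceiling(r_max / dr)
  counts <- numeric(nb)
  n_ref_frames <- 0L
  dens_sum <- 0
  for (f in window) {
    box <- traj$box[f, ]
    if (is.null(cent)) {
      ridx <- resolve_selection(traj, reference)
      if (length(ridx) == 0L)
        mc_stop("reference selection is empty", "mc_argument_error")
      rx <- traj$coords[f, ridx, 1]; ry <- traj$coords[f, ridx, 2]
    } else {
      rx <- cent$x[f, ]; ry <- cent$y[f, ]
    }
    tx <- traj$coords[f, tgt, 1]; ty <- traj$coords[f, tgt, 2]
    dx <- outer(rx, tx, `-`); dx <- dx - box[1] * round(dx / box[1])
    dy <- outer(ry, ty, `-`); dy <- dy - box[2] * round(dy / box[2])
    r <- sqrt(dx^2 + dy^2)
    r <- r[r > 0 & r < r_max]  # drop self-pairs when reference is a target
    if (length(r)) {
      ib <- floor(r / dr) + 1L
      counts <- counts + tabulate(ib, nb)
    }
    n_ref_frames <- n_ref_frames + length(rx)
    dens_sum <- dens_sum + length(tgt) / (box[1] * box[2])
  }
  mids <- (seq_len(nb) - 0.5) * dr
  shell_area <- pi * ((mids + dr / 2)^2 - (mids - dr / 2)^2)
  rho <- dens_sum / length(window)
  g <- counts / n_ref_frames / shell_area / rho
  out <- data.frame(r = mids, g = g, count = counts)
  attr(out, "dr") <- dr
  attr(out, "rho") <- rho
  attr(out, "n_reference") <- n_ref_frames / length(window)
  attr(out, "leaflet") <- leaflet
  class(out) <- c("rdf_profile", "data.frame")
  out
}

#' @export
plot.rdf_profile <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (nm)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 2, col = "grey")
  invisible(x)
}
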