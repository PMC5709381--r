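#' Assign phosphate beads to leaflets
#'
#' Labels each selected bead `inner`/`outer` by the sign of its z coordinate
#' relative to the local bilayer midplane. The midplane is bootstrapped from
#' the pooled per-cell mean height of all selected beads (which approximates
#' the midplane at any undulation amplitude), then refined by gridding each
#' provisional leaflet, averaging the two leaflet fields and relabelling
#' against the local midplane height; this tracks undulations far larger
#' than the leaflet separation.
#'
#' @param traj an [mc_trajectory()].
#' @param frame frame to label.
#' @param selection bead indices; default all `phosphate`-role beads.
#' @param g grid spacing (nm) for the local midplane.
#' @param iterations refinement passes.
#' @return character vector of labels (`"inner"` = below the midplane).
#' @export
assign_leaflets <- function(traj, frame = 1L, selection = NULL, g = 1,
                            iterations = 2L) {
  sel <- selection %||% which(traj$topology$role == "phosphate")
  if (length(sel) < 2L)
    mc_stop("need at least 2 phosphate beads to assign leaflets",
            "mc_labelling_error")
  x <- traj$coords[frame, sel, 1]; y <- traj$coords[frame, sel, 2]
  z <- traj$coords[frame, sel, 3]
  L <- traj$box[frame, 1:2]
  pooled <- fill_empty_cells(grid_mean_z(x, y, z, L, g)$z)$z
  ci <- cell_index(x, L[1], g, nrow(pooled))
  cj <- cell_index(y, L[2], g, ncol(pooled))
  lab <- ifelse(z < pooled[cbind(ci, cj)], "inner", "outer")
  if (length(unique(lab)) == 1L) {
    mc_warn("only one leaflet present in the selection",
            "mc_leaflet_warning")
    return(lab)
  }
  for (it in seq_len(iterations)) {
    fi <- fill_empty_cells(grid_mean_z(x[lab == "inner"], y[lab == "inner"],
                                       z[lab == "inner"], L, g)$z)$z
    fo <- fill_empty_cells(grid_mean_z(x[lab == "outer"], y[lab == "outer"],
                                       z[lab == "outer"], L, g)$z)$z
    ci <- cell_index(x, L[1], g, nrow(fi))
    cj <- cell_index(y, L[2], g, ncol(fi))
    # nearest leaflet field wins; robust where one leaflet has no beads in
    # a cell (the empty-cell fill carries its height in from neighbours)
    lab <- ifelse(abs(z - fi[cbind(ci, cj)]) <= abs(z - fo[cbind(ci, cj)]),
                  "inner", "outer")
    if (length(unique(lab)) == 1L) break
  }
  lab
}

cell_index <- function(u, L, g, n) pmin(floor((u %% L) / g) + 1L, n)

grid_mean_z <- function(x, y, z, L, g) {
  nx <- max(1L, floor(L[1] / g)); ny <- max(1L, floor(L[2] / g))
  ci <- cell_index(x, L[1], g, nx); cj <- cell_index(y, L[2], g, ny)
  lin <- (cj - 1L) * nx + ci
  cnt <- tabulate(lin, nx * ny)
  sums <- numeric(nx * ny)
  agg <- rowsum(z, lin)
  sums[as.integer(rownames(agg))] <- agg
  zmean <- matrix(ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_), nx, ny)
  list(z = zmean, occupancy = matrix(cnt, nx, ny))
}

# iterative nearest-neighbour averaging of NA cells (periodic neighbours)
fill_empty_cells <- function(z) {
  filled <- is.na(z)
  if (!any(filled)) return(list(z = z, filled = filled))
  if (all(is.na(z)))
    mc_stop("all grid cells are empty", "mc_data_error")
  nx <- nrow(z); ny <- ncol(z)
  up <- function(m) m[c(nx, 1:(nx - 1)), , drop = FALSE]
  dn <- function(m) m[c(2:nx, 1), , drop = FALSE]
  lf <- function(m) m[, c(ny, 1:(ny - 1)), drop = FALSE]
  rt <- function(m) m[, c(2:ny, 1), drop = FALSE]
  while (any(is.na(z))) {
    known <- !is.na(z)
    zz <- z; zz[!known] <- 0
    s <- up(zz) + dn(zz) + lf(zz) + rt(zz)
    n <- up(known) + dn(known) + lf(known) + rt(known)
    newly <- !known & n > 0
    if (!any(newly)) break
    z[newly] <- (s / pmax(n, 1L))[newly]
  }
  list(z = z, filled = filled)
}

#' Gridded bilayer height field
#'
#' Projects the selected beads (by default phosphates) of one frame onto a
#' lateral grid of spacing `g` (default 0.5 nm) and records the per-cell
#' mean z. Empty cells are filled by iterative nearest-neighbour averaging
#' (periodic) and flagged. With `leaflet = "midplane"` (the default for
#' spectra) the inner and outer leaflet fields are computed separately and
#' averaged.
#'
#' @param traj an [mc_trajectory()].
#' @param frame frame index.
#' @param selection bead indices; default all `phosphate` beads.
#' @param g grid spacing (nm).
#' @param leaflet `"midplane"`, `"inner"`, `"outer"` or `"all"` (pool both
#'   leaflets into one field).
#' @param leaflet_labels optional labels per selected bead; computed by
#'   [assign_leaflets()] when needed and absent from the topology.
#' @return a `height_field`: `z` matrix (nx x ny, nm), `occupancy`,
#'   `filled` flags, `g`, `L`, `frame`, `leaflet`.
#' @export
height_field <- function(traj, frame = 1L, selection = NULL, g = 0.5,
                         leaflet = c("midplane", "inner", "outer", "all"),
                         leaflet_labels = NULL) {
  leaflet <- match.arg(leaflet)
  sel <- selection %||% which(traj$topology$role == "phosphate")
  if (length(sel) == 0L)
    mc_stop("selection is empty", "mc_argument_error")
  L <- traj$box[frame, 1:2]
  if (any(L < 10 * g))
    mc_stop("box lateral dimensions must be at least 10 grid cells",
            "mc_argument_error")
  x <- traj$coords[frame, sel, 1]; y <- traj$coords[frame, sel, 2]
  z <- traj$coords[frame, sel, 3]
  one_field <- function(keep) {
    f <- grid_mean_z(x[keep], y[keep], z[keep], L, g)
    filled <- fill_empty_cells(f$z)
    list(z = filled$z, occupancy = f$occupancy, filled = filled$filled)
  }
  if (leaflet == "all") {
    f <- one_field(rep(TRUE, length(sel)))
  } else {
    labs <- leaflet_labels %||% {
      tl <- traj$topology$leaflet[sel]
      if (all(tl == "unassigned"))
        assign_leaflets(traj, frame, sel) else tl
    }
    if (leaflet %in% c("inner", "outer")) {
      f <- one_field(labs == leaflet)
    } else {
      fi <- one_field(labs == "inner"); fo <- one_field(labs == "outer")
      f <- list(z = (fi$z + fo$z) / 2, occupancy = fi$occupancy + fo$occupancy,
                filled = fi$filled | fo$filled)
    }
  }
  structure(c(f, list(g = g, L = L, frame = frame, leaflet = leaflet)),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf(
    "<height_field> %d x %d cells (g = %g nm, %s), frame %d; %.1f%% cells filled by interpolation\n",
    nrow(x$z), ncol(x$z), x$g, x$leaflet, x$frame, 100 * mean(x$filled)))
  invisible(x)
}

#' Radially averaged undulation power spectrum
#'
#' For each height field, takes the 2D discrete Fourier transform of the
#' mean-subtracted field with the forward transform divided by the number of
#' grid cells (so `sum_q |h_q|^2` equals the real-space variance exactly —
#' Parseval), accumulates `|h_q|^2` into radial wavenumber bins of width
#' `2 pi / L` (one fundamental mode), and averages over frames. The q = 0
#' mode is excluded.
#'
#' @param fields a `height_field` or list of them (same grid).
#' @return a `power_spectrum1d`: data frame with `q` (bin centre, nm^-1),
#'   `power` (mean `|h_q|^2` per mode, nm^2), `n_modes`; attributes
#'   `n_frames`, `total_power` (mean over frames of `sum_q |h_q|^2`) and
#'   `variance` (mean real-space variance, equal by Parseval).
#' @export
undulation_spectrum <- function(fields) {
  if (inherits(fields, "height_field")) fields <- list(fields)
  dims <- vapply(fields, function(f) dim(f$z), integer(2))
  if (any(dims != dims[, 1]))
    mc_stop("all height fields must share one grid", "mc_structural_error")
  nx <- dims[1, 1]; ny <- dims[2, 1]
  L <- fields[[1]]$L
  dq <- 2 * pi / L[1]
  qx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / L[1]
  qy <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / L[2]
  qmag <- sqrt(outer(qx^2, qy^2, `+`))
  bin <- as.integer(round(qmag / dq))
  nb <- max(bin)
  acc <- numeric(nb); total <- 0; varsum <- 0
  for (f in fields) {
    h <- f$z - mean(f$z)
    p <- Mod(stats::fft(h) / (nx * ny))^2
    varsum <- varsum + mean(h^2)
    total <- total + sum(p[bin > 0L])
    agg <- rowsum(as.numeric(p[bin > 0L]), bin[bin > 0L], reorder = TRUE)
    acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
  }
  n_modes <- tabulate(bin[bin > 0L], nb)
  keep <- n_modes > 0L
  out <- data.frame(q = (seq_len(nb) * dq)[keep],
                    power = (acc / length(fields))[keep] / n_modes[keep],
                    n_modes = n_modes[keep])
  attr(out, "n_frames") <- length(fields)
  attr(out, "total_power") <- total / length(fields)
  attr(out, "variance") <- varsum / length(fields)
  class(out) <- c("power_spectrum1d", "data.frame")
  out
}

#' @export
plot.power_spectrum1d <- function(x, ...) {
  graphics::plot(x$q, x$power, log = "xy", xlab = expression(q ~ (nm^-1)),
                 ylab = expression("<|h(q)|"^2 * "> (nm"^2 * ")"),
                 type = "b", ...)
  invisible(x)
}

#' Normalized z-density profile
#'
#' Histogram of the z coordinates of the selected beads over a frame window,
#' normalized to unit integral (so values are probability density per nm).
#'
#' @param traj an [mc_trajectory()].
#' @param selection bead indices; default `phosphate` beads.
#' @param bin bin width (nm).
#' @param window frames to pool; default all.
#' @param center subtract the per-frame mean z before binning (removes
#'   box-drift broadening).
#' @return a `density_profile`: data frame with `z` (bin centre) and
#'   `density` (1/nm).
#' @export
z_density_profile <- function(traj, selection = NULL, bin = 0.1,
                              window = NULL, center = FALSE) {
  if (bin <= 0) mc_stop("'bin' must be positive", "mc_argument_error")
  sel <- selection %||% which(traj$topology$role == "phosphate")
  if (length(sel) == 0L)
    mc_stop("selection is empty", "mc_argument_error")
  window <- window %||% seq_len(n_frames(traj))
  zs <- unlist(lapply(window, function(f) {
    z <- traj$coords[f, sel, 3]
    if (center) z - mean(z) else z
  }))
  breaks <- seq(floor(min(zs) / bin) * bin, ceiling(max(zs) / bin) * bin + bin,
                by = bin)
  h <- graphics::hist(zs, breaks = breaks, plot = FALSE)
  out <- data.frame(z = h$mids, density = h$counts / (length(zs) * bin))
  attr(out, "bin") <- bin
  class(out) <- c("density_profile", "data.frame")
  out
}
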