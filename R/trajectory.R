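#' Labelled particle trajectories under periodic boundaries
#'
#' `mc_trajectory()` is the package's central container: a frames x particles
#' x 3 coordinate array (nm) together with a per-frame orthorhombic box, a
#' constant frame spacing `dt` (ns), and a topology that labels every
#' particle by species, molecule, residue and bead role. All analyses in the
#' package consume this container; readers for GRO/PDB files and the internal
#' container produce it.
#'
#' Internal units are nm and ns throughout; converters live at the I/O
#' boundary only. Only orthorhombic boxes are supported.
#'
#' @param coords numeric array of dimension `c(n_frames, n_particles, 3)`,
#'   coordinates in nm.
#' @param box per-frame box edges in nm: a length-3 vector (constant box) or
#'   an `n_frames x 3` matrix. All edges must be positive.
#' @param dt frame spacing in ns (constant across the trajectory).
#' @param topology a data frame as built by [mc_topology()], or `NULL` for a
#'   default single-species topology.
#' @param wrapped logical; `TRUE` if coordinates are wrapped into `[0, edge)`.
#' @param unwrapped optional array of the same shape holding the unwrapped
#'   (image-continuous) coordinates, kept alongside wrapped ones by the
#'   synthetic generators.
#' @return an object of class `mc_trajectory`.
#' @seealso [mc_topology()], [read_trajectory()], [unwrap()],
#'   [remove_com_motion()]
#' @export
mc_trajectory <- function(coords, box, dt = 1, topology = NULL,
                          wrapped = FALSE, unwrapped = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    mc_stop("'coords' must be an n_frames x n_particles x 3 array",
            "mc_structural_error")
  n_frames <- dim(coords)[1]
  n_particles <- dim(coords)[2]
  box <- validate_box(box, n_frames)
  check_positive(dt, "dt")
  if (is.null(topology)) {
    topology <- mc_topology(data.frame(
      species = rep("particle", n_particles),
      molecule = seq_len(n_particles),
      residue = 1L,
      role = "other",
      leaflet = "unassigned"
    ))
  }
  if (nrow(topology) != n_particles)
    mc_stop(sprintf(
      "topology has %d particles but coordinates have %d",
      nrow(topology), n_particles), "mc_structural_error")
  if (!is.null(unwrapped) && !identical(dim(unwrapped), dim(coords)))
    mc_stop("'unwrapped' must match the shape of 'coords'",
            "mc_structural_error")
  structure(list(
    coords = coords, box = box, dt = dt, topology = topology,
    wrapped = isTRUE(wrapped), unwrapped = unwrapped
  ), class = "mc_trajectory")
}

# box -> n_frames x 3 matrix with positive edges
validate_box <- function(box, n_frames) {
  if (is.null(dim(box))) {
    if (length(box) == 3L) box <- matrix(box, n_frames, 3, byrow = TRUE)
    else mc_stop("'box' must be length 3 or an n_frames x 3 matrix",
                 "mc_structural_error")
  }
  box <- as.matrix(box)
  if (nrow(box) == 1L && n_frames > 1L)
    box <- box[rep(1L, n_frames), , drop = FALSE]
  if (ncol(box) != 3L || nrow(box) != n_frames)
    mc_stop("'box' must be an n_frames x 3 matrix of edges",
            "mc_structural_error")
  if (any(!is.finite(box)) || any(box <= 0))
    mc_stop("box edges must all be positive and finite (orthorhombic only)",
            "mc_argument_error")
  unname(box)
}

#' Particle labelling for a trajectory
#'
#' Builds the topology table attached to an [mc_trajectory()]. Each particle
#' record carries a species name, a molecule id, a 1-based residue id within
#' its molecule, a bead role (`"protein-bead"`, `"headgroup"`, `"phosphate"`,
#' `"tail"` or `"other"`) and a leaflet tag (`"inner"`, `"outer"`,
#' `"unassigned"`). Molecule ids listed in `proteins` are treated as channel
#' proteins by the cluster analyses.
#'
#' @param records data frame with columns `species`, `molecule`, `residue`,
#'   `role`, `leaflet` (missing label columns are filled with defaults).
#' @param proteins integer vector of molecule ids that are proteins; defaults
#'   to the molecules containing `"protein-bead"` roles.
#' @return the validated data frame with class `mc_topology` and attribute
#'   `proteins`.
#' @export
mc_topology <- function(records, proteins = NULL) {
  records <- as.data.frame(records)
  if (is.null(records$species)) mc_stop("topology needs a 'species' column",
                                        "mc_structural_error")
  n <- nrow(records)
  if (is.null(records$molecule)) records$molecule <- seq_len(n)
  if (is.null(records$residue)) records$residue <- 1L
  if (is.null(records$role)) records$role <- "other"
  if (is.null(records$leaflet)) records$leaflet <- "unassigned"
  roles <- c("protein-bead", "headgroup", "phosphate", "tail", "other")
  if (!all(records$role %in% roles))
    mc_stop(sprintf("bead roles must be one of: %s",
                    paste(roles, collapse = ", ")), "mc_labelling_error")
  if (!all(records$leaflet %in% c("inner", "outer", "unassigned")))
    mc_stop("leaflet tags must be 'inner', 'outer' or 'unassigned'",
            "mc_labelling_error")
  records$molecule <- as.integer(records$molecule)
  records$residue <- as.integer(records$residue)
  if (any(is.na(records$molecule)))
    mc_stop("every particle must belong to exactly one molecule",
            "mc_labelling_error")
  if (any(records$residue < 1L, na.rm = TRUE))
    mc_stop("residue ids are 1-based positive integers",
            "mc_labelling_error")
  if (is.null(proteins))
    proteins <- sort(unique(records$molecule[records$role == "protein-bead"]))
  attr(records, "proteins") <- as.integer(proteins)
  class(records) <- c("mc_topology", "data.frame")
  records
}

#' @export
print.mc_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "<mc_trajectory> %d frame%s x %d particles, dt = %g ns (%g ns total)\n",
    d[1], if (d[1] == 1L) "" else "s", d[2], x$dt, (d[1] - 1) * x$dt))
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm, %s\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3],
              if (x$wrapped) "wrapped" else "unwrapped"))
  sp <- table(x$topology$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
  np <- length(attr(x$topology, "proteins"))
  if (np > 0) cat(sprintf("  proteins: %d molecules\n", np))
  invisible(x)
}

#' Trajectory dimensions
#'
#' @param traj an [mc_trajectory()].
#' @return frame or particle count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Minimum-image displacement between points in a periodic box
#'
#' Returns the displacement `b - a` of smallest norm among all periodic
#' images. Each component of the result lies in `(-edge/2, edge/2]`. With
#' `lateral_only = TRUE` only x and y are image-corrected (z returned as the
#' raw difference), the convention used for all in-plane membrane analyses.
#'
#' @param a,b numeric vectors (or matrices with one row per point) of
#'   coordinates in nm.
#' @param box length-3 box edges in nm.
#' @param lateral_only apply the periodic correction to x,y only.
#' @return displacement vector (or matrix) in nm.
#' @export
minimum_image_displacement <- function(a, b, box, lateral_only = FALSE) {
  a <- rbind(a); b <- rbind(b)
  d <- b - a
  ncomp <- if (lateral_only) 2L else min(3L, ncol(d))
  for (k in seq_len(ncomp)) {
    L <- box[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
    # boundary convention: exactly -L/2 maps to +L/2
    at_edge <- abs(d[, k] + L / 2) < 1e-12
    d[at_edge, k] <- L / 2
  }
  if (nrow(d) == 1L) drop(d) else d
}

#' Remove centre-of-mass motion from a trajectory
#'
#' Translates every frame so that the centroid of `selection` stays at its
#' frame-0 position, eliminating net drift before diffusion analysis. All
#' particles in a frame are shifted identically. The default selection is all
#' particles (proteins and lipids together).
#'
#' @param traj an [mc_trajectory()]; should be unwrapped so the centroid is
#'   well defined.
#' @param selection integer particle indices defining the reference centroid;
#'   default all particles.
#' @return the translated trajectory (idempotent).
#' @export
remove_com_motion <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "mc_trajectory"))
  sel <- selection %||% seq_len(n_particles(traj))
  if (length(sel) == 0L)
    mc_stop("'selection' must contain at least one particle",
            "mc_argument_error")
  co <- if (traj$wrapped && !is.null(traj$unwrapped)) traj$unwrapped else traj$coords
  # per-frame centroid drift of the selection, relative to frame 1
  for (k in 1:3) {
    cm <- rowMeans(co[, sel, k, drop = FALSE])
    shift <- cm - cm[1L]
    co[, , k] <- co[, , k] - shift
  }
  traj$coords <- co
  traj$wrapped <- FALSE
  traj$unwrapped <- NULL
  traj
}

#' Unwrap a wrapped trajectory
#'
#' Reconstructs image-continuous coordinates by accumulating per-frame
#' minimum-image steps. Valid when every particle moves less than half a box
#' edge between consecutive frames; larger steps are ambiguous and trigger a
#' warning naming the first offending particle and frame.
#'
#' @param traj a wrapped [mc_trajectory()].
#' @return an unwrapped trajectory; re-wrapping with [wrap()] recovers the
#'   input exactly.
#' @export
unwrap <- function(traj) {
  stopifnot(inherits(traj, "mc_trajectory"))
  if (!traj$wrapped) return(traj)
  co <- traj$coords
  nf <- dim(co)[1]
  if (nf > 1L) {
    for (k in 1:3) {
      x <- co[, , k, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = nf)
      L <- traj$box[, k]
      dx <- x[-1L, , drop = FALSE] - x[-nf, , drop = FALSE]
      njump <- round(dx / L[-nf])
      # a minimum-image step close to half the box edge is ambiguous
      big <- abs(dx - njump * L[-nf]) >= 0.49 * L[-nf]
      if (any(big)) {
        ij <- which(big, arr.ind = TRUE)[1L, ]
        mc_warn(sprintf(
          "step of particle %d between frames %d and %d is >= half the box edge; image ambiguous",
          ij[2], ij[1], ij[1] + 1L), "mc_unwrap_warning")
      }
      dx <- dx - njump * L[-nf]
      x[-1L, ] <- x[rep(1L, nf - 1L), , drop = FALSE] +
        apply(dx, 2L, cumsum)
      co[, , k] <- x
    }
  }
  traj$coords <- co
  traj$wrapped <- FALSE
  traj$unwrapped <- NULL
  traj
}

#' Wrap coordinates into the primary box
#'
#' @param traj an [mc_trajectory()].
#' @return trajectory with every coordinate in `[0, edge)`.
#' @export
wrap <- function(traj) {
  stopifnot(inherits(traj, "mc_trajectory"))
  co <- traj$coords
  for (k in 1:3) {
    L <- traj$box[, k]
    co[, , k] <- co[, , k] - floor(co[, , k] / L) * L
  }
  mc_trajectory(co, traj$box, traj$dt, traj$topology, wrapped = TRUE,
                unwrapped = if (traj$wrapped) traj$unwrapped else traj$coords)
}

# coordinates to use for displacement-based analyses: unwrapped view
unwrapped_coords <- function(traj, caller = "analysis") {
  if (!traj$wrapped) return(traj$coords)
  if (!is.null(traj$unwrapped)) return(traj$unwrapped)
  mc_stop(sprintf(
    "%s requires an unwrapped trajectory; call unwrap() first", caller),
    "mc_precondition_error")
}
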