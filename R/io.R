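#' Read a trajectory from file
#'
#' Supported inputs: a GRO coordinate file (single frame, box from the last
#' line), a PDB file (single frame, coordinates converted from Angstrom to
#' nm; requires the bio3d package), or the package's internal container
#' written by [write_trajectory()]. GROMACS binary trajectories (XTC/TRR)
#' are not readable here; convert to GRO frames or the internal container
#' first.
#'
#' @param coordinate_file path to a `.gro`, `.pdb` or internal `.mct` file.
#' @param trajectory_file reserved; multi-frame input currently comes from
#'   the internal container only.
#' @param labels optional config: a named list mapping species names to
#'   residue-name patterns (regular expressions) and optionally
#'   `roles = c(pattern = role)` to assign bead roles by atom-name pattern.
#' @param expect_frames optional frame count; a mismatch raises a structural
#'   error (guards against truncated trajectories).
#' @return an [mc_trajectory()].
#' @export
read_trajectory <- function(coordinate_file, trajectory_file = NULL,
                            labels = NULL, expect_frames = NULL) {
  if (!file.exists(coordinate_file))
    mc_stop(sprintf("file not found: %s", coordinate_file), "mc_format_error")
  ext <- tolower(tools::file_ext(coordinate_file))
  traj <- switch(ext,
    gro = read_gro(coordinate_file, labels = labels),
    pdb = read_pdb_frame(coordinate_file, labels = labels),
    mct = read_container(coordinate_file),
    xtc = ,
    trr = mc_stop(sprintf(
      "GROMACS binary format '%s' is not supported; export GRO frames or use the internal container",
      ext), "mc_format_error"),
    mc_stop(sprintf("unrecognized trajectory format '.%s'", ext),
            "mc_format_error")
  )
  if (!is.null(expect_frames) && n_frames(traj) != expect_frames)
    mc_stop(sprintf("expected %d frames but read %d from %s",
                    expect_frames, n_frames(traj), coordinate_file),
            "mc_structural_error")
  traj
}

#' Write a trajectory to the internal container
#'
#' The container is a self-describing serialized bundle (format tag,
#' coordinate array, box series, dt, label table) whose read/write round
#' trip is bitwise lossless.
#'
#' @param traj an [mc_trajectory()].
#' @param path output path, conventionally `.mct`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mc_trajectory"))
  saveRDS(list(format = "memcrowd-trajectory", version = 1L, traj = traj),
          path)
  invisible(path)
}

read_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    mc_stop(sprintf("cannot read container %s: %s", path, conditionMessage(e)),
            "mc_format_error"))
  if (!identical(obj$format, "memcrowd-trajectory"))
    mc_stop(sprintf("%s is not a memcrowd trajectory container", path),
            "mc_format_error")
  obj$traj
}

#' Read a GRO coordinate file
#'
#' Fixed-width GROMACS GRO format: title, atom count, one line per atom
#' (residue id/name, atom name, index, x y z in nm), and the box line.
#' Only orthorhombic boxes (3 box numbers, or 9 with zero off-diagonals)
#' are accepted.
#'
#' @param path file path.
#' @param labels optional species/role mapping, see [read_trajectory()].
#' @return a single-frame [mc_trajectory()].
#' @export
read_gro <- function(path, labels = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    mc_stop(sprintf("%s: truncated GRO file", path), "mc_format_error")
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms) || length(lines) < natoms + 3L)
    mc_stop(sprintf("%s: atom count line invalid or file truncated (frame 1)",
                    path), "mc_format_error")
  at <- lines[3:(2 + natoms)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atname <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (any(is.na(x) | is.na(y) | is.na(z)))
    mc_stop(sprintf("%s: unparseable coordinates in frame 1", path),
            "mc_format_error")
  boxv <- scan(text = lines[natoms + 3L], quiet = TRUE)
  if (length(boxv) >= 9L && any(abs(boxv[4:9]) > 1e-12))
    mc_stop("triclinic boxes are not supported", "mc_format_error")
  if (length(boxv) < 3L)
    mc_stop(sprintf("%s: invalid box line", path), "mc_format_error")
  coords <- array(0, c(1L, natoms, 3L))
  coords[1, , 1] <- x; coords[1, , 2] <- y; coords[1, , 3] <- z
  topo <- topology_from_names(resid, resname, atname, labels)
  mc_trajectory(coords, boxv[1:3], dt = 1, topology = topo, wrapped = TRUE)
}

#' Write a single frame as a GRO file
#'
#' @param traj an [mc_trajectory()].
#' @param path output path.
#' @param frame frame index to write.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, frame = 1L) {
  stopifnot(inherits(traj, "mc_trajectory"))
  top <- traj$topology
  co <- traj$coords[frame, , , drop = FALSE]
  n <- dim(co)[2]
  lines <- c(
    "memcrowd frame",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            top$residue %% 100000L, substr(top$species, 1, 5),
            substr(top$species, 1, 5), seq_len(n) %% 100000L,
            co[1, , 1], co[1, , 2], co[1, , 3]),
    sprintf("%10.5f%10.5f%10.5f",
            traj$box[frame, 1], traj$box[frame, 2], traj$box[frame, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

read_pdb_frame <- function(path, labels = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    mc_stop("reading PDB files requires the bio3d package", "mc_format_error")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  n <- nrow(a)
  coords <- array(0, c(1L, n, 3L))
  coords[1, , 1] <- a$x / 10; coords[1, , 2] <- a$y / 10
  coords[1, , 3] <- a$z / 10  # Angstrom -> nm
  box <- c(max(coords[1, , 1]) - min(coords[1, , 1]) + 1,
           max(coords[1, , 2]) - min(coords[1, , 2]) + 1,
           max(coords[1, , 3]) - min(coords[1, , 3]) + 1)
  topo <- topology_from_names(a$resno, a$resid, a$elety, labels)
  mc_trajectory(coords, pmax(box, 1), dt = 1, topology = topo,
                wrapped = FALSE)
}

# map residue/atom names to species + roles via the label config
topology_from_names <- function(resid, resname, atname, labels = NULL) {
  species <- resname
  role <- rep("other", length(resname))
  if (!is.null(labels)) {
    for (sp in names(labels)) {
      spec <- labels[[sp]]
      pat <- if (is.list(spec)) spec$pattern %||% sp else spec
      species[grepl(pat, resname)] <- sp
      if (is.list(spec) && !is.null(spec$roles)) {
        for (rp in names(spec$roles))
          role[grepl(pat, resname) & grepl(rp, atname)] <- spec$roles[[rp]]
      }
    }
  }
  # heuristic defaults for common coarse-grained bead names
  role[role == "other" & grepl("^PO4?$", atname)] <- "phosphate"
  mol <- cumsum(c(1L, diff(as.integer(resid)) != 0L))
  mc_topology(data.frame(species = species, molecule = mol,
                         residue = as.integer(resid), role = role,
                         leaflet = "unassigned"))
}
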