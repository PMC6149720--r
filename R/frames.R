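#' Particle frame container
#'
#' Labelled bead coordinates with an orthorhombic periodic box, the input of
#' the trajectory observables ([order_parameter], [density_profile],
#' [bilayer_thickness_pp], [lateral_rdf], [group_distance]).
#'
#' Bead labels follow the coarse-grained membrane vocabulary: `NC3`, `PO4`
#' (phosphate), `GL1`, `GL2` (glycerols), `C1A`..`C4A`, `C1B`..`C4B` (acyl
#' tail beads, `D` marking unsaturated beads, e.g. `D2A`), `OH` (alcohol
#' hydroxyl), `C1T`.. (alcohol tail beads), `W` (water).
#'
#' @param positions N x 3 numeric matrix (Angstrom).
#' @param labels length-N character vector of bead names.
#' @param resid length-N integer vector of residue (molecule) ids.
#' @param box length-3 numeric vector of box edges (Angstrom).
#' @return object of class `particle_frame` (a data.frame with columns
#'   `label`, `resid`, `x`, `y`, `z` and a `box` attribute).
#' @export
particle_frame <- function(positions, labels, resid, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(labels) == nrow(positions),
            length(resid) == nrow(positions), length(box) == 3, all(box > 0))
  df <- data.frame(label = as.character(labels), resid = as.integer(resid),
                   x = positions[, 1], y = positions[, 2], z = positions[, 3],
                   stringsAsFactors = FALSE)
  attr(df, "box") <- as.numeric(box)
  class(df) <- c("particle_frame", "data.frame")
  df
}

frame_box <- function(frame) attr(frame, "box")

#' Write / read particle frames in an XYZ-dialect text format
#'
#' One frame is: a count line `N`, a comment line `box Lx Ly Lz`, then N
#' atom lines `label resid x y z`. Multiple frames are concatenated.
#'
#' @param frames list of [particle_frame] objects.
#' @param path file path.
#' @return `read_frames_xyz` returns a list of `particle_frame`s.
#' @export
write_frames_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    box <- frame_box(fr)
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("box %.6f %.6f %.6f", box[1], box[2], box[3]), con)
    writeLines(sprintf("%s %d %.6f %.6f %.6f", fr$label, fr$resid,
                       fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' @rdname write_frames_xyz
#' @export
read_frames_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("read_frames_xyz: expected atom count at line ", i)
    hdr <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (hdr[1] != "box" || length(hdr) < 4)
      stop("read_frames_xyz: expected 'box Lx Ly Lz' comment at line ", i + 1)
    box <- as.numeric(hdr[2:4])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[[`, character(1), 1)
    rid <- as.integer(vapply(parts, `[[`, character(1), 2))
    pos <- t(vapply(parts, function(p) as.numeric(p[3:5]), numeric(3)))
    frames[[length(frames) + 1]] <- particle_frame(pos, lab, rid, box)
    i <- i + 2 + n
  }
  frames
}

#' Read a GRO-format coordinate file as a particle frame
#'
#' Fixed-width GROMACS coordinate format; nm coordinates are converted to
#' Angstrom. Only orthorhombic boxes are supported.
#'
#' @param path file path.
#' @return a [particle_frame].
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  atoms <- lines[3:(2 + n)]
  resid <- as.integer(substr(atoms, 1, 5))
  lab <- trimws(substr(atoms, 11, 15))
  x <- as.numeric(substr(atoms, 21, 28))
  y <- as.numeric(substr(atoms, 29, 36))
  z <- as.numeric(substr(atoms, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  particle_frame(cbind(x, y, z) * 10, lab, resid, box * 10)
}

#' Synthetic frames with a prescribed bond order parameter
#'
#' Generates frames of two-bead molecules (labels `C1A`, `C2A`) whose
#' bond-orientation distribution has ensemble P2 equal to `order_target`:
#' bonds are drawn from a mixture of the isotropic distribution and the
#' fully aligned (target > 0) or fully in-plane (target < 0) distribution
#' with the mixing weight giving the requested expectation exactly.
#' Endpoints are deterministic: target 1 gives all bonds along the normal,
#' target -0.5 all bonds perpendicular.
#'
#' @param n_particles number of molecules (bonds) per frame.
#' @param box length-3 box, Angstrom.
#' @param order_target desired ensemble P2 in [-0.5, 1].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param bond_length bead-bead bond length, Angstrom (default 4.7, the
#'   coarse-grained bond of ~4 heavy atoms per bead).
#' @return list of [particle_frame] objects.
#' @export
synthetic_frames <- function(n_particles, box = c(80, 80, 100),
                             order_target = 0, n_frames = 1, seed = 1,
                             bond_length = 4.7) {
  if (order_target < -0.5 || order_target > 1)
    stop("synthetic_frames: order_target must be in [-0.5, 1]")
  stopifnot(n_particles >= 1, n_frames >= 1)
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) {
    # mixture weights: aligned (P2=1) / in-plane (P2=-1/2) vs isotropic (P2=0)
    if (order_target >= 0) {
      aligned <- stats::runif(n_particles) < order_target
      costh <- ifelse(aligned, 1, stats::runif(n_particles, -1, 1))
    } else {
      planar <- stats::runif(n_particles) < (-2 * order_target)
      costh <- ifelse(planar, 0, stats::runif(n_particles, -1, 1))
    }
    phi <- stats::runif(n_particles, 0, 2 * pi)
    sinth <- sqrt(pmax(0, 1 - costh^2))
    dvec <- cbind(sinth * cos(phi), sinth * sin(phi), costh) * bond_length
    base <- cbind(stats::runif(n_particles, 0, box[1]),
                  stats::runif(n_particles, 0, box[2]),
                  stats::runif(n_particles, 0, box[3]))
    pos <- rbind(base, base + dvec)
    labs <- c(rep("C1A", n_particles), rep("C2A", n_particles))
    rid <- c(seq_len(n_particles), seq_len(n_particles))
    particle_frame(pos, labs, rid, box)
  })
}

#' Uniform 2D Poisson point frame (ideal-gas RDF null)
#'
#' `n` beads labelled `PO4` placed uniformly in the x-y plane of the box at
#' a fixed height, the null fixture for which the lateral radial
#' distribution function is 1 at all distances.
#'
#' @param n number of points.
#' @param box length-3 box, Angstrom.
#' @param z_plane height of the plane, Angstrom.
#' @param n_frames number of independent frames.
#' @param seed integer seed.
#' @return list of [particle_frame] objects.
#' @export
synthetic_poisson_frame <- function(n, box = c(100, 100, 100), z_plane = 60,
                                    n_frames = 1, seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  lapply(seq_len(n_frames), function(f)
    particle_frame(cbind(stats::runif(n, 0, box[1]),
                         stats::runif(n, 0, box[2]),
                         rep(z_plane, n)),
                   rep("PO4", n), seq_len(n), box))
}

#' Hexagonal lattice frame (known first RDF peak)
#'
#' `nx * ny` beads on a triangular (hexagonal-packing) lattice of constant
#' `a` in the x-y plane; the lateral RDF has its first peak at `a`. The box
#' is sized to tile the lattice periodically.
#'
#' @param a lattice constant, Angstrom.
#' @param nx,ny number of cells in x and y (ny should be even for periodic
#'   tiling).
#' @param z_plane height of the plane, Angstrom.
#' @return a [particle_frame].
#' @export
synthetic_hex_frame <- function(a = 8, nx = 12, ny = 12, z_plane = 60) {
  stopifnot(a > 0, nx >= 2, ny >= 2, ny %% 2 == 0)
  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  x <- (ix + 0.5 * (iy %% 2)) * a
  y <- iy * a * sqrt(3) / 2
  box <- c(nx * a, ny * a * sqrt(3) / 2, 2 * z_plane)
  particle_frame(cbind(x, y, rep(z_plane, length(x))),
                 rep("PO4", length(x)), seq_along(x), box)
}
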