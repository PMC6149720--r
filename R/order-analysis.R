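#' P2 bond order parameters
#'
#' Second-rank order parameter of bonds relative to the membrane normal,
#' `P2 = (3 <cos^2 theta> - 1) / 2`, with theta the angle between the bond
#' vector and the normal axis. The ensemble average pools all molecules and
#' frames; the standard error is that of the pooled per-bond P2 samples.
#'
#' @param frames list of [particle_frame] objects.
#' @param bonds data.frame with columns `from`, `to`: ordered bead-label
#'   pairs defining the bonds (both beads of a bond must share a residue id).
#' @param normal_axis 1, 2 or 3 (x, y, z); default 3.
#' @return data.frame with columns `from`, `to`, `P2`, `stderr`, `n`.
#' @export
order_parameter <- function(frames, bonds, normal_axis = 3) {
  stopifnot(length(frames) >= 1, is.data.frame(bonds),
            all(c("from", "to") %in% names(bonds)), normal_axis %in% 1:3)
  axname <- c("x", "y", "z")[normal_axis]
  out <- lapply(seq_len(nrow(bonds)), function(b) {
    from <- bonds$from[b]; to <- bonds$to[b]
    p2s <- unlist(lapply(frames, function(fr) {
      a <- fr[fr$label == from, c("resid", "x", "y", "z")]
      bb <- fr[fr$label == to, c("resid", "x", "y", "z")]
      if (nrow(a) == 0 || nrow(bb) == 0)
        stop(sprintf("order_parameter: bond label '%s' or '%s' not present in frame",
                     from, to))
      m <- merge(a, bb, by = "resid", suffixes = c(".a", ".b"))
      if (nrow(m) == 0)
        stop(sprintf("order_parameter: labels '%s' and '%s' never share a residue",
                     from, to))
      v <- cbind(m$x.b - m$x.a, m$y.b - m$y.a, m$z.b - m$z.a)
      cs <- v[, normal_axis] / sqrt(rowSums(v^2))
      (3 * cs^2 - 1) / 2
    }))
    data.frame(from = from, to = to, P2 = mean(p2s),
               stderr = stats::sd(p2s) / sqrt(length(p2s)), n = length(p2s))
  })
  res <- do.call(rbind, out)
  attr(res, "normal_axis") <- axname
  res
}

bilayer_center <- function(frame, center_labels = NULL) {
  sel <- if (is.null(center_labels)) frame$label != "W"
  else frame$label %in% center_labels
  if (!any(sel)) stop("bilayer center: no beads selected")
  mean(frame$z[sel])
}

#' Leaflet-folded number density profile
#'
#' Number density of the selected beads versus distance from the bilayer
#' center along the normal. The center is taken per frame as the mean z of
#' the lipid beads (robust to membrane drift); distances are folded to |z|
#' (per-leaflet symmetrization) and binned. The central-90 percent span
#' (the [5th, 95th] percentile interval of |z|) is reported alongside.
#'
#' @param frames list of [particle_frame] objects.
#' @param label_set character vector of bead labels to profile.
#' @param bin_width bin width, Angstrom (> 0).
#' @param center_labels labels defining the bilayer center (default: all
#'   non-water beads).
#' @param normal_axis kept for interface symmetry; only z (3) is supported.
#' @return list with `z` (bin centers), `density` (counts per Angstrom per
#'   frame), `counts` (total), `span90` (5th and 95th percentiles of |z|),
#'   `n` (selection size).
#' @export
density_profile <- function(frames, label_set, bin_width = 1,
                            center_labels = NULL, normal_axis = 3) {
  stopifnot(bin_width > 0, normal_axis == 3)
  absz <- unlist(lapply(frames, function(fr) {
    sel <- fr$label %in% label_set
    if (!any(sel))
      stop("density_profile: empty selection for labels ",
           paste(label_set, collapse = ", "))
    abs(fr$z[sel] - bilayer_center(fr, center_labels))
  }))
  breaks <- seq(0, max(absz) + bin_width, by = bin_width)
  h <- graphics::hist(absz, breaks = breaks, plot = FALSE)
  list(z = h$mids,
       density = h$counts / (bin_width * length(frames)),
       counts = h$counts,
       span90 = stats::quantile(absz, c(0.05, 0.95), names = FALSE),
       n = length(absz))
}

#' Phosphate-to-phosphate bilayer thickness
#'
#' `D_PP`: distance along the normal between the mean positions of the
#' phosphate beads of the two leaflets, averaged over frames. Leaflets are
#' assigned by the sign of z after centering on the lipid beads.
#'
#' @param frames list of [particle_frame] objects.
#' @param phosphate_label bead label of the phosphate group (default "PO4").
#' @param center_labels labels defining the bilayer center.
#' @return list with `D_PP` (Angstrom), `per_frame` (vector).
#' @export
bilayer_thickness_pp <- function(frames, phosphate_label = "PO4",
                                 center_labels = NULL) {
  per_frame <- vapply(frames, function(fr) {
    sel <- fr$label == phosphate_label
    if (!any(sel)) stop("bilayer_thickness_pp: no '", phosphate_label, "' beads")
    zc <- fr$z[sel] - bilayer_center(fr, center_labels)
    up <- zc[zc > 0]; lo <- zc[zc <= 0]
    if (length(up) == 0 || length(lo) == 0)
      stop("bilayer_thickness_pp: one leaflet is empty")
    mean(up) - mean(lo)
  }, numeric(1))
  list(D_PP = mean(per_frame), per_frame = per_frame)
}

#' Lateral (2D) radial distribution function
#'
#' In-plane pair distribution of one bead type within one leaflet,
#' normalized by the ideal-gas annulus expectation:
#' `g(r) = <pairs in [r, r+dr]> / (N rho_2D pi (r_out^2 - r_in^2) / 2)`
#' with `rho_2D = (N - 1) / (Lx Ly)` (excess convention, so a Poisson plane
#' gives g = 1 without finite-N bias). Minimum-image convention in x-y.
#'
#' @param frames list of [particle_frame] objects.
#' @param label bead label (default "PO4").
#' @param leaflet "upper", "lower" or "all" (sign of centered z).
#' @param bin_width radial bin width, Angstrom.
#' @param r_max maximum distance; must not exceed half the smaller lateral
#'   box edge.
#' @param center_labels labels defining the bilayer center.
#' @return data.frame with `r` (bin centers), `g`, `g_sd` (per-bin sampling
#'   standard deviation of the g estimate, from Poisson pair counts), and
#'   `npairs`.
#' @export
lateral_rdf <- function(frames, label = "PO4", leaflet = c("all", "upper", "lower"),
                        bin_width = 0.5, r_max = NULL, center_labels = NULL) {
  leaflet <- match.arg(leaflet)
  box <- frame_box(frames[[1]])
  if (is.null(r_max)) r_max <- min(box[1:2]) / 2
  if (r_max > min(box[1:2]) / 2 + 1e-9)
    stop("lateral_rdf: r_max must be <= half the smaller lateral box edge")
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1
  counts <- numeric(nb); norm <- numeric(nb)
  for (fr in frames) {
    sel <- fr$label == label
    if (leaflet != "all") {
      zc <- fr$z - bilayer_center(fr, center_labels)
      sel <- sel & if (leaflet == "upper") zc > 0 else zc <= 0
    }
    n <- sum(sel)
    if (n < 2) stop("lateral_rdf: fewer than 2 particles selected")
    xs <- fr$x[sel]; ys <- fr$y[sel]
    dx <- outer(xs, xs, "-"); dy <- outer(ys, ys, "-")
    dx <- dx - box[1] * round(dx / box[1])   # minimum image
    dy <- dy - box[2] * round(dy / box[2])
    r <- sqrt(dx^2 + dy^2)[lower.tri(dx)]
    r <- r[r < r_max]
    counts <- counts + graphics::hist(r, breaks = breaks, plot = FALSE)$counts
    rho <- (n - 1) / (box[1] * box[2])
    ann <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
    norm <- norm + n * rho * ann / 2      # expected pair count per bin
  }
  g <- counts / norm
  data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
             g = g, g_sd = sqrt(pmax(counts, 1)) / norm, npairs = counts)
}

#' Mean-position distance between two bead groups
#'
#' Per-leaflet distance between the mean normal positions of groups A and B,
#' averaged over leaflets and frames. Sign convention: positive when A lies
#' farther from the bilayer center than B.
#'
#' @param frames list of [particle_frame] objects.
#' @param label_A,label_B bead labels of the two groups.
#' @param center_labels labels defining the bilayer center.
#' @return list with `distance` (signed, Angstrom), `per_leaflet`
#'   (frames x 2 matrix).
#' @export
group_distance <- function(frames, label_A, label_B, center_labels = NULL) {
  per <- t(vapply(frames, function(fr) {
    zc <- fr$z - bilayer_center(fr, center_labels)
    vapply(c(1, -1), function(s) {
      inleaf <- if (s > 0) zc > 0 else zc <= 0
      za <- abs(zc[inleaf & fr$label == label_A])
      zb <- abs(zc[inleaf & fr$label == label_B])
      if (length(za) == 0 || length(zb) == 0)
        stop("group_distance: empty group in a leaflet")
      mean(za) - mean(zb)
    }, numeric(1))
  }, numeric(2)))
  list(distance = mean(per), per_leaflet = per)
}
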