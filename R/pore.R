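#' Crossed distances between non-adjacent subunits
#'
#' The gate-aperture proxy: at a given prime ring, the distance between
#' the equivalent residues of each of the five non-adjacent subunit pairs
#' (P1-P3, P2-P4, P3-P5, P4-P1, P5-P2).  `selection_mode = "residue_com"`
#' uses the mass-weighted whole-residue center of mass (the selection the
#' gate restraint is defined on); `"calpha"` uses the C-alpha atom only.
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param prime_index integer prime index of the ring (e.g. 13 for the
#'   valine constriction).
#' @param selection_mode `"residue_com"` or `"calpha"`.
#' @return Named numeric vector of 5 distances (Angstrom).
#' @export
crossed_distances <- function(frame, topology, prime_index,
                              selection_mode = c("residue_com", "calpha")) {
  selection_mode <- match.arg(selection_mode)
  res <- prime_residue(topology, prime_index)
  pts <- ring_points(frame, topology, res, selection_mode)
  pairs <- nonadjacent_pairs(topology)
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    sqrt(sum((pts[pairs[k, 1], ] - pts[pairs[k, 2], ])^2))
  }, numeric(1))
  names(d) <- rownames(pairs)
  d
}

# one reference point per chain for a ring residue
ring_points <- function(frame, topology, res, selection_mode) {
  pts <- t(vapply(topology$chain_ids, function(ch) {
    idx <- if (selection_mode == "calpha")
      select_atoms(frame, chain = ch, resno = res, elety = "CA")
    else
      select_atoms(frame, chain = ch, resno = res, segment = "protein")
    if (length(idx) == 0L)
      stop("prime ring residue ", res, " unresolvable on chain ", ch)
    if (selection_mode == "calpha") frame$xyz[idx[1], ]
    else center_of_mass(frame, idx, "mass")
  }, numeric(3)))
  rownames(pts) <- topology$chain_ids
  pts
}

#' Axis-sampled pore radius profile
#'
#' A HOLE-style minimal-clearance profile without sphere wandering: the
#' pore axis is sampled at uniformly spaced stations; at each station the
#' radius is the smallest (center-to-axis distance minus van der Waals
#' radius) over the protein atoms whose axial coordinate falls in the
#' station's slab (half-width `spacing / 2`), floored at zero.  Stations
#' whose slab contains no atom are reported at `max_radius` and flagged.
#'
#' @param frame a [structure_frame()].
#' @param axisframe an [symmetry_axis()] result.
#' @param z_range length-2 axial interval (Angstrom, axis coordinates).
#' @param spacing station spacing (Angstrom, default 0.5).
#' @param vdw_table element -> radius lookup (default [vdw_radii()]).
#' @param max_radius radius reported for empty slabs.
#' @return A `pore_profile` data.frame: `z`, `radius`, `flagged`;
#'   attribute `spacing`.
#' @export
pore_radius_profile <- function(frame, axisframe, z_range, spacing = 0.5,
                                vdw_table = vdw_radii(), max_radius = 10) {
  if (spacing <= 0) stop("spacing must be positive")
  prot <- select_atoms(frame, segment = "protein")
  ac <- axis_coordinates(frame$xyz[prot, , drop = FALSE], axisframe)
  vdw <- vdw_table[frame$atoms$element[prot]]
  vdw[is.na(vdw)] <- vdw_table["C"]
  stations <- seq(z_range[1], z_range[2], by = spacing)
  radius <- numeric(length(stations))
  flagged <- logical(length(stations))
  half <- spacing / 2
  for (k in seq_along(stations)) {
    in_slab <- ac$z >= stations[k] - half & ac$z < stations[k] + half
    if (!any(in_slab)) {
      radius[k] <- max_radius
      flagged[k] <- TRUE
    } else {
      radius[k] <- max(0, min(ac$r[in_slab] - vdw[in_slab]))
    }
  }
  out <- data.frame(z = stations, radius = radius, flagged = flagged)
  attr(out, "spacing") <- spacing
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' M2 helix axis direction
#'
#' Axis of the overall (unbent) helix from its C-alpha trace.  The trace
#' is first smoothed by a moving average over 18 consecutive residues —
#' exactly five helical turns at 3.6 residues/turn — which cancels the
#' helical wobble, so the averaged points lie on the helix axis; the
#' direction is the first principal component through them.  For spans
#' too short to smooth, the raw principal component of the C-alpha
#' coordinates is used.  The axis is oriented by positive projection on
#' the channel `z` axis (intracellular to extracellular).
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param chain chain id.
#' @param z orientation reference (default the chain's own -2' to 20'
#'   C-alpha chord).
#' @return Unit length-3 vector.
#' @export
m2_helix_axis <- function(frame, topology, chain, z = NULL) {
  m2_res <- seq(topology$m2_range[1], topology$m2_range[2])
  idx <- select_atoms(frame, chain = chain, resno = m2_res, elety = "CA")
  if (length(idx) < length(m2_res))
    stop("missing M2 C-alpha atoms on chain ", chain)
  if (is.null(z)) {
    lo <- frame$xyz[idx[1], ]; hi <- frame$xyz[idx[length(idx)], ]
    z <- unit(hi - lo)
  }
  xyz <- frame$xyz[idx, , drop = FALSE]
  window <- 18L  # five full turns
  n <- nrow(xyz)
  pts <- if (n > window) {
    t(vapply(seq_len(n - window + 1L), function(k)
      colMeans(xyz[k:(k + window - 1L), , drop = FALSE]), numeric(3)))
  } else xyz
  a <- prcomp(pts)$rotation[, 1]
  if (sum(a * z) < 0) a <- -a
  unit(a)
}

#' M2 polar and azimuthal tilt angles
#'
#' Each helix axis is expressed in its subunit's local frame (x radial
#' outward, y tangential, z along the channel axis).  The polar tilt is
#' the signed angle between z and the axis's xz-plane projection
#' (positive toward +x, i.e. helix top leaning radially outward); the
#' azimuthal tilt is the signed angle from x to the xy-plane projection
#' (positive toward +y).  When the xy projection is numerically null the
#' azimuthal angle is reported as 0 and flagged degenerate.
#'
#' @param frame a [structure_frame()].
#' @param axisframe a [symmetry_axis()] result.
#' @param topology a [channel_topology()].
#' @return A `tilt_angles` data.frame: `chain`, `polar`, `azimuthal`
#'   (degrees), `degenerate` (logical).
#' @export
tilt_angles <- function(frame, axisframe, topology) {
  out <- lapply(topology$chain_ids, function(ch) {
    hf <- axisframe$helix_frames[[ch]]
    a <- m2_helix_axis(frame, topology, ch, z = hf$z)
    ax <- sum(a * hf$x); ay <- sum(a * hf$y); az <- sum(a * hf$z)
    polar <- atan2(ax, az) * 180 / pi
    degen <- sqrt(ax^2 + ay^2) < 1e-8
    azim <- if (degen) 0 else atan2(ay, ax) * 180 / pi
    data.frame(chain = ch, polar = polar, azimuthal = azim,
               degenerate = degen)
  })
  out <- do.call(rbind, out)
  class(out) <- c("tilt_angles", "data.frame")
  out
}

#' Quaternary twist angle between LBD and TMD
#'
#' For each subunit, the vectors from the whole-protein C-alpha center of
#' mass to the subunit's LBD and TMD C-alpha centers of mass are
#' projected on the plane perpendicular to the symmetry axis; the twist
#' is the signed angle from the TMD projection to the LBD projection
#' (positive counter-clockwise viewed from the extracellular side).
#' A larger twist associates with channel closure.
#'
#' @param frame a [structure_frame()].
#' @param axisframe a [symmetry_axis()] result.
#' @param topology a [channel_topology()].
#' @param lbd_span,tmd_span length-2 residue spans of the two domains.
#' @return List: `per_subunit` (named degrees), `mean`, `mean_abs`.
#' @export
twist_angle <- function(frame, axisframe, topology, lbd_span, tmd_span) {
  z <- axisframe$z
  ca_all <- select_atoms(frame, chain = topology$chain_ids, elety = "CA")
  com_all <- colMeans(frame$xyz[ca_all, , drop = FALSE])
  per <- vapply(topology$chain_ids, function(ch) {
    sel_l <- select_atoms(frame, chain = ch,
                          resno = seq(lbd_span[1], lbd_span[2]),
                          elety = "CA")
    sel_t <- select_atoms(frame, chain = ch,
                          resno = seq(tmd_span[1], tmd_span[2]),
                          elety = "CA")
    if (!length(sel_l) || !length(sel_t))
      stop("empty LBD/TMD span on chain ", ch)
    proj <- function(sel) {
      v <- colMeans(frame$xyz[sel, , drop = FALSE]) - com_all
      p <- v - sum(v * z) * z
      if (sqrt(sum(p^2)) < 1e-8) stop("degenerate domain projection")
      p
    }
    pl <- proj(sel_l); pt <- proj(sel_t)
    atan2(sum(cross3(pt, pl) * z), sum(pt * pl)) * 180 / pi
  }, numeric(1))
  list(per_subunit = per, mean = mean(per), mean_abs = mean(abs(per)))
}

#' Normalized distance histogram of a descriptor series
#'
#' Histogram of a (possibly multi-column) series; `merge_subunits` pools
#' all columns before binning, the convention used for crossed-distance
#' distributions so individual-subunit transitions are not blurred by
#' averaging.
#'
#' @param series a [descriptor_series()].
#' @param bin_width bin width in the series' units.
#' @param merge_subunits pool columns before binning (default `TRUE`).
#' @return Data.frame `bin_left`, `bin_right`, `count`, `density`;
#'   densities integrate to 1.
#' @export
distance_distribution <- function(series, bin_width, merge_subunits = TRUE) {
  if (bin_width <= 0) stop("bin width must be positive")
  x <- if (merge_subunits) as.vector(series$values) else series$values[, 1]
  if (!length(x)) stop("empty series")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(x) >= breaks[length(breaks)])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  cnt <- hist_counts(x, breaks)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = cnt, density = cnt / (sum(cnt) * bin_width))
}

# half-open [left, right) binning
hist_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  idx[idx == length(breaks)] <- length(breaks) - 1L
  tabulate(idx, nbins = length(breaks) - 1L)
}
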