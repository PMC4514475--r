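# Standard atomic masses (u) and van der Waals radii (Angstrom, Bondi).
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, Cl = 35.45, Na = 22.990)
.VDW_RADIUS <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                 S = 1.80, P = 1.80, Cl = 1.75, Na = 2.27)

atom_masses <- function(frame, idx) {
  m <- .ATOMIC_MASS[frame$atoms$element[idx]]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon
  unname(m)
}

#' Default van der Waals radius table
#'
#' Element -> radius (Angstrom) used by [pore_radius_profile()];
#' unlisted elements fall back to the carbon radius.
#' @return Named numeric vector.
#' @export
vdw_radii <- function() .VDW_RADIUS

#' Center of mass of a selection
#'
#' @param frame a [structure_frame()].
#' @param idx integer atom indices (from [select_atoms()]).
#' @param weighting `"mass"` (default) or `"geometric"` (all atoms equal).
#' @return Length-3 numeric position (Angstrom).
#' @export
center_of_mass <- function(frame, idx, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (length(idx) == 0L) stop("empty selection")
  w <- if (weighting == "mass") atom_masses(frame, idx) else
    rep(1, length(idx))
  drop(crossprod(frame$xyz[idx, , drop = FALSE], w)) / sum(w)
}

unit <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < tol) stop("degenerate (near-zero) vector")
  v / n
}

#' Pore axis frame and per-helix local frames
#'
#' Defines the channel reference geometry: the symmetry axis `z` is the
#' unit vector from the center of the -2' C-alpha ring to the center of
#' the 20' C-alpha ring (intracellular to extracellular), the origin is
#' the center of all M2 C-alpha atoms.  For each subunit a local frame is
#' built at the M2 helix center: `x` is the radial outward unit vector
#' (perpendicular to `z`), `y = z x x` (tangential).  These frames are
#' the coordinate system in which polar and azimuthal M2 tilts are read.
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param method `"rings"` (default, ring-center chord) or `"pca"` (first
#'   principal axis of all M2 C-alpha atoms, oriented like the chord).
#' @return An object of class `axis_frame`: `origin`, `z`, and
#'   `helix_frames` (per chain: `origin`, `x`, `y`, `z`).
#' @export
symmetry_axis <- function(frame, topology, method = c("rings", "pca")) {
  method <- match.arg(method)
  res_lo <- prime_residue(topology, min(as.integer(names(topology$prime_map))))
  res_hi <- prime_residue(topology, max(as.integer(names(topology$prime_map))))
  ring_com <- function(res) {
    idx <- select_atoms(frame, chain = topology$chain_ids, resno = res,
                       elety = "CA")
    if (length(idx) < 5L)
      stop("ring at residue ", res, " not resolvable on all chains")
    colMeans(frame$xyz[idx, , drop = FALSE])
  }
  lo <- ring_com(res_lo)
  hi <- ring_com(res_hi)
  chord <- hi - lo
  if (sqrt(sum(chord^2)) < 1e-6)
    stop("degenerate ring geometry: ring centers coincide")
  z <- unit(chord)
  m2_res <- seq(topology$m2_range[1], topology$m2_range[2])
  all_idx <- select_atoms(frame, chain = topology$chain_ids, resno = m2_res,
                          elety = "CA")
  origin <- colMeans(frame$xyz[all_idx, , drop = FALSE])
  if (method == "pca") {
    pc <- prcomp(frame$xyz[all_idx, , drop = FALSE])$rotation[, 1]
    if (sum(pc * z) < 0) pc <- -pc
    z <- unit(pc)
  }
  helix_frames <- lapply(topology$chain_ids, function(ch) {
    idx <- select_atoms(frame, chain = ch, resno = m2_res, elety = "CA")
    o <- colMeans(frame$xyz[idx, , drop = FALSE])
    radial <- o - origin
    radial <- radial - sum(radial * z) * z
    x <- unit(radial)
    list(origin = o, x = x, y = cross3(z, x), z = z)
  })
  names(helix_frames) <- topology$chain_ids
  structure(list(origin = origin, z = z, helix_frames = helix_frames),
            class = "axis_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Axial and lateral coordinates relative to an axis frame
#'
#' @param xyz N x 3 coordinate matrix.
#' @param axisframe an `axis_frame`.
#' @return List with `z` (axial coordinate, Angstrom, relative to the
#'   frame origin) and `r` (perpendicular distance from the axis line).
#' @export
axis_coordinates <- function(xyz, axisframe) {
  d <- sweep(xyz, 2, axisframe$origin)
  zc <- drop(d %*% axisframe$z)
  lat <- d - outer(zc, axisframe$z)
  list(z = zc, r = sqrt(rowSums(lat^2)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over matched atom
#' selections, via the SVD of the covariance matrix with the usual
#' reflection guard.
#'
#' @param mobile,reference [structure_frame()]s.
#' @param sel_mobile,sel_reference matched integer atom selections
#'   (equal length, at least 3 atoms).
#' @return List: `rotation` (3x3, applied after centering), `translation`,
#'   `rmsd` (post-fit RMSD over the selection, Angstrom), and `fit_xyz`,
#'   the full mobile coordinate set after the fit.
#' @export
superpose <- function(mobile, reference, sel_mobile,
                      sel_reference = sel_mobile) {
  if (length(sel_mobile) != length(sel_reference))
    stop("selection size mismatch")
  if (length(sel_mobile) < 3L)
    stop("at least 3 atoms required for superposition")
  P <- mobile$xyz[sel_mobile, , drop = FALSE]
  Q <- reference$xyz[sel_reference, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)    # x_fit = (x - cp) %*% R + cq
  fit_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fit_sel - Qc)^2)))
  fit_xyz <- sweep(mobile$xyz, 2, cp) %*% R
  fit_xyz <- sweep(fit_xyz, 2, cq, FUN = "+")
  list(rotation = R, translation = cq - drop(cp %*% R), rmsd = rmsd,
       fit_xyz = fit_xyz)
}

#' RMSD time series after superposition
#'
#' Per-frame C-alpha (or arbitrary-selection) RMSD from a reference
#' structure, after removing rigid-body motion by [superpose()].  With
#' `per_subunit = TRUE` each chain is fitted and scored independently,
#' which isolates intra-subunit deformation from quaternary rearrangement.
#'
#' @param traj a [channel_trajectory()].
#' @param reference a [structure_frame()] sharing the atom layout.
#' @param sel integer atom selection (applied to both).
#' @param per_subunit logical; fit each chain separately.
#' @param topology required when `per_subunit = TRUE`.
#' @return A [descriptor_series()] (one column, or one per chain).
#' @export
rmsd_series <- function(traj, reference, sel, per_subunit = FALSE,
                        topology = NULL) {
  nf <- n_frames(traj)
  if (per_subunit) {
    if (is.null(topology)) stop("topology required for per_subunit fits")
    chains <- topology$chain_ids
    sels <- lapply(chains, function(ch)
      intersect(sel, which(reference$atoms$chain == ch)))
    vals <- matrix(NA_real_, nf, length(chains),
                   dimnames = list(NULL, chains))
    for (i in seq_len(nf)) {
      fr <- get_frame(traj, i)
      for (k in seq_along(chains))
        vals[i, k] <- superpose(fr, reference, sels[[k]])$rmsd
    }
  } else {
    vals <- vapply(seq_len(nf), function(i)
      superpose(get_frame(traj, i), reference, sel)$rmsd, numeric(1))
  }
  descriptor_series(vals, traj$times, "rmsd", "Angstrom")
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF about the window-average structure: frames in the window are
#' aligned to their running average (two alignment passes, standard
#' practice), the average is recomputed, and each atom's RMS deviation
#' from its average position is reported.
#'
#' @param traj a [channel_trajectory()].
#' @param sel atom selection whose fluctuations are reported.
#' @param window integer frame indices (default: all frames).
#' @param align_sel atom selection used for the rigid-body alignment
#'   (default `sel`); use a stable core to avoid absorbing the motion of
#'   the atoms under study into the fit.
#' @return Numeric vector, one RMSF (Angstrom) per selected atom.
#' @export
rmsf <- function(traj, sel, window = seq_len(n_frames(traj)),
                 align_sel = sel) {
  if (length(window) == 0L) stop("empty frame window")
  coords <- lapply(window, function(i) frame_xyz(traj, i))
  ref <- coords[[1]]
  ref_frame <- structure(list(atoms = traj$atoms, xyz = ref, time = NA),
                         class = "structure_frame")
  for (pass in 1:2) {
    coords <- lapply(coords, function(x) {
      fr <- structure(list(atoms = traj$atoms, xyz = x, time = NA),
                      class = "structure_frame")
      superpose(fr, ref_frame, align_sel)$fit_xyz
    })
    avg <- Reduce(`+`, coords) / length(coords)
    ref_frame$xyz <- avg
  }
  dev2 <- lapply(coords, function(x)
    rowSums((x[sel, , drop = FALSE] - avg[sel, , drop = FALSE])^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}
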