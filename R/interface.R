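ca_com <- function(frame, chain, resnos) {
  idx <- select_atoms(frame, chain = chain, resno = resnos, elety = "CA")
  if (!length(idx))
    stop("residues ", paste(range(resnos), collapse = "-"),
         " unresolvable on chain ", chain)
  colMeans(frame$xyz[idx, , drop = FALSE])
}

#' LBD-TMD interface distances
#'
#' Per subunit, the two monitors of the gating interface: the distance
#' from the M2-M3 loop proline C-alpha (Pro256-equivalent) to (i) the
#' C-alpha center of mass of the Cys-loop (residues 122-136) and (ii)
#' the C-alpha of the beta1-beta2 loop lysine (Lys40-equivalent).  In
#' open forms the M2-M3 loop detaches from the beta1-beta2 loop and
#' resides closer to the Cys-loop.
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()] with `Pro256` and `Lys40` in
#'   `key_residues` and a `Cys_loop` span.
#' @return Data.frame: `chain`, `d_pro_cysloop`, `d_pro_lys` (Angstrom).
#' @export
interface_distances <- function(frame, topology) {
  pro <- topology$key_residues[["Pro256"]]
  lys <- topology$key_residues[["Lys40"]]
  cys <- topology$loops$Cys_loop
  out <- lapply(topology$chain_ids, function(ch) {
    p_pro <- ca_com(frame, ch, pro)
    p_cys <- ca_com(frame, ch, seq(cys[1], cys[2]))
    p_lys <- ca_com(frame, ch, lys)
    data.frame(chain = ch,
               d_pro_cysloop = sqrt(sum((p_pro - p_cys)^2)),
               d_pro_lys = sqrt(sum((p_pro - p_lys)^2)))
  })
  do.call(rbind, out)
}

#' C-loop closure distance (dCintra)
#'
#' Per subunit, the distance between the C-alpha center of mass of the
#' C-loop (residues 179-188), which caps the agonist, and the C-alpha
#' center of mass of the binding-site backwall (residues 139-140).
#' Larger values indicate a more open C-loop; its distribution is
#' multimodal when the ligand samples axial and equatorial orientations.
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()] with `C_loop` and `backwall`
#'   spans.
#' @return Named numeric vector, one distance (Angstrom) per chain.
#' @export
dCintra <- function(frame, topology) {
  cl <- topology$loops$C_loop
  bw <- topology$loops$backwall
  vapply(setNames(topology$chain_ids, topology$chain_ids), function(ch) {
    sqrt(sum((ca_com(frame, ch, seq(cl[1], cl[2])) -
                ca_com(frame, ch, seq(bw[1], bw[2])))^2))
  }, numeric(1))
}

#' Ligand-protein contact monitors
#'
#' Distances for a table of named atom (or ring-centroid) pairs between
#' the bound agonist and binding-site residues.  An endpoint given as a
#' single atom name uses that atom's position; a vector of atom names
#' uses the geometric centroid (ring-ring monitors).
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param contact_table list of monitors, each
#'   `list(name=, lig_atoms=, res_chain=, res_resno=, res_atoms=)`;
#'   see [default_ligand_monitors()].
#' @param lig_chain chain id carrying the ligand copy (the primary
#'   subunit of the binding interface).
#' @return Data.frame: `name`, `distance` (Angstrom).
#' @export
ligand_contacts <- function(frame, topology, contact_table, lig_chain) {
  lig <- select_atoms(frame, segment = "ligand", chain = lig_chain)
  if (!length(lig))
    stop("no ligand (", topology$ligand_resname, ") on chain ", lig_chain)
  pt <- function(idx, names_) {
    sub <- idx[frame$atoms$elety[idx] %in% names_]
    if (!length(sub))
      stop("atoms ", paste(names_, collapse = ","), " not found")
    colMeans(frame$xyz[sub, , drop = FALSE])
  }
  out <- lapply(contact_table, function(m) {
    p1 <- pt(lig, m$lig_atoms)
    ridx <- select_atoms(frame, chain = m$res_chain, resno = m$res_resno)
    p2 <- pt(ridx, m$res_atoms)
    data.frame(name = m$name, distance = sqrt(sum((p1 - p2)^2)))
  })
  do.call(rbind, out)
}

#' Default agonist-site monitor table
#'
#' The standard epibatidine-style monitor set for one binding interface:
#' three electrostatic contacts (bridge-ring amine to Tyr87 hydroxyl,
#' pyridine amine to Tyr189 hydroxyl and to Trp143 carbonyl), two
#' chlorine/backbone-nitrogen contacts (Leu103, Leu113 of the
#' complementary subunit), and three ring-centroid van der Waals
#' monitors (pyridine/Trp143, bridge/Tyr189, bridge/Tyr182).
#'
#' @param topology a [channel_topology()].
#' @param primary chain id of the primary subunit.
#' @param complementary chain id of the complementary subunit (backbone
#'   nitrogen contacts).
#' @return A contact table for [ligand_contacts()].
#' @export
default_ligand_monitors <- function(topology, primary, complementary) {
  kr <- topology$key_residues
  ring6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  list(
    list(name = "EPI-N2/TYR87-OH", lig_atoms = "N2",
         res_chain = primary, res_resno = kr[["Tyr87"]], res_atoms = "OH"),
    list(name = "EPI-N1/TYR189-OH", lig_atoms = "N1",
         res_chain = primary, res_resno = kr[["Tyr189"]], res_atoms = "OH"),
    list(name = "EPI-N1/TRP143-O", lig_atoms = "N1",
         res_chain = primary, res_resno = kr[["Trp143"]], res_atoms = "O"),
    list(name = "EPI-CL/LEU103-N", lig_atoms = "CL",
         res_chain = complementary, res_resno = kr[["Leu103"]],
         res_atoms = "N"),
    list(name = "EPI-CL/LEU113-N", lig_atoms = "CL",
         res_chain = complementary, res_resno = kr[["Leu113"]],
         res_atoms = "N"),
    list(name = "EPI-pyridine/TRP143-ring",
         lig_atoms = paste0("C", 6:11),
         res_chain = primary, res_resno = kr[["Trp143"]],
         res_atoms = ring6),
    list(name = "EPI-bridge/TYR189-ring",
         lig_atoms = paste0("C", 1:5),
         res_chain = primary, res_resno = kr[["Tyr189"]],
         res_atoms = ring6),
    list(name = "EPI-bridge/TYR182-ring",
         lig_atoms = paste0("C", 1:5),
         res_chain = primary, res_resno = kr[["Tyr182"]],
         res_atoms = ring6))
}

#' Classify the ligand orientation in the binding pocket
#'
#' Operationalizes the qualitative axial/equatorial description of bound
#' agonist poses: the unit vector from the ligand centroid to a marker
#' atom (e.g. the epibatidine chlorine) is compared with the channel
#' axis.  Within a 45-degree cone of +z / -z the pose is `axial_up` /
#' `axial_down`; if the vector lies within 22.5 degrees of the axis
#' plane (|dot| < cos 67.5 deg) and its lateral part points
#' predominantly radially inward (toward the pore axis) the pose is
#' `equatorial`; anything else is `intermediate`.  The cone half-angles
#' are this package's own thresholds, configurable below.
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param axisframe a [symmetry_axis()] result.
#' @param lig_chain chain carrying the ligand copy.
#' @param reference_atom marker atom name (default `"CL"`).
#' @param axial_deg,equatorial_deg cone half-angles (degrees).
#' @return Character class, with attribute `dot_z`.
#' @export
classify_ligand_orientation <- function(frame, topology, axisframe,
                                        lig_chain, reference_atom = "CL",
                                        axial_deg = 45,
                                        equatorial_deg = 67.5) {
  lig <- select_atoms(frame, segment = "ligand", chain = lig_chain)
  if (!length(lig)) stop("no ligand on chain ", lig_chain)
  ref <- lig[frame$atoms$elety[lig] == reference_atom]
  if (!length(ref))
    stop("reference atom ", reference_atom, " absent from ligand")
  cen <- colMeans(frame$xyz[lig, , drop = FALSE])
  u <- unit(frame$xyz[ref[1], ] - cen)
  z <- axisframe$z
  dz <- sum(u * z)
  cls <- if (dz > cos(axial_deg * pi / 180)) "axial_up"
  else if (dz < -cos(axial_deg * pi / 180)) "axial_down"
  else if (abs(dz) < cos(equatorial_deg * pi / 180)) {
    lat <- cen - axisframe$origin
    lat <- lat - sum(lat * z) * z
    inward <- -unit(lat)
    u_lat <- u - dz * z
    tang <- cross3(z, inward)
    if (sum(u_lat * inward) > abs(sum(u_lat * tang))) "equatorial"
    else "intermediate"
  } else "intermediate"
  structure(cls, dot_z = dz)
}

ion_indices <- function(frame, species = c("cation", "anion")) {
  species <- match.arg(species)
  resn <- if (species == "cation") .CATION_RESNAMES else .ANION_RESNAMES
  select_atoms(frame, segment = "ion", resid = resn)
}

#' Axial distribution of ions
#'
#' Histogram of ion axial coordinates pooled over all frames, within a
#' lateral cylinder of the pore axis (default 10 Angstrom, wide enough
#' for the extracellular vestibule).
#'
#' @param traj a [channel_trajectory()].
#' @param axisframe fixed [symmetry_axis()] frame.
#' @param species `"cation"` or `"anion"`.
#' @param z_range length-2 axial range (Angstrom).
#' @param bin_width histogram bin (Angstrom).
#' @param lateral_radius cylinder radius (Angstrom).
#' @return Data.frame: `bin_left`, `bin_right`, `count`, `density`.
#' @export
ion_z_distribution <- function(traj, axisframe, species, z_range,
                               bin_width = 2, lateral_radius = 10) {
  zs <- unlist(lapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    idx <- ion_indices(fr, species)
    if (!length(idx)) return(numeric())
    ac <- axis_coordinates(fr$xyz[idx, , drop = FALSE], axisframe)
    ac$z[ac$r <= lateral_radius & ac$z >= z_range[1] & ac$z < z_range[2]]
  }))
  breaks <- seq(z_range[1], z_range[2], by = bin_width)
  if (breaks[length(breaks)] < z_range[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  cnt <- if (length(zs)) hist_counts(zs, breaks) else
    integer(length(breaks) - 1L)
  dens <- if (sum(cnt)) cnt / (sum(cnt) * bin_width) else
    rep(0, length(cnt))
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = cnt, density = dens)
}

#' Ion occupancy of a pore region
#'
#' Per-frame count of ions of one species inside a [pore_region()];
#' the maximum simultaneous occupancy (e.g. two cations below the Leu9'
#' ring, a precursor of permeation) is attached as an attribute.
#'
#' @inheritParams ion_z_distribution
#' @param region a [pore_region()].
#' @return A [descriptor_series()] with attribute `max_occupancy`.
#' @export
ion_occupancy <- function(traj, axisframe, region, species) {
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    idx <- ion_indices(fr, species)
    if (!length(idx)) return(0)
    ac <- axis_coordinates(fr$xyz[idx, , drop = FALSE], axisframe)
    sum(ac$z >= region$z_lo & ac$z < region$z_hi & ac$r <= region$radius)
  }, numeric(1))
  out <- descriptor_series(vals, traj$times,
                           paste0(species, "s_", region$name), "count")
  attr(out, "max_occupancy") <- max(vals)
  out
}
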