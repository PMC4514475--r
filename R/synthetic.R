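# Canonical alpha-helix geometry, fixed so ground truth stays closed-form.
.HELIX_RISE <- 1.5      # Angstrom per residue
.HELIX_TURN <- 100      # degrees per residue
.HELIX_RADIUS <- 2.3    # C-alpha helix radius, Angstrom

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Blueprint for a synthetic pentameric channel
#'
#' Parameters of the generator that emulates the geometry the descriptor
#' suite assumes: five ideal M2-like alpha-helices (C-alpha plus one
#' side-chain proxy atom per residue) on a circle around the pore axis,
#' an LBD-proxy C-alpha cloud carrying the binding-site loops, a bound
#' agonist proxy, pore waters at prescribed per-region occupancy, and
#' vestibule ions.  With scalar tilts the construction is exactly
#' C5-symmetric, so crossed distances, ring pore radii, tilt, twist and
#' region water counts all have closed-form ground truth.
#'
#' @param ca_ring_radius distance of each helix axis from the pore axis
#'   (Angstrom).
#' @param ring_radius named numeric: side-chain proxy distance from the
#'   pore axis per prime index (sets the pore radius at that ring to
#'   `ring_radius - 1.7`); names are prime indices, default 6.7
#'   everywhere (pore radius 5).
#' @param polar_deg,azimuthal_deg prescribed M2 tilt components
#'   (degrees); scalar (all helices alike, C5 exact) or length 5.
#' @param twist_deg quaternary twist offset of the LBD proxy relative to
#'   the TMD (degrees, positive counter-clockwise from extracellular).
#' @param waters named list of region occupancies: `pore` (full lumen)
#'   and `gate` (10 Angstrom slab at the 13' ring).
#' @param n_cations,n_anions vestibule ion counts; cations are placed
#'   uniformly in -20 < z < 0, anions in -30 < z < -20 (lateral radius 6).
#' @param ligand logical, place one agonist proxy per subunit.
#' @param ligand_orientation `"axial_up"`, `"axial_down"` or
#'   `"equatorial"` (chlorine marker direction).
#' @param noise_sd isotropic Gaussian positional noise sigma (Angstrom)
#'   applied to protein and ligand atoms.
#' @param seed integer seed fixing all stochastic output.
#' @param topology a [channel_topology()]; defaults to
#'   [alpha7_topology()].
#' @return An object of class `pentamer_blueprint`.
#' @export
pentamer_blueprint <- function(ca_ring_radius = 12,
                               ring_radius = NULL,
                               polar_deg = 0, azimuthal_deg = 0,
                               twist_deg = 21,
                               waters = list(pore = 115, gate = 40),
                               n_cations = 8, n_anions = 8,
                               ligand = TRUE,
                               ligand_orientation = "axial_up",
                               noise_sd = 0, seed = 1,
                               topology = alpha7_topology()) {
  primes <- as.integer(names(topology$prime_map))
  if (is.null(ring_radius))
    ring_radius <- setNames(rep(6.7, length(primes)), primes)
  if (is.null(names(ring_radius)))
    stop("ring_radius must be named by prime indices")
  full <- setNames(rep(6.7, length(primes)), primes)
  full[names(ring_radius)] <- ring_radius
  if (any(full <= 0)) stop("ring radii must be positive")
  if (any(unlist(waters) < 0)) stop("water occupancies must be >= 0")
  stopifnot(length(polar_deg) %in% c(1L, 5L),
            length(azimuthal_deg) %in% c(1L, 5L))
  structure(list(ca_ring_radius = ca_ring_radius, ring_radius = full,
                 polar_deg = rep_len(polar_deg, 5L),
                 azimuthal_deg = rep_len(azimuthal_deg, 5L),
                 uniform_tilt = length(polar_deg) == 1L &&
                   length(azimuthal_deg) == 1L,
                 twist_deg = twist_deg, waters = waters,
                 n_cations = n_cations, n_anions = n_anions,
                 ligand = ligand, ligand_orientation = ligand_orientation,
                 noise_sd = noise_sd, seed = seed, topology = topology),
            class = "pentamer_blueprint")
}

#' Open and collapsed gate presets
#'
#' `blueprint_open()` mirrors a putative open channel: ~5 Angstrom pore
#' radius through the 9'-16' hydrophobic gate, a ~3 Angstrom constriction
#' at the intracellular 2' ring, small positive polar tilt, twist 21
#' degrees, a fully hydrated pore (115 waters in the lumen, 40 in the
#' gate slab).  `blueprint_collapsed()` mirrors the collapsed channel:
#' ~2 Angstrom minimum radius at the Leu9' ring, ~3 Angstrom through the
#' rest of the gate, slightly negative polar tilt, twist 24 degrees, a
#' dewetted gate (60 lumen waters, 4 in the gate slab).
#'
#' @param seed integer seed.
#' @param noise_sd positional noise sigma (Angstrom).
#' @param ... passed on to [pentamer_blueprint()].
#' @return A [pentamer_blueprint()].
#' @export
blueprint_open <- function(seed = 1, noise_sd = 0, ...) {
  rr <- c("2" = 4.7)   # intracellular constriction, radius ~3
  pentamer_blueprint(ring_radius = rr, polar_deg = 1.1, azimuthal_deg = 2,
                     twist_deg = 21, waters = list(pore = 115, gate = 40),
                     noise_sd = noise_sd, seed = seed, ...)
}

#' @rdname blueprint_open
#' @export
blueprint_collapsed <- function(seed = 1, noise_sd = 0, ...) {
  rr <- c("6" = 4.7, "9" = 3.7, "13" = 4.7, "16" = 4.7)
  pentamer_blueprint(ring_radius = rr, polar_deg = -2, azimuthal_deg = 0,
                     twist_deg = 24, waters = list(pore = 60, gate = 4),
                     noise_sd = noise_sd, seed = seed, ...)
}

# rotation by ang (radians) about axis u through the origin
rot_axis <- function(u, ang) {
  u <- unit(u)
  c_ <- cos(ang); s_ <- sin(ang)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_,
           ux * uz * (1 - c_) + uy * s_,
           uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),
           uy * uz * (1 - c_) - ux * s_,
           uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_,
           c_ + uz^2 * (1 - c_)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) rot_axis(c(0, 0, 1), deg * pi / 180)

# prescribed helix-axis direction in the subunit local frame and the
# closed-form tilt angles it realises under the package's conventions
tilt_direction <- function(polar_deg, azim_deg) {
  p <- polar_deg * pi / 180; a <- azim_deg * pi / 180
  d <- c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
  polar <- atan2(d[1], d[3]) * 180 / pi
  degen <- sqrt(d[1]^2 + d[2]^2) < 1e-8
  azim <- if (degen) 0 else atan2(d[2], d[1]) * 180 / pi
  list(d = d, polar = polar, azimuthal = azim, degenerate = degen)
}

# LBD arc helper: n C-alphas on a circle of radius r at height z, equally
# spaced by step degrees and centered on azimuth a0 (so the arc's centroid
# azimuth is exactly a0)
arc_points <- function(n, r, z, a0, step = 3) {
  offs <- (seq_len(n) - (n + 1) / 2) * step
  ang <- (a0 + offs) * pi / 180
  cbind(r * cos(ang), r * sin(ang), rep(z, n))
}

#' Build a synthetic pentamer with ground truth
#'
#' Constructs one [structure_frame()] from a [pentamer_blueprint()]:
#' five M2 helices (C-alpha `CA` plus side-chain proxy `CB` per residue,
#' primes -2'..20'), an M2-M3 loop, the LBD loop arcs used by the
#' interface and binding-site descriptors, optional agonist proxies,
#' pore waters, and vestibule ions.  The attached ground-truth record
#' holds every construction value a descriptor should recover.
#'
#' @param blueprint a [pentamer_blueprint()].
#' @return List: `frame` (a `structure_frame`), `ground_truth` (list),
#'   `topology`.
#' @export
build_pentamer <- function(blueprint) {
  with_seed(blueprint$seed, build_pentamer_impl(blueprint))
}

build_pentamer_impl <- function(bp) {
  topo <- bp$topology
  primes <- as.integer(names(topo$prime_map))
  n_res <- length(primes)
  chains <- topo$chain_ids

  # --- chain template in the local frame of subunit 1 (azimuth 0) -------
  j <- seq_len(n_res) - 1
  theta <- (j * .HELIX_TURN) * pi / 180
  helix <- cbind(.HELIX_RADIUS * cos(theta), .HELIX_RADIUS * sin(theta),
                 (j - (n_res - 1) / 2) * .HELIX_RISE)
  # center so the C-alpha centroid sits exactly on the helix axis: the
  # radial frame used by the tilt analysis is then exact by construction
  helix <- sweep(helix, 2, colMeans(helix))

  build_chain <- function(polar, azim) {
    td <- tilt_direction(polar, azim)
    # rotate the template so its axis (local z) maps onto td$d
    axis0 <- c(0, 0, 1)
    v <- cross3(axis0, td$d)
    s <- sqrt(sum(v^2))
    R <- if (s < 1e-12) diag(3) else rot_axis(v, atan2(s, sum(axis0 * td$d)))
    ca <- helix %*% t(R)
    ca <- sweep(ca, 2, c(bp$ca_ring_radius, 0, 0), FUN = "+")
    ca
  }

  ca1 <- build_chain(bp$polar_deg[1], bp$azimuthal_deg[1])
  # side-chain proxy: same z and azimuth as its C-alpha, at the ring's
  # prescribed distance from the pore axis
  proxy_for <- function(ca) {
    t(vapply(seq_len(nrow(ca)), function(k) {
      p <- ca[k, ]
      lat <- c(p[1], p[2], 0)
      rr <- bp$ring_radius[as.character(primes[k])]
      lat_u <- lat / sqrt(sum(lat^2))
      c(rr * lat_u[1], rr * lat_u[2], p[3])
    }, numeric(3)))
  }

  # M2-M3 loop C-alphas, continuing upward from the helix top
  loop_res <- seq(topo$loops$M2_M3[1], topo$loops$M2_M3[2])
  m2m3_1 <- arc_points(length(loop_res), 13, 19, 0, step = 4)

  # TMD centroid azimuth of chain 1 fixes where the LBD must sit for the
  # twist ground truth to be exact
  tmd_ca_1 <- rbind(ca1, m2m3_1)
  tmd_lat <- colMeans(tmd_ca_1)
  tmd_azimuth <- atan2(tmd_lat[2], tmd_lat[1]) * 180 / pi
  lbd_azimuth <- tmd_azimuth + bp$twist_deg

  # LBD loop arcs (residue number, radius, z); Lys40, the Cys-loop,
  # backwall and C-loop feed the interface descriptors
  lbd_spans <- list(
    list(res = 38:44,   r = 15.0, z = 27.0),
    list(res = 85:90,   r = 16.0, z = 36.0),
    list(res = 100:106, r = 17.0, z = 35.0),
    list(res = 110:116, r = 17.0, z = 33.0),
    list(res = 122:136, r = 13.0, z = 24.0),
    list(res = 139:140, r = 2.0,  z = 35.5),
    list(res = 143:145, r = 15.5, z = 36.5),
    list(res = 179:190, r = 16.0, z = 40.0))
  lbd_1 <- lapply(lbd_spans, function(sp)
    arc_points(length(sp$res), sp$r, sp$z, lbd_azimuth))

  # --- assemble all five chains by C5 rotation -------------------------
  atom_rows <- list(); coord_rows <- list()
  add <- function(elety, resid, chain, resno, element, xyz) {
    atom_rows[[length(atom_rows) + 1L]] <<- data.frame(
      elety = elety, resid = resid, chain = chain, resno = resno,
      element = element, stringsAsFactors = FALSE)
    coord_rows[[length(coord_rows) + 1L]] <<-
      matrix(xyz, ncol = 3)
  }
  resname_for <- function(resno) {
    special <- c("231" = "GLY", "235" = "SER", "239" = "THR",
                 "242" = "LEU", "243" = "SER", "245" = "THR",
                 "246" = "VAL", "249" = "LEU", "253" = "GLU",
                 "256" = "PRO", "40" = "LYS", "87" = "TYR",
                 "103" = "LEU", "113" = "LEU", "143" = "TRP",
                 "182" = "TYR", "189" = "TYR")
    out <- special[as.character(resno)]
    out[is.na(out)] <- "ALA"
    unname(out)
  }
  ring6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

  for (k in seq_along(chains)) {
    Rz <- rot_z(72 * (k - 1))
    ca_k <- if (bp$uniform_tilt) ca1 else
      build_chain(bp$polar_deg[k], bp$azimuthal_deg[k])
    ca <- ca_k %*% t(Rz)
    cb <- proxy_for(ca_k) %*% t(Rz)
    m2_res <- unname(topo$prime_map)
    add(rep(c("CA", "CB"), n_res),
        rep(resname_for(m2_res), each = 2L), chains[k],
        rep(m2_res, each = 2L), rep("C", 2L * n_res),
        matrix(rbind(t(ca), t(cb)), ncol = 3, byrow = TRUE))
    loop <- m2m3_1 %*% t(Rz)
    add(rep("CA", length(loop_res)), resname_for(loop_res), chains[k],
        loop_res, rep("C", length(loop_res)), loop)
    for (si in seq_along(lbd_spans)) {
      sp <- lbd_spans[[si]]
      pts <- lbd_1[[si]] %*% t(Rz)
      add(rep("CA", length(sp$res)), resname_for(sp$res), chains[k],
          sp$res, rep("C", length(sp$res)), pts)
      # side-chain atoms needed by the binding-site monitors
      for (m in seq_along(sp$res)) {
        rn <- sp$res[m]; p <- pts[m, ]
        inward <- -unit(c(p[1], p[2], 0))
        if (rn %in% c(87, 189))
          add("OH", resname_for(rn), chains[k], rn, "O", p + 1.2 * inward)
        if (rn == 143)
          add("O", resname_for(rn), chains[k], rn, "O", p + 1.2 * inward)
        if (rn %in% c(103, 113))
          add("N", resname_for(rn), chains[k], rn, "N", p + 1.0 * inward)
        if (rn %in% c(143, 182, 189)) {
          cen <- p + 1.5 * inward
          tang <- cross3(c(0, 0, 1), inward)
          ang <- seq(0, 300, by = 60) * pi / 180
          hex <- t(vapply(ang, function(a)
            cen + 1.39 * (cos(a) * inward + sin(a) * tang), numeric(3)))
          add(ring6, resname_for(rn), chains[k], rn, rep("C", 6), hex)
        }
      }
    }
  }

  # --- agonist proxies --------------------------------------------------
  orient_dir <- c(axial_up = 1, axial_down = -1, equatorial = 0)
  if (bp$ligand) {
    for (k in seq_along(chains)) {
      a0 <- (lbd_azimuth + 72 * (k - 1)) * pi / 180
      c0 <- c(16 * cos(a0), 16 * sin(a0), 37)
      inward <- -unit(c(c0[1], c0[2], 0))
      tang <- cross3(c(0, 0, 1), inward)
      d <- switch(bp$ligand_orientation,
                  axial_up = c(0, 0, 1), axial_down = c(0, 0, -1),
                  equatorial = inward,
                  stop("unknown ligand orientation"))
      e1 <- tang; e2 <- if (abs(sum(d * c(0, 0, 1))) > 0.5) inward else
        c(0, 0, 1)
      pent <- t(vapply(seq(0, 288, by = 72) * pi / 180, function(a)
        c0 - 1.2 * e1 + 1.2 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
      hexp <- t(vapply(seq(0, 300, by = 60) * pi / 180, function(a)
        c0 + 1.2 * e1 + 1.39 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
      # offsets chosen so the non-marker centroid sits exactly at c0;
      # the marker direction is then the exact orientation ground truth
      n1 <- c0 - 0.6 * e1 + 0.8 * e2
      n2 <- c0 - 0.6 * e1 - 0.8 * e2
      cl <- c0 + 2.5 * d
      add(c(paste0("C", 1:5), paste0("C", 6:11), "N1", "N2", "CL"),
          rep("EPI", 14), chains[k], 301L,
          c(rep("C", 11), "N", "N", "Cl"),
          rbind(pent, hexp, n1, n2, cl))
    }
  }

  # protein/ligand noise
  atoms <- do.call(rbind, atom_rows)
  xyz <- do.call(rbind, coord_rows)
  if (bp$noise_sd > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = bp$noise_sd), ncol = 3)

  # --- waters and ions (axis coordinates: pore axis is the lab z axis,
  # axial origin at the M2 C-alpha centroid = z = 0) --------------------
  gate_center <- mean(ca1[primes == 13L, 3])
  z_lo <- mean(ca1[primes == min(primes), 3])
  z_hi <- mean(ca1[primes == max(primes), 3])
  regions <- list(
    pore = c(z_lo, z_hi),
    gate = c(gate_center - 5, gate_center + 5))
  margin <- 0.2
  n_gate <- bp$waters$gate
  n_pore <- bp$waters$pore
  if (n_gate > n_pore) stop("gate occupancy cannot exceed pore occupancy")
  wat_xyz <- rbind(
    sample_cylinder(n_gate, regions$gate[1] + margin,
                    regions$gate[2] - margin, 3),
    sample_split_slab(n_pore - n_gate, z_lo + margin,
                      regions$gate[1] - margin,
                      regions$gate[2] + margin, z_hi - margin, 3))
  n_wat <- nrow(wat_xyz)
  if (n_wat > 0) {
    wlist <- water_sites(wat_xyz)
    add(rep(c("O", "H1", "H2"), n_wat), rep("HOH", 3L * n_wat), "W",
        rep(seq_len(n_wat) + 1000L, each = 3L),
        rep(c("O", "H", "H"), n_wat), wlist)
  }
  if (bp$n_cations > 0)
    add(rep("NA", bp$n_cations), rep("SOD", bp$n_cations), "I",
        seq_len(bp$n_cations) + 2000L, rep("Na", bp$n_cations),
        sample_cylinder(bp$n_cations, -19.5, -0.5, 6))
  if (bp$n_anions > 0)
    add(rep("CL", bp$n_anions), rep("CLA", bp$n_anions), "I",
        seq_len(bp$n_anions) + 2500L, rep("Cl", bp$n_anions),
        sample_cylinder(bp$n_anions, -29.5, -20.5, 6))

  atoms <- do.call(rbind, atom_rows)
  xyz_all <- do.call(rbind, coord_rows)
  n_pl <- nrow(xyz)
  xyz_all[seq_len(n_pl), ] <- xyz   # noise applied to protein/ligand only
  atoms$eleno <- seq_len(nrow(atoms))
  frame <- structure_frame(atoms, xyz_all, topology = topo)

  # --- closed-form ground truth ----------------------------------------
  td <- lapply(seq_len(5), function(k)
    tilt_direction(bp$polar_deg[k], bp$azimuthal_deg[k]))
  crossed <- crossed_ground_truth(ca1, proxy_for(ca1), primes)
  gt <- list(
    polar = vapply(td, `[[`, numeric(1), "polar"),
    azimuthal = vapply(td, `[[`, numeric(1), "azimuthal"),
    tilt_degenerate = vapply(td, `[[`, logical(1), "degenerate"),
    twist = bp$twist_deg,
    crossed_com = crossed$com, crossed_calpha = crossed$calpha,
    pore_radius_rings = setNames(pmax(0, bp$ring_radius - 1.7),
                                 names(bp$ring_radius)),
    water_pore = n_pore, water_gate = n_gate,
    n_cations = bp$n_cations, n_anions = bp$n_anions,
    ligand_orientation = bp$ligand_orientation,
    regions = regions, gate_center = gate_center,
    lbd_span = c(30L, 200L), tmd_span = c(topo$m2_range[1],
                                          topo$loops$M2_M3[2]))
  list(frame = frame, ground_truth = gt, topology = topo)
}

# chord ground truth: with C5 symmetry the five crossed distances at a
# ring all equal 2 R sin 72deg, R the point's distance from the axis
crossed_ground_truth <- function(ca1, cb1, primes) {
  chord <- function(p) 2 * sqrt(p[1]^2 + p[2]^2) * sin(72 * pi / 180)
  com <- vapply(seq_along(primes), function(k)
    chord((ca1[k, ] + cb1[k, ]) / 2), numeric(1))  # CA and CB both carbon
  calpha <- vapply(seq_along(primes), function(k) chord(ca1[k, ]),
                   numeric(1))
  list(com = setNames(com, primes), calpha = setNames(calpha, primes))
}

sample_cylinder <- function(n, z_lo, z_hi, radius) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a), runif(n, z_lo, z_hi))
}

# uniform over the union of two slabs (pore lumen minus the gate slab)
sample_split_slab <- function(n, lo1, hi1, lo2, hi2, radius) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  len1 <- max(0, hi1 - lo1); len2 <- max(0, hi2 - lo2)
  n1 <- rbinom(1, n, if (len1 + len2 > 0) len1 / (len1 + len2) else 0)
  rbind(sample_cylinder(n1, lo1, hi1, radius),
        sample_cylinder(n - n1, lo2, hi2, radius))
}

# 3-site water geometry: O plus two H at 0.9572 Angstrom, 104.52 degrees,
# randomly oriented
water_sites <- function(o_xyz) {
  n <- nrow(o_xyz)
  out <- matrix(0, 3L * n, 3L)
  half <- 104.52 / 2 * pi / 180
  for (i in seq_len(n)) {
    u <- unit(rnorm(3))
    w <- unit(cross3(u, rnorm(3)))
    h1 <- o_xyz[i, ] + 0.9572 * (cos(half) * u + sin(half) * w)
    h2 <- o_xyz[i, ] + 0.9572 * (cos(half) * u - sin(half) * w)
    out[3 * i - 2, ] <- o_xyz[i, ]
    out[3 * i - 1, ] <- h1
    out[3 * i, ] <- h2
  }
  out
}

#' Build a synthetic trajectory between two gate states
#'
#' Linear interpolation of the protein and ligand coordinates between two
#' blueprints sharing an atom layout (e.g. [blueprint_open()] to
#' [blueprint_collapsed()]), plus i.i.d. Gaussian positional noise per
#' atom per frame.  Waters are re-placed each frame at the linearly
#' interpolated (rounded) per-region occupancy; a constant-size water
#' pool is maintained by parking surplus waters in a bulk shell far from
#' the pore (lateral radius 30-35 Angstrom), so the frame atom count is
#' constant.  Ions are re-sampled each frame from the blueprint's
#' placement law.  Deterministic under `seed`.
#'
#' @param start,end [pentamer_blueprint()]s with identical layouts
#'   (same topology, ligand setting and ion counts).
#' @param n_frames number of frames.
#' @param noise_sd per-frame positional noise sigma (Angstrom) on
#'   protein/ligand atoms.
#' @param seed integer seed.
#' @param dt frame interval (ns).
#' @param origin trajectory label.
#' @return List: `trajectory` (a [channel_trajectory()]), `ground_truth`
#'   (per-frame occupancies and interpolation fractions plus the start /
#'   end records), `topology`.
#' @export
build_trajectory <- function(start, end = start, n_frames = 50,
                             noise_sd = 0, seed = start$seed, dt = 0.1,
                             origin = "synthetic") {
  if (start$n_cations != end$n_cations || start$n_anions != end$n_anions)
    stop("start and end blueprints must share ion counts")
  if (start$ligand != end$ligand)
    stop("start and end blueprints must share the ligand setting")
  bs <- build_pentamer(start)
  be <- build_pentamer(end)
  pl_s <- which(bs$frame$atoms$segment %in% c("protein", "ligand"))
  pl_e <- which(be$frame$atoms$segment %in% c("protein", "ligand"))
  if (length(pl_s) != length(pl_e))
    stop("blueprint layouts differ (protein/ligand atom counts)")
  xs <- bs$frame$xyz[pl_s, , drop = FALSE]
  xe <- be$frame$xyz[pl_e, , drop = FALSE]

  frac <- if (n_frames == 1L) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  occ_pore <- round(start$waters$pore + frac *
                      (end$waters$pore - start$waters$pore))
  occ_gate <- round(start$waters$gate + frac *
                      (end$waters$gate - start$waters$gate))
  pool <- max(occ_pore)
  gt_s <- bs$ground_truth
  margin <- 0.2
  gate <- gt_s$regions$gate
  lumen <- gt_s$regions$pore

  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      prot <- (1 - frac[i]) * xs + frac[i] * xe
      if (noise_sd > 0)
        prot <- prot + matrix(rnorm(length(prot), sd = noise_sd), ncol = 3)
      n_bulk <- pool - occ_pore[i]
      o_xyz <- rbind(
        sample_cylinder(occ_gate[i], gate[1] + margin, gate[2] - margin, 3),
        sample_split_slab(occ_pore[i] - occ_gate[i], lumen[1] + margin,
                          gate[1] - margin, gate[2] + margin,
                          lumen[2] - margin, 3),
        bulk_shell(n_bulk))
      wat <- water_sites(o_xyz)
      ions <- rbind(
        sample_cylinder(start$n_cations, -19.5, -0.5, 6),
        sample_cylinder(start$n_anions, -29.5, -20.5, 6))
      frames[[i]] <- rbind(prot, wat, ions)
    }
  })

  n_wat <- pool
  atoms <- rbind(
    bs$frame$atoms[pl_s, c("elety", "resid", "chain", "resno", "element")],
    data.frame(elety = rep(c("O", "H1", "H2"), n_wat),
               resid = rep("HOH", 3L * n_wat),
               chain = rep("W", 3L * n_wat),
               resno = rep(seq_len(n_wat) + 1000L, each = 3L),
               element = rep(c("O", "H", "H"), n_wat)),
    data.frame(elety = c(rep("NA", start$n_cations),
                         rep("CL", start$n_anions)),
               resid = c(rep("SOD", start$n_cations),
                         rep("CLA", start$n_anions)),
               chain = rep("I", start$n_cations + start$n_anions),
               resno = c(seq_len(start$n_cations) + 2000L,
                         seq_len(start$n_anions) + 2500L),
               element = c(rep("Na", start$n_cations),
                           rep("Cl", start$n_anions))))
  atoms$eleno <- seq_len(nrow(atoms))
  xyz <- t(vapply(frames, function(f) as.vector(t(f)),
                  numeric(3L * nrow(atoms))))
  traj <- channel_trajectory(atoms, xyz, times = (seq_len(n_frames) - 1) * dt,
                             origin = origin, topology = start$topology)
  list(trajectory = traj,
       ground_truth = list(frac = frac, water_pore = occ_pore,
                           water_gate = occ_gate, start = gt_s,
                           end = be$ground_truth,
                           regions = gt_s$regions),
       topology = start$topology)
}

bulk_shell <- function(n) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  r <- runif(n, 30, 35)
  a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a), runif(n, -20, 20))
}

#' Hydrogen-bond fixture trajectory with a scripted on/off schedule
#'
#' A minimal two-partner system whose bond is toggled per frame: in
#' `"water_residue"` mode a water is placed so its hydrogen sits at 1.8
#' Angstrom (on) or 4.5 Angstrom (off) from a serine side-chain oxygen;
#' in `"intra_protein"` mode a backbone N...O pair is toggled between
#' 2.8 and 4.5 Angstrom.  The persistence ground truth equals the
#' schedule's duty cycle exactly.
#'
#' @param schedule logical vector, one entry per frame (`TRUE` = formed).
#' @param mode `"water_residue"` or `"intra_protein"`.
#' @param dt frame interval (ns).
#' @return List: `trajectory`, `mode`, `duty_cycle` (percent), and the
#'   selections (`sel_donors`, `sel_acceptors`) to feed
#'   [hbond_persistence()].
#' @export
place_hbond_fixture <- function(schedule,
                                mode = c("water_residue", "intra_protein"),
                                dt = 0.1) {
  mode <- match.arg(mode)
  if (!length(schedule)) stop("schedule must be non-empty")
  on_d <- if (mode == "water_residue") 1.8 else 2.8
  off_d <- 4.5
  if (mode == "water_residue") {
    atoms <- data.frame(
      eleno = 1:6,
      elety = c("CA", "OG", "O", "H1", "H2", "CB"),
      resid = c("SER", "SER", "HOH", "HOH", "HOH", "SER"),
      chain = c("A", "A", "W", "W", "W", "A"),
      resno = c(1L, 1L, 1001L, 1001L, 1001L, 1L),
      element = c("C", "O", "O", "H", "H", "C"))
    base <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(10, 0, 0), c(9, 0, 0),
                  c(10.3, 0.9, 0), c(-1, 0, 0))
    frames <- lapply(schedule, function(on) {
      x <- base
      d <- if (on) on_d else off_d
      # water H1 at distance d from OG, O behind it along +x
      x[4, ] <- c(1.4 + d, 0, 0)
      x[3, ] <- c(1.4 + d + 0.9572, 0, 0)
      x[5, ] <- x[3, ] + c(0.24, 0.93, 0)
      x
    })
    sel_d <- 3:5   # water atoms
    sel_a <- c(1L, 2L, 6L)
  } else {
    atoms <- data.frame(
      eleno = 1:4,
      elety = c("N", "CA", "O", "CA"),
      resid = c("ALA", "ALA", "ALA", "ALA"),
      chain = c("A", "A", "B", "B"),
      resno = c(1L, 1L, 2L, 2L),
      element = c("N", "C", "O", "C"))
    frames <- lapply(schedule, function(on) {
      d <- if (on) on_d else off_d
      rbind(c(0, 0, 0), c(-1.5, 0, 0), c(d, 0, 0), c(d + 1.5, 0, 0))
    })
    sel_d <- 1:2
    sel_a <- 3:4
  }
  xyz <- t(vapply(frames, function(f) as.vector(t(f)),
                  numeric(3L * nrow(atoms))))
  traj <- channel_trajectory(atoms, xyz,
                             times = (seq_along(schedule) - 1) * dt,
                             origin = "hbond_fixture")
  list(trajectory = traj, mode = mode,
       duty_cycle = 100 * mean(schedule),
       sel_donors = sel_d, sel_acceptors = sel_a)
}
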