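topo5 <- alpha7_topology()

lab_axis <- structure(list(origin = c(0, 0, 0), z = c(0, 0, 1),
                           helix_frames = list()), class = "axis_frame")

test_that("interface distances and dCintra match direct arithmetic", {
  set.seed(70)
  for (k in 1:20) {
    g <- build_pentamer(pentamer_blueprint(
      polar_deg = runif(1, -5, 10), twist_deg = runif(1, 10, 25),
      waters = list(pore = 0, gate = 0), n_cations = 0, n_anions = 0,
      ligand = FALSE, noise_sd = 0.2, seed = 700 + k))
    fr <- g$frame
    idf <- interface_distances(fr, topo5)
    dci <- dCintra(fr, topo5)
    for (ch in topo5$chain_ids) {
      ca_mean <- function(resnos) {
        idx <- which(fr$atoms$chain == ch & fr$atoms$resno %in% resnos &
                       fr$atoms$elety == "CA")
        colMeans(fr$xyz[idx, , drop = FALSE])
      }
      p_pro <- ca_mean(256)
      expect_equal(idf$d_pro_cysloop[idf$chain == ch],
                   dist3(p_pro, ca_mean(122:136)), tolerance = 1e-10)
      expect_equal(idf$d_pro_lys[idf$chain == ch],
                   dist3(p_pro, ca_mean(40)), tolerance = 1e-10)
      expect_equal(unname(dci[ch]),
                   dist3(ca_mean(179:188), ca_mean(139:140)),
                   tolerance = 1e-10)
    }
  }
})

test_that("interface distances are invariant under rigid motion", {
  g <- build_pentamer(blueprint_open(seed = 12))
  fr <- g$frame
  base_i <- interface_distances(fr, topo5)
  base_d <- dCintra(fr, topo5)
  set.seed(71)
  for (k in 1:5) {
    fr2 <- rigid_move(fr)
    expect_equal(interface_distances(fr2, topo5)$d_pro_cysloop,
                 base_i$d_pro_cysloop, tolerance = 1e-8)
    expect_equal(dCintra(fr2, topo5), base_d, tolerance = 1e-8)
  }
  # coincident centers give zero
  two <- make_frame(rep("CA", 12), "ALA", "A",
                    c(179:188, 139:140), rep("C", 12),
                    matrix(rnorm(36), ncol = 3))
  two$xyz[11, ] <- colMeans(two$xyz[1:10, ]) + c(0.5, 0, 0)
  two$xyz[12, ] <- colMeans(two$xyz[1:10, ]) - c(0.5, 0, 0)
  mini <- channel_topology(c("A", "B", "C", "D", "E"), topo5$prime_map,
                           topo5$m2_range, topo5$loops)
  expect_error(dCintra(two, mini), "unresolvable")   # other chains absent
})

test_that("ligand contacts use atoms or ring centroids, per direct arithmetic", {
  g <- build_pentamer(blueprint_open(seed = 13))
  fr <- g$frame
  monitors <- default_ligand_monitors(topo5, "A", "B")
  got <- ligand_contacts(fr, topo5, monitors, "A")
  expect_equal(nrow(got), 8)
  expect_true(all(got$distance >= 0))
  a <- fr$atoms
  centroid <- function(chain, resno, names_) {
    idx <- which(a$chain == chain & a$resno == resno &
                   a$elety %in% names_)
    colMeans(fr$xyz[idx, , drop = FALSE])
  }
  lig_of <- function(names_) {
    idx <- which(a$chain == "A" & a$resid == "EPI" & a$elety %in% names_)
    colMeans(fr$xyz[idx, , drop = FALSE])
  }
  # single-atom monitor
  expect_equal(got$distance[got$name == "EPI-CL/LEU103-N"],
               dist3(lig_of("CL"), centroid("B", 103, "N")),
               tolerance = 1e-10)
  # ring-centroid monitor: centroid equals the mean of the six vertices
  ring6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  expect_equal(got$distance[got$name == "EPI-bridge/TYR182-ring"],
               dist3(lig_of(paste0("C", 1:5)), centroid("A", 182, ring6)),
               tolerance = 1e-10)
  expect_error(ligand_contacts(
    build_pentamer(pentamer_blueprint(ligand = FALSE, seed = 1))$frame,
    topo5, monitors, "A"), "no ligand")
})

test_that("ligand orientation classes match construction and partition", {
  for (ori in c("axial_up", "axial_down", "equatorial")) {
    g <- build_pentamer(pentamer_blueprint(ligand_orientation = ori,
                                           seed = 14))
    af <- symmetry_axis(g$frame, topo5)
    for (ch in topo5$chain_ids) {
      cls <- classify_ligand_orientation(g$frame, topo5, af, ch)
      expect_equal(as.character(cls), ori)
    }
  }
  # random marker directions always land in exactly one class
  g <- build_pentamer(pentamer_blueprint(seed = 15))
  af <- symmetry_axis(g$frame, topo5)
  set.seed(72)
  for (k in 1:50) {
    fr <- g$frame
    lig <- select_atoms(fr, segment = "ligand", chain = "A")
    ref <- lig[fr$atoms$elety[lig] == "CL"]
    cen <- colMeans(fr$xyz[lig, , drop = FALSE])
    u <- rnorm(3)
    fr$xyz[ref, ] <- cen + 2.5 * u / sqrt(sum(u^2))
    cls <- classify_ligand_orientation(fr, topo5, af, "A")
    expect_true(as.character(cls) %in%
                  c("axial_up", "axial_down", "equatorial",
                    "intermediate"))
  }
})

test_that("ion axial histograms match brute-force binning and conserve counts", {
  bp <- pentamer_blueprint(waters = list(pore = 0, gate = 0),
                           n_cations = 6, n_anions = 4, ligand = FALSE,
                           seed = 16)
  tr <- build_trajectory(bp, bp, n_frames = 8, seed = 16)
  for (sp in c("cation", "anion")) {
    h <- ion_z_distribution(tr$trajectory, lab_axis, sp,
                            z_range = c(-32, 2), bin_width = 2,
                            lateral_radius = 10)
    expect_equal(h$count,
                 oracle_ion_hist(tr$trajectory, c(0, 0, 0), c(0, 0, 1),
                                 sp, c(-32, 2), 2, 10))
    n_in <- if (sp == "cation") 6 else 4
    expect_equal(sum(h$count), n_in * 8)   # all ions in range, all frames
    if (sum(h$count) > 0)
      expect_equal(sum(h$density * 2), 1, tolerance = 1e-12)
  }
  # ions fixed at one depth put all pooled counts in one bin
  at <- data.frame(eleno = 1:3, elety = "NA", resid = "SOD", chain = "I",
                   resno = 1:3, element = "Na")
  xyz1 <- rbind(c(1, 0, -25), c(-1, 0, -25), c(0, 1, -25))
  xyz <- matrix(rep(as.vector(t(xyz1)), 10), nrow = 10, byrow = TRUE)
  trf <- channel_trajectory(at, xyz, times = 0:9)
  hf <- ion_z_distribution(trf, lab_axis, "cation", c(-30, -20), 2, 10)
  expect_equal(sum(hf$count), 30)
  expect_equal(hf$count[hf$bin_left == -26], 30)
  # no anions present: empty anion histogram
  ha <- ion_z_distribution(trf, lab_axis, "anion", c(-30, -20), 2, 10)
  expect_equal(sum(ha$count), 0)
  expect_error(ion_z_distribution(trf, lab_axis, "metal", c(-30, -20), 2),
               "arg")
})

test_that("ion occupancy counts per frame and reports the maximum", {
  at <- data.frame(eleno = 1:2, elety = "NA", resid = "SOD", chain = "I",
                   resno = 1:2, element = "Na")
  # scripted walk: both ions inside the region only in frame 2
  f1 <- rbind(c(0, 0, -15), c(0, 0, -12))
  f2 <- rbind(c(0, 0, -5), c(1, 0, -3))
  f3 <- rbind(c(0, 0, 5), c(0, 0, -5))
  xyz <- rbind(as.vector(t(f1)), as.vector(t(f2)), as.vector(t(f3)))
  tr <- channel_trajectory(at, xyz, times = 0:2)
  reg <- pore_region("below_gate", -10, 0, radius = 8)
  occ <- ion_occupancy(tr, lab_axis, reg, "cation")
  expect_equal(as.vector(occ$values), c(0, 2, 1))
  expect_equal(attr(occ, "max_occupancy"), 2)
  empty <- ion_occupancy(tr, lab_axis, pore_region("far", 50, 60), "cation")
  expect_true(all(empty$values == 0))
})
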