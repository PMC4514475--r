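topo5 <- alpha7_topology()

test_that("crossed distances equal the pentagon chord on C5 geometry", {
  for (R in c(10, 5)) {
    fr <- pentagon_frame(radius = R)
    d <- crossed_distances(fr, topo5, 13, "calpha")
    expect_equal(unname(d), rep(2 * R * sin(72 * pi / 180), 5),
                 tolerance = 1e-10)
  }
  # homogeneity: halving the circumradius halves every distance
  d10 <- crossed_distances(pentagon_frame(10), topo5, 13, "calpha")
  d5 <- crossed_distances(pentagon_frame(5), topo5, 13, "calpha")
  expect_equal(unname(d5), unname(d10) / 2, tolerance = 1e-12)
  expect_equal(names(d10),
               c("P1-P3", "P2-P4", "P3-P5", "P4-P1", "P5-P2"))
})

test_that("displacing one vertex changes exactly its two pairs, per direct arithmetic", {
  fr <- pentagon_frame(10)
  fr$xyz[1, ] <- fr$xyz[1, ] * 1.1   # vertex A radially out by 1 A
  d <- crossed_distances(fr, topo5, 13, "calpha")
  ora <- oracle_crossed(fr, topo5, 13, "calpha")
  expect_equal(unname(d), ora, tolerance = 1e-10)
  base <- 2 * 10 * sin(72 * pi / 180)
  expect_equal(unname(d["P3-P5"]), base, tolerance = 1e-10)
  expect_gt(d["P1-P3"], base)
  expect_gt(d["P4-P1"], base)
})

test_that("crossed distances match the brute-force oracle on random pentamers", {
  set.seed(202)
  for (rep in 1:20) {
    bp <- pentamer_blueprint(
      ca_ring_radius = runif(1, 9, 14),
      polar_deg = runif(1, -5, 10), azimuthal_deg = runif(1, -10, 10),
      waters = list(pore = 0, gate = 0), n_cations = 0, n_anions = 0,
      ligand = FALSE, noise_sd = 0.3, seed = rep)
    fr <- build_pentamer(bp)$frame
    for (p in c(13L, 16L, 9L)) {
      expect_equal(unname(crossed_distances(fr, topo5, p, "residue_com")),
                   oracle_crossed(fr, topo5, p, "residue_com"),
                   tolerance = 1e-10)
      expect_equal(unname(crossed_distances(fr, topo5, p, "calpha")),
                   oracle_crossed(fr, topo5, p, "calpha"),
                   tolerance = 1e-10)
    }
  }
})

test_that("COM and C-alpha crossed modes order open above collapsed alike", {
  fo <- build_pentamer(blueprint_open(seed = 3))$frame
  fc <- build_pentamer(blueprint_collapsed(seed = 3))$frame
  for (mode in c("residue_com", "calpha")) {
    do <- mean(crossed_distances(fo, topo5, 13, mode))
    dc <- mean(crossed_distances(fc, topo5, 13, mode))
    expect_gt(do, dc)
  }
})

test_that("pore radius is exact for a coaxial cylinder of atoms", {
  set.seed(30)
  n <- 400
  ang <- runif(n, 0, 2 * pi)
  fr <- make_frame(rep("CA", n), "ALA", "A", seq_len(n), rep("C", n),
                   cbind(8 * cos(ang), 8 * sin(ang), runif(n, -15, 15)))
  af <- structure(list(origin = c(0, 0, 0), z = c(0, 0, 1),
                       helix_frames = list()), class = "axis_frame")
  pp <- pore_radius_profile(fr, af, c(-10, 10), spacing = 0.5)
  filled <- pp[!pp$flagged, ]
  expect_gt(nrow(filled), 30)
  expect_equal(filled$radius, rep(8 - 1.7, nrow(filled)),
               tolerance = 1e-10)
  # empty slab is flagged at the configured maximum
  pp2 <- pore_radius_profile(fr, af, c(40, 42), max_radius = 10)
  expect_true(all(pp2$flagged))
  expect_true(all(pp2$radius == 10))
})

test_that("funnel fixture recovers the analytic linear profile", {
  set.seed(31)
  n <- 4000
  z <- runif(n, -10, 10)
  rad <- 5 + 0.2 * z    # funnel: radius linear in z
  ang <- runif(n, 0, 2 * pi)
  fr <- make_frame(rep("CA", n), "ALA", "A", seq_len(n), rep("C", n),
                   cbind(rad * cos(ang), rad * sin(ang), z))
  af <- structure(list(origin = c(0, 0, 0), z = c(0, 0, 1),
                       helix_frames = list()), class = "axis_frame")
  spacing <- 0.5
  pp <- pore_radius_profile(fr, af, c(-8, 8), spacing = spacing)
  filled <- pp[!pp$flagged, ]
  analytic <- 5 + 0.2 * filled$z - 1.7
  # discretization bounds the error by the radius change across one slab
  expect_true(all(abs(filled$radius - analytic) <= 0.2 * spacing + 1e-9))
})

test_that("helix axis recovers constructed directions", {
  topo <- alpha7_topology()
  build_helix_frame <- function(R = diag(3)) {
    j <- 0:22
    th <- j * 100 * pi / 180
    xyz <- cbind(2.3 * cos(th), 2.3 * sin(th), (j - 11) * 1.5)
    xyz <- sweep(xyz, 2, colMeans(xyz))
    make_frame(rep("CA", 23), "ALA", "A", 231:253, rep("C", 23),
               xyz %*% t(R))
  }
  fr <- build_helix_frame()
  a <- m2_helix_axis(fr, topo, "A")
  expect_lt(acos(min(1, sum(a * c(0, 0, 1)))) * 180 / pi, 0.5)
  ry <- 10 * pi / 180
  Ry <- matrix(c(cos(ry), 0, sin(ry), 0, 1, 0, -sin(ry), 0, cos(ry)),
               3, byrow = TRUE)
  a2 <- m2_helix_axis(build_helix_frame(Ry), topo, "A")
  expect_lt(acos(min(1, sum(a2 * drop(Ry %*% c(0, 0, 1))))) * 180 / pi,
            0.5)
  # noisy helix stays within 2 degrees of ground truth
  set.seed(40)
  worst <- 0
  for (k in 1:10) {
    frn <- build_helix_frame(Ry)
    frn$xyz <- frn$xyz + matrix(rnorm(69, sd = 0.3), ncol = 3)
    an <- m2_helix_axis(frn, topo, "A")
    worst <- max(worst,
                 acos(min(1, sum(an * drop(Ry %*% c(0, 0, 1))))) * 180 / pi)
  }
  expect_lt(worst, 2)
})

test_that("tilt angles follow the local-frame conventions", {
  # zero tilt: polar 0, azimuthal degenerate-flagged 0
  g0 <- build_pentamer(pentamer_blueprint(waters = list(pore = 0, gate = 0),
                                          n_cations = 0, n_anions = 0,
                                          ligand = FALSE, seed = 1))
  af0 <- symmetry_axis(g0$frame, topo5)
  t0 <- tilt_angles(g0$frame, af0, topo5)
  expect_true(all(abs(t0$polar) < 1e-6))
  expect_true(all(t0$degenerate))
  expect_true(all(t0$azimuthal == 0))
  # +10 degrees toward local +x: polar +10, azimuthal 0
  gx <- build_pentamer(pentamer_blueprint(polar_deg = 10, azimuthal_deg = 0,
                                          waters = list(pore = 0, gate = 0),
                                          n_cations = 0, n_anions = 0,
                                          ligand = FALSE, seed = 1))
  tx <- tilt_angles(gx$frame, symmetry_axis(gx$frame, topo5), topo5)
  expect_equal(tx$polar, rep(10, 5), tolerance = 1e-6)
  expect_equal(tx$azimuthal, rep(0, 5), tolerance = 1e-6)
  # tilt toward local +y: polar ~0, azimuthal +90
  gy <- build_pentamer(pentamer_blueprint(polar_deg = 10,
                                          azimuthal_deg = 90,
                                          waters = list(pore = 0, gate = 0),
                                          n_cations = 0, n_anions = 0,
                                          ligand = FALSE, seed = 1))
  ty <- tilt_angles(gy$frame, symmetry_axis(gy$frame, topo5), topo5)
  expect_equal(ty$azimuthal, rep(90, 5), tolerance = 1e-6)
  expect_true(all(abs(ty$polar) < 0.5))
})

test_that("twist angle matches construction and is rotation invariant", {
  for (tw in c(0, 21)) {
    g <- build_pentamer(pentamer_blueprint(twist_deg = tw,
                                           waters = list(pore = 0,
                                                         gate = 0),
                                           n_cations = 0, n_anions = 0,
                                           ligand = FALSE, seed = 2))
    af <- symmetry_axis(g$frame, topo5)
    res <- twist_angle(g$frame, af, topo5, g$ground_truth$lbd_span,
                       g$ground_truth$tmd_span)
    expect_equal(unname(res$per_subunit), rep(tw, 5), tolerance = 1e-8)
    expect_equal(res$mean, tw, tolerance = 1e-8)
    # rigid rotation about z leaves the twist unchanged
    fr2 <- rigid_move(g$frame, rot_z_test(37), c(0, 0, 0))
    af2 <- symmetry_axis(fr2, topo5)
    res2 <- twist_angle(fr2, af2, topo5, g$ground_truth$lbd_span,
                        g$ground_truth$tmd_span)
    expect_equal(res2$mean, res$mean, tolerance = 1e-8)
  }
})

test_that("distance distributions are normalized and pool subunits", {
  s <- descriptor_series(matrix(5, 10, 1), 1:10, "d", "Angstrom")
  h <- distance_distribution(s, 0.5)
  expect_equal(sum(h$count), 10)
  expect_equal(sum(h$density * 0.5), 1, tolerance = 1e-12)
  expect_equal(sum(h$count > 0), 1)
  # two pairs at distinct values: bimodal with equal masses
  two <- descriptor_series(cbind(rep(4, 20), rep(8, 20)), 1:20, "d", "A")
  h2 <- distance_distribution(two, 0.5, merge_subunits = TRUE)
  occ <- h2[h2$count > 0, ]
  expect_equal(nrow(occ), 2)
  expect_equal(occ$count, c(20, 20))
  expect_error(distance_distribution(s, 0), "positive")
})
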