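topo5 <- alpha7_topology()

lab_axis <- structure(list(origin = c(0, 0, 0), z = c(0, 0, 1),
                           helix_frames = list()), class = "axis_frame")

# frame with waters (O + 2 H) at given oxygen positions
water_frame <- function(o_xyz, extra = NULL) {
  n <- nrow(o_xyz)
  at <- data.frame(
    eleno = seq_len(3 * n),
    elety = rep(c("O", "H1", "H2"), n),
    resid = "HOH", chain = "W",
    resno = rep(seq_len(n) + 1000L, each = 3L),
    element = rep(c("O", "H", "H"), n))
  xyz <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    xyz[3 * i - 2, ] <- o_xyz[i, ]
    xyz[3 * i - 1, ] <- o_xyz[i, ] + c(0.96, 0, 0)
    xyz[3 * i, ] <- o_xyz[i, ] + c(-0.24, 0.93, 0)
  }
  if (!is.null(extra)) {
    at <- rbind(extra$atoms, at)
    at$eleno <- seq_len(nrow(at))
    xyz <- rbind(extra$xyz, xyz)
  }
  structure_frame(at, xyz)
}

test_that("water counts use a half-open slab and a lateral bound", {
  set.seed(55)
  inside <- cbind(runif(37, -2, 2), runif(37, -2, 2), runif(37, -4.9, 4.9))
  fr <- water_frame(inside)
  reg <- pore_region("slab", -5, 5, radius = 8)
  expect_equal(water_count(fr, lab_axis, reg), 37)
  # oxygen exactly at z_hi is excluded; lateral radius + eps is excluded
  edge <- water_frame(rbind(c(0, 0, 5), c(8 + 1e-9, 0, 0), c(8, 0, 0)))
  expect_equal(water_count(edge, lab_axis, reg), 1)
  expect_error(pore_region("bad", 3, 3), "z_lo")
})

test_that("water counts agree with brute-force membership on random placements", {
  set.seed(56)
  for (k in 1:25) {
    o <- cbind(runif(40, -12, 12), runif(40, -12, 12), runif(40, -20, 20))
    fr <- water_frame(o)
    z_lo <- runif(1, -15, -2)
    z_hi <- z_lo + runif(1, 2, 15)
    rad <- runif(1, 3, 10)
    reg <- pore_region("r", z_lo, z_hi, rad)
    expect_identical(water_count(fr, lab_axis, reg),
                     oracle_water_count(fr, c(0, 0, 0), c(0, 0, 1),
                                        z_lo, z_hi, rad))
  }
})

test_that("water counts are additive over a disjoint slab partition", {
  set.seed(57)
  o <- cbind(runif(80, -4, 4), runif(80, -4, 4), runif(80, -14, 14))
  fr <- water_frame(o)
  cuts <- c(-15, -7, -2, 3, 9, 15)
  parts <- vapply(seq_len(length(cuts) - 1), function(i)
    water_count(fr, lab_axis,
                pore_region("p", cuts[i], cuts[i + 1], 6)), integer(1))
  whole <- water_count(fr, lab_axis, pore_region("w", -15, 15, 6))
  expect_equal(sum(parts), whole)
})

test_that("ring-proximity water counts deduplicate and match the oracle", {
  g <- build_pentamer(pentamer_blueprint(seed = 6))
  fr <- g$frame
  n6 <- ring_proximity_water_count(fr, topo5, 6)
  expect_identical(n6, oracle_ring_waters(fr, topo5, 6, 3.0))
  for (p in c(2L, 10L, 12L))
    expect_identical(ring_proximity_water_count(fr, topo5, p),
                     oracle_ring_waters(fr, topo5, p, 3.0))
  # a water with two atoms within the shell still counts once
  ring_atom <- list(
    atoms = data.frame(eleno = 1L, elety = "CA", resid = "VAL",
                       chain = "A", resno = 246L, element = "C"),
    xyz = matrix(c(0, 0, 0), 1))
  fr2 <- water_frame(matrix(c(1.2, 0, 0), 1), extra = ring_atom)
  expect_identical(ring_proximity_water_count(fr2, topo5, 13), 1L)
  expect_error(ring_proximity_water_count(fr2, topo5, 13, cutoff = 0),
               "positive")
})

test_that("water-residue H-bond criterion is a 2 A hydrogen-heavy minimum", {
  # serine OG with a water hydrogen at 1.8 A: formed; at 2.1 A: not
  ser <- list(atoms = data.frame(eleno = 1:2, elety = c("CA", "OG"),
                                 resid = "SER", chain = "A", resno = 10L,
                                 element = c("C", "O")),
              xyz = rbind(c(-1.4, 0, 0), c(0, 0, 0)))
  place_water_h_at <- function(d) {
    fr <- water_frame(matrix(c(d + 0.96, 0, 0), 1), extra = ser)
    # rows 3:5 are the water O, H1, H2; put H1 at (d, 0, 0)
    fr$xyz[3, ] <- c(d + 0.96, 0, 0)
    fr$xyz[4, ] <- c(d, 0, 0)
    fr$xyz[5, ] <- c(d + 1.2, 0.93, 0)
    fr
  }
  sel_w <- 3:5
  sel_r <- 1:2
  near <- detect_hbonds(place_water_h_at(1.8), "water_residue",
                        sel_donors = sel_w, sel_acceptors = sel_r)
  expect_equal(nrow(near), 1)
  expect_equal(near$min_dist, 1.8, tolerance = 1e-9)
  far <- detect_hbonds(place_water_h_at(2.1), "water_residue",
                       sel_donors = sel_w, sel_acceptors = sel_r)
  expect_equal(nrow(far), 0)
})

test_that("water-residue H-bond pairs match the exhaustive oracle", {
  set.seed(60)
  for (k in 1:8) {
    g <- build_pentamer(pentamer_blueprint(
      waters = list(pore = 30, gate = 10), n_cations = 0, n_anions = 0,
      ligand = FALSE, seed = 600 + k))
    fr <- g$frame
    res10 <- prime_residue(topo5, 10)
    sel_res <- select_atoms(fr, resno = res10, segment = "protein")
    sel_wat <- select_atoms(fr, segment = "water")
    # use a permissive cutoff so some pairs form across random geometry
    got <- detect_hbonds(fr, "water_residue", sel_wat, sel_res,
                         cutoff = 4.0)
    expect_identical(sort(got$key),
                     oracle_water_hbond_pairs(fr, sel_wat, sel_res, 4.0))
  }
})

test_that("intra-protein H-bonds use a 3 A heavy-atom threshold", {
  mk <- function(d) make_frame(
    elety = c("N", "CA", "O", "CA"), resid = "ALA",
    chain = c("A", "A", "B", "B"), resno = c(1L, 1L, 2L, 2L),
    element = c("N", "C", "O", "C"),
    xyz = rbind(c(0, 0, 0), c(-1.5, 0, 0), c(d, 0, 0), c(d + 1.5, 0, 0)))
  hb <- detect_hbonds(mk(2.9), "intra_protein", 1:2, 3:4)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist, 2.9, tolerance = 1e-9)
  expect_equal(nrow(detect_hbonds(mk(3.1), "intra_protein", 1:2, 3:4)), 0)
  # same-residue donor/acceptor pairs are never reported
  same <- make_frame(elety = c("N", "O"), resid = "ALA", chain = "A",
                     resno = 1L, element = c("N", "O"),
                     xyz = rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(nrow(detect_hbonds(same, "intra_protein", 1:2, 1:2)), 0)
  no_type <- make_frame(elety = c("CB", "CB"), resid = "ALA",
                        chain = c("A", "B"), resno = 1:2,
                        element = c("C", "C"),
                        xyz = rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(detect_hbonds(no_type, "intra_protein", 1, 2), "typed")
})

test_that("persistence equals the scripted duty cycle exactly", {
  expect_equal(place_hbond_fixture(rep(c(TRUE, FALSE), c(120, 80)),
                                   "intra_protein")$duty_cycle, 60)
  for (mode in c("water_residue", "intra_protein")) {
    set.seed(61)
    sched <- runif(60) < 0.6
    fx <- place_hbond_fixture(sched, mode)
    hp <- hbond_persistence(fx$trajectory, mode, fx$sel_donors,
                            fx$sel_acceptors)
    expect_equal(nrow(hp), 1)
    expect_equal(hp$persistence, fx$duty_cycle)
    # always-on and never-on schedules
    on <- place_hbond_fixture(rep(TRUE, 10), mode)
    expect_equal(hbond_persistence(on$trajectory, mode, on$sel_donors,
                                   on$sel_acceptors)$persistence, 100)
    off <- place_hbond_fixture(rep(FALSE, 10), mode)
    hoff <- hbond_persistence(off$trajectory, mode, off$sel_donors,
                              off$sel_acceptors, min_persistence = 1)
    expect_equal(nrow(hoff), 0)
  }
})

test_that("wetting event detection applies hysteresis and min duration", {
  mk <- function(x) descriptor_series(x, seq_along(x) - 1, "w", "count")
  expect_equal(nrow(detect_wetting_events(mk(rep(40, 50)))), 0)
  step <- c(rep(40, 10), rep(2, 10), rep(40, 10))
  ev <- detect_wetting_events(mk(step), low = 10, high = 30,
                              min_duration = 5)
  expect_equal(ev$type, c("dewetting", "rewetting"))
  expect_equal(ev$start, c(11L, 21L))
  # a dip shorter than min_duration is ignored
  blip <- c(rep(40, 10), rep(2, 3), rep(40, 10))
  expect_equal(nrow(detect_wetting_events(mk(blip), 10, 30, 5)), 0)
  # square wave: one dewetting + one rewetting per cycle
  sq <- rep(c(rep(40, 8), rep(2, 8)), 4)
  evs <- detect_wetting_events(mk(sq), 10, 30, 5)
  expect_equal(sum(evs$type == "dewetting"), 4)
  expect_equal(sum(evs$type == "rewetting"), 3)
  expect_error(detect_wetting_events(mk(sq), 30, 10), "high > low")
})
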