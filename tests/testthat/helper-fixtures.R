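# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately naive (explicit loops, no shared code paths with the
# package implementation).

angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

circ_mean_deg <- function(a) {
  atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
}

rot_z_test <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
         byrow = TRUE)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to a structure_frame
rigid_move <- function(frame, R = random_rotation(),
                       t = runif(3, -20, 20)) {
  frame$xyz <- sweep(frame$xyz %*% t(R), 2, t, FUN = "+")
  frame
}

# radially compress the pore so the gate restraint becomes active
rigid_scale_gate <- function(frame, s = 0.9) {
  frame$xyz[, 1:2] <- s * frame$xyz[, 1:2]
  frame
}

# small ad-hoc frame from an atom spec list
make_frame <- function(elety, resid, chain, resno, element, xyz,
                       topology = NULL) {
  structure_frame(
    data.frame(eleno = seq_along(elety), elety = elety, resid = resid,
               chain = chain, resno = resno, element = element),
    xyz, topology = topology)
}

# frame with n protein atoms on each of 5 chains at pentagon vertices
pentagon_frame <- function(radius = 10, resno = 246, z = 0,
                           resid = "VAL") {
  ang <- (0:4) * 72 * pi / 180
  make_frame(elety = rep("CA", 5), resid = rep(resid, 5),
             chain = c("A", "B", "C", "D", "E"), resno = rep(resno, 5),
             element = rep("C", 5),
             xyz = cbind(radius * cos(ang), radius * sin(ang), z))
}

# ---- brute-force oracles --------------------------------------------------

dist3 <- function(p, q) sqrt(sum((p - q)^2))

# residue reference point by explicit averaging (equal masses when all
# atoms share an element; general mass table otherwise)
oracle_residue_point <- function(frame, chain, resno, mode) {
  a <- frame$atoms
  idx <- which(a$chain == chain & a$resno == resno &
                 a$segment == "protein")
  if (mode == "calpha") idx <- which(a$chain == chain & a$resno == resno &
                                       a$elety == "CA")
  mass_tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974, Cl = 35.45, Na = 22.990)
  w <- if (mode == "calpha") rep(1, length(idx)) else {
    m <- mass_tab[a$element[idx]]
    m[is.na(m)] <- 12.011
    m
  }
  out <- c(0, 0, 0)
  for (k in seq_along(idx)) out <- out + w[k] * frame$xyz[idx[k], ]
  out / sum(w)
}

oracle_crossed <- function(frame, topology, prime, mode) {
  res <- unname(topology$prime_map[as.character(prime)])
  ch <- topology$chain_ids
  pairs <- list(c(1, 3), c(2, 4), c(3, 5), c(4, 1), c(5, 2))
  vapply(pairs, function(p)
    dist3(oracle_residue_point(frame, ch[p[1]], res, mode),
          oracle_residue_point(frame, ch[p[2]], res, mode)),
    numeric(1))
}

# brute-force optimal-fit RMSD: optimize over rotations (Euler angles,
# multi-start), translation handled by centroid matching
oracle_fit_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(e) {
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cz <- cos(e[3]); sz <- sin(e[3])
    matrix(c(cy * cz, -cy * sz, sy,
             cx * sz + sx * sy * cz, cx * cz - sx * sy * sz, -sx * cy,
             sx * sz - cx * sy * cz, sx * cz + cx * sy * sz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(e) mean(rowSums((Pc %*% t(rot(e)) - Qc)^2))
  best <- Inf
  for (s in 1:8) {
    e0 <- runif(3, -pi, pi)
    o <- optim(e0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# point-in-cylinder membership test for water counting
oracle_water_count <- function(frame, origin, zaxis, z_lo, z_hi, radius) {
  a <- frame$atoms
  ox <- which(a$segment == "water" & a$element == "O")
  n <- 0L
  for (i in ox) {
    d <- frame$xyz[i, ] - origin
    zc <- sum(d * zaxis)
    r <- sqrt(sum((d - zc * zaxis)^2))
    if (zc >= z_lo && zc < z_hi && r <= radius) n <- n + 1L
  }
  n
}

oracle_ring_waters <- function(frame, topology, prime, cutoff) {
  a <- frame$atoms
  res <- unname(topology$prime_map[as.character(prime)])
  ring <- which(a$resno == res & a$chain %in% topology$chain_ids &
                  a$segment == "protein")
  wat <- which(a$segment == "water")
  hits <- character()
  for (i in wat) for (j in ring) {
    if (dist3(frame$xyz[i, ], frame$xyz[j, ]) <= cutoff) {
      hits <- c(hits, as.character(a$resno[i]))
      break
    }
  }
  length(unique(hits))
}

oracle_ion_hist <- function(traj, origin, zaxis, species, z_range,
                            bin_width, lateral) {
  resn <- if (species == "cation") c("SOD", "NA") else c("CLA", "CL")
  breaks <- seq(z_range[1], z_range[2], by = bin_width)
  if (breaks[length(breaks)] < z_range[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  cnt <- integer(length(breaks) - 1L)
  for (f in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, f)
    idx <- which(fr$atoms$resid %in% resn)
    for (i in idx) {
      d <- fr$xyz[i, ] - origin
      zc <- sum(d * zaxis)
      r <- sqrt(sum((d - zc * zaxis)^2))
      if (r > lateral || zc < z_range[1] || zc >= z_range[2]) next
      for (b in seq_len(length(breaks) - 1L))
        if (zc >= breaks[b] && zc < breaks[b + 1L]) {
          cnt[b] <- cnt[b] + 1L
          break
        }
    }
  }
  cnt
}

# exhaustive water-residue H-bond oracle reading the typing YAML itself
oracle_water_hbond_pairs <- function(frame, sel_water, sel_res, cutoff) {
  typ <- yaml::read_yaml(system.file("extdata", "hbond_types.yaml",
                                     package = "porescope"))
  a <- frame$atoms
  formed <- character()
  for (wr in unique(a$resno[sel_water])) {
    widx <- sel_water[a$resno[sel_water] == wr]
    w_h <- widx[a$element[widx] == "H"]
    w_o <- widx[a$element[widx] == "O"]
    rids <- unique(paste(a$chain[sel_res], a$resno[sel_res]))
    for (rid in rids) {
      parts <- strsplit(rid, " ")[[1]]
      ridx <- sel_res[a$chain[sel_res] == parts[1] &
                        a$resno[sel_res] == as.integer(parts[2])]
      rn <- a$resid[ridx[1]]
      t <- typ[[rn]]
      accs <- unique(c(unlist(t$acceptors), unlist(typ$BACKBONE$acceptors)))
      donH <- unlist(lapply(c(t$donors, typ$BACKBONE$donors),
                            function(d) d$hydrogens))
      best <- Inf
      for (i in w_h) for (j in ridx[a$elety[ridx] %in% accs])
        best <- min(best, dist3(frame$xyz[i, ], frame$xyz[j, ]))
      for (i in ridx[a$elety[ridx] %in% donH]) for (j in w_o)
        best <- min(best, dist3(frame$xyz[i, ], frame$xyz[j, ]))
      if (best < cutoff)
        formed <- c(formed, paste0("W", wr, ":", parts[1], parts[2]))
    }
  }
  sort(formed)
}
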