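#' Axial pore region
#'
#' A named axial slab in axis coordinates, laterally bounded by a
#' cylinder around the pore axis.  The two canonical regions are the full
#' pore lumen lined by the M2 helices (30 Angstrom, -2' ring to 20' ring)
#' and the 10 Angstrom hydrophobic-gate slab centered on the 13' ring.
#' The axial interval is half-open: `z_lo <= z < z_hi`.
#'
#' @param name region label.
#' @param z_lo,z_hi axial bounds (Angstrom, axis coordinates).
#' @param radius lateral cylinder radius (Angstrom, default 8).
#' @return An object of class `pore_region`.
#' @export
pore_region <- function(name, z_lo, z_hi, radius = 8) {
  if (z_lo >= z_hi) stop("z_lo must be below z_hi")
  if (radius <= 0) stop("radius must be positive")
  structure(list(name = name, z_lo = z_lo, z_hi = z_hi, radius = radius),
            class = "pore_region")
}

#' Gate and full-pore regions anchored to prime rings
#'
#' Convenience constructors in the axis coordinates of `axisframe`:
#' `gate_region()` is a slab of length `width` centered on the
#' `prime_index` ring's C-alpha center (default the 13' constriction,
#' 10 Angstrom); `pore_lumen_region()` spans the -2' to 20' ring centers.
#'
#' @param frame a [structure_frame()].
#' @param axisframe a [symmetry_axis()] result.
#' @param topology a [channel_topology()].
#' @param prime_index anchor ring (default 13).
#' @param width slab length (default 10).
#' @param radius lateral radius (default 8).
#' @return A [pore_region()].
#' @export
gate_region <- function(frame, axisframe, topology, prime_index = 13,
                        width = 10, radius = 8) {
  zc <- ring_axial_center(frame, axisframe, topology, prime_index)
  pore_region(sprintf("gate_%dprime", prime_index),
              zc - width / 2, zc + width / 2, radius)
}

#' @rdname gate_region
#' @export
pore_lumen_region <- function(frame, axisframe, topology, radius = 8) {
  primes <- as.integer(names(topology$prime_map))
  z1 <- ring_axial_center(frame, axisframe, topology, min(primes))
  z2 <- ring_axial_center(frame, axisframe, topology, max(primes))
  pore_region("pore_lumen", min(z1, z2), max(z1, z2), radius)
}

ring_axial_center <- function(frame, axisframe, topology, prime_index) {
  res <- prime_residue(topology, prime_index)
  idx <- select_atoms(frame, chain = topology$chain_ids, resno = res,
                      elety = "CA")
  mean(axis_coordinates(frame$xyz[idx, , drop = FALSE], axisframe)$z)
}

water_oxygen_idx <- function(frame) {
  intersect(select_atoms(frame, segment = "water"),
            which(frame$atoms$element == "O"))
}

#' Count waters in a pore region
#'
#' A water is counted when its oxygen lies inside the region's axial slab
#' (half-open) and within the lateral cylinder radius of the axis.
#'
#' @param frame a [structure_frame()].
#' @param axisframe a [symmetry_axis()] result.
#' @param region a [pore_region()].
#' @return Integer count.
#' @export
water_count <- function(frame, axisframe, region) {
  ox <- water_oxygen_idx(frame)
  if (!length(ox)) return(0L)
  ac <- axis_coordinates(frame$xyz[ox, , drop = FALSE], axisframe)
  sum(ac$z >= region$z_lo & ac$z < region$z_hi & ac$r <= region$radius)
}

#' Water-count time series over a trajectory
#'
#' @param traj a [channel_trajectory()].
#' @param axisframe fixed [symmetry_axis()] frame, or `NULL` to recompute
#'   per frame from `topology`.
#' @param region a [pore_region()].
#' @param topology needed when `axisframe` is `NULL`.
#' @return A [descriptor_series()] of counts.
#' @export
water_count_series <- function(traj, axisframe, region, topology = NULL) {
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    af <- if (is.null(axisframe)) symmetry_axis(fr, topology) else axisframe
    as.numeric(water_count(fr, af, region))
  }, numeric(1))
  descriptor_series(vals, traj$times, paste0("waters_", region$name),
                    "count")
}

#' Waters within a cutoff of a prime ring
#'
#' Number of distinct water molecules having any atom within `cutoff` of
#' any atom of the five ring residues at `prime_index` (3 Angstrom is the
#' conventional shell for the Ser/Thr hydrophilic rings).
#'
#' @param frame a [structure_frame()].
#' @param topology a [channel_topology()].
#' @param prime_index ring prime index.
#' @param cutoff shell distance (Angstrom, default 3).
#' @return Integer count of waters (each counted once).
#' @export
ring_proximity_water_count <- function(frame, topology, prime_index,
                                       cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  res <- prime_residue(topology, prime_index)
  ring <- select_atoms(frame, chain = topology$chain_ids, resno = res,
                       segment = "protein")
  if (!length(ring))
    stop("ring at prime ", prime_index, " unresolvable")
  wat <- select_atoms(frame, segment = "water")
  if (!length(wat)) return(0L)
  near <- atoms_within(frame$xyz[wat, , drop = FALSE],
                       frame$xyz[ring, , drop = FALSE], cutoff)
  length(unique(frame$atoms$resno[wat[near]]))
}

# indices (into query rows) of query atoms within cutoff of any target atom
atoms_within <- function(query, target, cutoff) {
  c2 <- cutoff^2
  qt <- rowSums(query^2)
  tt <- rowSums(target^2)
  d2 <- outer(qt, tt, "+") - 2 * tcrossprod(query, target)
  which(apply(d2 <= c2 + 1e-12, 1, any))
}

# ---------------------------------------------------------------------------
# hydrogen bonds

hbond_typing_env <- new.env(parent = emptyenv())

#' Donor/acceptor typing table
#'
#' Residue-template table of hydrogen-bond donors (heavy atom plus its
#' hydrogens) and acceptors, loaded from the editable YAML shipped in
#' `inst/extdata/hbond_types.yaml` (or a user file).
#'
#' @param path optional path to a custom YAML table.
#' @return Named list per residue name: `donors` (list of
#'   `list(atom, hydrogens)`) and `acceptors` (character).
#' @export
hbond_typing <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(hbond_typing_env$default)) return(hbond_typing_env$default)
    path <- system.file("extdata", "hbond_types.yaml", package = "porescope")
    tab <- yaml::read_yaml(path)
    hbond_typing_env$default <- tab
    return(tab)
  }
  yaml::read_yaml(path)
}

typed_for <- function(typing, resid) {
  t <- typing[[resid]]
  if (is.null(t)) t <- typing[["BACKBONE"]]
  else {
    bb <- typing[["BACKBONE"]]
    t$donors <- c(t$donors, bb$donors)
    t$acceptors <- unique(c(unlist(t$acceptors), unlist(bb$acceptors)))
  }
  t
}

residue_keys <- function(atoms, idx) {
  paste(atoms$chain[idx], atoms$resno[idx], atoms$resid[idx], sep = "|")
}

#' Detect hydrogen bonds in one frame
#'
#' Two purely distance-based criteria (no angular term):
#' * `mode = "water_residue"`: a water-residue bond is formed when the
#'   minimum over all donor-hydrogen / acceptor-heavy-atom combinations
#'   (in either direction) is below `cutoff` (default 2.0 Angstrom,
#'   a hydrogen-to-heavy-atom distance).
#' * `mode = "intra_protein"`: a bond is formed when a typed heavy donor
#'   and acceptor are closer than `cutoff` (default 3.0 Angstrom);
#'   same-residue pairs are excluded.
#'
#' @param frame a [structure_frame()].
#' @param mode `"water_residue"` or `"intra_protein"`.
#' @param sel_donors,sel_acceptors atom index selections delimiting the
#'   candidate residues.  For `water_residue`, `sel_donors` are water
#'   atoms and `sel_acceptors` protein-residue atoms.
#' @param cutoff distance criterion (Angstrom); defaults 2.0 / 3.0 by mode.
#' @param typing a [hbond_typing()] table.
#' @return Data.frame of formed pairs: partner identifiers (`chain`,
#'   `resno`, `resid` or atom-level ids), the realised minimum distance,
#'   and a `key` column naming the pair stably across frames.
#' @export
detect_hbonds <- function(frame, mode = c("water_residue", "intra_protein"),
                          sel_donors, sel_acceptors, cutoff = NULL,
                          typing = hbond_typing()) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "water_residue") 2.0 else 3.0
  if (mode == "water_residue")
    detect_hbonds_water(frame, sel_donors, sel_acceptors, cutoff, typing)
  else
    detect_hbonds_intra(frame, sel_donors, sel_acceptors, cutoff, typing)
}

detect_hbonds_water <- function(frame, sel_water, sel_res, cutoff, typing) {
  a <- frame$atoms
  wat_res <- unique(a$resno[sel_water])
  res_key <- unique(residue_keys(a, sel_res))
  out <- list()
  for (wr in wat_res) {
    widx <- sel_water[a$resno[sel_water] == wr]
    w_o <- widx[a$element[widx] == "O"]
    w_h <- widx[a$element[widx] == "H"]
    for (rk in res_key) {
      parts <- strsplit(rk, "|", fixed = TRUE)[[1]]
      ridx <- sel_res[a$chain[sel_res] == parts[1] &
                        a$resno[sel_res] == as.integer(parts[2])]
      t <- typed_for(typing, parts[3])
      if (is.null(t)) next
      acc <- ridx[a$elety[ridx] %in% unlist(t$acceptors)]
      dH <- ridx[a$elety[ridx] %in%
                   unlist(lapply(t$donors, `[[`, "hydrogens"))]
      dmin <- Inf
      if (length(w_h) && length(acc))
        dmin <- min(dmin, min_cross_dist(frame$xyz, w_h, acc))
      if (length(dH) && length(w_o))
        dmin <- min(dmin, min_cross_dist(frame$xyz, dH, w_o))
      if (dmin < cutoff)
        out[[length(out) + 1L]] <- data.frame(
          water_resno = wr, chain = parts[1],
          resno = as.integer(parts[2]), resid = parts[3],
          min_dist = dmin,
          key = paste0("W", wr, ":", parts[1], parts[2]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(water_resno = integer(), chain = character(),
                      resno = integer(), resid = character(),
                      min_dist = numeric(), key = character()))
  do.call(rbind, out)
}

min_cross_dist <- function(xyz, i, j) {
  q <- xyz[i, , drop = FALSE]; t <- xyz[j, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(t^2), "+") - 2 * tcrossprod(q, t)
  sqrt(max(0, min(d2)))
}

detect_hbonds_intra <- function(frame, sel_donors, sel_acceptors, cutoff,
                                typing) {
  a <- frame$atoms
  is_typed <- function(sel, what) {
    keep <- logical(length(sel))
    for (k in seq_along(sel)) {
      t <- typed_for(typing, a$resid[sel[k]])
      if (is.null(t)) next
      keep[k] <- if (what == "donor")
        a$elety[sel[k]] %in% unlist(lapply(t$donors, `[[`, "atom"))
      else a$elety[sel[k]] %in% unlist(t$acceptors)
    }
    sel[keep]
  }
  don <- is_typed(sel_donors, "donor")
  acc <- is_typed(sel_acceptors, "acceptor")
  if (!length(don) || !length(acc))
    stop("selection lacks typed donors or acceptors")
  q <- frame$xyz[don, , drop = FALSE]; t <- frame$xyz[acc, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(t^2), "+") - 2 * tcrossprod(q, t)
  d2[d2 < 0] <- 0
  hit <- which(sqrt(d2) < cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    same <- a$chain[don[hit[, 1]]] == a$chain[acc[hit[, 2]]] &
      a$resno[don[hit[, 1]]] == a$resno[acc[hit[, 2]]]
    hit <- hit[!same, , drop = FALSE]
  }
  if (!nrow(hit))
    return(data.frame(donor_idx = integer(), acceptor_idx = integer(),
                      donor = character(), acceptor = character(),
                      dist = numeric(), key = character()))
  di <- don[hit[, 1]]; ai <- acc[hit[, 2]]
  id <- function(i) paste0(a$chain[i], a$resno[i], ":", a$elety[i])
  data.frame(donor_idx = di, acceptor_idx = ai,
             donor = id(di), acceptor = id(ai),
             dist = sqrt(d2[hit]),
             key = paste(id(di), id(ai), sep = ">"),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond persistence along a trajectory
#'
#' Persistence of a candidate pair is the percentage of analysed frames
#' in which the bond is formed.  Bonds persistently formed (>60%) mark a
#' tense, collapsed-like interaction network; scarcely persistent bonds
#' (<5%) mark the relaxed open forms.
#'
#' @inheritParams detect_hbonds
#' @param traj a [channel_trajectory()].
#' @param min_persistence report only pairs at or above this percentage.
#' @return Data.frame: `key`, `n_formed`, `persistence` (0-100).
#' @export
hbond_persistence <- function(traj, mode = c("water_residue",
                                             "intra_protein"),
                              sel_donors, sel_acceptors, cutoff = NULL,
                              typing = hbond_typing(),
                              min_persistence = 0) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    hb <- detect_hbonds(fr, mode, sel_donors, sel_acceptors, cutoff, typing)
    for (k in unique(hb$key))
      assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L,
             counts)
  }
  keys <- ls(counts)
  n_formed <- vapply(keys, function(k) get(k, counts), integer(1))
  out <- data.frame(key = keys, n_formed = unname(n_formed),
                    persistence = 100 * unname(n_formed) / nf,
                    stringsAsFactors = FALSE)
  out <- out[out$persistence >= min_persistence, , drop = FALSE]
  out[order(-out$persistence, out$key), , drop = FALSE]
}

#' Detect dewetting / rewetting events in a water-count series
#'
#' Hysteresis threshold crossing: after the count has been above `high`
#' (wet regime), a run of at least `min_duration` frames below `low` is a
#' dewetting event; symmetrically, after a dry regime, a sustained run
#' above `high` is a rewetting event.
#'
#' @param series a scalar [descriptor_series()] of water counts.
#' @param low,high hysteresis thresholds (`high > low >= 0`); defaults
#'   10 / 30 waters.
#' @param min_duration minimum run length in frames (default 5).
#' @return Data.frame: `type` (`"dewetting"`/`"rewetting"`), `start`,
#'   `end` (frame indices), `t_start`, `t_end` (ns).
#' @export
detect_wetting_events <- function(series, low = 10, high = 30,
                                  min_duration = 5) {
  if (!(high > low && low >= 0)) stop("need high > low >= 0")
  x <- series$values[, 1]
  n <- length(x)
  state <- if (x[1] > high) "wet" else if (x[1] < low) "dry" else "mid"
  events <- list()
  i <- 1L
  while (i <= n) {
    if (state %in% c("wet", "mid") && x[i] < low) {
      j <- i
      while (j <= n && x[j] < low) j <- j + 1L
      if (j - i >= min_duration && state == "wet") {
        events[[length(events) + 1L]] <-
          data.frame(type = "dewetting", start = i, end = j - 1L)
        state <- "dry"
      } else if (j - i >= min_duration) state <- "dry"
      i <- j
    } else if (state %in% c("dry", "mid") && x[i] > high) {
      j <- i
      while (j <= n && x[j] > high) j <- j + 1L
      if (j - i >= min_duration && state == "dry") {
        events[[length(events) + 1L]] <-
          data.frame(type = "rewetting", start = i, end = j - 1L)
        state <- "wet"
      } else if (j - i >= min_duration) state <- "wet"
      i <- j
    } else {
      if (x[i] > high) state <- "wet" else if (x[i] < low) state <- "dry"
      i <- i + 1L
    }
  }
  if (!length(events))
    return(data.frame(type = character(), start = integer(),
                      end = integer(), t_start = numeric(),
                      t_end = numeric()))
  ev <- do.call(rbind, events)
  ev$t_start <- series$times[ev$start]
  ev$t_end <- series$times[ev$end]
  ev
}
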