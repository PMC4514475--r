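#' Run the full gate-state descriptor battery on one trajectory
#'
#' Computes, per frame: crossed distances at a set of prime rings, water
#' counts in the pore lumen and the hydrophobic-gate slab, tilt and
#' twist angles, dCintra and the LBD-TMD interface distances, plus one
#' pore-radius profile on the final frame.  Results are returned as a
#' list and, if `outdir` is given, written as CSV files re-parseable by
#' the package's own readers.
#'
#' @param traj a [channel_trajectory()].
#' @param topology a [channel_topology()].
#' @param crossed_primes prime rings to monitor (default the restrained
#'   and flanking rings 16', 13', 9', 20', -2').
#' @param selection_mode crossed-distance selection (see
#'   [crossed_distances()]).
#' @param lbd_span,tmd_span twist domain spans (residue numbers).
#' @param gate_radius,lumen_radius lateral bounds of the water-count
#'   cylinders (Angstrom).
#' @param outdir optional output directory for CSVs.
#' @param label prefix for output file names.
#' @return List of descriptor results (see details in the vignette).
#' @export
analyze_trajectory <- function(traj, topology,
                               crossed_primes = c(16L, 13L, 9L, 20L, -2L),
                               selection_mode = "residue_com",
                               lbd_span = c(30L, 200L),
                               tmd_span = NULL,
                               gate_radius = 8, lumen_radius = 8,
                               outdir = NULL, label = traj$origin) {
  if (is.null(tmd_span))
    tmd_span <- c(topology$m2_range[1],
                  if (!is.null(topology$loops$M2_M3))
                    topology$loops$M2_M3[2] else topology$m2_range[2])
  nf <- n_frames(traj)
  crossed <- lapply(crossed_primes, function(p)
    matrix(NA_real_, nf, 5L))
  names(crossed) <- as.character(crossed_primes)
  w_pore <- numeric(nf); w_gate <- numeric(nf)
  tilt_polar <- matrix(NA_real_, nf, 5L)
  tilt_azim <- matrix(NA_real_, nf, 5L)
  twist <- numeric(nf)
  dc <- matrix(NA_real_, nf, 5L)
  ifd <- array(NA_real_, c(nf, 5L, 2L))
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    af <- symmetry_axis(fr, topology)
    for (p in as.character(crossed_primes))
      crossed[[p]][i, ] <- crossed_distances(fr, topology, as.integer(p),
                                             selection_mode)
    w_pore[i] <- water_count(fr, af,
                             pore_lumen_region(fr, af, topology,
                                               lumen_radius))
    w_gate[i] <- water_count(fr, af,
                             gate_region(fr, af, topology,
                                         radius = gate_radius))
    ta <- tilt_angles(fr, af, topology)
    tilt_polar[i, ] <- ta$polar
    tilt_azim[i, ] <- ta$azimuthal
    twist[i] <- twist_angle(fr, af, topology, lbd_span, tmd_span)$mean
    dc[i, ] <- dCintra(fr, topology)
    idf <- interface_distances(fr, topology)
    ifd[i, , 1] <- idf$d_pro_cysloop
    ifd[i, , 2] <- idf$d_pro_lys
  }
  last <- get_frame(traj, nf)
  af_last <- symmetry_axis(last, topology)
  lumen <- pore_lumen_region(last, af_last, topology, lumen_radius)
  profile <- pore_radius_profile(last, af_last,
                                 c(lumen$z_lo, lumen$z_hi))
  pairnames <- rownames(nonadjacent_pairs(topology))
  out <- list(
    crossed = lapply(crossed, function(m) {
      colnames(m) <- pairnames
      descriptor_series(m, traj$times, "crossed_distance", "Angstrom")
    }),
    water_pore = descriptor_series(w_pore, traj$times, "waters_pore_lumen",
                                   "count"),
    water_gate = descriptor_series(w_gate, traj$times, "waters_gate",
                                   "count"),
    tilt_polar = descriptor_series(`colnames<-`(tilt_polar,
                                                topology$chain_ids),
                                   traj$times, "polar_tilt", "degrees"),
    tilt_azimuthal = descriptor_series(`colnames<-`(tilt_azim,
                                                    topology$chain_ids),
                                       traj$times, "azimuthal_tilt",
                                       "degrees"),
    twist = descriptor_series(twist, traj$times, "quaternary_twist",
                              "degrees"),
    dcintra = descriptor_series(`colnames<-`(dc, topology$chain_ids),
                                traj$times, "dCintra", "Angstrom"),
    d_pro_cysloop = descriptor_series(
      `colnames<-`(ifd[, , 1, drop = TRUE], topology$chain_ids),
      traj$times, "d_Pro_CysLoop", "Angstrom"),
    d_pro_lys = descriptor_series(
      `colnames<-`(ifd[, , 2, drop = TRUE], topology$chain_ids),
      traj$times, "d_Pro_Lys", "Angstrom"),
    pore_profile = profile)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (p in names(out$crossed))
      write_series(out$crossed[[p]],
                   file.path(outdir, paste0(label, "_crossed_", p, ".csv")))
    for (nm in c("water_pore", "water_gate", "tilt_polar",
                 "tilt_azimuthal", "twist", "dcintra"))
      write_series(out[[nm]], file.path(outdir,
                                        paste0(label, "_", nm, ".csv")))
    write.csv(as.data.frame(profile),
              file.path(outdir, paste0(label, "_pore_profile.csv")),
              row.names = FALSE)
  }
  out
}

series_mean_sd <- function(s) {
  v <- as.vector(s$values)   # pool subunits/pairs and frames
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Summary table of a descriptor battery
#'
#' Means and standard deviations pooled over subunits (or pairs) and
#' frames, one row per descriptor — the convention used for
#' ligand-monitor tables.
#'
#' @param results output of [analyze_trajectory()].
#' @return Data.frame: `descriptor`, `units`, `mean`, `sd`.
#' @export
summarize_report <- function(results) {
  rows <- list()
  push <- function(name, s) {
    ms <- series_mean_sd(s)
    rows[[length(rows) + 1L]] <<- data.frame(
      descriptor = name, units = s$units, mean = ms["mean"], sd = ms["sd"])
  }
  for (p in names(results$crossed))
    push(paste0("crossed_", p, "prime"), results$crossed[[p]])
  push("waters_pore_lumen", results$water_pore)
  push("waters_gate", results$water_gate)
  push("polar_tilt", results$tilt_polar)
  push("azimuthal_tilt", results$tilt_azimuthal)
  push("quaternary_twist", results$twist)
  push("dCintra", results$dcintra)
  push("d_Pro_CysLoop", results$d_pro_cysloop)
  push("d_Pro_Lys", results$d_pro_lys)
  gate <- results$pore_profile
  mid <- gate[!gate$flagged & gate$z > 0, , drop = FALSE]
  rows[[length(rows) + 1L]] <- data.frame(
    descriptor = "min_pore_radius_upper", units = "Angstrom",
    mean = if (nrow(mid)) min(mid$radius) else NA_real_, sd = 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end open vs collapsed comparison report
#'
#' Runs the descriptor battery on two trajectories (typically the
#' generator's open and collapsed presets), writes per-descriptor CSVs
#' and one side-by-side summary table, and returns both result sets.
#' The comparison reproduces the discrimination logic for gate state:
#' an open channel shows larger gate pore radius, larger gate water
#' count and larger crossed distances than a collapsed one.
#'
#' @param traj_open,traj_collapsed [channel_trajectory()]s.
#' @param topology a [channel_topology()].
#' @param outdir output directory (created if needed), or `NULL`.
#' @param ... passed to [analyze_trajectory()].
#' @return List: `open`, `collapsed` (battery results), `summary`
#'   (side-by-side data.frame).
#' @export
run_report <- function(traj_open, traj_collapsed, topology, outdir = NULL,
                       ...) {
  ro <- analyze_trajectory(traj_open, topology, outdir = outdir,
                           label = "open", ...)
  rc <- analyze_trajectory(traj_collapsed, topology, outdir = outdir,
                           label = "collapsed", ...)
  so <- summarize_report(ro)
  sc <- summarize_report(rc)
  summary <- data.frame(descriptor = so$descriptor, units = so$units,
                        open_mean = so$mean, open_sd = so$sd,
                        collapsed_mean = sc$mean, collapsed_sd = sc$sd)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(outdir, "summary_open_vs_collapsed.csv"),
              row.names = FALSE)
  }
  list(open = ro, collapsed = rc, summary = summary)
}

#' Gate pore radius (minimum over the gate slab)
#'
#' Minimum pore radius over the stations inside the hydrophobic-gate
#' region of a profile.
#'
#' @param profile a [pore_radius_profile()] result.
#' @param gate a [pore_region()] delimiting the gate slab.
#' @return Numeric radius (Angstrom).
#' @export
gate_min_radius <- function(profile, gate) {
  sel <- profile$z >= gate$z_lo & profile$z < gate$z_hi & !profile$flagged
  if (!any(sel)) return(NA_real_)
  min(profile$radius[sel])
}
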