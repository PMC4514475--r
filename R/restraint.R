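#' Flat-bottom crossed-distance restraint specification
#'
#' The pore-opening restraint: for each non-adjacent subunit pair at the
#' hydrophobic gate rings (Leu16' and Val13' by default), the distance
#' between the residue centers of mass is penalised quadratically when it
#' falls below a threshold `d0`, and not at all above it — the restraint
#' discourages gate contraction without biasing an already-open pore.
#'
#' With the default `convention = "half_k"` the pair energy is
#' `U = k/2 (d - d0)^2` for `d < d0`, so the restoring force magnitude at
#' a 1 Angstrom violation is exactly `k`; `convention = "full_k"` uses
#' `U = k (d - d0)^2`.
#'
#' @param topology a [channel_topology()].
#' @param prime_indices rings to restrain (default `c(16, 13)`).
#' @param k force constant, kcal/mol/Angstrom^2 (default 10).
#' @param selection_mode `"residue_com"` or `"calpha"` (see
#'   [crossed_distances()]).
#' @param d0 optional numeric vector of thresholds (one per pair, in ring
#'   x pair order); usually left `NA` and filled by
#'   [calibrate_thresholds()] from a reference structure.
#' @param convention `"half_k"` or `"full_k"`.
#' @return An object of class `restraint_spec` with a `pairs` data.frame
#'   (`prime`, `chain_a`, `chain_b`, `pair`, `d0`).
#' @export
restraint_spec <- function(topology, prime_indices = c(16L, 13L), k = 10,
                           selection_mode = c("residue_com", "calpha"),
                           d0 = NA_real_,
                           convention = c("half_k", "full_k")) {
  selection_mode <- match.arg(selection_mode)
  convention <- match.arg(convention)
  if (k < 0) stop("force constant must be non-negative")
  pr <- nonadjacent_pairs(topology)
  pairs <- do.call(rbind, lapply(prime_indices, function(p)
    data.frame(prime = p, chain_a = pr[, 1], chain_b = pr[, 2],
               pair = paste0(rownames(pr), "@", p, "'"),
               stringsAsFactors = FALSE)))
  rownames(pairs) <- NULL
  pairs$d0 <- rep_len(d0, nrow(pairs))
  if (any(!is.na(pairs$d0) & pairs$d0 <= 0))
    stop("thresholds d0 must be positive")
  structure(list(pairs = pairs, k = k, selection_mode = selection_mode,
                 convention = convention, topology = topology),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat("restraint_spec:", nrow(x$pairs), "pairs, k =", x$k,
      "kcal/mol/A^2,", x$convention, "convention,",
      if (anyNA(x$pairs$d0)) "uncalibrated" else "calibrated", "\n")
  invisible(x)
}

#' Calibrate restraint thresholds on a reference structure
#'
#' Sets each pair's threshold `d0` to its distance in the reference
#' frame, so the restraint is exactly flat (zero energy, no active pairs)
#' on that structure and switches on only when the gate contracts below
#' its reference geometry.
#'
#' @param reference a [structure_frame()] (the initial open structure).
#' @param spec a [restraint_spec()] template.
#' @return The spec with `d0` filled.
#' @export
calibrate_thresholds <- function(reference, spec) {
  spec$pairs$d0 <- pair_distances(reference, spec)
  spec
}

pair_distances <- function(frame, spec) {
  topo <- spec$topology
  vapply(seq_len(nrow(spec$pairs)), function(i) {
    p <- spec$pairs[i, ]
    res <- prime_residue(topo, p$prime)
    pts <- ring_points(frame, topo, res, spec$selection_mode)
    sqrt(sum((pts[p$chain_a, ] - pts[p$chain_b, ])^2))
  }, numeric(1))
}

pair_prefactor <- function(spec) if (spec$convention == "half_k") 0.5 else 1

#' Flat-bottom restraint energy
#'
#' @param frame a [structure_frame()].
#' @param spec a calibrated [restraint_spec()].
#' @return List: `energy` (total, kcal/mol), and `pairs` data.frame with
#'   per-pair `distance`, `d0`, `active` flag and `energy`.
#' @export
restraint_energy <- function(frame, spec) {
  if (anyNA(spec$pairs$d0)) stop("spec is uncalibrated (d0 missing)")
  d <- pair_distances(frame, spec)
  d0 <- spec$pairs$d0
  active <- d < d0
  u <- ifelse(active, pair_prefactor(spec) * spec$k * (d - d0)^2, 0)
  out <- spec$pairs
  out$distance <- d
  out$active <- active
  out$energy <- u
  list(energy = sum(u), pairs = out)
}

#' Analytic restraint forces
#'
#' Gradient of the flat-bottom energy distributed onto the atoms of each
#' center-of-mass group by mass fraction (the standard COM-restraint
#' chain rule).  Forces are zero for inactive pairs, sum to zero over
#' each pair, and exert no net force or torque on the system.
#'
#' @param frame a [structure_frame()].
#' @param spec a calibrated [restraint_spec()].
#' @return N x 3 matrix of forces (kcal/mol/Angstrom) over all frame
#'   atoms; attribute `energy` carries the total energy.
#' @export
restraint_forces <- function(frame, spec) {
  if (anyNA(spec$pairs$d0)) stop("spec is uncalibrated (d0 missing)")
  topo <- spec$topology
  F <- matrix(0, nrow(frame$xyz), 3L)
  pref <- pair_prefactor(spec)
  total_u <- 0
  for (i in seq_len(nrow(spec$pairs))) {
    p <- spec$pairs[i, ]
    res <- prime_residue(topo, p$prime)
    group <- function(ch) {
      if (spec$selection_mode == "calpha")
        select_atoms(frame, chain = ch, resno = res, elety = "CA")
      else
        select_atoms(frame, chain = ch, resno = res, segment = "protein")
    }
    ga <- group(p$chain_a); gb <- group(p$chain_b)
    if (!length(ga) || !length(gb))
      stop("restraint pair ", p$pair, " unresolvable")
    wa <- atom_masses(frame, ga); wa <- wa / sum(wa)
    wb <- atom_masses(frame, gb); wb <- wb / sum(wb)
    if (spec$selection_mode == "calpha") {
      wa <- rep(1 / length(ga), length(ga))
      wb <- rep(1 / length(gb), length(gb))
    }
    ca <- drop(crossprod(frame$xyz[ga, , drop = FALSE], wa))
    cb <- drop(crossprod(frame$xyz[gb, , drop = FALSE], wb))
    dv <- ca - cb
    d <- sqrt(sum(dv^2))
    if (d < 1e-9) stop("coincident restraint group centers")
    if (d >= p$d0) next
    total_u <- total_u + pref * spec$k * (d - p$d0)^2
    # dU/dd with either convention equals 2*pref*k*(d - d0)
    dudd <- 2 * pref * spec$k * (d - p$d0)
    u_ab <- dv / d
    f_on_a <- -dudd * u_ab   # force = -dU/d(com_a)
    F[ga, ] <- F[ga, ] + outer(wa, f_on_a)
    F[gb, ] <- F[gb, ] - outer(wb, f_on_a)
  }
  attr(F, "energy") <- total_u
  F
}

#' Restraint activity along a trajectory
#'
#' Per-frame, per-pair distances, active flags and energies — the log a
#' restrained simulation would emit, and the basis for selecting frames
#' where the restraint was not active (candidates for seeding free
#' simulations of the open state).
#'
#' @param traj a [channel_trajectory()].
#' @param spec a calibrated [restraint_spec()].
#' @return Data.frame: `frame`, `time_ns`, `pair`, `prime`, `distance`,
#'   `d0`, `active`, `energy`.
#' @export
restraint_activity_series <- function(traj, spec) {
  out <- lapply(seq_len(n_frames(traj)), function(i) {
    re <- restraint_energy(get_frame(traj, i), spec)
    data.frame(frame = i, time_ns = traj$times[i],
               pair = re$pairs$pair, prime = re$pairs$prime,
               distance = re$pairs$distance, d0 = re$pairs$d0,
               active = re$pairs$active, energy = re$pairs$energy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frames on which the restraint was inactive
#'
#' @param activity output of [restraint_activity_series()].
#' @return Integer frame indices where no pair was active.
#' @export
inactive_frames <- function(activity) {
  act <- tapply(activity$active, activity$frame, any)
  as.integer(names(act)[!act])
}

#' Read / write a restraint spec as YAML
#' @param spec a [restraint_spec()].
#' @param path file path.
#' @param topology a [channel_topology()] (the spec YAML stores only the
#'   restraint parameters, not the topology).
#' @return `read_restraint()` returns a `restraint_spec`.
#' @export
write_restraint <- function(spec, path) {
  yaml::write_yaml(list(
    prime_indices = unique(spec$pairs$prime),
    k = spec$k, selection_mode = spec$selection_mode,
    convention = spec$convention,
    d0 = as.list(setNames(spec$pairs$d0, spec$pairs$pair))), path,
    precision = 15L)
  invisible(path)
}

#' @rdname write_restraint
#' @export
read_restraint <- function(path, topology) {
  y <- yaml::read_yaml(path)
  spec <- restraint_spec(topology, prime_indices = unlist(y$prime_indices),
                         k = y$k, selection_mode = y$selection_mode,
                         convention = y$convention)
  d0 <- unlist(y$d0)
  spec$pairs$d0 <- unname(d0[spec$pairs$pair])
  spec
}
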