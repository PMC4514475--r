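#' Trajectory of structure frames
#'
#' A `channel_trajectory` stores an ordered set of frames sharing one atom
#' table: coordinates as an `n_frames x (3 N)` matrix (bio3d xyz layout),
#' strictly increasing time stamps in ns, and an origin label (e.g.
#' `"restrained"`, `"Free_4"`, `"synthetic"`).
#'
#' @param atoms atom table as in [structure_frame()].
#' @param xyz `n_frames x (3 N)` coordinate matrix.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param origin character label.
#' @param topology optional `channel_topology` for segment labelling.
#' @return An object of class `channel_trajectory`.
#' @export
channel_trajectory <- function(atoms, xyz, times = NULL, origin = "unknown",
                               topology = NULL) {
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("xyz must have 3 columns per atom (constant atom count)")
  nf <- nrow(xyz)
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  if (is.null(atoms$segment)) atoms$segment <- segment_atoms(atoms, topology)
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times),
                 origin = origin),
            class = "channel_trajectory")
}

#' @export
print.channel_trajectory <- function(x, ...) {
  cat("channel_trajectory:", n_frames(x), "frames x", nrow(x$atoms),
      "atoms, t =", x$times[1], "..", x$times[n_frames(x)], "ns,",
      "origin:", x$origin, "\n")
  invisible(x)
}

#' @rdname channel_trajectory
#' @param traj a `channel_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#' @rdname channel_trajectory
#' @param i frame index.
#' @export
frame_xyz <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Extract one frame as a structure_frame
#' @rdname channel_trajectory
#' @export
get_frame <- function(traj, i) {
  fr <- structure(list(atoms = traj$atoms, xyz = frame_xyz(traj, i),
                       time = traj$times[i]),
                  class = "structure_frame")
  fr
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' DCD files are read with `bio3d::read.dcd()`; anything else is treated
#' as a multi-model PDB.  Atom metadata come from `structure`, whose atom
#' count must match the trajectory frames.
#'
#' @param structure a [structure_frame()] supplying the atom table, or
#'   `NULL` for a multi-model PDB, whose own atom records are then used.
#' @param path trajectory file path.
#' @param stride keep every `stride`-th frame (starting at the first), so
#'   an N-frame file yields `ceiling(N / stride)` frames.
#' @param dt frame interval in ns (used when the file stores no times).
#' @param origin label for the trajectory.
#' @param topology optional [channel_topology()] for segment labelling
#'   when `structure` is `NULL`.
#' @return A [channel_trajectory()].
#' @export
read_trajectory <- function(structure, path, stride = 1L, dt = 0.1,
                            origin = basename(path), topology = NULL) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be a positive integer")
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(structure))
      stop("a structure is required to read a DCD trajectory")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (is.null(structure)) {
      atoms <- data.frame(
        eleno = pdb$atom$eleno, elety = pdb$atom$elety,
        resid = pdb$atom$resid,
        chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
        resno = pdb$atom$resno, stringsAsFactors = FALSE)
      structure <- structure_frame(atoms, matrix(xyz[1, ], ncol = 3,
                                                 byrow = TRUE),
                                   topology = topology)
    }
  }
  n_atoms <- nrow(structure$atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("atom count mismatch: trajectory has ", ncol(xyz) / 3,
         " atoms, structure has ", n_atoms)
  keep <- seq(1L, nrow(xyz), by = stride)
  channel_trajectory(structure$atoms, xyz[keep, , drop = FALSE],
                     times = (keep - 1L) * dt, origin = origin)
}

#' Per-frame descriptor time series
#'
#' A labelled, unit-carrying time series with one scalar or one
#' fixed-width vector of values per analysed frame (e.g. one value per
#' subunit, or per crossed pair).
#'
#' @param values numeric vector (scalar series) or matrix with one row per
#'   frame (vector series); column names label subunits/pairs.
#' @param times frame time stamps (ns).
#' @param label descriptor name.
#' @param units unit string (e.g. `"Angstrom"`, `"degrees"`, `"count"`).
#' @return An object of class `descriptor_series`.
#' @export
descriptor_series <- function(values, times, label, units) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("one value row per frame required")
  structure(list(values = values, times = as.numeric(times),
                 label = label, units = units),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("descriptor_series:", x$label, "[", x$units, "]",
      nrow(x$values), "frames x", ncol(x$values), "column(s)\n")
  invisible(x)
}

#' Write / read a descriptor series as CSV
#'
#' One row per frame, a `time_ns` column, one column per series component,
#' and the label/units kept in comment header lines so the file
#' round-trips bit-exactly through [read_series()].
#'
#' @param series a [descriptor_series()].
#' @param path output CSV path.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `descriptor_series`.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "descriptor_series") || nrow(series$values) == 0L)
    stop("series must be a non-empty descriptor_series")
  cols <- colnames(series$values)
  if (is.null(cols)) cols <- paste0("v", seq_len(ncol(series$values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", series$label),
               paste0("# units: ", series$units)), con)
  df <- data.frame(time_ns = format_full(series$times))
  for (k in seq_along(cols)) df[[cols[k]]] <- format_full(series$values[, k])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal representation so CSV round-trips are bit-exact
format_full <- function(x) formatC(x, format = "g", digits = 17)

#' @rdname write_series
#' @export
read_series <- function(path) {
  hdr <- readLines(path, n = 2L)
  lab <- sub("^# label: ", "", hdr[1])
  uni <- sub("^# units: ", "", hdr[2])
  df <- read.csv(path, comment.char = "#")
  vals <- as.matrix(df[, -1, drop = FALSE])
  descriptor_series(vals, df$time_ns, lab, uni)
}
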