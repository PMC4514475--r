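# Residue-name dialects for solvent and ions (naming varies by force field).
.WATER_RESNAMES <- c("HOH", "TIP3", "WAT", "SOL")
.CATION_RESNAMES <- c("SOD", "NA")
.ANION_RESNAMES <- c("CLA", "CL")

#' Atom-level structure frame
#'
#' A `structure_frame` holds one time point of a channel system as an atom
#' table (serial, atom name, residue name/number, chain, element, segment)
#' plus an N x 3 coordinate matrix in Angstrom.  Atoms are segmented into
#' `"protein"`, `"water"`, `"ion"`, `"ligand"` and `"other"` from their
#' residue names so descriptor code can select them uniformly.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno` and optionally `element`, `segment`.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param time optional time stamp in ns.
#' @param topology optional `channel_topology` used to label the ligand
#'   segment; waters and ions are recognised by residue name regardless.
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, xyz, time = NA_real_, topology = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be an N x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  need <- c("eleno", "elety", "resid", "chain", "resno")
  if (!all(need %in% names(atoms)))
    stop("atom table needs columns: ", paste(need, collapse = ", "))
  atoms$eleno <- as.integer(atoms$eleno)
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain <- as.character(atoms$chain)
  atoms$elety <- as.character(atoms$elety)
  atoms$resid <- as.character(atoms$resid)
  if (anyDuplicated(atoms$eleno))
    stop("duplicate atom serial numbers")
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$elety)
  if (is.null(atoms$segment))
    atoms$segment <- segment_atoms(atoms, topology)
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, time = time),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  tab <- table(x$atoms$segment)
  cat("structure_frame:", nrow(x$atoms), "atoms (",
      paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
  invisible(x)
}

# Element from a PDB atom name: strip digits/primes, take leading letter(s);
# two-letter names only for known dialects (CL, NA, CLA, SOD handled above).
guess_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(e, 1, 1))
  two <- toupper(substr(e, 1, 2))
  out <- first
  out[two == "CL" & nchar(e) == 2] <- "Cl"
  out[two == "NA" & nchar(e) == 2] <- "Na"
  out
}

segment_atoms <- function(atoms, topology = NULL) {
  seg <- rep("protein", nrow(atoms))
  seg[atoms$resid %in% .WATER_RESNAMES] <- "water"
  seg[atoms$resid %in% c(.CATION_RESNAMES, .ANION_RESNAMES)] <- "ion"
  lig <- if (!is.null(topology)) topology$ligand_resname else "EPI"
  seg[atoms$resid %in% lig] <- "ligand"
  seg
}

#' Select atom indices of a frame
#'
#' Conjunctive filter over the atom table; `NULL` criteria are ignored.
#'
#' @param frame a `structure_frame`.
#' @param chain,resno,elety,resid,segment vectors of admissible values.
#' @return Integer vector of row indices into the atom table.
#' @export
select_atoms <- function(frame, chain = NULL, resno = NULL, elety = NULL,
                         resid = NULL, segment = NULL) {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(segment)) keep <- keep & a$segment %in% segment
  which(keep)
}

#' Read a channel structure from PDB
#'
#' Wraps `bio3d::read.pdb()` and validates the result against a
#' [channel_topology()]: every topology chain must be present and the M2
#' span resolvable on each, so prime-indexed selections cannot silently
#' come back empty downstream.
#'
#' @param path PDB file path.
#' @param topology a `channel_topology`.
#' @return A [structure_frame()].
#' @export
read_structure <- function(path, topology) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- data.frame(
    eleno = pdb$atom$eleno, elety = pdb$atom$elety, resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
    resno = pdb$atom$resno, stringsAsFactors = FALSE)
  xyz <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  if (anyDuplicated(atoms$eleno))
    stop("duplicate atom serial numbers in ", path)
  missing <- setdiff(topology$chain_ids, unique(atoms$chain))
  if (length(missing))
    stop("topology mismatch: chain(s) ", paste(missing, collapse = ","),
         " absent from ", path)
  fr <- structure_frame(atoms, xyz, topology = topology)
  m2 <- topology$prime_map
  for (ch in topology$chain_ids) {
    have <- unique(atoms$resno[atoms$chain == ch])
    if (!all(m2 %in% have))
      stop("topology mismatch: chain ", ch, " lacks residues ",
           paste(setdiff(m2, have), collapse = ","))
  }
  fr
}

#' Write a structure (or trajectory) as PDB text
#'
#' Fixed-width PDB ATOM records; a [channel_trajectory()] is written as a
#' multi-model PDB (`MODEL`/`ENDMDL` per frame).  Coordinates are kept to
#' the format's 3-decimal precision, so write-then-read round-trips to
#' 1e-3 Angstrom.
#'
#' @param x a `structure_frame` or `channel_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "channel_trajectory")) return(write_trajectory(x, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_atom_records(x$atoms, x$xyz), con)
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_structure
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "channel_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_atom_records(x$atoms, frame_xyz(x, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_records <- function(atoms, xyz) {
  elety <- atoms$elety
  # PDB column convention: 1-3 character names start in column 14
  name_fmt <- ifelse(nchar(elety) < 4, sprintf(" %-3s", elety),
                     sprintf("%-4s", elety))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$eleno %% 100000L, name_fmt, substr(atoms$resid, 1, 3),
          substr(atoms$chain, 1, 1), atoms$resno %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(atoms$element))
}
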