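#' Channel topology: chains, prime-index residue map, loops, key residues
#'
#' A `channel_topology` is the single place where a pentameric channel's
#' residue bookkeeping lives: the five subunit chain identifiers, the map
#' from prime indices (the conserved M2 numbering, -2' at the intracellular
#' end through 20' at the extracellular end) to author residue numbers, the
#' M2 helix span, named loop spans, the agonist residue name, and named
#' single key residues.
#'
#' Prime indices follow the Cys-loop receptor convention: positions along
#' the pore-lining M2 helix counted from a conserved intracellular
#' reference, so that 9', 13' and 16' label the hydrophobic gate rings in
#' any family member.
#'
#' @param chain_ids character vector of exactly 5 chain identifiers,
#'   ordered around the pentamer (subunits P1..P5).
#' @param prime_map named integer vector mapping prime index (as character
#'   names, e.g. `"-2"`, `"13"`) to residue number; must be strictly
#'   increasing in residue number. The same numbering is assumed on all
#'   five chains.
#' @param m2_range integer length-2, first and last residue of the M2 helix.
#' @param loops named list of integer length-2 residue spans (closed
#'   intervals), e.g. `C_loop`, `Cys_loop`, `beta1_beta2`, `M2_M3`,
#'   `backwall`.
#' @param ligand_resname residue name of the bound agonist (e.g. `"EPI"`).
#' @param key_residues named integer vector of single residues
#'   (e.g. `c(Pro256 = 256, Lys40 = 40)`).
#' @return An object of class `channel_topology`.
#' @examples
#' topo <- alpha7_topology()
#' prime_residue(topo, 13)   # Val246, the 13' constriction
#' @export
channel_topology <- function(chain_ids, prime_map, m2_range, loops,
                             ligand_resname = "EPI",
                             key_residues = integer()) {
  chain_ids <- as.character(chain_ids)
  if (length(chain_ids) != 5L || anyDuplicated(chain_ids))
    stop("a pentamer topology needs exactly 5 distinct chain ids")
  pm <- as.integer(prime_map)
  names(pm) <- names(prime_map)
  if (is.null(names(pm)) || anyNA(suppressWarnings(as.integer(names(pm)))))
    stop("prime_map must be named by integer prime indices")
  ord <- order(as.integer(names(pm)))
  pm <- pm[ord]
  if (any(diff(pm) <= 0L))
    stop("prime_map must be strictly increasing in residue number")
  m2_range <- as.integer(m2_range)
  if (length(m2_range) != 2L || m2_range[1] > m2_range[2])
    stop("m2_range must be an increasing length-2 integer span")
  loops <- lapply(loops, function(sp) {
    sp <- as.integer(sp)
    if (length(sp) != 2L || sp[1] > sp[2]) stop("loop spans are closed, increasing intervals")
    sp
  })
  structure(
    list(chain_ids = chain_ids, prime_map = pm, m2_range = m2_range,
         loops = loops, ligand_resname = ligand_resname,
         key_residues = key_residues),
    class = "channel_topology")
}

#' @export
print.channel_topology <- function(x, ...) {
  cat("channel_topology: chains", paste(x$chain_ids, collapse = " "),
      "| M2", x$m2_range[1], "-", x$m2_range[2],
      "| primes", names(x$prime_map)[1], "'..",
      names(x$prime_map)[length(x$prime_map)], "'\n", sep = " ")
  invisible(x)
}

#' Default alpha7-style topology
#'
#' The residue map shipped with the package for a human alpha7 nAChR
#' homology model: prime index i maps to residue 233 + i, anchored at the
#' 13' constriction Val246, with the loop spans used by the interface and
#' binding-site descriptors (Cys-loop 122-136, backwall 139-140, C-loop
#' 179-188, beta1-beta2 around Lys40, M2-M3 around Pro256).  Any other
#' numbering is supplied through [read_topology()].
#'
#' @return A `channel_topology`.
#' @export
alpha7_topology <- function() {
  primes <- -2:20
  pm <- setNames(233L + primes, as.character(primes))
  channel_topology(
    chain_ids = c("A", "B", "C", "D", "E"),
    prime_map = pm,
    m2_range = c(231L, 253L),
    loops = list(
      C_loop      = c(179L, 188L),
      Cys_loop    = c(122L, 136L),
      beta1_beta2 = c(38L, 44L),
      M2_M3       = c(254L, 258L),
      backwall    = c(139L, 140L)),
    ligand_resname = "EPI",
    key_residues = c(Pro256 = 256L, Lys40 = 40L, Tyr87 = 87L,
                     Leu103 = 103L, Leu113 = 113L, Trp143 = 143L,
                     Tyr182 = 182L, Tyr189 = 189L, Val13p = 246L,
                     Leu16p = 249L, Leu9p = 242L))
}

#' Residue number at a prime index
#'
#' @param topology a `channel_topology`.
#' @param prime_index integer prime index (vectorised).
#' @return Integer residue number(s).
#' @export
prime_residue <- function(topology, prime_index) {
  key <- as.character(as.integer(prime_index))
  res <- topology$prime_map[key]
  if (anyNA(res))
    stop("prime index ", paste(key[is.na(res)], collapse = ","),
         " not in topology prime_map", call. = FALSE)
  unname(res)
}

#' Non-adjacent subunit pairs of the pentamer
#'
#' In a pentamer every subunit has exactly two non-adjacent partners; the
#' five crossed pairs, in stable order, are P1-P3, P2-P4, P3-P5, P4-P1,
#' P5-P2.
#'
#' @param topology a `channel_topology`.
#' @return A 5x2 character matrix of chain ids, rownames `"P1-P3"` etc.
#' @export
nonadjacent_pairs <- function(topology) {
  ch <- topology$chain_ids
  i <- 1:5
  j <- c(3L, 4L, 5L, 1L, 2L)
  m <- cbind(ch[i], ch[j])
  rownames(m) <- paste0("P", i, "-P", j)
  colnames(m) <- c("a", "b")
  m
}

#' Read / write a channel topology as YAML
#'
#' The YAML layout mirrors the [channel_topology()] fields; see
#' `system.file("extdata", "alpha7_topology.yaml", package = "porescope")`
#' for the shipped default.
#'
#' @param path file path.
#' @return `read_topology()` returns a `channel_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  pm <- unlist(y$prime_map)
  channel_topology(
    chain_ids = y$chain_ids,
    prime_map = setNames(as.integer(pm), names(pm)),
    m2_range = y$m2_range,
    loops = y$loops,
    ligand_resname = if (is.null(y$ligand_resname)) "EPI" else y$ligand_resname,
    key_residues = if (is.null(y$key_residues)) integer() else
      setNames(as.integer(unlist(y$key_residues)), names(y$key_residues)))
}

#' @rdname read_topology
#' @param topology a `channel_topology`.
#' @export
write_topology <- function(topology, path) {
  y <- list(
    chain_ids = as.list(topology$chain_ids),
    prime_map = as.list(setNames(as.integer(topology$prime_map),
                                 names(topology$prime_map))),
    m2_range = as.integer(topology$m2_range),
    loops = lapply(topology$loops, as.integer),
    ligand_resname = topology$ligand_resname,
    key_residues = as.list(setNames(as.integer(topology$key_residues),
                                    names(topology$key_residues))))
  yaml::write_yaml(y, path)
  invisible(path)
}
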