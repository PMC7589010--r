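## Polymer specification and topology. Residues are ordered from the
## nonreducing end (residue 1) to the reducing end (residue n): residue i
## donates its anomeric C1 to the glycosidic oxygen, which is the
## O3/O4 atom of the acceptor residue i+1 (PDB carbohydrate convention).
## The anomeric O1 is present only on the reducing-end residue.

.GAG_DEFS <- list(
  hyaluronan = list(
    residues = c("GlcA", "GlcNAcb"),
    linkages = c("GlcAb1-3GlcNAc", "GlcNAcb1-4GlcA"),
    acceptor_pos = c(3L, 4L)
  ),
  dermatan = list(
    residues = c("IdoA", "GalNAcb"),
    linkages = c("IdoAa1-3GalNAc", "GalNAcb1-4IdoA"),
    acceptor_pos = c(3L, 4L)
  ),
  keratan = list(
    residues = c("Gal", "GlcNAcb"),
    linkages = c("Galb1-4GlcNAc", "GlcNAcb1-3Gal"),
    acceptor_pos = c(4L, 3L)
  ),
  heparan = list(
    residues = c("IdoA", "GlcNAca"),
    linkages = c("IdoAa1-4GlcNAc", "GlcNAca1-4IdoA"),
    acceptor_pos = c(4L, 4L)
  )
)

#' Supported GAG types
#' @return Character vector of built-in GAG type names.
#' @export
gag_types <- function() names(.GAG_DEFS)

#' Specify a GAG polymer
#'
#' Defines the residue and linkage sequence of a polymer of one of the
#' built-in nonsulfated GAG types, or of a custom repeat.
#'
#' @param gag_type One of [gag_types()], or `"custom"` with `residues`,
#'   `linkages` and `acceptor_pos` giving the repeat unit explicitly.
#' @param n_residues Number of monosaccharide units (>= 2).
#' @param residues,linkages,acceptor_pos Custom repeat: residue types
#'   (see [residue_template()]), linkage type names, and the acceptor
#'   carbon position (3 or 4) of each linkage. `linkages[k]` joins
#'   `residues[k]` (donor) to the next residue in the repeat.
#' @return An object of class `gag_polymer_spec`: residue type and linkage
#'   type per position, ordered from the nonreducing end.
#' @examples
#' polymer_spec("hyaluronan", 20)
#' @export
polymer_spec <- function(gag_type, n_residues,
                         residues = NULL, linkages = NULL,
                         acceptor_pos = NULL) {
  stopifnot(n_residues >= 2)
  if (gag_type == "custom") {
    stopifnot(!is.null(residues), !is.null(linkages),
              length(linkages) == length(residues),
              length(acceptor_pos) == length(linkages))
    def <- list(residues = residues, linkages = linkages,
                acceptor_pos = as.integer(acceptor_pos))
  } else {
    def <- .GAG_DEFS[[match.arg(gag_type, gag_types())]]
  }
  p <- length(def$residues)
  ridx <- (seq_len(n_residues) - 1) %% p + 1
  lidx <- (seq_len(n_residues - 1) - 1) %% p + 1
  structure(list(
    gag_type = gag_type,
    n_residues = as.integer(n_residues),
    residue_types = def$residues[ridx],
    linkage_types = def$linkages[lidx],
    acceptor_pos = def$acceptor_pos[lidx],
    ## the position at which residue 1 would accept an upstream linkage:
    ## its free hydroxyl position, used as the nonreducing-end backbone atom
    nonreducing_pos = def$acceptor_pos[length(def$acceptor_pos)]
  ), class = "gag_polymer_spec")
}

#' @export
print.gag_polymer_spec <- function(x, ...) {
  cat("GAG polymer spec:", x$gag_type, "\n")
  cat("  residues:", x$n_residues, "(",
      paste(unique(x$residue_types), collapse = "/"), ")\n")
  cat("  linkages:", x$n_residues - 1L, "(",
      paste(unique(x$linkage_types), collapse = ", "), ")\n")
  invisible(x)
}

#' Build the topology of a GAG polymer
#'
#' Enumerates atoms, bonds, residue boundaries and the glycosidic linkage
#' map of a polymer specification.
#'
#' @param spec A [polymer_spec()].
#' @return An object of class `gag_topology`: `atoms` (data frame with
#'   `name`, `element`, `res_idx`, `res_type`), `bonds` (two-column index
#'   matrix), `residues` (list of atom-index vectors), `ring_idx` (n x 6
#'   matrix of ring atom indices per residue, O5..C5 order), and
#'   `linkages` (data frame mapping each junction to the atom indices
#'   playing the O5, C1, O, Cn, C(n-1), and auxiliary C5/C(n-2) roles).
#' @export
build_topology <- function(spec) {
  stopifnot(inherits(spec, "gag_polymer_spec"))
  n <- spec$n_residues
  atom_name <- character(0); atom_res <- integer(0); atom_type <- character(0)
  residues <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    type <- spec$residue_types[i]
    nm <- .res_atom_names(type)
    if (i < n) nm <- setdiff(nm, "O1")  # donors have no free anomeric O
    residues[[i]] <- seq_along(nm) + offset
    atom_name <- c(atom_name, nm)
    atom_res <- c(atom_res, rep(i, length(nm)))
    atom_type <- c(atom_type, rep(type, length(nm)))
    offset <- offset + length(nm)
  }
  atoms <- data.frame(name = atom_name, element = .atom_element(atom_name),
                      res_idx = atom_res, res_type = atom_type)
  aidx <- function(res, name) {
    ii <- residues[[res]]
    ii[match(name, atoms$name[ii])]
  }
  bonds <- NULL
  for (i in seq_len(n)) {
    bn <- .res_bond_names(spec$residue_types[i])
    if (i < n) bn <- bn[bn[, 2] != "O1", , drop = FALSE]
    bonds <- rbind(bonds, cbind(aidx(i, bn[, 1]), aidx(i, bn[, 2])))
  }
  ring_idx <- t(vapply(seq_len(n), function(i) aidx(i, .RING_ATOMS),
                       integer(6)))
  linkages <- NULL
  for (j in seq_len(n - 1L)) {
    npos <- spec$acceptor_pos[j]
    o_name <- paste0("O", npos)
    cn <- paste0("C", npos)
    cprev <- paste0("C", npos - 1L)
    cprev2 <- if (npos == 3L) "C1" else "C2"
    row <- data.frame(
      junction = j, type = spec$linkage_types[j], acceptor_pos = npos,
      o5 = aidx(j, "O5"), c1 = aidx(j, "C1"), c5 = aidx(j, "C5"),
      o = aidx(j + 1L, o_name), cn = aidx(j + 1L, cn),
      cprev = aidx(j + 1L, cprev), cprev2 = aidx(j + 1L, cprev2)
    )
    linkages <- rbind(linkages, row)
    bonds <- rbind(bonds, c(row$c1, row$o))  # glycosidic C1-O bond
  }
  structure(list(spec = spec, atoms = atoms, bonds = bonds,
                 residues = residues, ring_idx = ring_idx,
                 linkages = linkages),
            class = "gag_topology")
}

#' @export
print.gag_topology <- function(x, ...) {
  cat("GAG topology:", x$spec$gag_type, "-", x$spec$n_residues, "residues,",
      nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Measure the glycosidic phi/psi dihedrals of a conformation
#'
#' phi = O5-C1-O-Cn and psi = C1-O-Cn-C(n-1) for every junction.
#'
#' @param conf A `gag_conformation` (see [build_chain()]) or a coordinate
#'   matrix together with `topology`.
#' @param topology A `gag_topology`; taken from `conf` if missing.
#' @return Data frame with `junction`, `type`, `phi`, `psi` (degrees).
#' @export
linkage_dihedrals <- function(conf, topology = NULL) {
  if (inherits(conf, "gag_conformation")) {
    topology <- conf$topology
    coords <- conf$coords
  } else {
    coords <- conf
  }
  lk <- topology$linkages
  phi <- psi <- numeric(nrow(lk))
  for (j in seq_len(nrow(lk))) {
    phi[j] <- dihedral(coords[lk$o5[j], ], coords[lk$c1[j], ],
                       coords[lk$o[j], ], coords[lk$cn[j], ])
    psi[j] <- dihedral(coords[lk$c1[j], ], coords[lk$o[j], ],
                       coords[lk$cn[j], ], coords[lk$cprev[j], ])
  }
  data.frame(junction = lk$junction, type = lk$type, phi = phi, psi = psi)
}
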