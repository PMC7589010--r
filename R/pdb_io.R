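## PDB input/output. Conformations are written as HETATM records with the
## standard carbohydrate chemical-component codes, chain A, CONECT records
## for the glycosidic bonds, and MODEL/ENDMDL blocks for ensembles.
## Reading goes through bio3d and reconstructs the polymer topology from
## the residue codes and the documented atom-name conventions.

.PDB_CODES <- c(GlcA = "BDP", IdoA = "IDR", GlcNAcb = "NAG",
                GlcNAca = "NDG", GalNAcb = "NGA", Gal = "GAL")

#' Residue-code mapping used in PDB files
#'
#' @return Named character vector: residue type -> PDB chemical component
#'   code (BDP beta-D-glucuronic acid, IDR alpha-L-iduronic acid, NAG/NDG
#'   beta/alpha-GlcNAc, NGA beta-GalNAc, GAL beta-D-galactose).
#' @export
pdb_residue_codes <- function() .PDB_CODES

.pdb_atom_line <- function(serial, name, resname, resseq, xyz, element) {
  sprintf("HETATM%5d %-4s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resseq, xyz[1], xyz[2], xyz[3], element)
}

#' Write conformations to a PDB file
#'
#' @param x A `gag_conformation`, a list of them, or a `gag_ensemble` built
#'   with `keep_coords = TRUE`.
#' @param path Output file path.
#' @param multi_model Write MODEL/ENDMDL blocks (forced when more than one
#'   conformation is given).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, multi_model = NULL) {
  if (inherits(x, "gag_conformation")) {
    topo <- x$topology
    frames <- list(x$coords)
  } else if (inherits(x, "gag_ensemble")) {
    if (is.null(x$coords)) {
      stop("write_pdb: ensemble was generated without keep_coords = TRUE")
    }
    topo <- x$topology
    frames <- x$coords
  } else if (is.list(x) && length(x) > 0 &&
             inherits(x[[1]], "gag_conformation")) {
    topo <- x[[1]]$topology
    frames <- lapply(x, function(cf) cf$coords)
  } else {
    stop("write_pdb: unsupported input")
  }
  if (is.null(multi_model)) multi_model <- length(frames) > 1
  atoms <- topo$atoms
  resname <- .PDB_CODES[atoms$res_type]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    if (multi_model) writeLines(sprintf("MODEL %8d", m), con)
    lines <- vapply(seq_len(nrow(atoms)), function(i) {
      .pdb_atom_line(i, atoms$name[i], resname[i], atoms$res_idx[i],
                     frames[[m]][i, ], atoms$element[i])
    }, character(1))
    writeLines(lines, con)
    if (multi_model) writeLines("ENDMDL", con)
  }
  ## glycosidic bonds connect residues; intra-residue connectivity is
  ## implied by the component codes
  for (j in seq_len(nrow(topo$linkages))) {
    writeLines(sprintf("CONECT%5d%5d", topo$linkages$c1[j],
                       topo$linkages$o[j]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB ensemble
#'
#' Parses a PDB file written by [write_pdb()] (or any multi-model PDB
#' following the same residue codes and atom naming), infers the polymer
#' specification from the residue sequence, and returns the topology with
#' one coordinate matrix per model.
#'
#' @param path PDB file path.
#' @return List with `topology` (a `gag_topology`) and `conformations`
#'   (list of `gag_conformation`).
#' @export
read_pdb_ensemble <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_ensemble requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  codes <- unique(at$resid)
  unknown <- setdiff(codes, .PDB_CODES)
  if (length(unknown) > 0) {
    stop("read_pdb_ensemble: unknown residue code(s) ",
         paste(unknown, collapse = ", "), "; supported: ",
         paste(.PDB_CODES, collapse = ", "))
  }
  rev_codes <- stats::setNames(names(.PDB_CODES), .PDB_CODES)
  res_ids <- unique(at$resno)
  res_types <- vapply(res_ids, function(r) {
    rev_codes[[at$resid[match(r, at$resno)]]]
  }, character(1))
  gag <- NULL
  for (g in gag_types()) {
    cand <- polymer_spec(g, length(res_ids))
    if (identical(cand$residue_types, unname(res_types))) {
      gag <- cand
      break
    }
  }
  if (is.null(gag)) {
    stop("read_pdb_ensemble: residue sequence (",
         paste(res_types, collapse = ","),
         ") does not match a supported GAG repeat")
  }
  topo <- build_topology(gag)
  ## map file atoms onto topology order by (residue, atom name)
  key_file <- paste(at$resno, trimws(at$elety))
  key_topo <- paste(topo$atoms$res_idx, topo$atoms$name)
  perm <- match(key_topo, key_file)
  if (anyNA(perm)) {
    stop("read_pdb_ensemble: missing atoms: ",
         paste(utils::head(key_topo[is.na(perm)], 5), collapse = "; "))
  }
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  confs <- vector("list", nm)
  for (m in seq_len(nm)) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    co <- matrix(xyz, ncol = 3, byrow = TRUE)
    if (nrow(co) != length(key_file)) {
      stop("read_pdb_ensemble: model ", m, " has ", nrow(co),
           " atoms; expected ", length(key_file))
    }
    co <- co[perm, , drop = FALSE]
    rownames(co) <- topo$atoms$name
    confs[[m]] <- .new_conformation(topo, co, plan = NULL,
                                    provenance = list(file = path, model = m))
  }
  list(topology = topo, conformations = confs)
}
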