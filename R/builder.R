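## Chain assembly. A polymer conformation is realized atom by atom from
## internal coordinates: residue 1 (nonreducing end) is seeded at the
## origin; each junction then places the glycosidic O (auxiliary torsion
## C5-O5-C1-O), the acceptor linkage carbon Cn (phi), and the acceptor
## ring atom C(n-1) (psi), after which the rest of the acceptor ring and
## its exocyclic atoms follow from the ring conformer's internal
## coordinates. The full placement plan is retained on the conformation:
## it is the restraint target set for minimization and makes measured
## internals round-trip exactly against the sampled conformer values.

.link_donor_acceptor <- function(link_type) {
  ## "GlcAb1-3GlcNAc" -> donor "GlcA", acceptor "GlcNAc", anomer "b", pos 3
  m <- regmatches(link_type,
                  regexec("^([A-Za-z]+)([ab])1-([34])([A-Za-z]+)$", link_type))[[1]]
  if (length(m) == 0) stop("unparseable linkage type: ", link_type)
  list(donor = m[2], anomer = m[3], pos = as.integer(m[4]), acceptor = m[5])
}

## default (template-derived) linkage geometry for fixed-dihedral builds
## and synthetic generation; the glycosidic valence angle C1-O-Cn is the
## standard crystallographic value
.default_linkage_params <- function(link_type, donor_type, acceptor_type,
                                    npos) {
  dtpl <- residue_template(donor_type)
  atpl <- residue_template(acceptor_type)
  o1 <- which(dtpl$plan$atom == "O1")
  slot <- which(atpl$plan$atom == paste0("O", npos))
  c(c1_o = dtpl$plan$bond[o1],
    o_cn = atpl$plan$bond[slot],
    o5_c1_o = dtpl$plan$angle[o1],
    c1_o_cn = 116.5,
    phi = NA_real_, psi = NA_real_,
    tau_o = dtpl$plan$torsion[o1],
    o_cn_cprev = atpl$plan$angle[slot])
}

## assemble and realize a chain from per-residue local coordinates and
## per-junction linkage parameter vectors
.assemble_chain <- function(topology, ring_locals, link_params) {
  spec <- topology$spec
  n <- spec$n_residues
  atoms <- topology$atoms
  rows <- vector("list", 4096)
  nrow_used <- 0L
  push <- function(idx, a, b, c, bond, angle, torsion) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- c(idx, a, b, c, bond, angle, torsion)
  }
  gidx <- function(res, name) {
    ii <- topology$residues[[res]]
    ii[match(name, atoms$name[ii])]
  }
  dh <- function(co, a, b, c, d) dihedral(co[a, ], co[b, ], co[c, ], co[d, ])
  an <- function(co, a, b, c) bond_angle(co[a, ], co[b, ], co[c, ])
  bd <- function(co, a, b) atom_distance(co[a, ], co[b, ])
  ## residue 1: canonical plan measured from its local coordinates
  t1 <- spec$residue_types[1]
  pl <- .res_plan_names(t1)
  loc <- ring_locals[[1]]
  keep <- pl$atom %in% atoms$name[topology$residues[[1]]]
  for (r in which(keep)) {
    if (is.na(pl$a[r])) {
      bond <- if (r == 1) NA_real_ else bd(loc, pl$atom[max(1, r - 1)], pl$atom[r])
      angle <- if (r == 3) an(loc, pl$atom[1], pl$atom[2], pl$atom[3]) else NA_real_
      push(gidx(1, pl$atom[r]), NA, NA, NA, bond, angle, NA_real_)
    } else {
      push(gidx(1, pl$atom[r]),
           gidx(1, pl$a[r]), gidx(1, pl$b[r]), gidx(1, pl$c[r]),
           bd(loc, pl$c[r], pl$atom[r]), an(loc, pl$b[r], pl$c[r], pl$atom[r]),
           dh(loc, pl$a[r], pl$b[r], pl$c[r], pl$atom[r]))
    }
  }
  ## junctions + acceptor residues
  lk <- topology$linkages
  for (j in seq_len(n - 1L)) {
    p <- link_params[[j]]
    i <- j + 1L
    npos <- lk$acceptor_pos[j]
    loc <- ring_locals[[i]]
    o_name <- paste0("O", npos)
    cn <- paste0("C", npos); cm1 <- paste0("C", npos - 1L)
    ## glycosidic O, Cn (phi), C(n-1) (psi)
    push(lk$o[j], lk$c5[j], lk$o5[j], lk$c1[j],
         p[["c1_o"]], p[["o5_c1_o"]], p[["tau_o"]])
    push(lk$cn[j], lk$o5[j], lk$c1[j], lk$o[j],
         p[["o_cn"]], p[["c1_o_cn"]], p[["phi"]])
    push(lk$cprev[j], lk$c1[j], lk$o[j], lk$cn[j],
         bd(loc, cn, cm1), p[["o_cn_cprev"]], p[["psi"]])
    ## rest of the acceptor ring: C(n-2) oriented by the ring conformer's
    ## substituent direction at Cn, then pure ring internals
    trav <- if (npos == 4L) c("C4", "C3", "C2", "C1", "O5", "C5")
            else c("C3", "C2", "C1", "O5", "C5", "C4")
    push(gidx(i, trav[3]), lk$o[j], lk$cn[j], lk$cprev[j],
         bd(loc, trav[2], trav[3]), an(loc, trav[1], trav[2], trav[3]),
         dh(loc, o_name, trav[1], trav[2], trav[3]))
    for (r in 4:6) {
      push(gidx(i, trav[r]), gidx(i, trav[r - 3]), gidx(i, trav[r - 2]),
           gidx(i, trav[r - 1]),
           bd(loc, trav[r - 1], trav[r]), an(loc, trav[r - 2], trav[r - 1], trav[r]),
           dh(loc, trav[r - 3], trav[r - 2], trav[r - 1], trav[r]))
    }
    ## exocyclic atoms of the acceptor residue (slot O at Cn is the
    ## glycosidic O, already placed; O1 only on the reducing end)
    pla <- .res_plan_names(spec$residue_types[i])
    pres <- atoms$name[topology$residues[[i]]]
    for (r in 7:nrow(pla)) {
      nmr <- pla$atom[r]
      if (nmr == o_name || !(nmr %in% pres)) next
      push(gidx(i, nmr), gidx(i, pla$a[r]), gidx(i, pla$b[r]),
           gidx(i, pla$c[r]),
           bd(loc, pla$c[r], nmr), an(loc, pla$b[r], pla$c[r], nmr),
           dh(loc, pla$a[r], pla$b[r], pla$c[r], nmr))
    }
  }
  m <- do.call(rbind, rows[seq_len(nrow_used)])
  plan <- data.frame(idx = as.integer(m[, 1]), a = as.integer(m[, 2]),
                     b = as.integer(m[, 3]), c = as.integer(m[, 4]),
                     bond = m[, 5], angle = m[, 6], torsion = m[, 7])
  coords <- .nerf_realize(plan$idx, plan$a, plan$b, plan$c,
                          plan$bond, plan$angle, plan$torsion, nrow(atoms))
  rownames(coords) <- atoms$name
  list(coords = coords, plan = plan)
}

.new_conformation <- function(topology, coords, plan, provenance = list()) {
  structure(list(topology = topology, coords = coords, plan = plan,
                 provenance = provenance),
            class = "gag_conformation")
}

#' @export
print.gag_conformation <- function(x, ...) {
  cat("GAG conformation:", x$topology$spec$gag_type, "-",
      x$topology$spec$n_residues, "residues,", nrow(x$coords), "atoms\n")
  cat("  end-to-end:", round(end_to_end(x), 2), "A  Rg:",
      round(radius_of_gyration(x), 2), "A\n")
  invisible(x)
}

#' Build a polymer conformation by sampling a conformer database
#'
#' Draws one ring conformer per residue and one linkage conformer per
#' junction, independently and uniformly from the database pools, and
#' realizes the chain in Cartesian space. Pre-minimization measured
#' internals equal the sampled conformer values.
#'
#' @param spec A [polymer_spec()] (or a `gag_topology`).
#' @param db A `conformer_db` covering the spec's residue and linkage types.
#' @return A `gag_conformation` with provenance (pool row of every
#'   conformer used).
#' @export
build_chain <- function(spec, db) {
  topology <- if (inherits(spec, "gag_topology")) spec else build_topology(spec)
  sp <- topology$spec
  for (type in unique(sp$residue_types)) {
    if (is.null(db$rings[[type]])) stop("db missing ring pool: ", type)
  }
  for (type in unique(sp$linkage_types)) {
    if (is.null(db$linkages[[type]])) stop("db missing linkage pool: ", type)
  }
  ring_rows <- vapply(seq_len(sp$n_residues), function(i) {
    sample.int(nrow(db$rings[[sp$residue_types[i]]]), 1L)
  }, integer(1))
  link_rows <- vapply(seq_len(sp$n_residues - 1L), function(j) {
    sample.int(nrow(db$linkages[[sp$linkage_types[j]]]), 1L)
  }, integer(1))
  out <- .fast_build(topology, db, ring_rows, link_rows)
  .new_conformation(topology, out$coords, out$plan,
                    provenance = list(ring_rows = ring_rows,
                                      link_rows = link_rows))
}

#' Build a polymer with fixed glycosidic dihedrals
#'
#' Deterministic construction: every junction of a given linkage type gets
#' the same (phi, psi); rings are at template geometry (optionally at a
#' given pucker label per residue type). Used for the homogeneous-dihedral
#' reference constructions and the fully-extended reference.
#'
#' @param spec A [polymer_spec()] or `gag_topology`.
#' @param dihedrals Named list: linkage type -> `c(phi, psi)` in degrees.
#'   Must cover every linkage type of the spec.
#' @param ring_puckers Optional named list: residue type -> pucker label
#'   (default: the template reference chair).
#' @return A `gag_conformation`.
#' @examples
#' \donttest{
#' sp <- polymer_spec("hyaluronan", 20)
#' conf <- build_fixed(sp, list(
#'   "GlcAb1-3GlcNAc" = c(-83.75, -156.25),
#'   "GlcNAcb1-4GlcA" = c(-63.75, 118.75)))
#' end_to_end(conf)  # ~99 A
#' }
#' @export
build_fixed <- function(spec, dihedrals, ring_puckers = NULL) {
  topology <- if (inherits(spec, "gag_topology")) spec else build_topology(spec)
  sp <- topology$spec
  missing_types <- setdiff(unique(sp$linkage_types), names(dihedrals))
  if (length(missing_types) > 0) {
    stop("build_fixed: no dihedrals for linkage type(s): ",
         paste(missing_types, collapse = ", "))
  }
  ring_locals <- vector("list", sp$n_residues)
  for (i in seq_len(sp$n_residues)) {
    type <- sp$residue_types[i]
    tpl <- residue_template(type)
    if (!is.null(ring_puckers[[type]])) {
      v <- pucker_vertex(ring_puckers[[type]])
      ring_locals[[i]] <- .realize_residue(type, tpl$subst,
                                           Q = .RING_Q_REF, theta = v$theta,
                                           phi = v$phi,
                                           mean_bond = .RING_MEAN_BOND)
    } else {
      ring_locals[[i]] <- tpl$coords
    }
  }
  link_params <- vector("list", sp$n_residues - 1L)
  for (j in seq_len(sp$n_residues - 1L)) {
    type <- sp$linkage_types[j]
    p <- .default_linkage_params(type, sp$residue_types[j],
                                 sp$residue_types[j + 1L],
                                 sp$acceptor_pos[j])
    p[["phi"]] <- dihedrals[[type]][1]
    p[["psi"]] <- dihedrals[[type]][2]
    link_params[[j]] <- p
  }
  out <- .assemble_chain(topology, ring_locals, link_params)
  .new_conformation(topology, out$coords, out$plan,
                    provenance = list(fixed_dihedrals = dihedrals))
}

#' Build the fully-extended reference conformation
#'
#' Chooses one homogeneous (phi, psi) per linkage type from the database:
#' candidate bins within 1 kcal/mol of the free-energy minimum of each
#' linkage type's (phi, psi) map are combined on a grid, and the
#' combination maximizing the end-to-end distance is kept. Rings are at
#' the dominant pucker label of each residue pool. Deterministic given the
#' database.
#'
#' @param spec A [polymer_spec()] or `gag_topology`.
#' @param db A `conformer_db`.
#' @param max_candidates Cap on low-energy candidate bins per linkage type.
#' @return A `gag_conformation` (attribute `"dihedrals"` holds the chosen
#'   per-type values).
#' @export
build_extended_reference <- function(spec, db, max_candidates = 6L) {
  topology <- if (inherits(spec, "gag_topology")) spec else build_topology(spec)
  sp <- topology$spec
  ltypes <- unique(sp$linkage_types)
  cands <- lapply(ltypes, function(type) {
    pool <- db$linkages[[type]]
    if (is.null(pool)) stop("db missing linkage pool: ", type)
    fem <- free_energy_map(pool[, c("phi", "psi")])
    low <- which(fem$dG <= 1.0, arr.ind = TRUE)
    dg <- fem$dG[low]
    ord <- order(dg)
    take <- ord[unique(round(seq(1, length(ord),
                                 length.out = min(max_candidates,
                                                  length(ord)))))]
    data.frame(phi = fem$phi_centers[low[take, 1]],
               psi = fem$psi_centers[low[take, 2]])
  })
  names(cands) <- ltypes
  rtypes <- unique(sp$residue_types)
  puckers <- lapply(rtypes, function(type) {
    labs <- db$rings[[type]]$label
    names(sort(table(labs), decreasing = TRUE))[1]
  })
  names(puckers) <- rtypes
  grid <- expand.grid(lapply(cands, function(d) seq_len(nrow(d))))
  best <- NULL; best_e2e <- -Inf; best_dih <- NULL
  for (g in seq_len(nrow(grid))) {
    dih <- lapply(ltypes, function(type) {
      as.numeric(cands[[type]][grid[g, type], ])
    })
    names(dih) <- ltypes
    conf <- build_fixed(topology, dih, ring_puckers = puckers)
    e <- end_to_end(conf)
    if (e > best_e2e) {
      best_e2e <- e; best <- conf; best_dih <- dih
    }
  }
  attr(best, "dihedrals") <- best_dih
  best
}
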