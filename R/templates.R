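## Heavy-atom residue templates for the monosaccharides that occur in
## nonsulfated GAGs. Stereochemistry is encoded as which of the two
## tetrahedral substituent slots (equatorial or axial in the 4C1 reference
## chair) each exocyclic heavy atom occupies; the slot is realized as a
## chirality sign that is conformation-independent, so the same template
## describes the residue at any ring pucker. IdoA is the C5 epimer of GlcA
## (carboxylate axial in the 4C1 reference frame) and its reference pucker
## is the 1C4 chair, as in the iduronate force-field geometry.

.RING_ATOMS <- c("O5", "C1", "C2", "C3", "C4", "C5")
.RING_MEAN_BOND <- 1.49   # mean of four C-C (1.525) and two C-O (1.43) A
.RING_Q_REF <- 0.57       # typical pyranose total puckering amplitude, A

## substituent slot tables: substituent atom, host ring carbon, slot in the
## 4C1 reference chair, bond length (A)
.SUBST_TABLES <- list(
  GlcA = data.frame(
    atom = c("O1", "O2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("eq", "eq", "eq", "eq", "eq"),
    bond = c(1.41, 1.42, 1.42, 1.42, 1.52)
  ),
  IdoA = data.frame(  # C5 epimer of GlcA
    atom = c("O1", "O2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("eq", "eq", "eq", "eq", "ax"),
    bond = c(1.41, 1.42, 1.42, 1.42, 1.52)
  ),
  GlcNAcb = data.frame(
    atom = c("O1", "N2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("eq", "eq", "eq", "eq", "eq"),
    bond = c(1.41, 1.45, 1.42, 1.42, 1.52)
  ),
  GlcNAca = data.frame(  # alpha anomer: anomeric O axial in 4C1
    atom = c("O1", "N2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("ax", "eq", "eq", "eq", "eq"),
    bond = c(1.41, 1.45, 1.42, 1.42, 1.52)
  ),
  GalNAcb = data.frame(  # galacto: O4 axial
    atom = c("O1", "N2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("eq", "eq", "eq", "ax", "eq"),
    bond = c(1.41, 1.45, 1.42, 1.42, 1.52)
  ),
  Gal = data.frame(
    atom = c("O1", "O2", "O3", "O4", "C6"),
    host = c("C1", "C2", "C3", "C4", "C5"),
    slot = c("eq", "eq", "eq", "ax", "eq"),
    bond = c(1.41, 1.42, 1.42, 1.42, 1.52)
  )
)

## second-shell exocyclic atoms: placement quadruples (a, b, c are frame
## atom names), internal coordinates fixed at standard values
.SECOND_SHELL <- list(
  carboxylate = data.frame(   # GlcA, IdoA: C6 carboxylate
    atom = c("O6A", "O6B"),
    a = c("C4", "C4"), b = c("C5", "C5"), c = c("C6", "C6"),
    bond = c(1.25, 1.25), angle = c(117, 117), torsion = c(-30, 150)
  ),
  hydroxymethyl = data.frame( # Gal, GlcNAc, GalNAc: C6-O6
    atom = "O6",
    a = "C4", b = "C5", c = "C6",
    bond = 1.43, angle = 111, torsion = 60
  ),
  nacetyl = data.frame(       # GlcNAc, GalNAc: N-acetyl on N2
    atom = c("C7", "O7", "C8"),
    a = c("C1", "C2", "C2"), b = c("C2", "N2", "N2"), c = c("N2", "C7", "C7"),
    bond = c(1.33, 1.23, 1.50), angle = c(122, 123, 115),
    torsion = c(-108, 0, 180)
  )
)

.residue_types <- function() names(.SUBST_TABLES)

.res_has_nacetyl <- function(type) type %in% c("GlcNAcb", "GlcNAca", "GalNAcb")
.res_has_carboxylate <- function(type) type %in% c("GlcA", "IdoA")

## full atom list of a free monosaccharide of the given type
.res_atom_names <- function(type) {
  subst <- .SUBST_TABLES[[type]]
  second <- if (.res_has_carboxylate(type)) {
    .SECOND_SHELL$carboxylate$atom
  } else if (.res_has_nacetyl(type)) {
    c(.SECOND_SHELL$hydroxymethyl$atom, .SECOND_SHELL$nacetyl$atom)
  } else {
    .SECOND_SHELL$hydroxymethyl$atom
  }
  c(.RING_ATOMS, subst$atom, second)
}

.atom_element <- function(name) substr(name, 1, 1)

## intra-residue bond list (pairs of atom names) for a full monosaccharide
.res_bond_names <- function(type) {
  ring <- cbind(.RING_ATOMS, c(.RING_ATOMS[-1], .RING_ATOMS[1]))
  subst <- .SUBST_TABLES[[type]]
  sub <- cbind(subst$host, subst$atom)
  second <- if (.res_has_carboxylate(type)) {
    cbind(c("C6", "C6"), c("O6A", "O6B"))
  } else if (.res_has_nacetyl(type)) {
    cbind(c("C6", "N2", "C7", "C7"), c("O6", "C7", "O7", "C8"))
  } else {
    cbind("C6", "O6")
  }
  rbind(ring, sub, second)
}

## tetrahedral substituent directions at ring carbon c with ring neighbours
## p (previous) and n (next). Returns the two candidate unit directions,
## keyed by chirality sign: sign of det[u_prev, u_next, dir].
.subst_dirs <- function(cpos, ppos, npos, target_angle = 109.47) {
  u1 <- (ppos - cpos); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- (npos - cpos); u2 <- u2 / sqrt(sum(u2^2))
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  nrm <- .cross3(u1, u2); nrm <- nrm / sqrt(sum(nrm^2))
  half <- acos(min(1, max(-1, sum(u1 * u2)))) / 2
  cg <- -cos(target_angle * .deg2rad) / cos(half)
  cg <- min(1, max(-1, cg))
  sg <- sqrt(1 - cg^2)
  list(`1` = cg * bis + sg * nrm, `-1` = cg * bis - sg * nrm)
}

## positions of ring neighbours in ring order O5,C1,...,C5 (cyclic)
.ring_neighbours <- function(host) {
  i <- match(host, .RING_ATOMS)
  list(prev = .RING_ATOMS[(i - 2) %% 6 + 1], nxt = .RING_ATOMS[i %% 6 + 1])
}

## chirality sign giving the requested slot (eq/ax) in the 4C1 reference
## chair; derived geometrically from a constructed reference ring
.slot_signs <- function(subst) {
  ring <- ring_from_pucker(.RING_Q_REF, 0, 0, .RING_MEAN_BOND)
  signs <- integer(nrow(subst))
  for (k in seq_len(nrow(subst))) {
    nb <- .ring_neighbours(subst$host[k])
    dirs <- .subst_dirs(ring[subst$host[k], ], ring[nb$prev, ], ring[nb$nxt, ])
    ## mean-plane normal of the reference ring is +z; the equatorial slot
    ## is the more in-plane of the two candidates
    eq_sign <- if (abs(dirs$`1`[3]) < abs(dirs$`-1`[3])) 1L else -1L
    signs[k] <- if (subst$slot[k] == "eq") eq_sign else -eq_sign
  }
  signs
}

## canonical placement plan for a full residue: atom names + frame atom
## names; bond/angle/torsion filled by measurement (measure_plan) or left
## NA. Seed rows are O5, C1, C2.
.res_plan_names <- function(type) {
  subst <- .SUBST_TABLES[[type]]
  rows <- list(
    data.frame(atom = "O5", a = NA, b = NA, c = NA),
    data.frame(atom = "C1", a = NA, b = NA, c = NA),
    data.frame(atom = "C2", a = NA, b = NA, c = NA),
    data.frame(atom = "C3", a = "O5", b = "C1", c = "C2"),
    data.frame(atom = "C4", a = "C1", b = "C2", c = "C3"),
    data.frame(atom = "C5", a = "C2", b = "C3", c = "C4"),
    data.frame(atom = "O1", a = "C5", b = "O5", c = "C1"),
    data.frame(atom = subst$atom[2], a = "O5", b = "C1", c = "C2"),
    data.frame(atom = "O3", a = "C1", b = "C2", c = "C3"),
    data.frame(atom = "O4", a = "C2", b = "C3", c = "C4"),
    data.frame(atom = "C6", a = "C3", b = "C4", c = "C5")
  )
  second <- if (.res_has_carboxylate(type)) {
    .SECOND_SHELL$carboxylate[, c("atom", "a", "b", "c")]
  } else if (.res_has_nacetyl(type)) {
    rbind(.SECOND_SHELL$hydroxymethyl[, c("atom", "a", "b", "c")],
          .SECOND_SHELL$nacetyl[, c("atom", "a", "b", "c")])
  } else {
    .SECOND_SHELL$hydroxymethyl[, c("atom", "a", "b", "c")]
  }
  do.call(rbind, c(rows, list(second)))
}

.template_cache <- new.env(parent = emptyenv())

#' Idealized heavy-atom template of a monosaccharide residue
#'
#' Builds the reference geometry of one residue type at its reference ring
#' pucker (4C1, or 1C4 for IdoA), with exocyclic heavy atoms at idealized
#' tetrahedral positions encoding the residue stereochemistry.
#'
#' @param type One of `"GlcA"`, `"IdoA"`, `"GlcNAcb"`, `"GlcNAca"`,
#'   `"GalNAcb"`, `"Gal"`.
#' @return A list with `type`, `atoms` (names), `elements`, `coords`
#'   (local-frame matrix), `bonds` (two-column matrix of atom names), `b0`
#'   (equilibrium length per bond), `plan` (canonical placement plan with
#'   measured internal coordinates), `subst` (slot table with chirality
#'   signs), and `ref_theta` (reference Cremer-Pople theta, degrees).
#' @export
residue_template <- function(type) {
  type <- match.arg(type, .residue_types())
  if (!is.null(.template_cache[[type]])) return(.template_cache[[type]])
  subst <- .SUBST_TABLES[[type]]
  subst$sign <- .slot_signs(subst)
  ref_theta <- if (type == "IdoA") 180 else 0
  coords <- .realize_residue(type, subst,
                             Q = .RING_Q_REF, theta = ref_theta, phi = 0,
                             mean_bond = .RING_MEAN_BOND)
  atoms <- rownames(coords)
  plan <- .res_plan_names(type)
  plan_idx <- data.frame(idx = match(plan$atom, atoms),
                         a = match(plan$a, atoms),
                         b = match(plan$b, atoms),
                         c = match(plan$c, atoms),
                         bond = NA_real_, angle = NA_real_,
                         torsion = NA_real_)
  plan_idx <- measure_plan(coords, plan_idx)
  plan <- cbind(plan, plan_idx[, c("bond", "angle", "torsion")])
  bonds <- .res_bond_names(type)
  b0 <- vapply(seq_len(nrow(bonds)), function(i) {
    atom_distance(coords[bonds[i, 1], ], coords[bonds[i, 2], ])
  }, numeric(1))
  tpl <- list(type = type, atoms = atoms,
              elements = .atom_element(atoms),
              coords = coords, bonds = bonds, b0 = b0,
              plan = plan, subst = subst, ref_theta = ref_theta)
  .template_cache[[type]] <- tpl
  tpl
}

## realize a full residue's local coordinates for a given ring pucker and
## substituent internal coordinates; used for templates and for synthetic
## ring conformers. subst must carry the chirality signs.
.realize_residue <- function(type, subst, Q, theta, phi, mean_bond,
                             second_tweaks = NULL) {
  ring <- ring_from_pucker(Q, theta, phi, mean_bond)
  atoms <- .res_atom_names(type)
  coords <- matrix(NA_real_, length(atoms), 3,
                   dimnames = list(atoms, c("x", "y", "z")))
  coords[.RING_ATOMS, ] <- ring
  for (k in seq_len(nrow(subst))) {
    host <- subst$host[k]
    nb <- .ring_neighbours(host)
    dirs <- .subst_dirs(coords[host, ], coords[nb$prev, ], coords[nb$nxt, ])
    dir <- dirs[[as.character(subst$sign[k])]]
    coords[subst$atom[k], ] <- coords[host, ] + subst$bond[k] * dir
  }
  second <- if (.res_has_carboxylate(type)) {
    .SECOND_SHELL$carboxylate
  } else if (.res_has_nacetyl(type)) {
    rbind(.SECOND_SHELL$hydroxymethyl, .SECOND_SHELL$nacetyl)
  } else {
    .SECOND_SHELL$hydroxymethyl
  }
  if (!is.null(second_tweaks)) {
    m <- match(second$atom, second_tweaks$atom)
    ok <- !is.na(m)
    second[ok, c("bond", "angle", "torsion")] <-
      second_tweaks[m[ok], c("bond", "angle", "torsion")]
  }
  for (k in seq_len(nrow(second))) {
    coords[second$atom[k], ] <- place_atom(
      coords[second$a[k], ], coords[second$b[k], ], coords[second$c[k], ],
      second$bond[k], second$angle[k], second$torsion[k]
    )
  }
  coords
}
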