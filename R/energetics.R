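## Restrained energy model and the exclusion filter. The potential is a
## harmonic bond term over all topology bonds (the screened quantity), a
## harmonic restraint holding every placement-plan angle and torsion at
## its constructed value, and a soft-core repulsion between atoms more
## than three bonds apart. Minimization relieves steric overlap while the
## restraints maintain the sampled polymer conformation; a bond that is
## trapped through a ring or on top of another bond can only separate by
## stretching, which raises the post-minimization bond potential energy
## far above the defect-free baseline -- the screening signal.

#' Energy model parameters
#'
#' @param k_bond Harmonic bond constant, kcal/mol/A^2.
#' @param k_angle Angle restraint constant, kcal/mol/rad^2.
#' @param k_torsion Torsion restraint constant, kcal/mol/rad^2.
#' @param epsilon Soft-core repulsion well scale, kcal/mol.
#' @param r_min Repulsion onset distance, A (energy and force are zero at
#'   and beyond `r_min`).
#' @param max_iter L-BFGS-B iteration cap.
#' @param pgtol Projected-gradient convergence tolerance, kcal/mol/A.
#' @param factr L-BFGS-B relative energy-change tolerance factor.
#' @return List of class `gag_energy_params`.
#' @export
energy_params <- function(k_bond = 300, k_angle = 60, k_torsion = 500,
                          epsilon = 1.0, r_min = 2.8,
                          max_iter = 500L, pgtol = 0.02, factr = 1e10) {
  stopifnot(k_bond > 0, k_angle > 0, k_torsion > 0, epsilon > 0, r_min > 0)
  structure(list(k_bond = k_bond, k_angle = k_angle, k_torsion = k_torsion,
                 epsilon = epsilon, r_min = r_min,
                 max_iter = as.integer(max_iter), pgtol = pgtol,
                 factr = factr),
            class = "gag_energy_params")
}

## equilibrium bond lengths for every topology bond, from the residue
## templates (ring bonds share the uniform template ring bond length)
.topology_b0 <- function(topology) {
  b0 <- numeric(nrow(topology$bonds))
  atoms <- topology$atoms
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds[r, 1]; j <- topology$bonds[r, 2]
    if (atoms$res_idx[i] != atoms$res_idx[j]) {
      ## glycosidic C1-O bond
      dtpl <- residue_template(atoms$res_type[i])
      b0[r] <- dtpl$plan$bond[dtpl$plan$atom == "O1"]
      next
    }
    tpl <- residue_template(atoms$res_type[i])
    nm <- c(atoms$name[i], atoms$name[j])
    hit <- which((tpl$bonds[, 1] == nm[1] & tpl$bonds[, 2] == nm[2]) |
                 (tpl$bonds[, 1] == nm[2] & tpl$bonds[, 2] == nm[1]))
    b0[r] <- tpl$b0[hit[1]]
  }
  b0
}

## nonbonded exclusion keys (i*1e5 + j, i < j, 0-based) for atom pairs at
## bond-graph distance <= 3
.exclusion_keys <- function(topology) {
  n <- nrow(topology$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds[r, 1]; j <- topology$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  keys <- numeric(0)
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    near <- setdiff(unique(c(d1, d2, d3)), i)
    near <- near[near > i]
    if (length(near)) {
      keys <- c(keys, (i - 1) * 1e5 + (near - 1))
    }
  }
  sort(keys)
}

## restraint target arrays from a conformation's placement plan
.plan_restraints <- function(plan) {
  ang_rows <- which(!is.na(plan$angle) & !is.na(plan$b))
  tor_rows <- which(!is.na(plan$torsion))
  angles <- cbind(plan$b[ang_rows], plan$c[ang_rows], plan$idx[ang_rows])
  th0 <- plan$angle[ang_rows] * pi / 180
  seed3 <- which(is.na(plan$a) & !is.na(plan$angle))
  if (length(seed3) == 1) {
    angles <- rbind(angles, c(plan$idx[1], plan$idx[2], plan$idx[seed3]))
    th0 <- c(th0, plan$angle[seed3] * pi / 180)
  }
  tors <- cbind(plan$a[tor_rows], plan$b[tor_rows], plan$c[tor_rows],
                plan$idx[tor_rows])
  ph0 <- plan$torsion[tor_rows] * pi / 180
  list(angles = angles, th0 = th0, tors = tors, ph0 = ph0)
}

#' Bond potential energy of a conformation
#'
#' Sum of `k_bond * (b - b0)^2` over all topology bonds, with equilibrium
#' lengths from the residue templates. This is the quantity screened by
#' the exclusion cutoff.
#'
#' @param conf A `gag_conformation`.
#' @param params [energy_params()].
#' @param b0 Optional precomputed equilibrium lengths.
#' @return Energy in kcal/mol.
#' @export
bond_potential <- function(conf, params = energy_params(), b0 = NULL) {
  if (is.null(b0)) b0 <- .topology_b0(conf$topology)
  bm <- conf$topology$bonds
  d <- conf$coords[bm[, 1], , drop = FALSE] - conf$coords[bm[, 2], , drop = FALSE]
  b <- sqrt(rowSums(d^2))
  sum(params$k_bond * (b - b0)^2)
}

#' Detect nonphysical geometry
#'
#' Reports overlapping bonds (two bond segments, sharing no atom and not
#' joined by one, closer than `overlap_tol`) and ring piercings (a bond
#' segment intersecting the fan-triangulated surface of another residue's
#' ring hexagon).
#'
#' @param conf A `gag_conformation`.
#' @param overlap_tol Segment-segment distance threshold, A.
#' @return List with `overlaps` (two-column matrix of bond row indices),
#'   `piercings` (data frame: bond row, pierced residue), and the flag
#'   `nonphysical`.
#' @export
detect_nonphysical <- function(conf, overlap_tol = 0.5) {
  topo <- conf$topology
  res_of <- topo$atoms$res_idx
  out <- .detect_nonphysical(conf$coords, topo$bonds, topo$ring_idx,
                             as.integer(res_of), overlap_tol)
  piercings <- data.frame(bond = out$pierce_bond,
                          residue = out$pierce_residue)
  list(overlaps = out$overlap_bonds, piercings = piercings,
       nonphysical = nrow(out$overlap_bonds) > 0 || nrow(piercings) > 0)
}

#' Restrained energy minimization
#'
#' Minimizes bonds + angle/torsion restraints + soft-core repulsion with
#' L-BFGS-B, holding every placement-plan angle and torsion at its
#' constructed value. Non-convergence is reported via the `converged`
#' flag, not an error.
#'
#' @param conf A `gag_conformation` (must carry its placement plan).
#' @param params [energy_params()].
#' @param excl Optional precomputed exclusion keys.
#' @param b0 Optional precomputed equilibrium bond lengths.
#' @return A `gag_minimization` list: `conf` (minimized), `pre_bond_pe`,
#'   `post_bond_pe`, `post_total_pe`, `converged`, `iterations`,
#'   `max_dihedral_drift` (degrees).
#' @export
minimize_restrained <- function(conf, params = energy_params(),
                                excl = NULL, b0 = NULL) {
  topo <- conf$topology
  if (is.null(excl)) excl <- .exclusion_keys(topo)
  if (is.null(b0)) b0 <- .topology_b0(topo)
  rs <- .plan_restraints(conf$plan)
  bm <- topo$bonds
  storage.mode(bm) <- "integer"
  am <- rs$angles; storage.mode(am) <- "integer"
  tm <- rs$tors; storage.mode(tm) <- "integer"
  x0 <- as.numeric(t(conf$coords))
  fn <- function(x) {
    .gag_energy(x, bm, b0, params$k_bond, am, rs$th0, params$k_angle,
                tm, rs$ph0, params$k_torsion, excl, params$epsilon,
                params$r_min, FALSE)$energy
  }
  gr <- function(x) {
    .gag_energy(x, bm, b0, params$k_bond, am, rs$th0, params$k_angle,
                tm, rs$ph0, params$k_torsion, excl, params$epsilon,
                params$r_min, TRUE)$grad
  }
  pre <- bond_potential(conf, params, b0)
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = params$max_iter,
                                     pgtol = params$pgtol,
                                     factr = params$factr))
  co <- matrix(opt$par, ncol = 3, byrow = TRUE)
  rownames(co) <- rownames(conf$coords)
  out_conf <- conf
  out_conf$coords <- co
  post <- bond_potential(out_conf, params, b0)
  fin <- .gag_energy(opt$par, bm, b0, params$k_bond, am, rs$th0,
                     params$k_angle, tm, rs$ph0, params$k_torsion, excl,
                     params$epsilon, params$r_min, FALSE)
  ## dihedral drift against the constructed values
  drift <- 0
  for (r in seq_len(nrow(tm))) {
    d <- dihedral(co[tm[r, 1], ], co[tm[r, 2], ], co[tm[r, 3], ],
                  co[tm[r, 4], ])
    drift <- max(drift, abs(.wrap180(d - rs$ph0[r] * 180 / pi)))
  }
  ## converged means the final point is stationary (small gradient; the
  ## L-BFGS-B line search can terminate with a warning status at an
  ## essentially converged point, so the gradient is checked directly)
  ## AND the restraints held the conformation (every torsion within 5 deg
  ## of its constructed value); heavily strained (nonphysical) members
  ## typically fail the second part
  g_inf <- max(abs(gr(opt$par)))
  structure(list(conf = out_conf, pre_bond_pe = pre, post_bond_pe = post,
                 post_total_pe = fin$energy,
                 energy_terms = fin[c("bond", "angle", "torsion",
                                      "repulsion")],
                 converged = (opt$convergence == 0 || g_inf <= 50) &&
                   drift <= 5,
                 optim_status = opt$convergence,
                 final_grad = g_inf,
                 iterations = opt$counts[["function"]],
                 max_dihedral_drift = drift),
            class = "gag_minimization")
}

#' Exclusion cutoff from the fully-extended reference
#'
#' The cutoff is the post-minimization bond potential energy of the
#' fully-extended reference conformation plus a 100 kcal/mol buffer.
#'
#' @param spec A [polymer_spec()] or `gag_topology`.
#' @param db A `conformer_db`.
#' @param params [energy_params()].
#' @param buffer Buffer energy, kcal/mol.
#' @return List of class `gag_cutoff`: `reference` (post-minimization bond
#'   PE of the extended reference), `buffer`, `cutoff`, and the minimized
#'   reference conformation.
#' @export
compute_cutoff <- function(spec, db, params = energy_params(),
                           buffer = 100) {
  ref <- build_extended_reference(spec, db)
  mr <- minimize_restrained(ref, params)
  structure(list(reference = mr$post_bond_pe, buffer = buffer,
                 cutoff = mr$post_bond_pe + buffer,
                 reference_conf = mr$conf,
                 dihedrals = attr(ref, "dihedrals")),
            class = "gag_cutoff")
}

#' Plant a ring-piercing defect in a built conformation
#'
#' Scans glycosidic dihedrals of mid-chain junctions over a grid of
#' replacement values and returns the first variant whose geometry the
#' nonphysical detector confirms as a ring piercing. The placement plan is
#' edited consistently, so minimization restrains the planted torsion at
#' its defective value -- reproducing how an unlucky independent draw
#' threads a bond through a ring.
#'
#' @param conf A `gag_conformation` from [build_chain()].
#' @param junctions Junction indices to scan (default: the middle half).
#' @param grid Replacement torsion values to try, degrees.
#' @return The defective `gag_conformation` (attributes `"planted_row"`,
#'   `"planted_value"`, `"n_piercings"`), or `NULL` if the scan finds none.
#' @export
plant_ring_piercing <- function(conf, junctions = NULL,
                                grid = seq(-175, 180, by = 5)) {
  topo <- conf$topology
  lk <- topo$linkages
  nj <- nrow(lk)
  if (is.null(junctions)) {
    junctions <- seq(max(1L, nj %/% 4), min(nj, 3L * (nj %/% 4)))
  }
  plan <- conf$plan
  ## distance from the piercing bond's segment to the pierced ring's
  ## centroid: a centrally threaded bond (the nonphysical geometry the
  ## screen targets) passes near the centroid, while an edge graze can
  ## slip out during minimization
  seg_centroid_dist <- function(co, det) {
    min(vapply(seq_len(nrow(det$piercings)), function(k) {
      b <- topo$bonds[det$piercings$bond[k], ]
      cen <- colMeans(co[topo$ring_idx[det$piercings$residue[k], ], ])
      p <- co[b[1], ]; q <- co[b[2], ]
      u <- q - p
      t <- sum((cen - p) * u) / sum(u * u)
      t <- min(1, max(0, t))
      sqrt(sum((p + t * u - cen)^2))
    }, numeric(1)))
  }
  best <- NULL
  best_d <- Inf
  for (j in junctions) {
    for (rw in c(which(plan$idx == lk$cn[j]), which(plan$idx == lk$cprev[j]))) {
      for (v in grid) {
        p2 <- plan
        p2$torsion[rw] <- v
        co <- .nerf_realize(p2$idx, p2$a, p2$b, p2$c, p2$bond, p2$angle,
                            p2$torsion, nrow(topo$atoms))
        rownames(co) <- rownames(conf$coords)
        c2 <- conf
        c2$coords <- co
        c2$plan <- p2
        det <- detect_nonphysical(c2)
        if (nrow(det$piercings) > 0) {
          d <- seg_centroid_dist(co, det)
          if (d < best_d) {
            best_d <- d
            attr(c2, "planted_row") <- rw
            attr(c2, "planted_value") <- v
            attr(c2, "n_piercings") <- nrow(det$piercings)
            attr(c2, "centroid_dist") <- d
            best <- c2
          }
        }
      }
    }
  }
  best
}
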