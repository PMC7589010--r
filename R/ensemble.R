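## Fast chain assembly and ensemble generation. Per-conformer placement
## values are derived once per database row and cached (environments are
## reference objects, so the cache survives copies of the db), after which
## assembling a chain is pure indexing plus one compiled NeRF pass.

.db_cache <- function(db) {
  if (is.null(db$cache)) stop("conformer_db has no cache environment")
  db$cache
}

## placement-value table for one residue role:
##   "nre"  -- nonreducing-end residue 1 (canonical plan, no O1)
##   "accN" -- interior acceptor entered at Cn (no O1)
##   "redN" -- reducing-end acceptor (keeps O1)
.residue_role_table <- function(db, type, role) {
  key <- paste0(type, ":", role)
  cache <- .db_cache(db)
  if (!is.null(cache[[key]])) return(cache[[key]])
  pool <- db$rings[[type]]
  if (is.null(pool)) stop("db missing ring pool: ", type)
  pnames <- .ring_param_names(type)
  pm <- as.matrix(pool[, pnames])
  npool <- nrow(pm)
  tpl <- residue_template(type)
  if (role == "nre") {
    plan <- .res_plan_names(type)
    keep <- plan$atom != "O1"
    plan <- plan[keep, ]
    nr <- nrow(plan)
    B <- matrix(NA_real_, npool, nr)
    A <- matrix(NA_real_, npool, nr)
    T <- matrix(NA_real_, npool, nr)
    ## canonical plan values map directly onto the stored parameter vector
    colmap <- function(prefix, atom) match(paste0(prefix, atom), pnames)
    for (r in seq_len(nr)) {
      at <- plan$atom[r]
      if (r == 1) next
      B[, r] <- pm[, colmap("b_", at)]
      if (r >= 3) A[, r] <- pm[, colmap("a_", at)]
      if (r >= 4) T[, r] <- pm[, colmap("t_", at)]
    }
    entry <- list(frame = plan[, c("atom", "a", "b", "c")],
                  B = B, A = A, T = T)
    cache[[key]] <- entry
    return(entry)
  }
  npos <- as.integer(sub("^(acc|red)", "", role))
  reducing <- startsWith(role, "red")
  o_name <- paste0("O", npos)
  trav <- if (npos == 4L) c("C4", "C3", "C2", "C1", "O5", "C5")
          else c("C3", "C2", "C1", "O5", "C5", "C4")
  pla <- .res_plan_names(type)
  sub_rows <- which(seq_len(nrow(pla)) >= 7 & pla$atom != o_name &
                    (reducing | pla$atom != "O1"))
  frame <- rbind(
    data.frame(atom = trav[3], a = o_name, b = trav[1], c = trav[2]),
    data.frame(atom = trav[4], a = trav[1], b = trav[2], c = trav[3]),
    data.frame(atom = trav[5], a = trav[2], b = trav[3], c = trav[4]),
    data.frame(atom = trav[6], a = trav[3], b = trav[4], c = trav[5]),
    pla[sub_rows, c("atom", "a", "b", "c")]
  )
  nr <- nrow(frame)
  B <- matrix(NA_real_, npool, nr)
  A <- matrix(NA_real_, npool, nr)
  T <- matrix(NA_real_, npool, nr)
  cn_cm1 <- numeric(npool)
  for (p in seq_len(npool)) {
    loc <- realize_ring_conformer(type, pm[p, ])
    cn_cm1[p] <- atom_distance(loc[trav[1], ], loc[trav[2], ])
    for (r in seq_len(nr)) {
      at <- frame$atom[r]
      B[p, r] <- atom_distance(loc[frame$c[r], ], loc[at, ])
      A[p, r] <- bond_angle(loc[frame$b[r], ], loc[frame$c[r], ], loc[at, ])
      T[p, r] <- dihedral(loc[frame$a[r], ], loc[frame$b[r], ],
                          loc[frame$c[r], ], loc[at, ])
    }
  }
  entry <- list(frame = frame, B = B, A = A, T = T, cn_cm1 = cn_cm1)
  cache[[key]] <- entry
  entry
}

## assemble a chain from pool row indices; returns coords + plan vectors
.fast_build <- function(topology, db, ring_rows, link_rows) {
  sp <- topology$spec
  n <- sp$n_residues
  atoms <- topology$atoms
  n_atoms <- nrow(atoms)
  lk <- topology$linkages
  ## residue atom-name -> global index maps
  rmap <- lapply(seq_len(n), function(i) {
    ii <- topology$residues[[i]]
    stats::setNames(ii, atoms$name[ii])
  })
  roles <- c("nre",
             vapply(seq_len(n - 1L), function(j) {
               paste0(if (j == n - 1L) "red" else "acc", lk$acceptor_pos[j])
             }, character(1)))
  tables <- lapply(seq_len(n), function(i) {
    .residue_role_table(db, sp$residue_types[i], roles[i])
  })
  n_rows <- sum(vapply(tables, function(e) nrow(e$frame), integer(1))) +
    3L * (n - 1L)
  idx <- a <- b <- cc <- integer(n_rows)
  bond <- angle <- torsion <- rep(NA_real_, n_rows)
  pos <- 0L
  ## residue 1
  e1 <- tables[[1]]
  m1 <- rmap[[1]]
  r1 <- nrow(e1$frame)
  seq1 <- pos + seq_len(r1)
  idx[seq1] <- m1[e1$frame$atom]
  a[seq1] <- ifelse(is.na(e1$frame$a), NA_integer_, m1[e1$frame$a])
  b[seq1] <- ifelse(is.na(e1$frame$b), NA_integer_, m1[e1$frame$b])
  cc[seq1] <- ifelse(is.na(e1$frame$c), NA_integer_, m1[e1$frame$c])
  bond[seq1] <- e1$B[ring_rows[1], ]
  angle[seq1] <- e1$A[ring_rows[1], ]
  torsion[seq1] <- e1$T[ring_rows[1], ]
  pos <- pos + r1
  for (j in seq_len(n - 1L)) {
    i <- j + 1L
    type <- sp$linkage_types[j]
    lrow <- link_rows[j]
    cache <- .db_cache(db)
    lp <- cache[[paste0("linkmat:", type)]]
    if (is.null(lp)) {
      lp <- as.matrix(db$linkages[[type]][, .LINK_PARAM_NAMES])
      cache[[paste0("linkmat:", type)]] <- lp
    }
    ei <- tables[[i]]
    mi <- rmap[[i]]
    ## junction rows: O_g, Cn (phi), C(n-1) (psi)
    idx[pos + 1L] <- lk$o[j]
    a[pos + 1L] <- lk$c5[j]; b[pos + 1L] <- lk$o5[j]; cc[pos + 1L] <- lk$c1[j]
    bond[pos + 1L] <- lp[lrow, "c1_o"]
    angle[pos + 1L] <- lp[lrow, "o5_c1_o"]
    torsion[pos + 1L] <- lp[lrow, "tau_o"]
    idx[pos + 2L] <- lk$cn[j]
    a[pos + 2L] <- lk$o5[j]; b[pos + 2L] <- lk$c1[j]; cc[pos + 2L] <- lk$o[j]
    bond[pos + 2L] <- lp[lrow, "o_cn"]
    angle[pos + 2L] <- lp[lrow, "c1_o_cn"]
    torsion[pos + 2L] <- lp[lrow, "phi"]
    idx[pos + 3L] <- lk$cprev[j]
    a[pos + 3L] <- lk$c1[j]; b[pos + 3L] <- lk$o[j]; cc[pos + 3L] <- lk$cn[j]
    bond[pos + 3L] <- ei$cn_cm1[ring_rows[i]]
    angle[pos + 3L] <- lp[lrow, "o_cn_cprev"]
    torsion[pos + 3L] <- lp[lrow, "psi"]
    pos <- pos + 3L
    ri <- nrow(ei$frame)
    sq <- pos + seq_len(ri)
    idx[sq] <- mi[ei$frame$atom]
    a[sq] <- mi[ei$frame$a]
    b[sq] <- mi[ei$frame$b]
    cc[sq] <- mi[ei$frame$c]
    bond[sq] <- ei$B[ring_rows[i], ]
    angle[sq] <- ei$A[ring_rows[i], ]
    torsion[sq] <- ei$T[ring_rows[i], ]
    pos <- pos + ri
  }
  coords <- .nerf_realize(idx, a, b, cc, bond, angle, torsion, n_atoms)
  rownames(coords) <- atoms$name
  plan <- data.frame(idx = idx, a = a, b = b, c = cc,
                     bond = bond, angle = angle, torsion = torsion)
  list(coords = coords, plan = plan)
}

#' Generate a screened conformational ensemble
#'
#' Builds conformations by independent sampling from the database,
#' minimizes each under dihedral restraints, and retains those whose
#' post-minimization bond potential energy does not exceed the cutoff
#' (the extended-reference energy plus a 100 kcal/mol buffer). Excluded
#' conformations are replaced until `N` are retained. Fully deterministic
#' for a given seed: each build attempt uses its own counter-derived RNG
#' substream, so the retained set does not depend on iteration details.
#'
#' @param spec A [polymer_spec()] or `gag_topology`.
#' @param db A `conformer_db`.
#' @param N Number of retained conformations.
#' @param seed Master seed (integer).
#' @param params [energy_params()].
#' @param cutoff A `gag_cutoff` from [compute_cutoff()]; computed from the
#'   db if missing.
#' @param keep_coords Keep minimized coordinates of retained members
#'   (memory-heavy for long polymers).
#' @param min_retention Abort threshold: stop if the retention rate falls
#'   below this after 200 attempts.
#' @return A `gag_ensemble`: `members` (data frame: `attempt`, `e2e`, `rg`,
#'   `pre_pe`, `post_pe`, `converged`), feature matrices `phi`, `psi`
#'   (members x junctions), `pucker_label` (members x residues), the
#'   `cutoff`, excluded-member energies, and counts.
#' @export
generate_ensemble <- function(spec, db, N, seed, params = energy_params(),
                              cutoff = NULL, keep_coords = FALSE,
                              min_retention = 0.01) {
  topology <- if (inherits(spec, "gag_topology")) spec else build_topology(spec)
  sp <- topology$spec
  if (is.null(cutoff)) cutoff <- compute_cutoff(topology, db, params)
  excl <- .exclusion_keys(topology)
  b0 <- .topology_b0(topology)
  n <- sp$n_residues
  pool_sizes_r <- vapply(sp$residue_types, function(t) nrow(db$rings[[t]]),
                         integer(1))
  pool_sizes_l <- vapply(sp$linkage_types, function(t) nrow(db$linkages[[t]]),
                         integer(1))
  members <- vector("list", N)
  phi <- psi <- matrix(NA_real_, N, n - 1L)
  pucker_label <- matrix(NA_character_, N, n)
  coords_list <- if (keep_coords) vector("list", N) else NULL
  excluded_pe <- numeric(0)
  retained <- 0L
  attempt <- 0L
  while (retained < N) {
    attempt <- attempt + 1L
    if (attempt >= 200L && retained / attempt < min_retention) {
      stop("generate_ensemble: retention rate ", round(retained / attempt, 4),
           " after ", attempt, " attempts (cutoff = ",
           round(cutoff$cutoff, 1), " kcal/mol); check database and cutoff")
    }
    set.seed((seed * 1000003 + attempt) %% 2147483647)
    ring_rows <- vapply(seq_len(n), function(i) {
      sample.int(pool_sizes_r[i], 1L)
    }, integer(1))
    link_rows <- vapply(seq_len(n - 1L), function(j) {
      sample.int(pool_sizes_l[j], 1L)
    }, integer(1))
    built <- .fast_build(topology, db, ring_rows, link_rows)
    conf <- .new_conformation(topology, built$coords, built$plan,
                              provenance = list(attempt = attempt,
                                                ring_rows = ring_rows,
                                                link_rows = link_rows))
    mr <- minimize_restrained(conf, params, excl = excl, b0 = b0)
    if (mr$post_bond_pe > cutoff$cutoff) {
      excluded_pe <- c(excluded_pe, mr$post_bond_pe)
      next
    }
    retained <- retained + 1L
    mc <- mr$conf
    dihs <- linkage_dihedrals(mc)
    phi[retained, ] <- dihs$phi
    psi[retained, ] <- dihs$psi
    for (i in seq_len(n)) {
      pucker_label[retained, i] <-
        classify_pucker(mc$coords[topology$ring_idx[i, ], ])$label
    }
    members[[retained]] <- data.frame(
      attempt = attempt, e2e = end_to_end(mc), rg = radius_of_gyration(mc),
      pre_pe = mr$pre_bond_pe, post_pe = mr$post_bond_pe,
      converged = mr$converged)
    if (keep_coords) coords_list[[retained]] <- mc$coords
  }
  structure(list(topology = topology,
                 members = do.call(rbind, members),
                 phi = phi, psi = psi, pucker_label = pucker_label,
                 cutoff = cutoff, excluded_pe = excluded_pe,
                 n_attempts = attempt, seed = seed,
                 coords = coords_list),
            class = "gag_ensemble")
}

#' @export
print.gag_ensemble <- function(x, ...) {
  cat("GAG ensemble:", x$topology$spec$gag_type, "-",
      x$topology$spec$n_residues, "residues,", nrow(x$members),
      "retained /", x$n_attempts, "attempts\n")
  cat("  cutoff:", round(x$cutoff$cutoff, 1), "kcal/mol; excluded:",
      length(x$excluded_pe), "\n")
  cat("  e2e:", round(stats::median(x$members$e2e), 1), "A (median)  Rg:",
      round(stats::median(x$members$rg), 1), "A (median)\n")
  invisible(x)
}
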