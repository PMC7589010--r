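## Synthetic conformer databases. Linkage (phi, psi) values are drawn from
## mixtures of wrapped-Gaussian basins whose centers and relative free
## energies reproduce the published MD free-energy minima of each GAG
## type; basin weights are Boltzmann factors exp(-dG/RT) at 310 K. Ring
## conformers are drawn from a mixture over canonical pucker labels (the
## observed chair/boat/skew-boat proportions), realized through the
## inverse Cremer-Pople transform with Gaussian jitter on the puckering
## coordinates and on bond lengths and angles. Snapshots are i.i.d. by
## construction, matching the independence hypothesis the construction
## algorithm relies on.

.T_BODY <- 310  # K

#' Default basin and pucker specifications for a GAG type
#'
#' Returns the glycosidic free-energy basin list (center, relative dG,
#' angular spread) and the ring pucker mixtures used by [generate_db()].
#' Basin centers and dG values are the published MD 20-mer free-energy
#' minima; pucker proportions follow the reported chair/skew fractions
#' where printed (heparan IdoA ~54% 1C4 / ~25% 2SO / ~4% 4C1), and
#' documented defaults elsewhere (N-acetyl sugars and Gal >= 99.5% 4C1,
#' with the named rare boat/skew forms sharing the remainder; dermatan
#' IdoA 0.55/0.30/0.09 with 0.06 spread over other equator forms).
#' Basin spread defaults to 15 degrees.
#'
#' @param gag_type One of [gag_types()].
#' @return List with `basins` (linkage type -> data frame `phi`, `psi`,
#'   `dG`, `sigma`) and `pucker_mixes` (residue type -> data frame
#'   `label`, `prob`).
#' @export
default_specs <- function(gag_type) {
  gag_type <- match.arg(gag_type, gag_types())
  ## basin spread: the published contour plots reach ~3 kcal/mol at
  ## 30-40 degrees from each minimum; a quadratic well crossing 3 kcal/mol
  ## at ~35 degrees corresponds to a Gaussian spread of ~11 degrees at
  ## 310 K, which is the default here
  basin <- function(...) {
    m <- rbind(...)
    data.frame(phi = m[, 1], psi = m[, 2], dG = m[, 3], sigma = 11)
  }
  mix <- function(labels, probs) data.frame(label = labels, prob = probs)
  rare <- function(main, labels, rest = 0.005) {
    mix(c(main, labels), c(1 - rest, rep(rest / length(labels),
                                         length(labels))))
  }
  switch(gag_type,
    hyaluronan = list(
      basins = list(
        "GlcAb1-3GlcNAc" = basin(c(-71.25, -123.75, 0.00),
                                 c(-53.75, 91.25, 3.06)),
        "GlcNAcb1-4GlcA" = basin(c(-68.75, 116.25, 0.00),
                                 c(-83.75, -73.75, 1.31),
                                 c(-58.75, -33.75, 1.42))
      ),
      pucker_mixes = list(
        GlcA = rare("4C1", c("3S1", "B1,4", "5S1", "2,5B", "2SO",
                             "1S3", "1,4B", "1S5")),
        GlcNAcb = rare("4C1", c("B3,O", "1S3", "1,4B", "1S5"))
      )
    ),
    dermatan = list(
      basins = list(
        "IdoAa1-3GalNAc" = basin(c(-66.25, -123.75, 0.00)),
        "GalNAcb1-4IdoA" = basin(c(-61.25, 106.25, 0.00))
      ),
      pucker_mixes = list(
        IdoA = mix(c("1C4", "2SO", "4C1",
                     "B1,4", "5S1", "2,5B", "B3,O", "1S3", "1,4B", "1S5"),
                   c(0.55, 0.30, 0.09, rep(0.06 / 7, 7))),
        GalNAcb = rare("4C1", c("1S3", "1,4B", "1S5", "B2,5"))
      )
    ),
    keratan = list(
      basins = list(
        "Galb1-4GlcNAc" = basin(c(-73.75, 116.25, 0.00),
                                c(-56.25, -31.25, 1.75)),
        "GlcNAcb1-3Gal" = basin(c(-81.25, -156.25, 0.00))
      ),
      pucker_mixes = list(
        Gal = mix("4C1", 1),
        GlcNAcb = rare("4C1", c("2SO", "1S3", "1,4B", "1S5"))
      )
    ),
    heparan = list(
      basins = list(
        "IdoAa1-4GlcNAc" = basin(c(-73.75, 128.75, 0.00),
                                 c(-103.75, -68.75, 3.13),
                                 c(-66.25, -31.25, 3.38)),
        "GlcNAca1-4IdoA" = basin(c(76.25, 88.75, 0.00))
      ),
      pucker_mixes = list(
        IdoA = mix(c("1C4", "2SO", "4C1",
                     "B1,4", "5S1", "2,5B", "B3,O", "1S3", "1,4B", "1S5"),
                   c(0.54, 0.25, 0.04, rep(0.17 / 7, 7))),
        GlcNAca = mix("4C1", 1)
      )
    )
  )
}

#' Geometry jitter defaults for synthetic conformers
#'
#' @param bond_sd Bond length jitter, A.
#' @param angle_sd Bond angle jitter, degrees.
#' @param torsion_sd Exocyclic torsion jitter, degrees.
#' @param Q_sd,theta_sd,phi_sd Cremer-Pople jitter (A, degrees, degrees).
#' @return Named list.
#' @export
geometry_jitter <- function(bond_sd = 0.02, angle_sd = 2, torsion_sd = 3,
                            Q_sd = 0.02, theta_sd = 6, phi_sd = 8) {
  list(bond_sd = bond_sd, angle_sd = angle_sd, torsion_sd = torsion_sd,
       Q_sd = Q_sd, theta_sd = theta_sd, phi_sd = phi_sd)
}

## draw (phi, psi) from a wrapped-Gaussian basin mixture with Boltzmann
## weights exp(-dG/RT); uses the current RNG stream
.draw_phipsi <- function(basins, n, T = .T_BODY) {
  RT <- .R_KCAL * T
  w <- exp(-basins$dG / RT)
  bsel <- sample.int(nrow(basins), n, replace = TRUE, prob = w)
  data.frame(
    phi = .wrap180(basins$phi[bsel] + stats::rnorm(n, 0, basins$sigma[bsel])),
    psi = .wrap180(basins$psi[bsel] + stats::rnorm(n, 0, basins$sigma[bsel])),
    basin = bsel)
}

## reflect theta into [0, 180]
.reflect_theta <- function(th) {
  th <- abs(th)
  th <- th %% 360
  ifelse(th > 180, 360 - th, th)
}

#' Generate a synthetic conformer database
#'
#' @param gag_type One of [gag_types()].
#' @param n_per_pool Conformers per ring and linkage pool.
#' @param seed Integer seed; the database is fully seed-deterministic.
#' @param basins,pucker_mixes Overrides for [default_specs()] components.
#' @param jitter A [geometry_jitter()] list.
#' @param T Temperature for Boltzmann basin weights, K.
#' @return A `conformer_db`.
#' @export
generate_db <- function(gag_type, n_per_pool = 2000, seed = 1,
                        basins = NULL, pucker_mixes = NULL,
                        jitter = geometry_jitter(), T = .T_BODY) {
  specs <- default_specs(gag_type)
  if (!is.null(basins)) specs$basins <- basins
  if (!is.null(pucker_mixes)) specs$pucker_mixes <- pucker_mixes
  for (b in specs$basins) {
    stopifnot(all(b$dG >= 0), all(b$sigma > 0))
  }
  for (m in specs$pucker_mixes) {
    if (any(m$prob < 0) || abs(sum(m$prob) - 1) > 1e-9) {
      stop("generate_db: pucker probabilities must be >= 0 and sum to 1")
    }
  }
  set.seed(seed)
  sp <- polymer_spec(gag_type, 3)  # covers both linkage types of the repeat
  rings <- list()
  for (type in names(specs$pucker_mixes)) {
    mixdf <- specs$pucker_mixes[[type]]
    tpl <- residue_template(type)
    pnames <- .ring_param_names(type)
    rows <- matrix(NA_real_, n_per_pool, length(pnames) + 3)
    labs <- character(n_per_pool)
    draw <- sample.int(nrow(mixdf), n_per_pool, replace = TRUE,
                       prob = mixdf$prob)
    plan_n <- nrow(tpl$plan)
    for (s in seq_len(n_per_pool)) {
      v <- pucker_vertex(mixdf$label[draw[s]])
      Q <- abs(.RING_Q_REF + stats::rnorm(1, 0, jitter$Q_sd))
      th <- .reflect_theta(v$theta + stats::rnorm(1, 0, jitter$theta_sd))
      ph <- (v$phi + stats::rnorm(1, 0, jitter$phi_sd)) %% 360
      mb <- .RING_MEAN_BOND + stats::rnorm(1, 0, jitter$bond_sd / sqrt(6))
      loc <- .realize_residue(type, tpl$subst, Q = Q, theta = th, phi = ph,
                              mean_bond = mb)
      plan_idx <- .params_to_plan(type, rep(NA_real_, 3 * plan_n - 9))
      plan_idx <- measure_plan(loc, plan_idx)
      ## jitter the exocyclic internal coordinates (leaf atoms only, so
      ## ring closure is untouched)
      for (r in 7:plan_n) {
        plan_idx$bond[r] <- plan_idx$bond[r] +
          stats::rnorm(1, 0, jitter$bond_sd)
        plan_idx$angle[r] <- plan_idx$angle[r] +
          stats::rnorm(1, 0, jitter$angle_sd)
        plan_idx$torsion[r] <- .wrap180(plan_idx$torsion[r] +
                                          stats::rnorm(1, 0,
                                                       jitter$torsion_sd))
      }
      ring <- realize_plan(plan_idx, length(tpl$atoms))[seq_len(6), ]
      cp <- cremer_pople(ring)
      rows[s, ] <- c(.plan_to_params(plan_idx), cp$Q, cp$theta, cp$phi)
      labs[s] <- classify_pucker(cp)$label
    }
    df <- as.data.frame(rows)
    names(df) <- c(pnames, "Q", "theta", "phi")
    df$label <- labs
    df$source <- paste0("synthetic:", seed, ":", seq_len(n_per_pool))
    rings[[type]] <- df
  }
  links <- list()
  RT <- .R_KCAL * T
  for (type in names(specs$basins)) {
    bdf <- specs$basins[[type]]
    la <- .link_donor_acceptor(type)
    j <- match(type, sp$linkage_types)
    if (is.na(j)) stop("generate_db: linkage type not in repeat: ", type)
    donor <- sp$residue_types[j]
    acceptor <- sp$residue_types[j + 1L]
    defaults <- .default_linkage_params(type, donor, acceptor, la$pos)
    pp <- .draw_phipsi(bdf, n_per_pool, T)
    phi <- pp$phi
    psi <- pp$psi
    df <- data.frame(
      c1_o = defaults[["c1_o"]] + stats::rnorm(n_per_pool, 0, jitter$bond_sd),
      o_cn = defaults[["o_cn"]] + stats::rnorm(n_per_pool, 0, jitter$bond_sd),
      o5_c1_o = defaults[["o5_c1_o"]] +
        stats::rnorm(n_per_pool, 0, jitter$angle_sd),
      c1_o_cn = defaults[["c1_o_cn"]] +
        stats::rnorm(n_per_pool, 0, jitter$angle_sd),
      phi = phi, psi = psi,
      tau_o = .wrap180(defaults[["tau_o"]] +
                         stats::rnorm(n_per_pool, 0, jitter$torsion_sd)),
      o_cn_cprev = defaults[["o_cn_cprev"]] +
        stats::rnorm(n_per_pool, 0, jitter$angle_sd)
    )
    df$source <- paste0("synthetic:", seed, ":", seq_len(n_per_pool))
    links[[type]] <- df
  }
  conformer_db(rings, links,
               meta = list(gag_type = gag_type, source = "synthetic",
                           seed = seed, T = T))
}
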