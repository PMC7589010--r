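## Conformer database: per-residue-type pools of ring conformers and
## per-linkage-type pools of linkage conformers, extracted from coordinate
## ensembles or generated synthetically. Pools are stored as data frames
## (one conformer per row) for fast uniform sampling.
##
## A ring conformer records the internal coordinates of the canonical
## residue placement plan (ring spanning tree + all exocyclic heavy atoms,
## including the anomeric- and acceptor-position oxygen directions, which
## double as linkage attachment geometry) plus cached Cremer-Pople
## parameters. A linkage conformer records the six glycosidic parameters
## (C1-O and O-Cn lengths, O5-C1-O and C1-O-Cn angles, phi, psi) plus the
## two auxiliary junction coordinates needed for Cartesian reconstruction:
## the torsion C5-O5-C1-O placing the glycosidic O about C1, and the angle
## O-Cn-C(n-1) opening the acceptor ring off the linkage O.

.ring_param_names <- function(type) {
  plan <- .res_plan_names(type)
  nm <- c(paste0("b_", plan$atom[2]), paste0("b_", plan$atom[3]),
          paste0("a_", plan$atom[3]))
  for (r in 4:nrow(plan)) {
    nm <- c(nm, paste0(c("b_", "a_", "t_"), plan$atom[r]))
  }
  nm
}

.plan_to_params <- function(plan) {
  v <- c(plan$bond[2], plan$bond[3], plan$angle[3])
  for (r in 4:nrow(plan)) v <- c(v, plan$bond[r], plan$angle[r], plan$torsion[r])
  v
}

.params_to_plan <- function(type, params) {
  tpl <- residue_template(type)
  plan <- tpl$plan
  plan_idx <- data.frame(idx = match(plan$atom, tpl$atoms),
                         a = match(plan$a, tpl$atoms),
                         b = match(plan$b, tpl$atoms),
                         c = match(plan$c, tpl$atoms),
                         bond = NA_real_, angle = NA_real_,
                         torsion = NA_real_)
  plan_idx$bond[2] <- params[1]
  plan_idx$bond[3] <- params[2]
  plan_idx$angle[3] <- params[3]
  k <- 4
  for (r in 4:nrow(plan)) {
    plan_idx$bond[r] <- params[k]
    plan_idx$angle[r] <- params[k + 1]
    plan_idx$torsion[r] <- params[k + 2]
    k <- k + 3
  }
  plan_idx
}

#' Realize a ring conformer's local-frame coordinates
#'
#' @param type Residue type.
#' @param params Named numeric vector of plan internal coordinates
#'   (one row of a ring pool).
#' @return Coordinate matrix with atom-name rownames (full residue,
#'   including O1).
#' @export
realize_ring_conformer <- function(type, params) {
  tpl <- residue_template(type)
  plan_idx <- .params_to_plan(type, as.numeric(params))
  coords <- realize_plan(plan_idx, length(tpl$atoms))
  rownames(coords) <- tpl$atoms
  coords
}

.LINK_PARAM_NAMES <- c("c1_o", "o_cn", "o5_c1_o", "c1_o_cn",
                       "phi", "psi", "tau_o", "o_cn_cprev")

#' Extract ring and linkage conformers from a coordinate ensemble
#'
#' Measures, for every conformation, the internal coordinates of each
#' monosaccharide ring (with exocyclic heavy atoms) and of each glycosidic
#' junction, pooled by residue type and linkage type.
#'
#' @param ensemble A list of `gag_conformation` objects, or of coordinate
#'   matrices sharing `topology`.
#' @param topology A `gag_topology`; taken from the first conformation if
#'   missing.
#' @param source Character tag recorded with each conformer.
#' @return A `conformer_db` object.
#' @export
extract_conformers <- function(ensemble, topology = NULL, source = "extracted") {
  if (length(ensemble) == 0) stop("extract_conformers: empty ensemble")
  if (inherits(ensemble[[1]], "gag_conformation") && is.null(topology)) {
    topology <- ensemble[[1]]$topology
  }
  stopifnot(inherits(topology, "gag_topology"))
  n_res <- topology$spec$n_residues
  rings <- list(); links <- list()
  for (s in seq_along(ensemble)) {
    co <- ensemble[[s]]
    if (inherits(co, "gag_conformation")) co <- co$coords
    if (nrow(co) != nrow(topology$atoms)) {
      stop("extract_conformers: conformation ", s,
           " has ", nrow(co), " atoms, topology has ", nrow(topology$atoms))
    }
    for (i in seq_len(n_res)) {
      type <- topology$spec$residue_types[i]
      tpl <- residue_template(type)
      ii <- topology$residues[[i]]
      local <- matrix(NA_real_, length(tpl$atoms), 3,
                      dimnames = list(tpl$atoms, NULL))
      local[topology$atoms$name[ii], ] <- co[ii, ]
      if (!"O1" %in% topology$atoms$name[ii]) {
        ## donor residue: anomeric O direction filled from the template so
        ## the conformer is complete for terminal reuse
        seg <- match(c("C5", "O5", "C1"), tpl$atoms)
        prow <- which(tpl$plan$atom == "O1")
        local["O1", ] <- place_atom(local["C5", ], local["O5", ], local["C1", ],
                                    tpl$plan$bond[prow], tpl$plan$angle[prow],
                                    tpl$plan$torsion[prow])
      }
      plan_idx <- .params_to_plan(type, rep(NA_real_, 3 * nrow(tpl$plan) - 9))
      plan_idx <- measure_plan(local, plan_idx)
      cp <- cremer_pople(local[.RING_ATOMS, ])
      lab <- classify_pucker(cp)
      row <- c(.plan_to_params(plan_idx),
               cp$Q, cp$theta, cp$phi)
      rings[[type]] <- c(rings[[type]],
                         list(c(row, label = lab$label,
                                source = paste0(source, ":", s, ":", i))))
    }
    lk <- topology$linkages
    for (j in seq_len(nrow(lk))) {
      p <- c(
        c1_o = atom_distance(co[lk$c1[j], ], co[lk$o[j], ]),
        o_cn = atom_distance(co[lk$o[j], ], co[lk$cn[j], ]),
        o5_c1_o = bond_angle(co[lk$o5[j], ], co[lk$c1[j], ], co[lk$o[j], ]),
        c1_o_cn = bond_angle(co[lk$c1[j], ], co[lk$o[j], ], co[lk$cn[j], ]),
        phi = dihedral(co[lk$o5[j], ], co[lk$c1[j], ], co[lk$o[j], ],
                       co[lk$cn[j], ]),
        psi = dihedral(co[lk$c1[j], ], co[lk$o[j], ], co[lk$cn[j], ],
                       co[lk$cprev[j], ]),
        tau_o = dihedral(co[lk$c5[j], ], co[lk$o5[j], ], co[lk$c1[j], ],
                         co[lk$o[j], ]),
        o_cn_cprev = bond_angle(co[lk$o[j], ], co[lk$cn[j], ],
                                co[lk$cprev[j], ])
      )
      links[[lk$type[j]]] <- c(links[[lk$type[j]]],
                               list(c(p, source = paste0(source, ":", s, ":",
                                                         j))))
    }
  }
  ring_pools <- lapply(names(rings), function(type) {
    nm <- c(.ring_param_names(type), "Q", "theta", "phi")
    m <- do.call(rbind, rings[[type]])
    df <- as.data.frame(m[, seq_along(nm), drop = FALSE])
    df[] <- lapply(df, as.numeric)
    names(df) <- nm
    df$label <- m[, length(nm) + 1]
    df$source <- m[, length(nm) + 2]
    df
  })
  names(ring_pools) <- names(rings)
  link_pools <- lapply(names(links), function(type) {
    m <- do.call(rbind, links[[type]])
    df <- as.data.frame(m[, seq_along(.LINK_PARAM_NAMES), drop = FALSE])
    df[] <- lapply(df, as.numeric)
    names(df) <- .LINK_PARAM_NAMES
    df$source <- m[, length(.LINK_PARAM_NAMES) + 1]
    df
  })
  names(link_pools) <- names(links)
  conformer_db(ring_pools, link_pools,
               meta = list(gag_type = topology$spec$gag_type,
                           source = source,
                           n_conformations = length(ensemble)))
}

#' Construct a conformer database object
#'
#' @param rings Named list (residue type -> data frame) of ring pools.
#' @param linkages Named list (linkage type -> data frame) of linkage pools.
#' @param meta List of provenance metadata.
#' @return A `conformer_db`.
#' @export
conformer_db <- function(rings, linkages, meta = list()) {
  stopifnot(length(rings) > 0, length(linkages) > 0)
  for (nm in names(rings)) {
    if (nrow(rings[[nm]]) == 0) stop("empty ring pool: ", nm)
  }
  for (nm in names(linkages)) {
    if (nrow(linkages[[nm]]) == 0) stop("empty linkage pool: ", nm)
  }
  meta$counts <- list(rings = vapply(rings, nrow, integer(1)),
                      linkages = vapply(linkages, nrow, integer(1)))
  structure(list(rings = rings, linkages = linkages, meta = meta,
                 cache = new.env(parent = emptyenv())),
            class = "conformer_db")
}

#' @export
print.conformer_db <- function(x, ...) {
  cat("Conformer database (", x$meta$gag_type %||% "unknown", ")\n", sep = "")
  for (nm in names(x$rings)) {
    cat("  ring    ", format(nm, width = 16), nrow(x$rings[[nm]]), "\n")
  }
  for (nm in names(x$linkages)) {
    cat("  linkage ", format(nm, width = 16), nrow(x$linkages[[nm]]), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a conformer uniformly from a pool
#'
#' Draws use R's RNG stream, so results are reproducible under `set.seed`.
#'
#' @param db A `conformer_db`.
#' @param kind `"ring"` or `"linkage"`.
#' @param type Residue or linkage type naming the pool.
#' @return A one-row data frame (the sampled conformer record).
#' @export
sample_conformer <- function(db, kind = c("ring", "linkage"), type) {
  kind <- match.arg(kind)
  pool <- if (kind == "ring") db$rings[[type]] else db$linkages[[type]]
  if (is.null(pool)) stop("unknown ", kind, " type: ", type)
  pool[sample.int(nrow(pool), 1L), , drop = FALSE]
}

#' Save / load a conformer database (JSON-lines)
#'
#' One JSON record per line: a schema-versioned header followed by one
#' record per conformer. Floats survive a round trip losslessly (written
#' with full precision).
#'
#' @param db A `conformer_db`.
#' @param path File path.
#' @return `load_db` returns a `conformer_db`; `save_db` returns `path`
#'   invisibly.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "conformer_db"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(kind = "header", schema = 1L, meta = db$meta)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  for (type in names(db$rings)) {
    pool <- db$rings[[type]]
    for (r in seq_len(nrow(pool))) {
      rec <- list(kind = "ring", type = type,
                  params = as.list(pool[r, setdiff(names(pool),
                                                   c("label", "source"))]),
                  label = pool$label[r], source = pool$source[r])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  for (type in names(db$linkages)) {
    pool <- db$linkages[[type]]
    for (r in seq_len(nrow(pool))) {
      rec <- list(kind = "linkage", type = type,
                  params = as.list(pool[r, .LINK_PARAM_NAMES]),
                  source = pool$source[r])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("load_db: empty file: ", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i]),
                          error = function(e) {
                            stop("load_db: malformed record at line ", i,
                                 " of ", path, ": ", conditionMessage(e))
                          })
  }
  hdr <- recs[[1]]
  if (!identical(hdr$kind, "header")) stop("load_db: missing header record")
  if (!identical(as.integer(hdr$schema), 1L)) {
    stop("load_db: unsupported schema version: ", hdr$schema)
  }
  rings <- list(); links <- list()
  for (i in seq_along(recs)[-1]) {
    rec <- recs[[i]]
    if (identical(rec$kind, "ring")) {
      row <- as.data.frame(rec$params)
      row$label <- rec$label
      row$source <- rec$source
      rings[[rec$type]] <- c(rings[[rec$type]], list(row))
    } else if (identical(rec$kind, "linkage")) {
      row <- as.data.frame(rec$params)
      row$source <- rec$source
      links[[rec$type]] <- c(links[[rec$type]], list(row))
    } else {
      stop("load_db: unknown record kind at line ", i)
    }
  }
  meta <- hdr$meta
  meta$counts <- NULL
  conformer_db(lapply(rings, function(x) do.call(rbind, x)),
               lapply(links, function(x) do.call(rbind, x)),
               meta = meta)
}
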