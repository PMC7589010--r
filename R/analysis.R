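## Conformational descriptors: Boltzmann-inverted free-energy maps of
## glycosidic dihedrals, end-to-end distance and radius-of-gyration
## statistics, histogram modes, and sub-ensemble selection.

.R_KCAL <- 0.0019872  # kcal/mol/K

.ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999)

#' End-to-end distance of a polymer conformation
#'
#' Distance between the two chain-terminal oxygen atoms: the free anomeric
#' hydroxyl O1 of the reducing-end residue and the free hydroxyl oxygen at
#' the linkage position (O3 or O4, per the repeat) of the nonreducing-end
#' residue. These are the atoms through which the chain would extend, so
#' the distance spans the whole molecule; the convention is isolated here
#' so it can be changed in one place.
#'
#' @param conf A `gag_conformation`.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(conf) {
  topo <- conf$topology
  sp <- topo$spec
  n <- sp$n_residues
  i_red <- topo$residues[[n]]
  o1 <- i_red[match("O1", topo$atoms$name[i_red])]
  i_nre <- topo$residues[[1]]
  on_name <- paste0("O", sp$nonreducing_pos)
  on <- i_nre[match(on_name, topo$atoms$name[i_nre])]
  atom_distance(conf$coords[o1, ], conf$coords[on, ])
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the heavy atoms from the
#' center of mass (set `weighted = FALSE` for the unweighted form).
#'
#' @param conf A `gag_conformation`.
#' @param weighted Mass-weight the atoms (default TRUE).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf, weighted = TRUE) {
  co <- conf$coords
  w <- if (weighted) {
    .ATOMIC_MASS[conf$topology$atoms$element]
  } else {
    rep(1, nrow(co))
  }
  com <- colSums(co * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(co, 2, com)^2)) / sum(w))
}

#' Free-energy map of glycosidic dihedrals
#'
#' Sorts (phi, psi) samples into 2.5 x 2.5 degree bins over (-180, 180]
#' and Boltzmann-inverts the counts: dG(phi_i, psi_j) = -RT ln(n_ij) - k,
#' with k chosen so the global minimum is at 0 kcal/mol. Bin edges sit at
#' multiples of 2.5 degrees, so bin centers are at -178.75, -176.25, ...
#'
#' @param samples Data frame (or two-column matrix) of phi, psi in degrees.
#' @param T Temperature in K (default 310, body temperature).
#' @param bin Bin width in degrees (default 2.5).
#' @return An object of class `fe_map`: `counts` and `dG` matrices
#'   (phi rows x psi columns; empty bins are `NA` in `dG`), bin centers,
#'   `T`, `R`, and the normalization constant `k`.
#' @export
free_energy_map <- function(samples, T = 310, bin = 2.5) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) stop("free_energy_map: empty sample set")
  nb <- round(360 / bin)
  wrap <- function(x) {
    w <- (x + 180) %% 360 - 180
    w[w == -180] <- 180
    w
  }
  ix <- function(x) pmin(floor((wrap(x) + 180) / bin) + 1, nb)
  counts <- matrix(0L, nb, nb)
  tab <- table(factor(ix(samples[, 1]), levels = seq_len(nb)),
               factor(ix(samples[, 2]), levels = seq_len(nb)))
  counts <- matrix(as.integer(tab), nb, nb)
  RT <- .R_KCAL * T
  k <- -RT * log(max(counts))
  dG <- -RT * log(counts) - k
  dG[counts == 0] <- NA_real_
  centers <- -180 + bin * (seq_len(nb) - 0.5)
  structure(list(counts = counts, dG = dG,
                 phi_centers = centers, psi_centers = centers,
                 T = T, R = .R_KCAL, k = k, bin = bin,
                 n = nrow(samples)),
            class = "fe_map")
}

#' @export
print.fe_map <- function(x, ...) {
  occ <- sum(x$counts > 0)
  gm <- which(x$dG == 0, arr.ind = TRUE)[1, ]
  cat("Free-energy map:", x$n, "samples,", x$bin, "deg bins,", occ,
      "occupied;\n  global minimum at (",
      x$phi_centers[gm[1]], ",", x$psi_centers[gm[2]], ") deg\n")
  invisible(x)
}

#' Locate the free-energy minimum bin near a reference point
#'
#' Finds the occupied bin of lowest free energy within a (wrapped) window
#' around `center`; used to read basin minima off a map.
#'
#' @param fem An `fe_map`.
#' @param center Numeric `c(phi, psi)` in degrees.
#' @param window Half-width of the search window, degrees.
#' @return List with `phi`, `psi` (bin centers) and `dG`.
#' @export
fe_local_min <- function(fem, center, window = 30) {
  dphi <- abs(.wrap180(fem$phi_centers - center[1]))
  dpsi <- abs(.wrap180(fem$psi_centers - center[2]))
  sub <- fem$dG[dphi <= window, dpsi <= window, drop = FALSE]
  if (all(is.na(sub))) stop("fe_local_min: no occupied bins in window")
  ij <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(phi = fem$phi_centers[dphi <= window][ij[1]],
       psi = fem$psi_centers[dpsi <= window][ij[2]],
       dG = min(sub, na.rm = TRUE))
}

#' Histogram and most probable value
#'
#' Sorts values into bins of width `bin_width` anchored at integer
#' multiples of the width from zero; the most probable value is the center
#' of the maximal-count bin (ties broken toward the lowest center).
#'
#' @param values Numeric vector.
#' @param bin_width Bin width (e.g. 0.5 Angstrom for 20-mer end-to-end
#'   distances, 0.25 for 10-mers, 5 for 200-mers).
#' @return List with `histogram` (data frame: `center`, `count`,
#'   `probability`) and `most_probable`.
#' @export
histogram_mode <- function(values, bin_width) {
  if (length(values) == 0) stop("histogram_mode: empty input")
  if (bin_width <= 0) stop("histogram_mode: bin_width must be > 0")
  idx <- floor(values / bin_width)
  tab <- table(idx)
  centers <- (as.numeric(names(tab)) + 0.5) * bin_width
  ord <- order(centers)
  centers <- centers[ord]
  counts <- as.integer(tab)[ord]
  hist <- data.frame(center = centers, count = counts,
                     probability = counts / sum(counts))
  list(histogram = hist,
       most_probable = centers[which.max(counts)])
}

#' Percent difference (mean-denominator form)
#'
#' `|a - b| / ((a + b)/2) * 100`, the form used for comparing most
#' probable end-to-end distances between ensembles.
#'
#' @param a,b Positive values.
#' @return Percent difference.
#' @examples
#' percent_difference(80, 78)  # 2.53
#' @export
percent_difference <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("percent_difference: inputs must be > 0")
  abs(a - b) / ((a + b) / 2) * 100
}

#' R-squared of the end-to-end distance vs radius of gyration regression
#'
#' Ordinary least squares of Rg on end-to-end distance.
#'
#' @param e2e,rg Numeric vectors (>= 3 values), or a `gag_ensemble` as the
#'   first argument.
#' @return R-squared in \[0, 1\].
#' @export
e2e_rg_r2 <- function(e2e, rg = NULL) {
  if (inherits(e2e, "gag_ensemble")) {
    rg <- e2e$members$rg
    e2e <- e2e$members$e2e
  }
  stopifnot(length(e2e) >= 3, length(e2e) == length(rg))
  if (stats::var(e2e) == 0) stop("e2e_rg_r2: degenerate (constant) e2e")
  summary(stats::lm(rg ~ e2e))$r.squared
}

#' Select a sub-ensemble by a per-member predicate
#'
#' @param ensemble A `gag_ensemble` (see [generate_ensemble()]).
#' @param predicate Function of one member's feature list
#'   (`e2e`, `rg`, `post_pe`, `phi`, `psi` (per junction),
#'   `pucker_label` (per residue)) returning TRUE/FALSE.
#' @return A `gag_ensemble` containing the members for which the predicate
#'   holds, order preserved.
#' @export
subset_ensemble <- function(ensemble, predicate) {
  stopifnot(inherits(ensemble, "gag_ensemble"))
  keep <- vapply(seq_len(nrow(ensemble$members)), function(i) {
    feat <- list(e2e = ensemble$members$e2e[i],
                 rg = ensemble$members$rg[i],
                 post_pe = ensemble$members$post_pe[i],
                 phi = ensemble$phi[i, ],
                 psi = ensemble$psi[i, ],
                 pucker_label = ensemble$pucker_label[i, ])
    isTRUE(predicate(feat))
  }, logical(1))
  out <- ensemble
  out$members <- ensemble$members[keep, , drop = FALSE]
  out$phi <- ensemble$phi[keep, , drop = FALSE]
  out$psi <- ensemble$psi[keep, , drop = FALSE]
  out$pucker_label <- ensemble$pucker_label[keep, , drop = FALSE]
  if (!is.null(ensemble$coords)) out$coords <- ensemble$coords[keep]
  out
}
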