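#' @useDynLib gagchain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Internal-coordinate mathematics. All angles are in degrees; torsions lie
## in (-180, 180] under the IUPAC sign convention. Coordinates are numeric
## length-3 vectors (or n x 3 matrices) in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

#' Euclidean distance between two points
#'
#' @param p,q Numeric length-3 coordinate vectors (Angstrom).
#' @return Distance in Angstrom.
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
atom_distance <- function(p, q) {
  sqrt(sum((p - q)^2))
}

#' Bond angle at a vertex atom
#'
#' Angle p1-p2-p3 with the vertex at `p2`.
#'
#' @param p1,p2,p3 Numeric length-3 coordinate vectors.
#' @return Angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("bond_angle: coincident vertex atoms")
  }
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * .rad2deg
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral (torsion) angle of four atoms
#'
#' Torsion p1-p2-p3-p4 about the p2-p3 bond, IUPAC sign convention:
#' looking down p2->p3, a clockwise rotation of the far bond relative to the
#' near bond is positive. cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Torsion in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("dihedral: collinear reference triple")
  }
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * .rad2deg
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF-style) placement: given three previously placed
#' atoms `a`, `b`, `c`, returns the point `d` with bond length
#' `distance(c, d) = bond`, bond angle `bond_angle(b, c, d) = angle` and
#' torsion `dihedral(a, b, c, d) = torsion`.
#'
#' @param a,b,c Reference points (must not be collinear).
#' @param bond Bond length c-d in Angstrom (> 0).
#' @param angle Bond angle b-c-d in degrees, in (0, 180).
#' @param torsion Torsion a-b-c-d in degrees.
#' @return Numeric length-3 coordinate vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  stopifnot(bond > 0, angle > 0, angle < 180)
  bc <- c - b
  nbc <- sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nbc == 0 || nn < 1e-12 * nbc * sqrt(sum(ab^2))) {
    stop("place_atom: reference atoms are collinear")
  }
  bc <- bc / nbc
  n <- n / nn
  m <- .cross3(n, bc)
  th <- angle * .deg2rad
  ph <- torsion * .deg2rad
  ## local displacement in the (bc, m, n) frame
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Realize a chain of atoms from a placement plan
#'
#' Sequentially places atoms from internal coordinates. The plan is a data
#' frame whose rows give, for each atom to place, the indices of the three
#' already-placed frame atoms and the (bond, angle, torsion) values.
#'
#' The first three atoms of a structure are seeded directly: atom 1 at the
#' origin, atom 2 along +x at the given bond length, atom 3 in the xy plane.
#'
#' @param plan Data frame with columns `idx`, `a`, `b`, `c` (integer atom
#'   indices; `a`,`b`,`c` refer to already-placed atoms, NA for seed rows),
#'   `bond`, `angle`, `torsion`.
#' @param n_atoms Total number of atoms.
#' @return An `n_atoms` x 3 coordinate matrix.
#' @keywords internal
realize_plan <- function(plan, n_atoms) {
  coords <- matrix(NA_real_, n_atoms, 3)
  seed <- plan[is.na(plan$a), , drop = FALSE]
  if (nrow(seed) != 3) stop("realize_plan: expected exactly 3 seed rows")
  i1 <- seed$idx[1]; i2 <- seed$idx[2]; i3 <- seed$idx[3]
  coords[i1, ] <- c(0, 0, 0)
  coords[i2, ] <- c(seed$bond[2], 0, 0)
  th <- seed$angle[3] * .deg2rad
  coords[i3, ] <- coords[i2, ] +
    seed$bond[3] * c(-cos(th), sin(th), 0)
  rest <- plan[!is.na(plan$a), , drop = FALSE]
  for (r in seq_len(nrow(rest))) {
    coords[rest$idx[r], ] <- place_atom(
      coords[rest$a[r], ], coords[rest$b[r], ], coords[rest$c[r], ],
      rest$bond[r], rest$angle[r], rest$torsion[r]
    )
  }
  coords
}

#' Measure the internal coordinates of a placement plan
#'
#' Inverse of [realize_plan()]: given coordinates and a placement plan
#' (atom index plus three frame-atom indices per row), measures the
#' (bond, angle, torsion) of every row. Seed rows (frame indices NA)
#' measure what is defined: row 2 the seed bond, row 3 bond and angle.
#'
#' @param coords n x 3 coordinate matrix.
#' @param plan Placement plan (see [realize_plan()]); `bond`, `angle`,
#'   `torsion` columns are ignored and recomputed.
#' @return The plan with `bond`, `angle`, `torsion` filled in.
#' @keywords internal
measure_plan <- function(coords, plan) {
  for (r in seq_len(nrow(plan))) {
    i <- plan$idx[r]
    if (is.na(plan$a[r])) {
      if (r == 2) {
        plan$bond[r] <- atom_distance(coords[plan$idx[1], ], coords[i, ])
      } else if (r == 3) {
        plan$bond[r] <- atom_distance(coords[plan$idx[2], ], coords[i, ])
        plan$angle[r] <- bond_angle(coords[plan$idx[1], ],
                                    coords[plan$idx[2], ], coords[i, ])
      }
      next
    }
    a <- coords[plan$a[r], ]; b <- coords[plan$b[r], ]; cc <- coords[plan$c[r], ]
    p <- coords[i, ]
    plan$bond[r] <- atom_distance(cc, p)
    plan$angle[r] <- bond_angle(b, cc, p)
    plan$torsion[r] <- dihedral(a, b, cc, p)
  }
  plan
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two coordinate sets after optimal
#' rigid-body superposition.
#'
#' @param x,y n x 3 coordinate matrices with matching rows.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((yc %*% rot - xc)^2)))
}

## wrap an angle difference into (-180, 180]
.wrap180 <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
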