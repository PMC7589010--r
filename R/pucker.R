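## Cremer-Pople puckering for six-membered rings.
##
## Ring atoms are always ordered O5, C1, C2, C3, C4, C5. With this ordering
## and the phase convention below, the standard D-pyranose chair (C4 above
## and C1 below the O5/C2/C3/C5 reference plane) sits at theta ~ 0 and is
## labelled 4C1; the inverted chair sits at theta ~ 180 (1C4). The
## equatorial boat/skew-boat wheel at theta ~ 90 is calibrated by
## constructing idealized displacement patterns (see classify_pucker).

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' @param ring 6 x 3 coordinate matrix, atoms ordered O5, C1, C2, C3, C4, C5.
#' @return List with `Q` (total amplitude, Angstrom), `theta` (degrees,
#'   \[0, 180\]), `phi` (degrees, \[0, 360); 0 when undefined), and the
#'   component amplitudes `q2`, `q3`.
#' @export
cremer_pople <- function(ring) {
  stopifnot(is.matrix(ring), nrow(ring) == 6, ncol(ring) == 3)
  center <- colMeans(ring)
  r <- sweep(ring, 2, center)
  j <- 0:5
  s1 <- sin(2 * pi * j / 6)
  c1 <- cos(2 * pi * j / 6)
  rp <- colSums(r * s1)
  rpp <- colSums(r * c1)
  n <- .cross3(rp, rpp)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("cremer_pople: degenerate ring geometry")
  n <- n / nn
  z <- as.numeric(r %*% n)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < 1e-10) {
    return(list(Q = 0, theta = 0, phi = 0, q2 = 0, q3 = 0))
  }
  theta <- acos(min(1, max(-1, q3 / Q))) * .rad2deg
  phi <- if (q2 < 1e-10) 0 else (atan2(q2s, q2c) * .rad2deg) %% 360
  list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3)
}

#' Construct a six-membered ring with given puckering parameters
#'
#' Inverse transform: places a (near-)regular hexagon in the xy plane and
#' displaces atoms perpendicular to it so that [cremer_pople()] of the
#' result reproduces `(Q, theta, phi)`. In-plane radii are rescaled so that
#' the mean squared bond length equals `mean_bond^2`.
#'
#' @param Q Total puckering amplitude (Angstrom); feasibility bound ~1.2.
#' @param theta Polar angle, degrees in \[0, 180\].
#' @param phi Azimuthal angle, degrees.
#' @param mean_bond Mean ring bond length (Angstrom).
#' @return 6 x 3 coordinate matrix, atoms ordered O5, C1, C2, C3, C4, C5.
#' @export
ring_from_pucker <- function(Q, theta, phi, mean_bond = 1.49) {
  stopifnot(Q >= 0, theta >= 0, theta <= 180, mean_bond > 0)
  if (Q > 1.2) stop("ring_from_pucker: Q beyond geometric feasibility (~1.2 A)")
  j <- 0:5
  q2 <- Q * sin(theta * .deg2rad)
  q3 <- Q * cos(theta * .deg2rad)
  z <- sqrt(1 / 3) * q2 * cos(phi * .deg2rad + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  ## clockwise placement in xy (viewed from +z) so the C-P normal is +z
  a <- -2 * pi * j / 6
  xy <- cbind(cos(a), sin(a))
  ## rescale planar radius so mean squared edge length = mean_bond^2
  dz2 <- sum((z - z[c(2:6, 1)])^2)
  ## planar edge of a unit-radius hexagon is 1
  r2 <- (6 * mean_bond^2 - dz2) / 6
  if (r2 <= 0) stop("ring_from_pucker: Q infeasible for this bond length")
  ring <- cbind(xy * sqrt(r2), z)
  dimnames(ring) <- list(c("O5", "C1", "C2", "C3", "C4", "C5"),
                         c("x", "y", "z"))
  ring
}

## Canonical equator vertices: boats at even multiples of 30 deg in phi,
## skew-boats at odd multiples. Derived by projecting idealized displacement
## patterns (the two prow atoms of a boat up / the superscript-subscript
## atom pair of a skew-boat up and down) through the Cremer-Pople sums;
## test-pucker.R re-derives the wheel from constructed geometries.
.pucker_wheel <- c(
  "3,OB", "3S1", "B1,4", "5S1", "2,5B", "2SO",
  "B3,O", "1S3", "1,4B", "1S5", "B2,5", "OS2"
)

#' Classify puckering parameters into a canonical conformer label
#'
#' Chairs when `theta <= 45` (4C1) or `theta >= 135` (1C4); otherwise the
#' nearest canonical equator vertex: boats at even multiples of 30 degrees
#' in phi, skew-boats at odd multiples (ties broken toward the lower-phi
#' vertex).
#'
#' @param p A list with `theta` and `phi` (degrees), as returned by
#'   [cremer_pople()], or a 6 x 3 ring coordinate matrix.
#' @return List with `label` and `family`
#'   (`"chair"`, `"boat"` or `"skew-boat"`).
#' @export
classify_pucker <- function(p) {
  if (is.matrix(p)) p <- cremer_pople(p)
  stopifnot(is.numeric(p$theta), is.numeric(p$phi))
  if (p$theta <= 45) {
    return(list(label = "4C1", family = "chair"))
  }
  if (p$theta >= 135) {
    return(list(label = "1C4", family = "chair"))
  }
  k <- floor(p$phi / 30 + 0.5) %% 12  # ties (phi at +15 deg) round down? no:
  ## floor(x+.5) rounds half-up, i.e. a tie midway between vertices goes to
  ## the upper vertex; enforce the lower-vertex tie-break explicitly
  if (abs((p$phi / 30) %% 1 - 0.5) < 1e-12) {
    k <- floor(p$phi / 30) %% 12
  }
  label <- .pucker_wheel[k + 1]
  family <- if (grepl("B", label, fixed = TRUE) &&
                !grepl("S", label, fixed = TRUE)) "boat" else "skew-boat"
  list(label = label, family = family)
}

#' Canonical pucker coordinates for a conformer label
#'
#' Inverse of [classify_pucker()] at the vertex: returns the idealized
#' `(theta, phi)` of a canonical conformer.
#'
#' @param label One of `"4C1"`, `"1C4"`, or the 12 canonical boat/skew-boat
#'   labels (e.g. `"2SO"`, `"1C4"`, `"B3,O"`, `"1,4B"`).
#' @return List with `theta` and `phi` in degrees.
#' @export
pucker_vertex <- function(label) {
  if (label == "4C1") return(list(theta = 0, phi = 0))
  if (label == "1C4") return(list(theta = 180, phi = 0))
  k <- match(label, .pucker_wheel)
  if (is.na(k)) {
    stop("unknown pucker label: ", label, "; expected one of 4C1, 1C4, ",
         paste(.pucker_wheel, collapse = ", "))
  }
  list(theta = 90, phi = 30 * (k - 1))
}
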