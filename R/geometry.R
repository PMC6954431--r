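# ---- elementary vector geometry -------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Wrap angles to the (-180, 180] interval
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into (-180, 180].
#' @export
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Distance between two points
#' @param a,b 3-vectors (Angstrom).
#' @return Euclidean distance.
#' @export
bond_length <- function(a, b) vnorm(b - a)

#' Bond angle at vertex b
#' @param a,b,c 3-vectors (Angstrom).
#' @return angle a-b-c in degrees, in [0, 180].
#' @export
bond_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed torsion (dihedral) angle
#'
#' IUPAC sign convention: looking from `b` towards `c`, a clockwise rotation
#' of the far bond relative to the near bond is positive. A planar cis
#' arrangement gives 0 degrees, trans gives 180 degrees.
#'
#' @param a,b,c,d 3-vectors (Angstrom).
#' @return torsion angle in degrees, in (-180, 180].
#' @export
measure_torsion <- function(a, b, c, d) {
  stopifnot(all(is.finite(c(a, b, c, d))))
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined torsion: three consecutive atoms are collinear")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / vnorm(b2)
  wrap180(atan2(y, x) * 180 / pi)
}

# ---- pseudorotation --------------------------------------------------------

# Endocyclic torsion indexing used throughout:
#   nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
#   nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1'
# with the model nu_j = tau_m * cos(P + 144 * (j - 2)).

#' Pseudorotation parameters of a five-membered ring
#'
#' Solves nu_j = tau_m * cos(P + 144 * (j - 2)) for (P, tau_m) by linear least
#' squares over all five endocyclic torsions. The least-squares route is
#' robust to ring-closure noise, unlike the two-torsion closed form.
#'
#' @param nu numeric(5): endocyclic torsions nu0..nu4 in degrees.
#' @return list with `P` (phase, degrees in [0, 360)), `tau_m` (amplitude,
#'   degrees, >= 0) and `flat` (TRUE when the ring is planar and P is
#'   reported as 0 by convention).
#' @export
compute_pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5, all(is.finite(nu)))
  j <- 0:4
  th <- (144 * (j - 2)) * pi / 180
  # nu_j = A cos(th_j) - B sin(th_j), A = tau cos P, B = tau sin P.
  # cos/sin columns are orthogonal with squared norm 5/2.
  A <- (2 / 5) * sum(nu * cos(th))
  B <- -(2 / 5) * sum(nu * sin(th))
  tau_m <- sqrt(A^2 + B^2)
  if (tau_m < 1e-9)
    return(list(P = 0, tau_m = 0, flat = TRUE))
  P <- atan2(B, A) * 180 / pi
  list(P = P %% 360, tau_m = tau_m, flat = FALSE)
}

#' Endocyclic torsions for given pseudorotation parameters
#'
#' Inverse of [compute_pseudorotation()].
#'
#' @param P pseudorotation phase in degrees.
#' @param tau_m pucker amplitude in degrees.
#' @return numeric(5) of nu0..nu4 in degrees.
#' @export
nu_from_pucker <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) * pi / 180)
}
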