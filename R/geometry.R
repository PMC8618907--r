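# Internal 3D geometry helpers shared across modules. All lengths in Angstrom,
# all angles in degrees unless a name says otherwise.

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two 3-vectors in degrees, in [0, 180]
#' @noRd
vec_angle_deg <- function(a, b) {
  ua <- unit_vec(a)
  ub <- unit_vec(b)
  rad2deg(acos(max(-1, min(1, sum(ua * ub)))))
}

# Dihedral a-b-c-d in degrees, in (-180, 180]
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame (NeRF) atom placement: position a new atom
# bonded to `c` with bond length, angle new-c-b, and dihedral new-c-b-a.
place_nerf <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- deg2rad(dihedral)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit_vec(c - b)
  n <- unit_vec(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Rotation matrix about a unit axis by angle (degrees), Rodrigues form.
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic rotation set: identity plus n-1 rotations with axes on a
# Fibonacci sphere and angles spread over the circle. Used by the built-in
# docking engine; fully reproducible, no RNG.
rotation_set <- function(n) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  out[[1]] <- diag(3)
  if (n == 1) return(out)
  golden <- (1 + sqrt(5)) / 2
  for (i in seq_len(n - 1)) {
    z <- 1 - 2 * (i - 0.5) / (n - 1)
    r <- sqrt(max(0, 1 - z^2))
    phi <- 2 * pi * i / golden
    axis <- c(r * cos(phi), r * sin(phi), z)
    angle <- 360 * i / n
    out[[i + 1]] <- rotation_about_axis(axis, angle)
  }
  out
}

# Bondi-style van der Waals radii (Angstrom); boron from standard tabulations.
vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, B = 1.92, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, FE = 1.40, ZN = 1.39, MG = 1.73, `NA` = 2.27, K = 2.75,
  CA = 2.31
)

vdw_radius <- function(element) {
  r <- unname(vdw_radii[toupper(element)])
  r[is.na(r)] <- 1.70
  r
}

# All pairwise distances between two N x 3 coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

coords_matrix <- function(df) {
  m <- cbind(df$x, df$y, df$z)
  colnames(m) <- c("x", "y", "z")
  if (!is.null(df$atom)) rownames(m) <- df$atom
  m
}
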