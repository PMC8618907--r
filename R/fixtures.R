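# Deterministic synthetic structures and trajectories with known ground
# truth, so every pipeline stage is testable without downloading anything.
# Geometry is ideal (template internal coordinates, no minimisation): the
# fixtures are geometric objects, not physical models.

# Ideal backbone internal coordinates (Angstrom / degrees)
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           n_ca_c = 111.2, ca_c_n = 116.6, c_n_ca = 121.7,
           ca_c_o = 120.8, omega = 180)

# Side-chain template rows: atom, refs (a, b, c for NeRF), bond, angle,
# dihedral. refs name earlier atoms of the same residue.
sidechain_templates <- list(
  GLY = NULL,
  ALA = list(
    list("CB", c("C", "N", "CA"), 1.521, 110.4, 122.6)),
  PHE = list(
    list("CB", c("C", "N", "CA"), 1.521, 110.4, 122.6),
    list("CG", c("N", "CA", "CB"), 1.510, 114.0, 180),
    list("CD1", c("CA", "CB", "CG"), 1.390, 120.0, 90),
    list("CD2", c("CA", "CB", "CG"), 1.390, 120.0, -90),
    list("CE1", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.390, 120.0, 0)),
  TYR = list(
    list("CB", c("C", "N", "CA"), 1.521, 110.4, 122.6),
    list("CG", c("N", "CA", "CB"), 1.510, 114.0, 180),
    list("CD1", c("CA", "CB", "CG"), 1.390, 120.0, 90),
    list("CD2", c("CA", "CB", "CG"), 1.390, 120.0, -90),
    list("CE1", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.390, 120.0, 0),
    list("OH", c("CD1", "CE1", "CZ"), 1.375, 120.0, 180)),
  TRP = list(
    list("CB", c("C", "N", "CA"), 1.521, 110.4, 122.6),
    list("CG", c("N", "CA", "CB"), 1.500, 114.0, 180),
    list("CD1", c("CA", "CB", "CG"), 1.370, 127.0, 90),
    list("CD2", c("CA", "CB", "CG"), 1.430, 126.6, -90),
    list("NE1", c("CB", "CG", "CD1"), 1.380, 110.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.410, 107.0, 180),
    list("CE3", c("CD1", "CG", "CD2"), 1.400, 133.9, 180),
    list("CZ2", c("CG", "CD2", "CE2"), 1.400, 122.4, 180),
    list("CZ3", c("CG", "CD2", "CE3"), 1.400, 118.8, 180),
    list("CH2", c("CD2", "CE2", "CZ2"), 1.370, 117.5, 0)),
  HIS = list(
    list("CB", c("C", "N", "CA"), 1.521, 110.4, 122.6),
    list("CG", c("N", "CA", "CB"), 1.490, 114.0, 180),
    list("ND1", c("CA", "CB", "CG"), 1.380, 122.7, 90),
    list("CD2", c("CA", "CB", "CG"), 1.360, 131.0, -90),
    list("CE1", c("CB", "CG", "ND1"), 1.320, 109.0, 180),
    list("NE2", c("CB", "CG", "CD2"), 1.370, 107.0, 180))
)

one_to_three <- c(A = "ALA", G = "GLY", F = "PHE", Y = "TYR", W = "TRP",
                  H = "HIS")

#' Generate an ideal synthetic peptide structure
#'
#' Builds a peptide from one-letter codes over \{A, G, F, Y, W, H\} on an
#' ideal backbone (helix: phi/psi -57/-47; extended: -139/135) with
#' template side chains. Fully deterministic: the same call always yields
#' bitwise-identical coordinates.
#'
#' @param sequence One-letter sequence string, e.g. `"AYAYA"`.
#' @param conformation `"extended"` or `"helix"`.
#' @param chain Chain identifier (default `"A"`).
#' @return An atom table (heavy atoms only).
#' @examples
#' make_structure("AYA")  # middle residue is a complete tyrosine
#' @export
make_structure <- function(sequence, conformation = c("extended", "helix"),
                           chain = "A") {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) == 0) stop("empty sequence", call. = FALSE)
  bad <- setdiff(letters1, names(one_to_three))
  if (length(bad) > 0) {
    stop("unsupported residue letter(s): ", paste(unique(bad),
                                                  collapse = ", "),
         call. = FALSE)
  }
  ang <- if (conformation == "helix") c(phi = -57, psi = -47)
  else c(phi = -139, psi = 135)
  n_res <- length(letters1)
  # backbone via NeRF chain
  N <- list(); CA <- list(); C <- list(); O <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BB$n_ca, 0, 0)
  th <- deg2rad(BB$n_ca_c)
  C[[1]] <- CA[[1]] + BB$ca_c * c(-cos(th), sin(th), 0)
  if (n_res > 1) {
    for (i in seq_len(n_res - 1)) {
      N[[i + 1]] <- place_nerf(N[[i]], CA[[i]], C[[i]],
                               BB$c_n, BB$ca_c_n, ang[["psi"]])
      CA[[i + 1]] <- place_nerf(CA[[i]], C[[i]], N[[i + 1]],
                                BB$n_ca, BB$c_n_ca, BB$omega)
      C[[i + 1]] <- place_nerf(C[[i]], N[[i + 1]], CA[[i + 1]],
                               BB$ca_c, BB$n_ca_c, ang[["phi"]])
    }
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the following amide nitrogen
    O[[i]] <- place_nerf(N[[i]], CA[[i]], C[[i]], BB$c_o, BB$ca_c_o,
                         ang[["psi"]] + 180)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    resname <- one_to_three[[letters1[i]]]
    pos <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    tmpl <- sidechain_templates[[resname]]
    for (row in tmpl) {
      refs <- lapply(row[[2]], function(nm) pos[[nm]])
      pos[[row[[1]]]] <- place_nerf(refs[[1]], refs[[2]], refs[[3]],
                                    row[[3]], row[[4]], row[[5]])
    }
    nm <- names(pos)
    rows[[i]] <- tibble::tibble(
      chain = chain, resnum = i, resname = resname, atom = nm,
      element = substr(nm, 1, 1),
      x = unname(vapply(pos, `[[`, numeric(1), 1)),
      y = unname(vapply(pos, `[[`, numeric(1), 2)),
      z = unname(vapply(pos, `[[`, numeric(1), 3)))
  }
  as_atom_table(dplyr::bind_rows(rows))
}

#' Trajectory of a structure with isotropic Gaussian noise
#'
#' Each frame adds i.i.d. Gaussian noise (standard deviation `sigma` per
#' coordinate) to the reference coordinates. With this generator the
#' expected per-atom RMSF is `sigma * sqrt(3)` in closed form, which the
#' analytics are tested against.
#'
#' @param s Atom table.
#' @param sigma Noise standard deviation per coordinate, Angstrom.
#' @param n_frames Number of frames.
#' @param seed Integer seed; fully determines the output.
#' @return A [trajectory()].
#' @export
make_noisy_trajectory <- function(s, sigma = 0.3, n_frames = 100,
                                  seed = 1) {
  stopifnot(sigma >= 0, n_frames >= 1)
  s <- as_atom_table(s)
  base <- coords_matrix(s)
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      base + matrix(stats::rnorm(length(base), 0, sigma), nrow(base), 3)
    })
  })
  trajectory(s, frames)
}

#' Two-state trajectory with known state labels
#'
#' Generates a trajectory switching between two rigid conformations: in
#' state 2 a contiguous residue block is rigidly displaced by
#' `displacement` Angstrom. Frames are allocated to states in exact
#' proportion to `populations` (deterministic counts; a seeded permutation
#' sets their order) so the ground-truth top-state fraction is exactly
#' `max(populations)` and cluster-recovery tests measure the clustering,
#' not sampling noise. Gaussian noise `sigma` is added on top; keep
#' `displacement >> sigma` for separability.
#'
#' @param s Atom table.
#' @param populations Two state fractions summing to 1.
#' @param displacement Rigid displacement of the block in state 2,
#'   Angstrom.
#' @param sigma Per-coordinate Gaussian noise, Angstrom.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param block Residue numbers to displace; default the middle third.
#' @return List: `trajectory` ([trajectory()]) and `labels` (integer state
#'   per frame).
#' @export
make_two_state_trajectory <- function(s, populations = c(0.7, 0.3),
                                      displacement = 6, sigma = 0.3,
                                      n_frames = 200, seed = 1,
                                      block = NULL) {
  stopifnot(length(populations) == 2, abs(sum(populations) - 1) < 1e-9,
            sigma >= 0, n_frames >= 1)
  s <- as_atom_table(s)
  resn <- sort(unique(s$resnum))
  if (is.null(block)) {
    third <- max(1, floor(length(resn) / 3))
    block <- resn[seq(third + 1, min(length(resn), 2 * third))]
  }
  base <- coords_matrix(s)
  displaced <- base
  move <- s$resnum %in% block
  displaced[move, 1] <- displaced[move, 1] + displacement
  n1 <- round(populations[1] * n_frames)
  labels0 <- c(rep(1L, n1), rep(2L, n_frames - n1))
  out <- withr::with_seed(seed, {
    labels <- sample(labels0)
    frames <- lapply(labels, function(st) {
      ref <- if (st == 1) base else displaced
      ref + matrix(stats::rnorm(length(ref), 0, sigma), nrow(ref), 3)
    })
    list(labels = labels, frames = frames)
  })
  list(trajectory = trajectory(s, out$frames), labels = out$labels)
}

#' Structure with planted hydrogen bonds and apolar decoys
#'
#' Plants `k` ideal donor-H-acceptor triads (donor-acceptor distance
#' 2.8 A, D-H...A angle 170 degrees) on a widely spaced lattice, plus
#' apolar carbon decoys at least 6 A from everything. Because the
#' generator knows the ground truth, detector precision and recall can be
#' asserted exactly.
#'
#' @param k Number of planted hydrogen bonds.
#' @param seed Integer seed (orients each triad).
#' @param n_decoys Number of apolar decoy atoms (default `2 * k + 2`).
#' @return List: `structure` (atom table with hydrogens) and `bonds`
#'   (tibble of planted `donor`/`acceptor` atom ids).
#' @export
make_hbond_fixture <- function(k, seed = 1, n_decoys = 2 * k + 2) {
  stopifnot(k >= 0)
  spacing <- 15
  rows <- list()
  truth <- list()
  dirs <- withr::with_seed(seed, {
    lapply(seq_len(max(k, 1)), function(i) {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    })
  })
  for (i in seq_len(k)) {
    origin <- c((i - 1) %% 4, ((i - 1) %/% 4) %% 4, (i - 1) %/% 16) * spacing
    u <- dirs[[i]]
    n_at <- origin
    h_at <- origin + 1.0 * u
    # acceptor at D-A 2.8 A with D-H-A angle 170 degrees
    w <- perpendicular_to(u)
    ha <- solve_ha_distance(1.0, 2.8, 170)
    a_dir <- cos(deg2rad(10)) * u + sin(deg2rad(10)) * w
    a_at <- h_at + ha * a_dir
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "D", resnum = i, resname = "DON",
      atom = c("N", "H1"), element = c("N", "H"),
      x = c(n_at[1], h_at[1]), y = c(n_at[2], h_at[2]),
      z = c(n_at[3], h_at[3]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "E", resnum = i, resname = "ACC",
      atom = "O", element = "O",
      x = a_at[1], y = a_at[2], z = a_at[3])
    truth[[i]] <- tibble::tibble(donor = paste0("D:", i, "::N"),
                                 acceptor = paste0("E:", i, "::O"))
  }
  for (j in seq_len(n_decoys)) {
    origin <- c(7.5 + ((j - 1) %% 4) * spacing,
                7.5 + (((j - 1) %/% 4) %% 4) * spacing,
                7.5 + ((j - 1) %/% 16) * spacing)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "X", resnum = j, resname = "DEC",
      atom = "C1", element = "C",
      x = origin[1], y = origin[2], z = origin[3])
  }
  s <- as_atom_table(dplyr::bind_rows(rows))
  bonds <- if (k > 0) dplyr::bind_rows(truth) else
    tibble::tibble(donor = character(), acceptor = character())
  list(structure = s, bonds = bonds)
}

perpendicular_to <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(pracma_cross(u, ref))
}

# Distance H->A giving donor-acceptor distance `da` when |DH| = dh and the
# D-H...A angle is `angle` degrees.
solve_ha_distance <- function(dh, da, angle) {
  costh <- cos(deg2rad(180 - angle))
  # law of cosines in triangle D-H-A at vertex H
  # da^2 = dh^2 + ha^2 - 2 dh ha cos(angle at H between HD and HA) with
  # angle at H = angle (D-H...A); cos term sign folded into costh
  b <- 2 * dh * costh
  ha <- (-b + sqrt(b^2 + 4 * (da^2 - dh^2))) / 2
  ha
}
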