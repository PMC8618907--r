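# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own optimised code paths.

# Best RMSD over a rotation grid (z-y-z Euler angles), translations solved
# by centroid alignment. Coarse-to-fine: global sweep at `coarse` degrees,
# then a local sweep at `fine` degrees around the best cell. Since the
# Kabsch solution is optimal, its RMSD must be <= this grid minimum.
grid_search_rmsd <- function(ref, mov, coarse = 15, fine = 2) {
  refc <- sweep(ref, 2, colMeans(ref))
  movc <- sweep(mov, 2, colMeans(mov))
  rot_zyz <- function(a, b, g) {
    ra <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    rb <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    rg <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    ra %*% rb %*% rg
  }
  eval_grid <- function(alphas, betas, gammas) {
    best <- list(rmsd = Inf)
    for (a in alphas) for (b in betas) for (g in gammas) {
      r <- rot_zyz(a, b, g)
      d <- movc %*% t(r) - refc
      v <- sqrt(mean(rowSums(d^2)))
      if (v < best$rmsd) best <- list(rmsd = v, ang = c(a, b, g))
    }
    best
  }
  d2r <- pi / 180
  best <- eval_grid(seq(0, 2 * pi, by = coarse * d2r),
                    seq(0, pi, by = coarse * d2r),
                    seq(0, 2 * pi, by = coarse * d2r))
  w <- coarse * d2r
  s <- fine * d2r
  best2 <- eval_grid(seq(best$ang[1] - w, best$ang[1] + w, by = s),
                     seq(best$ang[2] - w, best$ang[2] + w, by = s),
                     seq(best$ang[3] - w, best$ang[3] + w, by = s))
  best2$rmsd
}

# Direct rescoring of a docking pose with the published contact/clash rule,
# written independently of the engine internals.
rescore_pose <- function(pose, probe, receptor) {
  rec <- as_atom_table(receptor)
  rec <- rec[toupper(rec$element) != "H", ]
  heavy <- probe$atoms$element != "H"
  pm <- pose[heavy, , drop = FALSE]
  score <- 0
  for (i in seq_len(nrow(pm))) {
    for (j in seq_len(nrow(rec))) {
      d <- sqrt(sum((pm[i, ] - c(rec$x[j], rec$y[j], rec$z[j]))^2))
      if (d < 2.5) score <- score + 10
      else if (d >= 3.0 && d <= 4.5) score <- score - 1
    }
  }
  score
}

# Leader clustering re-derived by exhaustive neighbour counting on a given
# distance matrix (the algorithmic definition, applied literally).
leader_cluster_oracle <- function(dm, cutoff) {
  n <- nrow(dm)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  repeat {
    un <- which(is.na(labels))
    if (length(un) == 0) break
    cl <- cl + 1L
    counts <- sapply(un, function(i) sum(dm[i, un] <= cutoff))
    leader <- un[which.max(counts)]
    members <- un[dm[leader, un] <= cutoff]
    labels[members] <- cl
  }
  labels
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Minimal single-atom "probe" honouring the bda_probe atom-table contract,
# for exhaustive-enumeration docking checks.
point_probe <- function() {
  structure(list(
    name = "point",
    atoms = tibble::tibble(atom = "C1", element = "C", docking_type = "C",
                           is_boron = FALSE, x = 0, y = 0, z = 0,
                           charge = 0),
    bonds = tibble::tibble(i = integer(), j = integer()),
    ligand_vector = c(tail = "C1", head = "C1"),
    torsion_tree = list()
  ), class = "bda_probe")
}
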