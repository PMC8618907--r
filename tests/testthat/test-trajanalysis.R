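all_atoms <- function(topo) rep(TRUE, nrow(topo))

test_that("kabsch recovers identity and pure translations exactly", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  sup <- kabsch(pts, pts)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  moved <- sweep(pts, 2, c(5, 0, 0), "+")
  sup2 <- kabsch(pts, moved)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup2$translation, c(-5, 0, 0), tolerance = 1e-10)
  expect_equal(apply_superposition(sup2, moved), pts, tolerance = 1e-10)
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch beats the brute-force rotation-grid oracle on noisy copies", {
  set.seed(42)
  for (rep in 1:3) {
    pts <- matrix(rnorm(12), 4, 3)
    rot <- random_rotation()
    noisy <- pts %*% t(rot) + matrix(rnorm(12, 0, 0.1), 4, 3)
    sup <- kabsch(pts, noisy)
    expect_gte(sup$rmsd, 0)
    expect_lte(sup$rmsd, 0.35)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    oracle <- grid_search_rmsd(pts, noisy)
    expect_lte(sup$rmsd, oracle + 1e-9)
  }
})

test_that("kabsch RMSD never exceeds the unsuperposed RMSD", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(rnorm(45), 15, 3)
    b <- a + matrix(rnorm(45, 0, runif(1, 0, 2)), 15, 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch(a, b)$rmsd, raw + 1e-12)
  }
})

test_that("kabsch agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  a <- matrix(rnorm(60), 20, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(60, 0, 0.3), 20, 3)
  ours <- kabsch(a, b)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 2e-3)  # bio3d rounds to 3 digits
})

test_that("rmsd series is zero for copies and rigid rotations of the reference", {
  s <- make_structure(strrep("G", 20))
  base <- bdascan:::coords_matrix(s)
  tr <- trajectory(s, list(base, base, base))
  expect_equal(rmsd_series(tr)$rmsd, rep(0, 3), tolerance = 1e-10)
  rot_frames <- lapply(1:3, function(i) {
    set.seed(i)
    base %*% t(random_rotation()) + matrix(rep(rnorm(3, 0, 5), each = nrow(base)), ncol = 3)
  })
  tr2 <- trajectory(s, rot_frames)
  expect_equal(rmsd_series(tr2)$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_error(rmsd_series(tr, selection = "XX"), "empty")
})

test_that("isotropic noise gives mean RMSD of sigma*sqrt(3) at 500 atoms", {
  s <- make_structure(strrep("G", 125))  # 500 heavy atoms
  sigma <- 0.4
  tr <- make_noisy_trajectory(s, sigma, n_frames = 30, seed = 21)
  rs <- rmsd_series(tr, selection = all_atoms)
  expect_equal(mean(rs$rmsd), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf is zero for a static trajectory and d for a two-position atom", {
  s <- make_structure(strrep("G", 75))
  base <- bdascan:::coords_matrix(s)
  static <- trajectory(s, list(base, base, base, base))
  expect_equal(rmsf(static, selection = all_atoms)$rmsf,
               rep(0, nrow(base)), tolerance = 1e-10)
  expect_error(rmsf(trajectory(s, list(base))), "at least 2")
  # one mobile atom at +/- d in half the frames, the rest fixed
  d <- 1.5
  up <- base; up[10, 1] <- up[10, 1] + d
  dn <- base; dn[10, 1] <- dn[10, 1] - d
  tr <- trajectory(s, rep(list(up, dn), 20))
  vals <- rmsf(tr, selection = all_atoms)$rmsf
  expect_equal(vals[10], d, tolerance = 0.02)
  expect_lt(max(vals[-10]), 0.05)
})

test_that("rmsf recovers sigma*sqrt(3) from Gaussian noise within 5 percent", {
  s <- make_structure(strrep("G", 50))  # 200 heavy atoms
  sigma <- 0.5
  tr <- make_noisy_trajectory(s, sigma, n_frames = 500, seed = 33)
  vals <- rmsf(tr, selection = all_atoms)$rmsf
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsd and rmsf are invariant under a global rototranslation", {
  s <- make_structure(strrep("A", 10))
  tr <- make_noisy_trajectory(s, 0.3, 10, seed = 5)
  set.seed(6)
  rot <- random_rotation()
  shift <- c(3, -8, 12)
  moved <- trajectory(s, lapply(tr$frames, function(fr) {
    sweep(fr %*% t(rot), 2, shift, "+")
  }))
  expect_equal(rmsd_series(moved)$rmsd, rmsd_series(tr)$rmsd,
               tolerance = 1e-9)
  expect_equal(rmsf(moved)$rmsf, rmsf(tr)$rmsf, tolerance = 1e-9)
})

test_that("planted hydrogen bonds are found and over-distance pairs are not", {
  fx <- make_hbond_fixture(1, seed = 2)
  hb <- find_hbonds(fx$structure)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, fx$bonds$donor)
  expect_equal(hb$acceptor, fx$bonds$acceptor)
  expect_equal(hb$distance, 2.8, tolerance = 1e-6)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  # stretch the acceptor beyond the cutoff: bond disappears
  s2 <- fx$structure
  i <- s2$chain == "E"
  dir <- c(s2$x[i], s2$y[i], s2$z[i]) - c(s2$x[1], s2$y[1], s2$z[1])
  dir <- dir / sqrt(sum(dir^2))
  s2$x[i] <- s2$x[1] + 3.5 * dir[1]
  s2$y[i] <- s2$y[1] + 3.5 * dir[2]
  s2$z[i] <- s2$z[1] + 3.5 * dir[3]
  expect_equal(nrow(find_hbonds(s2, d_max = 3.0)), 0)
  expect_equal(nrow(find_hbonds(s2, d_max = 3.6)), 1)
})

test_that("detector precision and recall are exactly 1 on planted fixtures", {
  for (k in c(0, 3, 5)) {
    fx <- make_hbond_fixture(k, seed = k + 1)
    hb <- find_hbonds(fx$structure)
    expect_equal(nrow(hb), k)
    if (k > 0) {
      expect_setequal(paste(hb$donor, hb$acceptor),
                      paste(fx$bonds$donor, fx$bonds$acceptor))
    }
  }
})

test_that("heavy-atom mode finds donor-acceptor pairs without hydrogens", {
  fx <- make_hbond_fixture(3, seed = 4)
  s <- fx$structure[fx$structure$element != "H", ]
  hb <- find_hbonds(s, mode = "heavy")
  expect_equal(nrow(hb), 3)
})

make_conservation_fixture <- function(drop_partner = integer()) {
  # site residue A:1 with three N-H donors aimed at acceptors B:1..B:3
  rows <- list()
  ha <- bdascan:::solve_ha_distance(1.0, 2.8, 170)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in 1:3) {
    u <- dirs[[i]]
    w <- bdascan:::perpendicular_to(u)
    n_at <- 8 * u
    h_at <- n_at + u
    a_dir <- cos(10 * pi / 180) * u + sin(10 * pi / 180) * w
    a_at <- h_at + ha * a_dir
    if (i %in% drop_partner) a_at <- a_at + 10 * u
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "A", resnum = 1L, resname = "SIT",
      atom = paste0(c("N", "H"), i), element = c("N", "H"),
      x = c(n_at[1], h_at[1]), y = c(n_at[2], h_at[2]),
      z = c(n_at[3], h_at[3]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = "B", resnum = i, resname = "ACC", atom = "O",
      element = "O", x = a_at[1], y = a_at[2], z = a_at[3])
  }
  topo <- as_atom_table(dplyr::bind_rows(rows))
  trajectory(topo, rep(list(bdascan:::coords_matrix(topo)), 5))
}

test_that("hydrogen-bond conservation compares partner sets at the site", {
  wt <- make_conservation_fixture()
  expect_equal(hbond_conservation(wt, wt, "A:1")$conservation, 1.0)
  # partner displaced beyond the cutoff in all mutant frames
  mut_all <- make_conservation_fixture(drop_partner = 1:3)
  expect_equal(hbond_conservation(wt, mut_all, "A:1")$conservation, 0.0)
  # two of three partners shared
  mut <- make_conservation_fixture(drop_partner = 3)
  res <- hbond_conservation(wt, mut, "A:1")
  expect_equal(res$conservation, 2 / 3)
  expect_setequal(res$wt_partners, c("B:1:", "B:2:", "B:3:"))
  expect_setequal(res$mut_partners, c("B:1:", "B:2:"))
  expect_error(hbond_conservation(wt, mut, "Z:9"), "absent")
})

test_that("identical frames cluster into one full-population cluster", {
  s <- make_structure(strrep("A", 8))
  base <- bdascan:::coords_matrix(s)
  tr <- trajectory(s, rep(list(base), 6))
  cl <- cluster_trajectory(tr)
  expect_equal(nrow(cl$populations), 1)
  expect_equal(cl$populations$population, 1.0)
  expect_equal(sum(cl$populations$population), 1.0)
  expect_equal(unique(cl$labels), 1L)
})

test_that("two-state trajectories are recovered at the planted populations", {
  s <- make_structure(strrep("A", 12))
  ts <- make_two_state_trajectory(s, populations = c(0.7, 0.3),
                                  displacement = 6, sigma = 0.3,
                                  n_frames = 200, seed = 8)
  cl <- cluster_trajectory(ts$trajectory, cutoff = 1.5)
  expect_equal(glance(cl)$top_population, 0.70, tolerance = 0.02 / 0.70)
  # cluster labels agree with the generator's ground truth up to relabeling
  top_frames <- which(cl$labels == 1)
  truth_top <- which(ts$labels == 1)
  expect_gte(length(intersect(top_frames, truth_top)) /
               length(union(top_frames, truth_top)), 0.98)
})

test_that("leader clustering equals brute-force neighbour counting", {
  s <- make_structure(strrep("A", 10))
  ts <- make_two_state_trajectory(s, populations = c(0.6, 0.4),
                                  displacement = 5, sigma = 0.4,
                                  n_frames = 60, seed = 13)
  cl <- cluster_trajectory(ts$trajectory, cutoff = 1.5)
  oracle_labels <- leader_cluster_oracle(cl$rmsd_matrix, 1.5)
  # same partition (labels may be permuted by population ordering)
  expect_equal(length(unique(cl$labels)), length(unique(oracle_labels)))
  tab <- table(cl$labels, oracle_labels)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_equal(sum(cl$populations$population), 1.0, tolerance = 1e-9)
  # representative frame belongs to its own cluster
  for (i in seq_len(nrow(cl$populations))) {
    expect_equal(cl$labels[cl$populations$representative_frame[i]],
                 cl$populations$cluster[i])
  }
})

test_that("pairwise cluster RMSDs agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  s <- make_structure(strrep("A", 6))
  ts <- make_two_state_trajectory(s, n_frames = 10, seed = 3)
  cl <- cluster_trajectory(ts$trajectory, selection = all_atoms,
                           cutoff = 1.5)
  fr <- ts$trajectory$frames
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    ref <- bio3d::rmsd(as.vector(t(fr[[pair[1]]])),
                       as.vector(t(fr[[pair[2]]])), fit = TRUE)
    expect_equal(cl$rmsd_matrix[pair[1], pair[2]], ref,
                 tolerance = 2e-3)  # bio3d rounds to 3 digits
  }
})

test_that("comparing a trajectory with itself reports no differences", {
  wt <- make_conservation_fixture()
  cmp <- compare_trajectories(wt, wt, site = "A:1",
                              selection = function(t) t$element == "N",
                              hbond_mode = "all-atom")
  g <- glance(cmp)
  expect_equal(g$delta_mean_rmsd, 0, tolerance = 1e-12)
  expect_equal(g$hbond_conservation, 1.0)
  expect_equal(g$top_population_wt, g$top_population_mut)
  expect_equal(g$representative_rmsd, 0, tolerance = 1e-9)
  expect_equal(cmp$rmsf$delta, rep(0, nrow(cmp$rmsf)), tolerance = 1e-12)
  # report row counts match frame counts
  expect_equal(nrow(cmp$rmsd), 2 * length(wt$frames))
  expect_equal(nrow(cmp$hbond_counts), 2 * length(wt$frames))
})

test_that("comparison detects no spurious RMSD shift for equal dynamics", {
  s <- make_structure(strrep("A", 10))
  wt <- make_noisy_trajectory(s, 0.3, 40, seed = 1)
  mut <- make_noisy_trajectory(s, 0.3, 40, seed = 2)
  g <- glance(compare_trajectories(wt, mut))
  expect_lt(abs(g$delta_mean_rmsd), 0.05)
})
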