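make_tyr_context <- function() {
  s <- make_structure("GAYAG")
  scan <- build_cavity_scan(s, "TYR", "GLY")
  probe <- build_probe("phenylboronic_acid")
  native <- dplyr::filter(s, resnum == 3)
  ideal <- superpose_probe_on_residue(probe, native)
  list(s = s, scan = scan, probe = probe, native = native, ideal = ideal)
}

test_that("poses map to the nearest cavity centroid within the radius", {
  ctx <- make_tyr_context()
  hit <- assign_pose_to_site(ctx$ideal, ctx$scan$sites, probe = ctx$probe)
  expect_equal(hit$resnum, 3L)
  far <- ctx$ideal + 20
  expect_null(assign_pose_to_site(far, ctx$scan$sites, probe = ctx$probe))
  # two sites at 2 and 3 A from the pose centroid: nearest wins
  pc <- colMeans(ctx$ideal[ctx$probe$atoms$element != "H", ])
  sites <- tibble::tibble(
    chain = "A", resnum = c(10L, 11L), icode = "", resname = "TYR",
    centroid_x = pc[1] + c(2, 3), centroid_y = pc[2], centroid_z = pc[3])
  expect_equal(assign_pose_to_site(ctx$ideal, sites,
                                   probe = ctx$probe)$resnum, 10L)
  # brute-force check of the distances it ranked on
  d <- sqrt(colSums((t(as.matrix(
    sites[, c("centroid_x", "centroid_y", "centroid_z")])) - pc)^2))
  expect_equal(unname(which.min(d)), 1L)
})

test_that("directionality angle reproduces 0/90/180 identities", {
  ctx <- make_tyr_context()
  # the ideal superposed pose points the boron the way the native OH went
  expect_lt(directionality_angle(ctx$native, ctx$ideal, probe = ctx$probe),
            5)
  # flip the pose 180 degrees about the axis perpendicular to the residue
  # vector: opposite directionality
  nc <- bdascan:::residue_coords(ctx$native)
  axis_v <- nc["CZ", ] - nc["CB", ]
  perp <- bdascan:::unit_vec(bdascan:::pracma_cross(axis_v, c(0, 0, 1)))
  rot <- bdascan:::rotation_about_axis(perp, 180)
  ctr <- colMeans(ctx$ideal)
  flipped <- sweep(sweep(ctx$ideal, 2, ctr) %*% t(rot), 2, ctr, "+")
  rownames(flipped) <- rownames(ctx$ideal)
  expect_gt(directionality_angle(ctx$native, flipped, probe = ctx$probe),
            175)
  # synthetic orthogonal case via a hand-built mapping on unit vectors
  native <- as_atom_table(tibble::tibble(
    chain = "A", resnum = 1, resname = "TYR",
    atom = c("CB", "CZ"), element = "C",
    x = c(0, 1), y = 0, z = 0))
  pose <- rbind(C4 = c(0, 0, 0), B = c(0, 1, 0))
  colnames(pose) <- c("x", "y", "z")
  m <- vector_mapping("TYR")
  m$probe_vector$tail <- "C4"
  expect_equal(directionality_angle(native, pose, m), 90)
  pose_same <- rbind(C4 = c(5, 5, 5), B = c(6, 5, 5))
  colnames(pose_same) <- c("x", "y", "z")
  expect_equal(directionality_angle(native, pose_same, m), 0)
  pose_opp <- rbind(C4 = c(0, 0, 0), B = c(-2, 0, 0))
  colnames(pose_opp) <- c("x", "y", "z")
  expect_equal(directionality_angle(native, pose_opp, m), 180)
  # zero-length vector errors
  pose_zero <- rbind(C4 = c(0, 0, 0), B = c(0, 0, 0))
  colnames(pose_zero) <- c("x", "y", "z")
  expect_error(directionality_angle(native, pose_zero, m), "zero-length")
})

test_that("the angle is invariant under global rotations of all coordinates", {
  ctx <- make_tyr_context()
  base <- directionality_angle(ctx$native, ctx$ideal, probe = ctx$probe)
  set.seed(11)
  for (i in 1:5) {
    rot <- random_rotation()
    nat <- ctx$native
    nm <- as.matrix(nat[, c("x", "y", "z")]) %*% t(rot)
    nat$x <- nm[, 1]; nat$y <- nm[, 2]; nat$z <- nm[, 3]
    pose <- ctx$ideal %*% t(rot)
    rownames(pose) <- rownames(ctx$ideal)
    expect_equal(directionality_angle(nat, pose, probe = ctx$probe), base,
                 tolerance = 1e-6)
  }
})

test_that("reference distance is plain Euclidean distance on mapped atoms", {
  native <- as_atom_table(tibble::tibble(
    chain = "A", resnum = 1, resname = "TYR", atom = c("CB", "CZ"),
    element = "C", x = c(0, 0), y = 0, z = c(0, 0)))
  pose <- rbind(C1 = c(0, 0, 2), B = c(0, 0, 3.5))
  colnames(pose) <- c("x", "y", "z")
  expect_equal(reference_distance(native, pose), 2)
  pose2 <- pose
  pose2["C1", ] <- c(0, 0, 0)
  expect_equal(reference_distance(native, pose2), 0)
  # independent recomputation from raw coordinates
  set.seed(3)
  pose3 <- pose
  pose3["C1", ] <- rnorm(3)
  cz <- as.numeric(native[native$atom == "CZ", c("x", "y", "z")])
  expect_equal(reference_distance(native, pose3),
               sqrt(sum((pose3["C1", ] - cz)^2)))
  pose_bad <- pose
  rownames(pose_bad) <- c("CX", "B")
  expect_error(reference_distance(native, pose_bad), "C1")
})

test_that("clash counting applies the vdW overlap rule monotonically", {
  rec <- as_atom_table(tibble::tibble(
    chain = "R", resnum = 1, resname = "GLY", atom = "CA", element = "C",
    x = 0, y = 0, z = 0))
  pose <- rbind(C1 = c(1, 0, 0))
  colnames(pose) <- c("x", "y", "z")
  # C-C vdW sum 3.4; 0.6 * 3.4 = 2.04 > 1.0 -> clash
  expect_gte(clash_count(pose, rec), 1)
  pose_far <- rbind(C1 = c(2.1, 0, 0))
  colnames(pose_far) <- c("x", "y", "z")
  expect_equal(clash_count(pose_far, rec, overlap_factor = 0.6), 0)
  # isolated pose has no clashes
  pose_iso <- rbind(C1 = c(30, 0, 0))
  colnames(pose_iso) <- c("x", "y", "z")
  expect_equal(clash_count(pose_iso, rec), 0)
  # raising the overlap factor never lowers the count
  factors <- seq(0.3, 1.2, by = 0.1)
  counts <- sapply(factors, function(f) {
    clash_count(pose_far, rec, overlap_factor = f)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("evaluation accepts the ideal re-occupying pose and makes it champion", {
  ctx <- make_tyr_context()
  poses <- tibble::tibble(probe_name = ctx$probe$name, mode_rank = 1L,
                          affinity = -5.6, coords = list(ctx$ideal))
  ev <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                          ctx$s, ctx$probe)
  expect_equal(ev$evaluations$verdict, "accept")
  expect_equal(nrow(ev$champions), 1)
  expect_equal(ev$champions$site, "A:3")
  expect_equal(glance(ev)$best_affinity, -5.6)
})

test_that("opposite-directionality poses are rejected with the right reason", {
  ctx <- make_tyr_context()
  nc <- bdascan:::residue_coords(ctx$native)
  perp <- bdascan:::unit_vec(
    bdascan:::pracma_cross(nc["CZ", ] - nc["CB", ], c(0, 0, 1)))
  rot <- bdascan:::rotation_about_axis(perp, 180)
  ctr <- colMeans(ctx$ideal)
  flipped <- sweep(sweep(ctx$ideal, 2, ctr) %*% t(rot), 2, ctr, "+")
  rownames(flipped) <- rownames(ctx$ideal)
  poses <- tibble::tibble(probe_name = ctx$probe$name, mode_rank = 1L,
                          affinity = -5.0, coords = list(flipped))
  ev <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                          ctx$s, ctx$probe,
                          thresholds = pose_thresholds(d_max = 10,
                                                       overlap_factor = 0))
  expect_equal(ev$evaluations$verdict, "reject")
  expect_match(ev$evaluations$reasons, "directionality")
})

test_that("the champion is the accepted pose with the lowest affinity", {
  ctx <- make_tyr_context()
  poses <- tibble::tibble(probe_name = ctx$probe$name, mode_rank = 1:2,
                          affinity = c(-4.2, -5.6),
                          coords = list(ctx$ideal, ctx$ideal))
  ev <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                          ctx$s, ctx$probe)
  expect_equal(sum(ev$evaluations$verdict == "accept"), 2)
  expect_equal(ev$champions$affinity, -5.6)
})

test_that("verdicts are pure in the inputs: permuting poses changes only order", {
  ctx <- make_tyr_context()
  far <- ctx$ideal + 30
  poses <- tibble::tibble(probe_name = ctx$probe$name, mode_rank = 1:3,
                          affinity = c(-5.6, -4.0, -3.0),
                          coords = list(ctx$ideal, far, ctx$ideal + 2))
  ev1 <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                           ctx$s, ctx$probe)
  perm <- poses[c(3, 1, 2), ]
  ev2 <- evaluate_and_rank(perm, ctx$scan$sites, ctx$scan$structure,
                           ctx$s, ctx$probe)
  key <- function(e) {
    o <- e$evaluations[order(e$evaluations$mode_rank), ]
    o[c("mode_rank", "verdict", "reasons", "distance", "angle")]
  }
  expect_equal(key(ev1), key(ev2))
})

test_that("tightening any threshold never converts a reject into an accept", {
  ctx <- make_tyr_context()
  set.seed(5)
  jitter <- matrix(rnorm(length(ctx$ideal), 0, 1.0), nrow(ctx$ideal), 3)
  poses <- tibble::tibble(
    probe_name = ctx$probe$name, mode_rank = 1:3,
    affinity = c(-5, -4, -3),
    coords = list(ctx$ideal, ctx$ideal + jitter, ctx$ideal + 4))
  base_th <- pose_thresholds()
  base <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                            ctx$s, ctx$probe, thresholds = base_th)
  tighter <- list(
    pose_thresholds(d_max = base_th$d_max / 2),
    pose_thresholds(theta_max = base_th$theta_max / 2),
    pose_thresholds(r_cavity = base_th$r_cavity / 2),
    pose_thresholds(overlap_factor = base_th$overlap_factor * 1.5))
  for (th in tighter) {
    ev <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                            ctx$s, ctx$probe, thresholds = th)
    was_reject <- base$evaluations$verdict[order(base$evaluations$mode_rank)]
    now <- ev$evaluations$verdict[order(ev$evaluations$mode_rank)]
    expect_true(all(!(was_reject == "reject" & now == "accept")))
  }
})

test_that("per-restype mappings cover all four residue types", {
  for (rt in c("PHE", "TYR", "TRP", "HIS")) {
    m <- vector_mapping(rt)
    expect_equal(m$residue_vector$tail, "CB")
    expect_equal(unname(m$reference_carbon_pair[["probe"]]), "C1")
  }
  expect_equal(vector_mapping("HIS")$residue_vector$head, c("NE2", "CE1"))
  expect_equal(vector_mapping("TYR", residue_tail = "CG")$residue_vector$tail,
               "CG")
})

test_that("pose reports round-trip through TSV and JSON", {
  ctx <- make_tyr_context()
  poses <- tibble::tibble(probe_name = ctx$probe$name, mode_rank = 1L,
                          affinity = -5.6, coords = list(ctx$ideal))
  ev <- evaluate_and_rank(poses, ctx$scan$sites, ctx$scan$structure,
                          ctx$s, ctx$probe)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_pose_report(ev, tsv, js)
  expect_equal(nrow(utils::read.delim(tsv)), 1)
  expect_equal(jsonlite::read_json(js)[[1]]$site, "A:3")
})
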