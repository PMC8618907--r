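#' Kabsch least-squares superposition
#'
#' Optimal rigid alignment of `mov` onto `ref` minimising (weighted) RMSD,
#' with the reflection corrected so the rotation is proper
#' (det = +1). Aligned coordinates are `mov %*% rotation + translation`
#' (see [apply_superposition()]).
#'
#' @param ref_coords,mov_coords `n x 3` matrices, equal `n >= 3`,
#'   non-degenerate.
#' @param weights Optional non-negative per-point weights.
#' @return A `bda_superposition`: list with `rotation` (3x3), `translation`
#'   (3-vector) and `rmsd` (Angstrom).
#' @export
kabsch <- function(ref_coords, mov_coords, weights = NULL) {
  ref <- as.matrix(ref_coords)
  mov <- as.matrix(mov_coords)
  n <- nrow(ref)
  if (n < 3 || nrow(mov) != n) {
    stop("kabsch needs two equal point sets with at least 3 points",
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cr <- colSums(ref * w)
  cm <- colSums(mov * w)
  refc <- sweep(ref, 2, cr)
  movc <- sweep(mov, 2, cm)
  if (qr(refc * sqrt(w))$rank < 2) {
    stop("degenerate (collinear) reference points", call. = FALSE)
  }
  h <- t(movc * w) %*% refc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- movc %*% rot
  rmsd <- sqrt(sum(w * rowSums((aligned - refc)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd),
            class = "bda_superposition")
}

#' @export
print.bda_superposition <- function(x, ...) {
  cat("<bda_superposition> rmsd = ", format(x$rmsd, digits = 4), " A\n",
      sep = "")
  invisible(x)
}

#' @rdname kabsch
#' @param x A `bda_superposition`.
#' @param ... Unused.
#' @export
glance.bda_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, det = det(x$rotation))
}

#' @rdname kabsch
#' @param sup A `bda_superposition`.
#' @param coords Coordinates to transform.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

select_rows <- function(topology, selection) {
  if (is.function(selection)) {
    which(selection(topology))
  } else if (is.character(selection)) {
    which(topology$atom %in% selection & is_heavy(topology))
  } else {
    as.integer(selection)
  }
}

#' Per-frame RMSD series against a reference
#'
#' Kabsch-minimised RMSD of each frame against the reference coordinates,
#' on the selected atoms (default C-alpha). Reported per chain and overall.
#'
#' @param traj A [trajectory()].
#' @param ref Reference atom table or coordinate matrix; defaults to the
#'   trajectory topology.
#' @param selection Atom names (default `"CA"`), a predicate on the
#'   topology, or row indices.
#' @return Tibble: `frame`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, ref = NULL, selection = "CA") {
  idx <- select_rows(traj$topology, selection)
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  refm <- if (is.null(ref)) {
    coords_matrix(traj$topology)
  } else if (is.matrix(ref)) {
    ref
  } else {
    coords_matrix(as_atom_table(ref))
  }
  refm <- refm[idx, , drop = FALSE]
  tibble::tibble(
    frame = traj$frame_index,
    rmsd = vapply(traj$frames, function(fr) {
      kabsch(refm, fr[idx, , drop = FALSE])$rmsd
    }, numeric(1))
  )
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation about the mean structure. Frames are
#' superposed onto the running average structure (two iterations) before
#' fluctuations are measured, so rigid-body motion does not inflate the
#' values.
#'
#' @inheritParams rmsd_series
#' @return Tibble: `chain`, `resnum`, `icode`, `resname`, `atom`, `rmsf`
#'   (Angstrom), one row per selected atom.
#' @export
rmsf <- function(traj, selection = "CA") {
  if (length(traj$frames) < 2) {
    stop("RMSF needs at least 2 frames", call. = FALSE)
  }
  idx <- select_rows(traj$topology, selection)
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  frames <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  mean_coords <- Reduce(`+`, frames) / length(frames)
  for (it in 1:2) {
    frames <- lapply(frames, function(fr) {
      apply_superposition(kabsch(mean_coords, fr), fr)
    })
    mean_coords <- Reduce(`+`, frames) / length(frames)
  }
  dev2 <- Reduce(`+`, lapply(frames, function(fr) {
    rowSums((fr - mean_coords)^2)
  })) / length(frames)
  topo <- traj$topology[idx, ]
  tibble::tibble(chain = topo$chain, resnum = topo$resnum,
                 icode = topo$icode, resname = topo$resname,
                 atom = topo$atom, rmsf = unname(sqrt(dev2)))
}

#' Geometric hydrogen-bond detection in one frame
#'
#' All-atom mode: a bond is a donor N/O with an attached hydrogen, an
#' acceptor N/O in another residue, donor-acceptor distance at most `d_max`
#' and D-H...A angle at least `angle_min`. Heavy-atom mode (for
#' hydrogen-free coordinates) uses the distance cutoff plus the requirement
#' that the angle at the donor between its bonded heavy neighbour and the
#' acceptor opens to at least 90 degrees. Boronic-acid hydroxyls donate
#' and their oxygens accept like any other O-H.
#'
#' @param frame Coordinate matrix congruent with `topology`, or `NULL` to
#'   use the topology coordinates.
#' @param topology Atom table.
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum D-H...A angle, degrees.
#' @param mode `"all-atom"` or `"heavy"`.
#' @return Tibble: `donor`, `hydrogen`, `acceptor` (atom ids
#'   `chain:resnum:atom`), `donor_res`, `acceptor_res`, `distance`, `angle`.
#' @export
find_hbonds <- function(topology, frame = NULL, d_max = 3.0,
                        angle_min = 135, mode = c("all-atom", "heavy")) {
  mode <- match.arg(mode)
  topo <- as_atom_table(topology)
  m <- if (is.null(frame)) coords_matrix(topo) else as.matrix(frame)
  el <- toupper(topo$element)
  polar <- which(el %in% c("N", "O"))
  empty <- tibble::tibble(donor = character(), hydrogen = character(),
                          acceptor = character(), donor_res = character(),
                          acceptor_res = character(), distance = double(),
                          angle = double())
  if (length(polar) == 0) return(empty)
  rid <- res_id(topo)
  aid <- paste(rid, topo$atom, sep = ":")
  hyd <- which(el == "H")
  # hydrogens belong to the nearest polar atom within covalent range
  h_parent <- rep(NA_integer_, nrow(topo))
  if (length(hyd) > 0 && length(polar) > 0) {
    dh <- cross_dist(m[hyd, , drop = FALSE], m[polar, , drop = FALSE])
    nearest <- apply(dh, 1, which.min)
    ok <- dh[cbind(seq_along(hyd), nearest)] <= 1.25
    h_parent[hyd[ok]] <- polar[nearest[ok]]
  }
  donors <- if (mode == "all-atom") {
    unique(stats::na.omit(h_parent))
  } else {
    polar
  }
  if (length(donors) == 0) return(empty)
  dd <- cross_dist(m[donors, , drop = FALSE], m[polar, , drop = FALSE])
  cand <- which(dd <= d_max & dd > 0.1, arr.ind = TRUE)
  out <- list()
  for (k in seq_len(nrow(cand))) {
    di <- donors[cand[k, 1]]
    ai <- polar[cand[k, 2]]
    if (rid[di] == rid[ai]) next
    # heavy mode cannot tell donor from acceptor: keep each pair once
    if (mode == "heavy" && ai < di) next
    if (mode == "all-atom") {
      hs <- which(h_parent == di)
      best <- NULL
      for (hi in hs) {
        ang <- vec_angle_deg(m[di, ] - m[hi, ], m[ai, ] - m[hi, ])
        if (ang >= angle_min && (is.null(best) || ang > best$angle)) {
          best <- list(h = hi, angle = ang)
        }
      }
      if (is.null(best)) next
      out[[length(out) + 1]] <- tibble::tibble(
        donor = aid[di], hydrogen = aid[best$h], acceptor = aid[ai],
        donor_res = rid[di], acceptor_res = rid[ai],
        distance = dd[cand[k, 1], cand[k, 2]], angle = best$angle)
    } else {
      nb <- heavy_neighbour(topo, m, di)
      ang <- if (is.null(nb)) 180 else {
        vec_angle_deg(m[nb, ] - m[di, ], m[ai, ] - m[di, ])
      }
      if (ang < 90) next
      out[[length(out) + 1]] <- tibble::tibble(
        donor = aid[di], hydrogen = NA_character_, acceptor = aid[ai],
        donor_res = rid[di], acceptor_res = rid[ai],
        distance = dd[cand[k, 1], cand[k, 2]], angle = ang)
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

heavy_neighbour <- function(topo, m, i) {
  heavy <- which(is_heavy(topo))
  heavy <- setdiff(heavy, i)
  if (length(heavy) == 0) return(NULL)
  d <- sqrt(colSums((t(m[heavy, , drop = FALSE]) - m[i, ])^2))
  j <- which.min(d)
  if (d[j] <= 1.8) heavy[j] else NULL
}

#' Per-frame hydrogen bonds over a trajectory
#'
#' @inheritParams find_hbonds
#' @param traj A [trajectory()].
#' @return Tibble of per-frame bonds with a `frame` column.
#' @export
hbond_series <- function(traj, d_max = 3.0, angle_min = 135,
                         mode = c("all-atom", "heavy")) {
  mode <- match.arg(mode)
  purrr::map2_dfr(traj$frames, traj$frame_index, function(fr, i) {
    hb <- find_hbonds(traj$topology, fr, d_max, angle_min, mode)
    if (nrow(hb) > 0) hb$frame <- i else hb$frame <- integer()
    hb
  })
}

#' Hydrogen-bond partner conservation at a mutated site
#'
#' Compares the hydrogen-bonding partner residues of a site between two
#' trajectories (wild type and mutant). A partner counts if it appears in
#' at least `occupancy_min` of frames. Conservation is the fraction of
#' wild-type partners retained by the mutant (1 when both sets are empty).
#'
#' @param wt_traj,mut_traj [trajectory()] objects sharing residue
#'   numbering.
#' @param site Residue id `"chain:resnum"` (or `"chain:resnum:icode"`).
#' @param occupancy_min Minimum fraction of frames (default 0.1).
#' @inheritParams find_hbonds
#' @return List: `conservation`, `wt_partners`, `mut_partners`.
#' @export
hbond_conservation <- function(wt_traj, mut_traj, site,
                               occupancy_min = 0.1, d_max = 3.0,
                               angle_min = 135,
                               mode = c("all-atom", "heavy")) {
  mode <- match.arg(mode)
  site <- if (grepl("^[^:]+:[^:]+$", site)) paste0(site, ":") else site
  for (tr in list(wt_traj, mut_traj)) {
    if (!site %in% res_id(tr$topology)) {
      stop("site ", site, " absent from trajectory topology", call. = FALSE)
    }
  }
  partners <- function(traj) {
    hb <- hbond_series(traj, d_max, angle_min, mode)
    hb <- hb[hb$donor_res == site | hb$acceptor_res == site, ]
    if (nrow(hb) == 0) return(character())
    hb$partner <- ifelse(hb$donor_res == site, hb$acceptor_res,
                         hb$donor_res)
    occ <- hb |>
      dplyr::distinct(.data$frame, .data$partner) |>
      dplyr::count(.data$partner)
    occ$partner[occ$n / length(traj$frames) >= occupancy_min]
  }
  wt <- partners(wt_traj)
  mut <- partners(mut_traj)
  cons <- if (length(wt) == 0) {
    if (length(mut) == 0) 1.0 else 1.0
  } else {
    length(intersect(wt, mut)) / length(wt)
  }
  list(conservation = cons, wt_partners = sort(wt),
       mut_partners = sort(mut))
}

#' Conformational clustering of a trajectory (leader algorithm)
#'
#' GROMOS-style leader clustering on pairwise Kabsch RMSD over the selected
#' atoms: repeatedly take the unassigned frame with the most unassigned
#' neighbours within `cutoff` as the next cluster's medoid (ties broken by
#' lowest frame index), assign it and its neighbours, and repeat.
#' Deterministic by construction.
#'
#' @inheritParams rmsd_series
#' @param cutoff Neighbour RMSD cutoff, Angstrom (default 1.5).
#' @return A `bda_cluster`: list with `labels` (per-frame cluster id, in
#'   population order), `populations` tibble (`cluster`, `n`, `population`,
#'   `representative_frame` — the medoid), and the `rmsd_matrix`.
#' @export
cluster_trajectory <- function(traj, selection = "CA", cutoff = 1.5) {
  stopifnot(cutoff > 0, length(traj$frames) >= 1)
  idx <- select_rows(traj$topology, selection)
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  n <- length(traj$frames)
  sel <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  rm <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        rm[i, j] <- rm[j, i] <- kabsch(sel[[i]], sel[[j]])$rmsd
      }
    }
  }
  labels <- rep(NA_integer_, n)
  medoids <- integer()
  cl <- 0L
  unassigned <- seq_len(n)
  while (length(unassigned) > 0) {
    cl <- cl + 1L
    counts <- vapply(unassigned, function(i) {
      sum(rm[i, unassigned] <= cutoff)  # includes self
    }, numeric(1))
    leader <- unassigned[which.max(counts)]  # which.max = lowest index tie
    members <- unassigned[rm[leader, unassigned] <= cutoff]
    labels[members] <- cl
    medoids[cl] <- leader
    unassigned <- setdiff(unassigned, members)
  }
  pops <- tibble::tibble(
    cluster = seq_len(cl),
    n = as.integer(table(factor(labels, levels = seq_len(cl)))),
    representative_frame = traj$frame_index[medoids]
  )
  pops$population <- pops$n / n
  pops <- pops[order(-pops$n, pops$cluster), ]
  relabel <- match(seq_len(cl), pops$cluster)
  pops$cluster <- seq_len(cl)
  structure(list(labels = relabel[labels],
                 populations = pops[c("cluster", "n", "population",
                                      "representative_frame")],
                 rmsd_matrix = rm, cutoff = cutoff),
            class = "bda_cluster")
}

#' @export
print.bda_cluster <- function(x, ...) {
  cat("<bda_cluster> ", nrow(x$populations), " clusters; top population ",
      format(x$populations$population[1], digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname cluster_trajectory
#' @param x A `bda_cluster`.
#' @param ... Unused.
#' @export
tidy.bda_cluster <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$labels), cluster = x$labels)
}

#' @rdname cluster_trajectory
#' @export
glance.bda_cluster <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$populations),
                 top_population = x$populations$population[1],
                 representative_frame = x$populations$representative_frame[1])
}

#' Wild-type versus mutant trajectory comparison
#'
#' Assembles the folding-evaluation report: per-frame RMSD series for both
#' trajectories, per-residue RMSF pair with deltas, per-frame hydrogen-bond
#' counts (the wild-type total is the scale reference), hydrogen-bond
#' partner conservation at the mutated site, cluster populations, and the
#' RMSD between the two top-cluster representative structures.
#'
#' @param wt_traj,mut_traj [trajectory()] objects.
#' @param site Optional mutated-site residue id `"chain:resnum"` for
#'   hydrogen-bond conservation.
#' @param selection Atom selection for RMSD/RMSF/clustering (default CA).
#' @param cutoff Clustering RMSD cutoff, Angstrom.
#' @param hbond_mode `"all-atom"` or `"heavy"`.
#' @param d_max,angle_min Hydrogen-bond criteria.
#' @return A `bda_comparison` list with tibbles `rmsd` (frame, series,
#'   rmsd), `rmsf` (per residue, both series and delta), `hbond_counts`,
#'   `clusters`, plus `conservation` and `representative_rmsd` scalars.
#' @export
compare_trajectories <- function(wt_traj, mut_traj, site = NULL,
                                 selection = "CA", cutoff = 1.5,
                                 hbond_mode = c("heavy", "all-atom"),
                                 d_max = 3.0, angle_min = 135) {
  hbond_mode <- match.arg(hbond_mode)
  rmsd_tbl <- dplyr::bind_rows(
    dplyr::mutate(rmsd_series(wt_traj, selection = selection),
                  series = "wt"),
    dplyr::mutate(rmsd_series(mut_traj, selection = selection),
                  series = "mutant"))
  rmsf_wt <- dplyr::rename(rmsf(wt_traj, selection), rmsf_wt = "rmsf")
  rmsf_mut <- dplyr::rename(rmsf(mut_traj, selection), rmsf_mut = "rmsf")
  rmsf_tbl <- dplyr::inner_join(
    rmsf_wt, rmsf_mut[c("chain", "resnum", "icode", "atom", "rmsf_mut")],
    by = c("chain", "resnum", "icode", "atom"))
  rmsf_tbl$delta <- rmsf_tbl$rmsf_mut - rmsf_tbl$rmsf_wt
  hb_counts <- dplyr::bind_rows(
    count_hbonds_per_frame(wt_traj, d_max, angle_min, hbond_mode, "wt"),
    count_hbonds_per_frame(mut_traj, d_max, angle_min, hbond_mode,
                           "mutant"))
  cl_wt <- cluster_trajectory(wt_traj, selection, cutoff)
  cl_mut <- cluster_trajectory(mut_traj, selection, cutoff)
  clusters <- dplyr::bind_rows(
    dplyr::mutate(cl_wt$populations, series = "wt"),
    dplyr::mutate(cl_mut$populations, series = "mutant"))
  idx_wt <- match(cl_wt$populations$representative_frame[1],
                  wt_traj$frame_index)
  idx_mut <- match(cl_mut$populations$representative_frame[1],
                   mut_traj$frame_index)
  sel_wt <- select_rows(wt_traj$topology, selection)
  sel_mut <- select_rows(mut_traj$topology, selection)
  rep_rmsd <- if (length(sel_wt) == length(sel_mut)) {
    kabsch(wt_traj$frames[[idx_wt]][sel_wt, , drop = FALSE],
           mut_traj$frames[[idx_mut]][sel_mut, , drop = FALSE])$rmsd
  } else {
    NA_real_
  }
  cons <- if (!is.null(site)) {
    hbond_conservation(wt_traj, mut_traj, site, d_max = d_max,
                       angle_min = angle_min, mode = hbond_mode)
  } else {
    NULL
  }
  structure(list(rmsd = rmsd_tbl, rmsf = rmsf_tbl,
                 hbond_counts = hb_counts, clusters = clusters,
                 conservation = cons, representative_rmsd = rep_rmsd,
                 site = site),
            class = "bda_comparison")
}

count_hbonds_per_frame <- function(traj, d_max, angle_min, mode, label) {
  hb <- hbond_series(traj, d_max, angle_min, mode)
  counts <- tibble::tibble(frame = traj$frame_index) |>
    dplyr::left_join(dplyr::count(hb, .data$frame), by = "frame")
  counts$n[is.na(counts$n)] <- 0L
  counts$series <- label
  counts
}

#' @export
print.bda_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<bda_comparison> mean RMSD wt ", format(g$mean_rmsd_wt, digits = 3),
      " A, mutant ", format(g$mean_rmsd_mut, digits = 3), " A; ",
      "top cluster ", format(g$top_population_wt, digits = 3), " vs ",
      format(g$top_population_mut, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname compare_trajectories
#' @param x A `bda_comparison`.
#' @param ... Unused.
#' @export
tidy.bda_comparison <- function(x, ...) x$rmsd

#' @rdname compare_trajectories
#' @export
glance.bda_comparison <- function(x, ...) {
  mw <- mean(x$rmsd$rmsd[x$rmsd$series == "wt"])
  mm <- mean(x$rmsd$rmsd[x$rmsd$series == "mutant"])
  tibble::tibble(
    mean_rmsd_wt = mw,
    mean_rmsd_mut = mm,
    sd_rmsd_wt = stats::sd(x$rmsd$rmsd[x$rmsd$series == "wt"]),
    sd_rmsd_mut = stats::sd(x$rmsd$rmsd[x$rmsd$series == "mutant"]),
    delta_mean_rmsd = mm - mw,
    mean_hbonds_wt = mean(x$hbond_counts$n[x$hbond_counts$series == "wt"]),
    mean_hbonds_mut =
      mean(x$hbond_counts$n[x$hbond_counts$series == "mutant"]),
    top_population_wt =
      x$clusters$population[x$clusters$series == "wt"][1],
    top_population_mut =
      x$clusters$population[x$clusters$series == "mutant"][1],
    representative_rmsd = x$representative_rmsd,
    hbond_conservation = if (is.null(x$conservation)) NA_real_
    else x$conservation$conservation
  )
}
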