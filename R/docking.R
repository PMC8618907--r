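#' Docking grid box
#'
#' @param center Numeric 3-vector, Angstrom.
#' @param size Numeric 3-vector of edge lengths, Angstrom (all > 0).
#' @return A `bda_grid_box` list. The cetuximab case study used a blind box
#'   of 56 x 64 x 88 A centred at (32.771, 37.27, 32.376).
#' @export
grid_box <- function(center, size) {
  center <- as.numeric(center)
  size <- as.numeric(size)
  stopifnot(length(center) == 3, length(size) == 3, all(size > 0))
  structure(list(center = center, size = size), class = "bda_grid_box")
}

box_min <- function(box) box$center - box$size / 2
box_max <- function(box) box$center + box$size / 2

#' Dock a fragment probe into a receptor
#'
#' Engine contract with three implementations:
#'
#' * `"builtin"` — the deterministic exhaustive grid scan
#'   ([builtin_grid_scan()]); a fully reproducible test scaffold, not a
#'   physics engine.
#' * `"vina"` — adapter around an external AutoDock-Vina-compatible
#'   executable (`params$exe`, default `"vina"`); writes receptor and ligand
#'   PDBQT (waters/ions stripped from the receptor), runs blind docking with
#'   `energy_range` 4 and `num_modes` 20 by default, and parses the output.
#' * `"replay"` — re-reads poses from `params$poses_file` (a Vina-dialect
#'   multi-model PDBQT), for reproducible downstream analysis.
#'
#' @param receptor Atom table of the (mutated) receptor.
#' @param probe A [build_probe()] object.
#' @param box A [grid_box()].
#' @param engine `"builtin"`, `"vina"` or `"replay"`.
#' @param params Engine parameters list; see details above and
#'   [builtin_grid_scan()].
#' @return Pose tibble: `probe_name`, `mode_rank`, `affinity` (kcal/mol for
#'   vina/replay; contact score for builtin), list-column `coords`
#'   (atom-name-rowed matrices), sorted by affinity ascending.
#' @export
dock <- function(receptor, probe, box,
                 engine = c("builtin", "vina", "replay"), params = list()) {
  engine <- match.arg(engine)
  if (engine == "builtin") {
    poses <- builtin_grid_scan(receptor, probe, box,
                               step = params$step %||% 2,
                               rotations = params$rotations %||% 8,
                               top_k = params$num_modes %||% 20)
  } else if (engine == "replay") {
    if (is.null(params$poses_file)) {
      stop("replay engine needs params$poses_file", call. = FALSE)
    }
    poses <- parse_vina_pdbqt(params$poses_file)
    poses$probe_name <- probe$name
  } else {
    poses <- vina_dock(receptor, probe, box, params)
  }
  poses <- poses[order(poses$affinity), ]
  poses$mode_rank <- seq_len(nrow(poses))
  poses
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic built-in grid-scan docking engine
#'
#' Exhaustive rigid placement of the probe on a cubic lattice (spacing
#' `step`) crossed with a fixed deterministic rotation set. The score of a
#' placement sums, over probe heavy atoms, `-1` for every receptor heavy
#' atom within 3.0-4.5 A (a contact) and `+10` for every receptor heavy
#' atom closer than 2.5 A (a clash). Lower is better; ties are broken by
#' lattice enumeration order, so repeated runs are identical. This engine
#' is a fully specified test scaffold for the pipeline, not a docking
#' scoring function.
#'
#' @inheritParams dock
#' @param step Lattice spacing, Angstrom.
#' @param rotations Number of rigid orientations (deterministic set).
#' @param top_k Number of poses to keep.
#' @return Pose tibble as in [dock()], with `affinity` = contact score.
#' @export
builtin_grid_scan <- function(receptor, probe, box, step = 2,
                              rotations = 8, top_k = 20) {
  stopifnot(step > 0)
  receptor <- as_atom_table(receptor)
  rec <- coords_matrix(receptor[is_heavy(receptor), ])
  pm <- coords_matrix(probe$atoms)
  heavy <- probe$atoms$element != "H"
  pc <- centroid_xyz(probe$atoms)
  centered <- sweep(pm, 2, pc)
  lo <- box_min(box); hi <- box_max(box)
  gx <- seq(lo[1], hi[1], by = step)
  gy <- seq(lo[2], hi[2], by = step)
  gz <- seq(lo[3], hi[3], by = step)
  if (length(gx) == 0 || length(gy) == 0 || length(gz) == 0) {
    stop("zero lattice points in box at step ", step, call. = FALSE)
  }
  rots <- rotation_set(rotations)
  lattice <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                   KEEP.OUT.ATTRS = FALSE))
  results <- list()
  for (ri in seq_along(rots)) {
    rotated <- centered %*% t(rots[[ri]])
    rh <- rotated[heavy, , drop = FALSE]
    for (li in seq_len(nrow(lattice))) {
      placed_h <- sweep(rh, 2, lattice[li, ], "+")
      s <- score_contacts(placed_h, rec)
      results[[length(results) + 1]] <-
        c(score = s, rot = ri, lat = li)
    }
  }
  res <- do.call(rbind, results)
  ord <- order(res[, "score"], res[, "lat"], res[, "rot"])
  keep <- ord[seq_len(min(top_k, nrow(res)))]
  coords <- lapply(keep, function(k) {
    m <- sweep(centered %*% t(rots[[res[k, "rot"]]]), 2,
               lattice[res[k, "lat"], ], "+")
    rownames(m) <- probe$atoms$atom
    colnames(m) <- c("x", "y", "z")
    m
  })
  tibble::tibble(probe_name = probe$name,
                 mode_rank = seq_along(keep),
                 affinity = res[keep, "score"],
                 coords = coords)
}

score_contacts <- function(probe_heavy, rec_heavy) {
  d <- cross_dist(probe_heavy, rec_heavy)
  sum(d >= 3.0 & d <= 4.5) * -1 + sum(d < 2.5) * 10
}

#' Parse AutoDock-Vina multi-model output PDBQT
#'
#' @param path PDBQT file with one `MODEL` per pose and a
#'   `REMARK VINA RESULT` line giving the affinity (kcal/mol).
#' @return Pose tibble as in [dock()] (without `probe_name`).
#' @export
parse_vina_pdbqt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0) {
    stop("no MODEL records in ", path, call. = FALSE)
  }
  ends <- c(starts[-1] - 1, length(lines))
  poses <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    res <- grep("^REMARK VINA RESULT", block, value = TRUE)
    if (length(res) == 0) {
      stop("MODEL starting at line ", s, " has no 'REMARK VINA RESULT'",
           call. = FALSE)
    }
    aff <- as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:?", "",
                                          res[1])), "[[:space:]]+")[[1]][1])
    at <- block[startsWith(block, "ATOM") | startsWith(block, "HETATM")]
    m <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
    rownames(m) <- trimws(substr(at, 13, 16))
    colnames(m) <- c("x", "y", "z")
    list(affinity = aff, coords = m)
  })
  out <- tibble::tibble(
    mode_rank = seq_along(poses),
    affinity = vapply(poses, `[[`, numeric(1), "affinity"),
    coords = lapply(poses, `[[`, "coords")
  )
  out[order(out$affinity), ]
}

#' Write poses as a Vina-dialect multi-model PDBQT
#'
#' Inverse of [parse_vina_pdbqt()]; used by the replay engine and tests.
#'
#' @param poses Pose tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_pdbqt <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(poses))) {
    writeLines(sprintf("MODEL %d", i), con)
    writeLines(sprintf("REMARK VINA RESULT:   %8.3f      0.000      0.000",
                       poses$affinity[i]), con)
    m <- poses$coords[[i]]
    nm <- rownames(m)
    writeLines(sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f",
                       seq_len(nrow(m)), nm, m[, 1], m[, 2], m[, 3]), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

# External Vina-compatible adapter. Kept thin: prepare inputs, shell out,
# parse. A fixed seed is passed for best-effort reproducibility.
vina_dock <- function(receptor, probe, box, params) {
  exe <- params$exe %||% "vina"
  if (Sys.which(exe) == "") {
    stop("external docking engine '", exe, "' not found on PATH; install ",
         "an AutoDock-Vina-compatible binary or use engine = 'builtin'",
         call. = FALSE)
  }
  dir <- tempfile("vina")
  dir.create(dir)
  rec_path <- file.path(dir, "receptor.pdbqt")
  lig_path <- file.path(dir, "ligand.pdbqt")
  out_path <- file.path(dir, "out.pdbqt")
  write_receptor_pdbqt(strip_solvent_ions(receptor), rec_path)
  export_probe_pdbqt(probe, lig_path)
  args <- c("--receptor", rec_path, "--ligand", lig_path,
            "--out", out_path,
            "--center_x", box$center[1], "--center_y", box$center[2],
            "--center_z", box$center[3],
            "--size_x", box$size[1], "--size_y", box$size[2],
            "--size_z", box$size[3],
            "--energy_range", params$energy_range %||% 4,
            "--num_modes", params$num_modes %||% 20,
            "--seed", params$seed %||% 42)
  status <- suppressWarnings(
    system2(exe, args, stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0
  if (code != 0 || !file.exists(out_path)) {
    stop("docking engine failed (exit ", code, "):\n",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  poses <- parse_vina_pdbqt(out_path)
  poses$probe_name <- probe$name
  poses
}

# Rigid-receptor PDBQT: element-derived AutoDock types and zero charges
# unless the atom table carries charges; real charge assignment is the
# job of an external preparation tool.
write_receptor_pdbqt <- function(s, path) {
  s <- as_atom_table(s)
  type <- toupper(s$element)
  type[type == "H"] <- "HD"
  type[type == "O"] <- "OA"
  type[type == "N"] <- "NA"
  q <- ifelse(is.na(s$charge), 0, s$charge)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
    seq_len(nrow(s)), s$atom, s$resname, s$chain, s$resnum,
    s$x, s$y, s$z, s$occupancy, s$bfactor, q, type)
  writeLines(lines, path)
  invisible(path)
}
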