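#' Reference vectors for pose directionality
#'
#' Per-residue-type defaults for the geometric pose criteria. The residue
#' vector runs along the side chain toward its outward terminus (CB->CZ for
#' Phe/Tyr; CB->CZ2 for Trp; CB to the NE2/CE1 midpoint for His); the probe
#' vector runs from the ring atom opposite the boron to the boron; and the
#' reference carbon pair ties a native carbon to the corresponding probe
#' carbon for the distance criterion (the side-chain attachment carbon of
#' the boron, CZ for Phe/Tyr, against the probe ipso carbon C1).
#'
#' @param restype `"PHE"`, `"TYR"`, `"TRP"` or `"HIS"`.
#' @param residue_tail Tail atom of the residue vector. The default is CB;
#'   set `"CG"` to use the alternative CG->head convention.
#' @return A `bda_vector_mapping` list with `residue_vector` (tail, head —
#'   head may be two atom names, meaning their midpoint), `probe_vector`
#'   and `reference_carbon_pair` (native, probe).
#' @export
vector_mapping <- function(restype = c("PHE", "TYR", "TRP", "HIS"),
                           residue_tail = "CB") {
  restype <- match.arg(restype)
  head <- switch(restype,
                 PHE = "CZ", TYR = "CZ", TRP = "CZ2",
                 HIS = c("NE2", "CE1"))
  ref_native <- switch(restype, PHE = "CZ", TYR = "CZ", TRP = "CZ2",
                       HIS = "CE1")
  structure(list(
    restype = restype,
    residue_vector = list(tail = residue_tail, head = head),
    probe_vector = list(tail = NULL, head = "B"),  # tail from the probe
    reference_carbon_pair = c(native = ref_native, probe = "C1")
  ), class = "bda_vector_mapping")
}

# Sites tables re-read from TSV may carry NA icodes/missing columns.
normalize_sites <- function(sites) {
  if (!("icode" %in% names(sites))) sites$icode <- ""
  sites$icode[is.na(sites$icode)] <- ""
  sites$icode <- as.character(sites$icode)
  sites$resnum <- as.integer(sites$resnum)
  sites
}

atom_point <- function(coords, names_wanted) {
  # coords: matrix with atom-name rownames; names_wanted length 1 or 2
  # (2 = midpoint)
  missing <- setdiff(names_wanted, rownames(coords))
  if (length(missing) > 0) {
    stop("atom not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- coords[names_wanted, , drop = FALSE]
  colMeans(m)
}

residue_coords <- function(res) coords_matrix(as_atom_table(res))

#' Assign a docking pose to the nearest cavity site
#'
#' A pose belongs to the cavity whose vacated side-chain centroid is nearest
#' to the pose heavy-atom centroid; poses farther than `r_cavity` from every
#' centroid are outside all cavities and get no site.
#'
#' @param pose Pose coordinates: a matrix with atom-name rownames (one
#'   element of the `coords` list-column from [dock()]).
#' @param sites Sites tibble (from [select_sites()] or a cavity scan).
#' @param probe Optional probe object used to tell heavy atoms apart;
#'   without it, rows named like hydrogens (`H*`) are dropped.
#' @param r_cavity Maximum centroid-centroid distance, Angstrom.
#' @return A one-row tibble (the site) or `NULL` if outside all cavities.
#' @export
assign_pose_to_site <- function(pose, sites, probe = NULL, r_cavity = 5.0) {
  stopifnot(nrow(sites) >= 1)
  sites <- normalize_sites(sites)
  heavy <- if (!is.null(probe)) {
    probe$atoms$element != "H"
  } else {
    !grepl("^H", rownames(pose))
  }
  pc <- colMeans(pose[heavy, , drop = FALSE])
  cen <- as.matrix(sites[, c("centroid_x", "centroid_y", "centroid_z")])
  d <- sqrt(rowSums(sweep(cen, 2, pc)^2))
  i <- which.min(d)
  if (d[i] > r_cavity) return(NULL)
  out <- sites[i, ]
  out$site_distance <- d[i]
  out
}

#' Directionality angle between residue and probe vectors
#'
#' The angle (degrees, in \[0, 180\]) between the native residue's
#' side-chain vector and the probe's ring-to-boron vector in the docked
#' pose. 0 means the boron points exactly the way the native side-chain
#' terminus did; 180 means opposite directionality, the rejection mode for
#' poses that sit in the cavity backwards.
#'
#' @param native Atom table rows of the original (un-truncated) residue.
#' @param pose Pose coordinate matrix with atom-name rownames.
#' @param mapping A [vector_mapping()]; defaults to the residue's type.
#' @param probe Optional probe object supplying the probe-vector tail.
#' @return Angle in degrees.
#' @export
directionality_angle <- function(native, pose, mapping = NULL,
                                 probe = NULL) {
  native <- as_atom_table(native)
  if (is.null(mapping)) mapping <- vector_mapping(native$resname[1])
  nc <- residue_coords(native)
  rv <- atom_point(nc, mapping$residue_vector$head) -
    atom_point(nc, mapping$residue_vector$tail)
  tail <- mapping$probe_vector$tail %||%
    (if (!is.null(probe)) probe$ligand_vector[["tail"]] else
       opposite_ring_atom(pose))
  pv <- atom_point(pose, mapping$probe_vector$head) - atom_point(pose, tail)
  vec_angle_deg(rv, pv)
}

# Fallback probe-vector tail: the ring carbon farthest from the boron.
opposite_ring_atom <- function(pose) {
  ring <- grep("^C[0-9]+$", rownames(pose), value = TRUE)
  if (length(ring) == 0 || !("B" %in% rownames(pose))) {
    stop("cannot infer probe vector tail from pose atom names",
         call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(pose[ring, , drop = FALSE], 2, pose["B", ])^2))
  ring[which.max(d)]
}

#' Reference-carbon distance between native residue and pose
#'
#' Euclidean distance (Angstrom) between the mapped reference carbon on the
#' original residue and the corresponding carbon on the probe pose.
#'
#' @inheritParams directionality_angle
#' @return Distance in Angstrom.
#' @export
reference_distance <- function(native, pose, mapping = NULL) {
  native <- as_atom_table(native)
  if (is.null(mapping)) mapping <- vector_mapping(native$resname[1])
  nc <- residue_coords(native)
  a <- atom_point(nc, mapping$reference_carbon_pair[["native"]])
  b <- atom_point(pose, mapping$reference_carbon_pair[["probe"]])
  vec_norm(a - b)
}

#' Count steric clashes between a pose and the receptor
#'
#' A clash is a (probe heavy atom, receptor heavy atom) pair closer than
#' `overlap_factor` times the sum of their van der Waals radii. Receptor
#' atoms include the retained stubs of the mutated sites.
#'
#' @param pose Pose coordinate matrix with atom-name rownames.
#' @param mutated_structure Atom table of the docked (mutated) receptor.
#' @param exclude_sites Optional sites tibble whose residues are ignored.
#' @param overlap_factor Fraction of the vdW-sum that counts as a clash.
#' @param probe Optional probe object (identifies heavy atoms and elements;
#'   otherwise inferred from atom names).
#' @return Integer clash count.
#' @export
clash_count <- function(pose, mutated_structure, exclude_sites = NULL,
                        overlap_factor = 0.6, probe = NULL) {
  rec <- as_atom_table(mutated_structure)
  if (!is.null(exclude_sites)) {
    if (!("icode" %in% names(exclude_sites))) exclude_sites$icode <- ""
    ex <- paste(exclude_sites$chain, exclude_sites$resnum,
                exclude_sites$icode, sep = ":")
    rec <- rec[!(res_id(rec) %in% ex), ]
  }
  rec <- rec[is_heavy(rec), ]
  if (!is.null(probe)) {
    heavy <- probe$atoms$element != "H"
    pel <- probe$atoms$element[heavy]
    pm <- pose[heavy, , drop = FALSE]
  } else {
    heavy <- !grepl("^H", rownames(pose))
    pm <- pose[heavy, , drop = FALSE]
    pel <- guess_element(rownames(pm))
  }
  d <- cross_dist(pm, coords_matrix(rec))
  lim <- overlap_factor *
    outer(vdw_radius(pel), vdw_radius(rec$element), "+")
  sum(d < lim)
}

#' Default pose-filter thresholds
#'
#' @param d_max Maximum reference-carbon distance, Angstrom.
#' @param theta_max Maximum directionality angle, degrees.
#' @param r_cavity Cavity assignment radius, Angstrom.
#' @param overlap_factor Clash vdW-overlap factor.
#' @return Named list of thresholds.
#' @export
pose_thresholds <- function(d_max = 2.0, theta_max = 60, r_cavity = 5.0,
                            overlap_factor = 0.6) {
  list(d_max = d_max, theta_max = theta_max, r_cavity = r_cavity,
       overlap_factor = overlap_factor)
}

#' Superimpose a probe onto a native aromatic side chain
#'
#' Places an aryl probe so its ring matches the six-membered ring of a
#' native Phe/Tyr residue, with the probe ipso carbon (C1, bearing the
#' boron) on the side-chain terminus carbon (CZ). The result is the ideal
#' re-occupying pose: useful as a positive control for the pose filter and
#' as the starting point for boronation.
#'
#' @param probe An aryl [build_probe()] object.
#' @param native Atom table rows of a single PHE or TYR residue.
#' @return Pose coordinate matrix (atom-name rownames).
#' @export
superpose_probe_on_residue <- function(probe, native) {
  native <- as_atom_table(native)
  if (!native$resname[1] %in% c("PHE", "TYR")) {
    stop("ring superposition is defined for PHE/TYR residues",
         call. = FALSE)
  }
  # ring correspondence: ipso C1 on CZ, then around the ring
  pairs <- c(C1 = "CZ", C2 = "CE1", C3 = "CD1", C4 = "CG", C5 = "CD2",
             C6 = "CE2")
  nc <- residue_coords(native)
  missing <- setdiff(pairs, rownames(nc))
  if (length(missing) > 0) {
    stop("native residue is missing ring atoms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pm <- coords_matrix(probe$atoms)
  sup <- kabsch(nc[pairs, ], pm[names(pairs), ])
  out <- apply_superposition(sup, pm)
  rownames(out) <- probe$atoms$atom
  colnames(out) <- c("x", "y", "z")
  out
}

#' Evaluate and rank docking poses against cavity sites
#'
#' The pose-filtering step: each pose is assigned to its nearest cavity,
#' measured against the native residue (reference-carbon distance and
#' directionality angle) and checked for steric clashes with the mutated
#' receptor. A pose is accepted when it lies inside a cavity, within
#' `d_max`, within `theta_max`, and clash-free; the per-site champion is
#' the accepted pose with the lowest (best) affinity.
#'
#' @param poses Pose tibble from [dock()] or [parse_vina_pdbqt()].
#' @param sites Sites tibble (cavity scan sites).
#' @param mutated_structure Mutated receptor atom table.
#' @param native_structure Original structure atom table (for native
#'   residue coordinates).
#' @param probe Probe object (atom identities and ligand vector).
#' @param mapping Optional [vector_mapping()] override.
#' @param thresholds A [pose_thresholds()] list.
#' @return A `bda_pose_eval`: list with `evaluations` (one row per pose:
#'   site id, rank, affinity, distance, angle, clash_count, inside_cavity,
#'   verdict, reasons) and `champions` (per-site best accepted pose).
#' @export
evaluate_and_rank <- function(poses, sites, mutated_structure,
                              native_structure, probe, mapping = NULL,
                              thresholds = pose_thresholds()) {
  native_structure <- as_atom_table(native_structure)
  sites <- normalize_sites(sites)
  if (!("probe_name" %in% names(poses))) poses$probe_name <- NA_character_
  rows <- purrr::map_dfr(seq_len(nrow(poses)), function(i) {
    pose <- poses$coords[[i]]
    site <- assign_pose_to_site(pose, sites, probe = probe,
                                r_cavity = thresholds$r_cavity)
    inside <- !is.null(site)
    reasons <- character()
    dist <- NA_real_
    ang <- NA_real_
    cl <- NA_integer_
    if (!inside) {
      reasons <- "outside_cavity"
      site_id <- NA_character_
    } else {
      site_id <- paste0(site$chain, ":", site$resnum,
                        ifelse(nzchar(site$icode), site$icode, ""))
      native <- native_structure[
        native_structure$model == 1 &
          native_structure$chain == site$chain &
          native_structure$resnum == site$resnum &
          native_structure$icode == site$icode, ]
      m <- mapping %||% vector_mapping(native$resname[1])
      dist <- reference_distance(native, pose, m)
      ang <- directionality_angle(native, pose, m, probe = probe)
      cl <- clash_count(pose, mutated_structure,
                        overlap_factor = thresholds$overlap_factor,
                        probe = probe)
      if (dist > thresholds$d_max) reasons <- c(reasons, "distance")
      if (ang > thresholds$theta_max) reasons <- c(reasons, "directionality")
      if (cl > 0) reasons <- c(reasons, "clash")
    }
    tibble::tibble(
      site = site_id,
      probe_name = poses$probe_name[i],
      mode_rank = poses$mode_rank[i],
      affinity = poses$affinity[i],
      distance = dist,
      angle = ang,
      clash_count = cl,
      inside_cavity = inside,
      verdict = if (length(reasons) == 0) "accept" else "reject",
      reasons = paste(reasons, collapse = ",")
    )
  })
  rows <- rows[order(rows$site, rows$mode_rank, na.last = TRUE), ]
  champs <- rows |>
    dplyr::filter(.data$verdict == "accept") |>
    dplyr::group_by(.data$site) |>
    dplyr::arrange(.data$affinity, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  structure(list(evaluations = rows, champions = champs,
                 thresholds = thresholds),
            class = "bda_pose_eval")
}

#' @export
print.bda_pose_eval <- function(x, ...) {
  cat("<bda_pose_eval> ", nrow(x$evaluations), " poses, ",
      sum(x$evaluations$verdict == "accept"), " accepted, ",
      nrow(x$champions), " site champions\n", sep = "")
  invisible(x)
}

#' @rdname evaluate_and_rank
#' @param x A `bda_pose_eval`.
#' @param ... Unused.
#' @export
tidy.bda_pose_eval <- function(x, ...) x$evaluations

#' @rdname evaluate_and_rank
#' @export
glance.bda_pose_eval <- function(x, ...) {
  tibble::tibble(
    n_poses = nrow(x$evaluations),
    n_accepted = sum(x$evaluations$verdict == "accept"),
    n_sites_hit = dplyr::n_distinct(stats::na.omit(x$evaluations$site)),
    n_champions = nrow(x$champions),
    best_affinity = if (nrow(x$champions)) min(x$champions$affinity)
    else NA_real_
  )
}

#' Write pose evaluations as TSV and champions as JSON
#'
#' @param eval A `bda_pose_eval`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `eval`, invisibly.
#' @export
write_pose_report <- function(eval, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(eval$evaluations, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(eval$champions, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(eval)
}
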