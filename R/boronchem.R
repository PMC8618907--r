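#' Boron bond geometry
#'
#' Bond lengths and angles used to place the B(OH)2 group. Defaults are
#' standard experimental arylboronic-acid values: B-C 1.56 A, B-O 1.36 A,
#' O-H 0.96 A, all angles at the sp2 boron 120 degrees, planar. All values
#' are overridable so the geometry can track any preferred literature set.
#'
#' @param b_c_length B-C bond length, Angstrom.
#' @param b_o_length B-O bond length, Angstrom.
#' @param o_h_length O-H bond length, Angstrom.
#' @param c_b_o_angle C-B-O angle, degrees.
#' @param o_b_o_angle O-B-O angle, degrees.
#' @param planar Keep the boronic group in the ring plane.
#' @return A `bda_boron_geometry` list.
#' @export
boron_geometry <- function(b_c_length = 1.56, b_o_length = 1.36,
                           o_h_length = 0.96, c_b_o_angle = 120,
                           o_b_o_angle = 120, planar = TRUE) {
  stopifnot(b_c_length > 0, b_o_length > 0, o_h_length > 0,
            c_b_o_angle > 0, c_b_o_angle < 180,
            o_b_o_angle > 0, o_b_o_angle < 180)
  structure(list(b_c_length = b_c_length, b_o_length = b_o_length,
                 o_h_length = o_h_length, c_b_o_angle = c_b_o_angle,
                 o_b_o_angle = o_b_o_angle, planar = planar),
            class = "bda_boron_geometry")
}

probe_names <- c("phenylboronic_acid", "p_toluene_boronic_acid",
                 "cyclopentylboronic_acid")

#' Build a boronic-acid fragment probe
#'
#' Constructs the 3D structure of one of the three fragment probes —
#' phenylboronic acid, p-toluene boronic acid or cyclopentylboronic acid —
#' from ideal internal geometry (aromatic ring bond 1.39 A, planar;
#' cyclopentane as a flat ring template with 1.54 A bonds) with the B(OH)2
#' group placed per `geom`. The boron atom is flagged and typed as carbon
#' for docking, because boron is not parameterised in common docking
#' engines; its true element is retained in metadata. The ligand reference
#' vector runs from the ring atom opposite the boron to the boron.
#'
#' @param name One of `"phenylboronic_acid"`, `"p_toluene_boronic_acid"`,
#'   `"cyclopentylboronic_acid"`.
#' @param geom A [boron_geometry()].
#' @param charges Optional charge table (`atom`, `charge`); defaults to the
#'   packaged Gasteiger set. Pass `NULL` for no charges.
#' @return A `bda_probe`: list with `name`, `atoms` tibble (`atom`,
#'   `element`, `docking_type`, `is_boron`, `x/y/z`, `charge`), `bonds`
#'   (index pairs), `torsion_tree`, and `ligand_vector` (tail, head atom
#'   names, head = boron).
#' @examples
#' p <- build_probe("phenylboronic_acid")
#' sum(p$atoms$element != "H")  # 9 heavy atoms
#' @export
build_probe <- function(name, geom = boron_geometry(),
                        charges = default_probe_charges(name)) {
  if (!name %in% probe_names) {
    stop("unknown probe '", name, "'; expected one of: ",
         paste(probe_names, collapse = ", "), call. = FALSE)
  }
  ring_atoms <- if (name == "cyclopentylboronic_acid") {
    flat_ring(5, 1.54)
  } else {
    flat_ring(6, 1.39)
  }
  n_ring <- nrow(ring_atoms)
  atoms <- ring_atoms
  atoms$element <- "C"
  atoms$docking_type <- if (name == "cyclopentylboronic_acid") "C" else "A"
  # C1 sits at the +x apex; grow B(OH)2 outward along +x in the ring plane
  c1 <- as.numeric(atoms[1, c("x", "y", "z")])
  b <- c1 + c(geom$b_c_length, 0, 0)
  half <- 180 - geom$c_b_o_angle
  o1 <- b + geom$b_o_length *
    c(cos(deg2rad(half)), sin(deg2rad(half)), 0)
  # second oxygen set o_b_o_angle away from the first, on the other side
  o2dir <- rotation_about_axis(c(0, 0, 1), -geom$o_b_o_angle) %*%
    unit_vec(o1 - b)
  o2 <- b + geom$b_o_length * as.numeric(o2dir)
  h1 <- place_nerf(c1, b, o1, geom$o_h_length, 114, 180)
  h2 <- place_nerf(c1, b, o2, geom$o_h_length, 114, 180)
  if (!geom$planar) {
    # pyramidalise slightly by lifting the oxygens off the plane
    o1[3] <- 0.2; o2[3] <- -0.2
  }
  extra <- tibble::tibble(
    atom = c("B", "O1", "O2", "HO1", "HO2"),
    x = c(b[1], o1[1], o2[1], h1[1], h2[1]),
    y = c(b[2], o1[2], o2[2], h1[2], h2[2]),
    z = c(b[3], o1[3], o2[3], h1[3], h2[3]),
    element = c("B", "O", "O", "H", "H"),
    docking_type = c("C", "OA", "OA", "HD", "HD")
  )
  atoms <- dplyr::bind_rows(atoms, extra)
  bonds <- ring_bonds(n_ring)
  bonds <- rbind(bonds,
                 cbind(1L, n_ring + 1L),              # C1-B
                 cbind(n_ring + 1L, n_ring + 2L),     # B-O1
                 cbind(n_ring + 1L, n_ring + 3L),     # B-O2
                 cbind(n_ring + 2L, n_ring + 4L),     # O1-HO1
                 cbind(n_ring + 3L, n_ring + 5L))     # O2-HO2
  if (name == "p_toluene_boronic_acid") {
    c4 <- as.numeric(atoms[4, c("x", "y", "z")])
    me <- c4 + 1.51 * unit_vec(c4 - centroid_xyz(ring_atoms))
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      atom = "C7", x = me[1], y = me[2], z = me[3],
      element = "C", docking_type = "C"))
    bonds <- rbind(bonds, cbind(4L, nrow(atoms)))
  }
  atoms$is_boron <- atoms$atom == "B"
  atoms$charge <- NA_real_
  if (!is.null(charges)) {
    atoms$charge <- charges$charge[match(atoms$atom, charges$atom)]
  }
  tail <- if (name == "cyclopentylboronic_acid") "C3" else "C4"
  probe <- structure(list(
    name = name,
    atoms = atoms[c("atom", "element", "docking_type", "is_boron",
                    "x", "y", "z", "charge")],
    bonds = tibble::tibble(i = as.integer(bonds[, 1]),
                           j = as.integer(bonds[, 2])),
    ligand_vector = c(tail = tail, head = "B")
  ), class = "bda_probe")
  probe$torsion_tree <- probe_torsion_tree(probe)
  probe
}

flat_ring <- function(n, bond) {
  r <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(atom = paste0("C", seq_len(n)),
                 x = r * cos(ang), y = r * sin(ang), z = 0)
}

ring_bonds <- function(n) {
  cbind(seq_len(n), c(seq_len(n)[-1], 1L))
}

centroid_xyz <- function(df) c(mean(df$x), mean(df$y), mean(df$z))

#' @export
print.bda_probe <- function(x, ...) {
  cat("<bda_probe> ", x$name, ": ", sum(x$atoms$element != "H"),
      " heavy atoms, ligand vector ", x$ligand_vector[["tail"]], "->",
      x$ligand_vector[["head"]], "\n", sep = "")
  invisible(x)
}

#' Packaged probe partial charges
#'
#' Gasteiger charges computed once for each probe and shipped as an editable
#' CSV (`inst/extdata/probe_charges.csv`); non-polar hydrogens are merged
#' into their parent carbons (united-atom docking convention).
#'
#' @param name Probe name.
#' @return Tibble with `atom` and `charge` columns.
#' @export
default_probe_charges <- function(name) {
  path <- system.file("extdata", "probe_charges.csv", package = "bdascan")
  tab <- tibble::as_tibble(utils::read.csv(path))
  out <- tab[tab$probe == name, c("atom", "charge")]
  if (nrow(out) == 0) return(NULL)
  out
}

# Rotatable bonds: acyclic single bonds that move at least one heavy atom on
# the distal side (terminal hydroxyl/methyl torsions move hydrogens only and
# are frozen, so a boronic acid has exactly one torsion: ring C - B).
probe_torsion_tree <- function(probe) {
  n <- nrow(probe$atoms)
  in_ring <- grepl("^C[0-9]+$", probe$atoms$atom) &
    seq_len(n) %in% unlist(ring_bonds_members(probe))
  adj <- lapply(seq_len(n), function(i) {
    c(probe$bonds$j[probe$bonds$i == i], probe$bonds$i[probe$bonds$j == i])
  })
  heavy <- probe$atoms$element != "H"
  rot <- list()
  for (k in seq_len(nrow(probe$bonds))) {
    i <- probe$bonds$i[k]; j <- probe$bonds$j[k]
    if (in_ring[i] && in_ring[j]) next
    side <- component_beyond(adj, from = i, through = j)
    if (sum(heavy[side]) >= 1 && length(side) > 1) {
      # needs >=2 substituents on the distal atom for the torsion to matter
      if (length(setdiff(side, j)) >= 1 &&
          any(heavy[setdiff(side, j)])) {
        rot[[length(rot) + 1]] <- list(bond = c(i, j), moves = side)
      }
    }
  }
  rot
}

ring_bonds_members <- function(probe) {
  n_ring <- sum(grepl("^C[1-6]$", probe$atoms$atom) &
                  probe$atoms$docking_type %in% c("A", "C"))
  # ring atoms are always the first block C1..Cn
  ring_n <- if (probe$name == "cyclopentylboronic_acid") 5 else 6
  list(seq_len(ring_n))
}

component_beyond <- function(adj, from, through) {
  seen <- c(from, through)
  queue <- through
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- setdiff(adj[[cur]], seen)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  setdiff(seen, from)
}

#' Export a probe as an AutoDock PDBQT ligand
#'
#' Writes a PDBQT with a ROOT/BRANCH torsion tree. The boron atom is written
#' with atom type `C` (the standard carbon substitution for unparameterised
#' boron) and a `REMARK` records the true boron atom index so downstream
#' reports can recover it.
#'
#' @param p A [build_probe()] object with charges assigned.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_probe_pdbqt <- function(p, path) {
  if (anyNA(p$atoms$charge)) {
    stop("probe has atoms without charges: ",
         paste(p$atoms$atom[is.na(p$atoms$charge)], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(p$atoms)
  moved <- unique(unlist(lapply(p$torsion_tree, `[[`, "moves")))
  root <- setdiff(seq_len(n), moved)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK  Name = %s", p$name), con)
  writeLines(sprintf("REMARK  %d active torsions", length(p$torsion_tree)),
             con)
  bidx <- which(p$atoms$is_boron)
  writeLines(sprintf("REMARK  BORON atom %d (%s) written with type C",
                     bidx, p$atoms$atom[bidx]), con)
  writeLines("ROOT", con)
  for (i in root) writeLines(pdbqt_atom_line(p$atoms[i, ], i), con)
  writeLines("ENDROOT", con)
  for (br in p$torsion_tree) {
    writeLines(sprintf("BRANCH %3d %3d", br$bond[1], br$bond[2]), con)
    for (i in setdiff(br$moves, root)) {
      writeLines(pdbqt_atom_line(p$atoms[i, ], i), con)
    }
    writeLines(sprintf("ENDBRANCH %3d %3d", br$bond[1], br$bond[2]), con)
  }
  writeLines(sprintf("TORSDOF %d", length(p$torsion_tree)), con)
  invisible(path)
}

pdbqt_atom_line <- function(a, serial) {
  sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          serial, a$atom, a$x, a$y, a$z, 1, 0, a$charge, a$docking_type)
}

#' Replace a tyrosine hydroxyl with a boronic-acid group (BPA)
#'
#' Builds the boronated residue: the side-chain OH oxygen (and its hydrogen,
#' if present) is removed and replaced by B(OH)2 — boron on the CZ->OH
#' direction at the configured B-C length, two oxygens at the B-O length
#' 120 degrees apart in the ring plane, one hydrogen on each. All other
#' atoms are untouched and the residue is renamed `"BPA"`.
#'
#' @param tyr Atom table rows of a single TYR residue with CZ and OH.
#' @param geom A [boron_geometry()].
#' @return The boronated residue atom table.
#' @examples
#' s <- make_structure("AYA")
#' tyr <- dplyr::filter(s, resnum == 2)
#' bpa <- build_bpa(tyr)
#' unique(bpa$resname)
#' @export
build_bpa <- function(tyr, geom = boron_geometry()) {
  tyr <- as_atom_table(tyr)
  if (tyr$resname[1] != "TYR") {
    stop("build_bpa expects a TYR residue, got ", tyr$resname[1],
         call. = FALSE)
  }
  need <- c("CZ", "OH", "CE1", "CE2")
  if (!all(need %in% tyr$atom)) {
    stop("TYR residue is missing atoms: ",
         paste(setdiff(need, tyr$atom), collapse = ", "), call. = FALSE)
  }
  at <- function(nm) as.numeric(tyr[tyr$atom == nm, c("x", "y", "z")])
  cz <- at("CZ"); oh <- at("OH")
  u <- unit_vec(oh - cz)
  normal <- unit_vec(pracma_cross(at("CE1") - cz, at("CE2") - cz))
  v <- unit_vec(pracma_cross(normal, u))  # in-plane, perpendicular to CZ->OH
  b <- cz + geom$b_c_length * u
  d1 <- cos(deg2rad(geom$c_b_o_angle)) * (-u) +
    sin(deg2rad(geom$c_b_o_angle)) * v
  o1 <- b + geom$b_o_length * d1
  # rotate the first B->O direction by the O-B-O angle about the ring
  # normal, picking the sense that lands on the far side of the CZ->OH axis
  cand <- lapply(c(-1, 1), function(s) {
    as.numeric(rotation_about_axis(normal, s * geom$o_b_o_angle) %*% d1)
  })
  d2 <- cand[[which.min(vapply(cand, function(d) sum(d * v), numeric(1)))]]
  o2 <- b + geom$b_o_length * d2
  h1 <- place_nerf(cz, b, o1, geom$o_h_length, 114, 180)
  h2 <- place_nerf(cz, b, o2, geom$o_h_length, 114, 180)
  out <- tyr[!(tyr$atom %in% c("OH", "HH")), ]
  template <- out[rep(which(out$atom == "CZ"), 5), ]
  template$atom <- c("B", "O1", "O2", "HO1", "HO2")
  template$element <- c("B", "O", "O", "H", "H")
  template$x <- c(b[1], o1[1], o2[1], h1[1], h2[1])
  template$y <- c(b[2], o1[2], o2[2], h1[2], h2[2])
  template$z <- c(b[3], o1[3], o2[3], h1[3], h2[3])
  template$serial <- max(out$serial) + seq_len(5)
  out <- dplyr::bind_rows(out, template)
  out$resname <- "BPA"
  out
}

#' Export a BPA residue template
#'
#' Writes the boronated-residue template in one of three layouts: `json`
#' (full record), `prepin-like` (Amber prep-style text with the N/C link
#' atoms marked for chain continuation), or `frcmod-like` (bond and angle
#' parameter stubs for the three bond classes absent from standard residues:
#' CZ-B, B-O and the boronic O-H).
#'
#' @param bpa Atom table from [build_bpa()].
#' @param charges Charge table (`atom`, `charge`) covering every atom;
#'   defaults to the packaged set.
#' @param format `"json"`, `"prepin-like"` or `"frcmod-like"`.
#' @param path Output path.
#' @param geom A [boron_geometry()] (used for frcmod-like stubs).
#' @param net_charge Target net charge the table must sum to (default 0).
#' @return `path`, invisibly. The JSON format round-trips through
#'   [jsonlite::read_json()].
#' @export
export_residue_template <- function(bpa, path,
                                    charges = default_bpa_charges(),
                                    format = c("json", "prepin-like",
                                               "frcmod-like"),
                                    geom = boron_geometry(),
                                    net_charge = 0) {
  format <- match.arg(format)
  bpa <- as_atom_table(bpa)
  missing <- setdiff(bpa$atom, charges$atom)
  if (length(missing) > 0) {
    stop("charge table incomplete; missing atoms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bpa$charge <- charges$charge[match(bpa$atom, charges$atom)]
  total <- sum(bpa$charge)
  if (abs(total - net_charge) > 0.01) {
    warning("template net charge ", round(total, 4),
            " differs from target ", net_charge)
  }
  bonds <- infer_bonds(bpa)
  if (format == "json") {
    rec <- list(
      resname = "BPA",
      net_charge = total,
      head = "N", tail = "C",
      atoms = lapply(seq_len(nrow(bpa)), function(i) {
        list(name = bpa$atom[i], element = bpa$element[i],
             charge = bpa$charge[i],
             xyz = c(bpa$x[i], bpa$y[i], bpa$z[i]))
      }),
      bonds = lapply(seq_len(nrow(bonds)), function(k) {
        c(bpa$atom[bonds$i[k]], bpa$atom[bonds$j[k]])
      })
    )
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else if (format == "prepin-like") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("BPA residue template (prepin-like)",
                 "RESIDUE BPA",
                 sprintf("NET_CHARGE %.4f", total),
                 "HEAD N", "TAIL C",
                 "ATOMS name element charge x y z"), con)
    writeLines(sprintf("  %-4s %-2s %8.4f %8.3f %8.3f %8.3f",
                       bpa$atom, bpa$element, bpa$charge,
                       bpa$x, bpa$y, bpa$z), con)
    writeLines("BONDS", con)
    writeLines(sprintf("  %-4s %-4s", bpa$atom[bonds$i], bpa$atom[bonds$j]),
               con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("Parameter stubs for the boronic-acid moiety of BPA",
                 "BOND"), con)
    writeLines(sprintf("%-5s  300.0   %7.4f", c("CA-B ", "B -OB", "OB-HO"),
                       c(geom$b_c_length, geom$b_o_length, geom$o_h_length)),
               con)
    writeLines("ANGLE", con)
    writeLines(sprintf("%-8s  70.0   %8.3f",
                       c("CA-B -OB", "OB-B -OB", "B -OB-HO"),
                       c(geom$c_b_o_angle, geom$o_b_o_angle, 114)), con)
  }
  invisible(path)
}

#' @rdname export_residue_template
#' @export
default_bpa_charges <- function() {
  path <- system.file("extdata", "bpa_charges.csv", package = "bdascan")
  tibble::as_tibble(utils::read.csv(path))
}

# Distance-based bond inference: heavy-heavy <= 1.9 A (B-C allowed up to
# 1.75), X-H <= 1.25 A.
infer_bonds <- function(res) {
  m <- coords_matrix(res)
  d <- cross_dist(m, m)
  h <- toupper(res$element) == "H"
  n <- nrow(res)
  pairs <- which(upper.tri(d) & d > 0.1 &
                   ((outer(!h, !h) & d <= 1.90) |
                      (outer(h, !h, "|") & !outer(h, h) & d <= 1.25)),
                 arr.ind = TRUE)
  tibble::tibble(i = pairs[, 1], j = pairs[, 2])
}
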