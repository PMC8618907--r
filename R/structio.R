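#' @title Atom tables: the coordinate model shared by all bdascan verbs
#'
#' @description
#' bdascan represents a structure as a plain tibble of atom records ("atom
#' table") with one row per atom and columns:
#'
#' * `model` (integer), `chain` (single character), `resnum` (integer),
#'   `icode` (insertion code, `""` if none), `resname` (3-letter code,
#'   including the non-standard `"BPA"`),
#' * `atom` (PDB atom name, e.g. `"CA"`, `"CZ"`, `"OH"`), `element`,
#' * `x`, `y`, `z` (Angstrom), `occupancy`, `bfactor`, `charge`
#'   (elementary charges, `NA` when unknown).
#'
#' Every user-facing function takes such a data frame first and returns a
#' tibble, so steps chain with the pipe. `as_atom_table()` validates and
#' normalises a data frame into this shape.
#'
#' @param df A data frame carrying at least `chain`, `resnum`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`.
#' @return A tibble in atom-table shape.
#' @examples
#' s <- make_structure("AYA")
#' as_atom_table(s)
#' @export
as_atom_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("chain", "resnum", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("atom table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!("model" %in% names(df))) df$model <- 1L
  if (!("icode" %in% names(df))) df$icode <- ""
  if (!("occupancy" %in% names(df))) df$occupancy <- 1
  if (!("bfactor" %in% names(df))) df$bfactor <- 0
  if (!("charge" %in% names(df))) df$charge <- NA_real_
  if (!("serial" %in% names(df))) df$serial <- seq_len(nrow(df))
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  if (any(bad)) stop("non-finite coordinates in atom table", call. = FALSE)
  if (any(!nzchar(df$element))) stop("empty element symbols", call. = FALSE)
  df[c("model", "serial", "chain", "resnum", "icode", "resname",
       "atom", "element", "x", "y", "z", "occupancy", "bfactor", "charge")]
}

res_id <- function(df) paste(df$chain, df$resnum, df$icode, sep = ":")

#' Read a PDB file into an atom table
#'
#' Parses fixed-width `ATOM`/`HETATM` records (with `MODEL`/`ENDMDL` splitting
#' into models) at 0.001 A coordinate precision. Alternate locations are
#' resolved to a single conformer: the highest-occupancy altloc is kept per
#' atom, ties broken by altloc letter order. Hydrogens present in the file are
#' kept; geometric selections elsewhere default to heavy atoms.
#'
#' @param path Path to a PDB file.
#' @param keep_het Keep `HETATM` records (default `TRUE`).
#' @return An atom table (see [as_atom_table()]); multi-MODEL files yield one
#'   `model` value per MODEL record, compatible with [read_trajectory()].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(make_structure("AYA"), f)
#' head(read_pdb(f))
#' @export
read_pdb <- function(path, keep_het = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | (keep_het & rec == "HETATM")
  is_model <- startsWith(rec, "MODEL")
  model_no <- cumsum(is_model)
  model_no[model_no == 0] <- 1L
  idx <- which(is_atom)
  if (length(idx) == 0) stop("empty structure: no ATOM records in ", path,
                             call. = FALSE)
  al <- lines[idx]
  short <- nchar(al) < 54
  if (any(short)) {
    stop("malformed fixed-width ATOM record at line ", idx[short][1],
         " of ", path, call. = FALSE)
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(al, 31, 38)); y <- num(substr(al, 39, 46)); z <- num(substr(al, 47, 54))
  bad <- is.na(x) | is.na(y) | is.na(z)
  if (any(bad)) {
    stop("malformed fixed-width ATOM record at line ", idx[bad][1],
         " of ", path, ": non-numeric coordinates", call. = FALSE)
  }
  occ <- num(substr(al, 55, 60)); occ[is.na(occ)] <- 1
  bf <- num(substr(al, 61, 66)); bf[is.na(bf)] <- 0
  element <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  element[!nzchar(element)] <- guess_element(name[!nzchar(element)])
  df <- tibble::tibble(
    model = as.integer(model_no[idx]),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    altloc = substr(al, 17, 17),
    chain = substr(al, 22, 22),
    resnum = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = trimws(substr(al, 27, 27)),
    resname = trimws(substr(al, 18, 20)),
    atom = name,
    element = element,
    x = x, y = y, z = z,
    occupancy = occ, bfactor = bf, charge = NA_real_
  )
  df$model <- df$model - min(df$model) + 1L
  df <- resolve_altloc(df)
  df$altloc <- NULL
  as_atom_table(df)
}

# Keep highest-occupancy altloc per (model, chain, resnum, icode, atom);
# ties broken by altloc letter order (blank sorts first).
resolve_altloc <- function(df) {
  df |>
    dplyr::group_by(.data$model, .data$chain, .data$resnum, .data$icode,
                    .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$model, .data$serial)
}

guess_element <- function(name) {
  e <- sub("^[0-9']*", "", name)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA"), two, one)
}

#' Remove water and monoatomic ion residues
#'
#' Drops `HOH`/`WAT` residues and any residue consisting of a single atom
#' (ions such as NA or CL); protein atoms are untouched. This mirrors the
#' receptor clean-up done before docking preparation.
#'
#' @param s An atom table.
#' @return The stripped atom table. Warns if nothing is left.
#' @export
strip_solvent_ions <- function(s) {
  s <- as_atom_table(s)
  keep <- s |>
    dplyr::group_by(.data$model, .data$chain, .data$resnum, .data$icode,
                    .data$resname) |>
    dplyr::filter(!(.data$resname[1] %in% c("HOH", "WAT")) &&
                    dplyr::n() > 1) |>
    dplyr::ungroup()
  if (nrow(keep) == 0) warning("no atoms left after solvent/ion stripping")
  keep
}

#' Write an atom table to a PDB file
#'
#' Fixed-width `ATOM` records; `TER` between chains; `MODEL`/`ENDMDL` wrapping
#' for multi-model tables. Non-standard residue names such as `"BPA"` are
#' written verbatim in columns 18-20.
#'
#' @param s An atom table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  s <- as_atom_table(s)
  if (any(nchar(s$atom) > 4)) {
    stop("atom name longer than 4 characters: ",
         s$atom[nchar(s$atom) > 4][1], call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  models <- sort(unique(s$model))
  multi <- length(models) > 1
  for (m in models) {
    sm <- s[s$model == m, ]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    chains <- unique(sm$chain)
    for (ch in chains) {
      sc <- sm[sm$chain == ch, ]
      for (i in seq_len(nrow(sc))) {
        serial <- serial + 1L
        writeLines(pdb_atom_line(sc[i, ], serial), con)
      }
      last <- sc[nrow(sc), ]
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %-3s %1s%4d%1s", serial,
                         last$resname, last$chain, last$resnum,
                         ifelse(nzchar(last$icode), last$icode, " ")), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_line <- function(a, serial) {
  name <- a$atom
  # PDB convention: 1-char-element names start in column 14
  name4 <- if (nchar(name) < 4 && nchar(a$element) == 1) {
    formatC(paste0(" ", name), width = -4)
  } else {
    formatC(name, width = -4)
  }
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, substr(paste0(name4, "    "), 1, 4), " ",
          a$resname, a$chain, a$resnum,
          ifelse(nzchar(a$icode), a$icode, " "),
          a$x, a$y, a$z, a$occupancy, a$bfactor,
          formatC(a$element, width = 2))
}

#' Trajectory objects
#'
#' A `bda_trajectory` couples a one-model topology atom table with a list of
#' frame coordinate matrices (rows congruent with the topology atom order,
#' Angstrom).
#'
#' @param topology A one-model atom table.
#' @param frames List of `n_atoms x 3` numeric matrices.
#' @param frame_index Optional integer frame labels (default `1:n`).
#' @return A `bda_trajectory` object.
#' @export
trajectory <- function(topology, frames, frame_index = NULL) {
  topology <- as_atom_table(topology)
  if (length(unique(topology$model)) != 1) {
    stop("trajectory topology must have exactly one model", call. = FALSE)
  }
  if (length(frames) < 1) stop("trajectory needs at least one frame",
                               call. = FALSE)
  n <- nrow(topology)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3) {
      stop("frame ", i, " has ", nrow(frames[[i]]),
           " atoms; topology has ", n, call. = FALSE)
    }
  }
  if (is.null(frame_index)) frame_index <- seq_along(frames)
  structure(list(topology = topology, frames = frames,
                 frame_index = as.integer(frame_index)),
            class = "bda_trajectory")
}

#' @export
print.bda_trajectory <- function(x, ...) {
  cat("<bda_trajectory> ", length(x$frames), " frames x ",
      nrow(x$topology), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.bda_trajectory <- function(x) length(x$frames)

#' Flatten a trajectory to a long tibble
#'
#' @param x A `bda_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per (frame, atom) and columns from the topology.
#' @export
as_tibble.bda_trajectory <- function(x, ...) {
  purrr::map2_dfr(x$frames, x$frame_index, function(fr, i) {
    out <- x$topology
    out$x <- fr[, 1]; out$y <- fr[, 2]; out$z <- fr[, 3]
    out$frame <- i
    out
  })
}

#' Read a trajectory from multi-model PDB or XYZ
#'
#' @param topology_path PDB file giving the topology (first model used).
#' @param traj_path Trajectory file; multi-model PDB or plain XYZ.
#' @param format `"multimodel-pdb"` or `"xyz"`.
#' @return A [trajectory()] object; frames in file order.
#' @export
read_trajectory <- function(topology_path, traj_path,
                            format = c("multimodel-pdb", "xyz")) {
  format <- match.arg(format)
  topo <- read_pdb(topology_path)
  topo <- topo[topo$model == 1, ]
  n <- nrow(topo)
  if (format == "multimodel-pdb") {
    all <- read_pdb(traj_path)
    frames <- lapply(split(all, all$model), coords_matrix)
  } else {
    frames <- read_xyz_frames(traj_path)
  }
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != n) {
      stop("frame ", i, " has ", nrow(frames[[i]]),
           " atoms but topology has ", n, call. = FALSE)
    }
  }
  trajectory(topo, unname(frames))
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom-count line ", i, call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(m))) stop("malformed XYZ coordinates near line ", i,
                            call. = FALSE)
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames in XYZ file", call. = FALSE)
  frames
}

#' Write a trajectory
#'
#' @param traj A [trajectory()] object.
#' @param path Output path.
#' @param format `"multimodel-pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("multimodel-pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "multimodel-pdb") {
    tabs <- purrr::map2_dfr(traj$frames, seq_along(traj$frames),
                            function(fr, i) {
      out <- traj$topology
      out$x <- fr[, 1]; out$y <- fr[, 2]; out$z <- fr[, 3]
      out$model <- i
      out
    })
    write_pdb(tabs, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(traj$frames)) {
      fr <- traj$frames[[i]]
      writeLines(as.character(nrow(fr)), con)
      writeLines(sprintf("frame %d", traj$frame_index[i]), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         traj$topology$element, fr[, 1], fr[, 2], fr[, 3]),
                 con)
    }
  }
  invisible(path)
}

is_heavy <- function(s) toupper(s$element) != "H"

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
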