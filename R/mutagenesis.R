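#' Residues protected by proximity to a bound receptor
#'
#' Identifies antibody residues at the binding interface so they can be
#' excluded from cavity scanning: any residue with a heavy atom within
#' `cutoff` of any receptor heavy atom is protected. The antibody and
#' receptor must share a coordinate frame (e.g. both taken from the complex
#' structure); alternatively pass an explicit residue list or bounding box
#' downstream instead of using this function.
#'
#' @param antibody Atom table of the antibody (or any protein to scan).
#' @param receptor Atom table of the bound receptor.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 8.0).
#' @return Tibble with one row per protected residue: `chain`, `resnum`,
#'   `icode`, `resname`, `min_dist`.
#' @export
protected_residues <- function(antibody, receptor, cutoff = 8.0) {
  ab <- as_atom_table(antibody)
  rc <- as_atom_table(receptor)
  ab <- ab[is_heavy(ab), ]
  rc <- rc[is_heavy(rc), ]
  d <- cross_dist(coords_matrix(ab), coords_matrix(rc))
  ab$min_dist <- apply(d, 1, min)
  if (min(ab$min_dist) > 50) {
    warning("no interface detected: closest heavy-atom pair is ",
            round(min(ab$min_dist), 1), " A apart")
  }
  ab |>
    dplyr::group_by(.data$chain, .data$resnum, .data$icode, .data$resname) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= cutoff) |>
    dplyr::arrange(.data$chain, .data$resnum, .data$icode)
}

excluded_ids <- function(excluded) {
  if (is.null(excluded)) return(character())
  if (is.data.frame(excluded)) {
    if (!("icode" %in% names(excluded))) excluded$icode <- ""
    return(paste(excluded$chain, excluded$resnum, excluded$icode, sep = ":"))
  }
  ex <- as.character(excluded)
  # accept "A:140" shorthand without icode
  ifelse(grepl("^[^:]+:[^:]+$", ex), paste0(ex, ":"), ex)
}

sidechain_beyond_cb <- function(res) {
  res[is_heavy(res) & !(res$atom %in% c("N", "CA", "C", "O", "CB", "OXT")), ]
}

#' Enumerate candidate mutation sites of one residue type
#'
#' Lists all residues of `restype` (one of PHE, TYR, TRP, HIS) outside the
#' exclusion set, each with the centroid of its side-chain heavy atoms beyond
#' CB — the point that marks the cavity vacated when the side chain is
#' truncated. Order is deterministic (chain, then residue number).
#'
#' @param s Atom table (first model used).
#' @param restype `"PHE"`, `"TYR"`, `"TRP"` or `"HIS"`.
#' @param excluded Protected residues: a tibble from [protected_residues()],
#'   or a character vector of `"chain:resnum"` / `"chain:resnum:icode"` ids.
#' @return Tibble of sites: `chain`, `resnum`, `icode`, `resname`,
#'   `centroid_x/y/z`.
#' @export
select_sites <- function(s, restype = c("PHE", "TYR", "TRP", "HIS"),
                         excluded = NULL) {
  restype <- match.arg(restype)
  s <- as_atom_table(s)
  s <- s[s$model == 1, ]
  ex <- excluded_ids(excluded)
  cand <- s[s$resname == restype & !(res_id(s) %in% ex), ]
  if (nrow(cand) == 0) {
    return(tibble::tibble(chain = character(), resnum = integer(),
                          icode = character(), resname = character(),
                          centroid_x = double(), centroid_y = double(),
                          centroid_z = double()))
  }
  cand |>
    dplyr::group_by(.data$chain, .data$resnum, .data$icode, .data$resname) |>
    dplyr::group_modify(function(res, key) {
      sc <- sidechain_beyond_cb(res)
      if (nrow(sc) == 0) {
        stop("residue ", key$chain, ":", key$resnum,
             " has no side-chain atoms beyond CB", call. = FALSE)
      }
      tibble::tibble(centroid_x = mean(sc$x), centroid_y = mean(sc$y),
                     centroid_z = mean(sc$z))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resnum, .data$icode)
}

#' Truncate a residue to glycine or alanine
#'
#' Side-chain truncation for cavity scanning: the GLY target keeps exactly
#' the backbone heavy atoms `{N, CA, C, O}` (plus backbone hydrogens if
#' present); the ALA target additionally keeps `CB` at its original position.
#' Retained atoms never move.
#'
#' @param r Atom table rows of a single residue with backbone N, CA, C, O.
#' @param target `"GLY"` or `"ALA"`.
#' @return The truncated residue rows with updated `resname`.
#' @export
truncate_residue <- function(r, target = c("GLY", "ALA")) {
  target <- match.arg(target)
  r <- as_atom_table(r)
  if (!all(c("N", "CA", "C", "O") %in% r$atom)) {
    stop("residue lacks complete backbone (N, CA, C, O)", call. = FALSE)
  }
  backbone_h <- c("H", "HA", "H1", "H2", "H3", "HA2", "HA3", "HN")
  keep <- c("N", "CA", "C", "O", "OXT", backbone_h)
  if (target == "ALA") {
    if (!("CB" %in% r$atom) && r$resname[1] != "GLY") {
      stop("cannot truncate to ALA: residue ", r$chain[1], ":", r$resnum[1],
           " has no CB atom", call. = FALSE)
    }
    keep <- c(keep, "CB")
  }
  out <- r[r$atom %in% keep, ]
  out$resname <- target
  out
}

#' Build a cavity-scan structure for one residue type
#'
#' Truncates every non-excluded residue of `restype` to `target`
#' simultaneously in one structure, the vacated side-chain volumes becoming
#' docking cavities. Eight such structures (four residue types times
#' GLY/ALA) reproduce a full scan.
#'
#' @inheritParams select_sites
#' @param target `"GLY"` or `"ALA"`.
#' @return A `bda_cavity_scan`: list with `restype`, `target`, `structure`
#'   (mutated atom table) and `sites` (tibble from [select_sites()] with a
#'   `target` column).
#' @export
build_cavity_scan <- function(s, restype = c("PHE", "TYR", "TRP", "HIS"),
                              target = c("GLY", "ALA"), excluded = NULL) {
  restype <- match.arg(restype)
  target <- match.arg(target)
  s <- as_atom_table(s)
  sites <- select_sites(s, restype, excluded)
  if (nrow(sites) == 0) {
    stop("nothing to scan: no non-excluded ", restype, " residues",
         call. = FALSE)
  }
  sites$original_resname <- sites$resname
  sites$target <- target
  site_ids <- paste(sites$chain, sites$resnum, sites$icode, sep = ":")
  mutated <- s |>
    dplyr::group_by(.data$model, .data$chain, .data$resnum, .data$icode) |>
    dplyr::group_modify(function(res, key) {
      id <- paste(key$chain, key$resnum, key$icode, sep = ":")
      if (id %in% site_ids) {
        tr <- truncate_residue(dplyr::bind_cols(key, res), target)
        tr[setdiff(names(tr), names(key))]
      } else {
        res
      }
    }) |>
    dplyr::ungroup()
  mutated <- as_atom_table(mutated[order(mutated$model, mutated$serial), ])
  structure(list(restype = restype, target = target,
                 structure = mutated, sites = sites),
            class = "bda_cavity_scan")
}

#' @export
print.bda_cavity_scan <- function(x, ...) {
  cat("<bda_cavity_scan> ", x$restype, " -> ", x$target, ": ",
      nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' @rdname build_cavity_scan
#' @param x A `bda_cavity_scan`.
#' @param ... Unused.
#' @export
tidy.bda_cavity_scan <- function(x, ...) x$sites

#' Write a sites table as TSV
#'
#' Columns: chain, resnum, icode, resname, target, centroid_x/y/z.
#'
#' @param sites Tibble of sites (from [select_sites()] or a cavity scan).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
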