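#' Side-chain weighted contact number
#'
#' The weighted contact number (WCN) of residue i is
#' \deqn{WCN_i = \sum_{j \ne i} 1 / r_{ij}^2,}
#' where \eqn{r_{ij}} is the Euclidean distance (Angstroms) between the
#' side-chain geometric centers of residues i and j (C-alpha for glycine).
#' High WCN means a tightly packed residue. Units are 1/Angstrom^2.
#'
#' @param centers A data frame of center points with columns `x`, `y`, `z`
#'   (as from [side_chain_centers()] or [synth_point_cloud()]); at least two
#'   rows, no two coincident.
#' @return The input tibble with a `wcn` column appended, rows in input
#'   order.
#' @examples
#' pts <- tibble::tibble(x = c(0, 2), y = 0, z = 0)
#' wcn_sidechain(pts)$wcn # 1/4, 1/4
#' @export
wcn_sidechain <- function(centers) {
  stopifnot(is.data.frame(centers), all(c("x", "y", "z") %in% names(centers)))
  n <- nrow(centers)
  if (n < 2) rlang::abort("WCN needs at least two center points")
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  zero <- which(d2 == 0 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    rlang::abort(sprintf(
      "singular distance: centers %d and %d coincide", zero[1, 1], zero[1, 2]
    ))
  }
  inv <- 1 / d2
  diag(inv) <- 0
  dplyr::mutate(tibble::as_tibble(centers), wcn = unname(rowSums(inv)))
}

# deterministic unit sphere quadrature: Fibonacci lattice
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley ASA: each heavy atom is expanded by the probe radius and
#' sampled with a deterministic Fibonacci point lattice; a sample point is
#' accessible if it lies outside every other atom's expanded sphere. Atom
#' areas are summed per residue. Results are reproducible bit-for-bit for a
#' fixed `n_sphere_points`.
#'
#' @param structure A `deltol_structure` atom table.
#' @param probe_radius Solvent probe radius in Angstroms (water: 1.4).
#' @param n_sphere_points Number of quadrature points per atom.
#' @return A tibble with one row per residue in structure order:
#'   `res_index`, `chain`, `resno`, `icode`, `resname`, `asa` (square
#'   Angstroms).
#' @examples
#' s <- synth_structure(5, seed = 1)
#' asa_per_residue(s)
#' @export
asa_per_residue <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(is.data.frame(structure), nrow(structure) > 0, probe_radius >= 0,
            n_sphere_points >= 1)
  unknown <- setdiff(unique(structure$element), names(.vdw_radii))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "no van der Waals radius for element(s): ", paste(unknown, collapse = ", ")
    ))
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  radii <- unname(.vdw_radii[structure$element]) + probe_radius
  sphere <- fibonacci_sphere(n_sphere_points)
  n_atoms <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  atom_asa <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(n_atoms) != i)
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(accessible)) break
      dx <- pts[, 1] - xyz[j, 1]
      dy <- pts[, 2] - xyz[j, 2]
      dz <- pts[, 3] - xyz[j, 3]
      accessible <- accessible & (dx * dx + dy * dy + dz * dz >= radii[j]^2)
    }
    atom_asa[i] <- 4 * pi * radii[i]^2 * sum(accessible) / n_sphere_points
  }
  structure |>
    dplyr::mutate(.asa = atom_asa) |>
    dplyr::group_by(.data$res_index, .data$chain, .data$resno, .data$icode,
                    .data$resname) |>
    dplyr::summarise(asa = sum(.data$.asa), .groups = "drop") |>
    dplyr::arrange(.data$res_index)
}

#' Relative solvent accessibility
#'
#' RSA is the residue ASA divided by that amino acid's maximum ASA in a
#' Gly-X-Gly tripeptide (see [max_asa_gxg()]): 0 = fully buried, 1 = fully
#' exposed. Values above 1 can occur (e.g. at chain termini) and are kept
#' as-is but flagged with a warning.
#'
#' @param asa Numeric vector of residue ASA values, square Angstroms.
#' @param residue Character vector of 3-letter amino-acid codes (recycled
#'   if length 1).
#' @param table Normalization table; defaults to [max_asa_gxg()].
#' @return Numeric vector of RSA fractions.
#' @examples
#' rsa(65, "ALA", tibble::tibble(residue = "ALA", max_asa = 130))
#' @export
rsa <- function(asa, residue, table = max_asa_gxg()) {
  stopifnot(is.numeric(asa), all(asa >= 0))
  residue <- toupper(rep_len(residue, length(asa)))
  mx <- table$max_asa[match(residue, table$residue)]
  if (anyNA(mx)) {
    rlang::abort(paste0(
      "no max-ASA entry for residue(s): ",
      paste(unique(residue[is.na(mx)]), collapse = ", ")
    ))
  }
  out <- asa / mx
  if (any(out > 1)) {
    rlang::warn(sprintf("%d RSA value(s) exceed 1; kept unclipped", sum(out > 1)))
  }
  out
}

#' Per-residue structural features
#'
#' Convenience wrapper computing side-chain centers, WCN, ASA and RSA for
#' every residue of a structure.
#'
#' @inheritParams asa_per_residue
#' @return A tibble with one row per residue: residue identifiers plus
#'   `wcn`, `asa`, `rsa` and the center `method`.
#' @export
residue_features <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  centers <- side_chain_centers(structure)
  wcn_tab <- wcn_sidechain(centers)
  asa_tab <- asa_per_residue(structure, probe_radius, n_sphere_points)
  out <- dplyr::left_join(
    dplyr::select(wcn_tab, "res_index", "chain", "resno", "icode", "resname",
                  "method", "wcn"),
    dplyr::select(asa_tab, "res_index", "asa"),
    by = "res_index"
  )
  out$rsa <- rsa(out$asa, out$resname)
  dplyr::arrange(out, .data$res_index)
}

#' Read a mutant table
#'
#' Reads the deletion-mutant annotation table from CSV or TSV (delimiter
#' auto-detected). Required columns: `mutant_id`, `position`, `ss`
#' (helix/sheet/loop) and `functional` (`TRUE`/`FALSE` or 1/0); `chain` is
#' optional.
#'
#' @param path Path to the delimited file.
#' @return A tibble of mutant records.
#' @export
read_mutant_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("mutant table not found: ", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  m <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  need <- c("mutant_id", "position", "ss", "functional")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    rlang::abort(paste0("mutant table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  m$mutant_id <- as.character(m$mutant_id)
  m$position <- as.integer(m$position)
  m$ss <- tolower(as.character(m$ss))
  m$functional <- as.logical(m$functional)
  validate_mutants(m)
  tibble::as_tibble(m)
}

validate_mutants <- function(mutants) {
  bad_ss <- setdiff(unique(mutants$ss), .ss_levels)
  if (length(bad_ss) > 0) {
    rlang::abort(paste0("unknown secondary-structure category: ",
                        paste(bad_ss, collapse = ", ")))
  }
  dup <- mutants$mutant_id[duplicated(mutants$mutant_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate mutant_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(mutants$functional)) rlang::abort("functional labels contain NA")
  invisible(mutants)
}

#' Assemble the per-mutant feature table
#'
#' Joins each deletion mutant to the structural features of its deleted
#' residue (RSA and side-chain WCN computed from the structure) and, when
#' provided, to its mean design score. This table is the input to the
#' classifiers and to the group statistics.
#'
#' @param structure A `deltol_structure` atom table.
#' @param mutants A data frame with columns `mutant_id`, `position`
#'   (author residue numbering), `ss` and `functional` (optionally `chain`).
#' @param scores Optional mean scores: a data frame with columns
#'   `mutant_id` and `mean_score`, or a named numeric vector.
#' @inheritParams asa_per_residue
#' @return A tibble with columns `mutant_id`, `rsa`, `wcn`, `ss` (factor),
#'   `mean_score` (NA when no scores supplied) and `functional` (logical).
#' @examples
#' s <- synth_structure(8, seed = 1)
#' m <- tibble::tibble(
#'   mutant_id = c("d2", "d5"), position = c(2L, 5L),
#'   ss = c("loop", "sheet"), functional = c(TRUE, FALSE)
#' )
#' build_feature_table(s, m, n_sphere_points = 120)
#' @export
build_feature_table <- function(structure, mutants, scores = NULL,
                                probe_radius = 1.4, n_sphere_points = 960) {
  mutants <- tibble::as_tibble(mutants)
  if (nrow(mutants) > 0) validate_mutants(mutants)
  feats <- residue_features(structure, probe_radius, n_sphere_points)
  if ("chain" %in% names(mutants) && !all(is.na(mutants$chain))) {
    idx <- match(paste(mutants$chain, mutants$position),
                 paste(feats$chain, feats$resno))
  } else {
    idx <- match(mutants$position, feats$resno)
  }
  if (anyNA(idx) && nrow(mutants) > 0) {
    rlang::abort(paste0(
      "mutant position(s) not found in structure: ",
      paste(mutants$mutant_id[is.na(idx)], collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    mutant_id = as.character(mutants$mutant_id),
    rsa = feats$rsa[idx],
    wcn = feats$wcn[idx],
    ss = factor(mutants$ss, levels = .ss_levels),
    mean_score = NA_real_,
    functional = as.logical(mutants$functional)
  )
  if (!is.null(scores)) {
    if (is.numeric(scores) && !is.null(names(scores))) {
      scores <- tibble::tibble(mutant_id = names(scores), mean_score = unname(scores))
    }
    stopifnot(all(c("mutant_id", "mean_score") %in% names(scores)))
    out$mean_score <- scores$mean_score[match(out$mutant_id, scores$mutant_id)]
  }
  out
}
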