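#' Read a protein structure from a PDB file or PDB text
#'
#' Parses ATOM records into a flat atom table, one row per heavy atom of a
#' standard amino-acid residue. Hydrogens are dropped; for alternate
#' locations only the copy with the highest occupancy is kept (ties broken
#' by file order); HETATM records are excluded unless their residue name is
#' listed in `include_het`, in which case they join the table as
#' pseudo-residues (e.g. the mature eGFP chromophore `"CRO"`).
#'
#' @param pdb Path to a PDB file, or a character string containing PDB
#'   records (detected by the presence of a newline).
#' @param chain Optional chain identifier; when given only that chain is kept.
#' @param include_het Character vector of HETATM residue names to retain as
#'   pseudo-residues. Default none.
#' @return A tibble of class `deltol_structure` with columns `chain`,
#'   `resno`, `icode`, `resname`, `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy` and a per-residue index `res_index` following file order.
#'   The structure id (file stem or `"structure"`) is stored in
#'   `attr(, "id")`.
#' @examples
#' pdb <- synth_structure(5, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(pdb, f)
#' s <- read_structure(f)
#' dplyr::count(s, res_index)
#' @export
read_structure <- function(pdb, chain = NULL, include_het = character()) {
  stopifnot(is.character(pdb), length(pdb) == 1)
  if (grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
    id <- "structure"
    on.exit(unlink(path))
  } else {
    if (!file.exists(pdb)) {
      rlang::abort(paste0("PDB input not found: ", pdb))
    }
    path <- pdb
    id <- sub("\\.[^.]*$", "", basename(pdb))
  }

  parsed <- tryCatch(
    # rm.alt = FALSE: alternate locations are resolved here by occupancy,
    # not by bio3d's keep-"A" default
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) {
      rlang::abort(paste0("empty structure: no parseable ATOM records (", conditionMessage(e), ")"))
    }
  )
  at <- tibble::as_tibble(parsed$atom)

  keep <- (at$type == "ATOM" & at$resid %in% .standard_aa) |
    (at$type == "HETATM" & at$resid %in% include_het)
  at <- at[keep, , drop = FALSE]
  if (!is.null(chain)) at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) {
    rlang::abort("empty structure: no ATOM records after filtering")
  }

  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "parse error: non-numeric coordinate at atom %s of residue %s %s%d",
      at$elety[i], at$resid[i], at$chain[i], at$resno[i]
    ))
  }

  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | elem == ""
  if (any(no_elem)) {
    # infer element from the atom name: strip leading digits, take first letter
    elem[no_elem] <- substr(sub("^[0-9]*", "", at$elety[no_elem]), 1, 1)
  }
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  elem <- elem[!elem %in% c("H", "D")]
  if (nrow(at) == 0) rlang::abort("empty structure: only hydrogens present")

  out <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )

  # alternate locations: highest occupancy wins, ties by file order
  out <- out |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$.file_order, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)

  key <- paste(out$chain, out$resno, out$icode, sep = "\r")
  out$res_index <- match(key, unique(key))
  out <- dplyr::select(out, -".file_order", -"altloc")

  new_structure(out, id = id)
}

new_structure <- function(df, id = "structure") {
  df <- tibble::as_tibble(df)
  class(df) <- c("deltol_structure", class(df))
  attr(df, "id") <- id
  df
}

#' Write an atom table back to PDB format
#'
#' @param structure A `deltol_structure` tibble as returned by
#'   [read_structure()] or [synth_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(is.data.frame(structure), nrow(structure) > 0)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(structure)),
    resno = structure$resno,
    resid = structure$resname,
    insert = ifelse(structure$icode == "", NA, structure$icode),
    chain = ifelse(structure$chain == "", NA, structure$chain),
    elety = structure$atom,
    eleno = seq_len(nrow(structure)),
    o = structure$occupancy,
    b = rep(0, nrow(structure)),
    elesy = structure$element
  )
  invisible(path)
}

#' Side-chain geometric centers
#'
#' Computes, per residue, the arithmetic mean of the coordinates of its
#' side-chain heavy atoms (all heavy atoms except backbone N, CA, C, O and
#' OXT). Glycine has no side-chain heavy atoms and falls back to its
#' C-alpha position; any other residue with no side-chain heavy atoms in
#' the file falls back likewise, with the fallback recorded in `method`.
#' These center points are the reference points for side-chain weighted
#' contact number.
#'
#' @param structure A `deltol_structure` atom table.
#' @return A tibble with one row per residue, in structure order:
#'   `res_index`, `chain`, `resno`, `icode`, `resname`, `x`, `y`, `z`,
#'   `method` (`"sidechain_geometric"` or `"calpha_fallback"`).
#' @examples
#' s <- synth_structure(5, seed = 1)
#' side_chain_centers(s)
#' @export
side_chain_centers <- function(structure) {
  stopifnot(is.data.frame(structure), nrow(structure) > 0)
  split_idx <- split(seq_len(nrow(structure)), structure$res_index)
  rows <- lapply(split_idx, function(i) {
    res <- structure[i, , drop = FALSE]
    sc <- res[!(res$atom %in% .backbone_atoms), , drop = FALSE]
    if (nrow(sc) > 0) {
      point <- c(mean(sc$x), mean(sc$y), mean(sc$z))
      method <- "sidechain_geometric"
    } else {
      ca <- res[res$atom == "CA", , drop = FALSE]
      if (nrow(ca) == 0) {
        rlang::abort(sprintf(
          "residue %s %s%d has neither side-chain heavy atoms nor CA",
          res$resname[1], res$chain[1], res$resno[1]
        ))
      }
      point <- c(ca$x[1], ca$y[1], ca$z[1])
      method <- "calpha_fallback"
    }
    tibble::tibble(
      res_index = res$res_index[1], chain = res$chain[1], resno = res$resno[1],
      icode = res$icode[1], resname = res$resname[1],
      x = point[1], y = point[2], z = point[3], method = method
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$res_index)
}
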