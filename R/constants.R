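#' Maximum solvent accessibility in a Gly-X-Gly tripeptide
#'
#' Theoretical maximum solvent-accessible surface area (ASA, in square
#' Angstroms) for each of the 20 standard amino acids, computed in an
#' extended Gly-X-Gly tripeptide context (the "theoretical" normalization
#' of Tien et al. 2013). Dividing an observed residue ASA by this maximum
#' gives relative solvent accessibility (RSA), nominally in \[0, 1\].
#'
#' @return A tibble with columns `residue` (3-letter code, upper case) and
#'   `max_asa` (square Angstroms).
#' @examples
#' max_asa_gxg()
#' @export
max_asa_gxg <- function() {
  tibble::tibble(
    residue = c(
      "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
    ),
    max_asa = c(
      129.0, 274.0, 195.0, 193.0, 167.0, 225.0, 223.0, 104.0, 224.0, 197.0,
      201.0, 236.0, 224.0, 240.0, 159.0, 155.0, 172.0, 285.0, 263.0, 174.0
    )
  )
}

# van der Waals radii (Angstroms) for heavy elements common in proteins
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

# backbone heavy-atom names; everything else heavy is "side chain"
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.ss_levels <- c("helix", "loop", "sheet")

#' Secondary-structure contingency counts for the eGFP deletion data set
#'
#' The published study of 72 single amino-acid eGFP deletion mutants
#' (34 tolerated, 38 non-tolerated) reported the tolerated fraction per
#' secondary-structure category: 78.3% in loops, 66.7% in helices and
#' 21.6% in sheets. Together with the class totals these fractions
#' determine the full 2x3 contingency table uniquely; the counts returned
#' here are that reconstruction (18/8/8 tolerated and 5/4/29 non-tolerated
#' deletions in loop/helix/sheet, i.e. 23 loop, 12 helix and 37 sheet
#' positions). They reproduce the reported chi-squared contingency
#' P = 3.642e-05 exactly.
#'
#' @return A tibble with columns `functional` (logical, `TRUE` =
#'   tolerated), `ss` (factor: helix/loop/sheet) and `n` (count).
#' @examples
#' egfp_ss_counts()
#' @export
egfp_ss_counts <- function() {
  tibble::tibble(
    functional = rep(c(TRUE, FALSE), each = 3),
    ss = factor(rep(c("loop", "helix", "sheet"), 2), levels = .ss_levels),
    n = c(18L, 8L, 8L, 5L, 4L, 29L)
  )
}
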