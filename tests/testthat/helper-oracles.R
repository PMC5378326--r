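# Independent brute-force oracles, deliberately naive implementations.

# O(N^2) double-loop weighted contact number
oracle_wcn <- function(xyz) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      acc <- acc + 1 / sum((xyz[i, ] - xyz[j, ])^2)
    }
    out[i] <- acc
  }
  out
}

# tie-corrected Mann-Whitney AUC by explicit pair counting
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Welch two-sample t statistic, df and two-sided p, straight from the formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson chi-squared statistic from observed counts
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# one well-formed PDB ATOM line (wwPDB v3.3 columns)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf(
    "ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, paste0(" ", name), altloc, resname, chain, resno,
    x, y, z, occ, 0, element
  )
}
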