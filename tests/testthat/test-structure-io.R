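test_that("a minimal ATOM record parses into one residue with one atom", {
  txt <- paste(pdb_atom_line(1, "CA", "ALA", "A", 5, 1, 2, 3), "END", sep = "\n")
  s <- read_structure(txt)
  expect_equal(nrow(s), 1)
  expect_equal(s$resname, "ALA")
  expect_equal(s$resno, 5L)
  expect_equal(c(s$x, s$y, s$z), c(1, 2, 3))
})

test_that("input without ATOM records is rejected", {
  expect_error(read_structure("HEADER    NOTHING\nEND"), "empty structure")
  expect_error(read_structure("\n"), "empty structure")
})

test_that("alternate locations keep the highest-occupancy copy", {
  txt <- paste(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.7, altloc = "A"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 9, 9, 9, occ = 0.3, altloc = "B"),
    "END", sep = "\n"
  )
  s <- read_structure(txt)
  cb <- s[s$atom == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$occupancy, 0.7)
  expect_equal(cb$x, 1)

  # the rule is occupancy-based, not altloc-letter-based: B wins at 0.8
  txt2 <- paste(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.2, altloc = "A"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 9, 9, 9, occ = 0.8, altloc = "B"),
    "END", sep = "\n"
  )
  cb2 <- read_structure(txt2) |> dplyr::filter(atom == "CB")
  expect_equal(nrow(cb2), 1)
  expect_equal(cb2$x, 9)

  # equal occupancies: first in file wins
  txt3 <- paste(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.5, altloc = "A"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 9, 9, 9, occ = 0.5, altloc = "B"),
    "END", sep = "\n"
  )
  cb3 <- read_structure(txt3) |> dplyr::filter(atom == "CB")
  expect_equal(cb3$x, 1)
})

test_that("hydrogens, HETATM and non-selected chains are filtered", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "HA", "GLY", "A", 1, 0.5, 0, 0, element = "H"),
    pdb_atom_line(3, "CA", "GLY", "B", 1, 5, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_atom_line(4, "C1", "CRO", "A", 66, 2, 2, 2)),
    "END"
  )
  s <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(s), 2) # both CA, no H, no HETATM
  expect_false(any(s$element == "H"))

  s_a <- read_structure(paste(lines, collapse = "\n"), chain = "A")
  expect_equal(unique(s_a$chain), "A")

  s_het <- read_structure(paste(lines, collapse = "\n"), chain = "A",
                          include_het = "CRO")
  expect_true("CRO" %in% s_het$resname)
})

test_that("synthetic structures round-trip through PDB to format precision", {
  s <- synth_structure(12, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$atom, s$atom)
  expect_equal(s2$resname, s$resname)
  expect_equal(s2$res_index, s$res_index)
  expect_equal(s2$x, s$x, tolerance = 1e-3)
  expect_equal(s2$y, s$y, tolerance = 1e-3)
  expect_equal(s2$z, s$z, tolerance = 1e-3)
})

test_that("side-chain centers follow the geometric-center and glycine rules", {
  gly <- tibble::tibble(
    chain = "A", resno = 1L, icode = "", resname = "GLY",
    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(0, 1, 2, 3), y = c(0, 2, 0, 0), z = c(0, 3, 0, 0),
    occupancy = 1, res_index = 1L
  )
  cen <- side_chain_centers(gly)
  expect_equal(cen$method, "calpha_fallback")
  expect_equal(c(cen$x, cen$y, cen$z), c(1, 2, 3))

  ala <- dplyr::mutate(gly, resname = "ALA")
  ala <- dplyr::bind_rows(ala, dplyr::mutate(ala[2, ], atom = "CB", x = 0, y = 0, z = 0))
  cen <- side_chain_centers(ala)
  expect_equal(cen$method, "sidechain_geometric")
  expect_equal(c(cen$x, cen$y, cen$z), c(0, 0, 0))

  two <- dplyr::bind_rows(
    dplyr::mutate(ala, resname = "SER"),
    dplyr::mutate(ala[2, ], resname = "SER", atom = "OG", element = "O",
                  x = 2, y = 0, z = 0)
  )
  cen <- side_chain_centers(two)
  expect_equal(c(cen$x, cen$y, cen$z), c(1, 0, 0)) # midpoint of (0,0,0),(2,0,0)
})

test_that("side-chain centers are translation-equivariant and finite", {
  s <- synth_structure(15, seed = 9)
  cen <- side_chain_centers(s)
  shift <- c(3.5, -2, 11)
  s2 <- dplyr::mutate(s, x = x + shift[1], y = y + shift[2], z = z + shift[3])
  cen2 <- side_chain_centers(s2)
  expect_equal(cen2$x, cen$x + shift[1])
  expect_equal(cen2$y, cen$y + shift[2])
  expect_equal(cen2$z, cen$z + shift[3])
  expect_true(all(is.finite(c(cen$x, cen$y, cen$z))))
})

test_that("a residue with neither side chain nor CA is an error", {
  res <- tibble::tibble(
    chain = "A", resno = 1L, icode = "", resname = "GLY",
    atom = "N", element = "N", x = 0, y = 0, z = 0,
    occupancy = 1, res_index = 1L
  )
  expect_error(side_chain_centers(res), "neither side-chain")
})
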