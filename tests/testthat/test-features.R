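test_that("WCN matches the analytic two-point and collinear fixtures", {
  two <- tibble::tibble(x = c(0, 2), y = 0, z = 0)
  expect_equal(wcn_sidechain(two)$wcn, c(0.25, 0.25))

  three <- tibble::tibble(x = c(0, 1, 2), y = 0, z = 0)
  expect_equal(wcn_sidechain(three)$wcn, c(1.25, 2.0, 1.25))
})

test_that("WCN equals the double-loop oracle on random clouds", {
  for (seed in 1:5) {
    n <- c(20, 50, 100, 150, 200)[seed]
    cloud <- synth_point_cloud(n, box = 40, min_separation = 1.0, seed = seed)
    got <- wcn_sidechain(cloud)$wcn
    expect_equal(got, oracle_wcn(as.matrix(cloud)), tolerance = 1e-12)
  }
})

test_that("WCN scales as 1/c^2 under coordinate scaling and rejects coincident points", {
  cloud <- synth_point_cloud(30, seed = 11)
  w1 <- wcn_sidechain(cloud)$wcn
  w3 <- wcn_sidechain(dplyr::mutate(cloud, x = 3 * x, y = 3 * y, z = 3 * z))$wcn
  expect_equal(w3, w1 / 9)

  dup <- dplyr::bind_rows(cloud[1:3, ], cloud[2, ])
  expect_error(wcn_sidechain(dup), "coincide")
  expect_error(wcn_sidechain(cloud[1, ]), "at least two")
})

one_atom <- function(x = 0, y = 0, z = 0, element = "S", resno = 1L) {
  tibble::tibble(
    chain = "A", resno = resno, icode = "", resname = "CYS",
    atom = "SG", element = element, x = x, y = y, z = z,
    occupancy = 1, res_index = resno
  )
}

test_that("ASA of an isolated atom approaches the analytic sphere area", {
  s <- one_atom() # S: r_vdw 1.8 + probe 1.4 = 3.2
  exact <- 4 * pi * 3.2^2
  got <- asa_per_residue(s, n_sphere_points = 960)$asa
  expect_lt(abs(got - exact) / exact, 0.02)

  # convergence: more quadrature points, smaller error
  err <- sapply(c(60, 240, 960), function(np) {
    abs(asa_per_residue(s, n_sphere_points = np)$asa - exact) / exact
  })
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 1e-12)
})

test_that("two far-apart atoms each expose their full sphere", {
  s <- dplyr::bind_rows(one_atom(), one_atom(x = 100, resno = 2L))
  a <- asa_per_residue(s, n_sphere_points = 480)$asa
  expect_equal(a[1], a[2])
  expect_equal(a[1], 4 * pi * 3.2^2, tolerance = 0.02)
})

test_that("an atom enclosed by a shell of neighbors has zero ASA", {
  shell_dirs <- deltol:::fibonacci_sphere(60)
  shell <- purrr::map(seq_len(60), function(i) {
    one_atom(2 * shell_dirs[i, 1], 2 * shell_dirs[i, 2], 2 * shell_dirs[i, 3],
             element = "N", resno = i + 1L)
  }) |> purrr::list_rbind()
  s <- dplyr::bind_rows(one_atom(element = "C"), shell)
  a <- asa_per_residue(s, n_sphere_points = 960)
  expect_equal(a$asa[a$res_index == 1], 0)
})

test_that("ASA is rotation-invariant up to quadrature tolerance and scales as c^2 when far apart", {
  s <- synth_structure(10, seed = 2)
  a <- asa_per_residue(s, n_sphere_points = 480)$asa
  th <- 0.7
  rot <- dplyr::mutate(s,
    x0 = x, y0 = y,
    x = cos(th) * x0 - sin(th) * y0,
    y = sin(th) * x0 + cos(th) * y0
  )
  a_rot <- asa_per_residue(rot, n_sphere_points = 480)$asa
  expect_equal(a_rot, a, tolerance = 0.03)

  # large-separation limit: scaling coordinates isolates every atom
  far <- dplyr::mutate(s, x = 50 * x, y = 50 * y, z = 50 * z)
  a_far <- asa_per_residue(far, n_sphere_points = 240)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80) + 1.4
  expected <- s |>
    dplyr::mutate(area = 4 * pi * radii[element]^2) |>
    dplyr::group_by(res_index) |>
    dplyr::summarise(asa = sum(area))
  expect_equal(a_far$asa, expected$asa, tolerance = 1e-6)
})

test_that("unknown elements are rejected with a radius-lookup error", {
  expect_error(asa_per_residue(one_atom(element = "ZZ")), "van der Waals")
})

test_that("RSA normalizes by the residue maximum and flags values above 1", {
  tab <- tibble::tibble(residue = c("ALA", "GLY"), max_asa = c(130, 104))
  expect_equal(rsa(0, "ALA", tab), 0)
  expect_equal(rsa(130, "ALA", tab), 1)
  expect_equal(rsa(65, "ALA", tab), 0.5)
  expect_warning(rsa(200, "ALA", tab), "exceed 1")
  expect_error(rsa(10, "XXX", tab), "no max-ASA entry")
  expect_error(rsa(-1, "ALA", tab))
})

test_that("the max-ASA table covers all 20 standard amino acids with positive values", {
  tab <- max_asa_gxg()
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$max_asa > 0))
  expect_equal(tab$max_asa[tab$residue == "GLY"], 104)
})

test_that("build_feature_table composes per-residue features with mutant rows", {
  s <- synth_structure(8, seed = 6)
  rf <- residue_features(s, n_sphere_points = 240)
  mutants <- tibble::tibble(
    mutant_id = c("d2", "d5", "d7"), position = c(2L, 5L, 7L),
    ss = c("loop", "sheet", "helix"), functional = c(TRUE, FALSE, TRUE)
  )
  scores <- c(d2 = -510, d5 = -490, d7 = -505)
  tab <- build_feature_table(s, mutants, scores, n_sphere_points = 240)
  expect_equal(nrow(tab), 3)
  expect_equal(names(tab), c("mutant_id", "rsa", "wcn", "ss", "mean_score", "functional"))
  expect_equal(tab$wcn, rf$wcn[match(mutants$position, rf$resno)])
  expect_equal(tab$rsa, rf$rsa[match(mutants$position, rf$resno)])
  expect_equal(tab$mean_score, unname(scores))

  expect_error(
    build_feature_table(s, dplyr::mutate(mutants, position = c(2L, 99L, 7L)),
                        n_sphere_points = 120),
    "d5"
  )
  expect_error(
    build_feature_table(s, dplyr::mutate(mutants, mutant_id = c("a", "a", "b")),
                        n_sphere_points = 120),
    "duplicate"
  )

  empty <- build_feature_table(s, mutants[0, ], n_sphere_points = 120)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), names(tab))
})

test_that("mutant tables read from CSV and TSV with label coercion", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant_id,position,ss,functional",
               "m1,2,loop,1", "m2,5,sheet,0"), f)
  m <- read_mutant_table(f)
  expect_equal(m$functional, c(TRUE, FALSE))

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutant_id\tposition\tss\tfunctional",
               "m1\t2\tHelix\tTRUE"), ft)
  expect_equal(read_mutant_table(ft)$ss, "helix")

  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant_id,position,ss,functional", "m1,2,coil,1"), fbad)
  expect_error(read_mutant_table(fbad), "unknown secondary-structure")
})
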