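test_that("structure reader round-trips a generated helix and filters records", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_helix_structure(strrep("A", 20), path = pdb)
  atoms <- read_structure(pdb)
  expect_equal(dplyr::n_distinct(atoms$resnum), 20L)
  expect_equal(nrow(atoms), 20L * 5L)  # N, CA, C, O, CB per Ala
  expect_true(all(atoms$element %in% c("N", "C", "O")))
  expect_error(read_structure(pdb, chains = "Z"), class = "ardscan_empty_selection")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               class = "ardscan_unreadable_file")
})

test_that("reader keeps the highest-occupancy altloc and drops H and water", {
  pdb <- altloc_pdb(withr::local_tempfile(fileext = ".pdb"))
  atoms <- read_structure(pdb)
  expect_equal(nrow(atoms), 4L)  # N, CA(A), C, O; H and HOH gone
  ca <- atoms[atoms$atom == "CA", ]
  expect_equal(ca$occupancy, 0.60)
  expect_equal(ca$x, 1.458)
})

test_that("mmCIF input parses to the same heavy atoms as PDB", {
  cif <- mini_cif(withr::local_tempfile(fileext = ".cif"))
  atoms <- read_structure(cif)
  expect_equal(nrow(atoms), 4L)
  expect_equal(atoms$resid, rep("ALA", 4))
  expect_equal(sort(atoms$atom), sort(c("N", "CA", "C", "O")))
  expect_equal(atoms$x[atoms$atom == "CA"], 1.458)
})

test_that("an isolated atom's SASA matches the closed form 4*pi*(r+p)^2", {
  lone <- tibble::tibble(x = 0, y = 0, z = 0, element = "S")  # r = 1.8
  s <- shrake_rupley(lone, probe_radius = 1.4, n_points = 960)$atom_sasa
  expect_lt(abs(s / (4 * pi * 3.2^2) - 1), 0.01)
  # two such atoms far apart do not interact
  pair <- tibble::tibble(x = c(0, 100), y = 0, z = 0, element = "S")
  s2 <- shrake_rupley(pair, 1.4, 960)$atom_sasa
  expect_equal(s2, rep(s, 2))
})

test_that("an atom enclosed in a tight cage has zero SASA", {
  # oracle by construction: 26 neighbours at 2 A on the unit grid directions
  # block every test point of the central sphere (each blocks a ~71 degree cap)
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- tibble::tibble(x = c(0, 2 * dirs[, 1]), y = c(0, 2 * dirs[, 2]),
                         z = c(0, 2 * dirs[, 3]), element = "C")
  s <- shrake_rupley(cage, 1.4, 960)$atom_sasa
  expect_identical(s[[1]], 0)
})

test_that("coincident atoms raise a degenerate-geometry error", {
  dup <- tibble::tibble(x = c(1, 1), y = 2, z = 3, element = "C")
  expect_error(shrake_rupley(dup), class = "ardscan_degenerate_geometry")
})

test_that("occlusion is monotone: adding atoms never increases existing SASA", {
  for (s in 1:10) {
    atoms <- withr::with_seed(s, tibble::tibble(
      x = runif(15, 0, 8), y = runif(15, 0, 8), z = runif(15, 0, 8),
      element = sample(c("C", "N", "O", "S"), 15, replace = TRUE)
    ))
    base <- shrake_rupley(atoms, n_points = 240)$atom_sasa
    extra <- withr::with_seed(s + 100, tibble::tibble(
      x = runif(3, 0, 8), y = runif(3, 0, 8), z = runif(3, 0, 8),
      element = "C"
    ))
    grown <- shrake_rupley(dplyr::bind_rows(atoms, extra), n_points = 240)$atom_sasa
    expect_true(all(grown[1:15] <= base + 1e-9))
    expect_true(all(grown >= 0))
  }
})

test_that("SASA converges: doubling the point count moves totals < 1%", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_helix_structure("MKTAYIAKQRQISFVK", path = pdb)
  atoms <- read_structure(pdb)
  t1 <- sum(shrake_rupley(atoms, n_points = 960)$atom_sasa)
  t2 <- sum(shrake_rupley(atoms, n_points = 1920)$atom_sasa)
  expect_lt(abs(t2 / t1 - 1), 0.01)
})

test_that("residue SASA sums atoms and normalizes by the reference maximum", {
  per_atom <- tibble::tibble(
    chain = "A", resnum = 1L, resid = "ALA",
    atom = c("CA", "CB"), atom_sasa = c(30, 34.5)
  )
  rs <- residue_sasa(per_atom)
  expect_equal(rs$abs_sasa, 64.5)
  expect_equal(rs$frac_sasa, 0.50)  # 64.5 / 129.0
  expect_error(
    residue_sasa(dplyr::mutate(per_atom, resid = "LIG")),
    class = "ardscan_unknown_residue"
  )
})

test_that("residue totals equal atom totals and a fully exposed residue nears its max", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_helix_structure("GAG", path = pdb, phi = -139, psi = 135)  # extended
  atoms <- shrake_rupley(read_structure(pdb))
  rs <- suppressWarnings(residue_sasa(atoms))
  expect_equal(sum(rs$abs_sasa), sum(atoms$atom_sasa))
  expect_true(all(rs$abs_sasa >= 0))
  # central residue of an extended Gly-X-Gly is the max-ASA reference geometry
  expect_lt(abs(rs$frac_sasa[rs$resnum == 2] - 1), 0.15)
})

test_that("compute_sasa reports one chain from a multi-chain context", {
  # two copies of a helix packed side by side (chain B shifted 6 A in x)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  a_lines <- generate_helix_structure(strrep("A", 10), chain = "A")
  bx <- read_structure(
    withr::local_tempfile(fileext = ".pdb",
                          lines = generate_helix_structure(strrep("V", 10), chain = "B"))
  )
  b_lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(bx)) + 100L,
    ifelse(nchar(bx$atom) < 4, sprintf(" %-3s", bx$atom), bx$atom),
    bx$resid, "B", bx$resnum, bx$x + 6, bx$y, bx$z, 1, 0, bx$element
  )
  writeLines(c(head(a_lines, -2), b_lines, "TER", "END"), pdb)

  ctx <- compute_sasa(pdb, report_chain = "A")
  alone <- compute_sasa(pdb, chains = "A", report_chain = "A")
  expect_equal(nrow(ctx), 10L)
  expect_true(all(ctx$chain == "A"))
  # packing against chain B can only bury chain A further
  expect_true(all(ctx$abs_sasa <= alone$abs_sasa + 1e-9))
  expect_error(compute_sasa(pdb, report_chain = "A", range = c(900, 950)),
               class = "ardscan_empty_selection")
})

test_that("the golden-spiral point set is deterministic and unit-norm", {
  p1 <- sphere_points(960)
  p2 <- sphere_points(960)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1^2), rep(1, 960), tolerance = 1e-12)
})
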