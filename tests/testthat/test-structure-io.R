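test_that("a hand-written PDB fixture parses to its written coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_three_atom_pdb(path)
  st <- read_structure(path)
  expect_s3_class(st, "bphp_structure")
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(unique(st$atoms$chain), "A")
  expect_equal(chain_lengths(st), c(A = 1L))
  expect_equal(st$atoms$x, c(1.0, 2.5, 3.2))
  expect_equal(st$atoms$b, c(10.0, 12.5, 15.0))
  expect_false(any(st$atoms$het))
})

test_that("PDB and mmCIF serializations of one model parse identically", {
  g <- make_synthetic_dimer(dimer_spec(n_core = 40L, n_phy = 20L,
                                       helix3 = c(10L, 19L),
                                       helix6 = c(25L, 34L), seed = 3L))
  p_pdb <- withr::local_tempfile(fileext = ".pdb")
  p_cif <- withr::local_tempfile(fileext = ".cif")
  write_structure_pdb(g$structure, p_pdb)
  write_structure_cif(g$structure, p_cif)
  a <- read_structure(p_pdb)
  b <- read_structure(p_cif)
  for (col in c("chain", "resno", "resid", "elety", "het"))
    expect_equal(a$atoms[[col]], b$atoms[[col]], info = col)
  # both dialects print 3 decimals
  for (col in c("x", "y", "z"))
    expect_equal(a$atoms[[col]], b$atoms[[col]], tolerance = 1e-9,
                 info = col)
})

test_that("parse/serialize round trip preserves coordinates to PDB precision", {
  st <- poly_ala_structure(8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  back <- read_structure(path)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               tolerance = 5e-4, ignore_attr = TRUE)
})

test_that("unreadable and empty inputs raise informative errors", {
  expect_error(read_structure("/nonexistent/file.pdb"), "cannot read")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", p)
  expect_error(read_structure(p), "parse|zero atoms")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA AALA A   2       0.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   2       0.000   9.000   0.000  0.50 10.00           C",
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 2L)
  expect_equal(st$atoms$x[1], 9.0)   # occupancy 0.6 wins
  expect_equal(st$atoms$y[2], 1.0)   # tie -> first altloc label
})

test_that("trace extraction restricts to domains and skips CA-less residues", {
  st <- poly_ala_structure(10)
  tr <- extract_trace(st, "A")
  expect_equal(length(tr$resno), 10L)
  expect_equal(tr$codes, rep("A", 10))

  scheme <- domain_scheme(domains = list(PAS = c(1L, 3L), GAF = c(4L, 6L),
                                         PHY = c(7L, 10L)),
                          interface_helices = list(h3 = c(1L, 3L),
                                                   h6 = c(4L, 6L)))
  trd <- extract_trace(st, "A", domains = scheme, domain = "PHY")
  expect_equal(trd$resno, 7:10)

  # drop the CA of residues 4 and 8: trace shrinks by exactly 2
  st2 <- st
  st2$atoms$elety[st2$atoms$resno %in% c(4L, 8L)] <- "CB"
  tr2 <- extract_trace(st2, "A")
  expect_equal(length(tr2$resno), 8L)
  expect_equal(attr(tr2, "n_skipped"), 2L)

  expect_error(extract_trace(st, "Z"), "unknown chain")
  expect_error(extract_trace(st, "A", domains = scheme, domain = "nope"),
               "unknown domain")
})

test_that("trace extraction is idempotent, order-preserving and reports breaks", {
  g <- make_synthetic_dimer(dimer_spec(n_core = 40L, n_phy = 20L,
                                       helix3 = c(10L, 19L),
                                       helix6 = c(25L, 34L), seed = 5L))
  tr <- extract_trace(g$structure, "A")
  expect_false(is.unsorted(tr$resno, strictly = TRUE))
  # lattice filler jumps exceed 4.5 A: breaks recorded, extraction succeeds
  expect_gt(length(attr(tr, "breaks")), 0L)
})

test_that("rigid transforms preserve all pairwise distances", {
  st <- poly_ala_structure(10)
  expect_identical(apply_transform(st, rigid_transform())$atoms, st$atoms)

  shifted <- apply_transform(st, rigid_transform(translation = c(1, 2, 3)))
  expect_equal(shifted$atoms$x, st$atoms$x + 1)
  expect_equal(shifted$atoms$z, st$atoms$z + 3)

  set.seed(11)
  pts <- matrix(rnorm(150, sd = 10), 50, 3)
  d0 <- dist(pts)
  for (i in 1:100) {
    tf <- random_rigid()
    d1 <- dist(sweep(pts %*% t(tf$R), 2, tf$t, "+"))
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("improper or non-orthonormal rotations are refused", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  expect_error(rigid_transform(matrix(runif(9), 3, 3)), "orthonormal")
  expect_error(apply_transform(poly_ala_structure(4),
                               list(R = diag(c(1, 1, -1)), t = c(0, 0, 0))),
               "proper")
})

test_that("transform composition and inversion are consistent", {
  set.seed(4)
  a <- random_rigid(); b <- random_rigid()
  p <- rnorm(3)
  via_compose <- compose_transform(a, b)
  expect_equal(as.numeric(b$R %*% (a$R %*% p + a$t) + b$t),
               as.numeric(via_compose$R %*% p + via_compose$t),
               tolerance = 1e-12)
  ident <- compose_transform(a, invert_transform(a))
  expect_equal(ident$R, diag(3), tolerance = 1e-12)
  expect_equal(ident$t, c(0, 0, 0), tolerance = 1e-12)
})

test_that("atom pair distances address protein and het atoms alike", {
  atoms <- data.frame(
    chain = "A", resno = c(1L, 1L, 289L, 600L), ins = "",
    resid = c("ALA", "ALA", "HIS", "BLA"),
    elety = c("N", "CA", "NE2", "O_D"),
    x = c(0, 1, 0, 0), y = 0, z = c(0, 0, 2.8, 5.9),
    b = 10, o = 1, het = c(FALSE, FALSE, FALSE, TRUE))
  st <- bphp_structure(atoms, "pocket")
  expect_equal(atom_pair_distance(st, c("A", 1, "N"), c("A", 289, "NE2")), 2.8)
  expect_equal(atom_pair_distance(st, c("A", 289, "NE2"), c("A", 1, "N")), 2.8)
  # het atom addressed by residue name
  expect_equal(atom_pair_distance(st, c("A", "BLA", "O_D"),
                                  c("A", 289, "NE2")), 3.1)
  expect_error(atom_pair_distance(st, c("A", 1, "CB"), c("A", 289, "NE2")),
               "atoms present")
})

test_that("config files supply domain scheme and symmetry operator", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "domains:",
    "  PAS: [1, 115]", "  GAF: [116, 320]", "  PHY: [321, 516]",
    "interface_helices:",
    "  h3: [240, 259]", "  h6: [270, 289]",
    "symmetry: [-1, 0, 0, 0, -1, 0, 0, 0, 1, 0, 0, 0]"), path)
  cfg <- read_config(path)
  expect_equal(cfg$scheme$domains$PHY, c(321L, 516L))
  expect_equal(cfg$scheme$interface_helices$h3, c(240L, 259L))
  expect_equal(cfg$symmetry$R, diag(c(-1, -1, 1)))
  expect_error(domain_scheme(domains = list(PAS = c(1L, 330L),
                                            PHY = c(320L, 516L))),
               "overlaps")

  shipped <- read_config(system.file("extdata", "sabphp1_pcm.yaml",
                                     package = "bphpgeom"))
  expect_equal(shipped$scheme$domains$tongue, c(435L, 485L))
  expect_equal(shipped$scheme$interface_helices$h6, c(280L, 299L))
  expect_equal(shipped$motifs$PRXSF, "PRXSF")
})
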