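# In-code fixtures shared across test files.

# Hand-written 3-atom, 1-residue PDB fixture (fixed-column records).
write_three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 12.50           C",
    "ATOM      3  C   ALA A   1       3.200   3.300   3.000  1.00 15.00           C",
    "END"), path)
  path
}

# Poly-alanine single-chain structure built from an ideal helix trace.
poly_ala_structure <- function(n = 10, chain = "A", id = "polyA") {
  h <- make_ideal_helix(n)
  bphp_structure(data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = "ALA",
    elety = "CA", x = h$xyz[, 1], y = h$xyz[, 2], z = h$xyz[, 3],
    b = 20, o = 1, het = FALSE), identifier = id)
}
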