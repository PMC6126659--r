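#' Coordinate containers and rigid-body plumbing
#'
#' @description
#' The pipeline represents a structure as a flat atom table (one row per atom)
#' wrapped in the S3 class `bphp_structure`. Coordinates are in Angstrom,
#' residue numbering is author numbering (1-based, as printed on residue labels
#' such as Thr289 or Arg472), and angles everywhere in the package are degrees.
#'
#' @name structure-model
#' @keywords internal
NULL

.amino1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common modified residues mapped to their parent code
  MSE = "M", SEC = "U", PYL = "O", CSO = "C", PTR = "Y", SEP = "S", TPO = "T"
)

aa3to1 <- function(resid) {
  out <- unname(.amino1[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `ins` (insertion code, `""` when absent), `resid` (3-letter
#'   residue name), `elety` (atom name, e.g. `"CA"`), `x`, `y`, `z` (Angstrom),
#'   `b` (B factor, Angstrom^2), `o` (occupancy), `het` (logical HETATM flag).
#' @param identifier character label for the model.
#' @return An object of class `bphp_structure`.
#' @export
bphp_structure <- function(atoms, identifier = "structure") {
  need <- c("chain", "resno", "ins", "resid", "elety",
            "x", "y", "z", "b", "o", "het")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty structure: zero atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite atom coordinates")
  if (any(atoms$b < 0, na.rm = TRUE))
    stop("negative B factor")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$ins), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier),
            class = "bphp_structure")
}

#' @export
print.bphp_structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("<bphp_structure> %s: %d atoms, %d chain(s) [%s], %d het atoms\n",
              x$identifier, nrow(at), length(unique(at$chain)),
              paste(unique(at$chain), collapse = ","), sum(at$het)))
  invisible(x)
}

#' Number of protein residues per chain
#' @param structure a `bphp_structure`.
#' @return Named integer vector, one entry per chain.
#' @export
chain_lengths <- function(structure) {
  at <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  vapply(split(at, at$chain),
         function(d) length(unique(paste(d$resno, d$ins))), integer(1))
}

## altloc resolution: keep the highest-occupancy conformer per
## (chain, resno, ins, elety); ties go to the first altloc label.
resolve_altloc <- function(atoms, alt) {
  alt[is.na(alt) | alt == ""] <- " "
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$resid, atoms$elety)
  keep <- unlist(lapply(split(seq_along(key), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$o[idx]
    best <- idx[occ == max(occ)]
    best[order(alt[best])][1L]
  }), use.names = FALSE)
  sort(keep)
}

#' Read a structure from a PDB or mmCIF file
#'
#' Parsing of both dialects is delegated to bio3d; the atom records are then
#' normalized into the package's atom table. Alternate locations are resolved
#' to the highest-occupancy conformer (ties broken by altloc label), and only
#' the first model of a multi-model file is kept.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension, default PDB).
#' @param identifier optional label; defaults to the file base name.
#' @return A [bphp_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") suppressWarnings(
      bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("zero atoms parsed from ", path)
  ins <- a$insert
  ins[is.na(ins)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  b <- a$b
  b[is.na(b)] <- 0
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    ins = as.character(ins), resid = as.character(a$resid),
    elety = as.character(a$elety),
    x = a$x, y = a$y, z = a$z, b = b, o = occ,
    het = a$type == "HETATM", stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- atoms[resolve_altloc(atoms, a$alt), , drop = FALSE]
  if (is.null(identifier))
    identifier <- sub("\\.[^.]*$", "", basename(path))
  bphp_structure(atoms, identifier = identifier)
}

#' Extract a C-alpha trace
#'
#' One point per residue that carries a CA atom (waters/hydrogens never have
#' one and are thereby excluded). Residues lacking a CA atom are skipped and
#' counted in the `n_skipped` attribute. Chain breaks (consecutive CA-CA
#' distance above 4.5 Angstrom) are recorded in the `breaks` attribute but do
#' not fail the extraction.
#'
#' @param structure a `bphp_structure`.
#' @param chain chain identifier.
#' @param domains optional [domain_scheme()].
#' @param domain optional domain name within `domains`; restricts the trace to
#'   that residue range.
#' @return An object of class `calpha_trace` with fields `resno`, `codes`
#'   (1-letter residue codes), `xyz` (n x 3 matrix) and `source`.
#' @export
extract_trace <- function(structure, chain, domains = NULL, domain = NULL) {
  at <- structure$atoms
  if (!chain %in% at$chain)
    stop("unknown chain '", chain, "' in ", structure$identifier)
  at <- at[at$chain == chain & !at$het, , drop = FALSE]
  if (!is.null(domain)) {
    if (is.null(domains))
      stop("domain name given without a domain scheme")
    rng <- domains$domains[[domain]]
    if (is.null(rng))
      stop("unknown domain '", domain, "' in scheme")
    at <- at[at$resno >= rng[1] & at$resno <= rng[2], , drop = FALSE]
  }
  n_res <- length(unique(paste(at$resno, at$ins)))
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno, ca$ins), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  tr <- structure(
    list(resno = ca$resno, codes = aa3to1(ca$resid), xyz = xyz,
         source = c(structure$identifier, chain)),
    class = "calpha_trace")
  if (nrow(xyz) > 1L) {
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-nrow(xyz), , drop = FALSE])^2))
    attr(tr, "breaks") <- which(d > 4.5)
  } else attr(tr, "breaks") <- integer(0)
  attr(tr, "n_skipped") <- n_res - nrow(ca)
  tr
}

#' @export
print.calpha_trace <- function(x, ...) {
  cat(sprintf("<calpha_trace> %s chain %s: %d residues (%d without CA, %d breaks)\n",
              x$source[1], x$source[2], length(x$resno),
              attr(x, "n_skipped"), length(attr(x, "breaks"))))
  invisible(x)
}

trace_sequence <- function(trace) paste(trace$codes, collapse = "")

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector, Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("rigid transform needs a 3x3 rotation and a length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Compose two rigid transforms (first `a`, then `b`)
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` equal to applying `a` then `b`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$R), as.numeric(-t(transform$R) %*% transform$t))
}

apply_xyz <- function(xyz, transform) {
  sweep(xyz %*% t(transform$R), 2, transform$t, "+")
}

#' Apply a rigid transform to a structure or trace
#'
#' Every position p becomes R p + t. Applies to a whole `bphp_structure` or a
#' `calpha_trace`; the return type matches the input.
#'
#' @param x a `bphp_structure` or `calpha_trace`.
#' @param transform a [rigid_transform()].
#' @return The transformed object, same class as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform$R, transform$t)
  if (inherits(x, "bphp_structure")) {
    xyz <- apply_xyz(as.matrix(x$atoms[, c("x", "y", "z")]), transform)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    x
  } else if (inherits(x, "calpha_trace")) {
    x$xyz <- apply_xyz(x$xyz, transform)
    x
  } else stop("apply_transform expects a bphp_structure or calpha_trace")
}

#' Domain scheme: named residue ranges
#'
#' Residue ranges are 1-based inclusive in author numbering. Defaults follow
#' the SaBphP1 photosensory core module: PAS-GAF core up to the GAF-to-PHY
#' helix kink near residue 325, PHY 326-516, sensory tongue 435-485.
#'
#' @param domains named list of length-2 integer ranges; must contain disjoint
#'   ranges within a subunit and a `PHY` range disjoint from `PAS`/`GAF`.
#' @param interface_helices named list of length-2 ranges for the dimer
#'   interface helices used for the offset-angle bundle axes (per subunit; the
#'   same author-numbered ranges are applied to both chains).
#' @return An object of class `domain_scheme`.
#' @export
domain_scheme <- function(
    domains = list(PAS = c(1L, 115L), GAF = c(116L, 325L),
                   PHY = c(326L, 516L), tongue = c(435L, 485L)),
    interface_helices = list(h3 = c(250L, 269L), h6 = c(280L, 299L))) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop("bad residue range for ", nm)
    as.integer(r)
  }
  domains <- mapply(chk, domains, names(domains), SIMPLIFY = FALSE)
  interface_helices <- mapply(chk, interface_helices,
                              names(interface_helices), SIMPLIFY = FALSE)
  core <- c("PAS", "GAF")
  have <- intersect(core, names(domains))
  if ("PHY" %in% names(domains) && length(have)) {
    phy <- domains$PHY
    for (nm in have) {
      r <- domains[[nm]]
      if (phy[1] <= r[2] && r[1] <= phy[2])
        stop("PHY range overlaps ", nm)
    }
  }
  structure(list(domains = domains, interface_helices = interface_helices),
            class = "domain_scheme")
}

#' Read a pipeline configuration file
#'
#' YAML key-value tree carrying the domain scheme, interface-helix ranges and
#' (optionally) a crystallographic symmetry operator given as 12 numbers
#' (row-major 3x3 rotation followed by the translation) used to build a
#' two-subunit assembly from a monomeric asymmetric unit.
#'
#' @param path YAML file path.
#' @return List with elements `scheme` (a [domain_scheme()]), `symmetry`
#'   (a [rigid_transform()] or `NULL`) and the remaining raw entries.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$domains))
    args$domains <- lapply(cfg$domains, as.integer)
  if (!is.null(cfg$interface_helices))
    args$interface_helices <- lapply(cfg$interface_helices, as.integer)
  scheme <- do.call(domain_scheme, args)
  symmetry <- NULL
  if (!is.null(cfg$symmetry)) {
    v <- as.numeric(cfg$symmetry)
    if (length(v) != 12L)
      stop("symmetry operator must be 12 numbers (row-major R, then t)")
    symmetry <- rigid_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
  }
  c(list(scheme = scheme, symmetry = symmetry),
    cfg[setdiff(names(cfg), c("domains", "interface_helices", "symmetry"))])
}

#' Distance between two named atoms
#'
#' Selectors address any atom, including ligand (HETATM) atoms such as the
#' biliverdin chromophore, by `(chain, residue number or het residue name,
#' atom name)`. Unlike the trace-based geometry, this sees all atoms.
#'
#' @param structure a `bphp_structure`.
#' @param sel_a,sel_b list or vector `(chain, residue, atom)`; `residue` is an
#'   author residue number, or a 3-letter residue name for het groups.
#' @return Euclidean distance in Angstrom.
#' @export
atom_pair_distance <- function(structure, sel_a, sel_b) {
  pick <- function(sel) {
    sel <- as.list(sel)
    at <- structure$atoms
    m <- at$chain == as.character(sel[[1]]) &
      at$elety == as.character(sel[[3]])
    res <- sel[[2]]
    m <- m & if (suppressWarnings(!is.na(as.numeric(res))))
      at$resno == as.integer(res) else at$resid == as.character(res)
    hit <- which(m)
    if (length(hit) == 0L) {
      near <- unique(at$elety[at$chain == as.character(sel[[1]]) &
                                (at$resno == suppressWarnings(as.integer(res)) |
                                   at$resid == as.character(res))])
      stop("atom selector (", paste(unlist(sel), collapse = ", "),
           ") not found; atoms present in that residue: ",
           paste(utils::head(near, 12), collapse = " "))
    }
    as.numeric(at[hit[1L], c("x", "y", "z")])
  }
  sqrt(sum((pick(sel_a) - pick(sel_b))^2))
}

#' Write a structure as a minimal PDB file
#'
#' Fixture writer (fixed-column ATOM/HETATM records via bio3d).
#'
#' @param structure a `bphp_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$ins == "", "", at$ins),
    elety = at$elety, o = at$o, b = at$b)
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' Fixture writer emitting a single `atom_site` loop; coordinates are printed
#' with three decimals to match the PDB fixture precision.
#'
#' @inheritParams write_structure_pdb
#' @return Invisibly, `path`.
#' @export
write_structure_cif <- function(structure, path) {
  at <- structure$atoms
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$identifier)),
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
             "auth_seq_id", "auth_comp_id", "auth_asym_id",
             "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)),
            substr(gsub("[0-9]", "", at$elety), 1, 1), at$elety, at$resid,
            at$chain, at$resno, ifelse(at$ins == "", "?", at$ins),
            at$x, at$y, at$z, at$o, at$b, at$resno, at$resid, at$chain,
            at$elety))
  writeLines(lines, path)
  invisible(path)
}
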