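#' Synthetic structures and spectra with known ground truth
#'
#' @description
#' Stand-ins for deposited crystal structures and measured spectra: two-chain
#' multi-domain C-alpha models whose interface offset angle, PHY centroid
#' separation, opening angle and PHY rotation/translation are set by
#' construction (plus optional Gaussian coordinate noise), and absorption
#' spectra built as Gaussian band mixtures on a 240-800 nm grid. Domains are
#' rigid point clouds (ideal helices plus filler lattices), not folded
#' proteins: the descriptors under study depend only on C-alpha geometry.
#'
#' @name synthetic-data
#' @keywords internal
NULL

.amino20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.amino321 <- stats::setNames(names(.amino1)[1:20], unname(.amino1[1:20]))

#' Ideal alpha-helix C-alpha trace
#'
#' Deterministic spiral along +z: residue k sits at
#' `(radius cos(k twist), radius sin(k twist), k rise)`. With the defaults the
#' consecutive C-alpha distance is the canonical ~3.8 Angstrom.
#'
#' @param n number of residues (>= 4).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @return A `calpha_trace` (poly-alanine codes, residues 1..n).
#' @export
make_ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  if (n < 4L) stop("ideal helix needs at least 4 residues")
  k <- seq_len(n) - 1
  th <- k * twist * pi / 180
  structure(list(resno = seq_len(n), codes = rep("A", n),
                 xyz = cbind(radius * cos(th), radius * sin(th), k * rise),
                 source = c("ideal_helix", "A")),
            class = "calpha_trace")
}

helix_block <- function(range, offset, rise = 1.5, twist = 100,
                        radius = 2.3) {
  n <- range[2] - range[1] + 1L
  h <- make_ideal_helix(n, rise, twist, radius)$xyz
  sweep(h, 2, c(offset[1], offset[2], offset[3] - (n - 1) * rise / 2), "+")
}

lattice_block <- function(n, origin, spacing = 4, nx = 8L, ny = 8L) {
  k <- seq_len(n) - 1L
  cbind(origin[1] + spacing * (k %% nx),
        origin[2] + spacing * ((k %/% nx) %% ny),
        origin[3] + spacing * (k %/% (nx * ny)))
}

#' Specification of a synthetic photosensory-module dimer
#'
#' Defaults emulate the wild-type photosensory core module: 516 residues per
#' subunit (core 1-325, PHY 326-516), interface offset angle 46 degrees, PHY
#' centroid separation 30 Angstrom and opening angle 54 degrees.
#'
#' @param n_core core (PAS-GAF) residues per subunit.
#' @param n_phy PHY residues per subunit.
#' @param helix3,helix6 interface-helix residue ranges within the core.
#' @param phi requested interface offset angle, degrees (0 < phi <= 135).
#' @param d_centroids requested PHY centroid separation, Angstrom.
#' @param omega requested opening angle, degrees (0 < omega <= 180).
#' @param phy_rotation,phy_translation PHY perturbation applied to both
#'   subunits in the same direction: rotation (degrees) about an axis through
#'   the interface vertex, then a shift (Angstrom) along +x.
#' @param noise_sigma isotropic Gaussian coordinate noise s.d., Angstrom.
#' @param domain_noise_sigma s.d. of an optional rigid per-domain random
#'   displacement (lattice-heterogeneity style correlated noise), Angstrom.
#' @param mutate_fraction fraction of subunit-B-sequence positions substituted
#'   by a random residue ("homolog" mode exercising the alignment; 0 keeps the
#'   two sequences identical).
#' @param seed RNG seed for the sequence and mutations.
#' @param noise_seed RNG seed for the coordinate noise (defaults to `seed`);
#'   two generated "crystals" of the same molecule share `seed` but differ in
#'   `noise_seed`.
#' @return List of class `dimer_spec`.
#' @export
dimer_spec <- function(n_core = 325L, n_phy = 191L,
                       helix3 = c(250L, 269L), helix6 = c(280L, 299L),
                       phi = 46, d_centroids = 30, omega = 54,
                       phy_rotation = 0, phy_translation = 0,
                       noise_sigma = 0, domain_noise_sigma = 0,
                       mutate_fraction = 0, seed = 1L, noise_seed = NULL) {
  if (!(phi > 0 && phi <= 135)) stop("phi must be in (0, 135] degrees")
  if (!(omega > 0 && omega <= 180)) stop("omega must be in (0, 180] degrees")
  if (d_centroids <= 0) stop("d_centroids must be positive")
  if (noise_sigma < 0 || domain_noise_sigma < 0) stop("negative noise sigma")
  if (helix3[2] > n_core || helix6[2] > n_core ||
      helix3[2] >= helix6[1])
    stop("interface helix ranges must be ordered and lie within the core")
  if (is.null(noise_seed)) noise_seed <- seed
  structure(as.list(environment()), class = "dimer_spec")
}

random_sequence <- function(n) paste(sample(.amino20, n, TRUE), collapse = "")

#' Generate a synthetic two-chain dimer with known geometry
#'
#' Builds one subunit from two ideal interface helices plus core and PHY
#' point clouds, places a two-fold-rotated copy as the second subunit so that
#' the measured interface offset angle equals `phi` exactly at zero noise,
#' positions the PHY centroids so that the centroid separation and opening
#' angle at the interface vertex equal `d_centroids` and `omega` exactly,
#' applies the requested PHY perturbation, and finally adds noise.
#'
#' @param spec a [dimer_spec()].
#' @return List with `structure` (a two-chain [bphp_structure()]), `scheme`
#'   (the matching [domain_scheme()]) and `truth` (realized ground truth:
#'   `phi`, `d_centroids`, `omega`, `phy_rotation`, `phy_translation` --- the
#'   realized PHY centroid shift --- and the generating parameters).
#' @export
make_synthetic_dimer <- function(spec) {
  stopifnot(inherits(spec, "dimer_spec"))
  set.seed(spec$seed)
  n_res <- spec$n_core + spec$n_phy
  phy_range <- c(spec$n_core + 1L, n_res)
  scheme <- domain_scheme(
    domains = list(PAS = c(1L, min(115L, spec$helix3[1] - 1L)),
                   GAF = c(min(116L, spec$helix3[1]), spec$n_core),
                   PHY = phy_range),
    interface_helices = list(h3 = spec$helix3, h6 = spec$helix6))
  seq1 <- strsplit(random_sequence(n_res), "")[[1]]
  seq2 <- seq1
  if (spec$mutate_fraction > 0) {
    k <- max(0L, round(spec$mutate_fraction * n_res))
    pos <- sample(n_res, k)
    seq2[pos] <- sample(.amino20, k, TRUE)
  }

  ## canonical subunit: helices along +z, filler lattices
  core_xyz <- matrix(NA_real_, spec$n_core, 3)
  h3_idx <- spec$helix3[1]:spec$helix3[2]
  h6_idx <- spec$helix6[1]:spec$helix6[2]
  core_xyz[h3_idx, ] <- helix_block(spec$helix3, c(6, 0, 0))
  core_xyz[h6_idx, ] <- helix_block(spec$helix6, c(-6, 4, 0))
  filler <- setdiff(seq_len(spec$n_core), c(h3_idx, h6_idx))
  core_xyz[filler, ] <- lattice_block(length(filler), c(-26, -30, -34))
  phy_blob <- lattice_block(spec$n_phy, c(0, 0, 0))
  phy_blob <- sweep(phy_blob, 2, colMeans(phy_blob))

  ## placement: bundle axes +/- phi/2 from z in the xz-plane; subunit B is
  ## the two-fold (about z) image of subunit A
  R_A <- rotation_about_axis(c(0, 1, 0), spec$phi / 2)
  t_A <- c(-12, 0, 0)
  C2 <- diag(c(-1, -1, 1))
  place_A <- function(p) sweep(p %*% t(R_A), 2, t_A, "+")
  core_A <- place_A(core_xyz)
  core_B <- core_A %*% t(C2)

  a3 <- core_A[spec$helix3[2], ]
  b6 <- core_B[spec$helix6[2], ]
  v <- (a3 + b6) / 2
  half <- spec$omega / 2 * pi / 180
  L <- spec$d_centroids / (2 * sin(half))
  w_A <- c(sin(half), 0, cos(half))
  w_B <- c(-sin(half), 0, cos(half))
  cen_A <- v + L * w_A
  cen_B <- v + L * w_B
  phy_A <- sweep(phy_blob %*% t(R_A), 2, cen_A, "+")
  phy_B <- sweep(phy_blob %*% t(C2 %*% R_A), 2, cen_B, "+")

  chain_atoms <- function(chain, core, phy, seq) {
    xyz <- rbind(core, phy)
    data.frame(chain = chain, resno = seq_len(n_res), ins = "",
               resid = unname(.amino321[seq]), elety = "CA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b = 30, o = 1, het = FALSE)
  }
  st <- bphp_structure(rbind(chain_atoms("A", core_A, phy_A, seq1),
                             chain_atoms("B", core_B, phy_B, seq2)),
                       identifier = sprintf("synthetic_dimer_seed%d",
                                            spec$seed))

  ## PHY perturbation: rotation about a y-axis through the vertex, then a
  ## common shift along +x (both subunits, same direction)
  shift <- c(spec$phy_translation, 0, 0)
  realized <- list(A = cen_A, B = cen_B)
  if (spec$phy_rotation != 0 || spec$phy_translation != 0) {
    st <- perturb_domain(st, "PHY", scheme, rotation = spec$phy_rotation,
                         axis_point = v, axis_dir = c(0, 1, 0),
                         translation = shift)
    Rp <- rotation_about_axis(c(0, 1, 0), spec$phy_rotation)
    realized <- lapply(realized,
                       function(cen) as.numeric(Rp %*% (cen - v)) + v + shift)
  }
  truth <- list(
    phi = spec$phi, antiparallel = FALSE,
    d_centroids = sqrt(sum((realized$A - realized$B)^2)),
    omega = {
      u1 <- realized$A - v; u2 <- realized$B - v
      acos(min(1, max(-1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))) *
        180 / pi
    },
    phy_rotation = spec$phy_rotation,
    phy_translation = sqrt(sum((realized$A - cen_A)^2)),
    seed = spec$seed, noise_sigma = spec$noise_sigma)

  set.seed(spec$noise_seed)
  if (spec$domain_noise_sigma > 0) {
    for (ch in c("A", "B")) for (dm in c("PAS", "GAF", "PHY")) {
      r <- scheme$domains[[dm]]
      idx <- st$atoms$chain == ch & st$atoms$resno >= r[1] &
        st$atoms$resno <= r[2]
      d <- stats::rnorm(3, 0, spec$domain_noise_sigma)
      st$atoms[idx, c("x", "y", "z")] <-
        sweep(as.matrix(st$atoms[idx, c("x", "y", "z")]), 2, d, "+")
    }
  }
  if (spec$noise_sigma > 0) {
    n_at <- nrow(st$atoms)
    st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * n_at, 0, spec$noise_sigma), n_at, 3)
  }
  list(structure = st, scheme = scheme, truth = truth)
}

#' Rigidly perturb one domain of a structure
#'
#' Applies `p -> R (p - axis_point) + axis_point + translation` (R the
#' rotation by `rotation` degrees about `axis_dir`) to the atoms of the named
#' domain only; all other atoms are bitwise unchanged.
#'
#' @param model a `bphp_structure`.
#' @param domain domain name in `scheme`.
#' @param scheme a [domain_scheme()].
#' @param rotation rotation angle, degrees.
#' @param axis_point point on the rotation axis (length 3).
#' @param axis_dir rotation axis direction (length 3).
#' @param translation translation vector, Angstrom (length 3).
#' @param chains chains to perturb (default: all).
#' @return The perturbed `bphp_structure`.
#' @export
perturb_domain <- function(model, domain, scheme, rotation = 0,
                           axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                           translation = c(0, 0, 0), chains = NULL) {
  r <- scheme$domains[[domain]]
  if (is.null(r)) stop("unknown domain '", domain, "'")
  if (is.null(chains)) chains <- unique(model$atoms$chain)
  idx <- model$atoms$chain %in% chains & model$atoms$resno >= r[1] &
    model$atoms$resno <= r[2] & !model$atoms$het
  if (rotation == 0 && all(translation == 0)) return(model)
  R <- rotation_about_axis(axis_dir, rotation)
  p <- as.matrix(model$atoms[idx, c("x", "y", "z")])
  p <- sweep(sweep(p, 2, axis_point) %*% t(R), 2,
             axis_point + translation, "+")
  model$atoms[idx, c("x", "y", "z")] <- p
  model
}

#' Specification of a synthetic absorption spectrum
#'
#' @param bands data.frame with columns `center` (nm), `width` (Gaussian
#'   s.d., nm) and `amplitude` (AU); defaults to a Pr-like band at 700 nm and
#'   a Pfr-like band at 750 nm.
#' @param noise_sigma additive Gaussian noise s.d., AU.
#' @param grid `(start, stop, step)` in nm (default 240-800 nm, 0.5 nm step,
#'   the instrument grid from which half-nanometre maxima arise).
#' @param seed RNG seed for the noise.
#' @return List of class `band_spec`.
#' @export
band_spec <- function(bands = data.frame(center = c(700, 750),
                                         width = c(20, 20),
                                         amplitude = c(1, 0)),
                      noise_sigma = 0, grid = c(240, 800, 0.5), seed = 1L) {
  if (any(bands$width <= 0)) stop("band widths must be positive")
  if (any(bands$center < grid[1] | bands$center > grid[2]))
    stop("band centers must lie within the grid")
  if (noise_sigma < 0) stop("negative noise sigma")
  structure(list(bands = bands, noise_sigma = noise_sigma, grid = grid,
                 seed = as.integer(seed)), class = "band_spec")
}

#' Generate a synthetic spectrum from a band specification
#'
#' Sum of Gaussian bands plus seeded Gaussian noise on the requested grid.
#'
#' @param spec a [band_spec()].
#' @param label label for the spectrum.
#' @return A [uvvis_spectrum()].
#' @export
make_synthetic_spectrum <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "band_spec"))
  w <- seq(spec$grid[1], spec$grid[2], by = spec$grid[3])
  a <- rep(0, length(w))
  for (i in seq_len(nrow(spec$bands)))
    a <- a + spec$bands$amplitude[i] *
      exp(-(w - spec$bands$center[i])^2 / (2 * spec$bands$width[i]^2))
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    a <- a + stats::rnorm(length(w), 0, spec$noise_sigma)
  }
  uvvis_spectrum(w, a, label = label)
}

#' Write a ground-truth sidecar file
#'
#' Key-value YAML consumed by the test suite alongside generated fixtures.
#'
#' @param truth named list (e.g. the `truth` element of
#'   [make_synthetic_dimer()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}
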