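#' Dimer-interface and domain-motion descriptors
#'
#' @description
#' The descriptors that summarize a photosensory-module dimer and its
#' conformational differences from a reference structure: the interface offset
#' angle phi between the two subunits' interface helix-bundle axes, the
#' distance between the PHY-domain C-alpha centroids and the opening angle
#' Omega they subtend at a vertex between the interface-helix ends, and the
#' residual PHY rotation/translation after aligning the PAS-GAF cores.
#'
#' @name dimer-geometry
#' @keywords internal
NULL

subset_trace <- function(trace, ranges) {
  if (!is.list(ranges)) ranges <- list(ranges)
  keep <- rep(FALSE, length(trace$resno))
  for (r in ranges) keep <- keep | (trace$resno >= r[1] & trace$resno <= r[2])
  out <- trace
  out$resno <- trace$resno[keep]
  out$codes <- trace$codes[keep]
  out$xyz <- trace$xyz[keep, , drop = FALSE]
  attr(out, "breaks") <- integer(0)
  attr(out, "n_skipped") <- 0L
  out
}

trace_centroid <- function(trace) colMeans(trace$xyz)

#' Fit a helix axis
#'
#' The direction is the screw axis of the least-squares rigid superposition
#' of the helix C-alpha trace onto its one-residue shift: exact for an ideal
#' helix (where that superposition is the helical symmetry operation) and
#' least-squares robust under coordinate noise. The direction is sign-aligned
#' N to C; the anchor is the C-alpha centroid.
#'
#' @param trace a `calpha_trace`.
#' @param range optional length-2 residue range restricting the fit.
#' @return An object of class `helix_axis`: `direction` (unit 3-vector,
#'   N->C), `anchor` (centroid, Angstrom), `range`, `fit_rms` (perpendicular
#'   scatter of the points about the axis line, Angstrom).
#' @export
fit_helix_axis <- function(trace, range = NULL) {
  tr <- if (is.null(range)) trace else subset_trace(trace, list(range))
  p <- tr$xyz
  n <- nrow(p)
  if (n < 6L) stop("helix axis fit needs at least 6 residues, got ", n)
  fit <- kabsch_fit(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  dir <- rotation_axis(fit$transform)
  span <- p[n, ] - p[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  anchor <- colMeans(p)
  rel <- sweep(p, 2, anchor)
  perp <- rel - outer(as.numeric(rel %*% dir), dir)
  radial <- sqrt(rowSums(perp^2))
  structure(list(direction = dir, anchor = anchor,
                 range = if (is.null(range)) base::range(tr$resno) else range,
                 fit_rms = stats::sd(radial)),
            class = "helix_axis")
}

bundle_axis <- function(axes) {
  d <- (axes[[1]]$direction + axes[[2]]$direction) / 2
  nd <- sqrt(sum(d^2))
  if (nd < 1e-8)
    stop("degenerate bundle: helix pair is anti-aligned within a subunit")
  d / nd
}

#' Interface offset angle between two subunits' helix bundles
#'
#' Per subunit the bundle axis is the normalized mean of its two interface
#' helix directions (each N->C oriented); phi is the angle between the two
#' bundle axes. When that angle exceeds 135 degrees the subunits are flagged
#' antiparallel (reported as AP) and phi is folded to `180 - angle`.
#'
#' @param axes_a,axes_b lists of two [fit_helix_axis()] results, one list per
#'   subunit.
#' @return List with `phi` (degrees) and `antiparallel` (logical).
#' @export
interface_offset_angle <- function(axes_a, axes_b) {
  da <- bundle_axis(axes_a)
  db <- bundle_axis(axes_b)
  ang <- acos(min(1, max(-1, sum(da * db)))) * 180 / pi
  if (ang > 135) list(phi = 180 - ang, antiparallel = TRUE)
  else list(phi = ang, antiparallel = FALSE)
}

#' PHY centroid separation and opening angle
#'
#' Centroids are the C-alpha centroids of the PHY range in each subunit. The
#' vertex V is the midpoint between the C-terminal C-alpha of the first
#' interface helix (helix-3 role) of subunit A and of the second interface
#' helix (helix-6 role) of subunit B; Omega is the angle centroid_A - V -
#' centroid_B and d_centroids the distance between the centroids.
#'
#' @param trace_a,trace_b full-chain `calpha_trace` objects of the two
#'   subunits.
#' @param scheme a [domain_scheme()] supplying the `PHY` range and the two
#'   interface-helix ranges.
#' @return List with `d_centroids` (Angstrom), `omega` (degrees), `vertex`
#'   and the two centroids.
#' @export
phy_centroid_metrics <- function(trace_a, trace_b, scheme) {
  phy <- scheme$domains$PHY
  if (is.null(phy)) stop("scheme has no PHY range")
  pa <- subset_trace(trace_a, list(phy))
  pb <- subset_trace(trace_b, list(phy))
  if (length(pa$resno) == 0L || length(pb$resno) == 0L)
    stop("PHY residues missing in one or both subunits")
  ca <- trace_centroid(pa)
  cb <- trace_centroid(pb)
  hel <- scheme$interface_helices
  if (length(hel) < 2L) stop("need two interface-helix ranges")
  cterm <- function(trace, r) {
    s <- subset_trace(trace, list(r))
    if (length(s$resno) == 0L)
      stop("interface helix range ", r[1], "-", r[2], " missing from chain")
    s$xyz[which.max(s$resno), ]
  }
  v <- (cterm(trace_a, hel[[1]]) + cterm(trace_b, hel[[2]])) / 2
  u1 <- ca - v; u2 <- cb - v
  omega <- acos(min(1, max(-1, sum(u1 * u2) /
                             sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
  list(d_centroids = sqrt(sum((ca - cb)^2)), omega = omega,
       vertex = v, centroid_a = ca, centroid_b = cb)
}

#' Residual domain rotation after core alignment
#'
#' Pairs and iteratively fits the core (default PAS+GAF) C-alpha positions of
#' one chain of the mobile structure onto the corresponding reference chain
#' (outliers beyond `cutoff` rejected), applies that transform to the whole
#' mobile chain, then fits the moving-domain (default PHY) pairs. The
#' reported rotation is the rotation angle of the second-stage transform; the
#' translation is the moving-domain centroid shift remaining after core
#' alignment (over paired residues).
#'
#' @param reference,mobile `bphp_structure` objects.
#' @param scheme a [domain_scheme()].
#' @param core character vector of domain names forming the alignment core.
#' @param moving name of the moving domain.
#' @param chain_ref,chain_mob chain identifiers (default: first chain).
#' @param cutoff outlier rejection cutoff in Angstrom.
#' @param params an [align_params()].
#' @return List of class `domain_motion`: `rotation` (degrees), `translation`
#'   (Angstrom), `axis` (unit vector), plus the two stage fits (`core_fit`,
#'   `moving_fit`) and pair counts.
#' @export
domain_rotation <- function(reference, mobile, scheme,
                            core = c("PAS", "GAF"), moving = "PHY",
                            chain_ref = NULL, chain_mob = NULL,
                            cutoff = 5, params = align_params()) {
  if (is.null(chain_ref)) chain_ref <- reference$atoms$chain[1]
  if (is.null(chain_mob)) chain_mob <- mobile$atoms$chain[1]
  tr_ref <- extract_trace(reference, chain_ref)
  tr_mob <- extract_trace(mobile, chain_mob)
  core_ranges <- scheme$domains[intersect(core, names(scheme$domains))]
  if (length(core_ranges) == 0L) stop("no core domain ranges in scheme")
  mov_range <- scheme$domains[[moving]]
  if (is.null(mov_range)) stop("unknown moving domain '", moving, "'")

  core_ref <- subset_trace(tr_ref, core_ranges)
  core_mob <- subset_trace(tr_mob, core_ranges)
  pairing <- smith_waterman_pair(core_mob, core_ref, params)
  if (nrow(pairing$pairs) < 3L)
    stop("degenerate fit in core stage: fewer than 3 pairs")
  core_fit <- iterative_fit(pairing, core_mob, core_ref, cutoff = cutoff)
  if (length(core_fit$retained) < 50L)
    warning("core alignment retains only ", length(core_fit$retained),
            " pairs")

  tr_mob_aln <- apply_transform(tr_mob, core_fit$transform)
  mov_ref <- subset_trace(tr_ref, list(mov_range))
  mov_mob <- subset_trace(tr_mob_aln, list(mov_range))
  mp <- smith_waterman_pair(mov_mob, mov_ref, params)
  if (nrow(mp$pairs) < 3L)
    stop("degenerate fit in moving-domain stage: fewer than 3 pairs")
  mov_fit <- iterative_fit(mp, mov_mob, mov_ref, cutoff = cutoff)
  ca_mob <- colMeans(mov_mob$xyz[mp$pairs[, 1], , drop = FALSE])
  ca_ref <- colMeans(mov_ref$xyz[mp$pairs[, 2], , drop = FALSE])
  structure(list(
    rotation = rotation_angle(mov_fit$transform),
    translation = sqrt(sum((ca_mob - ca_ref)^2)),
    axis = rotation_axis(mov_fit$transform),
    core_fit = core_fit, moving_fit = mov_fit,
    n_core_pairs = length(core_fit$retained),
    n_moving_pairs = nrow(mp$pairs)), class = "domain_motion")
}

#' @export
print.domain_motion <- function(x, ...) {
  cat(sprintf(paste0("<domain_motion> rotation %.2f deg, translation %.2f A ",
                     "(core: %d pairs, rmsd %.3f A)\n"),
              x$rotation, x$translation, x$n_core_pairs, x$core_fit$rmsd))
  invisible(x)
}

dimer_chains <- function(structure) {
  ch <- unique(structure$atoms$chain[!structure$atoms$het])
  if (length(ch) < 2L)
    stop(structure$identifier, " has fewer than 2 protein chains")
  ch[1:2]
}

dimer_descriptors <- function(structure, scheme) {
  ch <- dimer_chains(structure)
  ta <- extract_trace(structure, ch[1])
  tb <- extract_trace(structure, ch[2])
  hel <- scheme$interface_helices
  axes_a <- lapply(hel, function(r) fit_helix_axis(ta, r))
  axes_b <- lapply(hel, function(r) fit_helix_axis(tb, r))
  offs <- interface_offset_angle(axes_a, axes_b)
  cm <- phy_centroid_metrics(ta, tb, scheme)
  list(phi = offs$phi, antiparallel = offs$antiparallel,
       d_centroids = cm$d_centroids, omega = cm$omega)
}

## subunit correspondence: the chain assignment (identity or swapped) with
## the lower first-chain core r.m.s.d. wins
match_subunits <- function(reference, mobile, scheme, cutoff, params) {
  ref_ch <- dimer_chains(reference)
  mob_ch <- dimer_chains(mobile)
  score <- function(mc) {
    tryCatch(domain_rotation(reference, mobile, scheme,
                             chain_ref = ref_ch[1], chain_mob = mc,
                             cutoff = cutoff,
                             params = params)$core_fit$rmsd,
             error = function(e) Inf)
  }
  r1 <- score(mob_ch[1])
  r2 <- score(mob_ch[2])
  if (r2 < r1) mob_ch[2:1] else mob_ch
}

#' Geometry report over a set of structures
#'
#' One row per structure: its own dimer descriptors (phi or AP flag,
#' d_centroids, Omega) and, against the reference, the residual PHY rotation
#' of the first paired subunit and the core r.m.s.d. The reference itself
#' appears as the first row with `NA` rotation/r.m.s.d. (rendered "ref." by
#' [format_geometry_table()]). Per-row failures are recorded in `flags`;
#' remaining rows are still produced.
#'
#' @param reference a `bphp_structure` (two-chain dimer).
#' @param comparisons list of `bphp_structure` objects.
#' @param scheme a [domain_scheme()].
#' @param params an [align_params()].
#' @param cutoff outlier rejection cutoff in Angstrom (default 5).
#' @return data.frame with columns `structure`, `phi_deg`, `antiparallel`,
#'   `d_centroids_A`, `omega_deg`, `phy_rotation_deg`, `phy_translation_A`,
#'   `core_rmsd_A`, `n_pairs`, `flags`.
#' @export
geometry_table <- function(reference, comparisons, scheme,
                           params = align_params(), cutoff = 5) {
  row_for <- function(st, is_ref) {
    out <- data.frame(structure = st$identifier, phi_deg = NA_real_,
                      antiparallel = FALSE, d_centroids_A = NA_real_,
                      omega_deg = NA_real_, phy_rotation_deg = NA_real_,
                      phy_translation_A = NA_real_, core_rmsd_A = NA_real_,
                      n_pairs = NA_integer_, flags = "")
    flags <- character(0)
    desc <- tryCatch(dimer_descriptors(st, scheme), error = function(e) {
      flags <<- c(flags, conditionMessage(e)); NULL
    })
    if (!is.null(desc)) {
      out$phi_deg <- desc$phi
      out$antiparallel <- desc$antiparallel
      out$d_centroids_A <- desc$d_centroids
      out$omega_deg <- desc$omega
    }
    if (!is_ref) {
      mot <- tryCatch({
        mob_ch <- match_subunits(reference, st, scheme, cutoff, params)
        ref_ch <- dimer_chains(reference)
        first <- domain_rotation(reference, st, scheme,
                                 chain_ref = ref_ch[1], chain_mob = mob_ch[1],
                                 cutoff = cutoff, params = params)
        second <- tryCatch(
          domain_rotation(reference, st, scheme, chain_ref = ref_ch[2],
                          chain_mob = mob_ch[2], cutoff = cutoff,
                          params = params),
          error = function(e) NULL)
        if (!is.null(second))
          flags <<- c(flags, sprintf("subunit2: rotation %.1f deg",
                                     second$rotation))
        first
      }, error = function(e) {
        flags <<- c(flags, conditionMessage(e)); NULL
      })
      if (!is.null(mot)) {
        out$phy_rotation_deg <- mot$rotation
        out$phy_translation_A <- mot$translation
        out$core_rmsd_A <- mot$core_fit$rmsd
        out$n_pairs <- mot$n_core_pairs
      }
    }
    out$flags <- paste(flags, collapse = "; ")
    out
  }
  rows <- c(list(row_for(reference, TRUE)),
            lapply(comparisons, row_for, is_ref = FALSE))
  do.call(rbind, rows)
}

#' Render a geometry table for the TSV report
#'
#' Formats numeric columns, prints `AP` in the phi column for antiparallel
#' dimers and `ref.` for the reference row's rotation and r.m.s.d.
#'
#' @param tab a [geometry_table()] result.
#' @return data.frame of character columns ready for `write.table`.
#' @export
format_geometry_table <- function(tab) {
  fmt <- function(x, digits) ifelse(is.na(x), "ref.",
                                    formatC(x, format = "f", digits = digits))
  data.frame(
    structure = tab$structure,
    phi_deg = ifelse(tab$antiparallel, "AP", fmt(tab$phi_deg, 1)),
    d_centroids_A = fmt(tab$d_centroids_A, 1),
    omega_deg = fmt(tab$omega_deg, 1),
    phy_rotation_deg = fmt(tab$phy_rotation_deg, 1),
    core_rmsd_A = fmt(tab$core_rmsd_A, 2),
    n_pairs = ifelse(is.na(tab$n_pairs), "ref.", as.character(tab$n_pairs)),
    flags = tab$flags)
}
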