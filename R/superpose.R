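#' Least-squares rigid superposition with iterative outlier rejection
#'
#' @description
#' Paired C-alpha sets are superposed by the SVD-based least-squares rigid
#' fit (Kabsch) with reflection correction, optionally weighted. The r.m.s.d.
#' between homologous photosensory modules is computed after iteratively
#' discarding pairs deviating by more than a cutoff (default 5 Angstrom),
#' refitting until the rejected set stops growing.
#'
#' @name superposition
#' @keywords internal
NULL

as_xyz <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("expected an n x 3 coordinate matrix")
  storage.mode(p) <- "double"
  p
}

#' Optimal rigid superposition of paired points (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the (weighted)
#' sum of squared deviations of `R a + t` from `b`.
#'
#' @param points_a,points_b n x 3 coordinate matrices (n >= 3), paired row
#'   by row.
#' @param weights optional non-negative weights, length n.
#' @return An object of class `superposition_result`: `transform`
#'   (a [rigid_transform()] mapping a onto b), `rmsd` (Angstrom, over retained
#'   pairs), `n_input_pairs`, `retained`, `rejected` (index vectors) and
#'   `iterations`.
#' @export
kabsch_fit <- function(points_a, points_b, weights = NULL) {
  a <- as_xyz(points_a); b <- as_xyz(points_b)
  n <- nrow(a)
  if (nrow(b) != n) stop("point sets differ in length")
  if (n < 3L) stop("degenerate fit: need at least 3 pairs")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative, length n, not all zero")
  w <- weights / sum(weights)
  ca <- colSums(a * w); cb <- colSums(b * w)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- crossprod(a0 * w, b0)
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("degenerate fit: paired points are (near-)collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cb - as.numeric(R %*% ca)
  dev2 <- rowSums((sweep(a %*% t(R), 2, tvec, "+") - b)^2)
  structure(list(
    transform = rigid_transform(R, tvec),
    rmsd = sqrt(sum(w * dev2)),
    n_input_pairs = n, retained = seq_len(n), rejected = integer(0),
    iterations = 1L), class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(paste0("<superposition_result> rmsd %.3f A over %d/%d pairs ",
                     "(%d rejected, %d iteration(s)), rotation %.2f deg\n"),
              x$rmsd, length(x$retained), x$n_input_pairs,
              length(x$rejected), x$iterations,
              rotation_angle(x$transform)))
  invisible(x)
}

#' Iterative superposition with outlier rejection
#'
#' Fits the paired C-alpha positions, recomputes per-pair deviations, rejects
#' pairs deviating by more than `cutoff`, and refits, until the rejected set
#' is unchanged or `max_iter` is reached. The rejected set only ever grows;
#' the final r.m.s.d. is over retained pairs only.
#'
#' @param pairing a [smith_waterman_pair()] result (or a two-column index
#'   matrix).
#' @param trace_a,trace_b the `calpha_trace` objects the pairing indexes into
#'   (or plain n x 3 coordinate matrices).
#' @param cutoff rejection cutoff in Angstrom (default 5).
#' @param max_iter iteration cap (default 20).
#' @return A `superposition_result`; `retained`/`rejected` index the pair
#'   list.
#' @export
iterative_fit <- function(pairing, trace_a, trace_b, cutoff = 5,
                          max_iter = 20L) {
  pairs <- if (inherits(pairing, "residue_pairing")) pairing$pairs
           else as.matrix(pairing)
  xa <- if (inherits(trace_a, "calpha_trace")) trace_a$xyz else as_xyz(trace_a)
  xb <- if (inherits(trace_b, "calpha_trace")) trace_b$xyz else as_xyz(trace_b)
  a <- xa[pairs[, 1], , drop = FALSE]
  b <- xb[pairs[, 2], , drop = FALSE]
  n <- nrow(a)
  if (n < 3L) stop("degenerate fit: fewer than 3 pairs")
  rejected <- integer(0)
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    retained <- setdiff(seq_len(n), rejected)
    if (length(retained) < 3L)
      stop("degenerate fit: retained pairs dropped below 3 at iteration ",
           iter)
    fit <- kabsch_fit(a[retained, , drop = FALSE], b[retained, , drop = FALSE])
    dev <- sqrt(rowSums((apply_xyz(a, fit$transform) - b)^2))
    rejected_new <- sort(union(rejected, which(dev > cutoff)))
    if (identical(rejected_new, rejected)) {
      rejected <- rejected_new
      break
    }
    rejected <- rejected_new
  }
  retained <- setdiff(seq_len(n), rejected)
  dev2 <- rowSums((apply_xyz(a[retained, , drop = FALSE], fit$transform) -
                     b[retained, , drop = FALSE])^2)
  structure(list(
    transform = fit$transform, rmsd = sqrt(mean(dev2)),
    n_input_pairs = n, retained = retained, rejected = rejected,
    iterations = iter), class = "superposition_result")
}

#' Rotation angle of a rigid transform
#'
#' `acos((trace(R) - 1) / 2)` in degrees, clamped to `[0, 180]`; arguments up
#' to `1 + 1e-12` beyond the arccos domain are tolerated and clamped (guards
#' against rounding).
#'
#' @param transform a [rigid_transform()] (or a 3x3 rotation matrix).
#' @return Angle in degrees.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$R
       else as.matrix(transform)
  arg <- (sum(diag(R)) - 1) / 2
  if (abs(arg) > 1 + 1e-12)
    stop("rotation-angle argument outside [-1, 1]: not a rotation matrix")
  arg <- min(1, max(-1, arg))
  acos(arg) * 180 / pi
}

#' Rotation axis of a rigid transform
#'
#' Unit axis from the antisymmetric part of R (well-conditioned for angles
#' away from 0 and 180 degrees; near 0 the axis is arbitrary and the first
#' basis vector is returned).
#'
#' @inheritParams rotation_angle
#' @return Unit length-3 vector.
#' @export
rotation_axis <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$R
       else as.matrix(transform)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(1, 0, 0))
  v / nv
}

#' Rotation matrix about an axis (degrees)
#'
#' Rodrigues rotation; utility shared by the geometry and synthetic-data
#' modules.
#'
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Convert a crystallographic B factor to an r.m.s. displacement
#'
#' Isotropic conversion. The default is the three-dimensional form
#' `sqrt(3 B / (8 pi^2))`, which maps the ~100 Angstrom^2 mean PHY-domain B
#' factor of the photosensory-module structures to an r.m.s. displacement of
#' about 2 Angstrom; the one-dimensional per-axis form `sqrt(B / (8 pi^2))`
#' is also exposed.
#'
#' @param b_factor B factor in Angstrom^2 (>= 0); vectorized.
#' @param form `"3d"` (default) or `"1d"`.
#' @return data.frame with columns `b_factor` and `rms_displacement`
#'   (Angstrom).
#' @export
rms_displacement_from_b <- function(b_factor, form = c("3d", "1d")) {
  form <- match.arg(form)
  if (any(b_factor < 0)) stop("negative B factor")
  k <- if (form == "3d") 3 else 1
  data.frame(b_factor = b_factor,
             rms_displacement = sqrt(k * b_factor / (8 * pi^2)))
}
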