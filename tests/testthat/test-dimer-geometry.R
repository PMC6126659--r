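small_spec <- function(...) {
  dimer_spec(n_core = 60L, n_phy = 30L, helix3 = c(15L, 26L),
             helix6 = c(35L, 46L), ...)
}

test_that("helix axes are exact for ideal helices and rotate covariantly", {
  h <- make_ideal_helix(12)
  ax <- fit_helix_axis(h)
  expect_lt(sqrt(sum((ax$direction - c(0, 0, 1))^2)), 1e-6)
  expect_equal(ax$anchor, colMeans(h$xyz))

  set.seed(21)
  for (i in 1:10) {
    R <- random_rotation()
    hr <- h
    hr$xyz <- h$xyz %*% t(R)
    axr <- fit_helix_axis(hr)
    expect_lt(sqrt(sum((axr$direction - as.numeric(R %*% c(0, 0, 1)))^2)),
              1e-6)
  }
  expect_error(fit_helix_axis(make_ideal_helix(5)), "at least 6")
})

test_that("helix axis direction flips sign under N-to-C reversal", {
  h <- make_ideal_helix(15)
  rev_h <- h
  rev_h$xyz <- h$xyz[15:1, ]
  a1 <- fit_helix_axis(h)$direction
  a2 <- fit_helix_axis(rev_h)$direction
  expect_equal(a1, -a2, tolerance = 1e-9)
})

test_that("noisy helix axes stay within 3 degrees of truth", {
  set.seed(22)
  h <- make_ideal_helix(12)
  hits <- 0L
  for (i in 1:100) {
    noisy <- h
    noisy$xyz <- h$xyz + matrix(rnorm(36, sd = 0.3), 12, 3)
    d <- fit_helix_axis(noisy)$direction
    ang <- acos(min(1, abs(d[3]))) * 180 / pi
    if (ang < 3) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("interface offset angle reproduces constructed bundle angles", {
  rot_z_to <- function(dir) {
    z <- c(0, 0, 1)
    ax <- c(z[2] * dir[3] - z[3] * dir[2],
            z[3] * dir[1] - z[1] * dir[3],
            z[1] * dir[2] - z[2] * dir[1])
    if (sqrt(sum(ax^2)) < 1e-12) ax <- c(1, 0, 0)
    rotation_about_axis(ax, acos(min(1, max(-1, sum(z * dir)))) * 180 / pi)
  }
  mk_axes <- function(dir) {
    h <- make_ideal_helix(12)
    R <- rot_z_to(dir)
    lapply(1:2, function(i) {
      tr <- h
      tr$xyz <- h$xyz %*% t(R)
      fit_helix_axis(tr)
    })
  }
  z <- c(0, 0, 1)
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  res <- interface_offset_angle(mk_axes(z), mk_axes(d30))
  expect_equal(res$phi, 30, tolerance = 1e-6)
  expect_false(res$antiparallel)

  res0 <- interface_offset_angle(mk_axes(z), mk_axes(z))
  expect_equal(res0$phi, 0, tolerance = 1e-6)

  resAP <- interface_offset_angle(mk_axes(z), mk_axes(-z))
  expect_true(resAP$antiparallel)
  expect_equal(resAP$phi, 0, tolerance = 1e-6)
})

test_that("a perfectly anti-aligned in-subunit helix pair is degenerate", {
  h <- make_ideal_helix(12)
  up <- fit_helix_axis(h)
  down <- h
  down$xyz <- h$xyz %*% diag(c(1, -1, -1))   # proper flip, axis -> -z
  down <- fit_helix_axis(down)
  expect_error(interface_offset_angle(list(up, down), list(up, up)),
               "degenerate bundle")
})

test_that("PHY centroid metrics match the generating construction", {
  g <- make_synthetic_dimer(small_spec(d_centroids = 30, omega = 54,
                                       seed = 31L))
  ta <- extract_trace(g$structure, "A")
  tb <- extract_trace(g$structure, "B")
  m <- phy_centroid_metrics(ta, tb, g$scheme)
  expect_equal(m$d_centroids, 30, tolerance = 0.1)
  expect_equal(m$omega, 54, tolerance = 0.1)

  # isoceles closed form: |VA| = |VB| = d / (2 sin(omega/2))
  expect_equal(sqrt(sum((m$centroid_a - m$vertex)^2)),
               30 / (2 * sin(54 / 2 * pi / 180)), tolerance = 0.1)

  # collinear arrangement: omega = 180 by the same construction
  g180 <- make_synthetic_dimer(small_spec(d_centroids = 30, omega = 180,
                                          seed = 31L))
  m180 <- phy_centroid_metrics(extract_trace(g180$structure, "A"),
                               extract_trace(g180$structure, "B"),
                               g180$scheme)
  expect_equal(m180$omega, 180, tolerance = 0.1)
})

test_that("the law-of-cosines check holds for |VA|=|VB|=33, d=30", {
  omega_expect <- 2 * asin(15 / 33) * 180 / pi        # 54.09 deg
  g <- make_synthetic_dimer(small_spec(d_centroids = 30,
                                       omega = omega_expect, seed = 32L))
  m <- phy_centroid_metrics(extract_trace(g$structure, "A"),
                            extract_trace(g$structure, "B"), g$scheme)
  expect_equal(m$omega, 54.1, tolerance = 0.1)
  expect_equal(sqrt(sum((m$centroid_a - m$vertex)^2)), 33, tolerance = 0.05)
})

test_that("descriptors are symmetric under consistent subunit relabeling", {
  g <- make_synthetic_dimer(small_spec(phi = 40, seed = 33L))
  ta <- extract_trace(g$structure, "A")
  tb <- extract_trace(g$structure, "B")
  m1 <- phy_centroid_metrics(ta, tb, g$scheme)
  swapped <- g$scheme
  swapped$interface_helices <- rev(swapped$interface_helices)
  m2 <- phy_centroid_metrics(tb, ta, swapped)
  expect_equal(m1$d_centroids, m2$d_centroids, tolerance = 1e-9)
  expect_equal(m1$omega, m2$omega, tolerance = 1e-9)

  hel <- g$scheme$interface_helices
  axes <- function(tr) lapply(hel, function(r) fit_helix_axis(tr, r))
  r1 <- interface_offset_angle(axes(ta), axes(tb))
  r2 <- interface_offset_angle(axes(tb), axes(ta))
  expect_equal(r1$phi, r2$phi, tolerance = 1e-9)
})

test_that("all descriptors are invariant under a global rigid transform", {
  g <- make_synthetic_dimer(small_spec(phi = 37, d_centroids = 27,
                                       omega = 54, seed = 34L))
  d0 <- bphpgeom:::dimer_descriptors(g$structure, g$scheme)
  set.seed(35)
  for (i in 1:5) {
    moved <- apply_transform(g$structure, random_rigid())
    d1 <- bphpgeom:::dimer_descriptors(moved, g$scheme)
    expect_equal(d1$phi, d0$phi, tolerance = 1e-6)
    expect_equal(d1$d_centroids, d0$d_centroids, tolerance = 1e-6)
    expect_equal(d1$omega, d0$omega, tolerance = 1e-6)
  }
})

test_that("self-comparison gives exactly zero rotation and translation", {
  g <- make_synthetic_dimer(small_spec(seed = 36L))
  dm <- domain_rotation(g$structure, g$structure, g$scheme)
  expect_equal(dm$rotation, 0, tolerance = 1e-7)
  expect_equal(dm$translation, 0, tolerance = 1e-9)
})

test_that("a constructed 25-degree PHY rotation is recovered", {
  ref <- make_synthetic_dimer(small_spec(seed = 37L))
  mob <- make_synthetic_dimer(small_spec(seed = 37L, phy_rotation = 25))
  dm <- domain_rotation(ref$structure, mob$structure, ref$scheme)
  expect_equal(dm$rotation, 25, tolerance = 0.5)
  expect_equal(dm$translation, mob$truth$phy_translation, tolerance = 0.1)
})

test_that("domain rotation degrades gracefully under coordinate noise", {
  ref <- make_synthetic_dimer(small_spec(seed = 38L))
  mob <- make_synthetic_dimer(small_spec(seed = 38L, phy_rotation = 20,
                                         noise_sigma = 0.2,
                                         noise_seed = 39L))
  dm <- domain_rotation(ref$structure, mob$structure, ref$scheme)
  expect_equal(dm$rotation, 20, tolerance = 1)
})

test_that("geometry tables report the reference row and recover phi settings", {
  ref <- make_synthetic_dimer(small_spec(phi = 46, seed = 40L))
  tab <- geometry_table(ref$structure, list(ref$structure), ref$scheme)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$phy_rotation_deg[1]))       # reference row
  expect_equal(tab$phy_rotation_deg[2], 0, tolerance = 1e-6)
  expect_equal(tab$core_rmsd_A[2], 0, tolerance = 1e-9)

  phis <- c(20, 32, 46)
  comps <- lapply(phis, function(p)
    make_synthetic_dimer(small_spec(phi = p, seed = 40L))$structure)
  tab2 <- geometry_table(ref$structure, comps, ref$scheme)
  expect_equal(tab2$phi_deg[-1], phis, tolerance = 0.5)

  fmt <- format_geometry_table(tab)
  expect_equal(fmt$phy_rotation_deg[1], "ref.")
})

test_that("a failing row is recorded without aborting the others", {
  ref <- make_synthetic_dimer(small_spec(seed = 42L))
  ok <- make_synthetic_dimer(small_spec(seed = 42L, phy_rotation = 10))
  broken <- poly_ala_structure(10, id = "broken_monomer")   # single chain
  tab <- geometry_table(ref$structure, list(broken, ok$structure),
                        ref$scheme)
  expect_equal(nrow(tab), 3L)
  expect_match(tab$flags[2], "chains")
  expect_equal(tab$phy_rotation_deg[3], 10, tolerance = 0.5)
})
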